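#' Percentage with the tables' rounding rule
#'
#' `100 * numerator / denominator`, rounded half away from zero to 2
#' decimals (the convention that reproduces every printed "/DEG%" table
#' cell). A zero denominator yields `NA`.
#'
#' @param numerator,denominator Counts (vectorized).
#' @param digits Decimal places (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' percent(356, 1584)  # 22.47
#' percent(86, 2608)   # 3.30
#' @export
percent <- function(numerator, denominator, digits = 2L) {
  out <- ifelse(denominator > 0, 100 * numerator / denominator, NA_real_)
  round_half_away(out, digits)
}

# round half away from zero (R's round() is half-to-even)
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Decompose one contrast's DEGs against one catalog
#'
#' Intersects the contrast's up- and down-regulated gene lists with a
#' catalog and reports counts plus percentages of the contrast's TOTAL DEG
#' count (up + down over all genes, not only catalog genes) — the
#' denominator that reproduces the printed "/DEG%" cells. Catalog genes not
#' measured on the platform are simply absent from the intersection (no
#' coverage correction).
#'
#' @param contrast A `treg_contrast` (or data frame with `gene`, `status`).
#' @param catalog Character vector of genes, or a tibble with a `gene`
#'   column.
#' @param catalog_name Label used in the output row (defaults to the
#'   catalog's single `catalog` value when available).
#' @return One-row tibble: `dataset_id`, `catalog`, `total_deg`, `n_up`,
#'   `pct_up`, `n_down`, `pct_down`.
#' @export
decompose <- function(contrast, catalog, catalog_name = NULL) {
  stopifnot(all(c("gene", "status") %in% names(contrast)))
  if (is.data.frame(catalog)) {
    if (is.null(catalog_name) && "catalog" %in% names(catalog)) {
      catalog_name <- unique(catalog$catalog)
      stopifnot(length(catalog_name) == 1L)
    }
    catalog <- catalog$gene
  }
  catalog <- unique(normalize_symbol(catalog))
  up <- contrast$gene[contrast$status == "up"]
  down <- contrast$gene[contrast$status == "down"]
  total_deg <- length(up) + length(down)
  n_up <- length(intersect(up, catalog))
  n_down <- length(intersect(down, catalog))
  tibble::tibble(
    dataset_id = attr(contrast, "dataset_id") %||% NA_character_,
    catalog = catalog_name %||% NA_character_,
    total_deg = total_deg,
    n_up = n_up,
    pct_up = percent(n_up, total_deg),
    n_down = n_down,
    pct_down = percent(n_down, total_deg)
  )
}

#' Decompose a collection of contrasts against a catalog suite
#'
#' Complete cross product of contrasts and catalogs, in deterministic order
#' (dataset, then catalog).
#'
#' @param contrasts A list of `treg_contrast` objects.
#' @param catalogs Long catalog tibble (`catalog`, `gene`).
#' @return Tibble with one [decompose()] row per contrast x catalog.
#' @export
decompose_suite <- function(contrasts, catalogs) {
  catalogs <- validate_catalogs(catalogs)
  nms <- unique(catalogs$catalog)
  purrr::map_dfr(contrasts, function(ct) {
    purrr::map_dfr(nms, function(nm) {
      decompose(ct, catalog_genes(catalogs, nm), catalog_name = nm)
    })
  })
}

#' Mean and standard error of a decomposition column per condition group
#'
#' @param rows Tibble of decomposition (or any per-dataset) rows.
#' @param metadata Tibble mapping `dataset_id` to `condition_group`.
#' @param column Name of the numeric column to aggregate.
#' @return Tibble: `condition_group`, `n_datasets`, `mean`, `sem` (sample
#'   sd / sqrt(n); `NA` for single-dataset groups).
#' @export
aggregate_by_group <- function(rows, metadata, column) {
  stopifnot(column %in% names(rows),
            all(c("dataset_id", "condition_group") %in% names(metadata)))
  joined <- dplyr::inner_join(rows, metadata, by = "dataset_id")
  if (nrow(joined) == 0L) stop("No dataset in `rows` matches `metadata`.", call. = FALSE)
  joined |>
    dplyr::group_by(.data$condition_group) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      mean = mean(.data[[column]]),
      sem = if (dplyr::n() >= 2L) {
        stats::sd(.data[[column]]) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    )
}
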