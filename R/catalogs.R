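#' Catalog categories recognized by the pipeline
#'
#' The four secretome categories (canonical signal-peptide secretome,
#' caspase-1- and caspase-4-dependent gasdermin-D secretomes, exosome
#' secretome) are required to be pairwise disjoint; the screening panels
#' (immunometabolism enzymes, trained-immunity enzymes, ROS regulatome) may
#' overlap the secretomes.
#'
#' @return Character vector of category names.
#' @export
catalog_categories <- function() {
  c("secretome_canonical", "secretome_casp1", "secretome_casp4",
    "secretome_exosome", "panel_immunometabolism", "panel_trained_immunity",
    "panel_ros_regulatome", "housekeeping", "custom")
}

secretome_categories <- function() {
  c("secretome_canonical", "secretome_casp1", "secretome_casp4",
    "secretome_exosome")
}

#' Validate a catalog table
#'
#' Checks the long catalog tibble: non-empty sets, normalized symbols, no
#' duplicated (catalog, gene) pairs, and known categories when a `category`
#' column is present.
#'
#' @param catalogs Tibble with columns `catalog`, `gene` and optionally
#'   `category`.
#' @return The input, invisibly, normalized and deduplicated.
#' @export
validate_catalogs <- function(catalogs) {
  stopifnot(is.data.frame(catalogs), all(c("catalog", "gene") %in% names(catalogs)))
  if (nrow(catalogs) == 0L) stop("Catalog table is empty.", call. = FALSE)
  catalogs$gene <- normalize_symbol(catalogs$gene)
  if (anyDuplicated(catalogs[, c("catalog", "gene")])) {
    catalogs <- dplyr::distinct(catalogs, .data$catalog, .data$gene, .keep_all = TRUE)
  }
  if ("category" %in% names(catalogs)) {
    bad <- setdiff(unique(catalogs$category), catalog_categories())
    if (length(bad) > 0L) {
      stop("Unknown catalog category: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(catalogs)
}

#' Pairwise disjointness report for gene catalogs
#'
#' Lists the overlap size for every pair of catalogs. The check fails when
#' any pair among the four secretome-category catalogs overlaps; panels are
#' allowed to overlap secretomes.
#'
#' @param catalogs Tibble with columns `catalog`, `gene` and optionally
#'   `category` (used to decide which pairs are required to be disjoint; if
#'   absent, all pairs are required disjoint).
#' @return A list with `pairs` (tibble: `catalog_a`, `catalog_b`, `overlap`,
#'   `required_disjoint`) and `pass` (logical).
#' @export
validate_disjoint <- function(catalogs) {
  catalogs <- validate_catalogs(catalogs)
  nms <- unique(catalogs$catalog)
  if (length(nms) < 2L) stop("Need at least 2 catalogs.", call. = FALSE)
  sets <- split(catalogs$gene, catalogs$catalog)[nms]
  cat_of <- if ("category" %in% names(catalogs)) {
    stats::setNames(
      catalogs$category[match(nms, catalogs$catalog)], nms
    )
  } else {
    stats::setNames(rep("custom", length(nms)), nms)
  }
  idx <- utils::combn(length(nms), 2L)
  pairs <- tibble::tibble(
    catalog_a = nms[idx[1L, ]],
    catalog_b = nms[idx[2L, ]],
    overlap = purrr::map2_int(
      nms[idx[1L, ]], nms[idx[2L, ]],
      ~ length(intersect(sets[[.x]], sets[[.y]]))
    )
  )
  if ("category" %in% names(catalogs)) {
    pairs$required_disjoint <- cat_of[pairs$catalog_a] %in% secretome_categories() &
      cat_of[pairs$catalog_b] %in% secretome_categories()
  } else {
    pairs$required_disjoint <- TRUE
  }
  list(pairs = pairs, pass = all(pairs$overlap[pairs$required_disjoint] == 0L))
}

#' Number of distinct genes across catalogs
#'
#' For pairwise-disjoint catalogs this equals the sum of the set sizes; the
#' four secretome catalogs shipped by the synthetic generator (sizes 2641,
#' 961, 1223, 6560) union to 11,385 genes.
#'
#' @param catalogs Tibble with columns `catalog` and `gene`; an empty table
#'   gives 0.
#' @return Integer count of distinct genes.
#' @export
union_size <- function(catalogs) {
  stopifnot(is.data.frame(catalogs))
  if (nrow(catalogs) == 0L) return(0L)
  dplyr::n_distinct(normalize_symbol(catalogs$gene))
}

#' Extract one catalog's gene vector
#'
#' @param catalogs Long catalog tibble.
#' @param name Catalog name.
#' @return Character vector of member genes.
#' @export
catalog_genes <- function(catalogs, name) {
  g <- catalogs$gene[catalogs$catalog == name]
  if (length(g) == 0L) stop("Catalog not found or empty: ", name, call. = FALSE)
  unique(normalize_symbol(g))
}

#' Write a disjointness report as JSON
#'
#' @param report Result of [validate_disjoint()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disjoint_report <- function(report, path) {
  jsonlite::write_json(
    list(pass = report$pass, pairs = report$pairs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
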