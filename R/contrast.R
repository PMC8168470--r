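#' DEG thresholds
#'
#' The pipeline's differential-expression rule: a gene is called up when
#' `log2fc > fc_threshold` and `p < p_threshold`, down when
#' `log2fc < -fc_threshold` and `p < p_threshold`, otherwise non-significant.
#' Thresholds are strict inequalities by default ("more than 2-fold"):
#' a gene sitting exactly on a boundary is not called. Set `strict = FALSE`
#' to call boundary values too.
#'
#' @param fc_threshold Positive log2 fold-change cutoff (default 1, i.e.
#'   2-fold).
#' @param p_threshold p-value cutoff in (0, 1) (default 0.05, raw p).
#' @param strict Logical; strict (`>`/`<`) or inclusive (`>=`/`<=`)
#'   comparisons.
#' @return A list of class `treg_thresholds`.
#' @export
deg_thresholds <- function(fc_threshold = 1, p_threshold = 0.05, strict = TRUE) {
  stopifnot(is.numeric(fc_threshold), length(fc_threshold) == 1L, fc_threshold > 0,
            is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold < 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 strict = isTRUE(strict)),
            class = "treg_thresholds")
}

#' Classify a gene as up / down / ns
#'
#' Pure vectorized implementation of the DEG status rule; see
#' [deg_thresholds()] for the boundary convention.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param thresholds A [deg_thresholds()] object.
#' @return Character vector with values `"up"`, `"down"`, `"ns"`.
#' @export
classify_deg <- function(log2fc, p, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "treg_thresholds"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1].", call. = FALSE)
  fc <- thresholds$fc_threshold
  if (thresholds$strict) {
    sig <- p < thresholds$p_threshold
    up <- sig & log2fc > fc
    down <- sig & log2fc < -fc
  } else {
    sig <- p <= thresholds$p_threshold
    up <- sig & log2fc >= fc
    down <- sig & log2fc <= -fc
  }
  out <- rep("ns", length(log2fc))
  out[which(up)] <- "up"
  out[which(down)] <- "down"
  out
}

# Vectorized per-gene Welch (or pooled) two-sample t-test on a genes x samples
# matrix. Returns log2fc = mean(case) - mean(control). Genes with zero
# variance in both arms get p = 1 and zero_variance = TRUE.
row_t_test <- function(values, is_case, pooled = FALSE) {
  case <- values[, is_case, drop = FALSE]
  ctrl <- values[, !is_case, drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("Need at least 2 replicates per arm.", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
  if (pooled) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  zero_var <- se2 == 0
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero_var] <- 1
  tstat[zero_var] <- 0
  tibble::tibble(log2fc = unname(m1 - m2), t = unname(tstat),
                 df = unname(df), p = unname(p),
                 zero_variance = unname(zero_var))
}

#' Compute a case-vs-control contrast
#'
#' Per-gene two-sample test of case against control samples. Array data are
#' tested directly on log2 intensities; RNA-seq counts are first normalized
#' to counts per million per sample and transformed `log2(CPM + 0.5)`. The
#' default test is the Welch unequal-variance t; `pooled = TRUE` switches to
#' the classical pooled-variance t. `log2fc` is `mean(case) - mean(control)`
#' on the log2 scale. Benjamini-Hochberg adjusted `q` is reported for
#' information; the DEG status thresholds raw `p` (the pipeline's calling
#' rule).
#'
#' @param dataset A `treg_dataset` (see [simulate_dataset()] or
#'   [treg_dataset()]).
#' @param thresholds A [deg_thresholds()] object.
#' @param pooled Logical; use the pooled-variance t instead of Welch.
#' @return A tibble of class `treg_contrast` with columns `gene`, `log2fc`,
#'   `t`, `df`, `p`, `q`, `status`, `zero_variance`, and attributes
#'   `dataset_id`, `platform`, `metadata`, `thresholds`.
#' @export
compute_contrast <- function(dataset, thresholds = deg_thresholds(), pooled = FALSE) {
  stopifnot(inherits(dataset, "treg_dataset"))
  is_case <- dataset$sample_group == "case"
  values <- dataset$values
  if (dataset$platform == "rnaseq") {
    libsize <- colSums(values)
    if (any(libsize == 0)) stop("RNA-seq sample with zero total counts.", call. = FALSE)
    cpm <- sweep(values, 2L, libsize, "/") * 1e6
    values <- log2(cpm + 0.5)
  }
  res <- row_t_test(values, is_case, pooled = pooled)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$status <- classify_deg(res$log2fc, res$p, thresholds)
  out <- tibble::tibble(
    gene = rownames(dataset$values),
    log2fc = res$log2fc, t = res$t, df = res$df, p = res$p, q = res$q,
    status = res$status, zero_variance = res$zero_variance
  )
  new_contrast(out,
               dataset_id = dataset$dataset_id,
               platform = dataset$platform,
               metadata = dataset$metadata,
               thresholds = thresholds)
}

new_contrast <- function(tbl, dataset_id, platform = NA_character_,
                         metadata = list(), thresholds = deg_thresholds()) {
  structure(
    tbl,
    dataset_id = dataset_id,
    platform = platform,
    metadata = metadata,
    thresholds = thresholds,
    class = c("treg_contrast", class(tibble::as_tibble(tbl)))
  )
}

#' Construct an expression dataset
#'
#' @param values Numeric genes x samples matrix; rownames are gene symbols
#'   (normalized on construction). Log2 intensities for `platform = "array"`,
#'   non-negative integer counts for `platform = "rnaseq"`.
#' @param sample_group Character vector (`"case"` / `"control"`), one per
#'   column; at least 2 of each.
#' @param dataset_id Dataset identifier string.
#' @param platform `"array"` or `"rnaseq"`.
#' @param metadata Named list; conventionally `tissue`, `tissue_class`
#'   (`"lymphoid"` / `"non_lymphoid"`) and `condition_group` (`"normal"`,
#'   `"benign"`, `"tumor_spleen"`, `"tumor_tissue"`).
#' @return An object of class `treg_dataset`.
#' @export
treg_dataset <- function(values, sample_group, dataset_id,
                         platform = c("array", "rnaseq"), metadata = list()) {
  platform <- match.arg(platform)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(sample_group) == ncol(values))
  if (sum(sample_group == "case") < 2L || sum(sample_group == "control") < 2L) {
    stop("Need at least 2 case and 2 control samples.", call. = FALSE)
  }
  rn <- normalize_symbol(rownames(values))
  if (anyDuplicated(rn)) stop("Duplicate gene symbols in dataset.", call. = FALSE)
  rownames(values) <- rn
  if (platform == "rnaseq" &&
      (any(values < 0) || any(values != round(values)))) {
    stop("RNA-seq values must be non-negative integer counts.", call. = FALSE)
  }
  structure(
    list(dataset_id = dataset_id, platform = platform, values = values,
         sample_group = sample_group, metadata = metadata),
    class = "treg_dataset"
  )
}

#' @export
print.treg_dataset <- function(x, ...) {
  cat("<treg_dataset> ", x$dataset_id, ": ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (", x$platform, "), ",
      sum(x$sample_group == "case"), " case / ",
      sum(x$sample_group == "control"), " control\n", sep = "")
  invisible(x)
}

#' Summarize DEG counts for a contrast
#'
#' @param contrast A `treg_contrast` or any data frame with a `status`
#'   column.
#' @return One-row tibble: `dataset_id`, `n_genes`, `n_deg`, `n_up`,
#'   `n_down`, `pct_up` (percentage of DEGs that are up, 2 decimals; `NA`
#'   when there are no DEGs).
#' @export
deg_summary <- function(contrast) {
  stopifnot("status" %in% names(contrast))
  n_up <- sum(contrast$status == "up")
  n_down <- sum(contrast$status == "down")
  n_deg <- n_up + n_down
  tibble::tibble(
    dataset_id = attr(contrast, "dataset_id") %||% NA_character_,
    n_genes = nrow(contrast),
    n_deg = n_deg,
    n_up = n_up,
    n_down = n_down,
    pct_up = percent(n_up, n_deg)
  )
}

#' Housekeeping-gene quality control
#'
#' A contrast passes QC when every measured housekeeping gene has a log2
#' fold change inside the band. Housekeeping genes absent from the dataset
#' are reported as missing, not failing. The default band `c(-1.3, 1.3)`
#' comfortably contains the fold-change range observed for stable genes in
#' practice.
#'
#' @param contrast A `treg_contrast`.
#' @param hk Housekeeping catalog: tibble with a `gene` column or character
#'   vector (default [housekeeping_catalog()]).
#' @param band Numeric length-2 `(lo, hi)` log2 band.
#' @return A list with `per_gene` (tibble: `gene`, `log2fc`, `measured`,
#'   `within_band`) and `pass` (logical).
#' @export
housekeeping_qc <- function(contrast, hk = housekeeping_catalog(),
                            band = c(-1.3, 1.3)) {
  genes <- if (is.data.frame(hk)) hk$gene else hk
  genes <- unique(normalize_symbol(genes))
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  idx <- match(genes, contrast$gene)
  if (all(is.na(idx))) {
    stop("No housekeeping gene is measured in this contrast.", call. = FALSE)
  }
  per_gene <- tibble::tibble(
    gene = genes,
    log2fc = ifelse(is.na(idx), NA_real_, contrast$log2fc[idx]),
    measured = !is.na(idx)
  )
  per_gene$within_band <- ifelse(
    per_gene$measured,
    per_gene$log2fc >= band[1L] & per_gene$log2fc <= band[2L],
    NA
  )
  list(
    per_gene = per_gene,
    band = band,
    pass = all(per_gene$within_band[per_gene$measured])
  )
}

#' Import a pre-computed DEG table
#'
#' Adapter for externally exported contrast tables (e.g. GEO2R exports):
#' a delimited file with columns `gene`, `log2fc`, `p`. Status is assigned
#' with the package's thresholds.
#'
#' @param path Path to a TSV/CSV file.
#' @param dataset_id Identifier for the contrast.
#' @param thresholds A [deg_thresholds()] object.
#' @param metadata Optional named list (tissue, tissue_class,
#'   condition_group).
#' @return A `treg_contrast` tibble.
#' @export
read_deg_table <- function(path, dataset_id, thresholds = deg_thresholds(),
                           metadata = list()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% names(tbl))) {
    stop("DEG table must have columns gene, log2fc, p: ", path, call. = FALSE)
  }
  tbl$gene <- normalize_symbol(tbl$gene)
  if (anyDuplicated(tbl$gene)) stop("Duplicate genes in DEG table: ", path, call. = FALSE)
  tbl$q <- stats::p.adjust(tbl$p, method = "BH")
  tbl$status <- classify_deg(tbl$log2fc, tbl$p, thresholds)
  new_contrast(tibble::as_tibble(tbl), dataset_id = dataset_id,
               metadata = metadata, thresholds = thresholds)
}

#' Write a contrast table as TSV
#'
#' @param contrast A `treg_contrast`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  readr::write_tsv(tibble::as_tibble(contrast), path, progress = FALSE)
  invisible(path)
}

#' Build a contrast directly from per-gene statistics
#'
#' Convenience constructor used when the per-gene `log2fc` and `p` come from
#' elsewhere (simulations, fixtures).
#'
#' @param gene,log2fc,p Per-gene vectors.
#' @param dataset_id Identifier.
#' @param thresholds A [deg_thresholds()] object.
#' @param metadata Optional named list.
#' @return A `treg_contrast` tibble.
#' @export
contrast_from_stats <- function(gene, log2fc, p, dataset_id,
                                thresholds = deg_thresholds(),
                                metadata = list()) {
  gene <- normalize_symbol(gene)
  stopifnot(length(gene) == length(log2fc), length(gene) == length(p))
  tbl <- tibble::tibble(
    gene = gene, log2fc = log2fc, p = p,
    q = stats::p.adjust(p, method = "BH"),
    status = classify_deg(log2fc, p, thresholds)
  )
  new_contrast(tbl, dataset_id = dataset_id, metadata = metadata,
               thresholds = thresholds)
}

#' @importFrom rlang %||% .data
NULL
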