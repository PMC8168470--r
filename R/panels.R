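#' Screen one contrast against a gene panel
#'
#' Counts panel genes among the contrast's up- and down-regulated DEGs.
#'
#' @param contrast A `treg_contrast`.
#' @param panel Character vector of panel genes or a tibble with a `gene`
#'   column.
#' @param panel_name Label for the output row.
#' @return One-row tibble: `dataset_id`, `panel`, `n_up`, `n_down`,
#'   `n_total`.
#' @export
screen_panel <- function(contrast, panel, panel_name = NULL) {
  if (is.data.frame(panel)) {
    if (is.null(panel_name) && "catalog" %in% names(panel)) {
      panel_name <- unique(panel$catalog)
      stopifnot(length(panel_name) == 1L)
    }
    panel <- panel$gene
  }
  panel <- unique(normalize_symbol(panel))
  n_up <- length(intersect(contrast$gene[contrast$status == "up"], panel))
  n_down <- length(intersect(contrast$gene[contrast$status == "down"], panel))
  tibble::tibble(
    dataset_id = attr(contrast, "dataset_id") %||% NA_character_,
    panel = panel_name %||% NA_character_,
    n_up = n_up,
    n_down = n_down,
    n_total = n_up + n_down
  )
}

#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n-1 denominator) divided by
#' `sqrt(n)`; it is `NA` for a single value.
#'
#' @param values Numeric vector, length >= 1.
#' @return Named list `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  if (length(values) < 1L) stop("Need at least one value.", call. = FALSE)
  list(
    mean = mean(values),
    sem = if (length(values) >= 2L) stats::sd(values) / sqrt(length(values)) else NA_real_,
    n = length(values)
  )
}

#' Two-sample location test
#'
#' `welch_t`: the Welch unequal-variance t-test with Welch-Satterthwaite
#' degrees of freedom, two-sided. `mann_whitney`: the Wilcoxon rank-sum
#' test, exact for small samples without ties, normal approximation with
#' tie correction otherwise. When both groups have zero variance and equal
#' means the difference is degenerate and p = 1 is reported.
#'
#' @param a,b Numeric vectors (>= 2 values per group for `welch_t`, >= 1
#'   for `mann_whitney`).
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return One-row tibble: `method`, `statistic`, `df` (`NA` for
#'   mann_whitney), `p_value`.
#' @export
two_group_test <- function(a, b, method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  if (method == "welch_t") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("welch_t needs at least 2 values per group.", call. = FALSE)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        return(tibble::tibble(method = method, statistic = 0,
                              df = NA_real_, p_value = 1))
      }
      return(tibble::tibble(method = method,
                            statistic = sign(mean(a) - mean(b)) * Inf,
                            df = NA_real_, p_value = 0))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(method = method,
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter),
                   p_value = ht$p.value)
  } else {
    if (length(a) < 1L || length(b) < 1L) {
      stop("mann_whitney needs at least 1 value per group.", call. = FALSE)
    }
    exact <- min(length(a), length(b)) <= 8L && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = !exact)
    )
    tibble::tibble(method = method,
                   statistic = unname(ht$statistic),
                   df = NA_real_,
                   p_value = ht$p.value)
  }
}

#' Group-statistics engine: per-group mean/SEM plus focus-vs-rest test
#'
#' The shared contract behind the group comparisons (DEG percentages,
#' non-collaboration counts, panel and ROS screens): per-group descriptive
#' statistics, and a two-sample test of the focus group's values against
#' all remaining datasets pooled. Groups with fewer than 2 datasets are
#' excluded from the test with a warning (their descriptives are still
#' reported). BH-adjusted q across the (usually few) comparisons is left to
#' the caller; the raw p is the headline number.
#'
#' @param values Tibble with columns `dataset_id`, `value`.
#' @param metadata Tibble mapping `dataset_id` to `condition_group`.
#' @param metric Name of the compared quantity (bookkeeping).
#' @param focus_group Group compared against the pooled rest.
#' @param method See [two_group_test()].
#' @return An object of class `group_comparison`: list with `metric`,
#'   `groups` (tibble: `condition_group`, `n_datasets`, `mean`, `sem`),
#'   `test` (one-row tibble from [two_group_test()] plus `focus_group`).
#' @export
group_compare <- function(values, metadata, metric = "value",
                          focus_group = "tumor_tissue",
                          method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  stopifnot(all(c("dataset_id", "value") %in% names(values)),
            all(c("dataset_id", "condition_group") %in% names(metadata)))
  joined <- dplyr::inner_join(values, metadata, by = "dataset_id")
  if (nrow(joined) == 0L) stop("No dataset matches between values and metadata.", call. = FALSE)
  groups <- joined |>
    dplyr::group_by(.data$condition_group) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2L) stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  if (dplyr::n_distinct(joined$condition_group) < 2L) {
    stop("Need at least 2 condition groups to compare.", call. = FALSE)
  }
  small <- groups$condition_group[groups$n_datasets < 2L]
  if (length(small) > 0L) {
    warning("Groups with < 2 datasets excluded from testing: ",
            paste(small, collapse = ", "), call. = FALSE)
    joined <- joined[!joined$condition_group %in% small, ]
  }
  if (!focus_group %in% joined$condition_group) {
    stop("Focus group '", focus_group, "' absent (or too small) in metadata.",
         call. = FALSE)
  }
  a <- joined$value[joined$condition_group == focus_group]
  b <- joined$value[joined$condition_group != focus_group]
  if (length(b) < 2L) stop("Too few datasets outside the focus group.", call. = FALSE)
  test <- two_group_test(a, b, method = method)
  test$focus_group <- focus_group
  structure(list(metric = metric, groups = groups, test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$metric, " (", x$test$method, ", ",
      x$test$focus_group, " vs rest): statistic = ",
      signif(x$test$statistic, 4), ", p = ", signif(x$test$p_value, 4),
      "\n", sep = "")
  print(x$groups)
  invisible(x)
}
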