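#' Normalize a gene symbol
#'
#' Gene identifiers from different platforms and species casings are matched
#' on a shared canon: symbols are whitespace-trimmed and upper-cased, so mouse
#' `"Il6"` and human `"IL6"` intersect. No orthology mapping is attempted;
#' catalog intersections are plain symbol matches.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of normalized symbols. Idempotent:
#'   `normalize_symbol(normalize_symbol(x))` equals `normalize_symbol(x)`.
#' @examples
#' normalize_symbol(c("il6", " Foxp3 ", "GAPDH"))
#' @export
normalize_symbol <- function(raw) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector of gene symbols.", call. = FALSE)
  }
  out <- toupper(trimws(raw))
  # internal whitespace is never a legal part of a symbol
  out <- gsub("[[:space:]]+", "", out)
  if (any(!nzchar(out) | is.na(out))) {
    stop("Empty or missing gene symbol after normalization.", call. = FALSE)
  }
  out
}

#' The housekeeping gene panel used for contrast quality control
#'
#' Nine widely used stably expressed genes. A contrast passes QC when each of
#' these genes (where measured) has a log2 fold change inside a tolerance
#' band (default `c(-1.3, 1.3)`); see [housekeeping_qc()].
#'
#' @return A tibble with columns `catalog`, `category` and `gene`.
#' @export
housekeeping_catalog <- function() {
  tibble::tibble(
    catalog = "housekeeping",
    category = "housekeeping",
    gene = c("ACTB", "GAPDH", "PGK1", "PPIA", "B2M", "YWHAZ", "SDHA", "HMBS", "TBP")
  )
}
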