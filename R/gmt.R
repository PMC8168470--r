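#' Read gene-set catalogs from a GMT file
#'
#' GMT is the tab-separated gene-set dialect: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are normalized with
#' [normalize_symbol()] and duplicates within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per (set, gene): columns `catalog`,
#'   `description`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("GMT parse error at line ", bad[1L],
         ": expected at least 3 tab-separated fields.", call. = FALSE)
  }
  sets <- purrr::map_dfr(fields, function(f) {
    tibble::tibble(
      catalog = trimws(f[[1L]]),
      description = trimws(f[[2L]]),
      gene = unique(normalize_symbol(f[-(1:2)]))
    )
  })
  nm <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
  if (anyDuplicated(nm)) {
    stop("Duplicate set name in GMT file: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets
}

#' Write gene-set catalogs to a GMT file
#'
#' @param catalogs Tibble with columns `catalog`, `gene` and optionally
#'   `description` (defaults to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalogs, path) {
  stopifnot(is.data.frame(catalogs), all(c("catalog", "gene") %in% names(catalogs)))
  if (!"description" %in% names(catalogs)) catalogs$description <- catalogs$catalog
  lines <- catalogs |>
    dplyr::group_by(.data$catalog) |>
    dplyr::summarise(
      line = paste(c(.data$catalog[1L], .data$description[1L], .data$gene), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}

#' Read signed pathway signatures from an extended GMT file
#'
#' Signatures are gene sets whose members carry an expected regulation
#' direction. The extended dialect suffixes each gene token with `|+1`
#' (expected up), `|-1` (expected down); a bare symbol means direction
#' unknown (0). Direction-unknown members count toward overlap enrichment
#' but not toward the activation z-score.
#'
#' @param path Path to an extended GMT file.
#' @return A tibble with columns `signature`, `description`, `gene`,
#'   `direction` (integer in -1/0/+1).
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("Signature file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("Signature GMT parse error at line ", bad[1L],
         ": expected at least 3 tab-separated fields.", call. = FALSE)
  }
  out <- purrr::map_dfr(fields, function(f) {
    toks <- f[-(1:2)]
    has_dir <- grepl("|", toks, fixed = TRUE)
    sym <- ifelse(has_dir, sub("\\|.*$", "", toks), toks)
    dir <- ifelse(has_dir, sub("^.*\\|", "", toks), "0")
    dir <- suppressWarnings(as.integer(dir))
    if (any(is.na(dir)) || any(!dir %in% c(-1L, 0L, 1L))) {
      stop("Signature direction suffix must be +1, -1 or absent (set '",
           trimws(f[[1L]]), "').", call. = FALSE)
    }
    tibble::tibble(
      signature = trimws(f[[1L]]),
      description = trimws(f[[2L]]),
      gene = normalize_symbol(sym),
      direction = dir
    ) |>
      dplyr::distinct(.data$signature, .data$gene, .keep_all = TRUE)
  })
  sizes <- dplyr::count(out, .data$signature)
  if (any(sizes$n < 2L)) {
    stop("Every signature needs at least 2 members; offending: ",
         paste(sizes$signature[sizes$n < 2L], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write signed pathway signatures to an extended GMT file
#'
#' @param signatures Tibble with columns `signature`, `gene`, `direction` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  stopifnot(all(c("signature", "gene", "direction") %in% names(signatures)))
  if (!"description" %in% names(signatures)) signatures$description <- signatures$signature
  lines <- signatures |>
    dplyr::mutate(tok = ifelse(
      .data$direction == 0L, .data$gene,
      paste0(.data$gene, "|", ifelse(.data$direction > 0, "+1", "-1"))
    )) |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      line = paste(c(.data$signature[1L], .data$description[1L], .data$tok), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}
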