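#' Hypergeometric overlap enrichment
#'
#' Upper-tail overlap probability `P(X >= k)` for drawing `n` DEGs out of a
#' universe of `N` measured genes of which `K` belong to the signature. The
#' universe is the set of genes measured in the dataset, and signature
#' members are intersected with it before counting.
#'
#' @param deg_genes Character vector of DEG symbols (subset of `universe`).
#' @param signature Tibble with a `gene` column (direction column ignored
#'   here), or character vector of member genes.
#' @param universe Character vector of all measured genes.
#' @return One-row tibble: `k`, `K`, `n`, `N`, `p_value`.
#' @export
fisher_enrichment <- function(deg_genes, signature, universe) {
  if (is.data.frame(signature)) signature <- signature$gene
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0L) stop("Empty universe.", call. = FALSE)
  deg_genes <- unique(normalize_symbol(deg_genes))
  if (length(deg_genes) == 0L) stop("Empty DEG list.", call. = FALSE)
  if (!all(deg_genes %in% universe)) {
    stop("DEG genes must be a subset of the universe.", call. = FALSE)
  }
  members <- intersect(unique(normalize_symbol(signature)), universe)
  k <- length(intersect(deg_genes, members))
  K <- length(members)
  n <- length(deg_genes)
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(k = k, K = K, n = n, N = N, p_value = p)
}

#' Direction-agreement activation z-score
#'
#' Over the contrast's DEGs that are signature members with a nonzero
#' expected direction, let `c` be the number whose observed DEG sign equals
#' the expected direction and `d` the number where it is opposite; the
#' activation score is `z = (c - d) / sqrt(c + d)`. Members with unknown
#' direction (0) are ignored here (they still count toward overlap
#' enrichment). When no directional member overlaps, `z` is `NA` and the
#' pathway cannot be called.
#'
#' @param contrast A `treg_contrast` (columns `gene`, `status`).
#' @param signature Tibble with columns `gene`, `direction`.
#' @return Scalar z (possibly `NA`).
#' @export
activation_z <- function(contrast, signature) {
  stopifnot(all(c("gene", "direction") %in% names(signature)))
  deg <- contrast[contrast$status != "ns", c("gene", "status")]
  sig <- signature[signature$direction != 0L, c("gene", "direction")]
  m <- dplyr::inner_join(deg, sig, by = "gene")
  if (nrow(m) == 0L) return(NA_real_)
  obs <- ifelse(m$status == "up", 1L, -1L)
  consistent <- sum(obs == m$direction)
  inconsistent <- sum(obs == -m$direction)
  (consistent - inconsistent) / sqrt(consistent + inconsistent)
}

#' Call a pathway activated / inhibited / not called
#'
#' A pathway is activated when the overlap enrichment p-value is below
#' `p_cut` and `z >= z_cut`; inhibited when `p < p_cut` and `z <= -z_cut`;
#' otherwise not called. Note the asymmetric boundary convention: the
#' p-value comparison is strict (`p = p_cut` fails) while the z comparison
#' is inclusive (`|z| = z_cut` passes), matching the stated cutoffs
#' "p < 0.05, |z| >= 2". Missing z forces `not_called`.
#'
#' @param p Enrichment p-value(s).
#' @param z Activation z-score(s), may be `NA`.
#' @param p_cut,z_cut Cutoffs (defaults 0.05 and 2).
#' @return Character vector: `"activated"`, `"inhibited"`, `"not_called"`.
#' @export
classify_pathway <- function(p, z, p_cut = 0.05, z_cut = 2) {
  out <- rep("not_called", length(p))
  callable <- !is.na(z) & p < p_cut
  out[callable & z >= z_cut] <- "activated"
  out[callable & z <= -z_cut] <- "inhibited"
  out
}

#' Enrichment and activation calls for one contrast over a signature set
#'
#' Runs [fisher_enrichment()] and [activation_z()] for every signature and
#' classifies each with [classify_pathway()]. The universe is the gene list
#' measured in the contrast. BH-adjusted `q` is reported for information;
#' calling uses raw `p`.
#'
#' @param contrast A `treg_contrast`.
#' @param signatures Long signature tibble (`signature`, `gene`,
#'   `direction`).
#' @param p_cut,z_cut Calling cutoffs.
#' @return Tibble: `dataset_id`, `signature`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, `z`, `status`.
#' @export
enrich_contrast <- function(contrast, signatures, p_cut = 0.05, z_cut = 2) {
  stopifnot(all(c("signature", "gene") %in% names(signatures)))
  universe <- contrast$gene
  deg <- contrast$gene[contrast$status != "ns"]
  if (length(deg) == 0L) {
    return(tibble::tibble(
      dataset_id = character(), signature = character(), k = integer(),
      K = integer(), n = integer(), N = integer(), p_value = numeric(),
      q_value = numeric(), z = numeric(), status = character()
    ))
  }
  out <- signatures |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_map(function(sig, key) {
      enr <- fisher_enrichment(deg, sig$gene, universe)
      enr$signature <- key$signature
      enr$z <- activation_z(contrast, sig)
      enr
    }) |>
    dplyr::bind_rows()
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$status <- classify_pathway(out$p_value, out$z, p_cut, z_cut)
  out$dataset_id <- attr(contrast, "dataset_id") %||% NA_character_
  out[, c("dataset_id", "signature", "k", "K", "n", "N", "p_value",
          "q_value", "z", "status")]
}

#' Shared / specific / dual accounting within a dataset group
#'
#' Aggregates per-dataset pathway calls for one condition group. At group
#' level a pathway is `activated` when called activated in at least one
#' dataset and never inhibited, `inhibited` symmetrically, and `dual` when
#' both directions occur. Separately, a pathway is `shared` when called in
#' at least `min_shared` datasets with a consistent sign, `specific` when
#' called in exactly one dataset, and `dual` otherwise-conflicting calls.
#' Both labelings partition the pathways called at least once.
#'
#' @param group_records Tibble of [enrich_contrast()] rows for the group's
#'   datasets.
#' @param min_shared Minimum datasets for "shared" (default 2).
#' @return A list: `pathways` (tibble: `signature`, `n_activated`,
#'   `n_inhibited`, `direction`, `sharing`), and `counts` (one-row tibble:
#'   `n_called`, `n_activated`, `n_inhibited`, `n_dual`, `n_shared`,
#'   `n_specific`).
#' @export
venn_summary <- function(group_records, min_shared = 2L) {
  called <- group_records[group_records$status != "not_called", ]
  if (nrow(called) == 0L) {
    return(list(
      pathways = tibble::tibble(signature = character(),
                                n_activated = integer(), n_inhibited = integer(),
                                direction = character(), sharing = character()),
      counts = tibble::tibble(n_called = 0L, n_activated = 0L, n_inhibited = 0L,
                              n_dual = 0L, n_shared = 0L, n_specific = 0L)
    ))
  }
  pathways <- called |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      n_activated = sum(.data$status == "activated"),
      n_inhibited = sum(.data$status == "inhibited"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$n_activated > 0L & .data$n_inhibited > 0L ~ "dual",
        .data$n_activated > 0L ~ "activated",
        TRUE ~ "inhibited"
      ),
      n_calls = .data$n_activated + .data$n_inhibited,
      sharing = dplyr::case_when(
        .data$direction == "dual" ~ "dual",
        .data$n_calls >= min_shared ~ "shared",
        TRUE ~ "specific"
      )
    )
  counts <- tibble::tibble(
    n_called = nrow(pathways),
    n_activated = sum(pathways$direction == "activated"),
    n_inhibited = sum(pathways$direction == "inhibited"),
    n_dual = sum(pathways$direction == "dual"),
    n_shared = sum(pathways$sharing == "shared"),
    n_specific = sum(pathways$sharing == "specific")
  )
  list(pathways = dplyr::select(pathways, -"n_calls"), counts = counts)
}

#' Shared and specific pathways across dataset groups
#'
#' Plain set algebra over the group-level called-pathway sets, reported per
#' direction.
#'
#' @param summaries Named list of [venn_summary()] results (one per group).
#' @param direction Which group-level direction to compare: `"activated"`,
#'   `"inhibited"`, `"dual"` or `"any"` (default).
#' @return A list: `pairwise` (tibble: `group_a`, `group_b`, `n_shared`,
#'   `n_a_specific`, `n_b_specific`), `shared_all` (pathways called in every
#'   group), `per_group` (named list of pathway sets).
#' @export
cross_group_overlap <- function(summaries, direction = "any") {
  if (length(summaries) < 2L) stop("Need at least 2 groups.", call. = FALSE)
  sets <- purrr::map(summaries, function(s) {
    p <- s$pathways
    if (direction != "any") p <- p[p$direction == direction, ]
    unique(p$signature)
  })
  nms <- names(sets)
  idx <- utils::combn(length(nms), 2L)
  pairwise <- tibble::tibble(
    group_a = nms[idx[1L, ]],
    group_b = nms[idx[2L, ]]
  )
  pairwise$n_shared <- purrr::map2_int(pairwise$group_a, pairwise$group_b,
                                       ~ length(intersect(sets[[.x]], sets[[.y]])))
  pairwise$n_a_specific <- purrr::map2_int(pairwise$group_a, pairwise$group_b,
                                           ~ length(setdiff(sets[[.x]], sets[[.y]])))
  pairwise$n_b_specific <- purrr::map2_int(pairwise$group_a, pairwise$group_b,
                                           ~ length(setdiff(sets[[.y]], sets[[.x]])))
  list(
    pairwise = pairwise,
    shared_all = Reduce(intersect, sets),
    per_group = sets
  )
}
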