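#' Classify Treg DEGs into regulator collaboration quadrants
#'
#' Compares a Treg-vs-Tconv contrast with a regulator perturbation contrast
#' (knockout or antibody blockade vs control). The polarity convention is
#' fixed: a gene DOWN in the perturbation is a candidate regulator-induced
#' gene, a gene UP in the perturbation a candidate regulator-suppressed
#' gene. Quadrants:
#'
#' * `induced`: Treg-up AND perturbation-down (the regulator promotes it);
#' * `suppressed`: Treg-down AND perturbation-up;
#' * `noncollab_up` / `noncollab_down`: every other Treg DEG, by its Treg
#'   direction — including same-direction overlaps and genes non-DEG or
#'   unmeasured in the perturbation.
#'
#' The four sets are pairwise disjoint and union exactly to the Treg DEG
#' set. With `strict = TRUE`, Treg DEGs unmeasured in the perturbation
#' contrast are dropped from the partition (and from fraction denominators)
#' instead of counting as non-collaboration.
#'
#' @param treg A `treg_contrast` (the Treg vs conventional T cell
#'   comparison).
#' @param reg A `treg_contrast` for the perturbation (perturbed vs
#'   control).
#' @param strict Drop Treg DEGs unmeasured in the perturbation (default
#'   `FALSE`).
#' @return An object of class `collab_partition`: list with `genes` (tibble:
#'   `gene`, `treg_status`, `perturbation_status`, `class`), `counts`
#'   (named integer vector), `fractions` (tibble with the non-collaboration
#'   percentage over all DEGs and over up-DEGs only), `regulator`.
#' @export
partition_collaboration <- function(treg, reg, strict = FALSE) {
  stopifnot(all(c("gene", "status") %in% names(treg)),
            all(c("gene", "status") %in% names(reg)))
  deg <- treg[treg$status != "ns", c("gene", "status")]
  names(deg) <- c("gene", "treg_status")
  pert <- stats::setNames(reg$status, reg$gene)
  deg$perturbation_status <- unname(pert[deg$gene])
  measured <- !is.na(deg$perturbation_status)
  if (strict) deg <- deg[measured, ]
  deg$perturbation_status[is.na(deg$perturbation_status)] <- "unmeasured"
  deg$class <- dplyr::case_when(
    deg$treg_status == "up" & deg$perturbation_status == "down" ~ "induced",
    deg$treg_status == "down" & deg$perturbation_status == "up" ~ "suppressed",
    deg$treg_status == "up" ~ "noncollab_up",
    TRUE ~ "noncollab_down"
  )
  counts <- c(
    induced = sum(deg$class == "induced"),
    suppressed = sum(deg$class == "suppressed"),
    noncollab_up = sum(deg$class == "noncollab_up"),
    noncollab_down = sum(deg$class == "noncollab_down")
  )
  n_deg <- nrow(deg)
  n_up <- sum(deg$treg_status == "up")
  fractions <- tibble::tibble(
    pct_noncollab_of_deg = percent(counts[["noncollab_up"]] + counts[["noncollab_down"]], n_deg),
    pct_noncollab_up_of_up = percent(counts[["noncollab_up"]], n_up)
  )
  structure(
    list(
      genes = tibble::as_tibble(deg),
      counts = counts,
      n_deg = n_deg,
      fractions = fractions,
      regulator = attr(reg, "dataset_id") %||% NA_character_,
      dataset_id = attr(treg, "dataset_id") %||% NA_character_
    ),
    class = "collab_partition"
  )
}

#' @export
print.collab_partition <- function(x, ...) {
  cat("<collab_partition> ", x$dataset_id, " vs ", x$regulator, ": ",
      x$n_deg, " Treg DEGs | induced ", x$counts[["induced"]],
      ", suppressed ", x$counts[["suppressed"]],
      ", non-collaboration ", x$counts[["noncollab_up"]] + x$counts[["noncollab_down"]],
      " (", x$fractions$pct_noncollab_of_deg, "%)\n", sep = "")
  invisible(x)
}

#' Non-collaboration percentage of a partition
#'
#' @param partition A `collab_partition`.
#' @param of `"deg"` (default): percentage of all Treg DEGs; `"up"`:
#'   upregulated non-collaboration genes as a percentage of Treg up-DEGs.
#' @return Percentage rounded to 2 decimals ([percent()] rounding); `NA`
#'   for an empty partition.
#' @export
noncollab_fraction <- function(partition, of = c("deg", "up")) {
  of <- match.arg(of)
  stopifnot(inherits(partition, "collab_partition"))
  if (of == "deg") partition$fractions$pct_noncollab_of_deg
  else partition$fractions$pct_noncollab_up_of_up
}

#' Compare non-collaboration gene counts across condition groups
#'
#' Group-statistics contract shared with the panel screens: per-group mean
#' and SEM of the total non-collaboration count, plus a two-sample test of
#' one focus group against the pooled remaining datasets (see
#' [two_group_test()]). Groups with fewer than 2 datasets are excluded from
#' testing with a warning.
#'
#' @param partitions Named list of `collab_partition` objects (one per
#'   dataset).
#' @param metadata Tibble mapping `dataset_id` to `condition_group`.
#' @param focus_group Group compared against all others pooled (default
#'   `"tumor_tissue"`).
#' @param method Test method, see [two_group_test()].
#' @return A `group_comparison` object (see [group_compare()]).
#' @export
compare_noncollab_across_groups <- function(partitions, metadata,
                                            focus_group = "tumor_tissue",
                                            method = c("welch_t", "mann_whitney")) {
  values <- purrr::map_dfr(partitions, function(p) {
    tibble::tibble(
      dataset_id = p$dataset_id,
      value = p$counts[["noncollab_up"]] + p$counts[["noncollab_down"]]
    )
  })
  group_compare(values, metadata, metric = "n_noncollab",
                focus_group = focus_group, method = method)
}
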