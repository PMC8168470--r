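#' Build the ROS regulatome partition from dual knockout contrasts
#'
#' NOX2 encodes the catalytic subunit of the superoxide-producing NADPH
#' oxidase (its knockout lowers ROS), while NRF2 drives the antioxidant
#' response (its knockout raises ROS). Genes differentially expressed in
#' BOTH knockouts are classified by the cross-direction rule:
#'
#' * `promoted` (ROS-promoted): up in the NOX2 KO and down in the NRF2 KO;
#' * `suppressed` (ROS-suppressed): down in the NOX2 KO and up in the NRF2
#'   KO;
#' * `uncertain`: DEG in both contrasts with the same sign.
#'
#' Genes DEG in only one contrast are excluded from the partition entirely,
#' so `|promoted| + |suppressed| + |uncertain|` equals the size of the
#' intersection of the two DEG sets. Swapping the two inputs swaps promoted
#' and suppressed and leaves uncertain fixed.
#'
#' @param nox2 A `treg_contrast` for the NOX2-KO-vs-control comparison.
#' @param nrf2 A `treg_contrast` for the NRF2-KO-vs-control comparison.
#' @return An object of class `ros_partition`: list with `genes` (tibble:
#'   `gene`, `nox2_status`, `nrf2_status`, `class`) and `counts` (named
#'   integer vector `promoted`, `suppressed`, `uncertain`,
#'   `total_classified`).
#' @export
classify_ros <- function(nox2, nrf2) {
  stopifnot(all(c("gene", "status") %in% names(nox2)),
            all(c("gene", "status") %in% names(nrf2)))
  a <- nox2[nox2$status != "ns", c("gene", "status")]
  b <- nrf2[nrf2$status != "ns", c("gene", "status")]
  names(a) <- c("gene", "nox2_status")
  names(b) <- c("gene", "nrf2_status")
  both <- dplyr::inner_join(a, b, by = "gene")
  both$class <- dplyr::case_when(
    both$nox2_status == "up" & both$nrf2_status == "down" ~ "promoted",
    both$nox2_status == "down" & both$nrf2_status == "up" ~ "suppressed",
    TRUE ~ "uncertain"
  )
  counts <- c(
    promoted = sum(both$class == "promoted"),
    suppressed = sum(both$class == "suppressed"),
    uncertain = sum(both$class == "uncertain")
  )
  counts <- c(counts, total_classified = sum(counts))
  structure(
    list(genes = tibble::as_tibble(both), counts = counts),
    class = "ros_partition"
  )
}

#' @export
print.ros_partition <- function(x, ...) {
  cat("<ros_partition> ", x$counts[["total_classified"]], " genes: ",
      x$counts[["promoted"]], " ROS-promoted, ",
      x$counts[["suppressed"]], " ROS-suppressed, ",
      x$counts[["uncertain"]], " uncertain\n", sep = "")
  invisible(x)
}

#' Screen a Treg contrast against the ROS partition
#'
#' Plain set intersections of the contrast's up/down DEG lists with the
#' ROS-promoted and ROS-suppressed classes.
#'
#' @param treg A `treg_contrast`.
#' @param partition A `ros_partition`.
#' @return One-row tibble: `dataset_id`, `n_up_promoted`,
#'   `n_down_promoted`, `n_up_suppressed`, `n_down_suppressed`.
#' @export
screen_ros <- function(treg, partition) {
  stopifnot(inherits(partition, "ros_partition"))
  up <- treg$gene[treg$status == "up"]
  down <- treg$gene[treg$status == "down"]
  promoted <- partition$genes$gene[partition$genes$class == "promoted"]
  suppressed <- partition$genes$gene[partition$genes$class == "suppressed"]
  tibble::tibble(
    dataset_id = attr(treg, "dataset_id") %||% NA_character_,
    n_up_promoted = length(intersect(up, promoted)),
    n_down_promoted = length(intersect(down, promoted)),
    n_up_suppressed = length(intersect(up, suppressed)),
    n_down_suppressed = length(intersect(down, suppressed))
  )
}

#' Compare downregulated ROS-suppressed counts across condition groups
#'
#' Same group-statistics contract as the other comparisons: per-group mean
#' and SEM of `n_down_suppressed` plus a two-sample test of the focus group
#' against the pooled rest.
#'
#' @param records Tibble of [screen_ros()] rows.
#' @param metadata Tibble mapping `dataset_id` to `condition_group`.
#' @param focus_group Group tested against the pooled others (default
#'   `"tumor_tissue"`).
#' @param method See [two_group_test()].
#' @param column Which screen column to compare (default
#'   `"n_down_suppressed"`).
#' @return A `group_comparison` object.
#' @export
compare_ros_screens <- function(records, metadata,
                                focus_group = "tumor_tissue",
                                method = c("welch_t", "mann_whitney"),
                                column = "n_down_suppressed") {
  stopifnot(column %in% names(records))
  values <- tibble::tibble(dataset_id = records$dataset_id,
                           value = records[[column]])
  group_compare(values, metadata, metric = column,
                focus_group = focus_group, method = method)
}
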