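#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contrast into a plain tibble
#'
#' @param x A `treg_contrast`.
#' @param ... Unused.
#' @return A tibble with `dataset_id` as a leading column and the per-gene
#'   statistics.
#' @method tidy treg_contrast
#' @export
tidy.treg_contrast <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(dataset_id = attr(x, "dataset_id") %||% NA_character_),
    tibble::as_tibble(x)
  )
}

#' One-row summary of a contrast
#'
#' @param x A `treg_contrast`.
#' @param ... Unused.
#' @return The [deg_summary()] row.
#' @method glance treg_contrast
#' @export
glance.treg_contrast <- function(x, ...) {
  deg_summary(x)
}

#' Tidy a collaboration partition
#'
#' @param x A `collab_partition`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `treg_status`, `perturbation_status`,
#'   `class`.
#' @method tidy collab_partition
#' @export
tidy.collab_partition <- function(x, ...) {
  x$genes
}

#' One-row summary of a collaboration partition
#'
#' @param x A `collab_partition`.
#' @param ... Unused.
#' @return Tibble with quadrant counts and non-collaboration percentages.
#' @method glance collab_partition
#' @export
glance.collab_partition <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id,
    regulator = x$regulator,
    n_deg = x$n_deg,
    n_induced = x$counts[["induced"]],
    n_suppressed = x$counts[["suppressed"]],
    n_noncollab_up = x$counts[["noncollab_up"]],
    n_noncollab_down = x$counts[["noncollab_down"]],
    pct_noncollab_of_deg = x$fractions$pct_noncollab_of_deg,
    pct_noncollab_up_of_up = x$fractions$pct_noncollab_up_of_up
  )
}

#' Tidy a ROS partition
#'
#' @param x A `ros_partition`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `nox2_status`, `nrf2_status`, `class`.
#' @method tidy ros_partition
#' @export
tidy.ros_partition <- function(x, ...) {
  x$genes
}

#' One-row summary of a ROS partition
#'
#' @param x A `ros_partition`.
#' @param ... Unused.
#' @return Tibble with the three class sizes and the classified total.
#' @method glance ros_partition
#' @export
glance.ros_partition <- function(x, ...) {
  tibble::tibble(
    n_promoted = x$counts[["promoted"]],
    n_suppressed = x$counts[["suppressed"]],
    n_uncertain = x$counts[["uncertain"]],
    total_classified = x$counts[["total_classified"]]
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The per-group descriptive tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(metric = x$metric), x$groups)
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble: `metric`, `method`, `statistic`, `df`, `p_value`,
#'   `focus_group`.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(metric = x$metric), x$test)
}
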