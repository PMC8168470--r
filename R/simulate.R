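#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' small-replicate case/control expression matrices (array-style log2
#' intensities or negative-binomial RNA-seq counts) with planted
#' differentially expressed genes, planted catalog membership rates, and
#' planted overlap fractions with regulator perturbation contrasts.
#'
#' Planting is by exact count (`round(fraction * n)`), never by Bernoulli
#' draw, so truth sizes are deterministic. Randomness is split into
#' documented seed offsets so adding a later stage never perturbs earlier
#' draws: the expression dataset uses `seed` directly, regulator contrast
#' number `i` uses `seed + 10000 + i`, the dual-knockout pair uses
#' `seed + 20000`, catalog construction `seed + 30000` and signature
#' construction `seed + 40000`.
#'
#' @param seed Integer seed (< 2^31 - 50000).
#' @param n_genes Number of genes (default 10000). When `n_genes >= 50` the
#'   last nine gene names are the housekeeping symbols, always planted
#'   null.
#' @param platform `"array"` (Gaussian log2 intensities) or `"rnaseq"`
#'   (negative-binomial counts).
#' @param n_case,n_control Replicates per arm (>= 2; default 4 each).
#' @param frac_up,frac_down Planted DEG fractions in `[0, 1)`,
#'   `frac_up + frac_down < 1` (defaults 0.05 each).
#' @param effect_size_log2 Mean planted absolute log2 fold change; per-gene
#'   effects are drawn uniformly on `[0.6, 1.5] * effect_size_log2`
#'   (default 2, giving the 1.2-3 range).
#' @param noise_sd Within-arm Gaussian SD on the log2 scale for arrays
#'   (default 0.5).
#' @param dispersion Negative-binomial dispersion for RNA-seq (default
#'   0.1); library sizes are drawn log-normal around 10^6 with sdlog 0.2.
#' @param planted_catalog_deg_rate Fraction of each catalog's genes forced
#'   into the planted DEG set when catalogs are supplied to
#'   [simulate_dataset()] (default 0.1).
#' @param regulator_overlap Named list; each element
#'   `c(frac_induced, frac_suppressed)` gives the fraction of planted
#'   Treg-up genes that are down in that regulator's perturbation and of
#'   planted Treg-down genes that are up in it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10000L,
                       platform = c("array", "rnaseq"),
                       n_case = 4L, n_control = 4L,
                       frac_up = 0.05, frac_down = 0.05,
                       effect_size_log2 = 2,
                       noise_sd = 0.5,
                       dispersion = 0.1,
                       planted_catalog_deg_rate = 0.1,
                       regulator_overlap = list(FOXP3 = c(frac_induced = 0.8,
                                                          frac_suppressed = 0.8))) {
  platform <- match.arg(platform)
  stopifnot(
    is.numeric(seed), length(seed) == 1L, seed == round(seed),
    seed + 50000 < 2^31,
    n_genes >= 1L, n_case >= 2L, n_control >= 2L,
    frac_up >= 0, frac_up < 1, frac_down >= 0, frac_down < 1,
    frac_up + frac_down < 1,
    effect_size_log2 > 0, noise_sd > 0, dispersion > 0,
    planted_catalog_deg_rate >= 0, planted_catalog_deg_rate <= 1
  )
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         platform = platform, n_case = as.integer(n_case),
         n_control = as.integer(n_control),
         frac_up = frac_up, frac_down = frac_down,
         effect_size_log2 = effect_size_log2, noise_sd = noise_sd,
         dispersion = dispersion,
         planted_catalog_deg_rate = planted_catalog_deg_rate,
         regulator_overlap = regulator_overlap),
    class = "sim_config"
  )
}

# gene universe: synthetic symbols; for large universes the last nine are
# the housekeeping genes (planted null throughout)
sim_gene_universe <- function(n_genes) {
  hk <- housekeeping_catalog()$gene
  if (n_genes >= 50L) {
    c(sprintf("G%05d", seq_len(n_genes - length(hk))), hk)
  } else {
    sprintf("G%05d", seq_len(n_genes))
  }
}

#' Simulate an expression dataset with planted truth
#'
#' Draws a genes x samples matrix around per-gene baselines, shifting case
#' samples by the planted log2 fold changes. Arrays: Gaussian noise with
#' `noise_sd`. RNA-seq: negative-binomial counts with log-normal library
#' sizes (around 10^6, sdlog 0.2). Identical configs give bit-identical
#' outputs. Housekeeping genes are never planted as DEGs. When `catalogs`
#' is supplied, `round(planted_catalog_deg_rate * size)` members of each
#' catalog are forced into the planted DEG set (split between up and down
#' in proportion to `frac_up:frac_down`).
#'
#' @param config A [sim_config()].
#' @param catalogs Optional long catalog tibble whose genes live in this
#'   universe.
#' @param dataset_id Identifier (default `"SIM"`).
#' @param metadata Named list stored on the dataset (tissue,
#'   tissue_class, condition_group).
#' @return A list with `dataset` (a `treg_dataset`) and `truth` (tibble:
#'   `gene`, `status` in up/down/null, `log2fc` planted).
#' @export
simulate_dataset <- function(config, catalogs = NULL, dataset_id = "SIM",
                             metadata = list()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_universe(config$n_genes)
  hk <- intersect(genes, housekeeping_catalog()$gene)
  plantable <- setdiff(genes, hk)
  n_up <- round(config$frac_up * config$n_genes)
  n_down <- round(config$frac_down * config$n_genes)
  if (n_up + n_down > length(plantable)) {
    stop("Planted DEG fractions too large for the plantable universe.", call. = FALSE)
  }

  withr::with_seed(config$seed, {
    up_genes <- character(0)
    down_genes <- character(0)
    # catalog quotas first (exact counts per catalog), then fill the rest
    if (!is.null(catalogs) && config$planted_catalog_deg_rate > 0) {
      share_up <- if (config$frac_up + config$frac_down > 0) {
        config$frac_up / (config$frac_up + config$frac_down)
      } else 0
      for (nm in unique(catalogs$catalog)) {
        members <- intersect(catalog_genes(catalogs, nm), plantable)
        members <- setdiff(members, c(up_genes, down_genes))
        q <- round(config$planted_catalog_deg_rate *
                     sum(catalogs$catalog == nm))
        q <- min(q, length(members))
        if (q == 0L) next
        chosen <- sample(members, q)
        q_up <- round(q * share_up)
        up_genes <- c(up_genes, chosen[seq_len(q_up)])
        down_genes <- c(down_genes, chosen[setdiff(seq_len(q), seq_len(q_up))])
      }
      up_genes <- utils::head(up_genes, n_up)
      down_genes <- utils::head(down_genes, n_down)
    }
    pool <- setdiff(plantable, c(up_genes, down_genes))
    if (!is.null(catalogs) && config$planted_catalog_deg_rate > 0) {
      # remaining DEGs come from outside every catalog so that planted
      # catalog intersections are exactly the quotas
      pool <- setdiff(pool, catalogs$gene)
    }
    need_up <- n_up - length(up_genes)
    need_down <- n_down - length(down_genes)
    if (need_up + need_down > length(pool)) {
      stop("Not enough non-catalog genes to reach the planted DEG fractions.",
           call. = FALSE)
    }
    extra <- sample(pool, need_up + need_down)
    up_genes <- c(up_genes, extra[seq_len(need_up)])
    down_genes <- c(down_genes, extra[setdiff(seq_along(extra), seq_len(need_up))])

    effect <- stats::runif(n_up + n_down,
                           0.6 * config$effect_size_log2,
                           1.5 * config$effect_size_log2)
    lfc <- stats::setNames(rep(0, config$n_genes), genes)
    lfc[up_genes] <- effect[seq_len(n_up)]
    lfc[down_genes] <- -effect[n_up + seq_len(n_down)]

    n_samp <- config$n_case + config$n_control
    group <- rep(c("case", "control"), c(config$n_case, config$n_control))
    shift <- outer(lfc, as.numeric(group == "case"))

    if (config$platform == "array") {
      baseline <- stats::rnorm(config$n_genes, mean = 7, sd = 2)
      values <- baseline + shift +
        matrix(stats::rnorm(config$n_genes * n_samp, 0, config$noise_sd),
               config$n_genes, n_samp)
    } else {
      weight <- exp(stats::rnorm(config$n_genes, mean = 0, sd = 1.5))
      prop <- weight / sum(weight)
      libsize <- exp(stats::rnorm(n_samp, log(1e6), 0.2))
      mu <- (prop * 2^shift) %*% diag(libsize)
      values <- matrix(
        stats::rnbinom(config$n_genes * n_samp, mu = as.vector(mu),
                       size = 1 / config$dispersion),
        config$n_genes, n_samp
      )
    }
  })

  rownames(values) <- genes
  colnames(values) <- paste0(ifelse(group == "case", "case_", "ctrl_"),
                             seq_len(n_samp))
  truth <- tibble::tibble(
    gene = genes,
    status = dplyr::case_when(lfc > 0 ~ "up", lfc < 0 ~ "down", TRUE ~ "null"),
    log2fc = unname(lfc)
  )
  list(
    dataset = treg_dataset(values, group, dataset_id,
                           platform = config$platform, metadata = metadata),
    truth = truth
  )
}

#' Simulate a regulator perturbation contrast consistent with planted truth
#'
#' Builds a knockout / blockade-vs-control DEG table in which an exact
#' count `round(frac_induced * n_up)` of the planted Treg-up genes are DOWN
#' in the perturbation (regulator-induced) and `round(frac_suppressed *
#' n_down)` of the planted Treg-down genes are UP (regulator-suppressed).
#' Remaining Treg DEGs are non-DEG in the perturbation. A small fraction of
#' truth-null genes (`background_rate`) is made DEG in the perturbation for
#' realism; those genes never intersect the Treg DEG set, so planted
#' collaboration counts stay exact.
#'
#' @param config A [sim_config()] with the regulator listed in
#'   `regulator_overlap`.
#' @param truth Truth tibble from [simulate_dataset()].
#' @param regulator Name in `config$regulator_overlap`.
#' @param background_rate Fraction of truth-null genes made DEG in the
#'   perturbation (default 0.02).
#' @return A list with `contrast` (a `treg_contrast` for the perturbation)
#'   and `truth` (input truth plus a `<regulator>_relation` column with
#'   values induced / suppressed / none).
#' @export
simulate_regulator_contrast <- function(config, truth, regulator,
                                        background_rate = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  if (!regulator %in% names(config$regulator_overlap)) {
    stop("Unknown regulator: ", regulator, call. = FALSE)
  }
  ov <- config$regulator_overlap[[regulator]]
  frac_induced <- unname(ov[1L])
  frac_suppressed <- unname(ov[2L])
  idx <- match(regulator, names(config$regulator_overlap))

  up_genes <- truth$gene[truth$status == "up"]
  down_genes <- truth$gene[truth$status == "down"]
  null_genes <- truth$gene[truth$status == "null"]
  n_ind <- round(frac_induced * length(up_genes))
  n_sup <- round(frac_suppressed * length(down_genes))

  withr::with_seed(config$seed + 10000L + idx, {
    induced <- if (n_ind > 0) sample(up_genes, n_ind) else character(0)
    suppressed <- if (n_sup > 0) sample(down_genes, n_sup) else character(0)
    n_bg <- round(background_rate * length(null_genes))
    background <- if (n_bg > 0) sample(null_genes, n_bg) else character(0)
    bg_sign <- sample(c(-1, 1), length(background), replace = TRUE)
  })

  lfc <- stats::setNames(rep(0, nrow(truth)), truth$gene)
  p <- stats::setNames(rep(0.5, nrow(truth)), truth$gene)
  lfc[induced] <- -2; p[induced] <- 1e-4
  lfc[suppressed] <- 2; p[suppressed] <- 1e-4
  lfc[background] <- 2 * bg_sign; p[background] <- 1e-4

  contrast <- contrast_from_stats(
    truth$gene, unname(lfc), unname(p),
    dataset_id = paste0(regulator, "_perturbation")
  )
  relation <- rep("none", nrow(truth))
  relation[truth$gene %in% induced] <- "induced"
  relation[truth$gene %in% suppressed] <- "suppressed"
  truth[[paste0(regulator, "_relation")]] <- relation
  list(contrast = contrast, truth = truth)
}

#' Simulate a dual-knockout contrast pair with planted ROS classes
#'
#' Plants exactly `n_promoted` genes up in the NOX2 KO and down in the NRF2
#' KO, `n_suppressed` genes with the opposite pattern, and `n_uncertain`
#' genes DEG in both contrasts with the same sign. A fraction
#' `frac_single` of the remaining genes is made DEG in exactly one of the
#' two contrasts (these must be excluded by the classifier); everything
#' else is non-DEG in both.
#'
#' @param config A [sim_config()] (supplies the universe and the seed).
#' @param class_sizes Integer vector `c(n_promoted, n_suppressed,
#'   n_uncertain)`; must sum to at most `n_genes`.
#' @param frac_single Fraction of leftover genes DEG in exactly one
#'   contrast (default 0.02).
#' @return A list with `nox2`, `nrf2` (`treg_contrast`s) and `truth`
#'   (tibble: `gene`, `ros_class` in promoted / suppressed / uncertain /
#'   none).
#' @export
simulate_dual_ko <- function(config, class_sizes = c(1384L, 936L, 10L),
                             frac_single = 0.02) {
  stopifnot(inherits(config, "sim_config"), length(class_sizes) == 3L,
            all(class_sizes >= 0L))
  if (sum(class_sizes) > config$n_genes) {
    stop("Class sizes exceed the number of genes.", call. = FALSE)
  }
  genes <- sim_gene_universe(config$n_genes)
  n_pro <- class_sizes[[1L]]; n_sup <- class_sizes[[2L]]; n_unc <- class_sizes[[3L]]

  withr::with_seed(config$seed + 20000L, {
    shuffled <- sample(genes)
    promoted <- shuffled[seq_len(n_pro)]
    suppressed <- shuffled[n_pro + seq_len(n_sup)]
    uncertain <- shuffled[n_pro + n_sup + seq_len(n_unc)]
    rest <- shuffled[-seq_len(n_pro + n_sup + n_unc)]
    n_single <- round(frac_single * length(rest))
    single_nox2 <- utils::head(rest, n_single)
    single_nrf2 <- utils::head(setdiff(rest, single_nox2), n_single)
    unc_sign <- rep_len(c(1, -1), n_unc)
    single_nox2_sign <- sample(c(-1, 1), length(single_nox2), replace = TRUE)
    single_nrf2_sign <- sample(c(-1, 1), length(single_nrf2), replace = TRUE)
  })

  mk <- function(up, down, id) {
    lfc <- stats::setNames(rep(0, length(genes)), genes)
    p <- stats::setNames(rep(0.5, length(genes)), genes)
    lfc[up] <- 2; lfc[down] <- -2
    p[c(up, down)] <- 1e-4
    contrast_from_stats(genes, unname(lfc), unname(p), dataset_id = id)
  }
  nox2 <- mk(
    up = c(promoted, uncertain[unc_sign > 0], single_nox2[single_nox2_sign > 0]),
    down = c(suppressed, uncertain[unc_sign < 0], single_nox2[single_nox2_sign < 0]),
    id = "NOX2_KO"
  )
  nrf2 <- mk(
    up = c(suppressed, uncertain[unc_sign > 0], single_nrf2[single_nrf2_sign > 0]),
    down = c(promoted, uncertain[unc_sign < 0], single_nrf2[single_nrf2_sign < 0]),
    id = "NRF2_KO"
  )
  truth <- tibble::tibble(
    gene = genes,
    ros_class = dplyr::case_when(
      genes %in% promoted ~ "promoted",
      genes %in% suppressed ~ "suppressed",
      genes %in% uncertain ~ "uncertain",
      TRUE ~ "none"
    )
  )
  list(nox2 = nox2, nrf2 = nrf2, truth = truth)
}

#' Default synthetic catalog sizes
#'
#' The catalog sizes carried through the whole pipeline: canonical
#' secretome 2641, caspase-1 secretome 961, caspase-4 secretome 1223,
#' exosome secretome 6560 (union 11,385, pairwise disjoint), plus the
#' immunometabolism (191), trained-immunity (102) and ROS-regulatome (165)
#' screening panels.
#'
#' @return Named integer vector keyed by category.
#' @export
default_catalog_sizes <- function() {
  c(secretome_canonical = 2641L, secretome_casp1 = 961L,
    secretome_casp4 = 1223L, secretome_exosome = 6560L,
    panel_immunometabolism = 191L, panel_trained_immunity = 102L,
    panel_ros_regulatome = 165L)
}

#' Simulate a catalog suite over a gene universe
#'
#' Draws the four secretome catalogs as pairwise-disjoint samples from the
#' universe and the three screening panels as free samples (panels may
#' overlap secretomes, as real enzyme panels do). The housekeeping catalog
#' (9 fixed symbols) is appended when those genes are in the universe.
#'
#' @param genes Character vector of universe gene symbols (needs at least
#'   `sum` of the four secretome sizes).
#' @param sizes Named sizes as in [default_catalog_sizes()].
#' @param seed Integer seed (convention: dataset seed + 30000).
#' @return Long catalog tibble: `catalog`, `category`, `gene`.
#' @export
simulate_catalog_suite <- function(genes, sizes = default_catalog_sizes(),
                                   seed = 30001L) {
  genes <- unique(normalize_symbol(genes))
  hk <- intersect(genes, housekeeping_catalog()$gene)
  pool <- setdiff(genes, hk)
  secre <- intersect(names(sizes), secretome_categories())
  if (sum(sizes[secre]) > length(pool)) {
    stop("Universe too small for disjoint secretome catalogs.", call. = FALSE)
  }
  withr::with_seed(seed, {
    shuffled <- sample(pool)
    offset <- 0L
    out <- purrr::map_dfr(secre, function(nm) {
      g <- shuffled[offset + seq_len(sizes[[nm]])]
      offset <<- offset + sizes[[nm]]
      tibble::tibble(catalog = nm, category = nm, gene = g)
    })
    panels <- setdiff(names(sizes), secre)
    out <- dplyr::bind_rows(out, purrr::map_dfr(panels, function(nm) {
      tibble::tibble(catalog = nm, category = nm,
                     gene = sample(pool, sizes[[nm]]))
    }))
  })
  if (length(hk) > 0L) {
    out <- dplyr::bind_rows(out, housekeeping_catalog()[
      housekeeping_catalog()$gene %in% hk, ])
  }
  out
}

#' Simulate signed pathway signatures with planted activation structure
#'
#' Builds signatures whose expected directions agree with the planted truth
#' (activated), disagree (inhibited), or are drawn at random from the
#' universe (typically not called), for exercising the enrichment and
#' calling layer end to end.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param n_activated,n_inhibited,n_null Numbers of each signature flavour.
#' @param size Members per signature (default 25).
#' @param seed Integer seed (convention: dataset seed + 40000).
#' @return Long signature tibble: `signature`, `gene`, `direction`.
#' @export
simulate_signatures <- function(truth, n_activated = 3L, n_inhibited = 3L,
                                n_null = 4L, size = 25L, seed = 40001L) {
  up <- truth$gene[truth$status == "up"]
  down <- truth$gene[truth$status == "down"]
  allg <- truth$gene
  stopifnot(length(up) >= size, length(down) >= size)
  withr::with_seed(seed, {
    act <- purrr::map_dfr(seq_len(n_activated), function(i) {
      tibble::tibble(signature = sprintf("sig_activated_%02d", i),
                     gene = sample(up, size), direction = 1L)
    })
    inh <- purrr::map_dfr(seq_len(n_inhibited), function(i) {
      # expected-up members planted among down-DEGs: z goes negative
      tibble::tibble(signature = sprintf("sig_inhibited_%02d", i),
                     gene = sample(down, size), direction = 1L)
    })
    nul <- purrr::map_dfr(seq_len(n_null), function(i) {
      tibble::tibble(signature = sprintf("sig_background_%02d", i),
                     gene = sample(allg, size),
                     direction = sample(c(-1L, 1L), size, replace = TRUE))
    })
  })
  dplyr::bind_rows(act, inh, nul)
}
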