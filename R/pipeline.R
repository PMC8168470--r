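#' Write the packaged demo inputs
#'
#' Generates a complete synthetic input bundle under `dir`: the catalog
#' suite (secretome sizes 2641/961/1223/6560, panels 191/102/165,
#' housekeeping 9), one expression dataset per condition group (normal /
#' benign / tumor_spleen / tumor_tissue), signed signatures, a FOXP3
#' regulator contrast, the dual-knockout pair planted at class sizes
#' (1384, 936, 10), and table-reproduction fixtures: DEG tables engineered
#' so the decomposition reproduces selected printed count/percentage cells
#' (see [table_fixture_cells()]).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_genes Universe size (default 14000; must exceed the secretome
#'   union of 11,385).
#' @return Invisibly, a list of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L, n_genes = 14000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sim_gene_universe(n_genes)
  catalogs <- simulate_catalog_suite(genes, seed = seed + 30000L)
  write_gmt(catalogs[, c("catalog", "gene")], file.path(dir, "catalogs.gmt"))
  readr::write_tsv(catalogs, file.path(dir, "catalogs.tsv"), progress = FALSE)

  groups <- rep(c("normal", "benign", "tumor_spleen", "tumor_tissue"), each = 2L)
  meta <- tibble::tibble(
    dataset_id = paste0("SIM_", groups, "_", rep(1:2, times = 4L)),
    tissue = c("spleen", "kidney", "muscle", "kidney",
               "spleen", "spleen", "tumor", "tumor"),
    tissue_class = c("lymphoid", "non_lymphoid", "non_lymphoid", "non_lymphoid",
                     "lymphoid", "lymphoid", "non_lymphoid", "non_lymphoid"),
    condition_group = groups,
    platform = rep(c("array", "rnaseq"), times = 4L)
  )
  readr::write_tsv(meta, file.path(dir, "datasets.tsv"), progress = FALSE)

  sims <- list()
  for (i in seq_len(nrow(meta))) {
    cfg <- sim_config(seed = seed + i, n_genes = n_genes,
                      platform = meta$platform[i])
    sims[[meta$dataset_id[i]]] <- simulate_dataset(
      cfg, catalogs = catalogs, dataset_id = meta$dataset_id[i],
      metadata = as.list(meta[i, c("tissue", "tissue_class", "condition_group")])
    )
    ds <- sims[[meta$dataset_id[i]]]$dataset
    mat <- tibble::as_tibble(ds$values, rownames = "gene")
    readr::write_tsv(mat, file.path(dir, paste0(meta$dataset_id[i], "_expr.tsv")),
                     progress = FALSE)
    readr::write_tsv(sims[[meta$dataset_id[i]]]$truth,
                     file.path(dir, paste0(meta$dataset_id[i], "_truth.tsv")),
                     progress = FALSE)
    jsonlite::write_json(
      c(list(dataset_id = ds$dataset_id, platform = ds$platform,
             sample_group = ds$sample_group), ds$metadata),
      file.path(dir, paste0(meta$dataset_id[i], "_meta.json")),
      auto_unbox = TRUE
    )
  }

  first <- sims[[1L]]
  cfg1 <- sim_config(seed = seed + 1L, n_genes = n_genes)
  sig <- simulate_signatures(first$truth, seed = seed + 40000L)
  write_signatures(sig, file.path(dir, "signatures.gmt"))

  reg <- simulate_regulator_contrast(cfg1, first$truth, "FOXP3")
  write_contrast(reg$contrast, file.path(dir, "FOXP3_perturbation.tsv"))

  dual <- simulate_dual_ko(cfg1)
  write_contrast(dual$nox2, file.path(dir, "NOX2_KO.tsv"))
  write_contrast(dual$nrf2, file.path(dir, "NRF2_KO.tsv"))
  readr::write_tsv(dual$truth, file.path(dir, "ros_truth.tsv"), progress = FALSE)

  fix <- table_fixture_contrasts(catalogs, seed = seed + 50000L)
  for (nm in names(fix)) {
    write_contrast(fix[[nm]], file.path(dir, paste0("fixture_", nm, ".tsv")))
  }
  invisible(list(dir = dir, datasets = meta$dataset_id, fixtures = names(fix)))
}

#' Printed table cells reproduced by the decomposition fixtures
#'
#' Nine count/percentage cells from the published per-dataset decomposition
#' tables, used as exact arithmetic ground truth: each row gives the
#' catalog hit count among up- or down-regulated DEGs, the contrast's total
#' DEG count, and the printed percentage.
#'
#' @return Tibble: `fixture`, `catalog`, `direction`, `n_hits`,
#'   `total_deg`, `printed_pct`.
#' @export
table_fixture_cells <- function() {
  tibble::tribble(
    ~fixture,              ~catalog,              ~direction, ~n_hits, ~total_deg, ~printed_pct,
    "normal_kidney",       "secretome_exosome",   "up",       356L,    1584L,      22.47,
    "normal_kidney",       "secretome_exosome",   "down",     174L,    1584L,      10.98,
    "normal_kidney",       "secretome_casp1",     "up",       20L,     1584L,      1.26,
    "normal_kidney",       "secretome_casp4",     "up",       42L,     1584L,      2.65,
    "regen_kidney",        "secretome_canonical", "up",       265L,    2608L,      10.16,
    "regen_kidney",        "secretome_canonical", "down",     86L,     2608L,      3.30,
    "muscle4d_spleen",     "secretome_exosome",   "up",       115L,    313L,       36.74,
    "tc1_spleen",          "secretome_canonical", "up",       194L,    1776L,      10.92,
    "b16_tumor",           "secretome_exosome",   "up",       572L,    2462L,      23.23
  )
}

# Engineer DEG-table contrasts whose decomposition reproduces the printed
# cells: for each fixture, the required number of catalog members is placed
# among up/down DEGs and the DEG total padded with genes outside the
# involved catalogs.
table_fixture_contrasts <- function(catalogs, seed = 50001L) {
  cells <- table_fixture_cells()
  universe <- unique(catalogs$gene)
  out <- list()
  withr::with_seed(seed, {
    for (fx in unique(cells$fixture)) {
      rows <- cells[cells$fixture == fx, ]
      used <- character(0)
      up <- character(0); down <- character(0)
      for (j in seq_len(nrow(rows))) {
        members <- setdiff(catalog_genes(catalogs, rows$catalog[j]), used)
        pick <- members[seq_len(rows$n_hits[j])]
        used <- c(used, pick)
        if (rows$direction[j] == "up") up <- c(up, pick) else down <- c(down, pick)
      }
      total <- rows$total_deg[1L]
      involved <- unique(unlist(lapply(unique(rows$catalog), catalog_genes,
                                       catalogs = catalogs)))
      pool <- setdiff(universe, c(involved, housekeeping_catalog()$gene))
      n_pad <- total - length(up) - length(down)
      pad <- sample(pool, n_pad)
      # split padding so both directions are represented
      n_pad_up <- floor(n_pad / 2)
      up <- c(up, pad[seq_len(n_pad_up)])
      down <- c(down, pad[setdiff(seq_len(n_pad), seq_len(n_pad_up))])
      genes <- c(up, down, setdiff(universe, c(up, down)))
      lfc <- c(rep(2, length(up)), rep(-2, length(down)),
               rep(0, length(genes) - total))
      p <- c(rep(1e-4, total), rep(0.5, length(genes) - total))
      out[[fx]] <- contrast_from_stats(genes, lfc, p, dataset_id = fx)
    }
  })
  out
}

#' Run the full mining pipeline on an input bundle
#'
#' Executes the stages in order — differential expression with
#' housekeeping QC, DEG summary, secretome decomposition, pathway
#' enrichment with group accounting, regulator collaboration, ROS
#' regulatome, panel screens, and group statistics — reading the inputs
#' written by [make_fixtures()] and writing one TSV/JSON per stage plus a
#' manifest (config hash, seed, per-stage row counts, output checksums).
#' Re-running with an identical bundle and seed reproduces byte-identical
#' outputs.
#'
#' @param input_dir Directory produced by [make_fixtures()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [deg_thresholds()] object.
#' @param p_cut,z_cut Pathway-calling cutoffs.
#' @param focus_group Group for the focus-vs-rest tests.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         thresholds = deg_thresholds(),
                         p_cut = 0.05, z_cut = 2,
                         focus_group = "tumor_tissue") {
  need <- c("datasets.tsv", "catalogs.tsv", "signatures.gmt",
            "FOXP3_perturbation.tsv", "NOX2_KO.tsv", "NRF2_KO.tsv")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing) > 0L) {
    stop("Missing pipeline input(s) in ", input_dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- readr::read_tsv(file.path(input_dir, "datasets.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  catalogs <- readr::read_tsv(file.path(input_dir, "catalogs.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  signatures <- read_signatures(file.path(input_dir, "signatures.gmt"))
  manifest <- list(
    seed = NA_integer_,
    thresholds = unclass(thresholds),
    stages = list()
  )
  outputs <- character(0)
  stage <- function(name, tbl, file) {
    readr::write_tsv(tbl, file.path(out_dir, file), progress = FALSE)
    outputs <<- c(outputs, file)
    manifest$stages[[name]] <<- list(file = file, rows = nrow(tbl))
  }

  # 1. differential expression
  contrasts <- list()
  qc_rows <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$dataset_id[i]
    mat <- readr::read_tsv(file.path(input_dir, paste0(id, "_expr.tsv")),
                           show_col_types = FALSE, progress = FALSE)
    mjson <- jsonlite::read_json(file.path(input_dir, paste0(id, "_meta.json")),
                                 simplifyVector = TRUE)
    values <- as.matrix(mat[, -1L])
    rownames(values) <- mat$gene
    ds <- treg_dataset(values, mjson$sample_group, id,
                       platform = mjson$platform,
                       metadata = as.list(meta[i, c("tissue", "tissue_class",
                                                    "condition_group")]))
    contrasts[[id]] <- compute_contrast(ds, thresholds)
    qc <- housekeeping_qc(contrasts[[id]])
    qc_rows[[id]] <- dplyr::mutate(qc$per_gene, dataset_id = id, pass = qc$pass)
  }
  stage("deg", purrr::map_dfr(contrasts, tibble::as_tibble, .id = "dataset_id"),
        "contrasts.tsv")

  # 2. housekeeping QC
  stage("housekeeping_qc", dplyr::bind_rows(qc_rows), "housekeeping_qc.tsv")

  # 3. DEG summaries
  summaries <- purrr::map_dfr(contrasts, deg_summary)
  stage("deg_summary", summaries, "deg_summary.tsv")

  # 4. secretome decomposition
  decomp <- decompose_suite(contrasts, catalogs[
    catalogs$category %in% secretome_categories(), ])
  stage("decomposition", decomp, "decomposition.tsv")

  # 5. pathway enrichment + group accounting
  enr <- purrr::map_dfr(contrasts, enrich_contrast, signatures = signatures,
                        p_cut = p_cut, z_cut = z_cut)
  stage("enrichment", enr, "enrichment.tsv")
  group_sum <- meta |>
    dplyr::distinct(.data$condition_group) |>
    dplyr::pull() |>
    rlang::set_names() |>
    purrr::map(function(g) {
      ids <- meta$dataset_id[meta$condition_group == g]
      venn_summary(enr[enr$dataset_id %in% ids, ])
    })
  jsonlite::write_json(
    purrr::map(group_sum, function(s) list(counts = s$counts, pathways = s$pathways)),
    file.path(out_dir, "pathway_groups.json"), auto_unbox = TRUE, digits = NA
  )
  outputs <- c(outputs, "pathway_groups.json")
  manifest$stages[["pathway_groups"]] <- list(
    file = "pathway_groups.json",
    rows = sum(purrr::map_int(group_sum, ~ nrow(.x$pathways)))
  )

  # 6. regulator collaboration
  foxp3 <- read_deg_table(file.path(input_dir, "FOXP3_perturbation.tsv"),
                          dataset_id = "FOXP3_perturbation",
                          thresholds = thresholds)
  partitions <- purrr::map(contrasts, partition_collaboration, reg = foxp3)
  collab <- purrr::map_dfr(partitions, function(p) {
    tibble::tibble(dataset_id = p$dataset_id, regulator = p$regulator,
                   n_deg = p$n_deg,
                   n_induced = p$counts[["induced"]],
                   n_suppressed = p$counts[["suppressed"]],
                   n_noncollab_up = p$counts[["noncollab_up"]],
                   n_noncollab_down = p$counts[["noncollab_down"]],
                   pct_noncollab = p$fractions$pct_noncollab_of_deg)
  })
  stage("collaboration", collab, "collaboration.tsv")

  # 7. ROS regulatome
  nox2 <- read_deg_table(file.path(input_dir, "NOX2_KO.tsv"),
                         dataset_id = "NOX2_KO", thresholds = thresholds)
  nrf2 <- read_deg_table(file.path(input_dir, "NRF2_KO.tsv"),
                         dataset_id = "NRF2_KO", thresholds = thresholds)
  ros <- classify_ros(nox2, nrf2)
  stage("ros_partition", ros$genes, "ros_partition.tsv")
  ros_screens <- purrr::map_dfr(contrasts, screen_ros, partition = ros)
  stage("ros_screens", ros_screens, "ros_screens.tsv")

  # 8. panel screens + group statistics
  panels <- catalogs[startsWith(catalogs$category, "panel_"), ]
  screens <- purrr::map_dfr(contrasts, function(ct) {
    purrr::map_dfr(unique(panels$catalog), function(nm) {
      screen_panel(ct, catalog_genes(panels, nm), panel_name = nm)
    })
  })
  stage("panel_screens", screens, "panel_screens.tsv")

  gmeta <- meta[, c("dataset_id", "condition_group")]
  stats_out <- list(
    pct_up = group_compare(
      tibble::tibble(dataset_id = summaries$dataset_id, value = summaries$pct_up),
      gmeta, metric = "pct_up", focus_group = focus_group
    ),
    noncollab = compare_noncollab_across_groups(partitions, gmeta,
                                                focus_group = focus_group),
    ros_down_suppressed = compare_ros_screens(ros_screens, gmeta,
                                              focus_group = focus_group)
  )
  jsonlite::write_json(
    purrr::map(stats_out, function(gc) list(metric = gc$metric,
                                            groups = gc$groups, test = gc$test)),
    file.path(out_dir, "group_statistics.json"), auto_unbox = TRUE, digits = NA
  )
  outputs <- c(outputs, "group_statistics.json")
  manifest$stages[["group_statistics"]] <- list(
    file = "group_statistics.json", rows = length(stats_out)
  )

  manifest$config_hash <- rlang::hash(list(
    thresholds = unclass(thresholds), p_cut = p_cut, z_cut = z_cut,
    focus_group = focus_group, inputs = need
  ))
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
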