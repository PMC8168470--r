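test_that("simulation is bit-identical under the same config", {
  cfg <- sim_config(seed = 7, n_genes = 500)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)

  cfg_rna <- sim_config(seed = 7, n_genes = 500, platform = "rnaseq")
  r1 <- simulate_dataset(cfg_rna)
  r2 <- simulate_dataset(cfg_rna)
  expect_identical(r1$dataset$values, r2$dataset$values)
  expect_true(all(r1$dataset$values >= 0))
  expect_true(all(r1$dataset$values == round(r1$dataset$values)))
})

test_that("planting is by exact count and consistent with signs", {
  cfg <- sim_config(seed = 3, n_genes = 1000, frac_up = 0.07, frac_down = 0.03)
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$truth$status == "up"), 70L)
  expect_equal(sum(sim$truth$status == "down"), 30L)
  expect_true(all(sim$truth$log2fc[sim$truth$status == "up"] > 0))
  expect_true(all(sim$truth$log2fc[sim$truth$status == "down"] < 0))
  expect_true(all(sim$truth$log2fc[sim$truth$status == "null"] == 0))

  none <- simulate_dataset(sim_config(seed = 3, n_genes = 200,
                                      frac_up = 0, frac_down = 0))
  expect_equal(sum(none$truth$status != "null"), 0L)
})

test_that("housekeeping genes are in the universe and never planted", {
  sim <- simulate_dataset(sim_config(seed = 11, n_genes = 500))
  hk <- housekeeping_catalog()$gene
  expect_true(all(hk %in% sim$truth$gene))
  expect_true(all(sim$truth$status[sim$truth$gene %in% hk] == "null"))
})

test_that("catalog-quota planting forces the stated DEG rate per catalog", {
  genes <- tregmine:::sim_gene_universe(2000)
  cats <- tibble::tibble(catalog = "panel", category = "custom",
                         gene = sample(setdiff(genes, housekeeping_catalog()$gene), 1000))
  cfg <- sim_config(seed = 5, n_genes = 2000, frac_up = 0.1, frac_down = 0.1,
                    planted_catalog_deg_rate = 0.1)
  sim <- simulate_dataset(cfg, catalogs = cats)
  planted_deg <- sim$truth$gene[sim$truth$status != "null"]
  expect_equal(length(intersect(planted_deg, cats$gene)), 100L)
})

test_that("regulator contrast plants exact induced/suppressed overlap", {
  cfg <- sim_config(seed = 13, n_genes = 1000, frac_up = 0.1, frac_down = 0.1,
                    regulator_overlap = list(FOXP3 = c(0.8, 0.5)))
  sim <- simulate_dataset(cfg)
  reg <- simulate_regulator_contrast(cfg, sim$truth, "FOXP3")
  rel <- reg$truth$FOXP3_relation
  expect_equal(sum(rel == "induced"), 80L)     # 0.8 x 100 planted up
  expect_equal(sum(rel == "suppressed"), 50L)  # 0.5 x 100 planted down
  # induced genes really are down in the perturbation
  ind <- reg$truth$gene[rel == "induced"]
  expect_true(all(reg$contrast$status[match(ind, reg$contrast$gene)] == "down"))

  # boundary: full and zero overlap
  cfg1 <- sim_config(seed = 13, n_genes = 500, frac_up = 0.1, frac_down = 0.1,
                     regulator_overlap = list(R = c(1, 0)))
  sim1 <- simulate_dataset(cfg1)
  r1 <- simulate_regulator_contrast(cfg1, sim1$truth, "R")
  expect_equal(sum(r1$truth$R_relation == "induced"),
               sum(sim1$truth$status == "up"))
  expect_equal(sum(r1$truth$R_relation == "suppressed"), 0L)
  expect_error(simulate_regulator_contrast(cfg1, sim1$truth, "NOPE"),
               "Unknown regulator")
})

test_that("dual-KO planting matches requested class sizes exactly", {
  cfg <- sim_config(seed = 17, n_genes = 100)
  dk <- simulate_dual_ko(cfg, class_sizes = c(3L, 2L, 1L))
  expect_equal(sum(dk$truth$ros_class == "promoted"), 3L)
  expect_equal(sum(dk$truth$ros_class == "suppressed"), 2L)
  expect_equal(sum(dk$truth$ros_class == "uncertain"), 1L)

  empty <- simulate_dual_ko(cfg, class_sizes = c(0L, 0L, 0L), frac_single = 0)
  expect_equal(sum(empty$truth$ros_class != "none"), 0L)
  expect_error(simulate_dual_ko(sim_config(seed = 1, n_genes = 10),
                                class_sizes = c(8L, 8L, 8L)),
               "exceed")
})

test_that("adding downstream stages never perturbs earlier draws", {
  cfg <- sim_config(seed = 23, n_genes = 300)
  a <- simulate_dataset(cfg)
  # drawing a regulator contrast and dual KO must not change the dataset
  invisible(simulate_regulator_contrast(cfg, a$truth, "FOXP3"))
  invisible(simulate_dual_ko(cfg, class_sizes = c(5L, 5L, 2L)))
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_up = 0.6, frac_down = 0.5))
  expect_error(sim_config(n_case = 1))
  expect_error(sim_config(noise_sd = 0))
})
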