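test_that("quadrant definitions follow the cross-direction rule", {
  treg <- toy_contrast(genes_up = c("A", "B", "C"),
                       genes_down = c("D", "E"),
                       genes_ns = "F")
  # perturbation: A down (induced), D up (suppressed), B up (same direction),
  # C ns; E unmeasured
  reg <- toy_contrast(genes_up = c("D", "B"), genes_down = "A",
                      genes_ns = c("C", "F"), id = "KO")
  p <- partition_collaboration(treg, reg)
  cls <- setNames(p$genes$class, p$genes$gene)
  expect_equal(unname(cls["A"]), "induced")
  expect_equal(unname(cls["D"]), "suppressed")
  expect_equal(unname(cls["B"]), "noncollab_up")   # same-direction overlap
  expect_equal(unname(cls["C"]), "noncollab_up")   # ns in perturbation
  expect_equal(unname(cls["E"]), "noncollab_down") # unmeasured
  expect_false("F" %in% p$genes$gene)              # ns in Treg: not in partition

  # strict mode drops unmeasured genes from the partition
  ps <- partition_collaboration(treg, reg, strict = TRUE)
  expect_false("E" %in% ps$genes$gene)
  expect_equal(ps$n_deg, 4L)
})

test_that("the four quadrants partition the Treg DEG set on random inputs", {
  withr::with_seed(31, {
    for (i in 1:500) {
      n <- sample(10:60, 1)
      universe <- sprintf("P%03d", seq_len(n))
      treg <- random_contrast(universe, id = "T")
      # perturbation measured on a random subset to exercise 'unmeasured'
      reg <- random_contrast(sample(universe, sample(5:n, 1)), id = "R")
      p <- partition_collaboration(treg, reg)
      deg <- sort(treg$gene[treg$status != "ns"])
      expect_identical(sort(p$genes$gene), deg)
      expect_equal(sum(p$counts), length(deg))
      expect_false(anyDuplicated(p$genes$gene) > 0)
    }
  })
})

test_that("a sign-flipped copy of the contrast collaborates fully", {
  treg <- toy_contrast(genes_up = sprintf("U%02d", 1:20),
                       genes_down = sprintf("D%02d", 1:10),
                       genes_ns = sprintf("N%02d", 1:5))
  flipped <- contrast_from_stats(treg$gene, -treg$log2fc, treg$p, "FLIP")
  p <- partition_collaboration(treg, flipped)
  expect_equal(p$counts[["induced"]], 20L)
  expect_equal(p$counts[["suppressed"]], 10L)
  expect_equal(p$counts[["noncollab_up"]] + p$counts[["noncollab_down"]], 0L)
  expect_equal(noncollab_fraction(p), 0.00)
})

test_that("planted overlap fractions are recovered exactly from truth tables", {
  cfg <- sim_config(seed = 41, n_genes = 2000, frac_up = 0.05, frac_down = 0.05,
                    regulator_overlap = list(FOXP3 = c(0.8, 0.6)))
  sim <- simulate_dataset(cfg)
  reg <- simulate_regulator_contrast(cfg, sim$truth, "FOXP3")
  # noiseless Treg contrast from the truth table itself
  treg <- contrast_from_stats(
    sim$truth$gene, sim$truth$log2fc,
    ifelse(sim$truth$status == "null", 0.5, 1e-4), "TRUTH"
  )
  p <- partition_collaboration(treg, reg$contrast)
  expect_equal(p$counts[["induced"]], 80L)      # 0.8 x 100
  expect_equal(p$counts[["suppressed"]], 60L)   # 0.6 x 100
  expect_equal(p$counts[["noncollab_up"]], 20L)
  expect_equal(p$counts[["noncollab_down"]], 40L)
  expect_equal(noncollab_fraction(p), percent(60, 200))
  expect_equal(noncollab_fraction(p, of = "up"), percent(20, 100))

  # boundary: zero overlap -> all up-genes non-collaboration
  cfg0 <- sim_config(seed = 41, n_genes = 500, frac_up = 0.1, frac_down = 0,
                     regulator_overlap = list(R = c(0, 0)))
  sim0 <- simulate_dataset(cfg0)
  reg0 <- simulate_regulator_contrast(cfg0, sim0$truth, "R")
  treg0 <- contrast_from_stats(
    sim0$truth$gene, sim0$truth$log2fc,
    ifelse(sim0$truth$status == "null", 0.5, 1e-4), "T0"
  )
  p0 <- partition_collaboration(treg0, reg0$contrast)
  expect_equal(noncollab_fraction(p0, of = "up"), 100.00)
})

test_that("empty Treg DEG set yields an empty partition with missing fractions", {
  treg <- toy_contrast(genes_ns = c("A", "B"))
  reg <- toy_contrast(genes_up = "A", genes_ns = "B", id = "KO")
  p <- partition_collaboration(treg, reg)
  expect_equal(p$n_deg, 0L)
  expect_true(is.na(noncollab_fraction(p)))
})

test_that("group comparison of non-collaboration counts detects a planted shift", {
  mk_part <- function(id, n_noncollab) {
    treg <- toy_contrast(
      genes_up = sprintf("%s_U%03d", id, seq_len(n_noncollab)),
      genes_down = sprintf("%s_D%03d", id, 1:5), id = id
    )
    reg <- toy_contrast(genes_up = sprintf("%s_D%03d", id, 1:5),
                        genes_ns = "ZZ", id = "KO")
    partition_collaboration(treg, reg)
  }
  withr::with_seed(61, {
    lo <- round(rnorm(4, 10, 1)); hi <- round(rnorm(4, 20, 1))
  })
  parts <- c(
    purrr::imap(lo, ~ mk_part(paste0("L", .y), .x)),
    purrr::imap(hi, ~ mk_part(paste0("H", .y), .x))
  )
  meta <- tibble::tibble(
    dataset_id = purrr::map_chr(parts, "dataset_id"),
    condition_group = rep(c("normal", "tumor_tissue"), each = 4)
  )
  gc <- compare_noncollab_across_groups(parts, meta)
  expect_lt(gc$test$p_value, 0.05)
  expect_equal(gc$groups$n_datasets, c(4L, 4L))

  # single-group input errors
  meta1 <- dplyr::mutate(meta, condition_group = "tumor_tissue")
  expect_error(compare_noncollab_across_groups(parts, meta1), "2 condition groups")
})
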