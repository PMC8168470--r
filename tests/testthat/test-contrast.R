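test_that("Welch contrast matches the closed-form toy example", {
  # case {5,6,7} vs control {1,2,3}: log2fc = 4, t = 4/sqrt(2/3), df = 4
  vals <- matrix(c(5, 6, 7, 1, 2, 3), nrow = 1)
  vals <- rbind(vals, vals) # constructor needs >= 2 genes? no, but >= 2 reps
  rownames(vals) <- c("GENE1", "GENE2")
  ds <- treg_dataset(vals[, , drop = FALSE],
                     rep(c("case", "control"), each = 3),
                     "TOY1", platform = "array")
  ct <- compute_contrast(ds)
  expect_equal(ct$log2fc[1], 4)
  expect_equal(ct$t[1], 4 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ct$df[1], 4, tolerance = 1e-12)
  expect_equal(ct$p[1], 2 * pt(-4 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(ct$p[1], 0.00805, tolerance = 1e-3)
  expect_equal(ct$status[1], "up")
})

test_that("identical case and control columns give all-ns, zero log2fc", {
  withr::with_seed(1, {
    half <- matrix(rnorm(20 * 3), 20, 3)
  })
  vals <- cbind(half, half)
  rownames(vals) <- sprintf("G%02d", 1:20)
  ds <- treg_dataset(vals, rep(c("case", "control"), each = 3), "ID",
                     platform = "array")
  ct <- compute_contrast(ds)
  expect_true(all(ct$log2fc == 0))
  expect_true(all(ct$status == "ns"))
  expect_true(all(ct$p == 1))
  expect_false(any(ct$zero_variance))

  # genes constant in both arms: p reported as 1 and flagged
  const <- matrix(5, nrow = 2, ncol = 6,
                  dimnames = list(c("C1", "C2"), NULL))
  ds2 <- treg_dataset(const, rep(c("case", "control"), each = 3), "CONST",
                      platform = "array")
  ct2 <- compute_contrast(ds2)
  expect_true(all(ct2$zero_variance))
  expect_true(all(ct2$p == 1))
  expect_true(all(ct2$status == "ns"))
})

test_that("a strong planted shift is called up", {
  ds <- toy_dataset(n_genes = 30, shift_genes = "T005", shift = 2,
                    noise_sd = 0.1)
  ct <- compute_contrast(ds)
  expect_equal(ct$status[ct$gene == "T005"], "up")
  expect_equal(sum(ct$status != "ns"), 1L)
})

test_that("Welch p-values agree with stats::t.test to 1e-10", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- rnorm(n1, sd = runif(1, 0.5, 2))
      y <- rnorm(n2, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
      vals <- rbind(c(x, y), c(x, y) + rnorm(n1 + n2))
      rownames(vals) <- c("A1", "A2")
      ds <- treg_dataset(vals, rep(c("case", "control"), c(n1, n2)),
                         "W", platform = "array")
      ct <- compute_contrast(ds)
      ref <- t.test(x, y)
      expect_equal(ct$p[1], ref$p.value, tolerance = 1e-10)
      expect_equal(ct$df[1], unname(ref$parameter), tolerance = 1e-8)
    }
  })
})

test_that("pooled-variance mode matches var.equal t.test", {
  withr::with_seed(55, {
    x <- rnorm(4); y <- rnorm(5, 1)
  })
  vals <- rbind(c(x, y), c(x, y) * 2)
  rownames(vals) <- c("B1", "B2")
  ds <- treg_dataset(vals, rep(c("case", "control"), c(4, 5)), "P",
                     platform = "array")
  ct <- compute_contrast(ds, pooled = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ct$p[1], ref$p.value, tolerance = 1e-10)
})

test_that("status rule is strict at the boundaries by default", {
  th <- deg_thresholds()
  expect_equal(classify_deg(1.2, 0.01, th), "up")
  expect_equal(classify_deg(-1.5, 0.2, th), "ns")
  expect_equal(classify_deg(1.0, 0.01, th), "ns")   # |lfc| exactly at cutoff
  expect_equal(classify_deg(-1.0, 0.01, th), "ns")
  expect_equal(classify_deg(1.5, 0.05, th), "ns")   # p exactly at cutoff
  loose <- deg_thresholds(strict = FALSE)
  expect_equal(classify_deg(1.0, 0.05, loose), "up")
  expect_error(classify_deg(1, 1.5, th), "\\[0, 1\\]")
})

test_that("statuses partition the gene list and loosening never shrinks DEGs", {
  withr::with_seed(77, {
    lfc <- rnorm(500, 0, 1.5)
    p <- runif(500)
  })
  tight <- deg_thresholds(1, 0.05)
  s1 <- classify_deg(lfc, p, tight)
  expect_equal(sum(s1 == "up") + sum(s1 == "down") + sum(s1 == "ns"), 500L)
  for (th2 in list(deg_thresholds(0.5, 0.05), deg_thresholds(1, 0.2),
                   deg_thresholds(0.5, 0.2))) {
    s2 <- classify_deg(lfc, p, th2)
    expect_true(all(which(s1 != "ns") %in% which(s2 != "ns")))
  }
})

test_that("deg_summary counts and pct_up behave including the empty case", {
  ct <- toy_contrast(genes_up = sprintf("U%02d", 1:60),
                     genes_down = sprintf("D%02d", 1:40),
                     genes_ns = sprintf("N%02d", 1:10))
  s <- deg_summary(ct)
  expect_equal(s$n_deg, 100L)
  expect_equal(s$pct_up, 60.00)
  empty <- toy_contrast(genes_ns = c("A", "B"))
  expect_true(is.na(deg_summary(empty)$pct_up))
})

test_that("housekeeping QC passes inside the band and names offenders", {
  hk <- housekeeping_catalog()$gene
  ct <- contrast_from_stats(hk, rep(0, 9), rep(0.5, 9), "QC")
  qc <- housekeeping_qc(ct)
  expect_true(qc$pass)
  # observed housekeeping extremes sit inside the default band
  ct2 <- contrast_from_stats(hk, c(-1.27, 1.28, rep(0, 7)), rep(0.5, 9), "QC2")
  expect_true(housekeeping_qc(ct2)$pass)
  ct3 <- contrast_from_stats(hk, c(2, rep(0, 8)), rep(0.5, 9), "QC3")
  qc3 <- housekeeping_qc(ct3)
  expect_false(qc3$pass)
  expect_false(qc3$per_gene$within_band[qc3$per_gene$gene == "ACTB"])
  # genes absent from the platform are missing, not failing
  ct4 <- contrast_from_stats(c("ACTB", "XYZ"), c(0, 0), c(0.5, 0.5), "QC4")
  qc4 <- housekeeping_qc(ct4)
  expect_true(qc4$pass)
  expect_equal(sum(qc4$per_gene$measured), 1L)
  ct5 <- contrast_from_stats(c("FOO", "BAR"), c(0, 0), c(0.5, 0.5), "QC5")
  expect_error(housekeeping_qc(ct5), "No housekeeping gene")
})

test_that("RNA-seq CPM path recovers a strong planted fold change", {
  cfg <- sim_config(seed = 31, n_genes = 2000, platform = "rnaseq",
                    frac_up = 0.05, frac_down = 0.05, effect_size_log2 = 3)
  sim <- simulate_dataset(cfg)
  ct <- compute_contrast(sim$dataset)
  up_truth <- sim$truth$gene[sim$truth$status == "up"]
  sens <- mean(ct$status[match(up_truth, ct$gene)] == "up")
  expect_gt(sens, 0.6)
})

test_that("DEG table import adapter assigns statuses with the thresholds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = c("a1", "b2", "c3"),
                                  log2fc = c(2, -2, 0.2),
                                  p = c(0.001, 0.3, 0.001)), path)
  ct <- read_deg_table(path, "EXT")
  expect_equal(ct$gene, c("A1", "B2", "C3"))
  expect_equal(ct$status, c("up", "ns", "ns"))
  expect_equal(attr(ct, "dataset_id"), "EXT")
})

test_that("tidy and glance methods expose contrast results", {
  ct <- toy_contrast(genes_up = "A", genes_down = "B", genes_ns = "C")
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$dataset_id[1], "TOY")
  gl <- glance(ct)
  expect_equal(gl$n_deg, 2L)
})
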