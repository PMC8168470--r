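test_that("hypergeometric tail matches exact enumeration on the 2-of-2 draw", {
  # N=4, K=2, n=2, k=2: only 1 of the C(4,2)=6 draws contains both members
  r <- fisher_enrichment(c("A", "B"), c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(r$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(r$k, 2L)

  # k = 0: P(X >= 0) = 1
  r0 <- fisher_enrichment(c("C", "D"), c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(r0$p_value, 1)

  expect_error(fisher_enrichment(character(0), "A", c("A", "B")), "Empty DEG")
  expect_error(fisher_enrichment("Z", "A", c("A", "B")), "subset")
})

test_that("hypergeometric tail equals brute-force dhyper sums on random instances", {
  withr::with_seed(8, {
    for (i in 1:50) {
      N <- sample(5:100, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      universe <- sprintf("U%03d", 1:N)
      sig <- universe[1:K]
      deg <- sample(universe, n)
      r <- fisher_enrichment(deg, sig, universe)
      brute <- sum(dhyper(r$k:min(K, n), K, N - K, n))
      expect_equal(r$p_value, brute, tolerance = 1e-12)
    }
  })
})

test_that("activation z follows the sign-agreement formula", {
  sig <- function(genes, dir) tibble::tibble(gene = genes, direction = dir)
  ct <- toy_contrast(genes_up = sprintf("U%02d", 1:9),
                     genes_down = sprintf("D%02d", 1:9),
                     genes_ns = sprintf("N%02d", 1:9))
  # 9 consistent, 0 inconsistent
  expect_equal(activation_z(ct, sig(sprintf("U%02d", 1:9), 1L)), 3)
  # 2 consistent, 2 inconsistent
  expect_equal(activation_z(ct, sig(c("U01", "U02", "D01", "D02"),
                                    rep(1L, 4))), 0)
  # 8 consistent, 1 inconsistent
  expect_equal(activation_z(ct, sig(c(sprintf("U%02d", 1:8), "D01"),
                                    rep(1L, 9))), 7 / 3, tolerance = 1e-12)
  # direction-0 members never contribute
  expect_true(is.na(activation_z(ct, sig(c("U01", "U02"), c(0L, 0L)))))
  # members outside the DEG list do not contribute
  expect_equal(activation_z(ct, sig(c("U01", "N01", "ZZZ"), rep(1L, 3))), 1)
})

test_that("activation z is antisymmetric under flipping signature directions", {
  withr::with_seed(21, {
    universe <- sprintf("V%03d", 1:200)
    for (i in 1:20) {
      ct <- random_contrast(universe)
      sig <- tibble::tibble(
        gene = sample(universe, 30),
        direction = sample(c(-1L, 1L), 30, replace = TRUE)
      )
      z <- activation_z(ct, sig)
      flipped <- dplyr::mutate(sig, direction = -direction)
      if (is.na(z)) {
        expect_true(is.na(activation_z(ct, flipped)))
      } else {
        expect_equal(activation_z(ct, flipped), -z, tolerance = 1e-12)
      }
    }
  })
})

test_that("pathway calling applies the p and z cutoffs with stated boundaries", {
  expect_equal(classify_pathway(0.01, 2.5), "activated")
  expect_equal(classify_pathway(0.01, -3), "inhibited")
  expect_equal(classify_pathway(0.2, 3), "not_called")
  expect_equal(classify_pathway(0.01, NA_real_), "not_called")
  # z boundary inclusive, p boundary strict
  expect_equal(classify_pathway(0.01, 2), "activated")
  expect_equal(classify_pathway(0.01, -2), "inhibited")
  expect_equal(classify_pathway(0.05, 5), "not_called")
  expect_equal(classify_pathway(0.049999, 1.9999), "not_called")
})

test_that("a signature fully inside planted up-DEGs is called activated", {
  universe <- sprintf("W%03d", 1:500)
  up <- universe[1:40]
  ct <- toy_contrast(genes_up = up, genes_ns = universe[41:500])
  sig <- tibble::tibble(signature = "S", gene = up[1:10], direction = 1L)
  rec <- enrich_contrast(ct, sig)
  expect_equal(rec$status, "activated")
  expect_lt(rec$p_value, 0.05)
  expect_gte(rec$z, 2)
})

test_that("venn summary partitions pathways into shared/specific/dual", {
  rec <- function(id, sig, status) {
    tibble::tibble(dataset_id = id, signature = sig, status = status)
  }
  # A: P1 up, P2 up; B: P1 up
  g <- dplyr::bind_rows(rec("A", c("P1", "P2"), "activated"),
                        rec("B", "P1", "activated"))
  vs <- venn_summary(g)
  expect_equal(vs$pathways$sharing[vs$pathways$signature == "P1"], "shared")
  expect_equal(vs$pathways$sharing[vs$pathways$signature == "P2"], "specific")
  expect_equal(vs$counts$n_dual, 0L)
  expect_equal(vs$counts$n_called,
               vs$counts$n_activated + vs$counts$n_inhibited + vs$counts$n_dual)

  # opposite calls in one group -> dual
  g2 <- dplyr::bind_rows(rec("A", "P1", "activated"),
                         rec("B", "P1", "inhibited"))
  vs2 <- venn_summary(g2)
  expect_equal(vs2$pathways$direction, "dual")
  expect_equal(vs2$counts$n_dual, 1L)

  # single-dataset group: everything specific
  g3 <- rec("A", c("P1", "P2", "P3"), "activated")
  vs3 <- venn_summary(g3)
  expect_equal(vs3$counts$n_specific, 3L)
  expect_equal(vs3$counts$n_shared, 0L)

  # not_called rows are ignored entirely
  g4 <- dplyr::bind_rows(g3, rec("A", "P9", "not_called"))
  expect_equal(venn_summary(g4)$counts$n_called, 3L)
})

test_that("cross-group overlap does plain set algebra per direction", {
  mk_summary <- function(sigs, dirs) {
    list(pathways = tibble::tibble(signature = sigs, direction = dirs,
                                   n_activated = 1L, n_inhibited = 0L,
                                   sharing = "specific"))
  }
  s <- list(
    g1 = mk_summary(c("P1", "P2"), c("activated", "activated")),
    g2 = mk_summary(c("P2", "P3"), c("activated", "inhibited"))
  )
  ov <- cross_group_overlap(s)
  expect_equal(ov$pairwise$n_shared, 1L)
  expect_equal(ov$pairwise$n_a_specific, 1L)
  expect_equal(ov$pairwise$n_b_specific, 1L)
  expect_equal(ov$shared_all, "P2")
  ov_act <- cross_group_overlap(s, direction = "activated")
  expect_equal(ov_act$per_group$g2, "P2")
  # identical and disjoint groups
  expect_equal(cross_group_overlap(list(a = s$g1, b = s$g1))$pairwise$n_shared, 2L)
  expect_equal(cross_group_overlap(list(a = s$g1, b = mk_summary("Q", "activated")))$pairwise$n_shared, 0L)
  expect_error(cross_group_overlap(s["g1"]), "at least 2")
})
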