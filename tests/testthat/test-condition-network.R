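# inverse-coexpression filtering, Jaccard scoring and edge significance

test_that("pearson_correlation handles the canonical and degenerate cases", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(pearson_correlation(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_correlation(c(1, 2), c(2, 1)), "at least 3")
})

test_that("inverse_pair_filter keeps exactly the anti-correlated static pairs", {
  mi <- toy_expression(matrix(c(1, 2, 3, 4), 1, 4,
                              dimnames = list("miR-1", paste0("s", 1:4))))
  # gene gDown anti-correlated, gUp positively correlated, gFlat constant
  mr <- toy_expression(matrix(c(4, 3, 2, 1,
                                1, 2, 3, 4,
                                5, 5, 5, 5), 3, 4, byrow = TRUE,
                              dimnames = list(c("gDown", "gUp", "gFlat"),
                                              paste0("s", 1:4))))
  tm <- toy_target_map(list("miR-1" = c("gDown", "gUp", "gFlat", "gMissing")))
  expect_message(flt <- inverse_pair_filter(mi, mr, tm), "skipped 1 unmeasured and 1 zero-variance")
  expect_equal(nrow(flt$pairs), 1L)
  expect_equal(flt$pairs$gene_id, "gDown")
  expect_equal(flt$pairs$r, -1)
  expect_equal(flt$cond_targets[["miR-1"]], "gDown")
  expect_equal(flt$n_skipped, 1L)
})

test_that("a positively correlated pair is rejected and no-overlap samples error", {
  mi <- toy_expression(matrix(1:4, 1, 4, dimnames = list("miR-1", paste0("s", 1:4))))
  mr_pos <- toy_expression(matrix(1:4, 1, 4, dimnames = list("gA", paste0("s", 1:4))))
  tm <- toy_target_map(list("miR-1" = "gA"))
  flt <- suppressMessages(inverse_pair_filter(mi, mr_pos, tm))
  expect_equal(nrow(flt$pairs), 0L)
  expect_length(flt$cond_targets, 0L)

  mr_other <- toy_expression(matrix(1:4, 1, 4, dimnames = list("gA", paste0("x", 1:4))))
  expect_error(inverse_pair_filter(mi, mr_other, tm), "overlapping samples")
})

test_that("jaccard_overlap follows the shared-target definition", {
  expect_equal(jaccard_overlap(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_overlap(c("A", "B"), c("A", "B"), same_mirna = TRUE), 1)
  expect_equal(jaccard_overlap(c("A", "B"), c("C", "D")), 0)
  expect_error(jaccard_overlap(character(0), "A"), "empty")
})

test_that("jaccard_overlap is symmetric, bounded, and extreme iff sets demand it", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      a <- sample(letters, sample(1:10, 1))
      b <- sample(letters, sample(1:10, 1))
      t_ab <- jaccard_overlap(a, b)
      expect_identical(t_ab, jaccard_overlap(b, a))
      expect_gte(t_ab, 0); expect_lte(t_ab, 1)
      expect_identical(t_ab == 1, setequal(a, b))
      expect_identical(t_ab == 0, length(intersect(a, b)) == 0L)
    }
  })
})

test_that("exact overlap p-value matches the closed form and its bounds", {
  expect_equal(overlap_pvalue(4, 5, 3, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(overlap_pvalue(4, 5, 0, 10), 1)
  expect_error(overlap_pvalue(4, 5, 5, 10), "exceeds")
  expect_error(overlap_pvalue(6, 6, 1, 10), "cannot hold")
})

test_that("permutation p-value agrees with the exact tail within Monte-Carlo error", {
  p_exact <- overlap_pvalue(4, 5, 3, 10)
  p_perm <- overlap_pvalue(4, 5, 3, 10, method = "permutation",
                           n_perm = 10000L, rng_seed = 42L)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_perm - p_exact), 3 * se)
  # reproducible under the same seed
  expect_identical(p_perm, overlap_pvalue(4, 5, 3, 10, method = "permutation",
                                          n_perm = 10000L, rng_seed = 42L))
})

test_that("overlap p-value is non-increasing in the observed overlap", {
  for (universe in c(14L, 25L)) {
    ovs <- max(0L, 6L + 8L - universe):6L
    ps <- vapply(ovs, function(ov) overlap_pvalue(6, 8, ov, universe), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("condition network keeps only significant positive-overlap edges", {
  # identical 10-gene target sets in a 50-gene universe: p = 1/C(50,10) << 0.05
  genes <- sprintf("g%02d", 1:50)
  shared <- genes[1:10]
  flt <- structure(
    list(condition = "toy",
         pairs = tibble::tibble(mirna_id = character(0), gene_id = character(0),
                                r = numeric(0), n = integer(0)),
         cond_targets = list(mA = shared, mB = shared,
                             mC = genes[11:20], mD = genes[21:50]),
         measured_genes = genes, n_samples = 4L,
         n_skipped = 0L, n_degenerate = 0L),
    class = "coexpression_pairs"
  )
  net <- build_condition_mran(flt)
  et <- tidy(net)
  expect_equal(nrow(et), 1L)
  expect_equal(c(et$mirna_a, et$mirna_b), c("mA", "mB"))
  expect_equal(et$t, 1)
  expect_equal(et$p, 1 / choose(50, 10), tolerance = 1e-12)
  expect_equal(et$weight, 1 - et$p)
  expect_equal(glance(net)$n_mirnas, 4L)
})

test_that("single-miRNA input yields an edgeless network with a warning", {
  flt <- structure(
    list(condition = "toy", pairs = tibble::tibble(),
         cond_targets = list(mA = c("g1", "g2")),
         measured_genes = c("g1", "g2"), n_samples = 4L,
         n_skipped = 0L, n_degenerate = 0L),
    class = "coexpression_pairs"
  )
  expect_warning(net <- build_condition_mran(flt), "fewer than 2")
  expect_equal(igraph::vcount(net$graph), 1L)
  expect_equal(igraph::ecount(net$graph), 0L)
})

test_that("the edge set shrinks monotonically as alpha_edge decreases", {
  sim <- default_simulation()
  e <- sim$expression[[1]]
  flt <- suppressMessages(inverse_pair_filter(e$mirna, e$mrna, sim$targets))
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  edge_sets <- lapply(alphas, function(a) {
    et <- tidy(build_condition_mran(flt, alpha_edge = a))
    paste(et$mirna_a, et$mirna_b)
  })
  for (k in seq_along(alphas)[-1]) {
    expect_true(all(edge_sets[[k]] %in% edge_sets[[k - 1]]))
  }
})
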