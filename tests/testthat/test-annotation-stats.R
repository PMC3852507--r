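# hypergeometric kernel, motif co-occurrence and pathway enrichment

test_that("hypergeometric tail reproduces hand-derived values", {
  expect_equal(hypergeom_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 5), 1)
  expect_error(hypergeom_tail(5, 4, 5, 10), "exceeds")
  expect_error(hypergeom_tail(1, 4, 11, 10), "universe")
})

test_that("hypergeometric tail matches exhaustive enumeration for small universes", {
  for (N in 2:9) {
    for (m2 in 1:N) {
      draws <- utils::combn(N, m2)
      for (m1 in 1:N) {
        overlaps <- colSums(draws <= m1)
        for (c_obs in 0:min(m1, m2)) {
          expect_equal(hypergeom_tail(c_obs, m1, m2, N),
                       mean(overlaps >= c_obs), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the internal pmf sums to one and phyper agrees", {
  for (parms in list(c(4, 5, 10), c(7, 3, 12), c(10, 10, 30))) {
    m1 <- parms[1]; m2 <- parms[2]; N <- parms[3]
    support <- max(0, m1 + m2 - N):min(m1, m2)
    pmf <- vapply(support, function(i) {
      exp(lchoose(m1, i) + lchoose(N - m1, m2 - i) - lchoose(N, m2))
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    for (c_obs in support) {
      expect_equal(hypergeom_tail(c_obs, m1, m2, N),
                   phyper(c_obs - 1, m1, N - m1, m2, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("motif co-occurrence flags planted pairs and ignores saturated or disjoint ones", {
  # planted: X and Y co-occur on 12 of 40 miRNAs, each carried by 14
  mirnas <- sprintf("m%02d", 1:40)
  motifs_of <- setNames(rep(list(character(0)), 40), mirnas)
  co <- mirnas[1:12]
  xa <- c(co, mirnas[13:14]); yb <- c(co, mirnas[15:16])
  for (m in xa) motifs_of[[m]] <- c(motifs_of[[m]], "X")
  for (m in yb) motifs_of[[m]] <- c(motifs_of[[m]], "Y")
  # Z never co-occurs with X
  for (m in mirnas[17:20]) motifs_of[[m]] <- c(motifs_of[[m]], "Z")
  ann <- structure(list(motifs_of = motifs_of, mirnas = mirnas, universe_size = 40L),
                   class = "motif_annotation")
  res <- motif_cooccurrence(ann, mirnas, alpha = 1e-5)
  expect_equal(nrow(res), 1L)
  expect_equal(c(res$motif_a, res$motif_b), c("X", "Y"))
  expect_equal(res$p, hypergeom_tail(12, 14, 14, 40), tolerance = 1e-12)
  expect_lt(res$p_bonferroni, 1e-5)
  expect_equal(attr(res, "n_tested"), 3L)

  # saturated motifs (carried by everything in scope) are never significant
  sat <- structure(list(motifs_of = setNames(rep(list(c("A", "B")), 3), c("x", "y", "z")),
                        mirnas = c("x", "y", "z"), universe_size = 3L),
                   class = "motif_annotation")
  res_sat <- motif_cooccurrence(sat, c("x", "y", "z"), alpha = 0.5, correction = "none")
  expect_equal(nrow(res_sat), 0L)

  expect_error(motif_cooccurrence(ann, "m01"), "at least 2")
})

test_that("co-occurrence results do not depend on motif pair ordering", {
  sim <- default_simulation()
  scope <- sim$motifs$mirnas
  res <- motif_cooccurrence(sim$motifs, scope)
  rev_ann <- sim$motifs
  rev_ann$motifs_of <- lapply(rev_ann$motifs_of, rev)
  res_rev <- motif_cooccurrence(rev_ann, scope)
  expect_equal(res[order(res$motif_a, res$motif_b), ],
               res_rev[order(res_rev$motif_a, res_rev$motif_b), ],
               ignore_attr = TRUE)
  # planted pairs are all recovered
  planted <- vapply(sim$truth$planted_motif_pairs, paste, character(1), collapse = "|")
  found <- paste(res$motif_a, res$motif_b, sep = "|")
  expect_true(all(planted %in% found))
})

test_that("pathway enrichment reproduces the single-term tail and rejects bad input", {
  gs <- structure(list(sets = list(P = paste0("g", 1:5)),
                       descriptions = c(P = "toy")),
                  class = "gene_set_collection")
  bg <- paste0("g", 1:20)
  res <- pathway_enrichment(paste0("g", 1:5), bg, gs)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 6.450e-5, tolerance = 1e-3)
  expect_true(res$significant)

  # zero overlap is never significant
  res0 <- pathway_enrichment(paste0("g", 6:10), bg,
                             structure(list(sets = list(P = paste0("g", 1:5)),
                                            descriptions = c(P = "")),
                                       class = "gene_set_collection"))
  expect_equal(res0$p, 1)
  expect_false(res0$significant)

  expect_error(pathway_enrichment(c("g1", "nope"), bg, gs), "not in the background")
  expect_error(pathway_enrichment("g1", character(0), gs), "empty background")
  # pathways with no background overlap are skipped with a count
  gs2 <- structure(list(sets = list(P = paste0("g", 1:5), Q = "elsewhere"),
                        descriptions = c(P = "", Q = "")),
                   class = "gene_set_collection")
  expect_message(res2 <- pathway_enrichment(paste0("g", 1:5), bg, gs2), "skipped")
  expect_equal(attr(res2, "n_skipped"), 1L)
})

test_that("the enrichment matrix keeps only rows/columns with a significant cell", {
  cells <- tibble::tibble(
    module_id = c("M1", "M1", "M2", "M2", "M3", "M3"),
    pathway_id = c("P1", "P2", "P1", "P3", "P2", "P3"),
    p = c(0.001, 0.5, 0.9, 0.02, 0.6, 0.7),
    neglog10p = -log10(p), significant = p < 0.05
  )
  m <- enrichment_matrix(cells)
  expect_equal(sort(rownames(m)), c("M1", "M2"))
  expect_equal(sort(colnames(m)), c("P1", "P3"))
  expect_equal(m["M1", "P1"], 3, tolerance = 1e-12)

  none <- dplyr::mutate(cells, significant = FALSE)
  expect_equal(dim(enrichment_matrix(none)), c(0L, 0L))
})
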