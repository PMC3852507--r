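# sequence identity, structure parsing, tree edit distance, folding, rank tests

test_that("seed extraction honours the window and its bounds", {
  mat <- "ACGUACGUACGUACGUACGUAC"
  expect_equal(extract_seed(mat), "CGUACGU")
  expect_equal(extract_seed(mat, 1, 7), "ACGUACG")
  expect_error(extract_seed("ACGUAC"), "exceeds")
})

test_that("alignment identity matches exhaustive search over gap placements", {
  expect_equal(pairwise_identity("ACGU", "ACGU"), 1)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  expect_equal(pairwise_identity("ACGU", "ACGA"), 0.75)
  withr::with_seed(5, {
    for (rep in 1:20) {
      a <- paste(sample(c("A", "C", "G", "U"), sample(2:5, 1), TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "U"), sample(2:5, 1), TRUE), collapse = "")
      ident <- pairwise_identity(a, b)
      expect_true(any(abs(optimal_alignment_identities(a, b) - ident) < 1e-12),
                  label = sprintf("%s vs %s", a, b))
      expect_identical(ident, pairwise_identity(b, a))
    }
  })
  expect_error(pairwise_identity("", "ACGU"), "non-empty")
})

test_that("dot-bracket parsing extracts pairs and a consistent tree", {
  pt <- parse_dotbracket("((..))")
  expect_equal(unname(pt$pairs), cbind(c(1, 2), c(6, 5)), ignore_attr = TRUE)
  expect_equal(parse_dotbracket("....")$pairs[, 1], integer(0), ignore_attr = TRUE)
  expect_error(parse_dotbracket("((."), "position 3")
  # node count = pairs + unpaired + virtual root
  expect_equal(pt$n_nodes, 2L + 2L + 1L)
  expect_equal(sum(pt$labels == "P"), 2L)
  expect_equal(sum(pt$labels == "U"), 2L)
})

test_that("base pair distance is the symmetric difference and needs equal lengths", {
  expect_equal(base_pair_distance("((..))", "((..))"), 0)
  expect_equal(base_pair_distance("((..))", "(....)"), 1)
  expect_error(base_pair_distance("((..))", "(...)"), "length")
  # bound: at most twice the denser structure's pair count
  withr::with_seed(3, {
    for (rep in 1:20) {
      s1 <- nussinov_fold(paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = ""))
      s2 <- nussinov_fold(paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = ""))
      expect_lte(base_pair_distance(s1, s2),
                 2 * max(count_pairs(s1), count_pairs(s2)))
    }
  })
})

test_that("tree edit distance equals the exhaustive-recursion oracle on small trees", {
  expect_equal(tree_edit_distance("(..)", "(..)"), 0)
  expect_equal(tree_edit_distance("(..)", "(...)"), 1)
  expect_equal(tree_edit_distance("((..))", "(....)"), 3)
  structs <- all_small_structures(max_len = 10L, max_nodes = 6L)
  expect_gte(length(structs), 500L)
  sub <- withr::with_seed(8, sample(structs, 50L))
  trees <- lapply(sub, parse_dotbracket)
  idx <- which(upper.tri(diag(length(sub)), diag = TRUE), arr.ind = TRUE)
  imp <- mapply(function(i, j) tree_edit_distance(trees[[i]], trees[[j]]),
                idx[, 1], idx[, 2])
  orc <- mapply(function(i, j) naive_tree_dist(sub[i], sub[j]),
                idx[, 1], idx[, 2])
  expect_equal(imp, orc)
})

test_that("tree edit distance satisfies the metric axioms on random structures", {
  withr::with_seed(17, {
    ensemble <- replicate(30, nussinov_fold(
      paste(sample(c("A", "C", "G", "U"), sample(10:25, 1), TRUE), collapse = "")
    ))
    for (rep in 1:200) {
      abc <- sample(ensemble, 3L, replace = TRUE)
      dab <- tree_edit_distance(abc[1], abc[2])
      dba <- tree_edit_distance(abc[2], abc[1])
      dbc <- tree_edit_distance(abc[2], abc[3])
      dac <- tree_edit_distance(abc[1], abc[3])
      expect_identical(dab, dba)
      expect_lte(dac, dab + dbc + 1e-12)
      expect_identical(dab == 0, identical(abc[1], abc[2]))
    }
  })
})

test_that("nussinov matches exhaustive enumeration and handles degenerate input", {
  expect_equal(nussinov_fold("GCGAAACGC"), "(((...)))")
  expect_equal(nussinov_fold("AAAA"), "....")
  expect_equal(nussinov_fold("GC"), "..")
  expect_error(nussinov_fold("ACGX"), "non-RNA")
  withr::with_seed(23, {
    for (rep in 1:30) {
      n <- sample(4:12, 1)
      seq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
      db <- nussinov_fold(seq)
      expect_equal(count_pairs(db), enumerate_max_pairs(seq), label = seq)
      # the emitted structure is itself valid and uses only legal pairs
      pt <- parse_dotbracket(db)
      if (nrow(pt$pairs)) {
        chars <- strsplit(seq, "", fixed = TRUE)[[1]]
        for (r in seq_len(nrow(pt$pairs))) {
          expect_true(can_pair_rna(chars[pt$pairs[r, 1]], chars[pt$pairs[r, 2]]))
          expect_gte(pt$pairs[r, 2] - pt$pairs[r, 1] - 1, 3)
        }
      }
    }
  })
})

test_that("rank-sum exact branch reproduces full enumeration", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less"), 0.05)
  expect_gte(ranksum_test(c(1, 2, 3), c(1, 2, 3)), 0.99)
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      vals <- sample(1:50, n + m) # distinct -> tie-free
      x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
      for (alt in c("two_sided", "less", "greater")) {
        expect_equal(ranksum_test(x, y, alt), enumerate_ranksum(x, y, alt),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("similarity comparison separates planted structural families", {
  sim <- default_simulation()
  cmp <- compare_similarity_distributions(sim$truth$groups, sim$hairpins,
                                          layer = "precursor_struct", rng_seed = 7)
  expect_lt(cmp$p_within_vs_between, 0.01)
  expect_lt(cmp$p_within_vs_random, 0.01)
  # identical records make within and between indistinguishable
  rec <- sim$hairpins[[1]]
  same <- setNames(lapply(sprintf("hp%d", 1:6), function(id) {
    r <- rec; r$mirna_id <- id; r
  }), sprintf("hp%d", 1:6))
  cmp_same <- compare_similarity_distributions(
    list(sprintf("hp%d", 1:3), sprintf("hp%d", 4:6)), same,
    layer = "precursor_struct", rng_seed = 1
  )
  expect_gte(cmp_same$p_within_vs_between, 0.99)
  # a single module has no between comparison
  single <- compare_similarity_distributions(list(sprintf("hp%d", 1:3)), same,
                                             layer = "seed", rng_seed = 1)
  expect_true(is.na(single$p_within_vs_between))
  expect_length(single$between, 0L)
  # a member without a record errors by name
  expect_error(
    compare_similarity_distributions(list(c("hp1", "ghost")), same, layer = "seed"),
    "ghost"
  )
})

test_that("the similarity report covers all four layers and splits species", {
  sim <- default_simulation()
  recs <- sim$hairpins[unlist(sim$truth$groups[1:2], use.names = FALSE)]
  groups <- sim$truth$groups[1:2]
  rep_tbl <- similarity_report(groups, recs, rng_seed = 3)
  expect_equal(sort(unique(rep_tbl$layer)),
               sort(c("seed", "mature", "precursor_seq", "precursor_struct")))
  expect_true(all(rep_tbl$p_within_vs_random > 0 & rep_tbl$p_within_vs_random <= 1))

  # species prefixes split the analysis
  hsa <- setNames(recs[1:10], paste0("hsa-", names(recs)[1:10]))
  mmu <- setNames(recs[1:10], paste0("mmu-", names(recs)[1:10]))
  for (i in seq_along(hsa)) hsa[[i]]$mirna_id <- names(hsa)[i]
  for (i in seq_along(mmu)) mmu[[i]]$mirna_id <- names(mmu)[i]
  both <- c(hsa, mmu)
  groups2 <- list(paste0("hsa-", groups[[1]]), paste0("hsa-", groups[[2]]),
                  paste0("mmu-", groups[[1]]), paste0("mmu-", groups[[2]]))
  rep_sp <- similarity_report(groups2, both, rng_seed = 3, by_species = TRUE)
  expect_setequal(unique(rep_sp$species), c("hsa", "mmu"))
})
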