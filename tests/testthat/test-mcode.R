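# module detection: k-cores, core-clustering-coefficient weights, MCODE

test_that("core numbers match known graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(core_decomposition(k4)), rep(3L, 4))

  tree <- named_graph(c("a", "b", "b", "c", "b", "d", "d", "e"))
  expect_true(all(core_decomposition(tree) <= 1L))

  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_length(core_decomposition(empty), 0L)
})

test_that("core numbers agree with maximal-subgraph search and igraph on random graphs", {
  withr::with_seed(2024, {
    for (rep in 1:30) {
      n <- sample(3:8, 1)
      rg <- random_graph_pair(n, stats::runif(1, 0.2, 0.7))
      mine <- core_decomposition(rg$graph)
      brute <- brute_core_numbers(rg$adj)
      expect_equal(mine[names(brute)], brute)
      # independent cross-check against the established implementation
      expect_equal(unname(mine), unname(igraph::coreness(rg$graph)[names(mine)]))
    }
  })
})

test_that("vertex weights reproduce the core-clustering-coefficient values", {
  tri <- named_graph(c("a", "b", "b", "c", "c", "a"))
  expect_equal(vertex_weight(tri, "a"), 2)
  edge <- named_graph(c("a", "b"))
  expect_equal(vertex_weight(edge, "a"), 1)
  iso <- named_graph(c("a", "b"), isolated = "z")
  expect_equal(vertex_weight(iso, "z"), 0)
  expect_error(vertex_weight(tri, "nope"), "not in the graph")
})

test_that("two planted cliques joined by a path are recovered exactly", {
  el <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    el <- c(el, paste0("A", i), paste0("A", j), paste0("B", i), paste0("B", j))
  }
  g <- igraph::make_graph(c(el, "A1", "p1", "p1", "p2", "p2", "p3", "p3", "B1"),
                          directed = FALSE)
  mods <- mcode_complexes(g)
  expect_equal(nrow(mods), 2L)
  expect_setequal(vapply(mods$mirnas, paste, character(1), collapse = ","),
                  c("A1,A2,A3,A4,A5", "B1,B2,B3,B4,B5"))
  expect_equal(mods$n_links, c(10, 10))
})

test_that("trees yield no modules and a triangle yields one", {
  tree <- named_graph(c("a", "b", "b", "c", "c", "d", "b", "e"))
  expect_equal(nrow(mcode_complexes(tree)), 0L)
  tri <- named_graph(c("a", "b", "b", "c", "c", "a"))
  mods <- mcode_complexes(tri)
  expect_equal(nrow(mods), 1L)
  expect_equal(mods$mirnas[[1]], c("a", "b", "c"))
})

test_that("every emitted module has minimum induced degree >= 2", {
  withr::with_seed(99, {
    for (rep in 1:15) {
      rg <- random_graph_pair(8, 0.45)
      mods <- mcode_complexes(rg$graph)
      for (mem in mods$mirnas) {
        sub <- igraph::induced_subgraph(rg$graph, mem)
        expect_gte(min(igraph::degree(sub)), 2)
      }
    }
  })
})

test_that("module extraction is stable under vertex relabeling", {
  el <- c("a", "b", "b", "c", "c", "a", "c", "d", "d", "e", "e", "f", "f", "d")
  g1 <- igraph::make_graph(el, directed = FALSE)
  relabel <- c(a = "v6", b = "v5", c = "v4", d = "v3", e = "v2", f = "v1")
  g2 <- igraph::make_graph(unname(relabel[el]), directed = FALSE)
  m1 <- lapply(mcode_complexes(g1)$mirnas, function(x) sort(unname(relabel[x])))
  m2 <- lapply(mcode_complexes(g2)$mirnas, sort)
  expect_setequal(vapply(m1, paste, character(1), collapse = ","),
                  vapply(m2, paste, character(1), collapse = ","))
})

test_that("planted cliques on a sparse background are recovered across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 40L
      ids <- sprintf("v%02d", 1:n)
      adj <- matrix(0L, n, n, dimnames = list(ids, ids))
      cliques <- list(1:6, 7:12, 13:18)
      for (cl in cliques) adj[cl, cl] <- 1L
      # sparse Erdos-Renyi background: noise edges everywhere except directly
      # bridging two planted cliques (a direct clique-clique edge merges the
      # cliques under any density-based expansion, by design)
      in_clique <- rep(0L, n); for (k in seq_along(cliques)) in_clique[cliques[[k]]] <- k
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (in_clique[i] > 0L && in_clique[j] > 0L) next
        if (stats::runif(1) < 0.05) adj[i, j] <- adj[j, i] <- 1L
      }
      diag(adj) <- 0L
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      mods <- mcode_complexes(g)
      found <- vapply(cliques, function(cl) {
        any(vapply(mods$mirnas, function(m) setequal(m, ids[cl]), logical(1)))
      }, logical(1))
      if (all(found)) hits <- hits + 1L
    })
  }
  expect_gte(hits, 9L)
})

test_that("vwp outside [0, 1) is rejected", {
  tri <- named_graph(c("a", "b", "b", "c", "c", "a"))
  expect_error(mcode_complexes(tri, vwp = 1), "vwp")
  expect_error(mcode_complexes(tri, vwp = -0.1), "vwp")
})

test_that("merging condition networks unions nodes and stacks condition records", {
  sim <- default_simulation()
  nets <- default_networks()$nets
  g <- default_networks()$global
  expect_s3_class(g, "global_mran")
  expect_setequal(g$nodes, unique(c(igraph::V(nets[[1]]$graph)$name,
                                    igraph::V(nets[[2]]$graph)$name)))
  # simple view has one edge per distinct pair
  expect_equal(igraph::ecount(g$simple_view),
               nrow(dplyr::distinct(g$records, .data$mirna_a, .data$mirna_b)))
  # single net merges to itself
  g1 <- merge_condition_mrans(nets[1])
  expect_equal(igraph::ecount(g1$simple_view), igraph::ecount(nets[[1]]$graph))
  expect_error(merge_condition_mrans(list()), "non-empty")
})

test_that("module annotation unions condition-specific targets over contributing conditions", {
  sim <- default_simulation()
  parts <- default_networks()
  mods <- annotate_modules(mcode_complexes(parts$global), parts$global)
  expect_true(all(mods$n_links >= mods$n_mirnas - 1))
  # recompute one module's target union independently
  i <- 1L
  mem <- mods$mirnas[[i]]
  conds <- strsplit(mods$conditions[i], ";", fixed = TRUE)[[1]]
  manual <- sort(unique(tolower(unlist(lapply(conds, function(cn) {
    ct <- parts$global$cond_targets[[cn]]
    unlist(ct[intersect(mem, names(ct))], use.names = FALSE)
  })))))
  expect_equal(mods$targets[[i]], manual)
  expect_equal(mods$n_targets[i], length(manual))
  # an unknown member errors
  fake <- mods
  fake$mirnas[[1]] <- c(fake$mirnas[[1]], "mir-xxx")
  expect_error(annotate_modules(fake, parts$global), "mir-xxx")
})
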