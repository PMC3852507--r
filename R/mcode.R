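# From-scratch MCODE: core decomposition, core-clustering-coefficient vertex
# weighting, greedy complex prediction and post-processing. Operates on the
# collapsed simple graph; condition multiplicity stays annotation.

#' k-core decomposition
#'
#' Core numbers by iterative minimum-degree peeling: a vertex has core number
#' k when it survives in the maximal subgraph of minimum degree k but not
#' k + 1.
#'
#' @param graph An undirected igraph graph (self-loops and multi-edges are
#'   collapsed first).
#' @return Named integer vector of core numbers (empty for the empty graph).
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' core_decomposition(g)   # all 3
#' @export
core_decomposition <- function(graph) {
  graph <- .as_simple(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) return(setNames(integer(0), character(0)))
  ids <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    # deterministic among ties: smallest id
    ties <- cand[deg[cand] == deg[v]]
    v <- ties[order(ids[ties])][1L]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  setNames(core, ids)
}

#' MCODE vertex weight (core clustering coefficient)
#'
#' The weight of vertex `v` is `k_max * density(H)` where `H` is the highest
#' k-core of the closed neighborhood `N[v]`, `k_max` its core level, and
#' density the loop-free `2E / (n (n - 1))`. Isolated vertices weigh 0.
#'
#' @param graph An undirected igraph graph.
#' @param v Vertex name (or index).
#' @return Non-negative weight.
#' @export
vertex_weight <- function(graph, v) {
  graph <- .as_simple(graph)
  if (is.character(v) && !v %in% igraph::V(graph)$name) {
    rlang::abort(sprintf("vertex '%s' is not in the graph.", v))
  }
  .vertex_weights(graph)[[if (is.character(v)) v else igraph::V(graph)$name[v]]]
}

# weights for all vertices at once (mcode needs them all anyway)
.vertex_weights <- function(graph) {
  ids <- igraph::V(graph)$name
  w <- setNames(numeric(length(ids)), ids)
  for (v in seq_along(ids)) {
    nb <- as.integer(igraph::neighbors(graph, v))
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    core <- core_decomposition(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    top <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    nn <- igraph::vcount(top)
    dens <- if (nn < 2L) 0 else 2 * igraph::ecount(top) / (nn * (nn - 1))
    w[v] <- kmax * dens
  }
  w
}

#' Extract cooperative miRNA modules (MCODE)
#'
#' Three stages on the simple graph: (1) vertex weighting by the core
#' clustering coefficient; (2) greedy complex prediction — seeds in
#' descending weight order, breadth-first expansion admitting unassigned
#' neighbors whose weight exceeds `seed_weight * (1 - vwp)`, each vertex in
#' at most one complex; (3) post-processing — complexes lacking a
#' `min_core`-core are dropped, `haircut` iteratively strips members of
#' induced degree < 2, and `fluff` (off by default) adds outside neighbors
#' whose closed-neighborhood density exceeds `fluff_density`. Complexes are
#' ranked by score = density x size. Ties anywhere are broken
#' lexicographically by vertex id, making runs reproducible.
#'
#' @param graph An undirected igraph graph (e.g. `simple_view` of a
#'   [merge_condition_mrans()] result, which may be passed directly).
#' @param vwp Vertex weight percentage in `[0, 1)`; default 0.2.
#' @param haircut,fluff Post-processing switches (defaults `TRUE`, `FALSE`).
#' @param fluff_density Density threshold for fluff (default 0.1).
#' @param min_core Minimum k-core a complex must contain (default 2).
#' @return A tibble of modules, one row per complex: `module_id`, `mirnas`
#'   (list column), `n_mirnas`, `n_links`, `density`, `score`, `seed_vertex`.
#' @export
mcode_complexes <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                            fluff_density = 0.1, min_core = 2L) {
  if (inherits(graph, "global_mran")) graph <- graph$simple_view
  if (inherits(graph, "condition_mran")) graph <- graph$graph
  graph <- .as_simple(graph)
  .check_number(vwp, "vwp", min = 0, max = 1, strict_max = TRUE)
  min_core <- .check_count(min_core, "min_core", min = 1L)
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (n == 0L) return(.empty_module_table())
  w <- .vertex_weights(graph)
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)

  order_v <- order(-w, ids)
  assigned <- rep(FALSE, n)
  complexes <- list()
  seeds <- character(0)
  for (s in order_v) {
    if (assigned[s]) next
    threshold <- w[s] * (1 - vwp)
    members <- s
    assigned[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nbs <- adj[[v]]
      nbs <- nbs[!assigned[nbs] & w[nbs] > threshold]
      nbs <- nbs[order(ids[nbs])]
      if (length(nbs)) {
        assigned[nbs] <- TRUE
        members <- c(members, nbs)
        queue <- c(queue, nbs)
      }
    }
    if (length(members) >= 2L) {
      complexes[[length(complexes) + 1L]] <- sort(ids[members])
      seeds <- c(seeds, ids[s])
    }
  }

  # post-processing
  keep_members <- list(); keep_seeds <- character(0)
  for (ci in seq_along(complexes)) {
    mem <- complexes[[ci]]
    sub <- igraph::induced_subgraph(graph, mem)
    core <- core_decomposition(sub)
    if (!length(core) || max(core) < min_core) next
    if (isTRUE(haircut)) {
      mem <- .haircut(graph, mem)
      if (length(mem) < 2L) next
    }
    if (isTRUE(fluff)) {
      outside <- setdiff(unique(ids[unlist(adj[match(mem, ids)], use.names = FALSE)]), mem)
      add <- outside[vapply(outside, function(u) {
        nb <- c(u, ids[adj[[match(u, ids)]]])
        subu <- igraph::induced_subgraph(graph, nb)
        nn <- igraph::vcount(subu)
        dens <- if (nn < 2L) 0 else 2 * igraph::ecount(subu) / (nn * (nn - 1))
        dens > fluff_density
      }, logical(1))]
      mem <- sort(unique(c(mem, add)))
    }
    keep_members[[length(keep_members) + 1L]] <- mem
    keep_seeds <- c(keep_seeds, seeds[ci])
  }
  if (!length(keep_members)) return(.empty_module_table())

  stats_ <- lapply(keep_members, function(mem) {
    sub <- igraph::induced_subgraph(graph, mem)
    nn <- igraph::vcount(sub)
    dens <- if (nn < 2L) 0 else 2 * igraph::ecount(sub) / (nn * (nn - 1))
    list(n = nn, links = igraph::ecount(sub), density = dens, score = dens * nn)
  })
  tb <- tibble::tibble(
    mirnas = keep_members,
    n_mirnas = vapply(stats_, function(s) s$n, numeric(1)),
    n_links = vapply(stats_, function(s) s$links, numeric(1)),
    density = vapply(stats_, function(s) s$density, numeric(1)),
    score = vapply(stats_, function(s) s$score, numeric(1)),
    seed_vertex = keep_seeds,
    first_member = vapply(keep_members, `[`, character(1), 1L)
  )
  tb <- dplyr::arrange(tb, dplyr::desc(.data$score), .data$first_member)
  tb$first_member <- NULL
  tb <- dplyr::mutate(tb, module_id = dplyr::row_number(), .before = 1L)
  class(tb) <- c("cmm_table", class(tb))
  tb
}

.haircut <- function(graph, members) {
  repeat {
    sub <- igraph::induced_subgraph(graph, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2L]
    if (!length(drop)) return(sort(members))
    members <- setdiff(members, drop)
    if (length(members) < 2L) return(members)
  }
}

.empty_module_table <- function() {
  tb <- tibble::tibble(module_id = integer(0), mirnas = list(),
                       n_mirnas = numeric(0), n_links = numeric(0),
                       density = numeric(0), score = numeric(0),
                       seed_vertex = character(0))
  class(tb) <- c("cmm_table", class(tb))
  tb
}

.as_simple <- function(graph) {
  if (!igraph::is_igraph(graph)) rlang::abort("expected an igraph graph.")
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph, mode = "collapse")
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  igraph::simplify(graph, edge.attr.comb = "first")
}
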