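# Shared fixture builders. The default simulation is computed once per test
# run and reused; everything is generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

default_simulation <- function(seed = 7L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(rng_seed = seed)
  }
  .fixture_env[[key]]
}

# condition networks + merged global for a simulation (cached per seed)
default_networks <- function(seed = 7L) {
  key <- paste0("nets", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- default_simulation(seed)
    nets <- lapply(sim$expression, function(e) {
      flt <- suppressMessages(inverse_pair_filter(e$mirna, e$mrna, sim$targets))
      build_condition_mran(flt)
    })
    .fixture_env[[key]] <- list(nets = unname(nets),
                                global = merge_condition_mrans(unname(nets)))
  }
  .fixture_env[[key]]
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# tiny expression matrix built directly (bypassing files)
toy_expression <- function(values, condition = "toy") {
  mircoop:::new_expression_matrix(condition, values)
}

toy_target_map <- function(pairs) {
  # pairs: named list mirna -> gene vector
  mircoop:::.new_target_map(rep(names(pairs), lengths(pairs)),
                            unlist(pairs, use.names = FALSE))
}

named_graph <- function(edges, isolated = character(0)) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolated)) g <- g + igraph::vertices(isolated)
  g
}
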