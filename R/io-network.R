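#' Write / read a miRNA association network
#'
#' Serializes a condition-specific or global MRAN. Two formats are supported:
#'
#' * `"edgelist"` — TSV with columns `source`, `target`, `t` (target overlap
#'   score), `p` (randomization p-value), `weight` (connection strength
#'   `1 - p`) and `conditions` (semicolon-joined condition labels). Isolated
#'   nodes are preserved in a `# nodes:` comment line so that
#'   write-then-read is the identity on the node set.
#' * `"graphml"` — GraphML through igraph, same attributes.
#'
#' @param net A `condition_mran`, `global_mran`, or plain igraph object with
#'   edge attributes `t`, `p`, `weight`, `conditions`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an igraph graph with the attributes restored.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) rlang::abort(
                       sprintf("unknown network format '%s'.", format[1L])))
  g <- as_mran_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  edges <- .edge_table(g)
  lines <- c(
    sprintf("# nodes: %s", paste(sort(igraph::V(g)$name), collapse = ";")),
    paste(c("source", "target", "t", "p", "weight", "conditions"), collapse = "\t")
  )
  if (nrow(edges)) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%.15g\t%.15g\t%.15g\t%s",
      edges$source, edges$target, edges$t, edges$p, edges$weight, edges$conditions
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) rlang::abort(
                       sprintf("unknown network format '%s'.", format[1L])))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(g)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  node_line <- lines[startsWith(lines, "# nodes:")]
  nodes <- character(0)
  if (length(node_line)) {
    spec <- trimws(sub("^# nodes:", "", node_line[1L]))
    if (nzchar(spec)) nodes <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) rlang::abort(sprintf("'%s' has no header line.", path))
  edges <- readr::read_tsv(I(paste(body, collapse = "\n")),
                           col_types = "ccdddc", progress = FALSE)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(unique(c(nodes, edges$source, edges$target))))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$source, edges$target),
                           t = edges$t, p = edges$p, weight = edges$weight,
                           conditions = edges$conditions)
  }
  g
}

# coerce the package's network containers to a plain attributed igraph
as_mran_igraph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  if (inherits(net, "condition_mran") || inherits(net, "global_mran")) return(net$graph)
  rlang::abort("expected a condition_mran, global_mran or igraph object.")
}

.edge_table <- function(g) {
  if (igraph::ecount(g) == 0L) {
    return(tibble::tibble(source = character(0), target = character(0),
                          t = numeric(0), p = numeric(0), weight = numeric(0),
                          conditions = character(0)))
  }
  ends <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  tb <- tibble::tibble(
    source = pmin(ends[, 1L], ends[, 2L]),
    target = pmax(ends[, 1L], ends[, 2L]),
    t = ea$t %||% rep(NA_real_, nrow(ends)),
    p = ea$p %||% rep(NA_real_, nrow(ends)),
    weight = ea$weight %||% rep(NA_real_, nrow(ends)),
    conditions = ea$conditions %||% rep("", nrow(ends))
  )
  dplyr::arrange(tb, .data$source, .data$target)
}
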