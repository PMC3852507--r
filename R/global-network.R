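#' Merge condition-specific networks into the global MRAN
#'
#' Takes the union of nodes and concatenates per-condition edge records; a
#' miRNA pair that co-operates in several conditions keeps one record per
#' condition (the multigraph view) while `simple_view` collapses each pair
#' to a single edge for module detection.
#'
#' @param nets A list of `condition_mran` objects (length >= 1).
#' @return A `global_mran`: list with `nodes`, `records` (tibble: `mirna_a`,
#'   `mirna_b`, `condition`, `t`, `p`, `weight`), `simple_view` (igraph; edge
#'   attributes hold the best — smallest-p — record plus the semicolon-joined
#'   condition list), `graph` (alias of `simple_view` used by the writers),
#'   and the per-condition `cond_targets`.
#' @export
merge_condition_mrans <- function(nets) {
  if (inherits(nets, "condition_mran")) nets <- list(nets)
  if (!is.list(nets) || !length(nets)) {
    rlang::abort("`nets` must be a non-empty list of condition_mran objects.")
  }
  ok <- vapply(nets, inherits, logical(1), "condition_mran")
  if (!all(ok)) rlang::abort("all elements of `nets` must be condition_mran objects.")
  conds <- vapply(nets, `[[`, character(1), "condition")
  if (anyDuplicated(conds)) rlang::abort("condition labels must be unique across networks.")

  records <- dplyr::bind_rows(lapply(nets, tidy))
  nodes <- sort(unique(unlist(lapply(nets, function(n) igraph::V(n$graph)$name))))

  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(records)) {
    collapsed <- records |>
      dplyr::group_by(.data$mirna_a, .data$mirna_b) |>
      dplyr::summarise(
        t = .data$t[which.min(.data$p)],
        p = min(.data$p),
        weight = max(.data$weight),
        conditions = paste(sort(unique(.data$condition)), collapse = ";"),
        .groups = "drop"
      )
    g <- igraph::add_edges(g, rbind(collapsed$mirna_a, collapsed$mirna_b),
                           t = collapsed$t, p = collapsed$p,
                           weight = collapsed$weight,
                           conditions = collapsed$conditions)
  }
  cond_targets <- setNames(lapply(nets, `[[`, "cond_targets"), conds)
  structure(
    list(nodes = nodes, records = records, simple_view = g, graph = g,
         conditions = conds, cond_targets = cond_targets),
    class = "global_mran"
  )
}

#' @export
print.global_mran <- function(x, ...) {
  cat(sprintf("<global_mran> %d conditions: %d miRNAs, %d connections (%d condition records)\n",
              length(x$conditions), length(x$nodes),
              igraph::ecount(x$simple_view), nrow(x$records)))
  invisible(x)
}

#' @describeIn merge_condition_mrans Per-condition edge records, one row per
#'   (pair, condition).
#' @param x A `global_mran`.
#' @param ... Unused.
#' @export
tidy.global_mran <- function(x, ...) {
  x$records
}

#' @describeIn merge_condition_mrans One-row network summary (miRNA count,
#'   connection count, per-condition record count).
#' @export
glance.global_mran <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$conditions),
    n_mirnas = length(x$nodes),
    n_connections = igraph::ecount(x$simple_view),
    n_condition_records = nrow(x$records)
  )
}

#' Annotate modules with link counts and condition-specific target unions
#'
#' Fills, for each extracted module, the number of intra-module links in the
#' global simple graph and the union of the members' condition-specific
#' target sets over every condition that contributes at least one
#' intra-module edge.
#'
#' @param cmms Module table from [mcode_complexes()].
#' @param global A `global_mran` (or the list of `condition_mran`s it was
#'   merged from).
#' @return The module table with `n_links`, `conditions`, `targets` (list
#'   column) and `n_targets` columns filled.
#' @export
annotate_modules <- function(cmms, global) {
  if (is.list(global) && !inherits(global, "global_mran")) {
    global <- merge_condition_mrans(global)
  }
  stopifnot(inherits(global, "global_mran"))
  if (!nrow(cmms)) {
    cmms$conditions <- character(0)
    cmms$targets <- list()
    cmms$n_targets <- numeric(0)
    return(cmms)
  }
  all_members <- unique(unlist(cmms$mirnas, use.names = FALSE))
  known <- unique(unlist(lapply(global$cond_targets, names), use.names = FALSE))
  orphan <- setdiff(all_members, known)
  if (length(orphan)) {
    rlang::abort(sprintf("module member(s) absent from every condition network: %s",
                         paste(orphan, collapse = ", ")))
  }
  rec <- global$records
  out <- lapply(seq_len(nrow(cmms)), function(i) {
    mem <- cmms$mirnas[[i]]
    intra <- rec[rec$mirna_a %in% mem & rec$mirna_b %in% mem, , drop = FALSE]
    conds <- sort(unique(intra$condition))
    targ <- character(0)
    for (cond in conds) {
      ct <- global$cond_targets[[cond]]
      targ <- c(targ, unlist(ct[intersect(mem, names(ct))], use.names = FALSE))
    }
    targ <- sort(unique(.norm_id(targ)))
    n_links <- nrow(dplyr::distinct(intra, .data$mirna_a, .data$mirna_b))
    list(conditions = paste(conds, collapse = ";"), targets = targ,
         n_targets = length(targ), n_links = n_links)
  })
  cmms$n_links <- vapply(out, `[[`, numeric(1), "n_links")
  cmms$conditions <- vapply(out, `[[`, character(1), "conditions")
  cmms$targets <- lapply(out, `[[`, "targets")
  cmms$n_targets <- vapply(out, `[[`, numeric(1), "n_targets")
  cmms
}

#' Module table in the published layout
#'
#' One row per module: id, number of miRNAs, number of links, number of
#' targets and the member list — the columns of the cooperative-module
#' summary table.
#'
#' @param x An annotated `cmm_table`.
#' @param ... Unused.
#' @export
tidy.cmm_table <- function(x, ...) {
  tb <- tibble::tibble(
    module_id = x$module_id,
    n_mirnas = x$n_mirnas,
    n_links = x$n_links,
    n_targets = if ("n_targets" %in% names(x)) x$n_targets else NA_real_,
    members = vapply(x$mirnas, paste, character(1), collapse = ";")
  )
  tb
}
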