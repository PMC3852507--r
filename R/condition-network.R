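#' Pearson correlation between two expression profiles
#'
#' Plain sample Pearson correlation, with explicit errors for the degenerate
#' inputs that silently produce `NA` in `stats::cor()`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_correlation(c(1, 2, 3), c(3, 2, 1))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) rlang::abort("correlation needs at least 3 paired samples.")
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values in expression vectors.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("undefined correlation: zero variance in at least one vector.")
  }
  stats::cor(x, y)
}

#' Filter static miRNA-target pairs by inverse co-expression
#'
#' Restricts the static target map to the pairs that behave like functional
#' miRNA-target interactions under one experimental condition: both members
#' measured, and Pearson correlation across the matched samples strictly
#' below `r_max` (default 0, i.e. `r < 0`). The retained genes per miRNA are
#' that miRNA's *condition-specific target set*; miRNAs left with no such
#' gene drop out of the condition's node set.
#'
#' @param mirna_expr,mrna_expr `expression_matrix` objects for the same
#'   condition. Samples are matched by column name; at least 3 shared
#'   columns are required.
#' @param targets A `target_map` (static sequence-based predictions).
#' @param r_max Correlation ceiling, must be `<= 0`; a pair is kept when
#'   `r < r_max`.
#' @param cor_alpha Optional significance level for a one-sided test of
#'   `r < 0` (stricter runs); `NULL` (default) applies the sign rule only.
#' @return A `coexpression_pairs` object: list with `condition`, `pairs`
#'   (tibble: `mirna_id`, `gene_id`, `r`, `n`), `cond_targets` (named list of
#'   retained gene sets per miRNA), `measured_genes` (genes present in
#'   `mrna_expr`, the default enrichment background), and skip counters.
#' @export
inverse_pair_filter <- function(mirna_expr, mrna_expr, targets,
                                r_max = 0, cor_alpha = NULL) {
  stopifnot(inherits(mirna_expr, "expression_matrix"),
            inherits(mrna_expr, "expression_matrix"),
            inherits(targets, "target_map"))
  .check_number(r_max, "r_max", max = 0)
  if (!is.null(cor_alpha)) .check_number(cor_alpha, "cor_alpha", min = 0, max = 1,
                                         strict_min = TRUE)
  shared <- intersect(mirna_expr$sample_ids, mrna_expr$sample_ids)
  if (length(shared) < 3L) {
    rlang::abort(sprintf(
      "no usable overlapping samples between miRNA and mRNA matrices (%d shared; need >= 3).",
      length(shared)
    ))
  }
  mi <- mirna_expr$values[, shared, drop = FALSE]
  mr <- mrna_expr$values[, shared, drop = FALSE]
  mi_idx <- setNames(seq_len(nrow(mi)), .norm_id(rownames(mi)))
  mr_idx <- setNames(seq_len(nrow(mr)), .norm_id(rownames(mr)))

  n_skipped <- 0L
  n_degenerate <- 0L
  out_mirna <- character(0); out_gene <- character(0); out_r <- numeric(0)
  for (m in names(targets$targets_of)) {
    mk <- .norm_id(m)
    if (is.na(mi_idx[mk])) {
      n_skipped <- n_skipped + length(targets$targets_of[[m]])
      next
    }
    x <- mi[mi_idx[[mk]], ]
    for (gene in targets$targets_of[[m]]) {
      gk <- .norm_id(gene)
      if (is.na(mr_idx[gk])) {
        n_skipped <- n_skipped + 1L
        next
      }
      y <- mr[mr_idx[[gk]], ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      r <- stats::cor(x, y)
      keep <- r < r_max
      if (keep && !is.null(cor_alpha)) {
        keep <- .cor_pvalue_less(r, length(shared)) < cor_alpha
      }
      if (keep) {
        out_mirna <- c(out_mirna, m)
        out_gene <- c(out_gene, gene)
        out_r <- c(out_r, r)
      }
    }
  }
  if (n_skipped + n_degenerate > 0L) {
    rlang::inform(sprintf(
      "inverse_pair_filter [%s]: skipped %d unmeasured and %d zero-variance pair(s).",
      mirna_expr$condition, n_skipped, n_degenerate
    ))
  }
  pairs <- tibble::tibble(mirna_id = out_mirna, gene_id = out_gene,
                          r = out_r, n = length(shared))
  cond_targets <- lapply(split(out_gene, factor(out_mirna, levels = unique(out_mirna))),
                         unique)
  structure(
    list(condition = mirna_expr$condition,
         pairs = pairs,
         cond_targets = cond_targets,
         measured_genes = rownames(mr),
         n_samples = length(shared),
         n_skipped = n_skipped,
         n_degenerate = n_degenerate),
    class = "coexpression_pairs"
  )
}

# one-sided p for H1: rho < 0, via the t transform of the sample correlation
.cor_pvalue_less <- function(r, n) {
  stat <- r * sqrt((n - 2) / (1 - r^2))
  stats::pt(stat, df = n - 2)
}

#' @export
print.coexpression_pairs <- function(x, ...) {
  cat(sprintf("<coexpression_pairs> condition '%s': %d miRNAs, %d genes, %d inverse pairs\n",
              x$condition, length(x$cond_targets),
              length(unique(x$pairs$gene_id)), nrow(x$pairs)))
  invisible(x)
}

#' Jaccard target-overlap score between two miRNAs
#'
#' The fraction of shared condition-specific targets,
#' `|A intersect B| / |A union B|`, with the convention that a miRNA scores 1
#' against itself. Both sets must be non-empty — miRNAs without retained
#' targets are dropped upstream by [inverse_pair_filter()].
#'
#' @param targets_i,targets_j Character vectors of gene ids.
#' @param same_mirna Set `TRUE` when both arguments belong to the same miRNA
#'   (the diagonal of the overlap matrix).
#' @return Overlap score in `[0, 1]`.
#' @examples
#' jaccard_overlap(c("A", "B", "C"), c("B", "C", "D"))
#' @export
jaccard_overlap <- function(targets_i, targets_j, same_mirna = FALSE) {
  if (length(targets_i) == 0L || length(targets_j) == 0L) {
    rlang::abort("empty target set: miRNAs without condition-specific targets are not scored.")
  }
  if (isTRUE(same_mirna)) return(1)
  a <- unique(.norm_id(targets_i))
  b <- unique(.norm_id(targets_j))
  length(intersect(a, b)) / length(union(a, b))
}

#' Significance of a target-set overlap
#'
#' Probability of an overlap at least as large as observed between two
#' target sets of fixed sizes drawn from the condition's target universe.
#' `method = "exact"` evaluates the closed-form hypergeometric tail, which is
#' the exhaustive randomization of set membership at fixed sizes;
#' `method = "permutation"` draws `n_perm` random set pairs of the same sizes
#' (without replacement) and reports the add-one Monte-Carlo estimate
#' `(hits + 1) / (n_perm + 1)`.
#'
#' @param size_i,size_j Sizes of the two condition-specific target sets.
#' @param overlap Observed intersection size.
#' @param universe Number of distinct genes in the condition's target
#'   universe (union of all condition-specific target sets).
#' @param method `"exact"` (default) or `"permutation"`.
#' @param n_perm Number of random draws for the permutation method.
#' @param rng_seed Seed for the permutation draws (reproducibility).
#' @return p-value in `(0, 1]`.
#' @examples
#' overlap_pvalue(4, 5, 3, 10)   # 66/252
#' @export
overlap_pvalue <- function(size_i, size_j, overlap, universe,
                           method = c("exact", "permutation"),
                           n_perm = 1000L, rng_seed = NULL) {
  method <- match.arg(method)
  size_i <- .check_count(size_i, "size_i", min = 1L)
  size_j <- .check_count(size_j, "size_j", min = 1L)
  overlap <- .check_count(overlap, "overlap")
  universe <- .check_count(universe, "universe", min = 1L)
  if (overlap > min(size_i, size_j)) {
    rlang::abort(sprintf("overlap %d exceeds the smaller set size %d.",
                         overlap, min(size_i, size_j)))
  }
  if (universe < size_i + size_j - overlap) {
    rlang::abort(sprintf(
      "universe %d cannot hold %d + %d genes with overlap %d.",
      universe, size_i, size_j, overlap
    ))
  }
  if (method == "exact") {
    return(hypergeom_tail(overlap, size_i, size_j, universe))
  }
  n_perm <- .check_count(n_perm, "n_perm", min = 1L)
  .with_seed(rng_seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      s1 <- sample.int(universe, size_i)
      s2 <- sample.int(universe, size_j)
      if (length(intersect(s1, s2)) >= overlap) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Build a condition-specific miRNA association network
#'
#' Scores every pair of miRNAs retained by [inverse_pair_filter()] with the
#' Jaccard overlap of their condition-specific target sets, attaches a
#' randomization p-value, and keeps edges with positive overlap and
#' `p < alpha_edge`. Edge weight (the adjacency entry) is the connection
#' strength `1 - p`.
#'
#' @param filtered A `coexpression_pairs` object from [inverse_pair_filter()].
#' @param alpha_edge Edge significance threshold, strict comparison
#'   (default 0.05, mirroring "p < 0.05").
#' @param sig_method,n_perm,rng_seed Passed to [overlap_pvalue()].
#' @return A `condition_mran`: list with `condition`, `graph` (igraph with
#'   edge attributes `t`, `p`, `weight`, `conditions`), `cond_targets`,
#'   `universe` (condition target universe), and `summary` counts.
#' @export
build_condition_mran <- function(filtered, alpha_edge = 0.05,
                                 sig_method = c("exact", "permutation"),
                                 n_perm = 1000L, rng_seed = NULL) {
  stopifnot(inherits(filtered, "coexpression_pairs"))
  .check_number(alpha_edge, "alpha_edge", min = 0, max = 1, strict_min = TRUE)
  sig_method <- match.arg(sig_method)
  cond_targets <- filtered$cond_targets[lengths(filtered$cond_targets) > 0L]
  nodes <- sort(names(cond_targets))
  universe <- unique(.norm_id(unlist(cond_targets, use.names = FALSE)))
  n_univ <- length(universe)

  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(nodes) < 2L) {
    rlang::warn(sprintf("condition '%s': fewer than 2 miRNAs with retained targets; edgeless network.",
                        filtered$condition))
  } else {
    sets <- lapply(cond_targets[nodes], function(x) unique(.norm_id(x)))
    from <- character(0); to <- character(0)
    tt <- numeric(0); pp <- numeric(0)
    for (i in seq_len(length(nodes) - 1L)) {
      si <- sets[[i]]
      for (j in seq((i + 1L), length(nodes))) {
        sj <- sets[[j]]
        ov <- length(intersect(si, sj))
        if (ov == 0L) next
        t_ij <- ov / length(union(si, sj))
        p_ij <- overlap_pvalue(length(si), length(sj), ov, n_univ,
                               method = sig_method, n_perm = n_perm,
                               rng_seed = if (is.null(rng_seed)) NULL
                                          else rng_seed + i * 10000L + j)
        if (p_ij < alpha_edge) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j])
          tt <- c(tt, t_ij); pp <- c(pp, p_ij)
        }
      }
    }
    if (length(from)) {
      g <- igraph::add_edges(g, rbind(from, to), t = tt, p = pp,
                             weight = 1 - pp, conditions = filtered$condition)
    }
  }
  structure(
    list(condition = filtered$condition,
         graph = g,
         cond_targets = cond_targets,
         universe = universe,
         alpha_edge = alpha_edge,
         summary = tibble::tibble(
           condition = filtered$condition,
           n_mirnas = length(nodes),
           n_genes = n_univ,
           n_pairs = nrow(filtered$pairs),
           n_edges = igraph::ecount(g)
         )),
    class = "condition_mran"
  )
}

#' @export
print.condition_mran <- function(x, ...) {
  cat(sprintf("<condition_mran> '%s': %d miRNAs, %d genes, %d edges (alpha = %g)\n",
              x$condition, igraph::vcount(x$graph), length(x$universe),
              igraph::ecount(x$graph), x$alpha_edge))
  invisible(x)
}

#' Tidy a condition network into its edge table
#'
#' @param x A `condition_mran`.
#' @param ... Unused.
#' @return One row per edge: `mirna_a`, `mirna_b`, `t`, `p`, `weight`,
#'   `condition`.
#' @export
tidy.condition_mran <- function(x, ...) {
  et <- .edge_table(x$graph)
  tibble::tibble(mirna_a = et$source, mirna_b = et$target,
                 t = et$t, p = et$p, weight = et$weight,
                 condition = x$condition)
}

#' One-row summary of a condition network
#'
#' Mirrors the per-condition inverse-expression distribution table: numbers
#' of miRNAs, genes, miRNA-gene pairs, plus the edge count.
#'
#' @param x A `condition_mran`.
#' @param ... Unused.
#' @export
glance.condition_mran <- function(x, ...) {
  x$summary
}
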