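#' Transcription-factor motif co-occurrence on a miRNA scope
#'
#' Tests every unordered pair of motifs present in `scope` for
#' over-represented co-occurrence: with `m1` and `m2` carriers of the two
#' motifs among the `N = |scope|` miRNAs and `c_obs` co-carriers, the
#' p-value is the cumulative hypergeometric tail [hypergeom_tail()].
#' Bonferroni correction multiplies by the number of tested pairs (recorded
#' in the output for auditability).
#'
#' @param ann A `motif_annotation`.
#' @param scope Character vector of miRNA ids defining the test universe
#'   (typically one condition's network nodes). Must be annotated miRNAs.
#' @param alpha Significance threshold on the (corrected) p-value; default
#'   `1e-5` with Bonferroni, the published regime.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param condition Optional condition label carried into the result.
#' @return A tibble of significant pairs: `motif_a`, `motif_b`, `m1`, `m2`,
#'   `c_obs`, `N`, `p`, `p_bonferroni`, `condition`, with attributes
#'   `n_tested` (Bonferroni denominator) and `n_scope`.
#' @export
motif_cooccurrence <- function(ann, scope, alpha = 1e-5,
                               correction = c("bonferroni", "none"),
                               condition = NA_character_) {
  stopifnot(inherits(ann, "motif_annotation"))
  correction <- match.arg(correction)
  .check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  scope <- unique(scope)
  if (length(scope) < 2L) rlang::abort("co-occurrence needs a scope of at least 2 miRNAs.")
  keys <- .norm_id(names(ann$motifs_of))
  idx <- match(.norm_id(scope), keys)
  if (anyNA(idx)) {
    rlang::abort(sprintf("scope miRNA(s) missing from the annotation: %s",
                         paste(scope[is.na(idx)], collapse = ", ")))
  }
  N <- length(scope)
  carriers <- list()
  for (k in seq_along(scope)) {
    for (motif in ann$motifs_of[[idx[k]]]) {
      carriers[[motif]] <- c(carriers[[motif]], k)
    }
  }
  motifs <- sort(names(carriers))
  if (length(motifs) < 2L) {
    res <- .empty_cooccurrence(condition)
    attr(res, "n_tested") <- 0L
    attr(res, "n_scope") <- N
    return(res)
  }
  combos <- utils::combn(motifs, 2L)
  n_tested <- ncol(combos)
  rows <- vector("list", n_tested)
  for (q in seq_len(n_tested)) {
    a <- combos[1L, q]; b <- combos[2L, q]
    ca <- carriers[[a]]; cb <- carriers[[b]]
    c_obs <- length(intersect(ca, cb))
    p <- hypergeom_tail(c_obs, length(ca), length(cb), N)
    rows[[q]] <- tibble::tibble(
      motif_a = a, motif_b = b,
      m1 = length(ca), m2 = length(cb), c_obs = c_obs, N = N,
      p = p, p_bonferroni = min(1, p * n_tested),
      condition = condition
    )
  }
  res <- dplyr::bind_rows(rows)
  keep <- if (correction == "bonferroni") res$p_bonferroni < alpha else res$p < alpha
  res <- dplyr::arrange(res[keep, , drop = FALSE], .data$p, .data$motif_a, .data$motif_b)
  attr(res, "n_tested") <- n_tested
  attr(res, "n_scope") <- N
  res
}

.empty_cooccurrence <- function(condition = NA_character_) {
  tibble::tibble(motif_a = character(0), motif_b = character(0),
                 m1 = integer(0), m2 = integer(0), c_obs = integer(0),
                 N = integer(0), p = numeric(0), p_bonferroni = numeric(0),
                 condition = character(0))
}

#' Pathway enrichment of a module's target genes
#'
#' Upper-tail hypergeometric test per pathway: the probability of drawing at
#' least `k` pathway genes when the module's `n` target genes are drawn from
#' a background of `N_bg` genes containing `K` pathway members. The
#' published regime is uncorrected `p < 0.05`; all cells are returned with a
#' significance flag so heat maps can show the full landscape.
#'
#' @param genes Character vector of module target genes (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe, by default the
#'   genes measured in the contributing condition's mRNA matrix.
#' @param sets A `gene_set_collection`.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param module_id Optional label carried into the result.
#' @return A tibble with one row per pathway overlapping the background:
#'   `module_id`, `pathway_id`, `k`, `K`, `n`, `N_bg`, `p`, `neglog10p`,
#'   `significant`; attribute `n_skipped` counts pathways with no background
#'   overlap.
#' @export
pathway_enrichment <- function(genes, background, sets, alpha = 0.05,
                               module_id = NA_character_) {
  stopifnot(inherits(sets, "gene_set_collection"))
  .check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  background <- unique(.norm_id(background))
  if (!length(background)) rlang::abort("empty background gene universe.")
  genes <- unique(.norm_id(genes))
  stray <- setdiff(genes, background)
  if (length(stray)) {
    rlang::abort(sprintf("%d module target gene(s) are not in the background (e.g. %s).",
                         length(stray), stray[1L]))
  }
  N_bg <- length(background)
  n <- length(genes)
  rows <- list(); n_skipped <- 0L
  for (pid in names(sets$sets)) {
    members <- intersect(unique(.norm_id(sets$sets[[pid]])), background)
    K <- length(members)
    if (K == 0L) { n_skipped <- n_skipped + 1L; next }
    k <- length(intersect(genes, members))
    p <- hypergeom_tail(k, K, n, N_bg)
    rows[[pid]] <- tibble::tibble(
      module_id = as.character(module_id), pathway_id = pid,
      k = k, K = K, n = n, N_bg = N_bg,
      p = p, neglog10p = -log10(p), significant = p < alpha
    )
  }
  if (n_skipped > 0L) {
    rlang::inform(sprintf("pathway_enrichment: %d pathway(s) without background overlap skipped.",
                          n_skipped))
  }
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) {
    res <- tibble::tibble(module_id = character(0), pathway_id = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N_bg = integer(0), p = numeric(0),
                          neglog10p = numeric(0), significant = logical(0))
  }
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("enrichment_table", class(res))
  res
}

#' Modules-by-pathways significance matrix
#'
#' Arranges enrichment cells into a modules x pathways matrix of
#' `-log10(p)`. Modules and pathways without a single significant cell are
#' omitted, mirroring the heat-map convention that unmapped rows/columns are
#' dropped.
#'
#' @param cells Enrichment tibble(s) from [pathway_enrichment()] — rows from
#'   several modules may be bound together.
#' @return Numeric matrix (modules x pathways); 0 x 0 when nothing is
#'   significant.
#' @export
enrichment_matrix <- function(cells) {
  if (!nrow(cells)) return(matrix(numeric(0), 0L, 0L))
  keep_mod <- unique(cells$module_id[cells$significant])
  keep_path <- unique(cells$pathway_id[cells$significant])
  sub <- cells[cells$module_id %in% keep_mod & cells$pathway_id %in% keep_path, , drop = FALSE]
  if (!nrow(sub)) return(matrix(numeric(0), 0L, 0L))
  wide <- tidyr::pivot_wider(
    sub[, c("module_id", "pathway_id", "neglog10p")],
    names_from = "pathway_id", values_from = "neglog10p", values_fill = 0
  )
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$module_id
  m
}

#' Heat map of module pathway enrichment
#'
#' @param object An `enrichment_table` from [pathway_enrichment()].
#' @param ... Unused.
#' @return A ggplot object: modules x pathways tiles coloured by
#'   `-log10(p)`, significant cells outlined.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway_id, y = .data$module_id,
                                   fill = .data$neglog10p)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$significant), linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "#3b4cc0", high = "#b40426",
                                 name = expression(-log[10](p))) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(x = "pathway", y = "module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
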