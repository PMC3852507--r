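#' Within- vs between-module similarity of hairpin features
#'
#' The similarity analysis behind the "are cooperating miRNAs alike?"
#' question: pools pairwise similarity scores over all member pairs *within*
#' modules, over pairs *between* different modules, and over *random* pairs
#' of records, then tests (one-sided rank-sum) whether within-module pairs
#' are more similar.
#'
#' Layers: `seed`, `mature` and `precursor_seq` score pairs by
#' [pairwise_identity()]; `precursor_struct` scores by
#' [tree_edit_distance()] negated into a similarity so that "greater
#' similarity" is a single test direction across all layers.
#'
#' @param cmms Module table from [mcode_complexes()] (or a list of character
#'   vectors of member ids).
#' @param records Named list of `hairpin_record` objects covering every
#'   module member.
#' @param layer One of `"seed"`, `"mature"`, `"precursor_seq"`,
#'   `"precursor_struct"`.
#' @param n_random_pairs Cap on the between-module pair sample (the full set
#'   is used when smaller); the random baseline always matches the
#'   within-module pair count.
#' @param rng_seed Seed for the two subsampling steps.
#' @param seed_window Length-2 window for the `seed` layer (default
#'   `c(2, 8)`).
#' @return A `similarity_comparison`: list with `layer`, score vectors
#'   `within`, `between`, `random`, and `p_within_vs_between`,
#'   `p_within_vs_random` (one-sided, within more similar;
#'   `p_within_vs_between` is `NA` with a single module).
#' @export
compare_similarity_distributions <- function(cmms, records,
                                             layer = c("seed", "mature",
                                                       "precursor_seq",
                                                       "precursor_struct"),
                                             n_random_pairs = 200L,
                                             rng_seed = NULL,
                                             seed_window = c(2L, 8L)) {
  layer <- match.arg(layer)
  n_random_pairs <- .check_count(n_random_pairs, "n_random_pairs", min = 1L)
  groups <- .module_member_list(cmms)
  if (!length(groups)) rlang::abort("no modules supplied.")
  if (!length(records)) rlang::abort("no hairpin records supplied.")
  members <- unique(unlist(groups, use.names = FALSE))
  rec_keys <- .norm_id(names(records))
  miss <- members[!.norm_id(members) %in% rec_keys]
  if (length(miss)) {
    rlang::abort(sprintf("module member(s) without a hairpin record: %s",
                         paste(miss, collapse = ", ")))
  }

  feats <- .layer_features(records, layer, seed_window)
  score_pair <- function(a, b) {
    fa <- feats[[.norm_id(a)]]; fb <- feats[[.norm_id(b)]]
    if (layer == "precursor_struct") -tree_edit_distance(fa, fb)
    else pairwise_identity(fa, fb)
  }

  within_pairs <- list()
  for (g in groups) {
    g <- unique(g)
    if (length(g) < 2L) next
    cmb <- utils::combn(sort(g), 2L)
    within_pairs <- c(within_pairs, lapply(seq_len(ncol(cmb)), function(q) cmb[, q]))
  }
  if (!length(within_pairs)) rlang::abort("no module has >= 2 members to compare.")

  between_pairs <- list()
  if (length(groups) >= 2L) {
    gi <- utils::combn(seq_along(groups), 2L)
    for (q in seq_len(ncol(gi))) {
      a <- unique(groups[[gi[1L, q]]]); b <- unique(groups[[gi[2L, q]]])
      grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      # a member shared by both modules is not a cross-module pair
      grid <- grid[.norm_id(grid$a) != .norm_id(grid$b), , drop = FALSE]
      between_pairs <- c(between_pairs,
                         lapply(seq_len(nrow(grid)),
                                function(r) c(grid$a[r], grid$b[r])))
    }
  }

  .with_seed(rng_seed, {
    if (length(between_pairs) > n_random_pairs) {
      between_pairs <- between_pairs[sort(sample.int(length(between_pairs), n_random_pairs))]
    }
    all_ids <- names(records)
    random_pairs <- lapply(seq_along(within_pairs), function(q) {
      all_ids[sample.int(length(all_ids), 2L)]
    })
    within <- vapply(within_pairs, function(pr) score_pair(pr[1L], pr[2L]), numeric(1))
    between <- if (length(between_pairs)) {
      vapply(between_pairs, function(pr) score_pair(pr[1L], pr[2L]), numeric(1))
    } else numeric(0)
    random <- vapply(random_pairs, function(pr) score_pair(pr[1L], pr[2L]), numeric(1))
    structure(
      list(layer = layer,
           within = within, between = between, random = random,
           p_within_vs_between = if (length(between)) {
             ranksum_test(within, between, alternative = "greater")
           } else NA_real_,
           p_within_vs_random = ranksum_test(within, random, alternative = "greater")),
      class = "similarity_comparison"
    )
  })
}

.module_member_list <- function(cmms) {
  if (is.data.frame(cmms)) {
    if (!"mirnas" %in% names(cmms)) rlang::abort("module table lacks a `mirnas` column.")
    return(cmms$mirnas)
  }
  if (is.list(cmms)) return(cmms)
  rlang::abort("`cmms` must be a module table or a list of member vectors.")
}

.layer_features <- function(records, layer, seed_window) {
  feats <- lapply(records, function(rec) {
    switch(layer,
      seed = extract_seed(rec$mature_seq, seed_window[1L], seed_window[2L]),
      mature = rec$mature_seq,
      precursor_seq = rec$precursor_seq,
      precursor_struct = parse_dotbracket(rec$precursor_struct)
    )
  })
  setNames(feats, .norm_id(names(records)))
}

#' @export
print.similarity_comparison <- function(x, ...) {
  cat(sprintf("<similarity_comparison> layer '%s': %d within / %d between / %d random pairs\n",
              x$layer, length(x$within), length(x$between), length(x$random)))
  cat(sprintf("  within vs between: p = %s\n",
              format(x$p_within_vs_between, digits = 4)))
  cat(sprintf("  within vs random:  p = %s\n",
              format(x$p_within_vs_random, digits = 4)))
  invisible(x)
}

#' @export
tidy.similarity_comparison <- function(x, ...) {
  tibble::tibble(
    layer = x$layer,
    comparison = rep(c("within", "between", "random"),
                     c(length(x$within), length(x$between), length(x$random))),
    score = c(x$within, x$between, x$random)
  )
}

#' @export
autoplot.similarity_comparison <- function(object, ...) {
  df <- tidy(object)
  df$comparison <- factor(df$comparison, levels = c("within", "between", "random"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.7) +
    ggplot2::labs(title = sprintf("layer: %s", object$layer),
                  y = if (object$layer == "precursor_struct")
                        "similarity (-tree edit distance)" else "alignment identity",
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Similarity report across all layers (and species)
#'
#' Runs [compare_similarity_distributions()] for the four layers — seed,
#' mature, precursor sequence, precursor structure — and assembles the
#' published four-row comparison table. When `by_species = TRUE` and ids
#' carry a species prefix (`hsa-`, `mmu-`, ...), each species is analyzed
#' separately.
#'
#' @inheritParams compare_similarity_distributions
#' @param by_species Split records by the 3-letter dash-separated prefix of
#'   the miRNA id when at least two prefixes are present.
#' @return A `similarity_report` tibble: one row per layer (x species):
#'   `layer`, `species`, pair counts and the two one-sided p-values.
#'   Attribute `comparisons` keeps the per-layer score vectors.
#' @export
similarity_report <- function(cmms, records, n_random_pairs = 200L,
                              rng_seed = NULL, seed_window = c(2L, 8L),
                              by_species = FALSE) {
  groups <- .module_member_list(cmms)
  layers <- c("seed", "mature", "precursor_seq", "precursor_struct")
  splits <- list(pooled = list(groups = groups, records = records))
  if (isTRUE(by_species)) {
    prefix <- function(ids) ifelse(grepl("^[A-Za-z]{3}-", ids),
                                   tolower(substr(ids, 1L, 3L)), "unknown")
    sp <- prefix(names(records))
    if (length(unique(sp)) >= 2L) {
      splits <- lapply(setNames(nm = sort(unique(sp))), function(s) {
        recs <- records[sp == s]
        grps <- lapply(groups, function(g) g[.norm_id(g) %in% .norm_id(names(recs))])
        list(groups = grps[vapply(grps, length, integer(1)) >= 2L], records = recs)
      })
      splits <- splits[vapply(splits, function(x) length(x$groups) > 0L, logical(1))]
    }
  }
  rows <- list(); comparisons <- list()
  for (species in names(splits)) {
    sl <- splits[[species]]
    for (layer in layers) {
      cmp <- compare_similarity_distributions(
        sl$groups, sl$records, layer = layer,
        n_random_pairs = n_random_pairs, rng_seed = rng_seed,
        seed_window = seed_window
      )
      comparisons[[paste(species, layer, sep = ".")]] <- cmp
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = layer, species = species,
        n_within = length(cmp$within), n_between = length(cmp$between),
        n_random = length(cmp$random),
        p_within_vs_between = cmp$p_within_vs_between,
        p_within_vs_random = cmp$p_within_vs_random
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "comparisons") <- comparisons
  class(out) <- c("similarity_report", class(out))
  out
}

#' @export
autoplot.similarity_report <- function(object, ...) {
  cmps <- attr(object, "comparisons")
  df <- dplyr::bind_rows(lapply(cmps, tidy), .id = "panel")
  df$comparison <- factor(df$comparison, levels = c("within", "between", "random"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "similarity") +
    ggplot2::theme_minimal()
}
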