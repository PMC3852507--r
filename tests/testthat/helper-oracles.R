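# Independent oracles used to freeze expected values. Each deliberately
# takes a different route from the implementation it checks: exhaustive
# enumeration instead of closed forms or dynamic programs.

# hypergeometric tail by enumerating every placement of the second set
brute_hypergeom_tail <- function(c_obs, m1, m2, N) {
  draws <- utils::combn(N, m2)
  overlaps <- colSums(draws <= m1)
  mean(overlaps >= c_obs)
}

# core numbers by maximal-subgraph search: core(v) = max over vertex subsets
# containing v of the induced minimum degree
brute_core_numbers <- function(adj) {
  n <- nrow(adj)
  core <- setNames(integer(n), rownames(adj))
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size)
    for (q in seq_len(ncol(subsets))) {
      s <- subsets[, q]
      sub <- adj[s, s, drop = FALSE]
      mindeg <- min(rowSums(sub))
      core[s] <- pmax(core[s], mindeg)
    }
  }
  core
}

# ordered forests as lists of trees; a tree is list(label=, children=list)
dotbracket_to_forest <- function(struct) {
  chars <- strsplit(struct, "", fixed = TRUE)[[1L]]
  parse_forest <- function(pos) {
    forest <- list()
    while (pos <= length(chars) && chars[pos] != ")") {
      if (chars[pos] == ".") {
        forest[[length(forest) + 1L]] <- list(label = "U", children = list())
        pos <- pos + 1L
      } else {
        inner <- parse_forest(pos + 1L)
        forest[[length(forest) + 1L]] <- list(label = "P", children = inner$forest)
        pos <- inner$pos + 1L # skip ')'
      }
    }
    list(forest = forest, pos = pos)
  }
  parse_forest(1L)$forest
}

forest_size <- function(f) {
  if (!length(f)) return(0L)
  sum(vapply(f, function(t) 1L + forest_size(t$children), integer(1)))
}

# recursive ordered-forest edit distance, working directly on dot-bracket
# strings: a forest IS a balanced string, and deleting the root of the
# rightmost tree splices its children string in place, so every subproblem
# is again a pair of balanced strings. Decomposes on the *rightmost* tree
# (the Zhang-Shasha implementation works from leftmost leaves and keyroots)
# and memoizes on the string pair; caching does not change any value.
.forest_memo <- new.env(parent = emptyenv())

forest_nodes <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(chars != ")")
}

# split "alpha T" into alpha, T's children string and T's label
split_last_tree <- function(s) {
  n <- nchar(s)
  if (substr(s, n, n) == ".") {
    return(list(rest = substr(s, 1L, n - 1L), children = "", label = "U"))
  }
  depth <- 0L
  for (m in n:1) {
    ch <- substr(s, m, m)
    if (ch == ")") depth <- depth + 1L else if (ch == "(") depth <- depth - 1L
    if (depth == 0L) break
  }
  list(rest = substr(s, 1L, m - 1L),
       children = substr(s, m + 1L, n - 1L), label = "P")
}

naive_forest_dist <- function(a, b) {
  if (!nchar(a)) return(forest_nodes(b))
  if (!nchar(b)) return(forest_nodes(a))
  key <- paste(a, b, sep = "|")
  hit <- .forest_memo[[key]]
  if (!is.null(hit)) return(hit)
  ta <- split_last_tree(a)
  tb <- split_last_tree(b)
  del <- naive_forest_dist(paste0(ta$rest, ta$children), b) + 1
  ins <- naive_forest_dist(a, paste0(tb$rest, tb$children)) + 1
  rel <- naive_forest_dist(ta$rest, tb$rest) +
    naive_forest_dist(ta$children, tb$children) +
    (if (ta$label == tb$label) 0 else 1)
  out <- min(del, ins, rel)
  .forest_memo[[key]] <- out
  out
}

# tree edit distance between two dot-brackets with the virtual root added
# the virtual roots carry the same label, so mapping root to root is free
# and the tree distance reduces to the forest distance of the two strings
naive_tree_dist <- function(s1, s2) {
  naive_forest_dist(s1, s2)
}

# every balanced dot-bracket string (over lengths 0..max_len) whose tree has
# at most max_nodes nodes including the virtual root
all_small_structures <- function(max_len = 7L, max_nodes = 6L) {
  out <- character(0)
  gen <- function(prefix, open) {
    if (nchar(prefix) <= max_len && open == 0L) out <<- c(out, prefix)
    if (nchar(prefix) >= max_len) return()
    gen(paste0(prefix, "."), open)
    gen(paste0(prefix, "("), open + 1L)
    if (open > 0L) gen(paste0(prefix, ")"), open - 1L)
  }
  gen("", 0L)
  out <- unique(out[nzchar(out)])
  keep <- vapply(out, function(s) {
    forest_size(dotbracket_to_forest(s)) + 1L <= max_nodes
  }, logical(1))
  out[keep]
}

# maximum base pairs by explicit enumeration of all nested pair sets
can_pair_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

enumerate_max_pairs <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (i >= j || j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j) # i unpaired
    for (k in seq(i + min_loop + 1L, j)) {
      if (!can_pair_rna(chars[i], chars[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(chars))
}

count_pairs <- function(db) sum(strsplit(db, "", fixed = TRUE)[[1L]] == "(")

# exact rank-sum p-values by enumerating every rank assignment
enumerate_ranksum <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  subsets <- utils::combn(n + m, n)
  us <- colSums(matrix(seq_len(n + m)[subsets], nrow = n)) - n * (n + 1) / 2
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

# all global alignments of a and b, returning the identities achieved by
# score-optimal ones
optimal_alignment_identities <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  sa <- strsplit(a, "", fixed = TRUE)[[1L]]
  sb <- strsplit(b, "", fixed = TRUE)[[1L]]
  results <- list()
  rec <- function(i, j, score, matches, len) {
    if (i > length(sa) && j > length(sb)) {
      results[[length(results) + 1L]] <<- c(score, matches, len)
      return()
    }
    if (i <= length(sa) && j <= length(sb)) {
      hit <- sa[i] == sb[j]
      rec(i + 1L, j + 1L, score + if (hit) match else mismatch,
          matches + hit, len + 1L)
    }
    if (i <= length(sa)) rec(i + 1L, j, score + gap, matches, len + 1L)
    if (j <= length(sb)) rec(i, j + 1L, score + gap, matches, len + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  m <- do.call(rbind, results)
  best <- max(m[, 1L])
  unique(m[m[, 1L] == best, 2L] / m[m[, 1L] == best, 3L])
}

# random simple graph helper (adjacency + igraph) for the core-number suite
random_graph_pair <- function(n, p) {
  adj <- matrix(0L, n, n, dimnames = list(letters[seq_len(n)], letters[seq_len(n)]))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g)
}
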