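#' Parse a dot-bracket structure
#'
#' Stack-parses a balanced dot-bracket string into (a) the set of base pairs
#' `(i, j)` (1-based, `i < j`) and (b) an ordered rooted tree in which each
#' internal node is a base pair, each leaf an unpaired position, and the
#' root is virtual. The tree is stored in the postorder arrays consumed by
#' the tree-edit-distance dynamic program.
#'
#' @param struct Dot-bracket string over `(`, `)`, `.`.
#' @return A `structure_tree`: list with `dotbracket`, `pairs` (two-column
#'   matrix), `n_nodes`, and postorder arrays `labels` (`"P"`, `"U"`, `"R"`)
#'   and `lml` (leftmost-leaf index per node).
#' @examples
#' parse_dotbracket("((..))")$pairs
#' @export
parse_dotbracket <- function(struct) {
  .check_string(struct, "struct")
  chars <- strsplit(struct, "", fixed = TRUE)[[1L]]
  bad <- .dotbracket_balance(struct)
  if (!is.null(bad)) {
    rlang::abort(sprintf("unbalanced dot-bracket at position %d.", bad))
  }
  n <- length(chars)
  # children[[k]] lists the child node ids of node k; node 1 is the root
  children <- list(integer(0))
  labels <- "R"
  open_node <- integer(0)   # stack of open pair node ids
  open_pos <- integer(0)    # stack of their '(' positions
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (pos in seq_len(n)) {
    ch <- chars[pos]
    parent <- if (length(open_node)) open_node[length(open_node)] else 1L
    if (ch == "(") {
      id <- length(children) + 1L
      children[[id]] <- integer(0)
      labels[id] <- "P"
      children[[parent]] <- c(children[[parent]], id)
      open_node <- c(open_node, id)
      open_pos <- c(open_pos, pos)
    } else if (ch == ")") {
      k <- length(open_node)
      pairs_i <- c(pairs_i, open_pos[k])
      pairs_j <- c(pairs_j, pos)
      open_node <- open_node[-k]
      open_pos <- open_pos[-k]
    } else {
      id <- length(children) + 1L
      children[[id]] <- integer(0)
      labels[id] <- "U"
      children[[parent]] <- c(children[[parent]], id)
    }
  }
  post <- .postorder(children, labels)
  pairs <- cbind(i = pairs_i, j = pairs_j)
  pairs <- pairs[order(pairs_i), , drop = FALSE]
  structure(
    list(dotbracket = struct, pairs = pairs,
         n_nodes = length(labels),
         labels = post$labels, lml = post$lml),
    class = "structure_tree"
  )
}

# iterative postorder over the child lists, with leftmost-leaf bookkeeping
.postorder <- function(children, labels) {
  n <- length(children)
  post_labels <- character(n)
  lml <- integer(n)
  post_of <- integer(n)
  counter <- 0L
  # explicit stack: (node, child cursor)
  stack_node <- 1L
  stack_cursor <- 0L
  depth <- 1L
  while (depth > 0L) {
    v <- stack_node[depth]
    cur <- stack_cursor[depth] + 1L
    kids <- children[[v]]
    if (cur <= length(kids)) {
      stack_cursor[depth] <- cur
      depth <- depth + 1L
      stack_node[depth] <- kids[cur]
      stack_cursor[depth] <- 0L
    } else {
      counter <- counter + 1L
      post_of[v] <- counter
      post_labels[counter] <- labels[v]
      lml[counter] <- if (length(kids)) lml[post_of[kids[1L]]] else counter
      depth <- depth - 1L
    }
  }
  list(labels = post_labels, lml = lml)
}

#' @export
print.structure_tree <- function(x, ...) {
  cat(sprintf("<structure_tree> %s (%d pairs, %d nodes)\n",
              x$dotbracket, nrow(x$pairs), x$n_nodes))
  invisible(x)
}

#' Base-pair distance between two equal-length structures
#'
#' Size of the symmetric difference of the two base-pair sets — the fast
#' comparison for structures on the same sequence length.
#'
#' @param s1,s2 Dot-bracket strings of equal length (or `structure_tree`
#'   objects).
#' @return Non-negative integer count.
#' @examples
#' base_pair_distance("((..))", "(....)")
#' @export
base_pair_distance <- function(s1, s2) {
  t1 <- if (inherits(s1, "structure_tree")) s1 else parse_dotbracket(s1)
  t2 <- if (inherits(s2, "structure_tree")) s2 else parse_dotbracket(s2)
  if (nchar(t1$dotbracket) != nchar(t2$dotbracket)) {
    rlang::abort("structures differ in length; use tree_edit_distance() instead.")
  }
  k1 <- paste(t1$pairs[, 1L], t1$pairs[, 2L])
  k2 <- paste(t2$pairs[, 1L], t2$pairs[, 2L])
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Ordered tree edit distance between secondary structures
#'
#' Minimum-cost edit script (insert, delete, relabel; unit costs, where
#' relabelling a pair node to an unpaired leaf costs 1) between the ordered
#' structure trees, computed with the Zhang-Shasha keyroot dynamic program.
#' Zero iff the trees are identical; symmetric; satisfies the triangle
#' inequality.
#'
#' @param t1,t2 `structure_tree` objects or dot-bracket strings.
#' @return Non-negative distance.
#' @examples
#' tree_edit_distance("((..))", "(....)")   # 3
#' @export
tree_edit_distance <- function(t1, t2) {
  t1 <- if (inherits(t1, "structure_tree")) t1 else parse_dotbracket(t1)
  t2 <- if (inherits(t2, "structure_tree")) t2 else parse_dotbracket(t2)
  code <- c(U = 0L, P = 1L, R = 2L)
  ted_cpp(code[t1$labels], t1$lml, code[t2$labels], t2$lml)
}

#' Fold an RNA sequence by base-pair maximization
#'
#' Classic Nussinov dynamic program: finds a nested structure with the
#' maximum number of Watson-Crick or GU-wobble pairs subject to a minimum
#' hairpin loop of `min_loop` unpaired bases. The traceback is
#' deterministic (prefer pairing the left end, leftmost optimal partner),
#' so folds are reproducible. Used to give synthetic precursors a secondary
#' structure; it is a combinatorial folder, not an energy model.
#'
#' @param seq RNA string (A/C/G/U; T transliterated).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return Dot-bracket string of the same length.
#' @examples
#' nussinov_fold("GCGAAACGC")   # "(((...)))"
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  .check_string(seq, "seq")
  min_loop <- .check_count(min_loop, "min_loop")
  seq <- chartr("T", "U", toupper(seq))
  if (grepl("[^ACGU]", seq)) {
    rlang::abort("sequence contains non-RNA characters.")
  }
  nussinov_cpp(seq, min_loop)
}
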