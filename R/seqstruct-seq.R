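#' Extract the seed region of a mature miRNA
#'
#' The seed is the primary target-recognition element of a mature miRNA,
#' canonically residues 2-8, but shifted windows (1-7, 4-10) occur; the
#' window is therefore a parameter.
#'
#' @param mature_seq Mature miRNA sequence.
#' @param start,end 1-based inclusive window (defaults 2 and 8).
#' @return The seed substring.
#' @examples
#' extract_seed("ACGUACGUACGUACGUACGUAC")        # residues 2-8
#' extract_seed("ACGUACGUACGUACGUACGUAC", 1, 7)
#' @export
extract_seed <- function(mature_seq, start = 2L, end = 8L) {
  .check_string(mature_seq, "mature_seq")
  start <- .check_count(start, "start", min = 1L)
  end <- .check_count(end, "end", min = 1L)
  if (start > end) rlang::abort("`start` must not exceed `end`.")
  if (end > nchar(mature_seq)) {
    rlang::abort(sprintf("seed window [%d, %d] exceeds the mature sequence (length %d).",
                         start, end, nchar(mature_seq)))
  }
  substr(mature_seq, start, end)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match score `match`, mismatch
#' score `mismatch` and linear gap penalty `gap` (defaults 1 / 0 / -1);
#' identity is the number of matched columns divided by the alignment
#' length. Ties in the dynamic program are resolved deterministically
#' (diagonal, then up, then left), so the score is symmetric and
#' reproducible.
#'
#' @param a,b Non-empty RNA/DNA strings.
#' @param match,mismatch,gap Alignment scores.
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGU", "ACGA")   # 0.75
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  .check_string(a, "a")
  .check_string(b, "b")
  sa <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  sb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(sa); m <- length(sb)
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n)
  F[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    si <- sa[i]
    for (j in seq_len(m)) {
      diag <- F[i, j] + if (si == sb[j]) match else mismatch
      up <- F[i, j + 1L] + gap
      left <- F[i + 1L, j] + gap
      F[i + 1L, j + 1L] <- max(diag, up, left)
    }
  }
  # traceback counting matches and alignment length
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0L || j > 0L) {
    here <- F[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == F[i, j] + (if (sa[i] == sb[j]) match else mismatch)) {
      if (sa[i] == sb[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == F[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  matches / len
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper with the conventions used throughout the similarity
#' analysis: the exact null enumeration when the pooled sample is small
#' (`n + m <= 12`) and tie-free, the normal approximation with tie
#' correction (no continuity correction) otherwise.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (`x` against
#'   `y`).
#' @return p-value.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))                        # 0.1
#' ranksum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # 0.05
#' @export
ranksum_test <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) rlang::abort("both samples must be non-empty.")
  alt <- switch(alternative, two_sided = "two.sided", less = "less", greater = "greater")
  # fully degenerate data carries no evidence either way
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact, correct = FALSE)
  )
  unname(res$p.value)
}
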