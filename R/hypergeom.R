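#' Cumulative hypergeometric tail probability
#'
#' Probability of observing a co-occurrence count at least as large as
#' `c_obs` when `m1` and `m2` items are drawn from a universe of size `N`:
#'
#' \deqn{P(C \ge c') = \sum_{i=c'}^{\min(m_1, m_2)}
#'   \frac{\binom{m_1}{i}\binom{N-m_1}{m_2-i}}{\binom{N}{m_2}}}
#'
#' This is the significance kernel shared by the target-overlap edge test,
#' the TF-motif co-occurrence test and the pathway enrichment test. Terms
#' are accumulated in log space (`lchoose`) for numerical stability at large
#' `N`.
#'
#' @param c_obs Observed overlap/co-occurrence count.
#' @param m1,m2 Sizes of the two sets.
#' @param N Universe size.
#' @return The upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_tail(3, 4, 5, 10)   # 66/252
#' hypergeom_tail(0, 4, 5, 10)   # full tail = 1
#' @export
hypergeom_tail <- function(c_obs, m1, m2, N) {
  c_obs <- .check_count(c_obs, "c_obs")
  m1 <- .check_count(m1, "m1")
  m2 <- .check_count(m2, "m2")
  N <- .check_count(N, "N")
  if (m1 > N || m2 > N) {
    rlang::abort(sprintf("set sizes (%d, %d) exceed the universe size %d.", m1, m2, N))
  }
  if (c_obs > min(m1, m2)) {
    rlang::abort(sprintf("observed overlap %d exceeds min(m1, m2) = %d.",
                         c_obs, min(m1, m2)))
  }
  if (c_obs == 0L) return(1)
  i <- seq.int(c_obs, min(m1, m2))
  log_terms <- lchoose(m1, i) + lchoose(N - m1, m2 - i) - lchoose(N, m2)
  log_terms <- log_terms[is.finite(log_terms)]
  if (!length(log_terms)) return(0)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}
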