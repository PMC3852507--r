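# shared internal helpers

# identifiers are compared case-insensitively after trimming; the original
# spelling of the first occurrence is what gets reported back to the user
.norm_id <- function(x) tolower(trimws(x))

.check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    rlang::abort(sprintf("`%s` must be a single non-empty string.", what))
  }
  invisible(x)
}

.check_number <- function(x, what, min = -Inf, max = Inf,
                          strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single number.", what))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    rlang::abort(sprintf(
      "`%s` = %s is outside the allowed range %s%s, %s%s.",
      what, format(x), if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

.check_count <- function(x, what, min = 0L) {
  .check_number(x, what, min = min)
  if (x != floor(x)) rlang::abort(sprintf("`%s` must be an integer.", what))
  invisible(as.integer(x))
}

# run `expr` under a fixed seed without disturbing the caller's RNG state;
# seed = NULL leaves the current stream untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# unordered pair key, used wherever edges are matched across structures
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
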