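#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Row-wise sample variance of a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
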