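# Internal helpers shared across modules.

#' Derive a child seed from a root seed
#'
#' All stochastic stages draw their seeds from one root seed through this
#' deterministic map, so any record, fold or repeat is reproducible on its own,
#' independently of generation order. The result is always a positive integer
#' below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param ... one or more non-negative integer indices (record index, fold
#'   number, repeat number, ...) distinguishing the child stream.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483629 # largest prime < 2^31
  h <- as.double(seed) %% m
  for (i in idx) {
    # affine step in double precision; products stay far below 2^53
    h <- (h * 48271 + as.double(i) * 9973 + 101) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# Evaluate an expression under a local RNG state restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
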