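# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded substream seed from a master seed and a stream index,
# keeping the result a valid 32-bit R integer.
substream <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647L)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name, tol = 1e-12) {
  if (any(x < 0)) stop_config("%s contains negative entries", name)
  if (abs(sum(x) - 1) > tol) stop_config("%s does not sum to 1", name)
  invisible(TRUE)
}

# Dense numeric matrix from anything Matrix-like.
as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}
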