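#' Derive a child seed from a master seed
#'
#' Streams of randomness inside the pipeline (per stage, per gene, per
#' subsample round) each get their own seed derived deterministically from the
#' master seed, so serial and parallel execution orders give identical results.
#'
#' @param master integer master seed.
#' @param ... integer offsets identifying the stream (stage index, gene index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  offs <- c(...)
  x <- as.double(master) %% 2147483647
  for (o in offs) {
    # LCG-style mix keeps everything inside 32-bit integer range
    x <- (x * 48271 + as.double(o) * 8191 + 1) %% 2147483647
  }
  as.integer(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library functions that consume
#' randomness do not perturb the caller's stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Soft-thresholding operator
#'
#' `S(x, delta) = sign(x) * max(|x| - delta, 0)`, the proximal operator of the
#' l1 norm and the elementwise update inside the penalized matrix
#' decomposition.
#'
#' @param x numeric vector.
#' @param delta non-negative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(x, delta) {
  stopifnot(delta >= 0)
  sign(x) * pmax(abs(x) - delta, 0)
}

# stop() with a consistent prefix so pipeline stages can be identified in logs
abort_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable 32-bit hash of a string, for identity-derived seeds
id_hash <- function(x) {
  h <- 0
  for (cc in utf8ToInt(x)) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}
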