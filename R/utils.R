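#' @keywords internal
"_PACKAGE"

#' @useDynLib ifsrank, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a run seed
#'
#' Stages of the pipeline (simulation, each ranker, each CV fold) draw their
#' own seeds from the single run seed so that any stage can be re-run
#' standalone and reproduce its in-pipeline behaviour. The derivation is a
#' fixed affine map modulo the largest 32-bit prime, keeping every derived
#' seed a valid R integer.
#'
#' @param seed integer run seed.
#' @param ... one or more non-negative integer offsets identifying the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (o in offs) s <- (s * 7919 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

# run `expr` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
}

# stable decreasing order: ties resolved by original position
order_desc_stable <- function(score) order(-score, seq_along(score))
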