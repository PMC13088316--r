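#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}

#' Reverse-complement a nucleotide string
#' @param x character vector of sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) .revcomp_cpp(x)
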