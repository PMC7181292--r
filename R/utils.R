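#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the expression and restores the previous RNG state, so
#' that seeded generators do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific 31-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435761 + stream * 40503) %% 2147483647
  as.integer(s)
}

# linear interpolation of a trace at arbitrary instants (rule 2: clamp ends)
interp_trace <- function(trace, t_query) {
  stats::approx(trace_times(trace), trace$values, xout = t_query,
                rule = 2)$y
}
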