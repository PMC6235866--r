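#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the random-number generator seeded at \code{seed},
#' restoring the caller's RNG state afterwards. When \code{seed} is NULL the
#' expression runs against the current RNG stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so the state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# argmin with seeded uniform tie-breaking; ties detected at relative tolerance
# (distances are rationals computed in double, so exact equality is fragile)
argmin_random_tie <- function(x, tol = 1e-9) {
  m <- min(x)
  tied <- which(x <= m + tol * max(m, 1))
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
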