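# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library calls do not clobber the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# log-density of a Poisson law extended to non-negative real "counts":
# k*log(lambda) - lambda - lgamma(k + 1).  Needed because scaled detection
# counts Total_t * X_it are generally not integers.
dpois_cont_log <- function(k, lambda) {
  abort_if(any(k < 0), "Poisson channel received a negative count")
  out <- ifelse(k == 0, -lambda, k * log(lambda) - lambda - lgamma(k + 1))
  # k > 0 with lambda == 0 has zero density
  out[k > 0 & lambda <= 0] <- -Inf
  out
}

# Spearman rank correlation without the cor() "exact p" machinery.
spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Mean of bootstrap draws from a Beta distribution
#'
#' Monte-Carlo estimate of the mean of `Beta(alpha, beta)` from `n_draws`
#' samples of the current RNG stream.  Used for prior and posterior
#' bootstrap summaries; converges to `alpha / (alpha + beta)`.
#'
#' @param alpha,beta positive shape parameters.
#' @param n_draws number of draws (>= 1).
#' @return scalar mean of the draws.
#' @export
bootstrap_mean_beta <- function(alpha, beta, n_draws = 1000L) {
  abort_if(!is_scalar_number(n_draws) || n_draws < 1, "n_draws must be >= 1")
  abort_if(alpha <= 0 || beta <= 0, "alpha and beta must be positive")
  mean(stats::rbeta(as.integer(n_draws), alpha, beta))
}
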