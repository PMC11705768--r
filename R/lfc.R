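# Optional tumor-vs-normal log-fold-change channel.  Each gene's reported
# LFC seeds a Normal(lfc, 0.5) from which pseudo-observations are drawn;
# the model links them to sigma through lfc = -log10(sigma) * beta_lfc with
# beta_lfc ~ Beta(2, 1), so a large fold change pulls sigma toward 0.

#' Construct an LFC observation channel
#'
#' @param lfc named numeric vector, one log fold change per gene.
#' @param n_pseudo_obs pseudo-observations drawn per gene (default 100).
#' @param noise_sd Normal noise around the reported LFC (default 0.5).
#' @return an `LFCObservation` object.
#' @export
lfc_observation <- function(lfc, n_pseudo_obs = 100L, noise_sd = 0.5) {
  abort_if(is.null(names(lfc)), "lfc must be named by gene")
  abort_if(any(!is.finite(lfc)), "lfc values must be finite")
  abort_if(!is_scalar_number(n_pseudo_obs) || n_pseudo_obs < 1,
           "n_pseudo_obs must be >= 1")
  abort_if(!is_scalar_number(noise_sd) || noise_sd <= 0,
           "noise_sd must be positive")
  structure(list(lfc = lfc, n_pseudo_obs = as.integer(n_pseudo_obs),
                 noise_sd = noise_sd),
            class = "LFCObservation")
}

#' Read a two-column gene/LFC TSV
#'
#' @param path TSV with columns gene, lfc (header row).
#' @param ... passed to [lfc_observation()].
#' @return an `LFCObservation`.
#' @export
read_lfc <- function(path, ...) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  lfc_observation(stats::setNames(as.numeric(df[[2]]),
                                  as.character(df[[1]])), ...)
}

#' Draw the per-gene LFC pseudo-observations
#'
#' @param obs an [lfc_observation()].
#' @param seed RNG seed; the draw is deterministic given it.
#' @return matrix genes x `n_pseudo_obs`.
#' @export
sample_lfc_observations <- function(obs, seed = 1L) {
  n <- length(obs$lfc)
  with_seed(seed, {
    draws <- matrix(stats::rnorm(n * obs$n_pseudo_obs,
                                 mean = rep(obs$lfc, obs$n_pseudo_obs),
                                 sd = obs$noise_sd),
                    nrow = n, dimnames = list(names(obs$lfc), NULL))
    draws
  })
}

#' Expected log fold change implied by sigma
#'
#' `lfc = -log10(sigma) * beta_lfc`; strictly decreasing in sigma.
#'
#' @param sigma value(s) in the open interval (0, 1).
#' @param beta_lfc coefficient in (0, 1\].
#' @return expected LFC.
#' @export
lfc_link <- function(sigma, beta_lfc = 1) {
  abort_if(any(sigma <= 0 | sigma >= 1), "sigma must lie strictly in (0, 1)")
  -log10(sigma) * beta_lfc
}

#' Fit the model with the LFC channel enabled
#'
#' Identical to [fit_specificity()] with `lfc` supplied; present for
#' interface symmetry.  With `lfc = NULL` the result is bitwise identical
#' to the base fit at the same seed.
#'
#' @inheritParams fit_specificity
#' @return a `PosteriorSummary`.
#' @export
fit_with_lfc <- function(X = NULL, Y = NULL, Z = NULL, lfc = NULL,
                         weights = NULL, config = model_config(),
                         calibration = NULL) {
  fit_specificity(X = X, Y = Y, Z = Z, lfc = lfc, weights = weights,
                  config = config, calibration = calibration)
}
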