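# Empirical-Bayes calibration: (i) the Gamma shape y_ebayes linking sigma
# to the log-scale location of the count channel, via percentile-anchored
# no-intercept regression; (ii) per-modality loss scales that stop any one
# evidence type from dominating the joint ELBO.

#' Estimate the count-channel coefficient y_ebayes
#'
#' For each gene the empirical mean `m_g` of its normalized counts is
#' inverted to the LogNormal location `mu_g = log(m_g) - scale^2 / 2`.
#' The i-th percentile of the `mu_g` values (i = 1..100) anchors
#' `sigma = i/100`, and a least-squares fit with no intercept of `mu` on
#' `sigma` yields the slope `y_ebayes`.  Genes with zero mean are floored
#' at the smallest positive mean so all genes stay scoreable.
#'
#' @param panel an [expression_panel()].
#' @param lognormal_scale fixed LogNormal scale (default 0.5).
#' @return list with `y_ebayes` (slope) and `anchor_table`
#'   (100 sigma/mu pairs).
#' @export
estimate_y_ebayes <- function(panel, lognormal_scale = 0.5) {
  m <- rowMeans(panel$values, na.rm = TRUE)
  abort_if(length(m) < 100,
           "need >= 100 genes for percentile anchoring (got %d)", length(m))
  pos <- m[m > 0]
  abort_if(length(pos) == 0, "no gene with a positive mean")
  m[m <= 0] <- min(pos)
  mu <- log(m) - lognormal_scale^2 / 2
  sigma <- (1:100) / 100
  anchors <- stats::quantile(mu, probs = sigma, names = FALSE, type = 7)
  slope <- sum(sigma * anchors) / sum(sigma^2)
  abort_if(slope <= 0,
           paste("estimated y_ebayes is non-positive; the count data are",
                 "pathological — supply a coefficient manually"))
  list(y_ebayes = slope,
       anchor_table = data.frame(sigma = sigma, mu = anchors))
}

#' Loss scales from standalone maximum losses
#'
#' Given per-modality maximum losses `L_m`, returns
#' `c_m = min(L) / L_m`, so every scaled maximum loss equals the smallest
#' one.
#'
#' @param losses named positive numeric vector of maximum losses.
#' @return named numeric vector of scales.
#' @export
scaling_factors_from_losses <- function(losses) {
  abort_if(any(!is.finite(losses)), "non-finite standalone loss")
  abort_if(any(losses <= 0),
           paste("standalone maximum losses must be positive to define",
                 "scales; got %s"), paste(signif(losses, 4), collapse = ", "))
  min(losses) / losses
}

#' Calibrate per-modality loss scales by standalone training
#'
#' Trains the model on each supplied modality alone for `config$epochs`
#' steps, records the running maximum of each loss trace, and converts the
#' maxima into multiplicative scales via [scaling_factors_from_losses()].
#'
#' @param X,Y,Z,lfc evidence objects (at least two non-`NULL`).
#' @param config a [model_config()].
#' @param y_ebayes count-channel coefficient (required when `Y` given).
#' @return list with `modality_scales` and `standalone_max_losses`.
#' @export
calibrate_scaling_factors <- function(X = NULL, Y = NULL, Z = NULL,
                                      lfc = NULL, config = model_config(),
                                      y_ebayes = NULL) {
  sets <- Filter(function(s) !is.null(s$obj),
                 list(list(name = "X", obj = X), list(name = "Y", obj = Y),
                      list(name = "Z", obj = Z),
                      list(name = "LFC", obj = lfc)))
  abort_if(length(sets) < 2, "calibration needs at least two modalities")
  cal_frag <- list(y_ebayes = y_ebayes)
  losses <- vapply(sets, function(s) {
    args <- list(X = NULL, Y = NULL, Z = NULL, lfc = NULL)
    args[[if (s$name == "LFC") "lfc" else s$name]] <- s$obj
    run <- tryCatch(
      fit_specificity(X = args$X, Y = args$Y, Z = args$Z, lfc = args$lfc,
                      config = config, calibration = cal_frag),
      error = function(e) stop(sprintf(
        "standalone run of modality %s failed: %s", s$name,
        conditionMessage(e)), call. = FALSE))
    max(run$elbo_trace)
  }, 0)
  names(losses) <- vapply(sets, `[[`, "", "name")
  list(modality_scales = scaling_factors_from_losses(losses),
       standalone_max_losses = losses)
}

#' Full calibration: count coefficient plus loss scales
#'
#' Convenience wrapper producing the `CalibrationResult` consumed by
#' [fit_specificity()]: estimates `y_ebayes` from the count panel (when
#' present) and, when two or more modalities are supplied, the
#' per-modality loss scales.
#'
#' @param X,Y,Z,lfc evidence objects.
#' @param config a [model_config()].
#' @return list with `y_ebayes`, `anchor_table`, `modality_scales`,
#'   `standalone_max_losses`.
#' @export
calibrate <- function(X = NULL, Y = NULL, Z = NULL, lfc = NULL,
                      config = model_config()) {
  out <- list(y_ebayes = NULL, anchor_table = NULL,
              modality_scales = NULL, standalone_max_losses = NULL)
  if (!is.null(Y)) {
    eb <- estimate_y_ebayes(Y, config$lognormal_scale)
    out$y_ebayes <- eb$y_ebayes
    out$anchor_table <- eb$anchor_table
  }
  n_mod <- sum(!vapply(list(X, Y, Z, lfc), is.null, TRUE))
  if (n_mod >= 2) {
    sc <- calibrate_scaling_factors(X, Y, Z, lfc, config,
                                    y_ebayes = out$y_ebayes)
    out$modality_scales <- sc$modality_scales
    out$standalone_max_losses <- sc$standalone_max_losses
  }
  out
}
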