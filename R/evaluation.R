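# Benchmarking and model criticism: precision-recall ranking of known safe
# targets, prior/posterior predictive checks, and the reproducibility and
# leave-one-modality-out harnesses.

#' Area under the precision-recall curve of a score ranking
#'
#' Ranks all scored targets (ascending by default, since lower specificity
#' scores mean safer targets), sweeps every score cutoff — equal scores
#' are grouped so ties enter together — and integrates precision over
#' recall with the non-interpolated step rule
#' `sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @param scores named numeric vector, one score per target.
#' @param positives character vector of positive ("safe") identifiers; all
#'   other scored targets count as negatives.
#' @param ascending if `TRUE` (default) lower scores rank first.
#' @return list with `aupr` and `curve` (cutoff, precision, recall).
#' @export
compute_aupr <- function(scores, positives, ascending = TRUE) {
  abort_if(is.null(names(scores)), "scores must be named by target")
  abort_if(!all(positives %in% names(scores)),
           "every positive must be scored")
  labels <- names(scores) %in% positives
  abort_if(all(labels) || !any(labels),
           "degenerate benchmark: all or none of the targets are positive")
  ord <- order(scores, decreasing = !ascending)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))           # tie groups in rank order
  tp <- cumsum(l); npred <- seq_along(l)
  last <- which(!duplicated(grp, fromLast = TRUE))  # group boundaries
  precision <- tp[last] / npred[last]
  recall <- tp[last] / sum(l)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(aupr = aupr,
       curve = data.frame(cutoff = s[last], precision = precision,
                          recall = recall))
}

#' Prior and posterior predictive check for one gene
#'
#' Bootstraps the prior (`Beta(2,2)`) and the learned posterior guide mean
#' from `n_boot` draws each, then simulates replicate evidence of the
#' observed shapes under both: `T` Poisson tissue counts with coefficient
#' 25, `S` LogNormal counts with the calibrated coefficient, and `P`
#' categorical staining labels.
#'
#' @param gene gene identifier present in `fitted`.
#' @param fitted a `PosteriorSummary`.
#' @param X,Y,Z observed evidence (any subset; used for shapes and
#'   observed summaries).
#' @param config a [model_config()].
#' @param calibration [calibrate()] result (for the count coefficient).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return a `PredictiveCheck` list with `prior_sigma_mean`,
#'   `posterior_sigma_mean`, simulated summaries under both, and observed
#'   summaries.
#' @export
predictive_check <- function(gene, fitted, X = NULL, Y = NULL, Z = NULL,
                             config = model_config(), calibration = NULL,
                             n_boot = 1000L, seed = 1L) {
  abort_if(!is_scalar_number(n_boot) || n_boot < 1, "n_boot must be >= 1")
  s <- fitted$summary
  abort_if(!gene %in% s$gene, "gene %s not in the fitted summary", gene)
  row <- s[s$gene == gene, ]
  with_seed(seed, {
    prior_mean <- bootstrap_mean_beta(config$prior_alpha, config$prior_beta,
                                      n_boot)
    post_mean <- bootstrap_mean_beta(row$guide_alpha, row$guide_beta, n_boot)
    simulate_at <- function(sig) {
      out <- list(sigma = sig)
      if (!is.null(X)) {
        out$x_counts <- stats::rpois(ncol(X$fractions), 25 * sig)
      }
      if (!is.null(Y)) {
        abort_if(is.null(calibration$y_ebayes),
                 "count simulation needs a calibration with y_ebayes")
        out$y_counts <- stats::rlnorm(ncol(Y$values),
                                      calibration$y_ebayes * sig,
                                      config$lognormal_scale)
      }
      if (!is.null(Z)) {
        out$z_labels <- sample(0:3, ncol(Z$labels), replace = TRUE,
                               prob = category_probs(sig)[1, ])
      }
      out
    }
    observed <- list(
      x = if (!is.null(X)) X$fractions[gene, ],
      y = if (!is.null(Y)) Y$values[gene, ],
      z = if (!is.null(Z)) Z$labels[gene, ])
    structure(list(gene = gene,
                   prior_sigma_mean = prior_mean,
                   posterior_sigma_mean = post_mean,
                   prior_sim = simulate_at(prior_mean),
                   posterior_sim = simulate_at(post_mean),
                   observed = observed),
              class = "PredictiveCheck")
  })
}

#' Score stability across independent fits
#'
#' Refits the model `n_runs` times with seeds `config$seed + 0 ..
#' n_runs - 1` and summarizes the per-gene score dispersion.
#'
#' @param X,Y,Z,lfc evidence objects.
#' @param weights tissue weights (optional).
#' @param config a [model_config()].
#' @param calibration [calibrate()] result.
#' @param n_runs independent fits (>= 2, default 5).
#' @return list with `scores` (genes x runs matrix) and `dispersion`
#'   (gene, mean, sd, max_diff).
#' @export
reproducibility_study <- function(X = NULL, Y = NULL, Z = NULL, lfc = NULL,
                                  weights = NULL, config = model_config(),
                                  calibration = NULL, n_runs = 5L) {
  abort_if(!is_scalar_number(n_runs) || n_runs < 2, "n_runs must be >= 2")
  runs <- lapply(seq_len(n_runs) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    fit_specificity(X, Y, Z, lfc, weights = weights, config = cfg,
                    calibration = calibration)$summary
  })
  scores <- vapply(runs, `[[`, numeric(nrow(runs[[1]])), "score")
  rownames(scores) <- runs[[1]]$gene
  disp <- data.frame(
    gene = rownames(scores),
    mean = rowMeans(scores),
    sd = apply(scores, 1L, stats::sd),
    max_diff = apply(scores, 1L, function(r) max(r) - min(r)),
    row.names = NULL)
  list(scores = scores, dispersion = disp)
}

#' Leave-one-modality-out ablation study
#'
#' Fits the full three-modality model and each two-modality ablation at
#' the same seed and reports the per-gene scores side by side, plus the
#' score correlations between the full fit and each ablation.
#'
#' @param X,Y,Z the three evidence objects (all required).
#' @param weights tissue weights (optional).
#' @param config a [model_config()].
#' @param calibration [calibrate()] result.
#' @return list with `scores` (data frame: gene, full, no_X, no_Y, no_Z)
#'   and `correlations` (Spearman of each ablation against the full fit).
#' @export
leave_one_out_study <- function(X, Y, Z, weights = NULL,
                                config = model_config(),
                                calibration = NULL) {
  abort_if(is.null(X) || is.null(Y) || is.null(Z),
           "the ablation study needs all three modalities")
  fits <- list(
    full = fit_specificity(X, Y, Z, weights = weights, config = config,
                           calibration = calibration),
    no_X = fit_specificity(NULL, Y, Z, weights = weights, config = config,
                           calibration = calibration),
    no_Y = fit_specificity(X, NULL, Z, weights = weights, config = config,
                           calibration = calibration),
    no_Z = fit_specificity(X, Y, NULL, weights = weights, config = config,
                           calibration = calibration))
  genes <- fits$full$summary$gene
  sc <- vapply(fits, function(f) {
    stats::setNames(f$summary$score, f$summary$gene)[genes]
  }, numeric(length(genes)))
  list(
    scores = data.frame(gene = genes, sc, row.names = NULL),
    correlations = vapply(c("no_X", "no_Y", "no_Z"), function(k) {
      spearman(sc[, "full"], sc[, k])
    }, 0)
  )
}
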