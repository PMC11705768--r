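# The hierarchical generative model and its variational fit.
#
# Per target i with latent specificity sigma_i:
#   sigma_i            ~ Beta(2, 2)
#   beta_y,i           ~ Gamma(y_ebayes, 1)
#   Y_is               ~ LogNormal(beta_y,i * sigma_i, 0.5)
#   beta_x,i           ~ Gamma(25, 1)
#   Total_t            ~ Binomial(50, w_t)
#   Total_t * X_it     ~ Poisson(beta_x,i * sigma_i)
#   Z_ip               ~ Categorical(2s/3, s/3, (1-s)/3, 2(1-s)/3), s = sigma_i
#   LFC_ik (optional)  ~ Normal(-log10(sigma_i) * beta_lfc, 0.5),
#                        beta_lfc ~ Beta(2, 1)
#
# The guide is a per-gene Beta(alpha_i, beta_i) over sigma_i; the guides of
# all coefficients and of Total_t equal their priors, so their KL terms
# vanish and the ELBO reduces to
#   E_q[ sum_m c_m * loglik_m(sigma) ] - KL(q(sigma) || Beta(2,2))
# with the coefficient/total draws refreshed every epoch (stochastic VI).
# Every modality's log-likelihood is, as a function of sigma, of the form
#   A log(s) + B log(1-s) + C s + D s^2 + E log(s)^2 + const,
# so the expectation under a Beta guide has a closed form in digamma /
# trigamma moments and the gradient is analytic; Adam does the rest.

#' Model and optimizer configuration
#'
#' @param prior_alpha,prior_beta Beta prior on sigma (default 2, 2 — weakly
#'   informative, ~80% mass in (0.2, 0.8)).
#' @param lognormal_scale fixed scale of the LogNormal count channel (0.5).
#' @param total_count_base Binomial size for per-tissue totals (50, so the
#'   neutral weight 0.5 yields ~25 counts).
#' @param betax_prior Gamma (shape, rate) prior of the tissue-channel
#'   coefficient (25, 1).
#' @param betalfc_prior Beta (alpha, beta) prior of the LFC coefficient
#'   (2, 1).
#' @param learning_rate Adam learning rate (0.002).
#' @param adam_betas Adam moment decay rates (0.95, 0.999).
#' @param epochs SVI steps (5000; convergence typically by ~2000).
#' @param seed integer seed controlling all fit randomness.
#' @param n_draws posterior bootstrap draws for scoring (1000).
#' @param resample_total if `TRUE` (default) `Total_t` is redrawn every SVI
#'   step as a model random variable; if `FALSE` it is fixed at its mean.
#' @return a `ModelConfig` list.
#' @export
model_config <- function(prior_alpha = 2, prior_beta = 2,
                         lognormal_scale = 0.5, total_count_base = 50L,
                         betax_prior = c(shape = 25, rate = 1),
                         betalfc_prior = c(alpha = 2, beta = 1),
                         learning_rate = 0.002,
                         adam_betas = c(0.95, 0.999),
                         epochs = 5000L, seed = 1L, n_draws = 1000L,
                         resample_total = TRUE) {
  cfg <- list(prior_alpha = prior_alpha, prior_beta = prior_beta,
              lognormal_scale = lognormal_scale,
              total_count_base = as.integer(total_count_base),
              betax_prior = betax_prior, betalfc_prior = betalfc_prior,
              learning_rate = learning_rate, adam_betas = adam_betas,
              epochs = as.integer(epochs), seed = as.integer(seed),
              n_draws = as.integer(n_draws),
              resample_total = isTRUE(resample_total))
  hp <- c(cfg$prior_alpha, cfg$prior_beta, cfg$lognormal_scale,
          cfg$total_count_base, cfg$betax_prior, cfg$betalfc_prior,
          cfg$learning_rate, cfg$adam_betas)
  abort_if(any(hp <= 0), "all hyperparameters must be strictly positive")
  abort_if(cfg$epochs < 1, "epochs must be >= 1")
  class(cfg) <- "ModelConfig"
  cfg
}

#' Categorical staining probabilities implied by sigma
#'
#' `P(high) = 2s/3`, `P(medium) = s/3`, `P(low) = (1-s)/3`,
#' `P(not detected) = 2(1-s)/3`; sums to one for every sigma in \[0,1\].
#'
#' @param sigma value(s) in \[0,1\].
#' @return matrix with one row per sigma and columns high/medium/low/nd.
#' @export
category_probs <- function(sigma) {
  abort_if(any(sigma < 0 | sigma > 1), "sigma must lie in [0, 1]")
  cbind(high = 2 * sigma / 3, medium = sigma / 3,
        low = (1 - sigma) / 3, `not detected` = 2 * (1 - sigma) / 3)
}

# ---- sufficient statistics ------------------------------------------------

# Floors non-positive Y values at the smallest positive entry so logs exist
# (TPM zeros carry "undetected" information through the X channel already).
floor_positive <- function(values) {
  pos <- values[values > 0]
  abort_if(length(pos) == 0, "expression panel has no positive values")
  values[values <= 0] <- min(pos)
  values
}

# Per-gene statistics that never change across epochs.
prepare_evidence <- function(X = NULL, Y = NULL, Z = NULL, lfc = NULL,
                             config = model_config(), genes = NULL) {
  mats <- Filter(Negate(is.null), list(X = X, Y = Y, Z = Z))
  abort_if(length(mats) == 0 && is.null(lfc), "at least one modality needed")
  if (is.null(genes)) {
    gsets <- lapply(mats, gene_ids)
    if (!is.null(lfc)) gsets <- c(gsets, list(lfc = names(lfc$lfc)))
    genes <- Reduce(intersect, gsets)
    n_union <- length(unique(unlist(gsets)))
    abort_if(length(genes) == 0,
             "gene sets of the modalities do not overlap (%d ids mismatch)",
             n_union)
    if (n_union > length(genes)) {
      message(sprintf("intersecting modalities: %d gene(s) dropped",
                      n_union - length(genes)))
    }
  }
  ev <- list(genes = genes, n = length(genes))
  if (!is.null(Y)) {
    vals <- floor_positive(Y$values[genes, , drop = FALSE])
    ly <- log(vals)
    ev$y <- list(S = ncol(vals), sum_ly = rowSums(ly),
                 sum_ly2 = rowSums(ly^2))
  }
  if (!is.null(X)) {
    ev$x <- list(fractions = X$fractions[genes, , drop = FALSE],
                 tissues = colnames(X$fractions),
                 T = ncol(X$fractions))
  }
  if (!is.null(Z)) {
    lab <- Z$labels[genes, , drop = FALSE]
    n01 <- rowSums(lab <= 1L)
    n23 <- rowSums(lab >= 2L)
    n0 <- rowSums(lab == 0L); n1 <- rowSums(lab == 1L)
    n2 <- rowSums(lab == 2L); n3 <- rowSums(lab == 3L)
    ev$z <- list(A = n01, B = n23,
                 const = (n0 + n3) * log(2 / 3) + (n1 + n2) * log(1 / 3))
  }
  if (!is.null(lfc)) {
    draws <- sample_lfc_observations(lfc, seed = config$seed + 101L)
    d <- draws[genes, , drop = FALSE]
    ev$lfc <- list(K = ncol(d), sum_d = rowSums(d), sum_d2 = rowSums(d^2),
                   noise_sd = lfc$noise_sd)
  }
  ev
}

# Polynomial coefficients (A, B, C, D, E, const) of the weighted evidence
# log-likelihood at one set of coefficient draws.  Each is an n-vector.
evidence_coefficients <- function(ev, draws, scales, config) {
  n <- ev$n
  co <- list(A = numeric(n), B = numeric(n), C = numeric(n),
             D = numeric(n), E = numeric(n), const = numeric(n))
  s0 <- config$lognormal_scale
  if (!is.null(ev$y)) {
    c_y <- scales[["Y"]]
    by <- draws$beta_y
    co$C <- co$C + c_y * by * ev$y$sum_ly / s0^2
    co$D <- co$D - c_y * ev$y$S * by^2 / (2 * s0^2)
    co$const <- co$const + c_y *
      (-ev$y$sum_ly - ev$y$S * log(s0 * sqrt(2 * pi)) -
         ev$y$sum_ly2 / (2 * s0^2))
  }
  if (!is.null(ev$x)) {
    c_x <- scales[["X"]]
    k <- sweep(ev$x$fractions, 2L, draws$total, `*`)  # scaled counts
    sum_k <- rowSums(k)
    bx <- draws$beta_x
    co$A <- co$A + c_x * sum_k
    co$C <- co$C - c_x * ev$x$T * bx
    co$const <- co$const + c_x *
      (sum_k * log(bx) - rowSums(lgamma(k + 1)))
  }
  if (!is.null(ev$z)) {
    c_z <- scales[["Z"]]
    co$A <- co$A + c_z * ev$z$A
    co$B <- co$B + c_z * ev$z$B
    co$const <- co$const + c_z * ev$z$const
  }
  if (!is.null(ev$lfc)) {
    c_l <- scales[["LFC"]]
    sl <- ev$lfc$noise_sd
    cc <- draws$beta_lfc / log(10)   # lfc mean = -cc * log(sigma)
    co$A <- co$A - c_l * cc * ev$lfc$sum_d / sl^2
    co$E <- co$E - c_l * ev$lfc$K * cc^2 / (2 * sl^2)
    co$const <- co$const + c_l *
      (-ev$lfc$K * log(sl * sqrt(2 * pi)) - ev$lfc$sum_d2 / (2 * sl^2))
  }
  co
}

# One set of stochastic draws for coefficients and per-tissue totals.
draw_coefficients <- function(ev, weights, config, calibration) {
  n <- ev$n
  d <- list()
  if (!is.null(ev$y)) {
    d$beta_y <- stats::rgamma(n, shape = calibration$y_ebayes, rate = 1)
  }
  if (!is.null(ev$x)) {
    w <- weights[ev$x$tissues]
    d$beta_x <- stats::rgamma(n, shape = config$betax_prior[["shape"]],
                              rate = config$betax_prior[["rate"]])
    d$total <- if (config$resample_total) {
      stats::rbinom(ev$x$T, config$total_count_base, w)
    } else {
      config$total_count_base * w
    }
  }
  if (!is.null(ev$lfc)) {
    d$beta_lfc <- stats::rbeta(n, config$betalfc_prior[["alpha"]],
                               config$betalfc_prior[["beta"]])
  }
  d
}

# ---- closed-form Beta expectations and KL ---------------------------------

beta_guide_moments <- function(a, b) {
  ab <- a + b
  dga <- digamma(a); dgb <- digamma(b); dgab <- digamma(ab)
  tga <- trigamma(a); tgab <- trigamma(ab)
  S1 <- dga - dgab                      # E[log s]
  list(
    S1 = S1,
    S2 = dgb - dgab,                    # E[log(1-s)]
    M1 = a / ab,                        # E[s]
    M2 = a * (a + 1) / (ab * (ab + 1)), # E[s^2]
    Q  = tga - tgab + S1^2,             # E[log(s)^2]
    dS1_da = tga - tgab, dS1_db = -tgab,
    dS2_da = -tgab, dS2_db = trigamma(b) - tgab,
    dM1_da = b / ab^2, dM1_db = -a / ab^2,
    dM2_da = ((2 * a + 1) * ab * (ab + 1) -
                a * (a + 1) * (2 * ab + 1)) / (ab * (ab + 1))^2,
    dM2_db = -a * (a + 1) * (2 * ab + 1) / (ab * (ab + 1))^2,
    dQ_da = psigamma(a, 2) - psigamma(ab, 2) + 2 * S1 * (tga - tgab),
    dQ_db = -psigamma(ab, 2) - 2 * S1 * tgab
  )
}

kl_beta <- function(a, b, a0, b0) {
  list(
    value = lbeta(a0, b0) - lbeta(a, b) +
      (a - a0) * digamma(a) + (b - b0) * digamma(b) +
      (a0 + b0 - a - b) * digamma(a + b),
    da = (a - a0) * trigamma(a) + (a0 + b0 - a - b) * trigamma(a + b),
    db = (b - b0) * trigamma(b) + (a0 + b0 - a - b) * trigamma(a + b)
  )
}

# Loss (-ELBO) and its gradient w.r.t. (a, b), all n-vectors.
elbo_loss <- function(a, b, co, config) {
  m <- beta_guide_moments(a, b)
  kl <- kl_beta(a, b, config$prior_alpha, config$prior_beta)
  exp_ll <- co$A * m$S1 + co$B * m$S2 + co$C * m$M1 + co$D * m$M2 +
    co$E * m$Q + co$const
  d_da <- co$A * m$dS1_da + co$B * m$dS2_da + co$C * m$dM1_da +
    co$D * m$dM2_da + co$E * m$dQ_da
  d_db <- co$A * m$dS1_db + co$B * m$dS2_db + co$C * m$dM1_db +
    co$D * m$dM2_db + co$E * m$dQ_db
  list(loss = -(exp_ll) + kl$value,
       grad_a = -d_da + kl$da,
       grad_b = -d_db + kl$db)
}

# ---- SVI engine ------------------------------------------------------------

svi_run <- function(ev, weights, config, calibration, scales) {
  n <- ev$n
  theta_a <- rep(log(config$prior_alpha), n)
  theta_b <- rep(log(config$prior_beta), n)
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  lr <- config$learning_rate; eps <- 1e-8
  m_a <- v_a <- m_b <- v_b <- numeric(n)
  trace <- numeric(config$epochs)
  for (step in seq_len(config$epochs)) {
    draws <- draw_coefficients(ev, weights, config, calibration)
    co <- evidence_coefficients(ev, draws, scales, config)
    a <- exp(theta_a); b <- exp(theta_b)
    el <- elbo_loss(a, b, co, config)
    abort_if(!all(is.finite(el$loss)),
             paste("divergent loss (NaN/Inf) at epoch %d;",
                   "try a lower learning_rate"), step)
    trace[step] <- sum(el$loss)
    g_a <- el$grad_a * a   # chain rule through a = exp(theta)
    g_b <- el$grad_b * b
    m_a <- b1 * m_a + (1 - b1) * g_a
    v_a <- b2 * v_a + (1 - b2) * g_a^2
    m_b <- b1 * m_b + (1 - b1) * g_b
    v_b <- b2 * v_b + (1 - b2) * g_b^2
    c1 <- 1 - b1^step; c2 <- 1 - b2^step
    theta_a <- theta_a - lr * (m_a / c1) / (sqrt(v_a / c2) + eps)
    theta_b <- theta_b - lr * (m_b / c1) / (sqrt(v_b / c2) + eps)
  }
  list(alpha = exp(theta_a), beta = exp(theta_b), trace = trace)
}

active_scales <- function(present, calibration) {
  if (!is.null(calibration$modality_scales)) {
    sc <- calibration$modality_scales
    missing <- setdiff(present, names(sc))
    # standalone calibration of a subset: default absent channels to 1
    if (length(missing) > 0) sc[missing] <- 1
    sc
  } else {
    stats::setNames(rep(1, length(present)), present)
  }
}

#' Fit the tumor-specificity model by stochastic variational inference
#'
#' Runs `config$epochs` Adam steps on the per-gene guide `Beta(alpha_i,
#' beta_i)`, with the coefficient guides fixed at their priors.  Any subset
#' of modalities may be supplied (leave-one-out mode); the count channel
#' `Y` requires a calibration carrying `y_ebayes` (see [calibrate()]).
#'
#' @param X a [tissue_distribution()], or `NULL`.
#' @param Y an [expression_panel()], or `NULL`.
#' @param Z a [protein_label_panel()], or `NULL`.
#' @param lfc an [lfc_observation()], or `NULL`.
#' @param weights named tissue-weight vector; defaults to 0.5 everywhere.
#'   Non-neutral weights also trigger protein label reassignment when `Z`
#'   carries slide tissues.
#' @param config a [model_config()].
#' @param calibration a [calibrate()] result; mandatory when `Y` is present
#'   or when more than one modality is supplied.
#' @return a `PosteriorSummary`: data frame `summary` (gene, score, ci_low,
#'   ci_high, guide_alpha, guide_beta), `elbo_trace`, `converged`, plus the
#'   config and scales used.
#' @export
fit_specificity <- function(X = NULL, Y = NULL, Z = NULL, lfc = NULL,
                            weights = NULL, config = model_config(),
                            calibration = NULL) {
  present <- c(if (!is.null(X)) "X", if (!is.null(Y)) "Y",
               if (!is.null(Z)) "Z", if (!is.null(lfc)) "LFC")
  abort_if(length(present) == 0, "supply at least one modality")
  abort_if(!is.null(Y) && is.null(calibration$y_ebayes),
           "Y modality requires a calibration with y_ebayes; run calibrate()")
  if (is.null(weights)) {
    tissues <- unique(c(if (!is.null(X)) colnames(X$fractions),
                        if (!is.null(Z)) Z$slide_tissue))
    weights <- tissue_weights(if (length(tissues)) tissues else "all")
  }
  if (!is.null(Z) && !is.null(Z$slide_tissue) &&
      any(weights[unique(Z$slide_tissue)] != 0.5)) {
    Z <- reweight_protein_labels(Z, weights, seed = config$seed + 7L)
  }
  scales <- active_scales(present, calibration)
  ev <- prepare_evidence(X, Y, Z, lfc, config)
  res <- with_seed(config$seed,
                   svi_run(ev, weights, config, calibration, scales))
  n10 <- max(1L, config$epochs %/% 10L)
  converged <- mean(utils::tail(res$trace, n10)) <=
    mean(utils::head(res$trace, n10))
  if (!converged) {
    warning("loss did not decrease over training; inspect elbo_trace")
  }
  score <- with_seed(config$seed + 13L, vapply(seq_len(ev$n), function(i) {
    bootstrap_mean_beta(res$alpha[i], res$beta[i], config$n_draws)
  }, 0))
  out <- list(
    summary = data.frame(
      gene = ev$genes, score = score,
      ci_low = stats::qbeta(0.025, res$alpha, res$beta),
      ci_high = stats::qbeta(0.975, res$alpha, res$beta),
      guide_alpha = res$alpha, guide_beta = res$beta,
      row.names = NULL),
    n_draws = config$n_draws,
    elbo_trace = res$trace, converged = converged,
    modalities = present, scales = scales,
    config = config, calibration = calibration
  )
  class(out) <- "PosteriorSummary"
  out
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf(
    "PosteriorSummary: %d genes, modalities [%s], %d epochs%s\n",
    nrow(x$summary), paste(x$modalities, collapse = ", "),
    length(x$elbo_trace), if (x$converged) "" else " (NOT converged)"))
  print(utils::head(x$summary))
  invisible(x)
}

#' Bootstrap posterior scores from a fitted summary
#'
#' Rescores each gene as the mean of `n_draws` samples from its learned
#' `Beta(alpha_i, beta_i)` guide; converges to `alpha/(alpha+beta)` as
#' `n_draws` grows.
#'
#' @param summary a `PosteriorSummary` from [fit_specificity()].
#' @param n_draws number of bootstrap draws (>= 1).
#' @param seed RNG seed.
#' @return named numeric vector of scores.
#' @export
score_posterior <- function(summary, n_draws = 1000L, seed = 1L) {
  abort_if(!is_scalar_number(n_draws) || n_draws < 1, "n_draws must be >= 1")
  s <- summary$summary
  with_seed(seed, stats::setNames(vapply(seq_len(nrow(s)), function(i) {
    bootstrap_mean_beta(s$guide_alpha[i], s$guide_beta[i], n_draws)
  }, 0), s$gene))
}

#' Log joint probability of the generative model at one latent draw
#'
#' Sums, for each gene, the log prior of sigma, the (unscaled) log priors
#' of the latent coefficients and totals, and each present modality's
#' observation log-likelihood multiplied by its calibration scale.
#' Deterministic given the latent draw; used for oracle checks and
#' diagnostics.
#'
#' @param latents list with `sigma` (n-vector) and, per present channel,
#'   `beta_y`, `beta_x`, `total` (per tissue), `beta_lfc`.
#' @param X,Y,Z,lfc evidence objects as in [fit_specificity()].
#' @param weights tissue weights (for the Binomial total prior).
#' @param config a [model_config()].
#' @param calibration [calibrate()] result (needed when `Y` present).
#' @return scalar log probability.
#' @export
model_log_joint <- function(latents, X = NULL, Y = NULL, Z = NULL,
                            lfc = NULL, weights = NULL,
                            config = model_config(), calibration = NULL) {
  abort_if(!is.null(Y) && is.null(calibration$y_ebayes),
           "Y modality requires a calibration with y_ebayes")
  present <- c(if (!is.null(X)) "X", if (!is.null(Y)) "Y",
               if (!is.null(Z)) "Z", if (!is.null(lfc)) "LFC")
  scales <- active_scales(present, calibration)
  ev <- prepare_evidence(X, Y, Z, lfc, config)
  s <- latents$sigma
  abort_if(length(s) != ev$n, "sigma must have one entry per gene")
  lp <- sum(stats::dbeta(s, config$prior_alpha, config$prior_beta,
                         log = TRUE))
  if (!is.null(Y)) {
    lp <- lp + sum(stats::dgamma(latents$beta_y, calibration$y_ebayes,
                                 rate = 1, log = TRUE))
  }
  if (!is.null(X)) {
    w <- weights %||% tissue_weights(ev$x$tissues)
    lp <- lp + sum(stats::dgamma(latents$beta_x,
                                 config$betax_prior[["shape"]],
                                 rate = config$betax_prior[["rate"]],
                                 log = TRUE)) +
      sum(stats::dbinom(latents$total, config$total_count_base,
                        w[ev$x$tissues], log = TRUE))
  }
  if (!is.null(lfc)) {
    lp <- lp + sum(stats::dbeta(latents$beta_lfc,
                                config$betalfc_prior[["alpha"]],
                                config$betalfc_prior[["beta"]], log = TRUE))
  }
  co <- evidence_coefficients(ev, latents, scales, config)
  lp + sum(co$A * log(s) + co$B * log(1 - s) + co$C * s + co$D * s^2 +
             co$E * log(s)^2 + co$const)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
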