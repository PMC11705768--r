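# AUPR benchmarking, predictive checks, reproducibility and ablations.

test_that("perfect rankings give AUPR 1 and degenerate labels error", {
  scores <- setNames(1:10 / 10, letters[1:10])
  expect_equal(compute_aupr(scores, letters[1:3])$aupr, 1.0)
  expect_error(compute_aupr(scores, letters[1:10]), "degenerate")
  expect_error(compute_aupr(scores, character(0)), "degenerate")
  expect_error(compute_aupr(scores, "zz"), "scored")
})

test_that("AUPR matches a brute-force cutoff sweep on a worked example", {
  # 6 items scored 1..6 ascending, positives at ranks 1 and 3
  scores <- setNames(c(1, 2, 3, 4, 5, 6), letters[1:6])
  positives <- c("a", "c")
  got <- compute_aupr(scores, positives)$aupr
  # oracle: explicit loop over every cutoff, step integration
  lab <- names(scores) %in% positives
  ord <- order(scores)
  oracle <- 0; prev_r <- 0
  for (k in seq_along(ord)) {
    tp <- sum(lab[ord][1:k]); p <- tp / k; r <- tp / sum(lab)
    oracle <- oracle + (r - prev_r) * p
    prev_r <- r
  }
  # hand value: cutoffs with recall gains at k=1 (P=1) and k=3 (P=2/3)
  expect_equal(oracle, 0.5 * 1 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("random scores average an AUPR near the prevalence", {
  set.seed(77)
  n <- 200; prevalence <- 0.25
  positives <- sprintf("g%03d", 1:(n * prevalence))
  universe <- sprintf("g%03d", 1:n)
  auprs <- replicate(40, {
    compute_aupr(setNames(runif(n), universe), positives)$aupr
  })
  expect_lt(abs(mean(auprs) - prevalence), 0.03)
})

test_that("AUPR is invariant to strictly monotone score transforms", {
  set.seed(78)
  scores <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  positives <- sample(names(scores), 12)
  base <- compute_aupr(scores, positives)$aupr
  expect_equal(compute_aupr(exp(scores), positives)$aupr, base)
  expect_equal(compute_aupr(rank(scores), positives)$aupr, base)
  # descending convention mirrors with negated scores
  expect_equal(compute_aupr(-scores, positives, ascending = FALSE)$aupr,
               base)
})

test_that("ties enter the PR curve as a group", {
  scores <- setNames(c(1, 1, 1, 2), letters[1:4])
  res <- compute_aupr(scores, c("a"))
  # the three tied items form one cutoff: precision 1/3 at recall 1
  expect_equal(res$aupr, 1 / 3)
  expect_equal(nrow(res$curve), 2L)
})

test_that("predictive checks bootstrap the prior and posterior", {
  sc <- shared_fit()
  chk <- predictive_check("g010", sc$fit, sc$sim$X, sc$sim$Y, sc$sim$Z,
                          config = quick_config(), calibration = sc$cal,
                          n_boot = 1000, seed = 3)
  # prior Beta(2,2) mean ~ 0.5 within 3 Monte-Carlo s.e.
  expect_lt(abs(chk$prior_sigma_mean - 0.5), 3 * sqrt(0.05) / sqrt(1000))
  # g010 sits near the bottom of the sigma grid: posterior must drop
  expect_lt(chk$posterior_sigma_mean, chk$prior_sigma_mean)
  # simulated evidence has the observed shapes
  expect_length(chk$prior_sim$x_counts, ncol(sc$sim$X$fractions))
  expect_length(chk$prior_sim$y_counts, ncol(sc$sim$Y$values))
  expect_length(chk$prior_sim$z_labels, ncol(sc$sim$Z$labels))
  expect_error(predictive_check("nope", sc$fit, config = quick_config()),
               "nope")
  expect_error(predictive_check("g010", sc$fit, n_boot = 0), "n_boot")
})

test_that("posterior label draws reflect the categorical link", {
  sc <- shared_fit()
  # a high-sigma gene: fraction of "high" labels should approach 2 s / 3
  chk <- predictive_check("g118", sc$fit, Z = sc$sim$Z,
                          config = quick_config(), n_boot = 1000, seed = 5)
  # pool many label draws for a tight empirical fraction
  set.seed(6)
  draws <- sample(0:3, 3000, replace = TRUE,
                  prob = category_probs(chk$posterior_sigma_mean)[1, ])
  expected <- 2 * chk$posterior_sigma_mean / 3
  expect_lt(abs(mean(draws == 0) - expected),
            3 * sqrt(expected * (1 - expected) / 3000))
})

test_that("reproducibility study shapes and determinism", {
  sc <- shared_sim()
  # distinct seeds on a small subset: one row per gene, finite dispersion
  sub <- function(m, field) {
    m[[field]] <- m[[field]][sprintf("g%03d", seq(10, 100, 10)), ]
    m
  }
  rep5 <- reproducibility_study(sub(sc$sim$X, "fractions"),
                                Z = sub(sc$sim$Z, "labels"),
                                config = quick_config(epochs = 300),
                                calibration = sc$cal, n_runs = 3)
  expect_equal(dim(rep5$scores), c(10L, 3L))
  expect_equal(nrow(rep5$dispersion), 10L)
  expect_true(all(rep5$dispersion$sd < 0.2))
  expect_error(reproducibility_study(sc$sim$X, n_runs = 1), "n_runs")

  # identical seeds give exactly zero dispersion
  f1 <- fit_specificity(sub(sc$sim$X, "fractions"),
                        config = quick_config(epochs = 200),
                        calibration = sc$cal)
  f2 <- fit_specificity(sub(sc$sim$X, "fractions"),
                        config = quick_config(epochs = 200),
                        calibration = sc$cal)
  expect_identical(f1$summary$score, f2$summary$score)
})

test_that("leave-one-out keeps four score columns and tracks the full fit", {
  sc <- shared_sim()
  keep <- sprintf("g%03d", seq(5, 120, 5))
  X <- sc$sim$X; X$fractions <- X$fractions[keep, ]
  Y <- sc$sim$Y; Y$values <- Y$values[keep, ]
  Z <- sc$sim$Z; Z$labels <- Z$labels[keep, ]
  res <- leave_one_out_study(X, Y, Z, config = quick_config(epochs = 400),
                             calibration = sc$cal)
  expect_setequal(names(res$scores), c("gene", "full", "no_X", "no_Y",
                                       "no_Z"))
  expect_equal(nrow(res$scores), length(keep))
  # all modalities were simulated from the same sigma, so every ablation
  # stays strongly rank-correlated with the full fit
  expect_true(all(res$correlations > 0.8))
  expect_error(leave_one_out_study(X, Y, NULL), "three modalities")
})

test_that("independent protein noise only matters when Z is included", {
  # regenerate Z as pure noise, unrelated to the sigma that built X and Y
  sc <- shared_sim()
  set.seed(99)
  keep <- sprintf("g%03d", seq(4, 120, 4))
  X <- sc$sim$X; X$fractions <- X$fractions[keep, ]
  Y <- sc$sim$Y; Y$values <- Y$values[keep, ]
  noise_sigma <- runif(length(keep), 0.05, 0.95)
  lab <- t(vapply(noise_sigma, function(s) {
    sample(0:3, 40, replace = TRUE, prob = category_probs(s)[1, ])
  }, integer(40)))
  rownames(lab) <- keep
  Z <- protein_label_panel(lab)
  res <- leave_one_out_study(X, Y, Z, config = quick_config(epochs = 500),
                             calibration = sc$cal)
  # without Z the fit cannot know the protein noise: correlation of the
  # no-Z scores with the noise sigma stays weak, while a Z-only fit
  # tracks it closely
  no_z_r <- abs(cor(res$scores$no_Z, noise_sigma, method = "spearman"))
  expect_lt(no_z_r, 0.35)
  z_only <- fit_specificity(Z = Z, config = quick_config(epochs = 500),
                            calibration = sc$cal)
  expect_gt(cor(z_only$summary$score, noise_sigma, method = "spearman"),
            0.9)
})
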