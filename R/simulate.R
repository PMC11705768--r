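# Generative simulator: samples complete synthetic datasets from the
# model's own hierarchical process at known sigma, so every downstream
# module is testable without external downloads.

#' Specify a synthetic dataset
#'
#' Defaults describe a desk-scale healthy-tissue reference: 30 tissues of
#' 25 samples each (the typical per-tissue depth of large references),
#' 89 IHC slides per gene (the average slide count of public protein
#' atlases), x-coefficient 25 matching the Gamma(25, 1) prior, and
#' y-coefficient 8 so simulated TPMs span roughly 1-10^3.
#'
#' @param n_genes number of targets.
#' @param n_tissues number of tissues (T).
#' @param samples_per_tissue samples per tissue; `S = T * samples_per_tissue`.
#' @param slides_per_gene IHC slides per gene (P).
#' @param sigma_true per-gene specificities in (0, 1); default an even grid
#'   on \[0.05, 0.95\].
#' @param y_coefficient Gamma shape of the count coefficient.
#' @param x_coefficient Gamma shape of the tissue coefficient.
#' @param lognormal_scale LogNormal scale of the count channel.
#' @param seed RNG seed.
#' @return a `SimulationSpec` list.
#' @export
simulation_spec <- function(n_genes = 200L, n_tissues = 30L,
                            samples_per_tissue = 25L, slides_per_gene = 89L,
                            sigma_true = NULL, y_coefficient = 8,
                            x_coefficient = 25, lognormal_scale = 0.5,
                            seed = 1L) {
  if (is.null(sigma_true)) {
    sigma_true <- seq(0.05, 0.95, length.out = n_genes)
  }
  abort_if(length(sigma_true) != n_genes,
           "sigma_true must have one value per gene")
  abort_if(any(sigma_true <= 0 | sigma_true >= 1),
           "sigma_true must lie strictly in (0, 1)")
  counts <- c(n_genes, n_tissues, samples_per_tissue, slides_per_gene)
  abort_if(any(counts < 1), "all counts must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 slides_per_gene = as.integer(slides_per_gene),
                 sigma_true = sigma_true,
                 y_coefficient = y_coefficient,
                 x_coefficient = x_coefficient,
                 lognormal_scale = lognormal_scale,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate a complete multimodal dataset at known sigma
#'
#' Per gene draws `beta_x ~ Gamma(x_coefficient, 1)` and
#' `beta_y ~ Gamma(y_coefficient, 1)`; per tissue a Poisson
#' `(beta_x * sigma)` detection count capped at `samples_per_tissue`
#' (converted to a fraction); per sample a `LogNormal(beta_y * sigma,
#' scale)` count; per slide a categorical staining label with
#' probabilities `(2s/3, s/3, (1-s)/3, 2(1-s)/3)`.  Slides are spread
#' evenly across tissues so the panel supports tissue weighting.
#'
#' @param spec a [simulation_spec()].
#' @return list with `X` ([tissue_distribution()]), `Y`
#'   ([expression_panel()]), `Z` ([protein_label_panel()]) and
#'   `sigma_true` (named vector).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  n <- spec$n_genes; T_ <- spec$n_tissues
  spt <- spec$samples_per_tissue; P <- spec$slides_per_gene
  genes <- sprintf("g%03d", seq_len(n))
  tissues <- sprintf("tissue%02d", seq_len(T_))
  with_seed(spec$seed, {
    beta_x <- stats::rgamma(n, spec$x_coefficient, rate = 1)
    beta_y <- stats::rgamma(n, spec$y_coefficient, rate = 1)
    lam <- beta_x * spec$sigma_true
    det <- matrix(stats::rpois(n * T_, rep(lam, T_)), nrow = n)
    capped <- det > spt
    if (mean(capped) > 0.5) {
      warning(sprintf(
        "detection cap hit for %.0f%% of cells; sigma * beta_x too large for %d samples/tissue",
        100 * mean(capped), spt))
    }
    det[capped] <- spt
    frac <- det / spt
    dimnames(frac) <- list(genes, tissues)
    X <- tissue_distribution(frac, stats::setNames(rep(spt, T_), tissues))

    S <- T_ * spt
    mu <- beta_y * spec$sigma_true
    Yv <- matrix(stats::rlnorm(n * S, meanlog = rep(mu, S),
                               sdlog = spec$lognormal_scale), nrow = n)
    samples <- sprintf("s%04d", seq_len(S))
    dimnames(Yv) <- list(genes, samples)
    sample_tissue <- stats::setNames(rep(tissues, each = spt), samples)
    Y <- expression_panel(Yv, sample_tissue)

    probs <- category_probs(spec$sigma_true)
    Zv <- matrix(0L, nrow = n, ncol = P, dimnames = list(genes, NULL))
    for (i in seq_len(n)) {
      Zv[i, ] <- sample(0:3, P, replace = TRUE, prob = probs[i, ])
    }
    slide_tissue <- rep_len(tissues, P)
    Z <- protein_label_panel(Zv, slide_tissue)
    list(X = X, Y = Y, Z = Z,
         sigma_true = stats::setNames(spec$sigma_true, genes))
  })
}

#' Two tissue-complementary genes for AND-gate tests
#'
#' Builds a dataset where gene `geneA` behaves highly expressed only in
#' the first half of the tissues and `geneB` only in the second half, both
#' near-undetectable elsewhere.  Their AND-gate pair evidence is therefore
#' near zero everywhere — the mutual-exclusivity scenario.  Optionally
#' appends background genes simulated at the given sigmas.
#'
#' @param spec a [simulation_spec()] (needs `n_tissues >= 2`).
#' @param high_mu log-scale expression in the gene's own tissue block.
#' @param low_value TPM floor outside the block.
#' @return same shape as [simulate_dataset()], genes `geneA`, `geneB`
#'   first, plus `spec$n_genes` background genes.
#' @export
make_exclusive_pair_fixture <- function(spec = simulation_spec(n_genes = 20L),
                                        high_mu = 3, low_value = 0.01) {
  abort_if(spec$n_tissues < 2, "need at least two tissues")
  base <- simulate_dataset(spec)
  T_ <- spec$n_tissues; spt <- spec$samples_per_tissue
  P <- spec$slides_per_gene
  tissues <- colnames(base$X$fractions)
  block1 <- tissues[seq_len(T_ %/% 2)]
  block2 <- setdiff(tissues, block1)
  with_seed(spec$seed + 1L, {
    mk_gene <- function(own_block) {
      in_block <- colnames(base$X$fractions) %in% own_block
      x <- ifelse(in_block, 1, 0)
      samp_in <- base$Y$sample_tissue %in% own_block
      y <- ifelse(samp_in,
                  stats::rlnorm(ncol(base$Y$values), high_mu,
                                spec$lognormal_scale),
                  low_value)
      slide_in <- base$Z$slide_tissue %in% own_block
      z <- ifelse(slide_in, 0L, 3L)
      list(x = x, y = y, z = z)
    }
    a <- mk_gene(block1); b <- mk_gene(block2)
    X <- tissue_distribution(
      rbind(geneA = a$x, geneB = b$x, base$X$fractions),
      base$X$samples_per_tissue)
    Y <- expression_panel(
      rbind(geneA = a$y, geneB = b$y, base$Y$values),
      base$Y$sample_tissue)
    Z <- protein_label_panel(
      rbind(geneA = a$z, geneB = b$z, base$Z$labels),
      base$Z$slide_tissue)
    list(X = X, Y = Y, Z = Z,
         sigma_true = c(geneA = NA_real_, geneB = NA_real_,
                        base$sigma_true),
         pair = c("geneA", "geneB"))
  })
}
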