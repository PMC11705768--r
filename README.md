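# tumorspec

Bayesian tumor-specificity scoring of therapeutic targets from multimodal
normal-tissue evidence.

## The problem

Cell and immunotherapies (CAR-T, vaccines, antibody-drug conjugates) fail
dangerously when their target is also expressed in healthy tissue —
on-target, off-tumor toxicity. Deciding whether a candidate target (a gene,
a splice junction, any druggable entity) is *absent enough* from normal
tissue is usually done with ad-hoc cutoffs applied to one data type at a
time. `tumorspec` instead infers a single continuous **tumor-specificity
score σ ∈ (0, 1)** per target — low σ means low normal-tissue presence,
hence a safer target — by jointly modeling three independent lines of
healthy-reference evidence:

- **X** (genes × tissues): the fraction of samples per tissue in which the
  target is detected above a cutoff,
- **Y** (genes × samples): TPM-like normalized RNA counts,
- **Z** (genes × slides): immunohistochemistry staining labels
  (high / medium / low / not detected, coded 0–3).

## The model

Each target's σ ties the three channels together through a hierarchical
generative model:

    σ_i        ~ Beta(2, 2)                         weakly informative prior
    β_y,i      ~ Gamma(y_ebayes, 1)
    Y_is       ~ LogNormal(β_y,i · σ_i, 0.5)
    β_x,i      ~ Gamma(25, 1)
    Total_t    ~ Binomial(50, w_t)                  w_t = tissue weight, default 0.5
    Total_t·X_it ~ Poisson(β_x,i · σ_i)
    Z_ip       ~ Categorical(2σ/3, σ/3, (1−σ)/3, 2(1−σ)/3)

`y_ebayes` is calibrated empirically by percentile-anchored no-intercept
regression of per-gene LogNormal locations on a σ grid. The posterior over
σ is approximated by stochastic variational inference with a per-gene
Beta(α, β) guide (coefficients keep their priors as guides), trained with
Adam (lr 0.002, betas 0.95/0.999, 5,000 epochs); per-modality
log-likelihoods are rescaled so no single evidence type dominates the ELBO.
The reported score is the mean of 1,000 bootstrap draws from the learned
guide.

On top of the base model the package provides per-tissue importance
weights (shrinking or amplifying a tissue's evidence on both the RNA and
protein side), an optional tumor-vs-normal log-fold-change channel
(`lfc = −log10(σ)·β_lfc`, β_lfc ~ Beta(2, 1)), logic-AND combinatorial
pair scoring (pair evidence = per-element minimum expression), AUPR
benchmarking, prior/posterior predictive checks, and a generative
simulator producing fully synthetic datasets at known σ.

## Worked example

Simulate a 120-gene dataset from the model at a known σ grid, calibrate,
fit, and score AND-gate pairs:

```r
library(tumorspec)

spec <- simulation_spec(n_genes = 120, n_tissues = 12,
                        samples_per_tissue = 12, slides_per_gene = 40,
                        seed = 21)
sim <- simulate_dataset(spec)

cfg <- model_config(epochs = 2000, seed = 1)
cal <- calibrate(sim$X, sim$Y, sim$Z, config = cfg)
round(cal$y_ebayes, 3)
#> [1] 8.575
round(cal$modality_scales, 3)
#>     X     Y     Z
#> 0.483 0.011 1.000

fit <- fit_specificity(sim$X, sim$Y, sim$Z, config = cfg, calibration = cal)
fit
#> PosteriorSummary: 120 genes, modalities [X, Y, Z], 2000 epochs
#>   gene      score      ci_low   ci_high guide_alpha guide_beta
#> 1 g001 0.09253825 0.003340185 0.3125675    1.078937  10.242516
#> 2 g002 0.14829437 0.016814438 0.3991249    1.757798   9.746496
#> ...
cor(fit$summary$score, sim$sigma_true, method = "spearman")
#> [1] 0.925
```

`g001` was simulated at σ_true = 0.05 and is recovered near 0.09 with a
credible interval hugging zero — a "safe" call — while the fitted scores
rank the full σ grid at Spearman ρ = 0.93. Pair scoring reports each
pair's joint score and `delta`, its improvement over the better singleton:

```r
res <- score_pairs(c("g001", "g002", "g119", "g120"), sim$X, sim$Y, sim$Z,
                   config = cfg, calibration = cal)
head(as.data.frame(res)[, c("pair", "pair_score", "score_a", "score_b", "delta")], 3)
#>        pair pair_score    score_a   score_b        delta
#> 1 g001|g002 0.08078770 0.09339289 0.1498592  0.012605189
#> 2 g001|g119 0.09466316 0.09339289 0.8046699 -0.001270268
#> 3 g001|g120 0.09638460 0.09339289 0.8004531 -0.002991715
```

## Command line

```sh
Rscript inst/cli/tumorspec.R simulate --genes 200 --out sim/
Rscript inst/cli/tumorspec.R train --y sim/Y.tsv --tissue_map sim/tissue_map.tsv \
    --x sim/X.tsv --z sim/Z.tsv --out run/
Rscript inst/cli/tumorspec.R weights --x sim/X.tsv --set testis=0.1 --out run_w/
Rscript inst/cli/tumorspec.R pairs --x sim/X.tsv --z sim/Z.tsv \
    --targets targets.txt --out pairs/
Rscript inst/cli/tumorspec.R check --x sim/X.tsv --z sim/Z.tsv --gene g001 --out chk/
Rscript inst/cli/tumorspec.R benchmark --scores run/scores.tsv \
    --positives safe_targets.txt --out bench/
```

Every `train` run writes `scores.tsv`, `elbo_trace.tsv`, `calibration.tsv`
and a `manifest.json` from which the run is reproducible.

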