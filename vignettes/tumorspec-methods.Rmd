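---
title: "Methods: multimodal Bayesian tumor-specificity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal Bayesian tumor-specificity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorspec)
```

## The model and its assumptions

`tumorspec` treats a target's presence in healthy tissue as a single
latent quantity σ ∈ (0, 1) and assumes every observed line of evidence is
generated from it:

* **Prior.** σ ~ Beta(2, 2): symmetric around 0.5, with 79.2% of the mass
  in (0.2, 0.8) and only 2.8% below 0.1 (CDF `3x² − 2x³`), so the data —
  not the prior — decide whether a target is called safe.
* **Normalized counts (Y).** `Y_is ~ LogNormal(β_y·σ, 0.5)` with
  `β_y ~ Gamma(y_ebayes, 1)`. A fixed scale of 0.5 assumes no strong
  overdispersion on the log scale; the exponential magnitude of a
  LogNormal matches TPM-like data. Zeros have no LogNormal density; they
  are floored at the smallest positive value of the panel before taking
  logs (their "absence" information still enters through X), a pragmatic
  choice that keeps all genes scoreable.
* **Tissue detection (X).** Fractions are converted to counts through the
  per-tissue total `Total_t ~ Binomial(50, w_t)` and modeled as
  `Total_t·X_it ~ Poisson(β_x·σ)` with `β_x ~ Gamma(25, 1)`: a target at
  medium presence should be seen in about half of a typical 25-sample
  tissue. The Poisson log-pmf is evaluated with a continuous count
  argument (`k·log λ − λ − lgamma(k+1)`) because scaled fractions are not
  integers.
* **Protein labels (Z).** Each slide's staining level is categorical with
  probabilities `(2σ/3, σ/3, (1−σ)/3, 2(1−σ)/3)` over
  high/medium/low/not-detected (coded 0–3; note some public atlases'
  narrative text numbers the levels differently — the coding here is fixed
  by `label_semantics()`).
* **Fold change (optional).** A reported tumor-vs-normal log fold change
  seeds 100 pseudo-observations `~ Normal(lfc, 0.5)` linked by
  `lfc = −log10(σ)·β_lfc`, `β_lfc ~ Beta(2, 1)`. Only the *direction* of
  this channel is contractual: with β_lfc confined to (0, 1), specific
  absolute score values for conventional LFC cutoffs cannot be guaranteed,
  so the package (and its tests) assert monotonicity — higher fold change,
  lower score — and nothing sharper.

## Inference

The posterior over σ is approximated by stochastic variational inference.
The guide is a per-gene Beta(α_i, β_i); the coefficients β_x, β_y, β_lfc
and the totals keep their priors as guides, so their KL terms vanish and
the ELBO is

E<sub>q(σ)</sub> E<sub>priors</sub>[ Σ_m c_m · log p_m(data | σ, coeffs) ]
− KL(q(σ) ‖ Beta(2, 2)).

**Closed-form expectations.** Every channel's log-likelihood is, as a
function of σ, a linear combination of `log σ`, `log(1−σ)`, `σ`, `σ²` and
`log(σ)²`. Under a Beta guide each of those has an exact expectation in
digamma/trigamma terms, and the KL between Betas is analytic. The
implementation therefore computes the σ-expectation *exactly* and keeps
stochasticity only where the generative description has it: one fresh
draw per epoch of the coefficients (from their priors) and of the
per-tissue totals (`resample_total = TRUE` by default; a config switch
fixes them at their means). Compared to a sampled-σ estimator this is a
pure variance reduction of the same objective — the optimum is unchanged,
convergence is faster and the engine needs no autodiff framework. This
is the package's main numerical design choice.

**Optimizer.** Hand-rolled Adam on (log α, log β) with learning rate
0.002, betas (0.95, 0.999), 5,000 epochs (converging typically by
~2,000), initialized at the prior α = β = 2 (score 0.5). Convergence is
asserted by comparing the mean loss of the last 10% of epochs against the
first 10%; a non-finite loss aborts with a suggestion to lower the
learning rate.

**Scoring.** The reported score is the Monte-Carlo mean of 1,000 draws
from the learned Beta guide under a fixed scoring seed (converging to
α/(α+β)); the 95% interval is the guide's equal-tailed Beta quantile
interval.

## Calibration

* **Count coefficient.** Each gene's empirical mean m_g is inverted to a
  LogNormal location `μ_g = ln(m_g) − 0.5²/2` (the printed source formula
  for this inversion is typographically garbled; this is the standard
  lognormal mean inversion consistent with the likelihood). The i-th
  percentile of the μ values anchors σ = i/100, and a no-intercept least
  squares fit of μ on σ yields `y_ebayes`. Type-7 quantile interpolation
  is used; zero-mean genes are floored at the smallest positive mean.
* **Modality scales.** Because the three channels have very different
  numbers of observations, each is first trained alone; the running
  maximum L_m of each standalone loss trace sets `c_m = min(L)/L_m`, so
  all scaled maximum losses equal the smallest one and no channel
  dominates the joint fit. "Maximum loss" is read as the running maximum
  of the trace (the source does not specify initial-vs-running; the
  running maximum is invariant to warm-up noise).

## Tissue weights

A weight w_t ∈ [0, 1] per tissue (0.5 = neutral) acts twice. On the RNA
side it is the Binomial success probability of `Total_t`, so a tissue at
w = 0.1 only distributes ~5 counts instead of ~25 — even 90% detection
there contributes a scaled count of 4.5. On the protein side labels are
stochastically reassigned once per fit (fixed seed, as a preprocessing
transform of Z, not re-sampled per SVI step): for w < 0.5 each expressed
label survives with probability `sf = w/0.5` and otherwise becomes
"not detected" (at w = 0.1, survival 0.2); for w > 0.5 each non-high
label is promoted to "high" with probability `sf = w/0.5 − 1` (at
w = 0.9, promotion 0.8, i.e. survival 0.2); at w = 0.5 nothing changes.
Total label counts per gene are conserved. For w > 0.5 labels convert
*directly* to "high" (no one-level escalation) — the printed update rule
is explicit about the destination label. Both sides are driven by the
same weight vector.

## AND-gate pairs

For a pair, the effective expression in any healthy sample is the lower
of the two targets: per-sample minima on Y, per-tissue minima on X, and
on Z the lower-expression label (the *higher* numeric code) after
aligning the two genes' slides within each tissue by sorting codes
ascending (the source states only that the min rule applies to protein
levels; positionwise combination after within-tissue sorting makes the
result permutation-invariant and idempotent for self-pairs). Per-tissue
minima on X were preferred over recomputing X from paired per-sample Y
(the source is silent; the per-sample route can be had by rebuilding X
from the paired panel with `build_tissue_distribution()`). Pairs are
fitted exactly like singletons; `delta = min(score_a, score_b) −
pair_score` quantifies the gain from gating. Self-pairs are excluded by
default (`include_self` re-enables them for testing).

## The simulator: what it emulates and what it does not

`simulate_dataset()` runs the generative model forward at known σ:
defaults of 30 tissues × 25 samples (the typical per-tissue depth of
large healthy references), 89 slides per gene (the average slide count in
public protein atlases), x-coefficient 25 matching its prior, and
y-coefficient 8 — chosen once so simulated TPMs span roughly 1–10³ — with
a default σ grid on [0.05, 0.95]. Poisson detection counts are truncated
at the per-tissue sample count so fractions stay in [0, 1] (the
generative description does not address the cap; a warning fires if more
than half the cells hit it, meaning σ·β_x outran the sample budget).

The simulator deliberately does **not** emulate batch structure, library
size variation, within-tissue correlation, slide metadata beyond the
tissue label, or annotation reliability grades. A green recovery test
therefore establishes that the inference machinery inverts the model's
own generative process — not that the model is well-specified for any
particular real reference cohort.

## Numerical choices and degenerate inputs

* Detection is strict `value > cutoff`, so cutoff 0 means "any nonzero
  count"; tissues with fewer than 10 samples are excluded by default.
* Cutoff optimization breaks criterion ties toward the smallest cutoff
  (prefer sensitivity); a constant reference is rejected as undefined.
* Slide-count normalization uses largest-remainder rounding (ties to the
  earlier level) so every gene's labels sum exactly to P.
* Gene sets are intersected across modalities before fitting, with the
  dropped count logged.
* AUPR uses the non-interpolated step integral with tie groups entering
  as a block, on ascending score rank (most specific first); degenerate
  label sets (all or no positives) are errors.
* All randomness flows through explicit seeds; fits, simulations and
  label reassignments are bitwise reproducible at a fixed seed, and the
  run manifest records the full configuration.

## Known limitations

* Coefficient posteriors are deliberately *not* learned (guides pinned to
  priors, as specified): σ absorbs all adaptation, which can bias
  absolute scores when a gene's magnitude deviates strongly from the
  calibrated coefficient scale — rank order is much more stable, and the
  tests assert ranks.
* Standalone maximum losses must be positive for the scale rule to make
  sense; on unrealistically tiny fixtures continuous log-densities can
  flip the sign, which raises an informative error.
* The LFC channel's absolute score mapping is not contractual (see
  above).
* Real-atlas protein tables pool slides across tissues after rescaling,
  so tissue-weighted label reassignment requires slide-level tissue
  annotation (`protein_label_panel(..., slide_tissue = )`), which the
  simulator provides and public downloads generally do not.
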