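# Tissue-importance weighting.  A weight w_t in [0,1] per tissue, 0.5 being
# neutral.  On the RNA side the weight sets the Binomial success probability
# of the per-tissue total count (Total_t ~ Binomial(base, w_t)); on the
# protein side it stochastically reassigns staining labels toward
# "not detected" (w < 0.5) or "high" (w > 0.5).

#' Build a tissue weight vector
#'
#' @param tissues character vector of tissue names.
#' @param weights named numeric vector of overrides in \[0,1\]; tissues not
#'   listed keep the neutral default 0.5.
#' @return named numeric vector over `tissues`.
#' @export
tissue_weights <- function(tissues, weights = NULL) {
  w <- stats::setNames(rep(0.5, length(tissues)), tissues)
  if (!is.null(weights)) {
    abort_if(is.null(names(weights)), "weight overrides must be named")
    unknown <- setdiff(names(weights), tissues)
    abort_if(length(unknown) > 0, "unknown tissue(s): %s",
             paste(unknown, collapse = ", "))
    abort_if(any(weights < 0 | weights > 1), "weights must lie in [0, 1]")
    w[names(weights)] <- weights
  }
  w
}

#' Read tissue weights from a JSON or two-column TSV file
#'
#' @param path JSON object `{tissue: weight}` or a TSV with columns
#'   `tissue`, `weight`.
#' @param tissues tissue universe; unlisted tissues default to 0.5.
#' @return named numeric vector.
#' @export
read_tissue_weights <- function(path, tissues) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    overrides <- stats::setNames(as.numeric(raw), names(raw))
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t")
    overrides <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  }
  tissue_weights(tissues, overrides)
}

#' Expected per-tissue total count under a weight
#'
#' The total count a tissue can distribute is `Binomial(base, w)`; its mean
#' is `base * w` (25 at the neutral weight 0.5 with the default base 50).
#'
#' @param w weight in \[0,1\].
#' @param base binomial size (default 50).
#' @param sample if `TRUE`, return one random draw instead of the mean.
#' @return expected (or sampled) total count.
#' @export
expected_tissue_total <- function(w, base = 50L, sample = FALSE) {
  abort_if(any(w < 0 | w > 1), "weight must lie in [0, 1]")
  abort_if(!is_scalar_number(base) || base < 1, "base must be >= 1")
  if (sample) stats::rbinom(length(w), as.integer(base), w) else base * w
}

#' Scale detection fractions by per-tissue totals
#'
#' Converts fractions to the count scale consumed by the Poisson channel:
#' `scaledX[g, t] = Total_t * X[g, t]`.
#'
#' @param X a [tissue_distribution()].
#' @param totals numeric vector of per-tissue totals, recycled or named by
#'   tissue.
#' @return numeric matrix genes x tissues.
#' @export
scale_tissue_counts <- function(X, totals) {
  abort_if(any(totals < 0), "totals must be non-negative")
  if (!is.null(names(totals))) {
    abort_if(!all(colnames(X$fractions) %in% names(totals)),
             "totals must cover every tissue in X")
    totals <- totals[colnames(X$fractions)]
  } else {
    abort_if(length(totals) != 1L && length(totals) != ncol(X$fractions),
             "totals must align with the %d tissues", ncol(X$fractions))
  }
  sweep(X$fractions, 2L, totals, `*`)
}

#' Label-reassignment probabilities for a tissue weight
#'
#' For `w < 0.5` the scaling factor is `w / 0.5`: expressed labels
#' (high/medium/low) survive with that probability, otherwise they are
#' replaced by "not detected".  For `w > 0.5` the scaling factor is
#' `w / 0.5 - 1`: medium/low/not-detected labels are promoted to "high"
#' with that probability (i.e. they survive with its complement).  At
#' `w = 0.5` nothing changes.
#'
#' @param w weight in \[0,1\].
#' @return list with `direction` (`"down"`, `"up"`, `"none"`), `sf` (the
#'   scaling factor) and `replace_prob` (the per-label Bernoulli
#'   replacement probability).
#' @export
protein_scaling_factor <- function(w) {
  abort_if(!is_scalar_number(w) || w < 0 || w > 1, "weight must be in [0, 1]")
  if (w < 0.5) {
    sf <- w / 0.5
    list(direction = "down", sf = sf, replace_prob = 1 - sf)
  } else if (w > 0.5) {
    sf <- w / 0.5 - 1
    list(direction = "up", sf = sf, replace_prob = sf)
  } else {
    list(direction = "none", sf = 1, replace_prob = 0)
  }
}

#' Reassign protein labels according to tissue weights
#'
#' Applies the stochastic label update per tissue and gene: with weight
#' `w < 0.5` each expressed label (codes 0-2) independently survives with
#' probability `w/0.5` and is otherwise set to "not detected"; with
#' `w > 0.5` each non-high label (codes 1-3) is promoted to "high" with
#' probability `w/0.5 - 1`.  Total label counts per gene are conserved.
#' Applied once, before fitting, under the given seed.
#'
#' @param Z a [protein_label_panel()] with `slide_tissue` set.
#' @param weights named weight vector covering the slide tissues.
#' @param seed integer seed for the Bernoulli draws.
#' @return a new [protein_label_panel()].
#' @export
reweight_protein_labels <- function(Z, weights, seed = 1L) {
  abort_if(is.null(Z$slide_tissue),
           paste("protein panel lacks slide-level tissue annotation;",
                 "supply slide_tissue to protein_label_panel()"))
  abort_if(!all(unique(Z$slide_tissue) %in% names(weights)),
           "weights must cover every slide tissue")
  lab <- Z$labels
  with_seed(seed, {
    for (t in unique(Z$slide_tissue)) {
      fac <- protein_scaling_factor(weights[[t]])
      if (fac$direction == "none") next
      cols <- which(Z$slide_tissue == t)
      block <- lab[, cols, drop = FALSE]
      if (fac$direction == "down") {
        eligible <- block %in% 0:2
        flip <- stats::runif(length(block)) > fac$sf  # survive w.p. sf
        block[eligible & flip] <- 3L
      } else {
        eligible <- block %in% 1:3
        flip <- stats::runif(length(block)) < fac$sf  # promote w.p. sf
        block[eligible & flip] <- 0L
      }
      lab[, cols] <- block
    }
  })
  protein_label_panel(lab, Z$slide_tissue)
}
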