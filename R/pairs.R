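# Logic-AND combinatorial target pairs.  An AND-gated therapy requires
# both antigens on the same cell, so the pair's effective expression in a
# healthy sample is the lower of the two: per-sample minima on Y,
# per-tissue minima on X, and the lower-expression (higher-code) label on
# aligned protein slides.  Pair evidence is then scored with the standard
# model.

#' Enumerate all unordered target pairs
#'
#' @param targets character vector of unique identifiers (n >= 2).
#' @return data frame with columns `a`, `b` in lexicographic order;
#'   `n (n - 1) / 2` rows.
#' @export
enumerate_pairs <- function(targets) {
  abort_if(length(targets) < 2, "need at least two targets")
  abort_if(anyDuplicated(targets) > 0, "duplicate target identifiers")
  s <- sort(targets)
  idx <- utils::combn(length(s), 2L)
  data.frame(a = s[idx[1L, ]], b = s[idx[2L, ]],
             stringsAsFactors = FALSE)
}

pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# Align two genes' slide codes for the min rule: within each tissue (or
# globally when no tissue annotation) codes are sorted ascending and
# combined positionwise with pmax (higher code = lower expression).
combine_protein_rows <- function(za, zb, slide_tissue) {
  if (is.null(slide_tissue)) {
    return(pmax(sort(za), sort(zb)))
  }
  out <- integer(length(za))
  for (t in unique(slide_tissue)) {
    idx <- which(slide_tissue == t)
    out[idx] <- pmax(sort(za[idx]), sort(zb[idx]))
  }
  out
}

#' Derive AND-gate evidence for one target pair
#'
#' @param a,b target identifiers present in every supplied matrix.
#' @param X,Y,Z evidence objects (any subset non-`NULL`).
#' @return list with `x` (per-tissue minima), `y` (per-sample minima),
#'   `z` (combined slide codes); absent modalities are `NULL`.
#' @export
derive_pair_evidence <- function(a, b, X = NULL, Y = NULL, Z = NULL) {
  need <- function(obj, modality) {
    for (g in c(a, b)) {
      abort_if(!g %in% gene_ids(obj),
               "target %s missing from modality %s", g, modality)
    }
  }
  out <- list(x = NULL, y = NULL, z = NULL)
  if (!is.null(X)) {
    need(X, "X")
    out$x <- pmin(X$fractions[a, ], X$fractions[b, ])
  }
  if (!is.null(Y)) {
    need(Y, "Y")
    out$y <- pmin(Y$values[a, ], Y$values[b, ])
  }
  if (!is.null(Z)) {
    need(Z, "Z")
    out$z <- combine_protein_rows(Z$labels[a, ], Z$labels[b, ],
                                  Z$slide_tissue)
  }
  out
}

assemble_pair_matrices <- function(pairs, X, Y, Z) {
  ids <- pair_id(pairs$a, pairs$b)
  rows <- lapply(seq_len(nrow(pairs)),
                 function(i) derive_pair_evidence(pairs$a[i], pairs$b[i],
                                                  X, Y, Z))
  stack <- function(field, cols) {
    m <- do.call(rbind, lapply(rows, `[[`, field))
    dimnames(m) <- list(ids, cols)
    m
  }
  list(
    X = if (!is.null(X)) {
      tissue_distribution(stack("x", colnames(X$fractions)),
                          X$samples_per_tissue)
    },
    Y = if (!is.null(Y)) {
      expression_panel(stack("y", colnames(Y$values)), Y$sample_tissue)
    },
    Z = if (!is.null(Z)) {
      protein_label_panel(stack("z", NULL), Z$slide_tissue)
    }
  )
}

#' Score all AND-gate pairs of a target set
#'
#' Fits the model once on the singleton targets and once on the derived
#' pair evidence, and reports per pair its score, both singleton scores,
#' and `delta = min(singleton scores) - pair score` (the specificity
#' gained by gating).
#'
#' @param targets identifiers to pair (>= 2, unique).
#' @param X,Y,Z evidence objects covering the targets.
#' @param weights tissue weights (optional).
#' @param config a [model_config()].
#' @param calibration a [calibrate()] result.
#' @param include_self also score self-pairs (testing aid; default off).
#' @param score_threshold,delta_threshold optional filters echoed in the
#'   result as logical columns `pass_score`, `pass_delta`.
#' @return a `PairSet`: data frame sorted by pair score with columns
#'   pair, a, b, pair_score, score_a, score_b, delta, pass_score,
#'   pass_delta; singleton and pair `PosteriorSummary` objects attached as
#'   attributes `fit_singletons`, `fit_pairs`.
#' @export
score_pairs <- function(targets, X = NULL, Y = NULL, Z = NULL,
                        weights = NULL, config = model_config(),
                        calibration = NULL, include_self = FALSE,
                        score_threshold = 0.1, delta_threshold = 0.2) {
  pairs <- enumerate_pairs(targets)
  if (include_self) {
    pairs <- rbind(pairs, data.frame(a = sort(targets), b = sort(targets)))
  }
  keep_rows <- function(obj, field) {
    if (is.null(obj)) return(NULL)
    obj[[field]] <- obj[[field]][targets, , drop = FALSE]
    obj
  }
  sing_fit <- fit_specificity(
    X = keep_rows(X, "fractions"), Y = keep_rows(Y, "values"),
    Z = keep_rows(Z, "labels"), weights = weights, config = config,
    calibration = calibration)
  sing <- stats::setNames(sing_fit$summary$score, sing_fit$summary$gene)
  pm <- assemble_pair_matrices(pairs, X, Y, Z)
  pair_fit <- fit_specificity(X = pm$X, Y = pm$Y, Z = pm$Z,
                              weights = weights, config = config,
                              calibration = calibration)
  ps <- stats::setNames(pair_fit$summary$score, pair_fit$summary$gene)
  ids <- pair_id(pairs$a, pairs$b)
  res <- data.frame(
    pair = ids, a = pairs$a, b = pairs$b,
    pair_score = unname(ps[ids]),
    score_a = unname(sing[pairs$a]), score_b = unname(sing[pairs$b]),
    stringsAsFactors = FALSE)
  res$delta <- pmin(res$score_a, res$score_b) - res$pair_score
  res$pass_score <- res$pair_score < score_threshold
  res$pass_delta <- res$delta > delta_threshold
  res <- res[order(res$pair_score), ]
  rownames(res) <- NULL
  attr(res, "fit_singletons") <- sing_fit
  attr(res, "fit_pairs") <- pair_fit
  class(res) <- c("PairSet", "data.frame")
  res
}
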