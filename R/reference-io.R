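# Reading, validating and deriving the evidence matrices from tab-separated
# inputs: a genes x samples count table plus a sample->tissue map, and an
# HPA-style "Normal tissue data" annotation table.

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normalized-count table and its sample-to-tissue map
#'
#' Expects a tab-separated genes x samples table with a header row and gene
#' identifiers in the first column, plus a two-column tab-separated map
#' (`sample`, `tissue`) covering every sample.  Genes whose entire row is
#' missing are dropped with a message.
#'
#' @param path count table path.
#' @param tissue_map_path sample/tissue map path.
#' @return an [expression_panel()].
#' @export
read_expression_panel <- function(path, tissue_map_path) {
  values <- read_tsv_matrix(path)
  abort_if(any(values < 0, na.rm = TRUE),
           "negative values in expression table %s", path)
  map_df <- utils::read.delim(tissue_map_path, header = TRUE, sep = "\t",
                              check.names = FALSE)
  abort_if(ncol(map_df) < 2, "tissue map needs columns sample, tissue")
  sample_tissue <- stats::setNames(as.character(map_df[[2]]),
                                   as.character(map_df[[1]]))
  all_na <- apply(values, 1L, function(r) all(is.na(r)))
  if (any(all_na)) {
    message(sprintf("dropping %d gene(s) with all-missing rows", sum(all_na)))
    values <- values[!all_na, , drop = FALSE]
  }
  expression_panel(values, sample_tissue)
}

#' Write an expression panel back to disk
#'
#' @param panel an [expression_panel()].
#' @param path output TSV path.
#' @param tissue_map_path optional path for the sample/tissue map.
#' @return `path`, invisibly.
#' @export
write_expression_panel <- function(panel, path, tissue_map_path = NULL) {
  write_tsv_matrix(panel$values, path)
  if (!is.null(tissue_map_path)) {
    utils::write.table(
      data.frame(sample = names(panel$sample_tissue),
                 tissue = unname(panel$sample_tissue)),
      tissue_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Build per-tissue detection fractions from a count panel
#'
#' A sample detects a gene when its value is strictly greater than `cutoff`
#' (so `cutoff = 0` means "any nonzero count").  Tissues represented by
#' fewer than `min_samples` samples are excluded for lack of statistical
#' power.
#'
#' @param panel an [expression_panel()].
#' @param cutoff non-negative detection threshold on the normalized scale.
#' @param min_samples minimum samples a tissue needs to be retained
#'   (default 10).
#' @return a [tissue_distribution()].
#' @export
build_tissue_distribution <- function(panel, cutoff = 0, min_samples = 10L) {
  abort_if(!is_scalar_number(cutoff) || cutoff < 0, "cutoff must be >= 0")
  abort_if(!is_scalar_number(min_samples) || min_samples < 1,
           "min_samples must be >= 1")
  tissues <- split(seq_along(panel$sample_tissue), panel$sample_tissue)
  keep <- vapply(tissues, length, 1L) >= min_samples
  abort_if(!any(keep),
           "no tissue has >= %d samples; lower min_samples", min_samples)
  tissues <- tissues[keep]
  frac <- vapply(tissues, function(idx) {
    rowMeans(panel$values[, idx, drop = FALSE] > cutoff, na.rm = TRUE)
  }, numeric(nrow(panel$values)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1L,
                                         dimnames = list(rownames(panel$values),
                                                         names(tissues)))
  tissue_distribution(frac, vapply(tissues, length, 1L))
}

#' Pick the detection cutoff that best matches an external reference
#'
#' For each candidate cutoff the detection fractions are recomputed and
#' compared against a binary genes x tissues reference (e.g. an external
#' consensus of where each gene is expressed) by Spearman correlation and
#' the area under the precision-recall curve.  The returned cutoff
#' maximizes the chosen criterion; ties go to the smallest cutoff
#' (preferring sensitivity).
#'
#' @param panel an [expression_panel()].
#' @param reference_detected binary matrix, genes x tissues, aligned by
#'   dimnames with the candidate distributions.
#' @param candidate_cutoffs numeric vector of cutoffs to scan.
#' @param criterion `"spearman"`, `"aupr"`, or `"combined"` (their mean).
#' @param min_samples passed to [build_tissue_distribution()].
#' @return list with `cutoff` (the winner) and `table` (one row per
#'   candidate with both scores).
#' @export
optimize_detection_cutoff <- function(panel, reference_detected,
                                      candidate_cutoffs,
                                      criterion = c("combined", "spearman",
                                                    "aupr"),
                                      min_samples = 10L) {
  criterion <- match.arg(criterion)
  abort_if(length(candidate_cutoffs) < 1, "need at least one candidate")
  ref <- as.matrix(reference_detected)
  abort_if(all(ref == ref[1]),
           "reference is constant (all %s); correspondence undefined", ref[1])
  rows <- lapply(sort(unique(candidate_cutoffs)), function(cutoff) {
    dist <- build_tissue_distribution(panel, cutoff, min_samples)
    common_t <- intersect(colnames(dist$fractions), colnames(ref))
    common_g <- intersect(rownames(dist$fractions), rownames(ref))
    abort_if(length(common_t) == 0 || length(common_g) == 0,
             "reference shares no genes/tissues with the panel")
    f <- as.vector(dist$fractions[common_g, common_t, drop = FALSE])
    r <- as.vector(ref[common_g, common_t, drop = FALSE])
    sp <- if (stats::sd(f) == 0) 0 else spearman(f, r)
    au <- compute_aupr(stats::setNames(f, seq_along(f)),
                       positives = as.character(which(r == 1)),
                       ascending = FALSE)$aupr
    data.frame(cutoff = cutoff, spearman = sp, aupr = au,
               combined = (sp + au) / 2)
  })
  table <- do.call(rbind, rows)
  crit <- table[[criterion]]
  best <- which(crit == max(crit))[1L]  # sorted ascending -> smallest wins ties
  list(cutoff = table$cutoff[best], table = table)
}

#' Parse HPA-style normal-tissue protein annotations into label codes
#'
#' Reads a table with columns `Gene`, `Gene name`, `Tissue`, `Cell type`,
#' `Level`, `Reliability` (tab-separated; extra columns ignored), counts
#' staining levels per gene, rescales every gene's level counts so the
#' total equals `target_slide_count` (the across-gene rounded mean number
#' of annotated slides when `"auto"`), using largest-remainder rounding so
#' each row sums exactly to P, and expands the counts into a length-P code
#' vector ordered high -> not detected.
#'
#' No filtering on `Reliability` is applied.
#'
#' @param path annotation table path.
#' @param target_slide_count positive integer or `"auto"`.
#' @return a [protein_label_panel()] (no slide-tissue annotation: the
#'   rescaling pools slides across tissues).
#' @export
parse_protein_annotations <- function(path, target_slide_count = "auto") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  lvl_col <- grep("^level$", names(df), ignore.case = TRUE)
  gene_col <- grep("^gene$", names(df), ignore.case = TRUE)
  abort_if(length(lvl_col) != 1 || length(gene_col) != 1,
           "table must have Gene and Level columns")
  lv <- tolower(trimws(as.character(df[[lvl_col]])))
  known <- c("high", "medium", "low", "not detected")
  bad <- which(!lv %in% known)
  abort_if(length(bad) > 0,
           "unknown Level '%s' at row %d", df[[lvl_col]][bad[1]], bad[1])
  lv <- factor(lv, levels = known)
  counts <- table(df[[gene_col]], lv)   # genes x 4, ordered high..nd
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping %d gene(s) with zero annotated slides",
                    sum(totals == 0)))
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  abort_if(nrow(counts) == 0, "no gene with annotated slides")
  P <- if (identical(target_slide_count, "auto")) {
    as.integer(round(mean(totals)))
  } else {
    abort_if(!is_scalar_number(target_slide_count) || target_slide_count < 1,
             "target_slide_count must be a positive integer or 'auto'")
    as.integer(target_slide_count)
  }
  codes <- t(apply(counts, 1L, function(cnt) {
    scaled <- largest_remainder_round(cnt, P)
    rep(0:3, times = scaled)
  }))
  if (P == 1L) codes <- matrix(codes, ncol = 1L,
                               dimnames = list(rownames(counts), NULL))
  rownames(codes) <- rownames(counts)
  protein_label_panel(codes)
}

#' Largest-remainder rounding to a fixed total
#'
#' Scales a vector of non-negative counts so it sums exactly to `total`:
#' each entry gets the floor of its proportional share and leftover units
#' go to the largest fractional remainders (ties to the earlier entry).
#'
#' @param counts non-negative numeric vector.
#' @param total target integer sum.
#' @return integer vector of `length(counts)` summing to `total`.
#' @export
largest_remainder_round <- function(counts, total) {
  abort_if(any(counts < 0) || sum(counts) == 0, "counts must be >= 0, not all 0")
  share <- counts * total / sum(counts)
  base <- floor(share)
  rem <- share - base
  short <- as.integer(total - sum(base))
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
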