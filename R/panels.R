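# Evidence containers.  Three matrices, all rows = targets ("genes"):
#   ExpressionPanel    Y  genes x samples   non-negative normalized counts
#   TissueDistribution X  genes x tissues   detection fractions in [0,1]
#   ProteinLabelPanel  Z  genes x slides    IHC codes {0,1,2,3}
# Plain S3 wrappers around base matrices so downstream algebra stays cheap.

#' IHC label semantics
#'
#' Fixed coding of immunohistochemistry staining levels used throughout:
#' 0 = high, 1 = medium, 2 = low, 3 = not detected.  Lower code means more
#' protein.
#' @return named integer vector.
#' @export
label_semantics <- function() {
  c(high = 0L, medium = 1L, low = 2L, `not detected` = 3L)
}

#' Construct an expression panel (matrix Y)
#'
#' @param values non-negative numeric matrix, genes x samples, TPM-like.
#' @param sample_tissue named character vector mapping every sample
#'   (column name) to a tissue.
#' @return an `ExpressionPanel` object.
#' @export
expression_panel <- function(values, sample_tissue) {
  abort_if(!is.matrix(values) || !is.numeric(values),
           "values must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "values must carry gene rownames and sample colnames")
  abort_if(anyDuplicated(rownames(values)) > 0, "gene_ids must be unique")
  abort_if(any(values < 0, na.rm = TRUE),
           "expression values must be non-negative")
  missing <- setdiff(colnames(values), names(sample_tissue))
  abort_if(length(missing) > 0,
           "sample(s) missing from tissue map: %s",
           paste(utils::head(missing, 5L), collapse = ", "))
  structure(
    list(values = values,
         sample_tissue = sample_tissue[colnames(values)]),
    class = "ExpressionPanel"
  )
}

#' @export
print.ExpressionPanel <- function(x, ...) {
  cat(sprintf("ExpressionPanel: %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_tissue))))
  invisible(x)
}

#' Construct a tissue distribution (matrix X)
#'
#' @param fractions numeric matrix in \[0,1\], genes x tissues.
#' @param samples_per_tissue named integer vector, samples behind each
#'   tissue column.
#' @return a `TissueDistribution` object.
#' @export
tissue_distribution <- function(fractions, samples_per_tissue) {
  abort_if(!is.matrix(fractions) || !is.numeric(fractions),
           "fractions must be a numeric matrix")
  abort_if(any(fractions < 0 | fractions > 1, na.rm = TRUE),
           "detection fractions must lie in [0, 1]")
  abort_if(is.null(colnames(fractions)), "fractions needs tissue colnames")
  abort_if(!all(colnames(fractions) %in% names(samples_per_tissue)),
           "samples_per_tissue must cover every tissue")
  structure(
    list(fractions = fractions,
         samples_per_tissue = samples_per_tissue[colnames(fractions)]),
    class = "TissueDistribution"
  )
}

#' @export
print.TissueDistribution <- function(x, ...) {
  cat(sprintf("TissueDistribution: %d genes x %d tissues\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Construct a protein label panel (matrix Z)
#'
#' @param labels integer matrix genes x slides with codes in `{0,1,2,3}`
#'   (see [label_semantics()]).
#' @param slide_tissue optional character vector, one tissue per slide
#'   column; required only for tissue-weight label reassignment.
#' @return a `ProteinLabelPanel` object.
#' @export
protein_label_panel <- function(labels, slide_tissue = NULL) {
  abort_if(!is.matrix(labels), "labels must be a matrix")
  storage.mode(labels) <- "integer"
  abort_if(!all(labels %in% 0:3), "label codes must be in {0,1,2,3}")
  abort_if(is.null(rownames(labels)), "labels needs gene rownames")
  if (!is.null(slide_tissue)) {
    abort_if(length(slide_tissue) != ncol(labels),
             "slide_tissue must name a tissue for each of the %d slides",
             ncol(labels))
  }
  structure(
    list(labels = labels,
         label_semantics = label_semantics(),
         slide_tissue = slide_tissue),
    class = "ProteinLabelPanel"
  )
}

#' @export
print.ProteinLabelPanel <- function(x, ...) {
  cat(sprintf("ProteinLabelPanel: %d genes x %d slides%s\n",
              nrow(x$labels), ncol(x$labels),
              if (is.null(x$slide_tissue)) "" else " (tissue-annotated)"))
  invisible(x)
}

gene_ids <- function(x) {
  switch(class(x)[1],
         ExpressionPanel = rownames(x$values),
         TissueDistribution = rownames(x$fractions),
         ProteinLabelPanel = rownames(x$labels),
         stop("unsupported evidence object"))
}
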