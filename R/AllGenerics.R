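#' @include AllClasses.R
NULL

#' Accessors for the core data classes
#'
#' `exprValues()` returns the assay matrix of an [ExpressionMatrix-class];
#' `cohort()` and `exprUnit()` its cohort tag and unit. `geneIds()` and
#' `sampleIds()` return identifier vectors for expression, CNV and
#' annotation objects. `cnvValues()` returns the copy-number matrix.
#' `peakIds()`, `peakScores()`, `peakRanges()` and `peakMidpoints()` access
#' a [PeakSet-class]; midpoints are reported 0-based as
#' `floor((start + end) / 2)` of the half-open interval.
#' `tssPosition()` and `immuneRole()` access a [GeneAnnotation-class];
#' TSS positions are reported 0-based.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))
#' @rdname accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("cnvValues", function(x) standardGeneric("cnvValues"))
#' @rdname accessors
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))
#' @rdname accessors
#' @export
setGeneric("peakScores", function(x) standardGeneric("peakScores"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("peakMidpoints", function(x) standardGeneric("peakMidpoints"))
#' @rdname accessors
#' @export
setGeneric("tssPosition", function(x) standardGeneric("tssPosition"))
#' @rdname accessors
#' @export
setGeneric("immuneRole", function(x) standardGeneric("immuneRole"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x))
#' @rdname accessors
setMethod("cohort", "ExpressionMatrix", function(x) x@cohort)
#' @rdname accessors
setMethod("exprUnit", "ExpressionMatrix", function(x) x@unit)
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("cnvValues", "CNVMatrix", function(x) x@values)
#' @rdname accessors
setMethod("geneIds", "CNVMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "CNVMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("geneIds", "GeneAnnotation", function(x) names(x@tss))
#' @rdname accessors
setMethod("tssPosition", "GeneAnnotation", function(x) {
  p <- start(x@tss) - 1L
  names(p) <- names(x@tss)
  p
})
#' @rdname accessors
setMethod("immuneRole", "GeneAnnotation", function(x) {
  r <- mcols(x@tss)$immune_role
  names(r) <- names(x@tss)
  r
})
#' @rdname accessors
setMethod("peakIds", "PeakSet", function(x) names(x@ranges))
#' @rdname accessors
setMethod("peakScores", "PeakSet", function(x) x@scores)
#' @rdname accessors
setMethod("peakRanges", "PeakSet", function(x) x@ranges)
#' @rdname accessors
setMethod("sampleIds", "PeakSet", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("peakMidpoints", "PeakSet", function(x) {
  s0 <- start(x@ranges) - 1L
  e0 <- end(x@ranges)
  m <- as.integer(floor((s0 + e0) / 2))
  names(m) <- names(x@ranges)
  m
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s cohort, unit '%s']\n",
              nrow(object), ncol(object), object@cohort, object@unit))
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes\n", length(object@tss)))
  if (length(object@tss)) {
    tb <- table(mcols(object@tss)$immune_role)
    cat("  roles:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "CNVMatrix", function(object) {
  cat(sprintf("CNVMatrix: %d genes x %d samples\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peaks x %d samples [unit '%s']\n",
              length(object@ranges), ncol(object@scores), object@unit))
})

setMethod("show", "NMFFactorization", function(object) {
  cat(sprintf(
    "NMFFactorization: rank %d, %d x %d, %d iterations, final objective %.6g\n",
    object@r, nrow(object@W), ncol(object@H), length(object@loss_trajectory),
    utils::tail(object@loss_trajectory, 1L)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: rank %d over %d samples, cophenetic %.4f, CDF area %.4f\n",
    object@r, nrow(object@consensus), object@cophenetic, object@cdf_area))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d samples in %d subtypes, %d CNV-driven genes, %d TF edges\n",
    length(object@subtype_of_sample), length(unique(object@subtype_of_sample)),
    length(object@cnv_driven_genes), nrow(object@tf_edges)))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif %s (gene %s): length %d, threshold %.2f bits\n",
              object@tf_name, object@coding_gene_id, ncol(object@matrix),
              object@score_threshold))
})
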