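#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
NULL

.IMMUNE_ROLES <- c("nk_activator_ligand", "nk_inhibitor_ligand",
                   "tf_coding", "repressor_coding", "other")

.checkIds <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    return(sprintf("%s must be non-missing, non-empty strings", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicate %s: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  NULL
}

# ---- ExpressionMatrix -------------------------------------------------------

#' Gene-by-sample expression matrix for one cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a single
#' non-negative gene x sample assay, tagged with the cohort it came from
#' (`"tumor"` or `"normal"`) and the measurement unit (free text, e.g.
#' `"counts"` or `"log2(count+1)"`). All entries must be finite and
#' non-negative; gene and sample identifiers must be unique. Stages that
#' fit count models (differential expression) additionally require integer
#' counts and check for them at call time; every other stage accepts any
#' non-negative unit.
#'
#' @slot cohort single string, `"tumor"` or `"normal"`.
#' @slot unit single free-text string describing the measurement unit.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(cohort = "character", unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@cohort) != 1L || !object@cohort %in% c("tumor", "normal"))
    msg <- c(msg, "cohort must be one of 'tumor', 'normal'")
  if (length(object@unit) != 1L || is.na(object@unit))
    msg <- c(msg, "unit must be a single string")
  if (length(SummarizedExperiment::assays(object)) != 1L) {
    msg <- c(msg, "exactly one assay is required")
  } else {
    v <- assay(object)
    if (!is.numeric(v)) msg <- c(msg, "assay must be numeric")
    else {
      if (any(!is.finite(v))) msg <- c(msg, "assay contains non-finite values")
      else if (any(v < 0)) {
        bad <- which(v < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("negative entry at gene '%s', sample '%s'",
                              rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
      }
    }
    for (w in list(.checkIds(rownames(v), "gene ids"),
                   .checkIds(colnames(v), "sample ids")))
      if (!is.null(w)) msg <- c(msg, w)
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   unique row and column names; all entries finite and non-negative.
#' @param cohort `"tumor"` or `"normal"`.
#' @param unit free-text measurement unit; defaults to `"counts"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- ExpressionMatrix(m, cohort = "tumor")
#' exprValues(em)[1, ]
#' @export
ExpressionMatrix <- function(values, cohort = c("tumor", "normal"),
                             unit = "counts") {
  cohort <- match.arg(cohort)
  values <- as.matrix(values)
  se <- SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionMatrix", se, cohort = cohort, unit = unit)
}

# ---- GeneAnnotation ---------------------------------------------------------

#' Gene annotation: TSS coordinates and immune roles
#'
#' Wraps a width-one [GenomicRanges::GRanges] anchored at each gene's
#' transcription start site. Positions are supplied and reported 0-based
#' (BED convention) and stored internally in the usual 1-based Bioconductor
#' representation. Each gene carries an `immune_role` label drawn from
#' `nk_activator_ligand`, `nk_inhibitor_ligand`, `tf_coding`,
#' `repressor_coding`, `other`; the NK-ligand roles drive the
#' categorisation of differentially expressed ligands, and the coding roles
#' identify candidate regulators.
#'
#' @slot tss `GRanges`, one range per gene, names = gene ids,
#'   `mcols()$immune_role` the role label.
#' @export
setClass("GeneAnnotation", representation(tss = "GRanges"))

setValidity("GeneAnnotation", function(object) {
  gr <- object@tss
  msg <- character()
  if (length(gr)) {
    w <- .checkIds(names(gr), "gene ids")
    if (!is.null(w)) msg <- c(msg, w)
    if (any(width(gr) != 1L)) msg <- c(msg, "TSS ranges must have width 1")
    if (any(start(gr) < 1L)) msg <- c(msg, "TSS positions must be >= 0")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-' for every gene")
    role <- mcols(gr)$immune_role
    if (is.null(role) || !all(role %in% .IMMUNE_ROLES))
      msg <- c(msg, paste0("immune_role must be one of: ",
                           paste(.IMMUNE_ROLES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneAnnotation
#'
#' @param id character vector of unique gene ids.
#' @param chrom chromosome name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based TSS position per gene (integer, bp).
#' @param immune_role role label per gene; see [GeneAnnotation-class].
#' @return A [GeneAnnotation-class] object.
#' @examples
#' ann <- GeneAnnotation("CDH1", "chr16", "+", 68737292, "nk_inhibitor_ligand")
#' tssPosition(ann)
#' @export
GeneAnnotation <- function(id, chrom, strand, tss, immune_role) {
  if (length(id) == 0L)
    return(new("GeneAnnotation", tss = GRanges()))
  tss <- as.integer(tss)
  if (any(is.na(tss)) || any(tss < 0L)) stop("tss must be integers >= 0")
  gr <- GRanges(chrom, IRanges(tss + 1L, width = 1L), strand = strand)
  names(gr) <- id
  mcols(gr)$immune_role <- immune_role
  new("GeneAnnotation", tss = gr)
}

# ---- CNVMatrix --------------------------------------------------------------

#' Gene-by-sample copy-number matrix
#'
#' Holds per-gene copy-number estimates (discrete states or log-ratios) for
#' the tumor cohort. Values may be negative (log-ratios) but must be finite;
#' ids must be unique. Sample ids are matched by name against the tumor
#' [ExpressionMatrix-class] when correlating CNV with expression.
#'
#' @slot values numeric matrix with gene rownames and sample colnames.
#' @export
setClass("CNVMatrix", representation(values = "matrix"))

setValidity("CNVMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  else if (any(!is.finite(v))) msg <- c(msg, "values contain non-finite entries")
  for (w in list(.checkIds(rownames(v), "gene ids"),
                 .checkIds(colnames(v), "sample ids")))
    if (!is.null(w)) msg <- c(msg, w)
  if (length(msg)) msg else TRUE
})

#' Construct a CNVMatrix
#'
#' @param values numeric gene x sample matrix with unique dimnames.
#' @return A [CNVMatrix-class] object.
#' @export
CNVMatrix <- function(values) new("CNVMatrix", values = as.matrix(values))

# ---- PeakSet ----------------------------------------------------------------

#' ATAC-seq peaks with per-sample accessibility scores
#'
#' Couples peak genomic intervals (a [GenomicRanges::GRanges], one range per
#' peak, names = peak ids) with a peak x sample score matrix. Intervals are
#' supplied 0-based half-open (BED convention); internally the usual 1-based
#' closed representation is used. Scores are typically normalized
#' accessibility values (default unit `"log2([count + 5]PM)-qn"`) and must
#' be finite, one value per peak and ATAC sample.
#'
#' @slot ranges `GRanges` of peak intervals, names = peak ids.
#' @slot scores numeric matrix, rows = peak ids, columns = ATAC sample ids.
#' @slot unit free-text score unit.
#' @export
setClass("PeakSet",
  representation(ranges = "GRanges", scores = "matrix", unit = "character"))

setValidity("PeakSet", function(object) {
  msg <- character()
  gr <- object@ranges; sc <- object@scores
  w <- .checkIds(names(gr), "peak ids")
  if (!is.null(w)) msg <- c(msg, w)
  if (any(width(gr) < 1L)) msg <- c(msg, "peak intervals must satisfy start < end")
  if (length(gr) != nrow(sc))
    msg <- c(msg, "score matrix must have one row per peak")
  else if (length(gr) && !identical(names(gr), rownames(sc)))
    msg <- c(msg, "score rownames must match peak ids in order")
  if (length(sc) && any(!is.finite(sc)))
    msg <- c(msg, "scores contain non-finite values")
  w <- .checkIds(colnames(sc), "ATAC sample ids")
  if (!is.null(w) && ncol(sc) > 0) msg <- c(msg, w)
  if (length(object@unit) != 1L) msg <- c(msg, "unit must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param id character vector of unique peak ids.
#' @param chrom chromosome per peak.
#' @param start,end 0-based half-open interval per peak (bp), `start < end`.
#' @param scores numeric matrix of per-sample scores; rows in peak order
#'   (rownames are set to `id`), columns named by ATAC sample id.
#' @param unit free-text score unit.
#' @return A [PeakSet-class] object.
#' @export
PeakSet <- function(id, chrom, start, end, scores,
                    unit = "log2([count + 5]PM)-qn") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end))
    stop("empty or inverted peak interval (start >= end): ",
         paste(id[start >= end], collapse = ", "))
  gr <- GRanges(chrom, IRanges(start + 1L, end))
  names(gr) <- id
  scores <- as.matrix(scores)
  rownames(scores) <- id
  new("PeakSet", ranges = gr, scores = scores, unit = unit)
}

# ---- Configuration objects --------------------------------------------------

#' NMF configuration
#'
#' Controls the multiplicative-update factorization and the consensus run.
#' The loss is the (squared) Frobenius norm; an optional l1 penalty with
#' weight `gamma` encourages sparse factors. `tol` is the relative change
#' in the objective between successive iterations below which iteration
#' stops.
#'
#' @slot loss `"frobenius"` (the only supported loss).
#' @slot gamma non-negative l1 penalty weight (0 disables regularization).
#' @slot regularizer `"none"` or `"l1"`.
#' @slot max_iter maximum multiplicative-update iterations.
#' @slot tol relative objective-change stopping tolerance.
#' @slot n_restarts independently seeded factorizations per consensus run.
#' @slot rank_range candidate factorization ranks scanned.
#' @export
setClass("NMFConfig", representation(
  loss = "character", gamma = "numeric", regularizer = "character",
  max_iter = "integer", tol = "numeric", n_restarts = "integer",
  rank_range = "integer"))

setValidity("NMFConfig", function(object) {
  msg <- character()
  if (!identical(object@loss, "frobenius")) msg <- c(msg, "loss must be 'frobenius'")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (!object@regularizer %in% c("none", "l1"))
    msg <- c(msg, "regularizer must be 'none' or 'l1'")
  if (object@max_iter < 1L) msg <- c(msg, "max_iter must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@n_restarts < 1L) msg <- c(msg, "n_restarts must be >= 1")
  if (length(object@rank_range) < 1L || any(object@rank_range < 2L))
    msg <- c(msg, "rank_range must contain integers >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname NMFConfig-class
#' @param loss,gamma,regularizer,max_iter,tol,n_restarts,rank_range see slots.
#' @export
NMFConfig <- function(loss = "frobenius", gamma = 0, regularizer = "none",
                      max_iter = 400L, tol = 1e-6, n_restarts = 30L,
                      rank_range = 2:6) {
  new("NMFConfig", loss = loss, gamma = gamma, regularizer = regularizer,
      max_iter = as.integer(max_iter), tol = tol,
      n_restarts = as.integer(n_restarts),
      rank_range = as.integer(rank_range))
}

#' Pipeline configuration
#'
#' Collects the tunable constants of the full pipeline: the NMF consensus
#' settings, differential-expression thresholds, the Spearman strength
#' boundaries (moderate at |rho| >= 0.4, strong at |rho| >= 0.7), the
#' TSS window for peak-to-gene assignment (20 kb), the per-sample t-test
#' level, the accessibility quantile defining an "open" peak, and the
#' master seed from which every stage derives its randomness.
#'
#' @slot rank_range candidate NMF ranks.
#' @slot nmf an [NMFConfig-class].
#' @slot de_alpha FDR level for differential expression (default 0.05).
#' @slot de_lfc absolute log2-fold-change cutoff (default 1).
#' @slot spearman_moderate |rho| boundary between weak and moderate (0.4).
#' @slot spearman_strong |rho| boundary between moderate and strong (0.7).
#' @slot tss_window peak-to-TSS assignment window in bp (20000).
#' @slot ttest_alpha level for the single-sample t-test (0.05).
#' @slot high_score_quantile accessibility quantile above which a peak is
#'   called open in a sample (0.75).
#' @slot seed master integer seed.
#' @export
setClass("PipelineConfig", representation(
  rank_range = "integer", nmf = "NMFConfig", de_alpha = "numeric",
  de_lfc = "numeric", spearman_moderate = "numeric",
  spearman_strong = "numeric", tss_window = "integer",
  ttest_alpha = "numeric", high_score_quantile = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  inunit <- function(x) length(x) == 1L && x > 0 && x < 1
  if (!inunit(object@de_alpha)) msg <- c(msg, "de_alpha must be in (0,1)")
  if (object@de_lfc < 0) msg <- c(msg, "de_lfc must be >= 0")
  if (!inunit(object@spearman_moderate) || !inunit(object@spearman_strong) ||
      object@spearman_moderate > object@spearman_strong)
    msg <- c(msg, "spearman thresholds must satisfy 0 < moderate <= strong < 1")
  if (object@tss_window <= 0L) msg <- c(msg, "tss_window must be > 0")
  if (!inunit(object@ttest_alpha)) msg <- c(msg, "ttest_alpha must be in (0,1)")
  if (!inunit(object@high_score_quantile))
    msg <- c(msg, "high_score_quantile must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param rank_range,nmf,de_alpha,de_lfc,spearman_moderate,spearman_strong
#'   see slots.
#' @param tss_window,ttest_alpha,high_score_quantile,seed see slots.
#' @export
PipelineConfig <- function(rank_range = 2:6, nmf = NMFConfig(rank_range = rank_range),
                           de_alpha = 0.05, de_lfc = 1,
                           spearman_moderate = 0.4, spearman_strong = 0.7,
                           tss_window = 20000L, ttest_alpha = 0.05,
                           high_score_quantile = 0.75, seed = 1L) {
  new("PipelineConfig", rank_range = as.integer(rank_range), nmf = nmf,
      de_alpha = de_alpha, de_lfc = de_lfc,
      spearman_moderate = spearman_moderate, spearman_strong = spearman_strong,
      tss_window = as.integer(tss_window), ttest_alpha = ttest_alpha,
      high_score_quantile = high_score_quantile, seed = as.integer(seed))
}

# ---- NMF results ------------------------------------------------------------

#' A single NMF factorization
#'
#' Result of one multiplicative-update run: non-negative factors `W`
#' (genes x rank) and `H` (rank x samples), the rank, the trajectory of the
#' minimized objective (squared Frobenius residual plus any l1 penalty,
#' recorded once per iteration and non-increasing up to floating-point
#' round-off), and the seed that initialized it.
#'
#' @slot W,H non-negative factor matrices.
#' @slot r factorization rank.
#' @slot loss_trajectory objective value per iteration.
#' @slot seed integer seed used for initialization.
#' @export
setClass("NMFFactorization", representation(
  W = "matrix", H = "matrix", r = "integer",
  loss_trajectory = "numeric", seed = "integer"))

setValidity("NMFFactorization", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "factors must be non-negative")
  if (ncol(object@W) != object@r || nrow(object@H) != object@r)
    msg <- c(msg, "factor dimensions must match rank")
  d <- diff(object@loss_trajectory)
  slack <- 1e-8 * abs(object@loss_trajectory[1L]) + 1e-12
  if (length(d) && any(d > slack))
    msg <- c(msg, "loss trajectory must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result at one rank
#'
#' The sample x sample co-clustering frequency matrix across NMF restarts,
#' the hierarchical labels cut at the rank, and the rank-quality metrics:
#' cophenetic correlation, per-cluster mean within-cluster consensus, and
#' the area under the consensus CDF. `delta_area` is `NA` until filled in
#' across ranks by [rankMetrics()]. A cophenetic value of `NA` is the
#' sentinel for the degenerate all-constant-distance case.
#'
#' @slot r rank.
#' @slot consensus symmetric matrix in `[0,1]` with unit diagonal.
#' @slot labels named integer cluster labels per sample.
#' @slot cophenetic cophenetic correlation coefficient (or `NA` sentinel).
#' @slot cluster_consensus per-cluster mean within-cluster consensus.
#' @slot cdf_area area under the empirical CDF of off-diagonal consensus.
#' @slot delta_area relative area increase over the previous rank.
#' @export
setClass("ConsensusResult", representation(
  r = "integer", consensus = "matrix", labels = "integer",
  cophenetic = "numeric", cluster_consensus = "numeric",
  cdf_area = "numeric", delta_area = "numeric"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  C <- object@consensus
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    msg <- c(msg, "consensus must be symmetric")
  if (any(C < -1e-12) || any(C > 1 + 1e-12))
    msg <- c(msg, "consensus entries must lie in [0,1]")
  if (nrow(C) && max(abs(diag(C) - 1)) > 1e-12)
    msg <- c(msg, "consensus diagonal must be 1")
  if (length(object@labels) != nrow(C))
    msg <- c(msg, "labels must cover all samples")
  if (length(msg)) msg else TRUE
})

# ---- Simulation -------------------------------------------------------------

#' Synthetic-cohort simulation configuration
#'
#' Parameters of the planted-truth generator. Defaults describe the study
#' conditions every downstream stage is tested against: a 120-tumor /
#' 60-normal cohort over 800 genes with four planted subtypes of 40
#' marker genes each (log2 shift 2), negative-binomial counts at
#' dispersion 0.3, per-cluster differentially expressed genes at true
#' |log2FC| 2, copy-number-driven genes coupled at slope 1 per copy,
#' one planted TF -> peak -> target edge active in 60% of tumor samples,
#' and exponential survival with a hazard ratio of 3 across expression
#' tertiles under ~30% censoring.
#'
#' @slot n_genes,n_samples_tumor,n_samples_normal cohort dimensions.
#' @slot K planted subtype count (>= 2).
#' @slot subtype_effect log2 shift of a subtype's marker genes in its samples.
#' @slot n_markers_per_subtype marker genes per subtype.
#' @slot nb_dispersion shared negative-binomial dispersion.
#' @slot de_lfc_true true |log2FC| of planted DE genes vs normal.
#' @slot n_de_per_cluster planted DE genes per cluster (half up, half down).
#' @slot cnv_beta log2 expression change per copy for CNV-driven genes.
#' @slot n_cnv_driven number of planted CNV-driven genes.
#' @slot n_tf_edges planted TF -> peak -> target regulatory edges.
#' @slot tf_shift log2 up-shift of the TF coding gene in regulated samples.
#' @slot peak_alpha slope linking causal peak score to TF log2 expression.
#' @slot n_decoy_peaks decoy peaks without any expression coupling.
#' @slot peak_noise_sd s.d. of peak-score noise.
#' @slot frac_regulated_samples fraction of tumor samples where each planted
#'   edge is active, in (0,1].
#' @slot survival_effect hazard ratio per expression-tertile group.
#' @slot censoring_rate target fraction of censored subjects, in `[0,1)`.
#' @slot seed master seed; child seeds for each component are derived from it.
#' @export
setClass("SimulationConfig", representation(
  n_genes = "integer", n_samples_tumor = "integer", n_samples_normal = "integer",
  K = "integer", subtype_effect = "numeric", n_markers_per_subtype = "integer",
  nb_dispersion = "numeric", de_lfc_true = "numeric", n_de_per_cluster = "integer",
  cnv_beta = "numeric", n_cnv_driven = "integer", n_tf_edges = "integer",
  tf_shift = "numeric", peak_alpha = "numeric", n_decoy_peaks = "integer",
  peak_noise_sd = "numeric", frac_regulated_samples = "numeric",
  survival_effect = "numeric", censoring_rate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(n_genes = object@n_genes, n_samples_tumor = object@n_samples_tumor,
           n_samples_normal = object@n_samples_normal, K = object@K)
  if (any(pos < 1L)) msg <- c(msg, "counts must be positive")
  if (object@K < 2L) msg <- c(msg, "K must be >= 2")
  if (object@K > object@n_samples_tumor)
    msg <- c(msg, "K must not exceed the number of tumor samples")
  f <- object@frac_regulated_samples
  if (f <= 0 || f > 1) msg <- c(msg, "frac_regulated_samples must be in (0,1]")
  if (object@censoring_rate < 0 || object@censoring_rate >= 1)
    msg <- c(msg, "censoring_rate must be in [0,1)")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (object@K * object@n_markers_per_subtype +
      object@K * object@n_de_per_cluster + object@n_cnv_driven +
      2L * object@n_tf_edges > object@n_genes)
    msg <- c(msg, "planted gene sets exceed n_genes")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param n_genes,n_samples_tumor,n_samples_normal,K,subtype_effect see slots.
#' @param n_markers_per_subtype,nb_dispersion,de_lfc_true,n_de_per_cluster
#'   see slots.
#' @param cnv_beta,n_cnv_driven,n_tf_edges,tf_shift,peak_alpha see slots.
#' @param n_decoy_peaks,peak_noise_sd,frac_regulated_samples see slots.
#' @param survival_effect,censoring_rate,seed see slots.
#' @export
SimulationConfig <- function(n_genes = 800L, n_samples_tumor = 120L,
                             n_samples_normal = 60L, K = 4L,
                             subtype_effect = 2, n_markers_per_subtype = 40L,
                             nb_dispersion = 0.3, de_lfc_true = 2,
                             n_de_per_cluster = 30L, cnv_beta = 1,
                             n_cnv_driven = 10L, n_tf_edges = 1L,
                             tf_shift = 2, peak_alpha = 1,
                             n_decoy_peaks = 30L, peak_noise_sd = 1,
                             frac_regulated_samples = 0.6,
                             survival_effect = 3, censoring_rate = 0.3,
                             seed = 1L) {
  new("SimulationConfig",
      n_genes = as.integer(n_genes),
      n_samples_tumor = as.integer(n_samples_tumor),
      n_samples_normal = as.integer(n_samples_normal), K = as.integer(K),
      subtype_effect = subtype_effect,
      n_markers_per_subtype = as.integer(n_markers_per_subtype),
      nb_dispersion = nb_dispersion, de_lfc_true = de_lfc_true,
      n_de_per_cluster = as.integer(n_de_per_cluster), cnv_beta = cnv_beta,
      n_cnv_driven = as.integer(n_cnv_driven),
      n_tf_edges = as.integer(n_tf_edges), tf_shift = tf_shift,
      peak_alpha = peak_alpha, n_decoy_peaks = as.integer(n_decoy_peaks),
      peak_noise_sd = peak_noise_sd,
      frac_regulated_samples = frac_regulated_samples,
      survival_effect = survival_effect, censoring_rate = censoring_rate,
      seed = as.integer(seed))
}

#' Planted ground truth of a synthetic cohort
#'
#' Records everything the generator planted, for recovery testing:
#' the subtype of every tumor sample, the per-cluster differentially
#' expressed genes with their direction, the CNV-driven genes with their
#' coupling slopes, the TF -> peak -> target edges with the set of samples
#' in which each is active, and the survival hazard ratio.
#'
#' @slot subtype_of_sample named integer, sample -> cluster in 1..K.
#' @slot marker_genes list per cluster of marker gene ids.
#' @slot de_genes list per cluster: named character vector gene -> "up"/"down".
#' @slot cnv_driven_genes named numeric: gene -> coupling slope beta.
#' @slot tf_edges data.frame with columns tf_gene, peak_id, target_gene,
#'   direction.
#' @slot regulated_samples list per edge of active tumor sample ids.
#' @slot survival_gene gene whose tertiles drive the planted hazard.
#' @slot survival_effect hazard ratio per tertile group.
#' @export
setClass("SyntheticTruth", representation(
  subtype_of_sample = "integer", marker_genes = "list", de_genes = "list",
  cnv_driven_genes = "numeric", tf_edges = "data.frame",
  regulated_samples = "list", survival_gene = "character",
  survival_effect = "numeric"))

# ---- Motifs -----------------------------------------------------------------

#' Position-weight matrix for one transcription factor
#'
#' A probability matrix (rows A, C, G, T; one column per motif position),
#' the background base frequencies, and the log-odds score threshold above
#' which a scan position is reported as a hit. `coding_gene_id` names the
#' gene encoding the factor, linking motif hits back to the expression
#' matrix.
#'
#' @slot tf_name factor name.
#' @slot coding_gene_id id of the gene coding the factor.
#' @slot matrix 4 x L probability matrix, rownames A, C, G, T.
#' @slot background length-4 base frequencies, named A, C, G, T.
#' @slot score_threshold log2-odds cutoff for reporting a hit.
#' @export
setClass("PWMotif", representation(
  tf_name = "character", coding_gene_id = "character", matrix = "matrix",
  background = "numeric", score_threshold = "numeric"))

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix rownames must be A, C, G, T")
  if (ncol(m) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (length(m) && any(abs(colSums(m) - 1) > 1e-6))
    msg <- c(msg, "probability columns must sum to 1")
  if (any(m < 0)) msg <- c(msg, "probabilities must be non-negative")
  b <- object@background
  if (length(b) != 4L || abs(sum(b) - 1) > 1e-6 || any(b <= 0))
    msg <- c(msg, "background must be 4 positive frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PWMotif-class
#' @param tf_name,coding_gene_id,matrix,background,score_threshold see slots.
#' @export
PWMotif <- function(tf_name, coding_gene_id, matrix,
                    background = rep(0.25, 4), score_threshold = NULL) {
  rownames(matrix) <- c("A", "C", "G", "T")
  names(background) <- c("A", "C", "G", "T")
  if (is.null(score_threshold)) {
    # default: 80% of the maximal attainable log2-odds score
    mx <- sum(log2(apply(pmax(matrix, 1e-6), 2, max) / max(background)))
    score_threshold <- 0.8 * mx
  }
  new("PWMotif", tf_name = tf_name, coding_gene_id = coding_gene_id,
      matrix = matrix, background = background,
      score_threshold = score_threshold)
}
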