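#' @include AllClasses.R
NULL

#' Assign peaks to a gene's TSS window
#'
#' Retains every peak on the gene's chromosome whose midpoint
#' (`floor((start + end) / 2)` of the 0-based half-open interval) lies
#' within `window` bp of the TSS, bound included. Distances are absolute
#' midpoint-to-TSS offsets; mean peak scores are attached for later
#' tie-breaks.
#'
#' @param peaks a [PeakSet-class].
#' @param gene gene id (must have a TSS in the annotation).
#' @param annotation a [GeneAnnotation-class].
#' @param window window half-width in bp (default 20000).
#' @return a `data.frame` with `peak_id`, `gene_id`, `distance`,
#'   `mean_score`, `rho`, `rho_defined` (correlations `NA` until
#'   [linkCorrelations()]).
#' @export
assignPeaks <- function(peaks, gene, annotation, window = 20000L) {
  if (!gene %in% geneIds(annotation))
    stop("gene has no TSS in the annotation: ", gene)
  if (window <= 0) stop("window must be > 0")
  tss <- tssPosition(annotation)[gene]
  gchrom <- as.character(seqnames(annotation@tss))[
    match(gene, geneIds(annotation))]
  mids <- peakMidpoints(peaks)
  pchrom <- as.character(seqnames(peakRanges(peaks)))
  keep <- pchrom == gchrom & abs(mids - tss) <= window
  ms <- rowMeans(peakScores(peaks))
  data.frame(peak_id = peakIds(peaks)[keep], gene_id = rep(gene, sum(keep)),
             distance = abs(mids - tss)[keep],
             mean_score = unname(ms[keep]),
             rho = rep(NA_real_, sum(keep)),
             rho_defined = rep(NA, sum(keep)),
             row.names = NULL)
}

#' Correlate link peak scores with target expression
#'
#' Fills each link's Spearman correlation between the peak's
#' accessibility scores and the target gene's expression across the
#' samples shared by the ATAC and expression cohorts (matched by id).
#' Count units are log2-transformed first. Constant peak profiles give an
#' undefined correlation and are flagged, not dropped.
#'
#' @param links link table from [assignPeaks()].
#' @param peaks the [PeakSet-class].
#' @param expr tumor [ExpressionMatrix-class].
#' @return the link table with `rho` and `rho_defined` filled.
#' @export
linkCorrelations <- function(links, peaks, expr) {
  shared <- intersect(sampleIds(peaks), sampleIds(expr))
  if (length(shared) < 3L)
    stop("need >= 3 samples shared between ATAC and expression cohorts; ",
         "found ", length(shared))
  ev <- exprValues(expr)
  if (grepl("count", exprUnit(expr), ignore.case = TRUE)) ev <- log2(ev + 1)
  sc <- peakScores(peaks)
  for (i in seq_len(nrow(links))) {
    r <- spearmanRho(sc[links$peak_id[i], shared],
                     ev[links$gene_id[i], shared])
    links$rho[i] <- r$rho
    links$rho_defined[i] <- r$defined
  }
  links
}

#' Select up to three candidate peaks
#'
#' The multi-objective shortlist: the most positively correlated peak,
#' the most negatively correlated peak, and the closest peak (distance
#' ties broken by larger mean score, then lexicographic peak id).
#' Duplicate selections collapse; if every correlation is undefined only
#' the closest-peak slot is filled. Output order: positive, negative,
#' closest.
#'
#' @param links link table with correlations (from [linkCorrelations()]).
#' @return the selected rows with an extra `slot` column.
#' @export
selectCandidatePeaks <- function(links) {
  if (nrow(links) == 0L) return(cbind(links, slot = character(0L)))
  picks <- list()
  def <- which(!is.na(links$rho))
  if (length(def)) {
    picks$positive <- def[which.max(links$rho[def])]
    picks$negative <- def[which.min(links$rho[def])]
  }
  o <- order(links$distance, -links$mean_score, links$peak_id)
  picks$closest <- o[1L]
  idx <- unlist(picks)
  keep <- !duplicated(idx)
  out <- links[idx[keep], , drop = FALSE]
  out$slot <- names(picks)[keep]
  rownames(out) <- NULL
  out
}

#' Single-sample expression status vs a normal cohort
#'
#' One-sample Student t-test of the normal values against the single
#' tumor value taken as the hypothesized mean:
#' `t = (mean(normals) - x) / (sd(normals) / sqrt(n))` on `n - 1` degrees
#' of freedom, two-sided. Status is `high` when the tumor value exceeds
#' the normal mean at `p < alpha`, `low` when below it at `p < alpha`,
#' otherwise `unchanged`.
#'
#' @param x single tumor expression value.
#' @param normals numeric vector of >= 3 normal-cohort values with
#'   positive variance.
#' @param alpha significance level (default 0.05).
#' @return list with `status` and `p`.
#' @export
singleSampleTest <- function(x, normals, alpha = 0.05) {
  r <- .singleSampleStatus(x, normals, alpha)
  list(status = r$status[1L], p = r$p[1L])
}

# vectorized over tumor values
.singleSampleStatus <- function(xs, normals, alpha) {
  n <- length(normals)
  if (n < 3L) stop("need >= 3 normal values")
  m <- mean(normals); s <- stats::sd(normals)
  if (s == 0) stop("normal values have zero variance")
  tstat <- (m - xs) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  status <- rep("unchanged", length(xs))
  status[xs > m & p < alpha] <- "high"
  status[xs < m & p < alpha] <- "low"
  list(status = status, p = p)
}

#' Peak accessibility status in one sample
#'
#' A peak is called `high` (open) in a sample when its score reaches at
#' least the `quantile` of all peak scores in that sample - openness is
#' judged against the sample's genome-wide accessibility background, so a
#' constitutively open region is high in every sample. With all-equal
#' scores the bound is attained and the status is `high`.
#'
#' @param peak peak id.
#' @param sample ATAC sample id.
#' @param peaks a [PeakSet-class].
#' @param quantile accessibility quantile defining openness (default
#'   0.75).
#' @return `"high"` or `"low"`.
#' @export
peakScoreStatus <- function(peak, sample, peaks, quantile = 0.75) {
  sc <- peakScores(peaks)
  if (!sample %in% colnames(sc)) stop("sample not in ATAC cohort: ", sample)
  if (!peak %in% rownames(sc)) stop("unknown peak: ", peak)
  v <- sc[, sample]
  if (v[peak] >= stats::quantile(v, quantile, names = FALSE)) "high" else "low"
}

#' Combine statuses into a regulation call
#'
#' The per-sample decision rules: a highly expressed regulator over an
#' open peak is a positive call; a lowly expressed regulator over an open
#' peak is a negative call (the regulator's repression is read as
#' released); a closed peak, or an unchanged regulator, yields no call.
#'
#' @param reg_status regulator status (`high`/`low`/`unchanged`).
#' @param target_status target gene status (recorded as evidence).
#' @param peak_status peak openness (`high`/`low`).
#' @param sample_id,regulator_gene,target_gene,peak_id identifiers.
#' @param ttest_p regulator single-sample p-value (evidence).
#' @return a one-row `data.frame` call, or `NULL` when no call is made.
#' @export
callRegulation <- function(reg_status, target_status, peak_status,
                           sample_id = NA_character_,
                           regulator_gene = NA_character_,
                           target_gene = NA_character_,
                           peak_id = NA_character_, ttest_p = NA_real_) {
  if (peak_status != "high" || reg_status == "unchanged") return(NULL)
  data.frame(sample_id = sample_id, regulator_gene = regulator_gene,
             target_gene = target_gene, peak_id = peak_id,
             direction = if (reg_status == "high") "positive" else "negative",
             regulator_status = reg_status, target_status = target_status,
             peak_status = peak_status, ttest_p = ttest_p,
             row.names = NULL)
}

#' Per-sample regulatory analysis over target genes
#'
#' For each target gene: assign peaks within the TSS window, correlate
#' them with the target's expression, shortlist up to three candidate
#' peaks, nominate regulators whose motifs hit the candidate peak
#' sequences, and make per-sample calls by crossing the regulator's
#' single-sample expression status with the peak's openness. Targets
#' absent from the annotation are skipped and reported. The result is
#' deterministic for fixed inputs.
#'
#' @param tumor,normal [ExpressionMatrix-class] cohorts (counts are
#'   log2-transformed internally).
#' @param peaks a [PeakSet-class]; its samples are matched to tumor
#'   samples by id.
#' @param annotation a [GeneAnnotation-class].
#' @param pwms list of [PWMotif-class] (may be empty: no calls, but the
#'   candidate-peak report is still produced).
#' @param targets character vector of target gene ids.
#' @param sequences optional [Biostrings::DNAStringSet] of peak sequences
#'   keyed by peak id; peaks without a sequence are not scanned.
#' @param window TSS window (bp).
#' @param quantile peak openness quantile.
#' @param alpha single-sample t-test level.
#' @return list with `calls` (data frame of per-sample
#'   [callRegulation()] rows), `candidates` (per-target candidate-peak
#'   report; targets without peaks get a `no candidate peaks` row),
#'   `skipped` (targets missing from the annotation).
#' @export
runRegulatoryAnalysis <- function(tumor, normal, peaks, annotation, pwms,
                                  targets, sequences = NULL,
                                  window = 20000L, quantile = 0.75,
                                  alpha = 0.05) {
  skipped <- setdiff(targets, geneIds(annotation))
  targets <- intersect(targets, geneIds(annotation))
  shared <- intersect(sampleIds(peaks), sampleIds(tumor))
  lt <- log2(exprValues(tumor) + 1)
  ln <- log2(exprValues(normal) + 1)
  if (!grepl("count", exprUnit(tumor), ignore.case = TRUE))
    lt <- exprValues(tumor)
  if (!grepl("count", exprUnit(normal), ignore.case = TRUE))
    ln <- exprValues(normal)
  sc <- peakScores(peaks)
  qthr <- apply(sc[, shared, drop = FALSE], 2L, stats::quantile,
                probs = quantile, names = FALSE)
  calls <- list(); cands <- list()
  for (tg in targets) {
    links <- assignPeaks(peaks, tg, annotation, window)
    if (nrow(links) == 0L) {
      cands[[tg]] <- data.frame(gene_id = tg, peak_id = NA_character_,
                                slot = "no candidate peaks",
                                distance = NA_real_, mean_score = NA_real_,
                                rho = NA_real_, rho_defined = NA)
      next
    }
    links <- linkCorrelations(links, peaks, tumor)
    sel <- selectCandidatePeaks(links)
    cands[[tg]] <- data.frame(gene_id = tg, peak_id = sel$peak_id,
                              slot = sel$slot, distance = sel$distance,
                              mean_score = sel$mean_score, rho = sel$rho,
                              rho_defined = sel$rho_defined)
    if (!length(pwms) || is.null(sequences)) next
    for (pi in seq_len(nrow(sel))) {
      pid <- sel$peak_id[pi]
      if (!pid %in% names(sequences)) next
      hits <- scanMotifs(sequences[[pid]], pwms)
      regs <- unique(hits$coding_gene)
      regs <- regs[regs %in% geneIds(tumor) & regs %in% geneIds(normal)]
      for (rg in regs) {
        st <- .singleSampleStatus(lt[rg, shared], ln[rg, ], alpha)
        tgt <- .singleSampleStatus(lt[tg, shared], ln[tg, ], alpha)
        open <- ifelse(sc[pid, shared] >= qthr, "high", "low")
        for (si in seq_along(shared)) {
          cl <- callRegulation(st$status[si], tgt$status[si], open[si],
                               sample_id = shared[si], regulator_gene = rg,
                               target_gene = tg, peak_id = pid,
                               ttest_p = st$p[si])
          if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
        }
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), regulator_gene = character(),
               target_gene = character(), peak_id = character(),
               direction = character(), regulator_status = character(),
               target_status = character(), peak_status = character(),
               ttest_p = numeric())
  cands <- if (length(cands)) do.call(rbind, c(cands, make.row.names = FALSE))
           else data.frame()
  list(calls = calls, candidates = cands, skipped = skipped)
}
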