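#' @include AllClasses.R
NULL

#' Spearman correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with a
#' two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom. If either input is constant the correlation is undefined:
#' the result is flagged (`defined = FALSE`) rather than an error, so
#' callers can report such genes instead of crashing.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `pvalue`, `n`, `defined`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, pvalue = NA_real_, n = n, defined = FALSE))
  r <- stats::cor(rank(x), rank(y))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = r, pvalue = p, n = n, defined = TRUE)
}

#' Classify correlation strength
#'
#' `|rho| < moderate` is weak; `moderate <= |rho| < strong` is moderate
#' (the "moderate relationship at least" boundary at 0.4); `|rho| >=
#' strong` (default 0.7) is strong. `NA` maps to `"undefined"`.
#'
#' @param rho Spearman correlation value(s).
#' @param moderate,strong the two absolute thresholds.
#' @return character vector in `{weak, moderate, strong, undefined}`.
#' @export
classifyStrength <- function(rho, moderate = 0.4, strong = 0.7) {
  out <- rep("undefined", length(rho))
  ok <- !is.na(rho)
  out[ok & abs(rho) < moderate] <- "weak"
  out[ok & abs(rho) >= moderate & abs(rho) < strong] <- "moderate"
  out[ok & abs(rho) >= strong] <- "strong"
  out
}

#' Correlate per-gene copy number with expression
#'
#' For each requested gene, Spearman correlation between its copy-number
#' and expression profiles over the samples shared by both matrices
#' (matched by sample id, so column order is irrelevant), BH-adjusted
#' across the tested genes, with strength classification. Genes missing
#' from either matrix are reported in the `skipped` attribute, not an
#' error; genes with a constant profile get strength `"undefined"`.
#'
#' @param cnv a [CNVMatrix-class].
#' @param expr a tumor [ExpressionMatrix-class].
#' @param genes gene ids to test (default: all genes present in both).
#' @param moderate,strong strength thresholds (see [classifyStrength()]).
#' @return a `data.frame` with `gene`, `rho`, `pvalue`, `qvalue`, `n`,
#'   `strength`; attribute `skipped` lists genes absent from either
#'   matrix.
#' @export
cnvMrnaCorrelation <- function(cnv, expr, genes = NULL,
                               moderate = 0.4, strong = 0.7) {
  shared <- intersect(sampleIds(cnv), sampleIds(expr))
  if (length(shared) < 3L)
    stop("need >= 3 shared samples between CNV and expression; found ",
         length(shared))
  if (is.null(genes)) genes <- intersect(geneIds(cnv), geneIds(expr))
  present <- genes %in% geneIds(cnv) & genes %in% geneIds(expr)
  skipped <- genes[!present]
  genes <- genes[present]
  cv <- cnvValues(cnv)[genes, shared, drop = FALSE]
  ev <- exprValues(expr)[genes, shared, drop = FALSE]
  res <- lapply(seq_along(genes), function(i) spearmanRho(cv[i, ], ev[i, ]))
  rho <- vapply(res, `[[`, numeric(1L), "rho")
  pv <- vapply(res, `[[`, numeric(1L), "pvalue")
  out <- data.frame(gene = genes, rho = rho, pvalue = pv,
                    qvalue = bhAdjust(pv), n = length(shared),
                    strength = classifyStrength(rho, moderate, strong),
                    row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}
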