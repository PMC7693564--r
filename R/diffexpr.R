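#' @include AllClasses.R
NULL

.checkCounts <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
}

#' Median-of-ratios size factors
#'
#' The classical normalization for count matrices: each sample's factor is
#' the median across genes of its ratio to the geometric-mean reference
#' sample, computed over genes expressed in every sample.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of size factors (geometric mean 1-ish).
#' @export
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  .checkCounts(counts)
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) stop("no gene is expressed in every sample; cannot normalize")
  sf <- apply(counts, 2L, function(s) exp(stats::median(log(s[ok]) - lg[ok])))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion
#'
#' After median-of-ratios normalization, per-gene dispersion is estimated
#' by moments from the pooled within-group mean and variance:
#' `phi = (var - mu) / mu^2`, floored at `1e-8`. Genes with all-zero
#' counts have no defined dispersion; they are returned as `NA` and must
#' be excluded from testing. The shrunk variant used by the Wald test
#' pulls each log-dispersion halfway toward the mean log-dispersion
#' (geometric-mean shrinkage with weight 0.5).
#'
#' @param counts gene x sample count matrix.
#' @param groups group label per sample (>= 2 samples per group).
#' @param sf optional precomputed size factors.
#' @return list with `dispersion` (per-gene, `NA` where undefined),
#'   `shrunk` (the shrunken variant), and `flagged` (ids of all-zero
#'   genes).
#' @export
estimateDispersion <- function(counts, groups, sf = sizeFactors(counts)) {
  counts <- as.matrix(counts)
  .checkCounts(counts)
  groups <- as.character(groups)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  y <- sweep(counts, 2L, sf, "/")
  gs <- unique(groups)
  n <- vapply(gs, function(g) sum(groups == g), numeric(1L))
  mu <- vapply(gs, function(g) rowMeans(y[, groups == g, drop = FALSE]),
               numeric(nrow(y)))
  v <- vapply(gs, function(g) apply(y[, groups == g, drop = FALSE], 1L,
                                    stats::var), numeric(nrow(y)))
  mu <- matrix(mu, nrow = nrow(y)); v <- matrix(v, nrow = nrow(y))
  vw <- as.numeric(v %*% (n - 1)) / (sum(n) - length(gs))
  mw <- as.numeric(mu %*% n) / sum(n)
  phi <- pmax((vw - mw) / mw^2, 1e-8)
  flagged <- rowSums(counts) == 0
  phi[flagged] <- NA_real_
  lp <- log(phi)
  shrunk <- exp(0.5 * mean(lp, na.rm = TRUE) + 0.5 * lp)
  names(phi) <- names(shrunk) <- rownames(counts)
  list(dispersion = phi, shrunk = shrunk,
       flagged = rownames(counts)[flagged])
}

.normMeans <- function(counts, sf, idx, pseudo = 0.5) {
  rowMeans(sweep(counts[, idx, drop = FALSE], 2L, sf[idx], "/")) + pseudo
}

#' Exact conditional NB test for two groups
#'
#' Counts are first equalized by dividing by the size factors
#' (pseudo-counts), then the group totals are rounded back to integers.
#' Under the null of equal means, the conditional distribution of the
#' group-A total given the grand total is formed from the two group-total
#' NB distributions (group g total ~ NB with mean `n_g * mu` and size
#' `n_g / phi`); the two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one. As `phi -> 0` this
#' reduces to the exact binomial test with success probability
#' `n_A / (n_A + n_B)`. The log2 fold change compares normalized group
#' means with pseudo-count 0.5.
#'
#' @param counts gene x sample integer count matrix.
#' @param groupA,groupB column indices (or names) of the two groups.
#' @param dispersion per-gene dispersion (from [estimateDispersion()]);
#'   genes with `NA` dispersion are skipped (p and lfc `NA`).
#' @param sf optional size factors for the full matrix.
#' @return a `data.frame` with `gene`, `log2fc` (A vs B), `pvalue`,
#'   `qvalue` (BH), `method = "nb_exact"`.
#' @export
nbExactTest <- function(counts, groupA, groupB,
                        dispersion, sf = sizeFactors(counts)) {
  counts <- as.matrix(counts)
  .checkCounts(counts)
  if (length(groupA) < 1L || length(groupB) < 1L)
    stop("both groups must be non-empty")
  y <- sweep(counts, 2L, sf, "/")
  nA <- length(groupA); nB <- length(groupB)
  a <- round(rowSums(y[, groupA, drop = FALSE]))
  b <- round(rowSums(y[, groupB, drop = FALSE]))
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    ph <- dispersion[i]
    if (is.na(ph)) return(NA_real_)
    s <- a[i] + b[i]
    if (s == 0) return(1)
    mu <- s / (nA + nB)
    supp <- 0:s
    lp <- stats::dnbinom(supp, size = nA / ph, mu = nA * mu, log = TRUE) +
      stats::dnbinom(s - supp, size = nB / ph, mu = nB * mu, log = TRUE)
    lp <- lp - max(lp)
    pr <- exp(lp); pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[a[i] + 1L] * (1 + 1e-8)]))
  }, numeric(1L))
  lfc <- log2(.normMeans(counts, sf, groupA) / .normMeans(counts, sf, groupB))
  lfc[is.na(pv)] <- NA_real_
  data.frame(gene = rownames(counts), log2fc = lfc, pvalue = pv,
             qvalue = bhAdjust(pv), method = "nb_exact",
             row.names = NULL)
}

#' Wald test with shrunken dispersion
#'
#' Per gene, the log-link two-group Wald statistic
#' `log(muA/muB) / SE` with `SE^2 = (1/muA + phi)/nA + (1/muB + phi)/nB`
#' (the delta-method variance of a log NB mean), using the shrunken
#' dispersion, and a two-sided normal p-value. Normalized group means
#' carry a 0.5 pseudo-count.
#'
#' @inheritParams nbExactTest
#' @param shrunk_dispersion per-gene shrunken dispersion.
#' @return a `data.frame` as in [nbExactTest()] with
#'   `method = "nb_wald_shrunk"`.
#' @export
nbWaldShrunkTest <- function(counts, groupA, groupB,
                             shrunk_dispersion, sf = sizeFactors(counts)) {
  counts <- as.matrix(counts)
  .checkCounts(counts)
  if (length(groupA) < 1L || length(groupB) < 1L)
    stop("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  mA <- .normMeans(counts, sf, groupA)
  mB <- .normMeans(counts, sf, groupB)
  beta <- log(mA / mB)
  se <- sqrt((1 / mA + shrunk_dispersion) / nA +
             (1 / mB + shrunk_dispersion) / nB)
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  pv[is.na(shrunk_dispersion)] <- NA_real_
  lfc <- beta / log(2)
  lfc[is.na(pv)] <- NA_real_
  data.frame(gene = rownames(counts), log2fc = lfc, pvalue = pv,
             qvalue = bhAdjust(pv), method = "nb_wald_shrunk",
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]). `NA` p-values (untested genes) stay `NA`; `NaN`
#' is an error.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (or `NA`).
#' @return adjusted q-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.nan(pvalues))) stop("NaN p-value")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Consensus of two differential-expression results
#'
#' A gene is called only when it is significant in BOTH tests at `alpha`
#' (on q-values), has `|log2FC| >= lfc_cutoff` in both, and the fold
#' changes agree in sign; its direction is the common sign. The result is
#' always a subset of each single-method call set.
#'
#' @param resA,resB result tables over the same gene universe.
#' @param alpha FDR level.
#' @param lfc_cutoff absolute log2-fold-change cutoff.
#' @param cluster cluster index recorded on the result.
#' @return list (class `DEGeneSet`-like) with `cluster`, `genes` (named
#'   character vector gene -> "up"/"down"), `alpha`, `lfc_cutoff`.
#' @export
consensusDE <- function(resA, resB, alpha = 0.05, lfc_cutoff = 1,
                        cluster = 1L) {
  if (!identical(resA$gene, resB$gene))
    stop("result tables cover different gene universes")
  sig <- function(r) !is.na(r$qvalue) & r$qvalue < alpha &
    abs(r$log2fc) >= lfc_cutoff
  keep <- sig(resA) & sig(resB) & sign(resA$log2fc) == sign(resB$log2fc)
  genes <- stats::setNames(ifelse(resA$log2fc[keep] > 0, "up", "down"),
                           resA$gene[keep])
  structure(list(cluster = cluster, genes = genes, alpha = alpha,
                 lfc_cutoff = lfc_cutoff), class = "DEGeneSet")
}

#' Per-cluster consensus differential expression vs the normal cohort
#'
#' Runs both NB tests for every cluster against all normal samples on the
#' pooled count matrix (shared size factors and dispersions) and combines
#' them with [consensusDE()].
#'
#' @param tumor,normal [ExpressionMatrix-class] count matrices over the
#'   same genes.
#' @param labels named integer cluster labels covering the tumor samples.
#' @param alpha,lfc_cutoff consensus thresholds.
#' @return list with `sets` (per-cluster `DEGeneSet`), `tests` (per
#'   cluster, the two raw result tables), `dispersion` (the estimate
#'   object).
#' @export
clusterDE <- function(tumor, normal, labels, alpha = 0.05, lfc_cutoff = 1) {
  stopifnot(identical(geneIds(tumor), geneIds(normal)))
  labels <- labels[sampleIds(tumor)]
  if (anyNA(labels)) stop("labels must cover every tumor sample")
  counts <- cbind(exprValues(tumor), exprValues(normal))
  .checkCounts(counts)
  nT <- ncol(tumor)
  normal_idx <- nT + seq_len(ncol(normal))
  ks <- sort(unique(labels))
  sf <- sizeFactors(counts)
  sets <- list(); tests <- list()
  for (k in ks) {
    idxA <- which(labels == k)
    sub <- c(idxA, normal_idx)
    grp <- rep(c("cluster", "normal"), c(length(idxA), length(normal_idx)))
    disp <- estimateDispersion(counts[, sub, drop = FALSE], grp,
                               sf = sf[sub])
    resA <- nbExactTest(counts[, sub, drop = FALSE],
                        seq_along(idxA), length(idxA) + seq_along(normal_idx),
                        disp$dispersion, sf = sf[sub])
    resB <- nbWaldShrunkTest(counts[, sub, drop = FALSE],
                             seq_along(idxA),
                             length(idxA) + seq_along(normal_idx),
                             disp$shrunk, sf = sf[sub])
    sets[[as.character(k)]] <- consensusDE(resA, resB, alpha, lfc_cutoff,
                                           cluster = k)
    tests[[as.character(k)]] <- list(nb_exact = resA, nb_wald_shrunk = resB,
                                     dispersion = disp)
  }
  list(sets = sets, tests = tests)
}

#' Categorise differentially expressed NK ligands
#'
#' Crosses each cluster's consensus DE directions with the annotation's
#' NK-ligand roles: activator ligands called down are reported as
#' low-expressed activators, activator ligands called up as high
#' activators, and likewise for inhibitor ligands. Genes with any other
#' role are ignored. Empty categories are rendered `"-"` by
#' [formatNKLigandTable()].
#'
#' @param sets list of `DEGeneSet` per cluster (from [clusterDE()] or
#'   [consensusDE()]).
#' @param annotation a [GeneAnnotation-class] covering the gene universe.
#' @return a `data.frame` with one row per cluster and list-columns
#'   `low_activators`, `high_activators`, `low_inhibitors`,
#'   `high_inhibitors`.
#' @export
classifyNKLigands <- function(sets, annotation) {
  role <- immuneRole(annotation)
  rows <- lapply(sets, function(s) {
    g <- names(s$genes); d <- s$genes
    r <- role[g]
    list(cluster = s$cluster,
         low_activators = sort(g[r == "nk_activator_ligand" & d == "down"]),
         high_activators = sort(g[r == "nk_activator_ligand" & d == "up"]),
         low_inhibitors = sort(g[r == "nk_inhibitor_ligand" & d == "down"]),
         high_inhibitors = sort(g[r == "nk_inhibitor_ligand" & d == "up"]))
  })
  data.frame(
    cluster = vapply(rows, `[[`, numeric(1L), "cluster"),
    low_activators = I(lapply(rows, `[[`, "low_activators")),
    high_activators = I(lapply(rows, `[[`, "high_activators")),
    low_inhibitors = I(lapply(rows, `[[`, "low_inhibitors")),
    high_inhibitors = I(lapply(rows, `[[`, "high_inhibitors")),
    row.names = NULL)
}

#' Render the NK-ligand table as text
#'
#' Four category columns per cluster; an empty category is shown as
#' `"-"`.
#'
#' @param tab the table from [classifyNKLigands()].
#' @return a character `data.frame` ready for printing or writing.
#' @export
formatNKLigandTable <- function(tab) {
  fmt <- function(col) vapply(col, function(g)
    if (length(g)) paste(g, collapse = ", ") else "-", character(1L))
  data.frame(cluster = paste("Cluster", tab$cluster),
             low_activators = fmt(tab$low_activators),
             high_activators = fmt(tab$high_activators),
             low_inhibitors = fmt(tab$low_inhibitors),
             high_inhibitors = fmt(tab$high_inhibitors),
             row.names = NULL)
}
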