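#' @include AllClasses.R
NULL

#' Prepare an expression matrix for NMF
#'
#' Counts are transformed to `log2(x + 1)`; every gene is then shifted so
#' its minimum across samples is zero, which removes the shared baseline
#' component that would otherwise absorb one factor, and guarantees
#' non-negativity for inputs already on a log or normalized scale. Genes
#' left constant (all-zero rows) are dropped with a message.
#'
#' @param x an [ExpressionMatrix-class] or a non-negative numeric matrix
#'   (returned untransformed apart from the checks).
#' @return a non-negative numeric matrix ready for [nmfFactorize()].
#' @export
nmfInputMatrix <- function(x) {
  if (is(x, "ExpressionMatrix")) {
    v <- exprValues(x)
    if (grepl("count", exprUnit(x), ignore.case = TRUE)) v <- log2(v + 1)
    v <- v - apply(v, 1L, min)
    keep <- apply(v, 1L, max) > 0
    if (any(!keep))
      message(sum(!keep), " constant gene(s) dropped before NMF")
    v[keep, , drop = FALSE]
  } else {
    v <- as.matrix(x)
    if (any(v < 0)) stop("NMF input must be non-negative")
    v
  }
}

#' Factorize a non-negative matrix by multiplicative updates
#'
#' Minimises `||X - WH||_F^2 + gamma * (sum(W) + sum(H))` (the l1 penalty
#' only when `regularizer = "l1"`) by the classical multiplicative update
#' rules, which never increase the objective. The objective is recorded
#' once per iteration (after the H half-update, from cached
#' cross-products). Iteration stops when the relative objective change
#' drops below `cfg@tol` or after `cfg@max_iter` iterations. `W` is initialized with i.i.d. uniform(0,1]
#' entries scaled by `sqrt(mean(X))`; `H` starts as a constant matrix, so
#' after the first update every `H` column depends only on its own sample
#' - permuting input samples permutes the solution consistently.
#'
#' @param X non-negative numeric matrix (genes x samples), or an
#'   [ExpressionMatrix-class] which is first passed through
#'   [nmfInputMatrix()].
#' @param r factorization rank, `2 <= r < min(dim(X))`.
#' @param cfg an [NMFConfig-class].
#' @param seed integer seed for the initialization.
#' @param W0,H0 optional explicit initial factors (both must be given
#'   together); used for oracle comparisons and warm starts.
#' @return an [NMFFactorization-class].
#' @export
nmfFactorize <- function(X, r, cfg = NMFConfig(), seed = 1L,
                         W0 = NULL, H0 = NULL) {
  if (is(X, "ExpressionMatrix")) X <- nmfInputMatrix(X)
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  n <- nrow(X); p <- ncol(X)
  r <- as.integer(r)
  if (r < 2L || r >= min(n, p))
    stop(sprintf("rank r=%d out of range [2, %d)", r, min(n, p)))
  zr <- rowSums(X) == 0; zc <- colSums(X) == 0
  if (any(zr)) stop("all-zero row(s) in X: ",
                    paste(utils::head(which(zr)), collapse = ", "))
  if (any(zc)) stop("all-zero column(s) in X: ",
                    paste(utils::head(which(zc)), collapse = ", "))
  gamma <- if (cfg@regularizer == "l1") cfg@gamma else 0
  if (is.null(W0) != is.null(H0))
    stop("W0 and H0 must be supplied together")
  if (is.null(W0)) {
    set.seed(seed)
    sc <- sqrt(mean(X))
    W <- matrix(1 - stats::runif(n * r), n, r) * sc
    # H columns are drawn from per-sample streams keyed by the sample id,
    # so permuting input samples permutes the initialization (and hence
    # the whole trajectory) consistently
    H <- matrix(sc, r, p)
    ids <- colnames(X)
    for (j in seq_len(p)) {
      key <- if (is.null(ids)) j else sum(utf8ToInt(ids[j]) * seq_len(nchar(ids[j])))
      set.seed((seed + 131L * key) %% 999999937L)
      H[, j] <- (1 - stats::runif(r)) * sc
    }
  } else {
    W <- as.matrix(W0); H <- as.matrix(H0)
    if (any(W < 0) || any(H < 0)) stop("initial factors must be non-negative")
  }
  fit <- nmf_mu_cpp(X, W, H, cfg@max_iter, cfg@tol, gamma)
  W <- fit$W; H <- fit$H
  if (!is.null(colnames(X))) colnames(H) <- colnames(X)
  if (!is.null(rownames(X))) rownames(W) <- rownames(X)
  new("NMFFactorization", W = W, H = H, r = r,
      loss_trajectory = as.numeric(fit$loss), seed = as.integer(seed))
}

#' Frobenius residual of a factorization
#'
#' @param f an [NMFFactorization-class].
#' @param X the matrix that was factorized.
#' @return `||X - WH||_F`.
#' @export
frobResidual <- function(f, X) sqrt(sum((as.matrix(X) - f@W %*% f@H)^2))

#' Sample connectivity matrix of a factorization
#'
#' Entry (i, j) is 1 when samples i and j share the same dominant factor
#' (argmax over the rows of each `H` column), else 0; symmetric with unit
#' diagonal. Argmax ties are resolved to the lowest cluster index and
#' reported with a message.
#'
#' @param f an [NMFFactorization-class].
#' @return a p x p binary matrix.
#' @export
connectivity <- function(f) {
  H <- f@H
  cl <- max.col(t(H), ties.method = "first")
  tied <- vapply(seq_len(ncol(H)), function(j)
    sum(H[, j] == max(H[, j])) > 1L, logical(1L))
  if (any(tied))
    message("connectivity: argmax tie for ", sum(tied),
            " sample(s), resolved to the lowest cluster index")
  C <- outer(cl, cl, "==") + 0
  dimnames(C) <- list(colnames(H), colnames(H))
  C
}

#' Area under the consensus CDF
#'
#' Exact integral over `[0, 1]` of the empirical CDF of the off-diagonal
#' consensus entries; for values in `[0, 1]` this equals
#' `1 - mean(values)` (the step function integrated in closed form).
#'
#' @param consensus symmetric consensus matrix.
#' @return the area, a value in `[0, 1]`.
#' @export
consensusCDFArea <- function(consensus) {
  v <- consensus[upper.tri(consensus)]
  if (!length(v)) return(NA_real_)
  1 - mean(v)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the off-diagonal consensus distances
#' (`1 - consensus`) and the cophenetic distances of the average-linkage
#' dendrogram built from them. Returns the `NA` sentinel when either
#' distance vector is constant (the correlation is undefined).
#'
#' @param x a [ConsensusResult-class] or a consensus matrix.
#' @return a value in `[-1, 1]`, or `NA`.
#' @export
copheneticCoefficient <- function(x) {
  C <- if (is(x, "ConsensusResult")) x@consensus else as.matrix(x)
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0) return(NA_real_)
  stats::cor(d, cd)
}

#' Consensus clustering at one rank
#'
#' Runs `cfg@n_restarts` independently seeded factorizations (restart
#' seeds are drawn from the master `seed`), averages their connectivity
#' matrices into the consensus matrix, labels samples by average-linkage
#' hierarchical clustering of `1 - consensus` cut at `r` clusters, and
#' fills the rank-quality metrics (cophenetic correlation, per-cluster
#' mean within-cluster consensus, CDF area). `delta_area` is completed
#' across ranks by [rankMetrics()].
#'
#' @param X matrix or [ExpressionMatrix-class] (transformed via
#'   [nmfInputMatrix()]).
#' @param r rank.
#' @param cfg an [NMFConfig-class] (`n_restarts >= 2`).
#' @param seed master seed for the restarts.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(X, r, cfg = NMFConfig(), seed = 1L) {
  if (cfg@n_restarts < 2L) stop("n_restarts must be >= 2")
  if (is(X, "ExpressionMatrix")) X <- nmfInputMatrix(X)
  X <- as.matrix(X)
  set.seed(seed)
  restart_seeds <- sample.int(999999937L, cfg@n_restarts)
  p <- ncol(X)
  C <- matrix(0, p, p)
  for (s in restart_seeds) {
    f <- nmfFactorize(X, r, cfg, seed = s)
    C <- C + connectivity(f)
  }
  C <- C / cfg@n_restarts
  dimnames(C) <- list(colnames(X), colnames(X))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(hc, k = r)
  names(labels) <- colnames(X)
  cc <- vapply(seq_len(r), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2L) return(1)
    M <- C[idx, idx]
    mean(M[upper.tri(M)])
  }, numeric(1L))
  new("ConsensusResult", r = as.integer(r), consensus = C,
      labels = as.integer(labels) |> stats::setNames(names(labels)),
      cophenetic = copheneticCoefficient(C), cluster_consensus = cc,
      cdf_area = consensusCDFArea(C), delta_area = NA_real_)
}

#' Rank-quality table across consensus results
#'
#' Collects cophenetic correlation, CDF area and mean cluster consensus
#' per rank and computes the delta area: for the smallest rank the CDF
#' area itself, for every later rank the relative increase over the
#' previous rank.
#'
#' @param results list of [ConsensusResult-class], one per rank.
#' @return a `data.frame` with columns `rank`, `cophenetic`, `cdf_area`,
#'   `delta_area`, `mean_cluster_consensus`.
#' @export
rankMetrics <- function(results) {
  if (length(results) < 1L) stop("no consensus results supplied")
  ranks <- vapply(results, function(x) x@r, integer(1L))
  o <- order(ranks)
  results <- results[o]; ranks <- ranks[o]
  area <- vapply(results, function(x) x@cdf_area, numeric(1L))
  delta <- c(area[1L],
             if (length(area) > 1L) diff(area) / utils::head(area, -1L))
  data.frame(
    rank = ranks,
    cophenetic = vapply(results, function(x) x@cophenetic, numeric(1L)),
    cdf_area = area,
    delta_area = delta,
    mean_cluster_consensus = vapply(results, function(x)
      mean(x@cluster_consensus), numeric(1L)))
}

#' Select the factorization rank
#'
#' Default rule: the rank with the largest cophenetic correlation; exact
#' ties are broken by larger delta area, then by the smaller rank. Ranks
#' whose cophenetic value is the `NA` sentinel are excluded; if none
#' remain this is an error.
#'
#' @param metrics the table from [rankMetrics()].
#' @param rule currently only `"cophenetic"`.
#' @return list with `rank` (the chosen rank) and `metrics` (the full
#'   table).
#' @export
selectRank <- function(metrics, rule = c("cophenetic")) {
  rule <- match.arg(rule)
  stopifnot(nrow(metrics) >= 1L)
  ok <- !is.na(metrics$cophenetic)
  if (!any(ok)) stop("cophenetic undefined for every candidate rank")
  m <- metrics[ok, , drop = FALSE]
  best <- m[m$cophenetic == max(m$cophenetic), , drop = FALSE]
  if (nrow(best) > 1L)
    best <- best[best$delta_area == max(best$delta_area), , drop = FALSE]
  list(rank = min(best$rank), metrics = metrics)
}

#' Consensus NMF subtyping across a rank range
#'
#' Convenience wrapper: runs [consensusCluster()] for every rank in
#' `cfg@rank_range`, assembles [rankMetrics()], and applies
#' [selectRank()].
#'
#' @param X matrix or tumor [ExpressionMatrix-class].
#' @param cfg an [NMFConfig-class].
#' @param seed master seed.
#' @return list with `rank`, `metrics`, `results` (per-rank
#'   [ConsensusResult-class] list, named by rank) and `labels` (the
#'   sample labels at the chosen rank).
#' @export
subtypeNMF <- function(X, cfg = NMFConfig(), seed = 1L) {
  if (is(X, "ExpressionMatrix")) X <- nmfInputMatrix(X)
  results <- lapply(cfg@rank_range, function(r)
    consensusCluster(X, r, cfg, seed = seed + r))
  names(results) <- as.character(cfg@rank_range)
  metrics <- rankMetrics(results)
  sel <- selectRank(metrics)
  list(rank = sel$rank, metrics = metrics, results = results,
       labels = results[[as.character(sel$rank)]]@labels)
}
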