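#' @include AllClasses.R
NULL

#' Expression tertile groups
#'
#' Splits samples into `low` / `moderate` / `high` at the 1/3 and 2/3
#' empirical quantiles of the expression values. Values tied with a
#' boundary fall into the lower group (the split uses `<=`); group sizes
#' are attached as the `sizes` attribute. All-identical values admit no
#' stratification and are an error.
#'
#' @param x named numeric vector of per-sample expression (>= 3 samples).
#' @return factor with levels `low`, `moderate`, `high`, named like `x`;
#'   attribute `sizes` holds the group sizes.
#' @export
tertileGroups <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples")
  if (max(x) == min(x)) stop("all expression values identical; cannot stratify")
  qs <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  g <- ifelse(x <= qs[1L], "low", ifelse(x <= qs[2L], "moderate", "high"))
  g <- factor(g, levels = c("low", "moderate", "high"))
  names(g) <- names(x)
  attr(g, "sizes") <- table(g)
  g
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates via [survival::survfit()]; censored subjects
#' leave the risk set after their censoring time. Curve bounds and
#' monotonicity are asserted on every output.
#'
#' @param table survival `data.frame` (`sample_id`, `time`, `event`).
#' @param groups named group labels covering `table$sample_id` (e.g. from
#'   [tertileGroups()]).
#' @return a `data.frame` with `group`, `time`, `survival`, `at_risk`,
#'   `n_event` (one row per event/censoring time per group).
#' @export
kmEstimate <- function(table, groups) {
  table <- validateSurvivalTable(table)
  grp <- groups[table$sample_id]
  if (anyNA(grp)) stop("groups must cover every sample in the table")
  if (!length(table$time)) stop("empty survival table")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = table$time, event = table$event, grp = grp))
  sm <- summary(fit, censored = TRUE)
  gl <- if (is.null(sm$strata)) rep(levels(factor(grp))[1L],
                                    length(sm$time))
        else sub("^grp=", "", as.character(sm$strata))
  out <- data.frame(group = gl, time = sm$time, survival = sm$surv,
                    at_risk = sm$n.risk, n_event = sm$n.event,
                    row.names = NULL)
  stopifnot(all(out$survival >= 0 & out$survival <= 1.000000001))
  for (g in unique(out$group)) {
    s <- out$survival[out$group == g][order(out$time[out$group == g])]
    stopifnot(all(diff(s) <= 1e-12))
  }
  out
}

#' Log-rank test across groups
#'
#' K-group log-rank statistic via [survival::survdiff()]:
#' chi-square with `K - 1` degrees of freedom. Requires at least two
#' non-empty groups and one observed event.
#'
#' @inheritParams kmEstimate
#' @return list with `chi2`, `df`, `pvalue`.
#' @export
logrankTest <- function(table, groups) {
  table <- validateSurvivalTable(table)
  grp <- droplevels(factor(groups[table$sample_id]))
  if (anyNA(grp)) stop("groups must cover every sample in the table")
  if (nlevels(grp) < 2L) stop("need at least two non-empty groups")
  if (sum(table$event) < 1L) stop("need at least one observed event")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = table$time, event = table$event, grp = grp))
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       pvalue = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Survival stratification by one gene's expression
#'
#' Convenience wrapper: tertile groups of the gene's log2 expression in
#' the tumor cohort, Kaplan-Meier curves, and the log-rank test.
#'
#' @param table survival `data.frame`.
#' @param tumor tumor [ExpressionMatrix-class].
#' @param gene gene id.
#' @return list with `groups`, `curves`, `test`.
#' @export
survivalByExpression <- function(table, tumor, gene) {
  if (!gene %in% geneIds(tumor)) stop("gene not in tumor matrix: ", gene)
  x <- log2(exprValues(tumor)[gene, ] + 1)
  groups <- tertileGroups(x)
  table <- validateSurvivalTable(table)
  table <- table[table$sample_id %in% names(groups), , drop = FALSE]
  list(groups = groups, curves = kmEstimate(table, groups),
       test = logrankTest(table, groups))
}
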