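# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the package implementation.

# Spearman rho from explicit mid-ranks + t-approximation p-value
oracleSpearman <- function(x, y) {
  # mid-rank: mean position of a value's ties in the sorted vector
  midrank <- function(v) sapply(v, function(vi) mean(which(sort(v) == vi)))
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, pvalue = 2 * pt(-abs(tt), n - 2))
}

# type-7 quantile from the sorted vector, by the interpolation formula
oracleQuantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# one multiplicative-update NMF run, coded independently
oracleNMF <- function(X, W, H, iters, gamma = 0) {
  eps <- 1e-12
  for (i in seq_len(iters)) {
    H <- H * (2 * t(W) %*% X) / (2 * t(W) %*% W %*% H + gamma + eps)
    W <- W * (2 * X %*% t(H)) / (2 * W %*% H %*% t(H) + gamma + eps)
  }
  list(W = W, H = H, resid = sqrt(sum((X - W %*% H)^2)))
}

# exhaustive three-slot candidate-peak selection
oracleSelect <- function(links) {
  picks <- integer()
  slots <- character()
  def <- which(!is.na(links$rho))
  if (length(def)) {
    picks <- c(picks, def[order(links$rho[def], decreasing = TRUE)][1L])
    slots <- c(slots, "positive")
    picks <- c(picks, def[order(links$rho[def])][1L])
    slots <- c(slots, "negative")
  }
  best <- seq_len(nrow(links))
  best <- best[order(links$distance[best], -links$mean_score[best],
                     links$peak_id[best])][1L]
  picks <- c(picks, best); slots <- c(slots, "closest")
  keep <- !duplicated(picks)
  data.frame(idx = picks[keep], slot = slots[keep])
}

# Kaplan-Meier product-limit estimate at each event time, one group
oracleKM <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square by observed-minus-expected tabulation
oracleLogrank <- function(time, event, group) {
  gs <- sort(unique(group))
  stopifnot(length(gs) == 2L)
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == gs[1L])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == gs[1L])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# small deterministic expression fixture
makeCounts <- function(G = 8, n = 6, seed = 1, mu = 40, phi = 0.3) {
  set.seed(seed)
  m <- matrix(rnbinom(G * n, mu = mu, size = 1 / phi), G, n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n)))
  m
}
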