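test_that("an exact low-rank product is a fixed point of the updates", {
  set.seed(4)
  W0 <- matrix(runif(6 * 2, 0.5, 2), 6, 2)
  H0 <- matrix(runif(2 * 8, 0.5, 2), 2, 8)
  X <- W0 %*% H0
  f <- nmfFactorize(X, 2, NMFConfig(max_iter = 5L, tol = 1e-12),
                    W0 = W0, H0 = H0)
  expect_lt(frobResidual(f, X), 1e-8)
})

test_that("the factorization matches an independently coded update oracle", {
  set.seed(6)
  X <- matrix(runif(6 * 8, 0, 5), 6, 8)
  W0 <- matrix(runif(6 * 2, 0.1, 1), 6, 2)
  H0 <- matrix(runif(2 * 8, 0.1, 1), 2, 8)
  iters <- 50L
  f <- nmfFactorize(X, 2, NMFConfig(max_iter = iters, tol = 1e-300),
                    W0 = W0, H0 = H0)
  o <- oracleNMF(X, W0, H0, iters)
  expect_equal(frobResidual(f, X), o$resid, tolerance = 1e-8)
  expect_equal(f@W, o$W, tolerance = 1e-8)
})

test_that("the loss trajectory never increases", {
  set.seed(14)
  for (i in 1:20) {
    X <- matrix(runif(10 * 12, 0.01, 3), 10, 12)
    f <- nmfFactorize(X, sample(2:4, 1), NMFConfig(max_iter = 60L), seed = i)
    d <- diff(f@loss_trajectory)
    expect_true(all(d <= 1e-10 * f@loss_trajectory[1]))
  }
})

test_that("l1 regularization increases factor sparsity monotonically", {
  set.seed(25)
  sparsity <- function(gamma) {
    vals <- sapply(1:10, function(s) {
      X <- matrix(runif(15 * 10, 0, 2), 15, 10)
      f <- nmfFactorize(X, 3,
                        NMFConfig(gamma = gamma, regularizer = "l1",
                                  max_iter = 300L, tol = 1e-8), seed = s)
      mean(f@W < 1e-6)
    })
    mean(vals)
  }
  s0 <- sparsity(0)
  s1 <- sparsity(2)
  expect_gte(s1, s0)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(runif(20), 4, 5)
  expect_error(nmfFactorize(X, 1), "out of range")
  expect_error(nmfFactorize(X, 4), "out of range")
  X0 <- X; X0[2, ] <- 0
  expect_error(nmfFactorize(X0, 2), "all-zero row")
  X1 <- X; X1[, 3] <- 0
  expect_error(nmfFactorize(X1, 2), "all-zero column")
})

test_that("connectivity reflects dominant factors, with tie logging", {
  f <- new("NMFFactorization",
           W = matrix(1, 3, 2), H = cbind(c(1, 0), c(0, 1), c(1, 0)),
           r = 2L, loss_trajectory = c(2, 1), seed = 1L)
  C <- connectivity(f)
  expect_identical(unname(C), rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1)))

  # ties resolved to the lowest cluster index, with a message
  ftie <- new("NMFFactorization",
              W = matrix(1, 3, 2), H = cbind(c(1, 1), c(0, 1), c(1, 1)),
              r = 2L, loss_trajectory = c(2, 1), seed = 1L)
  expect_message(Ct <- connectivity(ftie), "tie")
  expect_identical(unname(Ct[1, 2]), 0)

  # permuting samples permutes rows/columns consistently
  perm <- c(3, 1, 2)
  fp <- new("NMFFactorization", W = f@W, H = f@H[, perm], r = 2L,
            loss_trajectory = c(2, 1), seed = 1L)
  expect_identical(unname(connectivity(fp)), unname(C[perm, perm]))
})

test_that("consensus on separable data is binary with cophenetic 1", {
  set.seed(33)
  # two well-separated blocks
  X <- cbind(matrix(runif(40 * 6, 4, 5), 40, 6),
             matrix(runif(40 * 6, 0, 0.2), 40, 6))
  X[1:20, ] <- X[1:20, c(7:12, 1:6)]
  colnames(X) <- sprintf("s%02d", 1:12)
  res <- consensusCluster(X, 2, NMFConfig(n_restarts = 8L), seed = 5)
  off <- res@consensus[upper.tri(res@consensus)]
  expect_true(all(off < 0.05 | off > 0.95))
  expect_equal(res@cophenetic, 1, tolerance = 1e-9)
  expect_equal(unname(res@cluster_consensus), c(1, 1), tolerance = 1e-9)
})

test_that("cophenetic coefficient matches a hand-built example", {
  C <- rbind(c(1, .9, .1, .1), c(.9, 1, .1, .1),
             c(.1, .1, 1, .8), c(.1, .1, .8, 1))
  # average linkage on 1-C: pairs at .1/.2, cross distances all .9 -> the
  # cophenetic distances are .1, .2 within pairs and .9 across, which
  # equals the original distances, so the correlation is exactly 1
  expect_equal(copheneticCoefficient(C), 1, tolerance = 1e-12)

  # invariance under simultaneous row/column permutation
  p <- c(3, 1, 4, 2)
  expect_equal(copheneticCoefficient(C[p, p]), copheneticCoefficient(C),
               tolerance = 1e-12)

  # constant consensus -> undefined sentinel
  expect_true(is.na(copheneticCoefficient(matrix(1, 3, 3))))
})

test_that("CDF area and delta area follow the closed forms", {
  # perfect binary consensus: area = fraction of zero entries
  C1 <- diag(4); C1[1, 2] <- C1[2, 1] <- 1
  a1 <- consensusCDFArea(C1)
  expect_equal(a1, 5 / 6, tolerance = 1e-12)  # 5 of 6 off-diag pairs are 0

  # hand-computed step integral for a small non-binary consensus
  C2 <- rbind(c(1, .5, .2), c(.5, 1, .8), c(.2, .8, 1))
  # off-diag values .5, .2, .8 -> integral of ECDF = 1 - mean = 0.5
  expect_equal(consensusCDFArea(C2), 0.5, tolerance = 1e-12)

  r1 <- new("ConsensusResult", r = 2L, consensus = C1,
            labels = setNames(c(1L, 1L, 2L, 2L), sprintf("s%d", 1:4)),
            cophenetic = 0.9, cluster_consensus = c(1, 1),
            cdf_area = a1, delta_area = NA_real_)
  C3 <- diag(4); C3[3, 4] <- C3[4, 3] <- 1
  r2 <- new("ConsensusResult", r = 3L, consensus = C3,
            labels = setNames(c(1L, 2L, 3L, 3L), sprintf("s%d", 1:4)),
            cophenetic = 0.8, cluster_consensus = c(1, 1, 1),
            cdf_area = consensusCDFArea(C3), delta_area = NA_real_)
  m <- rankMetrics(list(r1, r2))
  expect_equal(m$delta_area[1], 5 / 6, tolerance = 1e-12)
  expect_equal(m$delta_area[2], (m$cdf_area[2] - m$cdf_area[1]) /
                 m$cdf_area[1], tolerance = 1e-12)
})

test_that("rank selection maximises cophenetic with the stated tie-breaks", {
  m <- data.frame(rank = 2:4, cophenetic = c(.99, .99, .80),
                  cdf_area = c(.5, .6, .7), delta_area = c(.5, .6, .1),
                  mean_cluster_consensus = c(1, 1, 1))
  expect_identical(selectRank(m)$rank, 3L)

  # single candidate
  expect_identical(selectRank(m[2, ])$rank, 3L)

  # NA sentinels excluded; all-NA is an error
  m2 <- m; m2$cophenetic <- NA_real_
  expect_error(selectRank(m2), "undefined")
  m3 <- m; m3$cophenetic[2] <- NA_real_
  expect_identical(selectRank(m3)$rank, 2L)
})

test_that("cluster labels recover a small planted structure", {
  set.seed(55)
  cfg <- SimulationConfig(n_genes = 200L, n_samples_tumor = 40L,
                          n_samples_normal = 10L, K = 2L,
                          n_markers_per_subtype = 20L,
                          n_de_per_cluster = 5L, n_cnv_driven = 2L, seed = 9L)
  co <- simulateExpression(cfg)
  res <- consensusCluster(nmfInputMatrix(co$tumor), 2,
                          NMFConfig(n_restarts = 10L), seed = 2)
  truth <- co$truth@subtype_of_sample[names(res@labels)]
  agree <- max(mean(res@labels == truth), mean(res@labels == 3 - truth))
  expect_gte(agree, 0.9)
})
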