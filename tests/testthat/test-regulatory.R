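test_that("peak assignment respects the closed 20 kb midpoint window", {
  ann <- GeneAnnotation("G1", "chr1", "+", 100000L, "other")
  # midpoints: 100000 (at TSS), 120000 (at bound), 120001 (beyond),
  # 90000 (inside), on another chromosome, and far away
  ps <- PeakSet(sprintf("p%d", 1:6),
                c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
                start = c(99750, 119750, 119751, 89750, 99750, 200000),
                end = c(100250, 120250, 120251, 90250, 100250, 200500),
                scores = matrix(1, 6, 3,
                                dimnames = list(NULL, sprintf("s%d", 1:3))))
  links <- assignPeaks(ps, "G1", ann, window = 20000L)
  expect_setequal(links$peak_id, c("p1", "p2", "p4"))
  expect_identical(links$distance[links$peak_id == "p1"], 0L)
  expect_identical(links$distance[links$peak_id == "p2"], 20000L)

  # brute-force interval oracle on random peaks
  set.seed(17)
  mids <- sample(60000:140000, 200)
  ps2 <- PeakSet(sprintf("q%d", 1:200), "chr1", mids - 250, mids + 250,
                 matrix(0, 200, 3, dimnames = list(NULL, sprintf("s%d", 1:3))))
  links2 <- assignPeaks(ps2, "G1", ann, window = 20000L)
  expect_setequal(links2$peak_id,
                  sprintf("q%d", which(abs(mids - 100000) <= 20000)))

  expect_error(assignPeaks(ps, "NOPE", ann), "no TSS")
})

test_that("link correlations align ATAC and expression samples by id", {
  set.seed(19)
  n <- 20
  samp <- sprintf("s%02d", 1:n)
  expr_v <- matrix(rpois(n, 50), 1, n, dimnames = list("G1", samp))
  sc <- matrix(log2(expr_v + 1) + rnorm(n, 0, 0.1), 1, n,
               dimnames = list(NULL, samp))
  ps <- PeakSet("p1", "chr1", 99750, 100250, sc)
  ann <- GeneAnnotation("G1", "chr1", "+", 100000L, "other")
  em <- ExpressionMatrix(expr_v, "tumor")
  links <- linkCorrelations(assignPeaks(ps, "G1", ann), ps, em)
  expect_gt(links$rho, 0.8)

  # shuffling expression columns changes nothing (id alignment)
  em2 <- ExpressionMatrix(expr_v[, sample(n), drop = FALSE], "tumor")
  links2 <- linkCorrelations(assignPeaks(ps, "G1", ann), ps, em2)
  expect_equal(links2$rho, links$rho, tolerance = 1e-12)

  # constant peak scores: undefined, flagged
  ps3 <- PeakSet("p1", "chr1", 99750, 100250,
                 matrix(2, 1, n, dimnames = list(NULL, samp)))
  links3 <- linkCorrelations(assignPeaks(ps3, "G1", ann), ps3, em)
  expect_false(links3$rho_defined)
  expect_true(is.na(links3$rho))

  # too few shared samples is an error naming the deficit
  em4 <- ExpressionMatrix(expr_v[, 1:2, drop = FALSE], "tumor")
  expect_error(linkCorrelations(assignPeaks(ps, "G1", ann), ps, em4),
               ">= 3 samples")
})

test_that("candidate-peak selection matches exhaustive enumeration", {
  set.seed(23)
  for (i in 1:60) {
    nl <- sample(1:50, 1)
    links <- data.frame(
      peak_id = sprintf("p%02d", sample(99, nl)),
      gene_id = "G1",
      distance = sample(0:20000, nl, replace = TRUE),
      mean_score = round(runif(nl, 0, 10), 2),
      rho = ifelse(runif(nl) < 0.15, NA_real_,
                   round(runif(nl, -1, 1), 3)),
      rho_defined = TRUE)
    links$rho_defined <- !is.na(links$rho)
    sel <- selectCandidatePeaks(links)
    o <- oracleSelect(links)
    expect_identical(sel$peak_id, links$peak_id[o$idx])
    expect_identical(sel$slot, o$slot)
    expect_lte(nrow(sel), 3L)
    expect_true(all(sel$peak_id %in% links$peak_id))
  }
})

test_that("selection tie-breaks and degenerate cases follow the rules", {
  base <- data.frame(gene_id = "G1", rho = c(NA, NA), rho_defined = FALSE,
                     distance = c(100L, 100L), mean_score = c(5, 7),
                     peak_id = c("pA", "pB"))
  # all rho undefined: only the closest slot, score 7 wins the tie
  sel <- selectCandidatePeaks(base)
  expect_identical(sel$slot, "closest")
  expect_identical(sel$peak_id, "pB")

  # a single link fills all slots, deduplicated to one row
  one <- data.frame(gene_id = "G1", rho = 0.5, rho_defined = TRUE,
                    distance = 10L, mean_score = 1, peak_id = "pX")
  sel1 <- selectCandidatePeaks(one)
  expect_identical(nrow(sel1), 1L)
  expect_identical(sel1$peak_id, "pX")
})

test_that("the single-sample t-test statuses follow the stated form", {
  set.seed(29)
  normals <- rnorm(20, 5, 1)
  m <- mean(normals); s <- sd(normals)

  r0 <- singleSampleTest(m, normals)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  expect_identical(r0$status, "unchanged")

  rh <- singleSampleTest(10, normals)
  expect_identical(rh$status, "high")
  expect_lt(rh$p, 0.001)
  # t-distribution oracle
  tstat <- (m - 10) / (s / sqrt(20))
  expect_equal(rh$p, 2 * pt(-abs(tstat), 19), tolerance = 1e-12)

  # symmetric low case has the same p as its mirror image
  rl <- singleSampleTest(2 * m - 10, normals)
  expect_identical(rl$status, "low")
  expect_equal(rl$p, rh$p, tolerance = 1e-12)

  expect_error(singleSampleTest(1, rep(3, 10)), "zero variance")
  expect_error(singleSampleTest(1, c(1, 2)), ">= 3")
})

test_that("peak openness is judged against the sample's peak background", {
  samp <- sprintf("s%d", 1:4)
  # sample s1 scores across peaks: 10, 1, 2, 3 -> only p1 clears the
  # within-sample 0.75 quantile
  sc <- matrix(c(10, 5, 5, 5,
                 1, 2, 3, 9,
                 2, 2, 3, 4,
                 3, 2, 3, 4), 4, 4, byrow = TRUE,
               dimnames = list(NULL, samp))
  ps <- PeakSet(sprintf("p%d", 1:4), "chr1", (0:3) * 1000, (0:3) * 1000 + 500,
                sc)
  # p2 holds the maximal score in sample s4
  expect_identical(peakScoreStatus("p2", "s4", ps), "high")
  expect_identical(peakScoreStatus("p1", "s1", ps), "high")
  expect_identical(peakScoreStatus("p2", "s1", ps), "low")

  # all-equal scores in a sample: bound attained, high
  ps2 <- PeakSet(sprintf("p%d", 1:4), "chr1", (0:3) * 1000,
                 (0:3) * 1000 + 500,
                 matrix(2, 4, 4, dimnames = list(NULL, samp)))
  expect_identical(peakScoreStatus("p3", "s1", ps2), "high")

  # quantile boundary against the sort-based oracle
  set.seed(41)
  for (i in 1:50) {
    v <- rnorm(sample(5:40, 1))
    np <- length(v)
    psr <- PeakSet(sprintf("p%d", 1:np), "chr1", (0:(np - 1)) * 1000,
                   (0:(np - 1)) * 1000 + 500,
                   matrix(v, np, 1, dimnames = list(NULL, "s1")))
    thr <- oracleQuantile(v, 0.75)
    for (j in c(1, np)) {
      expect_identical(peakScoreStatus(sprintf("p%d", j), "s1", psr),
                       if (v[j] >= thr) "high" else "low")
    }
  }
})

test_that("regulation calls implement the decision rules", {
  pos <- callRegulation("high", "high", "high", "s1", "TF", "G", "p")
  expect_identical(pos$direction, "positive")
  neg <- callRegulation("low", "high", "high", "s1", "RP", "G", "p")
  expect_identical(neg$direction, "negative")
  expect_null(callRegulation("high", "high", "low"))
  expect_null(callRegulation("unchanged", "high", "high"))
})

test_that("the full regulatory loop recovers a planted edge", {
  cfg <- SimulationConfig(n_genes = 300L, n_samples_tumor = 60L,
                          n_samples_normal = 30L,
                          n_markers_per_subtype = 10L,
                          n_de_per_cluster = 5L, n_cnv_driven = 2L,
                          n_decoy_peaks = 20L, seed = 77L)
  co <- generateCohort(cfg)
  tr <- co$truth
  tf <- tr@tf_edges$tf_gene[1]; tgt <- tr@tf_edges$target_gene[1]
  res <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks, co$annotation,
                               co$pwms, tgt, sequences = co$sequences)
  cc <- res$calls
  # rule invariant on every output row
  expect_true(all(cc$peak_status == "high"))
  pos <- cc[cc$regulator_gene == tf & cc$target_gene == tgt &
              cc$direction == "positive", ]
  pred <- unique(pos$sample_id)
  reg <- tr@regulated_samples[[1]]
  expect_gte(mean(pred %in% reg), 0.8)
  expect_gte(mean(reg %in% pred), 0.7)

  # determinism
  res2 <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks, co$annotation,
                                co$pwms, tgt, sequences = co$sequences)
  expect_identical(res$calls, res2$calls)

  # empty PWM list: no calls, candidate report still produced
  res3 <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks, co$annotation,
                                list(), tgt, sequences = co$sequences)
  expect_identical(nrow(res3$calls), 0L)
  expect_gte(nrow(res3$candidates), 1L)

  # unknown target skipped with report
  res4 <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks, co$annotation,
                                co$pwms, c(tgt, "ghost"),
                                sequences = co$sequences)
  expect_identical(res4$skipped, "ghost")

  # candidate peaks are a subset of the assignment, at most 3
  links <- assignPeaks(co$peaks, tgt, co$annotation)
  got <- res$candidates$peak_id[res$candidates$gene_id == tgt]
  expect_true(all(got %in% links$peak_id))
  expect_lte(length(got), 3L)
})

test_that("a target with no peaks in its window is reported, not an error", {
  cfg <- SimulationConfig(n_genes = 100L, n_samples_tumor = 20L,
                          n_samples_normal = 10L, n_markers_per_subtype = 5L,
                          n_de_per_cluster = 3L, n_cnv_driven = 1L,
                          n_decoy_peaks = 4L, seed = 3L)
  co <- generateCohort(cfg)
  # pick a gene guaranteed to have no peak within 20 kb
  mids <- peakMidpoints(co$peaks)
  tsses <- tssPosition(co$annotation)
  chr_pk <- as.character(GenomicRanges::seqnames(peakRanges(co$peaks)))
  free <- names(tsses)[vapply(seq_along(tsses), function(i) {
    ann_chr <- as.character(GenomicRanges::seqnames(
      co$annotation@tss))[i]
    !any(chr_pk == ann_chr & abs(mids - tsses[i]) <= 20000)
  }, logical(1L))]
  res <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks, co$annotation,
                               co$pwms, free[1L], sequences = co$sequences)
  expect_identical(res$candidates$slot, "no candidate peaks")
  expect_identical(nrow(res$calls), 0L)
})
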