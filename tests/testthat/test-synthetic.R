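smallCfg <- function(seed = 1L, ...) {
  SimulationConfig(n_genes = 120L, n_samples_tumor = 30L,
                   n_samples_normal = 20L, K = 2L,
                   n_markers_per_subtype = 8L, n_de_per_cluster = 6L,
                   n_cnv_driven = 3L, n_decoy_peaks = 10L, seed = seed, ...)
}

test_that("the generator is deterministic in the master seed", {
  a <- generateCohort(smallCfg(5L))
  b <- generateCohort(smallCfg(5L))
  expect_identical(exprValues(a$tumor), exprValues(b$tumor))
  expect_identical(cnvValues(a$cnv), cnvValues(b$cnv))
  expect_identical(peakScores(a$peaks), peakScores(b$peaks))
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth@subtype_of_sample, b$truth@subtype_of_sample)

  c <- generateCohort(smallCfg(6L))
  expect_false(identical(exprValues(a$tumor), exprValues(c$tumor)))
})

test_that("a written cohort is byte-identical across runs of the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(generateCohort(smallCfg(3L)), d1)
  writeCohort(generateCohort(smallCfg(3L)), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every truth id resolves against the generated matrices", {
  co <- generateCohort(smallCfg(11L))
  tr <- co$truth
  genes <- geneIds(co$tumor)
  expect_true(all(names(tr@subtype_of_sample) %in% sampleIds(co$tumor)))
  expect_true(all(unlist(lapply(tr@de_genes, names)) %in% genes))
  expect_true(all(names(tr@cnv_driven_genes) %in% genes))
  expect_true(all(tr@tf_edges$tf_gene %in% genes))
  expect_true(all(tr@tf_edges$target_gene %in% genes))
  expect_true(all(tr@tf_edges$peak_id %in% peakIds(co$peaks)))
  expect_true(all(unlist(tr@regulated_samples) %in% sampleIds(co$tumor)))
  expect_true(all(tr@tf_edges$target_gene %in% geneIds(co$annotation)))
  # survival covers the tumor cohort
  expect_setequal(co$survival$sample_id, sampleIds(co$tumor))
  # all invariants hold (validity checked on construction)
  expect_true(validObject(co$tumor))
  expect_true(validObject(co$peaks))
  expect_true(validObject(co$annotation))
})

test_that("a planted up-gene shows the expected tumor/normal fold change", {
  # true lfc 2 under NB sampling: mean count ratio close to 4
  cfg <- SimulationConfig(n_genes = 100L, n_samples_tumor = 60L,
                          n_samples_normal = 60L, K = 2L,
                          n_markers_per_subtype = 0L, subtype_effect = 0,
                          n_de_per_cluster = 10L, n_cnv_driven = 0L,
                          seed = 19L)
  ex <- simulateExpression(cfg)
  de1 <- ex$truth@de_genes[[1]]
  ups <- setdiff(names(de1)[de1 == "up"], ex$truth@tf_edges$target_gene)
  cl1 <- names(ex$truth@subtype_of_sample)[ex$truth@subtype_of_sample == 1]
  ratio <- rowMeans(exprValues(ex$tumor)[ups, cl1]) /
    rowMeans(exprValues(ex$normal)[ups, ])
  expect_gte(mean(ratio), 3.4)
  expect_lte(mean(ratio), 4.7)
})

test_that("a null configuration plants no detectable subtype structure", {
  cfg <- SimulationConfig(n_genes = 150L, n_samples_tumor = 36L,
                          n_samples_normal = 12L, K = 4L,
                          subtype_effect = 0, n_markers_per_subtype = 10L,
                          n_de_per_cluster = 0L, n_cnv_driven = 0L,
                          seed = 23L)
  ex <- simulateExpression(cfg)
  res <- consensusCluster(nmfInputMatrix(ex$tumor), 4,
                          NMFConfig(n_restarts = 8L), seed = 1)
  truth <- ex$truth@subtype_of_sample[names(res@labels)]
  # agreement with the arbitrary 'planted' labels should be at chance level
  tab <- table(res@labels, truth)
  n <- sum(tab)
  agree <- sum(apply(tab, 1, max)) / n
  expect_lt(agree, 0.6)
})

test_that("CNV coupling drives expression only for the driven genes", {
  cfg <- smallCfg(31L)
  ex <- simulateExpression(cfg)
  cv <- simulateCNV(cfg, ex$tumor, ex$truth)
  driven <- names(ex$truth@cnv_driven_genes)[1]
  other <- setdiff(geneIds(cv$tumor),
                   c(names(ex$truth@cnv_driven_genes),
                     unlist(lapply(ex$truth@de_genes, names)),
                     unlist(ex$truth@marker_genes),
                     ex$truth@tf_edges$tf_gene))[1:20]
  rd <- spearmanRho(cnvValues(cv$cnv)[driven, ],
                    exprValues(cv$tumor)[driven, ])
  expect_gt(rd$rho, 0.4)
  ro <- vapply(other, function(g)
    spearmanRho(cnvValues(cv$cnv)[g, ], exprValues(cv$tumor)[g, ])$rho,
    numeric(1L))
  expect_lt(stats::median(abs(ro), na.rm = TRUE), 0.3)
  # undriven genes keep the original draw
  expect_identical(exprValues(cv$tumor)[other[1], ],
                   exprValues(ex$tumor)[other[1], ])
})

test_that("causal peaks out-correlate decoys with their target", {
  set.seed(1)
  wins <- 0; n_rep <- 20
  for (s in 1:n_rep) {
    co <- generateCohort(smallCfg(100L + s))
    tgt <- co$truth@tf_edges$target_gene[1]
    causal <- co$truth@tf_edges$peak_id[1]
    links <- linkCorrelations(
      assignPeaks(co$peaks, tgt, co$annotation), co$peaks, co$tumor)
    if (!causal %in% links$peak_id) next
    best <- links$peak_id[which.max(links$rho)]
    if (identical(best, causal)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("censoring control works at the extremes", {
  cfg0 <- smallCfg(41L, censoring_rate = 0)
  ex <- simulateExpression(cfg0)
  sv <- simulateSurvival(cfg0, ex$tumor, geneIds(ex$tumor)[1])
  expect_true(all(sv$event == 1L))
  expect_true(all(sv$time >= 0))

  cfg5 <- smallCfg(41L, censoring_rate = 0.5)
  sv5 <- simulateSurvival(cfg5, ex$tumor, geneIds(ex$tumor)[1])
  expect_gt(mean(sv5$event == 0L), 0.2)
  expect_lt(mean(sv5$event == 0L), 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(SimulationConfig(K = 1L), "K must be >= 2")
  expect_error(SimulationConfig(K = 10L, n_samples_tumor = 5L),
               "must not exceed")
  expect_error(SimulationConfig(frac_regulated_samples = 0),
               "frac_regulated_samples")
  expect_error(SimulationConfig(n_genes = 10L), "exceed n_genes")
})
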