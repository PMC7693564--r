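test_that("size factors and dispersion behave on known inputs", {
  cnt <- makeCounts(G = 200, n = 20, seed = 3, mu = 50, phi = 0.4)
  grp <- rep(c("A", "B"), each = 10)
  sf <- sizeFactors(cnt)
  expect_identical(length(sf), 20L)
  expect_true(all(sf > 0))
  # doubling one sample's counts doubles its size factor relative to the rest
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 2L
  sf2 <- sizeFactors(cnt2)
  expect_equal(unname(sf2[1] / sf2[2]), unname(2 * sf[1] / sf[2]),
               tolerance = 1e-9)

  disp <- estimateDispersion(cnt, grp)
  expect_true(stats::median(disp$dispersion) > 0.2 &&
              stats::median(disp$dispersion) < 0.6)

  # all-zero gene flagged, not crashed
  cnt3 <- rbind(cnt, zero = 0L)
  disp3 <- estimateDispersion(cnt3, grp)
  expect_identical(disp3$flagged, "zero")
  expect_true(is.na(disp3$dispersion["zero"]))
})

test_that("Poisson counts give near-zero estimated dispersion", {
  set.seed(8)
  cnt <- matrix(rpois(500 * 50, 60), 500, 50,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:50)))
  disp <- estimateDispersion(cnt, rep(c("A", "B"), each = 25))
  expect_lte(stats::median(disp$dispersion), 0.05)
})

test_that("the exact test reduces to the binomial test as dispersion -> 0", {
  # one gene with group totals 7 and 12, equal library sizes
  cnt <- matrix(c(3L, 4L, 5L, 7L), 1, 4,
                dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  sf <- setNames(rep(1, 4), colnames(cnt))
  res <- nbExactTest(cnt, 1:2, 3:4, dispersion = c(g1 = 1e-10), sf = sf)
  expect_equal(res$pvalue,
               binom.test(7, 19, p = 0.5)$p.value, tolerance = 1e-6)
})

test_that("a symmetric gene under identical groups has p = 1", {
  cnt <- matrix(c(5L, 10L, 10L, 5L), 1, 4,
                dimnames = list("g1", sprintf("s%d", 1:4)))
  sf <- setNames(rep(1, 4), colnames(cnt))
  res <- nbExactTest(cnt, 1:2, 3:4, dispersion = c(g1 = 0.2), sf = sf)
  expect_equal(res$pvalue, 1, tolerance = 1e-9)
  resw <- nbWaldShrunkTest(cnt, 1:2, 3:4, shrunk_dispersion = c(g1 = 0.2),
                           sf = sf)
  expect_equal(resw$log2fc, 0, tolerance = 1e-12)
  expect_equal(resw$pvalue, 1, tolerance = 1e-9)
})

test_that("both tests control type-I error near the nominal level", {
  set.seed(42)
  G <- 600; nA <- 20; nB <- 20
  mu0 <- exp(rnorm(G, log(50), 1))
  cnt <- cbind(matrix(rnbinom(G * nA, mu = mu0, size = 1 / 0.3), G, nA),
               matrix(rnbinom(G * nB, mu = mu0, size = 1 / 0.3), G, nB))
  dimnames(cnt) <- list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:(nA + nB)))
  disp <- estimateDispersion(cnt, rep(c("A", "B"), c(nA, nB)))
  ex <- nbExactTest(cnt, 1:nA, nA + (1:nB), disp$dispersion)
  wd <- nbWaldShrunkTest(cnt, 1:nA, nA + (1:nB), disp$shrunk)
  expect_gt(mean(ex$pvalue < 0.05), 0.02)
  expect_lt(mean(ex$pvalue < 0.05), 0.09)
  expect_gt(mean(wd$pvalue < 0.05), 0.02)
  expect_lt(mean(wd$pvalue < 0.05), 0.09)
})

test_that("planted fold changes are detected with small p-values", {
  set.seed(43)
  G <- 300; n <- 40
  mu0 <- exp(rnorm(G, log(50), 1))
  de <- 1:30
  muA <- mu0; muA[de] <- muA[de] * 4
  cnt <- cbind(matrix(rnbinom(G * n, mu = muA, size = 1 / 0.3), G, n),
               matrix(rnbinom(G * n, mu = mu0, size = 1 / 0.3), G, n))
  dimnames(cnt) <- list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:(2 * n)))
  disp <- estimateDispersion(cnt, rep(c("A", "B"), each = n))
  wd <- nbWaldShrunkTest(cnt, 1:n, n + (1:n), disp$shrunk)
  expect_lt(stats::median(wd$pvalue[de]), 1e-4)
  expect_gt(stats::median(wd$log2fc[de]), 1.5)
})

test_that("direction agreement with edgeR's exact test on a planted matrix", {
  skip_if_not_installed("edgeR")
  set.seed(77)
  G <- 200; n <- 15
  mu0 <- exp(rnorm(G, log(60), 0.8))
  muA <- mu0; muA[1:20] <- muA[1:20] * 4; muA[21:40] <- muA[21:40] / 4
  cnt <- cbind(matrix(rnbinom(G * n, mu = muA, size = 1 / 0.3), G, n),
               matrix(rnbinom(G * n, mu = mu0, size = 1 / 0.3), G, n))
  dimnames(cnt) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(2 * n)))
  grp <- rep(c("A", "B"), each = n)
  disp <- estimateDispersion(cnt, grp)
  ours <- nbExactTest(cnt, 1:n, n + (1:n), disp$dispersion)
  y <- edgeR::DGEList(counts = cnt, group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("B", "A"))
  expect_gt(cor(rank(ours$pvalue), rank(et$table$PValue)), 0.8)
  top <- which(ours$qvalue < 0.01)
  expect_gt(mean(sign(ours$log2fc[top]) == sign(et$table$logFC[top])), 0.95)
})

test_that("BH adjustment matches the hand computation and is monotone", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5), tolerance = 1e-12)
  set.seed(2)
  p <- runif(50)
  q <- bhAdjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bhAdjust(c(0.1, NaN)), "NaN")
})

test_that("consensus takes both-significant, sign-agreeing genes only", {
  mk <- function(q, lfc) data.frame(gene = sprintf("g%d", seq_along(q)),
                                    log2fc = lfc, pvalue = q, qvalue = q,
                                    method = "x")
  resA <- mk(c(0.001, 0.2, 0.001, 0.001), c(2, 2, 2, 1.5))
  resB <- mk(c(0.001, 0.001, 0.01, 0.001), c(2, 2, -2, -1.5))
  s <- consensusDE(resA, resB, alpha = 0.05, lfc_cutoff = 1)
  # g1: both significant, same sign -> kept; g2: A not significant;
  # g3: sign conflict; g4: sign conflict
  expect_identical(names(s$genes), "g1")
  expect_identical(unname(s$genes), "up")

  # consensus is always a subset of each single-method set, on random pairs
  set.seed(10)
  for (i in 1:50) {
    qA <- runif(30); qB <- runif(30)
    lA <- rnorm(30, 0, 2); lB <- rnorm(30, 0, 2)
    rA <- mk(qA, lA); rB <- mk(qB, lB)
    s <- consensusDE(rA, rB, alpha = 0.2, lfc_cutoff = 0.5)
    inA <- rA$gene[qA < 0.2 & abs(lA) >= 0.5]
    inB <- rB$gene[qB < 0.2 & abs(lB) >= 0.5]
    both <- intersect(inA, inB)
    same_sign <- rA$gene[sign(lA) == sign(lB)]
    expect_setequal(names(s$genes), intersect(both, same_sign))
  }
  expect_error(consensusDE(resA, resB[c(2, 1, 3, 4), ], 0.05, 1),
               "different gene universes")
})

test_that("NK ligand categorisation crosses role with direction", {
  ann <- GeneAnnotation(
    id = c("ACT1", "ACT2", "INH1", "INH2", "OTH1"),
    chrom = "chr1", strand = "+", tss = c(1e6, 2e6, 3e6, 4e6, 5e6),
    immune_role = c("nk_activator_ligand", "nk_activator_ligand",
                    "nk_inhibitor_ligand", "nk_inhibitor_ligand", "other"))
  sets <- list(structure(list(
    cluster = 1L,
    genes = c(ACT1 = "down", ACT2 = "up", INH1 = "up", OTH1 = "up"),
    alpha = 0.05, lfc_cutoff = 1), class = "DEGeneSet"))
  tab <- classifyNKLigands(sets, ann)
  expect_identical(tab$low_activators[[1]], "ACT1")
  expect_identical(tab$high_activators[[1]], "ACT2")
  expect_identical(tab$high_inhibitors[[1]], "INH1")
  # no inhibitor called down: rendered "-"
  fmt <- formatNKLigandTable(tab)
  expect_identical(fmt$low_inhibitors, "-")
  # 'other' role appears nowhere
  expect_false("OTH1" %in% unlist(tab[, -1]))

  # pure function: permuting the gene order changes nothing
  sets2 <- list(structure(list(
    cluster = 1L, genes = sets[[1]]$genes[c(3, 1, 4, 2)],
    alpha = 0.05, lfc_cutoff = 1), class = "DEGeneSet"))
  expect_identical(formatNKLigandTable(classifyNKLigands(sets2, ann)), fmt)
})
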