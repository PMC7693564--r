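#' @include AllClasses.R
NULL

# Child seeds for the sub-simulations are derived from the master seed by
# fixed offsets so each component is reproducible in isolation.
.childSeed <- function(seed, offset) as.integer((seed %% 1000000000L) + offset)
.SEED_EXPR <- 101L
.SEED_CNV  <- 211L
.SEED_PEAK <- 307L
.SEED_SURV <- 401L

.geneIds   <- function(n) sprintf("g%04d", seq_len(n))
.tumorIds  <- function(n) sprintf("T%03d", seq_len(n))
.normalIds <- function(n) sprintf("N%03d", seq_len(n))

#' Simulate tumor and normal expression with planted structure
#'
#' Draws negative-binomial counts for a tumor cohort with `K` planted
#' subtypes and a normal cohort sharing the same gene baselines. Gene
#' baseline log2 means are Gaussian (mean 5, sd 1.5, clipped to
#' `[2, 12]`); each subtype's marker genes are shifted by
#' `subtype_effect` log2 units in that subtype's tumor samples; each
#' cluster's planted DE genes are shifted by `+/- de_lfc_true` vs normal
#' (half up, half down); designated shared target genes (one per TF edge)
#' are shifted up in every cluster; TF coding genes are shifted up by
#' `tf_shift` in the samples where their edge is active. Dispersion is
#' shared (`nb_dispersion`).
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with elements `tumor` and `normal`
#'   ([ExpressionMatrix-class], counts) and `truth` (a partial
#'   [SyntheticTruth-class]: expression-side plantings; peak ids are filled
#'   in by [simulatePeaks()]).
#' @export
simulateExpression <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(.childSeed(cfg@seed, .SEED_EXPR))
  G <- cfg@n_genes; Tn <- cfg@n_samples_tumor; Nn <- cfg@n_samples_normal
  K <- cfg@K
  genes <- .geneIds(G); tums <- .tumorIds(Tn); nors <- .normalIds(Nn)

  mu2 <- pmin(pmax(stats::rnorm(G, 5, 1.5), 2), 12)
  names(mu2) <- genes
  subtype <- rep(seq_len(K), length.out = Tn)
  names(subtype) <- tums

  # disjoint planted gene sets
  n_mark <- K * cfg@n_markers_per_subtype
  n_de <- K * cfg@n_de_per_cluster
  n_special <- cfg@n_tf_edges * 2L + cfg@n_cnv_driven
  pick <- sample(G, n_mark + n_de + n_special)
  marker_idx <- if (n_mark) split(pick[seq_len(n_mark)],
                                  rep(seq_len(K), each = cfg@n_markers_per_subtype))
                else rep(list(integer()), K)
  off <- n_mark
  de_idx <- if (n_de) split(pick[off + seq_len(n_de)],
                            rep(seq_len(K), each = cfg@n_de_per_cluster))
            else rep(list(integer()), K)
  off <- off + n_de
  target_idx <- pick[off + seq_len(cfg@n_tf_edges)]
  off <- off + cfg@n_tf_edges
  tf_idx <- pick[off + seq_len(cfg@n_tf_edges)]
  off <- off + cfg@n_tf_edges
  cnv_idx <- pick[off + seq_len(cfg@n_cnv_driven)]

  # per-cluster DE directions: half up, half down
  de_genes <- lapply(seq_len(K), function(k) {
    idx <- de_idx[[k]]
    dirs <- rep(c("up", "down"), length.out = length(idx))
    shared <- rep("up", length(target_idx))
    # the first CNV-driven gene is also up in every cluster (a ligand whose
    # expression is CNV-explained), mirroring a CNV-driven NK inhibitor
    cnv_de <- if (cfg@n_cnv_driven > 0L) "up" else character()
    stats::setNames(c(dirs, shared, cnv_de),
                    c(genes[idx], genes[target_idx],
                      if (cfg@n_cnv_driven > 0L) genes[cnv_idx[1L]]))
  })
  names(de_genes) <- paste0("cluster", seq_len(K))

  # regulated samples per edge
  n_reg <- ceiling(cfg@frac_regulated_samples * Tn)
  regulated <- lapply(seq_len(cfg@n_tf_edges), function(e)
    sort(sample(tums, n_reg)))

  # tumor latent log2 means
  L <- matrix(mu2, G, Tn, dimnames = list(genes, tums))
  for (k in seq_len(K)) {
    sk <- subtype == k
    if (length(marker_idx[[k]]))
      L[marker_idx[[k]], sk] <- L[marker_idx[[k]], sk] + cfg@subtype_effect
    dd <- de_genes[[k]]
    if (length(dd))
      L[names(dd), sk] <- L[names(dd), sk] +
        ifelse(dd == "up", cfg@de_lfc_true, -cfg@de_lfc_true)
  }
  for (e in seq_len(cfg@n_tf_edges))
    L[genes[tf_idx[e]], regulated[[e]]] <-
      L[genes[tf_idx[e]], regulated[[e]]] + cfg@tf_shift

  size <- 1 / cfg@nb_dispersion
  tum_cnt <- matrix(stats::rnbinom(G * Tn, mu = 2^L, size = size), G, Tn,
                    dimnames = list(genes, tums))
  nor_cnt <- matrix(stats::rnbinom(G * Nn, mu = 2^mu2, size = size), G, Nn,
                    dimnames = list(genes, nors))

  tumor <- ExpressionMatrix(tum_cnt, "tumor", "counts")
  metadata(tumor)$log2_baseline <- mu2
  metadata(tumor)$latent_log2_mean <- L
  normal <- ExpressionMatrix(nor_cnt, "normal", "counts")

  edges <- data.frame(
    tf_gene = genes[tf_idx], peak_id = rep(NA_character_, cfg@n_tf_edges),
    target_gene = genes[target_idx],
    direction = rep("positive", cfg@n_tf_edges),
    stringsAsFactors = FALSE)

  truth <- new("SyntheticTruth",
    subtype_of_sample = subtype,
    marker_genes = stats::setNames(lapply(marker_idx, function(i) genes[i]),
                                   names(de_genes)),
    de_genes = de_genes,
    cnv_driven_genes = stats::setNames(rep(cfg@cnv_beta, cfg@n_cnv_driven),
                                       genes[cnv_idx]),
    tf_edges = edges, regulated_samples = regulated,
    survival_gene = if (cfg@n_tf_edges) genes[target_idx[1L]] else genes[1L],
    survival_effect = cfg@survival_effect)
  list(tumor = tumor, normal = normal, truth = truth)
}

#' Simulate copy number coupled to expression
#'
#' Draws discrete copy-number states in 0..4 (centred on the diploid state
#' 2) for every gene and tumor sample. For the planted CNV-driven genes the
#' tumor counts are re-drawn with the latent log2 mean shifted by
#' `beta * (CNV - 2)`, so the planted CNV/expression association acts at
#' the count-model level and is monotone by construction; all other genes'
#' copy numbers are independent of expression. A gene whose copy number
#' happens to be constant across the cohort is reported in the
#' `constant_cnv` element rather than being an error.
#'
#' @param cfg a [SimulationConfig-class].
#' @param tumor tumor [ExpressionMatrix-class] from [simulateExpression()].
#' @param truth the accompanying [SyntheticTruth-class].
#' @return list with `cnv` ([CNVMatrix-class]), `tumor` (expression with
#'   CNV-driven genes re-drawn), and `constant_cnv` (character vector of
#'   flagged genes).
#' @export
simulateCNV <- function(cfg, tumor, truth) {
  set.seed(.childSeed(cfg@seed, .SEED_CNV))
  genes <- geneIds(tumor); tums <- sampleIds(tumor)
  G <- length(genes); Tn <- length(tums)
  states <- 0:4
  probs <- c(0.05, 0.2, 0.5, 0.2, 0.05)
  cnv <- matrix(sample(states, G * Tn, replace = TRUE, prob = probs), G, Tn,
                dimnames = list(genes, tums))
  cnt <- exprValues(tumor)
  L <- metadata(tumor)$latent_log2_mean
  if (is.null(L)) L <- matrix(log2(rowMeans(cnt) + 1), G, Tn,
                              dimnames = list(genes, tums))
  driven <- names(truth@cnv_driven_genes)
  driven <- driven[truth@cnv_driven_genes != 0]
  for (g in driven) {
    mu <- 2^(L[g, ] + truth@cnv_driven_genes[g] * (cnv[g, ] - 2))
    cnt[g, ] <- stats::rnbinom(Tn, mu = mu, size = 1 / cfg@nb_dispersion)
  }
  tumor2 <- ExpressionMatrix(cnt, "tumor", exprUnit(tumor))
  metadata(tumor2) <- metadata(tumor)
  constant <- genes[apply(cnv, 1L, function(z) length(unique(z)) == 1L)]
  list(cnv = CNVMatrix(cnv), tumor = tumor2, constant_cnv = constant)
}

# common open-chromatin baseline score around which all peaks fluctuate
.PEAK_BASELINE <- 5

.randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

.sharpPWM <- function(len = 10L, p = 0.97) {
  cons <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m <- matrix((1 - p) / 3, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(len)) m[cons[j], j] <- p
  list(matrix = m, consensus = paste(cons, collapse = ""))
}

#' Simulate ATAC peaks, sequences, and motifs
#'
#' For every planted TF edge one causal peak is placed within 15 kb of the
#' target gene's TSS (safely inside the 20 kb assignment window). Its score
#' in a regulated sample is `peak_alpha * log2(TF count + 1)` plus Gaussian
#' noise; elsewhere it fluctuates around the unregulated baseline. Decoy
#' peaks - half inside target windows, half 25-100 kb away - carry noise
#' independent of any expression. Each TF gets a sharp 10-bp
#' position-weight matrix whose consensus is embedded in the causal peak's
#' sequence; decoy sequences are uniform random.
#'
#' @param cfg a [SimulationConfig-class].
#' @param tumor tumor [ExpressionMatrix-class] (counts; the ATAC cohort is
#'   the full tumor cohort).
#' @param annotation a [GeneAnnotation-class] covering the target genes.
#' @param truth the [SyntheticTruth-class]; its `tf_edges$peak_id` is
#'   filled in.
#' @return list with `peaks` ([PeakSet-class]), `sequences`
#'   ([Biostrings::DNAStringSet] keyed by peak id), `pwms` (list of
#'   [PWMotif-class]) and the updated `truth`.
#' @export
simulatePeaks <- function(cfg, tumor, annotation, truth) {
  set.seed(.childSeed(cfg@seed, .SEED_PEAK))
  edges <- truth@tf_edges
  missing <- setdiff(edges$target_gene, geneIds(annotation))
  if (length(missing))
    stop("target genes absent from annotation: ",
         paste(missing, collapse = ", "))
  tss <- tssPosition(annotation)
  chrom <- stats::setNames(as.character(seqnames(annotation@tss)),
                           geneIds(annotation))
  tums <- sampleIds(tumor)
  width <- 500L
  n_peaks <- nrow(edges) + cfg@n_decoy_peaks
  ids <- sprintf("pk%04d", seq_len(n_peaks))

  pk_chrom <- character(n_peaks); pk_start <- integer(n_peaks)
  scores <- matrix(0, n_peaks, length(tums), dimnames = list(ids, tums))
  seqs <- character(n_peaks)
  log2expr <- log2(exprValues(tumor) + 1)

  for (e in seq_len(nrow(edges))) {
    tgt <- edges$target_gene[e]
    mid <- tss[tgt] + sample(-15000:15000, 1L)
    pk_chrom[e] <- chrom[tgt]
    pk_start[e] <- max(0L, as.integer(mid - width %/% 2L))
    reg <- tums %in% truth@regulated_samples[[e]]
    tf_l2 <- log2expr[edges$tf_gene[e], ]
    # accessibility anchored at the common open-chromatin baseline; in
    # regulated samples the peak tracks the TF's activity deviation
    tf_base <- if (any(!reg)) stats::median(tf_l2[!reg]) else
      stats::median(tf_l2) - cfg@tf_shift
    mu <- .PEAK_BASELINE + ifelse(reg, cfg@peak_alpha * (tf_l2 - tf_base), 0)
    scores[e, ] <- mu + stats::rnorm(length(tums), 0, cfg@peak_noise_sd)
    edges$peak_id[e] <- ids[e]
  }

  pwms <- list()
  for (e in seq_len(nrow(edges))) {
    pw <- .sharpPWM()
    tf <- edges$tf_gene[e]
    pwms[[tf]] <- PWMotif(tf, tf, pw$matrix)
    bg <- .randomSeq(width)
    at <- width %/% 2L
    seqs[e] <- paste0(substr(bg, 1L, at), pw$consensus,
                      substr(bg, at + nchar(pw$consensus) + 1L, width))
  }

  anchors <- sample(geneIds(annotation), cfg@n_decoy_peaks, replace = TRUE)
  for (d in seq_len(cfg@n_decoy_peaks)) {
    i <- nrow(edges) + d
    g <- anchors[d]
    offd <- if (d %% 2L == 0L) sample(-18000:18000, 1L)
            else sample(c(-1L, 1L), 1L) * sample(25000:100000, 1L)
    pk_chrom[i] <- chrom[g]
    pk_start[i] <- max(0L, as.integer(tss[g] + offd - width %/% 2L))
    scores[i, ] <- stats::rnorm(length(tums), .PEAK_BASELINE,
                                max(cfg@peak_noise_sd, 1))
    seqs[i] <- .randomSeq(width)
  }

  peaks <- PeakSet(ids, pk_chrom, pk_start, pk_start + width, scores)
  sq <- Biostrings::DNAStringSet(seqs)
  names(sq) <- ids
  truth@tf_edges <- edges
  list(peaks = peaks, sequences = sq, pwms = pwms, truth = truth)
}

#' Simulate survival stratified by one gene's expression
#'
#' Event times are exponential; the hazard of a sample in tertile group
#' `g` (of the chosen gene's log2 expression) is
#' `lambda0 * survival_effect^(g-1)` with baseline `lambda0 = 1/1000`
#' per day. Censoring times are independent exponentials with rate
#' calibrated so that the expected censored fraction equals
#' `censoring_rate` (exact for exponential pairs at the mean hazard);
#' `censoring_rate = 0` observes every event.
#'
#' @param cfg a [SimulationConfig-class].
#' @param tumor tumor [ExpressionMatrix-class].
#' @param gene gene id whose expression tertiles carry the planted hazard.
#' @return a survival `data.frame` (`sample_id`, `time`, `event`).
#' @export
simulateSurvival <- function(cfg, tumor, gene) {
  if (!gene %in% geneIds(tumor)) stop("gene not in tumor matrix: ", gene)
  set.seed(.childSeed(cfg@seed, .SEED_SURV))
  x <- log2(exprValues(tumor)[gene, ] + 1)
  grp <- tertileGroups(x)
  lambda0 <- 1 / 1000
  haz <- lambda0 * cfg@survival_effect^(as.integer(grp) - 1)
  evt <- stats::rexp(length(haz), rate = haz)
  if (cfg@censoring_rate > 0) {
    lc <- mean(haz) * cfg@censoring_rate / (1 - cfg@censoring_rate)
    cen <- stats::rexp(length(haz), rate = lc)
  } else cen <- rep(Inf, length(haz))
  data.frame(sample_id = sampleIds(tumor),
             time = pmin(evt, cen),
             event = as.integer(evt <= cen))
}

# gene annotation for the synthetic genome: genes spaced 200 kb apart on
# four chromosomes so that 20 kb TSS windows never overlap
.makeAnnotation <- function(genes, truth, n_cnv_driven) {
  G <- length(genes)
  chrom <- paste0("chr", ((seq_len(G) - 1L) %% 4L) + 1L)
  idx_on_chr <- stats::ave(seq_len(G), chrom, FUN = seq_along)
  tss <- 500000L + (idx_on_chr - 1L) * 200000L
  strand <- rep(c("+", "-"), length.out = G)
  role <- rep("other", G)
  names(role) <- genes
  # per-cluster DE genes alternate activator / inhibitor ligand roles
  de_all <- unique(unlist(lapply(truth@de_genes, names)))
  shared <- unique(c(truth@tf_edges$target_gene,
                     if (n_cnv_driven > 0L) names(truth@cnv_driven_genes)[1L]))
  de_spec <- setdiff(de_all, shared)
  role[de_spec] <- rep(c("nk_activator_ligand", "nk_inhibitor_ligand"),
                       length.out = length(de_spec))
  role[shared] <- "nk_inhibitor_ligand"
  role[truth@tf_edges$tf_gene] <- "tf_coding"
  GeneAnnotation(genes, chrom, strand, tss, unname(role[genes]))
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Composes [simulateExpression()], [simulateCNV()], [simulatePeaks()] and
#' [simulateSurvival()] into a mutually consistent cohort: tumor and normal
#' count matrices, copy number, ATAC peaks with sequences and matched
#' position-weight matrices, a gene annotation (genes spaced 200 kb apart
#' so TSS windows never overlap; roles reflect the plantings), a survival
#' table driven by the first planted target gene, and the complete
#' [SyntheticTruth-class]. The same seed reproduces the cohort exactly.
#'
#' @param cfg a [SimulationConfig-class].
#' @return named list: `tumor`, `normal`, `cnv`, `peaks`, `sequences`,
#'   `pwms`, `annotation`, `survival`, `truth`, `config`.
#' @examples
#' cohort <- generateCohort(SimulationConfig(n_genes = 60,
#'     n_samples_tumor = 24, n_samples_normal = 12,
#'     n_markers_per_subtype = 5, n_de_per_cluster = 3, n_cnv_driven = 2,
#'     n_decoy_peaks = 6, seed = 7))
#' cohort$tumor
#' @export
generateCohort <- function(cfg = SimulationConfig()) {
  ex <- simulateExpression(cfg)
  cv <- simulateCNV(cfg, ex$tumor, ex$truth)
  ann <- .makeAnnotation(geneIds(cv$tumor), ex$truth, cfg@n_cnv_driven)
  pk <- simulatePeaks(cfg, cv$tumor, ann, ex$truth)
  surv <- simulateSurvival(cfg, cv$tumor, pk$truth@survival_gene)
  list(tumor = cv$tumor, normal = ex$normal, cnv = cv$cnv,
       peaks = pk$peaks, sequences = pk$sequences, pwms = pk$pwms,
       annotation = ann, survival = surv, truth = pk$truth, config = cfg)
}

#' Write or read a cohort as plain-text files
#'
#' Serialises every component of a [generateCohort()] result to a
#' directory using the package's standard formats (expression/CNV/score
#' TSVs, BED4 + FASTA for peaks, JASPAR text for motifs, annotation and
#' survival TSVs) plus ground-truth TSVs under `truth/`. `readCohort()`
#' reads them back (the truth directory is optional).
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(cohort$tumor, file.path(dir, "expression_tumor.tsv"))
  writeExpression(cohort$normal, file.path(dir, "expression_normal.tsv"))
  writeCNV(cohort$cnv, file.path(dir, "cnv.tsv"))
  writePeaks(cohort$peaks, file.path(dir, "peaks.bed"),
             file.path(dir, "peak_scores.tsv"))
  writePeakSequences(cohort$sequences, file.path(dir, "peaks.fasta"))
  writeJasparMotifs(cohort$pwms, file.path(dir, "pwms.jaspar"))
  writeAnnotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  writeSurvival(cohort$survival, file.path(dir, "survival.tsv"))
  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  tr <- cohort$truth
  utils::write.table(
    data.frame(sample_id = names(tr@subtype_of_sample),
               subtype = unname(tr@subtype_of_sample)),
    file.path(td, "subtypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  de <- do.call(rbind, lapply(names(tr@de_genes), function(k)
    if (length(tr@de_genes[[k]]))
      data.frame(cluster = k, gene = names(tr@de_genes[[k]]),
                 direction = unname(tr@de_genes[[k]]))))
  if (is.null(de)) de <- data.frame(cluster = character(),
                                    gene = character(),
                                    direction = character())
  utils::write.table(de, file.path(td, "de_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(tr@cnv_driven_genes),
               beta = unname(tr@cnv_driven_genes)),
    file.path(td, "cnv_driven.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(tr@tf_edges, file.path(td, "tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg <- do.call(rbind, lapply(seq_along(tr@regulated_samples), function(e)
    data.frame(edge = e, sample_id = tr@regulated_samples[[e]])))
  if (is.null(reg)) reg <- data.frame(edge = integer(),
                                      sample_id = character())
  utils::write.table(reg, file.path(td, "regulated_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  out <- list(
    tumor = readExpression(file.path(dir, "expression_tumor.tsv"), "tumor"),
    normal = readExpression(file.path(dir, "expression_normal.tsv"), "normal"),
    cnv = readCNV(file.path(dir, "cnv.tsv")),
    peaks = readPeaks(file.path(dir, "peaks.bed"),
                      file.path(dir, "peak_scores.tsv")),
    sequences = readPeakSequences(file.path(dir, "peaks.fasta")),
    pwms = readJasparMotifs(file.path(dir, "pwms.jaspar")),
    annotation = readAnnotation(file.path(dir, "annotation.tsv")),
    survival = readSurvival(file.path(dir, "survival.tsv")))
  td <- file.path(dir, "truth")
  if (dir.exists(td)) {
    sub <- utils::read.table(file.path(td, "subtypes.tsv"), sep = "\t",
                             header = TRUE)
    out$truth_subtypes <- stats::setNames(sub$subtype, sub$sample_id)
    out$truth_de <- utils::read.table(file.path(td, "de_genes.tsv"),
                                      sep = "\t", header = TRUE)
    out$truth_cnv <- utils::read.table(file.path(td, "cnv_driven.tsv"),
                                       sep = "\t", header = TRUE)
    out$truth_edges <- utils::read.table(file.path(td, "tf_edges.tsv"),
                                         sep = "\t", header = TRUE)
    out$truth_regulated <- utils::read.table(
      file.path(td, "regulated_samples.tsv"), sep = "\t", header = TRUE)
  }
  out
}
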