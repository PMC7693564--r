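#' @include AllClasses.R
NULL

#' Forward CNV-unexplained DE genes to regulatory analysis
#'
#' Splits the consensus DE genes by their CNV/expression correlation
#' strength: weak or undefined correlations cannot be explained by copy
#' number and become regulatory targets; moderate and strong genes are
#' reported as CNV-explained. DE genes absent from the correlation table
#' (no CNV data) are forwarded as targets and flagged.
#'
#' @param corr correlation table from [cnvMrnaCorrelation()].
#' @param sets per-cluster `DEGeneSet` list (from [clusterDE()]).
#' @return list with `targets`, `cnv_explained`, and `table` (per-gene
#'   disposition).
#' @export
forwardWeakGenes <- function(corr, sets) {
  de_genes <- sort(unique(unlist(lapply(sets, function(s) names(s$genes)))))
  strength <- stats::setNames(corr$strength, corr$gene)[de_genes]
  strength[is.na(strength)] <- "untested"
  targets <- de_genes[strength %in% c("weak", "undefined", "untested")]
  explained <- de_genes[strength %in% c("moderate", "strong")]
  list(targets = targets, cnv_explained = explained,
       table = data.frame(gene = de_genes, strength = unname(strength),
                          disposition = ifelse(de_genes %in% targets,
                                               "regulatory_target",
                                               "cnv_explained"),
                          row.names = NULL))
}

#' Simulation configuration of the bundled fixture cohort
#'
#' A reduced cohort (240 genes, 48 tumor / 24 normal samples, 4 subtypes)
#' with every kind of planted structure, used by the end-to-end examples
#' and the determinism checks.
#'
#' @return a [SimulationConfig-class].
#' @export
fixtureSimulationConfig <- function() {
  SimulationConfig(n_genes = 240L, n_samples_tumor = 48L,
                   n_samples_normal = 24L, K = 4L,
                   n_markers_per_subtype = 12L, n_de_per_cluster = 8L,
                   n_cnv_driven = 4L, n_tf_edges = 1L, n_decoy_peaks = 20L,
                   seed = 42L)
}

#' @rdname fixtureSimulationConfig
#' @export
fixturePipelineConfig <- function() {
  PipelineConfig(rank_range = 2:5,
                 nmf = NMFConfig(n_restarts = 10L, rank_range = 2:5),
                 seed = 42L)
}

.writeTSV <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1L))
  x[num] <- lapply(x[num], .fmtNum)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full fusion pipeline on a cohort directory
#'
#' Executes the five stages in order - consensus-NMF subtyping,
#' per-cluster consensus differential expression with NK-ligand
#' categorisation, CNV/mRNA correlation triage of the DE genes,
#' per-sample regulatory calling on the CNV-unexplained genes, and
#' survival stratification - reading the cohort from `input_dir` (the
#' [writeCohort()] layout) and writing every stage's tables plus a run
#' manifest to `output_dir`. The run is a pure function of the inputs and
#' the configuration: a fixed `cfg@seed` reproduces every output file
#' byte for byte (the manifest records wall-clock time and is identical
#' up to that field).
#'
#' @param input_dir cohort directory.
#' @param output_dir output directory (created if needed).
#' @param cfg a [PipelineConfig-class].
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
runPipeline <- function(input_dir, output_dir, cfg = PipelineConfig()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  co <- readCohort(input_dir)
  input_files <- list.files(input_dir, full.names = TRUE, recursive = FALSE)
  input_files <- input_files[!dir.exists(input_files)]
  digests <- tools::md5sum(input_files)
  names(digests) <- basename(names(digests))
  outputs <- character()
  put <- function(x, name) {
    outputs <<- c(outputs, name)
    .writeTSV(x, file.path(output_dir, name))
  }

  stage <- "subtype"
  res <- tryCatch({
    message("[subtype] consensus NMF over ranks ",
            paste(range(cfg@rank_range), collapse = "-"))
    nmf_cfg <- cfg@nmf
    nmf_cfg@rank_range <- cfg@rank_range
    sub <- subtypeNMF(co$tumor, nmf_cfg, seed = cfg@seed)
    put(sub$metrics, "subtype_metrics.tsv")
    put(data.frame(sample_id = names(sub$labels),
                   cluster = unname(sub$labels)), "subtype_labels.tsv")
    for (r in names(sub$results)) {
      cm <- sub$results[[r]]@consensus
      .writeMatrixTSV(cm, file.path(output_dir,
                                    sprintf("consensus_rank%s.tsv", r)),
                      "sample_id")
      outputs <- c(outputs, sprintf("consensus_rank%s.tsv", r))
    }
    message("[subtype] selected rank ", sub$rank)

    stage <- "de"
    de <- clusterDE(co$tumor, co$normal, sub$labels,
                    alpha = cfg@de_alpha, lfc_cutoff = cfg@de_lfc)
    for (k in names(de$sets)) {
      s <- de$sets[[k]]
      put(data.frame(gene = names(s$genes), direction = unname(s$genes)),
          sprintf("de_cluster%s.tsv", k))
    }
    nk <- formatNKLigandTable(classifyNKLigands(de$sets, co$annotation))
    put(nk, "nk_ligand_table.tsv")
    n_de <- length(unique(unlist(lapply(de$sets, function(s)
      names(s$genes)))))
    message("[de] ", n_de, " consensus DE genes across ",
            length(de$sets), " clusters")

    stage <- "cnvcorr"
    de_genes <- sort(unique(unlist(lapply(de$sets, function(s)
      names(s$genes)))))
    corr <- cnvMrnaCorrelation(co$cnv, co$tumor, genes = de_genes,
                               moderate = cfg@spearman_moderate,
                               strong = cfg@spearman_strong)
    put(corr, "cnv_correlation.tsv")
    message("[cnvcorr] ", nrow(corr), " genes tested, ",
            length(attr(corr, "skipped")), " skipped")

    stage <- "regulate"
    fw <- forwardWeakGenes(corr, de$sets)
    put(fw$table, "regulate_targets.tsv")
    reg <- runRegulatoryAnalysis(co$tumor, co$normal, co$peaks,
                                 co$annotation, co$pwms, fw$targets,
                                 sequences = co$sequences,
                                 window = cfg@tss_window,
                                 quantile = cfg@high_score_quantile,
                                 alpha = cfg@ttest_alpha)
    put(reg$calls, "regulation_calls.tsv")
    put(reg$candidates, "candidate_peaks.tsv")
    message("[regulate] ", nrow(reg$calls), " per-sample calls on ",
            length(fw$targets), " targets")

    stage <- "survival"
    surv_genes <- if (length(fw$targets)) fw$targets else de_genes
    stests <- do.call(rbind, lapply(surv_genes, function(g) {
      r <- tryCatch(survivalByExpression(co$survival, co$tumor, g),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(gene = g, chi2 = r$test$chi2, df = r$test$df,
                 pvalue = r$test$pvalue)
    }))
    if (is.null(stests))
      stests <- data.frame(gene = character(), chi2 = numeric(),
                           df = integer(), pvalue = numeric())
    put(stests, "survival_tests.tsv")
    if (length(surv_genes)) {
      km <- survivalByExpression(co$survival, co$tumor, surv_genes[1L])
      put(km$curves, "km_curves.tsv")
    }
    message("[survival] ", nrow(stests), " genes stratified")

    list(subtype = sub, de = de, corr = corr, forward = fw,
         regulatory = reg, survival = stests)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "immunofusion",
    version = as.character(utils::packageVersion("immunofusion")),
    seed = cfg@seed,
    config = list(
      rank_range = paste(range(cfg@rank_range), collapse = ":"),
      de_alpha = cfg@de_alpha, de_lfc = cfg@de_lfc,
      spearman_moderate = cfg@spearman_moderate,
      spearman_strong = cfg@spearman_strong,
      tss_window = cfg@tss_window, ttest_alpha = cfg@ttest_alpha,
      high_score_quantile = cfg@high_score_quantile,
      nmf = list(gamma = cfg@nmf@gamma, regularizer = cfg@nmf@regularizer,
                 max_iter = cfg@nmf@max_iter, tol = cfg@nmf@tol,
                 n_restarts = cfg@nmf@n_restarts)),
    input_digests = as.list(digests),
    outputs = outputs,
    stages = c("subtype", "de", "cnvcorr", "regulate", "survival"),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
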