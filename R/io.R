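#' @include AllClasses.R
NULL

# Numeric cells are written with %.17g so that doubles survive a
# write/read cycle exactly; integers print without a decimal point.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

.readMatrixTSV <- function(path, what = "matrix") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop(what, " file must have an id column plus samples")
  ids <- tab[[1L]]
  w <- .checkIds(ids, paste(what, "row ids"))
  if (!is.null(w)) stop(w)
  samples <- colnames(tab)[-1L]
  w <- .checkIds(samples, paste(what, "sample ids"))
  if (!is.null(w)) stop(w)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 vals[bad[1L], bad[2L]], ids[bad[1L]], samples[bad[2L]], path))
  }
  dimnames(num) <- list(ids, samples)
  num
}

.writeMatrixTSV <- function(values, path, id_col) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i], .fmtNum(values[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
}

#' Read and write expression matrices
#'
#' Tab-separated layout: a header row of sample ids, one row per gene with
#' the gene id in the first column. Duplicate ids, non-numeric cells and
#' negative entries are rejected with an error naming the offender; missing
#' values are not allowed.
#'
#' @param path file path.
#' @param cohort `"tumor"` or `"normal"`.
#' @param unit measurement unit recorded on the object.
#' @return [readExpression()] an [ExpressionMatrix-class];
#'   [writeExpression()] the path, invisibly.
#' @export
readExpression <- function(path, cohort = c("tumor", "normal"),
                           unit = "counts") {
  cohort <- match.arg(cohort)
  num <- .readMatrixTSV(path, "expression")
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression at gene '%s', sample '%s'",
                 rownames(num)[bad[1L]], colnames(num)[bad[2L]]))
  }
  ExpressionMatrix(num, cohort = cohort, unit = unit)
}

#' @rdname readExpression
#' @param x an [ExpressionMatrix-class].
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  .writeMatrixTSV(exprValues(x), path, "gene_id")
  invisible(path)
}

#' Read and write CNV matrices
#'
#' Same tab-separated layout as expression files; values may be negative
#' (log-ratios) but must be numeric and complete.
#'
#' @param path file path.
#' @return [readCNV()] a [CNVMatrix-class]; [writeCNV()] the path, invisibly.
#' @export
readCNV <- function(path) CNVMatrix(.readMatrixTSV(path, "CNV"))

#' @rdname readCNV
#' @param x a [CNVMatrix-class].
#' @export
writeCNV <- function(x, path) {
  stopifnot(is(x, "CNVMatrix"))
  .writeMatrixTSV(cnvValues(x), path, "gene_id")
  invisible(path)
}

#' Read and write an ATAC peak set
#'
#' Peaks are described by a BED4 file (chrom, 0-based half-open start/end,
#' peak id) plus a tab-separated score matrix keyed by peak id (first
#' column) with ATAC sample ids in the header. Every BED record must have a
#' score row; BED order is preserved regardless of matrix row order.
#'
#' @param bed_path BED4 file of peak intervals.
#' @param matrix_path TSV of per-sample peak scores keyed by peak id.
#' @param unit score unit recorded on the object.
#' @return [readPeaks()] a [PeakSet-class]; [writePeaks()] the paths,
#'   invisibly.
#' @export
readPeaks <- function(bed_path, matrix_path,
                      unit = "log2([count + 5]PM)-qn") {
  gr <- rtracklayer::import(bed_path, format = "BED")
  ids <- mcols(gr)$name
  w <- .checkIds(ids, "peak ids")
  if (!is.null(w)) stop(w)
  if (any(width(gr) < 1L))
    stop("empty peak interval (start >= end) for: ",
         paste(ids[width(gr) < 1L], collapse = ", "))
  scores <- .readMatrixTSV(matrix_path, "peak score")
  missing <- setdiff(ids, rownames(scores))
  if (length(missing))
    stop("peaks in BED without a score row: ",
         paste(missing, collapse = ", "))
  scores <- scores[ids, , drop = FALSE]
  PeakSet(ids, as.character(seqnames(gr)), start(gr) - 1L, end(gr),
          scores, unit = unit)
}

#' @rdname readPeaks
#' @param x a [PeakSet-class].
#' @export
writePeaks <- function(x, bed_path, matrix_path) {
  stopifnot(is(x, "PeakSet"))
  exportPeakBed(x, bed_path)
  .writeMatrixTSV(peakScores(x), matrix_path, "peak_id")
  invisible(c(bed_path, matrix_path))
}

#' Export peak intervals as BED4
#'
#' Writes the peak coordinates (0-based half-open, peak id in the name
#' column) for sequence extraction by standard tools.
#'
#' @param x a [PeakSet-class].
#' @param path output BED path.
#' @export
exportPeakBed <- function(x, path) {
  gr <- peakRanges(x)
  mcols(gr)$name <- names(gr)
  names(gr) <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write gene annotation
#'
#' Tab-separated columns `id`, `chrom`, `strand`, `tss`, `immune_role`
#' (header required). TSS positions are 0-based. Unknown role strings and
#' strands outside `+`/`-` are rejected; an empty file yields an empty
#' annotation.
#'
#' @param path file path.
#' @return [readAnnotation()] a [GeneAnnotation-class];
#'   [writeAnnotation()] the path, invisibly.
#' @export
readAnnotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c("id", "chrom", "strand", "tss", "immune_role")
  if (!all(need %in% colnames(tab)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) return(GeneAnnotation(character(), character(),
                                             character(), integer(),
                                             character()))
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'; offending genes: ",
         paste(tab$id[!tab$strand %in% c("+", "-")], collapse = ", "))
  bad <- !tab$immune_role %in% .IMMUNE_ROLES
  if (any(bad))
    stop("unknown immune_role '", tab$immune_role[bad][1L],
         "'; allowed values: ", paste(.IMMUNE_ROLES, collapse = ", "))
  tss <- suppressWarnings(as.integer(tab$tss))
  if (anyNA(tss)) stop("non-integer tss for gene ",
                       tab$id[is.na(tss)][1L])
  GeneAnnotation(tab$id, tab$chrom, tab$strand, tss, tab$immune_role)
}

#' @rdname readAnnotation
#' @param x a [GeneAnnotation-class].
#' @export
writeAnnotation <- function(x, path) {
  stopifnot(is(x, "GeneAnnotation"))
  gr <- x@tss
  tab <- data.frame(id = names(gr), chrom = as.character(seqnames(gr)),
                    strand = as.character(strand(gr)),
                    tss = start(gr) - 1L,
                    immune_role = mcols(gr)$immune_role)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a survival table
#'
#' Tab-separated columns `sample_id`, `time` (non-negative, days) and
#' `event` (1 = death observed, 0 = censored).
#'
#' @param path file path.
#' @return [readSurvival()] a validated `data.frame`; [writeSurvival()]
#'   the path, invisibly.
#' @export
readSurvival <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  validateSurvivalTable(tab)
}

#' @rdname readSurvival
#' @param x a survival `data.frame`.
#' @export
writeSurvival <- function(x, path) {
  x <- validateSurvivalTable(x)
  x$time <- .fmtNum(x$time)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a survival table
#'
#' Checks the `sample_id`/`time`/`event` contract: unique sample ids,
#' finite non-negative times, events coded 0/1.
#'
#' @param x a `data.frame`.
#' @return the validated `data.frame` with `event` as integer.
#' @export
validateSurvivalTable <- function(x) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(x)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  w <- .checkIds(as.character(x$sample_id), "sample ids")
  if (!is.null(w)) stop(w)
  if (any(!is.finite(x$time)) || any(x$time < 0))
    stop("survival times must be finite and >= 0")
  if (!all(x$event %in% c(0, 1))) stop("event must be 0 or 1")
  x$event <- as.integer(x$event)
  x[, need]
}

#' Read and write the pipeline configuration
#'
#' Flat `key: value` text mirroring [PipelineConfig-class] (plus the
#' embedded NMF settings, prefixed `nmf_`). Unknown keys are an error;
#' omitted keys keep their defaults. `rank_range` is written as
#' `first:last`.
#'
#' @param path file path.
#' @return [readPipelineConfig()] a [PipelineConfig-class];
#'   [writePipelineConfig()] the path, invisibly.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[lengths(kv) != 3L][1L])
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  known <- c("rank_range", "de_alpha", "de_lfc", "spearman_moderate",
             "spearman_strong", "tss_window", "ttest_alpha",
             "high_score_quantile", "seed", "nmf_gamma", "nmf_regularizer",
             "nmf_max_iter", "nmf_tol", "nmf_n_restarts")
  if (any(!keys %in% known))
    stop("unknown config key: ", keys[!keys %in% known][1L])
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  rr <- get("rank_range", "2:6")
  rr <- as.integer(strsplit(rr, ":", fixed = TRUE)[[1L]])
  rank_range <- rr[1L]:rr[length(rr)]
  nmf <- NMFConfig(
    gamma = as.numeric(get("nmf_gamma", 0)),
    regularizer = get("nmf_regularizer", "none"),
    max_iter = as.integer(get("nmf_max_iter", 200L)),
    tol = as.numeric(get("nmf_tol", 1e-4)),
    n_restarts = as.integer(get("nmf_n_restarts", 30L)),
    rank_range = rank_range)
  PipelineConfig(
    rank_range = rank_range, nmf = nmf,
    de_alpha = as.numeric(get("de_alpha", 0.05)),
    de_lfc = as.numeric(get("de_lfc", 1)),
    spearman_moderate = as.numeric(get("spearman_moderate", 0.4)),
    spearman_strong = as.numeric(get("spearman_strong", 0.7)),
    tss_window = as.integer(get("tss_window", 20000L)),
    ttest_alpha = as.numeric(get("ttest_alpha", 0.05)),
    high_score_quantile = as.numeric(get("high_score_quantile", 0.75)),
    seed = as.integer(get("seed", 1L)))
}

#' @rdname readPipelineConfig
#' @param x a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(x, path) {
  stopifnot(is(x, "PipelineConfig"))
  rr <- x@rank_range
  lines <- c(
    sprintf("rank_range: %d:%d", min(rr), max(rr)),
    sprintf("de_alpha: %s", .fmtNum(x@de_alpha)),
    sprintf("de_lfc: %s", .fmtNum(x@de_lfc)),
    sprintf("spearman_moderate: %s", .fmtNum(x@spearman_moderate)),
    sprintf("spearman_strong: %s", .fmtNum(x@spearman_strong)),
    sprintf("tss_window: %d", x@tss_window),
    sprintf("ttest_alpha: %s", .fmtNum(x@ttest_alpha)),
    sprintf("high_score_quantile: %s", .fmtNum(x@high_score_quantile)),
    sprintf("seed: %d", x@seed),
    sprintf("nmf_gamma: %s", .fmtNum(x@nmf@gamma)),
    sprintf("nmf_regularizer: %s", x@nmf@regularizer),
    sprintf("nmf_max_iter: %d", x@nmf@max_iter),
    sprintf("nmf_tol: %s", .fmtNum(x@nmf@tol)),
    sprintf("nmf_n_restarts: %d", x@nmf@n_restarts))
  writeLines(lines, path)
  invisible(path)
}

#' Read position-weight matrices in JASPAR text format
#'
#' Parses the JASPAR layout (`>ID NAME` header followed by four rows
#' `A [ n1 n2 ... ]` through `T [...]`). Counts are converted to
#' probabilities with a per-cell pseudocount. The gene coding each factor
#' defaults to the factor name itself and can be overridden with a named
#' `tf_map` (factor name -> gene id). Score thresholds default to 80% of
#' each motif's maximal log2-odds score.
#'
#' @param path JASPAR-format file.
#' @param tf_map optional named character vector mapping factor name to
#'   coding gene id.
#' @param pseudocount per-cell pseudocount added before normalisation.
#' @param background length-4 background base frequencies (A, C, G, T).
#' @return a list of [PWMotif-class] objects, named by factor.
#' @export
readJasparMotifs <- function(path, tf_map = NULL, pseudocount = 0.5,
                             background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers ('>') found in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    parts <- strsplit(hdr, "\\s+")[[1L]]
    name <- if (length(parts) >= 2L) parts[2L] else parts[1L]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- grep(paste0("^", b, "\\b"), block, value = TRUE)
      if (length(ln) != 1L) stop("motif ", name, ": missing row for base ", b)
      nums <- gsub("[][]", " ", sub(paste0("^", b, "\\s*"), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", name, ": rows of unequal length")
    m <- do.call(rbind, rows)
    m <- sweep(m + pseudocount, 2, colSums(m) + 4 * pseudocount, "/")
    rownames(m) <- c("A", "C", "G", "T")
    gene <- if (!is.null(tf_map) && name %in% names(tf_map))
      unname(tf_map[name]) else name
    out[[name]] <- PWMotif(name, gene, m, background = background)
  }
  out
}

#' @rdname readJasparMotifs
#' @param motifs list of [PWMotif-class] objects.
#' @param counts_scale counts written per column (probabilities are scaled
#'   to integers out of this total).
#' @export
writeJasparMotifs <- function(motifs, path, counts_scale = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m@tf_name, m@tf_name), con)
    cnt <- round(m@matrix * counts_scale)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(sprintf("%d", cnt[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read and write peak sequences (FASTA)
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; sequences are keyed by peak id.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readPeakSequences <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readPeakSequences
#' @param seqs a [Biostrings::DNAStringSet] named by peak id.
#' @export
writePeakSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
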