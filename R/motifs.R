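#' @include AllClasses.R
NULL

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# log2-odds scan of one strand; N positions contribute 0
.scanOne <- function(codes, lod) {
  L <- ncol(lod)
  S <- length(codes)
  if (S < L) return(numeric(0L))
  npos <- S - L + 1L
  sc <- numeric(npos)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + npos - 1L)]
    contrib <- numeric(npos)
    known <- cj > 0L
    contrib[known] <- lod[cbind(cj[known], j)]
    sc <- sc + contrib
  }
  sc
}

#' Scan a DNA sequence with position-weight matrices
#'
#' Computes the log2-odds score `sum_j log2(p[base_j, j] / bg[base_j])` at
#' every offset of every motif, on both strands (the minus strand scans
#' the reverse complement; its hits are reported at the position the
#' motif occupies in the forward sequence). Positions with `N` score as
#' background (contribution 0). All positions with score at or above the
#' motif's `score_threshold` are returned; a sequence shorter than a
#' motif simply yields no hits for it.
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param pwms a list of [PWMotif-class].
#' @return a `data.frame` with `tf`, `coding_gene`, `position` (1-based
#'   start of the match on the forward sequence), `strand`, `score`.
#' @export
scanMotifs <- function(sequence, pwms) {
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "")[[1L]]
  if (!all(chars %in% names(.BASE_CODE)))
    stop("sequence contains characters outside A, C, G, T, N")
  out <- list()
  strands <- list(`+` = chars, `-` = strsplit(.revcomp(s), "")[[1L]])
  for (m in pwms) {
    lod <- log2(pmax(m@matrix, 1e-12) / m@background)
    L <- ncol(lod)
    for (st in names(strands)) {
      codes <- unname(.BASE_CODE[strands[[st]]])
      sc <- .scanOne(codes, lod)
      hit <- which(sc >= m@score_threshold)
      if (length(hit)) {
        pos <- if (st == "+") hit else length(codes) - hit - L + 2L
        out[[length(out) + 1L]] <- data.frame(
          tf = m@tf_name, coding_gene = m@coding_gene_id, position = pos,
          strand = st, score = sc[hit])
      }
    }
  }
  if (!length(out))
    return(data.frame(tf = character(), coding_gene = character(),
                      position = integer(), strand = character(),
                      score = numeric()))
  res <- do.call(rbind, out)
  res[order(res$tf, res$position, res$strand), , drop = FALSE] ->
    res
  rownames(res) <- NULL
  res
}
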