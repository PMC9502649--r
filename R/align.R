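# Pairwise alignment utilities (Needleman-Wunsch via Biostrings) and
# reciprocal-best-hit mapping. Alignment-score thresholds stand in for
# BLAST E-value cuts at desk scale.

#' Global pairwise alignment
#'
#' Optimal global alignment under linear gap scoring.
#'
#' @param a,b DNA sequences (character scalars).
#' @param match,mismatch,gap scoring parameters (linear gap penalty per
#'   gapped position).
#' @return An `aligned_pair`: list with gapped `a_aln`/`b_aln`, `score`,
#'   `identity` (matches / aligned non-gap columns) and `coverage`
#'   (fraction of `a` in non-gap columns).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap
  )
  a_aln <- as.character(Biostrings::alignedPattern(al))
  b_aln <- as.character(Biostrings::alignedSubject(al))
  ac <- strsplit(a_aln, "")[[1]]
  bc <- strsplit(b_aln, "")[[1]]
  both <- ac != "-" & bc != "-"
  structure(
    list(a_aln = a_aln, b_aln = b_aln,
         score = Biostrings::score(al),
         identity = if (any(both)) sum(ac[both] == bc[both]) / sum(both)
                    else 0,
         coverage = sum(both) / nchar(a)),
    class = "aligned_pair"
  )
}

# score-only alignment of a set against one subject
align_scores <- function(set, subject, match = 1, mismatch = -1, gap = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(set), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE
  )
}

#' Reciprocal best hits between two sequence sets
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best-scoring hit and `a`
#' is `b`'s, with both scores at least `min_score`. Score ties are broken
#' by lexicographic id and recorded in the `ties` attribute.
#'
#' @param set_a,set_b named character vectors (or `DNAStringSet`s).
#' @param min_score minimum alignment score for either direction.
#' @param match,mismatch,gap scoring parameters.
#' @return data.frame `a`, `b`, `score_ab`, `score_ba`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_score = 0,
                                 match = 1, mismatch = -1, gap = -1) {
  if (inherits(set_a, "DNAStringSet")) set_a <- as.character(set_a)
  if (inherits(set_b, "DNAStringSet")) set_b <- as.character(set_b)
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  ids_a <- names(set_a)
  ids_b <- names(set_b)
  scores <- matrix(NA_real_, length(set_a), length(set_b),
                   dimnames = list(ids_a, ids_b))
  for (j in seq_along(set_b)) {
    scores[, j] <- align_scores(set_a, set_b[[j]], match, mismatch, gap)
  }
  best_of <- function(v, ids) {
    top <- which(v == max(v))
    ids[top][order(ids[top])][1]
  }
  tied <- character(0)
  best_b_for_a <- vapply(seq_along(ids_a), function(i) {
    if (sum(scores[i, ] == max(scores[i, ])) > 1) tied <<- c(tied, ids_a[i])
    best_of(scores[i, ], ids_b)
  }, character(1))
  best_a_for_b <- vapply(seq_along(ids_b), function(j) {
    if (sum(scores[, j] == max(scores[, j])) > 1) tied <<- c(tied, ids_b[j])
    best_of(scores[, j], ids_a)
  }, character(1))
  names(best_b_for_a) <- ids_a
  names(best_a_for_b) <- ids_b
  rows <- list()
  for (i in seq_along(ids_a)) {
    b <- best_b_for_a[[i]]
    if (best_a_for_b[[b]] == ids_a[i] &&
        scores[ids_a[i], b] >= min_score &&
        scores[ids_a[i], b] >= min_score) {
      rows[[length(rows) + 1]] <- data.frame(
        a = ids_a[i], b = b, score_ab = scores[ids_a[i], b],
        score_ba = scores[ids_a[i], b], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(0), b = character(0),
               score_ab = numeric(0), score_ba = numeric(0))
  attr(out, "ties") <- unique(tied)
  out
}

#' Codon-align two coding sequences
#'
#' Aligns the translated proteins globally and back-threads the codons;
#' a gap residue becomes a `---` codon in the corresponding nucleotide
#' string.
#'
#' @param x_cds,y_cds in-frame CDS (length divisible by 3, no internal
#'   stops required by the aligner).
#' @return List with codon-aligned `x` and `y` nucleotide strings of
#'   equal length divisible by 3.
#' @export
align_codons <- function(x_cds, y_cds) {
  if (nchar(x_cds) %% 3 != 0 || nchar(y_cds) %% 3 != 0) {
    stop("CDS lengths must be divisible by 3")
  }
  xp <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(x_cds),
                          if.fuzzy.codon = "X")))
  yp <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(y_cds),
                          if.fuzzy.codon = "X")))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(xp), Biostrings::AAString(yp),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  xa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ya <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  xi <- yi <- 0L
  xout <- yout <- character(length(xa))
  for (i in seq_along(xa)) {
    if (xa[i] == "-") {
      xout[i] <- "---"
    } else {
      xout[i] <- substring(x_cds, 3L * xi + 1L, 3L * xi + 3L)
      xi <- xi + 1L
    }
    if (ya[i] == "-") {
      yout[i] <- "---"
    } else {
      yout[i] <- substring(y_cds, 3L * yi + 1L, 3L * yi + 3L)
      yi <- yi + 1L
    }
  }
  list(x = paste(xout, collapse = ""), y = paste(yout, collapse = ""))
}
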