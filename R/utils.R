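# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Jaccard overlap of two half-open intervals
#'
#' @param a,b numeric length-2 vectors `c(start, end)`, 0-based half-open.
#' @return Intersection length divided by union length (0 when disjoint).
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (union <= 0) return(0)
  inter / union
}

# derive a reproducible child seed, kept inside the 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
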