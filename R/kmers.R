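# Sex-specific k-mer catalog and read binning. K-mers are stored in
# canonical form: the lexicographic minimum of a k-mer and its reverse
# complement, so a sequence and its reverse complement contribute the
# same entries.

#' Canonical k-mers of a sequence
#'
#' @param seq a character scalar (DNA).
#' @param k k-mer length.
#' @return Character vector of canonical k-mers (possibly with
#'   duplicates); empty when the sequence is shorter than `k`.
#' @export
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), k:n)
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

#' Build a per-sex k-mer presence catalog
#'
#' An individual "contains" a k-mer if it appears at least once in any of
#' that individual's sequences; counts are aggregated per sex. Sequences
#' shorter than `k` contribute nothing.
#'
#' @param seqs_by_individual named list, individual id -> character vector
#'   of sequences (or a `DNAStringSet`).
#' @param sexes named vector id -> "M"/"F".
#' @param k k-mer length (default 30).
#' @return An object of class `kmer_catalog`: data.frame `kmer`,
#'   `n_male`, `n_female`, with attributes `k`, `n_males`, `n_females`.
#' @export
build_kmer_catalog <- function(seqs_by_individual, sexes, k = 30L) {
  if (k < 3) stop("k must be at least 3")
  ids <- names(seqs_by_individual)
  if (is.null(ids) || anyNA(match(ids, names(sexes)))) {
    stop("every individual needs a sex label")
  }
  per_ind <- lapply(seqs_by_individual, function(seqs) {
    if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    unique(unlist(lapply(seqs, canonical_kmers, k = k), use.names = FALSE))
  })
  male_ids <- ids[sexes[ids] == "M"]
  female_ids <- ids[sexes[ids] == "F"]
  tab_m <- table(unlist(per_ind[male_ids], use.names = FALSE))
  tab_f <- table(unlist(per_ind[female_ids], use.names = FALSE))
  all_k <- union(names(tab_m), names(tab_f))
  cat <- data.frame(
    kmer = all_k,
    n_male = as.integer(ifelse(is.na(tab_m[all_k]), 0L, tab_m[all_k])),
    n_female = as.integer(ifelse(is.na(tab_f[all_k]), 0L, tab_f[all_k])),
    stringsAsFactors = FALSE
  )
  rownames(cat) <- NULL
  structure(cat, class = c("kmer_catalog", "data.frame"),
            k = as.integer(k), n_males = length(male_ids),
            n_females = length(female_ids))
}

#' Select male-specific k-mers
#'
#' K-mers present in at least `min_males` male individuals and at most
#' `max_females` females (default: strict absence).
#'
#' @param cat a [build_kmer_catalog()] result.
#' @param min_males minimum male individuals containing the k-mer.
#' @param max_females maximum female individuals (default 0).
#' @return Character vector of canonical k-mers.
#' @export
male_specific_kmers <- function(cat, min_males = 20L, max_females = 0L) {
  if (min_males > attr(cat, "n_males")) {
    stop("min_males exceeds the number of male individuals")
  }
  cat$kmer[cat$n_male >= min_males & cat$n_female <= max_females]
}

#' Bin reads by sex-specific k-mer content
#'
#' A read is selected iff at least one of its canonical k-mers is in
#' `kmer_set`.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param kmer_set canonical k-mer set (character vector).
#' @param k k-mer length used to build the set.
#' @return A read bin: data.frame `read_id`, `provenance` (`"kmer"`).
#' @export
bin_reads_by_kmers <- function(reads, kmer_set, k = 30L) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  hit <- vapply(reads, function(r) {
    any(canonical_kmers(r, k) %in% kmer_set)
  }, logical(1))
  data.frame(read_id = names(reads)[hit],
             provenance = rep("kmer", sum(hit)),
             stringsAsFactors = FALSE)
}

#' Write a canonical k-mer set as plain text (one per line)
#'
#' @param kmers character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_set <- function(kmers, path) {
  writeLines(kmers, path)
  invisible(path)
}
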