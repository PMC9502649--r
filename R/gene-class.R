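# SDR gene classification: tandem duplicates, pseudogene calling, and
# the shared / ancestral / autosomal-transposition / lost / specific
# labelling of X- and Y-SDR genes. Labels are not mutually exclusive
# except LOST vs SPECIFIC.

#' Tandem duplicate pairs within one region
#'
#' Pairs of genes whose alignment score reaches `min_score` (standing in
#' for a BLAST E-value cut at desk scale) and whose start positions lie
#' within `window` bp of each other. Self-pairings are excluded.
#'
#' @param seqs named character vector (or `DNAStringSet`) of gene
#'   sequences.
#' @param positions named numeric start positions, same coordinate
#'   system.
#' @param min_score minimum alignment score.
#' @param window maximum start distance in bp (default 500 kb).
#' @return data.frame `gene_a`, `gene_b`, `score`, `distance`.
#' @export
tandem_duplicates <- function(seqs, positions, min_score,
                              window = 500000) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        d <- abs(positions[[ids[i]]] - positions[[ids[j]]])
        if (d > window) next
        sc <- global_align(seqs[[i]], seqs[[j]])$score
        if (sc >= min_score) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_a = ids[i], gene_b = ids[j], score = sc, distance = d,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), distance = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Call a pseudogene from a candidate region and its parent CDS
#'
#' A pseudogene requires alignment identity above `min_identity`
#' (default 0.70), parent coverage at least `min_coverage`, and at least
#' one open-reading-frame disruption: a premature stop in the threaded
#' reading frame or a frameshift-inducing indel (gap length not a
#' multiple of 3).
#'
#' @param candidate_region candidate genomic sequence.
#' @param parent_cds the intact parent CDS.
#' @param min_identity identity threshold over aligned columns.
#' @param min_coverage fraction of the parent CDS that must align.
#' @return `NULL` when the candidate does not qualify; otherwise a list
#'   with `identity`, `coverage` and a `disruptions` data.frame
#'   (`type` in `premature_stop`/`frameshift`, `parent_pos`).
#' @export
call_pseudogene <- function(candidate_region, parent_cds,
                            min_identity = 0.70, min_coverage = 0.50) {
  if (nchar(parent_cds) %% 3 != 0) stop("parent CDS must be in frame")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(parent_cds), Biostrings::DNAString(candidate_region),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & sa != "-"
  if (!any(both)) return(NULL)
  identity <- sum(pa[both] == sa[both]) / sum(both)
  coverage <- sum(pa != "-") / nchar(parent_cds)
  if (identity <= min_identity || coverage < min_coverage) return(NULL)

  # thread the candidate through the parent reading frame
  p_start <- Biostrings::start(Biostrings::pattern(al)) - 1L  # 0-based
  disruptions <- list()
  threaded <- rep(NA_character_, nchar(parent_cds))
  p_pos <- p_start
  run_gap <- 0L
  run_type <- ""
  flush_gap <- function() {
    if (run_gap > 0L && run_gap %% 3L != 0L) {
      disruptions[[length(disruptions) + 1L]] <<- data.frame(
        type = "frameshift", parent_pos = p_pos + 1L,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(pa)) {
    if (pa[i] != "-" && sa[i] != "-") {
      flush_gap(); run_gap <- 0L
      p_pos <- p_pos + 1L
      threaded[p_pos] <- sa[i]
    } else if (pa[i] == "-") {           # insertion in candidate
      run_gap <- run_gap + 1L
    } else {                             # deletion in candidate
      run_gap <- run_gap + 1L
      p_pos <- p_pos + 1L
    }
  }
  flush_gap()

  # premature stops in complete threaded codons before the parent's last
  code <- get_gencode()
  n_cod <- nchar(parent_cds) / 3
  for (ci in seq_len(n_cod - 1)) {
    cc <- threaded[(3 * ci - 2):(3 * ci)]
    if (anyNA(cc)) next
    codon <- paste(cc, collapse = "")
    if (grepl("[^ACGT]", codon)) next
    if (code[[codon]] == "*") {
      disruptions[[length(disruptions) + 1L]] <- data.frame(
        type = "premature_stop", parent_pos = 3 * ci - 2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(disruptions)) return(NULL)
  list(identity = identity, coverage = coverage,
       disruptions = do.call(rbind, disruptions))
}

best_hit_score <- function(seq, set) {
  if (!length(set)) return(-Inf)
  max(align_scores(set, seq))
}

#' Classify SDR genes
#'
#' Applies the field's standard labelling: `X_Y_SHARED` when a gene has a
#' reciprocal best hit on the other haplotype; `ANCESTRAL` when it hits
#' the corresponding region of an outgroup genome; `AUTOSOMAL_TRANSPOSITION`
#' when it lacks an outgroup-region hit but has a mutual best hit to an
#' autosomal gene; genes without an X-Y homolog are `LOST` when a
#' pseudogenized copy and/or an ancestral homolog exists, otherwise
#' `SPECIFIC`. Labels may combine, except LOST/SPECIFIC.
#'
#' @param x_genes,y_genes named CDS vectors for the two haplotypes.
#' @param autosomal_genes named CDS vector of autosomal genes.
#' @param outgroup_genes named CDS vector for the corresponding outgroup
#'   region.
#' @param pseudogene_calls character vector of gene ids that have a
#'   pseudogenized copy on the other haplotype (see [call_pseudogene()]).
#' @param tandem_pairs optional output of [tandem_duplicates()]; members
#'   gain the `TANDEM` label.
#' @param min_score minimum alignment score for any homology call.
#' @return data.frame `gene`, `haplotype`, `labels`
#'   (comma-separated), plus one logical column per label.
#' @export
classify_sdr_genes <- function(x_genes, y_genes, autosomal_genes = character(0),
                               outgroup_genes = character(0),
                               pseudogene_calls = character(0),
                               tandem_pairs = NULL,
                               min_score = 50) {
  to_chr <- function(x) {
    if (inherits(x, "DNAStringSet")) as.character(x) else x
  }
  x_genes <- to_chr(x_genes)
  y_genes <- to_chr(y_genes)
  autosomal_genes <- to_chr(autosomal_genes)
  outgroup_genes <- to_chr(outgroup_genes)
  all_ids <- c(names(x_genes), names(y_genes), names(autosomal_genes),
               names(outgroup_genes))
  if (anyDuplicated(all_ids)) {
    stop("gene id(s) present in more than one input set: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  rbh_xy <- if (length(x_genes) && length(y_genes)) {
    reciprocal_best_hits(x_genes, y_genes, min_score = min_score)
  } else {
    data.frame(a = character(0), b = character(0))
  }
  tandem_ids <- if (!is.null(tandem_pairs) && nrow(tandem_pairs)) {
    unique(c(tandem_pairs$gene_a, tandem_pairs$gene_b))
  } else {
    character(0)
  }
  classify_one <- function(id, seq, hap, partner_set) {
    labels <- character(0)
    shared <- id %in% c(rbh_xy$a, rbh_xy$b)
    if (shared) labels <- c(labels, "X_Y_SHARED")
    ancestral <- length(outgroup_genes) > 0 &&
      best_hit_score(seq, outgroup_genes) >= min_score
    if (ancestral) labels <- c(labels, "ANCESTRAL")
    if (!ancestral && length(autosomal_genes)) {
      rbh_auto <- reciprocal_best_hits(
        stats::setNames(seq, id), autosomal_genes, min_score = min_score)
      if (nrow(rbh_auto)) labels <- c(labels, "AUTOSOMAL_TRANSPOSITION")
    }
    if (!shared) {
      if (id %in% pseudogene_calls || ancestral) {
        labels <- c(labels, "LOST")
      } else if (!length(labels)) {
        labels <- "SPECIFIC"
      }
    }
    if (id %in% tandem_ids) labels <- c(labels, "TANDEM")
    labels
  }
  rows <- list()
  for (hap in c("X", "Y")) {
    genes <- if (hap == "X") x_genes else y_genes
    partner <- if (hap == "X") y_genes else x_genes
    for (id in names(genes)) {
      labels <- classify_one(id, genes[[id]], hap, partner)
      rows[[length(rows) + 1]] <- data.frame(
        gene = id, haplotype = hap,
        labels = paste(labels, collapse = ","),
        X_Y_SHARED = "X_Y_SHARED" %in% labels,
        ANCESTRAL = "ANCESTRAL" %in% labels,
        AUTOSOMAL_TRANSPOSITION = "AUTOSOMAL_TRANSPOSITION" %in% labels,
        LOST = "LOST" %in% labels,
        SPECIFIC = "SPECIFIC" %in% labels,
        TANDEM = "TANDEM" %in% labels,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$haplotype, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
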