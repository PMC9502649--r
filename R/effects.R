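# Coding-variant effect annotation from the standard genetic code and a
# gene model: SYN / MISSENSE / LOF (stop-gained, start-lost, stop-lost).

#' Protein-coding gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param segments data.frame of CDS segments with `start`, `end`
#'   (0-based half-open, genomic coordinates, non-overlapping). They are
#'   stored sorted in transcription order (genomic order for `+`,
#'   reverse for `-`).
#' @return An object of class `gene_model` with per-segment frame
#'   offsets.
#' @export
gene_model <- function(gene_id, chrom, strand, segments) {
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)])) {
    stop("CDS segments overlap in gene ", gene_id)
  }
  total <- sum(segments$end - segments$start)
  if (total %% 3 != 0) {
    stop("CDS total length not divisible by 3 in gene ", gene_id)
  }
  if (strand == "-") segments <- segments[rev(seq_len(nrow(segments))), ]
  lens <- segments$end - segments$start
  segments$frame <- cumsum(c(0L, lens[-length(lens)])) %% 3L
  rownames(segments) <- NULL
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 segments = segments, frame = segments$frame,
                 cds_length = total),
            class = "gene_model")
}

COMPLEMENT_OF <- c(A = "T", C = "G", G = "C", T = "A")

# CDS coordinate (0-based) of a genomic position, or NA when outside
cds_offset <- function(model, chrom, pos) {
  if (chrom != model$chrom) return(NA_integer_)
  p0 <- pos - 1L
  off <- 0L
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    if (p0 >= s$start && p0 < s$end) {
      within <- if (model$strand == "+") p0 - s$start else s$end - 1L - p0
      return(off + within)
    }
    off <- off + (s$end - s$start)
  }
  NA_integer_
}

# spliced CDS sequence in transcription order
extract_cds <- function(model, genome) {
  chrom_seq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(model$segments)), function(i) {
    s <- model$segments[i, ]
    seg <- substring(chrom_seq, s$start + 1L, s$end)
    if (model$strand == "-") revcomp(seg) else seg
  }, character(1))
  paste(parts, collapse = "")
}

#' Annotate coding effects of SNVs
#'
#' Reconstructs the affected codon from the gene model and genome and
#' classifies each variant under the standard genetic code: `SYN`
#' (amino acid unchanged), `MISSENSE`, or `LOF` (stop gained, start lost
#' or stop lost). Minus-strand genes are handled by reverse complement.
#' Variants outside any CDS are reported as `NON_CODING` and excluded
#' from load analyses.
#'
#' @param variants data.frame `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases).
#' @param gene_models list of [gene_model()] objects.
#' @param genome named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @return data.frame with codon reconstruction and `effect` per
#'   variant.
#' @export
annotate_effects <- function(variants, gene_models, genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  code <- get_gencode()
  cds_cache <- lapply(gene_models, extract_cds, genome = genome)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    for (gi in seq_along(gene_models)) {
      model <- gene_models[[gi]]
      off <- cds_offset(model, v$chrom, v$pos)
      if (is.na(off)) next
      cds <- cds_cache[[gi]]
      ref_tx <- if (model$strand == "+") v$ref else COMPLEMENT_OF[[v$ref]]
      alt_tx <- if (model$strand == "+") v$alt else COMPLEMENT_OF[[v$alt]]
      if (substring(cds, off + 1L, off + 1L) != ref_tx) {
        stop("reference mismatch at ", v$chrom, ":", v$pos,
             " in gene ", model$gene_id)
      }
      ci <- off %/% 3L           # 0-based codon index
      cp <- off %% 3L            # position within codon
      ref_codon <- substring(cds, 3L * ci + 1L, 3L * ci + 3L)
      alt_codon <- ref_codon
      substring(alt_codon, cp + 1L, cp + 1L) <- alt_tx
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      effect <- if (alt_aa == ref_aa) {
        "SYN"
      } else if (alt_aa == "*" || ref_aa == "*" ||
                 (ci == 0L && ref_codon == "ATG")) {
        "LOF"  # stop gained, stop lost, or start lost
      } else {
        "MISSENSE"
      }
      return(data.frame(
        chrom = v$chrom, pos = v$pos, gene = model$gene_id,
        codon_index = ci + 1L, ref_codon = ref_codon,
        alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
        effect = effect, stringsAsFactors = FALSE))
    }
    data.frame(chrom = v$chrom, pos = v$pos, gene = NA_character_,
               codon_index = NA_integer_, ref_codon = NA_character_,
               alt_codon = NA_character_, ref_aa = NA_character_,
               alt_aa = NA_character_, effect = "NON_CODING",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
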