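# Deleteriousness calls from a conservation-based consensus stand-in and
# the between-region mutation-load comparison, with synonymous variants
# as the selectively neutral reference.

#' Conservation-based deleteriousness calls for missense variants
#'
#' Two independent rules vote on each missense variant from the ortholog
#' protein alignment column of its codon. Scorer A votes deleterious when
#' the reference residue's column conservation is at least `cons_min`
#' (default 0.8) and the variant residue is absent from the column.
#' Scorer B votes deleterious when the variant residue's column frequency
#' is below `freq_max` (default 0.05). A variant is `DEL` only when both
#' scorers agree (consensus rule), otherwise `TOL`. Synonymous variants
#' are never scored.
#'
#' @param effects output of [annotate_effects()].
#' @param ortholog_alignments named list, gene id -> character matrix
#'   (rows = ortholog sequences, columns = reference protein positions).
#' @param cons_min scorer-A conservation threshold.
#' @param freq_max scorer-B variant-frequency threshold.
#' @return data.frame `gene`, `chrom`, `pos`, `codon_index`, `class`
#'   (`DEL`/`TOL`), `conservation`, `vote_a`, `vote_b`; variants whose
#'   alignment column is missing are excluded and listed in the
#'   `excluded` attribute.
#' @export
conservation_scores <- function(effects, ortholog_alignments,
                                cons_min = 0.8, freq_max = 0.05) {
  mis <- effects[effects$effect == "MISSENSE", , drop = FALSE]
  excluded <- character(0)
  rows <- lapply(seq_len(nrow(mis)), function(i) {
    v <- mis[i, ]
    aln <- ortholog_alignments[[v$gene]]
    if (is.null(aln) || v$codon_index > ncol(aln)) {
      excluded <<- c(excluded, paste0(v$gene, ":", v$codon_index))
      return(NULL)
    }
    col <- aln[, v$codon_index]
    conservation <- mean(col == v$ref_aa)
    vote_a <- conservation >= cons_min && !(v$alt_aa %in% col)
    vote_b <- mean(col == v$alt_aa) < freq_max
    data.frame(gene = v$gene, chrom = v$chrom, pos = v$pos,
               codon_index = v$codon_index,
               class = if (vote_a && vote_b) "DEL" else "TOL",
               conservation = conservation, vote_a = vote_a,
               vote_b = vote_b, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), codon_index = integer(0),
                      class = character(0), conservation = numeric(0),
                      vote_a = logical(0), vote_b = logical(0))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Tally per-gene variant-class counts for a load comparison
#'
#' @param effects output of [annotate_effects()].
#' @param calls output of [conservation_scores()].
#' @param gene_regions named vector gene id -> region label.
#' @param pool_lof pool LOF variants with DEL (default TRUE).
#' @return data.frame `region`, `gene`, `n_del`, `n_tol`, `n_syn`.
#' @export
tally_load <- function(effects, calls, gene_regions, pool_lof = TRUE) {
  genes <- names(gene_regions)
  rows <- lapply(genes, function(g) {
    eff_g <- effects[!is.na(effects$gene) & effects$gene == g, ]
    calls_g <- calls[calls$gene == g, ]
    n_del <- sum(calls_g$class == "DEL") +
      if (pool_lof) sum(eff_g$effect == "LOF") else 0L
    data.frame(region = gene_regions[[g]], gene = g,
               n_del = n_del, n_tol = sum(calls_g$class == "TOL"),
               n_syn = sum(eff_g$effect == "SYN"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare deleterious load between regions
#'
#' Per-gene DEL/SYN and TOL/SYN ratios (genes with no synonymous variant
#' are excluded as undefined) compared between all region pairs with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test plus a
#' label-permutation p-value on the difference of mean ratios. Rank-sum
#' p-values are Holm-corrected across region pairs per metric.
#'
#' @param counts data.frame `region`, `gene`, `n_del`, `n_tol`, `n_syn`
#'   (see [tally_load()]).
#' @param n_perm permutation draws (0 skips the permutation p-value).
#' @param seed integer seed for the permutations.
#' @param min_genes minimum genes with defined ratios per region.
#' @return A `load_summary`: list with `per_gene` ratios, `tests`
#'   (pair, metric, rank-sum p, Holm-adjusted p, permutation p),
#'   `pooled` per-region counts, and `flagged` regions (all-zero SYN).
#' @export
load_compare <- function(counts, n_perm = 1000L, seed = 1L,
                         min_genes = 5L) {
  regions <- unique(counts$region)
  if (length(regions) < 2) stop("load comparison needs at least 2 regions")
  defined <- counts$n_syn > 0
  per_gene <- counts[defined, , drop = FALSE]
  per_gene$del_syn <- per_gene$n_del / per_gene$n_syn
  per_gene$tol_syn <- per_gene$n_tol / per_gene$n_syn
  flagged <- regions[vapply(regions, function(r) {
    all(counts$n_syn[counts$region == r] == 0)
  }, logical(1))]
  n_def <- table(per_gene$region)
  low <- regions[!regions %in% names(n_def)[n_def >= min_genes]]
  if (length(low)) {
    stop("region(s) with fewer than ", min_genes,
         " genes with defined ratios: ", paste(low, collapse = ", "))
  }
  pairs <- utils::combn(sort(regions), 2, simplify = FALSE)
  if (n_perm > 0) set.seed(seed)
  tests <- list()
  for (metric in c("del_syn", "tol_syn")) {
    for (pr in pairs) {
      xa <- per_gene[[metric]][per_gene$region == pr[1]]
      xb <- per_gene[[metric]][per_gene$region == pr[2]]
      w_p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      perm_p <- NA_real_
      if (n_perm > 0) {
        obs <- abs(mean(xa) - mean(xb))
        pool <- c(xa, xb)
        na <- length(xa)
        perm <- vapply(seq_len(n_perm), function(k) {
          idx <- sample.int(length(pool), na)
          abs(mean(pool[idx]) - mean(pool[-idx]))
        }, numeric(1))
        perm_p <- (1 + sum(perm >= obs)) / (n_perm + 1)
      }
      tests[[length(tests) + 1]] <- data.frame(
        region_a = pr[1], region_b = pr[2], metric = metric,
        p_ranksum = w_p, p_perm = perm_p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_ranksum_holm <- NA_real_
  for (metric in c("del_syn", "tol_syn")) {
    sel <- tests$metric == metric
    tests$p_ranksum_holm[sel] <- stats::p.adjust(tests$p_ranksum[sel],
                                                 method = "holm")
  }
  pooled <- do.call(rbind, lapply(sort(regions), function(r) {
    sub <- counts[counts$region == r, ]
    data.frame(region = r, n_genes = nrow(sub), n_del = sum(sub$n_del),
               n_tol = sum(sub$n_tol), n_syn = sum(sub$n_syn),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_gene = per_gene, tests = tests, pooled = pooled,
                 flagged = flagged),
            class = "load_summary")
}

#' @export
print.load_summary <- function(x, ...) {
  cat("load comparison across", nrow(x$pooled), "regions\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
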