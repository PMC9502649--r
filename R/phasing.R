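# Greedy read-backed phasing: heterozygous sites connected by reads form
# blocks; within a block reads are 2-coloured by agreement with the
# growing haplotype consensus. Replaces a weighted MEC solver at desk
# scale; an exhaustive 2-colouring oracle certifies it in the tests.

#' Greedy read-backed phasing of heterozygous sites
#'
#' Sites connected by at least one read form one block (connected
#' components of the read-site graph). Within a block, reads are
#' 2-coloured greedily: reads are visited in order of decreasing overlap
#' with already-phased sites (seeded by the read covering most sites) and
#' assigned to the colour whose running consensus they match; reads
#' agreeing with neither colour beyond `max_mismatch` sites are dropped
#' and reported as conflicting.
#'
#' @param obs data.frame `read_id`, `pos`, `allele` (0/1): one allele per
#'   covered heterozygous site per read.
#' @param het_sites optional integer vector of site positions; defaults
#'   to the positions observed.
#' @param max_mismatch per-read mismatch tolerance (default 1).
#' @return List of phase blocks, each
#'   `list(sites, hap1, hap2, reads_hap1, reads_hap2)` where `hap1`/`hap2`
#'   are complementary allele strings over `sites`; dropped reads are in
#'   the `conflicting` attribute.
#' @export
greedy_phase <- function(obs, het_sites = NULL, max_mismatch = 1L) {
  stopifnot(all(c("read_id", "pos", "allele") %in% names(obs)))
  sites <- sort(unique(het_sites %||% obs$pos))
  obs <- obs[obs$pos %in% sites, , drop = FALSE]
  reads <- split(obs, obs$read_id)
  read_sites <- lapply(reads, function(r) match(r$pos, sites))
  read_alleles <- lapply(reads, function(r) r$allele[order(match(r$pos, sites))])
  read_sites <- lapply(read_sites, sort)

  # union-find over sites
  parent <- seq_along(sites)
  for (rs in read_sites) {
    if (length(rs) > 1) {
      for (s in rs[-1]) {
        a <- rs[1]; while (parent[a] != a) a <- parent[a]
        b <- s; while (parent[b] != b) b <- parent[b]
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_along(sites), function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }, integer(1))

  conflicting <- character(0)
  blocks <- list()
  for (comp in unique(root)) {
    comp_sites <- which(root == comp)
    in_comp <- vapply(read_sites, function(rs) all(rs %in% comp_sites),
                      logical(1))
    rids <- names(read_sites)[in_comp]
    n_s <- length(comp_sites)
    # votes for allele of haplotype 1 at each comp site: counts of 0s, 1s
    votes0 <- votes1 <- rep(0L, n_s)
    local <- function(rs) match(rs, comp_sites)
    assigned <- stats::setNames(rep(NA_integer_, length(rids)), rids)
    remaining <- rids
    while (length(remaining)) {
      consensus <- ifelse(votes1 > votes0, 1L,
                          ifelse(votes0 > votes1, 0L, NA_integer_))
      overlap <- vapply(remaining, function(id) {
        sum(!is.na(consensus[local(read_sites[[id]])]))
      }, integer(1))
      cover <- vapply(remaining, function(id) length(read_sites[[id]]),
                      integer(1))
      pick <- remaining[order(-overlap, -cover, remaining)][1]
      rs <- local(read_sites[[pick]])
      al <- read_alleles[[pick]]
      cons <- consensus[rs]
      def <- !is.na(cons)
      d1 <- sum(def & al != cons)
      d2 <- sum(def & al == cons)
      if (min(d1, d2) > max_mismatch && any(def)) {
        conflicting <- c(conflicting, pick)
      } else {
        colr <- if (d1 <= d2) 1L else 2L
        assigned[pick] <- colr
        eff <- if (colr == 1L) al else 1L - al
        votes1[rs] <- votes1[rs] + (eff == 1L)
        votes0[rs] <- votes0[rs] + (eff == 0L)
      }
      remaining <- setdiff(remaining, pick)
    }
    # refinement: re-check every assigned read against the final
    # consensus so a conflicting read that seeded the block is still
    # caught; votes are rebuilt after each round of drops
    for (iter in 1:10) {
      consensus <- ifelse(votes1 > votes0, 1L,
                          ifelse(votes0 > votes1, 0L, NA_integer_))
      drop <- character(0)
      for (id in names(assigned)[!is.na(assigned)]) {
        rs <- local(read_sites[[id]])
        al <- read_alleles[[id]]
        cons <- consensus[rs]
        def <- !is.na(cons)
        d1 <- sum(def & al != cons)
        d2 <- sum(def & al == cons)
        if (min(d1, d2) > max_mismatch) drop <- c(drop, id)
      }
      if (!length(drop)) break
      conflicting <- c(conflicting, drop)
      assigned[drop] <- NA_integer_
      votes0 <- votes1 <- rep(0L, n_s)
      for (id in names(assigned)[!is.na(assigned)]) {
        rs <- local(read_sites[[id]])
        al <- read_alleles[[id]]
        eff <- if (assigned[[id]] == 1L) al else 1L - al
        votes1[rs] <- votes1[rs] + (eff == 1L)
        votes0[rs] <- votes0[rs] + (eff == 0L)
      }
    }
    hap1 <- ifelse(votes1 > votes0, "1", ifelse(votes0 > votes1, "0", "?"))
    hap2 <- ifelse(hap1 == "1", "0", ifelse(hap1 == "0", "1", "?"))
    blocks[[length(blocks) + 1]] <- list(
      sites = sites[comp_sites],
      hap1 = paste(hap1, collapse = ""),
      hap2 = paste(hap2, collapse = ""),
      reads_hap1 = names(assigned)[!is.na(assigned) & assigned == 1L],
      reads_hap2 = names(assigned)[!is.na(assigned) & assigned == 2L]
    )
  }
  ord <- order(vapply(blocks, function(b) min(b$sites), numeric(1)))
  blocks <- blocks[ord]
  attr(blocks, "conflicting") <- unique(conflicting)
  blocks
}

#' Assign phased blocks to the Y haplotype
#'
#' Within each block overlapping at least one significant site, the
#' haplotype carrying the male-associated allele at the majority of those
#' sites is labelled Y and its supporting reads are returned. Tied blocks
#' are excluded and reported as ambiguous.
#'
#' @param blocks output of [greedy_phase()].
#' @param male_alleles data.frame `pos`, `allele` (0/1): the
#'   male-associated allele at each significant site (see
#'   [male_associated_alleles()]).
#' @return Read bin data.frame `read_id`, `provenance` (`"phase"`), with
#'   ambiguous block indices in the `ambiguous` attribute.
#' @export
assign_y_blocks <- function(blocks, male_alleles) {
  y_reads <- character(0)
  ambiguous <- integer(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    hit <- match(b$sites, male_alleles$pos)
    use <- which(!is.na(hit))
    if (!length(use)) next
    h1 <- as.integer(strsplit(b$hap1, "")[[1]][use])
    target <- male_alleles$allele[hit[use]]
    ok <- !is.na(h1)
    m1 <- sum(h1[ok] == target[ok])
    m2 <- sum(ok) - m1
    if (m1 > m2) {
      y_reads <- c(y_reads, b$reads_hap1)
    } else if (m2 > m1) {
      y_reads <- c(y_reads, b$reads_hap2)
    } else {
      ambiguous <- c(ambiguous, i)
    }
  }
  out <- data.frame(read_id = unique(y_reads),
                    provenance = rep("phase", length(unique(y_reads))),
                    stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Male-associated allele per significant site
#'
#' The allele (0 = reference, 1 = alternate) whose frequency is higher in
#' males than in females at each significant site of an association
#' table.
#'
#' @param assocs output of [bonferroni_significant()]; only significant
#'   rows are used.
#' @return data.frame `pos`, `allele`.
#' @export
male_associated_alleles <- function(assocs) {
  sig <- assocs[assocs$significant, , drop = FALSE]
  m_tot <- sig$m_ref + sig$m_alt
  f_tot <- sig$f_ref + sig$f_alt
  m_freq <- ifelse(m_tot > 0, sig$m_alt / m_tot, NA_real_)
  f_freq <- ifelse(f_tot > 0, sig$f_alt / f_tot, NA_real_)
  data.frame(pos = sig$pos,
             allele = ifelse(!is.na(m_freq) & !is.na(f_freq) &
                               m_freq > f_freq, 1L, 0L))
}

#' Merge read bins with provenance tracking
#'
#' Union of the bins; a read appearing with more than one provenance is
#' marked `"both"`.
#'
#' @param bins list of read-bin data.frames (`read_id`, `provenance`).
#' @return A merged read bin with no duplicate ids.
#' @export
merge_read_bins <- function(bins) {
  all <- do.call(rbind, bins)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(read_id = character(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  prov <- vapply(split(all$provenance, all$read_id), function(p) {
    u <- unique(p)
    if (length(u) > 1) "both" else u
  }, character(1))
  out <- data.frame(read_id = names(prov), provenance = unname(prov),
                    stringsAsFactors = FALSE)
  out[order(out$read_id), , drop = FALSE]
}
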