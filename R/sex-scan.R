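# Sex-association scan: variant filtering, per-site Fisher tests with
# Bonferroni control, sex genotype profiles, recombinant detection,
# heterogamety classification, depth-ratio evidence and SDR delineation.

#' Configuration for the sex-association scan
#'
#' @param alpha family-wise error target for Bonferroni control.
#' @param min_quality minimum site quality (sites below are removed).
#' @param indel_exclusion_bp SNPs within this distance of an indel are
#'   removed.
#' @param depth_low_frac,depth_high_frac sites whose cohort mean depth is
#'   below/above these fractions of the genome-wide mean are removed.
#' @param het_high,het_low pooled heterozygosity thresholds separating the
#'   heterogametic (high) from the homogametic (low) sex.
#' @param missing_high one-sex missingness above this marks hemizygosity.
#' @param depth_ratio_target expected normalized depth of hemizygous
#'   sequence in its carrier sex.
#' @param depth_ratio_tol tolerance around `depth_ratio_target`.
#' @param depth_zero_max normalized depth at or below this counts as absent
#'   coverage in the non-carrier sex.
#' @param cluster_gap_bp maximum gap joining candidate sites into one
#'   interval.
#' @param min_cluster_sites minimum sites per emitted interval.
#' @param recombinant_het_threshold per-individual heterozygosity fraction
#'   (across significant sites) above which a homogametic individual is
#'   flagged as an X-Y recombinant.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05,
                        min_quality = 30,
                        indel_exclusion_bp = 5L,
                        depth_low_frac = 1 / 3,
                        depth_high_frac = 3,
                        het_high = 0.6,
                        het_low = 0.2,
                        missing_high = 0.5,
                        depth_ratio_target = 0.5,
                        depth_ratio_tol = 0.15,
                        depth_zero_max = 0.1,
                        cluster_gap_bp = 1e6,
                        min_cluster_sites = 5L,
                        recombinant_het_threshold = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (het_low >= het_high) stop("het_low must be below het_high")
  for (v in c(het_high, het_low, missing_high, recombinant_het_threshold)) {
    if (v < 0 || v > 1) stop("fraction thresholds must be in [0, 1]")
  }
  structure(as.list(environment()), class = "scan_config")
}

# cohort mean depth per site, averaged over individuals with coverage at
# the site's window; averaging zeros in would discard hemizygous sites
# whose non-carrier sex has no reads at all.
site_mean_depth <- function(gm, depth) {
  w <- depth$windows
  idx <- vapply(seq_len(nrow(gm$sites)), function(i) {
    hit <- which(w$chrom == gm$sites$chrom[i] &
                   w$start <= gm$sites$pos[i] - 1L &
                   w$end > gm$sites$pos[i] - 1L)
    if (!length(hit)) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("site(s) lacking a depth window: ",
         paste(gm$sites$chrom[bad], gm$sites$pos[bad],
               sep = ":", collapse = ", "))
  }
  vapply(idx, function(j) {
    v <- depth$values[j, ]
    v <- v[v > 0]
    if (!length(v)) 0 else mean(v)
  }, numeric(1))
}

#' Filter variants before association
#'
#' Removes sites with quality below `min_quality`, sites with more than
#' two alleles, SNPs within `indel_exclusion_bp` of an indel, and sites
#' whose cohort mean depth (over covered individuals) is below
#' `depth_low_frac` or above `depth_high_frac` of the genome-wide mean.
#'
#' @param gm a [genotype_matrix()].
#' @param depth a [depth_table()] covering every site.
#' @param indel_positions data.frame with `chrom`, `pos` of indels (may be
#'   NULL or empty).
#' @param cfg a [scan_config()].
#' @return A new, filtered `genotype_matrix`; the input is unmodified.
#' @export
filter_variants <- function(gm, depth, indel_positions = NULL,
                            cfg = scan_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(depth, "depth_table"))
  keep <- rep(TRUE, nrow(gm$sites))
  keep <- keep & !is.na(gm$sites$qual) & gm$sites$qual >= cfg$min_quality
  n_alt <- lengths(strsplit(gm$sites$alt, ",", fixed = TRUE))
  keep <- keep & (n_alt <= 1)
  if (!is.null(indel_positions) && nrow(indel_positions)) {
    near <- vapply(seq_len(nrow(gm$sites)), function(i) {
      same <- indel_positions$chrom == gm$sites$chrom[i]
      any(same & abs(indel_positions$pos - gm$sites$pos[i]) <=
            cfg$indel_exclusion_bp)
    }, logical(1))
    keep <- keep & !near
  }
  sd <- site_mean_depth(gm, depth)
  genome_mean <- mean(depth$values[depth$values > 0])
  keep <- keep & sd >= cfg$depth_low_frac * genome_mean &
    sd <= cfg$depth_high_frac * genome_mean
  subset_genotypes(gm, sites = which(keep))
}

#' Per-site association of alleles with sex (Fisher exact)
#'
#' Builds, for each site, the 2x2 table of allele counts by sex (genotype
#' code 0 contributes two reference alleles, 1 one of each, 2 two
#' alternate; missing genotypes are excluded) and computes a two-sided
#' Fisher exact p-value.
#'
#' @param gm a [genotype_matrix()] with at least one individual of each
#'   sex.
#' @return data.frame with site index, chrom, pos, the four allele counts
#'   (`m_ref`, `m_alt`, `f_ref`, `f_alt`) and `p_value`.
#' @export
associate_sex <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  is_m <- gm$individuals$sex == "M"
  is_f <- gm$individuals$sex == "F"
  if (!any(is_m) || !any(is_f)) {
    stop("association requires at least one individual of each sex")
  }
  count_alleles <- function(codes) {
    called <- codes >= 0
    c(ref = sum(2L * (codes == 0L) + (codes == 1L)),
      alt = sum(2L * (codes == 2L) + (codes == 1L)))
  }
  res <- t(vapply(seq_len(nrow(gm$sites)), function(i) {
    m <- count_alleles(gm$codes[i, is_m])
    f <- count_alleles(gm$codes[i, is_f])
    tab <- matrix(c(m, f), nrow = 2, byrow = TRUE)
    p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
    c(m, f, p)
  }, numeric(5)))
  data.frame(site = seq_len(nrow(gm$sites)), chrom = gm$sites$chrom,
             pos = gm$sites$pos, m_ref = res[, 1], m_alt = res[, 2],
             f_ref = res[, 3], f_alt = res[, 4], p_value = res[, 5],
             stringsAsFactors = FALSE)
}

#' Mark Bonferroni-significant associations
#'
#' A site is significant iff `p < alpha / m`, where `m` is the number of
#' sites tested (all rows of `assocs`), not the number of survivors.
#'
#' @param assocs output of [associate_sex()].
#' @param alpha family-wise error target.
#' @return `assocs` with a logical `significant` column and attributes
#'   `m` and `threshold`.
#' @export
bonferroni_significant <- function(assocs, alpha = 0.05) {
  m <- nrow(assocs)
  if (m < 1) stop("no sites tested")
  assocs$significant <- assocs$p_value < alpha / m
  attr(assocs, "m") <- m
  attr(assocs, "threshold") <- alpha / m
  assocs
}

#' Per-sex genotype profile over a set of sites
#'
#' Heterozygous/homozygous fractions are computed over called genotypes
#' only; missingness is reported separately over all genotypes. Cells with
#' no called genotypes are reported as `NA` (undefined), not 0.
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer site indices (non-empty).
#' @return List with `per_site` (data.frame of per-site fractions) and
#'   `pooled` (per-sex pooled fractions).
#' @export
genotype_profile <- function(gm, sites) {
  stopifnot(inherits(gm, "genotype_matrix"), length(sites) > 0)
  frac <- function(codes) {
    called <- sum(codes >= 0)
    c(het = if (called) sum(codes == 1L) / called else NA_real_,
      hom = if (called) sum(codes == 0L | codes == 2L) / called
            else NA_real_,
      missing = sum(codes < 0) / length(codes),
      called = called)
  }
  is_m <- gm$individuals$sex == "M"
  is_f <- gm$individuals$sex == "F"
  per_site <- t(vapply(sites, function(i) {
    c(frac(gm$codes[i, is_m]), frac(gm$codes[i, is_f]))
  }, numeric(8)))
  colnames(per_site) <- c(paste0("m_", c("het", "hom", "missing", "called")),
                          paste0("f_", c("het", "hom", "missing", "called")))
  per_site <- data.frame(site = sites, chrom = gm$sites$chrom[sites],
                         pos = gm$sites$pos[sites], per_site,
                         stringsAsFactors = FALSE)
  pooled <- list(
    male = frac(gm$codes[sites, is_m, drop = FALSE]),
    female = frac(gm$codes[sites, is_f, drop = FALSE])
  )
  list(per_site = per_site, pooled = pooled)
}

#' Detect X-Y recombinant individuals
#'
#' Flags homogametic-sex individuals whose personal heterozygosity
#' fraction across the significant sites exceeds
#' `recombinant_het_threshold`.
#'
#' @param gm a [genotype_matrix()].
#' @param significant_sites integer site indices (non-empty).
#' @param system_guess `"XY"` (homogametic sex is F) or `"ZW"` (M).
#' @param cfg a [scan_config()].
#' @return Character vector of flagged individual ids (possibly empty)
#'   with per-individual het fractions as the `het_fraction` attribute.
#' @export
detect_recombinants <- function(gm, significant_sites,
                                system_guess = c("XY", "ZW"),
                                cfg = scan_config()) {
  stopifnot(length(significant_sites) > 0)
  system_guess <- match.arg(system_guess)
  homo_sex <- if (system_guess == "XY") "F" else "M"
  idx <- which(gm$individuals$sex == homo_sex)
  hf <- vapply(idx, function(j) {
    codes <- gm$codes[significant_sites, j]
    called <- sum(codes >= 0)
    if (!called) return(0)
    sum(codes == 1L) / called
  }, numeric(1))
  names(hf) <- gm$individuals$id[idx]
  flagged <- names(hf)[hf > cfg$recombinant_het_threshold]
  attr(flagged, "het_fraction") <- hf
  flagged
}

#' Classify the heterogametic system from a pooled profile
#'
#' XY iff pooled male heterozygosity is at least `het_high` and female at
#' most `het_low`; ZW iff mirrored; otherwise UNDETERMINED. The profile
#' should be computed over significant sites with recombinants excluded.
#'
#' @param profile output of [genotype_profile()].
#' @param cfg a [scan_config()].
#' @return List with `call` (`"XY"`, `"ZW"` or `"UNDETERMINED"`) and the
#'   per-criterion `evidence` record.
#' @export
classify_heterogamety <- function(profile, cfg = scan_config()) {
  mh <- profile$pooled$male[["het"]]
  fh <- profile$pooled$female[["het"]]
  call <- if (!is.na(mh) && !is.na(fh) && mh >= cfg$het_high &&
              fh <= cfg$het_low) {
    "XY"
  } else if (!is.na(mh) && !is.na(fh) && fh >= cfg$het_high &&
             mh <= cfg$het_low) {
    "ZW"
  } else {
    "UNDETERMINED"
  }
  list(call = call,
       evidence = c(male_het = mh, female_het = fh,
                    het_high = cfg$het_high, het_low = cfg$het_low))
}

#' Per-window sex-normalized depth ratios
#'
#' For every window and sex: the mean over individuals of (window depth /
#' that individual's genome-wide mean depth). A diploid window is ~1; a
#' hemizygous window is ~0.5 in the carrier sex and ~0 in the other.
#'
#' @param depth a [depth_table()].
#' @param sexes named vector id -> "M"/"F" for the depth columns.
#' @return data.frame chrom, start, end, `m_ratio`, `f_ratio`.
#' @export
depth_ratio_profile <- function(depth, sexes) {
  stopifnot(inherits(depth, "depth_table"))
  ids <- colnames(depth$values)
  sx <- unname(sexes[ids])
  if (anyNA(sx)) stop("sexes missing for: ",
                      paste(ids[is.na(sx)], collapse = ", "))
  wlen <- depth$windows$end - depth$windows$start
  ind_mean <- colSums(depth$values * wlen) / sum(wlen)
  if (any(ind_mean <= 0)) {
    stop("zero genome-wide depth for: ",
         paste(ids[ind_mean <= 0], collapse = ", "))
  }
  ratios <- sweep(depth$values, 2, ind_mean, `/`)
  data.frame(chrom = depth$windows$chrom, start = depth$windows$start,
             end = depth$windows$end,
             m_ratio = rowMeans(ratios[, sx == "M", drop = FALSE]),
             f_ratio = rowMeans(ratios[, sx == "F", drop = FALSE]),
             stringsAsFactors = FALSE)
}

# gap-join site positions into candidate intervals
cluster_sites <- function(chrom, pos, gap_bp, min_sites) {
  out <- list()
  for (ch in unique(chrom)) {
    p <- sort(pos[chrom == ch])
    if (!length(p)) next
    grp <- cumsum(c(1, diff(p) > gap_bp))
    for (g in split(p, grp)) {
      if (length(g) >= min_sites) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(g) - 1L, end = max(g),
          n_sites = length(g), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0)))
  }
  do.call(rbind, out)
}

#' Delineate and classify sex-linked regions
#'
#' Candidate intervals are built by gap-joining (gaps at most
#' `cluster_gap_bp`, at least `min_cluster_sites` sites) two kinds of
#' informative sites: Bonferroni-significant sites, and sites whose
#' missingness in one sex exceeds `missing_high` (hemizygosity evidence;
#' fully hemizygous sequence yields no allelic contrast for the Fisher
#' test because the non-carrier sex has no calls at all). Each interval is
#' then labelled from the genotype profile and normalized depth ratios:
#' `X_SDR` (male het high, female het low, female depth diploid), `Y_SPECIFIC`
#' (female missingness high, male depth ~0.5, female depth ~0), the
#' mirrored `Z_SDR`/`W_SPECIFIC` classes, or `NOT_SEX_LINKED`.
#'
#' @param assocs output of [bonferroni_significant()].
#' @param profile [genotype_profile()] over all sites of the same matrix
#'   (recombinants excluded for the het evidence to be crisp).
#' @param ratios output of [depth_ratio_profile()].
#' @param cfg a [scan_config()].
#' @return data.frame of region calls with evidence columns, sorted by
#'   chrom then start.
#' @export
delineate_regions <- function(assocs, profile, ratios, cfg = scan_config()) {
  ps <- profile$per_site
  if (!identical(ps$site, assocs$site)) {
    ps <- ps[match(assocs$site, ps$site), ]
  }
  sig <- which(assocs$significant)
  hemi <- which((!is.na(ps$f_missing) & ps$f_missing > cfg$missing_high) |
                  (!is.na(ps$m_missing) & ps$m_missing > cfg$missing_high))
  cand <- list(
    assoc = cluster_sites(assocs$chrom[sig], assocs$pos[sig],
                          cfg$cluster_gap_bp, cfg$min_cluster_sites),
    hemi = cluster_sites(assocs$chrom[hemi], assocs$pos[hemi],
                         cfg$cluster_gap_bp, cfg$min_cluster_sites)
  )
  classify_one <- function(iv) {
    in_iv <- assocs$chrom == iv$chrom & assocs$pos - 1L >= iv$start &
      assocs$pos <= iv$end
    sub <- ps[in_iv, ]
    pool <- function(h, cl) {
      if (sum(cl, na.rm = TRUE) == 0) NA_real_
      else sum(h * cl, na.rm = TRUE) / sum(cl, na.rm = TRUE)
    }
    m_het <- pool(sub$m_het, sub$m_called)
    f_het <- pool(sub$f_het, sub$f_called)
    m_miss <- mean(sub$m_missing, na.rm = TRUE)
    f_miss <- mean(sub$f_missing, na.rm = TRUE)
    w <- ratios$chrom == iv$chrom & ratios$start < iv$end &
      ratios$end > iv$start
    m_depth <- stats::median(ratios$m_ratio[w])
    f_depth <- stats::median(ratios$f_ratio[w])
    tgt <- cfg$depth_ratio_target
    tol <- cfg$depth_ratio_tol
    cls <- if (!is.na(f_miss) && f_miss > cfg$missing_high &&
               !is.na(m_depth) && abs(m_depth - tgt) <= tol &&
               !is.na(f_depth) && f_depth <= cfg$depth_zero_max) {
      "Y_SPECIFIC"
    } else if (!is.na(m_miss) && m_miss > cfg$missing_high &&
               !is.na(f_depth) && abs(f_depth - tgt) <= tol &&
               !is.na(m_depth) && m_depth <= cfg$depth_zero_max) {
      "W_SPECIFIC"
    } else if (!is.na(m_het) && !is.na(f_het) && m_het >= cfg$het_high &&
               f_het <= cfg$het_low && !is.na(f_depth) &&
               abs(f_depth - 1) <= 2 * tol) {
      "X_SDR"
    } else if (!is.na(m_het) && !is.na(f_het) && f_het >= cfg$het_high &&
               m_het <= cfg$het_low && !is.na(m_depth) &&
               abs(m_depth - 1) <= 2 * tol) {
      "Z_SDR"
    } else {
      "NOT_SEX_LINKED"
    }
    p_in <- assocs$p_value[in_iv & assocs$significant]
    data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
               region_class = cls, n_sites = iv$n_sites,
               best_p = if (length(p_in)) min(p_in) else NA_real_,
               m_het = m_het, f_het = f_het, m_miss = m_miss,
               f_miss = f_miss, m_depth = m_depth, f_depth = f_depth,
               stringsAsFactors = FALSE)
  }
  calls <- list()
  for (src in names(cand)) {
    tab <- cand[[src]]
    for (i in seq_len(nrow(tab))) {
      cl <- classify_one(tab[i, ])
      # hemizygosity clusters are candidates only; keep them when they
      # classify as a hemizygous region class
      if (src == "hemi" && !cl$region_class %in% c("Y_SPECIFIC",
                                                   "W_SPECIFIC")) next
      calls[[length(calls) + 1]] <- cl
    }
  }
  if (!length(calls)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_class = character(0),
                      n_sites = integer(0), best_p = numeric(0),
                      m_het = numeric(0), f_het = numeric(0),
                      m_miss = numeric(0), f_miss = numeric(0),
                      m_depth = numeric(0), f_depth = numeric(0)))
  }
  calls <- do.call(rbind, calls)
  # drop duplicate same-class calls contained in (or equal to) another
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (i != j && keep[i] && keep[j] &&
          calls$region_class[i] == calls$region_class[j] &&
          calls$chrom[i] == calls$chrom[j] &&
          calls$start[i] >= calls$start[j] &&
          calls$end[i] <= calls$end[j] &&
          ((calls$end[i] - calls$start[i]) <
             (calls$end[j] - calls$start[j]) || j < i)) {
        keep[i] <- FALSE
      }
    }
  }
  calls <- calls[keep, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Summarize a sex-association scan
#'
#' Reports the total number of significant sites and, per region call,
#' the count and percentage (2 decimals) of significant sites inside.
#'
#' @param assocs output of [bonferroni_significant()].
#' @param calls output of [delineate_regions()].
#' @return List with `n_significant` and `intervals` (data.frame with
#'   `n_sig_inside` and `pct_of_significant`).
#' @export
summarize_scan <- function(assocs, calls) {
  n_sig <- sum(assocs$significant)
  if (is.null(calls) || nrow(calls) == 0 || n_sig == 0) {
    return(list(n_significant = n_sig,
                intervals = data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       region_class = character(0),
                                       n_sig_inside = integer(0),
                                       pct_of_significant = numeric(0))))
  }
  inside <- vapply(seq_len(nrow(calls)), function(i) {
    sum(assocs$significant & assocs$chrom == calls$chrom[i] &
          assocs$pos - 1L >= calls$start[i] & assocs$pos <= calls$end[i])
  }, numeric(1))
  list(
    n_significant = n_sig,
    intervals = data.frame(
      chrom = calls$chrom, start = calls$start, end = calls$end,
      region_class = calls$region_class, n_sig_inside = as.integer(inside),
      pct_of_significant = round(100 * inside / n_sig, 2),
      stringsAsFactors = FALSE
    )
  )
}
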