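# Variant filtering, sex association, heterogamety classification,
# recombinant detection and SDR delineation.

toy_gm <- function(sites, codes, sexes) {
  genotype_matrix(sites,
                  data.frame(id = sprintf("i%02d", seq_along(sexes)),
                             sex = sexes, stringsAsFactors = FALSE),
                  codes)
}

flat_depth <- function(chrom = "chr1", len = 1000L, ids, value = 30) {
  depth_table(data.frame(chrom = chrom, start = 0L, end = len),
              matrix(value, 1, length(ids), dimnames = list(NULL, ids)))
}

test_that("the four variant filters remove exactly the offending sites", {
  sexes <- c("M", "F")
  sites <- data.frame(
    chrom = "chr1", pos = c(10L, 50L, 100L, 150L, 200L, 300L),
    ref = "A",
    alt = c("G", "G,T", "G", "G", "G", "G"),
    qual = c(60, 60, 29, 60, 60, 60),
    stringsAsFactors = FALSE
  )
  codes <- matrix(0L, 6, 2)
  gm <- toy_gm(sites, codes, sexes)

  # quality < 30 and multi-allelic rules
  dp_flat <- depth_table(data.frame(chrom = "chr1", start = 0L, end = 400L),
                         matrix(30, 1, 2, dimnames = list(NULL,
                                                          c("i01", "i02"))))
  kept <- filter_variants(gm, dp_flat, NULL, scan_config())
  expect_identical(kept$sites$pos, c(10L, 150L, 200L, 300L))

  # depth rule: ten flat 30x windows plus one at 300x (covering pos 150)
  # and one at 5x (covering pos 200); both extremes are removed
  starts <- seq(0L, 399L, by = 40L)
  wins <- data.frame(chrom = "chr1", start = starts, end = starts + 40L)
  d <- rep(30, 10)
  d[ceiling(150 / 40)] <- 300  # window [120,160) holds pos 150
  d[ceiling(200 / 40)] <- 5    # window [160,200) holds pos 200
  dp <- depth_table(wins, matrix(rep(d, 2), 10, 2,
                                 dimnames = list(NULL, c("i01", "i02"))))
  kept2 <- filter_variants(gm, dp, NULL, scan_config())
  expect_false(any(c(150L, 200L) %in% kept2$sites$pos))
  expect_true(all(c(10L, 300L) %in% kept2$sites$pos))

  # indel exclusion: site within 5 bp removed, 6 bp kept
  indels <- data.frame(chrom = "chr1", pos = c(103L, 306L))
  kept3 <- filter_variants(gm, dp_flat, indels, scan_config())
  expect_false(100L %in% kept3$sites$pos)  # 3 bp from indel
  expect_true(300L %in% kept3$sites$pos)   # 6 bp away

  # hand application of all rules at once: quality-29 (100), triallelic
  # (50) and near-indel (one more) leave exactly 3 survivors of 6
  indels2 <- data.frame(chrom = "chr1", pos = 202L)
  kept4 <- filter_variants(gm, dp_flat, indels2, scan_config())
  expect_identical(kept4$sites$pos, c(10L, 150L, 300L))

  # site without a depth window is a hard error naming the site
  dp_short <- depth_table(data.frame(chrom = "chr1", start = 0L,
                                     end = 100L),
                          matrix(30, 1, 2,
                                 dimnames = list(NULL, c("i01", "i02"))))
  expect_error(filter_variants(gm, dp_short, NULL, scan_config()),
               "chr1:150")
})

test_that("associate_sex builds allele tables and matches the hypergeometric oracle", {
  # the frozen small-table values certify the oracle itself
  expect_equal(oracle_fisher_p(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252)
  expect_equal(oracle_fisher_p(matrix(c(4, 1, 1, 4), 2, byrow = TRUE)),
               52 / 252)
  expect_equal(oracle_fisher_p(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)

  set.seed(99)
  sexes <- c(rep("M", 4), rep("F", 4))
  for (rep in 1:25) {
    codes <- matrix(sample(c(-1L, 0L, 1L, 2L), 8 * 3, replace = TRUE), 3, 8)
    sites <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), ref = "A",
                        alt = "G", qual = 60, stringsAsFactors = FALSE)
    gm <- toy_gm(sites, codes, sexes)
    as <- associate_sex(gm)
    for (i in 1:3) {
      tab <- matrix(c(as$m_ref[i], as$m_alt[i], as$f_ref[i], as$f_alt[i]),
                    2, byrow = TRUE)
      expect_equal(as$p_value[i], oracle_fisher_p(tab), tolerance = 1e-12)
    }
  }
  gm_m <- toy_gm(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                            qual = 60),
                 matrix(0L, 1, 2), c("M", "M"))
  expect_error(associate_sex(gm_m), "each sex")
})

test_that("Bonferroni marks significance against the tested-site count", {
  mk <- function(p) data.frame(site = seq_along(p), chrom = "c", pos = seq_along(p),
                               p_value = p)
  a <- bonferroni_significant(mk(c(0.0004, rep(0.5, 99))), 0.05)
  expect_true(a$significant[1])
  b <- bonferroni_significant(mk(c(0.0006, rep(0.5, 99))), 0.05)
  expect_false(b$significant[1])
  c1 <- bonferroni_significant(mk(0.049), 0.05)
  expect_true(c1$significant[1])
  # monotone in alpha: significant at alpha stays significant at alpha' > alpha
  set.seed(5)
  p <- runif(200)^3
  for (alpha in c(0.01, 0.05)) {
    s1 <- bonferroni_significant(mk(p), alpha)$significant
    s2 <- bonferroni_significant(mk(p), alpha * 2)$significant
    expect_true(all(s2[s1]))
  }
})

test_that("genotype profiles count called genotypes only", {
  # 10 males: 3 missing, 5 het, 2 hom; 2 females with no calls at site 1
  codes <- matrix(c(rep(-1L, 3), rep(1L, 5), rep(0L, 2), -1L, -1L), 1)
  gm <- toy_gm(data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G",
                          qual = 60),
               codes, c(rep("M", 10), "F", "F"))
  pr <- genotype_profile(gm, 1L)
  expect_equal(pr$per_site$m_het, 5 / 7)
  expect_equal(pr$per_site$m_missing, 3 / 10)
  expect_true(is.na(pr$per_site$f_het))  # undefined, not zero
  # all-male-het / all-female-hom toy
  gm2 <- toy_gm(data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G",
                           qual = 60),
                matrix(c(1L, 1L, 0L, 0L), 1), c("M", "M", "F", "F"))
  pr2 <- genotype_profile(gm2, 1L)
  expect_equal(pr2$pooled$male[["het"]], 1)
  expect_equal(pr2$pooled$female[["het"]], 0)
})

test_that("recombinant females are flagged by their het fraction and exactly recovered", {
  # one female het at 69.3% of significant sites, one fully homozygous
  n_sites <- 1000
  set.seed(1)
  f1 <- ifelse(runif(n_sites) < 0.693, 1L, 0L)
  codes <- cbind(matrix(1L, n_sites, 2), f1, 0L)
  gm <- toy_gm(data.frame(chrom = "c", pos = seq_len(n_sites), ref = "A",
                          alt = "G", qual = 60),
               codes, c("M", "M", "F", "F"))
  flagged <- detect_recombinants(gm, seq_len(n_sites), "XY", scan_config())
  expect_identical(as.vector(flagged), "i03")

  co <- simulate_cohort(sim_config(seed = 31))
  gmf <- filter_variants(co$genotypes, co$depth)
  as <- bonferroni_significant(associate_sex(gmf), 0.05)
  rec <- detect_recombinants(gmf, which(as$significant), "XY",
                             scan_config())
  expect_setequal(rec, co$truth$recombinant_ids)

  # excluding recombinants can only lower the female het fraction
  sig <- which(as$significant)
  before <- genotype_profile(gmf, sig)$pooled$female[["het"]]
  gmx <- subset_genotypes(gmf, individuals = setdiff(gmf$individuals$id,
                                                     rec))
  after <- genotype_profile(gmx, sig)$pooled$female[["het"]]
  expect_lte(after, before)
})

test_that("heterogamety is called from the pooled het contrast", {
  mk_prof <- function(mh, fh) {
    list(pooled = list(male = c(het = mh), female = c(het = fh)))
  }
  expect_identical(classify_heterogamety(mk_prof(0.742, 0.071))$call, "XY")
  expect_identical(classify_heterogamety(mk_prof(0.05, 0.90))$call, "ZW")
  expect_identical(classify_heterogamety(mk_prof(0.45, 0.40))$call,
                   "UNDETERMINED")
})

test_that("depth ratios are exactly 1 for constant depth and track hemizygosity", {
  ids <- sprintf("i%02d", 1:4)
  dt <- depth_table(data.frame(chrom = "c", start = c(0L, 100L),
                               end = c(100L, 200L)),
                    matrix(25, 2, 4, dimnames = list(NULL, ids)))
  sexes <- stats::setNames(c("M", "M", "F", "F"), ids)
  r <- depth_ratio_profile(dt, sexes)
  expect_equal(r$m_ratio, c(1, 1))
  expect_equal(r$f_ratio, c(1, 1))

  co <- simulate_cohort(sim_config(seed = 13, mean_depth = 30))
  sex_map <- stats::setNames(co$genotypes$individuals$sex,
                             co$genotypes$individuals$id)
  rr <- depth_ratio_profile(co$depth, sex_map)
  hemi <- rr$chrom == "chr7" & rr$start >= 7.2e6 & rr$end <= 7.8e6
  expect_true(all(abs(rr$m_ratio[hemi] - 0.5) <= 0.15))
  expect_true(all(rr$f_ratio[hemi] <= 0.05))
  x_only <- rr$chrom == "chr7" & rr$start >= 6.4e6 & rr$end <= 7.1e6
  expect_true(all(abs(rr$f_ratio[x_only] - 1) <= 0.3))

  dt0 <- depth_table(data.frame(chrom = "c", start = 0L, end = 100L),
                     matrix(c(10, 0), 1, 2,
                            dimnames = list(NULL, c("a", "b"))))
  expect_error(depth_ratio_profile(dt0, c(a = "M", b = "F")),
               "zero genome-wide depth")
})

test_that("delineation recovers planted regions and is sex-label symmetric", {
  co <- simulate_cohort(sim_config(seed = 17))
  run_scan <- function(gm, depth) {
    cfg <- scan_config()
    gmf <- filter_variants(gm, depth, NULL, cfg)
    as <- bonferroni_significant(associate_sex(gmf), cfg$alpha)
    sig <- which(as$significant)
    raw <- genotype_profile(gmf, sig)
    guess <- if (isTRUE(raw$pooled$male[["het"]] >=
                        raw$pooled$female[["het"]])) "XY" else "ZW"
    rec <- detect_recombinants(gmf, sig, guess, cfg)
    gmu <- subset_genotypes(gmf, individuals = setdiff(gmf$individuals$id,
                                                       rec))
    asu <- bonferroni_significant(associate_sex(gmu), cfg$alpha)
    prof <- genotype_profile(gmu, seq_len(nrow(gmu$sites)))
    sexes <- stats::setNames(gm$individuals$sex, gm$individuals$id)
    ratios <- depth_ratio_profile(depth, sexes)
    list(assocs = asu, calls = delineate_regions(asu, prof, ratios, cfg))
  }
  res <- run_scan(co$genotypes, co$depth)
  xc <- res$calls[res$calls$region_class == "X_SDR", ]
  expect_identical(nrow(xc), 1L)
  expect_gte(interval_jaccard(c(xc$start, xc$end), co$truth$sdr_interval),
             0.8)
  yc <- res$calls[res$calls$region_class == "Y_SPECIFIC", ]
  expect_identical(nrow(yc), 1L)
  expect_gte(interval_jaccard(c(yc$start, yc$end),
                              co$truth$y_specific_interval), 0.8)

  # swap every sex label: X_SDR -> Z_SDR, Y_SPECIFIC -> W_SPECIFIC,
  # identical p-values
  gm_sw <- co$genotypes
  gm_sw$individuals$sex <- ifelse(gm_sw$individuals$sex == "M", "F", "M")
  res_sw <- run_scan(gm_sw, co$depth)
  expect_identical(sort(res_sw$calls$region_class),
                   sort(chartr("XY", "ZW",
                               sub("Y_SPECIFIC", "W_SPECIFIC",
                                   sub("X_SDR", "Z_SDR",
                                       res$calls$region_class)))))
  expect_equal(res_sw$assocs$p_value, res$assocs$p_value)

  # a lone significant site below min_cluster_sites emits nothing
  assocs1 <- data.frame(site = 1L, chrom = "c", pos = 100L, m_ref = 10,
                        m_alt = 10, f_ref = 20, f_alt = 0,
                        p_value = 1e-9, significant = TRUE)
  prof1 <- genotype_profile(
    toy_gm(data.frame(chrom = "c", pos = 100L, ref = "A", alt = "G",
                      qual = 60),
           matrix(c(1L, 0L), 1), c("M", "F")), 1L)
  rat1 <- data.frame(chrom = "c", start = 0L, end = 200L, m_ratio = 1,
                     f_ratio = 1)
  expect_identical(nrow(delineate_regions(assocs1, prof1, rat1,
                                          scan_config())), 0L)
})

test_that("a hemizygous contig with high female missingness is called Y-specific", {
  # mirrors the male-reference pattern: most genotypes missing in
  # females, males homozygous, male depth ratio ~ 0.5
  set.seed(8)
  n_sites <- 12
  nm <- nf <- 30
  codes <- cbind(matrix(2L, n_sites, nm),
                 matrix(ifelse(runif(n_sites * nf) < 0.7336, -1L, 0L),
                        n_sites, nf))
  sites <- data.frame(chrom = "ctg9", pos = seq(1000L, by = 1000L,
                                                length.out = n_sites),
                      ref = "A", alt = "G", qual = 60,
                      stringsAsFactors = FALSE)
  gm <- toy_gm(sites, codes, c(rep("M", nm), rep("F", nf)))
  as <- bonferroni_significant(associate_sex(gm), 0.05)
  prof <- genotype_profile(gm, seq_len(n_sites))
  rat <- data.frame(chrom = "ctg9", start = 0L, end = 20000L,
                    m_ratio = 0.51, f_ratio = 0.02)
  calls <- delineate_regions(as, prof, rat, scan_config())
  expect_identical(calls$region_class, "Y_SPECIFIC")
})

test_that("scan summaries report interval percentages to two decimals", {
  empty <- summarize_scan(
    data.frame(site = 1L, chrom = "c", pos = 1L, p_value = 0.5,
               significant = FALSE),
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               region_class = character(0)))
  expect_identical(empty$n_significant, 0L)
  expect_identical(nrow(empty$intervals), 0L)
})
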