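#' Configuration for the synthetic resequencing cohort
#'
#' Defines the diploid population the generator emulates: `n_males` +
#' `n_females` individuals, a recombination-suppressed sex-determination
#' region (SDR) on one chromosome, and a hemizygous Y- (or W-) specific
#' segment inside it. Defaults mirror a willow-style resequencing design:
#' 30 individuals per sex at ~32x coverage, an SDR between 6.39 and 8.73 Mb
#' of a 12-Mb sex chromosome, and roughly one in ten homogametic
#' individuals carrying a recombined SDR haplotype.
#'
#' @param seed integer seed; identical config + seed gives identical output.
#' @param n_males,n_females cohort sizes.
#' @param chrom_lengths named vector, chromosome name -> length in bp.
#' @param sdr_chrom name of the sex chromosome.
#' @param sdr_interval 0-based half-open interval of the SDR.
#' @param system `"XY"` (males heterogametic) or `"ZW"` (females).
#' @param y_specific_interval half-open interval inside `sdr_interval` that
#'   is hemizygous in the heterogametic sex (Y- or W-specific).
#' @param snp_rate expected segregating SNPs per bp.
#' @param mean_depth expected reads per base per individual.
#' @param depth_dispersion extra-variance coefficient a of the
#'   negative-binomial depth law, `var = m + a * m^2`.
#' @param recombinant_fraction probability that a homogametic individual
#'   carries the opposite SDR haplotype pattern (X-Y recombinant).
#' @param gametolog_ks_target expected synonymous divergence of planted
#'   X-Y gene pairs (used by downstream fixtures).
#' @param ltr_ages insertion ages (years) for planted LTR elements.
#' @param mu substitution rate per site per year.
#' @param kappa transition/transversion rate ratio for sequence fixtures.
#' @param read_length simulated read length in bp.
#' @param window_size depth-table window size in bp.
#' @param genotype_error probability a simulated genotype call is replaced
#'   by a random different code (miscall noise).
#' @param missing_rate probability a genotype call is dropped to missing
#'   (outside the hemizygous interval, which has its own missingness law).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_males = 30L,
                       n_females = 30L,
                       chrom_lengths = c(chr1 = 4e6, chr7 = 12e6),
                       sdr_chrom = "chr7",
                       sdr_interval = c(6.39e6, 8.73e6),
                       system = c("XY", "ZW"),
                       y_specific_interval = c(7.2e6, 7.8e6),
                       snp_rate = 5e-5,
                       mean_depth = 32,
                       depth_dispersion = 0.1,
                       recombinant_fraction = 0.1,
                       gametolog_ks_target = 0.033,
                       ltr_ages = c(1e6, 5e6, 1e7, 2e7),
                       mu = 2.5e-9,
                       kappa = 2.0,
                       read_length = 3000L,
                       window_size = 50000L,
                       genotype_error = 0.01,
                       missing_rate = 0.02) {
  system <- match.arg(system)
  if (n_males + n_females <= 0) stop("zero-length cohort")
  if (!sdr_chrom %in% names(chrom_lengths)) {
    stop("sdr_chrom must be one of chrom_lengths")
  }
  if (sdr_interval[2] <= sdr_interval[1]) stop("sdr_interval is empty")
  if (sdr_interval[1] < 0 || sdr_interval[2] > chrom_lengths[[sdr_chrom]]) {
    stop("sdr_interval outside chromosome")
  }
  if (y_specific_interval[1] < sdr_interval[1] ||
      y_specific_interval[2] > sdr_interval[2]) {
    stop("y_specific_interval must lie within sdr_interval")
  }
  if (recombinant_fraction < 0 || recombinant_fraction > 1) {
    stop("recombinant_fraction must be in [0, 1]")
  }
  if (mu <= 0) stop("mu must be positive")
  structure(
    list(seed = as.integer(seed), n_males = as.integer(n_males),
         n_females = as.integer(n_females), chrom_lengths = chrom_lengths,
         sdr_chrom = sdr_chrom, sdr_interval = sdr_interval, system = system,
         y_specific_interval = y_specific_interval, snp_rate = snp_rate,
         mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         recombinant_fraction = recombinant_fraction,
         gametolog_ks_target = gametolog_ks_target, ltr_ages = ltr_ages,
         mu = mu, kappa = kappa, read_length = as.integer(read_length),
         window_size = as.integer(window_size),
         genotype_error = genotype_error, missing_rate = missing_rate),
    class = "sim_config"
  )
}

#' Simulate a sexed resequencing cohort with a planted SDR
#'
#' Generates genotypes, a per-window depth table and the planted truth for
#' a diploid population. Autosomal sites segregate under Hardy-Weinberg
#' independently of sex. Inside the SDR, heterogametic-sex individuals are
#' heterozygous at diagnostic sites while the homogametic sex is
#' homozygous (pattern mirrored for ZW); a random subset of homogametic
#' individuals (probability `recombinant_fraction`) carries the swapped
#' haplotype pattern. Inside the hemizygous interval, homogametic-sex
#' genotypes are missing by construction and heterogametic-sex depth has
#' expectation `mean_depth / 2`; homogametic depth there is zero.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `depth` ([depth_table()]) and `truth` (planted intervals, system,
#'   recombinant ids and per-site classes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_males
  nf <- config$n_females
  ids <- c(sprintf("M%02d", seq_len(nm)), sprintf("F%02d", seq_len(nf)))
  sex <- c(rep("M", nm), rep("F", nf))
  individuals <- data.frame(id = ids, sex = sex, stringsAsFactors = FALSE)

  hetero_sex <- if (config$system == "XY") "M" else "F"
  homo_sex <- if (config$system == "XY") "F" else "M"
  homo_idx <- which(sex == homo_sex)
  hetero_idx <- which(sex == hetero_sex)
  recomb <- homo_idx[runif(length(homo_idx)) < config$recombinant_fraction]

  # --- sites -----------------------------------------------------------
  site_list <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    n <- rbinom(1L, as.integer(len), config$snp_rate)
    pos <- sort(sample.int(len, n))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  n_sites <- nrow(sites)
  alle <- t(vapply(seq_len(n_sites),
                   function(i) sample(DNA_BASES, 2L), character(2)))
  sites$ref <- alle[, 1]
  sites$alt <- alle[, 2]
  sites$qual <- round(runif(n_sites, 60, 900), 1)

  on_sdr <- sites$chrom == config$sdr_chrom
  p0 <- sites$pos - 1L  # 0-based
  in_sdr <- on_sdr & p0 >= config$sdr_interval[1] & p0 < config$sdr_interval[2]
  in_hemi <- on_sdr & p0 >= config$y_specific_interval[1] &
    p0 < config$y_specific_interval[2]
  site_class <- ifelse(in_hemi, "Y_SPECIFIC",
                       ifelse(in_sdr, "SDR_DIAGNOSTIC", "AUTOSOMAL"))

  # --- genotypes -------------------------------------------------------
  n_ind <- nm + nf
  codes <- matrix(0L, n_sites, n_ind)
  auto <- which(site_class == "AUTOSOMAL")
  if (length(auto)) {
    p <- runif(length(auto), 0.05, 0.95)
    codes[auto, ] <- matrix(
      rbinom(length(auto) * n_ind, 2L, rep(p, n_ind)),
      nrow = length(auto)
    )
  }
  diag_sites <- which(site_class == "SDR_DIAGNOSTIC")
  if (length(diag_sites)) {
    codes[diag_sites, hetero_idx] <- 1L
    codes[diag_sites, homo_idx] <- 0L
    if (length(recomb)) codes[diag_sites, recomb] <- 1L
  }
  hemi_sites <- which(site_class == "Y_SPECIFIC")
  if (length(hemi_sites)) {
    codes[hemi_sites, hetero_idx] <- 2L  # hemizygous alt reads as hom-alt
    codes[hemi_sites, homo_idx] <- -1L
  }

  # miscall / dropout noise, everywhere except the hemizygous rows (their
  # missingness law is structural, not technical)
  noisy <- which(site_class != "Y_SPECIFIC")
  if (length(noisy) && (config$genotype_error > 0 || config$missing_rate > 0)) {
    n_cell <- length(noisy) * n_ind
    u <- runif(n_cell)
    err <- u < config$genotype_error
    mis <- !err & u < config$genotype_error + config$missing_rate
    if (any(err)) {
      cur <- codes[noisy, ][err]
      shift <- sample.int(2L, sum(err), replace = TRUE)
      codes[noisy, ][err] <- (cur + shift) %% 3L
    }
    if (any(mis)) codes[noisy, ][mis] <- -1L
  }

  gm <- genotype_matrix(sites, individuals, codes)

  # --- depth -----------------------------------------------------------
  win_list <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = config$window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + config$window_size, len),
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  # fraction of each window inside the hemizygous interval
  hemi_frac <- ifelse(
    windows$chrom == config$sdr_chrom,
    pmax(0, pmin(windows$end, config$y_specific_interval[2]) -
           pmax(windows$start, config$y_specific_interval[1])) /
      (windows$end - windows$start),
    0
  )
  m <- config$mean_depth
  size <- 1 / config$depth_dispersion
  mu_mat <- outer(hemi_frac, ifelse(sex == hetero_sex, 1, 0),
                  function(f, is_het) m * (1 - f) + is_het * (m / 2) * f)
  vals <- matrix(rnbinom(length(mu_mat), size = size, mu = mu_mat),
                 nrow = nrow(windows))
  colnames(vals) <- ids
  depth <- depth_table(windows, vals)

  truth <- list(
    sdr_interval = config$sdr_interval,
    y_specific_interval = config$y_specific_interval,
    system = config$system,
    recombinant_ids = ids[recomb],
    site_class = site_class
  )
  list(genotypes = gm, depth = depth, truth = truth)
}
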