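# Sequence-level fixtures: gametolog CDS pairs, LTR arm pairs, reads and a
# full Y-identification scenario, all with planted truth.

# codon prefixes whose third position is 4-fold degenerate and whose first
# two positions admit no synonymous change; every such codon contributes
# exactly one NG86 synonymous site, so third-position Jukes-Cantor
# divergence d yields expected Ks = d with Ka = 0.
FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "TC")

#' Simulate X-Y gametolog coding-sequence pairs at a target Ks
#'
#' Each pair starts from a common ancestral CDS (`ATG` + codons drawn from
#' 4-fold-degenerate families, hence no internal stops) and the Y copy is
#' diverged by a Jukes-Cantor process at third codon positions calibrated
#' so that the expected NG86 synonymous divergence equals `ks_target`;
#' nonsynonymous sites are untouched (planted Ka = 0).
#'
#' @param n_pairs number of pairs.
#' @param cds_length CDS length in bp, divisible by 3.
#' @param ks_target expected synonymous divergence (substitutions per
#'   synonymous site).
#' @param seed integer seed.
#' @return A list of length `n_pairs`; each element is
#'   `list(x = , y = , true_ks = )` with `x`/`y` character CDS.
#' @export
simulate_gametolog_pairs <- function(n_pairs, cds_length, ks_target,
                                     seed = 1L) {
  if (cds_length %% 3 != 0) stop("cds_length must be divisible by 3")
  if (ks_target < 0 || !is.finite(ks_target)) stop("ks_target must be >= 0")
  if (ks_target >= 5) {
    stop("ks_target too large: the divergence correction is undefined ",
         "at this saturation level")
  }
  set.seed(seed)
  n_codons <- cds_length / 3
  # per-site probability of an observed difference under JC at divergence d
  p_diff <- 0.75 * (1 - exp(-4 * ks_target / 3))
  lapply(seq_len(n_pairs), function(i) {
    prefixes <- sample(FOURFOLD_PREFIXES, n_codons - 1, replace = TRUE)
    thirds <- sample(DNA_BASES, n_codons - 1, replace = TRUE)
    x_codons <- c("ATG", paste0(prefixes, thirds))
    y_thirds <- thirds
    hit <- runif(n_codons - 1) < p_diff
    if (any(hit)) {
      y_thirds[hit] <- vapply(thirds[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    y_codons <- c("ATG", paste0(prefixes, y_thirds))
    list(x = paste(x_codons, collapse = ""),
         y = paste(y_codons, collapse = ""),
         true_ks = ks_target)
  })
}

# K2P substitution probabilities after expected `d` substitutions per site
# with transition/transversion rate ratio kappa: returns c(same, ts, tv_each)
k2p_probs <- function(d, kappa) {
  beta_t <- d / (kappa + 2)
  alpha_t <- kappa * beta_t
  p_ts <- 0.25 + 0.25 * exp(-4 * beta_t) - 0.5 * exp(-2 * (alpha_t + beta_t))
  p_tv <- 0.25 - 0.25 * exp(-4 * beta_t)
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

# evolve a character-vector sequence along one branch of expected length d
evolve_k2p <- function(bases, d, kappa) {
  pr <- k2p_probs(d, kappa)
  fate <- sample.int(4L, length(bases), replace = TRUE,
                     prob = c(pr["same"], pr["ts"], pr["tv"], pr["tv"]))
  out <- bases
  ts <- fate == 2L
  out[ts] <- TRANSITION_OF[bases[ts]]
  tv <- fate >= 3L
  if (any(tv)) {
    out[tv] <- vapply(seq_len(sum(tv)), function(i) {
      b <- bases[tv][i]
      choices <- setdiff(DNA_BASES, c(b, TRANSITION_OF[[b]]))
      choices[fate[tv][i] - 2L]
    }, character(1))
  }
  out
}

#' Simulate paired-arm LTR retrotransposons of known insertion age
#'
#' Each element's two long terminal repeats descend from one ancestral arm
#' (identical at insertion) and accumulate substitutions independently for
#' `age` years per lineage at rate `mu` per site per year, with transitions
#' favoured by `kappa`; the expected total arm divergence is `2 * mu * age`.
#'
#' @param ages vector of insertion ages in years (>= 0).
#' @param mu substitution rate per site per year.
#' @param arm_length arm length in bp.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return A list of elements `list(id, arm5, arm3, true_age)`.
#' @export
simulate_ltr_elements <- function(ages, mu = 2.5e-9, arm_length = 5000L,
                                  kappa = 2.0, seed = 1L) {
  if (any(ages < 0)) stop("ages must be >= 0")
  if (arm_length <= 0) stop("arm_length must be positive")
  if (mu <= 0) stop("mu must be positive")
  set.seed(seed)
  lapply(seq_along(ages), function(i) {
    anc <- sample(DNA_BASES, arm_length, replace = TRUE)
    d <- mu * ages[i]
    list(id = sprintf("ltr%03d", i),
         arm5 = paste(evolve_k2p(anc, d, kappa), collapse = ""),
         arm3 = paste(evolve_k2p(anc, d, kappa), collapse = ""),
         true_age = ages[i])
  })
}

#' Simulate error-free reads from a sequence set
#'
#' Uniform start positions, expected per-base coverage equal to `depth`;
#' each read records its source sequence and coordinates for truth
#' tracking.
#'
#' @param genome named character vector (or `DNAStringSet`) of source
#'   sequences.
#' @param read_length read length in bp; must not exceed the shortest
#'   source sequence.
#' @param depth expected fold-coverage per source sequence.
#' @param seed integer seed.
#' @return A list with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `source`, `start`, `end`; 1-based inclusive).
#' @export
simulate_reads <- function(genome, read_length, depth, seed = 1L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0) stop("empty genome")
  lens <- nchar(genome)
  if (read_length > min(lens)) {
    stop("read_length exceeds the shortest source sequence")
  }
  set.seed(seed)
  out <- lapply(names(genome), function(nm) {
    len <- lens[[nm]]
    n_reads <- round(depth * len / read_length)
    if (n_reads == 0) {
      return(list(reads = character(0),
                  truth = data.frame(read_id = character(0),
                                     source = character(0),
                                     start = integer(0), end = integer(0))))
    }
    starts <- sample.int(len - read_length + 1L, n_reads, replace = TRUE)
    ids <- sprintf("%s_r%04d", nm, seq_len(n_reads))
    list(
      reads = stats::setNames(
        substring(genome[[nm]], starts, starts + read_length - 1L), ids),
      truth = data.frame(read_id = ids, source = nm, start = starts,
                         end = starts + read_length - 1L,
                         stringsAsFactors = FALSE)
    )
  })
  list(reads = do.call(c, lapply(out, `[[`, "reads")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Simulate a complete Y-read identification scenario
#'
#' Builds an X haplotype and a Y haplotype (the X backbone plus diagnostic
#' SNP alleles and a unique Y-specific insert), per-individual genome
#' sequences for a sexed cohort (males carry the Y haplotype, everyone
#' carries an X copy with private SNPs), long reads from one focal male,
#' and the read-to-site allele observation table used by read-backed
#' phasing. All truth needed for recall/precision evaluation is returned.
#'
#' @param seed integer seed.
#' @param n_males,n_females cohort sizes for the k-mer catalog.
#' @param x_length X backbone length (bp).
#' @param insert_length,insert_pos size and 1-based backbone position of
#'   the Y-specific insert.
#' @param n_het_sites number of X/Y diagnostic SNPs on the backbone.
#' @param read_length,depth read simulation parameters for the focal male.
#' @param private_snp_rate per-bp rate of individual-private SNPs on X
#'   copies (k-mer background diversity).
#' @return A list: `reads`, `read_truth`, `obs` (read_id, pos, allele),
#'   `het_sites` (pos, x_allele, y_allele), `y_read_ids`,
#'   `insert_interval` (1-based on the Y haplotype), `cohort_seqs`
#'   (named list id -> character vector), `sexes` (named M/F vector),
#'   `x_hap`, `y_hap`.
#' @export
simulate_y_scenario <- function(seed = 1L, n_males = 30L, n_females = 30L,
                                x_length = 20000L, insert_length = 4000L,
                                insert_pos = 10000L, n_het_sites = 20L,
                                read_length = 3000L, depth = 10,
                                private_snp_rate = 5e-4) {
  set.seed(seed)
  x_hap <- random_dna(x_length)
  insert <- random_dna(insert_length)

  # diagnostic het sites, roughly evenly spread along the backbone
  spacing <- x_length / (n_het_sites + 1)
  pos <- round(spacing * seq_len(n_het_sites) +
                 runif(n_het_sites, -spacing / 4, spacing / 4))
  pos <- sort(unique(pmin(pmax(pos, 1L), x_length)))
  x_allele <- substring(x_hap, pos, pos)
  y_allele <- vapply(x_allele, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)

  y_backbone <- x_hap
  for (i in seq_along(pos)) {
    substr(y_backbone, pos[i], pos[i]) <- y_allele[i]
  }
  y_hap <- paste0(substring(y_backbone, 1L, insert_pos - 1L), insert,
                  substring(y_backbone, insert_pos, x_length))

  mutate_private <- function(s, rate) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0) return(s)
    at <- sample.int(n, k)
    for (p in at) {
      substr(s, p, p) <- sample(setdiff(DNA_BASES, substring(s, p, p)), 1L)
    }
    s
  }
  ids <- c(sprintf("M%02d", seq_len(n_males)),
           sprintf("F%02d", seq_len(n_females)))
  sexes <- stats::setNames(c(rep("M", n_males), rep("F", n_females)), ids)
  cohort_seqs <- lapply(ids, function(id) {
    xs <- mutate_private(x_hap, private_snp_rate)
    if (sexes[[id]] == "M") c(xs, y_hap) else xs
  })
  names(cohort_seqs) <- ids

  sim <- simulate_reads(c(X = x_hap, Y = y_hap), read_length, depth,
                        seed = child_seed(seed, 101L))
  # map het sites onto each haplotype's own coordinates
  y_pos <- ifelse(pos >= insert_pos, pos + insert_length, pos)
  obs <- do.call(rbind, lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    if (tr$source == "X") {
      hit <- which(pos >= tr$start & pos <= tr$end)
      if (!length(hit)) return(NULL)
      data.frame(read_id = tr$read_id, pos = pos[hit], allele = 0L,
                 stringsAsFactors = FALSE)
    } else {
      hit <- which(y_pos >= tr$start & y_pos <= tr$end)
      if (!length(hit)) return(NULL)
      data.frame(read_id = tr$read_id, pos = pos[hit], allele = 1L,
                 stringsAsFactors = FALSE)
    }
  }))
  list(reads = sim$reads, read_truth = sim$truth, obs = obs,
       het_sites = data.frame(pos = pos, x_allele = x_allele,
                              y_allele = y_allele, stringsAsFactors = FALSE),
       y_read_ids = sim$truth$read_id[sim$truth$source == "Y"],
       insert_interval = c(insert_pos, insert_pos + insert_length - 1L),
       cohort_seqs = cohort_seqs, sexes = sexes,
       x_hap = x_hap, y_hap = y_hap)
}
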