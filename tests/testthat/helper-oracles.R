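# Independent oracles used to certify the implementation on small
# instances. These deliberately avoid the package's own code paths.

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# fixed margins, with the standard "sum of probabilities <= observed"
# rule (numerical ties included at relative tolerance 1e-7, the
# convention for tied tables).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# NG86 pathway oracle: enumerate every ordering of the differing codon
# positions explicitly, translate each single step with the genetic code,
# and average synonymous/nonsynonymous step counts over stop-free paths.
oracle_codon_diffs <- function(c1, c2) {
  code <- as.list(Biostrings::GENETIC_CODE)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  all_orders <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  sd <- nd <- 0; n_ok <- 0
  for (ord in all_orders(pos)) {
    cur <- c1; s <- ns <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) { sd <- sd + s; nd <- nd + ns; n_ok <- n_ok + 1 }
  }
  if (!n_ok) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd / n_ok, nd = nd / n_ok)
}

# per-codon NG86 site counts (stop-excluded denominators), from scratch
oracle_codon_sites <- function(codon) {
  code <- as.list(Biostrings::GENETIC_CODE)
  s <- 0
  for (p in 1:3) {
    syn <- nonstop <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substring(codon, p, p))) {
      mut <- codon
      substring(mut, p, p) <- b
      if (code[[mut]] == "*") next
      nonstop <- nonstop + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  s
}

# Exhaustive optimal 2-colouring (minimum-error-correction) phasing
# oracle for one connected instance: returns the best achievable total
# conflict count and the majority haplotype under an optimal colouring.
oracle_phase <- function(obs, sites) {
  rids <- unique(obs$read_id)
  n <- length(rids)
  best_cost <- Inf
  best_hap <- NULL
  read_idx <- split(seq_len(nrow(obs)), obs$read_id)[rids]
  for (mask in 0:(2^(n - 1) - 1)) {
    colr <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    votes1 <- votes0 <- numeric(length(sites))
    for (ri in seq_len(n)) {
      rows <- read_idx[[ri]]
      si <- match(obs$pos[rows], sites)
      al <- obs$allele[rows]
      eff <- if (colr[ri] == 1L) al else 1L - al
      votes1[si] <- votes1[si] + (eff == 1L)
      votes0[si] <- votes0[si] + (eff == 0L)
    }
    cost <- sum(pmin(votes0, votes1))
    if (cost < best_cost) {
      best_cost <- cost
      best_hap <- ifelse(votes1 > votes0, "1",
                         ifelse(votes0 > votes1, "0", "?"))
    }
  }
  list(cost = best_cost, hap = paste(best_hap, collapse = ""))
}

# all sense codons of the standard code
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

flip_hap <- function(h) {
  chartr("01", "10", h)
}
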