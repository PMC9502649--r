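# Alignment, reciprocal best hits, NG86 Ka/Ks, strata permutation test,
# K2P dating, tandem/pseudogene/classification calls.

test_that("global alignment scores and identity behave as specified", {
  id <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(id$identity, 1)
  expect_equal(id$score, 8)
  expect_false(grepl("-", id$a_aln))

  g <- global_align("ACGT", "ACT", match = 1, mismatch = -1, gap = -1)
  expect_equal(g$score, 2)
  expect_equal(nchar(g$a_aln) -
                 sum(strsplit(g$a_aln, "")[[1]] != "-" &
                       strsplit(g$b_aln, "")[[1]] != "-"), 1)

  set.seed(3)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("reciprocal best hits equal a brute-force all-pairs check", {
  set.seed(14)
  base <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  mutate <- function(s, k) {
    at <- sample(nchar(s), k)
    for (p in at) substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    substring(s, p, p)), 1)
    s
  }
  set_a <- stats::setNames(base, sprintf("a%d", 1:5))
  set_b <- stats::setNames(vapply(base, mutate, character(1), k = 5),
                           sprintf("b%d", 1:5))
  rbh <- reciprocal_best_hits(set_a, set_b, min_score = 10)
  # brute force with the package's scorer but independent best-pair logic
  sc <- sapply(names(set_b), function(jb) {
    sapply(names(set_a), function(ia) {
      global_align(set_a[[ia]], set_b[[jb]])$score
    })
  })
  expected <- list()
  for (ia in rownames(sc)) {
    jb <- colnames(sc)[which.max(sc[ia, ])]
    if (rownames(sc)[which.max(sc[, jb])] == ia && sc[ia, jb] >= 10) {
      expected[[length(expected) + 1]] <- c(ia, jb)
    }
  }
  expect_identical(nrow(rbh), length(expected))
  for (pr in expected) expect_true(any(rbh$a == pr[1] & rbh$b == pr[2]))

  # identical sets map to themselves
  self <- reciprocal_best_hits(set_a, stats::setNames(base,
                                                      sprintf("c%d", 1:5)))
  expect_identical(self$b, sub("a", "c", self$a))

  # reciprocity: a1's best is b1 but b1's best is a2 -> no pair for a1
  a1 <- mutate(base[1], 8)
  one_way <- reciprocal_best_hits(c(a1 = a1, a2 = base[1]),
                                  c(b1 = mutate(base[1], 2)))
  expect_false("a1" %in% one_way$a)
  expect_true("a2" %in% one_way$a)
})

test_that("NG86 reproduces hand-enumerated values and the pathway oracle", {
  p0 <- ng86_ka_ks("ATGGCT", "ATGGCT")
  expect_equal(p0$Ks, 0)
  expect_equal(p0$Ka, 0)

  # ten lysine codons, one synonymous third-position change
  x <- paste(rep("AAA", 10), collapse = "")
  y <- paste(c(rep("AAA", 9), "AAG"), collapse = "")
  r <- ng86_ka_ks(x, y)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 10 / 3)
  expect_equal(r$ps, 0.3)
  expect_equal(r$Ks, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(r$Ka, 0)

  # saturation is flagged, not silently corrected
  sat <- ng86_ka_ks("AAA", "AAG")
  expect_true(sat$saturated)
  expect_true(is.na(sat$Ks))

  # random sample of <=2-difference codon pairs against the oracle
  set.seed(20)
  sc <- sense_codons()
  for (rep in 1:80) {
    c1 <- sample(sc, 1)
    c2 <- sample(sc, 1)
    if (sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]) > 2) next
    r2 <- ng86_ka_ks(c1, c2)
    o <- oracle_codon_diffs(c1, c2)
    if (anyNA(o)) next
    expect_equal(r2$Sd, o[["sd"]], tolerance = 1e-12)
    expect_equal(r2$Nd, o[["nd"]], tolerance = 1e-12)
    expect_equal(r2$S, (oracle_codon_sites(c1) + oracle_codon_sites(c2)) / 2,
                 tolerance = 1e-12)
  }
  # gapped codons are excluded from the counts
  g <- ng86_ka_ks("ATG---AAA", "ATGGCTAAG")
  expect_equal(g$Sd, 1)
})

test_that("codon alignment back-threads indels onto codon boundaries", {
  x <- "ATGGCTGCAACTGTT"        # M A A T V
  y <- "ATGGCTACTGTT"           # M A T V (one codon deleted)
  al <- align_codons(x, y)
  expect_identical(nchar(al$x), nchar(al$y))
  expect_identical(nchar(al$x) %% 3L, 0L)
  expect_identical(gsub("-", "", al$y), y)
  r <- ng86_ka_ks(al$x, al$y)
  expect_equal(r$Ks, 0)  # remaining codons identical
})

test_that("the strata permutation test calibrates against exhaustive enumeration", {
  # constant Ks: every permutation ties the observed statistic
  const <- strata_test(1:10 * 100, rep(0.05, 10), n_perm = 200, seed = 1)
  expect_gt(const$p_value, 0.05)
  expect_length(const$breakpoints, 0)

  # planted two-level step is found near the true change point
  set.seed(33)
  hits <- 0
  for (s in 1:10) {
    ks <- c(rnorm(10, 0.02, 0.01), rnorm(10, 0.10, 0.01))
    st <- strata_test(1:20 * 1e5, ks, n_perm = 500, seed = s)
    if (st$p_value < 0.05 &&
        abs(st$breakpoints[1] - 10.5e5) <= 2e5) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # 8-point instance: Monte-Carlo p within 3 SE of full enumeration
  set.seed(7)
  ks8 <- rnorm(8, 0.05, 0.02)
  pos8 <- 1:8 * 10
  stat_of <- function(v) abs(mean(v[1:4]) - mean(v[5:8]))
  # enumerate all 8! orderings via recursive index permutations
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (r in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    }
    out
  }
  idx <- all_perms(1:8)
  obs <- stat_of(ks8)
  exact <- mean(vapply(idx, function(o) stat_of(ks8[o]), numeric(1)) >= obs)
  mc <- strata_test(pos8, ks8, n_perm = 10000, seed = 2)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc$p_value - exact), max(3 * se, 0.01))

  expect_error(strata_test(1:5, rnorm(5)), "at least 8")
})

test_that("K2P distances match the closed form, ape, and stay above raw p", {
  same <- kimura2p("ACGTACGT", "ACGTACGT")
  expect_equal(same$K, 0)

  # exactly 10 transitions and 5 transversions in 100 sites
  a <- rep("A", 100)
  b <- a
  b[1:10] <- "G"   # transitions
  b[11:15] <- "C"  # transversions
  k <- kimura2p(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(k$P, 0.1)
  expect_equal(k$Q, 0.05)
  expect_equal(k$K, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)

  # independent cross-check against ape's K80 distance
  set.seed(41)
  el <- simulate_ltr_elements(8e6, arm_length = 2000, seed = 3)[[1]]
  ours <- kimura2p(el$arm5, el$arm3)$K
  mat <- rbind(strsplit(tolower(el$arm5), "")[[1]],
               strsplit(tolower(el$arm3), "")[[1]])
  ape_k <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80"))
  expect_equal(ours, ape_k, tolerance = 1e-8)

  # correction never shrinks the raw difference proportion
  for (i in 1:10) {
    e <- simulate_ltr_elements(runif(1, 1e6, 2e7), arm_length = 1000,
                               seed = i)[[1]]
    kk <- kimura2p(e$arm5, e$arm3)
    expect_gte(kk$K, kk$P + kk$Q - 1e-12)
  }

  # sites with N are excluded
  kn <- kimura2p("ANGT", "AAGT")
  expect_equal(kn$n_sites, 3)
})

test_that("LTR ages follow K/(2 mu) and round-trip the simulation", {
  expect_equal(ltr_insertion_age(0, 2.5e-9), 0)
  expect_equal(ltr_insertion_age(0.05, 2.5e-9), 1e7)
  expect_error(ltr_insertion_age(0.05, 0), "mu")

  el <- simulate_ltr_elements(rep(1e7, 30), arm_length = 5000, seed = 8)
  dated <- date_ltr_elements(el)
  expect_lt(abs(mean(dated$age_years) - 1e7) / 1e7, 0.1)
})

test_that("tandem duplicates respect the score and 500-kb window rules", {
  set.seed(9)
  g <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  seqs <- c(g1 = g, g2 = g, g3 = other)
  near <- tandem_duplicates(seqs, c(g1 = 0, g2 = 4e5, g3 = 4.1e5),
                            min_score = 100)
  expect_true(any(near$gene_a == "g1" & near$gene_b == "g2"))
  expect_false(any(near$gene_a == "g1" & near$gene_b == "g1"))
  far <- tandem_duplicates(seqs[1:2], c(g1 = 0, g2 = 6e5),
                           min_score = 100)
  expect_identical(nrow(far), 0L)
})

test_that("pseudogene calls need identity, coverage and an ORF disruption", {
  set.seed(16)
  parent <- paste0("ATG", paste(sample(sdrscan:::FOURFOLD_PREFIXES, 60,
                                       TRUE),
                                sample(c("A", "C", "G", "T"), 60, TRUE),
                                collapse = ""), "TAA")
  parent <- gsub(" ", "", parent)
  # decayed copy: a few substitutions plus a premature stop
  cand <- parent
  for (p in sample(10:170, 12)) {
    substr(cand, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substring(cand, p, p)), 1)
  }
  substr(cand, 91, 93) <- "TGA"
  call <- call_pseudogene(cand, parent)
  expect_false(is.null(call))
  expect_gt(call$identity, 0.7)
  expect_true("premature_stop" %in% call$disruptions$type)

  # frameshift: single-base deletion
  fs <- paste0(substring(parent, 1, 50), substring(parent, 52))
  call_fs <- call_pseudogene(fs, parent)
  expect_false(is.null(call_fs))
  expect_true("frameshift" %in% call_fs$disruptions$type)

  # an intact identical copy is a gene, not a pseudogene
  expect_null(call_pseudogene(parent, parent))
  # an unrelated sequence fails the similarity gate
  junk <- paste(sample(c("A", "C", "G", "T"), 190, TRUE), collapse = "")
  expect_null(call_pseudogene(junk, parent))
})

test_that("SDR gene classification follows the shared/ancestral/transposed/lost rules", {
  set.seed(22)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  shared <- mk(120)
  auto_src <- mk(120)
  anc_src <- mk(120)
  x_genes <- c(x_shared = shared, x_lost = mk(120), x_anc = anc_src)
  y_genes <- c(y_shared = shared, y_auto = auto_src)
  autosomal <- c(a1 = auto_src, a2 = mk(120))
  outgroup <- c(o1 = anc_src)
  res <- classify_sdr_genes(x_genes, y_genes, autosomal, outgroup,
                            pseudogene_calls = "x_lost", min_score = 60)
  lab <- function(g) res$labels[res$gene == g]
  expect_match(lab("x_shared"), "X_Y_SHARED")
  expect_match(lab("y_shared"), "X_Y_SHARED")
  expect_match(lab("y_auto"), "AUTOSOMAL_TRANSPOSITION")
  expect_match(lab("x_lost"), "LOST")
  expect_match(lab("x_anc"), "ANCESTRAL")
  expect_match(lab("x_anc"), "LOST")  # ancestral homolog, no X-Y partner
  expect_false(any(res$LOST & res$SPECIFIC))
  expect_true(all(nchar(res$labels) > 0))

  # order permutation stability
  res2 <- classify_sdr_genes(x_genes[c(3, 1, 2)], y_genes[c(2, 1)],
                             autosomal[c(2, 1)], outgroup,
                             pseudogene_calls = "x_lost", min_score = 60)
  expect_identical(res[order(res$gene), ], res2[order(res2$gene), ])

  expect_error(classify_sdr_genes(c(dup = shared), c(dup = shared)),
               "more than one input set")
})
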