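# sdrscan

Mapping sex-determination regions (SDRs) and measuring sex-chromosome
divergence from sexed population resequencing data.

Young, homomorphic sex chromosomes — common in dioecious plants such as
willows and poplars, and in many fish and amphibians — differ from their
homolog only in a single recombination-suppressed interval. `sdrscan` is
for researchers who have genotypes and read depths for a cohort of sexed
individuals and want to answer, reproducibly: *where is the SDR, which
sex is heterogametic, what sequence is Y-specific, how old is the
region, and how much deleterious load has it accumulated?*

The package implements:

* **Sex-association scan** — standard variant filters (quality ≥ 30,
  biallelic, ≥ 5 bp from indels, depth within [1/3·μ, 3·μ]), a per-site
  two-sided Fisher exact test on the 2×2 sex × allele table with
  Bonferroni control at α = 0.05, detection of X–Y recombinant
  individuals, XY/ZW classification from the heterozygosity contrast,
  and delineation of `X_SDR` / `Y_SPECIFIC` (and mirrored ZW) intervals
  from association, missingness and normalized-depth evidence.
* **Y-read identification** — canonical 30-mers present in ≥ 20 males
  and absent from all females; greedy read-backed phasing of
  heterozygous sites with majority assignment of the male-associated
  haplotype; provenance-tracked union of both read bins.
* **Divergence** — NG86 Ka/Ks with Jukes–Cantor correction
  (d = −(3/4)·ln(1 − 4p/3)) on codon-aligned gametologs, a permutation
  test for evolutionary strata, Kimura two-parameter dating of LTR
  retrotransposon arm pairs (age = K/(2μ), μ = 2.5×10⁻⁹ per site per
  year), reciprocal-best-hit gene classification
  (shared / ancestral / autosomal transposition / lost / specific /
  tandem) and pseudogene calling (identity > 0.70, coverage ≥ 0.50, ≥ 1
  ORF disruption).
* **Mutation load** — SYN/MISSENSE/LOF annotation from the genetic
  code, a two-scorer conservation consensus (DEL only when both agree),
  and per-gene DEL/SYN, TOL/SYN comparisons between regions with
  Mann–Whitney and permutation tests.
* **Synthetic data** — a cohort generator (30M/30F at 32×, planted SDR
  and hemizygous segment, recombinants, negative-binomial depth) and
  sequence fixtures (gametolog pairs at a target Ks, LTR arms of known
  age, truth-tracked reads), so the whole pipeline is testable without
  external data.

## Worked example

Simulate a default cohort and run the scan:

```r
library(sdrscan)

co  <- simulate_cohort(sim_config(seed = 7))
cfg <- scan_config()
gm  <- filter_variants(co$genotypes, co$depth, NULL, cfg)
assoc <- bonferroni_significant(associate_sex(gm), cfg$alpha)
rec <- detect_recombinants(gm, which(assoc$significant), "XY", cfg)
gmu <- subset_genotypes(gm, individuals = setdiff(gm$individuals$id, rec))
assoc_u <- bonferroni_significant(associate_sex(gmu), cfg$alpha)
het <- classify_heterogamety(
  genotype_profile(gmu, which(assoc_u$significant)), cfg)
ratios <- depth_ratio_profile(
  co$depth, setNames(co$genotypes$individuals$sex,
                     co$genotypes$individuals$id))
calls <- delineate_regions(
  assoc_u, genotype_profile(gmu, seq_len(nrow(gmu$sites))), ratios, cfg)

het$call
#> [1] "XY"
rec
#> [1] "F04" "F14" "F16" "F18" "F26"
calls[, c("chrom", "start", "end", "region_class", "m_het", "f_het",
          "f_miss", "m_depth", "f_depth")]
#>   chrom   start     end region_class m_het  f_het f_miss m_depth f_depth
#> 1  chr7 6454180 8714381        X_SDR 0.743 0.0061  0.264   1.012   0.995
#> 2  chr7 7251769 7795065   Y_SPECIFIC 0.000     NA  1.000   0.532   0.000
```

The cohort is called XY (males heterozygous at ~74% of significant
sites after excluding five recombinant females), with an `X_SDR`
interval closely matching the planted 6.39–8.73 Mb region and a
`Y_SPECIFIC` interval showing the hemizygous signature: total female
missingness, male depth at half the genome-wide mean, female depth
zero.

Divergence of planted X–Y gametologs and LTR dating:

```r
pairs <- simulate_gametolog_pairs(37, 999, ks_target = 0.033, seed = 2)
ks <- sapply(pairs, function(p) ng86_ka_ks(p$x, p$y)$Ks)
round(median(ks), 3)
#> [1] 0.031
strata_test(seq_along(ks) * 5e4, ks, n_perm = 1000, seed = 3)
#> strata test: statistic=0.0080, p=0.4565, no strata detected

el <- simulate_ltr_elements(c(4e6, 2.1e7), seed = 4)
date_ltr_elements(el)
#>       id      P      Q      K age_years
#> 1 ltr001 0.0102 0.0084 0.0188   3769422
#> 2 ltr002 0.0520 0.0520 0.1123  22451022
```

The median Ks of 0.031 recovers the planted 0.033 target; ages of 3.8
and 22.5 Myr recover the planted 4 and 21 Myr insertions.

`run_pipeline(pipeline_config(out_dir, seed))` chains all stages,
writing TSV/BED outputs, a plain-text report and a JSON manifest whose
md5 hash is stamped into every output header; runs are byte-identical
under a fixed seed. See `vignette("sdr-analysis")` for the methods.

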