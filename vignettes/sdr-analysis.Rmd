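---
title: "Mapping sex-determination regions and measuring sex-chromosome divergence with sdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex-determination regions and measuring sex-chromosome divergence with sdrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

## The problem

In many dioecious plants and animals the sex chromosomes are young and
homomorphic: a single recombination-suppressed interval — the
sex-determination region (SDR) — distinguishes X from Y (or Z from W),
while the rest of the chromosome pair still recombines. Identifying that
interval from a resequenced population of sexed individuals, pulling out
the sequence found only on the Y, and quantifying how far the X and Y
copies have diverged are the standard first steps in studying such
systems. `sdrscan` implements this workflow end to end, together with a
synthetic-cohort generator that plants a known SDR so every stage can be
validated against ground truth.

The analysis rests on three signatures of a recombination-suppressed SDR
in an XY system (mirrored for ZW):

1. **Genotypic contrast.** At SDR-diagnostic SNPs, males (X/Y) are
   heterozygous and females (X/X) homozygous, so allele counts are
   strongly associated with sex.
2. **Hemizygosity.** Sequence present only on the Y yields missing
   genotypes in females and half the normalized read depth in males.
3. **Sequence divergence.** X–Y gametolog pairs accumulate synonymous
   divergence after recombination stops, and repeat elements (notably
   LTR retrotransposons) accumulate and date the region's age.

## The association scan

Variants are filtered with four standard criteria before testing: site
quality at least 30, at most two alleles, no indel within 5 bp, and
cohort mean depth between 1/3 and 3 times the genome-wide mean. One
non-obvious choice: per-site depth is averaged **over individuals with
nonzero coverage** at the site's window. Averaging zeros in would push
every hemizygous site (where one entire sex contributes no reads) below
the 1/3 cutoff and silently delete the Y-specific signal the scan is
looking for.

Each surviving site is tested with a two-sided Fisher exact test on the
2x2 table of allele counts by sex (genotype codes contribute two
alleles, missing genotypes contribute nothing). The Fisher allelic test
is the exact analogue of the usual GWAS allelic association and can be
certified against full hypergeometric enumeration, which the test suite
does to 1e-12 on all tables with margins up to 12. Family-wise error is
controlled by Bonferroni at `alpha = 0.05` over the number of sites
*tested* (not the number of survivors).

Recombination between X and Y occasionally produces females carrying a
Y-like SDR haplotype; these would dilute the female homozygosity signal.
An individual of the homogametic sex whose personal heterozygosity
across significant sites exceeds 0.5 is flagged as a recombinant and
excluded before the system is classified. Heterogamety is then called XY
when pooled male heterozygosity at significant sites is at least 0.6 and
female at most 0.2 (ZW when mirrored, UNDETERMINED otherwise). The
thresholds are deliberately generous: empirically observed SDR contrasts
in dioecious trees are on the order of 70–90% versus 0–10%, so 0.6/0.2
separates them with margin while remaining configurable.

### Delineation

Candidate intervals are built by gap-joining informative sites (gaps at
most 1 Mb, at least 5 sites — the reported SDRs are single contiguous
intervals per chromosome, so simple gap-joining is preferred over an
HMM). Two kinds of sites seed candidates:

* Bonferroni-significant sites, and
* sites whose missingness in one sex exceeds 0.5.

The second class matters because fully hemizygous sequence produces *no
allelic contrast at all*: if every female genotype is missing, the
Fisher table has an empty row and p = 1. In real data aligned to a
female reference, hemizygous contigs usually retain enough mismapped
female calls to reach significance, but the cleaner the data the weaker
that route becomes — so hemizygosity itself is treated as first-class
evidence. Each candidate interval is then labelled from its evidence:

* `Y_SPECIFIC`: female missingness > 0.5, median male normalized depth
  within 0.15 of 0.5, female depth at most 0.1;
* `X_SDR`: male heterozygosity >= 0.6, female <= 0.2, female depth
  diploid;
* `Z_SDR` / `W_SPECIFIC`: the same rules with sexes swapped;
* `NOT_SEX_LINKED` otherwise.

The rules are exactly mirror-symmetric, so relabelling every individual
M to F converts an XY call into a ZW call with identical p-values — a
property the test suite asserts.

## Y-read identification

Two independent lines of evidence select reads of Y origin, mirroring
how Y contigs are reconstructed when the male assembly lacks them:

* **Sex-specific k-mers.** All 30-bp k-mers are collected per
  individual in canonical form (the lexicographic minimum of k-mer and
  reverse complement). K-mers present in at least 20 males and absent
  from all females are Y-diagnostic; any read containing one is
  selected. With error-free reads fully inside Y-specific sequence and
  read length at least k, recall is exactly 1 — every such read carries
  at least one diagnostic k-mer by construction.
* **Read-backed phasing.** Heterozygous sites connected by reads form
  blocks; within a block, reads are 2-coloured greedily in order of
  decreasing overlap with the already-phased consensus, and a
  refinement pass re-checks every read against the final consensus so a
  conflicting (e.g. chimeric) read is dropped even if it happened to
  seed the block. The haplotype carrying the male-associated allele at
  the majority of significant sites is labelled Y and its reads are
  selected; tied blocks are reported as ambiguous and excluded. This
  greedy procedure replaces a weighted minimum-error-correction solver;
  at the scale used here an exhaustive 2-colouring oracle certifies
  that it recovers the optimal haplotypes on error-free instances.

The two bins are unioned with provenance tracking (`kmer`, `phase`,
`both`).

## Divergence

**NG86 Ka/Ks.** Gametolog pairs are codon-aligned by aligning the
translated proteins and back-threading codons (gap codons dropped).
Synonymous site fractions are computed per codon under the standard
genetic code with mutations through stop codons excluded from both the
pathways and the site denominators; codons differing at multiple
positions are averaged over all orderings of single steps; `pS = Sd/S`
and `pN = Nd/N` receive the Jukes–Cantor correction
`d = -(3/4) log(1 - 4p/3)`, flagged saturated when `p >= 3/4`. NG86 is
used in place of a maximum-likelihood codon model because it is fully
specified, hand-checkable (the suite verifies every <=2-difference
codon pair against explicit pathway enumeration), and adequate at the
divergence scale of young SDRs (Ks below ~0.2).

**Strata.** Whether the SDR contains strata — segments of distinct X–Y
divergence — is assessed with an explicit operationalization: order the
gametolog pairs along the X, take the maximum over breakpoints of the
absolute difference in mean Ks between the two sides (each side at
least 4 pairs), and compare against the permutation distribution of Ks
over positions. A breakpoint is reported only below p = 0.05.

**LTR dating.** The two long terminal repeats of a retrotransposon are
identical at insertion, so their divergence dates it. The package takes
aligned arm pairs, computes the Kimura two-parameter distance
`K = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` (transitions P and
transversions Q corrected separately, saturation flagged), and converts
to age as `K / (2 mu)` with `mu = 2.5e-9` substitutions per site per
year — the rate conventionally used for these genomes. Structural
detection of LTR elements is out of scope; the package dates given arm
pairs.

**Gene classification.** SDR genes are labelled by reciprocal best hits
(X_Y_SHARED), hits to the corresponding outgroup region (ANCESTRAL),
mutual best autosomal hits without an outgroup-region hit
(AUTOSOMAL_TRANSPOSITION), and, for genes without an X–Y homolog, LOST
when a pseudogenized copy or ancestral homolog testifies the gene was
once there, SPECIFIC otherwise; labels may combine, except
LOST/SPECIFIC. Tandem duplicates are pairs above an alignment-score
threshold within a 500-kb window; score thresholds stand in for BLAST
E-values because no database statistics exist at this scale. Pseudogene
calls require identity above 0.70 to the parent CDS, coverage of at
least 0.50 (the identity rule is the published convention; the coverage
default is this package's declared choice), and at least one ORF
disruption — a premature stop in the threaded reading frame or a
frameshift-inducing indel.

## Mutation load

Coding SNVs are classified SYN / MISSENSE / LOF directly from the gene
model and genetic code (the suite checks all 576 single-base codon
mutations against brute force, and minus-strand genes against their
reverse-complemented plus-strand construction). Deleteriousness of
missense variants uses a conservation-based consensus stand-in for
trained predictors: scorer A votes deleterious when the reference
residue is conserved in at least 80% of ortholog sequences and the
variant residue is absent from the column; scorer B votes deleterious
when the variant residue's column frequency is below 5%; a variant is
DEL only when both agree, otherwise TOL. The consensus structure ("both
programs agree") is retained; the thresholds 0.8 and 0.05 are this
package's documented defaults. LOF variants are kept as their own class
and pooled with DEL for load ratios by default (configurable).

Load is compared between regions on per-gene DEL/SYN and TOL/SYN ratios
with SYN as the neutral reference (genes with zero synonymous variants
are excluded as undefined), using a two-sided Mann–Whitney rank-sum
test plus an optional label-permutation p-value; rank-sum p-values are
Holm-corrected across region pairs. Per-gene ratios are the primary
comparison; pooled per-region counts are also emitted for inspection.

## The synthetic cohort

The generator's defaults define the study conditions: 30 males and 30
females at 32x mean depth, an XY system on a 12-Mb sex chromosome with
the SDR at 6.39–8.73 Mb and a 0.6-Mb hemizygous Y-specific segment
inside it, plus a 4-Mb autosome. SNP density (5e-5 per bp, giving on
the order of 100 SDR-diagnostic SNPs), genotype miscall (1%) and
dropout (2%) rates, and the depth law are declared defaults, not
inferred from data: depth is negative-binomial with extra-variance
`0.1 * m^2`, a realistic overdispersion that needs no extra
dependencies. Recombinant individuals (probability 0.1 per homogametic
individual, matching the observed ~3-in-30 pattern) are modelled as
whole-SDR haplotype swaps at diagnostic sites; the hemizygous interval
stays fully missing in the homogametic sex so the hemizygosity
invariant is exact by construction. Autosomal sites segregate under
Hardy–Weinberg with allele frequencies independent of sex.

Sequence fixtures are built the same way: gametolog pairs start from a
common ancestral CDS whose non-start codons come from 4-fold-degenerate
families, so each contributes exactly one NG86 synonymous site and
third-position Jukes–Cantor divergence `d` yields expected Ks = `d`
with Ka = 0 exactly; LTR arm pairs descend from one ancestral arm
evolved independently on both lineages under a two-class
(transition/transversion, kappa default 2) substitution process;
reads are error-free with uniform starts and truth-tracked sources.

What the generator does **not** emulate — read errors, indels,
structural variation, alignment artefacts, population structure,
reference bias — bounds what passing tests show: they certify the
statistical machinery and the planted-signal recovery, not robustness
to every artefact of real resequencing data. In particular, real
hemizygous contigs show partial (not total) female missingness caused
by mismapping, which the delineation handles through the same
missingness threshold but the generator does not reproduce.

## Numerical choices and scale

Fisher p-values come from `stats::fisher.test` with the standard
"sum of small p" two-sided rule; permutation p-values use the
`(1 + hits) / (1 + draws)` estimator; Needleman–Wunsch alignment is
delegated to `Biostrings::pairwiseAlignment` with linear gap scoring
and deterministic tie-breaking. All intervals are 0-based half-open
internally; VCF and GFF3 remain 1-based at their interfaces. Every
generator takes an explicit integer seed and is byte-reproducible;
derived stage seeds stay below 2^31.

The default verification sizes are chosen for desk-scale runs: 50
cohort seeds for parameter recovery, 200 gametolog pairs and 100 LTR
elements per age for dating round-trips, 1000 null and 200 enriched
simulations for the load-test calibration. At these sizes the full test
suite and the acceptance script each complete in minutes on one CPU.

## Known limitations

* The greedy phaser is certified only at desk scale; for genome-scale
  phasing a weighted MEC solver remains the right tool.
* The conservation stand-in is not a substitute for trained
  deleteriousness predictors on real proteins; it preserves the
  consensus logic, not the predictions.
* The strata test assumes exchangeability of Ks across positions under
  the null and detects single dominant breakpoints, not fine-grained
  stratification.
* Interval delineation reports the span of informative sites; the true
  recombination-suppression boundary can extend past the outermost
  informative SNP.
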