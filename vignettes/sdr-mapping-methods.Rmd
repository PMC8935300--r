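---
title: "Locating and dating a sex-determining region from family-based transcriptome genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and dating a sex-determining region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(sdrmap)
```

## The problem

In a dioecious species with male heterogamety (XY males, XX females), the
sex-determining region (SDR) and the non-recombining Y-specific region
(NRY) around it can be located from ordinary family data: SNPs called from
transcriptome reads of parents and F1 offspring across several crosses.
`sdrmap` implements that workflow end to end:

1. pedigree QC (relatedness of offspring to their named parents);
2. segregation-distortion filtering of markers;
3. a genome-wide scan for Y-specific SNPs — sites heterozygous in every
   male and homozygous reference in every female, jointly across crosses;
4. inference of NRY boundaries from the run of Y-SNP-bearing genes;
5. sexSNP-augmented two-point linkage mapping (per sex) and integration of
   the genetic with the physical map;
6. read-backed reconstruction of the Y-linked gametolog sequences
   (partitioning read pairs by the Y-specific alleles they carry);
7. NG86 synonymous/non-synonymous divergence with Jukes–Cantor correction,
   divergence dating, and Tajima's relative-rates test against an
   outgroup;
8. FPKM-based X/Y expression-ratio summaries (dosage and Y-degeneration
   diagnostics).

Every stage is an exported function; `run_all()` wires them together, and
the numbered scripts under `analysis/` run the same stages as a narrative
workflow on the packaged simulated study.

## Models and key statistics

**Y-SNP criterion.** A fixed X/Y difference surfaces in a VCF called
against the X (female) reference as a site where all males are `0/1` and
all females `0/0`. `find_y_snps()` applies this jointly across all
families; sites linked to, but outside, the NRY are removed whenever any
cross carries a recombinant. The default call-rate policy is strict
(`min_call_rate = 1`): the source data's handling of missing genotypes is
unstated, so tolerance for missingness is exposed as a parameter rather
than assumed.

**NRY boundaries.** `nry_boundaries()` reports two resolutions: the inner
span (first to last Y-SNP-bearing gene) and the outer bound (nearest
flanking genes that were tested — had scorable SNPs — but carry no
Y-SNPs). Genes without scorable SNPs cannot witness either way and do not
interrupt a run.

**Two-point linkage.** For testcross markers (one parent heterozygous,
the other homozygous) the transmitted parental allele is read off each
offspring. Recombination fractions use per-family phase resolution by
majority rule; the LOD is the base-10 binomial likelihood ratio against
free recombination, `LOD = r log10(r̂) + (n−r) log10(1−r̂) + n log10 2`,
evaluated at the maximum-likelihood r̂ with the `0·log 0 = 0` convention
(so zero recombinants in `n` meioses give `n log10 2`). Map distances use
the Haldane function `d = −50 ln(1−2r)` throughout, matching the
no-interference crossover model of the simulator.

**Map construction.** `build_map()` follows a two-point design rather
than multipoint annealing (the multipoint optimizer of pedigree-mapping
suites is not the object of interest here; ordering quality is instead
validated against simulation truth):

* grouping by single linkage on pairwise LOD ≥ 10, with leftover markers
  joined to their best group when LOD ≥ 8 and the margin over the second
  best is ≥ 2 (the conventional threshold triple);
* *binning*: co-segregating markers are collapsed by complete linkage on
  zero observed recombinants (a marker joins a bin only if it shows zero
  recombinants with **every** member it shares meioses with, one such
  pair resting on ≥ 25 meioses). Complete linkage stops chains of
  accidental zero estimates from merging across real distance;
* per-bin consensus transmission vectors (members phase-aligned per
  family, then per-meiosis majority), which reach far higher effective
  meiosis counts than single markers;
* global phase alignment of bins along a minimum spanning tree of close
  links, anchoring a family's phase only on a decisive majority (≥ 8
  shared meioses, mismatch fraction outside 0.25–0.75); pairs with an
  unanchored side fall back to per-family phase minimization. Pairs of
  bins whose data in a family are both intercross-derived are excluded:
  observing both transmissions there conditions on the other parent's
  co-transmission and biases the recombinant count;
* ordering: an anchor skeleton is seriated by an Isomap-style embedding
  (reliable short edges become additive Haldane distances, completed by
  graph shortest paths and projected to one dimension by classical MDS),
  polished by 2-opt reversals and or-opt segment moves, then refined by
  single-bin multipoint placement (each bin re-placed at the position
  maximizing the binomial likelihood of its recombinant counts against
  all others);
* map distances: per-gap lengths are fitted by windowed nonnegative
  weighted least squares over all informative pairs spanning up to eight
  gaps (direct adjacent estimates from ~25 shared meioses are far too
  noisy on their own), with one residual-trimming round; gaps fitted
  below 0.02 cM, or whose direct neighbours show zero recombinants on
  ≥ 30 meioses, collapse to exactly zero so that co-located markers
  share one cM position. Order within a shared cM position is not
  identifiable from recombination data; co-located markers are presented
  in physical order (synthetic markers without a position last).

**sexSNP.** Phenotypic sex is injected as a pseudo-marker heterozygous in
all males and homozygous in all females, so linkage mapping localizes the
sex locus like any other testcross marker. It is flagged `synthetic` and
carries no physical position.

**Read partitioning and consensus.** A read pair goes to the Y side if
any mate carries the Y allele at ≥ 1 Y-SNP and no mate carries an X
allele (mates are propagated together); the converse goes to the X side;
pairs with conflicting mates, third alleles only, or no Y-SNP coverage
stay unassigned (conflicts counted). These conflict policies are our own
stated choices — the original read-separation tool leaves them
undocumented — and exclusion is the conservative option. Consensus is a
per-position majority; ties and positions under `min_depth = 2` emit `N`,
never IUPAC codes, so downstream codon analyses skip rather than guess.

**Divergence.** NG86: per codon, each of the nine single-base neighbours
is classified as synonymous or non-synonymous, with changes to stop
codons excluded from the per-position denominator (every sense codon
contributes exactly 3 sites, so S + N equals the aligned length). Between
codons differing at k positions, differences are apportioned by averaging
over the k! substitution orderings, excluding orderings that pass through
a stop (remaining paths weighted equally) — this is what produces
fractional counts such as 43.50. Codons containing `N` (from consensus
masking), a gap, or a stop in either sequence are dropped pairwise, so
denominators shrink rather than bias. The Jukes–Cantor correction
`d = −(3/4) ln(1 − 4p/3)` is applied to both `ps` and `pn`; `Ka/Ks` is
reported as missing when `Ks = 0`. Only the standard genetic code is
used (nuclear plant CDS).

**Dating.** `T = g·Ks / (2m)`, with generation time `g` (years) and
per-site per-generation mutation rate `m`; divergence accumulates on two
lineages after recombination stops. Defaults `g = 25`, `m = 1e-8` give
the conservative minimal-age reading. A published alternative that
divides by a per-year substitution rate without the factor 2 is *not*
reproduced: we apply the stated formula consistently.

**Relative rates.** Each tripartite alignment site is classified as
invariable, X-specific, Y-specific, outgroup-specific, or
all-different; `chi2 = (mX − mY)² / (mX + mY)` with 1 df (upper tail, no
continuity correction), separately per codon position. Lineage counting
needs no tree.

**Expression ratios.** `FPKM = count / (length/1000 × library/1e6)`.
Ratios are ratios of within-sex medians (`mY/mX`, `(mX+mY)/fXX`,
`mX/fXX`), matching the median-FPKM table structure of the source
analyses; whether those were ratios-of-medians or medians-of-ratios is
not stated, so the alternative is exposed as
`method = "median_of_ratios"` for `mY/mX` (cross-sex ratios are unpaired
and always use medians). Library-size normalization is required because
cross-sex ratios do not cancel per-sample constants.

**Pedigree QC.** The per-marker allele-sharing score (1 = both alleles
shared, 0.5 = one, 0 = none) is reported as a diagnostic, but its
expectation for *unrelated* pairs exceeds 0.6 under any allele frequency,
so it cannot drive a `< 0.35` exclusion rule. The exclusion flag
therefore uses a KING-robust relatedness estimate
`r = 2(N_het,het − 2 N_opp.hom) / (N_het,1 + N_het,2)`, which is
frequency-free (immune to the family structure of the sample), ~0.5 for
a true parent–offspring pair and ~0 for an unrelated one; offspring with
`r < 0.35` to a named parent are excluded as possible contaminants.

## The synthetic-data generator

`sim_config()` defaults define the study conditions: four half-sib
crosses (three mothers, four fathers, the last two crosses sharing a
mother), 25 offspring each, one 300 Mb chromosome carrying a 50 Mb
interval (200–250 Mb) with recombination reduced to 5% of background in
both sexes, and a 2 Mb sub-interval (222–224 Mb) in which male
recombination is suppressed completely. Four NRY genes sit inside it at
222.55/222.97/223.53/223.87 Mb with CDS lengths of 644/110/410/920
codons and target X:Y divergences Ks = 0.102/0.038/0.033/0.018,
Ka = 0.031/0.020/0.008/0.007 — the per-gene values of the motivating
study. Sex-specific total map lengths default to 90 cM (female) and
109 cM (male), the chromosome-2 values. 250 genes at ~2 heterozygous
SNPs per gene approximate the source marker density (789 markers in 392
genes) at a size that keeps the full pipeline fast; at most 12 of a
gene's fixed X/Y differences surface as called markers (joint genotype
calling recovers only a fraction of divergent sites in real data — 61
called Y-SNPs against ~136 underlying differences in the motivating
study). Parental polymorphism (alternate-allele frequencies uniform on
0.15–0.5), genotyping error and missingness (both 0 by default) are free
parameters the source does not constrain.

Gametolog pairs are produced by placing substitutions one at a time on a
random lineage under a Jukes–Cantor-like uniform model (matching the
downstream correction), rejecting stops, and accepting each class until
the realized NG86+JC divergence first meets its target — so realized
values exceed targets by at most one substitution. Crossovers follow the
Haldane model (Poisson count in map length, positions uniform in map
distance); offspring sex is the paternal sex haplotype inherited at the
SDR. Expression counts are negative binomial around configured FPKM
means; females express the X copies only, and male X-copy means default
to half the female total (one X versus two).

What the generator does **not** emulate: base-quality structure, indels
and alignment artifacts; reference bias in read mapping; population
structure among founders beyond the shared-mother design; expression
variation beyond a global NB dispersion; genotype-calling error models.
Passing recovery tests therefore demonstrates the inference logic under
the stated models, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* rf is clamped to [0, 0.5] in the LOD (values above 0.5 carry no
  linkage evidence); the Haldane transform clamps r at 0.45 to keep
  distances finite.
* `jc_correct()` raises an explicit saturation error at `p ≥ 0.75`.
* A codon whose every substitution pathway passes through a stop is
  skipped with a warning (sites and differences both excluded).
* Empty read sets give an all-`N` consensus rather than an error; an
  empty Y-SNP scan gives an empty NRY interval.
* `two_point_rf()` with zero shared informative meioses is an error, not
  a silent 0.5.
* Determinism: a config seed fixes every simulation; `run_all()` reruns
  byte-identically.

## Validation scale

The test-suite and recovery checks run the full default design (four
crosses × 25 offspring; ~500 markers) over 20 replicate seeds for the
Y-SNP-scan and map-recovery properties, three replicates for consensus
reconstruction, 20 gametolog replicates at 400 codons for divergence
recovery, and 50 samples per sex for the expression-dosage check — sizes
chosen so the whole suite completes in a few minutes while leaving the
binomial tolerances meaningful. Ordering quality is summarized as the
Spearman correlation between inferred and true cM over the largest
linkage group; with ~100 meioses, markers a fraction of a centimorgan
apart are genuinely unorderable, which the binning makes explicit rather
than hiding.

## Known limitations

* Two-point grouping cannot place markers informative in a single small
  family (their maximum LOD, `n log10 2`, is below the grouping
  thresholds); such markers stay in singleton groups, exactly as a
  conventional LOD-threshold pipeline would leave them.
* Mid-range distances rest on phase alignment; residual phase errors
  inflate a minority of replicate maps by tens of percent.
* The NRY boundary is operationalized as the maximal run of
  Y-SNP-bearing genes uninterrupted by tested negatives; with sparse
  expressed genes the outer bound can be generous.
* Dating inherits full sensitivity to `g` and `m`, which the method
  cannot estimate; reported ages are minimal under the stated choices.
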