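---
title: "Prioritizing exome variants in a nuclear family: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing exome variants in a nuclear family: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedseg)
```

`pedseg` implements a family-based prioritization analysis for coding
variants in a nuclear pedigree segregating a dichotomous phenotype. This
vignette explains the model behind each stage, the parameters that matter
and their defaults, what the synthetic-data generator does and does not
emulate, and the design decisions we made where the procedure was genuinely
open.

## The design and its assumptions

The analysis assumes one nuclear family — two founders and their children —
jointly genotyped at every site of a multi-sample VCF, with affection
status known for the members entering phenotype contrasts. The premise is
that a family-specific coding variant of large effect may be carried by
every affected member and absent (or present in fewer copies) in every
unaffected member. That is a deterministic filter, not a statistical test:
with six members there is no power for inference at single variants, which
is why the package complements the segregation filter with a gene-set
burden comparison and a de novo scan.

Members with unknown affection are parsed and carried through I/O but
excluded from both phenotype sets; multi-generation pedigrees are rejected
with an explicit unsupported-structure error by the segregation and de novo
stages, because every rule below is stated for a single nuclear family.

## Hard quality filters

Six site-level flags mark a variant low quality; any single flag removes
it. Thresholds (all overridable via `qc_thresholds()`):

| rule | condition | default |
|---|---|---|
| `cluster3in10` | ≥ `cluster_k` variant positions in a `cluster_window` bp window | 3 in 10 bp |
| `map_ambiguity` | MQ0 reads ≥ `mq0_max` | 4 |
| `min_depth` | coverage < `min_depth` reads | 5 |
| `min_qual` | site quality < `min_qual` (Phred) | 50 |
| `min_qd` | quality / unfiltered depth < `min_qd` | 1.5 |
| `strand_bias` | FS > `max_fs` (Phred-scaled Fisher p) | 200 |

Numerical choices worth stating explicitly:

* **Boundary orientation is literal**: strictly-less-than for depth,
  quality and QD; strictly-greater-than for FS; at-least for the cluster
  count and MQ0 ("three or more", "four or more"). So `qual = 50` passes
  and `fs = 200` passes.
* **The cluster window is inclusive of span 10**: positions p and p + 9
  can share a window, p and p + 10 cannot. No boundary convention is
  standard here, so the window is configurable; the implementation is
  checked against a brute-force window oracle in the tests.
* **Distinct positions, not alternate alleles**, are counted in the
  cluster rule: a decomposed multi-allelic site contributes one position.
* **Absent metrics never fail a site.** A VCF lacking one INFO key would
  otherwise lose every record; instead the rule is recorded as
  unevaluated and counted in `qc_summary()`.
* The mapping-ambiguity count is read from INFO key `MQ0` — the classic
  convention for reads mapping equally well to multiple locations — and
  the key name is a `read_vcf()` argument, since pipelines differ.

## The segregation cascade

Stage 1 keeps exonic nonsynonymous variants with no dbSNP id. Stage 2
keeps variants whose non-reference allele counts (het = 1, hom-alt = 2)
satisfy

> every affected count ≥ 1 and max(unaffected) ≤ min(affected) − 1.

Stage 3 drops variants carrying a 1000 Genomes frequency. The stage counts
are monotone and the novelty/function filters commute with the segregation
filter (a property the tests assert).

Open points we had to decide:

* **"At least one fewer copy" when affected counts differ.** We formalize
  the contrast as `max(unaffected) ≤ min(affected) − 1`, the weakest
  reading consistent with the canonical outcome (all affecteds
  heterozygous, all unaffecteds homozygous reference). A hom-alt affected
  member therefore does not relax the bar for unaffected members below
  the het affected minimum.
* **"Minor allele" means the non-reference allele.** Counting follows the
  alternate allele per decomposed site; sample-frequency minorness is not
  computed (with six samples it would be noise).
* **Uncalled genotypes disqualify a variant** at the segregation stage
  (`complete = FALSE`): the criterion presupposes complete genotypes, and
  imputing either way would manufacture or destroy segregation silently.
* **Stopgain variants are excluded from stage 1** by default. Whether
  "nonsynonymous" should include them is ambiguous in common usage; the
  conservative reading is a plain amino-acid substitution, and
  `include_stopgain = TRUE` flips the switch.
* Multi-allelic records are decomposed into per-alternate pseudo-sites on
  input, with per-sample allele indices remapped (focal alternate → 1,
  anything else → 0), because novelty, annotation and segregation are all
  per-allele notions. Coordinates remain 1-based VCF convention
  throughout.

## Functional-prediction consensus

The five scores arrive already transformed to [0, 1] with larger = more
damaging / conserved / constrained. Per-algorithm cut-offs
(`consensus_thresholds()`): SIFT 0.95, PolyPhen2 0.85, PhyloP 0.95,
MutationTaster 0.95, LRT 0.95. A variant is flagged when ≥ 2 algorithms
call it functional.

* **Thresholds are inclusive (≥).** The worked scorecard stars an LRT
  score of exactly 0.95, so a strict reading of "> 0.95" would contradict
  it; the scorecard wins.
* **MutationTaster's cut-off is not published.** 0.95 is adopted by
  symmetry with SIFT/PhyloP and is consistent with every starred (1.00,
  0.99) and unstarred (≤ 0.72) cell of the worked example; it is
  configurable.
* **PolyPhen2's three-band scheme collapses to "damaging" only**: the
  possibly-damaging band (0.15–0.85) counts as not functional, consistent
  with an unstarred 0.78.
* Missing scores contribute no support and are no error: a variant scored
  by one algorithm is judged on that score alone.

## Candidate-gene burden

Per child, `count_burden()` sums non-reference alleles over QC-passed
variants whose annotated gene symbol is in the candidate set, at three
nested tiers (all, dbSNP-novel, novel + nonsynonymous). Gene membership is
an exact symbol match on the annotation's gene field; upstream/downstream
region classes carry their assigned symbol and therefore count.

`build_table()` forms a = Σ tier alleles over affected children,
b = Σ per-child QC-passed variant totals − a, and likewise c, d for
unaffected children. Two deliberate conventions:

* **The numerator counts alleles while the denominator counts variant
  sites per child.** This unit mismatch is the published arithmetic of
  the design (28,370 + 28,413 − 16 = 56,767) and is preserved as such; it
  is documented rather than "fixed" because changing it changes the
  statistic.
* **No continuity correction in the χ²** — the uncorrected Pearson
  statistic referred to χ²(1) reproduces the reference p-values (0.112,
  0.097), a Yates-corrected statistic does not. `odds_ratio_ci()` uses
  the Woolf interval with z = 1.96 exactly (not the 1.959964 quantile),
  which reproduces the reference intervals to the printed precision; the
  upper bound of the novel tier is 4.589 where 4.58 was printed, a
  one-unit-in-the-last-digit discrepancy we document rather than absorb.
  Zero cells error with a pointer to the opt-in Haldane–Anscombe
  correction (`correct = TRUE`, 0.5 to every cell).

## De novo detection

A child carrying ≥ 1 copy of an alternate allele absent from both parents'
called genotypes is a candidate; sites with an uncalled parent are skipped
and counted. Three depth criteria (`denovo_thresholds()`):

1. more than `min_reads` (10) total reads for mother, father and carrier
   child — read strictly, so 10 fails and 11 passes;
2. each parent's alternate fraction ≤ `max_parent_alt_fraction` (0.05) —
   inclusive, so exactly 5% passes;
3. a heterozygous child's reference fraction ≤ `max_child_ref_fraction`
   (0.70) — inclusive; homozygous-alternate children pass vacuously and
   are flagged `atypical_hom_alt` in the output, since a true de novo
   event is expected heterozygous.

Totals are per-person ref + alt allelic depths (the AD field), not the
site-level DP: the criteria are about the evidence in each person's reads.
Finalization restricts to dbSNP-novel calls and reports mean per-member
coverage over the final variants, rounded to the nearest integer.

## The synthetic-data generator

`simulate_family()` produces a mutually consistent bundle (VCF + PED +
annotation + gene list + truth labels) for a two-parent family. Defaults
encode the study conditions the package reproduces: four children with two
affected, an affected mother, 14 planted segregating novel nonsynonymous
variants of which 4 carry a 1000 Genomes frequency (cascade 14 → 10), two
planted de novo events, one de novo decoy per failure mode and one QC decoy
per filter, on a background of 120 common and 40 rare Mendelian variants.

* **Read totals** follow a negative binomial (mean 150, dispersion 8) to
  mimic exome capture variability; only mean coverages are published for
  the reference design, so the distribution shape is our choice.
* **Heterozygous allele balance is binomial at 0.5**; the allele-biased
  de novo decoy draws at 0.2 and resamples until the reference fraction
  exceeds 70%. Homozygous-reference error reads are capped at
  `error_alt_fraction` (1%) of the total so generated depths never
  contradict genotypes.
* **Backgrounds are strictly Mendelian** (one allele from each parent),
  so no background variant can be a de novo candidate. A rare novel
  nonsynonymous background variant can, however, mimic the planted
  segregating pattern by chance (~1/16 per mother-carried variant with
  four children); the generator redraws such transmissions so that
  planted truth is exactly recoverable, which is what makes the
  end-to-end property tests sharp rather than probabilistic.
* **Positions are spaced ≥ 20 bp apart** except where the cluster decoy
  plants three sites 4 bp apart, so the cluster filter fires only where
  intended.
* Identical seeds give byte-identical output files.

What the generator does **not** emulate: linkage and LD structure,
error-mode correlation between neighboring sites, indels and multi-allelic
sites (the simulator emits biallelic SNVs; the reader handles
multi-allelics), population structure beyond a single allele frequency per
site, and exome-scale variant counts. A passing pipeline on synthetic data
therefore demonstrates the logic of every rule and their composition, not
robustness to real sequencing artifacts.

`paper_family_fixture()` is the deterministic worked example: the ten
reference variants with their printed positions and scores, the four
1000-Genomes-flagged variants, the four common SNPs with their published
genotypes, the two de novo events with their printed per-member read
depths, and candidate-gene variants realizing the published per-child
burden numerators (8/8/3/5 novel, 6/6/1/4 novel + nonsynonymous).
Reference/alternate bases not printed in the source tables are arbitrary
but fixed. Exome-scale per-child totals (~28,000 QC-passed variants per
child) are *not* emulated by filler; the published 2×2 tables are instead
reproduced by passing the printed per-child totals
(`published_burden_counts()`) to `build_table()`, which is exactly how the
published arithmetic is defined.

## Problem sizes and runtime

The test-suite property checks run the full pipeline on 20 simulated
families of ~190 variants each, compare the cluster filter against an
O(n²) oracle on inputs up to 500 sites, and check the χ² closed form
against the expected-counts computation on random tables up to counts of
1000. These sizes make every check exact (set equality against planted
truth, not rate thresholds) while keeping the default suite fast; the
generator scales to larger bundles by raising the background counts in
`sim_config()`.

## Known limitations

* Phenotype is dichotomous; no covariates, no penetrance model.
* The segregation filter is deterministic — a single genotyping error in
  a phenotyped member hides a true variant (uncalled genotypes are at
  least surfaced as `complete = FALSE`).
* The burden test inherits the published design's unit mismatch and its
  per-child totals as denominators; it is a descriptive contrast for one
  family, not a calibrated gene-set test (no SKAT-style collapsing, no
  multiple-testing machinery — one pre-specified set).
* De novo QC is read-count based; it does not use genotype likelihoods,
  so it cannot rescue borderline calls the way joint-likelihood trio
  callers can.
* Annotation is consumed, not computed: region classes, gene symbols,
  novelty and scores are taken from the input table as ground truth.
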