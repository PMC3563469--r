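# pedseg

Family-based exome variant prioritization for nuclear pedigrees.

## The problem

Genome-wide association studies of common diseases such as asthma point at
loci, rarely at causal variants, and leave most heritability unexplained.
One complementary design sequences the exomes of a single nuclear family in
which the disease visibly segregates — say an affected mother, two affected
children, an unaffected father and two unaffected children — and asks which
coding variants track the phenotype through the pedigree. `pedseg`
implements that analysis for people working from a jointly-called
multi-sample VCF, a 6-column PED file, an ANNOVAR-style annotation table and
a candidate-gene list:

1. **Hard QC filters.** A variant is "low quality" if any one of six flags
   fires: ≥ 3 variant positions within a 10 bp window; ≥ 4 reads mapping
   equally well elsewhere (MQ0); coverage < 5 reads; site quality < 50;
   quality-by-depth QD < 1.5; Phred-scaled strand-bias FS > 200.
2. **Segregation cascade.** Keep exonic nonsynonymous variants with no
   dbSNP id; keep those whose non-reference allele counts segregate —
   every affected member carries ≥ 1 copy and
   max(unaffected) ≤ min(affected) − 1; drop variants with a 1000 Genomes
   frequency.
3. **Functional-prediction consensus.** Call each of five transformed
   scores (SIFT ≥ 0.95, PolyPhen2 ≥ 0.85, PhyloP ≥ 0.95,
   MutationTaster ≥ 0.95, LRT ≥ 0.95) functional or not; flag variants
   supported by ≥ 2 algorithms.
4. **Candidate-gene burden.** Per child, count non-reference alleles at
   candidate-gene variants (tiers: all / novel / novel + nonsynonymous) and
   test affected vs unaffected children with the 2×2 table
   a = Σ tier alleles (cases), b = Σ per-child QC-passed totals − a (and
   c, d for controls), using the uncorrected Pearson χ² (df = 1),
   OR = ad/bc, and the Woolf interval
   exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d)).
5. **De novo detection.** A child's allele absent from both parents' called
   genotypes is a candidate; it survives if every trio member has > 10
   reads, each parent has ≤ 5% alternate reads, a heterozygous child has
   ≤ 70% reference reads, and the site is dbSNP-novel.

A synthetic-data module (`simulate_family()`, `paper_family_fixture()`)
generates complete, mutually consistent input bundles for a nuclear family
with planted truth — segregating variants, de novo events, per-filter QC
decoys, per-criterion de novo decoys, Mendelian background — so every stage
is testable without sequencing data.

## Worked example

The bundled worked-example fixture encodes the published family: the ten
segregating novel nonsynonymous variants with their prediction scores, four
more removed at the 1000 Genomes stage, four common asthma SNPs, two de novo
events with their trio read depths, and per-child candidate-gene burden
variants.

```r
library(pedseg)

fx <- paper_family_fixture()
annotated <- join_annotation(qc_passed(qc_filter(fx$variants)),
                             fx$annotation, quiet = TRUE)

cascade <- run_cascade(annotated, fx$pedigree)
cascade
#> Segregation cascade
#>   input (QC-passed, annotated): 52
#>   novel nonsynonymous:          33
#>   segregating with affection:   14
#>   after 1000G exclusion:        10
```

14 variants are heterozygous in the affected mother and both affected
children and homozygous reference in all unaffected members; 4 of them have
a 1000 Genomes frequency, leaving 10. Consensus over the five prediction
scores flags four of the ten:

```r
flag_candidates(cascade$survivors)[, c("gene", "aa_change", "n_support")]
#> # A tibble: 4 × 3
#>   gene    aa_change n_support
#> 1 CBLB    D454A             3
#> 2 PDE4DIP I303L             2
#> 3 KALRN   L1644F            2
#> 4 GALNTL6 I160V             2
```

The burden test on the published per-child counts (8/8 novel alleles in the
affected children vs 3/5 in the unaffected, against per-child QC-passed
totals of ~28,000):

```r
burden_test(published_burden_counts(), fx$pedigree)
#> Candidate-gene rare-allele burden (affected vs unaffected children)
#>   novel         a/b = 16/56767, c/d = 8/55742  OR = 1.964 (95% CI 0.84-4.59), p = 0.112
#>   novel_nonsyn  a/b = 12/56771, c/d = 5/55745  OR = 2.357 (95% CI 0.83-6.69), p = 0.097
```

Neither tier reaches significance, but both odds ratios point toward excess
rare alleles in the affected children. De novo detection recovers the two
planted events:

```r
cand <- denovo_qc(denovo_candidates(annotated, fx$pedigree))
fin <- denovo_finalize(cand, annotated, fx$pedigree)
fin$final[, c("gene", "child_id")]        # MEF2A/child1, DST/child4
fin$mean_coverage                         # 212
```

`run_pipeline()` chains all stages from files and emits a JSON run report;
`autoplot()` methods draw the cascade funnel and the odds-ratio intervals,
and `tidy()`/`glance()` return the stage counts and test statistics as
tibbles.

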