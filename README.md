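# mitoplasmy

Heteroplasmy, multiplasmy and mutation-burden analysis for deep-sequenced
human mitochondrial DNA.

## The problem

Each cell carries hundreds to thousands of mtDNA copies, so a mitochondrial
variant can be **homoplasmic** (carried by essentially all copies) or
**heteroplasmic** (carried by a fraction of them). Deep sequencing
(10^3–10^4× coverage) makes the mutant fraction directly measurable from
per-position allele counts, but three analysis problems stand between raw
counts and cohort-level conclusions:

1. **Classification.** A site is called homoplasmic when its major allele
   reaches ≥ 95% of reads (boundary inclusive) and differs from the rCRS
   reference; any passing site whose major allele is below 95% is
   heteroplasmic; sites under 200 reads are filtered. The heteroplasmy
   level is the fraction of reads on the largest non-reference allele.
2. **Artifact control.** Illumina platforms over-call heteroplasmic A>C
   transversions in a reproducible sequence context — a run of ≥ 2 A's
   ending at the site followed immediately by ≥ 2 C's. These calls, plus a
   small blacklist of validated false positives, are flagged (never
   silently deleted) and excluded from burden statistics.
3. **Interpretation.** Coding variants are annotated under the vertebrate
   mitochondrial genetic code (ATA = Met, TGA = Trp, AGA/AGG = stop), with
   light-strand genes (ND6) reverse-complemented; variants are classified
   novel / rare / known against a population catalog of 26,850 genomes
   (rare = frequency < 0.1%); and case/control cohorts are compared by the
   per-subject rate of exclusive non-synonymous mutations, with a
   Poisson-rate z standardisation, a two-sample rate test, and a one-sided
   Fisher test of a dichotomised ("5+ mutations") load.

The package also calls **multiplasmy** — heteroplasmy of repeat *length* at
the hypervariable D-loop repeat loci: the (CA)n repeat at 514 (reference
(CA)5), the D310 poly-C tract, and the D16189 poly-C tract. Per-read repeat
lengths are extracted between exact flanking anchors; a locus is
multiplasmic when two or more lengths each have ≥ 5% support and ≥ 10
reads.

A seeded synthetic-data generator (`simulateCohort()` and friends) emulates
the study design the statistics assume — multi-group cohorts sampled across
11 brain regions and blood, germline haplotypes from a toy clade tree,
region-varying somatic heteroplasmy (5–35%), negative-binomial coverage,
base errors, A>C artifacts at motif sites, repeat stutter — and pairs every
dataset with its truth set, so the entire pipeline is testable offline.

The shipped reference is an rCRS-frame stand-in built from a real human
mitochondrial genome remapped into rCRS coordinates and corrected to the
documented rCRS content at all annotated positions (see
`?rCRSReference` and the methods vignette); its file is labelled
`rCRS_synthetic.fasta` accordingly.

## Worked example

```r
library(mitoplasmy)
ref <- rCRSReference()
th  <- thresholdConfig()     # 95% homoplasmy, 200 reads, 5% blood cutoff

## classify one position from its allele counts
classifyPosition(c(T = 811, C = 189), "T", th, position = 16519)
#>   position ref classification major_allele major_fraction alt heteroplasmy_level coverage
#> 1    16519   T  heteroplasmic            T          0.811   C              0.189     1000
```

The T/C site at 16519 is heteroplasmic at level 18.9% — the C fraction of
its 1000 reads.

```r
annotateVariant(ref, 9160, "T", "C")
#>   position ref alt region_class gene codon_index ref_aa alt_aa aa_change synonymous
#> 1     9160   T   C      protein ATP6         212    Tyr    His Tyr212His      FALSE
```

The T>C substitution at 9160 falls in codon 212 of ATP6 and replaces
tyrosine with histidine — non-synonymous.

```r
loci  <- defaultRepeatLoci(ref)
reads <- simulateRepeatReads(c(`5` = .60, `6` = .25, `7` = .15),
                             stutterRate = 0, nReads = 1500,
                             locus = loci$CA514, seed = 514)
callMultiplasmy(repeatDistribution(reads, loci$CA514))
#> MultiplasmyCall: lengths {5,6,7} multiplasmic
```

A 60/25/15% mixture of 5/6/7 CA units is called tri-allelic multiplasmy.

```r
coh <- cohortFromLociTable(caseOnlyLoci())
burdenTable(partitionVariants(coh), c(Control = 20, BD = 14, MDD = 15, SZ = 14))
#>     group n_subjects mutations      rate         z
#> 1 Control         20         0 0.0000000 -3.944053
#> 2      BD         14        14 1.0000000  0.942809
#> 3     MDD         15        13 0.8666667  0.390360
#> 4      SZ         14        22 1.5714286  3.367175
```

The packaged case-only loci table expands to 49 non-synonymous
observations at 37 loci; schizophrenia carries 22 of them across its 14
subjects, a rate of 1.57 exclusive non-synonymous mutations per subject
(the z column is the package's Poisson-rate standardisation against the
pooled rate).

`runPipeline(pipelineConfig(metadata, outputDir))` runs the whole chain —
calling, artifact flagging, annotation, novelty, haplogroup exclusion,
partition and burden — over a cohort metadata table and writes per-sample
VCFs and consensus FASTAs, report TSVs and a JSON run manifest.

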