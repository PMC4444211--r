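---
title: "Calling heteroplasmy, multiplasmy and mutation burden in mtDNA deep sequencing"
author: "mitoplasmy package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling heteroplasmy, multiplasmy and mutation burden in mtDNA deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoplasmy)
```

## The model

Mitochondria carry their own 16,569-base circular genome in hundreds to
thousands of copies per cell. A variant can therefore exist at any mutant
fraction between 0 and 1 within one tissue sample. With deep sequencing
the per-position allele counts estimate that fraction directly, and the
package's classification model is deliberately simple and fully
thresholded:

* let $d$ be the read depth at a position and $m$ the count of the most
  frequent base among A, C, G, T. Positions with $d < 200$ are *filtered*
  (no call is attempted);
* if $m/d \ge 0.95$ and the major base differs from the reference, the
  site is a *homoplasmic variant*; if the major base equals the
  reference, the site is *reference*;
* if $m/d < 0.95$ the site is *heteroplasmic*, and the reported
  heteroplasmy level is the read fraction of the largest non-reference
  allele — whichever side of 50% it falls on, so a 90% C / 10% T site at
  a T reference is heteroplasmic at level 0.90.

The 95% boundary is **inclusive** for homoplasmy. The two published
verbal definitions ("major allele < 95%" for heteroplasmy, "95% to 100%"
for homoplasmy) are only consistent with that choice, so a major
fraction of exactly 0.95 is homoplasmic here. Deletion reads count
toward depth but are never called as substitution variants; length
variation is handled only at the designated repeat loci (below).

Under this model the heteroplasmy estimator is the binomial proportion
$\hat f = X/d$, unbiased with standard deviation
$\sqrt{f(1-f)/d}$. The test suite verifies both properties at $d = 1000$
over planted fractions 0.05–0.5 (bias below 0.005, RMSE within 1.2× the
binomial standard deviation).

## Reference, coordinates and the genetic code

All coordinates are 1-based inclusive, the mitochondrial community
convention, and the genome is treated as circular: wrap-around arithmetic
is centralised in `circularPosition()` and used by the context-window and
codon machinery, nowhere else.

The packaged reference (`rCRSReference()`) is an **rCRS-frame synthetic
stand-in**, not a verbatim copy of NC_012920: it was built from the real
human mitochondrial genome NC_001807.4, remapped into rCRS coordinates
(removing that sequence's extra bases in the D310 and D16189 tracts and
restoring the historical 'N' placeholder at 3107), and then corrected to
the documented rCRS state at every position the packaged tables annotate:
the four error-hotspot contexts, all 43 annotated coding loci, the
(CA)$_5$ repeat at 514, both poly-C tracts, and the universally
documented rCRS reference alleles at the classic polymorphic positions
(73, 263, 750, 1438, 2706, 4769, 7028, 8860, 15326, ...). Every protein
gene translates without internal stop codons and each acceptance-visible
position carries the true rCRS base; residual private differences may
remain at unannotated positions, which is why the file is labelled
`rCRS_synthetic.fasta`. Analyses of real data should substitute a
verbatim NC_012920 FASTA via `loadReference()`; all code paths are
identical.

The gene model ships as a versioned TSV (13 protein genes, 2 rRNAs, 22
tRNAs, NC_012920 coordinates) exposed as a circular `GRanges`. The known
overlaps (ATP8/ATP6 at 8527–8572, ND4L/ND4 at 10760–10766) are both
present; annotation reports one row per overlapping gene, report writers
emit the first gene in model order, and a variant counts as
non-synonymous for burden purposes when it is non-synonymous in at least
one overlapping gene. Genes whose length is not a multiple of three end
in an incomplete stop codon completed by polyadenylation; positions in
such terminal codons are annotated as incomplete rather than translated.

Translation uses the vertebrate mitochondrial code (NCBI table 2:
ATA = Met, TGA = Trp, AGA/AGG = stop), obtained from Biostrings. For the
light-strand gene ND6 the codon index counts from the gene's 3' end in
heavy-strand coordinates and codon bases are reverse-complemented, which
is what turns the heavy-strand A>C call at 14280 into the coding-strand
Ser132Ala change. Codons touching the 'N' placeholder are reported as
explicitly untranslatable and excluded from synonymous/non-synonymous
tallies rather than silently guessed.

## Artifact filtering

Heteroplasmic A>C transversions are over-called by the platform in a
fixed sequence context: a run of at least two A's ending at the variant
position (the variant A itself counts toward the run) followed
immediately by at least two C's. `isAcHotspot()` implements the
predicate on the circular genome and agrees with a brute-force
regular-expression oracle at all 16,569 positions. A small blacklist
carries the validated non-A/C false positives (T3488A, T6415A, G9801T)
and the four motif loci. Flags *annotate* calls — nothing is deleted —
and burden statistics exclude flagged calls by default via a toggle,
mirroring the report-then-exclude convention of the source analysis.
Position 302's flagged context is treated as a substitution hotspot even
though it sits at the edge of the D310 length-noise region; the
ambiguity is inherent in the published table.

## Repeat loci and multiplasmy

Multiplasmy is heteroplasmy of repeat *length*. Per-read lengths are
extracted between exact-match 5-base anchors taken from the reference
itself (no alignment, no mismatch tolerance by default): a read spans
the locus when both anchors match with only whole or partial unit copies
between them, and the count of complete copies is its length. This is
deterministic, order-independent and adequate at mitochondrial depths;
reads failing the anchors are counted as discarded.

Three loci are configured:

* **CA514** — the (CA)$_n$ dinucleotide repeat at 514–523, reference
  (CA)$_5$;
* **D310** — modelled as the 5' C-run preceding the fixed T at 310
  (reference 7 C). The published description quotes an 11-base motif
  "from position 303 to 316", a 14-position span; the package derives
  the tract from the reference sequence instead of the quoted
  coordinates and notes the discrepancy here;
* **D16189** — the run 16184–16193, interrupted at 16189 in the
  reference. In 16189C carriers the tract becomes an uninterrupted run
  of 10 C, which is the configuration in which its length polymorphism
  is actually observed; reference-configuration reads (with the T) do
  not span under the single-unit model and the reference length is
  recorded as 10.

A repeat length is a supported allele when it has at least 10 spanning
reads and at least 5% of them; a locus is multiplasmic when two or more
lengths are supported. The published analysis states no support
thresholds, so these two values are this package's choice — both are
arguments of `callMultiplasmy()` — set so that 2% stutter on a pure
allele at realistic depths never produces a spurious second allele (a
property the tests check). Stutter is *not* modelled out during calling:
raw length mixtures are reported, matching how the source tables report
them; a stutter-aware denoising mode is deliberately deferred.

The deletion/wild-type ratio divides reads with fewer units than the
reference by reads with exactly the reference count, and is flagged
undefined when the denominator is empty.

## Cohort statistics

The case/control comparison operates on one tissue (DLPFC by default)
and, by default, on artifact-unflagged non-synonymous homoplasmic calls;
each inclusion criterion is a toggle. "Cases" defaults to BD, MDD and SZ;
METH users are a separate group excluded from the partition (toggleable).
A locus (position, alt) is *case-only* when observed in at least one
case and zero controls; the case-only/control-only/shared sets are
asserted disjoint and covering on every run. Observations are counted
once per subject and locus.

The burden table reports, per group, the exclusive observations, the
per-subject rate, and a z standardisation against the pooled rate:
$z = (c/n - \bar r)/\sqrt{\bar r / n}$, the normal approximation to a
Poisson count with mean $n\bar r$. The published table's z values do not
follow from any standard formula applied to its printed counts, so the
package fixes this documented form (recorded in the output's metadata
attribute) and treats the *counts and rates* as the reproducible
surface; the z calibration is instead verified against its own null
(type-I error ≈ 5% at |z| > 1.96 over 2000 simulated null cohorts, with
the true pooled rate supplied). The two-sample rate test uses the
pooled-rate normal approximation, and the dichotomised comparison
("5 or more non-synonymous mutations") is a one-sided hypergeometric
tail computed directly and cross-checked in the tests against both an
exhaustive enumeration oracle and `fisher.test`. No multiple-testing
correction is applied by default, matching the source analysis; a
Bonferroni toggle would be a one-liner for reuse.

Blood–brain comparison: homoplasmic concordance is the Jaccard overlap
between the blood set and the union of brain-region sets (1.0 for
identical sets), and a heteroplasmic locus is *brain-only* when it
reaches the 5% blood-detection cutoff in some brain region but stays
below it (or is absent) in blood. Per-region heteroplasmy profiles
report level and coverage per region with coverage-filtered regions
listed separately.

## The synthetic-data generator

`simulateCohort()` emulates the study conditions the statistics assume,
and its defaults *are* those conditions: groups of 20/14/15/14/6
subjects (Control/BD/MDD/SZ/METH), all with a DLPFC sample, 11 subjects
sampled in all 11 brain regions and 3 of those also in blood; germline
haplotypes drawn from a 3-clade toy tree (8 defining variants per clade,
so haplogroup exclusion has a planted truth) plus Poisson(12) private
homoplasmic variants; per-group extra non-synonymous mutations at
Poisson rates 0.55/1.00/0.87/1.57 per subject (the published per-group
rates, used as simulation parameters); somatic heteroplasmies at
Poisson(2) loci per subject, biased 70:30 toward the control region,
with an independent uniform 5–35% level per brain region (the span
observed across regions in the source data) and level 0 in blood;
negative-binomial coverage with mean 8,850 (the combined platform
average; the per-platform means were about 3,766 and 9,775) and
dispersion size 8, chosen because the published per-variant coverages
span two orders of magnitude and a Poisson model is far too narrow;
0.1% base error spread uniformly over the three non-template bases; an
8% A>C artifact fraction injected at every motif-matching A site,
strong enough to produce the robustly heteroplasmic artifact calls the
error-hotspot table reports; and 2% repeat stutter. All randomness
flows from the single config seed, and every dataset is paired with its
truth set.

What the generator does **not** emulate: read-level qualities and
alignment (counts are generated directly), NUMT contamination, platform
differences beyond the coverage model, linkage between somatic loci, and
realistic population phylogenetics. Passing recovery tests therefore
demonstrates correctness of the *analysis* under its stated sampling
model, not robustness to upstream alignment artifacts.

## Numerical and engineering choices

* Ties for the major allele are broken deterministically in base order
  A < C < G < T and flagged.
* The motif predicate, repeat extraction and all classification rules
  are deterministic; the only randomness anywhere is in the generator,
  always seeded.
* Count tables are plain TSV (`pos A C G T del`); calls are written as
  VCF 4.2 through VariantAnnotation with the allele fraction, depth,
  classification, consequence and novelty as INFO fields and artifact
  flags as FILTER values; consensus sequences as FASTA through
  Biostrings. The run manifest records the package version, seed,
  effective configuration, a hash of its semantic part (excluding the
  output directory) and per-stage call counts.
* Degenerate inputs have defined behaviour rather than errors where a
  result is still meaningful: zero spanning reads yield an abstained
  multiplasmy call, a missing catalog yields explicit `unknown` novelty,
  a zero pooled rate yields z = 0 or +Inf, degenerate Fisher margins
  yield p = 1, and an undefined deletion ratio is flagged.

## Problem sizes used by the shipped tests

The test suite runs the full pipeline on seeded cohorts of 2–4 subjects
restricted to a few thousand genome positions, 60–100 replicate
parameter-recovery runs at coverage 1000–8850, 2000-replicate null
calibrations and 1000-replicate power checks; these sizes were chosen to
exercise every code path and statistical property while keeping the
default suite fast enough to run habitually. The statistical tolerances
are derived from the binomial/multinomial sampling error of each check
(typically 4 standard deviations), never tuned to outcomes.

## Known limitations

* The shipped reference is anchor-exact but synthetic; verbatim rCRS
  analyses should load their own copy.
* Haplogroup-defining variants are excluded only against a user-supplied
  table; the package performs no haplogroup *calling*.
* Damage-prediction labels are opaque pass-through strings; no predictor
  is run.
* Repeat calling reports raw mixtures; severe stutter would require the
  deferred denoising mode.
* The BAM tallying adapter (`countTableFromBam()`) applies base- and
  mapping-quality filters (both 20 by default) but no realignment or
  base-quality recalibration; the pipeline's contract otherwise starts
  at count tables.
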