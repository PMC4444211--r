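Package: mitoplasmy
Title: Heteroplasmy, Multiplasmy and Mutation Burden in Mitochondrial DNA
    Deep Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies homoplasmic and heteroplasmic variants from
    per-position allele counts of deep-sequenced human mitochondrial DNA,
    calls repeat-length heteroplasmy (multiplasmy) at the hypervariable
    D-loop repeat loci, filters platform-specific A>C sequencing-error
    hotspots by sequence-context motif, annotates variant consequences
    under the vertebrate mitochondrial genetic code including light-strand
    genes, classifies novelty against a population frequency catalog, and
    computes case/control mutation-burden statistics for cohorts sampled
    across multiple brain regions and blood. A seeded synthetic-data
    generator emulates multi-region cohorts with germline haplotypes,
    region-varying somatic heteroplasmy, repeat stutter and context-
    dependent artifacts so that every pipeline stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, VariantDetection, Sequencing
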