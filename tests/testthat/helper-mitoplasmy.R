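## shared fixtures, loaded once per test run

.mp_env <- new.env()

refFixture <- function() {
  if (is.null(.mp_env$ref)) .mp_env$ref <- rCRSReference()
  .mp_env$ref
}

genesFixture <- function() {
  if (is.null(.mp_env$genes)) .mp_env$genes <- mitoGenes()
  .mp_env$genes
}

## count table for an error-free sample exactly matching a haplotype
perfectCountTable <- function(haplotype, depth = 1000L,
                              positions = seq_len(nchar(haplotype))) {
  base <- substring(haplotype, positions, positions)
  tab <- data.frame(pos = positions, A = 0L, C = 0L, G = 0L, T = 0L,
                    del = 0L)
  for (b in c("A", "C", "G", "T")) tab[[b]][base == b] <- depth
  tab
}

## independent whole-gene translation oracle (Biostrings, vertebrate
## mitochondrial code); used to cross-check per-codon annotation
oracleGeneProtein <- function(seqString, start, end, light = FALSE) {
  gene <- Biostrings::DNAString(substring(seqString, start, end))
  if (light) gene <- Biostrings::reverseComplement(gene)
  ncod <- length(gene) %/% 3L
  gene <- Biostrings::subseq(gene, 1L, ncod * 3L)
  as.character(Biostrings::translate(gene,
    genetic.code = Biostrings::getGeneticCode("SGC1"),
    if.fuzzy.codon = "X"))
}

## exhaustive hypergeometric enumeration oracle for one-sided 2x2 tests:
## P(cases with >= cutoff >= observed), enumerating all tables with the
## observed margins
oracleFisherOneSided <- function(caseHigh, caseLow, ctrlHigh, ctrlLow) {
  n1 <- caseHigh + caseLow
  n0 <- ctrlHigh + ctrlLow
  K <- caseHigh + ctrlHigh
  ks <- max(0L, K - n0):min(K, n1)
  probs <- vapply(ks, function(k)
    choose(n1, k) * choose(n0, K - k) / choose(n1 + n0, K), numeric(1))
  sum(probs[ks >= caseHigh])
}
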