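th <- thresholdConfig()

test_that("classifyPosition reproduces the published threshold behaviour", {
  ## published heteroplasmy: 16519 T/C at 18.9%
  r <- classifyPosition(c(T = 811, C = 189), "T", th, position = 16519)
  expect_identical(r$classification, "heteroplasmic")
  expect_equal(r$heteroplasmy_level, 0.189)
  ## pure non-reference site
  r <- classifyPosition(c(C = 1000), "T", th)
  expect_identical(r$classification, "homoplasmic_variant")
  expect_identical(r$major_allele, "C")
  expect_equal(r$major_fraction, 1)
  ## 200-read coverage boundary
  r <- classifyPosition(c(A = 190, C = 9), "A", th)
  expect_identical(r$classification, "filtered")
  expect_match(r$filter_reason, "coverage < 200")
  expect_identical(classifyPosition(c(A = 191, C = 9), "A", th)$classification,
                   "reference")
  ## the 95% boundary is inclusive for homoplasmy
  expect_identical(classifyPosition(c(A = 950, G = 50), "T", th)$classification,
                   "homoplasmic_variant")
  expect_identical(classifyPosition(c(A = 9499, G = 501), "T", th)$classification,
                   "heteroplasmic")
  expect_error(classifyPosition(c(A = 500), "Z", th), "refBase")
})

test_that("classification partitions all passing sites (brute force over fraction grid)", {
  depth <- 10000L
  for (major in seq(0L, depth, by = 250L)) {
    counts <- c(A = major, G = depth - major)
    r <- classifyPosition(counts, "A", th)
    cls <- r$classification
    expect_identical(sum(cls %in% c("reference", "homoplasmic_variant",
                                    "heteroplasmic")), 1L)
    majFrac <- max(counts) / depth
    if (majFrac < 0.95) expect_identical(cls, "heteroplasmic")
    else if (names(which.max(counts)) != "A")
      expect_identical(cls, "homoplasmic_variant")
    else expect_identical(cls, "reference")
  }
})

test_that("allele fractions are conserved and minor-allele growth never promotes to homoplasmy", {
  set.seed(11)
  for (i in 1:50) {
    counts <- setNames(rpois(5, c(800, 30, 5, 100, 10)),
                       c("A", "C", "G", "T", "del"))
    r <- classifyPosition(counts, "A", th)
    expect_equal(r$major_fraction,
                 max(counts[c("A", "C", "G", "T")]) / sum(counts))
  }
  ## monotonicity: raising the minor count at fixed depth can only move a
  ## call away from homoplasmy
  depth <- 2000L
  seen <- character(0)
  for (minor in seq(0L, 1000L, by = 50L)) {
    r <- classifyPosition(c(C = depth - minor, T = minor), "T", th)
    seen <- c(seen, r$classification)
  }
  ## once heteroplasmic, never homoplasmic again as minor grows
  het <- which(seen == "heteroplasmic")
  if (length(het))
    expect_false(any(seen[seq(min(het), length(seen))] ==
                       "homoplasmic_variant"))
})

test_that("callSample finds exactly the planted variants", {
  ref <- refFixture()
  positions <- 1:400
  hap <- refSequence(ref)
  otherBase <- function(b) setdiff(c("G", "A", "T", "C"), b)[1]
  planted_hom <- data.frame(position = c(50L, 150L, 250L))
  planted_hom$alt <- vapply(planted_hom$position, function(p)
    otherBase(substring(hap, p, p)), "")
  for (i in 1:3) substring(hap, planted_hom$position[i],
                           planted_hom$position[i]) <- planted_hom$alt[i]
  tab <- perfectCountTable(hap, depth = 1000L, positions = positions)
  ## two planted heteroplasmies at 20% and 40%
  plantHet <- function(tab, pos, frac) {
    rb <- substring(hap, pos, pos)
    alt <- otherBase(rb)
    n <- round(1000 * frac)
    tab[tab$pos == pos, rb] <- 1000L - n
    tab[tab$pos == pos, alt] <- n
    tab
  }
  tab <- plantHet(tab, 320L, 0.2)
  tab <- plantHet(tab, 380L, 0.4)
  res <- callSample(tab, ref, th)
  expect_identical(nrow(res$calls), 5L)
  expect_identical(sum(res$calls$classification == "homoplasmic_variant"), 3L)
  expect_identical(sum(res$calls$classification == "heteroplasmic"), 2L)
  expect_setequal(res$calls$position[res$calls$classification ==
                    "homoplasmic_variant"], planted_hom$position)
  expect_equal(res$calls$heteroplasmy_level[res$calls$position == 320], 0.2)

  ## reference-identical table yields no calls
  res0 <- callSample(perfectCountTable(refSequence(ref), 1000L, positions),
                     ref, th)
  expect_identical(nrow(res0$calls), 0L)

  ## under-covered site moves to the filtered report
  tab$A[tab$pos == 10] <- 0L; tab$C[tab$pos == 10] <- 0L
  tab$G[tab$pos == 10] <- 0L; tab$T[tab$pos == 10] <- 100L
  res2 <- callSample(tab, ref, th)
  expect_false(10L %in% res2$calls$position)
  expect_true(10L %in% res2$filtered$position)
  expect_match(res2$filtered$filter_reason[1], "coverage")

  ## duplicate positions are rejected
  expect_error(callSample(rbind(tab, tab[1, ]), ref, th), "duplicate")
})

test_that("consensus equals the simulated truth and masks sub-coverage sites", {
  ref <- refFixture()
  positions <- 1:300
  hap <- refSequence(ref)
  substring(hap, 100, 100) <- "G"
  tab <- perfectCountTable(hap, 1000L, positions)
  cons <- buildConsensus(tab, th, genomeLength = 300L)
  expect_identical(cons$sequence, substring(hap, 1, 300))
  expect_identical(length(cons$mask), 0L)
  ## all positions under-covered -> all-N consensus
  low <- perfectCountTable(hap, 10L, positions)
  consLow <- buildConsensus(low, th, genomeLength = 300L)
  expect_identical(consLow$sequence, strrep("N", 300))
  ## two samples from the same germline give identical consensus
  set.seed(5)
  t1 <- simulatePileup(substring(hap, 1, 300), coverageMean = 3000,
                       errorRate = 0.001)
  t2 <- simulatePileup(substring(hap, 1, 300), coverageMean = 3000,
                       errorRate = 0.001)
  expect_identical(buildConsensus(t1, th, 300L)$sequence,
                   buildConsensus(t2, th, 300L)$sequence)
})

test_that("transitions and transversions are separated by purine/pyrimidine class", {
  expect_identical(transitionOrTransversion("C", "T"), "transition")
  expect_identical(transitionOrTransversion("A", "G"), "transition")
  expect_identical(transitionOrTransversion("A", "C"), "transversion")
  expect_identical(transitionOrTransversion(c("G", "T"), c("A", "A")),
                   c("transition", "transversion"))
  expect_error(transitionOrTransversion("A", "A"), "differ")
})

test_that("heteroplasmy estimates are unbiased with near-binomial error", {
  ## planted fractions at coverage 1000; RMSE within 1.2x the binomial sd
  set.seed(20260922)
  ref <- refFixture()
  hap <- substring(refSequence(ref), 16510, 16530)
  for (f in c(0.1, 0.3)) {
    est <- replicate(300, {
      tab <- simulatePileup(hap, data.frame(position = 10, alt = "C",
                                            fraction = f),
                            coverageMean = 1000, coverageSize = 1e9,
                            errorRate = 0)
      r <- classifyPosition(setNames(as.numeric(tab[10, c("A","C","G","T","del")]),
                                     c("A","C","G","T","del")),
                            substring(hap, 10, 10), th)
      r$heteroplasmy_level
    })
    expect_lt(abs(mean(est) - f), 0.005)
    expect_lt(sqrt(mean((est - f)^2)), 1.2 * sqrt(f * (1 - f) / 1000))
  }
})

test_that("the BAM adapter tallies bases with quality filters applied", {
  ## three reads over a toy reference: two agree with ACGTACGTAC, one
  ## carries a T>G at position 4; one low-quality base must be dropped
  dir <- tempfile(); dir.create(dir)
  refFa <- file.path(dir, "toy.fa")
  writeLines(c(">chrM", strrep("ACGTACGTAC", 10)), refFa)
  sam <- file.path(dir, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrM\tLN:100",
    paste("r1", 0, "chrM", 1, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r2", 0, "chrM", 1, 60, "10M", "*", 0, 0,
          "ACGGACGTAC", "IIIIIIIIII", sep = "\t"),   # T>G at pos 4
    paste("r3", 0, "chrM", 1, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "III#IIIIII", sep = "\t")),  # pos 4 base qual 2
    sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"),
                          overwrite = TRUE, indexDestination = TRUE)
  tab <- countTableFromBam(bam)
  expect_identical(tab$A[tab$pos == 1], 3L)
  ## at position 4: one T (r1), one G (r2); r3's base fails quality
  expect_identical(tab$T[tab$pos == 4], 1L)
  expect_identical(tab$G[tab$pos == 4], 1L)
  ## and the classifier consumes the adapter's output directly
  res <- classifyPosition(
    setNames(as.numeric(tab[tab$pos == 1, c("A","C","G","T","del")]),
             c("A","C","G","T","del")),
    "A", thresholdConfig(minCoverage = 1))
  expect_identical(res$classification, "reference")
})
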