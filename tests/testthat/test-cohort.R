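test_that("the packaged loci table yields the published partition and burden", {
  coh <- cohortFromLociTable(caseOnlyLoci())
  p <- partitionVariants(coh)
  expect_identical(nrow(p$case_only), 37L)
  expect_identical(sum(p$case_only$total), 49L)
  expect_identical(sum(p$case_only$BD), 14L)
  expect_identical(sum(p$case_only$MDD), 13L)
  expect_identical(sum(p$case_only$SZ), 22L)
  expect_identical(nrow(p$control_only), 0L)
  b <- burdenTable(p, c(Control = 20, BD = 14, MDD = 15, SZ = 14))
  expect_equal(b$rate[b$group == "SZ"], 22 / 14)
  expect_identical(b$n_subjects[b$group == "SZ"], 14)
  expect_identical(b$mutations[b$group == "BD"], 14L)
  expect_identical(b$mutations[b$group == "MDD"], 13L)
})

test_that("partition sets are disjoint and cover all observed loci", {
  mkCohort <- function(callRows, subjectRows) {
    mitoCohort(callRows, subjectRows)
  }
  subj <- data.frame(subject = c("Control-01", "SZ-01"),
                     diagnosis = c("Control", "SZ"))
  row <- function(s, d, pos, alt) data.frame(subject = s, diagnosis = d,
    region = "DLPFC", position = pos, ref = "A", alt = alt,
    classification = "homoplasmic_variant", synonymous = FALSE,
    nonsynonymous_any = TRUE, hotspot_flag = FALSE, stringsAsFactors = FALSE)
  ## every variant in both a case and a control -> no exclusives
  calls <- rbind(row("Control-01", "Control", 100L, "G"),
                 row("SZ-01", "SZ", 100L, "G"))
  p <- partitionVariants(mkCohort(calls, subj))
  expect_identical(nrow(p$case_only), 0L)
  expect_identical(nrow(p$control_only), 0L)
  expect_identical(nrow(p$shared), 1L)
  ## single-subject case cohort: everything is case-only
  soloSubj <- data.frame(subject = "SZ-01", diagnosis = "SZ")
  solo <- partitionVariants(mkCohort(rbind(row("SZ-01", "SZ", 1L, "G"),
                                           row("SZ-01", "SZ", 2L, "T")),
                                     soloSubj))
  expect_identical(nrow(solo$case_only), 2L)
  ## random cohorts: the three sets always cover all loci disjointly
  set.seed(77)
  for (rep in 1:20) {
    ns <- 8L
    subj2 <- data.frame(
      subject = sprintf("S%02d", 1:ns),
      diagnosis = sample(c("Control", "BD", "MDD", "SZ"), ns, replace = TRUE))
    calls2 <- do.call(rbind, lapply(1:ns, function(i) {
      k <- rpois(1, 3)
      if (k == 0) return(NULL)
      row(subj2$subject[i], subj2$diagnosis[i],
          sample(50L, k), sample(c("G", "T", "C"), k, replace = TRUE))
    }))
    if (is.null(calls2)) next
    p2 <- partitionVariants(mkCohort(calls2, subj2))
    expect_identical(nrow(p2$case_only) + nrow(p2$control_only) +
                       nrow(p2$shared), p2$n_loci)
    keys <- c(paste(p2$case_only$position, p2$case_only$alt),
              paste(p2$control_only$position, p2$control_only$alt),
              paste(p2$shared$position, p2$shared$alt))
    expect_identical(anyDuplicated(keys), 0L)
  }
  expect_error(partitionVariants(mkCohort(calls[0, ],
    subj[0, ])), "empty cohort")
})

test_that("burden rates are invariant to subject order and call duplication", {
  coh <- cohortFromLociTable(caseOnlyLoci())
  p1 <- partitionVariants(coh)
  shuf <- mitoCohort(cohortCalls(coh)[sample(nrow(cohortCalls(coh))), ],
                     cohortSubjects(coh)[sample(nrow(cohortSubjects(coh))), ])
  p2 <- partitionVariants(shuf)
  expect_identical(sum(p1$case_only$total), sum(p2$case_only$total))
  dup <- mitoCohort(rbind(cohortCalls(coh), cohortCalls(coh)),
                    cohortSubjects(coh))
  p3 <- partitionVariants(dup)
  expect_identical(sum(p3$case_only$total), sum(p1$case_only$total))
})

test_that("the rate z standardisation matches closed-form arithmetic", {
  expect_equal(groupRateZ(10, 10, 1.0), 0)
  expect_equal(groupRateZ(20, 10, 1.0), (2 - 1) / sqrt(0.1))
  expect_identical(groupRateZ(3, 10, 0), Inf)
  expect_identical(groupRateZ(0, 10, 0), 0)
  expect_error(groupRateZ(1, 0, 1), "n must be")
})

test_that("the null rate z is calibrated: type-I error about 5% over 2000 cohorts", {
  set.seed(2000)
  n <- 14; rate0 <- 0.95
  z <- groupRateZ(rpois(2000, n * rate0), n, rate0)
  expect_lt(abs(mean(z)), 0.08)
  typeI <- mean(abs(z) > 1.96)
  expect_gt(typeI, 0.03)
  expect_lt(typeI, 0.07)
})

test_that("permuting diagnosis labels destroys planted burden signal", {
  coh <- cohortFromLociTable(caseOnlyLoci())
  sizes <- c(Control = 20, BD = 14, MDD = 15, SZ = 14)
  set.seed(8)
  zs <- replicate(100, {
    subj <- cohortSubjects(coh)
    subj$diagnosis <- sample(subj$diagnosis)
    calls <- cohortCalls(coh)
    calls$diagnosis <- subj$diagnosis[match(calls$subject, subj$subject)]
    p <- partitionVariants(mitoCohort(calls, subj))
    b <- burdenTable(p, sizes)
    b$z[b$group == "SZ"]
  })
  expect_lt(abs(mean(zs)), 0.25)
})

test_that("the two-sample rate test matches its documented formula", {
  same <- twoGroupRateTest(10, 10, 10, 10)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  r <- twoGroupRateTest(22, 14, 11, 20)
  pooled <- (22 + 11) / (14 + 20)
  zExp <- (22 / 14 - 11 / 20) / sqrt(pooled * (1 / 14 + 1 / 20))
  expect_equal(r$z, zExp)
  expect_equal(r$p, 2 * pnorm(-abs(zExp)))
  expect_equal(twoGroupRateTest(0, 5, 0, 5)$p, 1)
})

test_that("rate-test power on a planted 3x ratio matches the analytic approximation", {
  set.seed(300)
  n <- 20; r0 <- 0.5; r1 <- 1.5
  rejected <- replicate(1000, {
    twoGroupRateTest(rpois(1, n * r1), n, rpois(1, n * r0), n)$p < 0.05
  })
  ## analytic normal-approximation power for the pooled-variance z test
  pooled <- (r1 + r0) / 2
  se0 <- sqrt(pooled * 2 / n)
  se1 <- sqrt((r1 + r0) / n)
  power <- pnorm((r1 - r0 - 1.96 * se0) / se1)
  mcErr <- 4 * sqrt(power * (1 - power) / 1000)
  expect_lt(abs(mean(rejected) - power), mcErr + 0.02)
})

test_that("the dichotomised Fisher test equals the hypergeometric enumeration oracle", {
  mkCounts <- function(caseHigh, caseLow, ctrlHigh, ctrlLow, cutoff = 5L) {
    data.frame(
      subject = sprintf("s%03d", seq_len(caseHigh + caseLow + ctrlHigh +
                                           ctrlLow)),
      diagnosis = c(rep("SZ", caseHigh + caseLow),
                    rep("Control", ctrlHigh + ctrlLow)),
      n_mutations = c(rep(cutoff + 1L, caseHigh), rep(0L, caseLow),
                      rep(cutoff + 2L, ctrlHigh), rep(1L, ctrlLow)))
  }
  r <- fisherDichotomized(mkCounts(2, 8, 8, 2))
  expect_equal(r$p, oracleFisherOneSided(2, 8, 8, 2))
  expect_identical(unname(r$table[1, 1]), 2L)
  ## no subject above cutoff -> degenerate p = 1
  expect_equal(fisherDichotomized(mkCounts(0, 10, 0, 10))$p, 1)
  ## maximal separation -> minimal tail value
  rMax <- fisherDichotomized(mkCounts(10, 0, 0, 10))
  expect_equal(rMax$p, oracleFisherOneSided(10, 0, 0, 10))
  expect_equal(rMax$p, 1 / choose(20, 10))
  ## random tables with margins <= 40: oracle and fisher.test agreement
  set.seed(99)
  for (i in 1:60) {
    a <- sample(0:10, 4, replace = TRUE)
    if (sum(a[1:2]) == 0 || sum(a[3:4]) == 0 ||
        sum(a[c(1, 3)]) == 0 || sum(a[c(2, 4)]) == 0) next
    r <- fisherDichotomized(mkCounts(a[1], a[2], a[3], a[4]))
    expect_equal(r$p, oracleFisherOneSided(a[1], a[2], a[3], a[4]))
    ft <- fisher.test(matrix(a, 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("blood-brain comparison finds exactly the planted brain-only heteroplasmies", {
  th <- thresholdConfig()
  mkCall <- function(region, pos, cls, level) data.frame(
    subject = "Control-01", diagnosis = "Control", region = region,
    position = pos, ref = "T", alt = "C", classification = cls,
    heteroplasmy_level = level, coverage = 5000, stringsAsFactors = FALSE)
  subj <- data.frame(subject = "Control-01", diagnosis = "Control")
  ## identical homoplasmic sets -> concordance 1, nothing brain-only
  calls <- rbind(mkCall("blood", 100L, "homoplasmic_variant", 1),
                 mkCall("DLPFC", 100L, "homoplasmic_variant", 1))
  r <- bloodBrainConcordance(mitoCohort(calls, subj), "Control-01", th)
  expect_equal(r$homoplasmic_concordance, 1)
  expect_identical(nrow(r$brain_only), 0L)
  ## brain 8% / blood 2% -> brain-only under the 5% cutoff
  calls <- rbind(mkCall("DLPFC", 200L, "heteroplasmic", 0.08),
                 mkCall("blood", 200L, "heteroplasmic", 0.02),
                 mkCall("blood", 100L, "homoplasmic_variant", 1),
                 mkCall("DLPFC", 100L, "homoplasmic_variant", 1))
  r <- bloodBrainConcordance(mitoCohort(calls, subj), "Control-01", th)
  expect_identical(r$brain_only$position, 200L)
  ## five planted brain-only loci are all recovered
  brainPos <- c(2487L, 5755L, 13706L, 300L, 400L)
  calls <- rbind(
    do.call(rbind, lapply(brainPos, function(p)
      mkCall("HIPP", p, "heteroplasmic", 0.09))),
    mkCall("blood", 100L, "homoplasmic_variant", 1),
    mkCall("HIPP", 100L, "homoplasmic_variant", 1))
  r <- bloodBrainConcordance(mitoCohort(calls, subj), "Control-01", th)
  expect_setequal(r$brain_only$position, brainPos)
  ## missing blood sample is an error
  noBlood <- mitoCohort(mkCall("DLPFC", 1L, "heteroplasmic", 0.1), subj)
  expect_error(bloodBrainConcordance(noBlood, "Control-01", th), "blood")
})

test_that("region heteroplasmy profiles recover planted region-varying levels", {
  ref <- refFixture(); th <- thresholdConfig()
  regions <- c("NACC", "THAL", "DLPFC", "HIPP")
  planted <- c(NACC = 0.063, THAL = 0.325, DLPFC = 0.15, HIPP = 0.22)
  set.seed(64)
  hap <- substring(refSequence(ref), 16080, 16092)  # window holding 16086
  calls <- do.call(rbind, lapply(regions, function(rg) {
    tab <- simulatePileup(hap, data.frame(position = 7, alt = "C",
                                          fraction = planted[[rg]]),
                          coverageMean = 8000, errorRate = 0.001)
    tab$pos <- tab$pos + 16079L
    res <- callSample(tab, ref, th, sample = rg)
    k <- res$calls
    k$subject <- "C-58"; k$diagnosis <- "Control"; k$region <- rg
    k
  }))
  coh <- mitoCohort(calls, data.frame(subject = "C-58",
                                      diagnosis = "Control"))
  prof <- regionHeteroplasmyProfile(coh, "C-58", 16086L)
  got <- setNames(prof$profile$level, prof$profile$region)
  for (rg in regions) {
    tol <- 4 * sqrt(planted[[rg]] * (1 - planted[[rg]]) / 8000) + 0.002
    expect_lt(abs(got[[rg]] - planted[[rg]]), tol)
  }
  expect_gt(prof$range[["span"]], 0.2)
  ## a region below coverage is listed as filtered, not profiled
  filtRow <- calls[1, ]
  filtRow$region <- "CB"
  filtRow$alt <- NA_character_
  filtRow$classification <- "filtered"
  filtRow$heteroplasmy_level <- NA_real_
  filtRow$coverage <- 50
  coh2 <- mitoCohort(rbind(calls, filtRow),
                     data.frame(subject = "C-58", diagnosis = "Control"))
  prof2 <- regionHeteroplasmyProfile(coh2, "C-58", 16086L)
  expect_identical(prof2$filtered, "CB")
  expect_false("CB" %in% prof2$profile$region)
})
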