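## Cohort-level statistics: case-only/control-only partition of observed
## loci, per-group exclusive non-synonymous burden with a Poisson-rate
## z standardisation, dichotomised Fisher comparison, blood-brain
## concordance and per-region heteroplasmy profiles.

.DIAGNOSES <- c("Control", "BD", "MDD", "SZ", "METH")
.REGIONS <- c("ACC", "AMY", "CAUN", "CB", "DLPFC", "HIPP", "NACC", "OFC",
              "PUT", "SN", "THAL", "blood")

#' MitoCohort: calls and diagnoses for a sequenced cohort
#'
#' A cohort is a long-format call table (one row per sample-level call)
#' plus a subject table. Diagnoses come from the fixed vocabulary
#' \code{Control, BD, MDD, SZ, METH}; tissue labels from the controlled
#' region list (11 brain regions plus blood).
#'
#' @slot calls \code{data.frame}, one row per call, with at least
#'   \code{subject, diagnosis, region, position, ref, alt, classification}.
#' @slot subjects \code{data.frame} with \code{subject, diagnosis}.
#' @export
setClass("MitoCohort",
  representation(calls = "data.frame", subjects = "data.frame"))

setValidity("MitoCohort", function(object) {
  msg <- NULL
  need <- c("subject", "diagnosis", "region", "position", "ref", "alt",
            "classification")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns:",
                        paste(need, collapse = ", ")))
  if (!all(c("subject", "diagnosis") %in% names(object@subjects)))
    msg <- c(msg, "subjects must have columns subject, diagnosis")
  if (nrow(object@subjects) &&
      !all(object@subjects$diagnosis %in% .DIAGNOSES))
    msg <- c(msg, paste("diagnosis must be one of:",
                        paste(.DIAGNOSES, collapse = ", ")))
  if (nrow(object@calls) && !all(object@calls$region %in% .REGIONS))
    msg <- c(msg, paste("region must be one of:",
                        paste(.REGIONS, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MitoCohort", function(object) {
  cat("MitoCohort: ", nrow(object@subjects), " subjects (",
      paste(names(table(object@subjects$diagnosis)),
            table(object@subjects$diagnosis), sep = ":", collapse = ", "),
      "), ", nrow(object@calls), " calls\n", sep = "")
})

#' @rdname MitoCohort-class
#' @param calls,subjects see slots.
#' @return a \code{MitoCohort}.
#' @export
mitoCohort <- function(calls, subjects) {
  new("MitoCohort", calls = calls, subjects = subjects)
}

#' Cohort accessors
#'
#' @param cohort a \linkS4class{MitoCohort}.
#' @return \code{data.frame}.
#' @export
cohortCalls <- function(cohort) cohort@calls

#' @rdname cohortCalls
#' @export
cohortSubjects <- function(cohort) cohort@subjects

.selectBurdenCalls <- function(cohort, tissue, classifications,
                               nonsynonymousOnly, excludeFlagged) {
  k <- cohort@calls
  k <- k[k$region %in% tissue & k$classification %in% classifications, ,
         drop = FALSE]
  if (nonsynonymousOnly) {
    ns <- if ("nonsynonymous_any" %in% names(k)) k$nonsynonymous_any
          else if ("synonymous" %in% names(k)) !k$synonymous
          else stop("calls carry no synonymous annotation; run annotateCalls()")
    k <- k[!is.na(ns) & ns, , drop = FALSE]
  }
  if (excludeFlagged && "hotspot_flag" %in% names(k))
    k <- k[!k$hotspot_flag, , drop = FALSE]
  k
}

#' Partition observed loci into case-only / control-only / shared
#'
#' A locus (position, alt) is case-only iff it is observed in at least one
#' case and in zero controls within the requested tissue; control-only and
#' shared are defined symmetrically. Subjects outside \code{caseGroups}
#' and \code{controlGroup} (e.g. METH users under the default case set
#' BD/MDD/SZ) do not participate. By default only artifact-unflagged
#' non-synonymous homoplasmic variants are counted, mirroring the burden
#' analysis; each criterion is a toggle. The three sets are disjoint and
#' cover every observed locus (asserted on every run).
#'
#' @param cohort a \linkS4class{MitoCohort}.
#' @param caseGroups diagnoses counted as cases (default BD, MDD, SZ).
#' @param controlGroup the control diagnosis.
#' @param tissue region(s) compared (default DLPFC).
#' @param classifications call classes to include.
#' @param nonsynonymousOnly restrict to non-synonymous coding variants.
#' @param excludeFlagged drop error-hotspot-flagged calls.
#' @return list with \code{case_only}, \code{control_only}, \code{shared}
#'   (each a \code{data.frame} of loci with per-diagnosis observation
#'   counts and \code{total} observations on the exclusive side), and
#'   \code{n_loci}.
#' @export
partitionVariants <- function(cohort, caseGroups = c("BD", "MDD", "SZ"),
                              controlGroup = "Control", tissue = "DLPFC",
                              classifications = "homoplasmic_variant",
                              nonsynonymousOnly = TRUE,
                              excludeFlagged = TRUE) {
  if (!nrow(cohort@subjects)) stop("empty cohort")
  k <- .selectBurdenCalls(cohort, tissue, classifications,
                          nonsynonymousOnly, excludeFlagged)
  k <- k[k$diagnosis %in% c(caseGroups, controlGroup), , drop = FALSE]
  ## one observation per subject x locus
  k <- unique(k[c("subject", "diagnosis", "position", "ref", "alt")])
  key <- paste(k$position, k$alt)
  loci <- unique(k[c("position", "ref", "alt")])
  loci <- loci[order(loci$position, loci$alt), , drop = FALSE]
  lkey <- paste(loci$position, loci$alt)
  groups <- c(controlGroup, caseGroups)
  cnt <- sapply(groups, function(g)
    as.integer(table(factor(key[k$diagnosis == g], levels = lkey))))
  cnt <- matrix(cnt, nrow = length(lkey),
                dimnames = list(NULL, groups))
  loci <- cbind(loci, as.data.frame(cnt))
  caseObs <- rowSums(cnt[, caseGroups, drop = FALSE])
  ctrlObs <- cnt[, controlGroup]
  loci$total <- as.integer(caseObs + ctrlObs)
  sets <- list(
    case_only = loci[caseObs > 0 & ctrlObs == 0, , drop = FALSE],
    control_only = loci[ctrlObs > 0 & caseObs == 0, , drop = FALSE],
    shared = loci[caseObs > 0 & ctrlObs > 0, , drop = FALSE])
  stopifnot(sum(vapply(sets, nrow, 0L)) == nrow(loci))   # disjoint cover
  sets <- lapply(sets, function(d) { rownames(d) <- NULL; d })
  c(sets, list(n_loci = nrow(loci), case_groups = caseGroups,
               control_group = controlGroup))
}

#' Poisson-rate z standardisation of a group count
#'
#' Standardises an observed per-subject mutation rate against a pooled
#' rate: \code{z = (count/n - pooled) / sqrt(pooled / n)}, the normal
#' approximation for a Poisson count of \code{n * pooled} events. A pooled
#' rate of zero with a non-zero count yields \code{+Inf} (flagged by the
#' caller).
#'
#' @param count observed mutations in the group.
#' @param n subjects in the group.
#' @param pooledRate pooled mutations-per-subject rate.
#' @return numeric z.
#' @examples
#' groupRateZ(20, 10, 1.0)  # (2 - 1) / sqrt(0.1)
#' @export
groupRateZ <- function(count, n, pooledRate) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(pooledRate < 0)) stop("pooledRate must be >= 0")
  k <- max(length(count), length(n), length(pooledRate))
  count <- rep_len(count, k)
  n <- rep_len(n, k)
  pooledRate <- rep_len(pooledRate, k)
  z <- suppressWarnings((count / n - pooledRate) / sqrt(pooledRate / n))
  zero <- pooledRate == 0
  z[zero] <- ifelse(count[zero] == 0, 0, Inf)
  z
}

#' Per-group exclusive-mutation burden table
#'
#' Tabulates, per diagnosis group, the number of exclusive non-synonymous
#' mutation observations (case-only observations for each case group;
#' control-only observations for the control group), the per-subject rate,
#' and the \code{\link{groupRateZ}} standardisation against the pooled
#' rate over all listed groups. The z formula is recorded in the result's
#' metadata attribute.
#'
#' @param partition result of \code{\link{partitionVariants}}.
#' @param groupSizes named vector of subjects per group, e.g.
#'   \code{c(Control = 20, BD = 14, MDD = 15, SZ = 14)}.
#' @return \code{data.frame} with columns \code{group, n_subjects,
#'   mutations, rate, z}; attribute \code{z_formula}.
#' @export
burdenTable <- function(partition, groupSizes) {
  if (any(groupSizes <= 0)) stop("group sizes must be positive")
  ctrl <- partition$control_group
  cases <- partition$case_groups
  groups <- c(ctrl, cases)
  missing <- setdiff(groups, names(groupSizes))
  if (length(missing))
    stop("groupSizes missing: ", paste(missing, collapse = ", "))
  mutations <- vapply(groups, function(g) {
    side <- if (g == ctrl) partition$control_only else partition$case_only
    if (!nrow(side)) 0L else as.integer(sum(side[[g]]))
  }, integer(1))
  n <- as.numeric(groupSizes[groups])
  pooled <- sum(mutations) / sum(n)
  out <- data.frame(group = groups, n_subjects = n, mutations = mutations,
                    rate = mutations / n,
                    z = groupRateZ(mutations, n, pooled),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pooled_rate") <- pooled
  attr(out, "z_formula") <- "(count/n - pooled) / sqrt(pooled / n)"
  out
}

#' Two-sample Poisson-rate z test
#'
#' Compares two per-subject mutation rates with the pooled-rate normal
#' approximation: \code{z = (r1 - r0) / sqrt(pooled * (1/n1 + 1/n0))} with
#' \code{pooled = (c1 + c0) / (n1 + n0)}; the two-tailed p comes from the
#' normal distribution. Two all-zero counts give z = 0, p = 1.
#'
#' @param count1,n1 mutations and subjects in group 1.
#' @param count0,n0 mutations and subjects in group 0.
#' @return list with \code{z}, \code{p} (two-tailed), \code{rate1},
#'   \code{rate0}.
#' @examples
#' twoGroupRateTest(22, 14, 11, 20)
#' @export
twoGroupRateTest <- function(count1, n1, count0, n0) {
  if (n1 <= 0 || n0 <= 0) stop("group sizes must be > 0")
  pooled <- (count1 + count0) / (n1 + n0)
  if (pooled == 0) return(list(z = 0, p = 1, rate1 = 0, rate0 = 0))
  z <- (count1 / n1 - count0 / n0) / sqrt(pooled * (1 / n1 + 1 / n0))
  list(z = z, p = 2 * pnorm(-abs(z)), rate1 = count1 / n1,
       rate0 = count0 / n0)
}

#' Per-subject non-synonymous mutation counts
#'
#' Counts, per subject, the distinct loci with (by default) artifact-
#' unflagged non-synonymous homoplasmic calls in the requested tissue.
#' Subjects with no qualifying calls are listed with count zero.
#'
#' @inheritParams partitionVariants
#' @return \code{data.frame} with \code{subject, diagnosis, n_mutations}.
#' @export
subjectMutationCounts <- function(cohort, tissue = "DLPFC",
                                  classifications = "homoplasmic_variant",
                                  nonsynonymousOnly = TRUE,
                                  excludeFlagged = TRUE) {
  k <- .selectBurdenCalls(cohort, tissue, classifications,
                          nonsynonymousOnly, excludeFlagged)
  k <- unique(k[c("subject", "position", "alt")])
  n <- table(factor(k$subject, levels = cohort@subjects$subject))
  data.frame(subject = cohort@subjects$subject,
             diagnosis = cohort@subjects$diagnosis,
             n_mutations = as.integer(n), stringsAsFactors = FALSE)
}

#' One-sided Fisher test of a dichotomised mutation load
#'
#' Dichotomises subjects at \code{cutoff} or more non-synonymous mutations
#' and tests for an excess of high-load subjects among cases with the
#' one-sided hypergeometric tail. Degenerate margins (no subject above the
#' cutoff, or no variation) give p = 1 by convention.
#'
#' @param subjectCounts \code{data.frame} from
#'   \code{\link{subjectMutationCounts}}.
#' @param caseGroups diagnoses treated as cases.
#' @param controlGroup control diagnosis.
#' @param cutoff dichotomisation point (default 5 mutations).
#' @return list with \code{p} (one-sided), \code{table} (2 x 2 matrix),
#'   \code{cutoff}.
#' @export
fisherDichotomized <- function(subjectCounts,
                               caseGroups = c("BD", "MDD", "SZ"),
                               controlGroup = "Control", cutoff = 5L) {
  d <- subjectCounts[subjectCounts$diagnosis %in%
                       c(caseGroups, controlGroup), , drop = FALSE]
  isCase <- d$diagnosis %in% caseGroups
  high <- d$n_mutations >= cutoff
  tab <- matrix(c(sum(isCase & high), sum(isCase & !high),
                  sum(!isCase & high), sum(!isCase & !high)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c(paste0(">=", cutoff), paste0("<", cutoff))))
  K <- sum(high); n1 <- sum(isCase); n0 <- sum(!isCase); k <- sum(isCase & high)
  if (K == 0L || K == n1 + n0 || n1 == 0L || n0 == 0L)
    return(list(p = 1, table = tab, cutoff = cutoff))
  ## upper hypergeometric tail: P(cases with >= cutoff  >=  observed)
  kk <- seq.int(k, min(K, n1))
  p <- sum(dhyper(kk, n1, n0, K))
  list(p = p, table = tab, cutoff = cutoff)
}

#' Blood-brain variant concordance for one subject
#'
#' Compares the homoplasmic variant set found in blood with the union over
#' brain regions (Jaccard concordance; 1.0 for identical sets) and lists
#' heteroplasmic loci detected in brain at or above the blood-detection
#' cutoff but below it (or absent) in blood.
#'
#' @param cohort a \linkS4class{MitoCohort}.
#' @param subject subject id; must have blood and at least one brain
#'   region sampled.
#' @param thresholds a \linkS4class{ThresholdConfig}; its
#'   \code{bloodDetectionMin} is the detection cutoff.
#' @return list with \code{homoplasmic_concordance}, \code{brain_only}
#'   (\code{data.frame} of loci with max brain level and blood level),
#'   \code{n_blood_homoplasmic}, \code{n_brain_homoplasmic}.
#' @export
bloodBrainConcordance <- function(cohort, subject,
                                  thresholds = thresholdConfig()) {
  k <- cohort@calls[cohort@calls$subject == subject, , drop = FALSE]
  if (!any(k$region == "blood"))
    stop("subject ", subject, " has no blood sample")
  blood <- k[k$region == "blood", , drop = FALSE]
  brain <- k[k$region != "blood", , drop = FALSE]
  if (!nrow(brain)) stop("subject ", subject, " has no brain region")
  keyOf <- function(d) unique(paste(d$position, d$alt))
  bloodHom <- keyOf(blood[blood$classification == "homoplasmic_variant", ])
  brainHom <- keyOf(brain[brain$classification == "homoplasmic_variant", ])
  uni <- union(bloodHom, brainHom)
  conc <- if (!length(uni)) 1 else
    length(intersect(bloodHom, brainHom)) / length(uni)
  cut <- thresholds@bloodDetectionMin
  het <- brain[brain$classification == "heteroplasmic" &
                 brain$heteroplasmy_level >= cut, , drop = FALSE]
  if (nrow(het)) {
    agg <- stats::aggregate(heteroplasmy_level ~ position + alt, het, max)
    bloodLevel <- vapply(seq_len(nrow(agg)), function(i) {
      hit <- blood$position == agg$position[i] & !is.na(blood$alt) &
        blood$alt == agg$alt[i]
      if (any(hit)) max(blood$heteroplasmy_level[hit]) else 0
    }, numeric(1))
    brainOnly <- agg[bloodLevel < cut, , drop = FALSE]
    names(brainOnly)[names(brainOnly) == "heteroplasmy_level"] <-
      "max_brain_level"
    brainOnly$blood_level <- bloodLevel[bloodLevel < cut]
    rownames(brainOnly) <- NULL
  } else {
    brainOnly <- data.frame(position = integer(0), alt = character(0),
                            max_brain_level = numeric(0),
                            blood_level = numeric(0))
  }
  list(homoplasmic_concordance = conc, brain_only = brainOnly,
       n_blood_homoplasmic = length(bloodHom),
       n_brain_homoplasmic = length(brainHom))
}

#' Per-region heteroplasmy profile at one position
#'
#' Reports the heteroplasmy level and coverage per sampled region of one
#' subject at a position, with regions removed by the coverage filter
#' listed separately; regions sampled but carrying no call at the position
#' are reported at level 0.
#'
#' @param cohort a \linkS4class{MitoCohort}.
#' @param subject subject id.
#' @param position 1-based position.
#' @return list with \code{profile} (\code{data.frame}: region, level,
#'   coverage), \code{filtered} (regions failing coverage), and
#'   \code{range} (min, max, span over profiled regions).
#' @export
regionHeteroplasmyProfile <- function(cohort, subject, position) {
  k <- cohort@calls[cohort@calls$subject == subject, , drop = FALSE]
  regions <- unique(k$region)
  at <- k[k$position == position, , drop = FALSE]
  if (!nrow(at)) stop("position ", position, " not called in any region of ",
                      subject)
  filt <- unique(at$region[at$classification == "filtered"])
  at <- at[at$classification != "filtered", , drop = FALSE]
  lvl <- setNames(rep(0, length(regions)), regions)
  cov <- setNames(rep(NA_real_, length(regions)), regions)
  lvl[at$region] <- at$heteroplasmy_level
  if ("coverage" %in% names(at)) cov[at$region] <- at$coverage
  keep <- setdiff(regions, filt)
  prof <- data.frame(region = keep, level = unname(lvl[keep]),
                     coverage = unname(cov[keep]), stringsAsFactors = FALSE)
  list(profile = prof, filtered = filt,
       range = c(min = min(prof$level), max = max(prof$level),
                 span = diff(range(prof$level))))
}
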