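## Packaged variant tables: the published case-only non-synonymous loci,
## the novel/rare variant list, and a cohort expansion used for burden
## arithmetic and as an annotation truth set.

#' Packaged case-only non-synonymous loci table
#'
#' The 37 loci at which non-synonymous homoplasmic substitutions were
#' observed only in cases (never in controls) in the source cohort's
#' DLPFC samples, with per-diagnosis observation counts (49 observations
#' in total), reference/alternate alleles, amino-acid changes, damage
#' prediction labels (carried as opaque pass-through strings), haplogroup
#' backgrounds and population-catalog counts.
#'
#' @return \code{data.frame}, one row per locus.
#' @examples
#' t1 <- caseOnlyLoci()
#' nrow(t1)              # 37
#' sum(t1$total)         # 49
#' @export
caseOnlyLoci <- function() {
  read.delim(system.file("extdata", "case_only_loci.tsv",
                         package = "mitoplasmy", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Packaged novel/rare non-synonymous variant table
#'
#' The seven confirmed novel or rare variants (six coding, one D-loop)
#' with their carriers' diagnoses and the external damage-prediction
#' labels (pass-through strings; the package never computes damage
#' predictions).
#'
#' @return \code{data.frame}, one row per variant.
#' @export
novelRareVariants <- function() {
  read.delim(system.file("extdata", "novel_rare_variants.tsv",
                         package = "mitoplasmy", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Expand a loci table into a cohort of per-subject calls
#'
#' Reconstructs a \linkS4class{MitoCohort} consistent with a Table-1-shaped
#' loci table: subjects are created per diagnosis group and each
#' observation of a locus in a group is assigned to a distinct subject of
#' that group (rotating assignment), as DLPFC homoplasmic non-synonymous
#' calls. Group sizes default to the source cohort (20 controls, 14 BD,
#' 15 MDD, 14 SZ).
#'
#' @param loci \code{data.frame} as from \code{\link{caseOnlyLoci}}:
#'   columns \code{position, ref, alt} plus one observation-count column
#'   per diagnosis present in \code{groupSizes}.
#' @param groupSizes named vector of subjects per diagnosis.
#' @return a \linkS4class{MitoCohort}.
#' @examples
#' coh <- cohortFromLociTable(caseOnlyLoci())
#' nrow(cohortSubjects(coh))  # 63
#' @export
cohortFromLociTable <- function(loci,
    groupSizes = c(Control = 20, BD = 14, MDD = 15, SZ = 14)) {
  subjects <- do.call(rbind, lapply(names(groupSizes), function(g)
    data.frame(subject = sprintf("%s-%02d", g, seq_len(groupSizes[[g]])),
               diagnosis = g, stringsAsFactors = FALSE)))
  cursor <- setNames(integer(length(groupSizes)), names(groupSizes))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (g in intersect(names(groupSizes), names(loci))) {
      k <- loci[[g]][i]
      if (is.na(k) || k < 1) next
      idx <- ((cursor[[g]] + seq_len(k) - 1L) %% groupSizes[[g]]) + 1L
      cursor[[g]] <- cursor[[g]] + k
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s-%02d", g, idx), diagnosis = g,
        region = "DLPFC", position = loci$position[i], ref = loci$ref[i],
        alt = loci$alt[i], classification = "homoplasmic_variant",
        heteroplasmy_level = 1, coverage = 1000L, synonymous = FALSE,
        nonsynonymous_any = TRUE, hotspot_flag = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), diagnosis = character(0),
               region = character(0), position = integer(0),
               ref = character(0), alt = character(0),
               classification = character(0))
  mitoCohort(calls, subjects)
}
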