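## Allele-count classification: homoplasmy / heteroplasmy thresholds and
## consensus building. The 95% major-allele boundary is inclusive for
## homoplasmy: a major fraction of exactly 0.95 is homoplasmic.

.BASES <- c("A", "C", "G", "T")
.COUNT_COLS <- c("A", "C", "G", "T", "del")

#' ThresholdConfig: classification thresholds
#'
#' Thresholds used throughout variant classification: the minimum major-
#' allele fraction for a homoplasmic call (default 0.95, boundary
#' inclusive), the minimum read coverage for any call (default 200 reads),
#' the minimum heteroplasmy level considered detectable in blood for
#' blood-brain comparisons (default 5\%), and the maximum catalog frequency
#' below which a catalogued variant is called rare (default 0.1\%).
#'
#' @slot homoplasmyMajorMin numeric fraction in (0, 1].
#' @slot minCoverage integer reads, >= 1.
#' @slot bloodDetectionMin numeric fraction, at most 1 - homoplasmyMajorMin.
#' @slot rareCatalogFreqMax numeric fraction.
#' @export
setClass("ThresholdConfig",
  representation(homoplasmyMajorMin = "numeric", minCoverage = "numeric",
                 bloodDetectionMin = "numeric", rareCatalogFreqMax = "numeric"))

setValidity("ThresholdConfig", function(object) {
  msg <- NULL
  if (object@minCoverage < 1) msg <- c(msg, "minCoverage must be >= 1")
  if (object@homoplasmyMajorMin <= 0 || object@homoplasmyMajorMin > 1)
    msg <- c(msg, "homoplasmyMajorMin must be in (0, 1]")
  if (object@bloodDetectionMin <= 0 ||
      object@bloodDetectionMin > 1 - object@homoplasmyMajorMin + 1e-12)
    msg <- c(msg, "bloodDetectionMin must satisfy 0 < x <= 1 - homoplasmyMajorMin")
  if (object@rareCatalogFreqMax < 0 || object@rareCatalogFreqMax > 1)
    msg <- c(msg, "rareCatalogFreqMax must be a fraction")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ThresholdConfig", function(object) {
  cat("ThresholdConfig: homoplasmy >= ", object@homoplasmyMajorMin,
      ", coverage >= ", object@minCoverage,
      ", blood detection >= ", object@bloodDetectionMin,
      ", rare catalog freq < ", object@rareCatalogFreqMax, "\n", sep = "")
})

#' @rdname ThresholdConfig-class
#' @param homoplasmyMajorMin minimum major-allele fraction for homoplasmy.
#' @param minCoverage minimum read depth for any classification.
#' @param bloodDetectionMin blood detection cutoff for heteroplasmy.
#' @param rareCatalogFreqMax catalog frequency below which variants are rare.
#' @return a \code{ThresholdConfig}.
#' @examples
#' thresholdConfig()
#' @export
thresholdConfig <- function(homoplasmyMajorMin = 0.95, minCoverage = 200,
                            bloodDetectionMin = 0.05,
                            rareCatalogFreqMax = 0.001) {
  new("ThresholdConfig", homoplasmyMajorMin = homoplasmyMajorMin,
      minCoverage = minCoverage, bloodDetectionMin = bloodDetectionMin,
      rareCatalogFreqMax = rareCatalogFreqMax)
}

.asCountVector <- function(counts) {
  out <- setNames(numeric(5L), .COUNT_COLS)
  if (is.null(names(counts)))
    stop("counts must be named with bases among A, C, G, T, del")
  bad <- setdiff(names(counts), .COUNT_COLS)
  if (length(bad))
    stop("unknown allele names in counts: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  out[names(counts)] <- counts
  out
}

#' Classify one position from its allele counts
#'
#' Applies the coverage filter and the major-allele-fraction thresholds to a
#' single position. Positions with depth below the minimum coverage are
#' returned as \code{filtered} with a reason rather than classified. The
#' classifications partition all passing sites: \code{reference} (major
#' allele equals the reference at or above the homoplasmy threshold),
#' \code{homoplasmic_variant} (major allele differs from the reference and
#' its fraction is at or above the threshold; the boundary is inclusive),
#' and \code{heteroplasmic} (major-allele fraction below the threshold).
#' The heteroplasmy level reported is the fraction of reads supporting the
#' largest non-reference allele, whichever side of 50\% it falls on.
#'
#' Deletion reads count toward depth but are never called as substitution
#' variants; length variation is handled at the designated repeat loci.
#' Ties for the major allele are broken by base order A < C < G < T and
#' flagged.
#'
#' @param counts named numeric vector of read counts with names among
#'   \code{A, C, G, T, del}.
#' @param refBase reference base at the position (one of A, C, G, T, N).
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param position optional 1-based position carried into the result.
#' @return one-row \code{data.frame} with columns \code{position},
#'   \code{ref}, \code{classification}, \code{major_allele},
#'   \code{major_fraction}, \code{alt}, \code{heteroplasmy_level},
#'   \code{coverage}, \code{tie}, \code{filter_reason}.
#' @examples
#' th <- thresholdConfig()
#' classifyPosition(c(T = 811, C = 189), "T", th)$classification  # heteroplasmic
#' classifyPosition(c(C = 1000), "T", th)$classification  # homoplasmic_variant
#' @export
classifyPosition <- function(counts, refBase, thresholds = thresholdConfig(),
                             position = NA_integer_) {
  if (!refBase %in% c(.BASES, "N"))
    stop("refBase must be one of A, C, G, T, N; got '", refBase, "'")
  cnt <- .asCountVector(counts)
  depth <- sum(cnt)
  res <- data.frame(position = as.integer(position), ref = refBase,
                    classification = NA_character_,
                    major_allele = NA_character_, major_fraction = NA_real_,
                    alt = NA_character_, heteroplasmy_level = NA_real_,
                    coverage = depth, tie = FALSE,
                    filter_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (depth < thresholds@minCoverage) {
    res$classification <- "filtered"
    res$filter_reason <- paste0("coverage < ", thresholds@minCoverage)
    return(res)
  }
  baseCnt <- cnt[.BASES]
  major <- .BASES[which.max(baseCnt)]       # ties resolve A < C < G < T
  res$tie <- sum(baseCnt == max(baseCnt)) > 1L
  res$major_allele <- major
  res$major_fraction <- unname(baseCnt[major] / depth)
  nonref <- baseCnt[setdiff(.BASES, refBase)]
  if (length(nonref) && max(nonref) > 0) {
    altBase <- names(nonref)[which.max(nonref)]
    res$alt <- altBase
    res$heteroplasmy_level <- unname(nonref[altBase] / depth)
  } else {
    res$heteroplasmy_level <- 0
  }
  if (res$major_fraction < thresholds@homoplasmyMajorMin) {
    res$classification <- "heteroplasmic"
  } else if (major != refBase) {
    res$classification <- "homoplasmic_variant"
  } else {
    res$classification <- "reference"
  }
  res
}

#' Read and write per-position allele-count tables
#'
#' Tab-separated tables with header \code{pos A C G T del}, one row per
#' reference position present in the pileup.
#'
#' @param path file path.
#' @return \code{readCountTable} returns a \code{data.frame}.
#' @export
readCountTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos", .COUNT_COLS)
  if (!all(need %in% names(tab)))
    stop("count table must have columns: ", paste(need, collapse = " "))
  tab[need]
}

#' @rdname readCountTable
#' @param countTable a count table \code{data.frame}.
#' @export
writeCountTable <- function(countTable, path) {
  write.table(countTable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.checkCountTable <- function(countTable) {
  need <- c("pos", .COUNT_COLS)
  if (!all(need %in% names(countTable)))
    stop("count table must have columns: ", paste(need, collapse = " "))
  if (anyDuplicated(countTable$pos))
    stop("duplicate positions in count table: ",
         paste(unique(countTable$pos[duplicated(countTable$pos)])[1:3],
               collapse = ", "))
  countTable
}

#' Call variants for one sample from a count table
#'
#' Classifies every position of a per-position allele-count table against
#' the reference, returning all non-reference calls (homoplasmic variants
#' and heteroplasmies), the sites removed by the coverage filter, and a
#' per-sample summary. Classification is fully vectorised.
#'
#' @param countTable \code{data.frame} with columns \code{pos A C G T del}.
#' @param ref a \linkS4class{MitoReference}.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param sample optional sample label carried into the result.
#' @return list with \code{calls} (non-reference classifications),
#'   \code{filtered} (sub-coverage sites with reasons), and \code{summary}
#'   (named counts: n_homoplasmic, n_heteroplasmic, n_reference, n_filtered).
#' @export
callSample <- function(countTable, ref, thresholds = thresholdConfig(),
                       sample = NA_character_) {
  countTable <- .checkCountTable(countTable)
  m <- as.matrix(countTable[.BASES])
  del <- countTable$del
  depth <- rowSums(m) + del
  refBase <- refBaseAt(ref, countTable$pos)
  pass <- depth >= thresholds@minCoverage

  majIdx <- max.col(m, ties.method = "first")
  major <- .BASES[majIdx]
  majFrac <- m[cbind(seq_len(nrow(m)), majIdx)] / depth
  tie <- rowSums(m == m[cbind(seq_len(nrow(m)), majIdx)]) > 1L

  nonref <- m
  maskIdx <- match(refBase, .BASES)      # NA where ref is 'N': nothing masked
  hasRef <- !is.na(maskIdx)
  nonref[cbind(seq_len(nrow(m))[hasRef], maskIdx[hasRef])] <- -1L
  altIdx <- max.col(nonref, ties.method = "first")
  alt <- .BASES[altIdx]
  altCount <- nonref[cbind(seq_len(nrow(m)), altIdx)]
  level <- ifelse(altCount > 0, altCount / depth, 0)
  alt[altCount <= 0] <- NA_character_

  cls <- ifelse(majFrac < thresholds@homoplasmyMajorMin, "heteroplasmic",
         ifelse(major != refBase, "homoplasmic_variant", "reference"))

  all <- data.frame(sample = sample, position = countTable$pos, ref = refBase,
                    classification = cls, major_allele = major,
                    major_fraction = majFrac, alt = alt,
                    heteroplasmy_level = level, coverage = depth, tie = tie,
                    stringsAsFactors = FALSE)
  filtered <- all[!pass, , drop = FALSE]
  if (nrow(filtered)) {
    filtered$classification <- "filtered"
    filtered$filter_reason <- paste0("coverage < ", thresholds@minCoverage)
  } else filtered$filter_reason <- character(0)
  kept <- all[pass, , drop = FALSE]
  calls <- kept[kept$classification != "reference", , drop = FALSE]
  rownames(calls) <- rownames(filtered) <- NULL
  list(calls = calls, filtered = filtered,
       summary = c(n_homoplasmic = sum(kept$classification == "homoplasmic_variant"),
                   n_heteroplasmic = sum(kept$classification == "heteroplasmic"),
                   n_reference = sum(kept$classification == "reference"),
                   n_filtered = sum(!pass)))
}

#' Build a consensus sequence from a count table
#'
#' The consensus carries the major allele at every position passing the
#' coverage filter and 'N' at masked (sub-coverage or absent) positions.
#'
#' @inheritParams callSample
#' @param genomeLength consensus length; positions absent from the table
#'   are masked.
#' @return list with \code{sequence} (character string), \code{mask}
#'   (integer positions carrying 'N').
#' @export
buildConsensus <- function(countTable, thresholds = thresholdConfig(),
                           genomeLength = 16569L) {
  countTable <- .checkCountTable(countTable)
  m <- as.matrix(countTable[.BASES])
  depth <- rowSums(m) + countTable$del
  pass <- depth >= thresholds@minCoverage
  major <- .BASES[max.col(m, ties.method = "first")]
  seq <- rep("N", genomeLength)
  ok <- pass & countTable$pos >= 1L & countTable$pos <= genomeLength
  seq[countTable$pos[ok]] <- major[ok]
  list(sequence = paste(seq, collapse = ""), mask = which(seq == "N"))
}

#' Write a consensus sequence as FASTA
#'
#' @param consensus result of \code{\link{buildConsensus}}.
#' @param sample sample name for the FASTA header.
#' @param path output path.
#' @export
writeConsensusFasta <- function(consensus, sample, path) {
  x <- Biostrings::DNAStringSet(consensus$sequence)
  names(x) <- sample
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) substitutions are
#' transitions; all others are transversions.
#'
#' @param refBase,altBase base characters; vectors recycle.
#' @return character vector of \code{"transition"}/\code{"transversion"}.
#' @examples
#' transitionOrTransversion("C", "T")  # transition
#' transitionOrTransversion("A", "C")  # transversion
#' @export
transitionOrTransversion <- function(refBase, altBase) {
  if (any(refBase == altBase))
    stop("ref and alt bases must differ")
  if (any(!refBase %in% .BASES) || any(!altBase %in% .BASES))
    stop("bases must be among A, C, G, T")
  purine <- c("A", "G")
  ifelse((refBase %in% purine) == (altBase %in% purine),
         "transition", "transversion")
}

#' Tally a count table from an aligned BAM file
#'
#' Thin adapter over \link[Rsamtools]{pileup}: tallies per-position base
#' and deletion counts from reads aligned to the mitochondrial reference,
#' with base quality >= 20 and mapping quality >= 20 by default (upstream
#' pileup filters are otherwise the aligner's concern, not this
#' package's).
#'
#' @param bamPath path to a coordinate-sorted, indexed BAM.
#' @param seqname reference sequence name in the BAM (e.g. \code{"chrM"}).
#' @param minBaseQuality,minMapq pileup quality filters.
#' @param maxDepth per-position depth cap passed to the pileup engine.
#' @return count table \code{data.frame} (\code{pos A C G T del}), one row
#'   per covered position.
#' @export
countTableFromBam <- function(bamPath, seqname = "chrM",
                              minBaseQuality = 20L, minMapq = 20L,
                              maxDepth = 1000000L) {
  p <- Rsamtools::pileup(bamPath,
    pileupParam = Rsamtools::PileupParam(
      max_depth = maxDepth, min_base_quality = minBaseQuality,
      min_mapq = minMapq, min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = TRUE, include_insertions = FALSE))
  p <- p[p$seqnames == seqname, , drop = FALSE]
  pos <- sort(unique(p$pos))
  tab <- data.frame(pos = pos, A = 0L, C = 0L, G = 0L, T = 0L, del = 0L)
  colOf <- c(A = "A", C = "C", G = "G", T = "T", "-" = "del")
  for (nuc in names(colOf)) {
    sub <- p[p$nucleotide == nuc, , drop = FALSE]
    if (nrow(sub))
      tab[[colOf[[nuc]]]][match(sub$pos, pos)] <- sub$count
  }
  tab
}
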