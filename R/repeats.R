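## Per-read repeat-length extraction and multiplasmy (length heteroplasmy)
## calling at the hypervariable D-loop repeat loci. Extraction is exact-match
## anchored (default 5-base anchors, zero mismatches): deterministic and
## adequate at mitochondrial coverage depths; no alignment, no stutter
## denoising (raw length mixtures are reported).

#' RepeatLocus: a variable-length repeat locus
#'
#' Describes a repeat locus by its repeat unit, the number of units in the
#' reference, and exact-match flanking anchors. Anchors must not carry a
#' full copy of the unit at their locus-facing ends, so that the repeat
#' count is well defined.
#'
#' @slot name locus label, e.g. \code{"CA514"}.
#' @slot unit repeat unit, e.g. \code{"CA"} or \code{"C"}.
#' @slot referenceUnits units in the reference sequence.
#' @slot leftAnchor,rightAnchor flanking sequences matched exactly.
#' @export
setClass("RepeatLocus",
  representation(name = "character", unit = "character",
                 referenceUnits = "integer",
                 leftAnchor = "character", rightAnchor = "character"))

setValidity("RepeatLocus", function(object) {
  msg <- NULL
  if (nchar(object@unit) < 1L) msg <- c(msg, "unit must be non-empty")
  u <- object@unit
  la <- object@leftAnchor; ra <- object@rightAnchor
  if (nchar(la) >= nchar(u) &&
      substring(la, nchar(la) - nchar(u) + 1L) == u)
    msg <- c(msg, "left anchor ends with a full unit copy")
  if (nchar(ra) >= nchar(u) && substring(ra, 1L, nchar(u)) == u)
    msg <- c(msg, "right anchor begins with a full unit copy")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RepeatLocus", function(object) {
  cat("RepeatLocus ", object@name, ": (", object@unit, ")",
      object@referenceUnits, " between '", object@leftAnchor, "' and '",
      object@rightAnchor, "'\n", sep = "")
})

#' @rdname RepeatLocus-class
#' @param name,unit,referenceUnits,leftAnchor,rightAnchor see slots.
#' @return a \code{RepeatLocus}.
#' @export
repeatLocus <- function(name, unit, referenceUnits, leftAnchor, rightAnchor) {
  new("RepeatLocus", name = name, unit = toupper(unit),
      referenceUnits = as.integer(referenceUnits),
      leftAnchor = toupper(leftAnchor), rightAnchor = toupper(rightAnchor))
}

#' The three packaged D-loop repeat loci
#'
#' Builds the locus configuration for the three hypervariable repeat loci:
#' the (CA)n dinucleotide repeat beginning at position 514 (reference
#' (CA)5), the D310 poly-C tract (the 5' C-run preceding the fixed T at
#' 310; reference 7 C), and the D16189 poly-C tract (the run 16184..16193
#' interrupted at 16189 in the reference; in 16189C carriers the tract is
#' an uninterrupted run of 10 C, which is the configuration in which its
#' length polymorphism is called, so the reference length is recorded
#' as 10). Anchors (default 5 bases) are taken from the reference itself.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param anchorLen anchor length in bases.
#' @return named list of \linkS4class{RepeatLocus} objects
#'   (\code{CA514}, \code{D310}, \code{D16189}).
#' @examples
#' loci <- defaultRepeatLoci(rCRSReference())
#' loci$CA514
#' @export
defaultRepeatLoci <- function(ref = rCRSReference(), anchorLen = 5L) {
  s <- refSequence(ref)
  sub <- function(a, b) substring(s, a, b)
  list(
    CA514 = repeatLocus("CA514", "CA", 5L,
                        sub(514L - anchorLen, 513L),
                        sub(524L, 523L + anchorLen)),
    D310 = repeatLocus("D310", "C", 7L,
                       sub(303L - anchorLen, 302L),
                       sub(310L, 309L + anchorLen)),
    D16189 = repeatLocus("D16189", "C", 10L,
                         sub(16184L - anchorLen, 16183L),
                         sub(16194L, 16193L + anchorLen)))
}

#' Extract the repeat length from one read
#'
#' Both anchors must match exactly (no mismatches) with only whole or
#' partial copies of the repeat unit between them; the count of complete
#' unit copies is returned. Reads in which the anchors cannot be placed
#' that way do not span the locus and yield \code{NA}.
#'
#' @param read a base string (one sequencing read).
#' @param locus a \linkS4class{RepeatLocus}.
#' @return integer repeat-unit count, or \code{NA_integer_} if not spanning.
#' @examples
#' loc <- repeatLocus("toy", "CA", 5L, "GGGGG", "TTTTT")
#' extractRepeatLength("GGGGGCACACACACACATTTTT", loc)  # 6
#' @export
extractRepeatLength <- function(read, locus) {
  if (nchar(locus@unit) < 1L) stop("repeat unit must be non-empty")
  read <- toupper(read)
  u <- locus@unit
  partials <- if (nchar(u) > 1L)
    vapply(seq_len(nchar(u) - 1L), function(k) substring(u, 1L, k), "")
  else character(0)
  pat <- paste0("(?:", paste0("\\Q", u, "\\E"), ")*")
  if (length(partials))
    pat <- paste0(pat, "(?:", paste(paste0("\\Q", partials, "\\E"),
                                    collapse = "|"), ")?")
  full <- paste0("\\Q", locus@leftAnchor, "\\E(", pat, ")\\Q",
                 locus@rightAnchor, "\\E")
  m <- regexpr(full, read, perl = TRUE)
  if (m == -1L) return(NA_integer_)
  inner <- regmatches(read, m)
  inner <- sub(paste0("^\\Q", locus@leftAnchor, "\\E"), "", inner)
  inner <- sub(paste0("\\Q", locus@rightAnchor, "\\E$"), "", inner)
  as.integer(nchar(inner) %/% nchar(u))
}

#' RepeatDistribution: per-read repeat lengths at one locus
#'
#' @slot locus the \linkS4class{RepeatLocus}.
#' @slot counts named integer vector: repeat-unit count -> spanning reads.
#' @slot nSpanning total spanning reads.
#' @slot nDiscarded reads not spanning or anchor-mismatched.
#' @export
setClass("RepeatDistribution",
  representation(locus = "RepeatLocus", counts = "integer",
                 nSpanning = "integer", nDiscarded = "integer"))

setValidity("RepeatDistribution", function(object) {
  msg <- NULL
  if (length(object@counts) && any(as.integer(names(object@counts)) < 0))
    msg <- c(msg, "repeat lengths must be >= 0")
  if (sum(object@counts) != object@nSpanning)
    msg <- c(msg, "nSpanning must equal the sum of counts")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RepeatDistribution", function(object) {
  cat("RepeatDistribution at ", object@locus@name, ": ",
      object@nSpanning, " spanning / ", object@nDiscarded, " discarded\n",
      sep = "")
  if (length(object@counts)) print(object@counts)
})

#' @rdname RepeatDistribution-class
#' @param x a \code{RepeatDistribution}.
#' @export
setMethod("length", "RepeatDistribution", function(x) x@nSpanning)

#' Repeat-length counts accessor
#'
#' @param dist a \linkS4class{RepeatDistribution}.
#' @return named integer vector (names are repeat-unit counts).
#' @export
repeatCounts <- function(dist) dist@counts

#' Tally per-read repeat lengths over a read set
#'
#' @param reads character vector of read sequences (or a
#'   \link[Biostrings]{DNAStringSet}).
#' @param locus a \linkS4class{RepeatLocus}.
#' @return a \linkS4class{RepeatDistribution}.
#' @export
repeatDistribution <- function(reads, locus) {
  reads <- as.character(reads)
  lens <- vapply(reads, extractRepeatLength, integer(1), locus = locus,
                 USE.NAMES = FALSE)
  ok <- !is.na(lens)
  tab <- table(lens[ok])
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(as.integer(names(counts)))]
  new("RepeatDistribution", locus = locus, counts = counts,
      nSpanning = sum(ok), nDiscarded = sum(!ok))
}

#' Build a RepeatDistribution from known counts
#'
#' Convenience constructor when per-length read counts are already known
#' (e.g. from an external tally).
#'
#' @param counts named integer vector mapping repeat length to reads.
#' @param locus a \linkS4class{RepeatLocus}.
#' @param nDiscarded reads that did not span the locus.
#' @return a \linkS4class{RepeatDistribution}.
#' @export
repeatDistributionFromCounts <- function(counts, locus, nDiscarded = 0L) {
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[order(as.integer(names(counts)))]
  new("RepeatDistribution", locus = locus, counts = counts,
      nSpanning = sum(counts), nDiscarded = as.integer(nDiscarded))
}

#' MultiplasmyCall: coexisting repeat lengths at one locus
#'
#' @slot alleles sorted integer repeat lengths passing support thresholds.
#' @slot fractions support fraction per allele (of spanning reads).
#' @slot isMultiplasmic \code{TRUE} when two or more alleles are supported.
#' @slot abstained \code{TRUE} when no spanning reads were available.
#' @export
setClass("MultiplasmyCall",
  representation(alleles = "integer", fractions = "numeric",
                 isMultiplasmic = "logical", abstained = "logical"))

setMethod("show", "MultiplasmyCall", function(object) {
  if (object@abstained) {
    cat("MultiplasmyCall: abstained (no spanning reads)\n")
  } else {
    cat("MultiplasmyCall: lengths {",
        paste(object@alleles, collapse = ","), "} ",
        if (object@isMultiplasmic) "multiplasmic" else "single allele",
        "\n", sep = "")
  }
})

#' Multiplasmy alleles accessor
#'
#' @param call a \linkS4class{MultiplasmyCall}.
#' @return integer vector of supported repeat lengths.
#' @export
multiplasmyAlleles <- function(call) call@alleles

#' @rdname multiplasmyAlleles
#' @export
isMultiplasmic <- function(call) call@isMultiplasmic

#' Call multiplasmy from a repeat-length distribution
#'
#' Supported alleles are the repeat lengths carried by at least
#' \code{minReads} spanning reads and at least \code{minFraction} of them;
#' the locus is multiplasmic when two or more lengths are supported.
#' A distribution with no spanning reads yields an abstained call rather
#' than an error.
#'
#' @param dist a \linkS4class{RepeatDistribution}.
#' @param minFraction minimum support fraction per allele (default 0.05).
#' @param minReads minimum supporting reads per allele (default 10).
#' @return a \linkS4class{MultiplasmyCall}.
#' @examples
#' loc <- repeatLocus("toy", "CA", 5L, "GGGGG", "TTTTT")
#' d <- repeatDistributionFromCounts(c(`5` = 600, `6` = 250, `7` = 150), loc)
#' isMultiplasmic(callMultiplasmy(d))  # TRUE, tri-allelic
#' @export
callMultiplasmy <- function(dist, minFraction = 0.05, minReads = 10L) {
  if (dist@nSpanning == 0L)
    return(new("MultiplasmyCall", alleles = integer(0),
               fractions = numeric(0), isMultiplasmic = FALSE,
               abstained = TRUE))
  frac <- dist@counts / dist@nSpanning
  keep <- dist@counts >= minReads & frac >= minFraction
  alleles <- as.integer(names(dist@counts))[keep]
  new("MultiplasmyCall", alleles = alleles,
      fractions = unname(frac[keep]),
      isMultiplasmic = sum(keep) >= 2L, abstained = FALSE)
}

#' Deletion to wild-type ratio at a repeat locus
#'
#' The ratio of reads carrying fewer repeat units than the reference to
#' reads carrying exactly the reference number of units.
#'
#' @param dist a \linkS4class{RepeatDistribution}.
#' @param referenceUnits reference repeat count; defaults to the locus
#'   configuration.
#' @return list with \code{ratio} (numeric, \code{NA} when undefined) and
#'   \code{defined} (logical; \code{FALSE} when no reference-length reads).
#' @examples
#' loc <- repeatLocus("toy", "CA", 5L, "GGGGG", "TTTTT")
#' d <- repeatDistributionFromCounts(c(`4` = 30, `5` = 20), loc)
#' deletionRatio(d)$ratio  # 1.5
#' @export
deletionRatio <- function(dist, referenceUnits = dist@locus@referenceUnits) {
  lens <- as.integer(names(dist@counts))
  nRef <- sum(dist@counts[lens == referenceUnits])
  nDel <- sum(dist@counts[lens < referenceUnits])
  if (nRef == 0L)
    return(list(ratio = NA_real_, defined = FALSE))
  list(ratio = nDel / nRef, defined = TRUE)
}
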