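## Platform error-hotspot filtering. Heteroplasmic A>C transversions are
## over-called by the sequencing platform in a reproducible sequence
## context: a run of >= 2 A's ending at the variant position, immediately
## followed by >= 2 C's. Flags annotate calls; they never delete them.

#' A>C error-hotspot motif predicate
#'
#' \code{TRUE} iff the call is an A-to-C substitution whose reference
#' context carries a run of at least two consecutive A's ending at the
#' position (the variant A itself counts toward the run) immediately
#' followed by at least two consecutive C's. Runs are read on the circular
#' genome.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param position 1-based position of the call.
#' @param refBase,altBase the substitution.
#' @return logical.
#' @examples
#' isAcHotspot(rCRSReference(), 6419, "A", "C")   # TRUE
#' isAcHotspot(rCRSReference(), 6419, "A", "G")   # FALSE
#' @export
isAcHotspot <- function(ref, position, refBase, altBase) {
  if (refBase != "A" || altBase != "C") return(FALSE)
  if (refBaseAt(ref, position) != "A") return(FALSE)
  n <- length(ref)
  runA <- 1L
  while (runA < n && refBaseAt(ref, position - runA) == "A")
    runA <- runA + 1L
  runC <- 0L
  while (runC < n && refBaseAt(ref, position + 1L + runC) == "C")
    runC <- runC + 1L
  runA >= 2L && runC >= 2L
}

#' Packaged error-hotspot blacklist
#'
#' The default blacklist: the four A>C motif hotspots (302, 3492, 6419,
#' 10306) and the three non-A/C substitutions that failed orthogonal
#' validation (T3488A, T6415A, G9801T).
#'
#' @return \code{data.frame} with columns \code{position}, \code{ref},
#'   \code{alt}, \code{reason}.
#' @export
defaultBlacklist <- function() {
  readBlacklist(system.file("extdata", "error_hotspot_blacklist.tsv",
                            package = "mitoplasmy", mustWork = TRUE))
}

#' Read an error-hotspot blacklist
#'
#' Tab-separated with columns \code{position ref alt reason}; malformed
#' entries are reported with their line number.
#'
#' @param path blacklist file path.
#' @return validated \code{data.frame}.
#' @export
readBlacklist <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("blacklist must have columns: position, ref, alt")
  if (!"reason" %in% names(tab)) tab$reason <- "blacklist"
  bad <- which(is.na(suppressWarnings(as.integer(tab$position))) |
               !tab$ref %in% c("A", "C", "G", "T") |
               !tab$alt %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("malformed blacklist entry at line ", bad[1L] + 1L, " of ", path)
  tab$position <- as.integer(tab$position)
  tab
}

#' Flag blacklisted calls
#'
#' Calls matching a blacklist entry by (position, ref, alt) are flagged,
#' not removed: both the flagged and the retained subsets are returned and
#' the input rows gain \code{hotspot_flag}/\code{hotspot_reason} columns.
#' Flagging is idempotent and independent of call order.
#'
#' @param calls call \code{data.frame} with columns \code{position},
#'   \code{ref}, \code{alt} (as from \code{\link{callSample}}).
#' @param blacklist a blacklist \code{data.frame}
#'   (default \code{\link{defaultBlacklist}}).
#' @return list with \code{calls} (all rows, flag columns added),
#'   \code{flagged} and \code{retained} subsets.
#' @export
applyBlacklist <- function(calls, blacklist = defaultBlacklist()) {
  key <- paste(calls$position, calls$ref, calls$alt)
  bkey <- paste(blacklist$position, blacklist$ref, blacklist$alt)
  hit <- key %in% bkey
  calls$hotspot_flag <- hit
  calls$hotspot_reason <- ifelse(hit,
    blacklist$reason[match(key, bkey)], NA_character_)
  list(calls = calls, flagged = calls[hit, , drop = FALSE],
       retained = calls[!hit, , drop = FALSE])
}

#' Flag error-hotspot artifacts on a call set
#'
#' Combines the A>C context-motif predicate with the blacklist: a call is
#' flagged when it is an A>C substitution in the hotspot motif context, or
#' when it matches a blacklist entry. Flags annotate the calls; downstream
#' burden statistics exclude flagged calls by default but the rows are
#' never dropped here.
#'
#' @param calls call \code{data.frame} with \code{position}, \code{ref},
#'   \code{alt}.
#' @param ref a \linkS4class{MitoReference}.
#' @param blacklist blacklist \code{data.frame}; \code{NULL} to use only
#'   the motif.
#' @return \code{calls} with logical \code{hotspot_flag} and character
#'   \code{hotspot_reason} (\code{"motif_AC"} or \code{"blacklist"}) added.
#' @export
flagArtifacts <- function(calls, ref, blacklist = defaultBlacklist()) {
  if (!nrow(calls)) {
    calls$hotspot_flag <- logical(0)
    calls$hotspot_reason <- character(0)
    return(calls)
  }
  motif <- vapply(seq_len(nrow(calls)), function(i)
    !is.na(calls$alt[i]) &&
      isAcHotspot(ref, calls$position[i], calls$ref[i], calls$alt[i]),
    logical(1))
  flag <- motif
  reason <- ifelse(motif, "motif_AC", NA_character_)
  if (!is.null(blacklist)) {
    key <- paste(calls$position, calls$ref, calls$alt)
    bkey <- paste(blacklist$position, blacklist$ref, blacklist$alt)
    black <- key %in% bkey
    reason[black & !motif] <- "blacklist"
    flag <- flag | black
  }
  calls$hotspot_flag <- flag
  calls$hotspot_reason <- reason
  calls
}
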