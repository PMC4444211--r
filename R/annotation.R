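## Consequence annotation under the vertebrate mitochondrial genetic code,
## novelty/rarity classification against a frequency catalog, and
## haplogroup-defining-variant exclusion.

#' Annotate the consequence of a single-base substitution
#'
#' Determines the region class and, for positions inside protein genes, the
#' per-gene codon change: codon index, reference and alternate amino acids
#' (three-letter), and whether the change is synonymous. Light-strand genes
#' (ND6) are handled by reverse-complementation, so an A>C call on the
#' heavy strand is annotated as its T>G codon change on the coding strand.
#' Variants in gene overlaps (ATP8/ATP6, ND4L/ND4) produce one row per
#' gene. Codons touching the rCRS 'N' placeholder are reported as
#' untranslatable with \code{synonymous = NA} so they can be excluded from
#' synonymous/non-synonymous tallies.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param position 1-based position.
#' @param refBase expected reference base; an error names both bases if it
#'   does not match the reference sequence.
#' @param altBase alternate base.
#' @param genes gene model from \code{\link{mitoGenes}}.
#' @return \code{data.frame} with one row per overlapping protein gene (or
#'   a single row with \code{gene = NA} outside protein genes): columns
#'   \code{position, ref, alt, region_class, gene, codon_index, ref_aa,
#'   alt_aa, aa_change, synonymous}.
#' @examples
#' ref <- rCRSReference()
#' annotateVariant(ref, 9160, "T", "C")$aa_change   # "Tyr212His"
#' annotateVariant(ref, 14280, "A", "C")$aa_change  # "Ser132Ala"
#' @export
annotateVariant <- function(ref, position, refBase, altBase,
                            genes = mitoGenes()) {
  actual <- refBaseAt(ref, position)
  if (actual != refBase)
    stop("reference mismatch at ", position, ": call says '", refBase,
         "', reference '", refName(ref), "' has '", actual, "'")
  region <- regionClass(position, genes)
  hits <- genesAt(position, genes, kind = "protein")
  base <- data.frame(position = as.integer(position), ref = refBase,
                     alt = altBase, region_class = region,
                     stringsAsFactors = FALSE)
  if (!length(hits) || region == "control") {
    base$gene <- NA_character_
    base$codon_index <- NA_integer_
    base$ref_aa <- NA_character_
    base$alt_aa <- NA_character_
    base$aa_change <- NA_character_
    base$synonymous <- NA
    return(base)
  }
  rows <- lapply(hits, function(g) {
    gene <- mitoGene(g, genes)
    info <- codonAt(ref, gene, position, genes)
    light <- info$strand == "light"
    out <- base
    out$gene <- g
    out$codon_index <- info$codon_index
    if (info$incomplete || nchar(info$codon) < 3L) {
      out$ref_aa <- out$alt_aa <- out$aa_change <- NA_character_
      out$synonymous <- NA
      return(out)
    }
    altCoding <- if (light) chartr("ACGTN", "TGCAN", altBase) else altBase
    mutCodon <- info$codon
    substring(mutCodon, info$offset + 1L, info$offset + 1L) <- altCoding
    refT <- translateCodon(info$codon)
    altT <- translateCodon(mutCodon)
    if (refT$untranslatable || altT$untranslatable) {
      out$ref_aa <- out$alt_aa <- NA_character_
      out$aa_change <- "untranslatable"
      out$synonymous <- NA
      return(out)
    }
    out$ref_aa <- refT$three
    out$alt_aa <- altT$three
    out$aa_change <- paste0(refT$three, info$codon_index, altT$three)
    out$synonymous <- refT$one == altT$one
    out
  })
  do.call(rbind, rows)
}

#' Annotate a call table
#'
#' Adds consequence columns to a call \code{data.frame}. The reported
#' \code{gene}/\code{aa_change} come from the first overlapping gene in
#' gene-model (report priority) order; \code{genes_all} collapses all
#' overlapping genes and \code{nonsynonymous_any} is \code{TRUE} when the
#' change is non-synonymous in at least one overlapping gene (the
#' convention used for burden counting).
#'
#' @param calls \code{data.frame} with columns \code{position}, \code{ref},
#'   \code{alt}.
#' @param ref a \linkS4class{MitoReference}.
#' @param genes gene model.
#' @return \code{calls} with columns \code{region_class}, \code{gene},
#'   \code{codon_index}, \code{aa_change}, \code{synonymous},
#'   \code{genes_all}, \code{nonsynonymous_any} added.
#' @export
annotateCalls <- function(calls, ref, genes = mitoGenes()) {
  n <- nrow(calls)
  cols <- data.frame(region_class = character(n), gene = NA_character_,
                     codon_index = NA_integer_, aa_change = NA_character_,
                     synonymous = rep(NA, n), genes_all = NA_character_,
                     nonsynonymous_any = rep(NA, n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(calls$alt[i])) { cols$region_class[i] <-
        regionClass(calls$position[i], genes); next }
    ann <- annotateVariant(ref, calls$position[i], calls$ref[i],
                           calls$alt[i], genes)
    cols$region_class[i] <- ann$region_class[1L]
    cols$gene[i] <- ann$gene[1L]
    cols$codon_index[i] <- ann$codon_index[1L]
    cols$aa_change[i] <- ann$aa_change[1L]
    cols$synonymous[i] <- ann$synonymous[1L]
    cols$genes_all[i] <- if (all(is.na(ann$gene))) NA_character_ else
      paste(ann$gene, collapse = "/")
    cols$nonsynonymous_any[i] <- if (all(is.na(ann$synonymous))) NA else
      any(!ann$synonymous, na.rm = TRUE)
  }
  cbind(calls, cols)
}

#' Read a known-variant frequency catalog
#'
#' Tab-separated with columns \code{position alt count catalog_size} and an
#' optional logical \code{self_deposit} marking catalog entries that
#' originate from this study's own sequence deposit (discountable when
#' classifying novelty).
#'
#' @param path catalog path; default is the packaged catalog built from
#'   the published per-locus database counts.
#' @return \code{data.frame}.
#' @export
readCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "variant_catalog.tsv",
                        package = "mitoplasmy", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "alt", "count", "catalog_size")
  if (!all(need %in% names(tab)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (!"self_deposit" %in% names(tab)) tab$self_deposit <- FALSE
  tab
}

#' Classify variant novelty against a frequency catalog
#'
#' \code{novel}: never observed in the catalog; \code{rare}: observed at a
#' frequency below \code{rareCatalogFreqMax} (default 0.1\% of the catalog);
#' \code{known}: otherwise. With \code{discountSelf = TRUE}, catalog counts
#' flagged as originating from this study's own deposit are removed before
#' classification. Variants absent from the catalog table are treated as
#' count 0 (novel); with \code{catalog = NULL} every status is
#' \code{"unknown"}.
#'
#' @param position,alt vectors identifying the variants.
#' @param catalog catalog \code{data.frame} from \code{\link{readCatalog}}.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param discountSelf discount self-deposited catalog entries.
#' @return \code{data.frame} with \code{status} in \{novel, rare, known,
#'   unknown\} and the supporting \code{frequency}.
#' @examples
#' cat <- data.frame(position = 9055, alt = "A", count = 1401,
#'                   catalog_size = 26850, self_deposit = FALSE)
#' classifyNovelty(9055, "A", cat)$status  # "known"
#' @export
classifyNovelty <- function(position, alt, catalog = readCatalog(),
                            thresholds = thresholdConfig(),
                            discountSelf = FALSE) {
  n <- max(length(position), length(alt))
  position <- rep_len(position, n); alt <- rep_len(alt, n)
  if (is.null(catalog))
    return(data.frame(position = position, alt = alt, status = "unknown",
                      frequency = NA_real_, stringsAsFactors = FALSE))
  idx <- match(paste(position, alt), paste(catalog$position, catalog$alt))
  count <- ifelse(is.na(idx), 0, catalog$count[idx])
  if (discountSelf)
    count <- count - ifelse(is.na(idx), 0,
                            catalog$self_deposit[idx] * 1)
  count <- pmax(count, 0)
  size <- ifelse(is.na(idx), max(catalog$catalog_size),
                 catalog$catalog_size[idx])
  freq <- count / size
  status <- ifelse(count == 0, "novel",
            ifelse(freq < thresholds@rareCatalogFreqMax, "rare", "known"))
  data.frame(position = position, alt = alt, status = status,
             frequency = freq, stringsAsFactors = FALSE)
}

#' Exclude haplogroup-defining variants from a call set
#'
#' Calls matching a supplied haplogroup-defining table by (position, alt)
#' are moved to the excluded set; private variants are retained. A call at
#' a listed position with a different alternate allele is retained. The
#' table is user-provided (columns \code{position}, \code{alt}); the
#' package defines the format only.
#'
#' @param calls call \code{data.frame} with \code{position}, \code{alt}.
#' @param haplogroupTable \code{data.frame} with \code{position},
#'   \code{alt}; empty or \code{NULL} retains everything.
#' @return list with \code{retained} and \code{excluded} subsets.
#' @export
excludeHaplogroupDefining <- function(calls, haplogroupTable = NULL) {
  if (is.null(haplogroupTable) || !nrow(haplogroupTable))
    return(list(retained = calls, excluded = calls[0, , drop = FALSE]))
  key <- paste(calls$position, calls$alt)
  hkey <- paste(haplogroupTable$position, haplogroupTable$alt)
  hit <- key %in% hkey
  list(retained = calls[!hit, , drop = FALSE],
       excluded = calls[hit, , drop = FALSE])
}
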