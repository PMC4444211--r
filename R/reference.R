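#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom stats rbinom rpois rnbinom runif setNames pnorm dhyper
#' @importFrom utils read.delim write.table
NULL

## Coordinates are 1-based inclusive throughout; the mitochondrial genome is
## circular and all wrap-around arithmetic is funnelled through circularPosition().

#' Map positions onto the circular mitochondrial genome
#'
#' Reduces arbitrary integer positions (including 0 and negatives) to 1-based
#' positions on a circular genome of length \code{len}.
#'
#' @param position integer vector of (possibly out-of-range) positions.
#' @param len genome length in bases.
#' @return integer vector of positions in \code{1..len}.
#' @examples
#' circularPosition(0, 16569)      # 16569
#' circularPosition(16570, 16569)  # 1
#' @export
circularPosition <- function(position, len) {
  ((as.integer(position) - 1L) %% as.integer(len)) + 1L
}

#' MitoReference: a circular mitochondrial reference sequence
#'
#' Holds the reference sequence (typically the 16,569-base human rCRS frame)
#' together with its name and a flag recording whether position 3107 carries
#' the historical 'N' placeholder.
#'
#' @slot sequence a \link[Biostrings]{DNAString} over A, C, G, T, N.
#' @slot name single character, e.g. \code{"rCRS"}.
#' @slot placeholderN logical; \code{TRUE} when position 3107 is 'N'.
#' @export
setClass("MitoReference",
  representation(sequence = "DNAString", name = "character",
                 placeholderN = "logical"))

setValidity("MitoReference", function(object) {
  msg <- NULL
  if (length(object@sequence) < 1L)
    msg <- c(msg, "empty reference sequence")
  freq <- Biostrings::alphabetFrequency(object@sequence)
  nonacgtn <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (nonacgtn > 0)
    msg <- c(msg, "reference contains symbols outside {A,C,G,T,N}")
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MitoReference", function(object) {
  cat("MitoReference '", object@name, "': ", length(object@sequence),
      " bp circular", if (object@placeholderN) ", 'N' placeholder at 3107",
      "\n", sep = "")
})

#' @describeIn MitoReference-class genome length in bases.
#' @param x a \code{MitoReference}.
#' @export
setMethod("length", "MitoReference", function(x) length(x@sequence))

#' Reference sequence accessors
#'
#' \code{refSequence} returns the full sequence as a character string;
#' \code{refBaseAt} returns single bases at (circularly wrapped) positions;
#' \code{refName} the reference name.
#'
#' @param ref a \code{MitoReference}.
#' @param position integer vector of 1-based positions (wrapped circularly).
#' @return character.
#' @export
refSequence <- function(ref) as.character(ref@sequence)

#' @rdname refSequence
#' @export
refBaseAt <- function(ref, position) {
  s <- refSequence(ref)
  substring(s, circularPosition(position, nchar(s)),
               circularPosition(position, nchar(s)))
}

#' @rdname refSequence
#' @export
refName <- function(ref) ref@name

#' Load a mitochondrial reference from FASTA
#'
#' Reads a single-record FASTA and validates it as a circular mitochondrial
#' reference. The loader insists on the canonical rCRS length of 16,569
#' bases unless \code{allowLengthOverride} is set, and records whether
#' position 3107 carries the rCRS 'N' placeholder.
#'
#' @param fastaPath path to a FASTA file containing exactly one record.
#' @param name reference name; default is the first word of the FASTA header.
#' @param allowLengthOverride if \code{TRUE}, accept lengths other than 16,569.
#' @return a \linkS4class{MitoReference}.
#' @examples
#' ref <- rCRSReference()
#' length(ref)  # 16569
#' @export
loadReference <- function(fastaPath, name = NULL, allowLengthOverride = FALSE) {
  set <- Biostrings::readDNAStringSet(fastaPath)
  if (length(set) != 1L)
    stop("FASTA must contain exactly one record, found ", length(set))
  if (length(set[[1L]]) != 16569L && !allowLengthOverride)
    stop("reference length ", length(set[[1L]]),
         " != 16569 (rCRS); set allowLengthOverride = TRUE to accept")
  freq <- Biostrings::alphabetFrequency(set[[1L]])
  if (sum(freq) - sum(freq[c("A", "C", "G", "T", "N")]) > 0)
    stop("reference contains symbols outside {A,C,G,T,N}")
  if (is.null(name))
    name <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  seqlen <- length(set[[1L]])
  hasN <- seqlen >= 3107L &&
    as.character(Biostrings::subseq(set[[1L]], 3107L, 3107L)) == "N"
  new("MitoReference", sequence = set[[1L]], name = name, placeholderN = hasN)
}

#' Packaged rCRS-frame reference
#'
#' Loads the reference shipped with the package: a synthetic stand-in for
#' the revised Cambridge Reference Sequence built from a real human
#' mitochondrial genome (NC_001807.4) remapped into rCRS coordinates and
#' corrected to the literature-documented rCRS content at all annotated
#' positions (see the package vignette). It has the defining rCRS
#' properties: 16,569 bases, 'N' placeholder at 3107, (CA)5 at 514, the
#' D310 and D16189 poly-C tracts, and rCRS codons at every locus the
#' packaged variant tables annotate.
#'
#' @return a \linkS4class{MitoReference} named \code{"rCRS"}.
#' @export
rCRSReference <- function() {
  path <- system.file("extdata", "rCRS_synthetic.fasta",
                      package = "mitoplasmy", mustWork = TRUE)
  loadReference(path, name = "rCRS")
}

#' Circular sequence context around a position
#'
#' Returns the (2*flank + 1)-base window centred on \code{position}, wrapping
#' around the origin of the circular genome. The centre base is upper-case
#' and the flanks lower-case, the convention used for error-hotspot contexts.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param position 1-based position of the centre base.
#' @param flank non-negative number of bases on each side.
#' @return a character string of length \code{2 * flank + 1}.
#' @examples
#' contextWindow(rCRSReference(), 6419, 5)  # "ataaaAccccc"
#' @export
contextWindow <- function(ref, position, flank = 5L) {
  if (flank < 0) stop("flank must be >= 0")
  n <- length(ref)
  if (position < 1L || position > n) stop("position out of range 1..", n)
  idx <- circularPosition(seq.int(position - flank, position + flank), n)
  s <- refSequence(ref)
  bases <- substring(s, idx, idx)
  paste0(paste(tolower(bases[seq_len(flank)]), collapse = ""),
         bases[flank + 1L],
         paste(tolower(bases[flank + 1L + seq_len(flank)]), collapse = ""))
}

#' The mitochondrial gene model
#'
#' Returns the packaged gene model for the human mitochondrial genome (13
#' protein-coding genes, 2 rRNAs, 22 tRNAs) as a \link[GenomicRanges]{GRanges}
#' on the circular sequence \code{"chrM"}. Light-strand genes (e.g. ND6) are
#' on \code{"-"}; metadata columns give the feature kind and whether a
#' protein gene ends in an incomplete stop codon completed by
#' polyadenylation. Overlapping gene pairs (ATP8/ATP6, ND4L/ND4) are both
#' present. The model is a versioned configuration derived from the
#' NC_012920 annotation and is never fetched at runtime.
#'
#' @param path optional path to an alternative gene model TSV with columns
#'   \code{name, start, end, strand (H/L), kind, incomplete_stop}.
#' @return a \code{GRanges} with mcols \code{name}, \code{kind},
#'   \code{incomplete_stop}.
#' @examples
#' g <- mitoGenes()
#' g[g$name == "ATP6"]
#' @export
mitoGenes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mito_genes.tsv",
                        package = "mitoplasmy", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "strand", "kind", "incomplete_stop")
  if (!all(need %in% names(tab)))
    stop("gene model must have columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges("chrM",
          IRanges::IRanges(tab$start, tab$end),
          strand = ifelse(tab$strand == "L", "-", "+"))
  GenomeInfoDb::seqlengths(gr) <- 16569L
  GenomeInfoDb::isCircular(gr) <- TRUE
  mcols(gr)$name <- tab$name
  mcols(gr)$kind <- tab$kind
  mcols(gr)$incomplete_stop <- tab$incomplete_stop
  gr
}

#' Look up one gene by name
#'
#' @param name gene name as in the gene model, e.g. \code{"ATP6"}.
#' @param genes gene model from \code{\link{mitoGenes}}.
#' @return a length-1 \code{GRanges}.
#' @export
mitoGene <- function(name, genes = mitoGenes()) {
  hit <- genes[mcols(genes)$name == name]
  if (length(hit) != 1L) stop("gene not found in model: ", name)
  hit
}

#' Region classification of mitochondrial positions
#'
#' Maps every position to exactly one primary region class among
#' \code{control}, \code{protein}, \code{rRNA}, \code{tRNA},
#' \code{intergenic}. The control region is the circular interval
#' 16024..576. Within the coding span, protein takes precedence over rRNA
#' and tRNA where annotations abut.
#'
#' @param position integer vector of 1-based positions.
#' @param genes gene model from \code{\link{mitoGenes}}.
#' @return character vector of region classes.
#' @examples
#' regionClass(c(100, 1601, 9160))  # control, rRNA, protein
#' @export
regionClass <- function(position, genes = mitoGenes()) {
  position <- as.integer(position)
  out <- rep("intergenic", length(position))
  inControl <- position >= 16024L | position <= 576L
  for (kind in c("tRNA", "rRNA", "protein")) {  # later kinds win
    sub <- genes[mcols(genes)$kind == kind]
    hit <- IRanges::overlapsAny(IRanges::IRanges(position, width = 1L),
                                IRanges::ranges(sub))
    out[hit] <- kind
  }
  out[inControl] <- "control"
  out
}

#' Genes overlapping a position
#'
#' Returns the names of all gene-model features of the requested kind that
#' contain the position, in gene-model (report priority) order.
#'
#' @param position a single 1-based position.
#' @param genes gene model.
#' @param kind feature kinds to consider (default protein genes).
#' @return character vector (possibly empty).
#' @export
genesAt <- function(position, genes = mitoGenes(), kind = "protein") {
  sub <- genes[mcols(genes)$kind %in% kind]
  hit <- GenomicRanges::start(sub) <= position & GenomicRanges::end(sub) >= position
  mcols(sub)$name[hit]
}

#' Codon arithmetic within a gene
#'
#' Computes the 1-based codon index, the 0-based offset of the position
#' within that codon, and the codon bases read on the coding strand, for a
#' position inside a protein gene. Heavy-strand genes read forward; for
#' light-strand genes (ND6) the codon index counts from the gene end and
#' the codon bases are reverse-complemented. Terminal codons truncated by
#' an incomplete stop are flagged.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param gene a gene name or a length-1 \code{GRanges} row from the model.
#' @param position 1-based position inside the gene.
#' @param genes gene model used when \code{gene} is a name.
#' @return list with \code{codon_index}, \code{offset}, \code{codon},
#'   \code{incomplete} (codon truncated at the gene boundary), and
#'   \code{strand}.
#' @examples
#' codonAt(rCRSReference(), "ATP6", 8794)$codon_index  # 90
#' @export
codonAt <- function(ref, gene, position, genes = mitoGenes()) {
  if (is.character(gene)) gene <- mitoGene(gene, genes)
  position <- as.integer(position)
  s <- GenomicRanges::start(gene)
  e <- GenomicRanges::end(gene)
  if (position < s || position > e)
    stop("position ", position, " outside gene ", mcols(gene)$name,
         " (", s, "..", e, ")")
  light <- as.character(GenomicRanges::strand(gene)) == "-"
  if (!light) {
    idx <- (position - s) %/% 3L + 1L
    off <- (position - s) %% 3L
    cpos <- s + 3L * (idx - 1L) + 0:2
  } else {
    idx <- (e - position) %/% 3L + 1L
    off <- (e - position) %% 3L
    cpos <- e - 3L * (idx - 1L) - (0:2)
  }
  inside <- cpos >= s & cpos <= e
  bases <- refBaseAt(ref, cpos)
  if (light)
    bases <- chartr("ACGTN", "TGCAN", bases)
  codon <- paste(ifelse(inside, bases, ""), collapse = "")
  list(codon_index = idx, offset = off, codon = codon,
       incomplete = !all(inside), strand = if (light) "light" else "heavy")
}

## vertebrate mitochondrial genetic code, via Biostrings (NCBI table 2:
## ATA=Met, TGA=Trp, AGA/AGG=Stop)
.mitoCode <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("SGC1")
    cache
  }
})

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", "*" = "Ter")

#' Vertebrate mitochondrial genetic code
#'
#' @return named character vector mapping all 64 codons to one-letter
#'   amino-acid symbols (\code{"*"} for the stop codons TAA, TAG, AGA, AGG).
#' @export
mitoGeneticCode <- function() .mitoCode()

#' Translate one codon under the vertebrate mitochondrial code
#'
#' Codons containing 'N' (e.g. overlapping the rCRS placeholder at 3107)
#' yield an explicit untranslatable result rather than an error.
#'
#' @param codon a 3-base string over A, C, G, T, N.
#' @return list with \code{one} (one-letter symbol or \code{NA}),
#'   \code{three} (three-letter name or \code{"untranslatable"}), and
#'   \code{untranslatable} logical.
#' @examples
#' translateCodon("ATA")$three  # "Met"
#' translateCodon("TGA")$three  # "Trp"
#' translateCodon("AGA")$three  # "Ter"
#' @export
translateCodon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGTN]", codon))
    stop("codon must be 3 bases over {A,C,G,T,N}: ", codon)
  if (grepl("N", codon))
    return(list(one = NA_character_, three = "untranslatable",
                untranslatable = TRUE))
  one <- unname(.mitoCode()[codon])
  list(one = one, three = unname(.AA3[one]), untranslatable = FALSE)
}
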