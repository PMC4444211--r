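## Seeded synthetic-data generator. Emulates the study design the analysis
## assumes: multi-group cohorts (Control/BD/MDD/SZ/METH), germline
## homoplasmic haplotypes drawn from a small clade tree, region-varying
## somatic heteroplasmy, negative-binomial coverage in the thousands,
## uniform base errors, context-dependent A>C artifacts at motif sites and
## repeat stutter at the D-loop repeat loci. Every dataset is paired with
## its truth set and all randomness flows from one seed.

#' Simulation configuration
#'
#' Default values encode the emulated study conditions: group sizes
#' 20/14/15/14/6 (Control/BD/MDD/SZ/METH), 11 multi-region subjects of
#' which 3 also have blood, somatic heteroplasmy levels uniform on
#' 5--35\%, negative-binomial coverage with mean 8,850 reads (the
#' combined platform average; per-platform means were about 3,766 and
#' 9,775), base error rate 0.1\%, an 8\% A>C artifact fraction at motif
#' sites, 2\% repeat stutter, and per-group non-synonymous burden rates
#' 0.55/1.00/0.87/1.57 mutations per subject for Control/BD/MDD/SZ.
#'
#' @param seed integer seed; every simulation output is reproducible
#'   bit-for-bit from it.
#' @param nSubjects named integer vector of subjects per diagnosis.
#' @param nMultiRegion subjects sampled in all 11 brain regions.
#' @param nWithBlood subjects with an additional blood sample.
#' @param cladeCount,cladeVariants toy haplogroup tree: number of clades
#'   and defining variants per clade.
#' @param privateVariantMean mean private germline homoplasmic variants
#'   per subject (Poisson).
#' @param burdenRates named per-subject rates of extra non-synonymous
#'   coding mutations per group (Poisson means).
#' @param somaticHetMean mean somatic heteroplasmic loci per subject.
#' @param somaticLevelRange uniform range of per-region heteroplasmy
#'   levels.
#' @param controlRegionBias probability that a somatic locus falls in the
#'   control region (heteroplasmy clusters in the hypervariable region).
#' @param coverageMean,coverageSize negative-binomial coverage model
#'   (mean and dispersion size).
#' @param errorRate per-read-base miscall rate, spread uniformly over the
#'   three non-template bases.
#' @param acArtifactRate spurious C fraction injected at A>C motif sites.
#' @param stutterRate per-read probability of a +/-1-unit repeat stutter.
#' @param positions optional integer subset of genome positions to
#'   simulate pileups for (\code{NULL} = whole genome).
#' @return a list of class \code{mitoSimConfig}.
#' @export
simulationConfig <- function(seed = 1L,
    nSubjects = c(Control = 20L, BD = 14L, MDD = 15L, SZ = 14L, METH = 6L),
    nMultiRegion = 11L, nWithBlood = 3L,
    cladeCount = 3L, cladeVariants = 8L, privateVariantMean = 12,
    burdenRates = c(Control = 0.55, BD = 1.00, MDD = 0.87, SZ = 1.57,
                    METH = 0.55),
    somaticHetMean = 2, somaticLevelRange = c(0.05, 0.35),
    controlRegionBias = 0.7,
    coverageMean = 8850, coverageSize = 8,
    errorRate = 0.001, acArtifactRate = 0.08, stutterRate = 0.02,
    positions = NULL) {
  if (is.null(names(nSubjects)) ||
      !all(names(nSubjects) %in% .DIAGNOSES))
    stop("nSubjects names must be diagnosis groups among: ",
         paste(.DIAGNOSES, collapse = ", "))
  rates <- c(privateVariantMean = NA, errRate = errorRate,
             ac = acArtifactRate, st = stutterRate)
  if (errorRate < 0 || errorRate > 1 || acArtifactRate < 0 ||
      acArtifactRate > 1 || stutterRate < 0 || stutterRate > 1)
    stop("rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), nSubjects = nSubjects,
    nMultiRegion = nMultiRegion, nWithBlood = nWithBlood,
    cladeCount = cladeCount, cladeVariants = cladeVariants,
    privateVariantMean = privateVariantMean, burdenRates = burdenRates,
    somaticHetMean = somaticHetMean, somaticLevelRange = somaticLevelRange,
    controlRegionBias = controlRegionBias, coverageMean = coverageMean,
    coverageSize = coverageSize, errorRate = errorRate,
    acArtifactRate = acArtifactRate, stutterRate = stutterRate,
    positions = positions), class = "mitoSimConfig")
}

#' All A>C motif positions of a reference
#'
#' Positions p with reference A at p and p-1 and C at p+1 and p+2
#' (computed circularly): exactly the sites at which
#' \code{\link{isAcHotspot}} is \code{TRUE} for an A>C call.
#'
#' @param ref a \linkS4class{MitoReference}.
#' @return sorted integer vector of positions.
#' @export
motifPositions <- function(ref) {
  s <- strsplit(refSequence(ref), "")[[1L]]
  n <- length(s)
  at <- function(k) s[circularPosition(seq_len(n) + k, n)]
  which(at(-1L) == "A" & s == "A" & at(1L) == "C" & at(2L) == "C")
}

#' Apply substitutions to a reference haplotype
#'
#' @param ref a \linkS4class{MitoReference}.
#' @param variants \code{data.frame} with \code{position}, \code{alt}.
#' @return character string of the mutated haplotype.
#' @export
applyVariants <- function(ref, variants) {
  s <- strsplit(refSequence(ref), "")[[1L]]
  if (nrow(variants)) s[variants$position] <- variants$alt
  paste(s, collapse = "")
}

#' Simulate a per-position allele-count table
#'
#' Coverage is drawn per position from a negative-binomial model; at
#' heteroplasmic positions the alternate allele receives
#' binomial(depth, fraction) reads; sequencing errors are spread uniformly
#' over the three non-template bases.
#'
#' @param haplotype character string: the sample's true (germline)
#'   sequence.
#' @param heteroplasmy \code{data.frame} with \code{position}, \code{alt},
#'   \code{fraction} (may be empty) of somatic heteroplasmies.
#' @param coverageMean,coverageSize negative-binomial coverage parameters.
#' @param errorRate per-base miscall rate.
#' @param positions positions to emit (default: whole haplotype).
#' @param seed optional seed; \code{NULL} continues the caller's RNG
#'   stream.
#' @return count table \code{data.frame} (\code{pos A C G T del}).
#' @export
simulatePileup <- function(haplotype, heteroplasmy = NULL,
                           coverageMean = 8850, coverageSize = 8,
                           errorRate = 0.001, positions = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq_len(nchar(haplotype))
  n <- length(positions)
  tmpl <- substring(haplotype, positions, positions)
  depth <- rnbinom(n, mu = coverageMean, size = coverageSize)
  m <- matrix(0L, n, 4L, dimnames = list(NULL, .BASES))
  ## alternate reads at heteroplasmic positions
  altReads <- integer(n)
  altBase <- rep(NA_character_, n)
  if (!is.null(heteroplasmy) && nrow(heteroplasmy)) {
    if (any(heteroplasmy$fraction < 0 | heteroplasmy$fraction > 1))
      stop("heteroplasmy fractions must lie in [0, 1]")
    idx <- match(heteroplasmy$position, positions)
    ok <- !is.na(idx)
    altReads[idx[ok]] <- rbinom(sum(ok), depth[idx[ok]],
                                heteroplasmy$fraction[ok])
    altBase[idx[ok]] <- heteroplasmy$alt[ok]
  }
  remaining <- depth - altReads
  ## errors: uniform over the three non-template bases, drawn from the
  ## non-alternate reads
  for (b in .BASES) {
    eligible <- tmpl != b & (is.na(altBase) | altBase != b)
    err <- integer(n)
    err[eligible] <- rbinom(sum(eligible), remaining[eligible],
                            errorRate / 3)
    m[, b] <- m[, b] + err
    remaining <- remaining - err
  }
  for (b in .BASES) {
    hit <- !is.na(altBase) & altBase == b
    m[hit, b] <- m[hit, b] + altReads[hit]
    thit <- tmpl == b
    m[thit, b] <- m[thit, b] + pmax(remaining[thit], 0L)
  }
  data.frame(pos = positions, A = m[, "A"], C = m[, "C"], G = m[, "G"],
             T = m[, "T"], del = 0L)
}

#' Inject A>C artifact reads at motif sites
#'
#' At every motif-matching A position present in the table, the C count is
#' inflated by binomial(depth, artifactFraction) spurious reads,
#' reproducing the platform's context-dependent A>C error.
#'
#' @param countTable count table \code{data.frame}.
#' @param ref a \linkS4class{MitoReference}.
#' @param artifactFraction spurious C fraction in [0, 1].
#' @param seed optional seed.
#' @param motif precomputed \code{\link{motifPositions}} (recomputed when
#'   \code{NULL}).
#' @return the count table with inflated C counts; attribute
#'   \code{injected_at} lists the affected positions.
#' @export
injectAcArtifacts <- function(countTable, ref, artifactFraction,
                              seed = NULL, motif = NULL) {
  if (artifactFraction < 0 || artifactFraction > 1)
    stop("artifactFraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(motif)) motif <- motifPositions(ref)
  hit <- which(countTable$pos %in% motif)
  if (artifactFraction > 0 && length(hit)) {
    depth <- rowSums(countTable[hit, .COUNT_COLS])
    countTable$C[hit] <- countTable$C[hit] +
      rbinom(length(hit), depth, artifactFraction)
  }
  attr(countTable, "injected_at") <- countTable$pos[hit]
  countTable
}

#' Simulate reads over a repeat locus
#'
#' Each read's true repeat length is drawn from the mixture; with
#' probability \code{stutterRate} the observed length slips by one unit
#' (either direction). Reads carry the locus anchors so the extraction
#' path is exercised end to end.
#'
#' @param mixture named numeric vector: repeat length -> mixture fraction
#'   (must sum to 1).
#' @param stutterRate per-read slippage probability.
#' @param nReads reads to simulate.
#' @param locus a \linkS4class{RepeatLocus}.
#' @param seed optional seed.
#' @return character vector of read sequences; attribute
#'   \code{true_lengths} carries the pre-stutter truth.
#' @export
simulateRepeatReads <- function(mixture, stutterRate = 0.02, nReads = 1000L,
                                locus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("mixture fractions must sum to 1")
  lens <- as.integer(sample(names(mixture), nReads, replace = TRUE,
                            prob = mixture))
  slip <- runif(nReads) < stutterRate
  obs <- lens + ifelse(slip, sample(c(-1L, 1L), nReads, replace = TRUE), 0L)
  obs <- pmax(obs, 0L)
  reads <- paste0(locus@leftAnchor, strrep(locus@unit, obs),
                  locus@rightAnchor)
  attr(reads, "true_lengths") <- lens
  reads
}

## pool of candidate non-synonymous substitutions, used to plant burden;
## direct codon arithmetic (cross-checked against annotateVariant in the
## test suite) keeps cohort simulation fast
.nonsynonymousPool <- function(ref, genes, size = 300L) {
  prot <- genes[mcols(genes)$kind == "protein"]
  code <- .mitoCode()
  s <- refSequence(ref)
  out <- list()
  cand <- sample(seq_along(prot), size * 3L, replace = TRUE)
  for (i in cand) {
    if (length(out) >= size) break
    gs <- GenomicRanges::start(prot)[i]; ge <- GenomicRanges::end(prot)[i]
    light <- as.character(GenomicRanges::strand(prot))[i] == "-"
    p <- sample(seq.int(gs, ge), 1L)
    if (!light) {
      idx <- (p - gs) %/% 3L; off <- (p - gs) %% 3L
      cpos <- gs + 3L * idx + 0:2
    } else {
      idx <- (ge - p) %/% 3L; off <- (ge - p) %% 3L
      cpos <- ge - 3L * idx - (0:2)
    }
    if (any(cpos < gs | cpos > ge)) next        # incomplete terminal codon
    cod <- substring(s, cpos, cpos)
    if (light) cod <- chartr("ACGTN", "TGCAN", cod)
    cod <- paste(cod, collapse = "")
    if (grepl("N", cod)) next
    rb <- substring(s, p, p)
    for (alt in setdiff(.BASES, rb)) {
      altC <- if (light) chartr("ACGT", "TGCA", alt) else alt
      mut <- cod
      substring(mut, off + 1L, off + 1L) <- altC
      if (code[[mut]] != code[[cod]] && code[[mut]] != "*") {
        out[[length(out) + 1L]] <- data.frame(position = p, ref = rb,
          alt = alt, stringsAsFactors = FALSE)
        break
      }
    }
  }
  unique(do.call(rbind, out))
}

#' Simulate a full cohort with its truth set
#'
#' Generates germline haplotypes from a toy clade tree (clade-defining
#' plus private homoplasmic variants), plants per-group extra
#' non-synonymous mutations at the configured burden rates, assigns
#' region-varying somatic heteroplasmies, and emits per-sample allele
#' count tables with coverage noise, base errors and A>C artifacts at
#' motif sites. All subjects have a DLPFC sample; the first
#' \code{nMultiRegion} subjects are sampled in all 11 brain regions and
#' the first \code{nWithBlood} of those also in blood.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param ref a \linkS4class{MitoReference}.
#' @param genes gene model.
#' @return list with \code{counts} (named list of count tables, one per
#'   sample), \code{metadata} (\code{data.frame}: sample, subject,
#'   diagnosis, region), and \code{truth} (germline variants per subject,
#'   per-sample somatic heteroplasmies with true fractions, planted
#'   burden variants, artifact positions, clade assignments).
#' @export
simulateCohort <- function(config = simulationConfig(),
                           ref = rCRSReference(), genes = mitoGenes()) {
  set.seed(config$seed)
  nS <- config$nSubjects
  subjects <- do.call(rbind, lapply(names(nS), function(g)
    data.frame(subject = sprintf("%s-%02d", g, seq_len(nS[[g]])),
               diagnosis = g, stringsAsFactors = FALSE)))
  nsub <- nrow(subjects)

  ## toy clade tree with planted defining variants
  ctrlPos <- c(seq.int(16024L, 16569L), seq.int(1L, 576L))
  genomePos <- setdiff(seq_len(length(ref)), 3107L)
  cladeDef <- lapply(seq_len(config$cladeCount), function(cl) {
    p <- sample(genomePos, config$cladeVariants)
    rb <- refBaseAt(ref, p)
    data.frame(clade = cl, position = p, ref = rb,
               alt = vapply(rb, function(b) sample(setdiff(.BASES, b), 1L),
                            ""), stringsAsFactors = FALSE)
  })
  subjects$clade <- rep_len(seq_len(config$cladeCount), nsub)

  nsPool <- .nonsynonymousPool(ref, genes)

  germline <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    priv <- sample(genomePos, rpois(1L, config$privateVariantMean))
    privRef <- refBaseAt(ref, priv)
    privDf <- data.frame(position = priv, ref = privRef,
      alt = vapply(privRef, function(b) sample(setdiff(.BASES, b), 1L), ""),
      source = "private", stringsAsFactors = FALSE)
    rate <- config$burdenRates[[subjects$diagnosis[i]]]
    nb <- rpois(1L, if (is.null(rate) || is.na(rate)) 0 else rate)
    burdenDf <- if (nb > 0) {
      pick <- nsPool[sample(nrow(nsPool), min(nb, nrow(nsPool))), ,
                     drop = FALSE]
      cbind(pick, source = "burden")
    } else NULL
    clDf <- cbind(cladeDef[[subjects$clade[i]]][c("position", "ref", "alt")],
                  source = "clade")
    g <- rbind(clDf, privDf, burdenDf)
    germline[[i]] <- g[!duplicated(g$position), , drop = FALSE]
  }
  names(germline) <- subjects$subject

  ## somatic heteroplasmies: positions fixed per subject, level per region
  brainRegions <- setdiff(.REGIONS, "blood")
  somaticLoci <- lapply(seq_len(nsub), function(i) {
    nh <- rpois(1L, config$somaticHetMean)
    if (nh == 0L) return(NULL)
    inCtrl <- runif(nh) < config$controlRegionBias
    p <- ifelse(inCtrl, sample(ctrlPos, nh, replace = TRUE),
                sample(genomePos, nh, replace = TRUE))
    p <- unique(p)
    p <- p[!p %in% germline[[i]]$position]
    if (!length(p)) return(NULL)
    rb <- refBaseAt(ref, p)
    data.frame(position = p, ref = rb,
               alt = vapply(rb, function(b)
                 if (b %in% .BASES) sample(setdiff(.BASES, b), 1L) else "A",
                 ""), stringsAsFactors = FALSE)
  })

  ## sample layout
  meta <- list(); truthSomatic <- list(); countsList <- list()
  motif <- motifPositions(ref)
  for (i in seq_len(nsub)) {
    regions <- "DLPFC"
    if (i <= config$nMultiRegion) regions <- brainRegions
    if (i <= config$nWithBlood) regions <- c(regions, "blood")
    hap <- applyVariants(ref, germline[[i]])
    for (rg in regions) {
      het <- somaticLoci[[i]]
      if (!is.null(het)) {
        het$fraction <- runif(nrow(het), config$somaticLevelRange[1L],
                              config$somaticLevelRange[2L])
        if (rg == "blood") het$fraction <- 0   # somatic: brain only
      }
      id <- paste0(subjects$subject[i], ".", rg)
      tab <- simulatePileup(hap, het, config$coverageMean,
                            config$coverageSize, config$errorRate,
                            positions = config$positions)
      tab <- injectAcArtifacts(tab, ref, config$acArtifactRate,
                               motif = motif)
      countsList[[id]] <- tab
      meta[[id]] <- data.frame(sample = id, subject = subjects$subject[i],
        diagnosis = subjects$diagnosis[i], region = rg,
        stringsAsFactors = FALSE)
      truthSomatic[[id]] <- het
    }
  }
  list(counts = countsList, metadata = do.call(rbind, c(meta,
         list(make.row.names = FALSE))),
       truth = list(subjects = subjects, germline = germline,
                    somatic = truthSomatic, clade_variants = cladeDef,
                    motif_positions = motif, config = config))
}

#' Write a simulated cohort to disk
#'
#' Emits the per-sample count tables (TSV), the cohort metadata TSV
#' (with count-table paths) and the truth set as JSON, in the layout the
#' pipeline consumes.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return the metadata \code{data.frame} with a \code{count_table} column.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sim$metadata
  meta$count_table <- file.path(dir, paste0(meta$sample, ".counts.tsv"))
  for (i in seq_len(nrow(meta)))
    writeCountTable(sim$counts[[meta$sample[i]]], meta$count_table[i])
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  meta
}
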