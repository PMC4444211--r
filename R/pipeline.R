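## Pipeline orchestration: runs calling, artifact flagging, annotation,
## novelty, haplogroup exclusion and cohort statistics over a cohort
## metadata table, and writes report-shaped outputs (VCF and consensus per
## sample, loci/burden/heteroplasmy/hotspot TSVs, JSON run manifest).
## All thresholds live in the config; stages never hard-code them.

#' Pipeline configuration
#'
#' Collects the file paths, thresholds and stage toggles of a pipeline
#' run. All paths are resolved and checked before any stage runs; the
#' effective configuration is echoed into the run manifest.
#'
#' @param metadata cohort metadata: a \code{data.frame} (or TSV path) with
#'   columns \code{sample, subject, diagnosis, region, count_table}.
#' @param outputDir output directory.
#' @param referenceFasta reference FASTA (default: packaged rCRS-frame
#'   reference).
#' @param geneModel gene model TSV path (default: packaged model).
#' @param blacklist error-hotspot blacklist path (default: packaged).
#' @param catalog known-variant catalog path (default: packaged);
#'   \code{NA} to skip novelty classification.
#' @param haplogroupTable optional haplogroup-defining variant table
#'   (TSV with \code{position}, \code{alt}) or \code{NULL}.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param caseGroups diagnoses treated as cases in burden statistics.
#' @param excludeFlagged exclude artifact-flagged calls from burden
#'   statistics.
#' @param writeVcf write one VCF per sample.
#' @param writeConsensus write one consensus FASTA per sample.
#' @param seed integer seed recorded in the manifest.
#' @return list of class \code{mitoPipelineConfig}.
#' @export
pipelineConfig <- function(metadata, outputDir,
    referenceFasta = NULL, geneModel = NULL, blacklist = NULL,
    catalog = NULL, haplogroupTable = NULL,
    thresholds = thresholdConfig(), caseGroups = c("BD", "MDD", "SZ"),
    excludeFlagged = TRUE, writeVcf = TRUE, writeConsensus = TRUE,
    seed = 1L) {
  pkgFile <- function(f) system.file("extdata", f, package = "mitoplasmy",
                                     mustWork = TRUE)
  if (is.null(referenceFasta)) referenceFasta <- pkgFile("rCRS_synthetic.fasta")
  if (is.null(geneModel)) geneModel <- pkgFile("mito_genes.tsv")
  if (is.null(blacklist)) blacklist <- pkgFile("error_hotspot_blacklist.tsv")
  if (is.null(catalog)) catalog <- pkgFile("variant_catalog.tsv")
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    metadata <- read.delim(metadata, stringsAsFactors = FALSE)
  }
  need <- c("sample", "subject", "diagnosis", "region", "count_table")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!nrow(metadata)) stop("empty cohort: metadata has no samples")
  for (p in c(referenceFasta, geneModel, blacklist,
              if (!is.na(catalog)) catalog, haplogroupTable,
              metadata$count_table))
    if (!is.null(p) && !file.exists(p)) stop("path not found: ", p)
  structure(list(metadata = metadata, outputDir = outputDir,
    referenceFasta = referenceFasta, geneModel = geneModel,
    blacklist = blacklist, catalog = catalog,
    haplogroupTable = haplogroupTable, thresholds = thresholds,
    caseGroups = caseGroups, excludeFlagged = excludeFlagged,
    writeVcf = writeVcf, writeConsensus = writeConsensus,
    seed = as.integer(seed)), class = "mitoPipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, per sample: variant calling from the count table, artifact
#' flagging, consequence annotation and novelty classification; then
#' haplogroup-defining-variant exclusion, cohort assembly, the case/
#' control partition and the burden table. Writes per-sample VCFs and
#' consensus FASTAs plus report-shaped TSVs (case-only loci, burden,
#' heteroplasmies, flagged hotspots) and a machine-readable JSON manifest
#' with the effective config, its hash, and call counts at every filter
#' stage. Any stage failure aborts with the stage name and the offending
#' sample.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with \code{cohort} (a \linkS4class{MitoCohort}),
#'   \code{partition}, \code{burden}, \code{files} (paths written) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "mitoPipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  ref <- .stage("load_reference", loadReference(config$referenceFasta,
                                                name = "rCRS"))
  genes <- .stage("load_gene_model", mitoGenes(config$geneModel))
  blacklist <- .stage("load_blacklist", readBlacklist(config$blacklist))
  catalog <- if (is.na(config$catalog)) NULL else
    .stage("load_catalog", readCatalog(config$catalog))
  hapTable <- if (is.null(config$haplogroupTable)) NULL else
    .stage("load_haplogroup_table",
           read.delim(config$haplogroupTable, stringsAsFactors = FALSE))

  meta <- config$metadata
  allCalls <- list(); allFiltered <- list(); files <- character(0)
  stageCounts <- c(n_samples = nrow(meta), n_calls = 0L, n_filtered = 0L,
                   n_homoplasmic = 0L, n_heteroplasmic = 0L,
                   n_flagged = 0L, n_haplogroup_excluded = 0L)
  for (i in seq_len(nrow(meta))) {
    sm <- meta$sample[i]
    tab <- .stage(paste0("read_counts[", sm, "]"),
                  readCountTable(meta$count_table[i]))
    res <- .stage(paste0("call[", sm, "]"),
                  callSample(tab, ref, th, sample = sm))
    calls <- .stage(paste0("flag_artifacts[", sm, "]"),
                    flagArtifacts(res$calls, ref, blacklist))
    calls <- .stage(paste0("annotate[", sm, "]"),
                    annotateCalls(calls, ref, genes))
    nov <- classifyNovelty(calls$position, calls$alt, catalog, th)
    calls$novelty <- nov$status
    calls$subject <- rep(meta$subject[i], nrow(calls))
    calls$diagnosis <- rep(meta$diagnosis[i], nrow(calls))
    calls$region <- rep(meta$region[i], nrow(calls))
    stageCounts["n_calls"] <- stageCounts["n_calls"] + nrow(calls)
    stageCounts["n_filtered"] <- stageCounts["n_filtered"] +
      nrow(res$filtered)
    stageCounts["n_homoplasmic"] <- stageCounts["n_homoplasmic"] +
      res$summary["n_homoplasmic"]
    stageCounts["n_heteroplasmic"] <- stageCounts["n_heteroplasmic"] +
      res$summary["n_heteroplasmic"]
    stageCounts["n_flagged"] <- stageCounts["n_flagged"] +
      sum(calls$hotspot_flag)
    if (config$writeVcf) {
      f <- file.path(config$outputDir, paste0(sm, ".vcf"))
      .stage(paste0("write_vcf[", sm, "]"),
             writeVcfCalls(calls, res$filtered, sm, f))
      files <- c(files, f)
    }
    if (config$writeConsensus) {
      f <- file.path(config$outputDir, paste0(sm, ".consensus.fasta"))
      cons <- buildConsensus(tab, th, genomeLength = length(ref))
      writeConsensusFasta(cons, sm, f)
      files <- c(files, f)
    }
    allCalls[[sm]] <- calls
    fl <- res$filtered
    fl$subject <- rep(meta$subject[i], nrow(fl))
    fl$diagnosis <- rep(meta$diagnosis[i], nrow(fl))
    fl$region <- rep(meta$region[i], nrow(fl))
    allFiltered[[sm]] <- fl
  }
  calls <- do.call(rbind, c(allCalls, list(make.row.names = FALSE)))
  excl <- .stage("haplogroup_exclusion",
                 excludeHaplogroupDefining(calls, hapTable))
  stageCounts["n_haplogroup_excluded"] <- nrow(excl$excluded)
  kept <- excl$retained
  filtered <- do.call(rbind, c(allFiltered, list(make.row.names = FALSE)))
  subjects <- unique(meta[c("subject", "diagnosis")])
  cohort <- .stage("assemble_cohort", mitoCohort(kept, subjects))

  caseGroups <- intersect(config$caseGroups, unique(meta$diagnosis))
  if (!length(caseGroups))
    stop("pipeline stage 'partition' failed: no case-group subjects in cohort")
  partition <- .stage("partition", partitionVariants(cohort,
      caseGroups = caseGroups, excludeFlagged = config$excludeFlagged))
  sizes <- table(subjects$diagnosis)
  groupSizes <- setNames(as.integer(sizes), names(sizes))
  burden <- .stage("burden", burdenTable(partition, groupSizes))

  w <- function(d, f) {
    path <- file.path(config$outputDir, f)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(files,
    w(partition$case_only, "case_only_loci.tsv"),
    w(burden, "burden.tsv"),
    w(kept[kept$classification == "heteroplasmic", , drop = FALSE],
      "heteroplasmy.tsv"),
    w(kept[kept$hotspot_flag, , drop = FALSE], "flagged_hotspots.tsv"))

  ## the hash covers the semantic configuration: inputs, thresholds and
  ## toggles, but not where the reports happen to be written
  cfgEcho <- config; cfgEcho$metadata <- NULL; cfgEcho$outputDir <- NULL
  cfgEcho$thresholds <- list(
    homoplasmyMajorMin = th@homoplasmyMajorMin,
    minCoverage = th@minCoverage,
    bloodDetectionMin = th@bloodDetectionMin,
    rareCatalogFreqMax = th@rareCatalogFreqMax)
  cfgJson <- jsonlite::toJSON(unclass(cfgEcho), auto_unbox = TRUE,
                              digits = NA, null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mitoplasmy")),
    r_version = R.version.string,
    seed = config$seed,
    config = jsonlite::fromJSON(cfgJson),
    config_hash = unname(tools::md5sum(tmp)),
    stage_counts = as.list(stageCounts))
  unlink(tmp)
  mf <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, mf)
  list(cohort = cohort, calls = kept, filtered = filtered,
       excluded = excl$excluded, partition = partition, burden = burden,
       files = files, manifest = manifest)
}

#' Write calls as VCF 4.2
#'
#' One record per call with the allele fraction (AF), coverage (DP),
#' classification (CLS), gene (GENE), amino-acid change (AAC) and novelty
#' (NOV) as INFO fields; artifact flags appear as FILTER values
#' (\code{hotspot_motif} / \code{blacklist}) and coverage-filtered sites
#' as non-PASS \code{low_coverage} records with the reference as ALT
#' placeholder 'N'.
#'
#' @param calls annotated call \code{data.frame}.
#' @param filtered coverage-filtered sites (may be \code{NULL}).
#' @param sample sample name (used in the header).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeVcfCalls <- function(calls, filtered = NULL, sample = "sample", file) {
  calls <- calls[!is.na(calls$alt), , drop = FALSE]
  if (is.null(calls$hotspot_flag)) calls$hotspot_flag <- rep(FALSE, nrow(calls))
  if (is.null(calls$hotspot_reason))
    calls$hotspot_reason <- rep(NA_character_, nrow(calls))
  filt <- if (!config_is_df(filtered)) NULL else filtered
  df <- data.frame(
    position = c(calls$position, filt$position),
    ref = c(calls$ref, filt$ref),
    alt = c(calls$alt, rep("N", length(filt$position))),
    af = c(calls$heteroplasmy_level, rep(NA_real_, length(filt$position))),
    dp = c(calls$coverage, filt$coverage),
    cls = c(calls$classification, rep("filtered", length(filt$position))),
    filter = c(ifelse(calls$hotspot_flag,
                      ifelse(is.na(calls$hotspot_reason), "hotspot",
                             calls$hotspot_reason), "PASS"),
               rep("low_coverage", length(filt$position))),
    gene = c(calls$gene %||% rep(NA_character_, nrow(calls)),
             rep(NA_character_, length(filt$position))),
    aac = c(calls$aa_change %||% rep(NA_character_, nrow(calls)),
            rep(NA_character_, length(filt$position))),
    nov = c(calls$novelty %||% rep(NA_character_, nrow(calls)),
            rep(NA_character_, length(filt$position))),
    stringsAsFactors = FALSE)
  df <- df[order(df$position), , drop = FALSE]
  gr <- GenomicRanges::GRanges(rep("chrM", nrow(df)),
          IRanges::IRanges(df$position, width = 1L))
  fx <- DataFrame(REF = Biostrings::DNAStringSet(df$ref),
                  ALT = Biostrings::DNAStringSetList(as.list(df$alt)),
                  QUAL = rep(NA_real_, nrow(df)), FILTER = df$filter)
  info <- DataFrame(AF = df$af, DP = as.integer(df$dp), CLS = df$cls,
                    GENE = df$gene, AAC = df$aac, NOV = df$nov)
  hdr <- VariantAnnotation::VCFHeader(samples = character())
  VariantAnnotation::meta(hdr)$fileformat <-
    DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  VariantAnnotation::info(hdr) <- DataFrame(
    Number = rep("1", 6),
    Type = c("Float", "Integer", "String", "String", "String", "String"),
    Description = c("non-reference allele fraction", "read depth",
                    "classification", "gene", "amino-acid change",
                    "novelty status"),
    row.names = c("AF", "DP", "CLS", "GENE", "AAC", "NOV"))
  VariantAnnotation::fixed(hdr) <- IRanges::DataFrameList(
    FILTER = DataFrame(
      Description = c("call passes", "A>C error-hotspot context motif",
                      "blacklisted error hotspot",
                      "coverage below threshold"),
      row.names = c("PASS", "motif_AC", "blacklist", "low_coverage")))
  v <- VariantAnnotation::VCF(rowRanges = gr, fixed = fx, info = info,
                              collapsed = TRUE)
  S4Vectors::metadata(v)$header <- hdr
  VariantAnnotation::writeVcf(v, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_is_df <- function(x) is.data.frame(x) && nrow(x) > 0

#' Read calls back from a pipeline VCF
#'
#' Round-trip companion of \code{\link{writeVcfCalls}}.
#'
#' @param file VCF path.
#' @return \code{data.frame} with position, ref, alt, AF, DP,
#'   classification, filter.
#' @export
readVcfCalls <- function(file) {
  v <- VariantAnnotation::readVcf(file)
  alt <- vapply(VariantAnnotation::alt(v), function(a)
    as.character(a)[1L], "")
  data.frame(
    position = GenomicRanges::start(SummarizedExperiment::rowRanges(v)),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt,
    heteroplasmy_level = unlist(VariantAnnotation::info(v)$AF),
    coverage = unlist(VariantAnnotation::info(v)$DP),
    classification = unlist(VariantAnnotation::info(v)$CLS),
    filter = VariantAnnotation::filt(v),
    stringsAsFactors = FALSE, row.names = NULL)
}
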