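## Pipeline orchestration: simulate a full input set to disk, run
## depth scan -> BSA mapping -> KASP selection, and emit a reproducible
## report with a manifest.

#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom tools md5sum
#' @importFrom utils modifyList
NULL

defaultAnnotationRegions <- function(spec) {
  data.frame(
    chrom = c(spec@recipientChrom, spec@donorChrom),
    start = c(0, 0),
    end = c(spec@deletedLen, spec@addedLen),
    n_genes = c(894L, 613L),
    n_high = c(327L, 350L),
    n_low = c(567L, 263L),
    mean_gene_len = 3000)
}

#' Simulate a complete pipeline input set on disk
#'
#' Writes the six input files the analysis consumes -- depth TSV, SNP VCF,
#' gene GFF3, flanks FASTA, phenotype TSV and a simulation-truth JSON --
#' plus a manifest recording the seed, parameters and md5 checksums. All
#' randomness derives from `seed`, so identical seeds give identical files.
#'
#' @param outDir Output directory (created if needed).
#' @param spec A [GenomeSpec-class].
#' @param depthParams A [DepthSimParams-class]; its seed is overridden by
#'   `seed`.
#' @param popParams A [PopSimParams-class]; its seed is overridden by
#'   `seed + 1`.
#' @param annRegions Data.frame of annotation intervals for
#'   [simulateAnnotation()]; defaults place a high/low-confidence gene
#'   complement on the deleted and added distal segments.
#' @param seed Global integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
simulateInputs <- function(outDir, spec = GenomeSpec(),
                           depthParams = DepthSimParams(),
                           popParams = PopSimParams(),
                           annRegions = defaultAnnotationRegions(spec),
                           seed = 1L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  seed <- as.integer(seed)
  depthParams@seed <- seed
  popParams@seed <- seed + 1L

  prof <- simulateDepthProfile(spec, depthParams)
  sim <- simulateF2Bulks(popParams, spec)
  ann <- simulateAnnotation(annRegions, seed = seed + 2L)

  paths <- c(depth = file.path(outDir, "depth.tsv"),
             vcf = file.path(outDir, "snps.vcf"),
             gff3 = file.path(outDir, "genes.gff3"),
             flanks = file.path(outDir, "flanks.fasta"),
             phenotypes = file.path(outDir, "phenotypes.tsv"),
             truth = file.path(outDir, "truth.json"))
  writeDepth(prof, paths[["depth"]])
  writeSnpVcf(sim$snps, paths[["vcf"]])
  writeGeneAnnotation(ann, paths[["gff3"]])
  writeFlanksFasta(sim$snps, paths[["flanks"]])
  writePhenotypes(sim$phenotypes, paths[["phenotypes"]])
  write_json(list(donor_chrom = spec@donorChrom,
                  recipient_chrom = spec@recipientChrom,
                  added_len = spec@addedLen, deleted_len = spec@deletedLen,
                  causal_pos = sim$causalPos, seed = seed),
             paths[["truth"]], auto_unbox = TRUE, digits = NA)

  manifest <- list(seed = seed,
                   parameters = list(
                     mean_depth = depthParams@meanDepth,
                     window_size = depthParams@windowSize,
                     background_noise = depthParams@backgroundNoise,
                     n_f2 = popParams@nF2, bulk_size = popParams@bulkSize,
                     bulk_depth = popParams@bulkDepth,
                     causal_pos = popParams@causalPos),
                   files = as.list(md5sum(unname(paths))))
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest = file.path(outDir, "manifest.json")))
}

#' Run the full analysis chain on in-memory objects
#'
#' Executes the three analysis stages in order: depth-based translocation
#' detection, bulked-segregant candidate-region mapping, and the KASP filter
#' cascade restricted to the intersection of the detected donor segment and
#' the BSA candidate region. If the intersection is empty the KASP stage is
#' skipped with a logged reason.
#'
#' @param profile A [DepthProfile-class].
#' @param snps A [SnpTable-class].
#' @param annotation Optional `GRanges` gene annotation for segment gene
#'   counts.
#' @param donorChrom,recipientChrom Chromosome names for the depth scan.
#' @param controlChroms Normalisation controls (default: all other
#'   chromosomes).
#' @param absentThreshold,minRun Depth-scan parameters.
#' @param windowBp,stepBp,quantileLevel,bulkSize BSA parameters.
#' @param filterConfig A [FilterConfig-class].
#' @param seed Seed for the null-envelope simulation.
#' @param outDir Optional directory; when given, the report JSON, segment and
#'   region BEDs and marker TSV are written there.
#' @return A list: `translocation`, `segments`, `gene_counts`,
#'   `candidate_regions`, `markers`, `audit`, `log`.
#' @examples
#' \donttest{
#' prof <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 5))
#' sim <- simulateF2Bulks(PopSimParams(seed = 6))
#' res <- runAll(prof, sim$snps)
#' res$translocation
#' }
#' @export
runAll <- function(profile, snps, annotation = NULL,
                   donorChrom = "2D", recipientChrom = "2A",
                   controlChroms = NULL, absentThreshold = 0.25, minRun = 3L,
                   windowBp = 1e6, stepBp = 2.5e5, quantileLevel = 0.95,
                   bulkSize = 30, filterConfig = FilterConfig(), seed = 1L,
                   outDir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  ## stage 1: depth scan
  call <- tryCatch(
    detectTranslocation(profile, donorChrom, recipientChrom, controlChroms,
                        absentThreshold, minRun),
    error = function(e) stop(sprintf("depthscan stage failed: %s",
                                     conditionMessage(e))))
  chroms <- unique(as.character(seqnames(profile@windows)))
  if (is.null(controlChroms))
    controlChroms <- setdiff(chroms, c(donorChrom, recipientChrom))
  prof <- classifyWindows(normalizeDepth(profile, controlChroms),
                          absentThreshold)
  segs <- segmentStates(prof, minRun)
  note("depthscan: %s", if (isNoCall(call)) "no call" else call@name)

  geneCounts <- NULL
  if (!is.null(annotation) && !isNoCall(call)) {
    geneCounts <- list(added = countGenes(donorSegment(call), annotation),
                       deleted = countGenes(recipientSegment(call),
                                            annotation))
  }

  ## stage 2: BSA mapping
  deltas <- tryCatch({
    d <- deltaSnpIndex(snps)
    track <- windowDelta(d, windowBp, stepBp)
    env <- nullEnvelope(bulkSize = bulkSize,
                        depthGrid = unique(round(quantile(
                          d$depth, c(0.05, 0.25, 0.5, 0.75, 0.95)))),
                        nSims = 2000, quantileLevel = quantileLevel,
                        seed = seed)
    regions <- callCandidateRegion(track, env)
    list(deltas = d, track = track, envelope = env, regions = regions)
  }, error = function(e) stop(sprintf("bsamap stage failed: %s",
                                      conditionMessage(e))))
  note("bsamap: %d candidate region(s)", length(deltas$regions))

  ## stage 3: KASP selection on donor-segment /\ candidate-region SNPs
  markers <- data.frame(); audit <- NULL
  target <- GRanges()
  if (!isNoCall(call) && length(deltas$regions) > 0) {
    target <- GenomicRanges::intersect(
      donorSegment(call),
      deltas$regions[as.character(seqnames(deltas$regions)) == donorChrom],
      ignore.strand = TRUE)
  }
  if (length(target) == 0) {
    note("kaspselect: skipped (empty donor-segment/candidate-region intersection)")
  } else {
    inTarget <- countOverlaps(snps@gr, target, ignore.strand = TRUE) > 0
    cand <- snps[which(inTarget)]
    note("kaspselect: %d candidate SNP(s) in the target interval",
         nSnps(cand))
    if (nSnps(cand) > 0) {
      casc <- tryCatch(
        filterCascade(cand, filterConfig,
                      region = c(min(start(target)) - 1, max(end(target)))),
        error = function(e) stop(sprintf("kaspselect stage failed: %s",
                                         conditionMessage(e))))
      audit <- casc$audit
      markers <- buildKaspMarkers(casc$selected, allSnps = cand,
                                  config = filterConfig)
      note("kaspselect: %d marker(s) designed", nrow(markers))
    }
  }

  report <- list(translocation = call, segments = segs,
                 gene_counts = geneCounts,
                 candidate_regions = deltas$regions,
                 delta_track = deltas$track, envelope = deltas$envelope,
                 markers = markers, audit = audit, log = log)
  if (!is.null(outDir)) writeReport(report, outDir, seed)
  report
}

grToList <- function(gr) {
  lapply(seq_along(gr), function(i) {
    x <- list(chrom = as.character(seqnames(gr))[i],
              start = start(gr)[i] - 1, end = end(gr)[i])
    c(x, as.list(mcols(gr)[i, , drop = FALSE]))
  })
}

#' Write the pipeline report to disk
#'
#' Emits `report.json` (translocation call, candidate regions, gene counts,
#' run log, seed), `segments.bed`, `regions.bed`, `markers.tsv` and, when an
#' audit trail exists, `filter_audit.tsv`.
#'
#' @param report List returned by [runAll()].
#' @param outDir Output directory (created if needed).
#' @param seed Seed recorded in the report header.
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir, seed = NA) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  call <- report$translocation
  body <- list(
    seed = seed,
    translocation = if (isNoCall(call)) list(no_call = TRUE) else list(
      name = call@name,
      donor_segment = grToList(donorSegment(call))[[1]],
      recipient_segment = grToList(recipientSegment(call))[[1]]),
    gene_counts = report$gene_counts,
    candidate_regions = grToList(report$candidate_regions),
    n_markers = nrow(report$markers),
    log = report$log)
  write_json(body, file.path(outDir, "report.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  writeSegmentsBed(report$segments, file.path(outDir, "segments.bed"))
  writeRegionsBed(report$candidate_regions, file.path(outDir, "regions.bed"))
  write.table(report$markers, file.path(outDir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$audit))
    write.table(report$audit, file.path(outDir, "filter_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}

#' Read a pipeline configuration file
#'
#' YAML configuration with any of the sections `genome`, `depth`,
#' `population`, `filter`, `bsa`, `io`; unknown keys are rejected so typos
#' surface early. Values override the package defaults; command-line flags
#' (in the shipped `inst/scripts/introkasp.R` tool) override both.
#'
#' @param path YAML file path.
#' @return Nested list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("genome", "depth", "population", "filter", "bsa", "io", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown configuration section(s): %s",
                 paste(bad, collapse = ", ")))
  cfg
}
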