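#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlengths
#' @importFrom Biostrings DNAStringSet reverseComplement letterFrequency
#'   readDNAStringSet writeXStringSet
#' @importFrom stats rpois rbinom runif rgamma rexp median quantile approx
#'   rnorm setNames chisq.test uniroot
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Genome structure of a segmental translocation line
#'
#' Describes the merged recipient+donor reference and the introgression
#' architecture of a terminal-segment translocation line: a distal segment of
#' the donor chromosome is present (added) while the homoeologous distal
#' segment of the recipient chromosome is absent (deleted). Background
#' chromosomes are fully present and serve as depth controls.
#'
#' @slot chromosomes Named numeric vector of chromosome lengths in bp.
#' @slot donorChrom Name of the donor chromosome (distal segment present).
#' @slot recipientChrom Name of the recipient chromosome (distal segment
#'   absent).
#' @slot addedLen Length in bp of the distal donor segment that is present.
#' @slot deletedLen Length in bp of the distal recipient segment that is
#'   absent.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(
    chromosomes   = "numeric",
    donorChrom    = "character",
    recipientChrom = "character",
    addedLen      = "numeric",
    deletedLen    = "numeric"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (is.null(names(object@chromosomes)) || any(!nzchar(names(object@chromosomes))))
    msg <- c(msg, "chromosomes must be a named vector of lengths")
  if (any(object@chromosomes <= 0))
    msg <- c(msg, "all chromosome lengths must be > 0")
  if (anyDuplicated(names(object@chromosomes)))
    msg <- c(msg, "duplicated chromosome names")
  if (!(object@donorChrom %in% names(object@chromosomes)))
    msg <- c(msg, "donorChrom not among chromosomes")
  if (!(object@recipientChrom %in% names(object@chromosomes)))
    msg <- c(msg, "recipientChrom not among chromosomes")
  if (identical(object@donorChrom, object@recipientChrom))
    msg <- c(msg, "donorChrom and recipientChrom must differ")
  if (length(msg)) return(msg)
  if (object@addedLen <= 0 || object@addedLen > object@chromosomes[[object@donorChrom]])
    msg <- c(msg, "addedLen must be in (0, donor chromosome length]")
  if (object@deletedLen <= 0 || object@deletedLen > object@chromosomes[[object@recipientChrom]])
    msg <- c(msg, "deletedLen must be in (0, recipient chromosome length]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' Defaults describe a terminal 2D/2A translocation: a 13.8 Mb distal donor
#' (2DS) segment present and a 16.1 Mb distal recipient (2AS) segment absent,
#' on chromosomes of realistic wheat magnitude, with one fully present
#' background chromosome used for depth normalisation.
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param donorChrom,recipientChrom Chromosome names within `chromosomes`.
#' @param addedLen Present distal donor segment length (bp).
#' @param deletedLen Absent distal recipient segment length (bp).
#' @return A [GenomeSpec-class] object.
#' @examples
#' GenomeSpec()
#' @export
GenomeSpec <- function(chromosomes = c(`1A` = 3e8, `2A` = 7.8e8, `2D` = 6.5e8),
                       donorChrom = "2D", recipientChrom = "2A",
                       addedLen = 13.8e6, deletedLen = 16.1e6) {
  new("GenomeSpec", chromosomes = chromosomes, donorChrom = donorChrom,
      recipientChrom = recipientChrom, addedLen = addedLen,
      deletedLen = deletedLen)
}

#' Parameters for window-depth simulation
#'
#' @slot meanDepth Expected sequencing depth (x) of present-state windows.
#' @slot windowSize Window size in bp.
#' @slot backgroundNoise Expected depth (x) of absent-state windows, emulating
#'   residual mismapping; 0 gives perfectly clean absence.
#' @slot seed Integer seed for the pseudo-random draw.
#' @exportClass DepthSimParams
setClass("DepthSimParams",
  representation(meanDepth = "numeric", windowSize = "numeric",
                 backgroundNoise = "numeric", seed = "numeric")
)

setValidity("DepthSimParams", function(object) {
  msg <- character()
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@windowSize <= 0) msg <- c(msg, "windowSize must be > 0")
  if (object@backgroundNoise < 0) msg <- c(msg, "backgroundNoise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct DepthSimParams
#'
#' Defaults match a 35x whole-genome resequencing run summarised in 100 kb
#' windows, with 0.5x residual background depth on absent segments.
#'
#' @param meanDepth Present-state mean depth (x).
#' @param windowSize Window size (bp).
#' @param backgroundNoise Absent-state mean depth (x).
#' @param seed Integer seed.
#' @return A [DepthSimParams-class] object.
#' @export
DepthSimParams <- function(meanDepth = 35, windowSize = 1e5,
                           backgroundNoise = 0.5, seed = 1L) {
  new("DepthSimParams", meanDepth = meanDepth, windowSize = windowSize,
      backgroundNoise = backgroundNoise, seed = seed)
}

#' Parameters for F2 bulk-segregant simulation
#'
#' Describes an F2 population segregating a dominant wax-inhibitor locus
#' carried on the donor chromosome, with phenotypically contrasting bulks and
#' small parental bulks sequenced at moderate depth.
#'
#' @slot nF2 Number of F2 individuals.
#' @slot bulkSize Individuals per phenotype bulk.
#' @slot parentalBulkSize Individuals per parental bulk.
#' @slot causalPos Position (bp) of the causal locus on the donor chromosome.
#' @slot nSnps Number of simulated biallelic SNPs.
#' @slot snpRegion Length-2 numeric, bp interval holding the SNPs.
#' @slot bulkDepth Mean reads per SNP per bulk (Poisson).
#' @slot missingRate Per-sample genotype missing probability.
#' @slot flankLen Flanking sequence length per side (bp).
#' @slot cmPerMb Genetic map density (cM per Mb) for recombination.
#' @slot flankGC Expected GC fraction of simulated flanks.
#' @slot seed Integer seed.
#' @exportClass PopSimParams
setClass("PopSimParams",
  representation(nF2 = "numeric", bulkSize = "numeric",
                 parentalBulkSize = "numeric", causalPos = "numeric",
                 nSnps = "numeric", snpRegion = "numeric",
                 bulkDepth = "numeric", missingRate = "numeric",
                 flankLen = "numeric", cmPerMb = "numeric",
                 flankGC = "numeric", seed = "numeric")
)

setValidity("PopSimParams", function(object) {
  msg <- character()
  if (length(object@snpRegion) != 2L || diff(object@snpRegion) <= 0)
    msg <- c(msg, "snpRegion must be an increasing length-2 interval")
  else if (object@causalPos < object@snpRegion[1] ||
           object@causalPos > object@snpRegion[2])
    msg <- c(msg, "causalPos must lie inside snpRegion")
  if (2 * object@bulkSize > object@nF2)
    msg <- c(msg, "need 2*bulkSize <= nF2")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (object@flankLen < 150)
    msg <- c(msg, "flankLen must be >= 150")
  if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
  if (object@cmPerMb < 0) msg <- c(msg, "cmPerMb must be >= 0")
  if (object@flankGC < 0 || object@flankGC > 1)
    msg <- c(msg, "flankGC must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct PopSimParams
#'
#' Defaults emulate the mapping design used for a dominant wax inhibitor on a
#' distal donor segment: 2,000 F2 plants, 30+30 phenotype bulks, 10-plant
#' parental bulks, 200 SNPs over the distal 20 Mb, causal locus at 7.9 Mb,
#' about 50 reads per SNP per bulk, and a 1 cM/Mb map.
#'
#' @param nF2,bulkSize,parentalBulkSize Population and bulk sizes.
#' @param causalPos Causal position (bp).
#' @param nSnps Number of SNPs.
#' @param snpRegion Length-2 interval (bp).
#' @param bulkDepth Mean reads per SNP per bulk.
#' @param missingRate Per-sample missing-call probability.
#' @param flankLen Flank length per side (bp).
#' @param cmPerMb Map density (cM/Mb).
#' @param flankGC Expected flank GC fraction.
#' @param seed Integer seed.
#' @return A [PopSimParams-class] object.
#' @export
PopSimParams <- function(nF2 = 2000, bulkSize = 30, parentalBulkSize = 10,
                         causalPos = 7.9e6, nSnps = 200,
                         snpRegion = c(1e5, 2e7), bulkDepth = 50,
                         missingRate = 0.05, flankLen = 200, cmPerMb = 1,
                         flankGC = 0.5, seed = 1L) {
  new("PopSimParams", nF2 = nF2, bulkSize = bulkSize,
      parentalBulkSize = parentalBulkSize, causalPos = causalPos,
      nSnps = nSnps, snpRegion = snpRegion, bulkDepth = bulkDepth,
      missingRate = missingRate, flankLen = flankLen, cmPerMb = cmPerMb,
      flankGC = flankGC, seed = seed)
}

#' SNP filter cascade configuration
#'
#' Thresholds of the six-criterion marker filter: missing rate, minor allele
#' frequency, local spacing, polymorphism information content, flanking GC
#' content, and the even-distribution target count.
#'
#' @slot maxMissing Maximum tolerated genotype missing rate (sites strictly
#'   exceeding it are excluded).
#' @slot minMAF Minimum minor allele frequency (sites strictly below are
#'   removed).
#' @slot exclusionRadius No other SNP may lie within this many bp up- or
#'   downstream.
#' @slot minPIC Minimum polymorphism information content.
#' @slot gcFlank Flank length per side (bp) over which GC is computed.
#' @slot gcRange Inclusive admissible GC fraction range.
#' @slot targetCount Number of evenly distributed SNPs to select.
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(maxMissing = "numeric", minMAF = "numeric",
                 exclusionRadius = "numeric", minPIC = "numeric",
                 gcFlank = "numeric", gcRange = "numeric",
                 targetCount = "numeric")
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@maxMissing < 0 || object@maxMissing > 1)
    msg <- c(msg, "maxMissing must be in [0, 1]")
  if (object@minMAF < 0 || object@minMAF > 0.5)
    msg <- c(msg, "minMAF must be in [0, 0.5]")
  if (object@exclusionRadius < 0)
    msg <- c(msg, "exclusionRadius must be >= 0")
  if (object@minPIC < 0 || object@minPIC > 1)
    msg <- c(msg, "minPIC must be in [0, 1]")
  if (object@gcFlank <= 0) msg <- c(msg, "gcFlank must be > 0")
  if (length(object@gcRange) != 2L || object@gcRange[1] > object@gcRange[2] ||
      any(object@gcRange < 0) || any(object@gcRange > 1))
    msg <- c(msg, "gcRange must be an ordered pair in [0, 1]")
  if (object@targetCount <= 0)
    msg <- c(msg, "targetCount must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterConfig
#'
#' Defaults implement the standard KASP pre-selection cascade: missing rate
#' <= 20%, MAF >= 0.05, no neighbouring SNP within 50 bp, PIC >= 0.2, GC of
#' the 150 bp flanks within 40-60% inclusive, and 34 evenly spaced sites.
#'
#' @param maxMissing,minMAF,exclusionRadius,minPIC,gcFlank,gcRange,targetCount
#'   See the class slots.
#' @return A [FilterConfig-class] object.
#' @export
FilterConfig <- function(maxMissing = 0.20, minMAF = 0.05,
                         exclusionRadius = 50, minPIC = 0.2, gcFlank = 150,
                         gcRange = c(0.40, 0.60), targetCount = 34) {
  new("FilterConfig", maxMissing = maxMissing, minMAF = minMAF,
      exclusionRadius = exclusionRadius, minPIC = minPIC, gcFlank = gcFlank,
      gcRange = gcRange, targetCount = targetCount)
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Windowed depth profile over a merged reference
#'
#' Ordered, non-overlapping windows tiling each chromosome, each carrying a
#' mean sequencing depth. Coordinates are 0-based half-open internally; the
#' underlying [GenomicRanges::GRanges] stores 1-based starts as usual and the
#' TSV reader/writer converts at the boundary.
#'
#' @slot windows A `GRanges`, sorted, tiling each chromosome, with a numeric
#'   `depth` metadata column (and, after classification, a `state` column).
#' @slot windowSize Nominal window size in bp.
#' @slot normalized `TRUE` once depths have been divided by the control
#'   median.
#' @exportClass DepthProfile
setClass("DepthProfile",
  representation(windows = "GRanges", windowSize = "numeric",
                 normalized = "logical")
)

setValidity("DepthProfile", function(object) {
  gr <- object@windows
  if (length(gr) == 0L) return("profile has no windows")
  if (is.null(gr$depth)) return("windows must carry a 'depth' column")
  if (any(gr$depth < 0)) return("depths must be >= 0")
  for (chr in seqlevels(gr)) {
    w <- gr[seqnames(gr) == chr]
    if (length(w) == 0L) next
    if (is.unsorted(start(w))) return(sprintf("windows unsorted on %s", chr))
    if (length(w) > 1L && any(start(w)[-1] <= end(w)[-length(w)]))
      return(sprintf("overlapping or non-tiling windows on %s", chr))
  }
  TRUE
})

#' Table of biallelic SNPs with per-bulk allele depths
#'
#' One row per SNP with single-base ref/alt alleles, per-sample ref/alt read
#' depths and genotype calls (samples are the two phenotype bulks and the two
#' parental bulks), and flanking sequence on each side. The alt allele is the
#' donor-parent allele by construction in simulated tables; for observed data
#' use [polarizeByParents()] before mapping.
#'
#' @slot gr `GRanges` of SNP positions (width 1, sorted within chromosome).
#' @slot ref,alt Character vectors of single-base alleles.
#' @slot refDepth,altDepth Integer matrices, SNP x sample.
#' @slot geno Character matrix of genotype calls ("0/0", "0/1", "1/1" or NA
#'   for missing).
#' @slot flank5,flank3 `DNAStringSet` flanks (5' and 3' of the SNP base).
#' @exportClass SnpTable
setClass("SnpTable",
  representation(gr = "GRanges", ref = "character", alt = "character",
                 refDepth = "matrix", altDepth = "matrix", geno = "matrix",
                 flank5 = "DNAStringSet", flank3 = "DNAStringSet")
)

setValidity("SnpTable", function(object) {
  n <- length(object@gr)
  msg <- character()
  if (length(object@ref) != n || length(object@alt) != n)
    msg <- c(msg, "allele vectors must match the number of SNPs")
  if (nrow(object@refDepth) != n || nrow(object@altDepth) != n ||
      nrow(object@geno) != n)
    msg <- c(msg, "depth/geno matrices must have one row per SNP")
  if (!identical(dim(object@refDepth), dim(object@altDepth)) ||
      !identical(dim(object@refDepth), dim(object@geno)))
    msg <- c(msg, "refDepth, altDepth and geno must share dimensions")
  if (is.null(colnames(object@refDepth)))
    msg <- c(msg, "depth matrices must carry sample names")
  if (length(msg)) return(msg)
  if (n > 0L) {
    if (any(object@refDepth < 0) || any(object@altDepth < 0))
      msg <- c(msg, "allele depths must be >= 0")
    bad <- !grepl("^[ACGT]$", object@ref) | !grepl("^[ACGT]$", object@alt) |
      object@ref == object@alt
    if (any(bad))
      msg <- c(msg, "alleles must be single distinct bases (ACGT)")
    pos <- split(start(object@gr), as.character(seqnames(object@gr)))
    if (any(vapply(pos, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing per chromosome")
    if (length(object@flank5) != n || length(object@flank3) != n)
      msg <- c(msg, "flanks must have one sequence per SNP")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpTable
#'
#' Convenience constructor from parallel vectors. Depth matrices must carry
#' sample names; genotype calls default to a simple frequency rule (minor
#' read fraction below 0.1 is a homozygote) and flanks default to empty.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the SNPs.
#' @param refDepth,altDepth Integer matrices (SNP x sample) with identical
#'   dimnames.
#' @param geno Optional character matrix of genotype calls.
#' @param flank5,flank3 Optional character vectors or `DNAStringSet`s.
#' @return A [SnpTable-class].
#' @export
SnpTable <- function(chrom, pos, ref, alt, refDepth, altDepth, geno = NULL,
                     flank5 = NULL, flank3 = NULL) {
  n <- length(pos)
  refDepth <- as.matrix(refDepth); altDepth <- as.matrix(altDepth)
  if (is.null(geno)) {
    geno <- matrix(callFromCounts(as.vector(refDepth), as.vector(altDepth)),
                   nrow = n, dimnames = dimnames(refDepth))
  }
  toDSS <- function(x) {
    if (is.null(x)) DNAStringSet(rep("", n))
    else if (is(x, "DNAStringSet")) x
    else DNAStringSet(x)
  }
  obj <- new("SnpTable", gr = GRanges(chrom, IRanges(pos, width = 1L)),
             ref = ref, alt = alt, refDepth = refDepth, altDepth = altDepth,
             geno = geno, flank5 = toDSS(flank5), flank3 = toDSS(flank3))
  validObject(obj)
  obj
}

#' A translocation call from depth segmentation
#'
#' Pairs the distal present segment on the donor chromosome with the distal
#' absent segment on the recipient chromosome, named by the
#' "T<donor arm>-<recipient arm>.<recipient long arm>" convention. When no
#' qualifying distal segment exists on either chromosome the call is an
#' explicit no-call rather than an error.
#'
#' @slot donorSegment `GRanges` (length 1, or 0 for a no-call) with `state`,
#'   `size_mb`, `n_windows` metadata.
#' @slot recipientSegment Same, for the recipient chromosome.
#' @slot name Translocation name, e.g. "T2DS-2AS.2AL" ("" for a no-call).
#' @slot noCall `TRUE` when no qualifying segment pair was found.
#' @exportClass TranslocationCall
setClass("TranslocationCall",
  representation(donorSegment = "GRanges", recipientSegment = "GRanges",
                 name = "character", noCall = "logical")
)

setValidity("TranslocationCall", function(object) {
  if (object@noCall) return(TRUE)
  msg <- character()
  if (length(object@donorSegment) != 1L ||
      !identical(object@donorSegment$state, "present"))
    msg <- c(msg, "donorSegment must be a single present-state segment")
  if (length(object@recipientSegment) != 1L ||
      !identical(object@recipientSegment$state, "absent"))
    msg <- c(msg, "recipientSegment must be a single absent-state segment")
  if (length(msg)) msg else TRUE
})
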