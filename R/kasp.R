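## Six-criterion SNP filter cascade and KASP marker construction:
## (1) missing rate, (2) minor allele frequency, (3) local spacing,
## (4) polymorphism information content, (5) flanking GC content,
## (6) even genomic distribution; then allele-specific primer design and
## endpoint fluorescence cluster calling.

## Standard KASP reporter tails (LGC convention).
KASP_TAIL_FAM <- "GAAGGTGACCAAGTTCATGCT"
KASP_TAIL_HEX <- "GAAGGTCGGAGTCAACGGATT"

## Minor allele frequency from depths pooled across all samples.
pooledMAF <- function(snps) {
  altTot <- rowSums(snps@altDepth)
  refTot <- rowSums(snps@refDepth)
  tot <- altTot + refTot
  p <- ifelse(tot > 0, altTot / tot, NA_real_)
  pmin(p, 1 - p)
}

## Per-SNP genotype missing fraction over the samples.
missingRateOf <- function(snps) {
  if (ncol(snps@geno) == 0L) stop("no samples in the table")
  rowMeans(is.na(snps@geno))
}

#' Missing-rate filter
#'
#' Keeps a SNP iff its genotype missing rate does not exceed `maxMissing`
#' ("exceeding" is strict: exactly at the threshold is kept).
#'
#' @param snps A [SnpTable-class].
#' @param maxMissing Maximum tolerated missing fraction (default 0.20).
#' @return Logical keep vector.
#' @export
filterMissing <- function(snps, maxMissing = 0.20) {
  missingRateOf(snps) <= maxMissing
}

#' Minor-allele-frequency filter
#'
#' MAF is computed from read depths pooled across all samples; a SNP is kept
#' iff MAF >= `minMAF` (strictly below is removed). Sites with zero pooled
#' depth are excluded.
#'
#' @param snps A [SnpTable-class].
#' @param minMAF Minimum MAF (default 0.05).
#' @return Logical keep vector.
#' @export
filterMAF <- function(snps, minMAF = 0.05) {
  maf <- pooledMAF(snps)
  !is.na(maf) & maf >= minMAF
}

#' Local-spacing filter
#'
#' Keeps a SNP iff no other SNP of the candidate set lies within `radius` bp
#' up- or downstream (distance exactly `radius` excludes; `radius + 1` keeps).
#' The comparison set is the full pre-filter table: any nearby variant can
#' disturb primer annealing whether or not it survives the other filters.
#'
#' @param snps A [SnpTable-class] (the candidate set).
#' @param radius Exclusion radius in bp (default 50).
#' @return Logical keep vector.
#' @export
filterSpacing <- function(snps, radius = 50) {
  chrom <- as.character(seqnames(snps@gr))
  pos <- start(snps@gr)
  keep <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- pos[i]                       # strictly increasing by class validity
    dPrev <- c(Inf, diff(p))
    dNext <- c(diff(p), Inf)
    keep[i] <- dPrev > radius & dNext > radius
  }
  keep
}

#' Polymorphism information content (Botstein)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 over allele frequencies.
#' For a biallelic locus this is maximised at 0.375 when p = 0.5.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC value in \[0, 1\].
#' @examples
#' computePIC(c(0.5, 0.5))   # 0.375
#' @export
computePIC <- function(freqs) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("allele frequencies must be non-negative and sum to 1")
  p2 <- freqs^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2     # sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - 2 * cross
}

#' PIC filter
#'
#' Computes the biallelic PIC from pooled allele frequencies and keeps a SNP
#' iff PIC >= `minPIC` (strictly below is excluded). Zero-depth sites are
#' excluded.
#'
#' @param snps A [SnpTable-class].
#' @param minPIC Minimum PIC (default 0.2).
#' @return Logical keep vector.
#' @export
filterPIC <- function(snps, minPIC = 0.2) {
  maf <- pooledMAF(snps)
  pic <- vapply(maf, function(p) {
    if (is.na(p)) return(NA_real_)
    computePIC(c(p, 1 - p))
  }, numeric(1))
  !is.na(pic) & pic >= minPIC
}

## GC fraction of the gcFlank bases on each side of the SNP (SNP base
## excluded); NA when a flank is too short.
flankGCContent <- function(snps, gcFlank = 150) {
  f5 <- snps@flank5; f3 <- snps@flank3
  n <- nSnps(snps)
  out <- rep(NA_real_, n)
  long <- Biostrings::width(f5) >= gcFlank & Biostrings::width(f3) >= gcFlank
  if (any(long)) {
    i <- which(long)
    left <- Biostrings::subseq(f5[i], start = Biostrings::width(f5[i]) - gcFlank + 1)
    right <- Biostrings::subseq(f3[i], start = 1, width = gcFlank)
    gc <- letterFrequency(left, "GC") + letterFrequency(right, "GC")
    out[i] <- as.numeric(gc) / (2 * gcFlank)
  }
  out
}

#' Flanking-GC filter
#'
#' GC fraction is computed over the `gcFlank` bases immediately on each side
#' of the SNP (the SNP base itself excluded); kept iff within `gcRange`
#' inclusive. SNPs with flanks shorter than `gcFlank` are excluded.
#'
#' @param snps A [SnpTable-class].
#' @param gcFlank Flank length per side (default 150).
#' @param gcRange Inclusive range (default `c(0.40, 0.60)`).
#' @return Logical keep vector.
#' @export
filterGC <- function(snps, gcFlank = 150, gcRange = c(0.40, 0.60)) {
  gc <- flankGCContent(snps, gcFlank)
  !is.na(gc) & gc >= gcRange[1] & gc <= gcRange[2]
}

#' Even-distribution selection
#'
#' Splits `region` into `targetCount` equal bins and selects, per non-empty
#' bin, the passing SNP nearest the bin midpoint (ties go to the lower
#' coordinate). When no more than `targetCount` SNPs pass, all are returned.
#'
#' @param snps A [SnpTable-class] of SNPs that passed the preceding filters,
#'   all on one chromosome.
#' @param region Length-2 numeric, bp interval (0-based) covering the SNPs.
#' @param targetCount Number of markers wanted (default 34).
#' @return Integer indices (into `snps`) of the selected SNPs, sorted.
#' @export
selectEven <- function(snps, region, targetCount = 34) {
  if (targetCount <= 0) stop("targetCount must be > 0")
  n <- nSnps(snps)
  if (n <= targetCount) return(seq_len(n))
  pos <- start(snps@gr)
  binW <- (region[2] - region[1]) / targetCount
  bin <- pmin(pmax(floor((pos - region[1]) / binW), 0), targetCount - 1)
  sel <- integer(0)
  for (b in unique(sort(bin))) {
    mid <- region[1] + (b + 0.5) * binW
    i <- which(bin == b)
    d <- abs(pos[i] - mid)
    best <- i[d == min(d)]
    sel <- c(sel, best[which.min(pos[best])])
  }
  sort(sel)
}

#' Run the filter cascade with an audit trail
#'
#' Applies filters (1)-(5) as an order-independent conjunction (the spacing
#' filter always compares against the full candidate set), then the
#' even-distribution selection (6) over `region`. Returns per-SNP pass flags
#' and first-failure reason codes.
#'
#' @param snps A [SnpTable-class] candidate set (one chromosome for the
#'   even-distribution step).
#' @param config A [FilterConfig-class].
#' @param region Length-2 bp interval for even selection; defaults to the
#'   SNP extent.
#' @return A list: `selected` (a [SnpTable-class]), `audit` (data.frame with
#'   id, pos, the five pass flags, `reason` of the first failing filter or
#'   "", `selected` flag), `counts` (surviving count after each stage).
#' @export
filterCascade <- function(snps, config = FilterConfig(), region = NULL) {
  stopifnot(is(snps, "SnpTable"), is(config, "FilterConfig"))
  validObject(config)
  p1 <- filterMissing(snps, config@maxMissing)
  p2 <- filterMAF(snps, config@minMAF)
  p3 <- filterSpacing(snps, config@exclusionRadius)
  p4 <- filterPIC(snps, config@minPIC)
  p5 <- filterGC(snps, config@gcFlank, config@gcRange)
  pass <- p1 & p2 & p3 & p4 & p5
  reason <- rep("", nSnps(snps))
  codes <- c("missing_rate", "maf", "spacing", "pic", "gc")
  flags <- cbind(p1, p2, p3, p4, p5)
  firstFail <- apply(!flags, 1L, function(z) if (any(z)) which(z)[1] else 0L)
  reason[firstFail > 0] <- codes[firstFail[firstFail > 0]]

  if (is.null(region))
    region <- c(min(start(snps@gr)) - 1, max(start(snps@gr)))
  passing <- snps[which(pass)]
  selIdx <- which(pass)[selectEven(passing, region, config@targetCount)]
  audit <- data.frame(id = snpIds(snps), pos = start(snps@gr),
                      pass_missing = p1, pass_maf = p2, pass_spacing = p3,
                      pass_pic = p4, pass_gc = p5, reason = reason,
                      selected = seq_len(nSnps(snps)) %in% selIdx)
  list(selected = snps[selIdx], audit = audit,
       counts = c(input = nSnps(snps), missing_rate = sum(p1),
                  maf = sum(p1 & p2), spacing = sum(p1 & p2 & p3),
                  pic = sum(p1 & p2 & p3 & p4), gc = sum(pass),
                  even = length(selIdx)))
}

## ---------------------------------------------------------------------------
## Primer design
## ---------------------------------------------------------------------------

#' Approximate melting temperature of a primer
#'
#' Wallace rule (2(A+T) + 4(G+C)) below 14 nt, otherwise
#' 64.9 + 41 * (nGC - 16.4) / length. Adequate for the length/Tm constraints
#' of KASP design; not a thermodynamic nearest-neighbour model.
#'
#' @param seq A character string (ACGT).
#' @return Estimated Tm in degrees C.
#' @export
primerTm <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  nGC <- sum(b %in% c("G", "C"))
  n <- length(b)
  if (n < 14) 2 * (n - nGC) + 4 * nGC else 64.9 + 41 * (nGC - 16.4) / n
}

revComp <- function(seq)
  as.character(reverseComplement(DNAStringSet(seq))[[1]])

#' Design a KASP primer set for one SNP
#'
#' Builds two allele-specific forward primers whose 3'-terminal base is the
#' SNP allele. Primer length is chosen once on the shared upstream flank
#' context, extending 5' until the context's estimated Tm reaches `tmTarget`
#' or the primer is 30 nt long, so the two allele primers are colinear and
#' differ only at the 3' base; the standard FAM tail (ref allele) and HEX
#' tail (alt allele) are prepended. The common reverse primer
#' is the 18-25-mer on the opposite strand whose 5' end lies 50-150 bp
#' downstream of the SNP and whose Tm is nearest `tmTarget` (ties: shorter
#' amplicon, then shorter primer).
#'
#' @param snps A [SnpTable-class].
#' @param i Index of the SNP to design.
#' @param tmTarget Target melting temperature (default 57).
#' @param minLen Minimum allele-specific primer length (default 18).
#' @return A list: `id`, `alleles`, `primer_fam`, `primer_hex` (tailed),
#'   `primer_fam_core`, `primer_hex_core`, `common_reverse`,
#'   `amplicon_len`, `tm_fam`, `tm_hex`, `tm_common`.
#' @export
designKasp <- function(snps, i = 1L, tmTarget = 57, minLen = 18L) {
  stopifnot(is(snps, "SnpTable"), i >= 1L, i <= nSnps(snps))
  up <- as.character(snps@flank5[[i]])
  down <- as.character(snps@flank3[[i]])
  if (nchar(up) < 150 || nchar(down) < 150)
    stop("flanks must be >= 150 bp for primer design")

  ## primer length is fixed by the shared upstream context (the variant
  ## base excluded), so the two allele primers are colinear and differ only
  ## at the 3' terminus
  fwdLen <- 30L
  for (len in seq(minLen, 30L)) {
    ctx <- substr(up, nchar(up) - len + 2L, nchar(up))
    if (primerTm(ctx) >= tmTarget) { fwdLen <- len; break }
  }
  ctx <- substr(up, nchar(up) - fwdLen + 2L, nchar(up))
  coreRef <- paste0(ctx, snps@ref[i])
  coreAlt <- paste0(ctx, snps@alt[i])

  ## common reverse primer: top-strand window [d-L+1, d] downstream of the
  ## SNP, reverse-complemented; amplicon = distance SNP -> reverse 5' end =
  ## d. Tm depends only on length and GC count, so candidates are scored
  ## from a cumulative GC profile and only the winner is materialised.
  N <- min(150L, nchar(down))
  gcCum <- c(0L, cumsum(strsplit(substr(down, 1L, N), "")[[1]] %in%
                          c("G", "C")))
  best <- NULL
  for (d in 50:N) {
    for (L in 18:25) {
      if (d - L + 1L < 1L) next
      nGC <- gcCum[d + 1L] - gcCum[d - L + 1L]
      tm <- if (L < 14L) 2 * (L - nGC) + 4 * nGC
            else 64.9 + 41 * (nGC - 16.4) / L
      dTm <- abs(tm - tmTarget)
      if (is.null(best) || dTm < best$dTm - 1e-9)
        best <- list(d = d, L = L, dTm = dTm)
    }
  }
  if (is.null(best))
    stop("no reverse-primer window 50-150 bp downstream satisfies the length constraints")
  best$core <- revComp(substr(down, best$d - best$L + 1L, best$d))

  list(id = snpIds(snps)[i],
       alleles = c(ref = snps@ref[i], alt = snps@alt[i]),
       primer_fam = paste0(KASP_TAIL_FAM, coreRef),
       primer_hex = paste0(KASP_TAIL_HEX, coreAlt),
       primer_fam_core = coreRef, primer_hex_core = coreAlt,
       common_reverse = best$core, amplicon_len = best$d,
       tm_fam = primerTm(coreRef), tm_hex = primerTm(coreAlt),
       tm_common = primerTm(best$core))
}

#' Build the marker table for a set of filtered SNPs
#'
#' Runs [designKasp()] on every SNP and attaches the filter diagnostics
#' (missing rate, MAF, PIC, flanking GC, nearest-neighbour distance).
#'
#' @param snps A [SnpTable-class] of selected SNPs.
#' @param allSnps Optional [SnpTable-class] with the full candidate set, used
#'   for the nearest-neighbour distance diagnostic (defaults to `snps`).
#' @param config A [FilterConfig-class] (for the GC window).
#' @param tmTarget Target Tm.
#' @return A data.frame, one row per marker.
#' @export
buildKaspMarkers <- function(snps, allSnps = snps, config = FilterConfig(),
                             tmTarget = 57) {
  n <- nSnps(snps)
  if (n == 0L) return(data.frame())
  maf <- pooledMAF(snps)
  pic <- vapply(maf, function(p)
    if (is.na(p)) NA_real_ else computePIC(c(p, 1 - p)), numeric(1))
  gc <- flankGCContent(snps, config@gcFlank)
  miss <- missingRateOf(snps)
  allPos <- start(allSnps@gr)
  allChr <- as.character(seqnames(allSnps@gr))
  nn <- vapply(seq_len(n), function(i) {
    p <- start(snps@gr)[i]; ch <- as.character(seqnames(snps@gr))[i]
    d <- abs(allPos[allChr == ch] - p)
    d <- d[d > 0]
    if (length(d)) min(d) else Inf
  }, numeric(1))
  rows <- lapply(seq_len(n), function(i) {
    k <- designKasp(snps, i, tmTarget)
    data.frame(id = k$id,
               chrom = as.character(seqnames(snps@gr))[i],
               pos = start(snps@gr)[i],
               ref = k$alleles[["ref"]], alt = k$alleles[["alt"]],
               primer_fam = k$primer_fam, primer_hex = k$primer_hex,
               common_reverse = k$common_reverse,
               amplicon_len = k$amplicon_len,
               tm_fam = k$tm_fam, tm_hex = k$tm_hex,
               tm_common = k$tm_common,
               maf = maf[i], pic = pic[i], gc = gc[i],
               missing_rate = miss[i], nn_dist = nn[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Endpoint fluorescence genotype calling
## ---------------------------------------------------------------------------

#' Classify KASP endpoint fluorescence signals into genotype clusters
#'
#' Points within `noiseRadius` (after per-axis normalisation) of the
#' no-template-control centroid are no-calls. Remaining points are assigned
#' to the three canonical directions of a biallelic assay: along the FAM axis
#' (allele-1 homozygote), along the HEX axis (allele-2 homozygote), or the
#' diagonal (heterozygote), whichever is nearest in angle.
#'
#' @param points Numeric matrix (n x 2) of (FAM, HEX) intensities.
#' @param controls Numeric matrix (>= 1 x 2) of no-template-control
#'   intensities.
#' @param noiseRadius No-call radius around the control centroid on the
#'   normalised scale (default 0.15).
#' @return Character vector: "hom_allele1", "hom_allele2", "het" or
#'   "no_call". All-no-call input raises a warning.
#' @export
classifyKaspSignals <- function(points, controls, noiseRadius = 0.15) {
  points <- as.matrix(points); controls <- as.matrix(controls)
  stopifnot(ncol(points) == 2L, ncol(controls) == 2L, nrow(controls) >= 1L)
  ctr <- colMeans(controls)
  scale <- pmax(apply(points, 2L, max) - ctr, 1e-9)
  z <- sweep(sweep(points, 2L, ctr), 2L, scale, "/")
  r <- sqrt(rowSums(z^2))
  calls <- rep("no_call", nrow(points))
  live <- r >= noiseRadius
  if (any(live)) {
    ang <- atan2(z[live, 2L], z[live, 1L])
    targets <- c(hom_allele1 = 0, het = pi / 4, hom_allele2 = pi / 2)
    nearest <- apply(abs(outer(ang, targets, "-")), 1L,
                     function(d) names(targets)[which.min(d)])
    calls[live] <- nearest
  }
  if (!any(live)) warning("all points fall within the no-call radius")
  calls
}
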