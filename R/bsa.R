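## Bulked-segregant mapping: SNP-index statistics, sliding-window smoothing,
## a simulated null envelope, and candidate-region calling.

#' SNP index of a bulk
#'
#' Fraction of reads carrying the alt (donor) allele. Zero total depth gives
#' a missing value, never 0.
#'
#' @param refCount,altCount Non-negative read counts (vectorised).
#' @return Numeric vector in \[0, 1\], NA where depth is zero.
#' @examples
#' snpIndex(10, 10)  # 0.5
#' @export
snpIndex <- function(refCount, altCount) {
  if (any(refCount < 0, na.rm = TRUE) || any(altCount < 0, na.rm = TRUE))
    stop("allele counts must be >= 0")
  tot <- refCount + altCount
  ifelse(tot > 0, altCount / tot, NA_real_)
}

#' Exclude SNPs whose parental bulks are not fixed for opposite alleles
#'
#' For mapping, the alt allele must mean "donor allele". SNPs are kept only
#' when the donor parental bulk has SNP index >= `minIndex` and the recipient
#' parental bulk <= 1 - `minIndex` (or the mirror image, in which case the
#' orientation is flagged as flipped).
#'
#' @param snps A [SnpTable-class] with `parent_donor` and `parent_recipient`
#'   samples.
#' @param minIndex Near-fixation threshold (default 0.9).
#' @return A data.frame with columns `keep` (logical) and `flip` (logical,
#'   TRUE when ref is the donor allele).
#' @export
polarizeByParents <- function(snps, minIndex = 0.9) {
  stopifnot(is(snps, "SnpTable"))
  iDon <- snpIndex(snps@refDepth[, "parent_donor"],
                   snps@altDepth[, "parent_donor"])
  iRec <- snpIndex(snps@refDepth[, "parent_recipient"],
                   snps@altDepth[, "parent_recipient"])
  straight <- !is.na(iDon) & !is.na(iRec) &
    iDon >= minIndex & iRec <= 1 - minIndex
  flipped <- !is.na(iDon) & !is.na(iRec) &
    iRec >= minIndex & iDon <= 1 - minIndex
  data.frame(keep = straight | flipped, flip = flipped & !straight)
}

#' Per-SNP Delta SNP index between the phenotype bulks
#'
#' Delta = index(non-glaucous bulk) - index(glaucous bulk), after polarising
#' the alt allele to the donor parent. At a locus where a dominant donor
#' inhibitor allele drives the phenotype the expectation is 2/3 in the
#' carrier bulk and 0 in the non-carrier bulk, so Delta peaks at 2/3.
#'
#' @param snps A [SnpTable-class].
#' @param polarize Apply [polarizeByParents()] and drop non-informative SNPs
#'   (default TRUE).
#' @param minIndex Near-fixation threshold for polarisation.
#' @return A data.frame: `chrom`, `pos`, `index_high` (non-glaucous bulk),
#'   `index_low` (glaucous bulk), `delta`, `depth` (smaller of the two bulk
#'   depths). Delta is NA when either bulk has zero depth.
#' @export
deltaSnpIndex <- function(snps, polarize = TRUE, minIndex = 0.9) {
  stopifnot(is(snps, "SnpTable"))
  refD <- snps@refDepth; altD <- snps@altDepth
  flip <- rep(FALSE, nSnps(snps))
  keep <- rep(TRUE, nSnps(snps))
  if (polarize) {
    pol <- polarizeByParents(snps, minIndex)
    keep <- pol$keep
    flip <- pol$flip
  }
  iHigh <- snpIndex(refD[, "nonglaucous_bulk"], altD[, "nonglaucous_bulk"])
  iLow <- snpIndex(refD[, "glaucous_bulk"], altD[, "glaucous_bulk"])
  iHigh[flip] <- 1 - iHigh[flip]
  iLow[flip] <- 1 - iLow[flip]
  out <- data.frame(
    chrom = as.character(seqnames(snps@gr)),
    pos = start(snps@gr),
    index_high = iHigh, index_low = iLow,
    delta = iHigh - iLow,
    depth = pmin(refD[, "nonglaucous_bulk"] + altD[, "nonglaucous_bulk"],
                 refD[, "glaucous_bulk"] + altD[, "glaucous_bulk"]))
  out[keep, , drop = FALSE]
}

#' Sliding-window mean of the Delta SNP index
#'
#' Averages per-SNP Delta over windows of `windowBp` advanced by `stepBp`
#' within each chromosome, spanning the SNP extent. Windows containing no SNP
#' (or only NA Deltas) carry NA.
#'
#' @param deltas Data.frame from [deltaSnpIndex()].
#' @param windowBp,stepBp Window and step size in bp (`windowBp >= stepBp`).
#' @return A data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `n_snps`, `delta` (window mean), `depth` (mean SNP depth in window).
#' @export
windowDelta <- function(deltas, windowBp = 1e6, stepBp = 2.5e5) {
  stopifnot(windowBp >= stepBp, stepBp > 0)
  pieces <- lapply(split(deltas, deltas$chrom), function(d) {
    lo <- floor(min(d$pos) / stepBp) * stepBp
    hi <- max(d$pos)
    starts <- seq(lo, max(lo, hi - 1), by = stepBp)
    rows <- lapply(starts, function(s) {
      inWin <- d$pos > s & d$pos <= s + windowBp
      dd <- d$delta[inWin]
      data.frame(chrom = d$chrom[1], start = s, end = s + windowBp,
                 n_snps = sum(inWin),
                 delta = if (any(!is.na(dd))) mean(dd, na.rm = TRUE)
                         else NA_real_,
                 depth = if (any(inWin)) mean(d$depth[inWin]) else NA_real_)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulated null envelope for |Delta SNP index| at unlinked loci
#'
#' For each read depth in `depthGrid`, simulates `nSims` unlinked F2 loci:
#' each bulk's allele frequency is drawn as Binomial(2 * bulkSize, 1/2) /
#' (2 * bulkSize) (random segregation over the bulked gametes), then read
#' counts are Binomial(depth, frequency). The two-sided `quantileLevel`
#' quantile of |Delta| is returned per depth. As depth grows the envelope
#' approaches the sampling noise of the bulks alone.
#'
#' @param bulkSize Individuals per bulk.
#' @param depthGrid Integer vector of per-bulk read depths.
#' @param nSims Simulations per depth (>= 1000).
#' @param quantileLevel Envelope quantile (default 0.95).
#' @param seed Integer seed.
#' @return A data.frame: `depth`, `bound`.
#' @export
nullEnvelope <- function(bulkSize = 30, depthGrid = c(10, 20, 50, 100, 200),
                         nSims = 2000, quantileLevel = 0.95, seed = 1L) {
  if (nSims < 1000) stop("nSims must be >= 1000")
  set.seed(as.integer(seed))
  ng <- 2 * bulkSize
  bound <- vapply(depthGrid, function(dep) {
    f1 <- rbinom(nSims, ng, 0.5) / ng
    f2 <- rbinom(nSims, ng, 0.5) / ng
    i1 <- rbinom(nSims, dep, f1) / dep
    i2 <- rbinom(nSims, dep, f2) / dep
    as.numeric(quantile(abs(i1 - i2), quantileLevel))
  }, numeric(1))
  data.frame(depth = depthGrid, bound = bound)
}

#' Call candidate regions from a windowed Delta track
#'
#' Flags windows whose mean Delta exceeds the depth-matched null envelope
#' (linear interpolation over the envelope's depth grid), merges consecutive
#' flagged windows across gaps of at most one window, and reports each
#' resulting region with its peak.
#'
#' @param track Data.frame from [windowDelta()].
#' @param envelope Data.frame from [nullEnvelope()].
#' @return A `GRanges` of candidate regions with metadata `peak_pos`,
#'   `peak_delta` and `n_windows`; empty when no window exceeds the envelope.
#' @export
callCandidateRegion <- function(track, envelope) {
  pieces <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    thr <- approx(envelope$depth, envelope$bound, xout = tr$depth,
                  rule = 2)$y
    exceed <- !is.na(tr$delta) & tr$delta > thr
    if (!any(exceed)) return(NULL)
    idx <- which(exceed)
    grp <- cumsum(c(1, diff(idx) > 2))   # merge across gaps <= 1 window
    rows <- lapply(split(idx, grp), function(ii) {
      peak <- ii[which.max(tr$delta[ii])]
      data.frame(chrom = tr$chrom[1],
                 start = tr$start[min(ii)] + 1, end = tr$end[max(ii)],
                 peak_pos = (tr$start[peak] + tr$end[peak]) / 2,
                 peak_delta = tr$delta[peak], n_windows = length(ii))
    })
    out <- do.call(rbind, rows)
    ## sliding windows overlap in bp, so runs separated in window index can
    ## still collide in coordinates: coalesce such regions
    merged <- out[1, , drop = FALSE]
    for (k in seq_len(nrow(out))[-1]) {
      last <- nrow(merged)
      if (out$start[k] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], out$end[k])
        merged$n_windows[last] <- merged$n_windows[last] + out$n_windows[k]
        if (out$peak_delta[k] > merged$peak_delta[last]) {
          merged$peak_delta[last] <- out$peak_delta[k]
          merged$peak_pos[last] <- out$peak_pos[k]
        }
      } else {
        merged <- rbind(merged, out[k, , drop = FALSE])
      }
    }
    merged
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    empty <- GRanges()
    mcols(empty) <- DataFrame(peak_pos = numeric(0), peak_delta = numeric(0),
                              n_windows = integer(0))
    return(empty)
  }
  df <- do.call(rbind, pieces)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  GRanges(df$chrom, IRanges(start = df$start, end = df$end),
          peak_pos = df$peak_pos, peak_delta = df$peak_delta,
          n_windows = df$n_windows)
}
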