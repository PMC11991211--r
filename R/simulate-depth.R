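## Windowed-depth simulator for a merged recipient+donor reference.

## Present-state fraction of each window for one chromosome of the
## translocation architecture: background chromosomes fully present; the
## recipient chromosome absent over its distal [0, deletedLen); the donor
## chromosome present only over its distal [0, addedLen).
presentFraction <- function(chrom, starts, ends, spec) {
  if (chrom == spec@recipientChrom) {
    absent_bp <- pmax(0, pmin(ends, spec@deletedLen) - starts)
    1 - absent_bp / (ends - starts)
  } else if (chrom == spec@donorChrom) {
    present_bp <- pmax(0, pmin(ends, spec@addedLen) - starts)
    present_bp / (ends - starts)
  } else {
    rep(1, length(starts))
  }
}

#' Simulate a windowed depth profile of a translocation line
#'
#' Tiles every chromosome of `spec` with windows of `params@windowSize` bp and
#' draws each window's depth from a Poisson distribution whose mean reflects
#' the window's copy state: `meanDepth` where the segment is present,
#' `backgroundNoise` where it is absent, and the length-weighted mixture for
#' the window containing a breakpoint. A window longer than its chromosome is
#' truncated, not an error.
#'
#' @param spec A [GenomeSpec-class].
#' @param params A [DepthSimParams-class]; `params@seed` makes the draw
#'   reproducible.
#' @return A [DepthProfile-class] with a `true_state` metadata column
#'   ("present"/"absent"/"mixed") recording the simulated truth.
#' @examples
#' prof <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 7))
#' prof
#' @export
simulateDepthProfile <- function(spec, params) {
  stopifnot(is(spec, "GenomeSpec"), is(params, "DepthSimParams"))
  validObject(spec); validObject(params)
  set.seed(as.integer(params@seed))
  ws <- params@windowSize
  pieces <- lapply(names(spec@chromosomes), function(chrom) {
    len <- spec@chromosomes[[chrom]]
    starts <- seq(0, len - 1, by = ws)
    ends <- pmin(starts + ws, len)
    f <- presentFraction(chrom, starts, ends, spec)
    lambda <- f * params@meanDepth + (1 - f) * params@backgroundNoise
    depth <- rpois(length(starts), lambda)
    data.frame(chrom = chrom, start = starts + 1, end = ends,
               depth = as.numeric(depth),
               true_state = ifelse(f == 1, "present",
                                   ifelse(f == 0, "absent", "mixed")))
  })
  df <- do.call(rbind, pieces)
  gr <- GRanges(df$chrom, IRanges(start = df$start, end = df$end),
                depth = df$depth, true_state = df$true_state)
  new("DepthProfile", windows = gr, windowSize = ws, normalized = FALSE)
}

#' Build a DepthProfile from windows
#'
#' Low-level constructor for a profile from explicit window coordinates
#' (0-based half-open) and depths, validating sortedness and non-overlap.
#'
#' @param chrom,start,end,depth Parallel vectors; `start`/`end` 0-based
#'   half-open.
#' @param windowSize Nominal window size; inferred from the modal width when
#'   `NULL`.
#' @param normalized Whether depths are already on the normalized scale.
#' @return A [DepthProfile-class].
#' @export
DepthProfile <- function(chrom, start, end, depth, windowSize = NULL,
                         normalized = FALSE) {
  r <- rle(as.character(chrom))
  if (anyDuplicated(r$values))
    stop("windows are not grouped by chromosome")
  bad <- which(diff(start) <= 0 &
               chrom[-1] == chrom[-length(chrom)])
  if (length(bad))
    stop(sprintf("windows are not sorted (first offending record %d)",
                 bad[1] + 1L))
  gr <- GRanges(chrom, IRanges(start = start + 1, end = end),
                depth = as.numeric(depth))
  if (is.null(windowSize)) {
    w <- width(gr)
    windowSize <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  }
  obj <- new("DepthProfile", windows = gr, windowSize = windowSize,
             normalized = normalized)
  validObject(obj)
  obj
}
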