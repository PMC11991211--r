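## Breakpoint identification from windowed depth over a merged reference:
## normalize -> classify -> segment -> call the translocation.

#' Normalize window depths by the control-chromosome median
#'
#' Divides every window depth by the median window depth over the control
#' chromosomes (fully present background chromosomes, e.g. the A/B
#' subgenomes), so present-state windows have expectation 1.0.
#'
#' @param profile A [DepthProfile-class].
#' @param controlChroms Character vector of control chromosome names, all
#'   present in the profile.
#' @return A normalized [DepthProfile-class].
#' @export
normalizeDepth <- function(profile, controlChroms) {
  stopifnot(is(profile, "DepthProfile"))
  if (length(controlChroms) == 0L)
    stop("controlChroms must be nonempty")
  gr <- profile@windows
  present <- as.character(seqnames(gr)) %in% controlChroms
  missing <- setdiff(controlChroms, unique(as.character(seqnames(gr))))
  if (length(missing))
    stop(sprintf("control chromosome(s) not in profile: %s",
                 paste(missing, collapse = ", ")))
  m <- median(gr$depth[present])
  if (m == 0) stop("control median depth is 0; cannot normalize")
  gr$depth <- gr$depth / m
  new("DepthProfile", windows = gr, windowSize = profile@windowSize,
      normalized = TRUE)
}

#' Classify windows as present or absent
#'
#' A window is called absent when its normalized depth is strictly below
#' `absentThreshold`; a depth exactly at the threshold is present.
#'
#' @param profile A normalized [DepthProfile-class].
#' @param absentThreshold Normalized-depth threshold (default 0.25, midway on
#'   a log scale between a present window at 1.0 and residual-mismapping
#'   background).
#' @return The profile with a `state` metadata column ("present"/"absent").
#' @export
classifyWindows <- function(profile, absentThreshold = 0.25) {
  stopifnot(is(profile, "DepthProfile"))
  if (!profile@normalized)
    warning("classifying an unnormalized profile; threshold is on raw depth")
  gr <- profile@windows
  gr$state <- ifelse(gr$depth < absentThreshold, "absent", "present")
  new("DepthProfile", windows = gr, windowSize = profile@windowSize,
      normalized = profile@normalized)
}

## ---------------------------------------------------------------------------
## Minimal-change run smoothing
## ---------------------------------------------------------------------------

## Validity of a state string: every maximal run has length >= minRun, except
## that a sequence shorter than minRun must simply be constant.
runsValid <- function(states, minRun) {
  r <- rle(states)
  if (length(states) < minRun) return(length(r$lengths) == 1L)
  all(r$lengths >= minRun)
}

#' Smooth a window-state sequence by minimal-change run enforcement
#'
#' Returns the state sequence closest to the input (fewest changed windows)
#' in which every maximal run is at least `minRun` windows long, suppressing
#' isolated noise windows. Among equally close solutions the one agreeing
#' with the input at the earliest positions is chosen, which reproduces the
#' "absorb a short run into its neighbours, ties to the preceding segment"
#' behaviour. Computed by dynamic programming over (state, capped run length)
#' with a greedy input-preferring traceback, so the result is exactly the
#' minimal-change optimum. A sequence shorter than `minRun` is collapsed to
#' the majority state (tie: the first window's state).
#'
#' @param states Character vector of "present"/"absent" window states for one
#'   chromosome, in order.
#' @param minRun Minimum run length in windows (default 3).
#' @return Smoothed character vector, same length.
#' @export
smoothStates <- function(states, minRun = 3L) {
  n <- length(states)
  if (n == 0L) return(states)
  minRun <- as.integer(minRun)
  if (minRun <= 1L || runsValid(states, minRun)) return(states)
  lev <- c("present", "absent")
  x <- match(states, lev)
  if (anyNA(x)) stop("states must be 'present' or 'absent'")
  if (n < minRun) {
    nPres <- sum(x == 1L)
    keep <- if (nPres > n - nPres) 1L else if (nPres < n - nPres) 2L else x[1L]
    return(rep(lev[keep], n))
  }

  ## costToGo[i, s, k]: minimal future changes for windows i..n given window
  ## i-1 left us in state s with capped run length k (k = minRun means the
  ## current run is free to end). Transitions at window i: stay in s, or
  ## switch (only if k == minRun).
  INF <- n + 1
  costToGo <- array(INF, dim = c(n + 1L, 2L, minRun))
  costToGo[n + 1L, , minRun] <- 0
  for (i in n:1) {
    for (s in 1:2) {
      for (k in 1:minRun) {
        stay <- costToGo[i + 1L, s, min(k + 1L, minRun)] + (x[i] != s)
        best <- stay
        if (k == minRun) {
          sw <- costToGo[i + 1L, 3L - s, 1L] + (x[i] != (3L - s))
          if (sw < best) best <- sw
        }
        costToGo[i, s, k] <- best
      }
    }
  }

  out <- integer(n)
  ## first window: prefer the observed state if it attains the optimum
  opt <- min(costToGo[2L, 1L, 1L] + (x[1L] != 1L),
             costToGo[2L, 2L, 1L] + (x[1L] != 2L))
  s <- if (costToGo[2L, x[1L], 1L] == opt) x[1L] else 3L - x[1L]
  out[1L] <- s
  k <- 1L
  rem <- opt - (x[1L] != s)
  for (i in 2:n) {
    stayK <- min(k + 1L, minRun)
    canStay <- costToGo[i + 1L, s, stayK] + (x[i] != s) == rem
    canSwitch <- k == minRun &&
      costToGo[i + 1L, 3L - s, 1L] + (x[i] != (3L - s)) == rem
    takeSwitch <- if (canStay && canSwitch) x[i] == (3L - s) else canSwitch
    if (takeSwitch) {
      s <- 3L - s
      k <- 1L
    } else {
      k <- stayK
    }
    out[i] <- s
    rem <- rem - (x[i] != s)
  }
  lev[out]
}

#' Segment classified windows into maximal present/absent runs
#'
#' Applies [smoothStates()] per chromosome, then collapses the smoothed state
#' sequence into maximal runs. Breakpoints fall on shared window boundaries.
#'
#' @param profile A [DepthProfile-class] with a `state` column (from
#'   [classifyWindows()]).
#' @param minRun Minimum run length in windows passed to [smoothStates()].
#' @return A `GRanges` of segments with metadata `state`, `size_mb` (length
#'   in Mb rounded to 1 decimal) and `n_windows`; adjacent segments within a
#'   chromosome alternate state.
#' @export
segmentStates <- function(profile, minRun = 3L) {
  stopifnot(is(profile, "DepthProfile"))
  gr <- profile@windows
  if (is.null(gr$state)) stop("profile has no 'state' column; classify first")
  segs <- lapply(unique(as.character(seqnames(gr))), function(chr) {
    w <- gr[seqnames(gr) == chr]
    st <- smoothStates(as.character(w$state), minRun)
    r <- rle(st)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    data.frame(chrom = chr, start = start(w)[first], end = end(w)[last],
               state = r$values,
               size_mb = round((end(w)[last] - start(w)[first] + 1) / 1e6, 1),
               n_windows = r$lengths)
  })
  df <- do.call(rbind, segs)
  GRanges(df$chrom, IRanges(start = df$start, end = df$end),
          state = df$state, size_mb = df$size_mb, n_windows = df$n_windows)
}

## ---------------------------------------------------------------------------
## Translocation calling and gene counting
## ---------------------------------------------------------------------------

#' Detect a terminal-segment translocation from a depth profile
#'
#' Composes [normalizeDepth()], [classifyWindows()] and [segmentStates()] and
#' reports the distal (position-0) present segment on the donor chromosome
#' together with the distal absent segment on the recipient chromosome. If
#' either chromosome lacks a qualifying distal segment (wrong state at the
#' telomere, or a single segment spanning the whole chromosome) an explicit
#' no-call object is returned rather than an error.
#'
#' @param profile A [DepthProfile-class] (raw or already normalized).
#' @param donorChrom,recipientChrom Chromosome names in the profile.
#' @param controlChroms Chromosomes used for normalization; defaults to all
#'   chromosomes other than donor and recipient, or is ignored when the
#'   profile is already normalized.
#' @param absentThreshold,minRun Passed to [classifyWindows()] and
#'   [segmentStates()].
#' @return A [TranslocationCall-class].
#' @examples
#' prof <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 11))
#' detectTranslocation(prof, "2D", "2A")
#' @export
detectTranslocation <- function(profile, donorChrom, recipientChrom,
                                controlChroms = NULL, absentThreshold = 0.25,
                                minRun = 3L) {
  stopifnot(is(profile, "DepthProfile"))
  chroms <- unique(as.character(seqnames(profile@windows)))
  for (ch in c(donorChrom, recipientChrom))
    if (!(ch %in% chroms))
      stop(sprintf("chromosome '%s' is not in the profile", ch))
  if (!profile@normalized) {
    if (is.null(controlChroms))
      controlChroms <- setdiff(chroms, c(donorChrom, recipientChrom))
    if (length(controlChroms) == 0L)
      stop("no control chromosomes available for normalization")
    profile <- normalizeDepth(profile, controlChroms)
  }
  profile <- classifyWindows(profile, absentThreshold)
  segs <- segmentStates(profile, minRun)

  distal <- function(chrom, wantState) {
    s <- segs[as.character(seqnames(segs)) == chrom]
    s <- s[order(start(s))]
    if (length(s) < 2L) return(NULL)            # single segment: no breakpoint
    if (s$state[1L] != wantState) return(NULL)  # wrong state at the telomere
    s[1L]
  }
  don <- distal(donorChrom, "present")
  rec <- distal(recipientChrom, "absent")
  if (is.null(don) || is.null(rec)) {
    return(new("TranslocationCall", donorSegment = GRanges(),
               recipientSegment = GRanges(), name = "", noCall = TRUE))
  }
  name <- sprintf("T%sS-%sS.%sL", donorChrom, recipientChrom, recipientChrom)
  new("TranslocationCall", donorSegment = don, recipientSegment = rec,
      name = name, noCall = FALSE)
}

#' Count annotated genes overlapping a segment
#'
#' Counts genes whose interval overlaps the segment by at least 1 bp, split
#' by the annotation's confidence class. Genes without a confidence attribute
#' are counted in the total and reported through a warning.
#'
#' @param segment A `GRanges` of length 1 (e.g. from a
#'   [TranslocationCall-class]).
#' @param annotation A `GRanges` of gene features with a `confidence`
#'   metadata column ("HC"/"LC"; NA allowed).
#' @return A list with `total`, `high_conf`, `low_conf` counts.
#' @export
countGenes <- function(segment, annotation) {
  stopifnot(is(segment, "GRanges"), length(segment) == 1L,
            is(annotation, "GRanges"))
  if (length(annotation) == 0L)
    return(list(total = 0L, high_conf = 0L, low_conf = 0L))
  hit <- countOverlaps(annotation, segment, ignore.strand = TRUE) > 0L
  conf <- if (is.null(annotation$confidence))
    rep(NA_character_, length(annotation)) else annotation$confidence
  nMissing <- sum(hit & is.na(conf))
  if (nMissing > 0L)
    warning(sprintf("%d overlapping gene(s) lack a confidence attribute",
                    nMissing))
  list(total = sum(hit),
       high_conf = sum(hit & !is.na(conf) & conf == "HC"),
       low_conf = sum(hit & !is.na(conf) & conf == "LC"))
}
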