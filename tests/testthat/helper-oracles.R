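## Independent oracles and fixture builders used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## ---------------------------------------------------------------------------
## Brute-force run-smoothing oracle: enumerate every state string whose
## maximal runs are all >= minRun (constant strings when n < minRun), take
## the one with fewest changed windows, break ties by the lexicographically
## smallest mismatch vector (i.e. agree with the input at the earliest
## positions).
## ---------------------------------------------------------------------------

.compositionsMin <- function(n, m) {
  if (n == 0L) return(list(integer(0)))
  if (n < m) return(list())
  out <- list()
  for (first in seq(m, n)) {
    for (rest in .compositionsMin(n - first, m))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

.candCache <- new.env(parent = emptyenv())

candidateStateStrings <- function(n, minRun) {
  key <- paste(n, minRun, sep = "_")
  if (!is.null(.candCache[[key]])) return(.candCache[[key]])
  if (n < minRun) {
    m <- rbind(rep(1L, n), rep(2L, n))
  } else {
    comps <- .compositionsMin(n, minRun)
    rows <- list()
    for (cp in comps) {
      for (s0 in 1:2) {
        states <- rep(c(s0, 3L - s0), length.out = length(cp))
        rows[[length(rows) + 1L]] <- rep(states, cp)
      }
    }
    m <- do.call(rbind, rows)
  }
  .candCache[[key]] <- m
  m
}

oracleSmooth <- function(states, minRun) {
  lev <- c("present", "absent")
  x <- match(states, lev)
  cand <- candidateStateStrings(length(x), minRun)
  mism <- cand != matrix(x, nrow(cand), length(x), byrow = TRUE)
  changes <- rowSums(mism)
  best <- which(changes == min(changes))
  if (length(best) > 1L) {
    mv <- apply(mism[best, , drop = FALSE], 1L,
                function(z) paste(as.integer(z), collapse = ""))
    best <- best[order(mv)]
  }
  lev[cand[best[1L], ]]
}

## ---------------------------------------------------------------------------
## SnpTable fixtures
## ---------------------------------------------------------------------------

## Small table with explicit per-sample depths; geno defaults from counts.
fixtureSnpTable <- function(pos, refD, altD, chrom = "2D", ref = NULL,
                            alt = NULL, geno = NULL, flank5 = NULL,
                            flank3 = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  SnpTable(chrom = rep(chrom, n), pos = pos, ref = ref, alt = alt,
           refDepth = refD, altDepth = altD, geno = geno,
           flank5 = flank5, flank3 = flank3)
}

## Random base string of given length and GC probability.
randomSeq <- function(len, gc = 0.5) {
  paste(ifelse(runif(len) < gc,
               sample(c("G", "C"), len, replace = TRUE),
               sample(c("A", "T"), len, replace = TRUE)), collapse = "")
}

## Random candidate table exercising all five per-SNP filters: clustered
## positions, variable missingness, MAF and flank GC. 5 samples so missing
## fractions hit 0/0.2/0.4...
randomFilterTable <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample(seq_len(n * 150), n))
  nS <- 5L
  samples <- paste0("s", seq_len(nS))
  p <- runif(n, 0.01, 0.5)                       # pooled alt frequency
  tot <- matrix(rpois(n * nS, 30), n, dimnames = list(NULL, samples))
  altD <- matrix(rbinom(n * nS, as.vector(tot), rep(p, nS)), n,
                 dimnames = list(NULL, samples))
  refD <- tot - altD
  geno <- matrix(ifelse(runif(n * nS) < 0.12, NA_character_, "0/1"), n,
                 dimnames = list(NULL, samples))
  fl5 <- vapply(runif(n, 0.25, 0.75), function(g) randomSeq(160, g),
                character(1))
  fl3 <- vapply(runif(n, 0.25, 0.75), function(g) randomSeq(160, g),
                character(1))
  fixtureSnpTable(pos, refD, altD, geno = geno, flank5 = fl5, flank3 = fl3)
}

## Direct per-SNP conjunction of the five filter criteria, computed from raw
## slots without the package's filter functions' vectorised paths.
bruteForceFilter <- function(snps, config) {
  n <- nSnps(snps)
  geno <- genotypes(snps)
  refD <- alleleDepths(snps, "ref"); altD <- alleleDepths(snps, "alt")
  pos <- start(snpRanges(snps))
  f5 <- as.character(flankSeqs(snps, "5")); f3 <- as.character(flankSeqs(snps, "3"))
  gcLen <- config@gcFlank
  vapply(seq_len(n), function(i) {
    miss <- sum(is.na(geno[i, ])) / ncol(geno)
    if (miss > config@maxMissing) return(FALSE)
    tot <- sum(refD[i, ]) + sum(altD[i, ])
    if (tot == 0) return(FALSE)
    pAlt <- sum(altD[i, ]) / tot
    maf <- min(pAlt, 1 - pAlt)
    if (maf < config@minMAF) return(FALSE)
    if (any(abs(pos[-i] - pos[i]) <= config@exclusionRadius)) return(FALSE)
    pic <- 1 - (pAlt^2 + (1 - pAlt)^2) - 2 * pAlt^2 * (1 - pAlt)^2
    if (pic < config@minPIC) return(FALSE)
    if (nchar(f5[i]) < gcLen || nchar(f3[i]) < gcLen) return(FALSE)
    win <- paste0(substr(f5[i], nchar(f5[i]) - gcLen + 1, nchar(f5[i])),
                  substr(f3[i], 1, gcLen))
    gc <- sum(strsplit(win, "")[[1]] %in% c("G", "C")) / (2 * gcLen)
    gc >= config@gcRange[1] && gc <= config@gcRange[2]
  }, logical(1))
}
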