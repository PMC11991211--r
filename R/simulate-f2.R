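## F2 bulked-segregant simulator: a dominant wax-inhibitor locus on the donor
## chromosome, phenotype bulks, parental bulks, and read-level allele depths.

BULK_SAMPLES <- c("glaucous_bulk", "nonglaucous_bulk",
                  "parent_donor", "parent_recipient")

## Haldane map function: recombination fraction for a distance in Morgans.
haldaneR <- function(morgans) 0.5 * (1 - exp(-2 * morgans))

## Simulate gamete origin matrix (nGametes x nLoci, 1 = donor allele) along
## one chromosome with recombination fractions r between adjacent loci.
simulateGametes <- function(nGametes, r) {
  L <- length(r) + 1L
  origins <- matrix(0L, nrow = nGametes, ncol = L)
  origins[, 1L] <- rbinom(nGametes, 1L, 0.5)
  for (j in seq_len(L - 1L)) {
    sw <- rbinom(nGametes, 1L, r[j])
    origins[, j + 1L] <- (origins[, j] + sw) %% 2L
  }
  origins
}

## Random flanking sequences with a given expected GC fraction.
randomFlanks <- function(n, len, gc) {
  bases <- matrix(
    ifelse(runif(n * len) < gc,
           sample(c("G", "C"), n * len, replace = TRUE),
           sample(c("A", "T"), n * len, replace = TRUE)),
    nrow = n)
  DNAStringSet(apply(bases, 1L, paste0, collapse = ""))
}

## Genotype call from allele counts: homozygote if the minor fraction is
## below 0.1, else heterozygote; no reads -> missing.
callFromCounts <- function(refC, altC) {
  tot <- refC + altC
  frac <- ifelse(tot > 0, altC / tot, NA_real_)
  ifelse(tot == 0, NA_character_,
         ifelse(frac >= 0.9, "1/1", ifelse(frac <= 0.1, "0/0", "0/1")))
}

#' Simulate F2 phenotype bulks and their SNP allele depths
#'
#' Simulates `nF2` F2 individuals from a cross between a donor line carrying
#' a dominant wax-inhibitor allele at `causalPos` on the donor chromosome and
#' a recipient line without it. Each individual inherits two gametes whose
#' parental origin switches along the chromosome with Haldane recombination at
#' `cmPerMb`. A single inhibitor copy suppresses wax, so genotypes with at
#' least one donor allele at the causal locus are non-glaucous (3:1 expected
#' ratio). `bulkSize` individuals per phenotype form the two contrasting
#' bulks; parental bulks are fixed for opposite alleles. Per-SNP bulk read
#' depth is Poisson(`bulkDepth`) and the donor-allele (alt) read count is
#' binomial in the bulk allele frequency. Genotype calls are set to missing
#' independently at `missingRate`; flanking sequence of `flankLen` bp per side
#' is attached to every SNP.
#'
#' @param params A [PopSimParams-class]; `params@seed` fixes all draws.
#' @param spec A [GenomeSpec-class]; SNPs are placed on `spec@donorChrom`.
#' @return A list with elements `snps` (a [SnpTable-class] with samples
#'   glaucous_bulk, nonglaucous_bulk, parent_donor, parent_recipient),
#'   `phenotypes` (data.frame: id, phenotype, bulk), and `causalPos`.
#' @examples
#' sim <- simulateF2Bulks(PopSimParams(nF2 = 200, nSnps = 20, seed = 3))
#' table(sim$phenotypes$phenotype)
#' @export
simulateF2Bulks <- function(params, spec = GenomeSpec()) {
  stopifnot(is(params, "PopSimParams"), is(spec, "GenomeSpec"))
  validObject(params); validObject(spec)
  set.seed(as.integer(params@seed))
  chrom <- spec@donorChrom
  n <- as.integer(params@nSnps)

  pos <- sort(sample(seq(ceiling(params@snpRegion[1]),
                         floor(params@snpRegion[2])), n))
  loci <- sort(unique(c(pos, params@causalPos)))
  causalIdx <- match(params@causalPos, loci)
  snpIdx <- match(pos, loci)

  rFrac <- haldaneR(params@cmPerMb * diff(loci) / 1e6 / 100)
  gam <- simulateGametes(2L * as.integer(params@nF2), rFrac)
  odd <- seq(1L, nrow(gam), by = 2L)
  genoCopies <- gam[odd, , drop = FALSE] + gam[odd + 1L, , drop = FALSE]

  phenotype <- ifelse(genoCopies[, causalIdx] >= 1L,
                      "non-glaucous", "glaucous")
  bulkOf <- rep(NA_character_, params@nF2)
  pools <- list(glaucous_bulk = which(phenotype == "glaucous"),
                nonglaucous_bulk = which(phenotype == "non-glaucous"))
  for (nm in names(pools)) {
    cls <- sub("_bulk", "", nm)
    if (length(pools[[nm]]) < params@bulkSize)
      stop(sprintf("too few %s individuals for a bulk of %d (have %d)",
                   cls, params@bulkSize, length(pools[[nm]])))
    bulkOf[sample(pools[[nm]], params@bulkSize)] <- nm
  }

  ## bulk donor-allele frequency at every SNP
  bulkFreq <- function(idx)
    colSums(genoCopies[idx, snpIdx, drop = FALSE]) / (2 * length(idx))
  freqs <- cbind(glaucous_bulk = bulkFreq(which(bulkOf == "glaucous_bulk")),
                 nonglaucous_bulk = bulkFreq(which(bulkOf == "nonglaucous_bulk")),
                 parent_donor = rep(1, n),
                 parent_recipient = rep(0, n))

  tot <- matrix(rpois(n * 4L, params@bulkDepth), ncol = 4L,
                dimnames = list(NULL, BULK_SAMPLES))
  altD <- matrix(rbinom(n * 4L, as.vector(tot), as.vector(freqs)), ncol = 4L,
                 dimnames = list(NULL, BULK_SAMPLES))
  refD <- tot - altD
  geno <- matrix(callFromCounts(as.vector(refD), as.vector(altD)), ncol = 4L,
                 dimnames = list(NULL, BULK_SAMPLES))
  geno[matrix(runif(n * 4L) < params@missingRate, ncol = 4L)] <- NA_character_

  refBase <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  altBase <- vapply(refBase, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)

  snps <- new("SnpTable",
              gr = GRanges(chrom, IRanges(pos, width = 1L)),
              ref = refBase, alt = altBase,
              refDepth = refD, altDepth = altD, geno = geno,
              flank5 = randomFlanks(n, params@flankLen, params@flankGC),
              flank3 = randomFlanks(n, params@flankLen, params@flankGC))
  validObject(snps)

  list(snps = snps,
       phenotypes = data.frame(id = sprintf("F2_%04d", seq_len(params@nF2)),
                               phenotype = phenotype, bulk = bulkOf,
                               stringsAsFactors = FALSE),
       causalPos = params@causalPos)
}
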