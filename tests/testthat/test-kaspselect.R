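fourSamples <- function(refRow, altRow, genoRow) {
  list(refD = matrix(refRow, 1, dimnames = list(NULL, paste0("s", 1:4))),
       altD = matrix(altRow, 1, dimnames = list(NULL, paste0("s", 1:4))),
       geno = matrix(genoRow, 1, dimnames = list(NULL, paste0("s", 1:4))))
}

test_that("missing-rate filter excludes only rates strictly above the cap", {
  g0 <- fourSamples(rep(10L, 4), rep(10L, 4), rep("0/1", 4))
  t0 <- fixtureSnpTable(100, g0$refD, g0$altD, geno = g0$geno)
  expect_true(filterMissing(t0, 0.20))                  # 0 of 4 missing
  g1 <- fourSamples(rep(10L, 4), rep(10L, 4),
                    c(NA, "0/1", "0/1", "0/1"))
  t1 <- fixtureSnpTable(100, g1$refD, g1$altD, geno = g1$geno)
  expect_false(filterMissing(t1, 0.20))                 # 25% > 20%
  ## exactly 20% (1 of 5) is kept: only "exceeding" is excluded
  s5 <- paste0("s", 1:5)
  t2 <- fixtureSnpTable(
    100,
    matrix(10L, 1, 5, dimnames = list(NULL, s5)),
    matrix(10L, 1, 5, dimnames = list(NULL, s5)),
    geno = matrix(c(NA, rep("0/1", 4)), 1, dimnames = list(NULL, s5)))
  expect_true(filterMissing(t2, 0.20))
})

test_that("MAF filter pools depths and removes strictly below threshold", {
  mk <- function(ref, alt) {
    g <- fourSamples(as.integer(c(ref, 0, 0, 0)),
                     as.integer(c(alt, 0, 0, 0)), rep("0/1", 4))
    fixtureSnpTable(100, g$refD, g$altD, geno = g$geno)
  }
  expect_true(filterMAF(mk(50, 50), 0.05))      # MAF 0.5
  expect_false(filterMAF(mk(97, 3), 0.05))      # MAF 0.03
  expect_true(filterMAF(mk(95, 5), 0.05))       # exactly 0.05 kept
  expect_false(filterMAF(mk(0, 0), 0.05))       # zero pooled depth excluded
})

test_that("spacing filter uses strict radius against all candidates", {
  g <- function(n) list(
    refD = matrix(10L, n, 4, dimnames = list(NULL, paste0("s", 1:4))),
    altD = matrix(10L, n, 4, dimnames = list(NULL, paste0("s", 1:4))))
  one <- g(1)
  expect_true(filterSpacing(fixtureSnpTable(500, one$refD, one$altD), 50))
  three <- g(3)
  keep <- filterSpacing(fixtureSnpTable(c(100, 130, 300), three$refD,
                                        three$altD), 50)
  expect_identical(keep, c(FALSE, FALSE, TRUE))
  two <- g(2)
  keep2 <- filterSpacing(fixtureSnpTable(c(100, 151), two$refD, two$altD),
                         50)
  expect_identical(keep2, c(TRUE, TRUE))        # distance 51 > 50
})

test_that("PIC matches the closed forms and is monotone in MAF", {
  expect_equal(computePIC(1.0), 0)
  expect_equal(computePIC(c(0.5, 0.5)), 0.375)
  expect_equal(computePIC(c(0.05, 0.95)), 0.0904875)
  expect_error(computePIC(c(0.5, 0.6)), "sum to 1")
  ## biallelic PIC in [0, 0.375], strictly increasing on (0, 0.5]
  p <- seq(0.005, 0.5, by = 0.005)
  pic <- vapply(p, function(q) computePIC(c(q, 1 - q)), numeric(1))
  expect_true(all(pic >= 0 & pic <= 0.375))
  expect_true(all(diff(pic) > 0))
  ## PIC >= 0.2 implies MAF above the root of PIC(p) = 0.2: the pinned
  ## bound, recomputed here by root-finding
  bound <- uniroot(function(q) computePIC(c(q, 1 - q)) - 0.2,
                   c(1e-6, 0.5), tol = 1e-10)$root
  expect_equal(bound, 0.1294621, tolerance = 1e-6)
  expect_gt(bound, 0.05)   # filter (4) strictly stronger than filter (2)
})

test_that("GC filter windows exclude the SNP base and are strand-symmetric", {
  mkFlank <- function(f5, f3) {
    g <- fourSamples(rep(10L, 4), rep(10L, 4), rep("0/1", 4))
    fixtureSnpTable(100, g$refD, g$altD, geno = g$geno,
                    flank5 = f5, flank3 = f3)
  }
  allG <- strrep("G", 150)
  expect_false(filterGC(mkFlank(allG, allG)))          # GC 1.0
  half <- paste0(strrep("G", 75), strrep("A", 75))     # 75 GC per side
  expect_true(filterGC(mkFlank(half, half)))           # exactly 0.50
  ## boundary 40% and 60% inclusive
  gc40 <- paste0(strrep("G", 60), strrep("A", 90))
  gc60 <- paste0(strrep("G", 90), strrep("A", 60))
  expect_true(filterGC(mkFlank(gc40, gc40)))
  expect_true(filterGC(mkFlank(gc60, gc60)))
  ## reverse-complementing both flanks leaves the decision unchanged
  set.seed(2); fl <- randomSeq(150, 0.45)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(filterGC(mkFlank(fl, fl)),
                   filterGC(mkFlank(rc(fl), rc(fl))))
  ## short flank excluded
  expect_false(filterGC(mkFlank(strrep("G", 100), allG)))
})

test_that("even selection picks one midpoint-nearest SNP per bin", {
  mk <- function(pos) {
    n <- length(pos)
    fixtureSnpTable(pos,
      matrix(10L, n, 4, dimnames = list(NULL, paste0("s", 1:4))),
      matrix(10L, n, 4, dimnames = list(NULL, paste0("s", 1:4))))
  }
  ## fewer SNPs than target: all kept
  few <- mk(seq(1e5, 1e6, length.out = 10))
  expect_identical(selectEven(few, c(0, 13.8e6), 34), 1:10)
  ## uniform 200 SNPs on [0, 13.8 Mb]: exactly one per bin, brute-force
  pos <- round(seq(5e4, 13.75e6, length.out = 200))
  many <- mk(pos)
  sel <- selectEven(many, c(0, 13.8e6), 34)
  expect_identical(length(sel), 34L)
  binW <- 13.8e6 / 34
  bins <- floor(pos[sel] / binW)
  expect_identical(bins, unique(bins))             # one per bin
  ## brute-force midpoint check within each bin
  for (k in seq_along(sel)) {
    b <- bins[k]
    inBin <- pos[floor(pos / binW) == b]
    mid <- (b + 0.5) * binW
    expect_identical(pos[sel[k]], inBin[which.min(abs(inBin - mid))])
  }
  ## tie goes to the lower coordinate
  tie <- mk(c(190, 210))
  expect_identical(selectEven(tie, c(0, 400), 1), 1L)
  expect_error(selectEven(tie, c(0, 400), 0), "targetCount")
  ## deterministic subset with bounded deviation from bin midpoints
  sel2 <- selectEven(many, c(0, 13.8e6), 34)
  expect_identical(sel, sel2)
  mids <- (floor(pos[sel] / binW) + 0.5) * binW
  expect_true(all(abs(pos[sel] - mids) <= binW / 2 + 1))
})

test_that("filter cascade equals brute-force conjunction on random tables", {
  cfg <- FilterConfig()
  for (seed in c(11, 23)) {
    tab <- randomFilterTable(500, seed)
    casc <- filterCascade(tab, cfg)
    want <- bruteForceFilter(tab, cfg)
    got <- with(casc$audit,
                pass_missing & pass_maf & pass_spacing & pass_pic & pass_gc)
    expect_identical(unname(got), unname(want))
    ## selected set is a subset of survivors, at most targetCount
    expect_lte(sum(casc$audit$selected), cfg@targetCount)
    expect_true(all(got[casc$audit$selected]))
    ## audit reason codes only on failures
    expect_true(all((casc$audit$reason == "") == got))
  }
})

test_that("allele-specific primers end at the SNP and carry distinct tails", {
  set.seed(9)
  g <- fourSamples(rep(10L, 4), rep(10L, 4), rep("0/1", 4))
  balanced <- randomSeq(200, 0.5)
  tab <- fixtureSnpTable(1000, g$refD, g$altD, geno = g$geno,
                         ref = "A", alt = "G",
                         flank5 = balanced, flank3 = randomSeq(200, 0.5))
  k <- designKasp(tab, 1)
  ## 3'-terminal base equals the target allele
  expect_identical(substr(k$primer_fam_core, nchar(k$primer_fam_core),
                          nchar(k$primer_fam_core)), "A")
  expect_identical(substr(k$primer_hex_core, nchar(k$primer_hex_core),
                          nchar(k$primer_hex_core)), "G")
  ## tails are the distinct FAM/HEX standards
  expect_true(startsWith(k$primer_fam, "GAAGGTGACCAAGTTCATGCT"))
  expect_true(startsWith(k$primer_hex, "GAAGGTCGGAGTCAACGGATT"))
  ## same flank for both alleles: primers differ only at the 3' base
  expect_identical(nchar(k$primer_fam_core), nchar(k$primer_hex_core))
  nc <- nchar(k$primer_fam_core)
  expect_identical(substr(k$primer_fam_core, 1, nc - 1),
                   substr(k$primer_hex_core, 1, nc - 1))
  expect_error(designKasp(fixtureSnpTable(
    100, g$refD, g$altD, geno = g$geno,
    flank5 = "ACGT", flank3 = "ACGT"), 1), "150")
})

test_that("amplicon length stays in 50-150 bp over random fixtures", {
  set.seed(77)
  g <- fourSamples(rep(10L, 4), rep(10L, 4), rep("0/1", 4))
  for (i in 1:100) {
    tab <- fixtureSnpTable(1000, g$refD, g$altD, geno = g$geno,
                           flank5 = randomSeq(200, runif(1, 0.3, 0.7)),
                           flank3 = randomSeq(200, runif(1, 0.3, 0.7)))
    k <- designKasp(tab, 1)
    expect_gte(k$amplicon_len, 50)
    expect_lte(k$amplicon_len, 150)
    expect_gte(nchar(k$common_reverse), 18)
    expect_lte(nchar(k$common_reverse), 25)
  }
})

test_that("endpoint fluorescence clusters classify correctly", {
  ctr <- matrix(c(0.05, 0.05), 1)
  ## point at the control centroid is a no-call; pure-FAM is allele 1
  expect_warning(
    nc <- classifyKaspSignals(matrix(c(0.05, 0.05), 1), ctr),
    "no-call")
  expect_identical(nc, "no_call")
  expect_identical(
    classifyKaspSignals(matrix(c(1, 0.05), 1), ctr), "hom_allele1")
  expect_identical(
    classifyKaspSignals(matrix(c(0.05, 1), 1), ctr), "hom_allele2")
  ## synthetic clusters at canonical positions, sigma = 0.05: >= 99% correct
  set.seed(15)
  n <- 200
  pts <- rbind(cbind(rnorm(n, 1, 0.05), rnorm(n, 0.05, 0.05)),
               cbind(rnorm(n, 0.05, 0.05), rnorm(n, 1, 0.05)),
               cbind(rnorm(n, 0.6, 0.05), rnorm(n, 0.6, 0.05)))
  truth <- rep(c("hom_allele1", "hom_allele2", "het"), each = n)
  calls <- classifyKaspSignals(pts, ctr)
  expect_gte(mean(calls == truth), 0.99)
})
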