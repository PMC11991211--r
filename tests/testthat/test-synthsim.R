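test_that("depth simulator honours the copy-state architecture", {
  spec <- GenomeSpec(chromosomes = c(bg = 2e6, rec = 3e6, don = 2.5e6),
                     donorChrom = "don", recipientChrom = "rec",
                     addedLen = 1e6, deletedLen = 1.5e6)
  prof <- simulateDepthProfile(spec, DepthSimParams(
    meanDepth = 35, windowSize = 1e5, backgroundNoise = 0, seed = 42))
  gr <- profileWindows(prof)
  ## absent-state windows with zero background are exactly Poisson(0) = 0
  expect_true(all(gr$depth[gr$true_state == "absent"] == 0))
  ## donor present only on [0, addedLen); recipient absent on [0, deletedLen)
  don <- gr[seqnames(gr) == "don"]
  expect_identical(don$true_state,
                   rep(c("present", "absent"), c(10, 15)))
  rec <- gr[seqnames(gr) == "rec"]
  expect_identical(rec$true_state,
                   rep(c("absent", "present"), c(15, 15)))
  expect_true(all(gr$true_state[as.logical(seqnames(gr) == "bg")] ==
                  "present"))
})

test_that("breakpoint mid-window gets the length-weighted mixture mean", {
  spec <- GenomeSpec(chromosomes = c(bg = 1e6, rec = 1e6, don = 1e6),
                     donorChrom = "don", recipientChrom = "rec",
                     addedLen = 2.5e5, deletedLen = 2.5e5)
  ## window 2 of the donor covers [1e5, 2e5): fully present; window 3
  ## covers [2e5, 3e5): half present -> mixture state "mixed"
  prof <- simulateDepthProfile(spec, DepthSimParams(windowSize = 1e5,
                                                    seed = 5))
  don <- profileWindows(prof)[seqnames(profileWindows(prof)) == "don"]
  expect_identical(don$true_state[3], "mixed")
  ## mixture mean check by moment: many draws of that window
  lam <- 0.5 * 35 + 0.5 * 0.5
  draws <- vapply(1:300, function(s) {
    p <- simulateDepthProfile(spec, DepthSimParams(windowSize = 1e5,
                                                   seed = s))
    w <- profileWindows(p)
    w$depth[as.logical(seqnames(w) == "don")][3]
  }, numeric(1))
  expect_lt(abs(mean(draws) - lam), 4 * sqrt(lam / 300))
})

test_that("windows truncate at chromosome ends and reject zero lengths", {
  spec <- GenomeSpec(chromosomes = c(bg = 1e6, rec = 1e6, don = 1e6),
                     donorChrom = "don", recipientChrom = "rec",
                     addedLen = 5e5, deletedLen = 5e5)
  prof <- simulateDepthProfile(spec, DepthSimParams(windowSize = 3e6,
                                                    seed = 1))
  gr <- profileWindows(prof)
  expect_identical(length(gr), 3L)          # one truncated window per chrom
  expect_true(all(width(gr) == 1e6))
  expect_error(GenomeSpec(chromosomes = c(bg = 0, rec = 1e6, don = 1e6),
                          donorChrom = "don", recipientChrom = "rec",
                          addedLen = 5e5, deletedLen = 5e5),
               "length")
})

test_that("depth draws are reproducible under the seed and conserve mass", {
  p1 <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 9))
  p2 <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 9))
  p3 <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 10))
  expect_identical(profileWindows(p1)$depth, profileWindows(p2)$depth)
  expect_false(identical(profileWindows(p1)$depth,
                         profileWindows(p3)$depth))
  ## depth conservation: total present-state mass within 3 sigma of Poisson
  gr <- profileWindows(p1)
  pres <- gr$true_state == "present"
  nPres <- sum(pres)
  expect_lt(abs(sum(gr$depth[pres]) - 35 * nPres),
            3 * sqrt(35 * nPres))
})

test_that("F2 simulator segregates 3:1 and fixes parents oppositely", {
  sim <- simulateF2Bulks(PopSimParams(nF2 = 2000, seed = 21))
  tab <- table(sim$phenotypes$phenotype)
  chi <- suppressWarnings(chisq.test(c(tab[["non-glaucous"]],
                                       tab[["glaucous"]]), p = c(3, 1) / 4))
  expect_gt(chi$p.value, 0.01)
  ad <- alleleDepths(sim$snps, "alt")
  rd <- alleleDepths(sim$snps, "ref")
  expect_true(all(rd[, "parent_donor"] == 0))      # donor fixed for alt
  expect_true(all(ad[, "parent_recipient"] == 0))  # recipient fixed for ref
})

test_that("causal-locus bulk allele frequencies follow dominance", {
  ## no recombination: every SNP co-segregates with the causal locus, so the
  ## glaucous bulk is fixed for the recipient allele and the non-glaucous
  ## bulk has donor-allele frequency near the enumerated 2/3 (1:2 ratio of
  ## DD:Dd classes among carriers)
  sim <- simulateF2Bulks(PopSimParams(nF2 = 2000, cmPerMb = 0,
                                      bulkDepth = 200, seed = 8))
  d <- deltaSnpIndex(sim$snps, polarize = FALSE)
  expect_true(all(d$index_low == 0))
  expect_lt(abs(mean(d$index_high) - 2 / 3), 0.05)
  expect_lt(abs(mean(d$delta) - 2 / 3), 0.05)
})

test_that("a phenotype class smaller than the bulk errors with its name", {
  expect_error(
    simulateF2Bulks(PopSimParams(nF2 = 80, bulkSize = 40, seed = 2)),
    "glaucous")
})

test_that("F2 simulation is byte-identical under the seed", {
  a <- simulateF2Bulks(PopSimParams(nF2 = 150, nSnps = 25, seed = 5))
  b <- simulateF2Bulks(PopSimParams(nF2 = 150, nSnps = 25, seed = 5))
  expect_identical(alleleDepths(a$snps, "alt"), alleleDepths(b$snps, "alt"))
  expect_identical(as.character(flankSeqs(a$snps, "5")),
                   as.character(flankSeqs(b$snps, "5")))
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("annotation simulator places exact counts with the right split", {
  reg <- data.frame(chrom = "2A", start = 0, end = 16.1e6,
                    n_genes = 894L, n_high = 327L, n_low = 567L)
  ann <- simulateAnnotation(reg, seed = 4)
  expect_identical(length(ann), 894L)
  expect_identical(sum(ann$confidence == "HC"), 327L)
  expect_identical(sum(ann$confidence == "LC"), 567L)
  ## genes inside the interval and non-overlapping
  expect_true(all(start(ann) >= 1 & end(ann) <= 16.1e6))
  expect_true(all(start(ann)[-1] > end(ann)[-length(ann)]))
})

test_that("annotation simulator rejects bad specs", {
  expect_error(simulateAnnotation(
    data.frame(chrom = "c", start = 0, end = 1e6,
               n_genes = 613L, n_high = 350L, n_low = 350L)),
    "sum")
  expect_error(simulateAnnotation(
    data.frame(chrom = "c", start = 0, end = 1e4,
               n_genes = 100L, n_high = 50L, n_low = 50L,
               mean_gene_len = 3000)),
    "too small")
  empty <- simulateAnnotation(
    data.frame(chrom = "c", start = 0, end = 1e6,
               n_genes = 0L, n_high = 0L, n_low = 0L))
  expect_identical(length(empty), 0L)
})
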