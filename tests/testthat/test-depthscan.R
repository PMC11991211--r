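smallProfile <- function(depths, chrom = "c", ws = 100) {
  n <- length(depths)
  DepthProfile(chrom = rep(chrom, n), start = (0:(n - 1)) * ws,
               end = (1:n) * ws, depth = depths, windowSize = ws)
}

test_that("normalization scales by the control median", {
  prof <- DepthProfile(chrom = rep(c("ctl", "t"), each = 3),
                       start = rep(c(0, 100, 200), 2),
                       end = rep(c(100, 200, 300), 2),
                       depth = c(35, 35, 35, 0, 35, 70), windowSize = 100)
  norm <- normalizeDepth(prof, "ctl")
  expect_true(isNormalized(norm))
  d <- profileWindows(norm)$depth
  expect_equal(d, c(1, 1, 1, 0, 1, 2))
  expect_error(normalizeDepth(prof, character(0)), "nonempty")
  expect_error(normalizeDepth(prof, "nope"), "not in profile")
  zero <- smallProfile(c(0, 0, 0), chrom = "ctl")
  expect_error(normalizeDepth(zero, "ctl"), "median")
})

test_that("normalized Poisson control mean converges to 1", {
  spec <- GenomeSpec(chromosomes = c(bg = 6e8, rec = 1e6, don = 1e6),
                     donorChrom = "don", recipientChrom = "rec",
                     addedLen = 5e5, deletedLen = 5e5)
  prof <- simulateDepthProfile(spec, DepthSimParams(seed = 3))
  norm <- normalizeDepth(prof, "bg")
  gr <- profileWindows(norm)
  ctl <- gr$depth[as.logical(seqnames(gr) == "bg")]
  expect_gt(length(ctl), 5000)
  expect_lt(abs(mean(ctl) - 1), 0.02)
})

test_that("window classification uses a strict absent threshold", {
  prof <- smallProfile(c(0, 1.0, 0.25, 0.2499))
  prof@normalized <- TRUE
  cls <- classifyWindows(prof, absentThreshold = 0.25)
  expect_identical(profileWindows(cls)$state,
                   c("absent", "present", "present", "absent"))
  ## monotonicity: raising the threshold never turns absent into present
  for (thr in c(0.1, 0.25, 0.5, 0.9)) {
    lo <- profileWindows(classifyWindows(prof, thr))$state
    hi <- profileWindows(classifyWindows(prof, thr + 0.05))$state
    expect_true(all(!(lo == "absent" & hi == "present")))
  }
})

test_that("segmentation finds maximal runs with boundary breakpoints", {
  prof <- smallProfile(c(1, 1, 1, 1, 0, 0, 0, 0))
  prof@normalized <- TRUE
  segs <- segmentStates(classifyWindows(prof), minRun = 1)
  expect_identical(length(segs), 2L)
  expect_identical(segs$state, c("present", "absent"))
  expect_identical(end(segs)[1], 400L)     # breakpoint at window-4 boundary
  expect_identical(start(segs)[2] - 1L, 400L)
  ## all-present chromosome: one segment
  one <- smallProfile(rep(1, 6)); one@normalized <- TRUE
  expect_identical(length(segmentStates(classifyWindows(one), 3)), 1L)
})

test_that("short-run smoothing matches the hand-worked example", {
  st <- c("present", "present", "absent", "present", "present",
          "absent", "absent", "absent")
  expect_identical(smoothStates(st, 3),
                   rep(c("present", "absent"), c(5, 3)))
  expect_identical(smoothStates(st, 3), oracleSmooth(st, 3))
})

test_that("smoothing equals the exhaustive minimal-change oracle", {
  set.seed(404)
  for (rep in 1:300) {
    n <- sample(1:16, 1)
    minRun <- sample(2:4, 1)
    st <- sample(c("present", "absent"), n, replace = TRUE)
    got <- smoothStates(st, minRun)
    want <- oracleSmooth(st, minRun)
    expect_identical(got, want)
  }
})

test_that("translocation detection reports exact sizes on clean input", {
  ## noise-free: donor present on windows [0,138), recipient absent [0,161)
  mk <- function(chrom, n, presentRuns) {
    depth <- rep(0, n); depth[presentRuns] <- 35
    data.frame(chrom = chrom, start = (0:(n - 1)) * 1e5, end = (1:n) * 1e5,
               depth = depth)
  }
  df <- rbind(mk("1A", 500, 1:500), mk("2A", 1000, 162:1000),
              mk("2D", 1000, 1:138))
  prof <- DepthProfile(df$chrom, df$start, df$end, df$depth,
                       windowSize = 1e5)
  call <- detectTranslocation(prof, "2D", "2A", controlChroms = "1A")
  expect_false(isNoCall(call))
  expect_identical(call@name, "T2DS-2AS.2AL")
  expect_equal(donorSegment(call)$size_mb, 13.8)
  expect_equal(recipientSegment(call)$size_mb, 16.1)
  ## deleted segment is windows 1..161 (absent run ends at 16.1 Mb)
  expect_identical(end(recipientSegment(call)), 16100000L)
})

test_that("inverted architecture yields an explicit no-call", {
  df <- rbind(
    data.frame(chrom = "1A", start = (0:99) * 1e5, end = (1:100) * 1e5,
               depth = 35),
    data.frame(chrom = "2A", start = (0:99) * 1e5, end = (1:100) * 1e5,
               depth = 35),                       # recipient fully present
    data.frame(chrom = "2D", start = (0:99) * 1e5, end = (1:100) * 1e5,
               depth = 0))                        # donor fully absent
  prof <- DepthProfile(df$chrom, df$start, df$end, df$depth,
                       windowSize = 1e5)
  call <- detectTranslocation(prof, "2D", "2A", controlChroms = "1A")
  expect_true(isNoCall(call))
  expect_error(detectTranslocation(prof, "9Z", "2A", "1A"), "9Z")
})

test_that("identical calls produce identical name strings", {
  prof1 <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 31))
  prof2 <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 31))
  c1 <- detectTranslocation(prof1, "2D", "2A")
  c2 <- detectTranslocation(prof2, "2D", "2A")
  expect_identical(c1@name, c2@name)
  expect_identical(start(donorSegment(c1)), start(donorSegment(c2)))
})

test_that("gene counting splits by confidence and uses 1 bp overlap", {
  seg <- GRanges("2A", IRanges(1, 16100000), state = "absent",
                 size_mb = 16.1, n_windows = 161L)
  empty <- GRanges()
  expect_identical(countGenes(seg, empty),
                   list(total = 0L, high_conf = 0L, low_conf = 0L))
  ann <- simulateAnnotation(
    data.frame(chrom = "2A", start = 0, end = 16.1e6,
               n_genes = 894L, n_high = 327L, n_low = 567L), seed = 12)
  got <- countGenes(seg, ann)
  expect_identical(got$total, 894L)
  expect_identical(got$high_conf, 327L)
  expect_identical(got$low_conf, 567L)
  ## a gene straddling the segment boundary still counts, and a missing
  ## confidence attribute is flagged but counted in the total
  straddle <- GRanges("2A", IRanges(16099000, 16110000), ID = "g1",
                      type = "gene", confidence = NA_character_)
  expect_warning(res <- countGenes(seg, straddle), "confidence")
  expect_identical(res$total, 1L)
  expect_identical(res$high_conf, 0L)
})
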