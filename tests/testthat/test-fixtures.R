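test_that("bundled synthetic regions load with verified checksums", {
  expect_setequal(overlapFixtureNames(),
                  c("casq2_wt", "casq2_gau_gac", "casq2_ag", "casq2_scramble",
                    "casq2_de", "casq2_de_plus", "c22orf32", "ccdc36",
                    "wdr45", "casq1", "nt5c2", "tmem97"))
  wt <- loadOverlapFixture("casq2_wt")
  expect_identical(nchar(wt), 81L)
  for (nm in overlapFixtureNames()) {
    s <- loadOverlapFixture(nm)
    expect_identical(nchar(s) %% 3L, 0L)
    # region ends with the ORF-1 stop and is open upstream
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in%
                  c("UAA", "UAG", "UGA"))
  }
  # the CASQ2 mutant series shares the wild-type length and composition rules
  expect_identical(nchar(loadOverlapFixture("casq2_ag")), 81L)
  expect_identical(sort(strsplit(wt, "")[[1]]),
                   sort(strsplit(loadOverlapFixture("casq2_scramble"),
                                 "")[[1]]))
  expect_error(loadOverlapFixture("nope"), "unknown fixture")
})

test_that("embedding a region yields exactly one scannable pair", {
  for (nm in c("casq2_wt", "nt5c2", "tmem97", "wdr45")) {
    region <- loadOverlapFixture(nm)
    ts <- embedOverlap(region, id = nm)
    pairs <- scanTranscripts(ts, scanConfig())
    expect_identical(nrow(pairs), 1L)
    # the codon-aligned region spans from the codon providing the 5'-most
    # AUG; stored displays may carry further upstream context (nt5c2, tmem97)
    expect_identical(overlapRegionLen(pairs),
                     pairs$overlap_len_max + pairs$frame_offset)
    expect_lte(overlapRegionLen(pairs), nchar(region))
    expect_gte(pairs$orf1_end - pairs$orf1_start, 150L)
    expect_gte(pairs$orf2_end - pairs$orf2_start, 150L)
  }
  expect_identical(
    overlapRegionLen(scanTranscripts(
      embedOverlap(loadOverlapFixture("casq2_wt"), id = "c"), scanConfig())),
    81L)
  expect_error(embedOverlap("AUGCC", id = "x"), "whole ORF-1 codons")
  expect_error(embedOverlap("GCCGCC", id = "x"), "must end with")
})

test_that("the reporter-context fixture places the next in-frame stop 36 nt downstream", {
  ts <- reporterContextFixture()
  orfs <- findOrfs(as.character(ts[[1]]), minLen = 150)
  orf1End <- orfs$end[which.min(orfs$start)]
  mc <- designStopMutant(as.character(ts[[1]]), orf1End)
  expect_identical(nextStopDistance(mc), 36L)
  # the context still carries the CASQ2-like candidate pair
  pairs <- scanTranscripts(ts, scanConfig())
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$overlap_len, 8L)
})

test_that("background transcripts are seeded, composition-faithful draws", {
  a <- generateBackgroundTranscript(42, 500)
  b <- generateBackgroundTranscript(42, 500)
  expect_identical(as.character(a), as.character(b))
  expect_identical(S4Vectors::mcols(a)$source, "synthetic")
  allA <- generateBackgroundTranscript(1, 100, composition = c(1, 0, 0, 0))
  expect_identical(as.character(allA[[1]]), strrep("A", 100))
  expect_error(generateBackgroundTranscript(1, 0), "positive")
  expect_error(generateBackgroundTranscript(1, 10, composition = c(1, 1, 0, 0)),
               "summing to 1")
})

test_that("infeasible plant specifications fail before any randomness", {
  expect_error(plantSpec(1, overlapLen = 6L), "divisible by 3")
  expect_error(plantSpec(1, overlapLen = 5L), "infeasible")
  expect_error(plantSpec(1, overlapLen = 121L), "\\[4, 120\\]")
  expect_error(plantSpec(1, overlapLen = 7L, aspRepeat = TRUE), "\\+1 frame")
  expect_error(plantSpec(1, overlapLen = 110L, nOverlapAugs = 10L,
                         aspRepeat = TRUE), "window")
  expect_error(plantSpec(1, orf1Len = 120L), ">= 150")
  expect_error(plantCandidate(plantSpec(1, totalLen = 400L)), "totalLen")
})

test_that("planted candidates are recovered exactly by the scanner", {
  cfg <- scanConfig()
  for (seed in 1:6) {
    sp <- plantSpec(seed, totalLen = 900L, orf1Len = 240L, orf2Len = 210L,
                    overlapLen = c(8L, 11L, 4L, 7L, 14L, 119L)[seed],
                    nOverlapAugs = c(1L, 3L, 2L, 1L, 5L, 1L)[seed],
                    aspRepeat = seed %in% c(1, 2, 5))
    res <- plantCandidate(sp)
    pairs <- scanTranscripts(res$transcript, cfg)
    expect_identical(nrow(pairs), 1L)
    truth <- res$truth
    for (col in c("orf1_start", "orf1_end", "orf2_start", "orf2_end",
                  "frame_offset", "overlap_len", "overlap_len_max"))
      expect_identical(pairs[[col]], truth[[col]])
    fv <- extractFeatures(pairs, res$transcript, cfg)
    expect_identical(fv$n_aug_window, truth$n_aug_window)
    expect_identical(fv$n_trailing_ac, truth$n_trailing_ac)
    # determinism: the same spec replants the same transcript
    expect_identical(as.character(plantCandidate(sp)$transcript),
                     as.character(res$transcript))
  }
})

test_that("a CASQ2-like plant (81-nt region, 15 AUGs) reproduces the published geometry", {
  sp <- plantSpec(9, totalLen = 1200L, orf1Len = 300L, orf2Len = 300L,
                  overlapLen = 8L, nOverlapAugs = 15L, aspRepeat = TRUE)
  res <- plantCandidate(sp)
  pairs <- scanTranscripts(res$transcript, scanConfig())
  expect_identical(pairs$overlap_len_max, 8L + 3L * 14L)   # contiguous run
  fv <- extractFeatures(pairs, res$transcript, scanConfig())
  expect_identical(fv$n_aug_window, 15L)
  # the planted GAU repeat writes an aspartate run into ORF-1
  rep <- motifReport(pairs, res$transcript)
  expect_gte(rep$max_asp_run, 15L)
  expect_true(rep$asp_c_terminal)
})
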