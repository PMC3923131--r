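test_that("background models derive the per-codon probabilities", {
  u <- backgroundModel(mode = "uniform")
  expect_equal(unname(u@freqs), rep(0.25, 4))
  expect_equal(u@pAug, 1 / 64)
  expect_equal(u@pAc, 1 / 2)
  expect_equal(u@pStop, 3 / 64)

  one <- backgroundModel(c(t = "AUGC"), mode = "transcript")
  expect_equal(unname(one@freqs), rep(0.25, 4))
  # T pools with U, corpus pools transcripts
  corp <- backgroundModel(c(a = "AT", b = "GC"), mode = "corpus")
  expect_equal(unname(corp@freqs), rep(0.25, 4))
  expect_error(backgroundModel(character(), mode = "corpus"), "at least one")
  expect_error(backgroundModel(c(a = "A", b = "C"), mode = "transcript"),
               "exactly one")
})

test_that("degenerate composition: pAug = 0 forces the boundary behaviour", {
  deg <- backgroundModel(c(t = "AAAA"), mode = "transcript")
  expect_equal(deg@pAug, 0)
  fv <- S4Vectors::DataFrame(transcript_id = "t", n_aug_window = 0L,
                             n_trailing_ac = 0L, n_window_codons = 40L,
                             orf2_len_nt = 150L, overlap_len = 4L,
                             orf1_start = 0L)
  sc <- scoreCandidates(methods::new("OverlapPairSet", fv), deg, scanConfig())
  expect_equal(sc$p_starts, 1)
  fv$n_aug_window <- 1L
  expect_error(scoreCandidates(methods::new("OverlapPairSet", fv), deg,
                               scanConfig()),
               "pAug = 0")
})

test_that("binomial upper tails match the reference to 1e-12 relative", {
  set.seed(5)
  for (i in 1:400) {
    n <- sample(1:64, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 1e-6, 0.999)
    mine <- binomUpperTail(k, n, p)
    ref <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
    expect_lt(abs(mine - ref), 1e-12 * max(ref, .Machine$double.xmin))
  }
  expect_equal(binomUpperTail(0, 10, 0.1), 1)
  expect_equal(binomUpperTail(11, 10, 0.1), 0)
})

test_that("score factors take their closed forms at the boundaries", {
  cfg <- scanConfig()
  bg <- backgroundModel(mode = "uniform")
  fv <- S4Vectors::DataFrame(transcript_id = "t", orf1_start = 0L,
                             n_aug_window = 0L, n_trailing_ac = 0L,
                             n_window_codons = 40L, orf2_len_nt = 150L,
                             overlap_len = 4L)
  sc <- scoreCandidates(methods::new("OverlapPairSet", fv), bg, cfg)
  expect_equal(sc$p_starts, 1)              # no starts observed
  expect_equal(sc$p_trailing, 1)            # defined as 1 when k = 0
  expect_equal(sc$p_overlap, 1 / 117)       # minimum overlap, inclusive CDF
  expect_equal(sc$p_orf2_len, (61 / 64)^48) # 50 codons minus start and stop
  expect_equal(sc$joint_score,
               sc$p_starts * sc$p_trailing * sc$p_orf2_len * sc$p_overlap,
               tolerance = 1e-12)

  fv$overlap_len <- 120L
  expect_equal(scoreCandidates(methods::new("OverlapPairSet", fv), bg,
                               cfg)$p_overlap, 1)

  fv$n_aug_window <- 3L; fv$n_window_codons <- 40L
  sc3 <- scoreCandidates(methods::new("OverlapPairSet", fv), bg, cfg)
  exact <- 1 - sum(choose(40, 0:2) * (1 / 64)^(0:2) * (63 / 64)^(40 - 0:2))
  expect_equal(sc3$p_starts, exact, tolerance = 1e-12)

  fv$n_aug_window <- 41L
  expect_error(scoreCandidates(methods::new("OverlapPairSet", fv), bg, cfg),
               "invariant violation")
})

test_that("tail probabilities are monotone in the observed counts", {
  cfg <- scanConfig()
  bg <- backgroundModel(mode = "uniform")
  base <- S4Vectors::DataFrame(transcript_id = "t", orf1_start = 0L,
                               n_trailing_ac = 0L, n_window_codons = 40L,
                               orf2_len_nt = 300L, overlap_len = 10L)
  pstarts <- vapply(1:10, function(k) {
    base$n_aug_window <- k
    scoreCandidates(methods::new("OverlapPairSet", base), bg, cfg)$p_starts
  }, 0)
  expect_true(all(diff(pstarts) < 0))
  base$n_aug_window <- 5L
  poverlap <- vapply(c(4L, 10L, 50L, 119L, 120L), function(ov) {
    base$overlap_len <- ov
    scoreCandidates(methods::new("OverlapPairSet", base), bg, cfg)$p_overlap
  }, 0)
  expect_true(all(diff(poverlap) > 0))
})

test_that("all factors live in (0, 1] on real candidates", {
  ts <- coupledGeneTranscripts()
  cfg <- scanConfig()
  sc <- scoreCandidates(extractFeatures(scanTranscripts(ts, cfg), ts, cfg),
                        backgroundModel(mode = "uniform"), cfg)
  for (col in c("p_starts", "p_trailing", "p_orf2_len", "p_overlap",
                "joint_score")) {
    expect_true(all(sc[[col]] > 0))
    expect_true(all(sc[[col]] <= 1))
  }
  expect_true(all(sc$joint_score <= pmin(sc$p_starts, sc$p_trailing,
                                         sc$p_orf2_len, sc$p_overlap)))
})

test_that("window features count ORF-2-frame AUGs and their trailing bases", {
  ts <- coupledGeneTranscripts()
  cfg <- scanConfig()
  pairs <- extractFeatures(scanTranscripts(ts, cfg), ts, cfg)
  casq2 <- pairs[pairs$transcript_id == "casq2_wt", ]
  expect_identical(casq2$n_aug_window, 15L)
  expect_true(all(pairs$n_trailing_ac <= pairs$n_aug_window))
  expect_true(all(pairs$n_aug_window <= pairs$n_window_codons))
  # window with no ORF-2-frame AUG
  seq <- paste0("AUG", strrep("GCC", 24), loadOverlapFixture("casq2_wt"))
  fake <- S4Vectors::DataFrame(transcript_id = "t", orf1_start = 0L,
                               orf1_end = 75L,   # inside the GCC filler
                               orf2_start = 76L, orf2_end = 150L,
                               overlap_len = 4L, orf2_len_nt = 74L)
  fv <- extractFeatures(methods::new("OverlapPairSet", fake), c(t = seq), cfg)
  expect_identical(fv$n_aug_window, 0L)
  expect_identical(fv$n_trailing_ac, 0L)
})

test_that("ranking orders by ascending joint score with documented tie rules", {
  df <- S4Vectors::DataFrame(
    transcript_id = c("b", "a", "a"), orf1_start = c(0L, 50L, 10L),
    joint_score = c(0.1, 0.001, 0.001))
  ranked <- rankCandidates(methods::new("OverlapPairSet", df))
  expect_identical(as.character(ranked$transcript_id), c("a", "a", "b"))
  expect_identical(ranked$orf1_start, c(10L, 50L, 0L))
  expect_identical(ranked$rank, 1:3)
  # invariant under positive rescaling of the joints
  df2 <- df
  df2$joint_score <- df2$joint_score * 1e6
  ranked2 <- rankCandidates(methods::new("OverlapPairSet", df2))
  expect_identical(as.character(ranked2$transcript_id),
                   as.character(ranked$transcript_id))
  expect_identical(ranked2$orf1_start, ranked$orf1_start)
})
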