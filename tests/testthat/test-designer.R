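test_that("STOP mutants abolish the stop with a U->C edit and find the next in-frame stop", {
  seq <- paste0("AUGAAAUAACCCUGA", strrep("GCC", 5))
  mc <- designStopMutant(seq, orf1End = 9L)
  expect_identical(mc@edits$pos, 6L)
  expect_identical(mc@edits$from, "U")
  expect_identical(mc@edits$to, "C")
  expect_identical(substr(mc@seq, 7, 9), "CAA")
  expect_identical(nextStopDistance(mc), 6L)

  uga <- designStopMutant(paste0("AUGAAAUGAAAAUAG"), orf1End = 9L)
  expect_identical(substr(uga@seq, 7, 9), "CGA")   # UGA -> CGA (Arg)
  expect_identical(nextStopDistance(uga), 6L)

  expect_error(designStopMutant("AUGAAAUAAGCC", orf1End = 9L),
               "no downstream in-frame stop")
  expect_error(designStopMutant("AUGAAACCCUAA", orf1End = 9L),
               "no stop codon at position")
})

test_that("next-stop distance is always a multiple of 3", {
  set.seed(31)
  n <- 0
  while (n < 25) {
    seq <- randomRna(400)
    orfs <- findOrfs(seq, minLen = 30)
    if (nrow(orfs) == 0) next
    o <- orfs[sample(nrow(orfs), 1), ]
    mc <- tryCatch(designStopMutant(seq, o$end), error = function(e) NULL)
    if (is.null(mc)) next
    expect_identical(nextStopDistance(mc) %% 3L, 0L)
    expect_gte(nextStopDistance(mc), 3L)
    n <- n + 1
  }
})

test_that("synonymous de-AUG removes exactly the non-kept AUGs, protein unchanged", {
  toy <- "GAUGAUGAUGGCUAA"            # AUGs at 1, 4, 7 in the +1 frame
  mc <- designSynonymousDeAug(toy, keepAugPositions = 1L)
  expect_identical(reinitScan:::framedCodonPositions(mc@seq, "AUG", 1L), 1L)
  expect_identical(reinitScan:::translateFrame(mc@seq, 0L),
                   reinitScan:::translateFrame(toy, 0L))
  # keeping every AUG is the identity
  all3 <- designSynonymousDeAug(toy, keepAugPositions = c(1L, 4L, 7L))
  expect_identical(all3@seq, toy)
  expect_identical(nrow(all3@edits), 0L)
  # an AUG not backed by a GAU codon cannot be removed synonymously
  hard <- "CAUGGCUAA"                 # AUG at 1 arises from CAU + GGC
  expect_error(designSynonymousDeAug(hard, keepAugPositions = integer()),
               "cannot be removed")
  expect_error(designSynonymousDeAug(toy, keepAugPositions = 2L),
               "existing ORF-2-frame AUG")
})

test_that("de-AUG never changes the ORF-1 translation on random GAU-rich regions", {
  set.seed(32)
  for (rep in 1:100) {
    region <- randomGauRegion(sample(10:30, 1))
    augs <- reinitScan:::framedCodonPositions(region, "AUG", 1L)
    if (length(augs) == 0) next
    keep <- sort(augs[sample.int(length(augs),
                                 sample(0:length(augs), 1))])
    mc <- designSynonymousDeAug(region, keepAugPositions = keep)
    expect_identical(reinitScan:::translateFrame(mc@seq, 0L),
                     reinitScan:::translateFrame(region, 0L))
    expect_identical(reinitScan:::framedCodonPositions(mc@seq, "AUG", 1L),
                     as.integer(keep))
  }
})

test_that("AUG knockouts replace codons verbatim and report what remains", {
  parent <- loadOverlapFixture("casq2_gau_gac")   # AUGs 1, 2, 3
  ko1 <- knockoutAugs(parent, replacements = c("1" = "ACG"))
  expect_identical(ko1@report$detail, "2,3")
  expect_identical(substr(ko1@seq, 2, 4), "ACG")
  koAll <- knockoutAugs(parent,
                        replacements = c("1" = "ACG", "2" = "AGC",
                                         "3" = "AGA"))
  expect_identical(
    length(reinitScan:::framedCodonPositions(koAll@seq, "AUG", 1L)), 0L)
  ident <- knockoutAugs(parent, replacements = character())
  expect_identical(ident@seq, parent)
  expect_error(knockoutAugs(parent, replacements = c("1" = "AUG")),
               "must not be AUG")
  expect_error(knockoutAugs(parent, replacements = c("9" = "ACG")),
               "out of range")
})

test_that("scrambles are seeded, composition-preserving and pin-respecting", {
  wt <- loadOverlapFixture("casq2_wt")
  a <- designScramble(wt, seed = 101)
  b <- designScramble(wt, seed = 101)
  expect_identical(a@seq, b@seq)
  pinAug <- max(reinitScan:::framedCodonPositions(wt, "AUG", 1L))
  for (seed in 1:20) {
    sc <- designScramble(wt, seed = seed)
    expect_true(all(sc@report$pass))
    expect_identical(sort(strsplit(sc@seq, "")[[1]]),
                     sort(strsplit(wt, "")[[1]]))
    expect_identical(substr(sc@seq, 79, 81), substr(wt, 79, 81))
    expect_identical(reinitScan:::framedCodonPositions(sc@seq, "AUG", 1L),
                     pinAug)
    prot <- reinitScan:::translateFrame(substr(sc@seq, 1, 78), 0L)
    runs <- rle(strsplit(prot, "")[[1]] == "D")
    expect_false(any(runs$values & runs$lengths >= 2))
  }
  expect_error(designScramble(wt, seed = 1, maxIter = 1L),
               "no accepted permutation within 1")
  expect_error(designScramble("GCCUAA", seed = 1), "no ORF-2-frame AUG")
})

test_that("residue swaps use minimal-edit codons with the lexicographic tie rule", {
  # D -> E on a lone GAU: GAA and GAG both need one edit; GAA sorts first
  toy <- "GAUGGCUAA"
  mc <- designResidueSwap(toy, fromAa = "D", toAa = "E")
  expect_identical(substr(mc@seq, 1, 3), "GAA")
  expect_identical(nrow(mc@edits), 1L)
  wt <- loadOverlapFixture("casq2_wt")
  de <- designResidueSwap(wt, fromAa = "D", toAa = "E",
                          keepOrdinals = c(1L, 8L, 15L))
  expect_identical(de@seq, loadOverlapFixture("casq2_de"))
  prot <- reinitScan:::translateFrame(substr(de@seq, 1, 78), 0L)
  runs <- rle(strsplit(prot, "")[[1]])
  expect_false(any(runs$values == "D" & runs$lengths >= 2))
  dep <- designResidueSwap(wt, fromAa = "D", toAa = "E",
                           keepOrdinals = c(1:9, 15L))
  expect_identical(dep@seq, loadOverlapFixture("casq2_de_plus"))
  # nine amino-terminal aspartates are retained in the plus variant
  protp <- reinitScan:::translateFrame(substr(dep@seq, 1, 78), 0L)
  expect_identical(sum(strsplit(substr(protp, 1, 14), "")[[1]] == "D"), 9L)
  # D -> S swaps likewise remove the aspartate motif
  ds <- designResidueSwap(wt, fromAa = "D", toAa = "S",
                          keepOrdinals = c(1L, 15L))
  expect_true(all(ds@report$pass))
  expect_error(designResidueSwap(wt, fromAa = "D", toAa = "*"),
               "no sense codon")
  expect_error(designResidueSwap("GCCUAA", fromAa = "D", toAa = "E"),
               "does not occur")
})

test_that("sequence diffs label transitions and transversions", {
  expect_identical(nrow(diffSequences("AAG", "AAG")), 0L)
  one <- diffSequences("AAG", "GAG")
  expect_identical(one$type, "transition")
  tv <- diffSequences("AAG", "CAG")
  expect_identical(tv$type, "transversion")
  expect_error(diffSequences("AA", "AAA"), "differ in length")
  d <- diffSequences(loadOverlapFixture("casq2_wt"),
                     loadOverlapFixture("casq2_ag"))
  s <- attr(d, "summary")
  expect_identical(unname(s["n_edits"]), 27L)
  expect_identical(unname(s["n_transitions"]), 27L)
  expect_true(all((d$from == "A" & d$to == "G") |
                  (d$from == "G" & d$to == "A")))
})

test_that("every designer output satisfies the edit round trip", {
  wt <- loadOverlapFixture("casq2_wt")
  constructs <- list(
    designStopMutant(paste0("AUGAAAUAACCCUGA"), orf1End = 9L),
    designSynonymousDeAug(wt, keepAugPositions = c(1L, 31L, 73L)),
    knockoutAugs(loadOverlapFixture("casq2_gau_gac"),
                 replacements = c("2" = "AGC")),
    designScramble(wt, seed = 7),
    designResidueSwap(wt, fromAa = "D", toAa = "E", keepOrdinals = 1L))
  for (mc in constructs) {
    expect_identical(applyEdits(mc@parent, mc@edits), mc@seq)
    expect_true(methods::validObject(mc))
  }
})
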