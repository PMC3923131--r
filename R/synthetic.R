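#' Specification for a planted synthetic candidate
#'
#' See \code{\linkS4class{PlantSpec}} for the geometry rules. The defaults
#' plant a minimal qualifying candidate in a 1-kb transcript with uniform
#' background composition.
#'
#' @param seed RNG seed for the background draws.
#' @param totalLen total transcript length in nt.
#' @param orf1Len,orf2Len ORF lengths in nt (>= 150, multiples of 3).
#' @param overlapLen canonical overlap in nt (4--120, not divisible by 3).
#' @param nOverlapAugs number of ORF-2-frame AUGs planted in the 120-nt
#'   window.
#' @param aspRepeat encode the AUGs as GAU aspartate repeats (requires a +1
#'   frame offset, i.e. \code{overlapLen \%\% 3 == 2}).
#' @param composition background base frequencies (A, C, G, U).
#' @return a validated \code{PlantSpec}.
#' @export
plantSpec <- function(seed, totalLen = 1000L, orf1Len = 300L, orf2Len = 300L,
                      overlapLen = 8L, nOverlapAugs = 1L, aspRepeat = FALSE,
                      composition = c(A = 0.25, C = 0.25, G = 0.25,
                                      U = 0.25)) {
  methods::new("PlantSpec", seed = as.integer(seed),
               totalLen = as.integer(totalLen), orf1Len = as.integer(orf1Len),
               orf2Len = as.integer(orf2Len),
               overlapLen = as.integer(overlapLen),
               nOverlapAugs = as.integer(nOverlapAugs), aspRepeat = aspRepeat,
               composition = composition)
}

#' Generate a background transcript by i.i.d. composition draws
#'
#' @param seed RNG seed (same seed, same sequence).
#' @param length sequence length in nt (> 0).
#' @param composition base frequencies (A, C, G, U) summing to 1.
#' @param id transcript id.
#' @return a length-1 \code{RNAStringSet} with \code{source = "synthetic"}.
#' @examples
#' generateBackgroundTranscript(1, 30)
#' @export
generateBackgroundTranscript <- function(seed, length,
                                         composition = c(0.25, 0.25, 0.25,
                                                         0.25),
                                         id = "background") {
  if (length <= 0L) stop("length must be positive", call. = FALSE)
  if (length(composition) != 4L || abs(sum(composition) - 1) > 1e-9)
    stop("composition must be 4 frequencies summing to 1", call. = FALSE)
  seq <- withSeed(seed, paste(
    sample(RNA_BASES, length, replace = TRUE, prob = composition),
    collapse = ""))
  ts <- Biostrings::RNAStringSet(stats::setNames(seq, id))
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(gene = NA_character_,
                                               source = "synthetic")
  ts
}

# random background string using the current RNG stream
.bgDraw <- function(length, composition) {
  if (length <= 0L) return("")
  paste(sample(RNA_BASES, length, replace = TRUE, prob = composition),
        collapse = "")
}

# Deterministic ORF-1 tail (as a codon vector, 5'->3') planting `n` ORF-2
# frame AUGs whose distances from the ORF-1 end (== their overlaps) are
# `L + step*(0:(n-1))`. Codons are assembled by from-the-end index `c`
# (c = 1 is the stop codon). For a +1 offset an AUG at overlap 3c-1 is the
# A+U of a GAU/CAU codon at index c completed by a G-starting codon at c-1;
# for a +2 offset an AUG at overlap 3c-2 is the terminal A of a ..A codon at
# index c completed by UG from index c-1 (the stop UGA itself when L = 4).
.plantTail <- function(L, n, aspRepeat) {
  offset <- if (L %% 3L == 2L) 1L else 2L
  if (offset == 1L) {
    i <- (L + 1L) %/% 3L                     # from-the-end index of the 3'-most AUG codon
    if (aspRepeat) {
      top <- i + n - 1L
      fe <- rep("GCC", top)
      fe[1L] <- "UAA"
      fe[i - 1L] <- "GGC"
      fe[i:(i + n - 1L)] <- "GAU"            # contiguous aspartate repeat
      step <- 3L
    } else {
      top <- i + 2L * (n - 1L)
      fe <- rep("GCC", top)
      fe[1L] <- "UAA"
      for (j in seq_len(n)) {
        cj <- i + 2L * (j - 1L)
        fe[cj] <- "CAU"
        fe[cj - 1L] <- "GGC"
      }
      step <- 6L
    }
  } else {
    i <- (L + 2L) %/% 3L
    top <- max(i + 2L * (n - 1L), 2L)
    fe <- rep("GCC", top)
    fe[1L] <- if (L == 4L) "UGA" else "UAA"
    for (j in seq_len(n)) {
      cj <- i + 2L * (j - 1L)
      fe[cj] <- "GCA"
      if (cj - 1L > 1L) fe[cj - 1L] <- "UGG"
    }
    step <- 6L
  }
  list(codons = rev(fe), overlaps = L + step * ((n - 1L):0L))
}

#' Plant a synthetic candidate transcript with ground truth
#'
#' Constructs a transcript containing exactly one qualifying overlap pair
#' with known coordinates and feature counts: ORF-1 and ORF-2 of the
#' specified lengths overlapping by \code{overlapLen} nt, with exactly
#' \code{nOverlapAugs} ORF-2-frame AUGs in the 120-nt window (contiguous GAU
#' repeats when \code{aspRepeat}, isolated AUGs otherwise). ORF interiors use
#' GC-only filler so planted counts are exact by construction; the UTRs are
#' i.i.d. draws from \code{composition}, re-rolled (bounded retries) until the
#' assembly contains no incidental ORF of \code{minOrfLen} or more outside
#' the two planted (frame, stop) groups and no stray window AUG.
#'
#' @param spec a \code{\link{plantSpec}}.
#' @param minOrfLen purge threshold for incidental ORFs (default 150).
#' @param maxRetries UTR re-roll limit.
#' @return list with \code{transcript} (length-1 \code{RNAStringSet}) and
#'   \code{truth} (one-row data.frame: coordinates, \code{frame_offset},
#'   \code{overlap_len}, \code{overlap_len_max}, \code{n_aug_window},
#'   \code{n_trailing_ac}).
#' @export
plantCandidate <- function(spec, minOrfLen = 150L, maxRetries = 200L) {
  methods::validObject(spec)
  L <- spec@overlapLen
  tail <- .plantTail(L, spec@nOverlapAugs, spec@aspRepeat)
  tailLen <- 3L * length(tail$codons)
  nBody <- (spec@orf1Len - 3L - tailLen) %/% 3L
  if (nBody < 0L || (spec@orf1Len - 3L - tailLen) %% 3L != 0L)
    stop("orf1Len too short for the planted tail (needs >= ",
         tailLen + 3L, " nt)", call. = FALSE)
  orf1 <- paste0("AUG", strrep("GCC", nBody), paste(tail$codons, collapse = ""))
  ext <- spec@orf2Len - L                    # ORF-2 nt beyond the ORF-1 end
  phase <- ext %% 3L                         # pad to the next ORF-2 codon boundary
  # continuation: pad to the ORF-2 boundary, GCC codons, UAA stop
  nCont <- (ext - phase - 3L) %/% 3L
  if (nCont < 0L) stop("orf2Len too short for the overlap", call. = FALSE)
  cont <- paste0(strrep("C", phase), strrep("GCC", nCont), "UAA")
  stopifnot(nchar(cont) == ext)
  fixedLen <- nchar(orf1) + ext
  slack <- spec@totalLen - fixedLen
  if (slack < 2L)
    stop("totalLen too small for the requested geometry (needs >= ",
         fixedLen + 2L, " nt)", call. = FALSE)
  u5 <- slack %/% 2L
  u3 <- slack - u5
  truthFor <- function(orf1_start) {
    orf1_end <- orf1_start + nchar(orf1)
    data.frame(orf1_start = orf1_start, orf1_end = orf1_end,
               orf2_start = orf1_end - L, orf2_end = orf1_end + ext,
               frame_offset = if (L %% 3L == 2L) 1L else 2L,
               overlap_len = L,
               overlap_len_max = as.integer(max(tail$overlaps)),
               n_aug_window = spec@nOverlapAugs,
               stringsAsFactors = FALSE)
  }
  res <- withSeed(spec@seed, {
    out <- NULL
    for (try in seq_len(maxRetries)) {
      seq <- paste0(.bgDraw(u5, spec@composition), orf1, cont,
                    .bgDraw(u3, spec@composition))
      truth <- truthFor(u5)
      if (.plantClean(seq, truth, minOrfLen)) { out <- seq; break }
    }
    out
  })
  if (is.null(res))
    stop("could not purge incidental ORFs within ", maxRetries,
         " retries (seed ", spec@seed, ")", call. = FALSE)
  truth <- truthFor(u5)
  # trailing bases of the planted AUGs, read off the assembled sequence
  augs <- truth$orf1_end - tail$overlaps
  trail <- substring(res, augs + 4L, augs + 4L)
  truth$n_trailing_ac <- sum(trail %in% c("A", "C"))
  ts <- Biostrings::RNAStringSet(stats::setNames(
    res, paste0("planted_seed", spec@seed)))
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(gene = NA_character_,
                                               source = "synthetic")
  list(transcript = ts, truth = truth)
}

# TRUE when the assembly carries no incidental >= minOrfLen ORF outside the
# two planted (frame, stop) groups, the planted ORF-1 start is the 5'-most
# AUG of its group, and the window holds no stray ORF-2-frame AUG.
.plantClean <- function(seq, truth, minOrfLen) {
  orfs <- findOrfs(seq, minLen = minOrfLen)
  if (nrow(orfs) == 0L) return(FALSE)
  g <- paste(orfs$frame, orfs$end, sep = ":")
  g1 <- paste(truth$orf1_start %% 3L, truth$orf1_end, sep = ":")
  g2 <- paste(truth$orf2_start %% 3L, truth$orf2_end, sep = ":")
  if (!all(g %in% c(g1, g2))) return(FALSE)
  in1 <- orfs$start[g == g1]
  if (length(in1) == 0L || min(in1) != truth$orf1_start) return(FALSE)
  # window AUG inventory must be exactly the planted one
  f2 <- truth$orf2_start %% 3L
  augs <- framedCodonPositions(seq, "AUG", f2)
  ws <- max(0L, truth$orf1_end - 120L)
  inWin <- augs[augs >= ws & augs + 3L <= truth$orf1_end]
  length(inWin) == truth$n_aug_window
}
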