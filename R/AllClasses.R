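#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

#' Scan configuration
#'
#' Parameters controlling ORF detection and overlap-pair enumeration. Defaults
#' reproduce the published screen of the human transcriptome: both ORFs at
#' least 150 nt, overlap between 4 and 120 nt, and start codons counted in a
#' 120-nt window abutting the end of ORF-1.
#'
#' @slot minOrfLen minimum ORF length in nt (stop codon included when
#'   \code{minLenIncludesStop}); must be >= 6 and divisible by 3.
#' @slot overlapMin,overlapMax inclusive bounds on the overlap between the
#'   canonical ORF-2 start and the end of ORF-1, in nt.
#' @slot window length in nt of the window upstream of the ORF-1 stop in which
#'   candidate reinitiation AUGs are inventoried; must be >= \code{overlapMax}.
#' @slot requireOrf2Stop if \code{TRUE} (default) ORF-2 must terminate at a
#'   stop codon within the transcript.
#' @slot minLenIncludesStop whether \code{minOrfLen} is applied to the length
#'   including the stop codon (default) or excluding it.
#' @slot anyFrameStarts count window AUGs in every frame instead of only the
#'   ORF-2 frame (sensitivity analysis; default \code{FALSE}).
#' @export
setClass("ScanConfig",
  representation(minOrfLen = "integer", overlapMin = "integer",
                 overlapMax = "integer", window = "integer",
                 requireOrf2Stop = "logical", minLenIncludesStop = "logical",
                 anyFrameStarts = "logical"),
  prototype(minOrfLen = 150L, overlapMin = 4L, overlapMax = 120L,
            window = 120L, requireOrf2Stop = TRUE, minLenIncludesStop = TRUE,
            anyFrameStarts = FALSE))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@overlapMin <= 0L) msg <- c(msg, "overlapMin must be positive")
  if (object@overlapMin > object@overlapMax)
    msg <- c(msg, "overlapMin must be <= overlapMax")
  if (object@window < object@overlapMax)
    msg <- c(msg, "window must be >= overlapMax")
  if (object@minOrfLen < 6L || object@minOrfLen %% 3L != 0L)
    msg <- c(msg, "minOrfLen must be >= 6 and divisible by 3")
  if (length(msg)) msg else TRUE
})

#' @rdname ScanConfig-class
#' @param minOrfLen,overlapMin,overlapMax,window,requireOrf2Stop,minLenIncludesStop,anyFrameStarts
#'   see the corresponding slots.
#' @return a validated \code{ScanConfig}.
#' @examples
#' scanConfig()
#' scanConfig(minOrfLen = 30, overlapMin = 4, overlapMax = 60, window = 60)
#' @export
scanConfig <- function(minOrfLen = 150L, overlapMin = 4L, overlapMax = 120L,
                       window = 120L, requireOrf2Stop = TRUE,
                       minLenIncludesStop = TRUE, anyFrameStarts = FALSE) {
  new("ScanConfig", minOrfLen = as.integer(minOrfLen),
      overlapMin = as.integer(overlapMin), overlapMax = as.integer(overlapMax),
      window = as.integer(window), requireOrf2Stop = requireOrf2Stop,
      minLenIncludesStop = minLenIncludesStop, anyFrameStarts = anyFrameStarts)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: minOrfLen=", object@minOrfLen,
      " overlap=[", object@overlapMin, ",", object@overlapMax, "]",
      " window=", object@window,
      " requireOrf2Stop=", object@requireOrf2Stop, "\n", sep = "")
})

#' Background nucleotide model
#'
#' Composition-derived null model used by the candidate score. Per-codon
#' probabilities are products of mononucleotide frequencies: \code{pAug} is the
#' chance that a random codon is AUG, \code{pAc} the chance that a random base
#' is A or C, and \code{pStop} the chance that a random codon is one of UAA,
#' UAG, UGA.
#'
#' @slot freqs named numeric of length 4 (A, C, G, U) summing to 1.
#' @slot pAug,pAc,pStop derived per-codon/per-base probabilities.
#' @slot mode one of \code{"uniform"}, \code{"transcript"}, \code{"corpus"}.
#' @export
setClass("BackgroundModel",
  representation(freqs = "numeric", pAug = "numeric", pAc = "numeric",
                 pStop = "numeric", mode = "character"))

setValidity("BackgroundModel", function(object) {
  msg <- character()
  if (!identical(names(object@freqs), c("A", "C", "G", "U")))
    msg <- c(msg, "freqs must be named A, C, G, U")
  if (any(object@freqs < 0)) msg <- c(msg, "frequencies must be non-negative")
  if (abs(sum(object@freqs) - 1) > 1e-12)
    msg <- c(msg, "frequencies must sum to 1")
  if (!object@mode %in% c("uniform", "transcript", "corpus"))
    msg <- c(msg, "mode must be uniform, transcript or corpus")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel (", object@mode, "): ",
      paste(sprintf("%s=%.4f", names(object@freqs), object@freqs),
            collapse = " "),
      sprintf("\n  pAug=%.6g pAc=%.6g pStop=%.6g\n",
              object@pAug, object@pAc, object@pStop), sep = "")
})

#' Candidate overlap-pair container
#'
#' A \code{DataFrame}-backed table of qualifying ORF-1/ORF-2 pairs, one row per
#' pair. Coordinates are 0-based half-open. Scoring appends the feature and
#' probability columns in place.
#'
#' @export
setClass("OverlapPairSet", contains = "DFrame")

setMethod("show", "OverlapPairSet", function(object) {
  cat("OverlapPairSet with", nrow(object), "candidate pair(s)\n")
  if (nrow(object) > 0) {
    cols <- intersect(c("transcript_id", "orf1_start", "orf1_end",
                        "orf2_start", "orf2_end", "frame_offset",
                        "overlap_len", "overlap_len_max", "joint_score",
                        "rank"), colnames(object))
    print(utils::head(as.data.frame(object[, cols, drop = FALSE]), 8))
    if (nrow(object) > 8) cat("...\n")
  }
})

#' Mutant construct
#'
#' A derived sequence together with the verified edit list that transforms the
#' parent into it, a constraint report, and (for stochastic designs) the seed.
#' Edit positions are 0-based.
#'
#' @slot name construct name.
#' @slot parent,seq parent and mutant nucleotide strings (RNA alphabet).
#' @slot edits data.frame with columns \code{pos} (0-based), \code{from},
#'   \code{to}, sorted by position.
#' @slot report data.frame with columns \code{constraint}, \code{pass},
#'   \code{detail}; every design constraint is evaluated.
#' @slot info list of design-specific results (e.g. \code{next_stop_distance}).
#' @slot seed integer seed or \code{NA}.
#' @export
setClass("MutantConstruct",
  representation(name = "character", parent = "character", seq = "character",
                 edits = "data.frame", report = "data.frame", info = "list",
                 seed = "integer"),
  prototype(info = list(), seed = NA_integer_))

setValidity("MutantConstruct", function(object) {
  msg <- character()
  ed <- object@edits
  if (nrow(ed)) {
    if (is.unsorted(ed$pos)) msg <- c(msg, "edits must be sorted by position")
    rebuilt <- applyEdits(object@parent, ed)
    if (!identical(rebuilt, object@seq))
      msg <- c(msg, "applying edits to parent does not reproduce seq")
  } else if (!identical(object@parent, object@seq)) {
    msg <- c(msg, "empty edit list but parent != seq")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MutantConstruct", function(object) {
  cat("MutantConstruct '", object@name, "': ", nchar(object@seq), " nt, ",
      nrow(object@edits), " edit(s)", sep = "")
  if (!is.na(object@seed)) cat(", seed =", object@seed)
  cat("\n")
  if (nrow(object@report)) {
    ok <- all(object@report$pass)
    cat("  constraints:", if (ok) "all pass" else "FAILURES PRESENT", "\n")
  }
})

#' Homology filter report
#'
#' Partition of candidate pairs into kept and rejected sets under the two
#' BLAST-based rejection rules. \code{reasons} and \code{evidence} parallel the
#' rows of \code{rejected}.
#'
#' @slot kept,rejected \code{OverlapPairSet}s partitioning the input.
#' @slot reasons character, \code{"both_orfs_same_protein"} or
#'   \code{"orf1_no_match"}, one per rejected row.
#' @slot evidence subject id supporting rule-1 rejections (\code{NA} for
#'   rule 2), one per rejected row.
#' @slot threshold the E-value threshold applied (strict inequality).
#' @export
setClass("FilterReport",
  representation(kept = "OverlapPairSet", rejected = "OverlapPairSet",
                 reasons = "character", evidence = "character",
                 threshold = "numeric"))

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport: ", nrow(object@kept), " kept, ", nrow(object@rejected),
      " rejected (E < ", format(object@threshold), ")\n", sep = "")
  if (length(object@reasons))
    print(table(object@reasons))
})

#' Planted-candidate specification
#'
#' Geometry and composition of a synthetic transcript carrying exactly one
#' qualifying overlap pair with known coordinates and feature counts.
#' Overlap lengths divisible by 3 are geometrically impossible (the two ORFs
#' would share a frame) and are rejected. Lengths of the form 3m+2 produce a
#' +1 frame offset; lengths 3m+1 a +2 offset (the minimum, 4 nt, uses an AUG
#' straddling a UGA stop). \code{aspRepeat} (GAU-repeat encoding of the window
#' AUGs) requires a +1 offset.
#'
#' @slot seed RNG seed for the background sequence.
#' @slot totalLen,orf1Len,orf2Len,overlapLen geometry in nt.
#' @slot nOverlapAugs number of ORF-2-frame AUGs planted in the window.
#' @slot aspRepeat encode window AUGs as GAU aspartate repeats.
#' @slot composition background base frequencies (A, C, G, U).
#' @export
setClass("PlantSpec",
  representation(seed = "integer", totalLen = "integer", orf1Len = "integer",
                 orf2Len = "integer", overlapLen = "integer",
                 nOverlapAugs = "integer", aspRepeat = "logical",
                 composition = "numeric"))

setValidity("PlantSpec", function(object) {
  msg <- character()
  if (object@orf1Len < 150L || object@orf2Len < 150L)
    msg <- c(msg, "orf1Len and orf2Len must be >= 150")
  if (object@orf1Len %% 3L || object@orf2Len %% 3L)
    msg <- c(msg, "ORF lengths must be divisible by 3")
  L <- object@overlapLen
  if (L < 4L || L > 120L) msg <- c(msg, "overlapLen must be in [4, 120]")
  if (L %% 3L == 0L)
    msg <- c(msg, "overlapLen divisible by 3 is infeasible for ORFs in different frames")
  if (L == 5L)
    msg <- c(msg, "overlapLen 5 is infeasible: the AUG would need its G inside the stop codon, whose first base is U")
  if (object@aspRepeat && L %% 3L != 2L)
    msg <- c(msg, "aspRepeat requires a +1 frame offset (overlapLen == 2 mod 3)")
  if (object@nOverlapAugs < 1L) msg <- c(msg, "nOverlapAugs must be >= 1")
  step <- if (object@aspRepeat) 3L else 6L
  if (L + step * (object@nOverlapAugs - 1L) > 120L)
    msg <- c(msg, "planted AUGs do not fit in the 120-nt window")
  if (length(object@composition) != 4L || abs(sum(object@composition) - 1) > 1e-9)
    msg <- c(msg, "composition must be 4 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})
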