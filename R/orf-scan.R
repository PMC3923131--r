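#' Find AUG-initiated, stop-terminated ORFs in all three forward frames
#'
#' Every AUG upstream of an in-frame stop is emitted as its own ORF (nested
#' same-stop ORFs are all returned); downstream stages choose representative
#' starts by their own rules. Only ORFs terminating at a genuine stop codon
#' within the transcript are returned, and ORFs spanning an N are suppressed.
#' Coordinates are 0-based half-open; \code{end} points one past the stop
#' codon.
#'
#' @param seq a nucleotide string (RNA or DNA alphabet; normalized
#'   internally), an \code{RNAString}, or a length-1 \code{RNAStringSet}.
#' @param minLen minimum ORF length in nt.
#' @param includeStopInLen whether \code{minLen} applies to the length
#'   including the stop codon (default) or excluding it.
#' @return data.frame with columns \code{start}, \code{end}, \code{frame},
#'   \code{nt_len}, \code{protein} (stop excluded), sorted by start then end.
#' @examples
#' findOrfs("AUGAAAUAA", minLen = 9)
#' @export
findOrfs <- function(seq, minLen = 150L, includeStopInLen = TRUE) {
  seq <- .asRnaString(seq)
  n <- nchar(seq)
  out <- list()
  hasN <- grepl("N", seq, fixed = TRUE)
  if (hasN) {
    npos <- gregexpr("N", seq, fixed = TRUE)[[1]]
    ncum <- cumsum(tabulate(npos, nbins = n))  # Ns at positions <= i (1-based)
  }
  for (f in 0:2) {
    stops <- framedCodonPositions(seq, STOP_CODONS, f)
    if (length(stops) == 0L) next
    augs <- framedCodonPositions(seq, "AUG", f)
    if (length(augs) == 0L) next
    idx <- findInterval(augs, stops) + 1L   # first stop strictly after the AUG
    ok <- idx <= length(stops)
    augs <- augs[ok]; idx <- idx[ok]
    if (length(augs) == 0L) next
    end <- stops[idx] + 3L
    len <- end - augs
    eff <- if (includeStopInLen) len else len - 3L
    keep <- eff >= minLen
    augs <- augs[keep]; end <- end[keep]; len <- len[keep]
    if (hasN && length(augs)) {
      noN <- (ncum[end] - c(0, ncum)[augs + 1L]) == 0L
      augs <- augs[noN]; end <- end[noN]; len <- len[noN]
    }
    if (length(augs) == 0L) next
    prot <- vapply(seq_along(augs), function(i)
      translateFrame(substr(seq, augs[i] + 1L, end[i] - 3L)), "")
    out[[length(out) + 1L]] <- data.frame(
      start = augs, end = end, frame = f, nt_len = len, protein = prot,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_len = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.asRnaString <- function(seq) {
  if (methods::is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- as.character(seq[[1L]])
  } else if (methods::is(seq, "XString")) {
    seq <- as.character(seq)
  }
  normalizeRna(seq)
}

#' Enumerate qualifying ORF-1/ORF-2 overlap pairs on one transcript
#'
#' Implements the screen's pair criteria: two ORFs in different frames, each
#' at least \code{minOrfLen} nt, overlapping by \code{overlapMin} to
#' \code{overlapMax} nt, with at least one ORF-2 AUG upstream of the ORF-1
#' stop. Per (frame, stop) group the 5'-most AUG represents ORF-1 (annotated
#' CDS convention); among ORF-2-frame AUGs beginning within \code{window} nt
#' of the end of ORF-1, the one giving the smallest overlap still >=
#' \code{overlapMin} defines the canonical ORF-2 start, and the 5'-most sets
#' \code{overlap_len_max}. AUGs closer to the ORF-1 end than
#' \code{overlapMin} are not part of the in-overlap inventory (strict reading
#' of the 4--120-nt bounds).
#'
#' @param orfs data.frame from \code{\link{findOrfs}} run on the same
#'   transcript with \code{minLen = cfg@minOrfLen}.
#' @param seq the transcript sequence (same conventions as
#'   \code{\link{findOrfs}}).
#' @param cfg a \code{\link{scanConfig}}.
#' @param transcript_id,gene identifiers recorded in the output.
#' @return an \code{\link{OverlapPairSet-class}} with one row per qualifying
#'   pair (possibly empty).
#' @export
findOverlapPairs <- function(orfs, seq, cfg = scanConfig(),
                             transcript_id = "transcript",
                             gene = NA_character_) {
  methods::validObject(cfg)
  seq <- .asRnaString(seq)
  n <- nchar(seq)
  empty <- .emptyPairSet()
  if (nrow(orfs) == 0L) return(empty)
  grp <- paste(orfs$frame, orfs$end, sep = ":")
  groups <- split(seq_len(nrow(orfs)), grp)
  # ORF-1 representative per group: 5'-most AUG
  reps <- lapply(groups, function(ix) orfs[ix[which.min(orfs$start[ix])], ])
  # ORF-2 candidate groups are derived from the sequence itself so that the
  # AUG inventory includes starts whose own ORF is below minOrfLen (such a
  # canonical start disqualifies the pair rather than deferring to a more
  # 5' AUG). One group per (frame, stop); when ORF-2 need not terminate, an
  # open-ended group per frame covers AUGs 3' of the last in-frame stop,
  # truncated to whole codons at the transcript end.
  o2groups <- list()
  for (f in 0:2) {
    stops <- framedCodonPositions(seq, STOP_CODONS, f)
    augs <- framedCodonPositions(seq, "AUG", f)
    if (length(augs) == 0L) next
    bounds <- c(-1L, stops)
    for (k in seq_along(stops)) {
      inseg <- augs[augs > bounds[k] & augs < stops[k]]
      if (length(inseg))
        o2groups[[paste(f, stops[k] + 3L, sep = ":")]] <-
          list(frame = f, end = stops[k] + 3L, starts = inseg)
    }
    if (!cfg@requireOrf2Stop) {
      open <- if (length(stops)) augs[augs > max(stops)] else augs
      if (length(open)) {
        endf <- f + 3L * ((n - f) %/% 3L)
        o2groups[[paste0("open:", f)]] <-
          list(frame = f, end = endf, starts = open)
      }
    }
  }
  rows <- list()
  for (g1 in names(groups)) {
    o1 <- reps[[g1]]
    for (g2 in names(o2groups)) {
      if (g2 == g1) next
      f2 <- o2groups[[g2]]$frame
      e2 <- o2groups[[g2]]$end
      if (f2 == o1$frame) next
      if (e2 <= o1$end) next                 # ORF-2 must extend downstream
      starts2 <- o2groups[[g2]]$starts
      lo <- max(0L, o1$end - cfg@window)
      augs <- starts2[starts2 >= lo & starts2 <= o1$end - cfg@overlapMin]
      if (length(augs) == 0L) next
      canonical <- max(augs)                 # smallest overlap >= overlapMin
      ov <- o1$end - canonical
      if (ov > cfg@overlapMax) next
      len2 <- e2 - canonical
      eff2 <- if (cfg@minLenIncludesStop) len2 else len2 - 3L
      if (eff2 < cfg@minOrfLen) next
      rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
        transcript_id = transcript_id, gene = gene,
        orf1_start = o1$start, orf1_end = o1$end,
        orf2_start = canonical, orf2_end = e2,
        frame_offset = as.integer((canonical - o1$start) %% 3L),
        overlap_len = as.integer(ov),
        overlap_len_max = as.integer(o1$end - min(augs)),
        orf2_len_nt = as.integer(len2),
        aug_positions = IRanges::IntegerList(as.integer(augs)))
    }
  }
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$orf1_start, df$orf2_start), , drop = FALSE]
  methods::new("OverlapPairSet", df)
}

.emptyPairSet <- function() {
  methods::new("OverlapPairSet", S4Vectors::DataFrame(
    transcript_id = character(), gene = character(),
    orf1_start = integer(), orf1_end = integer(),
    orf2_start = integer(), orf2_end = integer(),
    frame_offset = integer(), overlap_len = integer(),
    overlap_len_max = integer(), orf2_len_nt = integer(),
    aug_positions = IRanges::IntegerList()))
}

#' Scan a transcript set for overlap-pair candidates
#'
#' Runs \code{\link{findOrfs}} and \code{\link{findOverlapPairs}} on each
#' transcript in order and concatenates the results. Per-transcript candidate
#' counts are reported via \code{message} when \code{verbose}.
#'
#' @param ts an \code{RNAStringSet} from \code{\link{readTranscripts}} (or a
#'   named character vector of sequences).
#' @param cfg a \code{\link{scanConfig}}.
#' @param verbose log per-transcript counts.
#' @return an \code{\link{OverlapPairSet-class}}.
#' @examples
#' ts <- Biostrings::RNAStringSet(c(demo = paste0(
#'   "GCCGCC", "AUG", strrep("GCC", 49), "UAA")))
#' scanTranscripts(ts, scanConfig())   # no qualifying pair
#' @export
scanTranscripts <- function(ts, cfg = scanConfig(), verbose = FALSE) {
  methods::validObject(cfg)
  seqs <- if (is.character(ts)) ts else txSeqs(ts)
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("transcript", seq_along(seqs))
  genes <- if (is.character(ts)) rep(NA_character_, length(ts)) else txGenes(ts)
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    orfs <- findOrfs(seqs[[i]], minLen = cfg@minOrfLen,
                     includeStopInLen = cfg@minLenIncludesStop)
    parts[[i]] <- findOverlapPairs(orfs, seqs[[i]], cfg,
                                   transcript_id = names(seqs)[i],
                                   gene = genes[i])
    if (verbose)
      message(names(seqs)[i], ": ", nrow(parts[[i]]), " candidate pair(s)")
  }
  if (length(parts) == 0L) return(.emptyPairSet())
  methods::new("OverlapPairSet", do.call(rbind, lapply(parts, as, "DFrame")))
}

#' Overlap-region length as printed in figure displays
#'
#' The published display convention for an overlap region is the span of whole
#' ORF-1 codons from the codon contributing the 5'-most ORF-2 AUG through the
#' ORF-1 stop codon. Because an ORF-2-frame AUG never starts on an ORF-1 codon
#' boundary, this equals \code{overlap_len_max + frame_offset} and is always a
#' multiple of 3 (81 nt for the CASQ2-like fixture), whereas the AUG-to-end
#' distance \code{overlap_len_max} is congruent to 2 (mod 3) for a +1 offset.
#'
#' @param pairs an \code{OverlapPairSet}.
#' @return integer vector of region lengths in nt.
#' @export
overlapRegionLen <- function(pairs) {
  as.integer(pairs$overlap_len_max + pairs$frame_offset)
}
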