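#' Frame offset of ORF-2 relative to ORF-1
#'
#' \code{(orf2_start - orf1_start) mod 3}; 1 means the ORF-2 codon grid starts
#' one nucleotide 3' of ORF-1's, the configuration in which GAU-GAU aspartate
#' repeats of ORF-1 present AUG codons to ORF-2.
#'
#' @param pairs an \code{OverlapPairSet}.
#' @return integer vector in \{1, 2\}.
#' @export
frameOffset <- function(pairs) {
  off <- as.integer((pairs$orf2_start - pairs$orf1_start) %% 3L)
  if (any(off == 0L))
    stop("frame offset 0: ORFs share a frame (invariant violation)",
         call. = FALSE)
  off
}

#' Find runs of consecutive in-frame AUG codons
#'
#' Scans codons in the given frame and records maximal runs of successive AUG
#' codon positions. Reinitiation-competent overlaps in coupled genes carry
#' such AUG clusters of three or more.
#'
#' @param seq nucleotide string.
#' @param frame 0, 1 or 2.
#' @param minCluster cluster size counted by \code{n_clusters_ge} (default 3).
#' @return list with \code{clusters} (data.frame \code{first_aug_index}
#'   0-based, \code{n_consecutive}), \code{n_clusters_ge} and
#'   \code{total_augs}.
#' @examples
#' findAugClusters("AUGAUGAUGCCC", frame = 0)
#' @export
findAugClusters <- function(seq, frame, minCluster = 3L) {
  stopifnot(frame %in% 0:2)
  seq <- .asRnaString(seq)
  pos <- framedCodonPositions(seq, "AUG", frame)
  if (length(pos) == 0L)
    return(list(clusters = data.frame(first_aug_index = integer(),
                                      n_consecutive = integer()),
                n_clusters_ge = 0L, total_augs = 0L))
  brk <- c(0L, which(diff(pos) != 3L), length(pos))
  first <- pos[brk[-length(brk)] + 1L]
  sizes <- diff(brk)
  list(clusters = data.frame(first_aug_index = first, n_consecutive = sizes),
       n_clusters_ge = sum(sizes >= minCluster),
       total_augs = length(pos))
}

#' Find aspartate runs in a protein and flag carboxyl-terminal location
#'
#' Maximal runs of 'D' of at least \code{minRun} residues are reported;
#' \code{c_terminal} is \code{TRUE} when such a run ends within
#' \code{tailWindow} residues of the C terminus. Coupled overlap regions carry
#' short aspartate runs at the ORF-1 carboxyl terminus.
#'
#' @param protein amino-acid string over the 20-letter alphabet.
#' @param minRun minimum run length (default 2, "short runs").
#' @param tailWindow residues from the C terminus that count as terminal
#'   (default 30).
#' @return list with \code{runs} (data.frame \code{start_index} 0-based
#'   residue index, \code{length}), \code{max_run}, \code{total_d},
#'   \code{c_terminal}.
#' @examples
#' findAspRuns("MKDDDDDA")
#' @export
findAspRuns <- function(protein, minRun = 2L, tailWindow = 30L) {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", protein)
  if (bad > 0)
    stop("invalid residue '", substr(protein, bad, bad), "' at position ",
         bad, call. = FALSE)
  v <- s2c(protein) == "D"
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- r$values & r$lengths >= minRun
  runs <- data.frame(start_index = starts[qual] - 1L,
                     length = r$lengths[qual])
  n <- nchar(protein)
  cterm <- any(qual & (n - ends) <= tailWindow)
  list(runs = runs,
       max_run = if (nrow(runs)) max(runs$length) else 0L,
       total_d = sum(v),
       c_terminal = cterm)
}

#' Tally the base following each in-frame AUG
#'
#' For every AUG codon in the given frame, the immediately following
#' nucleotide is tallied; an AUG flush with the sequence end is tallied under
#' \code{none}. A trailing A or C is the favourable-context feature used by
#' the candidate score.
#'
#' @param seq nucleotide string.
#' @param frame 0, 1 or 2.
#' @return named integer vector with elements A, C, G, U, none.
#' @examples
#' trailingBaseProfile("AUGA", frame = 0)
#' @export
trailingBaseProfile <- function(seq, frame) {
  stopifnot(frame %in% 0:2)
  seq <- .asRnaString(seq)
  pos <- framedCodonPositions(seq, "AUG", frame)
  out <- stats::setNames(integer(5), c("A", "C", "G", "U", "none"))
  if (length(pos) == 0L) return(out)
  nxt <- substring(seq, pos + 4L, pos + 4L)
  nxt[nxt == ""] <- "none"
  tab <- table(nxt)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Per-candidate motif report
#'
#' Characterizes the overlap region of each candidate pair: frame offset, AUG
#' clusters in the ORF-2 frame (computed on the overlap region plus
#' \code{flank} nt of context on each side where context exists), trailing
#' bases, and aspartate runs at the ORF-1 carboxyl terminus.
#'
#' @param pairs an \code{OverlapPairSet}.
#' @param ts the transcripts the pairs were scanned from.
#' @param flank nt of flanking context around the overlap region used for
#'   cluster counting (default 15).
#' @param minRun,tailWindow passed to \code{\link{findAspRuns}}.
#' @return data.frame with one row per pair: \code{transcript_id},
#'   \code{frame_offset}, \code{region_len}, \code{n_augs},
#'   \code{n_clusters_ge3}, \code{max_cluster}, \code{n_trailing_ac},
#'   \code{max_asp_run}, \code{total_asp}, \code{asp_c_terminal}.
#' @export
motifReport <- function(pairs, ts, flank = 15L, minRun = 2L,
                        tailWindow = 30L) {
  seqs <- if (is.character(ts)) ts else txSeqs(ts)
  off <- frameOffset(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    seq <- seqs[[pairs$transcript_id[i]]]
    e1 <- pairs$orf1_end[i]
    rstart <- e1 - (pairs$overlap_len_max[i] + off[i])  # whole ORF-1 codons
    lo <- max(0L, rstart - flank)
    hi <- min(nchar(seq), e1 + flank)
    ctx <- substr(seq, lo + 1L, hi)
    f2 <- (pairs$orf2_start[i] - lo) %% 3L
    cl <- findAugClusters(ctx, frame = f2)
    tb <- trailingBaseProfile(ctx, frame = f2)
    prot1 <- translateFrame(substr(seq, pairs$orf1_start[i] + 1L, e1 - 3L))
    ar <- findAspRuns(prot1, minRun = minRun, tailWindow = tailWindow)
    data.frame(transcript_id = pairs$transcript_id[i],
               frame_offset = off[i],
               region_len = pairs$overlap_len_max[i] + off[i],
               n_augs = cl$total_augs,
               n_clusters_ge3 = cl$n_clusters_ge,
               max_cluster = if (nrow(cl$clusters))
                 max(cl$clusters$n_consecutive) else 0L,
               n_trailing_ac = unname(tb["A"] + tb["C"]),
               max_asp_run = ar$max_run,
               total_asp = ar$total_d,
               asp_c_terminal = ar$c_terminal,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(), frame_offset = integer(),
                      region_len = integer(), n_augs = integer(),
                      n_clusters_ge3 = integer(), max_cluster = integer(),
                      n_trailing_ac = integer(), max_asp_run = integer(),
                      total_asp = integer(), asp_c_terminal = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
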