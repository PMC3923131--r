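#' Build a background nucleotide model
#'
#' Frequencies are estimated from observed base counts (U and T pooled, N
#' ignored), or fixed at 0.25 each for \code{mode = "uniform"}. The null
#' distributions behind the candidate score treat codons as i.i.d. draws from
#' this composition.
#'
#' @param ts transcripts (\code{RNAStringSet} or character vector);
#'   \code{mode = "transcript"} requires exactly one, \code{"corpus"} pools
#'   all, \code{"uniform"} ignores them.
#' @param mode one of \code{"transcript"}, \code{"corpus"}, \code{"uniform"}.
#' @return a \code{\link{BackgroundModel-class}}.
#' @examples
#' backgroundModel(mode = "uniform")@pAug   # 1/64
#' @export
backgroundModel <- function(ts = NULL,
                            mode = c("transcript", "corpus", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    f <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  } else {
    if (is.null(ts) || length(ts) == 0L)
      stop("composition modes need at least one transcript", call. = FALSE)
    seqs <- if (is.character(ts)) ts else txSeqs(ts)
    if (mode == "transcript" && length(seqs) != 1L)
      stop("mode 'transcript' requires exactly one transcript", call. = FALSE)
    seqs <- normalizeRna(seqs)
    cnt <- vapply(RNA_BASES, function(b)
      sum(vapply(seqs, function(s)
        lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), 0L)), 0)
    if (sum(cnt) == 0L) stop("no A/C/G/U bases in input", call. = FALSE)
    f <- cnt / sum(cnt)
    names(f) <- RNA_BASES
  }
  methods::new("BackgroundModel", freqs = f,
               pAug = unname(f["A"] * f["U"] * f["G"]),
               pAc = unname(f["A"] + f["C"]),
               pStop = unname(f["U"] * f["A"] * f["A"] +
                              f["U"] * f["A"] * f["G"] +
                              f["U"] * f["G"] * f["A"]),
               mode = mode)
}

#' Extract the score's feature vector for each candidate pair
#'
#' The feature window is the \code{cfg@window} nucleotides abutting the end of
#' ORF-1, \code{[max(0, orf1_end - window), orf1_end)}. \code{n_aug_window}
#' counts AUG trinucleotides in the ORF-2 frame lying fully inside the window
#' (any frame when \code{cfg@anyFrameStarts}); \code{n_trailing_ac} counts
#' those immediately followed by A or C; \code{n_window_codons} is the number
#' of complete ORF-2-frame codon positions inside the window.
#'
#' @param pairs an \code{OverlapPairSet}.
#' @param ts the transcripts the pairs were scanned from.
#' @param cfg the \code{\link{scanConfig}} used for the scan.
#' @return \code{pairs} with columns \code{n_aug_window},
#'   \code{n_trailing_ac}, \code{n_window_codons} appended
#'   (\code{orf2_len_nt} and \code{overlap_len} are already present).
#' @export
extractFeatures <- function(pairs, ts, cfg = scanConfig()) {
  seqs <- if (is.character(ts)) ts else txSeqs(ts)
  k <- m <- nc <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    seq <- seqs[[pairs$transcript_id[i]]]
    if (is.null(seq)) stop("transcript '", pairs$transcript_id[i],
                           "' not found", call. = FALSE)
    e1 <- pairs$orf1_end[i]
    ws <- max(0L, e1 - cfg@window)
    f2 <- pairs$orf2_start[i] %% 3L
    augs <- if (cfg@anyFrameStarts) allCodonPositions(seq, "AUG")
            else framedCodonPositions(seq, "AUG", f2)
    augs <- augs[augs >= ws & augs + 3L <= e1]
    k[i] <- length(augs)
    m[i] <- if (length(augs)) {
      trail <- substring(seq, augs + 4L, augs + 4L)
      sum(trail %in% c("A", "C"))
    } else 0L
    first <- ws + (f2 - ws) %% 3L
    nc[i] <- max(0L, (e1 - first) %/% 3L)
  }
  pairs$n_aug_window <- k
  pairs$n_trailing_ac <- m
  pairs$n_window_codons <- nc
  pairs
}

#' Upper tail of a binomial distribution by exact summation
#'
#' Computes P(X >= k) for X ~ Binomial(n, p) by summing the individual
#' probability terms (evaluated in log space), smallest terms first. Defined
#' as 1 for k <= 0 and 0 for k > n.
#'
#' @param k,n,p tail threshold, size and success probability.
#' @return the tail probability.
#' @export
binomUpperTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  i <- k:n
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  min(1, sum(exp(sort(lt))))
}

#' Score candidate pairs by the four-factor joint probability
#'
#' The score multiplies four tail probabilities, each measuring how surprising
#' an observed feature is under the background model; smaller joint values
#' mark stronger candidates. \code{p_starts} is the binomial upper tail for
#' the window AUG count among \code{n_window_codons} codon positions with
#' per-codon probability \code{pAug}; \code{p_trailing} the upper tail for the
#' trailing-A/C count among the observed starts with per-base probability
#' \code{pAc} (1 when no starts); \code{p_orf2_len} the probability of an
#' ORF-2 at least as long, \code{(1 - pStop)^c} over the \code{c} internal
#' sense codons (start and stop excluded); and \code{p_overlap} the inclusive
#' discrete-uniform probability of an overlap no longer than observed,
#' \code{(overlap_len - overlapMin + 1) / (overlapMax - overlapMin + 1)}, so
#' the minimum overlap scores 1/117 under the default 4--120 bounds rather
#' than a degenerate 0.
#'
#' @param pairs an \code{OverlapPairSet} with features
#'   (\code{\link{extractFeatures}}).
#' @param bg a \code{\link{backgroundModel}}.
#' @param cfg the \code{\link{scanConfig}} used for the scan.
#' @return \code{pairs} with columns \code{p_starts}, \code{p_trailing},
#'   \code{p_orf2_len}, \code{p_overlap}, \code{joint_score} appended.
#' @export
scoreCandidates <- function(pairs, bg, cfg = scanConfig()) {
  if (!"n_aug_window" %in% colnames(pairs))
    stop("run extractFeatures() first", call. = FALSE)
  n <- nrow(pairs)
  ps <- pt <- po <- pv <- numeric(n)
  for (i in seq_len(n)) {
    k <- pairs$n_aug_window[i]
    nc <- pairs$n_window_codons[i]
    if (k > nc)
      stop("invariant violation: more window AUGs (", k,
           ") than window codons (", nc, ")", call. = FALSE)
    if (bg@pAug == 0 && k > 0)
      stop("degenerate background: pAug = 0 but ", k,
           " start codon(s) observed", call. = FALSE)
    ps[i] <- binomUpperTail(k, nc, bg@pAug)
    pt[i] <- if (k == 0) 1 else binomUpperTail(pairs$n_trailing_ac[i], k, bg@pAc)
    cint <- max(0L, pairs$orf2_len_nt[i] %/% 3L - 2L)
    po[i] <- (1 - bg@pStop)^cint
    pv[i] <- (pairs$overlap_len[i] - cfg@overlapMin + 1) /
             (cfg@overlapMax - cfg@overlapMin + 1)
  }
  pairs$p_starts <- ps
  pairs$p_trailing <- pt
  pairs$p_orf2_len <- po
  pairs$p_overlap <- pv
  pairs$joint_score <- ps * pt * po * pv
  pairs
}

#' Rank scored candidates
#'
#' Candidates are ordered by ascending joint score (the least probable
#' feature combination ranks first); ties break lexicographically by
#' transcript id, then by ORF-1 start.
#'
#' @param pairs a scored \code{OverlapPairSet}.
#' @return \code{pairs} sorted with a \code{rank} column filled 1..N.
#' @export
rankCandidates <- function(pairs) {
  if (!"joint_score" %in% colnames(pairs))
    stop("run scoreCandidates() first", call. = FALSE)
  ord <- order(pairs$joint_score, pairs$transcript_id, pairs$orf1_start)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$rank <- seq_len(nrow(pairs))
  pairs
}
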