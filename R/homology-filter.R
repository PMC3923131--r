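#' Apply the two BLAST-based rejection rules to candidate pairs
#'
#' A pair is rejected as \code{both_orfs_same_protein} when some subject is
#' hit by both its ORFs with E-values below the threshold (a likely
#' misannotation of a single known protein), and as \code{orf1_no_match} when
#' ORF-1 has no hit below the threshold (a likely misidentified first ORF).
#' Rule 1 takes precedence when both apply. Comparisons use strict inequality
#' (E < threshold). Hit query ids must follow the
#' \code{"<transcript_id>:ORF1"} / \code{":ORF2"} convention; hits referencing
#' transcripts absent from \code{pairs} produce a warning and are ignored.
#'
#' @param pairs an \code{OverlapPairSet}.
#' @param hits data.frame from \code{\link{readBlastTabular}}.
#' @param threshold E-value threshold (default \code{1e-5}).
#' @return a \code{\link{FilterReport-class}}.
#' @examples
#' ts <- embedOverlap(loadOverlapFixture("casq2_wt"), id = "t1")
#' pairs <- scanTranscripts(ts)
#' hits <- data.frame(query_orf_id = c("t1:ORF1", "t1:ORF2"),
#'                    subject_id = "sp|P1", evalue = c(1e-30, 1e-8))
#' applyRejectionRules(pairs, hits)   # rejected: both ORFs match one protein
#' @export
applyRejectionRules <- function(pairs, hits, threshold = 1e-5) {
  stopifnot(is.data.frame(hits),
            all(c("query_orf_id", "subject_id", "evalue") %in% colnames(hits)))
  qt <- sub(":ORF[12]$", "", hits$query_orf_id)
  unknown <- setdiff(unique(qt), pairs$transcript_id)
  if (length(unknown))
    warning("ignoring hits for unknown transcript id(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  sig <- hits[hits$evalue < threshold, , drop = FALSE]
  sigt <- sub(":ORF[12]$", "", sig$query_orf_id)
  sigo <- sub("^.*:(ORF[12])$", "\\1", sig$query_orf_id)
  n <- nrow(pairs)
  reason <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tid <- pairs$transcript_id[i]
    s1 <- unique(sig$subject_id[sigt == tid & sigo == "ORF1"])
    s2 <- unique(sig$subject_id[sigt == tid & sigo == "ORF2"])
    shared <- intersect(s1, s2)
    if (length(shared)) {
      reason[i] <- "both_orfs_same_protein"
      evidence[i] <- shared[1]
    } else if (length(s1) == 0L) {
      reason[i] <- "orf1_no_match"
    }
  }
  rej <- !is.na(reason)
  methods::new("FilterReport",
               kept = pairs[!rej, , drop = FALSE],
               rejected = pairs[rej, , drop = FALSE],
               reasons = reason[rej], evidence = evidence[rej],
               threshold = threshold)
}

#' Write the rejection sidecar TSV
#'
#' One line per rejected pair: transcript id, rejection reason, and (for
#' rule-1 rejections) the shared subject id.
#'
#' @param report a \code{\link{FilterReport-class}}.
#' @param path output file.
#' @return invisibly, the output path.
#' @export
writeRejectionSidecar <- function(report, path) {
  df <- data.frame(transcript_id = report@rejected$transcript_id,
                   reason = report@reasons,
                   evidence_subject_id = report@evidence,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
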