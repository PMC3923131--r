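# Pipeline entry points backing the command-line wrapper in exec/. Each
# returns an exit-code integer (0 success, 2 empty candidate set) and raises
# an R error for configuration/input problems (the wrapper maps those to
# exit 1). Every output file starts with a header comment block echoing the
# tool version, configuration and seed, so a run is reproducible from its
# header alone.

.runHeader <- function(cfg = NULL, seed = NULL, extra = character()) {
  h <- c(paste0(utils::packageName(), " ",
                as.character(utils::packageVersion(utils::packageName()))),
         paste0("date: ", format(Sys.time(), "%Y-%m-%d")))
  if (!is.null(cfg))
    h <- c(h, sprintf(
      "config: minOrfLen=%d overlapMin=%d overlapMax=%d window=%d requireOrf2Stop=%s",
      cfg@minOrfLen, cfg@overlapMin, cfg@overlapMax, cfg@window,
      cfg@requireOrf2Stop))
  if (!is.null(seed)) h <- c(h, paste0("seed: ", seed))
  c(h, extra)
}

#' Run the full scan -> features -> score -> rank pipeline
#'
#' @param input FASTA or GenBank transcript file.
#' @param out output TSV path for the ranked candidate table.
#' @param cfg a \code{\link{scanConfig}}.
#' @param bgMode background model mode; \code{"transcript"} scores each
#'   candidate against its own transcript's composition.
#' @param format input format passed to \code{\link{readTranscripts}}.
#' @return invisibly, 0 on success or 2 when no candidate qualifies (the
#'   header-only table is still written).
#' @export
runScan <- function(input, out, cfg = scanConfig(), bgMode = "transcript",
                    format = "auto") {
  methods::validObject(cfg)
  ts <- readTranscripts(input, format = format)
  pairs <- scanTranscripts(ts, cfg, verbose = TRUE)
  if (nrow(pairs)) {
    pairs <- extractFeatures(pairs, ts, cfg)
    scored <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      bg <- if (bgMode == "transcript")
        backgroundModel(ts[pairs$transcript_id[i]], mode = "transcript")
      else backgroundModel(ts, mode = bgMode)
      scored[[i]] <- scoreCandidates(pairs[i, , drop = FALSE], bg, cfg)
    }
    pairs <- methods::new("OverlapPairSet",
                          do.call(rbind, lapply(scored, as, "DFrame")))
    pairs <- rankCandidates(pairs)
  } else {
    pairs$n_aug_window <- integer(); pairs$n_trailing_ac <- integer()
    pairs$n_window_codons <- integer()
    pairs$p_starts <- numeric(); pairs$p_trailing <- numeric()
    pairs$p_orf2_len <- numeric(); pairs$p_overlap <- numeric()
    pairs$joint_score <- numeric(); pairs$rank <- integer()
  }
  writeCandidateTable(pairs, out,
                      header = .runHeader(cfg, extra = paste0(
                        "bg_mode: ", bgMode)))
  invisible(if (nrow(pairs)) 0L else 2L)
}

#' Scan and apply the BLAST-based rejection rules
#'
#' @param input transcript file; \code{blastTab} 12-column BLAST tabular hits
#'   for the ORF-1/ORF-2 protein queries.
#' @param blastTab BLAST tabular file.
#' @param outKept,outRejected output TSVs.
#' @param evalue rejection threshold (strict inequality).
#' @param cfg a \code{\link{scanConfig}}.
#' @return invisibly, 0 (2 when nothing is kept).
#' @export
runFilter <- function(input, blastTab, outKept, outRejected, evalue = 1e-5,
                      cfg = scanConfig()) {
  ts <- readTranscripts(input)
  pairs <- scanTranscripts(ts, cfg)
  hits <- readBlastTabular(blastTab)
  rep <- applyRejectionRules(pairs, hits, threshold = evalue)
  keepDf <- as.data.frame(rep@kept[, setdiff(colnames(rep@kept),
                                             "aug_positions"), drop = FALSE])
  utils::write.table(keepDf, outKept, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeRejectionSidecar(rep, outRejected)
  invisible(if (nrow(rep@kept)) 0L else 2L)
}

#' Scan and emit per-candidate motif reports
#'
#' Writes a TSV of motif summaries and, when \code{outText} is given, a
#' human-readable block per candidate.
#'
#' @param input transcript file.
#' @param out TSV output path.
#' @param outText optional text-report path.
#' @param cfg a \code{\link{scanConfig}}.
#' @return invisibly, 0 (2 when no candidates).
#' @export
runMotifs <- function(input, out, outText = NULL, cfg = scanConfig()) {
  ts <- readTranscripts(input)
  pairs <- scanTranscripts(ts, cfg)
  rep <- motifReport(pairs, ts)
  utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(outText)) {
    blocks <- vapply(seq_len(nrow(rep)), function(i) paste0(
      "candidate: ", rep$transcript_id[i], "\n",
      "  frame offset:        +", rep$frame_offset[i], "\n",
      "  overlap region:      ", rep$region_len[i], " nt\n",
      "  ORF-2-frame AUGs:    ", rep$n_augs[i],
      " (clusters >=3: ", rep$n_clusters_ge3[i],
      ", largest: ", rep$max_cluster[i], ")\n",
      "  trailing A/C starts: ", rep$n_trailing_ac[i], "\n",
      "  aspartates in ORF-1: ", rep$total_asp[i],
      " (longest run: ", rep$max_asp_run[i],
      ", C-terminal: ", rep$asp_c_terminal[i], ")\n"), "")
    writeLines(blocks, outText)
  }
  invisible(if (nrow(rep)) 0L else 2L)
}

#' Run a construct-design subcommand on an overlap region
#'
#' Thin dispatcher over the designer functions, reading the region from a
#' single-record FASTA and writing the mutant FASTA plus constraint report.
#'
#' @param design one of \code{"stop"}, \code{"deaug"}, \code{"knockout"},
#'   \code{"scramble"}, \code{"swap"}.
#' @param input single-record FASTA; for \code{"stop"} a full transcript,
#'   otherwise an overlap region (ORF-1 frame 0, ORF-2 frame +1).
#' @param out mutant FASTA output path; the constraint report goes to
#'   \code{paste0(out, ".report.tsv")}.
#' @param ... arguments forwarded to the designer (e.g. \code{seed},
#'   \code{keepAugPositions}, \code{replacements}, \code{fromAa},
#'   \code{toAa}, \code{keepOrdinals}, \code{orf1End}).
#' @return invisibly, 0.
#' @export
runDesign <- function(design = c("stop", "deaug", "knockout", "scramble",
                                 "swap"),
                      input, out, ...) {
  design <- match.arg(design)
  seqs <- txSeqs(readTranscripts(input))
  if (length(seqs) != 1L)
    stop("design subcommands expect a single-record FASTA", call. = FALSE)
  seq <- seqs[[1L]]
  args <- list(...)
  mc <- switch(design,
    stop = {
      orf1End <- args$orf1End
      if (is.null(orf1End)) {
        orfs <- findOrfs(seq, minLen = args$minOrfLen %||% 150L)
        if (nrow(orfs) == 0L) stop("no ORF found for the STOP design",
                                   call. = FALSE)
        orf1End <- orfs$end[which.min(orfs$start)]
      }
      designStopMutant(seq, orf1End)
    },
    deaug = designSynonymousDeAug(seq,
                                  keepAugPositions = args$keepAugPositions),
    knockout = knockoutAugs(seq, replacements = args$replacements),
    scramble = designScramble(seq, seed = args$seed %||% 1L,
                              maxIter = args$maxIter %||% 2000L),
    swap = designResidueSwap(seq, fromAa = args$fromAa %||% "D",
                             toAa = args$toAa %||% "E",
                             keepOrdinals = args$keepOrdinals %||% integer()))
  writeConstruct(mc, out, reportPath = paste0(out, ".report.tsv"))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a planted-candidate transcript from a key=value spec file
#'
#' The spec file holds one \code{key=value} per line with the
#' \code{\link{plantSpec}} argument names (\code{seed}, \code{totalLen},
#' \code{orf1Len}, \code{orf2Len}, \code{overlapLen}, \code{nOverlapAugs},
#' \code{aspRepeat}); blank lines and \code{#} comments are skipped.
#'
#' @param specFile key=value file.
#' @param outFasta FASTA output path for the planted transcript.
#' @param outTruth TSV output path for the ground-truth record.
#' @return invisibly, 0.
#' @export
runSimulate <- function(specFile, outFasta, outTruth) {
  lines <- readLines(specFile, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("spec file must contain key=value lines", call. = FALSE)
  vals <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  num <- function(k, d) if (k %in% names(vals)) as.integer(vals[[k]]) else d
  spec <- plantSpec(seed = num("seed", 1L),
                    totalLen = num("totalLen", 1000L),
                    orf1Len = num("orf1Len", 300L),
                    orf2Len = num("orf2Len", 300L),
                    overlapLen = num("overlapLen", 8L),
                    nOverlapAugs = num("nOverlapAugs", 1L),
                    aspRepeat = isTRUE(as.logical(vals["aspRepeat"])))
  res <- plantCandidate(spec)
  writeFasta(res$transcript, outFasta)
  utils::write.table(res$truth, outTruth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(0L)
}
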