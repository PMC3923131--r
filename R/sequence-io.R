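#' Read transcript sequences from FASTA or GenBank flat files
#'
#' Records are normalized to the internal RNA alphabet (T mapped to U,
#' upper-cased). The record id is the first whitespace-delimited token of the
#' description line; a \code{gene=} key in the remainder of the description is
#' parsed into the \code{gene} metadata column. \code{format = "auto"} sniffs
#' the first non-blank character: \code{>} selects FASTA, a line starting with
#' \code{LOCUS} selects GenBank.
#'
#' Records containing characters outside IUPAC A/C/G/T/U/N are rejected with a
#' diagnostic naming the record and character. N is accepted on input; ORFs
#' spanning an N are suppressed by the scanner.
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"fasta"}, \code{"genbank"}.
#' @param source provenance label stored in the metadata (default follows the
#'   detected format).
#' @return an \code{\link[Biostrings]{RNAStringSet}} named by record id with
#'   metadata columns \code{gene} and \code{source}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x gene=DEMO", "ATGAAATAA"), fa)
#' readTranscripts(fa)
#' @export
readTranscripts <- function(path, format = c("auto", "fasta", "genbank"),
                            source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    head <- readLines(path, n = 50L, warn = FALSE)
    head <- head[nzchar(trimws(head))]
    format <- if (length(head) == 0L) "fasta"
              else if (startsWith(head[1], ">")) "fasta"
              else if (any(startsWith(head, "LOCUS"))) "genbank"
              else stop("cannot determine format of '", path,
                        "' (neither '>' nor 'LOCUS' found)", call. = FALSE)
  }
  rec <- if (format == "fasta") .readFastaRecords(path)
         else .readGenbankRecords(path)
  if (length(rec$seq) == 0L) {
    warning("no records in '", path, "'", call. = FALSE)
  }
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup))
    stop("duplicate transcript id '", dup[1], "' in '", path, "'",
         call. = FALSE)
  seqs <- normalizeRna(rec$seq, id = rec$id)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record '", rec$id[which(empty)[1]], "' has an empty sequence",
         call. = FALSE)
  ts <- Biostrings::RNAStringSet(seqs)
  names(ts) <- rec$id
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(
    gene = rec$gene,
    source = rep(if (is.null(source)) format else source, length(ts)))
  ts
}

.readFastaRecords <- function(path) {
  x <- Biostrings::readBStringSet(path)
  desc <- names(x)
  id <- sub("\\s.*$", "", desc)
  gene <- rep(NA_character_, length(desc))
  m <- regmatches(desc, regexpr("gene=[^[:space:]]+", desc))
  has <- grepl("gene=", desc)
  gene[has] <- sub("^gene=", "", m)
  list(id = id, gene = gene, seq = as.character(x))
}

# Minimal GenBank flat-file reader: LOCUS name, /gene qualifier (first one),
# ORIGIN sequence block. Enough for transcript records saved from Entrez.
.readGenbankRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id <- character(); gene <- character(); seq <- character()
  cur_id <- NULL; cur_gene <- NA_character_; cur_seq <- NULL; in_origin <- FALSE
  flush <- function() {
    if (!is.null(cur_id)) {
      id <<- c(id, cur_id); gene <<- c(gene, cur_gene)
      seq <<- c(seq, paste(cur_seq, collapse = ""))
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "LOCUS")) {
      flush()
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(tok) < 2L) stop("malformed LOCUS line", call. = FALSE)
      cur_id <- tok[2]; cur_gene <- NA_character_; cur_seq <- character()
      in_origin <- FALSE
    } else if (grepl("^\\s+/gene=", ln) && !is.null(cur_id) &&
               is.na(cur_gene)) {
      cur_gene <- gsub("\"", "", sub("^/gene=", "", trimws(ln)))
    } else if (startsWith(ln, "ORIGIN")) {
      in_origin <- TRUE
    } else if (startsWith(ln, "//")) {
      in_origin <- FALSE
    } else if (in_origin) {
      cur_seq <- c(cur_seq, gsub("[0-9[:space:]]", "", ln))
    }
  }
  flush()
  list(id = id, gene = gene, seq = seq)
}

#' Read BLAST tabular (12-column) hit files
#'
#' Parses the standard 12-column tab-separated BLAST output (\code{-outfmt 6}
#' dialect): column 1 is the query id, column 2 the subject id, column 11 the
#' E-value. Other columns are ignored. Blank lines and lines starting with
#' \code{#} are skipped. Query ids are expected to follow the
#' \code{"<transcript_id>:ORF1"} / \code{":ORF2"} convention used by
#' \code{\link{applyRejectionRules}}.
#'
#' @param path input file.
#' @return data.frame with columns \code{query_orf_id}, \code{subject_id},
#'   \code{evalue}.
#' @export
readBlastTabular <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(query_orf_id = character(), subject_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("line ", lineno[which(nf < 12L)[1]],
         ": expected 12 tab-separated columns, found ", min(nf), call. = FALSE)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 11L)))
  if (anyNA(ev))
    stop("line ", lineno[which(is.na(ev))[1]], ": malformed E-value '",
         vapply(fields, `[`, "", 11L)[which(is.na(ev))[1]], "'", call. = FALSE)
  if (any(ev < 0))
    stop("line ", lineno[which(ev < 0)[1]], ": negative E-value",
         call. = FALSE)
  data.frame(query_orf_id = vapply(fields, `[`, "", 1L),
             subject_id = vapply(fields, `[`, "", 2L),
             evalue = ev, stringsAsFactors = FALSE)
}

.CANDIDATE_COLS <- c("transcript_id", "gene", "orf1_start", "orf1_end",
                     "orf2_start", "orf2_end", "frame_offset", "overlap_len",
                     "overlap_len_max", "n_aug_window", "n_trailing_ac",
                     "orf2_len_nt", "p_starts", "p_trailing", "p_orf2_len",
                     "p_overlap", "joint_score", "rank")

#' Write a ranked candidate table as TSV
#'
#' Columns are written in a fixed order (coordinates 0-based half-open), rows
#' sorted by rank. Numeric probability columns are written with 15 significant
#' digits so that a round trip preserves them to at least 12. Optional header
#' comment lines (prefixed \code{#}) may carry the run configuration.
#'
#' @param pairs a scored, ranked \code{OverlapPairSet}
#'   (see \code{\link{rankCandidates}}).
#' @param path output file.
#' @param header optional character vector written as \code{#}-prefixed
#'   comment lines before the column header.
#' @return invisibly, the output path.
#' @export
writeCandidateTable <- function(pairs, path, header = NULL) {
  df <- as.data.frame(pairs[, intersect(.CANDIDATE_COLS, colnames(pairs)),
                            drop = FALSE])
  missing <- setdiff(.CANDIDATE_COLS, colnames(df))
  if (length(missing))
    stop("pairs must be scored and ranked; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[order(df$rank), .CANDIDATE_COLS, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a candidate table written by \code{writeCandidateTable}
#'
#' @param path TSV file.
#' @return data.frame with the standard candidate columns.
#' @export
readCandidateTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   gene = "character"))
}

#' Write transcripts as FASTA
#'
#' Sequences are stored internally as RNA; by default they are written as RNA
#' (U). Set \code{dna = TRUE} to back-convert U to T on output.
#'
#' @param ts an \code{RNAStringSet} or named character vector.
#' @param path output file.
#' @param dna write in the DNA alphabet.
#' @return invisibly, the output path.
#' @export
writeFasta <- function(ts, path, dna = FALSE) {
  seqs <- if (is.character(ts)) ts else txSeqs(ts)
  if (dna) seqs <- chartr("U", "T", seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}
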