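# Bundled overlap-region fixtures and deterministic transcript contexts.
#
# The published figures print the overlap-region sequences of the coupled
# genes and the CASQ2 mutant series; those exact figure sequences are not
# redistributed here. The bundled regions are SYNTHETIC stand-ins constructed
# to satisfy every property stated in the text: the CASQ2-like region is
# 81 nt with 15 ORF-2-frame AUGs in three clusters (6, 5, 4) encoded by GAU
# aspartate repeats; the A/G mutant differs from it at 27 positions, all
# A<->G transitions, removing the aspartate runs and all but the first and
# last AUG; the GAU/GAC mutant is fully synonymous in ORF-1 and keeps the
# first, one central, and the last AUG; the D/E and D/E-plus mutants swap
# aspartates for glutamates (retaining nine amino-terminal aspartates in the
# plus variant); NT5C2- and TMEM97-like regions are glutamate- and
# lysine-rich with no aspartate runs. File checksums guard against drift.

.FIXTURE_NAMES <- c("casq2_wt", "casq2_gau_gac", "casq2_ag", "casq2_scramble",
                    "casq2_de", "casq2_de_plus", "c22orf32", "ccdc36",
                    "wdr45", "casq1", "nt5c2", "tmem97")

.COUPLED_GENES <- c(casq2_wt = "CASQ2", c22orf32 = "C22orf32",
                    ccdc36 = "CCDC36", wdr45 = "WDR45", casq1 = "CASQ1")

#' Names of the bundled synthetic overlap-region fixtures
#' @return character vector of fixture names.
#' @export
overlapFixtureNames <- function() .FIXTURE_NAMES

#' Load a bundled synthetic overlap region
#'
#' Returns the region as an RNA string: ORF-1 in frame 0 ending with its stop
#' codon, ORF-2 in the +1 frame. The stored file's checksum is verified
#' against the bundled manifest so silent drift fails loudly. These sequences
#' are synthetic stand-ins emulating the documented properties of the
#' corresponding published regions, not transcriptions of them.
#'
#' @param name one of \code{\link{overlapFixtureNames}()}.
#' @return nucleotide string.
#' @examples
#' nchar(loadOverlapFixture("casq2_wt"))   # 81
#' @export
loadOverlapFixture <- function(name) {
  if (!name %in% .FIXTURE_NAMES)
    stop("unknown fixture '", name, "'; see overlapFixtureNames()",
         call. = FALSE)
  dir <- system.file("extdata", "synthetic_overlaps",
                     package = utils::packageName(), mustWork = TRUE)
  path <- file.path(dir, paste0(name, ".fa"))
  manifest <- utils::read.table(file.path(dir, "CHECKSUMS.tsv"), sep = "\t",
                                col.names = c("file", "md5"),
                                stringsAsFactors = FALSE)
  want <- manifest$md5[manifest$file == basename(path)]
  got <- unname(tools::md5sum(path))
  if (!identical(got, want))
    stop("checksum mismatch for fixture '", name,
         "': file may have drifted from the committed sequence",
         call. = FALSE)
  as.character(txSeqs(readTranscripts(path, format = "fasta",
                                      source = "fixture"))[[1]])
}

#' Embed an overlap region in a minimal transcript context
#'
#' Builds a deterministic transcript around a region whose ORF-1 occupies
#' frame 0 and ends with the ORF-1 stop: a short GC-only 5' UTR, an ORF-1
#' (AUG + GC-only filler codons + region) of at least \code{orf1MinLen} nt,
#' an ORF-2 continuation in the region's +1 frame padded to at least
#' \code{orf2MinLen} nt from the canonical start and closed with UAA, and a
#' GC-only 3' UTR. The GC-only filler cannot form AUG or stop codons in any
#' frame, so the region's start-codon inventory is exactly what the scanner
#' and scorer see.
#'
#' @param region overlap-region string (see \code{\link{loadOverlapFixture}}).
#' @param id transcript id.
#' @param gene optional gene symbol for the metadata.
#' @param orf1MinLen,orf2MinLen minimum ORF lengths in nt.
#' @param overlapMin smallest overlap considered when locating the region's
#'   canonical ORF-2 start (default 4).
#' @return a length-1 \code{RNAStringSet} with \code{gene} and \code{source}
#'   metadata.
#' @export
embedOverlap <- function(region, id, gene = NA_character_,
                         orf1MinLen = 153L, orf2MinLen = 153L,
                         overlapMin = 4L) {
  region <- .asRnaString(region)
  L <- nchar(region)
  if (L %% 3L != 0L) stop("region must be whole ORF-1 codons", call. = FALSE)
  if (!substr(region, L - 2L, L) %in% STOP_CODONS)
    stop("region must end with the ORF-1 stop codon", call. = FALSE)
  augs <- framedCodonPositions(region, "AUG", 1L)
  augs <- augs[L - augs >= overlapMin]
  if (length(augs) == 0L)
    stop("region has no ORF-2-frame AUG giving an overlap >= ", overlapMin,
         call. = FALSE)
  canonical <- max(augs)
  utr5 <- strrep("GCC", 5L)
  nFill <- max(0L, ceiling((orf1MinLen - 3L - L) / 3)) + 2L
  orf1 <- paste0("AUG", strrep("GCC", nFill), region)
  orf1_start <- nchar(utr5)
  orf1_end <- orf1_start + nchar(orf1)
  orf2_start <- orf1_end - (L - canonical)
  # ORF-2 continuation: pad to the next ORF-2 codon boundary with C, then GCC
  # codons, closing with UAA so that the canonical ORF-2 is >= orf2MinLen nt
  need <- max(0L, orf2MinLen - (orf1_end - orf2_start))
  phase <- (orf2_start - orf1_end) %% 3L     # nt to the next ORF-2 boundary
  body <- need - phase - 3L                  # full codons between pad and stop
  body <- 3L * max(0L, ceiling(body / 3))
  cont <- paste0(strrep("C", phase), strrep("GCC", body %/% 3L), "UAA")
  seq <- paste0(utr5, orf1, cont, strrep("GCC", 5L))
  ts <- Biostrings::RNAStringSet(stats::setNames(seq, id))
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(
    gene = as.character(gene), source = "fixture")
  ts
}

#' Transcript contexts for the five coupled-gene overlap fixtures
#'
#' The CASQ2-, C22orf32-, CCDC36-, WDR45- and CASQ1-like synthetic overlap
#' regions, each embedded via \code{\link{embedOverlap}}.
#'
#' @return an \code{RNAStringSet} of five transcripts with gene metadata.
#' @export
coupledGeneTranscripts <- function() {
  parts <- lapply(names(.COUPLED_GENES), function(nm)
    embedOverlap(loadOverlapFixture(nm), id = nm,
                 gene = unname(.COUPLED_GENES[nm])))
  do.call(c, parts)
}

#' Reporter-context fixture for the STOP-mutant geometry
#'
#' A deterministic transcript reproducing the reporter-construct geometry
#' used to diagnose coupling: ORF-1 carries the CASQ2-like overlap region and
#' the downstream (reporter) sequence places the next in-frame stop codon
#' exactly 36 nt past the ORF-1 stop, so displacing termination with
#' \code{\link{designStopMutant}} extends ORF-1 by 36 nt. The ORF-2 frame
#' remains open through and beyond the displaced stop.
#'
#' @return a length-1 \code{RNAStringSet}.
#' @export
reporterContextFixture <- function() {
  region <- loadOverlapFixture("casq2_wt")
  L <- nchar(region)
  utr5 <- strrep("GCC", 5L)
  orf1 <- paste0("AUG", strrep("GCC", 24L), region)
  orf1_end <- nchar(utr5) + nchar(orf1)
  canonical <- max(framedCodonPositions(region, "AUG", 1L))
  orf2_start <- orf1_end - (L - canonical)
  # downstream: 11 non-stop ORF-1-frame codons then UGA at +36
  down <- paste0(strrep("GCC", 11L), "UGA")
  # close ORF-2 (>= 153 nt from its canonical start) beyond the displaced stop
  covered <- orf1_end + nchar(down) - orf2_start
  need <- max(0L, 153L - covered)
  phase <- (orf2_start - (orf1_end + nchar(down))) %% 3L
  body <- 3L * max(0L, ceiling((need - phase - 3L) / 3))
  cont <- paste0(strrep("C", phase), strrep("GCC", body %/% 3L), "UAA")
  seq <- paste0(utr5, orf1, down, cont, strrep("GCC", 5L))
  ts <- Biostrings::RNAStringSet(c(casq2_reporter = seq))
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(gene = "CASQ2",
                                               source = "fixture")
  ts
}
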