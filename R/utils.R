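# Low-level sequence helpers. All coordinates are 0-based half-open unless a
# function says otherwise; sequences are RNA-alphabet character strings.

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

# RNA-keyed standard genetic code
geneticCodeRna <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  gc
}

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and maps T to U. Characters outside IUPAC A, C, G, T, U, N are
#' rejected.
#'
#' @param x character vector of nucleotide strings.
#' @param id optional record names used in error messages.
#' @return character vector over A/C/G/U/N.
#' @examples normalizeRna("atgaaataa")
#' @export
normalizeRna <- function(x, id = names(x)) {
  out <- chartr("T", "U", toupper(x))
  bad <- regexpr("[^ACGUN]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    nm <- if (!is.null(id)) id[i] else as.character(i)
    stop("record '", nm, "' contains invalid character '",
         substr(out[i], bad[i], bad[i]), "' at position ", bad[i], call. = FALSE)
  }
  out
}

# split a string into single characters
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# 0-based start positions of codon `codon` at positions == frame (mod 3)
framedCodonPositions <- function(seq, codons, frame) {
  n <- nchar(seq)
  if (n < frame + 3L) return(integer())
  starts <- seq.int(frame, n - 3L, by = 3L)
  hit <- substring(seq, starts + 1L, starts + 3L) %in% codons
  as.integer(starts[hit])
}

# 0-based positions of all occurrences of a trinucleotide in any frame
allCodonPositions <- function(seq, codons) {
  n <- nchar(seq)
  if (n < 3L) return(integer())
  starts <- seq.int(0L, n - 3L)
  as.integer(starts[substring(seq, starts + 1L, starts + 3L) %in% codons])
}

# translate full codons of `seq` starting at 0-based `frame`; trailing partial
# codon ignored; stops rendered as '*'
translateFrame <- function(seq, frame = 0L) {
  n <- nchar(seq)
  k <- (n - frame) %/% 3L
  if (k <= 0L) return("")
  starts <- frame + 3L * (seq_len(k) - 1L)
  cods <- substring(seq, starts + 1L, starts + 3L)
  gc <- geneticCodeRna()
  aa <- gc[cods]
  if (anyNA(aa))
    stop("cannot translate codon containing ambiguity: ",
         cods[which(is.na(aa))[1]], call. = FALSE)
  paste(aa, collapse = "")
}

#' Apply an edit list to a sequence
#'
#' @param parent nucleotide string.
#' @param edits data.frame with 0-based \code{pos}, \code{from}, \code{to}.
#' @return the edited string.
#' @export
applyEdits <- function(parent, edits) {
  v <- s2c(parent)
  if (nrow(edits)) {
    if (!all(v[edits$pos + 1L] == edits$from))
      stop("edit list inconsistent with parent sequence", call. = FALSE)
    v[edits$pos + 1L] <- edits$to
  }
  paste(v, collapse = "")
}

# run a block with a private, restored RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# sequences of a transcript set as plain character, names preserved
txSeqs <- function(ts) {
  out <- as.character(ts)
  names(out) <- names(ts)
  out
}

# gene symbols from mcols, NA-filled
txGenes <- function(ts) {
  mc <- S4Vectors::mcols(ts)
  if (!is.null(mc) && "gene" %in% colnames(mc)) as.character(mc$gene)
  else rep(NA_character_, length(ts))
}
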