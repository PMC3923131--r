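# Mutant-construct designers. All operate on RNA-alphabet strings; overlap
# ops take the region with ORF-1 in `orf1Frame` and ORF-2 in `orf2Frame`
# (0-based frames relative to the string), the region ending at the ORF-1
# stop codon. Edit positions are 0-based.

.newConstruct <- function(name, parent, seq, report,
                          info = list(), seed = NA_integer_) {
  v <- s2c(parent); w <- s2c(seq)
  pos <- which(v != w) - 1L
  edits <- data.frame(pos = pos, from = v[pos + 1L], to = w[pos + 1L],
                      stringsAsFactors = FALSE)
  methods::new("MutantConstruct", name = name, parent = parent, seq = seq,
               edits = edits, report = report, info = info,
               seed = as.integer(seed))
}

.reportRow <- function(constraint, pass, detail = "") {
  data.frame(constraint = constraint, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

#' Design a STOP mutant: displace the ORF-1 termination codon downstream
#'
#' The first nucleotide of the ORF-1 stop codon is substituted U -> C (UAA ->
#' CAA, UAG -> CAG, UGA -> CGA), which abolishes all three stop codons with a
#' single deterministic rule, so that termination moves to the next in-frame
#' stop. The distance from the old stop's first nucleotide to the new one is
#' returned; it is divisible by 3 by construction. STOP mutants are the
#' diagnostic for coupling: transcripts accessed by termination-reinitiation
#' lose ORF-2 expression when termination is displaced.
#'
#' @param seq full transcript sequence.
#' @param orf1End 0-based exclusive end of ORF-1 (one past the stop codon),
#'   e.g. the \code{end} column of \code{\link{findOrfs}}.
#' @param name construct name.
#' @return a \code{\link{MutantConstruct-class}}; the displacement is in
#'   \code{info(x)$next_stop_distance} (see \code{\link{nextStopDistance}}).
#' @export
designStopMutant <- function(seq, orf1End, name = "STOP") {
  seq <- .asRnaString(seq)
  p <- orf1End - 3L                         # first nt of the stop codon
  stopifnot(p >= 0L, orf1End <= nchar(seq))
  cod <- substr(seq, p + 1L, p + 3L)
  if (!cod %in% STOP_CODONS)
    stop("no stop codon at position ", p, " (found ", cod, ")", call. = FALSE)
  v <- s2c(seq)
  v[p + 1L] <- "C"
  mut <- paste(v, collapse = "")
  newcod <- substr(mut, p + 1L, p + 3L)
  if (newcod %in% STOP_CODONS)
    stop("internal error: mutated codon is still a stop", call. = FALSE)
  frame <- p %% 3L
  downstream <- framedCodonPositions(mut, STOP_CODONS, frame)
  downstream <- downstream[downstream >= orf1End]
  if (length(downstream) == 0L)
    stop("no downstream in-frame stop codon within the transcript",
         call. = FALSE)
  dist <- min(downstream) - p
  report <- rbind(
    .reportRow("stop_abolished", TRUE, paste(cod, "->", newcod)),
    .reportRow("next_stop_in_frame", dist %% 3L == 0L,
               paste0("distance ", dist, " nt")))
  .newConstruct(name, seq, mut, report,
                info = list(next_stop_distance = as.integer(dist)))
}

#' @rdname designStopMutant
#' @param x a \code{MutantConstruct} from \code{designStopMutant}.
#' @export
nextStopDistance <- function(x) x@info$next_stop_distance

#' Synonymous de-AUG mutant (GAU -> GAC)
#'
#' Removes ORF-2-frame AUG codons without altering the ORF-1 protein:
#' every ORF-1-frame GAU aspartate codon whose U forms the middle base of a
#' non-kept ORF-2-frame AUG is rewritten to the synonymous GAC. The mutant is
#' verified to leave the ORF-1 translation unchanged and to carry exactly the
#' kept AUG set; a non-kept AUG that no synonymous ORF-1 edit can remove
#' aborts the design (no partial output).
#'
#' @param overlap overlap-region string.
#' @param orf1Frame,orf2Frame 0-based frames of the two ORFs in the string.
#' @param keepAugPositions 0-based start positions of ORF-2-frame AUGs to
#'   retain.
#' @param name construct name.
#' @return a \code{\link{MutantConstruct-class}}.
#' @export
designSynonymousDeAug <- function(overlap, orf1Frame = 0L, orf2Frame = 1L,
                                  keepAugPositions,
                                  name = "GAU/GAC") {
  overlap <- .asRnaString(overlap)
  augs <- framedCodonPositions(overlap, "AUG", orf2Frame)
  if (!all(keepAugPositions %in% augs))
    stop("keepAugPositions must be existing ORF-2-frame AUG starts",
         call. = FALSE)
  drop <- setdiff(augs, keepAugPositions)
  v <- s2c(overlap)
  for (p in drop) {
    q <- p - 1L                              # candidate GAU codon start
    removable <- q >= 0L && (q - orf1Frame) %% 3L == 0L &&
      substr(overlap, q + 1L, q + 3L) == "GAU"
    if (!removable)
      stop("AUG at position ", p,
           " cannot be removed by a synonymous ORF-1 edit (no GAU codon); ",
           "no output produced", call. = FALSE)
    v[q + 3L] <- "C"                         # GAU -> GAC
  }
  mut <- paste(v, collapse = "")
  protSame <- identical(translateFrame(overlap, orf1Frame),
                        translateFrame(mut, orf1Frame))
  remaining <- framedCodonPositions(mut, "AUG", orf2Frame)
  augsExact <- identical(sort(as.integer(remaining)),
                         sort(as.integer(keepAugPositions)))
  report <- rbind(
    .reportRow("orf1_translation_unchanged", protSame),
    .reportRow("aug_set_equals_kept", augsExact,
               paste("remaining:", paste(remaining, collapse = ","))))
  if (!all(report$pass))
    stop("de-AUG design failed verification: ",
         paste(report$constraint[!report$pass], collapse = ", "),
         call. = FALSE)
  .newConstruct(name, overlap, mut, report)
}

#' Knock out specific ORF-2 AUG codons
#'
#' Replaces targeted ORF-2-frame AUG codons (addressed by 5'-to-3' ordinal)
#' verbatim with assigned non-AUG codons, as in the mutant series probing
#' which reinitiation codon is used (AUGs 1, 2, 3 mutated to ACG, AGC, AGA).
#'
#' @param overlap overlap-region string.
#' @param orf2Frame 0-based ORF-2 frame in the string.
#' @param replacements named character vector or list mapping AUG ordinal
#'   (\code{"1"}, \code{"2"}, ...) to replacement codon.
#' @param name construct name.
#' @return a \code{\link{MutantConstruct-class}}; remaining AUG ordinals are
#'   listed in the report.
#' @export
knockoutAugs <- function(overlap, orf2Frame = 1L, replacements,
                         name = "AUG-KO") {
  overlap <- .asRnaString(overlap)
  reps <- unlist(replacements)
  augs <- framedCodonPositions(overlap, "AUG", orf2Frame)
  ords <- as.integer(names(reps))
  if (length(reps) && (anyNA(ords) || any(ords < 1L) ||
                       any(ords > length(augs))))
    stop("AUG ordinal out of range (1..", length(augs), ")", call. = FALSE)
  reps <- toupper(chartr("T", "U", reps))
  if (any(reps == "AUG"))
    stop("replacement codon must not be AUG", call. = FALSE)
  if (length(reps) && any(nchar(reps) != 3L))
    stop("replacement codons must be trinucleotides", call. = FALSE)
  v <- s2c(overlap)
  for (j in seq_along(reps)) {
    p <- augs[ords[j]]
    v[p + 1:3] <- s2c(reps[[j]])
  }
  mut <- paste(v, collapse = "")
  remaining <- framedCodonPositions(mut, "AUG", orf2Frame)
  remOrd <- match(remaining, augs)
  report <- .reportRow("remaining_aug_ordinals", TRUE,
                       if (length(remOrd)) paste(remOrd, collapse = ",")
                       else "none")
  .newConstruct(name, overlap, mut, report)
}

#' Composition-preserving constrained scramble of an overlap region
#'
#' Seeded rejection sampling over permutations of the region with two pinned
#' trinucleotides: the ORF-1 stop codon at its original position and the
#' ORF-2-frame AUG closest to the ORF-1 termination point. An accepted
#' permutation (a) preserves the exact nucleotide multiset, (b) introduces no
#' ORF-1-frame stop upstream of the pinned stop within the region, (c)
#' contains no ORF-1-frame aspartate run of two or more, and (d) contains no
#' ORF-2-frame AUG besides the pinned one -- the scramble retains the
#' wild-type composition and geometry while removing the aspartate runs and
#' surplus reinitiation codons.
#'
#' @param overlap overlap-region string ending with the ORF-1 stop codon.
#' @param orf1Frame,orf2Frame 0-based frames in the string.
#' @param seed RNG seed (same seed, same output).
#' @param maxIter maximum permutations attempted before failing.
#' @param name construct name.
#' @return a \code{\link{MutantConstruct-class}} whose report records all four
#'   checks; failure to accept within \code{maxIter} raises an error with the
#'   iteration count.
#' @export
designScramble <- function(overlap, orf1Frame = 0L, orf2Frame = 1L, seed,
                           maxIter = 2000L, name = "Scramble") {
  overlap <- .asRnaString(overlap)
  L <- nchar(overlap)
  stops1 <- framedCodonPositions(overlap, STOP_CODONS, orf1Frame)
  lastCodon <- orf1Frame + 3L * ((L - orf1Frame) %/% 3L) - 3L
  if (!(lastCodon %in% stops1))
    stop("overlap must end with an ORF-1-frame stop codon", call. = FALSE)
  augs <- framedCodonPositions(overlap, "AUG", orf2Frame)
  if (length(augs) == 0L)
    stop("overlap contains no ORF-2-frame AUG", call. = FALSE)
  pinAug <- max(augs)                        # closest to the termination point
  pin <- c(pinAug + 1:3, lastCodon + 1:3)    # 1-based pinned positions
  v <- s2c(overlap)
  free <- setdiff(seq_len(L), pin)
  aspProt <- function(s) translateFrame(substr(s, orf1Frame + 1L, lastCodon),
                                        0L)
  result <- withSeed(seed, {
    acc <- NULL
    for (it in seq_len(maxIter)) {
      cand <- v
      cand[free] <- v[sample(free)]
      s <- paste(cand, collapse = "")
      if (!identical(framedCodonPositions(s, STOP_CODONS, orf1Frame),
                     as.integer(lastCodon))) next
      if (!identical(framedCodonPositions(s, "AUG", orf2Frame),
                     as.integer(pinAug))) next
      r <- rle(s2c(aspProt(s)) == "D")
      if (any(r$values & r$lengths >= 2L)) next
      acc <- list(seq = s, iter = it)
      break
    }
    acc
  })
  if (is.null(result))
    stop("no accepted permutation within ", maxIter,
         " iterations (seed ", seed, "); reseed or raise maxIter",
         call. = FALSE)
  s <- result$seq
  report <- rbind(
    .reportRow("composition_preserved",
               identical(sort(s2c(overlap)), sort(s2c(s)))),
    .reportRow("no_upstream_orf1_stop",
               identical(framedCodonPositions(s, STOP_CODONS, orf1Frame),
                         as.integer(lastCodon))),
    .reportRow("no_asp_run_ge2",
               !any(with(rle(s2c(aspProt(s)) == "D"),
                         values & lengths >= 2L))),
    .reportRow("single_pinned_aug",
               identical(framedCodonPositions(s, "AUG", orf2Frame),
                         as.integer(pinAug)),
               paste0("pinned AUG at ", pinAug, ", accepted at iteration ",
                      result$iter)))
  .newConstruct(name, overlap, s, report, seed = seed,
                info = list(iterations = result$iter, pinned_aug = pinAug))
}

#' Replace a residue throughout the ORF-1 frame of an overlap region
#'
#' Every non-kept codon of \code{fromAa} in the ORF-1 frame is replaced by a
#' codon of \code{toAa} chosen to minimize the number of nucleotide edits
#' (ties broken by the alphabetically smallest codon, so D -> E rewrites GAU
#' to GAA). Used for the aspartate-to-glutamate (and related) swaps probing
#' whether the aspartate motif, rather than charge alone, drives coupling.
#'
#' @param overlap overlap-region string.
#' @param orf1Frame 0-based ORF-1 frame in the string.
#' @param fromAa,toAa single-letter residues; \code{toAa} must be codable.
#' @param keepOrdinals 1-based ordinals (in ORF-1 reading order) of
#'   \code{fromAa} occurrences to leave untouched.
#' @param orf2Frame frame used to report the change in AUG inventory.
#' @param name construct name.
#' @return a \code{\link{MutantConstruct-class}}.
#' @export
designResidueSwap <- function(overlap, orf1Frame = 0L, fromAa, toAa,
                              keepOrdinals = integer(), orf2Frame = 1L,
                              name = paste0(fromAa, "/", toAa)) {
  overlap <- .asRnaString(overlap)
  gc <- geneticCodeRna()
  toCodons <- sort(names(gc)[gc == toAa])
  if (toAa == "*" || length(toCodons) == 0L)
    stop("no sense codon encodes '", toAa, "'", call. = FALSE)
  L <- nchar(overlap)
  nC <- (L - orf1Frame) %/% 3L
  starts <- orf1Frame + 3L * (seq_len(nC) - 1L)
  cods <- substring(overlap, starts + 1L, starts + 3L)
  isFrom <- gc[cods] == fromAa
  if (!any(isFrom))
    stop("'", fromAa, "' does not occur in the ORF-1 frame", call. = FALSE)
  ordinals <- cumsum(isFrom)
  augsBefore <- framedCodonPositions(overlap, "AUG", orf2Frame)
  v <- s2c(overlap)
  swapped <- integer()
  for (i in which(isFrom)) {
    if (ordinals[i] %in% keepOrdinals) next
    d <- vapply(toCodons, function(tc)
      sum(s2c(tc) != s2c(cods[i])), 0L)
    best <- toCodons[which.min(d)]           # ties: lexicographically smallest
    v[starts[i] + 1:3] <- s2c(best)
    swapped <- c(swapped, i)
  }
  mut <- paste(v, collapse = "")
  newCods <- substring(mut, starts + 1L, starts + 3L)
  okSwap <- all(gc[newCods[swapped]] == toAa)
  okKeep <- all(newCods[isFrom & !(seq_len(nC) %in% swapped)] ==
                cods[isFrom & !(seq_len(nC) %in% swapped)])
  augsAfter <- framedCodonPositions(mut, "AUG", orf2Frame)
  report <- rbind(
    .reportRow("swapped_positions_encode_target", okSwap,
               paste0(length(swapped), " codon(s) swapped")),
    .reportRow("kept_ordinals_untouched", okKeep),
    .reportRow("orf2_aug_inventory", TRUE,
               paste0("before: ", paste(augsBefore, collapse = ","),
                      "; after: ", paste(augsAfter, collapse = ","))))
  .newConstruct(name, overlap, mut, report)
}

#' Per-position differences between two equal-length sequences
#'
#' Labels each mismatch as a transition (A<->G, C<->U) or transversion and
#' summarizes the counts -- e.g. the published A/G overlap mutant differs from
#' wild type by 27 transitions.
#'
#' @param parent,mutant equal-length nucleotide strings.
#' @return data.frame with 0-based \code{pos}, \code{from}, \code{to},
#'   \code{type}; the counts are in \code{attr(x, "summary")}.
#' @export
diffSequences <- function(parent, mutant) {
  parent <- .asRnaString(parent); mutant <- .asRnaString(mutant)
  if (nchar(parent) != nchar(mutant))
    stop("sequences differ in length", call. = FALSE)
  v <- s2c(parent); w <- s2c(mutant)
  pos <- which(v != w) - 1L
  pur <- c("A", "G")
  type <- ifelse((v[pos + 1L] %in% pur) == (w[pos + 1L] %in% pur),
                 "transition", "transversion")
  out <- data.frame(pos = pos, from = v[pos + 1L], to = w[pos + 1L],
                    type = type, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(n_edits = length(pos),
                            n_transitions = sum(type == "transition"),
                            n_transversions = sum(type == "transversion"))
  out
}

#' Write a mutant construct as FASTA with its edit list
#'
#' The description line carries the edit list (\code{pos:from>to}, 0-based);
#' the constraint report is written alongside as TSV when \code{reportPath}
#' is given.
#'
#' @param x a \code{MutantConstruct}.
#' @param path FASTA output path.
#' @param reportPath optional TSV path for the constraint report.
#' @param dna write in the DNA alphabet.
#' @return invisibly, \code{path}.
#' @export
writeConstruct <- function(x, path, reportPath = NULL, dna = FALSE) {
  ed <- x@edits
  desc <- paste0(x@name, " edits=",
                 if (nrow(ed)) paste0(ed$pos, ":", ed$from, ">", ed$to,
                                      collapse = ",") else "none")
  seq <- if (dna) chartr("U", "T", x@seq) else x@seq
  writeLines(c(paste0(">", desc), seq), path)
  if (!is.null(reportPath))
    utils::write.table(x@report, reportPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
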