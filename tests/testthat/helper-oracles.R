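# Independent brute-force references used to validate the scanner, plus
# small random-sequence generators shared across test files.

# Naive cubic-time ORF finder: for every AUG, walk codons until a stop.
oracleOrfs <- function(seq, minLen = 150L) {
  n <- nchar(seq)
  res <- list()
  for (i in 0:(n - 3)) {
    if (substr(seq, i + 1, i + 3) != "AUG") next
    j <- i
    repeat {
      if (j + 3 > n) { j <- NA_integer_; break }
      cod <- substr(seq, j + 1, j + 3)
      if (j > i && cod %in% c("UAA", "UAG", "UGA")) break
      j <- j + 3
    }
    if (is.na(j)) next
    len <- j + 3L - i
    if (len >= minLen && !grepl("N", substr(seq, i + 1, j + 3), fixed = TRUE))
      res[[length(res) + 1L]] <- data.frame(start = i, end = j + 3L,
                                            frame = i %% 3L, nt_len = len)
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_len = integer()))
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive pair enumeration applying the published criteria literally.
oraclePairs <- function(seq, minLen = 150L, omin = 4L, omax = 120L,
                        win = 120L) {
  orfs <- oracleOrfs(seq, minLen = 6L)
  res <- list()
  grp <- paste(orfs$frame, orfs$end)
  for (g1 in unique(grp)) {
    ix <- which(grp == g1)
    o1 <- orfs[ix[which.min(orfs$start[ix])], ]
    if (o1$nt_len < minLen) next
    for (g2 in unique(grp)) {
      if (g2 == g1) next
      jx <- which(grp == g2)
      if (orfs$frame[jx[1]] == o1$frame) next
      e2 <- orfs$end[jx[1]]
      if (e2 <= o1$end) next
      starts <- sort(orfs$start[jx])
      augs <- starts[starts >= o1$end - win & starts <= o1$end - omin]
      if (!length(augs)) next
      can <- max(augs)
      ov <- o1$end - can
      if (ov > omax) next
      if (e2 - can < minLen) next
      res[[length(res) + 1L]] <- data.frame(
        o1s = o1$start, o1e = o1$end, o2s = can, o2e = e2,
        ov = ov, ovmax = o1$end - min(augs))
    }
  }
  if (!length(res))
    return(data.frame(o1s = integer(), o1e = integer(), o2s = integer(),
                      o2e = integer(), ov = integer(), ovmax = integer()))
  df <- do.call(rbind, res)
  df <- df[order(df$o1s, df$o2s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

pairsAsOracleFrame <- function(mp) {
  if (nrow(mp) == 0)
    return(data.frame(o1s = integer(), o1e = integer(), o2s = integer(),
                      o2e = integer(), ov = integer(), ovmax = integer()))
  data.frame(o1s = mp$orf1_start, o1e = mp$orf1_end, o2s = mp$orf2_start,
             o2e = mp$orf2_end, ov = mp$overlap_len,
             ovmax = mp$overlap_len_max)
}

randomRna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Random GAU-rich overlap region ending with an ORF-1 stop; every ORF-2-frame
# AUG in it arises from a GAU codon, so all are synonymously removable.
randomGauRegion <- function(nCodons = 20L) {
  pool <- c("GAU", "GAU", "GAU", "GAA", "CAC", "GGC", "GCU", "AAG", "CUC")
  paste(c(sample(pool, nCodons, replace = TRUE), "UAA"), collapse = "")
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}
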