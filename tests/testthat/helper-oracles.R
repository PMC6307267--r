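# Independent oracles used by the tests. Each is written as plain,
# direct R so it shares no code path with the implementation it checks.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# brute-force degenerate match by explicit set membership per position
iupacMatchOracle <- function(pattern, sequence) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  all(vapply(seq_along(p), function(i) s[i] %in% IUPAC_ORACLE[[p[i]]],
             logical(1)))
}

revcompOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

randomSeqOracle <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# positionwise brute-force candidate count for a 3'-PAM profile on one
# strand of a plain-ACGT sequence
countTargetsOneStrand <- function(seq, pamPattern, spacerLen) {
  L <- nchar(seq)
  plen <- nchar(pamPattern)
  n <- 0L
  for (ps in seq_len(L - plen + 1)) {
    pam <- substr(seq, ps, ps + plen - 1)
    if (ps - spacerLen >= 1 && iupacMatchOracle(pamPattern, pam))
      n <- n + 1L
  }
  n
}

# naive positionwise off-target scan: degenerate PAM match + spacer
# Hamming distance at every offset on both strands; 3'-PAM profiles
offTargetOracle <- function(records, spacer, pamPattern, maxMm) {
  sl <- nchar(spacer)
  plen <- nchar(pamPattern)
  siteLen <- sl + plen
  spc <- strsplit(spacer, "")[[1]]
  hits <- list()
  for (rn in names(records)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") records[[rn]] else revcompOracle(records[[rn]])
      L <- nchar(seq)
      for (ss in seq_len(L - siteLen + 1)) {
        site <- substr(seq, ss, ss + siteLen - 1)
        if (grepl("[^ACGT]", site)) next
        sp <- substr(site, 1, sl)
        pam <- substr(site, sl + 1, siteLen)
        if (!iupacMatchOracle(pamPattern, pam)) next
        mm <- sum(strsplit(sp, "")[[1]] != spc)
        if (mm <= maxMm) {
          pos0 <- if (strand == "+") ss - 1L else L - (ss + sl - 1L)
          hits[[length(hits) + 1]] <- data.frame(
            seq_name = rn, position = pos0, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(seq_name = character(), position = integer(),
                      strand = character(), mismatches = integer()))
  df <- do.call(rbind, hits)
  df[order(df$seq_name, df$position, df$strand), , drop = FALSE]
}

# vectorized variant of the positionwise scan for large genomes:
# accumulates spacer mismatches and PAM degeneracy checks over every
# offset with whole-vector comparisons (3'-PAM profiles)
offTargetOracleFast <- function(records, spacer, pamPattern, maxMm) {
  sl <- nchar(spacer)
  plen <- nchar(pamPattern)
  spc <- strsplit(spacer, "")[[1]]
  pat <- strsplit(pamPattern, "")[[1]]
  hits <- list()
  for (rn in names(records)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") records[[rn]] else revcompOracle(records[[rn]])
      chars <- strsplit(seq, "")[[1]]
      L <- length(chars)
      npos <- L - (sl + plen) + 1
      if (npos < 1) next
      pos <- seq_len(npos)
      mm <- integer(npos)
      for (j in seq_len(sl))
        mm <- mm + (chars[pos + j - 1] != spc[j])
      pamOk <- rep(TRUE, npos)
      for (j in seq_len(plen))
        pamOk <- pamOk & chars[pos + sl + j - 1] %in% IUPAC_ORACLE[[pat[j]]]
      clean <- rep(TRUE, npos)
      nonACGT <- !chars %in% c("A", "C", "G", "T")
      if (any(nonACGT)) {
        cs <- cumsum(nonACGT)
        hi <- pos + sl + plen - 1
        clean <- (cs[hi] - ifelse(pos > 1, cs[pos - 1], 0)) == 0
      }
      sel <- which(pamOk & clean & mm <= maxMm)
      if (length(sel))
        hits[[length(hits) + 1]] <- data.frame(
          seq_name = rn,
          position = if (strand == "+") sel - 1L else L - (sel + sl - 1L),
          strand = strand, mismatches = mm[sel],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(seq_name = character(), position = integer(),
                      strand = character(), mismatches = integer()))
  df <- do.call(rbind, hits)
  df[order(df$seq_name, df$position, df$strand), , drop = FALSE]
}

# plain-R affine-gap DP, score only (Gotoh recurrences written
# independently; no traceback, no shared code with the package)
alignScoreOracle <- function(a, b, match = 5, mismatch = -4,
                             open = 10, ext = 0.5) {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Hamming distance of equal-length strings (test-side copy)
hammingOracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# minimum Hamming distance of a pattern over all windows of a read
minHammingOracle <- function(read, pattern) {
  k <- nchar(pattern)
  if (nchar(read) < k) return(Inf)
  min(vapply(seq_len(nchar(read) - k + 1), function(i)
    hammingOracle(substr(read, i, i + k - 1), pattern), numeric(1)))
}
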