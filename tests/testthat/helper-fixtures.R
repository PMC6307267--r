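# Shared fixture: a 63-nt amplicon with a single SpCas9 target site.
#
# Layout (1-based reference coordinates):
#   1-15   left indicator
#   16-20  pad (CAGTT)
#   21-40  protospacer GATTCAGTGCTGATGATGAT (on the + strand)
#   41-43  PAM AGG
#   44-48  pad (TTGAC)
#   49-63  right indicator
#
# With BE3 (window 13-17 nt upstream of the PAM, i.e. spacer offsets
# 3-7) the window covers reference positions 24-28 and contains exactly
# one editable C, at reference position 25 (spacer offset 4, 16 nt
# upstream of the PAM). A second C sits at spacer offset 9 (reference
# position 30): inside the default 5-nt flanks but outside the window,
# so it is a bystander position.

TEST_LEFT <- "ATGCTAGCTAGGATC"
TEST_RIGHT <- "CGGTAGCTTAGCAAT"
TEST_SPACER <- "GATTCAGTGCTGATGATGAT"
TEST_PAM <- "AGG"
TEST_REF <- paste0(TEST_LEFT, "CAGTT", TEST_SPACER, TEST_PAM, "TTGAC",
                   TEST_RIGHT)
TEST_SITE <- paste0(TEST_SPACER, TEST_PAM)
TEST_WINDOW_C <- 25L    # reference position of the window C
TEST_BYSTANDER_C <- 30L # reference position of the flank C

makeTestConfig <- function(...) {
  analysisConfig(TEST_REF, TEST_SITE, "+", nuclease = "SpCas9",
                 editor = "BE3", ...)
}

# write a QualityScaledDNAStringSet (or plain sequences at Q30) to a
# temporary FASTQ file, optionally gzipped
writeTempFastq <- function(reads, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  if (is.character(reads)) {
    con <- if (gz) gzfile(path, "w") else file(path, "w")
    for (i in seq_along(reads))
      writeLines(c(paste0("@read_", i), reads[i], "+",
                   strrep("?", nchar(reads[i]))), con)
    close(con)
  } else {
    writeFastqReads(reads, path)
  }
  path
}

# substitute single bases of a string at 1-based positions
withBase <- function(seq, pos, base) {
  for (i in seq_along(pos))
    substr(seq, pos[i], pos[i]) <- base[i]
  seq
}

# guaranteed base change (transversion partner) at 1-based positions
flipBase <- function(seq, pos) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  for (p in pos)
    substr(seq, p, p) <- flip[[substr(seq, p, p)]]
  seq
}
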