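SPACER <- "GATTCAGTGCTGATGATGAT"

test_that("a planted on-target site is recovered at zero mismatches", {
  toy <- makeToyGenome(11, nRecords = 1, recordLength = 2000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "TGG",
                              mismatches = 0, strand = "+")))
  hits <- findOffTargets(toy$genome, SPACER, "SpCas9")
  exact <- hits[hits$mismatches == 0, ]
  expect_true(toy$truth$position[1] %in% exact$position)
  expect_true("+" %in% exact$strand)
  expect_identical(exact$site_spacer[exact$position == toy$truth$position[1]],
                   SPACER)
})

test_that("sites beyond the mismatch bound are excluded, planted ones kept", {
  toy <- makeToyGenome(12, nRecords = 2, recordLength = 3000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 0, strand = "+"),
                         list(spacer = SPACER, pam = "TGG",
                              mismatches = 1, strand = "-"),
                         list(spacer = SPACER, pam = "CGG",
                              mismatches = 2, strand = "+"),
                         list(spacer = SPACER, pam = "GGG",
                              mismatches = 3, strand = "-")))
  hits <- findOffTargets(toy$genome, SPACER, "SpCas9", maxMismatches = 2)
  expect_true(all(hits$mismatches <= 2))
  planted <- toy$truth
  for (i in which(planted$mismatches <= 2)) {
    sel <- hits$seq_name == planted$seq_name[i] &
      hits$position == planted$position[i] &
      hits$strand == planted$strand[i]
    expect_identical(sum(sel), 1L)
    expect_identical(hits$mismatches[sel], planted$mismatches[i])
  }
  deep <- planted[planted$mismatches == 3, ]
  expect_false(any(hits$seq_name == deep$seq_name &
                   hits$position == deep$position &
                   hits$strand == deep$strand))
  # summary counters agree with the table
  s <- offTargetSummary(hits)
  expect_identical(s$n_mm0, sum(hits$mismatches == 0))
  expect_identical(s$n_mm2, sum(hits$mismatches == 2))
})

test_that("at zero mismatches the scan equals exact substring search", {
  toy <- makeToyGenome(13, nRecords = 1, recordLength = 10000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "TGG",
                              mismatches = 0, strand = "+"),
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 0, strand = "-")))
  hits <- findOffTargets(toy$genome, SPACER, "SpCas9", maxMismatches = 0)
  seq <- as.character(toy$genome[[1]])
  found <- list()
  # exact-substring oracle: spacer + NGG expanded over the 4 N bases
  for (n1 in c("A", "C", "G", "T")) {
    site <- paste0(SPACER, n1, "GG")
    for (m in gregexpr(site, seq, fixed = TRUE)[[1]])
      if (m > 0) found[[length(found) + 1]] <- c(m - 1, "+")
    rsite <- revcompOracle(site)
    for (m in gregexpr(rsite, seq, fixed = TRUE)[[1]])
      if (m > 0) found[[length(found) + 1]] <- c(m + 2, "-")
  }
  oracle <- do.call(rbind, found)
  expect_identical(nrow(hits), nrow(oracle))
  key <- paste(hits$position, hits$strand)
  okey <- paste(as.integer(oracle[, 1]), oracle[, 2])
  expect_setequal(key, okey)
})

test_that("the scan agrees position-for-position with the Hamming oracle", {
  toy <- makeToyGenome(14, nRecords = 2, recordLength = 5000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 1, strand = "+"),
                         list(spacer = SPACER, pam = "TGG",
                              mismatches = 2, strand = "-")))
  records <- as.list(as.character(toy$genome))
  hits <- findOffTargets(toy$genome, SPACER, "SpCas9", maxMismatches = 2)
  oracle <- offTargetOracle(records, SPACER, "NGG", 2)
  expect_identical(nrow(hits), nrow(oracle))
  expect_identical(paste(hits$seq_name, hits$position, hits$strand,
                         hits$mismatches),
                   paste(oracle$seq_name, oracle$position, oracle$strand,
                         oracle$mismatches))
})

test_that("hit sets are monotone in the mismatch bound", {
  toy <- makeToyGenome(15, nRecords = 1, recordLength = 8000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "GGG",
                              mismatches = 0, strand = "+"),
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 2, strand = "+")))
  key <- function(h) paste(h$seq_name, h$position, h$strand)
  prev <- character(0)
  for (k in 0:3) {
    hits <- findOffTargets(toy$genome, SPACER, "SpCas9", maxMismatches = k)
    expect_true(all(prev %in% key(hits)))
    prev <- key(hits)
  }
})

test_that("reverse-complementing the genome mirrors the hit set", {
  toy <- makeToyGenome(16, nRecords = 1, recordLength = 4000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "TGG",
                              mismatches = 1, strand = "+"),
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 2, strand = "-")))
  hits <- findOffTargets(toy$genome, SPACER, "SpCas9")
  rcGenome <- Biostrings::reverseComplement(toy$genome)
  names(rcGenome) <- names(toy$genome)
  rcHits <- findOffTargets(rcGenome, SPACER, "SpCas9")
  L <- nchar(as.character(toy$genome[[1]]))
  mirrored <- data.frame(
    position = L - (rcHits$position + nchar(SPACER)),
    strand = ifelse(rcHits$strand == "+", "-", "+"),
    mismatches = rcHits$mismatches)
  expect_setequal(paste(hits$position, hits$strand, hits$mismatches),
                  paste(mirrored$position, mirrored$strand,
                        mirrored$mismatches))
})

test_that("sites overlapping non-ACGT genome bases are excluded", {
  seq <- paste0(strrep("T", 30), SPACER, "AGG", strrep("T", 30))
  seqN <- withBase(seq, 35L, "N")  # N inside the planted spacer
  genome <- Biostrings::DNAStringSet(c(ok = seq, masked = seqN))
  hits <- findOffTargets(genome, SPACER, "SpCas9", maxMismatches = 2)
  expect_true("ok" %in% hits$seq_name)
  expect_false("masked" %in% hits$seq_name)
})

test_that("FASTA round-trip and error handling work", {
  fa <- tempfile(fileext = ".fa")
  toy <- makeToyGenome(17, nRecords = 1, recordLength = 1000,
                       plantedSites = list(
                         list(spacer = SPACER, pam = "AGG",
                              mismatches = 0, strand = "+")),
                       path = fa)
  hits <- findOffTargets(fa, SPACER, "SpCas9")
  expect_true(toy$truth$position[1] %in% hits$position)
  expect_error(findOffTargets(tempfile(), SPACER, "SpCas9"),
               "not readable")
  short <- Biostrings::DNAStringSet(c(tiny = "ACGT"))
  expect_warning(h <- findOffTargets(short, SPACER, "SpCas9"),
                 "skipped")
  expect_identical(nrow(h), 0L)
})
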