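test_that("analysisConfig validates geometry and site uniqueness", {
  cfg <- makeTestConfig()
  expect_s4_class(cfg, "AnalysisConfig")
  expect_error(analysisConfig(TEST_REF, "ACGTACGTACGTACGTACGTTGG"),
               "not found")
  dupRef <- paste0(TEST_REF, TEST_SITE, strrep("T", 20))
  expect_error(analysisConfig(dupRef, TEST_SITE), "more than once")
  expect_error(makeTestConfig(flankLeft = 50), "outside the reference")
  expect_error(makeTestConfig(minFrequency = 0), "minFrequency")
})

test_that("indicators are the reference's first and last 15 nt", {
  ref60 <- paste0(TEST_LEFT, strrep("A", 30), TEST_RIGHT)
  ind <- extractIndicators(ref60)
  expect_identical(unname(ind["left"]), substr(ref60, 1, 15))
  expect_identical(unname(ind["right"]), substr(ref60, 46, 60))
  ref30 <- paste0(TEST_LEFT, TEST_RIGHT)
  ind30 <- extractIndicators(ref30)
  expect_identical(paste0(ind30["left"], ind30["right"]), ref30)
  expect_error(extractIndicators(substr(ref30, 1, 29)), "too short")
})

test_that("the indicator filter enforces the one-mismatch bound", {
  ind <- extractIndicators(TEST_REF)
  reads <- c(
    TEST_REF,                      # 0 mismatches
    flipBase(TEST_REF, 3),         # 1 mismatch in the left indicator
    flipBase(TEST_REF, c(3, 7)),   # 2 mismatches in the left indicator
    flipBase(TEST_REF, 55),        # 1 mismatch in the right indicator
    flipBase(TEST_REF, c(55, 60))) # 2 mismatches in the right indicator
  flt <- filterByIndicators(reads, ind["left"], ind["right"])
  expect_identical(unname(flt$stats),
                   c(5L, 3L, 2L))
  # every retained read's best per-indicator Hamming distance is <= 1
  for (q in flt$queries) {
    expect_lte(minHammingOracle(q, ind[["left"]]), 1)
    expect_lte(minHammingOracle(q, ind[["right"]]), 1)
  }
  # the 2-mismatch reads are the dropped ones
  expect_false(any(vapply(flt$queries, function(q)
    minHammingOracle(q, ind[["left"]]) > 1, logical(1))))
})

test_that("reads are trimmed to the indicator span and reoriented", {
  ind <- extractIndicators(TEST_REF)
  # read with adapter tails: trimmed back to the reference span
  tailed <- paste0("GGGGG", TEST_REF, "AAAAA")
  flt <- filterByIndicators(tailed, ind["left"], ind["right"])
  expect_identical(flt$queries, TEST_REF)
  # a reverse-complement read is recognized and trimmed identically
  flt2 <- filterByIndicators(revcompOracle(tailed), ind["left"],
                             ind["right"])
  expect_identical(flt2$queries, TEST_REF)
})

test_that("tallyUnique counts, sorts and applies the frequency cut", {
  expect_identical(tallyUnique(c("A", "A", "B")),
                   data.frame(sequence = c("A", "B"), count = c(2L, 1L),
                              stringsAsFactors = FALSE))
  expect_identical(tallyUnique(c("A", "A", "B"), 2),
                   data.frame(sequence = "A", count = 2L,
                              stringsAsFactors = FALSE))
  expect_identical(nrow(tallyUnique(rep(c("A", "B", "C"), 5), 6)), 0L)
  # ties break lexicographically for determinism
  expect_identical(tallyUnique(c("B", "A"))$sequence, c("A", "B"))
})

test_that("classification follows the windowed hyphen/mismatch rules", {
  cfg <- makeTestConfig()
  # identical rows: wild type
  cl <- classifyAlignment(TEST_REF, TEST_REF, cfg)
  expect_identical(cl$label, "wt")
  expect_false(cl$intended)
  # single window C->T: an intended substitution
  edited <- withBase(TEST_REF, TEST_WINDOW_C, "T")
  al <- globalAlign(TEST_REF, edited)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "substitution")
  expect_true(cl$intended)
  expect_identical(cl$products, "T")
  # bystander C->T in the flank: substitution but not intended
  bys <- withBase(TEST_REF, TEST_BYSTANDER_C, "T")
  al <- globalAlign(TEST_REF, bys)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "substitution")
  expect_false(cl$intended)
  # non-C window mismatch: substitution, not intended
  nonC <- withBase(TEST_REF, 24, "C")  # T -> C at a window position
  al <- globalAlign(TEST_REF, nonC)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "substitution")
  expect_false(cl$intended)
})

test_that("indels are scoped to the window plus flanks", {
  cfg <- makeTestConfig()
  # deletion inside the window
  del <- paste0(substr(TEST_REF, 1, 24), substr(TEST_REF, 26, 63))
  al <- globalAlign(TEST_REF, del)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "deletion")
  # insertion inside the window (extra bases in the query)
  ins <- paste0(substr(TEST_REF, 1, 25), "AA", substr(TEST_REF, 26, 63))
  al <- globalAlign(TEST_REF, ins)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "insertion")
  # hand-built tie (one gap in each row, both in scope) counts as deletion
  refRow <- paste0(substr(TEST_REF, 1, 26), "-", substr(TEST_REF, 27, 63))
  qryRow <- paste0(substr(TEST_REF, 1, 23), "-",
                   substr(TEST_REF, 25, 26), "A", substr(TEST_REF, 27, 63))
  cl <- classifyAlignment(refRow, qryRow, cfg)
  expect_identical(cl$label, "deletion")
  # gaps and mismatches entirely outside the scope leave the read WT
  outSub <- flipBase(TEST_REF, 5)
  al <- globalAlign(TEST_REF, outSub)
  expect_identical(classifyAlignment(al$ref_row, al$query_row, cfg)$label,
                   "wt")
  outDel <- paste0(substr(TEST_REF, 1, 44), substr(TEST_REF, 46, 63))
  al <- globalAlign(TEST_REF, outDel)
  expect_identical(classifyAlignment(al$ref_row, al$query_row, cfg)$label,
                   "wt")
})

test_that("minus-strand targets mirror the window and products", {
  cfg <- analysisConfig(TEST_REF, revcompOracle(TEST_SITE), "-",
                        nuclease = "SpCas9", editor = "BE3")
  # on the minus strand the window covers reference positions 36-40;
  # a minus-strand C->T reads as G->A on the plus strand (G at 38)
  edited <- withBase(TEST_REF, 38, "A")
  al <- globalAlign(TEST_REF, edited)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_identical(cl$label, "substitution")
  expect_true(cl$intended)
  expect_identical(cl$products, "T")
  # the plus-strand window C is now out of window: not intended
  other <- withBase(TEST_REF, TEST_WINDOW_C, "T")
  al <- globalAlign(TEST_REF, other)
  cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
  expect_false(cl$intended)
})

test_that("summarizeRun fills nine fields and conserves read counts", {
  cfg <- makeTestConfig()
  mk <- function(label, intended, count, products = character(0)) {
    d <- S4Vectors::DataFrame(ref_row = TEST_REF, query_row = TEST_REF,
                              count = count, label = label,
                              intended = intended)
    d$products <- list(products)
    d
  }
  # 10 WT reads only
  s <- summarizeRun(mk("wt", FALSE, 10L), 12L, 10L, cfg@editor)
  expect_identical(s@wt, 10L)
  expect_identical(s@insertions + s@deletions + s@withSubstitution, 0L)
  expect_equal(intendedRate(s), 0)
  # 6 intended substitution reads + 4 WT
  aligned <- rbind(mk("substitution", TRUE, 6L, "T"), mk("wt", FALSE, 4L))
  s2 <- summarizeRun(aligned, 10L, 10L, cfg@editor)
  expect_equal(intendedRate(s2), 0.6)
  expect_equal(unname(s2@perProductRate["C>T"]), 0.6)
  expect_identical(ncol(as.data.frame(s2)), 9L)
  expect_error(summarizeRun(mk("wt", FALSE, 0L)[0, ], 0L, 0L, cfg@editor),
               "no analyzable reads")
})

test_that("substitution profiles tabulate weighted base percentages", {
  cfg <- makeTestConfig()
  mkAligned <- function(queries, counts) {
    rows <- lapply(seq_along(queries), function(i) {
      al <- globalAlign(TEST_REF, queries[i])
      cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
      d <- S4Vectors::DataFrame(ref_row = al$ref_row,
                                query_row = al$query_row,
                                count = counts[i], label = cl$label,
                                intended = cl$intended)
      d$products <- list(cl$products)
      d
    })
    do.call(rbind, rows)
  }
  # single C->T substitution read, count 8
  prof <- buildSubstitutionProfile(
    mkAligned(withBase(TEST_REF, TEST_WINDOW_C, "T"), 8L), cfg)
  j <- match(TEST_WINDOW_C, prof@positions)
  expect_equal(unname(prof@basePercent["T", j]), 100)
  expect_equal(unname(prof@transitionRate["C>T", j]), 1.0)
  expect_identical(prof@refBases[j], "C")
  # two substitution reads, counts 3 (C->T) and 1 (C->G)
  prof2 <- buildSubstitutionProfile(
    mkAligned(c(withBase(TEST_REF, TEST_WINDOW_C, "T"),
                withBase(TEST_REF, TEST_WINDOW_C, "G")), c(3L, 1L)), cfg)
  expect_equal(unname(prof2@transitionRate["C>T", j]), 0.75)
  expect_equal(unname(prof2@transitionRate["C>G", j]), 0.25)
  # base percentages sum to 100 at every covered position
  sums <- colSums(prof2@basePercent)
  expect_true(all(abs(sums[!is.na(sums)] - 100) < 0.01))
  # transition rates are NA away from edited-base positions
  expect_true(all(is.na(prof2@transitionRate[, prof2@refBases != "C"])))
  # a WT-only run yields an empty-flagged profile
  prof3 <- buildSubstitutionProfile(mkAligned(TEST_REF, 5L), cfg)
  expect_true(prof3@empty)
})

test_that("translateFrames follows the standard genetic code", {
  expect_identical(translateFrames("ATGAAA")[["0"]], "MK")
  expect_identical(translateFrames("TATGAAA")[["1"]], "MK")
  expect_identical(translateFrames("TAA")[["0"]], "*")
  # trailing partial codons are dropped
  expect_identical(translateFrames("ATGAA")[["0"]], "M")
  expect_error(translateFrames("AT"), ">= 3")
})

test_that("control overlay signs control rates and flags background", {
  cfg <- makeTestConfig()
  mkProf <- function(query, count) {
    al <- globalAlign(TEST_REF, query)
    cl <- classifyAlignment(al$ref_row, al$query_row, cfg)
    d <- S4Vectors::DataFrame(ref_row = al$ref_row,
                              query_row = al$query_row, count = count,
                              label = cl$label, intended = cl$intended)
    d$products <- list(cl$products)
    buildSubstitutionProfile(d, cfg)
  }
  treated <- mkProf(withBase(TEST_REF, TEST_WINDOW_C, "T"), 10L)
  ctlZero <- mkProf(TEST_REF, 10L)
  ov <- controlOverlay(treated, ctlZero)
  expect_false(any(ov@background))
  expect_true(all(ov@controlRate[!is.na(ov@controlRate)] <= 0))
  # control rate equal to the treated rate flags the position
  ctlSame <- mkProf(withBase(TEST_REF, TEST_WINDOW_C, "T"), 10L)
  ov2 <- controlOverlay(treated, ctlSame)
  j <- match(TEST_WINDOW_C, ov2@positions)
  expect_true(ov2@background[j])
  expect_equal(unname(ov2@controlRate["C>T", j]), -1.0)
  # mismatched position grids are rejected
  cfgWide <- makeTestConfig(flankLeft = 6L)
  alWt <- globalAlign(TEST_REF, TEST_REF)
  dWt <- S4Vectors::DataFrame(ref_row = alWt$ref_row,
                              query_row = alWt$query_row, count = 1L,
                              label = "wt", intended = FALSE)
  dWt$products <- list(character(0))
  wide <- buildSubstitutionProfile(dWt, cfgWide)
  expect_error(controlOverlay(treated, wide), "different positions")
})

test_that("the full pipeline recovers simulated ground truth", {
  cfg <- makeTestConfig()
  # clean WT reads only
  simWt <- simulateEditedReads(cfg, n = 50, seed = 9)
  res <- analyzeBaseEdits(as.character(simWt$reads), cfg)
  expect_identical(runSummary(res)@wt, 50L)
  expect_equal(intendedRate(res), 0)
  # mixed outcomes: summary matches the simulator's labels exactly.
  # flankRight reaches past the cut site so cut-site indels are in scope
  cfg <- makeTestConfig(flankRight = 12L)
  sim <- simulateEditedReads(cfg, n = 300, seed = 10,
                             intendedProb = 0.3, bystanderProb = 0.1,
                             indelProb = 0.1)
  res <- analyzeBaseEdits(as.character(sim$reads), cfg)
  s <- runSummary(res)
  expect_identical(s@totalSequences, 300L)
  expect_identical(s@withBothIndicators, 300L)
  expect_identical(s@aboveMinFrequency, 300L)
  truthLabels <- table(sim$truth$expected_label)
  expect_identical(s@wt, as.integer(truthLabels["wt"]))
  expect_identical(s@insertions,
                   as.integer(truthLabels["insertion"]))
  expect_identical(s@deletions, as.integer(truthLabels["deletion"]))
  expect_identical(s@withSubstitution,
                   as.integer(truthLabels["substitution"]))
  expect_identical(s@intendedInWindow, sum(sim$truth$intended))
  # conservation
  expect_identical(s@wt + s@insertions + s@deletions + s@withSubstitution,
                   s@aboveMinFrequency)
})

test_that("intended rate recovers the simulated edit probability", {
  cfg <- makeTestConfig()
  p <- 0.3; n <- 500
  sim <- simulateEditedReads(cfg, n = n, seed = 11, intendedProb = p)
  res <- analyzeBaseEdits(as.character(sim$reads), cfg)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(intendedRate(res) - p), 3 * se)
  # and it matches the per-read truth exactly at zero error
  expect_equal(intendedRate(res), mean(sim$truth$intended))
})

test_that("the minimum-frequency cut gates rare sequences", {
  cfg <- makeTestConfig(minFrequency = 3L)
  reads <- c(rep(TEST_REF, 5),
             rep(withBase(TEST_REF, TEST_WINDOW_C, "T"), 3),
             flipBase(TEST_REF, 27))  # singleton, discarded
  res <- analyzeBaseEdits(reads, cfg)
  s <- runSummary(res)
  expect_identical(s@withBothIndicators, 9L)
  expect_identical(s@aboveMinFrequency, 8L)
  expect_identical(s@wt, 5L)
  expect_identical(s@withSubstitution, 3L)
  expect_equal(intendedRate(res), 3 / 8)
})

test_that("paired-end input is merged before analysis", {
  cfg <- makeTestConfig()
  sim <- simulateEditedReads(cfg, n = 60, seed = 12, intendedProb = 0.5,
                             paired = TRUE)
  r1 <- writeTempFastq(sim$r1, gz = TRUE)
  r2 <- writeTempFastq(sim$r2, gz = TRUE)
  res <- analyzeBaseEdits(r1, cfg, fastq2 = r2)
  expect_identical(unname(res@mergeReport[c("pairs_in", "merged")]),
                   c(60L, 60L))
  expect_identical(runSummary(res)@aboveMinFrequency, 60L)
  expect_equal(intendedRate(res), mean(sim$truth$intended))
})

test_that("a control run is overlaid on the treated profile", {
  cfg <- makeTestConfig()
  sim <- simulateEditedReads(cfg, n = 80, seed = 13, intendedProb = 0.4)
  ctl <- simulateEditedReads(cfg, n = 80, seed = 14)
  res <- analyzeBaseEdits(as.character(sim$reads), cfg,
                          control = as.character(ctl$reads))
  prof <- substitutionProfile(res)
  expect_identical(dim(prof@controlRate), dim(prof@transitionRate))
  expect_false(any(prof@background))
})

test_that("analysis fails loudly when nothing passes the filter", {
  cfg <- makeTestConfig()
  expect_error(analyzeBaseEdits(rep(strrep("ACGT", 20), 3), cfg),
               "no reads survive")
})
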