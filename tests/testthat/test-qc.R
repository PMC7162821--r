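# Assembly QC: circularity, long/short repeats, concatemer flagging,
# GC-skew profiling and origin reorientation.

test_that("circularity detector equals the brute-force oracle", {
  set.seed(201L)
  for (rep in 1:30) {
    n <- sample(2000:20000, 1L)
    s <- randomDna(n)
    if (rep %% 2L == 0L) {               # plant an overlap half the time
      L <- sample(50:400, 1L)
      s <- paste0(s, substr(s, 1L, L))
      n <- n + L
    }
    got <- detectCircularity(s, minOverlap = 50L, maxOverlap = 1000L)
    want <- bruteCircularity(s, 50L, 1000L)
    expect_identical(got$overlap, want)
    expect_identical(got$potentiallyComplete, !is.na(want))
  }
})

test_that("planted terminal repeats are recovered and flag completeness", {
  set.seed(202L)
  s <- randomDna(200000L)
  expect_true(is.na(detectCircularity(s)$overlap))
  s2 <- paste0(s, substr(s, 1L, 120L))
  got <- detectCircularity(s2)
  expect_equal(got$overlap, 120L)
  expect_true(got$potentiallyComplete)
  expect_warning(detectCircularity(randomDna(60L)), "shorter")
})

test_that("long-repeat detector equals the brute-force diagonal scan", {
  set.seed(203L)
  for (rep in 1:12) {
    n <- 6000L
    s <- randomDna(n)
    if (rep > 2L) {                      # plant one or two long repeats
      L <- sample(1000:2000, 1L)
      src <- sample(n - L, 1L)
      dst <- sample(n - L, 1L)
      substr(s, dst, dst + L - 1L) <- substr(s, src, src + L - 1L)
    }
    got <- detectLongDirectRepeats(s, minLen = 1000L)
    want <- bruteDirectRepeats(s, 1000L)
    expect_equal(got[, c("start1", "start2", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("tandem dimers are flagged artifacts with exact corrected length", {
  set.seed(204L)
  unit <- randomDna(250000L)
  s <- paste0(unit, unit)
  hits <- detectLongDirectRepeats(s)
  expect_true(any(hits$length >= 250000L))
  fc <- flagConcatemer(s, hits)
  expect_true(fc$isArtifact)
  expect_equal(fc$correctedLength, 250000L)
  expect_equal(fc$units, 2L)
})

test_that("an isolated 6 kb repeat needs manual review, 4999 bp is silent", {
  set.seed(205L)
  s <- randomDna(60000L)
  substr(s, 40000L, 45999L) <- substr(s, 1000L, 6999L)   # 6 kb copy
  hits <- detectLongDirectRepeats(s, minLen = 5000L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length, 6000L)
  fc <- flagConcatemer(s, hits)
  expect_false(fc$isArtifact)
  expect_true(fc$needsReview)

  s2 <- randomDna(60000L)
  substr(s2, 40000L, 44998L) <- substr(s2, 1000L, 5998L) # 4,999 bp copy
  expect_equal(nrow(detectLongDirectRepeats(s2, minLen = 5000L)), 0L)
  expect_equal(nrow(detectLongDirectRepeats(s2, minLen = 4999L)), 1L)
})

test_that("short-repeat tabulation equals brute force, direct and inverted", {
  set.seed(206L)
  for (rep in 1:10) {
    n <- 1500L
    s <- randomDna(n)
    if (rep > 2L) {                      # plant a direct and an inverted copy
      L <- sample(26:60, 1L)
      substr(s, 800L, 800L + L - 1L) <- substr(s, 100L, 100L + L - 1L)
      Li <- sample(26:60, 1L)
      substr(s, 1200L, 1200L + Li - 1L) <-
        .str(.rc(.chars(substr(s, 300L, 300L + Li - 1L))))
    }
    got <- tabulateShortRepeats(s, minLen = 26L)
    wantD <- bruteDirectRepeats(s, 26L)
    wantI <- bruteInvertedRepeats(s, 26L)
    gd <- got[got$type == "direct", c("start1", "start2", "length")]
    gi <- got[got$type == "inverted", c("start1", "start2", "length")]
    expect_equal(gd, wantD, ignore_attr = TRUE)
    expect_equal(gi, wantI, ignore_attr = TRUE)
  }
})

test_that("a planted 40 bp duplicate is reported, a 25 bp one is not", {
  set.seed(207L)
  s <- randomDna(100000L)
  substr(s, 60000L, 60039L) <- substr(s, 20000L, 20039L)
  got <- tabulateShortRepeats(s)
  dir40 <- got[got$type == "direct" & got$length == 40L, ]
  expect_true(nrow(dir40) >= 1L)
  expect_true(any(dir40$start1 == 20000L & dir40$start2 == 60000L))

  s2 <- randomDna(100000L)
  substr(s2, 60000L, 60024L) <- substr(s2, 20000L, 20024L)  # exactly 25 bp
  got2 <- tabulateShortRepeats(s2)
  expect_false(any(got2$start1 == 20000L & got2$start2 == 60000L))
})

test_that("cumulative skew telescopes to the whole-sequence G-C excess", {
  set.seed(208L)
  s <- randomDna(50000L, gc = 0.55)
  prof <- gcSkew(s, window = 1000L, step = 1000L)
  fr <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
  expect_equal(tail(prof@cumulative, 1L), unname(fr["G"] - fr["C"]))
  expect_equal(length(prof@positions), length(prof@skew))
})

test_that("planted replication modes and breakpoints are recovered", {
  comm <- smallCommunity()
  ctg <- contigs(comm)
  tr <- communityTruth(comm)
  for (id in names(ctg)) {
    truth <- tr$contigs[[id]]$skew
    prof <- classifyReplicationMode(gcSkew(ctg[[id]]))
    expect_equal(skewMode(prof), truth$mode, label = paste("mode of", id))
    if (truth$mode == "bidirectional") {
      bp <- sort(breakpoints(prof))
      expect_equal(length(bp), 2L)
      expect_lt(abs(bp[1L] - truth$ori), 5000)
      expect_lt(abs(bp[2L] - truth$ter), 5000)
    }
  }
})

test_that("degenerate skew profiles classify as none with a warning", {
  s <- randomDna(3000L)
  prof <- gcSkew(s, window = 1000L, step = 500L)
  expect_warning(out <- classifyReplicationMode(prof), "fewer than 10")
  expect_equal(skewMode(out), "none")
})

test_that("reorientation starts at the intergenic gap nearest the origin", {
  comm <- smallCommunity()
  ctg <- contigs(comm)
  tr <- communityTruth(comm)
  id <- "phage01"                         # bidirectional, circularized
  truth <- tr$contigs[[id]]
  prof <- classifyReplicationMode(gcSkew(ctg[[id]]))
  genes <- truth$genes
  rot <- reorientToOrigin(ctg[[id]], prof, genes,
                          overlap = truth$terminalOverlap)
  n <- truth$unitLength
  expect_equal(length(rot$seq), n)        # overlap removed, length conserved
  expect_lt(abs(rot$origin - truth$skew$ori), 5000)
  # the new start is intergenic and near the origin
  inGene <- any(genes$start <= rot$newStart & genes$end >= rot$newStart)
  expect_false(inGene)
  # rotation is a bijection: rotating back restores the trimmed input
  trimmed <- Biostrings::subseq(contigs(comm)[[id]], 1L, n)
  back <- if (rot$newStart == 1L) rot$seq else
    Biostrings::xscat(Biostrings::subseq(rot$seq, n - rot$newStart + 2L, n),
                      Biostrings::subseq(rot$seq, 1L, n - rot$newStart + 1L))
  expect_equal(as.character(back), as.character(trimmed))
})

test_that("non-bidirectional contigs are left unchanged with a warning", {
  set.seed(209L)
  s <- randomDna(30000L)
  prof <- classifyReplicationMode(gcSkew(s))
  genes <- data.frame(start = c(100L, 2000L), end = c(1000L, 3000L))
  expect_warning(rot <- reorientToOrigin(s, prof, genes, overlap = 0L),
                 "unchanged")
  expect_equal(as.character(rot$seq), s)
  expect_error(reorientToOrigin(s, prof, genes, overlap = NA), "circular")
})
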