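# CRISPR array detection, spacer matching tiers, repeat comparison and the
# interaction network.

plantArray <- function(s, pos, repeatSeq, spacers) {
  arr <- repeatSeq
  for (sp in spacers) arr <- paste0(arr, sp, repeatSeq)
  substr(s, pos, pos + nchar(arr) - 1L) <- arr
  list(seq = s, start = pos, end = pos + nchar(arr) - 1L,
       len = nchar(arr))
}

test_that("planted arrays are recovered with exact structure", {
  set.seed(501L)
  for (rep in 1:6) {
    n <- 150000L
    s <- randomDna(n)
    repLen <- sample(21:45, 1L)
    spLen <- sample(28:40, 1L)
    nRep <- sample(3:10, 1L)
    repSeq <- randomDna(repLen)
    spacers <- vapply(seq_len(nRep - 1L), function(i) randomDna(spLen), "")
    pl <- plantArray(s, 60000L, repSeq, spacers)
    arrays <- detectArrays(pl$seq, contigId = "t")
    expect_equal(length(arrays), 1L)
    a <- arrays[[1L]]
    expect_equal(nrow(repeats(a)), nRep)
    expect_lte(abs(a@start - pl$start), 2L)
    expect_lte(abs(a@end - pl$end), 2L)
    expect_equal(consensusRepeat(a), repSeq)
    expect_equal(spacers(a)$seq, spacers)
  }
})

test_that("arrays below the repeat-count floor are not called", {
  set.seed(502L)
  s <- randomDna(100000L)
  pl <- plantArray(s, 50000L, randomDna(32L),
                   vapply(1:1, function(i) randomDna(34L), ""))  # 2 repeats
  expect_length(detectArrays(pl$seq, contigId = "t", minRepeats = 3L), 0L)
  # the same locus is found once the floor is met
  pl3 <- plantArray(s, 50000L, randomDna(32L),
                    vapply(1:2, function(i) randomDna(34L), ""))  # 3 repeats
  expect_length(detectArrays(pl3$seq, contigId = "t", minRepeats = 3L), 1L)
})

test_that("random sequence yields no arrays (false-positive bound)", {
  set.seed(503L)
  nArr <- 0L
  for (rep in 1:10) nArr <- nArr + length(detectArrays(randomDna(200000L)))
  expect_equal(nArr, 0L)               # < 0.05 arrays per Mb over 2 Mb
})

test_that("spacer matching equals a brute-force Hamming scan", {
  set.seed(504L)
  for (rep in 1:10) {
    target <- randomDna(20000L)
    spacer <- randomDna(34L)
    if (rep %% 2L == 0L) {             # plant a mutated occurrence
      mm <- sample(0:3, 1L)
      v <- .chars(spacer)
      if (mm > 0L)
        for (q in sample(34L, mm))
          v[q] <- sample(setdiff(c("A", "C", "G", "T"), v[q]), 1L)
      pos <- sample(10000L, 1L)
      substr(target, pos, pos + 33L) <- .str(v)
    }
    spTab <- data.frame(id = "sp1", seq = spacer, arrayId = "a1",
                        sourceContig = "src")
    got <- matchSpacers(spTab, Biostrings::DNAStringSet(c(t1 = target)),
                        strictMismatch = 3L)   # report everything <= 3
    want <- bruteSpacerScan(spacer, target, maxMm = 3L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$target_start, got$strand), ]
      expect_equal(got$target_start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("the strict tier needs >24 bp alignment and <=1 mismatch", {
  set.seed(505L)
  target <- randomDna(50000L)
  sp25 <- substr(target, 1000L, 1024L)   # 25 bp exact occurrence
  sp24 <- substr(target, 2000L, 2023L)   # 24 bp exact occurrence
  spTab <- data.frame(id = c("s25", "s24"), seq = c(sp25, sp24),
                      arrayId = "a1", sourceContig = "src")
  got <- matchSpacers(spTab, Biostrings::DNAStringSet(c(t1 = target)))
  expect_true(any(got$spacer_id == "s25" & got$tier == "strict" &
                    got$align_len == 25L))
  expect_false(any(got$spacer_id == "s24"))

  # 1 mismatch stays strict; 2 mismatches alone are dropped, but are
  # rescued into the expanded tier when the array has a strict anchor
  sp <- randomDna(34L)
  v1 <- .chars(sp); v1[5L] <- setdiff(c("A","C","G","T"), v1[5L])[1L]
  v2 <- .chars(sp); for (q in c(3L, 9L))
    v2[q] <- setdiff(c("A","C","G","T"), v2[q])[1L]
  t2 <- randomDna(30000L)
  substr(t2, 5000L, 5033L) <- .str(v1)
  substr(t2, 9000L, 9033L) <- .str(v2)
  tS <- Biostrings::DNAStringSet(c(t1 = t2))
  one <- matchSpacers(data.frame(id = "m1", seq = sp, arrayId = "a1",
                                 sourceContig = "src"), tS)
  expect_setequal(one$tier[one$target_start == 5000L], "strict")
  expect_setequal(one$tier[one$target_start == 9000L], "expanded")
  # without the strict anchor the 2-mismatch hit is not reported
  t3 <- randomDna(30000L)
  substr(t3, 9000L, 9033L) <- .str(v2)
  none <- matchSpacers(data.frame(id = "m1", seq = sp, arrayId = "a1",
                                  sourceContig = "src"),
                       Biostrings::DNAStringSet(c(t1 = t3)))
  expect_equal(nrow(none), 0L)
})

test_that("planted community links are recovered with exact tiers", {
  comm <- smallCommunity()
  arrays <- smallArrays()
  m <- matchSpacers(arrays, contigs(comm), targetArrays = arrays)
  links <- communityTruth(comm)$links
  for (k in seq_len(nrow(links))) {
    lk <- links[k, ]
    hit <- m[m$target_contig == lk$targetContig &
               m$target_start == lk$start, ]
    expect_equal(nrow(hit), 1L, label = paste("link", lk$spacer_id))
    expect_equal(hit$mismatches, lk$mismatches)
    expect_equal(hit$strand, lk$strand)
    expect_equal(hit$tier, if (lk$mismatches <= 1L) "strict" else "expanded")
    expect_equal(hit$source_contig, lk$sourceContig)
  }
})

test_that("repeat comparison finds identity in both orientations", {
  set.seed(506L)
  r <- randomDna(30L)
  expect_equal(compareRepeats(r, r)$identity, 1)
  expect_equal(compareRepeats(r, r)$orientation, "forward")
  rc <- .str(.rc(.chars(r)))
  cmp <- compareRepeats(r, rc)
  expect_equal(cmp$identity, 1)
  expect_equal(cmp$orientation, "reverse")
  # unrelated repeats stay near background identity
  ids <- replicate(30L, compareRepeats(randomDna(30L), randomDna(30L))$identity)
  expect_true(all(ids <= 0.6))
})

test_that("the network collapses matches, conserving counts and styles", {
  m <- data.frame(
    spacer_id = sprintf("s%d", 1:6), array_id = "a1",
    source_contig = c("h1", "h1", "h1", "p3", "p3", "p4"),
    target_contig = c("p1", "p1", "p1", "p4", "p4", "p2"),
    target_start = 1:6, target_end = 35:40, strand = "+",
    align_len = 34L, mismatches = c(0L, 1L, 2L, 3L, 2L, 0L),
    tier = c("strict", "strict", "expanded", "expanded", "expanded",
             "strict"))
  net <- buildNetwork(m, nodeTypes = c(h1 = "bacteria", p1 = "phage",
                                       p3 = "phage", p4 = "phage"))
  e <- net$edges
  expect_equal(nrow(e), 3L)
  expect_equal(sum(e$nStrict) + sum(e$nExpanded), nrow(m))
  h1p1 <- e[e$source == "h1", ]
  expect_equal(h1p1$nStrict, 2L)
  expect_equal(h1p1$nExpanded, 1L)
  expect_equal(h1p1$style, "solid")
  p3p4 <- e[e$source == "p3", ]
  expect_equal(p3p4$style, "dashed")      # only 2-3 mismatch support
  expect_equal(p3p4$sourceType, "phage")
  # self-targeting is reported separately
  m2 <- rbind(m, data.frame(spacer_id = "s7", array_id = "a2",
                            source_contig = "p1", target_contig = "p1",
                            target_start = 7L, target_end = 41L,
                            strand = "+", align_len = 34L, mismatches = 0L,
                            tier = "strict"))
  net2 <- buildNetwork(m2)
  expect_equal(nrow(net2$selfTargeting), 1L)
  expect_equal(nrow(net2$edges), 3L)
  # empty input gives an empty network
  expect_equal(nrow(buildNetwork(m[0L, ])$edges), 0L)
})
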