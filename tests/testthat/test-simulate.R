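# Synthetic-community generator: determinism, planted-feature
# self-consistency and spec validation.

test_that("identical spec and seed give byte-identical outputs", {
  spec <- communitySpec(seed = 9L, nPhage = 2L, nHost = 1L, nPlasmid = 0L,
                        phageLengthRange = c(40000L, 50000L),
                        hostLengthRange = c(40000L, 40000L))
  d1 <- file.path(tempdir(), "comm_a")
  d2 <- file.path(tempdir(), "comm_b")
  writeCommunity(generateCommunity(spec), d1)
  writeCommunity(generateCommunity(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = paste("bytes of", f))
  }
})

test_that("terminal overlap plants an exact prefix-suffix duplicate", {
  spec <- communitySpec(seed = 4L, nPhage = 1L, nHost = 0L, nPlasmid = 0L,
                        phageLengthRange = c(50000L, 50000L),
                        terminalOverlapBp = 120L)
  comm <- generateCommunity(spec)
  tr <- communityTruth(comm)$contigs$phage01
  expect_equal(tr$terminalOverlap, 120L)
  s <- as.character(contigs(comm)[["phage01"]])
  n <- nchar(s)
  expect_equal(n, tr$unitLength + 120L)
  expect_identical(substr(s, 1L, 120L), substr(s, n - 119L, n))
})

test_that("a 2-unit concatemer emits identical tandem halves", {
  spec <- communitySpec(seed = 4L, nPhage = 2L, nHost = 0L, nPlasmid = 0L,
                        phageLengthRange = c(60000L, 60000L),
                        params = list(concatemerUnitLength = 60000L))
  comm <- generateCommunity(spec)
  tr <- communityTruth(comm)$contigs$phage02
  expect_equal(tr$concatemerUnits, 2L)
  s <- as.character(contigs(comm)[["phage02"]])
  expect_equal(nchar(s), 2L * tr$unitLength)
  expect_identical(substr(s, 1L, tr$unitLength),
                   substr(s, tr$unitLength + 1L, 2L * tr$unitLength))
})

test_that("planted features are found verbatim at recorded coordinates", {
  comm <- smallCommunity()
  ctg <- contigs(comm)
  tr <- communityTruth(comm)
  for (id in names(tr$contigs)) {
    ct <- tr$contigs[[id]]
    s <- as.character(ctg[[id]])
    for (arr in ct$arrays) {
      for (k in seq_along(arr$repeatStarts))
        expect_identical(substr(s, arr$repeatStarts[k], arr$repeatEnds[k]),
                         arr$repeatSeq)
      for (k in seq_len(nrow(arr$spacers)))
        expect_identical(substr(s, arr$spacers$start[k], arr$spacers$end[k]),
                         arr$spacers$seq[k])
    }
  }
  # protospacers occur at the recorded Hamming distance from their spacer
  links <- tr$links
  spacerSeq <- function(lk) {
    arr <- tr$contigs[[lk$sourceContig]]$arrays[[1L]]
    arr$spacers$seq[match(lk$spacer_id, arr$spacers$id)]
  }
  for (k in seq_len(nrow(links))) {
    lk <- links[k, ]
    planted <- substr(as.character(ctg[[lk$targetContig]]), lk$start, lk$end)
    if (lk$strand == "-") planted <- .str(.rc(.chars(planted)))
    sp <- spacerSeq(lk)
    expect_equal(sum(.chars(planted) != .chars(sp)), lk$mismatches,
                 label = paste("hamming distance of", lk$spacer_id))
  }
})

test_that("GC content of large genomes is within 2 points of the target", {
  comm <- smallCommunity()
  gc <- Biostrings::letterFrequency(contigs(comm), "GC", as.prob = TRUE)
  target <- communitySpecOf(comm)@genomes$gcContent
  expect_true(all(abs(gc - target) <= 0.02))
})

test_that("contradictory specs are rejected with the offending field named", {
  spec <- communitySpec(seed = 1L, nPhage = 2L, nHost = 1L)
  bad <- spec
  bad@plantedArrays$nRepeats[1L] <- 100000L   # array longer than the genome
  expect_error(generateCommunity(bad), "array longer than genome")
  expect_error(communitySpec(seed = 1L, nPhage = 2L, nHost = 1L,
                             gcContent = 1.5), "gcContent")
  bad2 <- spec
  bad2@genomes$length[1L] <- -5L
  expect_error(validObject(bad2), "positive")
})

test_that("plantCrisprLink extends the array and plants exact protospacers", {
  spec <- communitySpec(seed = 21L, nPhage = 4L, nHost = 1L, nPlasmid = 0L,
                        phageLengthRange = c(150000L, 200000L))
  comm <- generateCommunity(spec)
  set.seed(55L)
  comm2 <- plantCrisprLink(comm, "phage03", "phage01", nSpacers = 2L,
                           mismatches = c(0L, 1L))
  tr <- communityTruth(comm2)
  arr <- tr$contigs$phage03$arrays[[1L]]
  arr0 <- communityTruth(comm)$contigs$phage03$arrays[[1L]]
  expect_equal(arr$nRepeats, arr0$nRepeats + 2L)
  links <- tr$links
  newLinks <- links[links$targetContig == "phage01" &
                      links$sourceContig == "phage03", ]
  expect_equal(nrow(newLinks), 2L)
  expect_setequal(newLinks$mismatches, c(0L, 1L))
  s <- as.character(contigs(comm2)[["phage01"]])
  for (k in seq_len(nrow(newLinks))) {
    lk <- newLinks[k, ]
    planted <- substr(s, lk$start, lk$end)
    if (lk$strand == "-") planted <- .str(.rc(.chars(planted)))
    sp <- arr$spacers$seq[match(lk$spacer_id, arr$spacers$id)]
    expect_equal(sum(.chars(planted) != .chars(sp)), lk$mismatches)
  }
  # mismatch-0 spacer occurs verbatim in the target
  mm0 <- newLinks[newLinks$mismatches == 0L, ][1L, ]
  sp0 <- arr$spacers$seq[match(mm0$spacer_id, arr$spacers$id)]
  hits <- bruteSpacerScan(sp0, s, maxMm = 0L)
  expect_true(mm0$start %in% hits$start)
})

test_that("simulated tRNA tables carry the planted rank correlation", {
  tab <- simulateTrnaTable(n = 200L, rho = 0.6, seed = 31L)
  rho <- cor(tab$length, tab$trna, method = "spearman")
  expect_lt(abs(rho - 0.6), 0.1)
})
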