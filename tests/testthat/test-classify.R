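# Taxonomy voting, marker detection, prophage transitions and the
# element-type rule engine.

mkHits <- function(phyla, keywords = NULL, bitscores = NULL,
                   starts = NULL, width = 900L) {
  n <- length(phyla)
  if (is.null(keywords)) keywords <- rep("some protein", n)
  if (is.null(bitscores)) bitscores <- rep(120, n)
  if (is.null(starts)) starts <- seq(1L, by = 1000L, length.out = n)
  data.frame(contig_id = "c", gene_id = sprintf("g%03d", seq_len(n)),
             gene_start = starts, gene_end = starts + width - 1L,
             gene_strand = "+",
             domain = ifelse(phyla == "", "", "Bacteria"), phylum = phyla,
             class = "", order = "", family = "", genus = "",
             keyword = keywords, bitscore = bitscores)
}

test_that("taxonomy voting needs a strict majority per rank", {
  v <- voteTaxonomy(mkHits(c(rep("Firmicutes", 6L), rep("Proteobacteria", 4L))))
  expect_equal(v$winner[v$rank == "phylum"], "Firmicutes")
  # exactly 50% is not a winner
  v2 <- voteTaxonomy(mkHits(c(rep("Firmicutes", 5L), rep("Proteobacteria", 5L))))
  expect_true(is.na(v2$winner[v2$rank == "phylum"]))
  # 51% wins
  v3 <- voteTaxonomy(mkHits(c(rep("Firmicutes", 51L), rep("Proteobacteria", 49L))))
  expect_equal(v3$winner[v3$rank == "phylum"], "Firmicutes")
  # no hits: winnerless at every rank
  v4 <- voteTaxonomy(emptyHits())
  expect_true(all(is.na(v4$winner)))
  # abstaining genes are excluded from the denominator
  v5 <- voteTaxonomy(mkHits(c(rep("Firmicutes", 3L), rep("", 7L))))
  expect_equal(v5$winner[v5$rank == "phylum"], "Firmicutes")
  expect_equal(v5$votes[v5$rank == "phylum"], 3L)
})

test_that("marker lexicon matching is case-insensitive and class-based", {
  h <- mkHits(rep("", 3L),
              keywords = c("Large Terminase Subunit", "hypothetical protein",
                           "major CAPSID protein"))
  mk <- findPhageMarkers(h)
  expect_setequal(mk, c("terminase", "capsid"))
  expect_length(findPhageMarkers(mkHits("", keywords = "DNA polymerase")), 0L)
})

test_that("hypothetical fraction counts missing and hypothetical genes", {
  h <- mkHits(rep("", 4L), keywords = rep("hypothetical protein", 4L))
  expect_equal(hypotheticalFraction(h), 1)
  h2 <- mkHits(rep("", 4L), keywords = c("hypothetical protein", "portal",
                                         "DNA ligase", "helicase"))
  expect_equal(hypotheticalFraction(h2), 0.25)
  expect_equal(hypotheticalFraction(h2, nGenes = 8L), 5 / 8)  # 4 missing
  expect_error(hypotheticalFraction(h2[0L, ], nGenes = 0L), "undefined")
})

test_that("prophage transitions are located near the planted boundaries", {
  comm <- smallCommunity()
  tr <- communityTruth(comm)$contigs$host01
  h <- annotations(comm)
  h <- h[h$contig_id == "host01", ]
  b <- detectProphageTransition(h, tr$length)
  expect_equal(length(b), 2L)
  expect_lt(abs(b[1L] - tr$prophage$start), 5000)
  expect_lt(abs(b[2L] - tr$prophage$end), 5000)
})

test_that("uniform contigs and short flanks yield no prophage transition", {
  set.seed(401L)
  # uniformly phage-like contig
  n <- 60L
  h <- mkHits(rep("", n), keywords = rep("hypothetical protein", n),
              bitscores = rep(50, n))
  expect_null(detectProphageTransition(h, 60000L))
  # bacterial flank of only 10 kb is below the 20 kb window
  kw <- c(rep("DNA gyrase subunit A", 10L), rep("hypothetical protein", 50L))
  h2 <- mkHits(rep("", 60L), keywords = kw, bitscores = rep(150, 60L))
  expect_null(detectProphageTransition(h2, 60000L))
})

test_that("the rule engine follows the documented rule order", {
  voteNone <- voteTaxonomy(emptyHits())
  voteBact <- voteTaxonomy(mkHits(rep("Firmicutes", 10L)))
  # rule 3: markers => phage (plasmid genes present but markers win rule order
  # only when no plasmid rule fires; plasmid rule requires NO markers)
  r <- classifyElement("c", 300000L, voteNone, c("terminase", "capsid"),
                       0.7)
  expect_equal(elementType(r), "phage")
  # rule 2: plasmid genes and no markers => plasmid_like
  r2 <- classifyElement("c", 300000L, voteBact, character(), 0.2,
                        plasmidGenes = c("ParA partitioning protein",
                                         "conjugative transfer protein TraG"))
  expect_equal(elementType(r2), "plasmid_like")
  # plasmid genes plus markers: the phage rule wins
  r2b <- classifyElement("c", 300000L, voteBact, "terminase", 0.2,
                         plasmidGenes = "ParA partitioning protein")
  expect_equal(elementType(r2b), "phage")
  # rule 1 precedes everything
  r3 <- classifyElement("c", 300000L, voteNone, c("terminase"), 0.8,
                        plasmidGenes = "relaxase MobA",
                        prophageBoundaries = c(40000, 260000))
  expect_equal(elementType(r3), "prophage_containing")
  # markerless phage: no domain winner + high hypothetical fraction
  r4 <- classifyElement("c", 300000L, voteNone, character(), 0.65)
  expect_equal(elementType(r4), "phage")
  # same but low hypothetical fraction => unknown
  r5 <- classifyElement("c", 300000L, voteNone, character(), 0.3)
  expect_equal(elementType(r5), "unknown")
  # domain winner blocks the markerless phage rule
  r6 <- classifyElement("c", 300000L, voteBact, character(), 0.9)
  expect_equal(elementType(r6), "unknown")
  # placement override rescues a markerless candidate
  r7 <- classifyElement("c", 300000L, voteBact, character(), 0.3,
                        phageOverride = TRUE)
  expect_equal(elementType(r7), "phage")
})

test_that("the 200 kb gate admits only CRISPR-bearing short contigs", {
  voteNone <- voteTaxonomy(emptyHits())
  rej <- classifyElement("c", 180000L, voteNone, "terminase", 0.7,
                         crisprPresent = FALSE)
  expect_false(rej@retained)
  expect_false(rej@lengthException)
  kept <- classifyElement("c", 180000L, voteNone, "terminase", 0.7,
                          crisprPresent = TRUE)
  expect_true(kept@retained)
  expect_true(kept@lengthException)
  expect_equal(elementType(kept), "phage")
  big <- classifyElement("c", 200000L, voteNone, "terminase", 0.7)
  expect_true(big@retained)
  expect_false(big@lengthException)
})

test_that("classification is a pure function with a faithful rule trace", {
  voteBact <- voteTaxonomy(mkHits(rep("Firmicutes", 10L)))
  a <- classifyElement("c", 250000L, voteBact, "portal", 0.5)
  b <- classifyElement("c", 250000L, voteBact, "portal", 0.5)
  expect_identical(elementType(a), elementType(b))
  expect_identical(ruleTrace(a), ruleTrace(b))
  expect_match(paste(ruleTrace(a), collapse = " "), "rule 3")
})

test_that("planted element types are recovered across the community", {
  comm <- smallCommunity()
  ctg <- contigs(comm)
  annot <- annotations(comm)
  tr <- communityTruth(comm)
  arrayIds <- unique(vapply(smallArrays(), function(a) a@contigId, ""))
  for (id in names(ctg)) {
    h <- annot[annot$contig_id == id, ]
    res <- classifyElement(
      id, length(ctg[[id]]), voteTaxonomy(h), findPhageMarkers(h),
      hypotheticalFraction(h), findPlasmidGenes(h),
      detectProphageTransition(h, length(ctg[[id]])),
      crisprPresent = id %in% arrayIds)
    want <- switch(tr$contigs[[id]]$role,
                   phage = "phage", plasmid = "plasmid_like",
                   host = if (!is.null(tr$contigs[[id]]$prophage))
                     "prophage_containing" else "unknown")
    expect_equal(elementType(res), want, label = paste("type of", id))
  }
})
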