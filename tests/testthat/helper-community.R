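# Shared fixtures: a mid-sized community generated once per test run.
# Sizes are scaled down from the defaults so module tests stay fast; the
# full-scale community is exercised in test-acceptance.R.

.fixtures <- new.env(parent = emptyenv())

smallCommunity <- function() {
  if (is.null(.fixtures$small)) {
    spec <- communitySpec(seed = 101L, nPhage = 5L, nHost = 3L,
                          nPlasmid = 1L,
                          phageLengthRange = c(200000L, 300000L))
    .fixtures$small <- generateCommunity(spec)
  }
  .fixtures$small
}

emptyHits <- function() {
  data.frame(contig_id = character(), gene_id = character(),
             gene_start = integer(), gene_end = integer(),
             gene_strand = character(), domain = character(),
             phylum = character(), class = character(), order = character(),
             family = character(), genus = character(),
             keyword = character(), bitscore = numeric())
}

smallArrays <- function() {
  if (is.null(.fixtures$smallArrays)) {
    comm <- smallCommunity()
    ctg <- contigs(comm)
    arrays <- list()
    for (id in names(ctg))
      arrays <- c(arrays, detectArrays(ctg[[id]], contigId = id))
    .fixtures$smallArrays <- arrays
  }
  .fixtures$smallArrays
}
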