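# Synthetic phage-host community generator. Every feature the downstream
# modules detect (terminal overlaps, concatemer artifacts, GC skew, recoded
# stop codons, CRISPR arrays, spacer-protospacer links, taxonomy-vote
# profiles, protein-family structure) is planted here with a machine-readable
# ground-truth ledger, so the whole pipeline is testable without external
# data.

.PHYLA <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria",
            "Verrucomicrobia", "Chloroflexi")

.MARKER_KEYWORDS <- c("large terminase subunit", "major capsid protein",
                      "portal protein", "tail fiber protein",
                      "baseplate wedge protein")

.PHAGE_FUNCTIONAL <- c("DNA polymerase", "DNA helicase",
                       "ribonucleotide reductase", "thymidylate synthase",
                       "HNH endonuclease", "sigma factor",
                       "RNA polymerase subunit", "peptide deformylase",
                       "lysozyme-like protein", "DNA ligase")

.BACT_FUNCTIONAL <- c("DNA gyrase subunit A", "30S ribosomal protein S4",
                      "ATP synthase subunit beta", "elongation factor Tu",
                      "citrate synthase", "cell division protein FtsZ",
                      "peptidoglycan glycosyltransferase",
                      "ABC transporter permease",
                      "RNA polymerase beta subunit", "chaperonin GroEL")

.PLASMID_KEYWORDS <- c("ParA partitioning protein", "ParB partitioning protein",
                       "conjugative transfer protein TraG",
                       "relaxase MobA",
                       "type IV secretion system protein VirB4")

#' Build a synthetic community specification
#'
#' Lays out a community of huge-phage, bacterial-host and plasmid-like
#' contigs together with every genomic feature to plant. Assignments are
#' deterministic functions of the counts (no randomness lives here; all
#' randomness is drawn in [generateCommunity()] from the single seed):
#' phage lengths are spread evenly across `phageLengthRange`; replication
#' skew modes cycle bidirectional / unidirectional / none; every fifth phage
#' starting at the second uses the TAG-recoded genetic code; odd-indexed
#' phages carry a terminal direct repeat (circularized assembly); the last
#' phage is emitted as a tandem concatemer artifact of a 250 kb unit; two
#' phages and three hosts carry CRISPR arrays, wired with
#' spacer-protospacer links at 0-3 mismatches; the first host contains an
#' integrated prophage flanked by bacterial sequence.
#'
#' @param seed Integer seed for [generateCommunity()].
#' @param nPhage,nHost,nPlasmid Number of contigs per role.
#' @param phageLengthRange Min/max phage genome length (bp).
#' @param hostLengthRange Min/max host contig length (bp).
#' @param gcContent Target GC fraction of all genomes.
#' @param terminalOverlapBp Terminal direct-repeat length for circularized
#'   phages.
#' @param params Named list of overrides for generator parameters (skew
#'   amplitude `skewAmp`, TAG usage `tagRate` in recoded genomes, gene-length
#'   log-normal `geneMeanlog`/`geneSdlog`, intergenic `gapRange`, annotation
#'   vote fractions, protein-family layout, ...).
#' @return A validated [CommunitySpec-class].
#' @examples
#' spec <- communitySpec(seed = 1, nPhage = 2, nHost = 1,
#'                       phageLengthRange = c(50000, 60000))
#' @export
communitySpec <- function(seed = 1L, nPhage = 10L, nHost = 5L, nPlasmid = 1L,
                          phageLengthRange = c(200000L, 700000L),
                          hostLengthRange = c(280000L, 420000L),
                          gcContent = 0.5, terminalOverlapBp = 120L,
                          params = list()) {
  stopifnot(nPhage >= 1L, nHost >= 0L, nPlasmid >= 0L,
            phageLengthRange[1] > 0, diff(phageLengthRange) >= 0)
  p <- list(skewAmp = 0.05, tagRate = 0.025,
            geneMeanlog = log(300), geneSdlog = 0.45,
            geneLenClip = c(70L, 2000L), gapRange = c(20L, 150L),
            oriFrac = 0.25, terFrac = 0.75,
            phageHypoFrac = 0.55, phageViralFrac = 0.20,
            voteTopFrac = 0.18, voteSecondFrac = 0.04, voteThirdFrac = 0.015,
            hostHypoFrac = 0.08, nMarkers = 5L,
            prophageFlank = 40000L, prophageLength = 250000L,
            concatemerUnitLength = 250000L,
            arrayRepeatLen = 32L, arraySpacerLen = 34L,
            nRepeatsPhage = 6L, nRepeatsHost = 8L,
            familyLayout = list(c(6L, 4L, 3L), c(5L, 5L), c(8L), c(4L, 3L),
                                c(7L, 2L), c(3L, 3L, 3L), c(10L), c(2L, 2L)),
            nSingletonProteins = 5L)
  p[names(params)] <- params

  phId <- sprintf("phage%02d", seq_len(nPhage))
  phLen <- round(seq(phageLengthRange[1], phageLengthRange[2],
                     length.out = nPhage))
  skew <- rep_len(c("bidirectional", "unidirectional", "none"), nPhage)
  code <- ifelse(seq_len(nPhage) %% 5L == 2L, "TAG_recoded", "code11")
  over <- ifelse(seq_len(nPhage) %% 2L == 1L, as.integer(terminalOverlapBp), 0L)
  conc <- rep(1L, nPhage)
  if (nPhage >= 2L) {                      # last phage: tandem dimer artifact
    conc[nPhage] <- 2L
    over[nPhage] <- 0L
    skew[nPhage] <- "none"
    phLen[nPhage] <- p$concatemerUnitLength
  }
  phages <- data.frame(id = phId, role = "phage", length = phLen,
                       gcContent = gcContent, skewMode = skew,
                       geneticCode = code, terminalOverlapBp = over,
                       concatemerUnits = conc,
                       phylum = NA_character_,
                       hostPhylum = NA_character_, prophage = FALSE)

  genomes <- phages
  if (nHost >= 1L) {
    hoId <- sprintf("host%02d", seq_len(nHost))
    hoLen <- round(seq(hostLengthRange[1], hostLengthRange[2],
                       length.out = max(nHost, 2L)))[seq_len(nHost)]
    hosts <- data.frame(id = hoId, role = "host", length = hoLen,
                        gcContent = gcContent, skewMode = "none",
                        geneticCode = "code11", terminalOverlapBp = 0L,
                        concatemerUnits = 1L,
                        phylum = rep_len(.PHYLA, nHost),
                        hostPhylum = NA_character_, prophage = FALSE)
    hosts$prophage[1L] <- TRUE             # host01 carries an integrated phage
    hosts$length[1L] <- 2L * p$prophageFlank + p$prophageLength
    genomes <- rbind(genomes, hosts)
    genomes$hostPhylum[genomes$role == "phage"] <-
      hosts$phylum[((seq_len(nPhage) - 1L) %% nHost) + 1L]
  }
  if (nPlasmid >= 1L) {
    pl <- data.frame(id = sprintf("plasmid%02d", seq_len(nPlasmid)),
                     role = "plasmid", length = 250000L,
                     gcContent = gcContent, skewMode = "none",
                     geneticCode = "code11", terminalOverlapBp = 0L,
                     concatemerUnits = 1L,
                     phylum = rep_len(.PHYLA, nPlasmid),
                     hostPhylum = NA_character_, prophage = FALSE)
    genomes <- rbind(genomes, pl)
  }

  arrays <- data.frame(contig = character(), repeatLen = integer(),
                       nRepeats = integer(), spacerLen = integer())
  links <- data.frame(sourceContig = character(), targetContig = character(),
                      mismatches = integer())
  arrayFor <- function(ids, nRep)
    data.frame(contig = ids, repeatLen = p$arrayRepeatLen, nRepeats = nRep,
               spacerLen = p$arraySpacerLen)
  phArr <- intersect(c("phage03", "phage04"), genomes$id)
  hoArr <- intersect(sprintf("host%02d", 1:3), genomes$id)
  if (length(phArr)) arrays <- rbind(arrays, arrayFor(phArr, p$nRepeatsPhage))
  if (length(hoArr)) arrays <- rbind(arrays, arrayFor(hoArr, p$nRepeatsHost))
  addLink <- function(src, tgt, mm) {
    if (all(c(src, tgt) %in% genomes$id) && src %in% arrays$contig)
      links <<- rbind(links, data.frame(sourceContig = src,
                                        targetContig = tgt, mismatches = mm))
  }
  addLink("host01", "phage01", 0L)
  addLink("host01", "phage01", 2L)
  addLink("host02", "phage02", 1L)
  addLink("host03", "phage03", 0L)
  addLink("phage03", "phage04", 0L)
  addLink("phage03", "phage04", 3L)
  addLink("phage04", "phage05", 0L)

  new("CommunitySpec", seed = as.integer(seed), genomes = genomes,
      plantedArrays = arrays, crisprLinks = links, params = p)
}

# ---- genome synthesis -----------------------------------------------------

# Random gene sequence (char vector) under a code: ATG start, body of sense
# codons drawn from `tab`, terminal stop. In TAG-recoded genomes the body
# additionally carries TAG at rate tagRate (the reassigned sense codon).
.synthGeneSeq <- function(nCodons, code, tab, tagRate) {
  nb <- nCodons - 2L
  body <- sample(tab$codons, nb, replace = TRUE, prob = tab$probs)
  if (code@id == "TAG_recoded" && tagRate > 0) {
    flip <- runif(nb) < tagRate
    body[flip] <- "TAG"
  }
  stopCod <- sample(code@stopCodons, 1L)
  .s2c(paste0("ATG", paste(body, collapse = ""), stopCod))
}

# Synthesize one genome unit: iid background bases with the requested GC and
# positional skew, overwritten by a dense tiling of random-codon genes.
.synthUnit <- function(len, gc, skewMode, code, p) {
  ori <- round(p$oriFrac * len)
  ter <- round(p$terFrac * len)
  sigma <- switch(skewMode,
    bidirectional = ifelse(seq_len(len) > ori & seq_len(len) <= ter, 1L, -1L),
    unidirectional = rep(1L, len),
    none = rep(0L, len))
  bases <- character(len)
  for (sg in c(-1L, 0L, 1L)) {             # fixed order for determinism
    idx <- which(sigma == sg)
    if (length(idx))
      bases[idx] <- .sampleBases(length(idx),
                                 .baseProbs(gc, p$skewAmp, sg))
  }
  # codon tables per sigma (body codons exclude the code's stops; in the
  # TAG-recoded code TAG is also excluded from random draws and planted
  # explicitly at tagRate)
  excl <- union(code@stopCodons, names(code@reassigned))
  tabs <- lapply(setNames(c(-1L, 0L, 1L), c("-1", "0", "1")), function(sg)
    .codonTable(.baseProbs(gc, p$skewAmp, sg), exclude = excl))
  nGuess <- ceiling(len / (3 * exp(p$geneMeanlog) * 0.8)) + 20L
  glens <- pmin(pmax(round(rlnorm(nGuess, p$geneMeanlog, p$geneSdlog)),
                     p$geneLenClip[1]), p$geneLenClip[2])
  gaps <- sample(p$gapRange[1]:p$gapRange[2], nGuess, replace = TRUE)
  strands <- sample(c("+", "-"), nGuess, replace = TRUE)
  genes <- data.frame(start = integer(), end = integer(), strand = character())
  pos <- 1L
  for (i in seq_len(nGuess)) {
    pos <- pos + gaps[i]
    e <- pos + 3L * glens[i] - 1L
    if (e > len - 60L) break
    mid <- (pos + e) %/% 2L
    sg <- sigma[mid]
    useSg <- if (strands[i] == "-") -sg else sg
    gseq <- .synthGeneSeq(glens[i], code, tabs[[as.character(useSg)]],
                          p$tagRate)
    bases[pos:e] <- if (strands[i] == "-") .revcompChar(gseq) else gseq
    genes <- rbind(genes, data.frame(start = pos, end = e,
                                     strand = strands[i]))
    pos <- e + 1L
  }
  list(bases = bases, genes = genes, ori = ori, ter = ter)
}

# Random CRISPR array sequence with exact repeat copies and unique spacers.
.makeArraySeq <- function(repeatLen, nRepeats, spacerLen, gc = 0.5) {
  probs <- .baseProbs(gc)
  repSeq <- .c2s(.sampleBases(repeatLen, probs))
  spacerSeqs <- character(nRepeats - 1L)
  for (i in seq_len(nRepeats - 1L)) {
    repeat {
      sp <- .c2s(.sampleBases(spacerLen, probs))
      if (!sp %in% c(spacerSeqs, repSeq)) break
    }
    spacerSeqs[i] <- sp
  }
  parts <- character(2L * nRepeats - 1L)
  parts[seq(1L, by = 2L, length.out = nRepeats)] <- repSeq
  if (nRepeats > 1L)
    parts[seq(2L, by = 2L, length.out = nRepeats - 1L)] <- spacerSeqs
  seq <- paste(parts, collapse = "")
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  repIdx <- seq(1L, by = 2L, length.out = nRepeats)
  spIdx <- if (nRepeats > 1L) seq(2L, by = 2L, length.out = nRepeats - 1L)
           else integer()
  list(seq = seq, repeatSeq = repSeq, spacerSeqs = spacerSeqs,
       repeatStarts = starts[repIdx], repeatEnds = ends[repIdx],
       spacerStarts = starts[spIdx], spacerEnds = ends[spIdx])
}

# Pick a placement for a feature of length flen inside [lo, hi] avoiding
# reserved intervals; NA if none found after `tries` draws.
.placeFeature <- function(flen, lo, hi, reserved, tries = 200L) {
  for (i in seq_len(tries)) {
    s <- sample(lo:(hi - flen), 1L)
    if (!.overlapsAny(s - 50L, s + flen + 49L, reserved)) return(s)
  }
  NA_integer_
}

# Mutate a spacer at exactly `mm` positions.
.mutateSpacer <- function(sp, mm) {
  v <- .s2c(sp)
  if (mm > 0L) {
    posn <- sample(length(v), mm)
    for (j in posn) v[j] <- sample(setdiff(BASES, v[j]), 1L)
  }
  .c2s(v)
}

# ---- annotation tables ----------------------------------------------------

.lineageFor <- function(phylum) {
  c(domain = "Bacteria", phylum = phylum,
    class = paste0(phylum, "_class"), order = paste0(phylum, "_order"),
    family = paste0(phylum, "_family"), genus = paste0(phylum, "_genus"))
}

.emptyLineage <- c(domain = "", phylum = "", class = "", order = "",
                   family = "", genus = "")

.viralLineage <- c(domain = "Viruses", phylum = "", class = "", order = "",
                   family = "", genus = "")

# One annotation row per gene for a genome region, under a profile:
# list(hypo, viral, top, second, third, topPhylum, secondPhylum, thirdPhylum,
#      keywordPool, bitscoreMean, markers (indices into genes))
.annotateGenes <- function(contigId, genes, profile, geneIdOffset = 0L) {
  ng <- nrow(genes)
  if (ng == 0L) return(NULL)
  u <- runif(ng)
  cuts <- cumsum(c(profile$hypo, profile$viral, profile$top, profile$second,
                   profile$third))
  cat <- findInterval(u, cuts) + 1L   # 1 hypo, 2 viral, 3 top, 4 second,
                                      # 5 third, 6 generic-functional no-taxon
  lin <- matrix("", ng, 6L,
                dimnames = list(NULL, names(.emptyLineage)))
  keyword <- character(ng)
  bits <- numeric(ng)
  for (i in seq_len(ng)) {
    if (cat[i] == 1L) {
      keyword[i] <- "hypothetical protein"
      bits[i] <- rnorm(1, 55, 8)
    } else if (cat[i] == 2L) {
      lin[i, ] <- .viralLineage
      keyword[i] <- sample(profile$keywordPool, 1L)
      bits[i] <- rnorm(1, profile$bitscoreMean, 30)
    } else if (cat[i] %in% 3:5) {
      ph <- switch(cat[i] - 2L, profile$topPhylum, profile$secondPhylum,
                   profile$thirdPhylum)
      lin[i, ] <- .lineageFor(ph)
      keyword[i] <- sample(profile$keywordPool, 1L)
      bits[i] <- rnorm(1, profile$bitscoreMean, 30)
    } else {
      keyword[i] <- sample(profile$keywordPool, 1L)
      bits[i] <- rnorm(1, profile$bitscoreMean, 30)
    }
  }
  if (length(profile$markers)) {
    mk <- profile$markers[profile$markers <= ng]
    keyword[mk] <- rep_len(.MARKER_KEYWORDS, length(mk))
    bits[mk] <- rnorm(length(mk), 130, 20)
  }
  if (length(profile$plasmidGenes)) {
    pg <- profile$plasmidGenes[profile$plasmidGenes <= ng]
    keyword[pg] <- rep_len(.PLASMID_KEYWORDS, length(pg))
    bits[pg] <- rnorm(length(pg), 140, 20)
  }
  data.frame(contig_id = contigId,
             gene_id = sprintf("%s_g%04d", contigId,
                               geneIdOffset + seq_len(ng)),
             gene_start = genes$start, gene_end = genes$end,
             gene_strand = genes$strand,
             domain = lin[, "domain"], phylum = lin[, "phylum"],
             class = lin[, "class"], order = lin[, "order"],
             family = lin[, "family"], genus = lin[, "genus"],
             keyword = keyword, bitscore = round(pmax(bits, 30), 1))
}

# ---- protein similarity edges ---------------------------------------------

.makeProteinEdges <- function(layout, nSingletons) {
  fam <- integer(); subfam <- character(); prot <- character()
  pid <- 0L
  for (f in seq_along(layout)) {
    for (s in seq_along(layout[[f]])) {
      ids <- sprintf("p%04d", pid + seq_len(layout[[f]][s]))
      pid <- pid + layout[[f]][s]
      prot <- c(prot, ids)
      subfam <- c(subfam, rep(ids[1L], length(ids)))  # smallest id = rep
      fam <- c(fam, rep(f, length(ids)))
    }
  }
  if (nSingletons > 0L) {
    ids <- sprintf("p%04d", pid + seq_len(nSingletons))
    prot <- c(prot, ids); subfam <- c(subfam, ids)
    fam <- c(fam, max(fam, 0L) + seq_len(nSingletons))
  }
  truthDf <- data.frame(protein = prot, subfamily = subfam, family = fam)
  # all-vs-all edges: complete within subfamily, strong scores
  av <- NULL
  for (sf in unique(subfam)) {
    m <- prot[subfam == sf]
    if (length(m) < 2L) next
    pr <- t(combn(m, 2L))
    av <- rbind(av, data.frame(query = pr[, 1L], target = pr[, 2L],
                               evalue = 10^runif(nrow(pr), -40, -10),
                               coverage = runif(nrow(pr), 0.70, 0.95)))
  }
  # sub-threshold noise edges between random proteins (filtered upstream)
  nn <- max(4L, length(prot) %/% 4L)
  q <- sample(prot, nn, replace = TRUE)
  t2 <- sample(prot, nn, replace = TRUE)
  ok <- q != t2
  noise <- data.frame(query = q[ok], target = t2[ok],
                      evalue = 10^runif(sum(ok), -2, 0),
                      coverage = runif(sum(ok), 0.10, 0.45))
  av <- rbind(av, noise)
  # profile-profile edges between subfamily representatives
  reps <- unique(subfam)
  pf <- NULL
  for (f in unique(fam)) {
    r <- unique(subfam[fam == f])
    if (length(r) < 2L) next
    pr <- t(combn(r, 2L))
    pf <- rbind(pf, data.frame(query = pr[, 1L], target = pr[, 2L],
                               probability = runif(nrow(pr), 96, 99.9),
                               coverage = runif(nrow(pr), 0.65, 0.90)))
  }
  realFams <- unique(fam)
  if (length(realFams) > 1L) {
    prF <- t(combn(sort(realFams), 2L))
    between <- data.frame(
      query = vapply(prF[, 1L], function(f) reps[which(fam[match(reps, prot)] == f)[1L]], ""),
      target = vapply(prF[, 2L], function(f) reps[which(fam[match(reps, prot)] == f)[1L]], ""),
      probability = runif(nrow(prF), 30, 70),
      coverage = runif(nrow(prF), 0.15, 0.45))
    pf <- rbind(pf, between)
  }
  list(allvsall = av, profile = pf, truth = truthDf)
}

# ---- main generator -------------------------------------------------------

#' Generate a synthetic community with ground truth
#'
#' Emits contig sequences, a per-gene annotation table, protein-similarity
#' edge tables, a tRNA-count table and a truth ledger, all deterministically
#' from `spec@seed` (same spec implies byte-identical output). Genomes are
#' dense tilings of random-codon ORFs separated by short intergenic gaps, so
#' coding density is controllable; planted features are kept mutually
#' non-destructive (arrays and protospacers never overlap terminal repeats or
#' each other).
#'
#' @param spec A [CommunitySpec-class] from [communitySpec()].
#' @return A [SyntheticCommunity-class].
#' @examples
#' comm <- generateCommunity(communitySpec(seed = 7, nPhage = 2, nHost = 1,
#'   phageLengthRange = c(40000, 50000), hostLengthRange = c(40000, 40000)))
#' comm
#' @export
generateCommunity <- function(spec) {
  validObject(spec)
  g <- spec@genomes
  p <- spec@params
  if (nrow(spec@plantedArrays)) {
    arrLen <- with(spec@plantedArrays,
                   nRepeats * repeatLen + (nRepeats - 1L) * spacerLen)
    tooLong <- arrLen + 8000L >
      g$length[match(spec@plantedArrays$contig, g$id)]
    if (any(tooLong))
      stop("plantedArrays: array longer than genome for contig(s) ",
           paste(spec@plantedArrays$contig[tooLong], collapse = ", "))
  }
  set.seed(spec@seed)

  units <- vector("list", nrow(g)); names(units) <- g$id
  truthContigs <- vector("list", nrow(g)); names(truthContigs) <- g$id

  # 1. genome units
  for (i in seq_len(nrow(g))) {
    id <- g$id[i]
    code <- geneticCode(g$geneticCode[i])
    u <- .synthUnit(g$length[i], g$gcContent[i], g$skewMode[i], code, p)
    units[[id]] <- u
    truthContigs[[id]] <- list(
      id = id, role = g$role[i],
      unitLength = g$length[i],
      terminalOverlap = g$terminalOverlapBp[i],
      concatemerUnits = g$concatemerUnits[i],
      skew = list(mode = g$skewMode[i],
                  ori = if (g$skewMode[i] == "bidirectional") u$ori else NA,
                  ter = if (g$skewMode[i] == "bidirectional") u$ter else NA),
      geneticCode = g$geneticCode[i],
      phylum = g$phylum[i], hostPhylum = g$hostPhylum[i],
      prophage = if (g$prophage[i])
        list(start = p$prophageFlank + 1L,
             end = p$prophageFlank + p$prophageLength) else NULL,
      genes = u$genes,
      arrays = list(),
      protospacers = data.frame(spacer_id = character(),
                                sourceContig = character(),
                                start = integer(), end = integer(),
                                strand = character(), mismatches = integer()),
      reserved = data.frame(start = integer(), end = integer(),
                            what = character()))
  }

  # 2. CRISPR arrays (planted away from contig ends so they can never touch
  #    terminal repeats)
  for (k in seq_len(nrow(spec@plantedArrays))) {
    pa <- spec@plantedArrays[k, ]
    id <- pa$contig
    arr <- .makeArraySeq(pa$repeatLen, pa$nRepeats, pa$spacerLen,
                         g$gcContent[match(id, g$id)])
    flen <- nchar(arr$seq)
    tr <- truthContigs[[id]]
    margin <- max(2000L, tr$terminalOverlap + 1000L)
    s <- .placeFeature(flen, margin, tr$unitLength - margin, tr$reserved)
    if (is.na(s)) stop("could not place array on ", id)
    units[[id]]$bases[s:(s + flen - 1L)] <- .s2c(arr$seq)
    nr <- pa$nRepeats
    spacerIds <- sprintf("%s_a%d_sp%02d", id, length(tr$arrays) + 1L,
                         seq_len(nr - 1L))
    tr$arrays[[length(tr$arrays) + 1L]] <- list(
      start = s, end = s + flen - 1L,
      repeatSeq = arr$repeatSeq, nRepeats = nr,
      repeatStarts = s + arr$repeatStarts - 1L,
      repeatEnds = s + arr$repeatEnds - 1L,
      spacers = data.frame(id = spacerIds,
                           start = s + arr$spacerStarts - 1L,
                           end = s + arr$spacerEnds - 1L,
                           seq = arr$spacerSeqs, usedForLink = FALSE))
    tr$reserved <- rbind(tr$reserved,
                         data.frame(start = s, end = s + flen - 1L,
                                    what = "array"))
    truthContigs[[id]] <- tr
  }

  # 3. spacer-protospacer links
  truthLinks <- NULL
  for (k in seq_len(nrow(spec@crisprLinks))) {
    lk <- spec@crisprLinks[k, ]
    src <- truthContigs[[lk$sourceContig]]
    tgt <- truthContigs[[lk$targetContig]]
    ai <- which(vapply(src$arrays, function(a) any(!a$spacers$usedForLink),
                       TRUE))[1L]
    if (is.na(ai)) stop("no free spacer on ", lk$sourceContig)
    sp <- src$arrays[[ai]]$spacers
    si <- which(!sp$usedForLink)[1L]
    spacerSeq <- sp$seq[si]
    proto <- .mutateSpacer(spacerSeq, lk$mismatches)
    strand <- sample(c("+", "-"), 1L)
    planted <- if (strand == "-") .revcompStr(proto) else proto
    flen <- nchar(planted)
    margin <- max(2000L, tgt$terminalOverlap + 1000L)
    s <- .placeFeature(flen, margin, tgt$unitLength - margin, tgt$reserved)
    if (is.na(s)) stop("could not place protospacer on ", lk$targetContig)
    units[[lk$targetContig]]$bases[s:(s + flen - 1L)] <- .s2c(planted)
    tgt$protospacers <- rbind(tgt$protospacers,
      data.frame(spacer_id = sp$id[si], sourceContig = lk$sourceContig,
                 start = s, end = s + flen - 1L, strand = strand,
                 mismatches = lk$mismatches))
    tgt$reserved <- rbind(tgt$reserved,
                          data.frame(start = s, end = s + flen - 1L,
                                     what = "protospacer"))
    src$arrays[[ai]]$spacers$usedForLink[si] <- TRUE
    truthContigs[[lk$sourceContig]] <- src
    truthContigs[[lk$targetContig]] <- tgt
    truthLinks <- rbind(truthLinks,
      data.frame(spacer_id = sp$id[si], sourceContig = lk$sourceContig,
                 targetContig = lk$targetContig, start = s,
                 end = s + flen - 1L, strand = strand,
                 mismatches = lk$mismatches))
  }

  # 4. expansion: terminal overlap / concatemer
  seqs <- character(nrow(g)); names(seqs) <- g$id
  for (i in seq_len(nrow(g))) {
    id <- g$id[i]
    bv <- units[[id]]$bases
    tr <- truthContigs[[id]]
    if (g$concatemerUnits[i] > 1L) {
      bv <- rep(bv, g$concatemerUnits[i])
      genes0 <- tr$genes
      genesAll <- genes0
      for (u2 in seq_len(g$concatemerUnits[i] - 1L)) {
        sh <- genes0
        sh$start <- sh$start + u2 * tr$unitLength
        sh$end <- sh$end + u2 * tr$unitLength
        genesAll <- rbind(genesAll, sh)
      }
      tr$genes <- genesAll
      tr$correctedLength <- tr$unitLength
    } else if (g$terminalOverlapBp[i] > 0L) {
      bv <- c(bv, bv[seq_len(g$terminalOverlapBp[i])])
      tr$correctedLength <- tr$unitLength
    } else {
      tr$correctedLength <- tr$unitLength
    }
    tr$length <- length(bv)
    seqs[id] <- .c2s(bv)
    truthContigs[[id]] <- tr
  }

  # 5. annotations
  annot <- NULL
  for (i in seq_len(nrow(g))) {
    id <- g$id[i]
    tr <- truthContigs[[id]]
    genes <- tr$genes
    role <- g$role[i]
    if (role == "phage") {
      prof <- list(hypo = p$phageHypoFrac, viral = p$phageViralFrac,
                   top = p$voteTopFrac, second = p$voteSecondFrac,
                   third = p$voteThirdFrac,
                   topPhylum = g$hostPhylum[i],
                   secondPhylum = .PHYLA[.PHYLA != g$hostPhylum[i]][1L],
                   thirdPhylum = .PHYLA[.PHYLA != g$hostPhylum[i]][2L],
                   keywordPool = .PHAGE_FUNCTIONAL, bitscoreMean = 110,
                   markers = sort(sample(nrow(genes), p$nMarkers)),
                   plasmidGenes = integer())
      annot <- rbind(annot, .annotateGenes(id, genes, prof))
    } else if (role == "host" && !is.null(tr$prophage)) {
      inProph <- genes$start >= tr$prophage$start &
        genes$end <= tr$prophage$end
      hostProf <- list(hypo = p$hostHypoFrac, viral = 0,
                       top = 1 - p$hostHypoFrac - 0.02, second = 0.02,
                       third = 0,
                       topPhylum = g$phylum[i],
                       secondPhylum = .PHYLA[.PHYLA != g$phylum[i]][1L],
                       thirdPhylum = .PHYLA[.PHYLA != g$phylum[i]][2L],
                       keywordPool = .BACT_FUNCTIONAL, bitscoreMean = 150,
                       markers = integer(), plasmidGenes = integer())
      prophProf <- list(hypo = 0.70, viral = 0.20, top = 0.10, second = 0,
                        third = 0,
                        topPhylum = g$phylum[i], secondPhylum = .PHYLA[1L],
                        thirdPhylum = .PHYLA[2L],
                        keywordPool = .PHAGE_FUNCTIONAL, bitscoreMean = 70,
                        markers = integer(), plasmidGenes = integer())
      a1 <- .annotateGenes(id, genes[!inProph & genes$end < tr$prophage$start, ,
                                     drop = FALSE], hostProf)
      a2 <- .annotateGenes(id, genes[inProph, , drop = FALSE], prophProf,
                           geneIdOffset = if (is.null(a1)) 0L else nrow(a1))
      off <- (if (is.null(a1)) 0L else nrow(a1)) +
        (if (is.null(a2)) 0L else nrow(a2))
      a3 <- .annotateGenes(id, genes[genes$start > tr$prophage$end, ,
                                     drop = FALSE], hostProf,
                           geneIdOffset = off)
      ann <- rbind(a1, a2, a3)
      ann <- ann[order(ann$gene_start), , drop = FALSE]
      annot <- rbind(annot, ann)
    } else if (role == "host") {
      prof <- list(hypo = p$hostHypoFrac, viral = 0,
                   top = 1 - p$hostHypoFrac - 0.02, second = 0.02, third = 0,
                   topPhylum = g$phylum[i],
                   secondPhylum = .PHYLA[.PHYLA != g$phylum[i]][1L],
                   thirdPhylum = .PHYLA[.PHYLA != g$phylum[i]][2L],
                   keywordPool = .BACT_FUNCTIONAL, bitscoreMean = 150,
                   markers = integer(), plasmidGenes = integer())
      annot <- rbind(annot, .annotateGenes(id, genes, prof))
    } else {                               # plasmid-like
      prof <- list(hypo = 0.30, viral = 0,
                   top = 0.60, second = 0.05, third = 0,
                   topPhylum = g$phylum[i],
                   secondPhylum = .PHYLA[.PHYLA != g$phylum[i]][1L],
                   thirdPhylum = .PHYLA[.PHYLA != g$phylum[i]][2L],
                   keywordPool = .BACT_FUNCTIONAL, bitscoreMean = 120,
                   markers = integer(),
                   plasmidGenes = sort(sample(nrow(genes), 5L)))
      annot <- rbind(annot, .annotateGenes(id, genes, prof))
    }
  }
  rownames(annot) <- NULL

  # 6. protein-similarity edges with planted family structure
  pe <- .makeProteinEdges(p$familyLayout, p$nSingletonProteins)

  # 7. tRNA counts: increase with genome size, plus noise
  lens <- vapply(truthContigs, function(tr) tr$length, 0)
  isPhage <- g$role == "phage"
  trna <- data.frame(genome = g$id[isPhage],
                     length = unname(lens[g$id[isPhage]]),
                     trna = pmax(0L, round(lens[g$id[isPhage]] / 20000 +
                                           rnorm(sum(isPhage), 0, 4))))

  truth <- list(contigs = truthContigs, links = truthLinks,
                proteinFamilies = pe$truth)
  new("SyntheticCommunity",
      contigs = Biostrings::DNAStringSet(seqs),
      annotations = annot,
      proteinEdges = list(allvsall = pe$allvsall, profile = pe$profile),
      trnaTable = trna, truth = truth, spec = spec)
}

#' Plant an extra CRISPR spacer-protospacer link in a community
#'
#' Extends an existing array on `sourceContig` with `nSpacers` new spacers
#' (each with one more repeat copy, overwriting the sequence immediately
#' downstream of the array) and plants the matching protospacers in
#' `targetContig` at exactly the requested Hamming distance. Fails when the
#' extension or a protospacer would collide with another planted feature,
#' or when the target is a concatemer artifact (planting would break its
#' tandem structure). Draws from the current RNG stream.
#'
#' @param community A [SyntheticCommunity-class].
#' @param sourceContig Contig carrying the array that gains the spacers.
#' @param targetContig Contig that receives the protospacers.
#' @param nSpacers Number of new spacer/protospacer pairs.
#' @param mismatches Hamming distance of each planted pair (0-3, recycled).
#' @return The updated [SyntheticCommunity-class].
#' @export
plantCrisprLink <- function(community, sourceContig, targetContig,
                            nSpacers = 1L, mismatches = 0L) {
  stopifnot(is(community, "SyntheticCommunity"),
            all(mismatches >= 0L), all(mismatches <= 3L))
  mismatches <- rep_len(as.integer(mismatches), nSpacers)
  tc <- community@truth$contigs
  if (!sourceContig %in% names(tc) || !targetContig %in% names(tc))
    stop("unknown contig id")
  src <- tc[[sourceContig]]
  tgt <- tc[[targetContig]]
  if (length(src$arrays) == 0L)
    stop("sourceContig carries no planted array")
  if (tgt$concatemerUnits > 1L)
    stop("cannot plant a protospacer into a concatemer artifact")
  ai <- 1L
  arr <- src$arrays[[ai]]
  repLen <- nchar(arr$repeatSeq)
  spLen <- nchar(arr$spacers$seq[1L])
  extLen <- nSpacers * (repLen + spLen)
  extStart <- arr$end + 1L
  extEnd <- arr$end + extLen
  resOther <- src$reserved[!(src$reserved$start == arr$start &
                               src$reserved$end == arr$end), , drop = FALSE]
  if (extEnd > src$unitLength - 1000L ||
      .overlapsAny(extStart, extEnd, resOther))
    stop("array extension collides with another planted feature")

  srcChars <- .s2c(as.character(community@contigs[[sourceContig]]))
  tgtChars <- .s2c(as.character(community@contigs[[targetContig]]))
  links <- community@truth$links
  for (k in seq_len(nSpacers)) {
    repeat {
      spSeq <- .c2s(.sampleBases(spLen, .baseProbs(0.5)))
      if (!spSeq %in% arr$spacers$seq) break
    }
    s0 <- arr$end + 1L
    piece <- .s2c(paste0(spSeq, arr$repeatSeq))
    srcChars[s0:(s0 + length(piece) - 1L)] <- piece
    spId <- sprintf("%s_a%d_sp%02d", sourceContig, ai,
                    nrow(arr$spacers) + 1L)
    arr$spacers <- rbind(arr$spacers,
      data.frame(id = spId, start = s0, end = s0 + spLen - 1L, seq = spSeq,
                 usedForLink = TRUE))
    arr$repeatStarts <- c(arr$repeatStarts, s0 + spLen)
    arr$repeatEnds <- c(arr$repeatEnds, s0 + spLen + repLen - 1L)
    arr$nRepeats <- arr$nRepeats + 1L
    arr$end <- s0 + spLen + repLen - 1L

    proto <- .mutateSpacer(spSeq, mismatches[k])
    strand <- sample(c("+", "-"), 1L)
    planted <- if (strand == "-") .revcompStr(proto) else proto
    margin <- max(2000L, tgt$terminalOverlap + 1000L)
    s <- .placeFeature(nchar(planted), margin, tgt$unitLength - margin,
                       tgt$reserved)
    if (is.na(s))
      stop("requested protospacer collides with another planted feature")
    tgtChars[s:(s + nchar(planted) - 1L)] <- .s2c(planted)
    tgt$protospacers <- rbind(tgt$protospacers,
      data.frame(spacer_id = spId, sourceContig = sourceContig,
                 start = s, end = s + nchar(planted) - 1L, strand = strand,
                 mismatches = mismatches[k]))
    tgt$reserved <- rbind(tgt$reserved,
      data.frame(start = s, end = s + nchar(planted) - 1L,
                 what = "protospacer"))
    links <- rbind(links,
      data.frame(spacer_id = spId, sourceContig = sourceContig,
                 targetContig = targetContig, start = s,
                 end = s + nchar(planted) - 1L, strand = strand,
                 mismatches = mismatches[k]))
  }
  src$reserved[src$reserved$start == arr$start &
                 src$reserved$what == "array", "end"] <- arr$end
  src$arrays[[ai]] <- arr
  # rebuild contigs (re-apply terminal overlap on the source if present)
  if (src$terminalOverlap > 0L)
    srcChars[(src$unitLength + 1L):(src$unitLength + src$terminalOverlap)] <-
      srcChars[seq_len(src$terminalOverlap)]
  newSeqs <- as.character(community@contigs)
  newSeqs[sourceContig] <- .c2s(srcChars)
  newSeqs[targetContig] <- .c2s(tgtChars)
  tc[[sourceContig]] <- src
  tc[[targetContig]] <- tgt
  truth <- community@truth
  truth$contigs <- tc
  truth$links <- links
  initialize(community, contigs = Biostrings::DNAStringSet(newSeqs),
             truth = truth)
}

#' Simulate a genome-size / tRNA-count table with a planted rank correlation
#'
#' Draws `n` (size, tRNA-count) pairs from a Gaussian copula whose Pearson
#' parameter is chosen so the population Spearman correlation equals `rho`;
#' sizes are log-normal around 300 kb, counts Poisson-like around 30.
#'
#' @param n Number of genomes.
#' @param rho Target Spearman rank correlation.
#' @param seed Optional seed.
#' @return `data.frame` with columns `genome`, `length`, `trna`.
#' @export
simulateTrnaTable <- function(n = 201L, rho = 0.61, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- 2 * sin(pi * rho / 6)               # copula parameter for Spearman rho
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  len <- round(stats::qlnorm(stats::pnorm(z1), log(3e5), 0.35))
  trna <- stats::qpois(stats::pnorm(z2), 30)
  data.frame(genome = sprintf("genome%03d", seq_len(n)), length = len,
             trna = trna)
}

#' Write a synthetic community to disk
#'
#' Writes `contigs.fasta` (80-column wrap), `annotations.tsv`,
#' `edges_allvsall.tsv`, `edges_profile.tsv`, `trna_counts.tsv` and
#' `truth.json`. Output is byte-identical for identical communities.
#'
#' @param community A [SyntheticCommunity-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "contigs.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    allvsall = file.path(dir, "edges_allvsall.tsv"),
    profile = file.path(dir, "edges_profile.tsv"),
    trna = file.path(dir, "trna_counts.tsv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(community@contigs, paths["fasta"], width = 80L)
  .writeTsv(community@annotations, paths["annotations"])
  .writeTsv(community@proteinEdges$allvsall, paths["allvsall"])
  .writeTsv(community@proteinEdges$profile, paths["profile"])
  .writeTsv(community@trnaTable, paths["trna"])
  writeLines(jsonlite::toJSON(community@truth, dataframe = "columns",
                              auto_unbox = TRUE, digits = NA, null = "null",
                              pretty = FALSE),
             paths["truth"])
  invisible(paths)
}
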