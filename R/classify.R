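# Element-type classification of large contigs: taxonomy voting, phage
# marker genes, plasmid discrimination and prophage-transition detection.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Per-rank taxonomy vote of a contig
#'
#' Each annotated gene casts one vote per taxonomic rank (its best hit's
#' lineage); genes without a hit at a rank abstain. A rank has a winner only
#' when the top taxon holds a strict majority (more than 50%) of the
#' non-abstaining votes at that rank.
#'
#' @param hits Annotation table (columns `domain` ... `genus`; empty string
#'   or `NA` = abstain) restricted to one contig's genes.
#' @return A `data.frame` with one row per rank: `rank`, `winner` (`NA` when
#'   no strict majority), `topCount`, `votes` (non-abstaining genes).
#' @export
voteTaxonomy <- function(hits) {
  out <- data.frame(rank = .RANKS, winner = NA_character_,
                    topCount = 0L, votes = 0L)
  for (i in seq_along(.RANKS)) {
    v <- hits[[.RANKS[i]]]
    v <- v[!is.na(v) & v != ""]
    out$votes[i] <- length(v)
    if (length(v) == 0L) next
    tab <- sort(table(v), decreasing = TRUE)
    out$topCount[i] <- as.integer(tab[1L])
    if (tab[1L] > length(v) / 2) out$winner[i] <- names(tab)[1L]
  }
  out
}

#' Default phage marker lexicon
#'
#' Marker classes and the case-insensitive patterns that detect them in
#' functional keywords: capsid, tail, terminase, spike, holin, portal and
#' baseplate. The shipped lexicon lives in
#' `system.file("extdata", "phage_markers.tsv", package = "hugephage")` and
#' can be edited or replaced.
#'
#' @param path Optional path to an alternative lexicon TSV
#'   (columns `class`, `pattern`).
#' @return `data.frame` with columns `class` and `pattern`.
#' @export
phageMarkerLexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phage_markers.tsv",
                        package = "hugephage")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Find phage marker gene classes among annotation keywords
#'
#' @param hits Annotation table with a `keyword` column.
#' @param lexicon Marker lexicon from [phageMarkerLexicon()].
#' @return Character vector of marker classes present.
#' @export
findPhageMarkers <- function(hits, lexicon = phageMarkerLexicon()) {
  kw <- hits$keyword
  kw <- kw[!is.na(kw)]
  found <- vapply(seq_len(nrow(lexicon)), function(i)
    any(grepl(lexicon$pattern[i], kw, ignore.case = TRUE)), TRUE)
  lexicon$class[found]
}

#' Fraction of genes without a functional annotation
#'
#' @param hits Annotation table for the contig's genes (one row per gene;
#'   keyword `"hypothetical protein"`, empty or `NA` counts as hypothetical).
#' @param nGenes Total gene count (>= number of hit rows; genes without any
#'   hit count as hypothetical).
#' @return Fraction in \[0, 1\].
#' @export
hypotheticalFraction <- function(hits, nGenes = nrow(hits)) {
  if (nGenes == 0L) stop("hypothetical fraction is undefined for zero genes")
  kw <- hits$keyword
  hypo <- is.na(kw) | kw == "" | grepl("hypothetical", kw, ignore.case = TRUE)
  (sum(hypo) + (nGenes - nrow(hits))) / nGenes
}

# Is a gene's best hit a confident bacterial functional prediction?
.confidentBacterial <- function(hits, bitscoreMin = 60,
                                lexicon = phageMarkerLexicon()) {
  kw <- hits$keyword
  hypo <- is.na(kw) | kw == "" | grepl("hypothetical", kw, ignore.case = TRUE)
  marker <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(lexicon)))
    marker <- marker | grepl(lexicon$pattern[i], kw, ignore.case = TRUE)
  !hypo & !marker & !is.na(hits$bitscore) & hits$bitscore >= bitscoreMin
}

#' Detect a prophage transition into flanking host sequence
#'
#' Scans the gene-order profile of a contig for a boundary where a flank of
#' at least `window` bp is dominated (>= `confFrac`) by confident bacterial
#' functional predictions (non-hypothetical keyword, bitscore >=
#' `bitscoreMin`, not a phage marker) while the adjacent interior is
#' phage-like (confident-bacterial fraction <= `1 - confFrac`). A phage
#' region embedded in a host chromosome yields one boundary per flank.
#'
#' @param hits Annotation table for one contig with `gene_start`, `gene_end`,
#'   `keyword`, `bitscore` columns, ordered or not.
#' @param contigLength Length of the contig in bp.
#' @param window Minimum flank extent in bp (default 20 kb).
#' @param confFrac Required confident-bacterial fraction in the flank.
#' @param bitscoreMin Bitscore floor for a confident prediction.
#' @return Numeric vector of boundary positions (bp), or `NULL` when no
#'   transition is found.
#' @export
detectProphageTransition <- function(hits, contigLength, window = 20000L,
                                     confFrac = 0.7, bitscoreMin = 60) {
  if (nrow(hits) < 4L) return(NULL)
  hits <- hits[order(hits$gene_start), , drop = FALSE]
  conf <- .confidentBacterial(hits, bitscoreMin)
  ng <- nrow(hits)
  ends <- hits$gene_end
  starts <- hits$gene_start
  cum <- cumsum(conf)
  bounds <- numeric()

  # Bernoulli changepoint along the gene order: a first pass with symmetric
  # weights locates the split, a second pass reweights by the estimated
  # log-likelihood ratio of the two regimes (flank-confident vs interior),
  # which sharpens the boundary when the regimes are asymmetric.
  changepoint <- function(v) {
    cs <- cumsum(v)
    i0 <- which.max(cs - 0.5 * seq_along(v))
    if (i0 >= length(v)) return(i0)
    p1 <- min(max(mean(v[seq_len(i0)]), 0.05), 0.95)
    p2 <- min(max(mean(v[(i0 + 1L):length(v)]), 0.05), 0.95)
    if (p1 <= p2) return(i0)
    w <- ifelse(v, log(p1 / p2), log((1 - p1) / (1 - p2)))
    which.max(cumsum(w))
  }

  # a boundary is accepted when the flank spans at least `window` bp with a
  # confident fraction >= confFrac, and everything beyond it is clearly a
  # different regime (confident fraction at most half the flank's)
  i <- changepoint(conf)
  if (i < ng - 4L) {
    fracIn <- cum[i] / i
    fracOut <- (cum[ng] - cum[i]) / (ng - i)
    if (ends[i] >= window && fracIn >= confFrac && fracOut <= fracIn / 2)
      bounds <- c(bounds, ends[i])
  }

  # right flank: same from the other end
  jr <- changepoint(rev(conf))
  j <- ng - jr + 1L                        # first gene of the right flank
  if (j > 5L) {
    fracIn <- (cum[ng] - cum[j - 1L]) / (ng - j + 1L)
    fracOut <- cum[j - 1L] / (j - 1L)
    if (contigLength - starts[j] + 1L >= window &&
        fracIn >= confFrac && fracOut <= fracIn / 2)
      bounds <- c(bounds, starts[j])
  }
  if (length(bounds)) sort(unique(bounds)) else NULL
}

#' Find plasmid hallmark genes (partitioning / conjugative transfer)
#'
#' @param hits Annotation table with a `keyword` column.
#' @return Character vector of matched plasmid keywords.
#' @export
findPlasmidGenes <- function(hits) {
  pat <- paste0("partition|\\bparA\\b|\\bparB\\b|conjuga|relaxase|",
                "type IV secretion|mobiliz|\\btra[A-Z]\\b|\\btrb[A-Z]\\b")
  kw <- hits$keyword
  kw <- kw[!is.na(kw)]
  unique(kw[grepl(pat, kw, ignore.case = TRUE)])
}

#' Classify a contig as phage, plasmid-like, prophage-containing or unknown
#'
#' Rule order: (1) a detected prophage transition makes the contig
#' prophage-containing; (2) plasmid partitioning/conjugation genes with no
#' phage markers make it plasmid-like; (3) phage markers, or no domain-level
#' taxonomy winner together with a high hypothetical fraction
#' (>= `hypoHigh`), make it a phage; (4) otherwise unknown. Contigs shorter
#' than `minLength` are rejected (`retained = FALSE`) unless they carry a
#' CRISPR array, in which case they are kept with `lengthException = TRUE`.
#'
#' @param contigId Contig identifier.
#' @param contigLength Contig length in bp.
#' @param vote Taxonomy vote table from [voteTaxonomy()].
#' @param markers Marker classes from [findPhageMarkers()].
#' @param hypoFraction Fraction from [hypotheticalFraction()].
#' @param plasmidGenes Matches from [findPlasmidGenes()].
#' @param prophageBoundaries Result of [detectProphageTransition()].
#' @param crisprPresent Does the contig carry a detected CRISPR array?
#' @param minLength Retention threshold in bp (default 200 kb).
#' @param hypoHigh Hypothetical-fraction threshold for the markerless phage
#'   rule.
#' @param phageOverride User override asserting phage placement from
#'   external evidence (e.g. a phylogenetic tree of replication genes).
#' @return A [ClassificationResult-class].
#' @export
classifyElement <- function(contigId, contigLength, vote, markers,
                            hypoFraction, plasmidGenes = character(),
                            prophageBoundaries = NULL,
                            crisprPresent = FALSE, minLength = 200000L,
                            hypoHigh = 0.6, phageOverride = FALSE) {
  trace <- character()
  lengthException <- FALSE
  retained <- TRUE
  if (contigLength < minLength) {
    if (crisprPresent) {
      lengthException <- TRUE
      trace <- c(trace, sprintf("length %d < %d but CRISPR present: retained",
                                contigLength, minLength))
    } else {
      retained <- FALSE
      trace <- c(trace, sprintf("length %d < %d and no CRISPR: rejected",
                                contigLength, minLength))
    }
  }
  domainWinner <- vote$winner[vote$rank == "domain"]
  type <- NULL
  if (!is.null(prophageBoundaries) && length(prophageBoundaries)) {
    type <- "prophage_containing"
    trace <- c(trace, sprintf("rule 1: prophage transition at %s",
                              paste(round(prophageBoundaries),
                                    collapse = ", ")))
  } else if (length(plasmidGenes) && length(markers) == 0L) {
    type <- "plasmid_like"
    trace <- c(trace, sprintf("rule 2: plasmid genes (%s), no phage markers",
                              paste(head(plasmidGenes, 3L), collapse = "; ")))
  } else if (length(markers) || phageOverride ||
             (is.na(domainWinner) && hypoFraction >= hypoHigh)) {
    type <- "phage"
    trace <- c(trace, if (length(markers))
      sprintf("rule 3: phage markers (%s)", paste(markers, collapse = ", "))
      else if (phageOverride) "rule 3: phage placement override"
      else sprintf("rule 3: no domain winner and hypothetical fraction %.2f >= %.2f",
                   hypoFraction, hypoHigh))
  } else {
    type <- "unknown"
    trace <- c(trace, "rule 4: no rule fired")
  }
  new("ClassificationResult", contigId = contigId, elementType = type,
      hypotheticalFraction = hypoFraction,
      markersFound = as.character(markers), ruleTrace = trace,
      lengthException = lengthException, retained = retained)
}
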