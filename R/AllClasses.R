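#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats median rlnorm rnorm runif setNames quantile cor
#' @importFrom utils write.table read.delim head tail combn
#' @importFrom graphics hist
NULL

#' Genetic code for ORF calling
#'
#' A minimal genetic-code descriptor: which codons terminate translation and
#' which canonical stop codons have been reassigned to an amino acid. Bacterial
#' code 11 is the default; the recoded variants model stop-codon reassignment
#' as observed in some huge phages (for example the amber/TAG codon read as an
#' amino acid).
#'
#' @slot id Code identifier (for example `"code11"`, `"TAG_recoded"`).
#' @slot stopCodons Character vector of codons treated as stops.
#' @slot reassigned Named character vector mapping reassigned codons to the
#'   single-letter amino acid they are read as (`"X"` when unknown).
#' @export
setClass("GeneticCode",
  representation(id = "character", stopCodons = "character",
                 reassigned = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@stopCodons) < 1L)
      msg <- c(msg, "a genetic code must retain at least one stop codon")
    if (any(names(object@reassigned) %in% object@stopCodons))
      msg <- c(msg, "reassigned codons must be disjoint from stop codons")
    if (is.null(msg)) TRUE else msg
  })

#' GC-skew profile of a contig
#'
#' Windowed (G-C)/(G+C) values plus the cumulative per-window G-C excess used
#' to infer the replication mode. The cumulative curve of a bidirectionally
#' replicating genome is piecewise linear with slope changes at the origin and
#' terminus; a unidirectional replicator gives a single consistent slope.
#'
#' @slot window,step Window and step size in bp.
#' @slot positions Window center positions (bp).
#' @slot skew Per-window (G-C)/(G+C); windows with G+C == 0 yield 0.
#' @slot cumulative Running sum of per-window (G-C) counts.
#' @slot breakpoints Inferred breakpoint positions (0-2 values, bp).
#' @slot mode One of `"bidirectional"`, `"unidirectional"`, `"none"`.
#' @slot fitQuality R-squared of the winning piecewise-linear fit (0-1).
#' @export
setClass("SkewProfile",
  representation(window = "numeric", step = "numeric", positions = "numeric",
                 skew = "numeric", cumulative = "numeric",
                 breakpoints = "numeric", mode = "character",
                 fitQuality = "numeric"),
  prototype(breakpoints = numeric(), mode = "none", fitQuality = NA_real_),
  validity = function(object) {
    msg <- NULL
    if (length(object@positions) != length(object@skew))
      msg <- c(msg, "positions and skew must have equal length")
    if (length(object@cumulative) != length(object@skew))
      msg <- c(msg, "cumulative and skew must have equal length")
    if (length(object@breakpoints) > 2L)
      msg <- c(msg, "at most two breakpoints are allowed")
    if (!object@mode %in% c("bidirectional", "unidirectional", "none"))
      msg <- c(msg, "mode must be bidirectional, unidirectional or none")
    if (is.null(msg)) TRUE else msg
  })

#' CRISPR array
#'
#' An ordered run of near-identical direct repeats separated by unique
#' spacers. Coordinates are 1-based inclusive on the forward strand of the
#' contig; the array spans the first to the last repeat. Orientation is
#' reported as detected (`"unknown"`), no repeat-degeneracy orientation call
#' is attempted.
#'
#' @slot contigId Contig the array lies on.
#' @slot start,end Array span (first repeat start to last repeat end).
#' @slot repeats `data.frame` with columns `start`, `end`, `seq`.
#' @slot spacers `data.frame` with columns `id`, `start`, `end`, `seq`.
#' @slot consensusRepeat Per-column majority consensus of the repeat copies.
#' @slot orientation `"unknown"` (kept for interface stability).
#' @export
setClass("CrisprArray",
  representation(contigId = "character", start = "numeric", end = "numeric",
                 repeats = "data.frame", spacers = "data.frame",
                 consensusRepeat = "character", orientation = "character"),
  prototype(orientation = "unknown"),
  validity = function(object) {
    msg <- NULL
    nr <- nrow(object@repeats)
    ns <- nrow(object@spacers)
    if (nr < 2L) msg <- c(msg, "an array needs at least two repeats")
    if (ns != nr - 1L)
      msg <- c(msg, "repeats and spacers must strictly alternate (n_spacers == n_repeats - 1)")
    if (nr >= 1L && (object@start != object@repeats$start[1L] ||
                     object@end != object@repeats$end[nr]))
      msg <- c(msg, "array span must run from first to last repeat")
    if (is.null(msg)) TRUE else msg
  })

#' Element-type classification of a contig
#'
#' Result of the rule engine that assigns each large contig to
#' phage / plasmid-like / prophage-containing / unknown, with the ordered rule
#' trace that produced the call.
#'
#' @slot contigId Contig identifier.
#' @slot elementType `"phage"`, `"plasmid_like"`, `"prophage_containing"` or
#'   `"unknown"`.
#' @slot hypotheticalFraction Fraction of genes without a functional keyword.
#' @slot markersFound Phage marker classes detected.
#' @slot ruleTrace Ordered record of rule firings.
#' @slot lengthException `TRUE` only for CRISPR-bearing contigs under the
#'   length threshold that were retained anyway.
#' @slot retained Whether the contig passes the length gate.
#' @export
setClass("ClassificationResult",
  representation(contigId = "character", elementType = "character",
                 hypotheticalFraction = "numeric", markersFound = "character",
                 ruleTrace = "character", lengthException = "logical",
                 retained = "logical"),
  validity = function(object) {
    msg <- NULL
    ok <- c("phage", "plasmid_like", "prophage_containing", "unknown")
    if (!object@elementType %in% ok)
      msg <- c(msg, paste("elementType must be one of:", paste(ok, collapse = ", ")))
    if (!is.na(object@hypotheticalFraction) &&
        (object@hypotheticalFraction < 0 || object@hypotheticalFraction > 1))
      msg <- c(msg, "hypotheticalFraction must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Genetic-code inference result
#'
#' @slot contigId Contig identifier.
#' @slot chosenCode Winning code id.
#' @slot densityByCode Named numeric vector of coding densities per code.
#' @slot flagged `TRUE` when the code-11 density fell below the flag
#'   threshold and alternative codes were evaluated.
#' @slot ruledOut `data.frame` with columns `code`, `reason`.
#' @export
setClass("CodeInferenceResult",
  representation(contigId = "character", chosenCode = "character",
                 densityByCode = "numeric", flagged = "logical",
                 ruledOut = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!object@chosenCode %in% names(object@densityByCode))
      msg <- c(msg, "chosenCode must be present in densityByCode")
    d <- object@densityByCode
    if (any(!is.na(d) & (d < 0 | d > 1)))
      msg <- c(msg, "densities must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Specification of a synthetic phage-host community
#'
#' Describes the community the generator emits: how many phage, host and
#' plasmid-like contigs, their sizes and base composition, and which genomic
#' features (terminal overlaps, concatemer artifacts, GC skew, recoded stop
#' codons, CRISPR arrays and spacer-protospacer links, annotation vote
#' profiles) are planted in which genome. Constructed with
#' [communitySpec()]; every field of the default corresponds to a feature the
#' downstream modules are expected to recover.
#'
#' @slot seed Integer seed driving the single RNG stream.
#' @slot genomes `data.frame` with one row per planned contig (id, role,
#'   length, gcContent, skewMode, geneticCode, terminalOverlapBp,
#'   concatemerUnits, phylum, hostPhylum, prophage flag, ...).
#' @slot plantedArrays `data.frame` of CRISPR arrays to plant (contig,
#'   repeatLen, nRepeats, spacerLen).
#' @slot crisprLinks `data.frame` of spacer-protospacer links to plant
#'   (sourceContig, targetContig, mismatches).
#' @slot params Named list of scalar generator parameters (skew amplitude,
#'   TAG usage rate in recoded genomes, hypothetical fractions, vote
#'   fractions, protein-family layout, ...).
#' @export
setClass("CommunitySpec",
  representation(seed = "integer", genomes = "data.frame",
                 plantedArrays = "data.frame", crisprLinks = "data.frame",
                 params = "list"),
  validity = function(object) {
    msg <- NULL
    g <- object@genomes
    need <- c("id", "role", "length", "gcContent", "skewMode", "geneticCode",
              "terminalOverlapBp", "concatemerUnits")
    if (!all(need %in% names(g)))
      msg <- c(msg, paste("genomes table must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(g$length <= 0)) msg <- c(msg, "all genome lengths must be positive")
      if (any(g$gcContent <= 0 | g$gcContent >= 1))
        msg <- c(msg, "gcContent must lie strictly in (0, 1)")
      if (any(g$concatemerUnits < 1)) msg <- c(msg, "concatemerUnits must be >= 1")
      if (any(g$terminalOverlapBp < 0)) msg <- c(msg, "terminalOverlapBp must be >= 0")
      if (any(g$terminalOverlapBp > 0 & g$concatemerUnits > 1))
        msg <- c(msg, "a genome cannot have both a terminal overlap and concatemer units")
      if (anyDuplicated(g$id)) msg <- c(msg, "genome ids must be unique")
      if (!all(g$skewMode %in% c("bidirectional", "unidirectional", "none")))
        msg <- c(msg, "skewMode must be bidirectional, unidirectional or none")
    }
    pa <- object@plantedArrays
    if (nrow(pa) && !all(pa$contig %in% g$id))
      msg <- c(msg, "plantedArrays reference unknown contig ids")
    cl <- object@crisprLinks
    if (nrow(cl)) {
      if (!all(c(cl$sourceContig, cl$targetContig) %in% g$id))
        msg <- c(msg, "crisprLinks reference unknown contig ids")
      if (any(cl$mismatches < 0 | cl$mismatches > 3))
        msg <- c(msg, "crisprLinks: mismatches must be between 0 and 3")
      if (nrow(pa) && !all(cl$sourceContig %in% pa$contig))
        msg <- c(msg, "crisprLinks: sourceContig must carry a planted array")
    }
    vf <- object@params$voteFractions
    if (!is.null(vf) && any(vapply(vf, sum, 0) > 1 + 1e-9))
      msg <- c(msg, "vote fractions per genome must sum to <= 1")
    if (is.null(msg)) TRUE else msg
  })

#' A generated synthetic community
#'
#' Bundle of everything [generateCommunity()] emits: the contig sequences,
#' the per-gene annotation table (standing in for database search results),
#' protein-protein similarity edge tables, a per-genome tRNA-count table and
#' the machine-readable ground-truth ledger used by the test suite.
#'
#' @slot contigs A [Biostrings::DNAStringSet] of contig sequences.
#' @slot annotations Per-gene annotation hits (contig_id, gene_id, lineage
#'   columns domain..genus, keyword, bitscore).
#' @slot proteinEdges List with elements `allvsall` and `profile`, the two
#'   similarity edge tables consumed by the family-clustering module.
#' @slot trnaTable Per-genome tRNA counts and sizes.
#' @slot truth Ground-truth ledger (per-contig planted features).
#' @slot spec The [CommunitySpec-class] that produced the community.
#' @export
setClass("SyntheticCommunity",
  representation(contigs = "DNAStringSet", annotations = "data.frame",
                 proteinEdges = "list", trnaTable = "data.frame",
                 truth = "list", spec = "CommunitySpec"),
  validity = function(object) {
    msg <- NULL
    if (!all(names(object@truth$contigs) %in% names(object@contigs)))
      msg <- c(msg, "truth ledger references unknown contigs")
    if (nrow(object@annotations) &&
        !all(object@annotations$contig_id %in% names(object@contigs)))
      msg <- c(msg, "annotations reference unknown contigs")
    if (is.null(msg)) TRUE else msg
  })
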