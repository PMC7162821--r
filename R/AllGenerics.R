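#' @include AllClasses.R
NULL

#' Accessors for synthetic communities and result objects
#'
#' `contigs()` returns the contig sequences, `annotations()` the per-gene
#' annotation table, `communityTruth()` the planted ground-truth ledger and
#' `communitySpecOf()` the generating specification of a
#' [SyntheticCommunity-class]. `elementType()`, `ruleTrace()`,
#' `consensusRepeat()`, `spacers()`, `repeats()`, `skewMode()` and
#' `breakpoints()` expose the corresponding slots of result objects.
#'
#' @param x A package object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("communityTruth", function(x) standardGeneric("communityTruth"))
#' @rdname accessors
#' @export
setGeneric("communitySpecOf", function(x) standardGeneric("communitySpecOf"))
#' @rdname accessors
#' @export
setGeneric("proteinEdges", function(x) standardGeneric("proteinEdges"))
#' @rdname accessors
#' @export
setGeneric("trnaTable", function(x) standardGeneric("trnaTable"))
#' @rdname accessors
#' @export
setGeneric("elementType", function(x) standardGeneric("elementType"))
#' @rdname accessors
#' @export
setGeneric("ruleTrace", function(x) standardGeneric("ruleTrace"))
#' @rdname accessors
#' @export
setGeneric("consensusRepeat", function(x) standardGeneric("consensusRepeat"))
#' @rdname accessors
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))
#' @rdname accessors
#' @export
setGeneric("repeats", function(x) standardGeneric("repeats"))
#' @rdname accessors
#' @export
setGeneric("skewMode", function(x) standardGeneric("skewMode"))
#' @rdname accessors
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname accessors
#' @export
setGeneric("chosenCode", function(x) standardGeneric("chosenCode"))
#' @rdname accessors
#' @export
setGeneric("densityByCode", function(x) standardGeneric("densityByCode"))

setMethod("contigs", "SyntheticCommunity", function(x) x@contigs)
setMethod("annotations", "SyntheticCommunity", function(x) x@annotations)
setMethod("communityTruth", "SyntheticCommunity", function(x) x@truth)
setMethod("communitySpecOf", "SyntheticCommunity", function(x) x@spec)
setMethod("proteinEdges", "SyntheticCommunity", function(x) x@proteinEdges)
setMethod("trnaTable", "SyntheticCommunity", function(x) x@trnaTable)
setMethod("elementType", "ClassificationResult", function(x) x@elementType)
setMethod("ruleTrace", "ClassificationResult", function(x) x@ruleTrace)
setMethod("consensusRepeat", "CrisprArray", function(x) x@consensusRepeat)
setMethod("spacers", "CrisprArray", function(x) x@spacers)
setMethod("repeats", "CrisprArray", function(x) x@repeats)
setMethod("skewMode", "SkewProfile", function(x) x@mode)
setMethod("breakpoints", "SkewProfile", function(x) x@breakpoints)
setMethod("chosenCode", "CodeInferenceResult", function(x) x@chosenCode)
setMethod("densityByCode", "CodeInferenceResult", function(x) x@densityByCode)

setMethod("show", "SyntheticCommunity", function(object) {
  g <- object@spec@genomes
  cat("SyntheticCommunity with", length(object@contigs), "contigs",
      sprintf("(%d phage, %d host, %d plasmid-like)\n",
              sum(g$role == "phage"), sum(g$role == "host"),
              sum(g$role == "plasmid")))
  cat("  total length:", sum(Biostrings::width(object@contigs)), "bp\n")
  cat("  annotated genes:", nrow(object@annotations), "\n")
  cat("  seed:", object@spec@seed, "\n")
})

setMethod("show", "SkewProfile", function(object) {
  cat("SkewProfile:", length(object@positions), "windows",
      sprintf("(window %d bp, step %d bp)\n", as.integer(object@window),
              as.integer(object@step)))
  cat("  mode:", object@mode)
  if (length(object@breakpoints))
    cat("; breakpoints at", paste(round(object@breakpoints), collapse = ", "), "bp")
  cat("\n  fit quality (R^2):", round(object@fitQuality, 3), "\n")
})

setMethod("show", "CrisprArray", function(object) {
  cat(sprintf("CrisprArray on %s: %d-%d (%d repeats, %d spacers)\n",
              object@contigId, as.integer(object@start), as.integer(object@end),
              nrow(object@repeats), nrow(object@spacers)))
  cat("  consensus repeat:", object@consensusRepeat, "\n")
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult for %s: %s%s\n", object@contigId,
              object@elementType,
              if (object@lengthException) " (length exception)" else ""))
  cat("  markers:", if (length(object@markersFound))
    paste(object@markersFound, collapse = ", ") else "none", "\n")
  cat("  hypothetical fraction:", round(object@hypotheticalFraction, 3), "\n")
  cat("  rule trace:", paste(object@ruleTrace, collapse = " -> "), "\n")
})

setMethod("show", "CodeInferenceResult", function(object) {
  cat("CodeInferenceResult:", object@chosenCode,
      if (object@flagged) "(low code-11 density flagged)" else "", "\n")
  d <- object@densityByCode
  cat(paste(sprintf("  %s: %.3f", names(d), d), collapse = "\n"), "\n")
  if (nrow(object@ruledOut))
    cat("  ruled out:", paste(object@ruledOut$code, collapse = ", "), "\n")
})

setMethod("show", "CommunitySpec", function(object) {
  g <- object@genomes
  cat("CommunitySpec (seed", object@seed, "):",
      nrow(g), "genomes,", nrow(object@plantedArrays), "planted arrays,",
      nrow(object@crisprLinks), "spacer links\n")
})
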