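#' Built-in genetic codes
#'
#' Returns a [GeneticCode-class] descriptor. `code11` is the standard
#' bacterial table (stops TAA, TAG, TGA). `TAG_recoded` reads the amber stop
#' as glutamine (as in some human/animal-associated huge phages),
#' `TGA_recoded` reads opal as tryptophan, and `code6_like` retains only TGA
#' as a stop (both TAA and TAG read as glutamine). Further codes can be built
#' directly with [methods::new()] on the class.
#'
#' @param id One of `"code11"`, `"TAG_recoded"`, `"TGA_recoded"`,
#'   `"code6_like"`.
#' @return A [GeneticCode-class] object.
#' @examples
#' geneticCode("TAG_recoded")
#' @export
geneticCode <- function(id = c("code11", "TAG_recoded", "TGA_recoded",
                               "code6_like")) {
  id <- match.arg(id)
  switch(id,
    code11 = new("GeneticCode", id = "code11",
                 stopCodons = c("TAA", "TAG", "TGA"),
                 reassigned = character()),
    TAG_recoded = new("GeneticCode", id = "TAG_recoded",
                      stopCodons = c("TAA", "TGA"),
                      reassigned = c(TAG = "Q")),
    TGA_recoded = new("GeneticCode", id = "TGA_recoded",
                      stopCodons = c("TAA", "TAG"),
                      reassigned = c(TGA = "W")),
    code6_like = new("GeneticCode", id = "code6_like",
                     stopCodons = "TGA",
                     reassigned = c(TAA = "Q", TAG = "Q")))
}

START_CODONS <- c("ATG", "GTG", "TTG")

# Split a base vector into codon strings for one frame (frame in 0:2).
# Returns the codon strings and the 1-based nt position of each codon start.
.frameCodons <- function(bv, frame) {
  n <- length(bv)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L)
    return(list(codons = character(), starts = integer()))
  list(codons = paste0(bv[starts], bv[starts + 1L], bv[starts + 2L]),
       starts = starts)
}

# ORFs for one frame of one strand, in codon indices:
# data.frame(startCodon, stopCodon) where both are indices into the codon
# vector and the ORF runs from a start codon to (and including) a stop codon.
.frameOrfs <- function(codons, stopSet, minLenCodons) {
  nc <- length(codons)
  if (nc == 0L) return(NULL)
  stopIdx <- which(codons %in% stopSet)
  if (length(stopIdx) == 0L) return(NULL)
  startIdx <- which(codons %in% START_CODONS)
  if (length(startIdx) == 0L) return(NULL)
  # region of a start codon: index of the next stop at or after it
  reg <- findInterval(startIdx - 1L, stopIdx) + 1L     # 1..length(stopIdx)+1
  ok <- reg <= length(stopIdx)
  startIdx <- startIdx[ok]; reg <- reg[ok]
  if (length(startIdx) == 0L) return(NULL)
  first <- !duplicated(reg)                            # first start per region
  st <- startIdx[first]
  sp <- stopIdx[reg[first]]
  lenCod <- sp - st + 1L
  keep <- lenCod >= minLenCodons
  if (!any(keep)) return(NULL)
  data.frame(startCodon = st[keep], stopCodon = sp[keep])
}

#' Call open reading frames under a genetic code
#'
#' A minimal six-frame ORF caller: on each strand and frame, maximal ORFs
#' start at the first in-frame start codon (ATG/GTG/TTG) following a stop (or
#' the sequence start) and end at the next stop codon of the code. ORFs that
#' run off the end of the sequence without a stop are not called. Overlapping
#' calls across frames and strands are resolved greedily by length, ties by
#' leftmost position then by the forward strand.
#'
#' Coordinates are 1-based inclusive on the forward axis; reverse-strand calls
#' report `strand == "-"` with `start < end` on the forward axis.
#'
#' @param contig A DNAString / DNAStringSet of length 1 / character scalar.
#' @param code A [GeneticCode-class] (default code 11).
#' @param minLenCodons Minimum ORF length in codons, stop codon included.
#' @param resolveOverlaps Resolve overlapping calls greedily (default `TRUE`).
#' @return `data.frame` with columns `start`, `end`, `strand`, `frame`,
#'   `lengthCodons`.
#' @export
callOrfs <- function(contig, code = geneticCode("code11"), minLenCodons = 60L,
                     resolveOverlaps = TRUE) {
  x <- .asDNA(contig)
  n <- length(x)
  if (n < 3L * minLenCodons)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      lengthCodons = integer()))
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c("+", "-")) {
    bv <- .s2c(as.character(if (strand == "+") x else
      Biostrings::reverseComplement(x)))
    for (frame in 0:2) {
      fc <- .frameCodons(bv, frame)
      orf <- .frameOrfs(fc$codons, code@stopCodons, minLenCodons)
      k <- k + 1L
      if (is.null(orf)) next
      sNt <- fc$starts[orf$startCodon]
      eNt <- fc$starts[orf$stopCodon] + 2L
      if (strand == "-") {                 # map back to forward axis
        tmp <- n - eNt + 1L
        eNt <- n - sNt + 1L
        sNt <- tmp
      }
      out[[k]] <- data.frame(start = sNt, end = eNt, strand = strand,
                             frame = frame,
                             lengthCodons = orf$stopCodon - orf$startCodon + 1L)
    }
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(calls))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      lengthCodons = integer()))
  if (resolveOverlaps && nrow(calls) > 1L) {
    ord <- order(-calls$lengthCodons, calls$start,
                 match(calls$strand, c("+", "-")))
    calls <- calls[ord, , drop = FALSE]
    mask <- logical(n)
    keep <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      s <- calls$start[i]; e <- calls$end[i]
      if (!any(mask[s:e])) {
        keep[i] <- TRUE
        mask[s:e] <- TRUE
      }
    }
    calls <- calls[keep, , drop = FALSE]
  }
  calls <- calls[order(calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Coding density of a contig
#'
#' Fraction of positions covered by at least one gene (union over both
#' strands).
#'
#' @param contig Contig sequence (or its length as a single number).
#' @param genes `data.frame` with `start`, `end` columns as from [callOrfs()].
#' @return A fraction in \[0, 1\].
#' @export
codingDensity <- function(contig, genes) {
  n <- if (is.numeric(contig) && length(contig) == 1L) contig
       else length(.asDNA(contig))
  if (nrow(genes) == 0L) return(0)
  if (any(genes$start < 1L) || any(genes$end > n))
    stop("gene coordinates fall outside the contig")
  ir <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  sum(IRanges::width(ir)) / n
}

#' Infer the genetic code of a contig from coding density
#'
#' Genomes using a non-standard genetic code show anomalously low coding
#' density when genes are called under code 11, because reassigned stop
#' codons truncate ORFs. When the code-11 density falls below
#' `flagThreshold`, ORFs are re-called under each candidate recoded table and
#' an alternative is chosen only when its density exceeds the code-11 density
#' by more than `margin`. Candidate codes that retain a single stop codon are
#' additionally screened for implausible gene fusions: the candidate is ruled
#' out (reason `"gene fusion"`) when its 95th-percentile gene length exceeds
#' 3x that of the code-11 calls, or when more than 20% of its genes each span
#' three or more code-11 genes.
#'
#' @param contig Contig sequence.
#' @param flagThreshold Code-11 density below which alternatives are tried.
#' @param margin Required density gain over code 11.
#' @param candidates Candidate code ids to evaluate (see [geneticCode()]).
#' @param minLenCodons Passed to [callOrfs()].
#' @param contigId Identifier recorded in the result.
#' @return A [CodeInferenceResult-class].
#' @export
inferGeneticCode <- function(contig, flagThreshold = 0.78, margin = 0.10,
                             candidates = c("TAG_recoded", "TGA_recoded"),
                             minLenCodons = 60L, contigId = "contig") {
  x <- .asDNA(contig)
  g11 <- callOrfs(x, geneticCode("code11"), minLenCodons)
  d11 <- codingDensity(length(x), g11)
  dens <- c(code11 = d11)
  ruledOut <- data.frame(code = character(), reason = character())
  if (d11 >= flagThreshold)
    return(new("CodeInferenceResult", contigId = contigId,
               chosenCode = "code11", densityByCode = dens, flagged = FALSE,
               ruledOut = ruledOut))
  ir11 <- IRanges::IRanges(g11$start, g11$end)
  q95_11 <- if (nrow(g11)) quantile(g11$lengthCodons, 0.95, names = FALSE) else 0
  best <- "code11"
  for (cid in candidates) {
    cd <- geneticCode(cid)
    g <- callOrfs(x, cd, minLenCodons)
    d <- codingDensity(length(x), g)
    dens[cid] <- d
    if (length(cd@stopCodons) == 1L && nrow(g) && nrow(g11)) {
      q95 <- quantile(g$lengthCodons, 0.95, names = FALSE)
      spans <- IRanges::countOverlaps(IRanges::IRanges(g$start, g$end), ir11,
                                      type = "any")
      fusion <- (q95 > 3 * q95_11) || (mean(spans >= 3L) > 0.20)
      if (fusion) {
        ruledOut <- rbind(ruledOut,
                          data.frame(code = cid, reason = "gene fusion"))
        next
      }
    }
    if (d > d11 + margin && (best == "code11" || d > dens[best]))
      best <- cid
  }
  new("CodeInferenceResult", contigId = contigId, chosenCode = best,
      densityByCode = dens, flagged = TRUE, ruledOut = ruledOut)
}

#' Translate gene calls to protein sequences
#'
#' Translates each call under the given code; reassigned codons are rendered
#' as their reassigned amino acid, remaining in-frame canonical stops (other
#' than the terminal one) as `"*"`.
#'
#' @param contig Contig sequence.
#' @param genes Gene table from [callOrfs()].
#' @param code The [GeneticCode-class] used for the calls.
#' @return An [Biostrings::AAStringSet] (terminal stop trimmed).
#' @export
translateGenes <- function(contig, genes, code = geneticCode("code11")) {
  x <- .asDNA(contig)
  gcode <- Biostrings::getGeneticCode("11")
  for (cd in names(code@reassigned)) gcode[cd] <- code@reassigned[[cd]]
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(genes)), function(i) {
    s <- Biostrings::subseq(x, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  aa <- Biostrings::translate(seqs, genetic.code = gcode,
                              if.fuzzy.codon = "X")
  Biostrings::subseq(aa, 1L, Biostrings::width(aa) - 1L)
}
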