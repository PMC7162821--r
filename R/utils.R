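# Internal sequence helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# character string -> character vector of single bases
.s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.c2s <- function(v) paste(v, collapse = "")

.revcompChar <- function(v) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[v]))
}

.revcompStr <- function(s) .c2s(.revcompChar(.s2c(s)))

# Coerce contig input to a single DNAString.
.asDNA <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  Biostrings::DNAString(x)
}

# Base probabilities (A, C, G, T) at a given GC content, with the G/C pair
# skewed by a signed amplitude: sigma = +1 means G excess, -1 means C excess.
.baseProbs <- function(gc, skewAmp = 0, sigma = 0) {
  at <- (1 - gc) / 2
  p <- c(A = at,
         C = gc / 2 * (1 - skewAmp * sigma),
         G = gc / 2 * (1 + skewAmp * sigma),
         T = at)
  p / sum(p)
}

# Sample n iid bases under the given probabilities; returns a character vector.
.sampleBases <- function(n, probs) {
  if (n <= 0L) return(character())
  sample(BASES, n, replace = TRUE, prob = probs[BASES])
}

# All 64 codons in a fixed order.
.allCodons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

# Codon sampling table: codons (minus the excluded ones) with probabilities
# proportional to the product of base probabilities.
.codonTable <- function(probs, exclude = character()) {
  cods <- .allCodons()
  p <- vapply(cods, function(cd) prod(probs[.s2c(cd)]), numeric(1))
  keep <- !cods %in% exclude
  list(codons = cods[keep], probs = p[keep] / sum(p[keep]))
}

# Positions (1-based) covered by a set of [start, end] intervals, as a
# logical mask of length n.
.coverMask <- function(n, starts, ends) {
  mask <- logical(n)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  mask
}

# Do [s, e] and any of the reserved intervals overlap?
.overlapsAny <- function(s, e, reserved) {
  if (is.null(reserved) || nrow(reserved) == 0L) return(FALSE)
  any(s <= reserved$end & e >= reserved$start)
}

# Derive a bounded sub-seed from a master seed and a stream label, keeping
# the result well inside 32-bit integer range.
.subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}
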