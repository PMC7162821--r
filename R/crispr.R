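# De novo CRISPR array detection, spacer-protospacer matching under the
# strict (>24 bp, <=1 mismatch) and expanded (<=3 mismatches, same target)
# tiers, repeat comparison and the derived interaction network.

#' @importFrom Biostrings mismatch nmismatch
NULL

# 2-bit encode a base vector; returns integer codes of all k-mers (or NA at
# positions containing non-ACGT).
.kmerCodes <- function(bv, k) {
  n <- length(bv)
  b <- match(bv, BASES) - 1L
  np <- n - k + 1L
  if (np < 1L) return(integer())
  code <- numeric(np)
  for (i in seq_len(k)) code <- code * 4 + b[i:(i + np - 1L)]
  code
}

# Count mismatches between two equal-length char windows.
.hamming <- function(a, b) sum(a != b)

#' Detect CRISPR arrays de novo
#'
#' CRT-style detection: exact 8-mer seeds recurring at an admissible period
#' (repeat length + spacer length bounds) nominate a repeat pair, which is
#' extended to the maximal exact match between the two copies; the repeat is
#' then walked left and right across the contig, allowing up to one mismatch
#' per additional copy, while spacer lengths stay within bounds. Array
#' boundaries are refined so every column of the repeat agrees across (all
#' but at most one of) the copies; the consensus is the per-column majority.
#' Arrays need at least `minRepeats` repeat copies.
#'
#' @param contig Contig sequence.
#' @param contigId Identifier recorded on the arrays.
#' @param minRepeats Minimum number of repeat copies (default 3).
#' @param repeatLen Admissible repeat length range in bp.
#' @param spacerLen Admissible spacer length range in bp.
#' @param seedK Seed k-mer size.
#' @return List of [CrisprArray-class] objects (possibly empty).
#' @export
detectArrays <- function(contig, contigId = "contig", minRepeats = 3L,
                         repeatLen = c(19L, 48L), spacerLen = c(17L, 72L),
                         seedK = 8L) {
  x <- .asDNA(contig)
  n <- length(x)
  bv <- .s2c(as.character(x))
  minPeriod <- repeatLen[1L] + spacerLen[1L]
  maxPeriod <- repeatLen[2L] + spacerLen[2L]
  if (n < 2L * minPeriod) return(list())
  codes <- .kmerCodes(bv, seedK)
  ord <- order(codes, method = "radix")
  cs <- codes[ord]
  grpNew <- c(TRUE, cs[-1L] != cs[-length(cs)])
  grp <- cumsum(grpNew)
  sizes <- tabulate(grp)
  covered <- logical(n)
  arrays <- list()

  # candidate seed pairs (two-pointer within each multi-occurrence k-mer)
  candidates <- NULL
  multi <- which(sizes > 1L)
  if (length(multi)) {
    posByGrp <- split(ord, grp)
    for (gi in multi) {
      p <- sort(posByGrp[[gi]])
      for (a in seq_len(length(p) - 1L)) {
        b <- a + 1L
        while (b <= length(p) && p[b] - p[a] <= maxPeriod) {
          if (p[b] - p[a] >= minPeriod)
            candidates <- rbind(candidates, c(p[a], p[b]))
          b <- b + 1L
        }
      }
    }
  }
  if (is.null(candidates)) return(list())
  candidates <- candidates[order(candidates[, 1L]), , drop = FALSE]

  matchNear <- function(pat, lo, hi, mism = 1L) {
    # first occurrence of pat in x[lo..hi] with <= mism mismatches
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi - lo + 1L < nchar(pat)) return(NA_integer_)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::subseq(x, lo, hi),
                                  max.mismatch = mism)
    if (length(m) == 0L) return(NA_integer_)
    Biostrings::start(m)[1L] + lo - 1L
  }

  for (ci in seq_len(nrow(candidates))) {
    i <- candidates[ci, 1L]; j <- candidates[ci, 2L]
    if (covered[i] || covered[j]) next
    period <- j - i
    # exact extension of the seed between the two copies
    l <- 0L
    while (i - l - 1L >= 1L && j - l - 1L >= 1L &&
           bv[i - l - 1L] == bv[j - l - 1L] && l < repeatLen[2L]) l <- l + 1L
    r <- 0L
    while (j + seedK + r <= n && i + seedK + r <= n &&
           bv[i + seedK + r] == bv[j + seedK + r] &&
           seedK + r < repeatLen[2L]) r <- r + 1L
    repLen <- seedK + l + r
    if (repLen < repeatLen[1L] || repLen > repeatLen[2L]) next
    s1 <- i - l
    spLen1 <- period - repLen
    if (spLen1 < spacerLen[1L] || spLen1 > spacerLen[2L]) next
    repSeq <- .c2s(bv[s1:(s1 + repLen - 1L)])

    starts <- c(s1, s1 + period)
    # walk right (2 mismatches absorb chance over-extension of the seed pair)
    repeat {
      last <- starts[length(starts)]
      lo <- last + repLen + spacerLen[1L]
      hi <- last + repLen + spacerLen[2L] + repLen - 1L
      nxt <- matchNear(repSeq, lo, hi, mism = 2L)
      if (is.na(nxt)) break
      starts <- c(starts, nxt)
    }
    # walk left
    repeat {
      first <- starts[1L]
      hi <- first - spacerLen[1L] - 1L
      lo <- first - spacerLen[2L] - repLen
      prv <- matchNear(repSeq, lo, hi, mism = 2L)
      if (is.na(prv) || prv + repLen - 1L + spacerLen[1L] > first) break
      starts <- c(prv, starts)
    }
    if (length(starts) < minRepeats) next

    # boundary refinement across all copies: the repeat is the maximal run
    # of (near-)unanimous columns overlapping the seed, so boundaries come
    # from the full array rather than from chance extension of one copy pair
    seedOff <- i - s1                       # seed offset within the repeat
    cores <- starts + seedOff               # seed start in every copy
    nc <- length(cores)
    maxDissent <- as.integer(nc >= 6L)
    colOK <- function(offs) {
      pos <- cores + offs
      if (min(pos) < 1L || max(pos) > n) return(FALSE)
      tb <- tabulate(match(bv[pos], BASES), 4L)
      max(tb) >= nc - maxDissent
    }
    offWin <- seq(-(repeatLen[2L] - 1L), seedK + repeatLen[2L] - 2L)
    unan <- vapply(offWin, colOK, TRUE)
    rl <- rle(unan)
    rEnds <- cumsum(rl$lengths)
    rStarts <- rEnds - rl$lengths + 1L
    bestRun <- 0L; bestOv <- 0L
    for (q in which(rl$values)) {
      a <- offWin[rStarts[q]]; b <- offWin[rEnds[q]]
      ov <- min(b, seedK - 1L) - max(a, 0L) + 1L
      if (ov > bestOv || (ov == bestOv && ov > 0L && bestRun > 0L &&
                          (b - a) > diff(range(offWin[c(rStarts[bestRun],
                                                        rEnds[bestRun])])))) {
        bestRun <- q; bestOv <- ov
      }
    }
    if (bestRun == 0L || bestOv <= 0L) next
    a <- offWin[rStarts[bestRun]]; b <- offWin[rEnds[bestRun]]
    repLen <- b - a + 1L
    if (repLen < repeatLen[1L] || repLen > repeatLen[2L]) next
    starts <- cores + a

    # check spacer bounds between consecutive repeats; trim to the maximal
    # consistent run of copies
    gapLens <- diff(starts) - repLen
    okGap <- gapLens >= spacerLen[1L] & gapLens <= spacerLen[2L]
    if (!all(okGap)) {
      runs <- rle(okGap)
      stops <- cumsum(runs$lengths)
      bi <- which.max(ifelse(runs$values, runs$lengths, 0L))
      from <- if (bi == 1L) 1L else stops[bi - 1L] + 1L
      starts <- starts[from:(stops[bi] + 1L)]
      if (length(starts) < minRepeats) next
    }

    copies <- Biostrings::DNAStringSet(vapply(starts, function(s0)
      .c2s(bv[s0:(s0 + repLen - 1L)]), ""))
    cm <- Biostrings::consensusMatrix(copies)[BASES, , drop = FALSE]
    consensus <- .c2s(BASES[apply(cm, 2L, which.max)])
    nr <- length(starts)
    repDf <- data.frame(start = starts, end = starts + repLen - 1L,
                        seq = as.character(copies))
    spDf <- data.frame(
      id = sprintf("%s_arr%d_sp%02d", contigId, length(arrays) + 1L,
                   seq_len(nr - 1L)),
      start = starts[-nr] + repLen,
      end = starts[-1L] - 1L)
    spDf$seq <- vapply(seq_len(nr - 1L), function(q)
      .c2s(bv[spDf$start[q]:spDf$end[q]]), "")
    arrays[[length(arrays) + 1L]] <-
      new("CrisprArray", contigId = contigId, start = starts[1L],
          end = starts[nr] + repLen - 1L, repeats = repDf, spacers = spDf,
          consensusRepeat = consensus, orientation = "unknown")
    covered[starts[1L]:(starts[nr] + repLen - 1L)] <- TRUE
  }
  arrays
}

# Spacer table from a list of arrays.
.spacerTable <- function(arrays) {
  if (length(arrays) == 0L)
    return(data.frame(id = character(), seq = character(),
                      arrayId = character(), sourceContig = character(),
                      start = integer(), end = integer()))
  do.call(rbind, lapply(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    sp <- a@spacers
    data.frame(id = sp$id, seq = sp$seq,
               arrayId = sprintf("%s_arr%d", a@contigId, i),
               sourceContig = a@contigId, start = sp$start, end = sp$end)
  }))
}

#' Match CRISPR spacers against target contigs
#'
#' Ungapped scan of both strands of every target for each spacer, reporting
#' full-length Hamming matches. The strict tier keeps matches with alignment
#' length greater than 24 bp and at most one mismatch; for every
#' (array, target) pair with at least one strict match, the same target is
#' rescanned for further spacers of that array at up to three mismatches
#' (expanded tier). Matches falling inside a detected CRISPR array on the
#' target (the spacers themselves) are excluded.
#'
#' @param spacers Spacer table: either the list of arrays from
#'   [detectArrays()] (ids are derived) or a `data.frame` with columns `id`,
#'   `seq`, `arrayId`, `sourceContig`.
#' @param targets Named [Biostrings::DNAStringSet] of target contigs.
#' @param targetArrays Optional list of [CrisprArray-class] on the targets;
#'   matches inside these spans are dropped.
#' @param minAlignLen Minimum alignment length (default 25, i.e. > 24 bp).
#' @param strictMismatch Mismatch ceiling of the strict tier.
#' @param expandedMismatch Mismatch ceiling of the expanded tier.
#' @return `data.frame` with columns `spacer_id`, `array_id`,
#'   `source_contig`, `target_contig`, `target_start`, `target_end`,
#'   `strand`, `align_len`, `mismatches`, `tier`.
#' @export
matchSpacers <- function(spacers, targets, targetArrays = list(),
                         minAlignLen = 25L, strictMismatch = 1L,
                         expandedMismatch = 3L) {
  if (is.list(spacers) && !is.data.frame(spacers))
    spacers <- .spacerTable(spacers)
  empty <- data.frame(spacer_id = character(), array_id = character(),
                      source_contig = character(), target_contig = character(),
                      target_start = integer(), target_end = integer(),
                      strand = character(), align_len = integer(),
                      mismatches = integer(), tier = character())
  if (nrow(spacers) == 0L || length(targets) == 0L) return(empty)
  if (is.null(names(targets))) names(targets) <- seq_along(targets)
  excl <- lapply(setNames(nm = names(targets)), function(nm) {
    a <- Filter(function(z) z@contigId == nm, targetArrays)
    if (length(a) == 0L) return(NULL)
    data.frame(start = vapply(a, function(z) z@start, 0),
               end = vapply(a, function(z) z@end, 0))
  })
  rows <- list()
  for (si in seq_len(nrow(spacers))) {
    sp <- spacers$seq[si]
    L <- nchar(sp)
    if (L < minAlignLen) next
    pats <- list(`+` = Biostrings::DNAString(sp),
                 `-` = Biostrings::reverseComplement(Biostrings::DNAString(sp)))
    for (tn in names(targets)) {
      tx <- targets[[tn]]
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPattern(pats[[strand]], tx,
                                      max.mismatch = expandedMismatch)
        if (length(m) == 0L) next
        mst <- Biostrings::start(m)
        mm <- Biostrings::nmismatch(pats[[strand]], m)
        for (q in seq_along(mst)) {
          s0 <- mst[q]; e0 <- s0 + L - 1L
          if (!is.null(excl[[tn]]) && .overlapsAny(s0, e0, excl[[tn]]))
            next
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = spacers$id[si], array_id = spacers$arrayId[si],
            source_contig = spacers$sourceContig[si], target_contig = tn,
            target_start = s0, target_end = e0, strand = strand,
            align_len = L, mismatches = mm[q], tier = NA_character_)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  res$tier <- ifelse(res$mismatches <= strictMismatch, "strict", NA)
  # expanded tier: <= expandedMismatch hits of an array against a target
  # that already has a strict hit from the same array
  key <- paste(res$array_id, res$target_contig)
  strictKeys <- unique(key[!is.na(res$tier)])
  res$tier[is.na(res$tier) & key %in% strictKeys] <- "expanded"
  res <- res[!is.na(res$tier), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare consensus repeats of two CRISPR arrays
#'
#' Ungapped sliding alignment in both orientations; identity is the match
#' fraction over the best overlap of at least 80% of the shorter repeat.
#' Phages lacking their own interference machinery often carry repeats
#' nearly identical to their host's, so high identity is evidence of a
#' shared Cas system.
#'
#' @param repeat1,repeat2 Consensus repeat sequences (character).
#' @return List with `identity`, `offset` (of `repeat2` relative to
#'   `repeat1`), `orientation` (`"forward"`/`"reverse"`).
#' @export
compareRepeats <- function(repeat1, repeat2) {
  a <- .s2c(repeat1)
  best <- list(identity = 0, offset = 0L, orientation = "forward")
  minOv <- max(1L, ceiling(0.8 * min(nchar(repeat1), nchar(repeat2))))
  for (orient in c("forward", "reverse")) {
    b <- if (orient == "forward") .s2c(repeat2) else .revcompChar(.s2c(repeat2))
    for (off in seq(-(length(b) - minOv), length(a) - minOv)) {
      ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
      len <- min(length(a) - ia, length(b) - ib) + 1L
      if (len < minOv) next
      idn <- mean(a[ia:(ia + len - 1L)] == b[ib:(ib + len - 1L)])
      if (idn > best$identity)
        best <- list(identity = idn, offset = off, orientation = orient)
    }
  }
  best
}

#' Build the CRISPR interaction network
#'
#' Collapses spacer matches into directed edges from the array owner to the
#' targeted contig, with strict and expanded match counts. Edges with at
#' least one strict (no or one mismatch) match are drawn solid; edges
#' supported only by two-to-three-mismatch matches are dashed.
#' Self-targeting (owner == target) is reported separately.
#'
#' @param matches Match table from [matchSpacers()].
#' @param nodeTypes Named character vector mapping contig id to
#'   `"phage"` / `"bacteria"` / other.
#' @return List with `edges` and `selfTargeting` data frames (columns
#'   `source`, `target`, `sourceType`, `targetType`, `nStrict`, `nExpanded`,
#'   `style`).
#' @export
buildNetwork <- function(matches, nodeTypes = character()) {
  empty <- data.frame(source = character(), target = character(),
                      sourceType = character(), targetType = character(),
                      nStrict = integer(), nExpanded = integer(),
                      style = character())
  if (nrow(matches) == 0L) return(list(edges = empty, selfTargeting = empty))
  key <- paste(matches$source_contig, matches$target_contig, sep = "\r")
  agg <- do.call(rbind, lapply(split(matches, key), function(d) {
    data.frame(source = d$source_contig[1L], target = d$target_contig[1L],
               nStrict = sum(d$tier == "strict"),
               nExpanded = sum(d$tier == "expanded"))
  }))
  rownames(agg) <- NULL
  typeOf <- function(id) {
    t <- nodeTypes[id]
    ifelse(is.na(t), "unknown", t)
  }
  agg$sourceType <- unname(typeOf(agg$source))
  agg$targetType <- unname(typeOf(agg$target))
  agg$style <- ifelse(agg$nStrict >= 1L, "solid", "dashed")
  agg <- agg[, c("source", "target", "sourceType", "targetType",
                 "nStrict", "nExpanded", "style")]
  self <- agg[agg$source == agg$target, , drop = FALSE]
  edges <- agg[agg$source != agg$target, , drop = FALSE]
  rownames(self) <- rownames(edges) <- NULL
  list(edges = edges, selfTargeting = self)
}
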