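# Assembly quality control: end-overlap circularization, long direct repeats
# and tandem-concatemer artifacts, short perfect repeats, GC-skew replication
# profiling and origin-based reorientation.

#' Detect circularization by terminal end overlap
#'
#' A de novo assembled circular genome is represented linearly with its two
#' ends overlapping: the first L bases equal the last L bases. This returns
#' the longest exact prefix-suffix overlap within `[minOverlap, maxOverlap]`,
#' or `NA` when none exists. Search is seeded with a 31-mer anchor (the
#' sequence prefix located near the 3' end) and verified by full comparison,
#' so it is exactly equivalent to trying every overlap length.
#'
#' @param contig Contig sequence.
#' @param minOverlap Minimum overlap length (>= 20 bp).
#' @param maxOverlap Maximum overlap length (<= half the contig).
#' @return A list with `overlap` (length in bp, or `NA`) and
#'   `potentiallyComplete` (`TRUE` when an overlap was found).
#' @export
detectCircularity <- function(contig, minOverlap = 50L, maxOverlap = 20000L) {
  x <- .asDNA(contig)
  n <- length(x)
  stopifnot(minOverlap >= 20L)
  maxOverlap <- min(maxOverlap, n %/% 2L)
  if (n < 2L * minOverlap) {
    warning("contig shorter than twice the minimum overlap")
    return(list(overlap = NA_integer_, potentiallyComplete = FALSE))
  }
  best <- NA_integer_
  k <- 31L
  if (maxOverlap >= k && minOverlap <= maxOverlap) {
    anchor <- Biostrings::subseq(x, 1L, k)
    tailStart <- n - maxOverlap + 1L
    hits <- Biostrings::matchPattern(anchor,
                                     Biostrings::subseq(x, tailStart, n))
    starts <- Biostrings::start(hits) + tailStart - 1L
    lens <- n - starts + 1L
    ok <- lens >= max(minOverlap, k) & lens <= maxOverlap
    for (L in sort(lens[ok], decreasing = TRUE)) {
      if (Biostrings::subseq(x, 1L, L) ==
          Biostrings::subseq(x, n - L + 1L, n)) {
        best <- L
        break
      }
    }
  }
  if (is.na(best) && minOverlap < k) {     # short overlaps below anchor size
    for (L in seq(min(k - 1L, maxOverlap), minOverlap)) {
      if (Biostrings::subseq(x, 1L, L) ==
          Biostrings::subseq(x, n - L + 1L, n)) {
        best <- L
        break
      }
    }
  }
  list(overlap = best, potentiallyComplete = !is.na(best))
}

# Extend an exact match around two seed positions (same diagonal) to its
# maximal extent, via binary search on block comparisons.
.extendExact <- function(x, p1, p2, k) {
  n <- length(x)
  eq <- function(a1, a2, len) {
    len > 0L &&
      Biostrings::subseq(x, a1, a1 + len - 1L) ==
      Biostrings::subseq(x, a2, a2 + len - 1L)
  }
  # left extension: largest l with x[p1-l..p1-1] == x[p2-l..p2-1]
  # (tandem overlap with period < length is allowed)
  lo <- 0L; hi <- p1 - 1L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (eq(p1 - mid, p2 - mid, mid)) lo <- mid else hi <- mid - 1L
  }
  l <- lo
  # right extension beyond the k-mer
  lo <- 0L; hi <- n - (p2 + k - 1L)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (eq(p1 + k, p2 + k, mid)) lo <- mid else hi <- mid - 1L
  }
  r <- lo
  c(start1 = p1 - l, start2 = p2 - l, length = l + k + r)
}

#' Detect long exact direct repeats
#'
#' Finds all maximal exact direct repeats of at least `minLen` bp, the
#' signature used to flag tandem-concatenated assembly artifacts. Search is
#' seeded by 31-mer anchors placed densely enough that every repeat of
#' `minLen` contains one, then extended to maximal exact matches; hits are
#' therefore exactly the maximal repeats of length >= `minLen`.
#'
#' @param contig Contig sequence.
#' @param minLen Minimum repeat length in bp (>= 1000; default 5000).
#' @return `data.frame` with columns `start1`, `start2` (`start1 < start2`),
#'   `length`, `identity` (always 1 for exact search).
#' @export
detectLongDirectRepeats <- function(contig, minLen = 5000L) {
  stopifnot(minLen >= 1000L)
  x <- .asDNA(contig)
  n <- length(x)
  empty <- data.frame(start1 = integer(), start2 = integer(),
                      length = integer(), identity = numeric())
  if (n < 2L * minLen) return(empty)
  k <- 31L
  stride <- minLen - k                      # every minLen-window has an anchor
  anchors <- seq(1L, n - k + 1L, by = stride)
  hits <- NULL
  for (a in anchors) {
    pat <- Biostrings::subseq(x, a, a + k - 1L)
    m <- Biostrings::start(Biostrings::matchPattern(pat, x))
    m <- m[m != a]
    for (p2 in m) {
      p1 <- min(a, p2); q2 <- max(a, p2)
      ext <- .extendExact(x, p1, q2, k)
      if (ext["length"] >= minLen)
        hits <- rbind(hits, ext)
    }
  }
  if (is.null(hits)) return(empty)
  hits <- as.data.frame(hits)
  hits <- unique(hits)
  hits <- hits[hits$start1 < hits$start2, , drop = FALSE]
  hits <- hits[order(hits$start1, hits$start2), , drop = FALSE]
  rownames(hits) <- NULL
  hits$identity <- 1
  hits
}

#' Flag a tandem-concatemer assembly artifact
#'
#' A contig that is k >= 2 near-perfect tandem copies of a unit shows a
#' self-overlap at lag equal to the unit length that covers essentially the
#' whole sequence. Such contigs are flagged artifacts with
#' `correctedLength` equal to the unit length. Contigs with other long
#' repeats are flagged for manual review instead.
#'
#' @param contig Contig sequence.
#' @param hits Repeat table from [detectLongDirectRepeats()].
#' @param tol Tolerance in bp at the contig ends (assembly ragged ends).
#' @return A list with `isArtifact`, `correctedLength` (unit length, or `NA`),
#'   `units` (estimated copy number) and `needsReview`.
#' @export
flagConcatemer <- function(contig, hits, tol = 100L) {
  x <- .asDNA(contig)
  n <- length(x)
  res <- list(isArtifact = FALSE, correctedLength = NA_integer_,
              units = 1L, needsReview = FALSE)
  if (nrow(hits) == 0L) return(res)
  for (i in seq_len(nrow(hits))) {
    lag <- hits$start2[i] - hits$start1[i]
    covered <- hits$start1[i] <= tol + 1L &
      (hits$start2[i] + hits$length[i] - 1L) >= n - tol
    if (covered && lag >= 1L && round(n / lag) >= 2L) {
      res$isArtifact <- TRUE
      res$correctedLength <- as.integer(lag)
      res$units <- as.integer(round(n / lag))
      return(res)
    }
  }
  res$needsReview <- TRUE                   # large repeats, not tandem cover
  res
}

#' Tabulate short perfect repeats
#'
#' All maximal exact repeats -- direct and inverted (reverse-complement) --
#' of length > `minLen - 1` bp at 100% identity. Uses shared k-mer seeds
#' (k = `minLen`) merged along diagonals, which enumerates maximal exact
#' repeats completely.
#'
#' @param contig Contig sequence.
#' @param minLen Minimum repeat length (default 26, i.e. strictly more than
#'   25 bp).
#' @return `data.frame` with `start1`, `start2`, `length`, `type`
#'   (`"direct"`/`"inverted"`), `identity`. For inverted repeats `start2` is
#'   the start of the reverse-complemented copy on the forward strand.
#' @export
tabulateShortRepeats <- function(contig, minLen = 26L) {
  x <- .asDNA(contig)
  n <- length(x)
  empty <- data.frame(start1 = integer(), start2 = integer(),
                      length = integer(), type = character(),
                      identity = numeric())
  k <- as.integer(minLen)
  if (n < 2L * k) return(empty)
  s <- as.character(x)
  np <- n - k + 1L
  kmers <- substring(s, 1:np, k:n)
  out <- NULL

  mergeDiag <- function(i, j) {
    # pairs (i, j) on diagonals d = j - i; merge runs of consecutive i
    d <- j - i
    o <- order(d, i)
    i <- i[o]; j <- j[o]; d <- d[o]
    newRun <- c(TRUE, d[-1L] != d[-length(d)] | diff(i) != 1L)
    run <- cumsum(newRun)
    st1 <- tapply(i, run, min)
    len <- tapply(i, run, length) + k - 1L
    st2 <- tapply(j, run, min)
    data.frame(start1 = as.integer(st1), start2 = as.integer(st2),
               length = as.integer(len))
  }

  # direct repeats: duplicated k-mers
  o <- order(kmers)
  km <- kmers[o]
  dupGrp <- cumsum(c(TRUE, km[-1L] != km[-length(km)]))
  sizes <- tabulate(dupGrp)
  if (any(sizes > 1L)) {
    ii <- integer(); jj <- integer()
    idx <- split(o[order(dupGrp)], rep(seq_along(sizes), sizes))
    for (grp in idx[sizes > 1L]) {
      grp <- sort(grp)
      pr <- t(combn(grp, 2L))
      ii <- c(ii, pr[, 1L]); jj <- c(jj, pr[, 2L])
    }
    if (length(ii)) {
      dd <- mergeDiag(ii, jj)
      dd$type <- "direct"
      out <- rbind(out, dd)
    }
  }

  # inverted repeats: k-mers shared between forward and reverse complement
  rc <- as.character(Biostrings::reverseComplement(x))
  rkmers <- substring(rc, 1:np, k:n)
  shared <- intersect(rkmers, kmers)        # k-mers seen on both strands
  if (length(shared)) {
    ii <- integer(); rr <- integer()
    for (kmstr in shared) {
      fwPos <- which(kmers == kmstr)
      rcPos <- which(rkmers == kmstr)
      for (q in rcPos) {
        ii <- c(ii, fwPos)
        rr <- c(rr, rep(q, length(fwPos)))
      }
    }
    if (length(ii)) {
      # merge along rc diagonals (i and q advance together), then convert
      d <- ii - rr
      o2 <- order(d, ii)
      ii <- ii[o2]; rr <- rr[o2]; d <- d[o2]
      newRun <- c(TRUE, d[-1L] != d[-length(d)] | diff(ii) != 1L)
      run <- cumsum(newRun)
      st1 <- as.integer(tapply(ii, run, min))
      len <- as.integer(tapply(ii, run, length)) + k - 1L
      qLast <- as.integer(tapply(rr, run, max))
      st2 <- n - qLast - k + 2L             # fw start of the rc'd copy
      inv <- data.frame(start1 = st1, start2 = st2, length = len)
      # each inverted repeat is seen from both copies; keep one record
      a <- pmin(inv$start1, inv$start2)
      b <- pmax(inv$start1, inv$start2)
      inv$start1 <- a; inv$start2 <- b
      inv <- unique(inv)
      inv <- inv[inv$start1 <= inv$start2, , drop = FALSE]
      inv$type <- "inverted"
      out <- rbind(out, inv)
    }
  }
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out$identity <- 1
  out <- out[order(out$type, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed GC-skew profile
#'
#' Computes (G-C)/(G+C) in sliding windows plus the cumulative per-window
#' G-C excess, the curve whose slope changes locate the replication origin
#' and terminus.
#'
#' @param contig Contig sequence.
#' @param window Window size in bp (>= 100).
#' @param step Step size in bp (<= window).
#' @return A [SkewProfile-class] with `mode` unset (`"none"`); run
#'   [classifyReplicationMode()] to fill it in.
#' @export
gcSkew <- function(contig, window = 1000L, step = 500L) {
  stopifnot(window >= 100L, step <= window, step >= 1L)
  x <- .asDNA(contig)
  n <- length(x)
  starts <- seq.int(1L, max(n - window + 1L, 1L), by = step)
  starts <- starts[starts + window - 1L <= n]
  if (length(starts) == 0L)
    return(new("SkewProfile", window = window, step = step,
               positions = numeric(), skew = numeric(),
               cumulative = numeric()))
  v <- Biostrings::Views(x, start = starts, width = window)
  fr <- Biostrings::letterFrequency(v, c("G", "C"))
  gmc <- fr[, "G"] - fr[, "C"]
  gpc <- fr[, "G"] + fr[, "C"]
  skew <- ifelse(gpc == 0, 0, gmc / gpc)
  new("SkewProfile", window = window, step = step,
      positions = starts + window / 2, skew = as.numeric(skew),
      cumulative = cumsum(as.numeric(gmc)))
}

# Continuous piecewise-linear least squares with fixed knots; returns
# R^2 and the per-segment slopes.
.pwFit <- function(xs, ys, knots) {
  X <- cbind(1, xs)
  for (b in knots) X <- cbind(X, pmax(xs - b, 0))
  f <- stats::lm.fit(X, ys)
  rss <- sum(f$residuals^2)
  tss <- sum((ys - mean(ys))^2)
  co <- f$coefficients
  co[is.na(co)] <- 0
  slopes <- cumsum(co[-1L])
  list(r2 = if (tss > 0) 1 - rss / tss else 0, slopes = unname(slopes))
}

#' Classify the replication mode from a GC-skew profile
#'
#' Fits the cumulative skew curve with a straight line and with continuous
#' piecewise-linear models of one and two breakpoints. `"bidirectional"`
#' requires an alternating-sign piecewise fit (each segment slope at least
#' `minRate` in absolute value) with R^2 >= `r2Threshold` that clearly beats
#' the straight line; `"unidirectional"` a straight-line fit with
#' |slope| >= `minRate` and R^2 >= `r2Threshold`; anything else (including
#' profiles of fewer than 10 windows) is `"none"`. Breakpoints are refined
#' on the window grid.
#'
#' @param profile A [SkewProfile-class] from [gcSkew()].
#' @param r2Threshold Minimum R^2 of the winning fit.
#' @param minRate Minimum |slope| of the cumulative curve, in G-C counts per
#'   bp (0.01 corresponds to a skew amplitude of about 2% at GC 0.5).
#' @return The input profile with `mode`, `breakpoints` and `fitQuality`
#'   filled in.
#' @export
classifyReplicationMode <- function(profile, r2Threshold = 0.85,
                                    minRate = 0.01) {
  stopifnot(is(profile, "SkewProfile"))
  m <- length(profile@positions)
  if (m < 10L) {
    warning("fewer than 10 windows; replication mode set to none")
    profile@mode <- "none"
    profile@fitQuality <- NA_real_
    return(profile)
  }
  xs <- profile@positions
  # scale cumulative counts to per-bp rate units: each step adds one window's
  # G-C count, so divide by (window/step) to express slope per bp
  ys <- profile@cumulative * (profile@step / profile@window)
  lin <- .pwFit(xs, ys, numeric())
  linRate <- lin$slopes[1L]

  # breakpoint candidates: the extrema of the cumulative curve (the
  # least-squares changepoints of a sign-alternating piecewise-constant
  # skew are the argmin/argmax of its cumulative sum)
  bmin <- which.min(ys)
  bmax <- which.max(ys)
  interior <- function(b) b > 1L && b < m
  cand <- list()
  if (interior(bmin) && interior(bmax) && abs(bmax - bmin) >= 3L)
    cand <- c(cand, list(sort(c(bmin, bmax))))
  if (interior(bmin)) cand <- c(cand, list(bmin))
  if (interior(bmax)) cand <- c(cand, list(bmax))

  bestBi <- list(r2 = -Inf, knots = numeric())
  evalKnots <- function(kn) {
    f <- .pwFit(xs, ys, xs[kn])
    sl <- f$slopes
    if (all(abs(sl) >= minRate) && all(sign(sl[-1L]) != sign(sl[-length(sl)])))
      list(r2 = f$r2, knots = xs[kn]) else NULL
  }
  for (kn in cand) {
    r <- evalKnots(kn)
    if (!is.null(r) && r$r2 > bestBi$r2) bestBi <- r
  }

  if (is.finite(bestBi$r2) && bestBi$r2 >= r2Threshold &&
      bestBi$r2 > lin$r2 + 0.05) {
    profile@mode <- "bidirectional"
    profile@breakpoints <- bestBi$knots
    profile@fitQuality <- bestBi$r2
  } else if (lin$r2 >= r2Threshold && abs(linRate) >= minRate) {
    profile@mode <- "unidirectional"
    profile@breakpoints <- numeric()
    profile@fitQuality <- lin$r2
  } else {
    profile@mode <- "none"
    profile@breakpoints <- numeric()
    profile@fitQuality <- max(lin$r2, if (is.finite(bestBi$r2)) bestBi$r2 else 0)
  }
  profile
}

#' Rotate a circular contig so it starts near the replication origin
#'
#' For a circularizable contig (terminal overlap detected), removes the
#' duplicated end overlap and rotates the sequence so the new start lies in
#' the intergenic gap nearest the inferred origin (the breakpoint where the
#' cumulative skew slope turns from negative to positive). Contigs whose
#' profile is not bidirectional are returned unchanged with a warning.
#'
#' @param contig Contig sequence.
#' @param profile A classified [SkewProfile-class].
#' @param genes Gene table (`start`, `end`) used to find intergenic gaps.
#' @param overlap Terminal overlap length from [detectCircularity()]
#'   (0 if already trimmed). `NA` is an error: only circular contigs can be
#'   reoriented.
#' @return A list with `seq` (rotated [Biostrings::DNAString]), `newStart`
#'   (1-based position of the old coordinate that now starts the sequence)
#'   and `origin` (inferred origin position on the trimmed sequence).
#' @export
reorientToOrigin <- function(contig, profile, genes, overlap = 0L) {
  x <- .asDNA(contig)
  if (is.na(overlap)) stop("reorientToOrigin requires a circular contig")
  if (overlap > 0L) x <- Biostrings::subseq(x, 1L, length(x) - overlap)
  n <- length(x)
  if (profile@mode != "bidirectional" || length(profile@breakpoints) == 0L) {
    warning("no bidirectional skew signal; contig left unchanged")
    return(list(seq = x, newStart = 1L, origin = NA_real_))
  }
  # origin: breakpoint whose incoming slope is negative and outgoing positive
  ys <- profile@cumulative
  xs <- profile@positions
  ori <- NA_real_
  for (b in profile@breakpoints) {
    i <- which.min(abs(xs - b))
    lo <- max(1L, i - 5L); hi <- min(length(xs), i + 5L)
    sIn <- if (i > lo) (ys[i] - ys[lo]) / (xs[i] - xs[lo]) else NA
    sOut <- if (hi > i) (ys[hi] - ys[i]) / (xs[hi] - xs[i]) else NA
    if (!is.na(sIn) && !is.na(sOut) && sIn < 0 && sOut > 0) {
      ori <- b
      break
    }
  }
  if (is.na(ori)) ori <- profile@breakpoints[1L]
  ori <- min(max(round(ori), 1L), n)
  # nearest intergenic gap midpoint (circular distance)
  gaps <- NULL
  if (nrow(genes)) {
    gg <- genes[genes$end <= n, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(gg$start, gg$end))
    gapR <- IRanges::gaps(ir, start = 1L, end = n)
    if (length(gapR))
      gaps <- (IRanges::start(gapR) + IRanges::end(gapR)) / 2
  }
  newStart <- if (is.null(gaps)) ori else {
    dcirc <- pmin(abs(gaps - ori), n - abs(gaps - ori))
    round(gaps[which.min(dcirc)])
  }
  newStart <- min(max(as.integer(newStart), 1L), n)
  rotated <- if (newStart == 1L) x else
    Biostrings::xscat(Biostrings::subseq(x, newStart, n),
                      Biostrings::subseq(x, 1L, newStart - 1L))
  list(seq = Biostrings::DNAString(as.character(rotated)),
       newStart = newStart, origin = ori)
}
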