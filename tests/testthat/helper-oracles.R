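# Brute-force oracles, deliberately written as direct transcriptions of the
# definitions (quadratic scans, explicit loops) and kept independent of the
# package's seeded/anchored implementations.

.chars <- function(s) strsplit(as.character(s), "", fixed = TRUE)[[1]]
.str <- function(v) paste(v, collapse = "")
.rc <- function(v) rev(unname(c(A = "T", C = "G", G = "C", T = "A")[v]))

randomDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .str(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p))
}

# longest exact prefix-suffix overlap, trying every length
bruteCircularity <- function(s, minOverlap, maxOverlap) {
  n <- nchar(s)
  for (L in seq(min(maxOverlap, n %/% 2L), minOverlap)) {
    if (substr(s, 1L, L) == substr(s, n - L + 1L, n)) return(L)
  }
  NA_integer_
}

# all maximal exact direct repeats >= minLen: full diagonal scan
bruteDirectRepeats <- function(s, minLen) {
  v <- .chars(s)
  n <- length(v)
  out <- NULL
  for (d in seq_len(n - minLen)) {
    eqs <- v[seq_len(n - d)] == v[seq.int(1L + d, n)]
    r <- rle(eqs)
    ends <- cumsum(r$lengths)
    for (q in which(r$values & r$lengths >= minLen)) {
      st <- ends[q] - r$lengths[q] + 1L
      out <- rbind(out, data.frame(start1 = st, start2 = st + d,
                                   length = r$lengths[q]))
    }
  }
  if (is.null(out))
    data.frame(start1 = integer(), start2 = integer(), length = integer())
  else out[order(out$start1, out$start2), , drop = FALSE]
}

# all maximal inverted (reverse-complement) repeats >= minLen:
# diagonal scan of the sequence against its reverse complement
bruteInvertedRepeats <- function(s, minLen) {
  v <- .chars(s)
  n <- length(v)
  rc <- .rc(v)
  out <- NULL
  for (d in seq.int(-(n - minLen), n - minLen)) {
    # compare v[i] with rc[i - d] over the valid range
    iLo <- max(1L, 1L + d); iHi <- min(n, n + d)
    if (iHi - iLo + 1L < minLen) next
    idx <- iLo:iHi
    eqs <- v[idx] == rc[idx - d]
    r <- rle(eqs)
    ends <- cumsum(r$lengths)
    for (q in which(r$values & r$lengths >= minLen)) {
      st <- idx[ends[q] - r$lengths[q] + 1L]
      L <- r$lengths[q]
      # v[st..st+L-1] == rc[(st-d)..(st-d+L-1)]; rc position q1 maps to the
      # forward-strand copy starting at n - (q1 + L - 1) + 1
      q1 <- st - d
      j <- n - (q1 + L - 1L) + 1L
      a <- min(st, j); b <- max(st, j)
      out <- rbind(out, data.frame(start1 = a, start2 = b, length = L))
    }
  }
  if (is.null(out))
    return(data.frame(start1 = integer(), start2 = integer(),
                      length = integer()))
  out <- unique(out)
  out[order(out$start1, out$start2), , drop = FALSE]
}

# all ungapped full-length matches of a spacer on both strands with
# mismatch count <= maxMm, by scanning every window
bruteSpacerScan <- function(spacer, target, maxMm = 3L) {
  tv <- .chars(target)
  n <- length(tv)
  out <- NULL
  for (strand in c("+", "-")) {
    sv <- if (strand == "+") .chars(spacer) else .rc(.chars(spacer))
    L <- length(sv)
    if (L > n) next
    for (st in seq_len(n - L + 1L)) {
      mm <- sum(tv[st:(st + L - 1L)] != sv)
      if (mm <= maxMm)
        out <- rbind(out, data.frame(start = st, strand = strand,
                                     mismatches = mm))
    }
  }
  if (is.null(out))
    data.frame(start = integer(), strand = character(),
               mismatches = integer())
  else out[order(out$start, out$strand), , drop = FALSE]
}

# six-frame ORF scan with an explicit state machine, no overlap resolution
bruteOrfs <- function(s, stopCodons, minLenCodons = 60L,
                      startCodons = c("ATG", "GTG", "TTG")) {
  n <- nchar(s)
  out <- NULL
  for (strand in c("+", "-")) {
    sv <- if (strand == "+") s else .str(.rc(.chars(s)))
    for (frame in 0:2) {
      pos <- frame + 1L
      inOrf <- FALSE
      orfStart <- NA_integer_
      while (pos + 2L <= n) {
        cod <- substr(sv, pos, pos + 2L)
        if (!inOrf && cod %in% startCodons) {
          inOrf <- TRUE
          orfStart <- pos
        }
        if (cod %in% stopCodons) {
          if (inOrf) {
            lenCod <- (pos + 2L - orfStart + 1L) %/% 3L
            if (lenCod >= minLenCodons) {
              s1 <- orfStart; e1 <- pos + 2L
              if (strand == "-") {
                tmp <- n - e1 + 1L; e1 <- n - s1 + 1L; s1 <- tmp
              }
              out <- rbind(out, data.frame(start = s1, end = e1,
                                           strand = strand, frame = frame,
                                           lengthCodons = lenCod))
            }
          }
          inOrf <- FALSE
        }
        pos <- pos + 3L
      }
    }
  }
  if (is.null(out))
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), lengthCodons = integer())
  else out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# reference Markov clustering: dense matrices, no pruning, fixed iteration
# count, clusters read as connected components of the attractor support graph
naiveMcl <- function(nodes, edges, inflation = 2, iters = 200L) {
  nN <- length(nodes)
  M <- matrix(0, nN, nN, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    a <- match(edges$query[k], nodes); b <- match(edges$target[k], nodes)
    w <- max(M[a, b], edges$weight[k])    # duplicate edges: keep the largest
    M[a, b] <- M[b, a] <- w
  }
  for (v in seq_len(nN)) {
    mx <- max(M[, v])
    M[v, v] <- if (mx > 0) mx else 1
  }
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M ^ inflation
    M[M < 1e-5] <- 0                       # pruning is part of the procedure
    for (v in which(colSums(M) == 0)) M[v, v] <- 1
    M <- sweep(M, 2, colSums(M), "/")
  }
  thr <- 1e-4
  g <- igraph::make_empty_graph(n = nN, directed = FALSE)
  for (a in which(diag(M) > thr))
    for (v in which(M[a, ] > thr))
      g <- igraph::add_edges(g, c(a, v))
  comp <- igraph::components(g)$membership
  split(nodes, comp)
}

# canonical form of a clustering for set comparison
clusterSets <- function(membership) {
  s <- lapply(split(names(membership), membership), sort)
  unname(s[order(vapply(s, `[`, "", 1L))])
}
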