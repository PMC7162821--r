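# Two-step protein-family clustering: greedy set-cover subfamilies on the
# filtered all-vs-all similarity graph, then Markov clustering of the
# profile-profile similarity network weighted by probability x coverage.

#' Greedy set-cover subfamily clustering
#'
#' Filters the all-vs-all similarity edges by E-value and coverage, then
#' repeatedly selects the node that covers the most still-uncovered nodes
#' (itself plus its neighbours) as a subfamily representative, assigning the
#' covered nodes to it. Ties are broken by node id (lexicographic), which
#' makes the procedure independent of input order.
#'
#' @param edges `data.frame` with columns `query`, `target`, `evalue`,
#'   `coverage`.
#' @param proteins Optional character vector of all protein ids (isolated
#'   proteins become singleton subfamilies).
#' @param evalueMax E-value ceiling (default 1e-3).
#' @param covMin Coverage floor (default 0.5).
#' @return `data.frame` with columns `protein`, `subfamily` (representative
#'   id).
#' @export
subfamilySetCover <- function(edges, proteins = NULL, evalueMax = 1e-3,
                              covMin = 0.5) {
  keep <- edges$evalue <= evalueMax & edges$coverage >= covMin &
    edges$query != edges$target
  e <- edges[keep, c("query", "target"), drop = FALSE]
  # nodes seen only on sub-threshold edges still become singletons
  nodes <- sort(unique(c(edges$query, edges$target, proteins)))
  if (length(nodes) == 0L)
    return(data.frame(protein = character(), subfamily = character()))
  adj <- lapply(setNames(nm = nodes), function(z) character())
  if (nrow(e)) {
    nb1 <- split(e$target, e$query)
    nb2 <- split(e$query, e$target)
    for (nm in names(nb1)) adj[[nm]] <- c(adj[[nm]], nb1[[nm]])
    for (nm in names(nb2)) adj[[nm]] <- c(adj[[nm]], nb2[[nm]])
    adj <- lapply(adj, unique)
  }
  uncovered <- setNames(rep(TRUE, length(nodes)), nodes)
  assign <- setNames(rep(NA_character_, length(nodes)), nodes)
  while (any(uncovered)) {
    gain <- vapply(nodes, function(v)
      if (!uncovered[[v]] && !any(uncovered[adj[[v]]])) 0L
      else sum(uncovered[c(v, adj[[v]])]), 0L)
    best <- max(gain)
    rep_ <- min(nodes[gain == best])        # tie-break: smallest id
    members <- c(rep_, adj[[rep_]])
    members <- members[uncovered[members]]
    assign[members] <- rep_
    uncovered[members] <- FALSE
  }
  data.frame(protein = names(assign), subfamily = unname(assign),
             row.names = NULL)
}

#' Markov clustering (MCL) of a weighted similarity network
#'
#' Filters profile-profile edges by probability and coverage, weights them
#' by probability x coverage (probability rescaled from percent), adds
#' self-loops (weight = maximum incident edge weight), column-normalizes and
#' iterates expansion (matrix squaring) and inflation (elementwise power,
#' then renormalization) with pruning, until the matrix change falls below
#' `tol` or `maxIter` is reached. Clusters are read from attractor rows;
#' nodes supported by several attractors go to the one carrying more mass
#' (ties: lower id).
#'
#' @param edges `data.frame` with columns `query`, `target`, `probability`
#'   (percent), `coverage`; or columns `query`, `target`, `weight`.
#' @param inflation Inflation exponent (default 2.0).
#' @param probMin Minimum probability in percent (default 95).
#' @param covMin Minimum coverage (default 0.5).
#' @param nodes Optional vector of all node ids (isolated nodes become
#'   singleton clusters).
#' @param maxIter Iteration cap (default 100).
#' @param tol Convergence threshold on the max absolute matrix change.
#' @param prune Entries below this are zeroed each iteration.
#' @return `data.frame` with columns `node`, `cluster` (integer). The
#'   attribute `"iterations"` records the number of iterations run; a
#'   warning is raised when `maxIter` was hit before convergence.
#' @export
mclCluster <- function(edges, inflation = 2.0, probMin = 95, covMin = 0.5,
                       nodes = NULL, maxIter = 100L, tol = 1e-6,
                       prune = 1e-5) {
  if (!"weight" %in% names(edges)) {
    keep <- edges$probability >= probMin & edges$coverage >= covMin &
      edges$query != edges$target
    e <- edges[keep, , drop = FALSE]
    w <- (e$probability / 100) * e$coverage
    e <- data.frame(query = e$query, target = e$target, weight = w)
  } else {
    e <- edges[edges$query != edges$target, , drop = FALSE]
  }
  ids <- sort(unique(c(e$query, e$target, nodes)))
  nN <- length(ids)
  if (nN == 0L)
    return(data.frame(node = character(), cluster = integer()))
  M <- matrix(0, nN, nN, dimnames = list(ids, ids))
  if (nrow(e)) {
    qi <- match(e$query, ids); ti <- match(e$target, ids)
    for (k in seq_len(nrow(e))) {
      M[qi[k], ti[k]] <- max(M[qi[k], ti[k]], e$weight[k])
      M[ti[k], qi[k]] <- max(M[ti[k], qi[k]], e$weight[k])
    }
  }
  selfW <- apply(M, 2L, max)
  selfW[selfW == 0] <- 1
  diag(M) <- selfW
  normalize <- function(A) sweep(A, 2L, colSums(A), "/")
  M <- normalize(M)
  iter <- 0L
  convergedAt <- NA_integer_
  while (iter < maxIter) {
    iter <- iter + 1L
    M2 <- M %*% M                 # expansion
    M2 <- M2 ^ inflation          # inflation
    M2[M2 < prune] <- 0
    zero <- colSums(M2) == 0
    if (any(zero)) diag(M2)[zero] <- 1
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      convergedAt <- iter
      break
    }
  }
  if (is.na(convergedAt))
    warning("MCL did not converge within maxIter; returning current clustering")
  # attractors: nodes with positive diagonal mass
  attr_ <- which(diag(M) > prune)
  member <- rep(NA_integer_, nN)
  if (length(attr_) == 0L) attr_ <- seq_len(nN)
  # support of each node: attractor rows with positive mass in its column
  clusterOfAttr <- rep(NA_integer_, nN)
  nextCl <- 0L
  for (a in attr_) {
    if (!is.na(clusterOfAttr[a])) next
    nextCl <- nextCl + 1L
    # attractors that share support belong to one cluster
    grp <- a
    repeat {
      sup <- which(rowSums(M[attr_, grp, drop = FALSE] > prune) > 0)
      grp2 <- sort(unique(c(grp, attr_[sup])))
      if (identical(grp2, grp)) break
      grp <- grp2
    }
    clusterOfAttr[grp] <- nextCl
  }
  for (v in seq_len(nN)) {
    sup <- attr_[M[attr_, v] > prune]
    if (length(sup) == 0L) {
      member[v] <- if (!is.na(clusterOfAttr[v])) clusterOfAttr[v] else {
        nextCl <- nextCl + 1L
        nextCl
      }
    } else if (length(sup) == 1L) {
      member[v] <- clusterOfAttr[sup]
    } else {
      mass <- M[sup, v]
      best <- sup[mass == max(mass)]
      member[v] <- clusterOfAttr[min(best)]   # larger mass, then lower id
    }
  }
  out <- data.frame(node = ids, cluster = member, row.names = NULL)
  attr(out, "iterations") <- iter
  out
}

#' Assemble protein families from subfamilies and MCL clusters
#'
#' A family is the union of the member proteins of all subfamilies that fell
#' in one MCL cluster; subfamilies absent from the profile network become
#' families of their own. The result is a partition of the input proteins:
#' every protein appears exactly once.
#'
#' @param subfamilies `data.frame` from [subfamilySetCover()].
#' @param mclClusters `data.frame` from [mclCluster()] over subfamily ids.
#' @return `data.frame` with columns `protein`, `subfamily`, `family`
#'   (`"F0001"`, ...).
#' @export
assembleFamilies <- function(subfamilies, mclClusters) {
  if (anyDuplicated(mclClusters$node))
    stop("a subfamily appears in two clusters; families must partition proteins")
  if (anyDuplicated(subfamilies$protein))
    stop("a protein appears in two subfamilies; families must partition proteins")
  cl <- setNames(mclClusters$cluster, mclClusters$node)
  sf <- unique(subfamilies$subfamily)
  famKey <- character(length(sf))
  names(famKey) <- sf
  for (s in sf)
    famKey[s] <- if (s %in% names(cl)) paste0("c", cl[[s]]) else paste0("u", s)
  uniq <- unique(famKey[order(names(famKey))])
  famId <- setNames(sprintf("F%04d", seq_along(uniq)), uniq)
  out <- data.frame(protein = subfamilies$protein,
                    subfamily = subfamilies$subfamily,
                    family = unname(famId[famKey[subfamilies$subfamily]]))
  stopifnot(!anyDuplicated(out$protein))
  out <- out[order(out$family, out$subfamily, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-step protein-family clustering
#'
#' Runs [subfamilySetCover()] on the all-vs-all edges, [mclCluster()] on the
#' profile edges (restricted to subfamily representative ids) and
#' [assembleFamilies()].
#'
#' @param allvsall All-vs-all similarity edges (`query`, `target`, `evalue`,
#'   `coverage`).
#' @param profile Profile-profile edges (`query`, `target`, `probability`,
#'   `coverage`).
#' @param proteins Optional vector of all protein ids.
#' @param inflation,probMin,covMin,evalueMax Thresholds as in the step
#'   functions.
#' @return List with `subfamilies`, `clusters`, `families`.
#' @export
clusterProteinFamilies <- function(allvsall, profile, proteins = NULL,
                                   inflation = 2.0, probMin = 95,
                                   covMin = 0.5, evalueMax = 1e-3) {
  sub <- subfamilySetCover(allvsall, proteins = proteins,
                           evalueMax = evalueMax, covMin = covMin)
  reps <- unique(sub$subfamily)
  prof <- profile[profile$query %in% reps & profile$target %in% reps, ,
                  drop = FALSE]
  cl <- mclCluster(prof, inflation = inflation, probMin = probMin,
                   covMin = covMin, nodes = reps)
  fam <- assembleFamilies(sub, cl)
  list(subfamilies = sub, clusters = cl, families = fam)
}
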