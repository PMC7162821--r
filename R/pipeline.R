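# End-to-end orchestration: simulate/read -> qc -> genes -> classify ->
# crispr -> hosts -> families -> summary, with stable on-disk artifact names.

#' Summary statistics of a genome table
#'
#' Genome-size histogram, median size, and -- when a tRNA-count column is
#' present -- the Spearman rank correlation between tRNA count and genome
#' size with a seeded permutation p-value.
#'
#' @param genomeTable `data.frame` with columns `length` and optionally
#'   `trna`.
#' @param binWidth Histogram bin width in bp (default 50 kb).
#' @param nPerm Number of permutations for the p-value (default 10000).
#' @param seed Seed for the permutation draw.
#' @return List with `n`, `medianLength`, `histogram` (`data.frame`), and
#'   when tRNA counts are present `spearmanRho` and `permutationP`
#'   (`NA` with a note when the correlation is undefined).
#' @export
summaryStats <- function(genomeTable, binWidth = 50000L, nPerm = 10000L,
                         seed = 1L) {
  if (nrow(genomeTable) < 3L)
    stop("at least 3 genomes are required")
  len <- genomeTable$length
  breaks <- seq(0, ceiling(max(len) / binWidth) * binWidth, by = binWidth)
  h <- hist(len, breaks = breaks, plot = FALSE)
  out <- list(n = length(len), medianLength = median(len),
              histogram = data.frame(binStart = head(breaks, -1L),
                                     binEnd = breaks[-1L],
                                     count = h$counts))
  if ("trna" %in% names(genomeTable)) {
    trna <- genomeTable$trna
    if (length(unique(len)) < 2L || length(unique(trna)) < 2L) {
      out$spearmanRho <- NA_real_
      out$permutationP <- NA_real_
      out$note <- "correlation undefined for constant input"
    } else {
      rho <- cor(len, trna, method = "spearman")
      set.seed(seed)
      perm <- replicate(nPerm, cor(len, sample(trna), method = "spearman"))
      out$spearmanRho <- rho
      out$permutationP <- (1 + sum(abs(perm) >= abs(rho))) / (nPerm + 1)
    }
  }
  out
}

#' Run the full discovery pipeline
#'
#' Orchestrates all stages over a synthetic community (when the config has a
#' `community` block) or user-supplied inputs (`inputs$fasta`,
#' `inputs$annotations`, optional edge tables and tRNA table). Stage outputs
#' are written with stable filenames under `outdir`; the JSON report embeds
#' the seed, package version and configuration, so identical configurations
#' reproduce identical artifacts (no timestamps are written).
#'
#' @param config A named list (see [readRunConfig()]) or a path to a
#'   YAML/JSON config. Recognized keys: `seed`, `outdir`, `community`
#'   (arguments to [communitySpec()]), `inputs`, per-stage parameter blocks
#'   (`qc`, `genes`, `classify`, `crispr`, `hosts`, `families`), `stages`
#'   (character vector to restrict which stages run).
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% stop("config$outdir is required")
  stages <- config$stages %||% c("qc", "genes", "classify", "crispr",
                                 "hosts", "families", "summary")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs ----
  community <- NULL
  if (!is.null(config$community)) {
    specArgs <- config$community
    specArgs$seed <- specArgs$seed %||% seed
    spec <- do.call(communitySpec, specArgs)
    community <- generateCommunity(spec)
    writeCommunity(community, file.path(outdir, "community"))
    ctg <- contigs(community)
    annot <- annotations(community)
    edgesAv <- proteinEdges(community)$allvsall
    edgesPf <- proteinEdges(community)$profile
    trna <- trnaTable(community)
  } else {
    inp <- config$inputs
    if (is.null(inp$fasta) || !file.exists(inp$fasta))
      stop("inputs$fasta is missing or does not exist")
    if (!is.null(inp$annotations) && !file.exists(inp$annotations))
      stop("inputs$annotations does not exist")
    ctg <- readContigs(inp$fasta)
    annot <- if (!is.null(inp$annotations)) readAnnotations(inp$annotations)
             else NULL
    edgesAv <- if (!is.null(inp$allvsall)) readEdges(inp$allvsall) else NULL
    edgesPf <- if (!is.null(inp$profile)) readEdges(inp$profile) else NULL
    trna <- if (!is.null(inp$trna)) read.delim(inp$trna) else NULL
  }
  ids <- names(ctg)
  report <- list(seed = seed, package = "hugephage",
                 version = as.character(utils::packageVersion("hugephage")),
                 config = config, stages = list())

  # ---- qc ----
  qcTab <- NULL
  skews <- list()
  if ("qc" %in% stages) {
    qcPar <- config$qc %||% list()
    minRep <- qcPar$minRepeat %||% 5000L
    win <- qcPar$window %||% 1000L
    stp <- qcPar$step %||% 500L
    rows <- lapply(ids, function(id) {
      x <- ctg[[id]]
      circ <- detectCircularity(x)
      reps <- detectLongDirectRepeats(x, minLen = minRep)
      conc <- flagConcatemer(x, reps)
      prof <- classifyReplicationMode(gcSkew(x, window = win, step = stp))
      skews[[id]] <<- prof
      data.frame(contig = id, length = length(x),
                 circular_overlap = circ$overlap,
                 potentially_complete = circ$potentiallyComplete,
                 n_long_repeats = nrow(reps),
                 concatemer_artifact = conc$isArtifact,
                 corrected_length = if (conc$isArtifact) conc$correctedLength
                                    else length(x) -
                                      ifelse(is.na(circ$overlap), 0L,
                                             circ$overlap),
                 skew_mode = skewMode(prof),
                 skew_breakpoints = paste(round(breakpoints(prof)),
                                          collapse = ";"),
                 skew_fit = prof@fitQuality)
    })
    qcTab <- do.call(rbind, rows)
    .writeTsv(qcTab, file.path(outdir, "qc_report.tsv"))
    report$stages$qc <- list(nContigs = nrow(qcTab),
                             circularized = sum(qcTab$potentially_complete),
                             artifacts = sum(qcTab$concatemer_artifact))
  }

  # ---- genes + genetic code ----
  geneTabs <- list()
  codeTab <- NULL
  if ("genes" %in% stages) {
    gPar <- config$genes %||% list()
    minLen <- gPar$minLenCodons %||% 60L
    flagT <- gPar$flagThreshold %||% 0.78
    rows <- lapply(ids, function(id) {
      inf <- inferGeneticCode(ctg[[id]], flagThreshold = flagT,
                              minLenCodons = minLen, contigId = id)
      code <- geneticCode(chosenCode(inf))
      genes <- callOrfs(ctg[[id]], code, minLenCodons = minLen)
      genes$contig <- id
      geneTabs[[id]] <<- genes
      data.frame(contig = id, chosen_code = chosenCode(inf),
                 flagged = inf@flagged,
                 density_code11 = unname(densityByCode(inf)["code11"]),
                 density_chosen = unname(densityByCode(inf)[chosenCode(inf)]),
                 n_genes = nrow(genes))
    })
    codeTab <- do.call(rbind, rows)
    .writeTsv(codeTab, file.path(outdir, "genetic_codes.tsv"))
    allGenes <- do.call(rbind, geneTabs)
    writeGenesGff3(allGenes, file.path(outdir, "genes.gff3"))
    report$stages$genes <- list(nGenes = nrow(allGenes),
                                recoded = sum(codeTab$chosen_code != "code11"))
  }

  # ---- crispr detection (needed by classify's length exception) ----
  arrays <- list()
  if ("crispr" %in% stages) {
    cPar <- config$crispr %||% list()
    for (id in ids)
      arrays <- c(arrays,
                  detectArrays(ctg[[id]], contigId = id,
                               minRepeats = cPar$minRepeats %||% 3L))
    writeArrays(arrays, file.path(outdir, "crispr_arrays.gff3"),
                file.path(outdir, "crispr_spacers.tsv"))
    report$stages$crispr <- list(nArrays = length(arrays))
  }
  arrayContigs <- unique(vapply(arrays, function(a) a@contigId, ""))

  # ---- classify ----
  classTab <- NULL
  if ("classify" %in% stages && !is.null(annot)) {
    clPar <- config$classify %||% list()
    minLength <- clPar$minLength %||% 200000L
    rows <- lapply(ids, function(id) {
      h <- annot[annot$contig_id == id, , drop = FALSE]
      nGenes <- max(nrow(h), 1L)
      vote <- voteTaxonomy(h)
      markers <- findPhageMarkers(h)
      hypo <- if (nrow(h)) hypotheticalFraction(h, nGenes) else 1
      plas <- findPlasmidGenes(h)
      proph <- if (nrow(h) >= 4L)
        detectProphageTransition(h, length(ctg[[id]])) else NULL
      res <- classifyElement(id, length(ctg[[id]]), vote, markers, hypo,
                             plasmidGenes = plas,
                             prophageBoundaries = proph,
                             crisprPresent = id %in% arrayContigs,
                             minLength = minLength)
      data.frame(contig = id, element_type = elementType(res),
                 retained = res@retained,
                 length_exception = res@lengthException,
                 hypothetical_fraction = round(hypo, 4),
                 markers = paste(markers, collapse = ","),
                 domain_winner = vote$winner[vote$rank == "domain"],
                 phylum_winner = vote$winner[vote$rank == "phylum"],
                 prophage_boundaries = paste(round(proph %||% numeric()),
                                             collapse = ";"),
                 rule_trace = paste(ruleTrace(res), collapse = " | "))
    })
    classTab <- do.call(rbind, rows)
    .writeTsv(classTab, file.path(outdir, "classification.tsv"))
    report$stages$classify <-
      list(counts = as.list(table(classTab$element_type[classTab$retained])))
  }

  # ---- spacer matching, network, hosts ----
  matches <- NULL
  if ("crispr" %in% stages && length(arrays)) {
    matches <- matchSpacers(arrays, ctg, targetArrays = arrays)
    .writeTsv(matches, file.path(outdir, "spacer_matches.tsv"))
    nodeTypes <- if (!is.null(classTab))
      setNames(ifelse(classTab$element_type == "phage", "phage",
                      ifelse(!is.na(classTab$domain_winner) &
                               classTab$domain_winner == "Bacteria",
                             "bacteria", "unknown")), classTab$contig)
      else character()
    net <- buildNetwork(matches, nodeTypes)
    writeNetwork(net, file.path(outdir, "crispr_network.tsv"),
                 file.path(outdir, "crispr_network.graphml"))
    report$stages$network <- list(nEdges = nrow(net$edges),
                                  nSelf = nrow(net$selfTargeting))
  }

  hostTab <- NULL
  if ("hosts" %in% stages && !is.null(annot) && !is.null(classTab)) {
    phageIds <- classTab$contig[classTab$element_type == "phage" &
                                  classTab$retained]
    bactIds <- classTab$contig[classTab$element_type != "phage" &
                                 !is.na(classTab$phylum_winner)]
    bactTaxa <- setNames(classTab$phylum_winner[match(bactIds,
                                                      classTab$contig)],
                         bactIds)
    hostTab <- predictHosts(annot, phageIds,
                            matches %||% data.frame(tier = character(),
                                                    source_contig = character(),
                                                    target_contig = character()),
                            bactTaxa)
    .writeTsv(hostTab, file.path(outdir, "host_predictions.tsv"))
    report$stages$hosts <- list(assigned = sum(!is.na(hostTab$final)))
  }

  # ---- families ----
  famTab <- NULL
  if ("families" %in% stages && !is.null(edgesAv)) {
    fPar <- config$families %||% list()
    prots <- if (!is.null(community))
      unique(communityTruth(community)$proteinFamilies$protein)
    else unique(c(edgesAv$query, edgesAv$target))
    fams <- clusterProteinFamilies(edgesAv, edgesPf %||%
                                     data.frame(query = character(),
                                                target = character(),
                                                probability = numeric(),
                                                coverage = numeric()),
                                   proteins = prots,
                                   inflation = fPar$inflation %||% 2.0)
    famTab <- fams$families
    .writeTsv(famTab, file.path(outdir, "protein_families.tsv"))
    report$stages$families <-
      list(nProteins = nrow(famTab),
           nSubfamilies = length(unique(famTab$subfamily)),
           nFamilies = length(unique(famTab$family)))
  }

  # ---- summary ----
  if ("summary" %in% stages && !is.null(trna) && nrow(trna) >= 3L) {
    ss <- summaryStats(trna, seed = seed)
    report$stages$summary <- ss[c("n", "medianLength", "spearmanRho",
                                  "permutationP")]
  }

  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(outdir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
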