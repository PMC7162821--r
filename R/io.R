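# Readers and writers for the pipeline's tabular and sequence formats.
# All writers are deterministic (fixed column order, no timestamps) so reruns
# under the same seed are byte-identical.

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read contigs from a FASTA file
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readContigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Read a per-gene annotation hit table
#'
#' Expected columns: `contig_id`, `gene_id`, `gene_start`, `gene_end`,
#' lineage columns `domain` ... `genus`, `keyword`, `bitscore`.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
readAnnotations <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA"),
             colClasses = NA)
}

#' Read a similarity edge table
#'
#' @param path TSV path (columns `query`, `target` plus `evalue`/`coverage`
#'   or `probability`/`coverage`).
#' @return `data.frame`.
#' @export
readEdges <- function(path) read.delim(path, stringsAsFactors = FALSE)

# Write features as GFF3 (1-based inclusive coordinates).
# df: seqid, source, type, start, end, score, strand, attributes
.writeGff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                     df$seqid, df$source, df$type, as.integer(df$start),
                     as.integer(df$end), df$score, df$strand, df$attributes)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export gene calls as GFF3
#'
#' @param genes Gene table from [callOrfs()] plus a `contig` column (or a
#'   single `contigId` argument).
#' @param path Output path.
#' @param contigId Contig id used when `genes` lacks a `contig` column.
#' @return Invisibly, the path.
#' @export
writeGenesGff3 <- function(genes, path, contigId = "contig") {
  cid <- if ("contig" %in% names(genes)) genes$contig else
    rep(contigId, nrow(genes))
  df <- data.frame(seqid = cid, source = "hugephage", type = "CDS",
                   start = genes$start, end = genes$end, score = ".",
                   strand = genes$strand,
                   attributes = sprintf("ID=%s_g%04d", cid,
                                        seq_len(nrow(genes))))
  .writeGff3(df, path)
}

#' Export CRISPR arrays as GFF3 and a spacer TSV
#'
#' @param arrays List of [CrisprArray-class].
#' @param gffPath,tsvPath Output paths (`NULL` to skip one).
#' @return Invisibly, the written paths.
#' @export
writeArrays <- function(arrays, gffPath = NULL, tsvPath = NULL) {
  if (!is.null(gffPath)) {
    rows <- lapply(seq_along(arrays), function(i) {
      a <- arrays[[i]]
      data.frame(seqid = a@contigId, source = "hugephage",
                 type = "repeat_region", start = a@start, end = a@end,
                 score = ".", strand = ".",
                 attributes = sprintf(
                   "ID=%s_arr%d;n_repeats=%d;consensus=%s",
                   a@contigId, i, nrow(a@repeats), a@consensusRepeat))
    })
    .writeGff3(do.call(rbind, c(rows, list(
      data.frame(seqid = character(), source = character(),
                 type = character(), start = integer(), end = integer(),
                 score = character(), strand = character(),
                 attributes = character())))), gffPath)
  }
  if (!is.null(tsvPath)) {
    sp <- do.call(rbind, c(lapply(arrays, function(a) {
      d <- a@spacers
      d$contig <- a@contigId
      d$consensus_repeat <- a@consensusRepeat
      d[, c("contig", "id", "start", "end", "seq", "consensus_repeat")]
    }), list(data.frame(contig = character(), id = character(),
                        start = integer(), end = integer(),
                        seq = character(), consensus_repeat = character()))))
    .writeTsv(sp, tsvPath)
  }
  invisible(c(gffPath, tsvPath))
}

#' Export the CRISPR interaction network
#'
#' Writes the edge list as TSV and, optionally, GraphML (via igraph).
#'
#' @param network Result of [buildNetwork()].
#' @param tsvPath Edge-list TSV path.
#' @param graphmlPath Optional GraphML path.
#' @return Invisibly, the written paths.
#' @export
writeNetwork <- function(network, tsvPath, graphmlPath = NULL) {
  .writeTsv(network$edges, tsvPath)
  if (!is.null(graphmlPath)) {
    if (nrow(network$edges)) {
      g <- igraph::graph_from_data_frame(network$edges, directed = TRUE)
      igraph::write_graph(g, graphmlPath, format = "graphml")
    } else {
      igraph::write_graph(igraph::make_empty_graph(), graphmlPath,
                          format = "graphml")
    }
  }
  invisible(c(tsvPath, graphmlPath))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown top-level keys are rejected.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("seed", "outdir", "community", "inputs", "qc", "genes",
             "classify", "crispr", "hosts", "families", "stages", "summary")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
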