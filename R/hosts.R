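# Host-phylum prediction: annotation-profile voting under the 3x rule,
# CRISPR-targeting evidence, and their reconciliation.

#' Vote a phage's host phylum from its annotation profile
#'
#' Sums phylum-level best-hit counts over the phage's genes (abstaining
#' genes excluded) and assigns the top phylum only when it has at least
#' three times as many counts as the runner-up (a single voted phylum always
#' qualifies).
#'
#' @param hits Annotation table restricted to the phage's genes, with a
#'   `phylum` column (empty string / `NA` = abstain).
#' @param ratio Required top:second count ratio (default 3).
#' @return List with `votePhylum` (`NA` when the ratio is not met) and
#'   `voteCounts` (named integer vector, decreasing).
#' @export
voteHost <- function(hits, ratio = 3) {
  v <- hits$phylum
  v <- v[!is.na(v) & v != ""]
  if (length(v) == 0L)
    return(list(votePhylum = NA_character_, voteCounts = integer()))
  tab <- sort(table(v), decreasing = TRUE)
  counts <- setNames(as.integer(tab), names(tab))
  second <- if (length(counts) >= 2L) counts[2L] else 0L
  vote <- if (counts[1L] >= ratio * second) names(counts)[1L]
          else NA_character_
  list(votePhylum = vote, voteCounts = counts)
}

#' Infer host phyla from CRISPR targeting
#'
#' A bacterial contig whose array strictly targets a phage (alignment
#' length > 24 bp, at most one mismatch) is taken as evidence that the
#' phage replicates in that bacterium's phylum. Strict matches from
#' multiple phyla onto the same phage are flagged as a conflict.
#'
#' @param matches Match table from [matchSpacers()].
#' @param bacterialTaxa Named character vector: bacterial contig id ->
#'   phylum.
#' @return `data.frame` with one row per targeted phage: `phage`,
#'   `crisprPhylum` (`NA` on conflict), `conflict`, `phyla` (collapsed list).
#' @export
crisprHost <- function(matches, bacterialTaxa) {
  m <- matches[matches$tier == "strict" &
                 matches$source_contig %in% names(bacterialTaxa), ,
               drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(phage = character(), crisprPhylum = character(),
                      conflict = logical(), phyla = character()))
  out <- do.call(rbind, lapply(split(m, m$target_contig), function(d) {
    ph <- unique(unname(bacterialTaxa[d$source_contig]))
    data.frame(phage = d$target_contig[1L],
               crisprPhylum = if (length(ph) == 1L) ph else NA_character_,
               conflict = length(ph) > 1L,
               phyla = paste(sort(ph), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}

#' Reconcile vote-based and CRISPR-based host evidence
#'
#' Agreement of the two evidence lines yields a final host call; a single
#' line of evidence is reported with a `single_evidence` flag; disagreement
#' leaves the host unassigned. The operation is symmetric in the two
#' evidence lines.
#'
#' @param phageId Phage contig id.
#' @param votePhylum Phylum from [voteHost()] (`NA` when absent).
#' @param crisprPhylum Phylum from [crisprHost()] (`NA` when absent).
#' @param voteCounts Optional named counts recorded in the result.
#' @return `data.frame` row: `phage`, `votePhylum`, `crisprPhylum`, `final`,
#'   `agreement` (`"agree"`, `"conflict"`, `"single_evidence"`, `"none"`).
#' @export
reconcileHost <- function(phageId, votePhylum, crisprPhylum,
                          voteCounts = NULL) {
  haveV <- !is.na(votePhylum)
  haveC <- !is.na(crisprPhylum)
  if (haveV && haveC) {
    if (votePhylum == crisprPhylum) {
      final <- votePhylum; agreement <- "agree"
    } else {
      final <- NA_character_; agreement <- "conflict"
    }
  } else if (haveV || haveC) {
    final <- if (haveV) votePhylum else crisprPhylum
    agreement <- "single_evidence"
  } else {
    final <- NA_character_; agreement <- "none"
  }
  data.frame(phage = phageId, votePhylum = votePhylum,
             crisprPhylum = crisprPhylum, final = final,
             agreement = agreement)
}

#' Predict hosts for a set of phages
#'
#' Convenience wrapper running [voteHost()], [crisprHost()] and
#' [reconcileHost()] across all phage contigs.
#'
#' @param annotations Full annotation table (`contig_id`, `phylum`, ...).
#' @param phageIds Phage contig ids.
#' @param matches Spacer match table from [matchSpacers()].
#' @param bacterialTaxa Named vector: bacterial contig -> phylum.
#' @param ratio Vote ratio (default 3).
#' @return `data.frame` with one row per phage.
#' @export
predictHosts <- function(annotations, phageIds, matches, bacterialTaxa,
                         ratio = 3) {
  ch <- crisprHost(matches, bacterialTaxa)
  out <- lapply(phageIds, function(id) {
    v <- voteHost(annotations[annotations$contig_id == id, , drop = FALSE],
                  ratio = ratio)
    ci <- match(id, ch$phage)
    cp <- if (!is.na(ci) && !ch$conflict[ci]) ch$crisprPhylum[ci]
          else NA_character_
    r <- reconcileHost(id, v$votePhylum, cp, v$voteCounts)
    r$crisprConflict <- !is.na(ci) && ch$conflict[ci]
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
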