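## Alien Index screening: per-gene log-ratio of the best Dikarya vs best
## bacterial homology E-values, aggregated per cluster (avg_AI over all
## genes, avg_AI_core over core-family genes).

#' Read group-labelled taxonomic hits
#'
#' A TSV with header and columns \code{protein_id}, \code{subject_id},
#' \code{group} (\code{Dikarya} or \code{Bacteria}) and \code{evalue}.
#' Alternatively, the two-file convention: one table per group, each
#' without the \code{group} column, read with \code{group} set — the two
#' results simply \code{rbind} together.
#'
#' @param path input TSV
#' @param group when the table carries no \code{group} column, the group
#'   label to stamp on every row (\code{"Dikarya"} or \code{"Bacteria"})
#' @return data.frame of taxonomic hits
#' @examples \dontrun{
#' hits <- rbind(readTaxonomicHits("dikarya_hits.tsv", group = "Dikarya"),
#'               readTaxonomicHits("bacteria_hits.tsv", group = "Bacteria"))
#' }
#' @export
readTaxonomicHits <- function(path, group = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(tab) && !is.null(group))
    tab$group <- match.arg(group, c("Dikarya", "Bacteria"))
  need <- c("protein_id", "subject_id", "group", "evalue")
  if (!all(need %in% names(tab)))
    stop("taxonomic hit table needs columns: ", paste(need, collapse = ", "))
  bad <- !tab$group %in% c("Dikarya", "Bacteria")
  if (any(bad)) stop("group must be 'Dikarya' or 'Bacteria'")
  tab[need]
}

#' Best E-value per protein and taxon group
#'
#' Drops hits above the E-value ceiling (default 1e-05, the survey setting)
#' and self-matches (subject equal to the query's own id), then takes the
#' minimum E-value per protein within each of the two groups.
#'
#' @param hits taxonomic hits (see [readTaxonomicHits()])
#' @param e_max E-value ceiling (default 1e-05)
#' @param proteins optional protein ids to report even without hits
#' @return data.frame \code{protein_id}, \code{best_e_dikarya},
#'   \code{best_e_bacteria} (\code{NA} where a group has no qualifying hit)
#' @export
bestHitsByGroup <- function(hits, e_max = 1e-05, proteins = NULL) {
  h <- hits[hits$evalue <= e_max & hits$protein_id != hits$subject_id, ,
            drop = FALSE]
  ids <- sort(unique(c(proteins, h$protein_id)))
  bestOf <- function(group) {
    hg <- h[h$group == group, , drop = FALSE]
    if (!nrow(hg)) return(stats::setNames(rep(NA_real_, length(ids)), ids))
    m <- tapply(hg$evalue, hg$protein_id, min)
    stats::setNames(unname(m[ids]), ids)
  }
  data.frame(protein_id = ids,
             best_e_dikarya = unname(bestOf("Dikarya")),
             best_e_bacteria = unname(bestOf("Bacteria")))
}

#' Alien Index of a gene
#'
#' \code{AI = ln(best_e_dikarya + pseudo) - ln(best_e_bacteria + pseudo)}:
#' positive when the bacterial best hit is stronger (smaller E-value) than
#' the best hit in the recipient lineage — the signature of a candidate
#' horizontally transferred gene. An absent group is treated as a best
#' E-value of 1 (the weakest possible hit), keeping AI finite; the
#' pseudocount (default 1e-200) guards against exact-zero E-values. The
#' statistic is antisymmetric in its two arguments. Vectorised.
#'
#' @param best_e_dikarya,best_e_bacteria best E-values per group, \code{NA}
#'   for absent
#' @param pseudo pseudocount added inside the logarithms
#' @param absent E-value substituted for an absent group (default 1)
#' @return numeric Alien Index value(s)
#' @examples
#' alienIndex(1e-5, 1e-50)    # 45 * log(10), bacterial hit far stronger
#' @export
alienIndex <- function(best_e_dikarya, best_e_bacteria, pseudo = 1e-200,
                       absent = 1) {
  d <- ifelse(is.na(best_e_dikarya), absent, best_e_dikarya)
  b <- ifelse(is.na(best_e_bacteria), absent, best_e_bacteria)
  if (any(d < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("E-values must be non-negative")
  log(d + pseudo) - log(b + pseudo)
}

#' Per-gene Alien Index records
#'
#' Convenience wrapper: best hits per group plus the AI value per protein.
#'
#' @inheritParams bestHitsByGroup
#' @param pseudo,absent see [alienIndex()]
#' @return data.frame \code{protein_id}, \code{best_e_dikarya},
#'   \code{best_e_bacteria}, \code{ai}
#' @export
alienIndexRecords <- function(hits, e_max = 1e-05, proteins = NULL,
                              pseudo = 1e-200, absent = 1) {
  rec <- bestHitsByGroup(hits, e_max = e_max, proteins = proteins)
  rec$ai <- alienIndex(rec$best_e_dikarya, rec$best_e_bacteria,
                       pseudo = pseudo, absent = absent)
  rec
}

#' Cluster-level Alien Index averages
#'
#' \code{avg_AI} is the arithmetic mean of the per-gene AI over all cluster
#' genes; genes without a record (no qualifying hit in either group)
#' contribute 0 rather than being dropped, so sparsely annotated clusters
#' are not biased toward their annotated genes. \code{avg_AI_core} averages
#' only the genes whose family label belongs to the core set (the core
#' biosynthetic families plus FAAL); it is \code{NA} when the cluster
#' carries no core-family gene.
#'
#' @param cluster a [ClusterRegion-class]; must contain at least one gene
#' @param records AI records from [alienIndexRecords()]
#' @param family_map named vector: protein id to family label
#' @param core_set family labels counting as core (default
#'   [coreFamilyLabels()], which already includes FAAL)
#' @return the cluster with \code{avg_AI}/\code{avg_AI_core} slots filled
#' @export
clusterAI <- function(cluster, records, family_map = NULL,
                      core_set = coreFamilyLabels()) {
  g <- regionGenes(cluster)
  if (!nrow(g)) stop("cluster ", clusterId(cluster), " has no genes")
  ai <- stats::setNames(records$ai, records$protein_id)[g$gene_id]
  ai[is.na(ai)] <- 0
  cluster@avg_AI <- mean(ai)
  core_genes <- if (is.null(family_map)) character(0) else
    g$gene_id[!is.na(family_map[g$gene_id]) &
              family_map[g$gene_id] %in% core_set]
  cluster@avg_AI_core <- if (length(core_genes))
    mean(ai[core_genes]) else NA_real_
  cluster
}

#' Cluster AI table over a dataset
#'
#' @param clusters list of [ClusterRegion-class] objects
#' @param records AI records from [alienIndexRecords()]
#' @param family_map,core_set see [clusterAI()]
#' @return data.frame \code{cluster_id}, \code{avg_AI}, \code{avg_AI_core}
#' @export
clusterAITable <- function(clusters, records, family_map = NULL,
                           core_set = coreFamilyLabels()) {
  rows <- lapply(clusters, function(cl) {
    cl <- clusterAI(cl, records, family_map, core_set)
    data.frame(cluster_id = clusterId(cl), avg_AI = cl@avg_AI,
               avg_AI_core = cl@avg_AI_core)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
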