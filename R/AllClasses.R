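#' ClusterRegion: one candidate secondary metabolite cluster
#'
#' An S4 container for a single candidate secondary metabolite cluster (SMC):
#' a genomic interval on one contig of one assembly, its member gene models,
#' and the annotations accumulated along the pipeline (assigned type, hybrid
#' types, core-family labels, Alien Index averages).
#'
#' Coordinates are internal 0-based half-open throughout; GenBank I/O
#' converts 1-based inclusive coordinates at the boundary.
#'
#' The \code{genes} slot is a data.frame with one row per gene model and
#' columns \code{gene_id}, \code{contig}, \code{start}, \code{end},
#' \code{strand} (\code{"+"}/\code{"-"}), \code{protein} (amino-acid string)
#' and \code{product}; rows are kept sorted by \code{start}.
#'
#' @slot cluster_id unique cluster identifier, by convention
#'   \code{assembly_id + "__" + ordinal + source suffix} (e.g.
#'   \code{"GCA_000507065__21_glim"})
#' @slot assembly_id assembly accession the cluster belongs to
#' @slot contig contig/scaffold name
#' @slot start,end cluster interval in base pairs (0-based half-open)
#' @slot genes data.frame of member gene models (see Details)
#' @slot assigned_type SMC type label or \code{"unassigned"}
#' @slot hybrid_types character vector of additional satisfied type labels
#' @slot core_families character vector of core-family labels found in the
#'   cluster
#' @slot avg_AI,avg_AI_core mean Alien Index over all genes / over core-family
#'   genes (\code{NA_real_} until computed; \code{avg_AI_core} stays \code{NA}
#'   when the cluster carries no core-family gene)
#'
#' @seealso [clusterRegion()] for the user-facing constructor,
#'   [readClusterGenBank()] to import regions.
#' @export
setClass("ClusterRegion",
  representation(
    cluster_id    = "character",
    assembly_id   = "character",
    contig        = "character",
    start         = "numeric",
    end           = "numeric",
    genes         = "data.frame",
    assigned_type = "character",
    hybrid_types  = "character",
    core_families = "character",
    avg_AI        = "numeric",
    avg_AI_core   = "numeric"
  ),
  prototype(
    assigned_type = "unassigned",
    hybrid_types  = character(0),
    core_families = character(0),
    avg_AI        = NA_real_,
    avg_AI_core   = NA_real_
  )
)

.GENE_COLS <- c("gene_id", "contig", "start", "end", "strand", "protein",
                "product")

setValidity("ClusterRegion", function(object) {
  msg <- character(0)
  if (length(object@cluster_id) != 1L || !nzchar(object@cluster_id))
    msg <- c(msg, "cluster_id must be a single non-empty string")
  if (length(object@start) != 1L || length(object@end) != 1L ||
      object@start < 0 || object@start >= object@end)
    msg <- c(msg, "need 0 <= start < end")
  g <- object@genes
  if (!all(.GENE_COLS %in% names(g)))
    msg <- c(msg, paste("genes must have columns:",
                        paste(.GENE_COLS, collapse = ", ")))
  if (nrow(g) > 0L && all(.GENE_COLS %in% names(g))) {
    if (any(g$start >= g$end)) msg <- c(msg, "gene intervals need start < end")
    if (is.unsorted(g$start)) msg <- c(msg, "genes must be sorted by start")
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_id not unique")
    if (any(!nzchar(g$protein))) msg <- c(msg, "empty protein translation")
    if (any(g$start < object@start) || any(g$end > object@end))
      msg <- c(msg, "gene interval outside the cluster interval")
    if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be +/-")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterRegion
#'
#' @param cluster_id cluster identifier (convention:
#'   \code{assembly__ordinal_source})
#' @param genes data.frame of gene models with columns \code{gene_id},
#'   \code{contig}, \code{start}, \code{end}, \code{strand}, \code{protein},
#'   \code{product}; any order, re-sorted by \code{start}
#' @param assembly_id assembly accession; default: the part of
#'   \code{cluster_id} before \code{"__"}
#' @param contig contig name; defaults to the genes' contig
#' @param start,end cluster interval (0-based half-open); default: the outer
#'   span of the genes
#' @param assigned_type,hybrid_types,core_families optional annotations
#' @return a [ClusterRegion-class] object
#' @examples
#' g <- data.frame(gene_id = "g1", contig = "ctg1", start = 100, end = 400,
#'                 strand = "+", protein = "MKV", product = "hypothetical")
#' clusterRegion("ASM1__1_glim", g)
#' @export
clusterRegion <- function(cluster_id, genes,
                          assembly_id = sub("__.*$", "", cluster_id),
                          contig = NULL, start = NULL, end = NULL,
                          assigned_type = "unassigned",
                          hybrid_types = character(0),
                          core_families = character(0)) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) > 0L)
    genes <- genes[order(genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(contig))
    contig <- if (nrow(genes)) genes$contig[1L] else cluster_id
  if (is.null(start)) start <- if (nrow(genes)) min(genes$start) else 0
  if (is.null(end))   end   <- if (nrow(genes)) max(genes$end) else 1
  new("ClusterRegion", cluster_id = cluster_id, assembly_id = assembly_id,
      contig = contig, start = as.numeric(start), end = as.numeric(end),
      genes = genes, assigned_type = assigned_type,
      hybrid_types = hybrid_types, core_families = core_families)
}

#' Hit filter for cluster-similarity scoring
#'
#' Thresholds applied to protein-vs-protein hits before and during
#' synteny-aware cluster-pair scoring.
#'
#' @slot min_identity minimum percent identity (default 30)
#' @slot min_coverage minimum alignment coverage in percent (default 60)
#' @slot coverage_mode \code{"both"} applies \code{min_coverage} to query and
#'   subject coverage (the stricter, symmetric reading); \code{"query"} to the
#'   query side only
#' @slot max_boundary_gap maximum distance in bp between syntenic region
#'   boundaries (default 1e6; the boundary itself is inclusive)
#' @slot min_hits minimum number of distinct syntenic query genes for an edge
#'   (default 1, i.e. single-gene matches count; 2 reproduces the legacy
#'   behaviour)
#' @slot synteny_weight weight of the colinear-chain length in the combined
#'   score (default 0.5)
#' @export
setClass("HitFilter",
  representation(
    min_identity     = "numeric",
    min_coverage     = "numeric",
    coverage_mode    = "character",
    max_boundary_gap = "numeric",
    min_hits         = "numeric",
    synteny_weight   = "numeric"
  ),
  prototype(min_identity = 30, min_coverage = 60, coverage_mode = "both",
            max_boundary_gap = 1e6, min_hits = 1, synteny_weight = 0.5)
)

setValidity("HitFilter", function(object) {
  msg <- character(0)
  for (s in c("min_identity", "min_coverage", "max_boundary_gap", "min_hits",
              "synteny_weight"))
    if (methods::slot(object, s) < 0)
      msg <- c(msg, paste(s, "must be >= 0"))
  if (!object@coverage_mode %in% c("both", "query"))
    msg <- c(msg, "coverage_mode must be 'both' or 'query'")
  if (length(msg)) msg else TRUE
})

#' @rdname HitFilter-class
#' @param min_identity,min_coverage,coverage_mode,max_boundary_gap,min_hits,synteny_weight
#'   see the class slots
#' @return a \code{HitFilter} object
#' @examples
#' hitFilter()                 # paper-mode defaults
#' hitFilter(min_hits = 2)     # legacy two-hit requirement
#' @export
hitFilter <- function(min_identity = 30, min_coverage = 60,
                      coverage_mode = c("both", "query"),
                      max_boundary_gap = 1e6, min_hits = 1,
                      synteny_weight = 0.5) {
  new("HitFilter", min_identity = min_identity, min_coverage = min_coverage,
      coverage_mode = match.arg(coverage_mode),
      max_boundary_gap = max_boundary_gap, min_hits = min_hits,
      synteny_weight = synteny_weight)
}

setMethod("show", "ClusterRegion", function(object) {
  cat("ClusterRegion", object@cluster_id, "\n")
  cat("  ", object@contig, ":", object@start, "-", object@end,
      " (", object@end - object@start, " bp, ",
      nrow(object@genes), " genes)\n", sep = "")
  cat("  type:", object@assigned_type,
      if (length(object@hybrid_types))
        paste0("(+ ", paste(object@hybrid_types, collapse = ", "), ")")
      else "", "\n")
  if (!is.na(object@avg_AI))
    cat("  avg_AI:", format(object@avg_AI, digits = 4),
        " avg_AI_core:", format(object@avg_AI_core, digits = 4), "\n")
  invisible(object)
})

setMethod("show", "HitFilter", function(object) {
  cat("HitFilter: identity >=", object@min_identity,
      "% | coverage >=", object@min_coverage, "% (", object@coverage_mode,
      ") | gap <=", object@max_boundary_gap,
      "bp | min_hits", object@min_hits,
      "| synteny_weight", object@synteny_weight, "\n")
  invisible(object)
})
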