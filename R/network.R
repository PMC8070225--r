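## Synteny-aware all-vs-all cluster similarity: hit filtering, syntenic-region
## grouping under a boundary-gap rule, combined scoring with colinear-chain
## bonus, identity-weighted network construction and export.

#' Filter protein-vs-protein hits for network construction
#'
#' Retains a hit iff its percent identity is at least \code{min_identity}
#' and its coverage meets \code{min_coverage} — on both query and subject
#' side in \code{"both"} mode (the default), or on the query side only in
#' \code{"query"} mode. Self-hits (query == subject) are always removed;
#' with a \code{protein_to_cluster} map, intra-cluster hits are removed
#' too.
#'
#' @param hits similarity-hit data.frame
#' @param filter a [hitFilter()]
#' @param protein_to_cluster optional named vector mapping protein ids to
#'   cluster ids (enables intra-cluster removal)
#' @return the retained hits
#' @export
filterHits <- function(hits, filter = hitFilter(),
                       protein_to_cluster = NULL) {
  keep <- hits$query_id != hits$subject_id &
    hits$pct_identity >= filter@min_identity &
    hits$q_cov >= filter@min_coverage
  if (filter@coverage_mode == "both")
    keep <- keep & hits$s_cov >= filter@min_coverage
  if (!is.null(protein_to_cluster)) {
    qc <- unname(protein_to_cluster[hits$query_id])
    sc <- unname(protein_to_cluster[hits$subject_id])
    keep <- keep & !(!is.na(qc) & !is.na(sc) & qc == sc)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## gap between an interval [s,e) and a span [a,b): 0 when they overlap
.intervalGap <- function(a, b, s, e) pmax(0, s - b, a - e)

#' Group cluster-pair hits into syntenic regions
#'
#' Hits (annotated with the genomic intervals of their query and subject
#' genes) are sorted by query-gene start and scanned once: a hit joins the
#' current group iff the gap between the group's running span boundary and
#' the hit's gene interval is at most \code{max_boundary_gap} on BOTH
#' genomes (the boundary itself, e.g. exactly 1.0 Mbp, still joins);
#' otherwise a new group starts.
#'
#' @param pair_hits data.frame of hits between one cluster pair carrying
#'   columns \code{q_gstart}, \code{q_gend}, \code{s_gstart}, \code{s_gend}
#'   (genomic gene intervals, bp)
#' @param max_boundary_gap maximum boundary distance in bp (default 1e6)
#' @return list of data.frames, one per syntenic group, in query order
#' @export
syntenicRegions <- function(pair_hits, max_boundary_gap = 1e6) {
  if (!nrow(pair_hits)) return(list())
  h <- pair_hits[order(pair_hits$q_gstart, pair_hits$q_gend,
                       pair_hits$s_gstart), , drop = FALSE]
  groups <- list()
  cur <- h[1L, , drop = FALSE]
  span <- c(q1 = h$q_gstart[1L], q2 = h$q_gend[1L],
            s1 = h$s_gstart[1L], s2 = h$s_gend[1L])
  for (i in seq_len(nrow(h))[-1L]) {
    gq <- .intervalGap(span["q1"], span["q2"], h$q_gstart[i], h$q_gend[i])
    gs <- .intervalGap(span["s1"], span["s2"], h$s_gstart[i], h$s_gend[i])
    if (gq <= max_boundary_gap && gs <= max_boundary_gap) {
      cur <- rbind(cur, h[i, , drop = FALSE])
      span <- c(q1 = min(span["q1"], h$q_gstart[i]),
                q2 = max(span["q2"], h$q_gend[i]),
                s1 = min(span["s1"], h$s_gstart[i]),
                s2 = max(span["s2"], h$s_gend[i]))
      names(span) <- c("q1", "q2", "s1", "s2")
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- h[i, , drop = FALSE]
      span <- c(q1 = h$q_gstart[i], q2 = h$q_gend[i],
                s1 = h$s_gstart[i], s2 = h$s_gend[i])
    }
  }
  groups[[length(groups) + 1L]] <- cur
  lapply(groups, function(g) { rownames(g) <- NULL; g })
}

## longest colinear chain over distinct (query gene, subject gene) pairs:
## strictly increasing in query order and strictly monotone (either
## direction, strand-aware) in subject order
.syntenyChain <- function(q_order, s_order) {
  keep <- !duplicated(paste(q_order, s_order))
  q <- q_order[keep]; s <- s_order[keep]
  o <- order(q, s)
  q <- q[o]; s <- s[o]
  n <- length(q)
  if (n == 0L) return(0L)
  lis <- function(qv, sv, cmp) {
    best <- rep(1L, length(sv))
    for (i in seq_along(sv))
      for (j in seq_len(i - 1L))
        if (qv[j] < qv[i] && cmp(sv[j], sv[i]) && best[j] + 1L > best[i])
          best[i] <- best[j] + 1L
    max(best)
  }
  max(lis(q, s, `<`), lis(q, s, `>`))
}

#' Score one cluster pair
#'
#' From already-filtered hits between one cluster pair, selects the best
#' syntenic group (most hits; ties by higher summed bitscore), then scores
#' \code{score = n_hit_genes + synteny_weight * synteny_score} where
#' \code{n_hit_genes} counts distinct query genes in the group and
#' \code{synteny_score} is the length of the longest chain of hits colinear
#' in gene order on both clusters (a chain may run in reversed subject
#' order, so inverted segments still count). The edge weight is the mean
#' percent identity over the group's hits. No edge is emitted when fewer
#' than \code{min_hits} distinct query genes are hit — with the default
#' \code{min_hits = 1} a single shared gene suffices, which is what rescues
#' the frequently single-gene siderophore regions; \code{min_hits = 2}
#' reproduces the legacy behaviour.
#'
#' @param pair_hits filtered hits between one cluster pair with gene
#'   annotation columns \code{q_gene}, \code{s_gene}, \code{q_gstart},
#'   \code{q_gend}, \code{s_gstart}, \code{s_gend}, \code{q_order},
#'   \code{s_order} (gene rank within each cluster)
#' @param filter a [hitFilter()]
#' @return one-row data.frame (\code{n_hit_genes}, \code{synteny_score},
#'   \code{score}, \code{weight}, \code{n_hits}) or \code{NULL}
#' @export
scorePair <- function(pair_hits, filter = hitFilter()) {
  if (!nrow(pair_hits)) return(NULL)
  groups <- syntenicRegions(pair_hits, filter@max_boundary_gap)
  sizes <- vapply(groups, nrow, integer(1L))
  bs <- vapply(groups, function(g) sum(g$bitscore), numeric(1L))
  best <- order(-sizes, -bs)[1L]
  g <- groups[[best]]
  n_hit_genes <- length(unique(g$q_gene))
  if (n_hit_genes < filter@min_hits) return(NULL)
  synteny <- .syntenyChain(g$q_order, g$s_order)
  data.frame(n_hit_genes = n_hit_genes, synteny_score = synteny,
             score = n_hit_genes + filter@synteny_weight * synteny,
             weight = mean(g$pct_identity), n_hits = nrow(g))
}

## annotate hits with gene/cluster metadata from the regions
.annotateHits <- function(hits, clusters) {
  gene_tab <- do.call(rbind, lapply(clusters, function(cl) {
    g <- regionGenes(cl)
    if (!nrow(g)) return(NULL)
    data.frame(gene_id = g$gene_id, cluster_id = clusterId(cl),
               gstart = g$start, gend = g$end,
               gorder = rank(g$start, ties.method = "first"))
  }))
  idx <- match(hits$query_id, gene_tab$gene_id)
  jdx <- match(hits$subject_id, gene_tab$gene_id)
  hits$q_cluster <- gene_tab$cluster_id[idx]
  hits$s_cluster <- gene_tab$cluster_id[jdx]
  hits$q_gene <- hits$query_id
  hits$s_gene <- hits$subject_id
  hits$q_gstart <- gene_tab$gstart[idx]; hits$q_gend <- gene_tab$gend[idx]
  hits$s_gstart <- gene_tab$gstart[jdx]; hits$s_gend <- gene_tab$gend[jdx]
  hits$q_order <- gene_tab$gorder[idx]; hits$s_order <- gene_tab$gorder[jdx]
  hits[!is.na(hits$q_cluster) & !is.na(hits$s_cluster), , drop = FALSE]
}

#' Build the cluster-similarity network
#'
#' All-vs-all: protein hits are filtered ([filterHits()], intra-cluster hits
#' removed), mapped onto cluster pairs, and each unordered pair is scored
#' with [scorePair()]; pairs passing \code{min_hits} become edges weighted
#' by average sequence identity. Nodes carry the cluster annotations
#' (type, assembly, taxon, core families).
#'
#' @param clusters list of typed [ClusterRegion-class] objects
#' @param all_hits similarity-hit data.frame over the clusters' proteins
#' @param filter a [hitFilter()]
#' @param taxa optional named vector: assembly id to taxon label
#' @return an \pkg{igraph} undirected graph; edge attributes \code{weight},
#'   \code{score}, \code{n_hit_genes}, \code{synteny_score}; vertex
#'   attributes \code{assigned_type}, \code{assembly}, \code{taxon},
#'   \code{core_families}
#' @export
buildNetwork <- function(clusters, all_hits, filter = hitFilter(),
                         taxa = NULL) {
  p2c <- do.call(c, lapply(clusters, function(cl)
    stats::setNames(rep(clusterId(cl), nrow(regionGenes(cl))),
                    regionGenes(cl)$gene_id)))
  h <- filterHits(all_hits, filter, protein_to_cluster = p2c)
  h <- .annotateHits(h, clusters)

  ids <- vapply(clusters, clusterId, character(1L))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "assigned_type",
    value = vapply(clusters, assignedType, character(1L)))
  asm <- vapply(clusters, assemblyId, character(1L))
  g <- igraph::set_vertex_attr(g, "assembly", value = asm)
  g <- igraph::set_vertex_attr(g, "taxon",
    value = if (is.null(taxa)) rep("", length(ids)) else
      unname(taxa[asm]))
  g <- igraph::set_vertex_attr(g, "core_families",
    value = vapply(clusters, function(cl)
      paste(coreFamilies(cl), collapse = ","), character(1L)))

  if (nrow(h)) {
    a <- pmin(h$q_cluster, h$s_cluster)
    b <- pmax(h$q_cluster, h$s_cluster)
    ## orient every hit so the lexicographically smaller cluster is query
    flip <- h$q_cluster != a
    if (any(flip)) {
      sw <- function(x, y) { tmp <- h[[x]][flip]; h[[x]][flip] <<- h[[y]][flip]
        h[[y]][flip] <<- tmp }
      sw("q_gene", "s_gene"); sw("q_gstart", "s_gstart")
      sw("q_gend", "s_gend"); sw("q_order", "s_order")
      sw("q_cluster", "s_cluster")
    }
    key <- paste(a, b, sep = "\r")
    for (k in unique(key)) {
      ph <- h[key == k, , drop = FALSE]
      sc <- scorePair(ph, filter)
      if (is.null(sc)) next
      pair <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      g <- igraph::add_edges(g, pair, weight = sc$weight, score = sc$score,
                             n_hit_genes = sc$n_hit_genes,
                             synteny_score = sc$synteny_score)
    }
  }
  g
}

#' Summarise the connected components of the cluster network
#'
#' @param graph network from [buildNetwork()]
#' @return data.frame with one row per connected component:
#'   \code{component_id}, \code{size}, \code{types} (comma-joined
#'   \code{type:count} tally) and \code{singleton} flag
#' @export
componentSummary <- function(graph) {
  comp <- igraph::components(graph)
  types <- igraph::vertex_attr(graph, "assigned_type")
  if (is.null(types)) types <- rep("", igraph::vcount(graph))
  rows <- lapply(seq_len(comp$no), function(i) {
    members <- which(comp$membership == i)
    tally <- sort(table(types[members]), decreasing = TRUE)
    data.frame(component_id = i, size = length(members),
               types = paste(paste0(names(tally), ":", tally),
                             collapse = ","),
               singleton = length(members) == 1L)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export the network as GraphML and a TSV edge list
#'
#' @param graph network from [buildNetwork()]
#' @param graphml_path,edges_path output files (either may be NULL to skip)
#' @return invisibly, a list of the written paths
#' @export
writeNetwork <- function(graph, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    e <- igraph::as_data_frame(graph, what = "edges")
    names(e)[1:2] <- c("cluster_a", "cluster_b")
    writeTsv(e, edges_path)
  }
  invisible(list(graphml = graphml_path, edges = edges_path))
}
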