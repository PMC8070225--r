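## Protein-family inference over SMC-encoded proteins: an E-value-weighted
## similarity graph, a from-scratch Markov Cluster Algorithm (MCL), a
## silhouette-width grid for choosing (E-value threshold, inflation), and
## family naming/annotation.

.WEIGHT_CAP <- 200

#' Build the protein similarity graph
#'
#' Admits a hit iff its E-value is at or below \code{e_threshold} and weights
#' edges by \code{min(cap, -log10(max(evalue, 1e-200)))}, so an E-value of 0
#' gets the cap. Hits are deduplicated per ordered pair (best bitscore
#' kept), self-hits are dropped, and the two directions of a pair collapse
#' into one undirected edge carrying the larger weight.
#'
#' @param hits similarity-hit data.frame (see [readSimilarityTable()])
#' @param e_threshold admission E-value (default 1e-10, the survey value)
#' @param cap weight cap (default 200)
#' @param nodes optional node id vector; proteins without admissible hits are
#'   kept as isolated nodes
#' @return an \pkg{igraph} undirected graph with edge attribute
#'   \code{weight} and graph attributes \code{e_threshold} and \code{cap}
#' @export
buildSimilarityGraph <- function(hits, e_threshold = 1e-10,
                                 cap = .WEIGHT_CAP, nodes = NULL) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h)) {
    h <- h[order(h$query_id, h$subject_id, -h$bitscore), , drop = FALSE]
    h <- h[!duplicated(h[c("query_id", "subject_id")]), , drop = FALSE]
    h <- h[h$evalue <= e_threshold, , drop = FALSE]
  }
  ids <- sort(unique(c(nodes, h$query_id, h$subject_id)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(h)) {
    w <- pmin(cap, -log10(pmax(h$evalue, 1e-200)))
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste(a, b, sep = "\r")
    best <- tapply(w, key, max)
    pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(pairs)),
                           weight = as.numeric(best))
  }
  g <- igraph::set_graph_attr(g, "e_threshold", e_threshold)
  igraph::set_graph_attr(g, "cap", cap)
}

## One column-normalisation; dead columns (all-zero) get a self-loop.
.colNormalise <- function(M) {
  s <- colSums(M)
  dead <- s == 0
  if (any(dead)) {
    M[cbind(which(dead), which(dead))] <- 1
    s[dead] <- 1
  }
  sweep(M, 2L, s, "/")
}

#' Markov Cluster Algorithm (MCL)
#'
#' Clusters the similarity graph by alternating expansion (matrix
#' self-multiplication) and inflation (entrywise power followed by column
#' renormalisation), with pruning of small entries, until the matrix
#' converges. Self-loops are added first (per node: the maximum incident
#' edge weight, or 1 for isolated nodes) and the matrix is column-normalised
#' to a stochastic matrix. Clusters are read off the attractor rows; a node
#' claimed by several attractors goes to the attractor with the largest
#' value, ties to the smallest attractor index, so the output is always a
#' partition. The procedure involves no randomness.
#'
#' Families are ranked by decreasing size (ties broken lexicographically by
#' smallest member id) and named \code{MCL0001}, \code{MCL0002}, ...
#'
#' @param graph similarity graph from [buildSimilarityGraph()]
#' @param inflation inflation parameter, must be > 1 (default 1.55, the
#'   survey value)
#' @param self_loop \code{"max"} (default) or a positive number
#' @param prune_below entries below this are zeroed each iteration
#' @param tol convergence tolerance on the max entry change
#' @param max_iter iteration cap
#' @return data.frame with columns \code{family_id}, \code{protein_id}
#' @references Van Dongen S. (2000) Graph clustering by flow simulation.
#' @export
mclCluster <- function(graph, inflation = 1.55, self_loop = "max",
                       prune_below = 1e-5, tol = 1e-6, max_iter = 100L) {
  if (inflation <= 1) stop("inflation must be > 1")
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (n == 0L)
    return(data.frame(family_id = character(0), protein_id = character(0)))
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph))
    "weight" else NULL, sparse = FALSE)
  A <- (A + t(A)) / 2     # enforce exact symmetry
  loop <- if (identical(self_loop, "max")) {
    mx <- apply(A, 1L, max)
    ifelse(mx > 0, mx, 1)
  } else rep(as.numeric(self_loop), n)
  diag(A) <- loop
  M <- .colNormalise(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2 ^ inflation                # inflation
    M2 <- .colNormalise(M2)
    M2[M2 < prune_below] <- 0           # pruning
    M2 <- .colNormalise(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  ## attractors: nodes with mass on their own row (diagonal > 0)
  attractors <- which(diag(M) > prune_below)
  if (!length(attractors)) attractors <- seq_len(n)
  membership <- integer(n)
  for (j in seq_len(n)) {
    vals <- M[attractors, j]
    if (max(vals) <= 0) { membership[j] <- NA_integer_; next }
    membership[j] <- attractors[which.max(vals)]   # ties: smallest index
  }
  ## unclaimed nodes (fully pruned columns) become their own family
  membership[is.na(membership)] <- which(is.na(membership))
  ## attractors of one attractor system assign to the system's smallest
  ## index; follow assignment chains so every node lands on that root
  root <- function(j) {
    seen <- integer(0)
    while (!(j %in% seen) && membership[j] != j) {
      seen <- c(seen, j)
      j <- membership[j]
    }
    j
  }
  comp <- vapply(seq_len(n), root, integer(1L))
  fam <- split(ids, comp)
  ## rank: size desc, ties by smallest member id
  keymin <- vapply(fam, function(x) min(x), character(1L))
  ord <- order(-vapply(fam, length, integer(1L)), keymin)
  fam <- fam[ord]
  out <- data.frame(
    family_id = rep(sprintf("MCL%04d", seq_along(fam)),
                    vapply(fam, length, integer(1L))),
    protein_id = unlist(lapply(fam, sort), use.names = FALSE))
  out[order(out$family_id, out$protein_id), , drop = FALSE]
}

#' Mean silhouette width of a family partition
#'
#' Silhouette under the graph-derived distance
#' \code{d(a,b) = 1 - weight(a,b)/cap} (1 for non-adjacent pairs, 0 on the
#' diagonal): for each point \code{i} in a family of size >= 2,
#' \code{s(i) = (b(i) - a(i)) / max(a(i), b(i))} with \code{a(i)} the mean
#' distance to its own family and \code{b(i)} the smallest mean distance to
#' any other family. Points in singleton families are excluded; the mean is
#' undefined (NA) unless at least two families of size >= 2 exist.
#'
#' @param graph similarity graph
#' @param families family membership data.frame (from [mclCluster()])
#' @return mean silhouette width, or \code{NA_real_} when undefined
#' @export
meanSilhouette <- function(graph, families) {
  ids <- igraph::V(graph)$name
  cap <- igraph::graph_attr(graph, "cap")
  if (is.null(cap)) cap <- .WEIGHT_CAP
  n <- length(ids)
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph))
    "weight" else NULL, sparse = FALSE)
  A <- pmax(A, t(A))
  D <- 1 - A / cap
  D[A == 0] <- 1
  diag(D) <- 0
  memb <- stats::setNames(families$family_id, families$protein_id)[ids]
  sizes <- table(memb)
  eligible_fams <- names(sizes)[sizes >= 2L]
  if (length(eligible_fams) < 2L) return(NA_real_)
  s <- numeric(0)
  for (i in seq_len(n)) {
    fi <- memb[i]
    if (!(fi %in% eligible_fams)) next
    own <- which(memb == fi); own <- own[own != i]
    a_i <- mean(D[i, own])
    b_i <- min(vapply(setdiff(unique(memb), fi), function(f)
      mean(D[i, memb == f]), numeric(1L)))
    s <- c(s, (b_i - a_i) / max(a_i, b_i))
  }
  mean(s)
}

#' Sample MCL parameters on a silhouette-width grid
#'
#' Exhaustively evaluates every combination of E-value admission threshold
#' and inflation: builds the graph, runs MCL, and scores the partition by
#' mean silhouette width under the graph distance (see [meanSilhouette()]).
#' Samples where fewer than two families of size >= 2 exist are flagged
#' undefined rather than scored.
#'
#' @param hits similarity-hit data.frame
#' @param thresholds E-value thresholds to try
#' @param inflations inflation values to try
#' @param nodes optional full node set (isolated proteins included)
#' @return data.frame with columns \code{e_threshold}, \code{inflation},
#'   \code{n_clusters}, \code{mean_silhouette}, \code{defined}
#' @export
silhouetteSample <- function(hits, thresholds, inflations, nodes = NULL) {
  if (!length(thresholds) || !length(inflations))
    stop("empty parameter grid")
  grid <- expand.grid(e_threshold = thresholds, inflation = inflations,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- buildSimilarityGraph(hits, e_threshold = grid$e_threshold[i],
                              nodes = nodes)
    fam <- mclCluster(g, inflation = grid$inflation[i])
    ms <- meanSilhouette(g, fam)
    data.frame(e_threshold = grid$e_threshold[i],
               inflation = grid$inflation[i],
               n_clusters = length(unique(fam$family_id)),
               mean_silhouette = ms, defined = !is.na(ms))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Annotate protein families from reference hits
#'
#' Attaches per-family cluster counts and annotation labels. Families
#' represented in at least \code{major_n_smcs} candidate clusters are always
#' labelled — with the consensus reference name among qualifying hits, or
#' \code{"unlabelled-major"} when none qualifies. Smaller families of at
#' least two members are labelled only when some hit against the curated
#' references has both coverages above \code{min_dual_cov} and a category in
#' \code{categories} (MIBiG-style \code{biosynthetic},
#' \code{biosynthetic-additional}, \code{transporter}).
#'
#' @param families data.frame from [mclCluster()]
#' @param protein_to_cluster named vector: protein id to cluster id
#' @param ref_hits reference hits with columns \code{query_id},
#'   \code{subject_id}, \code{bitscore}, \code{q_cov}, \code{s_cov},
#'   \code{category}, \code{label}
#' @param min_dual_cov dual-coverage threshold in percent (default 50)
#' @param major_n_smcs cluster-count threshold for the always-labelled tier
#'   (default 10)
#' @param categories qualifying reference categories
#' @return data.frame with one row per family: \code{family_id},
#'   \code{n_members}, \code{n_smcs}, \code{label}
#' @export
nameAndAnnotate <- function(families, protein_to_cluster, ref_hits = NULL,
                            min_dual_cov = 50, major_n_smcs = 10,
                            categories = c("biosynthetic",
                                           "biosynthetic-additional",
                                           "transporter")) {
  fam_ids <- unique(families$family_id)
  if (!length(fam_ids))
    return(data.frame(family_id = character(0), n_members = integer(0),
                      n_smcs = integer(0), label = character(0)))
  out <- do.call(rbind, lapply(fam_ids, function(fid) {
    members <- families$protein_id[families$family_id == fid]
    n_smcs <- length(unique(stats::na.omit(
      unname(protein_to_cluster[members]))))
    label <- ""
    qual <- NULL
    if (!is.null(ref_hits) && nrow(ref_hits)) {
      h <- ref_hits[ref_hits$query_id %in% members &
                    ref_hits$q_cov > min_dual_cov &
                    ref_hits$s_cov > min_dual_cov, , drop = FALSE]
      qual <- h[h$category %in% categories, , drop = FALSE]
    }
    pick_label <- function(h) {
      lab <- if ("label" %in% names(h)) h$label else h$subject_id
      names(sort(table(lab), decreasing = TRUE))[1L]
    }
    if (n_smcs >= major_n_smcs) {
      label <- if (!is.null(qual) && nrow(qual)) pick_label(qual) else
        "unlabelled-major"
    } else if (length(members) >= 2L && !is.null(qual) && nrow(qual)) {
      label <- pick_label(qual)
    }
    data.frame(family_id = fid, n_members = length(members),
               n_smcs = n_smcs, label = label)
  }))
  out[order(out$family_id), , drop = FALSE]
}

#' Write an ABC-format edge list
#'
#' Three whitespace-separated columns (node, node, weight) interoperable
#' with the reference MCL implementation.
#'
#' @param graph similarity graph
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeAbcGraph <- function(graph, path) {
  e <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(e[c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
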