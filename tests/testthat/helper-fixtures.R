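## Shared fixture builders: all in-code, seeded, no files.

## one similarity-hit row with sensible defaults
simHit <- function(q, s, pident = 90, qlen = 100, slen = 100,
                   qs = 0, qe = qlen, ss = 0, se = slen,
                   evalue = 1e-40, bitscore = 200) {
  data.frame(query_id = q, subject_id = s, pct_identity = pident,
             ali_len = qe - qs, mismatch = round((qe - qs) * (1 - pident / 100)),
             gapopen = 0, q_start = qs, q_end = qe, s_start = ss, s_end = se,
             evalue = evalue, bitscore = bitscore, q_len = qlen, s_len = slen,
             q_cov = 100 * (qe - qs) / qlen, s_cov = 100 * (se - ss) / slen)
}

## a toy cluster with n genes of given protein length, genes 3 kb apart
toyCluster <- function(cluster_id, n = 3, plen = 100, assembly_id = NULL,
                       contig = "ctg1", offset = 0, gap = 3000) {
  genes <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- offset + (i - 1) * (3 * plen + gap)
    data.frame(gene_id = sprintf("%s_g%d", cluster_id, i), contig = contig,
               start = st, end = st + 3 * plen, strand = "+",
               protein = strrep("M", plen), product = "")
  }))
  if (is.null(assembly_id)) assembly_id <- sub("__.*$", "", cluster_id)
  clusterRegion(cluster_id, genes, assembly_id = assembly_id)
}

## domain-hit rows for one protein
domHits <- function(protein_id, accessions, evalue = 1e-30) {
  data.frame(protein_id = protein_id, accession = accessions,
             name = accessions, evalue = evalue, bitscore = 100,
             ali_start = 0, ali_end = 10)
}

## random hit table over n proteins: each unordered pair gets a hit with
## probability p_edge, E-value log-uniform in [1e-40, 1e-2] so some straddle
## the 1e-10 admission threshold
randomHitTable <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) > p_edge) next
    ev <- 10^runif(1, -40, -2)
    rows[[length(rows) + 1L]] <- simHit(ids[i], ids[j], evalue = ev,
                                        bitscore = round(-log10(ev) * 5))
  }
  list(ids = ids,
       hits = if (length(rows)) do.call(rbind, rows) else
         simHit("x", "y")[0, ])
}

## brute-force O(n^2) mean silhouette from a hit table, fully independent of
## the package implementation: distances straight from the definition
bruteSilhouette <- function(hits, ids, families, e_threshold = 1e-10,
                            cap = 200) {
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (k in seq_len(nrow(hits))) {
    if (hits$evalue[k] > e_threshold) next
    w <- min(cap, -log10(max(hits$evalue[k], 1e-200)))
    i <- hits$query_id[k]; j <- hits$subject_id[k]
    d <- 1 - w / cap
    D[i, j] <- min(D[i, j], d); D[j, i] <- D[i, j]
  }
  memb <- setNames(families$family_id, families$protein_id)[ids]
  sizes <- table(memb)
  ok_fams <- names(sizes)[sizes >= 2]
  if (length(ok_fams) < 2) return(NA_real_)
  vals <- c()
  for (i in seq_len(n)) {
    if (!memb[i] %in% ok_fams) next
    a <- mean(D[i, setdiff(which(memb == memb[i]), i)])
    b <- Inf
    for (f in setdiff(unique(memb), memb[i]))
      b <- min(b, mean(D[i, which(memb == f)]))
    vals <- c(vals, (b - a) / max(a, b))
  }
  mean(vals)
}

## exhaustive syntenic-grouping oracle for small hit sets: enumerate every
## partition of the query-sorted hits into consecutive blocks, keep the
## valid ones, and pick the lexicographically largest block-size sequence
oracleSyntenicSizes <- function(pair_hits, gap) {
  h <- pair_hits[order(pair_hits$q_gstart, pair_hits$q_gend,
                       pair_hits$s_gstart), , drop = FALSE]
  n <- nrow(h)
  validBlock <- function(idx) {
    span <- c(h$q_gstart[idx[1]], h$q_gend[idx[1]],
              h$s_gstart[idx[1]], h$s_gend[idx[1]])
    for (i in idx[-1]) {
      gq <- max(0, h$q_gstart[i] - span[2], span[1] - h$q_gend[i])
      gs <- max(0, h$s_gstart[i] - span[4], span[3] - h$s_gend[i])
      if (gq > gap || gs > gap) return(FALSE)
      span <- c(min(span[1], h$q_gstart[i]), max(span[2], h$q_gend[i]),
                min(span[3], h$s_gstart[i]), max(span[4], h$s_gend[i]))
    }
    TRUE
  }
  best <- NULL
  recurse <- function(start, sizes) {
    if (start > n) {
      if (is.null(best)) best <<- sizes
      else {
        l <- max(length(best), length(sizes))
        a <- c(sizes, rep(-1, l - length(sizes)))
        b <- c(best, rep(-1, l - length(best)))
        for (k in seq_len(l)) {
          if (a[k] > b[k]) { best <<- sizes; break }
          if (a[k] < b[k]) break
        }
      }
      return(invisible())
    }
    for (end in start:n)
      if (validBlock(start:end)) recurse(end + 1, c(sizes, end - start + 1))
      else break   # blocks are prefix-valid: a longer block cannot revalidate
  }
  recurse(1, integer(0))
  best
}

## adjusted Rand index between two labelled partitions (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
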