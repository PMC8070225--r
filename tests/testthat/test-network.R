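## gene-annotated pair hits for synteny tests: positions in bp
pairHit <- function(qg, sg, q_at, s_at, glen = 300, pident = 90,
                    bitscore = 200, q_ord = NA, s_ord = NA) {
  h <- simHit(qg, sg, pident = pident, bitscore = bitscore)
  h$q_gene <- qg; h$s_gene <- sg
  h$q_gstart <- q_at; h$q_gend <- q_at + glen
  h$s_gstart <- s_at; h$s_gend <- s_at + glen
  h$q_order <- q_ord; h$s_order <- s_ord
  h
}

test_that("hit filtering enforces identity and bilateral coverage", {
  hits <- rbind(
    simHit("a", "b", pident = 29.9),                       # identity fails
    simHit("c", "d", pident = 100),                        # retained
    simHit("e", "f", pident = 80, qs = 0, qe = 50),        # q_cov 50: fails
    simHit("g", "h", pident = 80, ss = 0, se = 50),        # s_cov 50: fails
    simHit("i", "i", pident = 100))                        # self-hit
  out <- filterHits(hits, hitFilter())
  expect_equal(out$query_id, c("c"))
  ## query-only coverage mode readmits the subject-side failure
  out2 <- filterHits(hits, hitFilter(coverage_mode = "query"))
  expect_setequal(out2$query_id, c("c", "g"))
  ## intra-cluster removal
  p2c <- c(c = "X", d = "X")
  expect_equal(nrow(filterHits(hits, hitFilter(),
                               protein_to_cluster = p2c)), 0)
})

test_that("12 synthetic hits with 4 single-threshold failures leave 8", {
  ok <- lapply(1:8, function(i) simHit(paste0("q", i), paste0("s", i),
                                       pident = 60))
  bad <- list(simHit("q9", "s9", pident = 10),
              simHit("q10", "s10", qs = 0, qe = 40),
              simHit("q11", "s11", ss = 0, se = 40),
              simHit("q12", "s12", pident = 29))
  expect_equal(nrow(filterHits(do.call(rbind, c(ok, bad)), hitFilter())), 8)
})

test_that("raising min_identity never adds an edge (monotone filtering)", {
  set.seed(4)
  hits <- do.call(rbind, lapply(1:30, function(i)
    simHit(paste0("q", i), paste0("s", i), pident = runif(1, 10, 100))))
  n_prev <- Inf
  for (mi in c(10, 30, 50, 90)) {
    n <- nrow(filterHits(hits, hitFilter(min_identity = mi)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("syntenic grouping obeys the 1 Mbp boundary rule", {
  ## three hits within 40 kb -> one group
  h3 <- rbind(pairHit("qa", "sa", 0, 0), pairHit("qb", "sb", 15000, 20000),
              pairHit("qc", "sc", 40000, 35000))
  expect_length(syntenicRegions(h3), 1)
  expect_equal(nrow(syntenicRegions(h3)[[1]]), 3)

  ## 0.9 Mbp apart on both genomes -> one region
  near <- rbind(pairHit("qa", "sa", 0, 0), pairHit("qb", "sb", 9e5, 9e5))
  expect_length(syntenicRegions(near), 1)

  ## exactly 1.0 Mbp boundary gap still joins (<= semantics)
  at <- rbind(pairHit("qa", "sa", 0, 0, glen = 300),
              pairHit("qb", "sb", 300 + 1e6, 300 + 1e6, glen = 300))
  expect_length(syntenicRegions(at), 1)

  ## 1.2 Mbp apart -> two regions
  far <- rbind(pairHit("qa", "sa", 0, 0), pairHit("qb", "sb", 1.2e6, 1.2e6))
  expect_length(syntenicRegions(far), 2)

  ## the gap must hold on BOTH genomes
  skew <- rbind(pairHit("qa", "sa", 0, 0), pairHit("qb", "sb", 1e4, 1.5e6))
  expect_length(syntenicRegions(skew), 2)
})

test_that("syntenic grouping matches the exhaustive oracle on small sets", {
  set.seed(9)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    gap <- 1e6
    h <- do.call(rbind, lapply(seq_len(n), function(i)
      pairHit(paste0("q", i), paste0("s", i),
              q_at = sample(0:4, 1) * 7e5,
              s_at = sample(0:4, 1) * 7e5,
              glen = sample(c(300, 3000), 1))))
    got <- vapply(syntenicRegions(h, gap), nrow, integer(1))
    want <- oracleSyntenicSizes(h, gap)
    expect_identical(got, as.integer(want), info = paste("rep", rep))
  }
})

test_that("pair scoring combines hit genes and colinear chain length", {
  ## two identical 3-gene clusters, all hits 100%: 3 genes, chain 3,
  ## score 3 + 0.5 * 3 = 4.5, weight 100
  h <- do.call(rbind, lapply(1:3, function(i)
    pairHit(paste0("A_g", i), paste0("B_g", i), q_at = (i - 1) * 4000,
            s_at = (i - 1) * 4000, pident = 100, q_ord = i, s_ord = i)))
  sc <- scorePair(h, hitFilter())
  expect_equal(sc$n_hit_genes, 3)
  expect_equal(sc$synteny_score, 3)
  expect_equal(sc$score, 4.5)
  expect_equal(sc$weight, 100)

  ## an inverted segment still chains (reversed subject order)
  hrev <- do.call(rbind, lapply(1:3, function(i)
    pairHit(paste0("A_g", i), paste0("B_g", 4 - i), q_at = (i - 1) * 4000,
            s_at = (3 - i) * 4000, pident = 90, q_ord = i, s_ord = 4 - i)))
  expect_equal(scorePair(hrev, hitFilter())$synteny_score, 3)

  ## shuffled, non-colinear pairs chain shorter
  hmix <- rbind(
    pairHit("A_g1", "B_g2", 0, 4000, q_ord = 1, s_ord = 2),
    pairHit("A_g2", "B_g1", 4000, 0, q_ord = 2, s_ord = 1),
    pairHit("A_g3", "B_g3", 8000, 8000, q_ord = 3, s_ord = 3))
  sc2 <- scorePair(hmix, hitFilter())
  expect_equal(sc2$n_hit_genes, 3)
  expect_equal(sc2$synteny_score, 2)
})

test_that("single-gene matches form edges only in min_hits=1 mode", {
  h <- pairHit("A_g1", "B_g1", 0, 0, pident = 80, q_ord = 1, s_ord = 1)
  expect_false(is.null(scorePair(h, hitFilter(min_hits = 1))))
  expect_null(scorePair(h, hitFilter(min_hits = 2)))
  expect_null(scorePair(h[0, ], hitFilter()))
})

test_that("pair scoring is symmetric under hit-table transposition", {
  set.seed(21)
  perm <- sample(1:5)     # one hit per gene pair, bijective
  h <- do.call(rbind, lapply(1:5, function(i)
    pairHit(paste0("A_g", i), paste0("B_g", perm[i]),
            q_at = (i - 1) * 5000, s_at = (perm[i] - 1) * 5000,
            pident = runif(1, 40, 100), q_ord = i, s_ord = perm[i])))
  ht <- h
  ht[c("q_gene", "q_gstart", "q_gend", "q_order")] <-
    h[c("s_gene", "s_gstart", "s_gend", "s_order")]
  ht[c("s_gene", "s_gstart", "s_gend", "s_order")] <-
    h[c("q_gene", "q_gstart", "q_gend", "q_order")]
  a <- scorePair(h, hitFilter())
  b <- scorePair(ht, hitFilter())
  expect_equal(a$n_hit_genes, b$n_hit_genes)
  expect_equal(a$score, b$score)
  expect_equal(a$weight, b$weight)
})

test_that("network recovery: components equal planted homology groups", {
  gs <- data.frame(group_id = sprintf("G%d", 1:5),
                   template = c("NRPS", "terpene", "siderophore", "PKS",
                                "NRPS-like"),
                   n_copies = 4, identity = c(85, 80, 90, 80, 85))
  ds <- generateDataset(n_assemblies = 4, groups = gs, seed = 11)
  expect_length(ds$clusters, 20)
  hits <- generateHitTable(ds, between_identity = 20, seed = 2)
  net <- buildNetwork(ds$clusters, hits, hitFilter())
  memb <- igraph::components(net)$membership
  truth <- ds$truth$group_of[names(memb)]
  expect_equal(ari(memb, truth), 1.0)
  expect_equal(igraph::components(net)$no, 5)

  ## every emitted edge satisfies the thresholds
  e <- igraph::as_data_frame(net)
  expect_true(all(e$weight >= 30))
  expect_true(all(e$n_hit_genes >= 1))
  expect_true(all(e$synteny_score <= e$n_hit_genes))

  ## min_hits=1 edge set is a superset of min_hits=2
  net2 <- buildNetwork(ds$clusters, hits, hitFilter(min_hits = 2))
  e1 <- paste(e$from, e$to)
  e2 <- with(igraph::as_data_frame(net2), paste(from, to))
  expect_true(all(e2 %in% e1))
})

test_that("single-gene siderophore-like regions connect only at min_hits=1", {
  ## two clusters sharing exactly one gene-level hit
  a <- toyCluster("SIDA__1_glim", n = 1, plen = 400)
  b <- toyCluster("SIDB__1_glim", n = 1, plen = 400)
  h <- simHit("SIDA__1_glim_g1", "SIDB__1_glim_g1", pident = 75,
              qlen = 400, slen = 400)
  n1 <- buildNetwork(list(a, b), h, hitFilter(min_hits = 1))
  n2 <- buildNetwork(list(a, b), h, hitFilter(min_hits = 2))
  expect_equal(igraph::ecount(n1), 1)
  expect_equal(igraph::ecount(n2), 0)
})

test_that("component summary counts singletons and type composition", {
  a <- toyCluster("A__1_glim", n = 1); assignedType(a) <- "terpene"
  b <- toyCluster("B__1_glim", n = 1); assignedType(b) <- "terpene"
  c3 <- toyCluster("C__1_glim", n = 1); assignedType(c3) <- "NRPS"
  empty <- buildNetwork(list(a, b, c3), simHit("x", "y")[0, ])
  cs0 <- componentSummary(empty)
  expect_equal(nrow(cs0), 3)
  expect_true(all(cs0$singleton))

  one <- buildNetwork(list(a, b, c3),
                      simHit("A__1_glim_g1", "B__1_glim_g1", pident = 90))
  cs1 <- componentSummary(one)
  expect_equal(nrow(cs1), 2)      # one edge merged exactly two components
  expect_true("terpene:2" %in% cs1$types)

  ## a dataset with one cluster has no edges
  solo <- buildNetwork(list(a), simHit("x", "y")[0, ])
  expect_equal(igraph::ecount(solo), 0)
})

test_that("network export writes GraphML and an edge list", {
  a <- toyCluster("A__1_glim", n = 1)
  b <- toyCluster("B__1_glim", n = 1)
  net <- buildNetwork(list(a, b),
                      simHit("A__1_glim_g1", "B__1_glim_g1", pident = 90))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, gml, tsv)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
  e <- read.delim(tsv)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 90)
})
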