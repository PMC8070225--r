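test_that("similarity graph applies the admission threshold and weight cap", {
  hits <- rbind(simHit("a", "b", evalue = 1e-9),    # above threshold: out
                simHit("b", "c", evalue = 1e-10),   # at threshold: in
                simHit("c", "d", evalue = 0),       # capped weight
                simHit("d", "d", evalue = 1e-99))   # self-hit: out
  g <- buildSimilarityGraph(hits, e_threshold = 1e-10)
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 2)
  expect_false(any(e$from == "a" | e$to == "a"))
  w <- setNames(e$weight, paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(unname(w["b c"]), 10)
  expect_equal(unname(w["c d"]), 200)                # cap
})

test_that("directed duplicates collapse to one undirected edge (max weight)", {
  hits <- rbind(simHit("a", "b", evalue = 1e-20, bitscore = 100),
                simHit("b", "a", evalue = 1e-30, bitscore = 120),
                simHit("a", "b", evalue = 1e-50, bitscore = 90))  # worse bitscore dup
  g <- buildSimilarityGraph(hits)
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 30)   # per-direction dedup keeps best bitscore row
})

test_that("6 proteins with 7 admissible hits give a 7-edge graph", {
  pairs <- list(c("p1","p2"), c("p2","p3"), c("p3","p4"), c("p4","p5"),
                c("p5","p6"), c("p1","p6"), c("p2","p5"))
  hits <- do.call(rbind, lapply(pairs, function(p)
    simHit(p[1], p[2], evalue = 1e-20)))
  g <- buildSimilarityGraph(hits)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 7)
})

test_that("MCL handles singletons and separates disjoint triangles", {
  ## single isolated node
  g0 <- buildSimilarityGraph(simHit("x", "y")[0, ], nodes = "lonely")
  f0 <- mclCluster(g0)
  expect_equal(f0$family_id, "MCL0001")
  expect_equal(f0$protein_id, "lonely")

  ## two unit-weight triangles -> exactly two families of three
  tri <- function(ids) do.call(rbind, lapply(
    list(ids[1:2], ids[2:3], ids[c(1, 3)]),
    function(p) simHit(p[1], p[2], evalue = 1e-20)))
  g <- buildSimilarityGraph(rbind(tri(c("a1", "a2", "a3")),
                                  tri(c("b1", "b2", "b3"))))
  fam <- mclCluster(g, inflation = 1.55)
  sizes <- table(fam$family_id)
  expect_equal(as.integer(sort(sizes)), c(3L, 3L))
  byfam <- split(fam$protein_id, fam$family_id)
  expect_true(all(vapply(byfam, function(m)
    all(startsWith(m, "a")) || all(startsWith(m, "b")), logical(1))))
})

test_that("MCL output is a deterministic partition with size-ranked ids", {
  rh <- randomHitTable(10, seed = 3)
  g <- buildSimilarityGraph(rh$hits, nodes = rh$ids)
  f1 <- mclCluster(g)
  f2 <- mclCluster(g)
  expect_identical(f1, f2)                       # no randomness
  expect_setequal(f1$protein_id, rh$ids)         # partition covers all nodes
  expect_equal(anyDuplicated(f1$protein_id), 0L)
  sizes <- table(f1$family_id)
  expect_true(all(diff(as.vector(sizes)) <= 0))  # MCL0001 is the largest
})

test_that("MCL recovers a planted 5-family partition at inflation 1.55", {
  ids <- outer(sprintf("f%d", 1:5), sprintf("m%d", 1:8), paste0)
  rows <- list()
  for (f in 1:5) {
    members <- ids[f, ]
    for (i in 1:7) for (j in (i + 1):8)
      rows[[length(rows) + 1]] <- simHit(members[i], members[j],
                                         evalue = 1e-40)
  }
  for (f in 1:4)   # between-family hits above the admission threshold
    rows[[length(rows) + 1]] <- simHit(ids[f, 1], ids[f + 1, 1],
                                       evalue = 1e-3)
  g <- buildSimilarityGraph(do.call(rbind, rows), e_threshold = 1e-10)
  fam <- mclCluster(g, inflation = 1.55)
  truth <- rep(1:5, each = 8)
  names(truth) <- as.vector(t(ids))
  got <- setNames(fam$family_id, fam$protein_id)[names(truth)]
  expect_equal(ari(got, truth), 1.0)
})

test_that("MCL families refine the connected components on random graphs", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 9)
    rh <- randomHitTable(n, seed = seed)
    g <- buildSimilarityGraph(rh$hits, nodes = rh$ids)
    fam <- mclCluster(g)
    comp <- igraph::components(g)$membership[fam$protein_id]
    ## every MCL family lies inside exactly one connected component
    per_fam <- tapply(comp, fam$family_id, function(x) length(unique(x)))
    expect_true(all(per_fam == 1), info = paste("seed", seed))
    ## and the families partition the node set
    expect_setequal(fam$protein_id, rh$ids)
  }
})

test_that("mean silhouette equals the brute-force oracle", {
  for (seed in 1:40) {
    n <- 5 + (seed %% 8)
    rh <- randomHitTable(n, seed = 100 + seed)
    g <- buildSimilarityGraph(rh$hits, nodes = rh$ids)
    fam <- mclCluster(g)
    got <- meanSilhouette(g, fam)
    want <- bruteSilhouette(rh$hits, rh$ids, fam)
    if (is.na(want)) expect_true(is.na(got), info = paste("seed", seed))
    else expect_equal(got, want, tolerance = 1e-12,
                      info = paste("seed", seed))
  }
})

test_that("well-separated planted families score a high silhouette", {
  ## within-family E 1e-150 -> distance 0.25 inside, 1 between: s = 0.75
  rows <- list()
  for (f in 1:2) {
    members <- sprintf("f%d_m%d", f, 1:6)
    for (i in 1:5) for (j in (i + 1):6)
      rows[[length(rows) + 1]] <- simHit(members[i], members[j],
                                         evalue = 1e-150)
  }
  hits <- do.call(rbind, rows)
  samples <- silhouetteSample(hits, thresholds = 1e-10, inflations = 1.55)
  expect_true(samples$defined)
  expect_gt(samples$mean_silhouette, 0.5)
  expect_equal(samples$n_clusters, 2)
})

test_that("silhouette sampling flags degenerate grids and rejects empty ones", {
  one <- do.call(rbind, lapply(list(c("a", "b"), c("b", "c"), c("a", "c")),
    function(p) simHit(p[1], p[2], evalue = 1e-40)))
  s <- silhouetteSample(one, thresholds = 1e-10, inflations = c(1.2, 1.55))
  expect_true(all(!s$defined))          # single family: silhouette undefined
  expect_true(all(is.na(s$mean_silhouette)))
  expect_error(silhouetteSample(one, numeric(0), 1.55), "empty")
})

test_that("family annotation follows the size and dual-coverage rules", {
  fam <- data.frame(
    family_id = c(rep("MCL0001", 12), rep("MCL0002", 2), rep("MCL0003", 2)),
    protein_id = c(sprintf("big%02d", 1:12), "s1", "s2", "t1", "t2"))
  ## each big protein sits in its own cluster -> n_smcs = 12 >= 10
  p2c <- setNames(c(sprintf("c%02d", 1:12), "cA", "cA", "cB", "cB"),
                  fam$protein_id)
  ref <- rbind(
    data.frame(query_id = "big01", subject_id = "mibig1", bitscore = 500,
               q_cov = 80, s_cov = 80, category = "biosynthetic",
               label = "NPS"),
    ## 45% coverage: never qualifies
    data.frame(query_id = "s1", subject_id = "mibig2", bitscore = 400,
               q_cov = 45, s_cov = 90, category = "biosynthetic",
               label = "LYS2"),
    data.frame(query_id = "t1", subject_id = "mibig3", bitscore = 300,
               q_cov = 80, s_cov = 80, category = "transporter",
               label = "MFS"))
  ann <- nameAndAnnotate(fam, p2c, ref)
  lab <- setNames(ann$label, ann$family_id)
  expect_equal(unname(lab["MCL0001"]), "NPS")       # major family, labelled
  expect_equal(unname(lab["MCL0002"]), "")          # coverage fails
  expect_equal(unname(lab["MCL0003"]), "MFS")       # transporter at 80/80
  expect_equal(ann$n_smcs[ann$family_id == "MCL0001"], 12)
  ## a major family with no qualifying reference still gets a label
  ann2 <- nameAndAnnotate(fam, p2c, ref[0, ])
  expect_equal(setNames(ann2$label, ann2$family_id)[["MCL0001"]],
               "unlabelled-major")
})

test_that("ABC edge-list export round-trips through the graph", {
  hits <- rbind(simHit("a", "b", evalue = 1e-20),
                simHit("b", "c", evalue = 1e-30))
  g <- buildSimilarityGraph(hits)
  f <- withr::local_tempfile(fileext = ".abc")
  writeAbcGraph(g, f)
  tab <- read.table(f, sep = "\t")
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$V3), c(20, 30))
})
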