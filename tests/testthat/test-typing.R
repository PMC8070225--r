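test_that("the built-in rule table carries the canonical signatures", {
  rules <- defaultRuleTable()
  labels <- vapply(rules, `[[`, character(1), "type_label")
  ## siderophore requires exactly the IucA_IucC domain
  sid <- rules[[which(labels == "siderophore")]]
  expect_identical(sid$all_of, list("PF04183"))
  ## NRPS-like accepts NAD_binding_4 + AMP-binding, but not with a
  ## condensation domain
  nl <- rules[[which(labels == "NRPS-like")]]
  expect_true(all(
    vapply(nl$all_of, function(s) any(s %in% c("PF07993", "PF00501")),
           logical(1))))
  expect_true("PF00668" %in% nl$none_of)
  ## no rule has an empty all_of; priorities unique
  expect_true(all(vapply(rules, function(r) length(r$all_of) > 0,
                         logical(1))))
  expect_false(anyDuplicated(vapply(rules, `[[`, integer(1), "priority")) > 0)
})

test_that("type assignment follows domain content and rule priority", {
  cl <- toyCluster("A__1_glim", n = 4)
  gids <- regionGenes(cl)$gene_id

  ## IucA_IucC + FhuF -> siderophore
  a <- assignType(cl, domHits(gids[1], c("PF04183", "PF06276")))
  expect_equal(a$primary_type, "siderophore")
  expect_length(a$hybrid_types, 0)

  ## no domains -> unassigned
  expect_equal(assignType(cl, domHits("zzz", "PF04183"))$primary_type,
               "unassigned")

  ## full NRPS signature plus IucA_IucC: NRPS wins on priority, the
  ## siderophore rule is also satisfied and becomes a hybrid label;
  ## NRPS-like is blocked by its condensation exclusion
  a2 <- assignType(cl, rbind(
    domHits(gids[1], c("PF00501", "PF00668", "PF00550")),
    domHits(gids[2], "PF04183")))
  expect_equal(a2$primary_type, "NRPS")
  expect_true("siderophore" %in% a2$hybrid_types)
  expect_false("NRPS-like" %in% a2$hybrid_types)

  ## adenylate-forming + carrier without condensation -> NRPS-like
  a3 <- assignType(cl, domHits(gids[1], c("PF07993", "PF00501")))
  expect_equal(a3$primary_type, "NRPS-like")
})

test_that("assignment is a pure function of the domain set", {
  cl <- toyCluster("A__2_glim", n = 3)
  gids <- regionGenes(cl)$gene_id
  hits <- rbind(domHits(gids[2], "PF00494"), domHits(gids[1], "PF01593"))
  a <- assignType(cl, hits)
  ## permuting rows (gene order) never changes the assignment
  b <- assignType(cl, hits[rev(seq_len(nrow(hits))), ])
  expect_identical(a$primary_type, b$primary_type)
  expect_identical(a$hybrid_types, b$hybrid_types)
})

test_that("adding a domain never removes a satisfied type", {
  cl <- toyCluster("A__3_glim", n = 2)
  gid <- regionGenes(cl)$gene_id[1]
  pool <- c("PF00501", "PF00668", "PF00550", "PF04183", "PF00494",
            "PF05114", "PF00109", "PF07993")
  set.seed(11)
  for (rep in 1:20) {
    base <- sample(pool, sample(0:4, 1))
    extra <- sample(setdiff(pool, base), 1)
    t1 <- assignType(cl, domHits(gid, c(base, "PF99999")))
    t2 <- assignType(cl, domHits(gid, c(base, extra, "PF99999")))
    before <- setdiff(c(t1$primary_type, t1$hybrid_types), "unassigned")
    after <- c(t2$primary_type, t2$hybrid_types)
    ## exception: the NRPS-like rule has a none_of exclusion, so adding the
    ## condensation domain may legitimately retire it
    if (extra != "PF00668") expect_true(all(before %in% after))
  }
})

test_that("curation rejects FAS-like and signature-free clusters", {
  cls <- lapply(sprintf("A__%d_glim", 1:6), toyCluster, n = 1)
  gid <- function(i) regionGenes(cls[[i]])$gene_id[1]
  hits <- rbind(domHits(gid(1), "PF04183"),           # siderophore
                domHits(gid(2), "PF01648"),           # ACPS only -> FAS-like
                domHits(gid(3), "PF00494"),           # terpene
                domHits(gid(4), c("PF01648", "PF99999")))  # junk, no rule
  assigns <- lapply(cls, assignType, domain_hits = hits)
  cur <- curateAssignments(assigns)
  expect_equal(sort(cur$retained$cluster_id), c("A__1_glim", "A__3_glim"))
  expect_equal(nrow(cur$rejected), 4)
  rej <- setNames(cur$rejected$rejection_reason, cur$rejected$cluster_id)
  expect_equal(unname(rej["A__2_glim"]), "fatty-acid-synthesis-like")
  expect_equal(unname(rej["A__5_glim"]), "no biosynthetic signature")
  ## PF01648 plus an unrelated domain is not the pure-ACPS case
  expect_equal(unname(rej["A__4_glim"]), "no biosynthetic signature")
  ## every rejected cluster has a reason, every retained one a type
  expect_true(all(nzchar(cur$rejected$rejection_reason)))
  expect_true(all(cur$retained$primary_type != "unassigned"))
})

test_that("core-family matrix codes 0/1/2 and keeps empty assemblies", {
  cls <- list(
    toyCluster("ASM1__1_glim", n = 1), toyCluster("ASM1__2_glim", n = 1),
    toyCluster("ASM1__3_glim", n = 1), toyCluster("ASM2__1_glim", n = 1))
  fmap <- c(ASM1__1_glim_g1 = "NPS", ASM1__2_glim_g1 = "NPS",
            ASM1__3_glim_g1 = "NPS", ASM2__1_glim_g1 = "LYS2")
  m <- coreFamilyMatrix(cls, fmap, assemblies = c("ASM1", "ASM2", "ASM3"))
  expect_identical(colnames(m), coreFamilyLabels())
  expect_equal(m["ASM1", "NPS"], 2L)      # 3 clusters -> "multiple"
  expect_equal(m["ASM2", "LYS2"], 1L)
  expect_true(all(m["ASM3", ] == 0L))
  expect_true(all(m %in% 0:2))
})

test_that("core-family matrix recovers a planted copy-number plan", {
  plan <- data.frame(
    assembly = c(1, 1, 2, 3, 3, 3),
    template = c("NRPS", "siderophore", "terpene", "NRPS-like",
                 "NRPS-like", "PKS"),
    n = c(1, 1, 2, 1, 2, 1))
  ds <- generateDataset(n_assemblies = 3, plan = plan, seed = 5)
  m <- coreFamilyMatrix(ds$clusters, ds$truth$family_of)
  cn <- ds$truth$copy_number
  for (r in seq_len(nrow(cn)))
    if (cn$family[r] %in% coreFamilyLabels())
      expect_equal(m[cn$assembly_id[r], cn$family[r]],
                   min(2L, cn$n[r]),
                   info = paste(cn$assembly_id[r], cn$family[r]))
  expect_equal(m["GCA_SYN0003", "NPS"], 2L)   # 1 + 2 NRPS-like planted
  expect_equal(m["GCA_SYN0002", "SQS"], 2L)
  expect_equal(m["GCA_SYN0001", "NRPS"], 1L)
})

test_that("reference synthetase matching takes the best qualifying hit", {
  p2c <- c(p1 = "A__1", p2 = "A__1", p3 = "B__1")
  hits <- rbind(
    simHit("p1", "malpicyclin_synthetase", pident = 95, bitscore = 900),
    simHit("p1", "malpibaldin_synthetase", pident = 90, bitscore = 700),
    simHit("p3", "malpicyclin_synthetase", pident = 40, bitscore = 100,
           qs = 0, qe = 30))   # 30% coverage: fails
  lab <- matchReferenceSynthetases(hits, p2c, min_identity = 50,
                                   min_cov = 50)
  expect_equal(unname(lab["A__1"]), "malpicyclin_synthetase")
  expect_false("B__1" %in% names(lab))
  ## no hits at all -> no labels
  expect_length(matchReferenceSynthetases(hits[0, ], p2c), 0)
})

test_that("rule tables round-trip through the JSON config format", {
  f <- withr::local_tempfile(fileext = ".json")
  writeRuleTable(defaultRuleTable(), f)
  back <- readRuleTable(f)
  expect_identical(back, defaultRuleTable())
  ## a custom user rule survives too and drives typing
  custom <- c(defaultRuleTable(),
              list(list(type_label = "ectoine", all_of = list("PF06339"),
                        none_of = character(0), priority = 7L)))
  writeRuleTable(custom, f)
  cl <- toyCluster("E__1_glim", n = 1)
  a <- assignType(cl, domHits(regionGenes(cl)$gene_id[1], "PF06339"),
                  rules = readRuleTable(f))
  expect_equal(a$primary_type, "ectoine")
  ## invalid tables are rejected
  bad <- defaultRuleTable()
  bad[[2]]$priority <- 1L
  expect_error(writeRuleTable(bad, f), "unique")
})
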