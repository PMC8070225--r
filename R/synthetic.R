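## Seeded synthetic-data generator with planted truth: protein families at
## controlled pairwise identity, cluster regions instantiated from per-type
## domain templates, homologous cluster groups shared across assemblies,
## self-consistent homology hit tables, and taxonomic best-hit tables with a
## controlled Alien Index signal. Everything is a pure function of
## (config, seed).

.AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
         "T","W","Y","V")

## evaluate code under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

#' Generate a protein family at a controlled pairwise identity
#'
#' Draws a random ancestor of the requested length and derives each member
#' by independent uniform point substitutions, with the per-member mutation
#' rate set so the expected pairwise identity between members approximates
#' \code{target_identity} (two members of identity t share an unmutated
#' position with probability \code{sqrt(t)^2}). At 100\% all members are
#' identical. Deterministic under \code{seed}.
#'
#' @param n_members number of member sequences
#' @param target_identity expected pairwise identity in percent, in (0, 100]
#' @param length protein length in residues
#' @param seed optional integer seed
#' @return character vector of \code{n_members} amino-acid sequences
#' @export
generateFamily <- function(n_members, target_identity, length = 300,
                           seed = NULL) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  .withSeed(seed, {
    ancestor <- sample(.AA, length, replace = TRUE)
    rate <- 1 - sqrt(target_identity / 100)
    vapply(seq_len(n_members), function(i) {
      s <- ancestor
      mut <- stats::runif(length) < rate
      if (any(mut))
        s[mut] <- vapply(s[mut], function(orig)
          sample(setdiff(.AA, orig), 1L), character(1L))
      paste(s, collapse = "")
    }, character(1L))
  })
}

#' Built-in cluster type templates
#'
#' One template per built-in SMC type: the ordered domain layout of the
#' signature gene(s) (accessory genes carry no domains), the gene-count
#' range, the gene-length range in residues, and the core-family label of
#' the signature gene. Each layout satisfies exactly its own rule in
#' [defaultRuleTable()], so typing on template-generated clusters is
#' exact-recoverable.
#'
#' @return named list of templates (\code{type_label}, \code{domain_layout},
#'   \code{n_genes}, \code{gene_len}, \code{core_family})
#' @export
typeTemplates <- function() {
  list(
    NRPS = list(type_label = "NRPS",
                domain_layout = list(c("PF00501", "PF00668", "PF00550")),
                n_genes = c(3L, 6L), gene_len = c(200L, 600L),
                core_family = "NRPS"),
    `NRPS-like` = list(type_label = "NRPS-like",
                domain_layout = list(c("PF00501", "PF00550")),
                n_genes = c(2L, 4L), gene_len = c(200L, 600L),
                core_family = "NPS"),
    siderophore = list(type_label = "siderophore",
                domain_layout = list(c("PF04183", "PF06276")),
                n_genes = c(1L, 2L), gene_len = c(300L, 600L),
                core_family = "SID"),
    terpene = list(type_label = "terpene",
                domain_layout = list("PF00494", "PF01593"),
                n_genes = c(2L, 5L), gene_len = c(200L, 500L),
                core_family = "SQS"),
    PKS = list(type_label = "PKS",
                domain_layout = list(c("PF00109", "PF02801")),
                n_genes = c(3L, 6L), gene_len = c(300L, 600L),
                core_family = "PKS"),
    bacteriocin = list(type_label = "bacteriocin",
                domain_layout = list("PF05114"),
                n_genes = c(1L, 3L), gene_len = c(150L, 400L),
                core_family = "")
  )
}

## accessions used by no rule: safe decoys
.NOISE_DOMAINS <- sprintf("PF9%04d", 9001:9020)

## instantiate one cluster from a template; proteins may be supplied (for
## homolog groups) or drawn fresh; returns list(region, domain_rows,
## family_rows)
.instantiateCluster <- function(assembly_id, ordinal, template,
                                contig = "ctg1", offset = 0,
                                proteins = NULL, n_genes = NULL,
                                noise_domain_rate = 0.1,
                                family_prefix = NULL) {
  tpl <- template
  if (is.null(n_genes))
    n_genes <- sample(seq(tpl$n_genes[1L], tpl$n_genes[2L]), 1L)
  n_genes <- max(n_genes, length(tpl$domain_layout))
  cluster_id <- sprintf("%s__%d_glim", assembly_id, ordinal)
  lens <- sample(seq(tpl$gene_len[1L], tpl$gene_len[2L]), n_genes,
                 replace = TRUE)
  pos <- offset
  rows <- list(); dom <- list(); fam <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("%s_g%d", cluster_id, i)
    prot <- if (!is.null(proteins) && i <= length(proteins) &&
                !is.na(proteins[i])) proteins[i] else
      paste(sample(.AA, lens[i], replace = TRUE), collapse = "")
    plen <- nchar(prot)
    gstart <- pos
    gend <- gstart + 3 * plen
    pos <- gend + sample(200:2000, 1L)
    strand <- sample(c("+", "-"), 1L)
    rows[[i]] <- data.frame(gene_id = gid, contig = contig, start = gstart,
                            end = gend, strand = strand, protein = prot,
                            product = if (i <= length(tpl$domain_layout))
                              paste0(tpl$type_label, " signature gene") else
                              "hypothetical protein")
    accs <- if (i <= length(tpl$domain_layout))
      tpl$domain_layout[[i]] else character(0)
    if (noise_domain_rate > 0 && stats::runif(1L) < noise_domain_rate)
      accs <- c(accs, sample(.NOISE_DOMAINS, 1L))
    if (length(accs))
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = gid, accession = accs, name = accs,
        evalue = 10^-stats::runif(length(accs), 20, 50),
        bitscore = round(stats::runif(length(accs), 100, 300), 1),
        ali_start = 0, ali_end = pmin(50, plen))
    if (!is.null(family_prefix))
      fam[[length(fam) + 1L]] <- data.frame(
        protein_id = gid, family = sprintf("%s_pos%d", family_prefix, i))
    else if (i == 1L && nzchar(tpl$core_family))
      fam[[length(fam) + 1L]] <- data.frame(protein_id = gid,
                                            family = tpl$core_family)
  }
  genes <- do.call(rbind, rows)
  region <- clusterRegion(cluster_id, genes, assembly_id = assembly_id,
                          contig = contig, start = offset,
                          end = max(genes$end))
  list(region = region,
       domains = if (length(dom)) do.call(rbind, dom) else NULL,
       families = if (length(fam)) do.call(rbind, fam) else NULL)
}

#' Generate a synthetic survey dataset with planted truth
#'
#' Instantiates cluster regions from the built-in type templates over a set
#' of synthetic assemblies, with realistic intergenic gaps, per-type domain
#' hits (plus configurable noise domains that never collide with rule
#' accessions), optional homologous cluster groups shared across assemblies
#' (corresponding genes form protein families at a controlled identity),
#' and a complete truth record.
#'
#' @param n_assemblies number of synthetic assemblies
#' @param plan data.frame (\code{assembly}, \code{template}, \code{n}) of
#'   independent clusters per assembly, with \code{assembly} an index in
#'   \code{1..n_assemblies}; NULL for none
#' @param groups data.frame (\code{group_id}, \code{template},
#'   \code{n_copies}, \code{identity}, optionally \code{n_genes}) of
#'   homologous cluster groups whose copies are distributed round-robin
#'   over assemblies; \code{n_genes = 1} with a single-signature template
#'   produces the single-gene regions typical of siderophore clusters;
#'   NULL for none
#' @param noise_domain_rate per-gene probability of one decoy domain row
#'   (default 0.1)
#' @param bacterial_core_groups group ids whose signature genes are planted
#'   as bacterial-origin (for Alien Index tests)
#' @param seed integer seed; the dataset is a pure function of the
#'   arguments and this seed
#' @return list with \code{clusters} (list of [ClusterRegion-class]),
#'   \code{domain_hits} (data.frame), \code{proteins} (named vector),
#'   \code{truth} (list: \code{family_of}, \code{group_of}, \code{type_of},
#'   \code{origin_of}, \code{copy_number}, \code{identity_of},
#'   \code{seed})
#' @export
generateDataset <- function(n_assemblies = 3, plan = NULL, groups = NULL,
                            noise_domain_rate = 0.1,
                            bacterial_core_groups = character(0),
                            seed = 1) {
  templates <- typeTemplates()
  if (!is.null(plan) && nrow(plan) &&
      !all(plan$template %in% names(templates)))
    stop("unknown template in plan: ",
         paste(setdiff(plan$template, names(templates)), collapse = ", "))
  if (!is.null(groups) && nrow(groups) &&
      !all(groups$template %in% names(templates)))
    stop("unknown template in groups")
  .withSeed(seed, {
    assemblies <- sprintf("GCA_SYN%04d", seq_len(n_assemblies))
    ordinals <- stats::setNames(rep(0L, n_assemblies), assemblies)
    offsets <- stats::setNames(rep(0, n_assemblies), assemblies)
    clusters <- list(); dom <- list(); fam <- list()
    group_of <- character(0); type_of <- character(0)
    identity_of <- numeric(0)

    place <- function(asm, template_name, proteins = NULL, n_genes = NULL,
                      family_prefix = NULL) {
      ordinals[asm] <<- ordinals[asm] + 1L
      inst <- .instantiateCluster(asm, ordinals[asm],
                                  templates[[template_name]],
                                  offset = offsets[asm],
                                  proteins = proteins, n_genes = n_genes,
                                  noise_domain_rate = noise_domain_rate,
                                  family_prefix = family_prefix)
      ## next cluster lands well beyond the synteny gap rule
      offsets[asm] <<- inst$region@end + 2e6
      clusters[[length(clusters) + 1L]] <<- inst$region
      if (!is.null(inst$domains)) dom[[length(dom) + 1L]] <<- inst$domains
      if (!is.null(inst$families)) fam[[length(fam) + 1L]] <<- inst$families
      inst$region
    }

    if (!is.null(plan) && nrow(plan))
      for (r in seq_len(nrow(plan))) {
        asm <- assemblies[plan$assembly[r]]
        for (k in seq_len(plan$n[r])) {
          reg <- place(asm, plan$template[r])
          group_of[clusterId(reg)] <- ""
          type_of[clusterId(reg)] <-
            templates[[plan$template[r]]]$type_label
        }
      }

    if (!is.null(groups) && nrow(groups))
      for (r in seq_len(nrow(groups))) {
        gid <- groups$group_id[r]
        tpl <- templates[[groups$template[r]]]
        n_copies <- groups$n_copies[r]
        n_genes <- if ("n_genes" %in% names(groups) &&
                       !is.na(groups$n_genes[r]))
          max(groups$n_genes[r], length(tpl$domain_layout)) else
          max(tpl$n_genes[1L], length(tpl$domain_layout) + 1L)
        lens <- sample(seq(tpl$gene_len[1L], tpl$gene_len[2L]), n_genes,
                       replace = TRUE)
        ## one protein family per gene position, shared across copies
        mats <- lapply(seq_len(n_genes), function(i)
          generateFamily(n_copies, groups$identity[r], lens[i]))
        for (cpy in seq_len(n_copies)) {
          asm <- assemblies[((cpy - 1L) %% n_assemblies) + 1L]
          prot <- vapply(mats, `[[`, character(1L), cpy)
          reg <- place(asm, groups$template[r], proteins = prot,
                       n_genes = n_genes, family_prefix = gid)
          group_of[clusterId(reg)] <- gid
          type_of[clusterId(reg)] <- tpl$type_label
          identity_of[clusterId(reg)] <- groups$identity[r]
        }
      }

    proteins <- do.call(c, lapply(clusters, function(cl)
      stats::setNames(regionGenes(cl)$protein, regionGenes(cl)$gene_id)))
    fam_tab <- if (length(fam)) do.call(rbind, fam) else
      data.frame(protein_id = character(0), family = character(0))
    family_of <- stats::setNames(fam_tab$family, fam_tab$protein_id)

    ## origin: bacterial for signature genes of the flagged groups
    origin_of <- stats::setNames(rep("fungal", length(proteins)),
                                 names(proteins))
    if (length(bacterial_core_groups)) {
      bac_clusters <- names(group_of)[group_of %in% bacterial_core_groups]
      for (cl in clusters) {
        if (!clusterId(cl) %in% bac_clusters) next
        tpl <- templates[[type_of[clusterId(cl)]]]
        sig <- regionGenes(cl)$gene_id[seq_along(tpl$domain_layout)]
        origin_of[sig] <- "bacterial"
      }
    }

    copy_number <- do.call(rbind, lapply(clusters, function(cl) {
      labels <- unique(stats::na.omit(
        unname(family_of[regionGenes(cl)$gene_id])))
      if (!length(labels)) return(NULL)
      data.frame(assembly_id = assemblyId(cl), family = labels)
    }))
    copy_number <- if (is.null(copy_number))
      data.frame(assembly_id = character(0), family = character(0),
                 n = integer(0)) else
      stats::aggregate(cbind(n = rep(1L, nrow(copy_number))) ~
                         assembly_id + family, data = copy_number, FUN = sum)

    list(clusters = clusters,
         domain_hits = if (length(dom)) do.call(rbind, dom) else
           .emptyDomainHits(),
         proteins = proteins,
         truth = list(family_of = family_of, group_of = group_of,
                      type_of = type_of, origin_of = origin_of,
                      identity_of = identity_of,
                      copy_number = copy_number, seed = seed))
  })
}

## sequence-free percent identity of two equal-length proteins
.pairIdentity <- function(x, y) {
  a <- strsplit(x, "")[[1L]]; b <- strsplit(y, "")[[1L]]
  n <- min(length(a), length(b))
  100 * sum(a[seq_len(n)] == b[seq_len(n)]) / n
}

#' Generate a homology hit table from planted families
#'
#' Emits symmetric protein-vs-protein hits for every within-family pair of
#' the dataset's planted protein families, at the realised sequence
#' identity, with full coverages and E-values from a monotone law
#' \code{E = 10^(-(identity/100) * length / 15)} clipped to
#' \code{[1e-180, 10]} — calibrated so the survey's 1e-10 admission
#' threshold separates well-conserved within-family pairs (80\% identity)
#' from diverged between-family ones (20\%) across the default gene-length
#' range of 200-600 residues. Between-family hits are emitted only when
#' \code{between_identity} is set (drawn at that identity, same law).
#'
#' @param dataset a dataset from [generateDataset()]
#' @param between_identity percent identity for between-family decoy hits
#'   (default NULL: none)
#' @param seed optional seed (only used for between-family draws)
#' @return similarity-hit data.frame (columns of [readSimilarityTable()])
#' @export
generateHitTable <- function(dataset, between_identity = NULL, seed = NULL) {
  fam <- dataset$truth$family_of
  prot <- dataset$proteins
  .withSeed(seed, {
    rows <- list()
    mkhit <- function(q, s, id) {
      ql <- nchar(prot[[q]]); sl <- nchar(prot[[s]])
      ev <- min(10, max(1e-180, 10^(-(id / 100) * min(ql, sl) / 15)))
      data.frame(query_id = q, subject_id = s, pct_identity = id,
                 ali_len = min(ql, sl), mismatch = round(min(ql, sl) *
                   (1 - id / 100)), gapopen = 0,
                 q_start = 0, q_end = ql, s_start = 0, s_end = sl,
                 evalue = ev, bitscore = round(2 * min(ql, sl) * id / 100, 1),
                 q_len = ql, s_len = sl, q_cov = 100, s_cov = 100)
    }
    fams <- split(names(fam), unname(fam))
    for (members in fams) {
      members <- members[members %in% names(prot)]
      if (length(members) < 2L) next
      for (i in seq_along(members)) for (j in seq_along(members)) {
        if (i == j) next
        id <- .pairIdentity(prot[[members[i]]], prot[[members[j]]])
        rows[[length(rows) + 1L]] <- mkhit(members[i], members[j], id)
      }
    }
    if (!is.null(between_identity)) {
      fnames <- names(fams)
      if (length(fnames) >= 2L)
        for (i in seq_along(fnames)) for (j in seq_along(fnames)) {
          if (i == j) next
          q <- fams[[i]][1L]; s <- fams[[j]][1L]
          if (!q %in% names(prot) || !s %in% names(prot)) next
          rows[[length(rows) + 1L]] <- mkhit(q, s, between_identity)
        }
    }
    if (!length(rows)) return(.emptySimilarityHits())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate taxonomic best-hit tables with a planted Alien Index signal
#'
#' For every protein of the dataset, draws best-hit E-values for the two
#' taxon groups. Bacterial-origin genes (per the planted truth) get a
#' bacterial exponent drawn log-uniformly and a Dikarya exponent smaller by
#' \code{effect_size} orders of magnitude (with Gaussian jitter);
#' fungal-origin genes the reverse. Exponents below \code{min_exponent}
#' produce no hit in that group (the gene then falls back to the absent
#' convention of [alienIndex()]). Deterministic under \code{seed}.
#'
#' @param dataset a dataset from [generateDataset()]
#' @param effect_size planted asymmetry in orders of magnitude (default 20)
#' @param jitter_sd standard deviation of the exponent jitter (default 2)
#' @param min_exponent weakest emitted hit, as -log10(E) (default 6, just
#'   inside the 1e-05 ceiling)
#' @param seed integer seed
#' @return data.frame of taxonomic hits (\code{protein_id},
#'   \code{subject_id}, \code{group}, \code{evalue})
#' @export
generateTaxonomicHits <- function(dataset, effect_size = 20, jitter_sd = 2,
                                  min_exponent = 6, seed = 1) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  origin <- dataset$truth$origin_of
  .withSeed(seed, {
    rows <- list()
    for (p in names(origin)) {
      strong <- stats::runif(1L, 30, 60)
      weak <- strong - effect_size + stats::rnorm(1L, 0, jitter_sd)
      if (origin[[p]] == "bacterial") {
        be <- strong; de <- weak
      } else {
        de <- strong; be <- weak
      }
      if (de >= min_exponent)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = p, subject_id = paste0("DIK_", p),
          group = "Dikarya", evalue = 10^-de)
      if (be >= min_exponent)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = p, subject_id = paste0("BACT_", p),
          group = "Bacteria", evalue = 10^-be)
    }
    if (!length(rows))
      return(data.frame(protein_id = character(0),
                        subject_id = character(0), group = character(0),
                        evalue = numeric(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Serialise / reload the planted truth
#'
#' JSON round trip of the truth record; reloading reproduces the original
#' bit-exactly.
#'
#' @param truth truth list from [generateDataset()]
#' @param path file path
#' @return \code{path} invisibly, or the reloaded truth list
#' @export
writeTruth <- function(truth, path) {
  out <- truth
  ## named vectors must survive as JSON objects, not bare arrays
  for (f in c("family_of", "group_of", "type_of", "origin_of",
              "identity_of"))
    out[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$copy_number <- as.data.frame(x$copy_number)
  for (f in c("family_of", "group_of", "type_of", "origin_of")) {
    v <- unlist(x[[f]])
    x[[f]] <- if (is.null(v)) stats::setNames(character(0), character(0))
    else v
  }
  v <- unlist(x$identity_of)
  x$identity_of <- if (is.null(v)) stats::setNames(numeric(0), character(0))
  else v
  x
}

#' Write a dataset's files to a directory
#'
#' Emits exactly what the readers consume: one GenBank file per assembly
#' (\code{<assembly>.gbk}), the domain hits as generic TSV
#' (\code{domains.tsv}), the protein homology hits as 14-column tabular
#' (\code{hits.tsv}, when supplied) and the truth as JSON
#' (\code{truth.json}).
#'
#' @param dataset dataset from [generateDataset()]
#' @param dir output directory (created if needed)
#' @param hits optional similarity hits to include
#' @return the directory, invisibly
#' @export
writeDataset <- function(dataset, dir, hits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asms <- split(dataset$clusters,
                vapply(dataset$clusters, assemblyId, character(1L)))
  for (asm in names(asms))
    writeClusterGenBank(asms[[asm]], file.path(dir, paste0(asm, ".gbk")))
  writeTsv(dataset$domain_hits, file.path(dir, "domains.tsv"))
  if (!is.null(hits))
    writeSimilarityTable(hits, file.path(dir, "hits.tsv"))
  writeTruth(dataset$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
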