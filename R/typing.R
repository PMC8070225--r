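## Rule-based typing of candidate clusters from their Pfam/InterPro domain
## content, curation of the candidate list, and the per-assembly core-family
## presence/absence matrix.

#' Built-in cluster-typing rule table
#'
#' Each rule is a list with \code{type_label}, \code{all_of} (a list of
#' accession vectors; every vector is an any-of alternative, all vectors must
#' be satisfied), \code{none_of} (accessions that must be absent) and a
#' unique integer \code{priority} (1 = highest). A cluster's domain set
#' satisfies a rule when every \code{all_of} alternative set intersects it
#' and no \code{none_of} accession is present.
#'
#' The built-in rules encode the canonical biosynthetic signatures:
#' \describe{
#'   \item{NRPS}{adenylation (AMP-binding, PF00501) + condensation (PF00668)
#'     + carrier or thioesterase (PP-binding PF00550 | thioesterase PF00975).}
#'   \item{PKS}{ketoacyl-synthase N/C signatures (PF00109 | PF02801).}
#'   \item{siderophore}{NRPS-independent siderophore synthase, IucA_IucC
#'     (PF04183) alone suffices — these regions frequently consist of a
#'     single IucA/IucC homologue; FhuF (PF06276) corroborates but is not
#'     required.}
#'   \item{terpene}{any of polyprenyl synthetase (PF00348; sometimes
#'     misprinted "PF003480" in the literature), squalene/phytoene synthase
#'     (SQS_PSY, PF00494), phytoene-desaturase-like amino-oxidase (PF01593),
#'     lycopene cyclase (TIGR03462 / IPR017825), terpene cyclase-like 2
#'     (IPR034686), squalene-hopene-cyclase-like ERG7 signatures (PF13243 |
#'     PF13249).}
#'   \item{NRPS-like}{carrier/reductase (PP-binding PF00550 | NAD_binding_4
#'     PF07993) + adenylate-forming (PF00501), with no condensation domain.}
#'   \item{bacteriocin}{DUF692 (PF05114).}
#' }
#' Priorities order NRPS > PKS > siderophore > terpene > NRPS-like >
#' bacteriocin. Additional rules (e.g. betalactone, fungal-RiPP, ectoine)
#' can be appended by the user; no built-in signature ships for them.
#'
#' @return list of typing rules
#' @seealso [assignType()], [curateAssignments()]
#' @examples
#' vapply(defaultRuleTable(), `[[`, character(1), "type_label")
#' @export
defaultRuleTable <- function() {
  list(
    list(type_label = "NRPS",
         all_of = list("PF00501", "PF00668", c("PF00550", "PF00975")),
         none_of = character(0), priority = 1L),
    list(type_label = "PKS",
         all_of = list(c("PF00109", "PF02801")),
         none_of = character(0), priority = 2L),
    list(type_label = "siderophore",
         all_of = list("PF04183"),
         none_of = character(0), priority = 3L),
    list(type_label = "terpene",
         all_of = list(c("PF00348", "PF00494", "PF01593", "TIGR03462",
                         "IPR017825", "IPR034686", "PF13243", "PF13249")),
         none_of = character(0), priority = 4L),
    list(type_label = "NRPS-like",
         all_of = list(c("PF00550", "PF07993"), "PF00501"),
         none_of = "PF00668", priority = 5L),
    list(type_label = "bacteriocin",
         all_of = list("PF05114"),
         none_of = character(0), priority = 6L)
  )
}

#' Read or write a typing rule table as JSON
#'
#' Rules travel as a structured JSON file: an array of objects with
#' \code{type_label}, \code{all_of} (array of accession arrays),
#' \code{none_of} and \code{priority}. Reading validates uniqueness of
#' priorities and non-emptiness of \code{all_of}.
#'
#' @param rules rule table (list, as from [defaultRuleTable()])
#' @param path JSON file path
#' @return \code{path} invisibly, or the rule table
#' @export
writeRuleTable <- function(rules, path) {
  .checkRuleTable(rules)
  jsonlite::write_json(rules, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRuleTable
#' @export
readRuleTable <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw, function(r) list(
    type_label = r$type_label,
    all_of = lapply(r$all_of, function(s) unlist(s)),
    none_of = as.character(unlist(r$none_of)),
    priority = as.integer(r$priority)))
  .checkRuleTable(rules)
  rules
}

.checkRuleTable <- function(rules) {
  pr <- vapply(rules, `[[`, integer(1L), "priority")
  if (anyDuplicated(pr)) stop("rule priorities must be unique")
  if (any(vapply(rules, function(r) length(r$all_of) == 0L, logical(1L))))
    stop("every rule needs a non-empty all_of")
  invisible(rules)
}

.ruleSatisfied <- function(rule, accessions) {
  all(vapply(rule$all_of, function(s) any(s %in% accessions), logical(1L))) &&
    !any(rule$none_of %in% accessions)
}

#' Assign an SMC type from domain content
#'
#' Evaluates every rule against the union of domain accessions seen on the
#' cluster's proteins. The highest-priority satisfied rule provides the
#' primary type; every other satisfied rule goes into \code{hybrid_types}
#' (e.g. a region carrying both adenylation/condensation and IucA_IucC
#' signatures is an NRPS with a siderophore hybrid label). With no satisfied
#' rule the primary type is \code{"unassigned"}. The result is a pure
#' function of the domain set and the rule table.
#'
#' @param cluster a [ClusterRegion-class]
#' @param domain_hits domain-hit data.frame (as from [readDomainTable()]),
#'   restricted or not — only hits on the cluster's gene ids are used
#' @param rules rule table, default [defaultRuleTable()]
#' @return list with \code{cluster_id}, \code{primary_type},
#'   \code{hybrid_types}, \code{matched_domains}, \code{curated} (NA until
#'   [curateAssignments()]), \code{rejection_reason}
#' @export
assignType <- function(cluster, domain_hits, rules = defaultRuleTable()) {
  .checkRuleTable(rules)
  ids <- regionGenes(cluster)$gene_id
  acc <- unique(domain_hits$accession[domain_hits$protein_id %in% ids])
  sat <- vapply(rules, .ruleSatisfied, logical(1L), accessions = acc)
  labels <- vapply(rules, `[[`, character(1L), "type_label")
  prio <- vapply(rules, `[[`, integer(1L), "priority")
  if (any(sat)) {
    best <- which(sat)[which.min(prio[sat])]
    primary <- labels[best]
    hybrids <- setdiff(labels[sat], primary)
  } else {
    primary <- "unassigned"
    hybrids <- character(0)
  }
  list(cluster_id = clusterId(cluster), primary_type = primary,
       hybrid_types = hybrids, matched_domains = sort(acc),
       curated = NA, rejection_reason = "")
}

#' Curate a batch of type assignments
#'
#' Splits assignments into retained and rejected sets. Clusters whose only
#' signature is the 4'-phosphopantetheinyl transferase domain (ACPS,
#' PF01648) and that match no rule are fatty-acid-synthesis-like false
#' positives and are rejected as such; any other cluster without a
#' biosynthetic signature is rejected for lacking one; everything with a
#' satisfied rule is retained.
#'
#' @param assignments list of assignments from [assignType()]
#' @return list with data.frames \code{retained} and \code{rejected}
#'   (columns \code{cluster_id}, \code{primary_type}, \code{hybrid_types}
#'   — comma-joined, \code{curated}, \code{rejection_reason})
#' @export
curateAssignments <- function(assignments) {
  rows <- lapply(assignments, function(a) {
    if (a$primary_type == "unassigned") {
      reason <- if (length(a$matched_domains) &&
                    all(a$matched_domains %in% "PF01648"))
        "fatty-acid-synthesis-like" else "no biosynthetic signature"
      curated <- FALSE
    } else {
      reason <- ""
      curated <- TRUE
    }
    data.frame(cluster_id = a$cluster_id, primary_type = a$primary_type,
               hybrid_types = paste(a$hybrid_types, collapse = ","),
               curated = curated, rejection_reason = reason)
  })
  tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(cluster_id = character(0), primary_type = character(0),
               hybrid_types = character(0), curated = logical(0),
               rejection_reason = character(0))
  list(retained = tab[tab$curated, , drop = FALSE],
       rejected = tab[!tab$curated, , drop = FALSE])
}

#' Fixed column order of the core-family matrix
#'
#' The core gene families tallied per assembly, in fixed report order:
#' aminoadipate reductase (LYS2), non-NRPS siderophore synthase (SID),
#' squalene synthases (SQS, SQS_NDUF6), geranylgeranyl phosphate synthase
#' (GGPS), terpene synthases (ERG7, TS2), bifunctional lycopene
#' cyclase/phytoene desaturases (carRA_1, carRA_2), aryl-forming reductase
#' (NPS), NRPS, PKS, hybrid PKS-NRPS and fatty acid acyl-CoA AMP ligase
#' (FAAL).
#'
#' @return character vector of family labels
#' @export
coreFamilyLabels <- function() {
  c("LYS2", "SID", "SQS", "SQS_NDUF6", "GGPS", "ERG7", "TS2",
    "carRA_1", "carRA_2", "NPS", "NRPS", "PKS", "PKS-NRPS", "FAAL")
}

#' Presence/absence matrix of core families per assembly
#'
#' For every assembly and core family, counts the clusters of that assembly
#' containing at least one protein mapped to the family, coded 0 (absent),
#' 1 (single copy) or 2 (multiple copies per genome). Assemblies without any
#' cluster get an all-zero row.
#'
#' @param clusters list of typed [ClusterRegion-class] objects
#' @param family_map named character vector: protein id to family label
#' @param assemblies assembly ids to report (rows); defaults to the
#'   assemblies seen in \code{clusters}
#' @return integer matrix, rows = assemblies, columns =
#'   [coreFamilyLabels()], cells in \{0, 1, 2\}
#' @export
coreFamilyMatrix <- function(clusters, family_map,
                             assemblies = NULL) {
  fams <- coreFamilyLabels()
  if (is.null(assemblies))
    assemblies <- sort(unique(vapply(clusters, assemblyId, character(1L))))
  m <- matrix(0L, nrow = length(assemblies), ncol = length(fams),
              dimnames = list(assemblies, fams))
  for (cl in clusters) {
    asm <- assemblyId(cl)
    if (!asm %in% assemblies) next
    labels <- unique(stats::na.omit(
      unname(family_map[regionGenes(cl)$gene_id])))
    for (f in intersect(labels, fams))
      m[asm, f] <- m[asm, f] + 1L
  }
  m[m > 2L] <- 2L
  m
}

#' Label clusters by best hit to reference synthetases
#'
#' Maps each cluster to the reference protein (e.g. a characterised
#' malpicyclin or malpibaldin synthetase) of its best qualifying homology
#' hit. A hit qualifies when its percent identity and both coverages meet
#' the thresholds; ties and multiple hits are resolved by bitscore. Clusters
#' without a qualifying hit receive no label.
#'
#' @param ref_hits similarity-hit data.frame, queries = cluster proteins,
#'   subjects = reference ids
#' @param protein_to_cluster named character vector mapping protein ids to
#'   cluster ids
#' @param min_identity,min_cov qualifying thresholds in percent
#' @return named character vector: cluster id to reference label (only
#'   labelled clusters appear)
#' @export
matchReferenceSynthetases <- function(ref_hits, protein_to_cluster,
                                      min_identity = 50, min_cov = 50) {
  if (!nrow(ref_hits)) return(stats::setNames(character(0), character(0)))
  ok <- ref_hits$pct_identity >= min_identity &
    ref_hits$q_cov >= min_cov & ref_hits$s_cov >= min_cov
  h <- ref_hits[ok, , drop = FALSE]
  h$cluster <- unname(protein_to_cluster[h$query_id])
  h <- h[!is.na(h$cluster), , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(character(0), character(0)))
  h <- h[order(h$cluster, -h$bitscore, h$subject_id), , drop = FALSE]
  h <- h[!duplicated(h$cluster), , drop = FALSE]
  stats::setNames(h$subject_id, h$cluster)
}
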