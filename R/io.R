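## I/O for the formats cluster surveys travel in: GenBank flat files holding
## one candidate cluster region per record, domain-hit tables (rps-blast /
## hmmscan / generic TSV) and BLAST-style protein homology tables.
## Internal coordinates are 0-based half-open everywhere; GenBank's 1-based
## inclusive convention is converted exactly at the file boundary.

#' Convert between GenBank and internal coordinates
#'
#' GenBank locations are 1-based inclusive; internally all intervals are
#' 0-based half-open. The two helpers are exact inverses of each other.
#'
#' @param start1,end1 1-based inclusive interval
#' @param start0,end0 0-based half-open interval
#' @return a two-column data.frame (\code{start}, \code{end}) in the target
#'   convention
#' @examples
#' gbToInternal(101, 400)   # start 100, end 400
#' internalToGb(100, 400)   # start 101, end 400
#' @export
gbToInternal <- function(start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  data.frame(start = start1 - 1L, end = end1)
}

#' @rdname gbToInternal
#' @export
internalToGb <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  data.frame(start = start0 + 1L, end = end0)
}

## Parse one GenBank location string at gene granularity: join(...) is
## collapsed to its outer span (exon structure is not modelled),
## complement(...) flips the strand.
.parseGbLocation <- function(loc, record = "?") {
  strand <- "+"
  x <- gsub("\\s", "", loc)
  while (grepl("^(complement|join|order)\\(", x)) {
    if (grepl("^complement\\(", x)) strand <- if (strand == "+") "-" else "+"
    x <- sub("^(complement|join|order)\\(", "", x)
    x <- sub("\\)$", "", x)
  }
  nums <- suppressWarnings(
    as.numeric(unlist(regmatches(x, gregexpr("[0-9]+", x)))))
  if (length(nums) < 2L || anyNA(nums))
    stop("malformed location '", loc, "' in record ", record)
  list(start1 = min(nums), end1 = max(nums), strand = strand)
}

## Split a GenBank flat file into record chunks ("//" terminated).
.gbRecordChunks <- function(lines) {
  locus <- grep("^LOCUS", lines)
  if (!length(locus)) return(list())
  ends <- grep("^//", lines)
  lapply(seq_along(locus), function(i) {
    to <- ends[ends > locus[i]]
    to <- if (length(to)) to[1L] - 1L else length(lines)
    lines[locus[i]:to]
  })
}

## Parse the qualifier block of one feature into a named character vector.
.parseQualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = "\n")
  parts <- strsplit(txt, "\n/", fixed = TRUE)[[1L]]
  parts <- parts[grepl("=", parts) | grepl("^/", txt)]
  out <- character(0)
  for (p in parts) {
    p <- sub("^/", "", p)
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) next
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    val <- gsub("\n", "", val)
    val <- gsub("^\"|\"$", "", val)
    out[key] <- val
  }
  out
}

#' Read candidate cluster regions from a GenBank flat file
#'
#' One [ClusterRegion-class] per GenBank record. CDS features supply the gene
#' models: the locus tag (or \code{protein_id}/\code{gene} qualifier) becomes
#' the gene id, the \code{/translation} the protein sequence. Compound
#' (\code{join}) locations are collapsed to their outer span;
#' \code{complement} locations get strand \code{"-"}. 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' CDS features lacking a translation are skipped with a warning.
#'
#' The DEFINITION line may carry \code{contig=... start=... end=...} tokens
#' (as written by [writeClusterGenBank()]) placing the region on its source
#' contig; without them the region starts at 0 on a contig named after the
#' record.
#'
#' @param path GenBank file with one or more records
#' @return list of [ClusterRegion-class] objects (empty list for an empty
#'   file)
#' @seealso [writeClusterGenBank()]
#' @export
readClusterGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  chunks <- .gbRecordChunks(lines)
  lapply(chunks, .parseGbRecord)
}

.parseGbRecord <- function(rec) {
  locus_fields <- strsplit(trimws(rec[1L]), "\\s+")[[1L]]
  if (length(locus_fields) < 2L) stop("malformed LOCUS line: ", rec[1L])
  cluster_id <- locus_fields[2L]

  ## optional region placement on the DEFINITION line
  contig <- cluster_id; g_start <- 0; g_end <- NA_real_
  defn <- grep("^DEFINITION", rec, value = TRUE)
  if (length(defn)) {
    kv <- regmatches(defn[1L], gregexpr("[A-Za-z_]+=[^ .]+", defn[1L]))[[1L]]
    for (tok in kv) {
      p <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      if (p[1L] == "contig") contig <- p[2L]
      if (p[1L] == "start") g_start <- as.numeric(p[2L])
      if (p[1L] == "end") g_end <- as.numeric(p[2L])
    }
  }

  feat_from <- grep("^FEATURES", rec)
  genes <- data.frame(gene_id = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), protein = character(0),
                      product = character(0))
  if (length(feat_from)) {
    to <- grep("^(ORIGIN|CONTIG)", rec)
    to <- if (length(to)) min(to[to > feat_from[1L]]) - 1L else length(rec)
    flines <- rec[(feat_from[1L] + 1L):to]
    ## feature starts: a key in column 6
    starts <- grep("^ {4,5}\\S", flines)
    if (length(starts)) {
      bounds <- c(starts, length(flines) + 1L)
      for (i in seq_along(starts)) {
        block <- flines[starts[i]:(bounds[i + 1L] - 1L)]
        key <- strsplit(trimws(block[1L]), "\\s+")[[1L]][1L]
        if (key != "CDS") next
        locline <- sub("^\\s*CDS\\s+", "", block[1L])
        ## location may continue over lines until the first qualifier
        qual_at <- grep("^\\s+/", block)
        loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
        if (loc_end > 1L)
          locline <- paste0(locline,
                            paste(trimws(block[2L:loc_end]), collapse = ""))
        loc <- .parseGbLocation(locline, record = cluster_id)
        quals <- if (length(qual_at))
          .parseQualifiers(block[qual_at[1L]:length(block)]) else character(0)
        gid <- quals["locus_tag"]
        if (is.na(gid)) gid <- quals["protein_id"]
        if (is.na(gid)) gid <- quals["gene"]
        if (is.na(gid)) gid <- paste0(cluster_id, "_cds", i)
        if (is.na(quals["translation"]) || !nzchar(quals["translation"])) {
          warning("CDS ", gid, " in record ", cluster_id,
                  " has no translation; skipped")
          next
        }
        iv <- gbToInternal(loc$start1, loc$end1)
        genes <- rbind(genes, data.frame(
          gene_id = unname(gid), contig = contig,
          start = iv$start + g_start, end = iv$end + g_start,
          strand = loc$strand,
          protein = unname(quals["translation"]),
          product = if (is.na(quals["product"])) "" else
            unname(quals["product"])))
      }
    }
  }
  if (is.na(g_end))
    g_end <- if (nrow(genes)) max(genes$end) else
      g_start + suppressWarnings(as.numeric(locus_fields[3L]))
  if (is.na(g_end) || g_end <= g_start)
    g_end <- g_start + max(1, if (nrow(genes)) max(genes$end) else 1)
  clusterRegion(cluster_id, genes, contig = contig,
                start = g_start, end = g_end)
}

.wrapGbText <- function(text, width = 58, indent = 21) {
  pieces <- substring(text, seq(1, nchar(text), width),
                      pmin(seq(width, nchar(text) + width - 1, width),
                           nchar(text)))
  paste0(strrep(" ", indent), pieces, collapse = "\n")
}

#' Write cluster regions as a GenBank flat file
#'
#' Inverse of [readClusterGenBank()]: emits one record per region with CDS
#' features (locus_tag, product, translation), converting internal 0-based
#' half-open coordinates back to GenBank 1-based inclusive ones. Gene
#' coordinates are written relative to the region start; the region placement
#' goes on the DEFINITION line so the round trip is exact.
#'
#' @param regions list of [ClusterRegion-class] objects
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeClusterGenBank <- function(regions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in regions) {
    len <- r@end - r@start
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNK",
                       r@cluster_id, as.integer(len)), con)
    writeLines(sprintf("DEFINITION  %s contig=%s start=%d end=%d.",
                       r@cluster_id, r@contig, as.integer(r@start),
                       as.integer(r@end)), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- r@genes
    if (nrow(g)) for (i in seq_len(nrow(g))) {
      iv <- internalToGb(g$start[i] - r@start, g$end[i] - r@start)
      loc <- sprintf("%d..%d", as.integer(iv$start), as.integer(iv$end))
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', g$gene_id[i]),
                 con)
      if (nzchar(g$product[i]))
        writeLines(sprintf('                     /product="%s"',
                           g$product[i]), con)
      writeLines(.wrapGbText(sprintf('/translation="%s"', g$protein[i])), con)
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  invisible(path)
}

## Normalise a domain accession: strip a trailing ".N" version and map CDD's
## lower-case "pfamNNNNN" spelling to "PFNNNNN"; rule matching must be
## version-independent.
.normaliseAccession <- function(acc) {
  acc <- sub("\\.[0-9]+$", "", acc)
  sub("^pfam", "PF", acc)
}

.emptyDomainHits <- function() {
  data.frame(protein_id = character(0), accession = character(0),
             name = character(0), evalue = numeric(0), bitscore = numeric(0),
             ali_start = numeric(0), ali_end = numeric(0))
}

#' Read protein-vs-domain hits
#'
#' Parses one of three tabular dialects into a uniform domain-hit table:
#' \describe{
#'   \item{\code{generic-tsv}}{header + columns \code{protein_id},
#'     \code{accession}, \code{name}, \code{evalue}, \code{bitscore},
#'     \code{ali_start}, \code{ali_end} (0-based half-open).}
#'   \item{\code{rpsblast-tab}}{BLAST outfmt-6 rows (query = protein,
#'     subject = domain accession, possibly prefixed \code{gnl|CDD|}).}
#'   \item{\code{hmmscan-domtbl}}{HMMER3 \code{--domtblout}; the per-domain
#'     i-E-value and score are used.}
#' }
#' Accessions are normalised (version suffix stripped, \code{pfamNNNNN}
#' mapped to \code{PFNNNNN}). Rows with E-value above \code{e_max} are
#' dropped; rows with a non-numeric E-value are rejected with a warning.
#'
#' @param path input file
#' @param dialect one of \code{"generic-tsv"}, \code{"rpsblast-tab"},
#'   \code{"hmmscan-domtbl"}
#' @param e_max E-value ceiling (default 10)
#' @return data.frame with columns \code{protein_id}, \code{accession},
#'   \code{name}, \code{evalue}, \code{bitscore}, \code{ali_start},
#'   \code{ali_end}
#' @export
readDomainTable <- function(path,
                            dialect = c("generic-tsv", "rpsblast-tab",
                                        "hmmscan-domtbl"),
                            e_max = 10) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- switch(dialect,
    "generic-tsv" = {
      if (length(lines) <= 1L) .emptyDomainHits() else {
        tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
        need <- c("protein_id", "accession", "name", "evalue", "bitscore",
                  "ali_start", "ali_end")
        if (!all(need %in% names(tab)))
          stop("generic-tsv domain table needs columns: ",
               paste(need, collapse = ", "))
        tab[need]
      }
    },
    "rpsblast-tab" = {
      if (!length(lines)) .emptyDomainHits() else {
        f <- strsplit(lines, "\t", fixed = TRUE)
        do.call(rbind, lapply(f, function(x) {
          acc <- sub("^gnl\\|CDD\\|", "", x[2L])
          acc <- utils::tail(strsplit(acc, "|", fixed = TRUE)[[1L]], 1L)
          data.frame(protein_id = x[1L], accession = acc, name = acc,
                     evalue = x[11L], bitscore = x[12L],
                     ali_start = as.numeric(x[7L]) - 1,
                     ali_end = as.numeric(x[8L]))
        }))
      }
    },
    "hmmscan-domtbl" = {
      if (!length(lines)) .emptyDomainHits() else {
        f <- strsplit(trimws(lines), "\\s+")
        do.call(rbind, lapply(f, function(x) {
          data.frame(protein_id = x[4L], accession = x[2L], name = x[1L],
                     evalue = x[13L], bitscore = x[14L],
                     ali_start = as.numeric(x[18L]) - 1,
                     ali_end = as.numeric(x[19L]))
        }))
      }
    })
  if (!nrow(out)) return(.emptyDomainHits())
  ev <- suppressWarnings(as.numeric(out$evalue))
  bad <- is.na(ev)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric E-value rejected")
    out <- out[!bad, , drop = FALSE]; ev <- ev[!bad]
  }
  out$evalue <- ev
  out$bitscore <- as.numeric(out$bitscore)
  out$accession <- .normaliseAccession(out$accession)
  out <- out[out$evalue <= e_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.SIMHIT_COLS <- c("query_id", "subject_id", "pct_identity", "ali_len",
                  "mismatch", "gapopen", "q_start", "q_end", "s_start",
                  "s_end", "evalue", "bitscore", "q_len", "s_len",
                  "q_cov", "s_cov")

.emptySimilarityHits <- function() {
  out <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(.SIMHIT_COLS)), .SIMHIT_COLS))
  out$query_id <- character(0); out$subject_id <- character(0)
  out
}

#' Read protein-vs-protein homology hits (BLAST tabular)
#'
#' Accepts the 12-column BLAST/DIAMOND outfmt-6 layout, optionally extended
#' with \code{qlen}/\code{slen} as columns 13-14. When lengths are absent a
#' named \code{lengths} lookup (protein id to residue length) must be
#' supplied. Alignment coordinates are converted to 0-based half-open and the
#' coverages are derived as query coverage normalised to the query length
#' (\code{q_cov = 100 * (q_end - q_start) / q_len}; \code{s_cov}
#' analogously).
#'
#' @param path tabular file (no header, tab-separated)
#' @param protein_lengths optional named numeric vector of protein lengths
#' @return data.frame of hits with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{ali_len}, \code{mismatch}, \code{gapopen},
#'   \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end},
#'   \code{evalue}, \code{bitscore}, \code{q_len}, \code{s_len},
#'   \code{q_cov}, \code{s_cov}
#' @export
readSimilarityTable <- function(path, protein_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(.emptySimilarityHits())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(vapply(f, length, integer(1L)))
  if (length(ncol) != 1L || !ncol %in% c(12L, 14L))
    stop("similarity table must have 12 or 14 tab-separated columns")
  m <- do.call(rbind, f)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    pct_identity = as.numeric(m[, 3L]),
                    ali_len = as.numeric(m[, 4L]),
                    mismatch = as.numeric(m[, 5L]),
                    gapopen = as.numeric(m[, 6L]),
                    q_start = as.numeric(m[, 7L]) - 1,
                    q_end = as.numeric(m[, 8L]),
                    s_start = as.numeric(m[, 9L]) - 1,
                    s_end = as.numeric(m[, 10L]),
                    evalue = as.numeric(m[, 11L]),
                    bitscore = as.numeric(m[, 12L]))
  if (ncol == 14L) {
    out$q_len <- as.numeric(m[, 13L])
    out$s_len <- as.numeric(m[, 14L])
  } else {
    if (is.null(protein_lengths))
      stop("12-column table without qlen/slen: supply a protein_lengths lookup")
    out$q_len <- unname(protein_lengths[out$query_id])
    out$s_len <- unname(protein_lengths[out$subject_id])
    miss <- is.na(out$q_len) | is.na(out$s_len)
    if (any(miss)) {
      offender <- unique(c(out$query_id[miss & is.na(out$q_len)],
                           out$subject_id[miss & is.na(out$s_len)]))
      stop("no length available for: ", paste(offender, collapse = ", "))
    }
  }
  out$q_cov <- 100 * (out$q_end - out$q_start) / out$q_len
  out$s_cov <- 100 * (out$s_end - out$s_start) / out$s_len
  out[.SIMHIT_COLS]
}

#' Write protein-vs-protein hits as 14-column BLAST-style tabular
#'
#' Emits the layout [readSimilarityTable()] reads back (12 standard columns
#' plus \code{qlen}, \code{slen}); coordinates are converted back to 1-based
#' inclusive.
#'
#' @param hits similarity-hit data.frame
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSimilarityTable <- function(hits, path) {
  m <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                  hits$ali_len, hits$mismatch, hits$gapopen,
                  hits$q_start + 1, hits$q_end, hits$s_start + 1, hits$s_end,
                  format(hits$evalue, digits = 6, scientific = TRUE,
                         trim = TRUE),
                  hits$bitscore, hits$q_len, hits$s_len)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with a header line
#'
#' The package's uniform writer for report tables: tab-separated, header,
#' no quoting, no row names — byte-identical across runs for identical
#' input.
#'
#' @param x data.frame
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
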