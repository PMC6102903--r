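#' @title Best-hit functional profiling
#'
#' @description
#' Reads (through six-frame translation) or contig-pool ORF proteins are
#' assigned the functional category of their best passing hit in a
#' user-mounted protein database. Three category schemes are supported:
#' COG-style functional categories, CAZy-style enzyme families, and
#' metabolic pathways. Entries mapping to k categories contribute 1/k to
#' each so that totals are conserved. No reference database is bundled;
#' databases are mounted as `entries.faa` + `categories.tsv`
#' (accession, comma-separated categories).
#' @name functional_profiler
NULL

FUNCTIONAL_SCHEMES <- c("cog-category", "cazy-family", "pathway")

#' Construct a functional database
#'
#' @param entries protein entries data.frame (accession, organism, seq,
#'   lineage columns; see [reference_tier()]).
#' @param category_map data.frame with columns accession, category;
#'   `category` may be a comma-separated list.
#' @param scheme one of cog-category / cazy-family / pathway.
#' @return object of class `functional_database`.
#' @export
functional_database <- function(entries, category_map,
                                scheme = FUNCTIONAL_SCHEMES) {
  scheme <- match.arg(scheme)
  if (nrow(entries) == 0L) stopf("empty functional database")
  missing <- setdiff(entries$accession, category_map$accession)
  if (length(missing))
    stopf("entries without category mapping: %s", missing[1L])
  if (any(!nzchar(category_map$category)))
    stopf("empty category label in category map")
  tier <- reference_tier(scheme, 1L, entries, kind = "protein")
  cats <- strsplit(category_map$category, ",[[:space:]]*")
  structure(list(scheme = scheme, tier = tier,
                 categories = stats::setNames(cats,
                                              category_map$accession)),
            class = "functional_database")
}

#' Load a functional database from FASTA + category TSV
#' @param faa_path protein FASTA (RefSeq-style headers).
#' @param categories_path TSV with header columns accession, category.
#' @param scheme category scheme.
#' @return a `functional_database`.
#' @export
load_functional_database <- function(faa_path, categories_path,
                                     scheme = FUNCTIONAL_SCHEMES) {
  recs <- read_fasta(faa_path)
  org <- vapply(seq_len(nrow(recs)), function(i)
    parse_refseq_header(paste(recs$id[i], recs$desc[i]))$organism, "")
  entries <- cbind(data.frame(accession = recs$id, organism = org,
                              seq = recs$seq, stringsAsFactors = FALSE),
                   empty_lineage(nrow(recs)))
  cm <- read.table(categories_path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character")
  functional_database(entries, cm, scheme)
}

#' Six-frame translations of a nucleotide sequence
#' @param seq nucleotide string.
#' @return character vector of 6 protein strings (frames +0,+1,+2,-0,-1,-2);
#'   stops appear as `*` (which never matches in protein search).
#' @export
translate_six_frames <- function(seq) {
  out <- character(6L)
  n <- 0L
  for (s in c(toupper(seq), revcomp(seq))) {
    L <- nchar(s)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      n <- n + 1L
      if (ncod < 1L) { out[n] <- ""; next }
      cpos <- f + 3L * (seq_len(ncod) - 1L) + 1L
      out[n] <- translate_codons(substring(s, cpos, cpos + 2L))
    }
  }
  out
}

best_protein_hits <- function(queries, index, params, translated) {
  # best passing protein hit per query; reads are searched in six frames
  if (!translated)
    return(search_hits(queries, index, params))
  qs <- lapply(seq_len(nrow(queries)), function(i) {
    fr <- translate_six_frames(queries$seq[i])
    data.frame(id = paste0(queries$id[i], "\rF", seq_along(fr)),
               seq = fr, stringsAsFactors = FALSE)
  })
  q6 <- do.call(rbind, qs)
  q6 <- q6[nchar(q6$seq) > 0L, , drop = FALSE]
  hits <- search_hits(q6, index, params)
  if (nrow(hits) == 0L) return(hits)
  hits$query_id <- sub("\rF[0-9]$", "", hits$query_id)
  sort_hits(hits, query_order = unique(queries$id))
}

#' Functional category profile of reads or ORF proteins
#'
#' Each query is assigned the category (or categories, fractionally) of
#' its best passing hit. Unassigned queries are counted separately and
#' never enter the denominator.
#'
#' @param queries records data.frame; nucleotide reads when
#'   `translated = TRUE` (the default), ORF proteins otherwise.
#' @param db a `functional_database`.
#' @param params protein [alignment_params()].
#' @param translated six-frame-translate the queries before the protein
#'   search.
#' @return object of class `functional_profile`: scheme, counts,
#'   total_assigned, n_unassigned, relative_abundance.
#' @export
functional_profile <- function(queries, db,
                               params = alignment_params("protein"),
                               translated = TRUE) {
  if (!inherits(db, "functional_database")) stopf("db must be a functional_database")
  idx <- suppressWarnings(build_index(db$tier, params))
  hits <- best_protein_hits(queries, idx, params, translated)
  counts <- numeric(0)
  assigned <- character(0)
  if (nrow(hits) > 0L) {
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]
    assigned <- best$query_id
    for (i in seq_len(nrow(best))) {
      cats <- db$categories[[best$subject_accession[i]]]
      w <- 1 / length(cats)
      for (cc in cats)
        counts[cc] <- (if (is.na(counts[cc])) 0 else counts[cc]) + w
    }
    counts <- counts[order(names(counts))]
  }
  total <- length(assigned)
  structure(list(scheme = db$scheme, counts = counts,
                 total_assigned = total,
                 n_unassigned = nrow(queries) - total,
                 relative_abundance = if (total > 0) 100 * counts / total
                                      else counts),
            class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("<functional_profile scheme=%s> %d assigned, %d unassigned\n",
              x$scheme, x$total_assigned, x$n_unassigned))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-30s %8.2f  (%5.2f%%)\n", names(x$counts)[i],
                x$counts[i], x$relative_abundance[i]))
  invisible(x)
}

#' Per-gene read abundance against a user gene database
#'
#' Best-hit read counts per gene with relative abundance over assigned
#' reads; gene lineages are passed through from the database.
#'
#' @param reads nucleotide records data.frame.
#' @param gene_db a nucleotide `reference_tier` of genes.
#' @param params nucleotide [alignment_params()].
#' @return data.frame: gene, read_count, relative_abundance_pct, realm,
#'   family, genus, species (genes with zero reads omitted).
#' @export
gene_database_abundance <- function(reads, gene_db,
                                    params = alignment_params()) {
  idx <- suppressWarnings(build_index(gene_db, params))
  hits <- search_hits(reads, idx, params)
  if (nrow(hits) == 0L)
    return(data.frame(gene = character(0), read_count = integer(0),
                      relative_abundance_pct = numeric(0),
                      realm = character(0), family = character(0),
                      genus = character(0), species = character(0),
                      stringsAsFactors = FALSE))
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  counts <- table(best$subject_accession)
  out <- data.frame(gene = names(counts), read_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$relative_abundance_pct <- 100 * out$read_count / sum(out$read_count)
  m <- match(out$gene, gene_db$entries$accession)
  out <- cbind(out, gene_db$entries[m, RANKS])
  out <- out[order(-out$read_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
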