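#' Alignment parameters for the built-in homology engine
#'
#' The engine is a deterministic seed-and-extend local aligner: exact
#' k-mer seeds are clustered by diagonal and extended with a banded
#' affine-gap Smith-Waterman (band 15). Percent identity is
#' `100 * matches / alignment columns` with gap columns counting as
#' non-matches. The e-value proxy is `N_db * query_len * 2^(-score/2)`
#' — an explicit, uncalibrated screening statistic, not a Karlin-Altschul
#' e-value; all cutoffs are configurable.
#'
#' @param kind "nucleotide" (word size 11) or "protein" (word size 4).
#' @param word_size exact-seed length k (>= 4 recommended, <= 12).
#' @param match,mismatch,gap_open,gap_extend alignment scores; a gap of
#'   length L scores `gap_open + L * gap_extend`.
#' @param min_identity minimum percent identity for a passing hit.
#' @param min_alignment_length minimum alignment columns for a passing
#'   hit; defaults 30 nt / 15 aa.
#' @param max_evalue_proxy maximum e-value proxy for a passing hit;
#'   defaults 1e-5 (nucleotide) / 0.05 (protein) — under the unit-score
#'   scheme a short exact protein hit carries far fewer bits than a
#'   same-length nucleotide hit, so the protein screen must sit higher.
#' @param band half-width of the extension band around seed diagonals.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(kind = c("nucleotide", "protein"),
                             word_size = NULL, match = 1L, mismatch = -1L,
                             gap_open = -5L, gap_extend = -2L,
                             min_identity = 0, min_alignment_length = NULL,
                             max_evalue_proxy = NULL, band = 15L) {
  kind <- match.arg(kind)
  word_size <- word_size %||% if (kind == "nucleotide") 11L else 4L
  min_alignment_length <- min_alignment_length %||%
    if (kind == "nucleotide") 30L else 15L
  max_evalue_proxy <- max_evalue_proxy %||%
    if (kind == "nucleotide") 1e-5 else 0.05
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            word_size >= 2, word_size <= 12)
  structure(list(kind = kind, word_size = as.integer(word_size),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity,
                 min_alignment_length = as.integer(min_alignment_length),
                 max_evalue_proxy = max_evalue_proxy,
                 band = as.integer(band)),
            class = "alignment_params")
}

#' Build a k-mer index over a reference tier
#'
#' Only the plus strand is indexed; minus-strand nucleotide hits are found
#' by searching the reverse-complemented query. Entries shorter than the
#' word size are kept in the database (they contribute to `N_db`) but
#' cannot seed and a warning is raised.
#'
#' @param tier a `reference_tier` (all entries of one kind).
#' @param params an [alignment_params()] whose kind matches the tier's.
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(tier, params = alignment_params(tier$kind)) {
  if (params$kind != tier$kind)
    stopf("params kind '%s' does not match tier kind '%s'",
          params$kind, tier$kind)
  short <- nchar(tier$entries$seq) < params$word_size
  if (any(short))
    warning(sprintf("%d entr%s shorter than word size %d cannot seed",
                    sum(short), if (sum(short) == 1L) "y is" else "ies are",
                    params$word_size), call. = FALSE)
  ptr <- cpp_build_index(tier$entries$seq, tier$entries$accession,
                         params$word_size, tier$kind == "nucleotide")
  info <- cpp_index_info(ptr)
  structure(list(ptr = ptr, k = params$word_size, kind = tier$kind,
                 tier_name = tier$name,
                 accessions = tier$entries$accession,
                 entry_lengths = nchar(tier$entries$seq),
                 n_db = info$ndb),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index tier '%s'> k=%d, %d entries, %.0f residues\n",
              x$tier_name, x$k, length(x$accessions), x$n_db))
  invisible(x)
}

HIT_COLS <- c("query_id", "subject_accession", "percent_identity",
              "alignment_length", "mismatches", "gap_opens", "query_start",
              "query_end", "subject_start", "subject_end", "evalue_proxy",
              "score", "query_coverage", "tier_name")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_accession = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             evalue_proxy = numeric(0), score = integer(0),
             query_coverage = numeric(0), tier_name = character(0),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits, query_order = NULL) {
  if (nrow(hits) == 0L) return(hits)
  qo <- if (is.null(query_order)) hits$query_id
        else factor(hits$query_id, levels = query_order)
  o <- order(qo, -hits$score, hits$evalue_proxy, hits$subject_accession,
             hits$query_start, hits$subject_start)
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search queries against a k-mer index
#'
#' Returns one row per local-alignment hit surviving the thresholds in
#' `params`, sorted by (query order, score desc, e-value proxy asc,
#' subject accession asc). Coordinates are 1-based inclusive on the
#' forward query; minus-strand hits carry `subject_start > subject_end`.
#'
#' @param queries records data.frame (or character vector of sequences,
#'   names used as ids).
#' @param index a [build_index()] result.
#' @param params [alignment_params()]; thresholds applied here.
#' @return hit table (see `HIT_COLS`).
#' @export
search_hits <- function(queries, index, params = alignment_params(index$kind)) {
  if (is.character(queries)) {
    ids <- names(queries) %||% as.character(seq_along(queries))
    queries <- data.frame(id = ids, seq = unname(queries),
                          stringsAsFactors = FALSE)
  }
  if (nrow(queries) == 0L) return(empty_hits())
  raw <- cpp_search_batch(index$ptr, queries$seq, params$match,
                          params$mismatch, params$gap_open,
                          params$gap_extend, params$band,
                          index$kind == "nucleotide")
  if (length(raw$qidx) == 0L) return(empty_hits())
  qlen <- nchar(queries$seq)[raw$qidx]
  hits <- data.frame(
    query_id = queries$id[raw$qidx],
    subject_accession = index$accessions[raw$sidx],
    percent_identity = 100 * raw$matches / raw$columns,
    alignment_length = raw$columns,
    mismatches = raw$mismatches,
    gap_opens = raw$gap_opens,
    query_start = raw$qstart, query_end = raw$qend,
    subject_start = raw$sstart, subject_end = raw$send,
    evalue_proxy = index$n_db * qlen * 2^(-0.5 * raw$score),
    score = raw$score,
    query_coverage = 100 * (raw$qend - raw$qstart + 1) / qlen,
    tier_name = index$tier_name,
    stringsAsFactors = FALSE)
  keep <- hits$percent_identity >= params$min_identity &
    hits$alignment_length >= params$min_alignment_length &
    hits$evalue_proxy <= params$max_evalue_proxy
  sort_hits(hits[keep, , drop = FALSE], query_order = unique(queries$id))
}

#' Export hits as a tabular (outfmt-6 dialect) file
#'
#' Twelve standard columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore) plus `query_coverage` and
#' `tier_name`; no header.
#'
#' @param hits hit table from [search_hits()].
#' @param path output path.
#' @export
export_hits <- function(hits, path) {
  out <- hits[, HIT_COLS]
  out$percent_identity <- sprintf("%.3f", out$percent_identity)
  out$query_coverage <- sprintf("%.3f", out$query_coverage)
  out$evalue_proxy <- sprintf("%.3g", out$evalue_proxy)
  # outfmt-6 column order
  ord <- c("query_id", "subject_accession", "percent_identity",
           "alignment_length", "mismatches", "gap_opens", "query_start",
           "query_end", "subject_start", "subject_end", "evalue_proxy",
           "score", "query_coverage", "tier_name")
  write.table(out[, ord], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a tabular hit file (outfmt-6 dialect)
#'
#' Accepts 12-column tables from external aligners or 14-column tables
#' written by [export_hits()]. Missing query coverage is recomputed from
#' `query_lengths` when provided, else set to `NA`.
#'
#' @param path tabular hit file (no header).
#' @param tier_name tier to attribute hits to (overridden by column 14
#'   when present).
#' @param query_lengths optional named vector of query lengths.
#' @return hit table.
#' @export
import_hits <- function(path, tier_name = "imported", query_lengths = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", colClasses = "character")
  if (!ncol(tab) %in% c(12L, 14L))
    stopf("expected 12 or 14 tab-separated columns, found %d", ncol(tab))
  num <- function(col, name, integer = FALSE) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x))
    if (length(bad))
      stopf("non-numeric %s at line %d: '%s'", name, bad[1L],
            tab[[col]][bad[1L]])
    if (integer) as.integer(round(x)) else x
  }
  hits <- data.frame(
    query_id = tab[[1L]], subject_accession = tab[[2L]],
    percent_identity = num(3L, "identity"),
    alignment_length = num(4L, "alignment length", TRUE),
    mismatches = num(5L, "mismatches", TRUE),
    gap_opens = num(6L, "gap opens", TRUE),
    query_start = num(7L, "query start", TRUE),
    query_end = num(8L, "query end", TRUE),
    subject_start = num(9L, "subject start", TRUE),
    subject_end = num(10L, "subject end", TRUE),
    evalue_proxy = num(11L, "evalue"), score = num(12L, "score"),
    stringsAsFactors = FALSE)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
    stopf("percent identity outside [0, 100] at line %d",
          which(hits$percent_identity < 0 | hits$percent_identity > 100)[1L])
  if (any(hits$query_end < hits$query_start))
    stopf("query_end < query_start at line %d",
          which(hits$query_end < hits$query_start)[1L])
  if (ncol(tab) == 14L) {
    hits$query_coverage <- num(13L, "query coverage")
    hits$tier_name <- tab[[14L]]
  } else {
    hits$query_coverage <- if (!is.null(query_lengths))
      100 * (hits$query_end - hits$query_start + 1) /
        unname(query_lengths[hits$query_id]) else NA_real_
    hits$tier_name <- tier_name
  }
  hits[, HIT_COLS]
}
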