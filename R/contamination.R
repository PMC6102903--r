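#' @title Cross-sample contaminant detection and read scrubbing
#'
#' @description
#' Reagent/lab ("kitome") contamination shows up as near-identical contigs
#' recurring across unrelated samples. Cross-sample contig pairs linked at
#' high identity are clustered by single linkage; reads mapping to the
#' contaminant contigs at >= 99% identity are then scrubbed, the inclusive
#' threshold deliberately admitting the ~1% substitution error of short-read
#' sequencing. Samples that are biologically related (e.g. a mother-infant
#' pair) must not be cross-checked against each other: shared sequence
#' within such a pair is signal, not contamination.
#' @name contamination_screen
NULL

#' Find near-identical contigs shared across samples
#'
#' All cross-sample contig pairs with a hit of identity >= `min_identity`
#' covering >= `min_cov` percent of the shorter contig are linked;
#' single-linkage clusters spanning >= `min_samples` distinct samples are
#' reported, largest first.
#'
#' @param contig_sets named list (sample_id -> records data.frame) of
#'   assembled contigs from samples the caller declares unrelated.
#' @param min_identity percent identity floor for a link (default 99).
#' @param min_cov percent of the shorter contig the alignment must cover
#'   (default 90).
#' @param min_samples minimum distinct samples per reported cluster.
#' @param params nucleotide [alignment_params()] for the cross-alignment.
#' @return list of clusters; each has members (data.frame sample_id,
#'   contig_id, length), representative (longest member as a records row),
#'   pairwise_identity (minimum identity among links), n_samples.
#' @export
find_shared_contigs <- function(contig_sets, min_identity = 99,
                                min_cov = 90, min_samples = 2L,
                                params = alignment_params()) {
  if (length(contig_sets) < 2L)
    stopf("cross-sample check needs >= 2 samples, got %d",
          length(contig_sets))
  if (is.null(names(contig_sets)) || any(!nzchar(names(contig_sets))))
    stopf("contig_sets must be a named list (sample ids)")
  samples <- names(contig_sets)
  node <- function(s, cid) paste0(s, "\r", cid)
  # permissive search params; link thresholds applied explicitly below
  sp <- alignment_params("nucleotide", word_size = params$word_size,
                         min_identity = 0,
                         min_alignment_length = params$min_alignment_length,
                         max_evalue_proxy = params$max_evalue_proxy,
                         band = params$band)
  edges <- character(0)
  edge_ident <- numeric(0)
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i >= j) next
      a <- contig_sets[[i]]; b <- contig_sets[[j]]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      tier <- reference_tier(samples[j], 1L, cbind(
        data.frame(accession = b$id, organism = "", seq = b$seq,
                   stringsAsFactors = FALSE), empty_lineage(nrow(b))))
      idx <- suppressWarnings(build_index(tier, sp))
      hits <- search_hits(a, idx, sp)
      if (nrow(hits) == 0L) next
      la <- nchar(a$seq)[match(hits$query_id, a$id)]
      lb <- nchar(b$seq)[match(hits$subject_accession, b$id)]
      shorter <- pmin(la, lb)
      span <- pmax(hits$query_end - hits$query_start + 1,
                   abs(hits$subject_end - hits$subject_start) + 1)
      keep <- hits$percent_identity >= min_identity &
        100 * span / shorter >= min_cov
      hits <- hits[keep, , drop = FALSE]
      if (nrow(hits) == 0L) next
      # one link per contig pair, at its best identity
      key <- paste(hits$query_id, hits$subject_accession)
      best <- !duplicated(key)
      edges <- c(edges, rbind(node(samples[i], hits$query_id[best]),
                              node(samples[j],
                                   hits$subject_accession[best])))
      edge_ident <- c(edge_ident, hits$percent_identity[best])
    }
  }
  if (!length(edges)) return(list())
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    mem <- vnames[comp$membership == ci]
    parts <- strsplit(mem, "\r", fixed = TRUE)
    md <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                     contig_id = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
    md$length <- vapply(seq_len(nrow(md)), function(r)
      nchar(contig_sets[[md$sample_id[r]]]$seq[
        contig_sets[[md$sample_id[r]]]$id == md$contig_id[r]]), 1L)
    md <- md[order(md$sample_id, md$contig_id), , drop = FALSE]
    rownames(md) <- NULL
    n_samples <- length(unique(md$sample_id))
    if (n_samples < min_samples) next
    in_cl <- matrix(edges, nrow = 2L)[1, ] %in% mem
    rep_i <- which.max(md$length)
    rep_set <- contig_sets[[md$sample_id[rep_i]]]
    clusters[[length(clusters) + 1L]] <- list(
      members = md,
      representative = rep_set[rep_set$id == md$contig_id[rep_i], ,
                               drop = FALSE],
      pairwise_identity = min(edge_ident[in_cl]),
      n_samples = n_samples)
  }
  ord <- order(-vapply(clusters, `[[`, 1L, "n_samples"),
               vapply(clusters, function(cl) cl$members$contig_id[1L], ""))
  clusters[ord]
}

#' Collect all member contigs of contaminant clusters
#' @param clusters result of [find_shared_contigs()].
#' @param contig_sets the contig sets the clusters were found in.
#' @return records data.frame of every member contig, ids prefixed with
#'   their sample id.
#' @export
cluster_contigs <- function(clusters, contig_sets) {
  parts <- lapply(clusters, function(cl) {
    m <- cl$members
    do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
      cs <- contig_sets[[m$sample_id[r]]]
      row <- cs[cs$id == m$contig_id[r], , drop = FALSE]
      row$id <- paste0(m$sample_id[r], ".", row$id)
      row
    }))
  })
  out <- do.call(rbind, parts)
  out[!duplicated(out$id), , drop = FALSE]
}

#' Scrub reads matching contaminant contigs
#'
#' A read is removed iff it has a hit to any contaminant contig with
#' identity >= `min_identity` and query coverage >= `min_read_cov`. The
#' kept/removed sets partition the input.
#'
#' @param reads records data.frame.
#' @param contaminant_contigs records data.frame of contaminant contigs
#'   (e.g. [cluster_contigs()] output).
#' @param min_identity inclusive identity threshold (default 99; a 100 nt
#'   read with one mismatch is removed, with two it is kept).
#' @param min_read_cov percent of the read the alignment must cover.
#' @param params nucleotide [alignment_params()].
#' @return list(kept, removed, removed_count).
#' @export
scrub_reads <- function(reads, contaminant_contigs, min_identity = 99,
                        min_read_cov = 90, params = alignment_params()) {
  if (is.null(contaminant_contigs) || nrow(contaminant_contigs) == 0L)
    return(list(kept = reads, removed = reads[0, , drop = FALSE],
                removed_count = 0L))
  sp <- alignment_params("nucleotide", word_size = params$word_size,
                         min_identity = min_identity,
                         min_alignment_length = params$min_alignment_length,
                         max_evalue_proxy = params$max_evalue_proxy,
                         band = params$band)
  tier <- reference_tier("contaminants", 1L, cbind(
    data.frame(accession = contaminant_contigs$id, organism = "",
               seq = contaminant_contigs$seq, stringsAsFactors = FALSE),
    empty_lineage(nrow(contaminant_contigs))))
  idx <- suppressWarnings(build_index(tier, sp))
  hits <- search_hits(reads, idx, sp)
  hits <- hits[hits$query_coverage >= min_read_cov, , drop = FALSE]
  bad <- reads$id %in% hits$query_id
  list(kept = reads[!bad, , drop = FALSE],
       removed = reads[bad, , drop = FALSE],
       removed_count = sum(bad))
}

#' Report on a sham (no-template) control
#'
#' Quality-filters the control reads, reports depth adequacy against the
#' target sequencing depth, runs the assembler adapter, and issues the
#' verdict "background" iff no contig of at least `min_contig_len` was
#' produced (background = sequencing/demultiplexing noise only).
#'
#' @param reads sham control reads.
#' @param target_depth target sequencing depth in reads.
#' @param assembler a function(records) -> records of contigs.
#' @param min_len,min_mean_q quality-filter settings.
#' @param min_contig_len minimum reportable contig length (default 1000).
#' @return list: n_input, n_filtered, depth_adequacy_pct, n_contigs,
#'   verdict ("background" or "non-background").
#' @export
sham_report <- function(reads, target_depth, assembler, min_len = 50L,
                        min_mean_q = 20, min_contig_len = 1000L) {
  qf <- quality_filter(reads, min_len, min_mean_q)
  contigs <- if (nrow(qf$kept) > 0L) assembler(qf$kept)
             else qf$kept[0, c("id", "seq"), drop = FALSE]
  n_big <- if (nrow(contigs)) sum(nchar(contigs$seq) >= min_contig_len)
           else 0L
  list(n_input = nrow(reads), n_filtered = nrow(qf$kept),
       depth_adequacy_pct = depth_adequacy(nrow(qf$kept), target_depth),
       n_contigs = n_big,
       verdict = if (n_big == 0L) "background" else "non-background")
}
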