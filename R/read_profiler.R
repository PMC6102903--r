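#' @title Read quality control, subsampling and iterative classification
#'
#' @description
#' Reads are classified by consecutive annotation steps against an ordered
#' list of reference tiers (default order: viral, archaeal, bacterial,
#' whole). Hits against the highest-priority tier win: a read with at
#' least one passing hit in a tier is assigned that tier's best hit and
#' lower tiers are never consulted for it. Viral assignments populate
#' family + species; cellular assignments populate genus + species.
#' @name read_profiler
NULL

#' Quality-filter reads
#'
#' Keeps reads with length >= `min_len` and mean Phred score >=
#' `min_mean_q` (both thresholds inclusive); input order is preserved.
#' Reads lacking qualities pass the length check only, with a warning.
#'
#' @param reads records data.frame with `qual`.
#' @param min_len minimum read length (default 50).
#' @param min_mean_q minimum mean Phred score (default 20).
#' @return list with `kept` (records) and `n_removed`.
#' @export
quality_filter <- function(reads, min_len = 50L, min_mean_q = 20) {
  if (nrow(reads) == 0L) return(list(kept = reads, n_removed = 0L))
  len_ok <- nchar(reads$seq) >= min_len
  noq <- is.na(reads$qual)
  if (any(noq))
    warning(sprintf("%d read(s) lack qualities; length check only",
                    sum(noq)), call. = FALSE)
  meanq <- rep(Inf, nrow(reads))
  withq <- which(!noq)
  meanq[withq] <- vapply(reads$qual[withq],
                         function(q) mean(phred_scores(q)), 0,
                         USE.NAMES = FALSE)
  keep <- len_ok & meanq >= min_mean_q
  list(kept = reads[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Subsample reads uniformly without replacement
#'
#' Deterministic for a fixed seed; the original relative order of the
#' selected reads is preserved.
#'
#' @param reads records data.frame.
#' @param n number of reads to draw.
#' @param seed RNG seed.
#' @return records data.frame of `n` reads.
#' @export
subsample_reads <- function(reads, n, seed) {
  if (n > nrow(reads))
    stopf("cannot subsample %d reads from a pool of %d", n, nrow(reads))
  idx <- with_seed(seed, sort(sample.int(nrow(reads), n)))
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

passing_hits <- function(hits, params) {
  hits[hits$percent_identity >= params$min_identity &
         hits$alignment_length >= params$min_alignment_length &
         hits$evalue_proxy <= params$max_evalue_proxy, , drop = FALSE]
}

assign_from_tier <- function(ids, seqs, tier, index, params) {
  # best passing hit per query against one tier; NA rows where none
  hits <- search_hits(data.frame(id = ids, seq = seqs,
                                 stringsAsFactors = FALSE), index, params)
  if (nrow(hits) == 0L) return(NULL)
  hits[!duplicated(hits$query_id), , drop = FALSE]  # already sorted
}

#' Classify reads through the iterative tier cascade
#'
#' @param reads records data.frame (nucleotide).
#' @param tiers list of nucleotide `reference_tier`s; consulted in
#'   priority order (1 first).
#' @param params [alignment_params()] defining what a passing hit is
#'   (identity, alignment length, e-value proxy cutoffs).
#' @param indexes optional pre-built list of [build_index()] results
#'   parallel to `tiers` (reused across calls for speed).
#' @return data.frame with one row per read: read_id, tier_name
#'   ("unclassified" when no tier produced a passing hit), lineage columns,
#'   best-hit accession, identity and score.
#' @export
classify_reads <- function(reads, tiers, params = alignment_params(),
                           indexes = NULL) {
  if (length(tiers) == 0L) stopf("empty tier list")
  tiers <- sort_tiers(tiers)
  n <- nrow(reads)
  out <- data.frame(read_id = reads$id, tier_name = "unclassified",
                    realm = "", family = "", genus = "", species = "",
                    accession = NA_character_, percent_identity = NA_real_,
                    score = NA_real_, stringsAsFactors = FALSE)
  todo <- seq_len(n)
  for (ti in seq_along(tiers)) {
    if (length(todo) == 0L) break
    tier <- tiers[[ti]]
    idx <- if (!is.null(indexes)) indexes[[ti]]
           else suppressWarnings(build_index(tier, params))
    best <- assign_from_tier(reads$id[todo], reads$seq[todo], tier, idx,
                             params)
    if (is.null(best) || nrow(best) == 0L) next
    m <- match(best$query_id, out$read_id)
    e <- match(best$subject_accession, tier$entries$accession)
    out$tier_name[m] <- tier$name
    out$realm[m] <- tier$entries$realm[e]
    viral <- tier$entries$realm[e] == "viral"
    out$family[m] <- ifelse(viral, tier$entries$family[e], "")
    out$genus[m] <- ifelse(viral, "", tier$entries$genus[e])
    out$species[m] <- tier$entries$species[e]
    out$accession[m] <- best$subject_accession
    out$percent_identity[m] <- best$percent_identity
    out$score[m] <- best$score
    todo <- todo[!reads$id[todo] %in% best$query_id]
  }
  out
}

#' Aggregate read classifications into a taxonomic profile
#'
#' Relative abundances are percentages of classified reads; unclassified
#' reads are reported alongside, never in the denominator.
#'
#' @param classifications output of [classify_reads()] (or any table with
#'   tier_name + lineage columns).
#' @param rank "family", "genus" or "species".
#' @return an object of class `taxonomic_profile` with elements rank,
#'   counts, total_classified, relative_abundance, unclassified_count.
#' @export
profile_taxa <- function(classifications,
                         rank = c("species", "family", "genus")) {
  rank <- match.arg(rank)
  cl <- classifications$tier_name != "unclassified"
  labs <- taxon_label(classifications[cl, RANKS, drop = FALSE], rank)
  counts <- if (length(labs)) table(labs) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (length(counts)) counts <- counts[order(names(counts))]
  total <- sum(counts)
  structure(list(rank = rank, counts = counts, total_classified = total,
                 relative_abundance = if (total > 0) 100 * counts / total
                                      else counts * 0,
                 unclassified_count = sum(!cl)),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("<taxonomic_profile rank=%s> %d taxa, %d classified, %d unclassified\n",
              x$rank, length(x$counts), x$total_classified,
              x$unclassified_count))
  if (length(x$counts)) {
    top <- sort(x$relative_abundance, decreasing = TRUE)
    top <- utils::head(top, 10L)
    for (i in seq_along(top))
      cat(sprintf("  %-45s %6.2f%%\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' Write a taxonomic profile as TSV
#' @param profile a `taxonomic_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(taxon = names(profile$counts),
                   count = unname(profile$counts),
                   relative_abundance_pct =
                     sprintf("%.6f", unname(profile$relative_abundance)))
  writeLines(c(sprintf("# rank: %s", profile$rank),
               sprintf("# total_classified: %d", profile$total_classified),
               sprintf("# unclassified: %d", profile$unclassified_count),
               paste(names(df), collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))), path)
  invisible(path)
}

#' Taxa shared by two profiles above an abundance floor
#'
#' A taxon is shared when its relative abundance is strictly greater than
#' `min_abundance_pct` in both profiles (the "> 0.01%" rule used for
#' mother-infant comparisons).
#'
#' @param profile_a,profile_b `taxonomic_profile`s at the same rank.
#' @param min_abundance_pct abundance floor in percent (default 0.01).
#' @return lexicographically sorted character vector of shared labels.
#' @export
shared_taxa <- function(profile_a, profile_b, min_abundance_pct = 0.01) {
  if (profile_a$rank != profile_b$rank)
    stopf("profiles have different ranks (%s vs %s)",
          profile_a$rank, profile_b$rank)
  a <- names(profile_a$relative_abundance)[
    profile_a$relative_abundance > min_abundance_pct]
  b <- names(profile_b$relative_abundance)[
    profile_b$relative_abundance > min_abundance_pct]
  sort(intersect(a, b))
}

#' Sequencing-depth adequacy
#'
#' Percent of a target sequencing depth achieved by the filtered read
#' count, reported to one decimal (e.g. 46,269 reads against a
#' 1,000,000-read target is 4.6).
#'
#' @param n_filtered_reads filtered read count.
#' @param target_depth target read count (> 0).
#' @return percentage, rounded to one decimal.
#' @export
depth_adequacy <- function(n_filtered_reads, target_depth) {
  if (target_depth <= 0) stopf("target_depth must be > 0")
  round(100 * n_filtered_reads / target_depth, 1L)
}
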