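#' @title Rarefaction of viral taxon richness
#'
#' @description
#' Distinct-viral-taxon counts are computed at increasing subsampling
#' depths, either from read classifications ("read" mode) or from
#' assembled contigs above the 5000 nt gate ("contig" mode). A
#' logarithmic trend y = a*ln(x) + b is fitted to size sequencing effort:
#' its doubling gain `100 * a*ln(2) / y(x)` quantifies how little extra
#' richness doubling the depth would buy, and coverage fractions report
#' the share of full-pool richness recovered at a given depth.
#'
#' Subsampling replicates use derived seeds (seed + replicate index).
#' Because per-read classification does not depend on which other reads
#' are in the pool, read-mode rarefaction classifies the full pool once
#' and subsamples the classifications — exactly equivalent to
#' classify-after-subsample, at a fraction of the cost.
#' @name rarefaction
NULL

new_curve <- function(depths, reps, mode, full_pool_taxa) {
  structure(list(depths = depths,
                 taxa_counts = rowMeans(reps),
                 replicates = reps, mode = mode,
                 n_replicates = ncol(reps),
                 full_pool_taxa = full_pool_taxa, fit = NULL),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("<rarefaction_curve mode=%s> %d depths, %d replicate(s), full pool %d taxa\n",
              x$mode, length(x$depths), x$n_replicates, x$full_pool_taxa))
  print(data.frame(depth = x$depths, mean_taxa = x$taxa_counts))
  invisible(x)
}

count_viral_taxa <- function(classifications, rank) {
  v <- classifications$realm == "viral" &
    classifications$tier_name != "unclassified"
  length(unique(taxon_label(classifications[v, RANKS, drop = FALSE], rank)))
}

#' Read-based rarefaction curve
#'
#' @param reads records data.frame (full pool).
#' @param depths strictly increasing positive read counts,
#'   max <= pool size.
#' @param seed base seed; replicate r uses seed + r - 1.
#' @param n_replicates subsample replicates per depth (default 3).
#' @param tiers,params classification cascade (see [classify_reads()]).
#' @param rank taxon rank counted (default "species").
#' @param classifications optional precomputed [classify_reads()] output
#'   for the full pool (computed here when NULL).
#' @return a `rarefaction_curve` (mode "read").
#' @export
read_rarefaction <- function(reads, depths, seed, n_replicates = 3L,
                             tiers = NULL, params = alignment_params(),
                             rank = "species", classifications = NULL) {
  depths <- as.integer(depths)
  if (any(depths <= 0L)) stopf("depths must be positive")
  if (is.unsorted(depths, strictly = TRUE))
    stopf("depths must be strictly increasing")
  if (max(depths) > nrow(reads))
    stopf("depth %d exceeds pool size %d", max(depths), nrow(reads))
  if (is.null(classifications))
    classifications <- classify_reads(reads, tiers, params)
  cls <- classifications[match(reads$id, classifications$read_id), ,
                         drop = FALSE]
  reps <- matrix(0L, length(depths), n_replicates)
  for (r in seq_len(n_replicates)) {
    for (di in seq_along(depths)) {
      idx <- with_seed(seed + r - 1L,
                       sort(sample.int(nrow(reads), depths[di])))
      reps[di, r] <- count_viral_taxa(cls[idx, , drop = FALSE], rank)
    }
  }
  new_curve(depths, reps, "read", count_viral_taxa(cls, rank))
}

#' Contig-based rarefaction curve
#'
#' Per depth (and replicate): subsample reads, run the assembler adapter,
#' classify the contigs, and count distinct viral taxa owning at least
#' one contig longer than `min_len_nt`.
#'
#' @param reads records data.frame (full pool).
#' @param depths strictly increasing positive read counts.
#' @param seed base seed; replicate r uses seed + r - 1.
#' @param assembler function(records) -> contig records (e.g. a
#'   [mock_assembler()] or an adapter around a real assembler).
#' @param classifier function(contig records) -> classification table
#'   with columns contig_id, length, realm and the lineage ranks (e.g.
#'   built from [classify_contigs()], or a truth lookup on fixtures).
#' @param min_len_nt contig length gate (default 5000, strict >).
#' @param n_replicates replicates per depth (default 1).
#' @param rank taxon rank counted (default "species").
#' @return a `rarefaction_curve` (mode "contig").
#' @export
contig_rarefaction <- function(reads, depths, seed, assembler, classifier,
                               min_len_nt = 5000L, n_replicates = 1L,
                               rank = "species") {
  depths <- as.integer(depths)
  if (any(depths <= 0L)) stopf("depths must be positive")
  if (is.unsorted(depths, strictly = TRUE))
    stopf("depths must be strictly increasing")
  if (max(depths) > nrow(reads))
    stopf("depth %d exceeds pool size %d", max(depths), nrow(reads))
  count_one <- function(sub, depth) {
    contigs <- tryCatch(assembler(sub), error = function(e)
      stopf("assembler failed at depth %d: %s", depth, conditionMessage(e)))
    if (is.null(contigs) || nrow(contigs) == 0L) return(0L)
    cls <- classifier(contigs)
    keep <- cls$realm == "viral" & cls$length > min_len_nt
    length(unique(taxon_label(cls[keep, RANKS, drop = FALSE], rank)))
  }
  reps <- matrix(0L, length(depths), n_replicates)
  for (r in seq_len(n_replicates)) {
    for (di in seq_along(depths)) {
      idx <- with_seed(seed + r - 1L,
                       sort(sample.int(nrow(reads), depths[di])))
      reps[di, r] <- count_one(reads[idx, , drop = FALSE], depths[di])
    }
  }
  full <- count_one(reads, nrow(reads))
  new_curve(depths, reps, "contig", full)
}

#' Mock coverage-threshold assembler
#'
#' A documented stand-in for a real assembler, for testing
#' coverage-dependent behavior: a genome is "assembled" (emitted whole as
#' one contig) iff the mean coverage of its truth-assigned reads is at
#' least `min_coverage`. Real assemblers plug in through the same
#' function(records) -> records adapter.
#'
#' @param genomes records data.frame of source genomes.
#' @param truth truth table mapping read_id -> source genome label
#'   (columns read_id, source), as emitted by [simulate_reads()].
#' @param min_coverage mean-coverage threshold (default 5).
#' @return a function(records) -> contig records (ids
#'   `contig_<label>`).
#' @export
mock_assembler <- function(genomes, truth, min_coverage = 5) {
  force(genomes); force(truth); force(min_coverage)
  function(reads) {
    src <- truth$source[match(reads$id, truth$read_id)]
    bases <- tapply(nchar(reads$seq), src, sum)
    glen <- stats::setNames(nchar(genomes$seq), genomes$id)
    cov <- bases / glen[names(bases)]
    made <- names(cov)[!is.na(cov) & cov >= min_coverage]
    made <- made[order(made)]
    if (!length(made))
      return(data.frame(id = character(0), desc = character(0),
                        seq = character(0), qual = character(0),
                        stringsAsFactors = FALSE))
    g <- genomes[match(made, genomes$id), , drop = FALSE]
    seq_records(paste0("contig_", g$id), g$seq)
  }
}

#' Fit a logarithmic trend to a rarefaction curve
#'
#' Least squares on `y = a * ln(x) + b` over the replicate-mean curve.
#'
#' @param curve a `rarefaction_curve` with >= 3 depths.
#' @return list(a, b, r_squared).
#' @export
fit_log_trend <- function(curve) {
  x <- curve$depths; y <- curve$taxa_counts
  if (length(x) < 3L) stopf("need >= 3 depths to fit")
  if (length(unique(x)) < 2L) stopf("singular fit: all depths equal")
  fit <- lm(y ~ log(x))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = unname(coef(fit)[2L]), b = unname(coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Relative richness gain from doubling the sequencing depth
#'
#' Under the fitted trend y = a*ln(x) + b, doubling the depth adds
#' a*ln(2) taxa; the gain is reported relative to the predicted richness
#' at depth x: `100 * a*ln(2) / (a*ln(x) + b)`.
#'
#' @param fit result of [fit_log_trend()].
#' @param x depth at which to evaluate the gain.
#' @return percentage gain.
#' @export
doubling_gain <- function(fit, x) {
  y <- fit$a * log(x) + fit$b
  if (y <= 0) stopf("predicted richness is nonpositive at depth %s",
                    format(x))
  100 * fit$a * log(2) / y
}

#' Fraction of full-pool richness recovered at a depth
#'
#' @param curve a `rarefaction_curve` with `full_pool_taxa > 0`.
#' @param depth one of `curve$depths`.
#' @return percentage `100 * taxa(depth) / full_pool_taxa`.
#' @export
coverage_fraction <- function(curve, depth) {
  if (curve$full_pool_taxa == 0L) stopf("full pool has zero taxa")
  i <- match(depth, curve$depths)
  if (is.na(i)) stopf("depth %s not in curve", format(depth))
  100 * curve$taxa_counts[i] / curve$full_pool_taxa
}

#' Average several rarefaction curves over shared depths
#'
#' The integrated curve is the arithmetic mean of per-sample
#' replicate-mean curves at each shared depth.
#'
#' @param curves list of `rarefaction_curve`s with identical depths.
#' @return a `rarefaction_curve` whose replicate columns are the input
#'   curves' means.
#' @export
average_curves <- function(curves) {
  d <- curves[[1L]]$depths
  for (cu in curves) if (!identical(cu$depths, d))
    stopf("curves must share the same depth grid")
  reps <- vapply(curves, function(cu) cu$taxa_counts, numeric(length(d)))
  reps <- matrix(reps, nrow = length(d))
  out <- new_curve(d, reps, curves[[1L]]$mode,
                   as.integer(round(mean(vapply(curves, `[[`, numeric(1),
                                                "full_pool_taxa")))))
  out$n_replicates <- length(curves)
  out
}

#' Write a rarefaction curve and fit summary as TSV
#' @param curve a `rarefaction_curve`.
#' @param path output path for the curve table; a `<path>.fit.tsv`
#'   companion holds a, b, r-squared and the doubling gain at max depth.
#' @export
write_curve <- function(curve, path) {
  tab <- data.frame(depth = rep(curve$depths, curve$n_replicates),
                    replicate = rep(seq_len(curve$n_replicates),
                                    each = length(curve$depths)),
                    taxa_count = as.vector(curve$replicates))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(curve$depths) >= 3L && length(unique(curve$depths)) > 1L) {
    fit <- fit_log_trend(curve)
    fp <- paste0(path, ".fit.tsv")
    write.table(data.frame(a = fit$a, b = fit$b,
                           r_squared = fit$r_squared,
                           doubling_gain_at_max_pct =
                             doubling_gain(fit, max(curve$depths))),
                fp, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
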