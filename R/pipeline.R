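#' @title Pipeline configuration and orchestration
#'
#' @description
#' One flat key=value configuration drives the end-to-end workflow:
#' quality filtering, optional subsampling, iterative read
#' classification, rank profiles, and (when contigs are supplied) ORF
#' annotation, majority-vote contig classification and GenBank output.
#' Decontamination must precede transmission analysis in any workflow
#' that uses both. All outputs are tabular (TSV) or GenBank; reruns with
#' the same config and inputs are byte-identical. A thin command-line
#' wrapper over [run_pipeline()] ships in `inst/scripts/`.
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' Every numeric constant used by the pipeline stages is a config key;
#' there are no hidden thresholds.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_read_len = 50L,        # quality filter: minimum length, nt
    min_mean_q = 20,           # quality filter: minimum mean Phred
    subsample_n = NA_integer_, # optional subsample size (NA = all)
    seed = 1L,                 # seed for all stochastic stages
    word_size_nt = 11L,        # engine word sizes
    word_size_aa = 4L,
    min_alignment_length_nt = 30L,
    min_alignment_length_aa = 15L,
    max_evalue_nt = 1e-5,
    max_evalue_aa = 0.05,
    min_identity = 0,          # classification passing-hit floor
    scrub_identity = 99,       # contaminant scrub / stringent mapping
    min_read_cov = 90,         # read-coverage floor, percent
    contig_gate_nt = 5000L,    # strict > gate for contig classification
    min_len_aa = 60L,          # ORF caller minimum protein length
    shared_abundance_pct = 0.01,  # strict > floor for shared taxa
    error_rate = 0.01,         # assumed sequencing substitution rate
    profile_ranks = "family,species",
    group_rank = "upper")      # GenBank grouping rank
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config key: %s", unknown[1L])
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as a flat key=value file
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.na(v)) "NA" else as.character(v), "")
  writeLines(sprintf("%s=%s", names(config), vals), path)
  invisible(path)
}

#' Read a flat key=value pipeline configuration
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  defaults <- pipeline_config()
  out <- defaults
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(defaults)) stopf("unknown config key: %s", k)
    proto <- defaults[[k]]
    out[[k]] <- if (is.character(proto)) vals[i]
    else if (vals[i] == "NA") NA_integer_
    else if (is.integer(proto)) as.integer(vals[i])
    else as.numeric(vals[i])
  }
  out
}

params_from_config <- function(config, kind = "nucleotide") {
  nt <- kind == "nucleotide"
  alignment_params(kind,
                   word_size = if (nt) config$word_size_nt
                               else config$word_size_aa,
                   min_identity = config$min_identity,
                   min_alignment_length =
                     if (nt) config$min_alignment_length_nt
                     else config$min_alignment_length_aa,
                   max_evalue_proxy = if (nt) config$max_evalue_nt
                                      else config$max_evalue_aa)
}

log_stage <- function(log, stage, n_in, n_kept, n_removed) {
  c(log, sprintf("%s\tin=%d\tkept=%d\tremoved=%d", stage, n_in, n_kept,
                 n_removed))
}

#' Run the read (and optional contig) analysis workflow
#'
#' Stages, in order: quality_filter, optional subsample, classify_reads,
#' per-rank profiles; when `contigs` is supplied additionally ORF
#' calling, protein-level ORF classification, majority-vote contig
#' classification and GenBank output. Every stage logs in/kept/removed
#' counts; reads-in always equals reads-kept + reads-removed.
#'
#' @param reads records data.frame of input reads.
#' @param tiers nucleotide tier list for read classification.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param contigs optional records data.frame of assembled contigs.
#' @param protein_tiers optional protein tier list for ORF
#'   classification (required with `contigs`).
#' @return named character vector of output paths (invisibly); outputs:
#'   read_assignments.tsv, profile_<rank>.tsv, pipeline.log and, with
#'   contigs, contig_classification.tsv plus GenBank files under
#'   `genbank/`.
#' @export
run_pipeline <- function(reads, tiers, out_dir, config = pipeline_config(),
                         contigs = NULL, protein_tiers = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log <- character(0)

  qf <- quality_filter(reads, config$min_read_len, config$min_mean_q)
  log <- log_stage(log, "quality_filter", nrow(reads), nrow(qf$kept),
                   qf$n_removed)
  kept <- qf$kept

  if (!is.na(config$subsample_n) && config$subsample_n < nrow(kept)) {
    kept <- subsample_reads(kept, config$subsample_n, config$seed)
    log <- log_stage(log, "subsample", nrow(qf$kept), nrow(kept),
                     nrow(qf$kept) - nrow(kept))
  }

  np <- params_from_config(config, "nucleotide")
  cls <- classify_reads(kept, tiers, np)
  n_cl <- sum(cls$tier_name != "unclassified")
  log <- log_stage(log, "classify_reads", nrow(kept), n_cl,
                   nrow(kept) - n_cl)
  p <- file.path(out_dir, "read_assignments.tsv")
  write.table(cls, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["read_assignments"] <- p

  for (rank in strsplit(config$profile_ranks, ",")[[1]]) {
    pr <- profile_taxa(cls, rank)
    p <- file.path(out_dir, sprintf("profile_%s.tsv", rank))
    write_profile(pr, p)
    paths[sprintf("profile_%s", rank)] <- p
  }

  if (!is.null(contigs)) {
    if (is.null(protein_tiers))
      stopf("contig stage requires protein_tiers")
    orfs <- find_all_orfs(contigs, config$min_len_aa)
    pp <- params_from_config(config, "protein")
    orfs <- classify_orfs(orfs, protein_tiers, pp)
    ccls <- classify_contigs(contigs, orfs, config$contig_gate_nt)
    log <- log_stage(log, "classify_contigs", nrow(contigs),
                     sum(nzchar(ccls$realm)),
                     sum(!nzchar(ccls$realm)))
    p <- file.path(out_dir, "contig_classification.tsv")
    write.table(ccls, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["contig_classification"] <- p
    gb <- write_annotated_contigs(contigs, orfs, ccls,
                                  file.path(out_dir, "genbank"),
                                  config$group_rank)
    paths[paste0("genbank_", names(gb))] <- gb
  }

  p <- file.path(out_dir, "pipeline.log")
  writeLines(log, p)
  paths["log"] <- p
  invisible(paths)
}
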