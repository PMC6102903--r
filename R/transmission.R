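#' @title Mother-infant phage transmission detection
#'
#' @description
#' Viral contigs longer than 5000 bp assembled from an infant sample are
#' used as backbones for stringent mapping (>= 99% identity over >= 90%
#' of the read) of the corresponding mother's reads. Contigs that attract
#' mapped reads indicate a shared phage genotype and hence a candidate
#' vertical transmission event; cross-alignment of mothers against
#' unrelated infants' contigs serves as the negative control. Reads
#' should be decontaminated (see [scrub_reads()]) before this analysis.
#' @name transmission_detector
NULL

#' Stringently map reads onto contigs
#'
#' A read maps to a contig iff its best hit on that contig has identity
#' >= `min_identity` and query coverage >= `min_read_cov`; each read
#' counts toward at most one contig (its best-scoring one, ties broken by
#' accession). Breadth is the percent of the contig covered by at least
#' one mapped read.
#'
#' @param reads records data.frame.
#' @param contigs records data.frame of backbone contigs.
#' @param min_identity stringent identity cutoff (default 99).
#' @param min_read_cov read-coverage floor in percent (default 90).
#' @param params nucleotide [alignment_params()].
#' @return data.frame: contig_id, mapped_reads, breadth_pct, plus a
#'   `read_ids` list-column of mapped read ids.
#' @export
map_reads_stringent <- function(reads, contigs, min_identity = 99,
                                min_read_cov = 90,
                                params = alignment_params()) {
  empty <- data.frame(contig_id = character(0), mapped_reads = integer(0),
                      breadth_pct = numeric(0), stringsAsFactors = FALSE)
  empty$read_ids <- list()
  if (nrow(contigs) == 0L || nrow(reads) == 0L) return(empty)
  sp <- alignment_params("nucleotide", word_size = params$word_size,
                         min_identity = min_identity,
                         min_alignment_length = params$min_alignment_length,
                         max_evalue_proxy = params$max_evalue_proxy,
                         band = params$band)
  tier <- reference_tier("backbones", 1L, cbind(
    data.frame(accession = contigs$id, organism = "", seq = contigs$seq,
               stringsAsFactors = FALSE), empty_lineage(nrow(contigs))))
  idx <- suppressWarnings(build_index(tier, sp))
  hits <- search_hits(reads, idx, sp)
  hits <- hits[hits$query_coverage >= min_read_cov, , drop = FALSE]
  # best hit per read (hits are sorted by query, score desc, accession)
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  out <- lapply(contigs$id, function(cid) {
    h <- hits[hits$subject_accession == cid, , drop = FALSE]
    if (nrow(h) == 0L)
      return(list(contig_id = cid, mapped_reads = 0L, breadth_pct = 0,
                  read_ids = character(0)))
    s1 <- pmin(h$subject_start, h$subject_end)
    s2 <- pmax(h$subject_start, h$subject_end)
    cov <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s1, s2))))
    clen <- nchar(contigs$seq[contigs$id == cid])
    list(contig_id = cid, mapped_reads = nrow(h),
         breadth_pct = 100 * cov / clen, read_ids = h$query_id)
  })
  res <- data.frame(contig_id = vapply(out, `[[`, "", "contig_id"),
                    mapped_reads = vapply(out, `[[`, 1L, "mapped_reads"),
                    breadth_pct = vapply(out, `[[`, 1, "breadth_pct"),
                    stringsAsFactors = FALSE)
  res$read_ids <- lapply(out, `[[`, "read_ids")
  res
}

#' Detect shared phage genotypes between an infant's contigs and the
#' mother's reads
#'
#' Only contigs classified viral and longer than `min_len_nt` (strict >)
#' are used as backbones. A backbone is flagged shared when it attracts
#' at least `min_reads` stringently mapped reads (default 1: any mapped
#' read is evidence of the shared genotype); breadth is reported so
#' stricter post-hoc evidence rules can be applied.
#'
#' @param infant_contigs records data.frame of infant contigs.
#' @param contig_classifications classification table for those contigs
#'   (from [classify_contigs()]; needs contig_id, length, realm).
#' @param mother_reads records data.frame of the mother's (scrubbed)
#'   reads.
#' @param min_len_nt backbone length gate (default 5000, strict >).
#' @param min_reads minimum mapped reads to call a contig shared.
#' @param min_identity,min_read_cov stringent mapping thresholds.
#' @param params nucleotide [alignment_params()].
#' @return list of class `transmission_report`: per_contig table,
#'   shared_contigs, n_backbones, reason (when no usable backbone).
#' @export
detect_transmission <- function(infant_contigs, contig_classifications,
                                mother_reads, min_len_nt = 5000L,
                                min_reads = 1L, min_identity = 99,
                                min_read_cov = 90,
                                params = alignment_params()) {
  cls <- contig_classifications
  viral <- cls$contig_id[cls$realm == "viral" & cls$length > min_len_nt]
  backbones <- infant_contigs[infant_contigs$id %in% viral, , drop = FALSE]
  if (nrow(backbones) == 0L) {
    return(structure(list(per_contig = NULL, shared_contigs = character(0),
                          n_backbones = 0L,
                          reason = "no viral contigs above length gate"),
                     class = "transmission_report"))
  }
  mp <- map_reads_stringent(mother_reads, backbones, min_identity,
                            min_read_cov, params)
  m <- match(mp$contig_id, cls$contig_id)
  mp$length <- cls$length[m]
  mp$label <- cls$label[m]
  structure(list(per_contig = mp,
                 shared_contigs = mp$contig_id[mp$mapped_reads >= min_reads],
                 n_backbones = nrow(backbones), reason = ""),
            class = "transmission_report")
}

#' @export
print.transmission_report <- function(x, ...) {
  cat(sprintf("<transmission_report> %d backbones, %d shared\n",
              x$n_backbones, length(x$shared_contigs)))
  if (nzchar(x$reason)) cat("  note:", x$reason, "\n")
  if (!is.null(x$per_contig))
    print(x$per_contig[, c("contig_id", "length", "label", "mapped_reads",
                           "breadth_pct")])
  invisible(x)
}

#' Cross-pair negative control
#'
#' Maps every mother read set onto every infant's viral backbones. The
#' diagonal holds matched pairs; off-diagonal totals should be zero for
#' clean, unrelated pairs — non-zero entries point at contamination.
#'
#' @param pairs named list; each element is
#'   `list(mother_reads =, infant_contigs =, classifications =)`.
#' @param min_len_nt,min_reads,min_identity,min_read_cov,params passed to
#'   [detect_transmission()].
#' @return integer matrix (mothers x infants) of total stringently mapped
#'   reads.
#' @export
cross_pair_control <- function(pairs, min_len_nt = 5000L, min_reads = 1L,
                               min_identity = 99, min_read_cov = 90,
                               params = alignment_params()) {
  if (length(pairs) < 2L) stopf("cross-pair control needs >= 2 pairs")
  ids <- names(pairs) %||% as.character(seq_along(pairs))
  mat <- matrix(0L, length(pairs), length(pairs),
                dimnames = list(mother = ids, infant = ids))
  for (mi in seq_along(pairs)) {
    for (ii in seq_along(pairs)) {
      rep <- detect_transmission(pairs[[ii]]$infant_contigs,
                                 pairs[[ii]]$classifications,
                                 pairs[[mi]]$mother_reads,
                                 min_len_nt, min_reads, min_identity,
                                 min_read_cov, params)
      mat[mi, ii] <- if (is.null(rep$per_contig)) 0L
                     else sum(rep$per_contig$mapped_reads)
    }
  }
  mat
}
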