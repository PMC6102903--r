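#' @title CRISPR-spacer host prediction and novel-phage screening
#'
#' @description
#' A protospacer match between a viral contig and a host CRISPR spacer is
#' evidence of a past phage-host encounter, so spacer databases predict
#' hosts for viral contigs. Conversely, bacterial or unclassified contigs
#' whose ORFs hit marker proteins from several distinct phage genomic
#' modules (replication, packaging, head, tail, lysis, lysogeny) are
#' candidate (pro)phages lacking database homologs. Spacer matching is
#' substitution-only (Hamming) on both strands: spacers are short, and
#' indel tolerance would inflate false links.
#' @name host_novel_phage
NULL

PHAGE_MODULES <- c("replication", "packaging", "head", "tail", "lysis",
                   "lysogeny")

#' Construct a CRISPR spacer database
#'
#' @param spacers data.frame: spacer_id, seq (20-60 nt) and host lineage
#'   columns realm, family, genus, species (genus or species required).
#' @return object of class `spacer_database`.
#' @export
spacer_database <- function(spacers) {
  need <- c("spacer_id", "seq", RANKS)
  if (!all(need %in% names(spacers)))
    stopf("spacer table needs columns: %s", paste(need, collapse = ", "))
  len <- nchar(spacers$seq)
  if (any(len < 20L | len > 60L))
    stopf("spacer lengths must be within [20, 60] nt")
  if (any(!nzchar(spacers$genus) & !nzchar(spacers$species)))
    stopf("every spacer needs a host genus or species")
  structure(list(spacers = spacers), class = "spacer_database")
}

#' Load a spacer database from FASTA + host taxonomy TSV
#' @param fasta_path spacer FASTA.
#' @param taxonomy_path host taxonomy TSV (accession = spacer id).
#' @return a `spacer_database`.
#' @export
load_spacer_database <- function(fasta_path, taxonomy_path) {
  recs <- read_fasta(fasta_path)
  tax <- read_taxonomy(taxonomy_path)
  m <- match(recs$id, tax$accession)
  lin <- empty_lineage(nrow(recs))
  lin[!is.na(m), ] <- tax[m[!is.na(m)], RANKS]
  spacer_database(cbind(data.frame(spacer_id = recs$id, seq = recs$seq,
                                   stringsAsFactors = FALSE), lin))
}

#' Predict hosts of viral contigs from CRISPR protospacer matches
#'
#' Every spacer occurrence on either contig strand with at most
#' `max_mismatches` substitutions (no indels) is reported. Positions are
#' 1-based starts on the forward contig strand.
#'
#' @param viral_contigs records data.frame.
#' @param spacer_db a `spacer_database`.
#' @param max_mismatches maximum substitutions (default 1).
#' @return data.frame: contig_id, spacer_id, host lineage columns,
#'   mismatches, position, strand; sorted by (contig, mismatches,
#'   position).
#' @export
predict_hosts <- function(viral_contigs, spacer_db, max_mismatches = 1L) {
  sp <- spacer_db$spacers
  rows <- list()
  for (ci in seq_len(nrow(viral_contigs))) {
    subject <- Biostrings::DNAString(toupper(viral_contigs$seq[ci]))
    L <- length(subject)
    for (si in seq_len(nrow(sp))) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") toupper(sp$seq[si]) else revcomp(sp$seq[si])
        m <- Biostrings::matchPattern(pat, subject,
                                      max.mismatch = max_mismatches,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        mm <- Biostrings::neditAt(pat, subject, at = Biostrings::start(m),
                                  with.indels = FALSE)
        for (k in seq_along(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = viral_contigs$id[ci], spacer_id = sp$spacer_id[si],
            realm = sp$realm[si], family = sp$family[si],
            genus = sp$genus[si], species = sp$species[si],
            mismatches = mm[k], position = Biostrings::start(m)[k],
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), spacer_id = character(0),
                      realm = character(0), family = character(0),
                      genus = character(0), species = character(0),
                      mismatches = integer(0), position = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$mismatches, out$position,
                   out$spacer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a phage marker set
#'
#' @param entries protein entries data.frame (see [reference_tier()]),
#'   with a `product` column used for annotation.
#' @param module_map data.frame: accession, module (each accession mapped
#'   to exactly one of the six phage modules).
#' @return object of class `phage_marker_set`.
#' @export
phage_marker_set <- function(entries, module_map) {
  if (!all(module_map$module %in% PHAGE_MODULES))
    stopf("unknown module '%s'",
          setdiff(module_map$module, PHAGE_MODULES)[1L])
  if (anyDuplicated(module_map$accession))
    stopf("marker mapped to more than one module: %s",
          module_map$accession[duplicated(module_map$accession)][1L])
  missing <- setdiff(entries$accession, module_map$accession)
  if (length(missing)) stopf("marker without module: %s", missing[1L])
  structure(list(tier = reference_tier("phage-markers", 1L, entries,
                                       kind = "protein"),
                 module_map = stats::setNames(module_map$module,
                                              module_map$accession)),
            class = "phage_marker_set")
}

#' Screen non-viral contigs for hidden phage genomes
#'
#' Contig ORFs are searched against the phage marker proteins; a contig
#' is flagged as a candidate (pro)phage iff its ORF hits span at least
#' `min_modules` distinct modules. Lysogeny-module presence is reported
#' as a separate boolean (phages lacking integrases are candidate
#' strictly lytic phages). Contigs without ORFs are skipped with a note.
#'
#' @param contigs records data.frame of bacterial/unclassified contigs.
#' @param orfs ORF table for those contigs (from [find_all_orfs()]).
#' @param marker_set a `phage_marker_set`.
#' @param params protein [alignment_params()].
#' @param min_modules distinct-module threshold (default 3).
#' @return data.frame: contig_id, n_modules, modules, n_marker_orfs,
#'   has_lysogeny, flagged.
#' @export
screen_novel_phage <- function(contigs, orfs, marker_set,
                               params = alignment_params("protein"),
                               min_modules = 3L) {
  idx <- suppressWarnings(build_index(marker_set$tier, params))
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$id[ci]
    co <- orfs[orfs$contig_id == cid, , drop = FALSE]
    if (nrow(co) == 0L) {
      message(sprintf("contig '%s' has no ORFs; skipped", cid))
      next
    }
    oid <- sprintf("o%04d", seq_len(nrow(co)))
    hits <- search_hits(data.frame(id = oid, seq = co$aa,
                                   stringsAsFactors = FALSE), idx, params)
    mods <- character(0); n_hit <- 0L
    if (nrow(hits) > 0L) {
      best <- hits[!duplicated(hits$query_id), , drop = FALSE]
      mods <- unname(marker_set$module_map[best$subject_accession])
      n_hit <- nrow(best)
    }
    umods <- sort(unique(mods))
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, n_modules = length(umods),
      modules = paste(umods, collapse = ";"), n_marker_orfs = n_hit,
      has_lysogeny = "lysogeny" %in% umods,
      flagged = length(umods) >= min_modules, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), n_modules = integer(0),
                      modules = character(0), n_marker_orfs = integer(0),
                      has_lysogeny = logical(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
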