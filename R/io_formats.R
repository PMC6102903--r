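#' @title Sequence records and on-disk formats
#'
#' @description
#' All modules exchange sequences as a plain data frame of records with
#' columns `id`, `desc`, `seq` and (for reads) `qual`, a Phred+33-encoded
#' quality string of the same length as `seq`. Internal coordinates are
#' 0-based half-open; on-disk formats keep their native conventions
#' (GenBank and tabular hit files are 1-based inclusive).
#' @name io_formats
NULL

#' Construct a set of sequence records
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param desc optional free-text descriptions.
#' @param qual optional Phred+33 quality strings, `NA` when absent.
#' @return a data.frame with columns id, desc, seq, qual.
#' @export
seq_records <- function(id, seq, desc = "", qual = NA_character_) {
  id <- as.character(id); seq <- as.character(seq)
  if (length(id) != length(seq)) stopf("id and seq lengths differ")
  if (any(nchar(seq) < 1L)) stopf("empty sequence not allowed")
  if (any(grepl("[[:space:]]", id))) stopf("record ids must not contain whitespace")
  if (anyDuplicated(id)) stopf("duplicate record id: %s", id[duplicated(id)][1L])
  qual <- rep_len(as.character(qual), length(id))
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) stopf("quality length differs from sequence length for '%s'", id[bad][1L])
  data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual a single quality string.
#' @return integer vector of Phred scores.
#' @export
phred_scores <- function(qual) {
  if (is.na(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores (0-93).
#' @return a quality string.
#' @export
phred_string <- function(scores) intToUtf8(as.integer(scores) + 33L)

split_header <- function(headers) {
  sp <- regexpr("[[:space:]]", headers)
  id <- ifelse(sp > 0, substr(headers, 1L, sp - 1L), headers)
  desc <- ifelse(sp > 0, sub("^[[:space:]]+", "",
                             substring(headers, sp + 1L)), "")
  list(id = id, desc = desc)
}

#' Read a FASTA file (plain or gzipped)
#'
#' @param path file path; `.gz` handled transparently.
#' @return records data.frame (see [seq_records()]); `qual` is `NA`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stopf("malformed FASTA '%s': %s",
                                          path, conditionMessage(e)))
  h <- split_header(names(x))
  if (anyDuplicated(h$id))
    stopf("duplicate FASTA id '%s' in %s", h$id[duplicated(h$id)][1L], path)
  seq_records(h$id, as.character(x), h$desc)
}

#' Write records to FASTA
#'
#' @param records records data.frame.
#' @param path output path; ends with `.gz` for gzip output.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- ifelse(nzchar(records$desc),
                     paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file (Phred+33, plain or gzipped)
#'
#' @param path file path.
#' @return records data.frame with `qual` populated.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stopf("malformed FASTQ '%s': %s",
                              path, conditionMessage(e)))
  q <- tryCatch(as.character(S4Vectors::mcols(x)$qualities),
                error = function(e) stopf("malformed FASTQ '%s': %s",
                                          path, conditionMessage(e)))
  h <- split_header(names(x))
  if (anyDuplicated(h$id))
    stopf("duplicate FASTQ id '%s' in %s", h$id[duplicated(h$id)][1L], path)
  if (any(nchar(q) != nchar(as.character(x))))
    stopf("sequence/quality length mismatch in %s", path)
  seq_records(h$id, as.character(x), h$desc, q)
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records records data.frame; records lacking qualities get a
#'   constant Q30 string.
#' @param path output path; ends with `.gz` for gzip output.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  miss <- is.na(qual)
  if (any(miss))
    qual[miss] <- vapply(nchar(records$seq[miss]),
                         function(n) strrep(rawToChar(as.raw(63L)), n), "")
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Parse a RefSeq-style FASTA definition line
#'
#' The accession is the first whitespace-delimited token; the organism is
#' the bracketed `[...]` suffix when present, otherwise the remainder of
#' the line.
#'
#' @param header the definition line without the leading `>`.
#' @return list with elements `accession` and `organism`.
#' @export
parse_refseq_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  header <- sub("^[[:space:]]+|[[:space:]]+$", "", header)
  if (!nzchar(header)) stopf("empty FASTA header")
  h <- split_header(header)
  org <- h$desc
  m <- regmatches(org, regexpr("\\[[^][]*\\]$", org))
  if (length(m) == 1L && nzchar(m))
    org <- substr(m, 2L, nchar(m) - 1L)
  list(accession = h$id, organism = org)
}

# ---- taxonomy ------------------------------------------------------------

RANKS <- c("realm", "family", "genus", "species")
REALMS <- c("viral", "archaeal", "bacterial", "eukaryote")

#' Construct taxonomic lineages
#'
#' Viral lineages are reported at family and species level, cellular
#' (archaeal/bacterial/eukaryote) lineages at genus and species level;
#' unknown ranks are stored as the empty string.
#'
#' @param realm one of viral/archaeal/bacterial/eukaryote (vectorized).
#' @param family,genus,species optional rank names ("" = unknown).
#' @return data.frame with columns realm, family, genus, species.
#' @export
lineage <- function(realm, family = "", genus = "", species = "") {
  n <- max(length(realm), length(family), length(genus), length(species))
  realm <- rep_len(as.character(realm), n)
  bad <- nzchar(realm) & !realm %in% REALMS
  if (any(bad)) stopf("unknown realm '%s'", realm[bad][1L])
  data.frame(realm = realm,
             family = rep_len(as.character(family), n),
             genus = rep_len(as.character(genus), n),
             species = rep_len(as.character(species), n),
             stringsAsFactors = FALSE)
}

empty_lineage <- function(n = 1L) lineage(rep("", n))

#' Label a lineage at a given rank
#'
#' Known ranks print their name; unknown ranks print
#' `Unclassified__<nearest-known>` where the nearest known higher rank is
#' searched upward (species -> genus -> family -> realm).
#'
#' @param lin lineage data.frame (columns realm/family/genus/species).
#' @param rank one of "family", "genus", "species".
#' @return character vector of labels.
#' @export
taxon_label <- function(lin, rank = c("species", "family", "genus")) {
  rank <- match.arg(rank)
  val <- lin[[rank]]
  higher <- switch(rank, species = c("genus", "family", "realm"),
                   genus = c("family", "realm"), family = c("realm"))
  out <- val
  missing <- !nzchar(val)
  if (any(missing)) {
    near <- rep("", sum(missing))
    sub <- lin[missing, , drop = FALSE]
    for (h in higher) near <- ifelse(nzchar(near), near, sub[[h]])
    out[missing] <- ifelse(nzchar(near),
                           paste0("Unclassified__", near), "Unclassified")
  }
  out
}

#' Read a taxonomy table
#'
#' Tab-separated with columns accession, realm, family, genus, species
#' (header required; empty cells = unknown rank).
#'
#' @param path TSV path.
#' @return data.frame keyed by accession.
#' @export
read_taxonomy <- function(path) {
  tx <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", colClasses = "character", fill = TRUE)
  need <- c("accession", RANKS)
  if (!all(need %in% names(tx)))
    stopf("taxonomy table must have columns: %s", paste(need, collapse = ", "))
  for (r in RANKS) tx[[r]][is.na(tx[[r]])] <- ""
  tx[, need]
}

#' Write a taxonomy table
#' @param tax data.frame with columns accession, realm, family, genus, species.
#' @param path output TSV path.
#' @export
write_taxonomy <- function(tax, path) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- reference tiers -----------------------------------------------------

#' Construct a reference tier
#'
#' A tier is one prioritized database in the iterative classification
#' cascade (default cascade: viral, archaeal, bacterial, whole).
#'
#' @param name tier name.
#' @param priority integer >= 1; 1 is consulted first.
#' @param entries data.frame with columns accession, organism, seq and the
#'   lineage columns realm, family, genus, species.
#' @param kind "nucleotide" or "protein".
#' @return an object of class `reference_tier`.
#' @export
reference_tier <- function(name, priority, entries,
                           kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  need <- c("accession", "organism", "seq", RANKS)
  if (!all(need %in% names(entries)))
    stopf("tier entries need columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(entries$accession))
    stopf("duplicate accession within tier '%s'", name)
  keep <- c(need, intersect("product", names(entries)))
  structure(list(name = name, priority = as.integer(priority),
                 entries = entries[, keep], kind = kind),
            class = "reference_tier")
}

#' @export
print.reference_tier <- function(x, ...) {
  cat(sprintf("<reference_tier '%s'> priority %d, %d %s entries\n",
              x$name, x$priority, nrow(x$entries), x$kind))
  invisible(x)
}

#' Number of entries in a tier
#' @param tier a `reference_tier`.
#' @return integer entry count.
#' @export
n_entries <- function(tier) nrow(tier$entries)

#' Load a reference tier from FASTA + taxonomy TSV
#'
#' FASTA headers must be RefSeq-style (`accession description [organism]`);
#' lineages come from the taxonomy table, matched on accession.
#'
#' @param fasta_path FASTA of reference sequences.
#' @param taxonomy_path taxonomy TSV (see [read_taxonomy()]).
#' @param name,priority tier identity (see [reference_tier()]).
#' @param kind "nucleotide" or "protein".
#' @return a `reference_tier`.
#' @export
load_reference_tier <- function(fasta_path, taxonomy_path, name, priority,
                                kind = "nucleotide") {
  recs <- read_fasta(fasta_path)
  tax <- read_taxonomy(taxonomy_path)
  org <- vapply(seq_len(nrow(recs)), function(i) {
    parse_refseq_header(paste(recs$id[i], recs$desc[i]))$organism
  }, "")
  m <- match(recs$id, tax$accession)
  lin <- empty_lineage(nrow(recs))
  known <- !is.na(m)
  lin[known, ] <- tax[m[known], RANKS]
  product <- sub("[[:space:]]*\\[[^][]*\\]$", "", recs$desc)
  entries <- cbind(data.frame(accession = recs$id, organism = org,
                              seq = recs$seq, product = product,
                              stringsAsFactors = FALSE), lin)
  reference_tier(name, priority, entries, kind)
}

#' Merge additional entries into a tier
#'
#' Entries whose accession is already present are dropped (database
#' accounting follows the non-redundant union, e.g. a 7485-genome tier
#' merged with 5530 additional unique genomes totals 13,015).
#'
#' @param tier a `reference_tier`.
#' @param extra a second `reference_tier` or an entries data.frame.
#' @return the merged `reference_tier`.
#' @export
merge_tiers <- function(tier, extra) {
  ee <- if (inherits(extra, "reference_tier")) extra$entries else extra
  new <- ee[!ee$accession %in% tier$entries$accession, , drop = FALSE]
  reference_tier(tier$name, tier$priority,
                 rbind(tier$entries, new[, names(tier$entries)]), tier$kind)
}

#' Order tiers by priority
#' @param tiers list of `reference_tier`s.
#' @return the list sorted by priority; priorities must be unique and
#'   contiguous from 1.
#' @export
sort_tiers <- function(tiers) {
  if (length(tiers) == 0L) stopf("empty tier list")
  p <- unname(vapply(tiers, function(t) t$priority, 1L))
  if (!identical(sort(p), seq_along(tiers)))
    stopf("tier priorities must be unique and contiguous from 1")
  tiers[order(p)]
}

# ---- GenBank output ------------------------------------------------------

wrap_qualifier <- function(text, width = 58L) {
  # fold a qualifier line to GenBank's 80-column layout
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1L, width))
    text <- substring(text, width + 1L)
  }
  c(out, text)
}

format_genbank_record <- function(id, seq, lin_label, orfs) {
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     linear   PHG 01-JAN-1970",
            id, n),
    sprintf("DEFINITION  %s [%s].", id, lin_label),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("                     /note=\"taxonomy: %s\"", lin_label))
  if (nrow(orfs) > 0L) {
    orfs <- orfs[order(orfs$start), , drop = FALSE]
    for (i in seq_len(nrow(orfs))) {
      loc <- sprintf("%d..%d", orfs$start[i] + 1L, orfs$end[i])
      if (orfs$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      tag <- sprintf("%s_%03d", id, i)
      orf_lab <- taxon_label(orfs[i, RANKS], "species")
      quals <- c(sprintf("/locus_tag=\"%s\"", tag),
                 sprintf("/product=\"%s\"", orfs$product[i]),
                 sprintf("/note=\"taxonomy: %s\"", orf_lab),
                 sprintf("/translation=\"%s\"", orfs$aa[i]))
      lines <- c(lines, sprintf("     CDS             %s", loc),
                 unlist(lapply(quals, function(q)
                   paste0("                     ",
                          wrap_qualifier(q)))))
    }
  }
  lines <- c(lines, "ORIGIN")
  lower <- tolower(seq)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(lower, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  c(lines, "//")
}

sanitize_filename <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]+", "_", x)
  ifelse(nzchar(x), x, "Unclassified")
}

#' Write annotated contigs as GenBank flat files grouped by taxon
#'
#' One file per taxon at `group_rank`; `"upper"` groups at viral family /
#' cellular genus (the ranks used for contig pooling), `"species"` at
#' species. Contigs without a classification are written to
#' `Unclassified.gbk`, never dropped. Feature coordinates are 1-based
#' inclusive; minus-strand ORFs use `complement(a..b)` notation.
#'
#' @param contigs records data.frame of contig sequences.
#' @param orfs annotated ORF table (from [classify_orfs()]).
#' @param classifications contig classification table
#'   (from [classify_contigs()]).
#' @param out_dir output directory (created if missing).
#' @param group_rank "upper" or "species".
#' @return named character vector of written file paths.
#' @export
write_annotated_contigs <- function(contigs, orfs, classifications, out_dir,
                                    group_rank = c("upper", "species")) {
  group_rank <- match.arg(group_rank)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classifications[match(contigs$id, classifications$contig_id), ,
                         drop = FALSE]
  lab <- rep("Unclassified", nrow(contigs))
  has <- !is.na(cls$contig_id) & nzchar(cls$realm)
  if (any(has)) {
    lin <- cls[has, RANKS]
    lab[has] <- if (group_rank == "species") taxon_label(lin, "species")
    else ifelse(lin$realm == "viral", taxon_label(lin, "family"),
                taxon_label(lin, "genus"))
  }
  out <- character(0)
  for (g in sort(unique(lab))) {
    path <- file.path(out_dir, paste0(sanitize_filename(g), ".gbk"))
    idx <- which(lab == g)
    lines <- character(0)
    for (i in idx) {
      cid <- contigs$id[i]
      co <- orfs[orfs$contig_id == cid, , drop = FALSE]
      full_lab <- if (has[i]) taxon_label(cls[i, RANKS], "species")
                  else "Unclassified"
      lines <- c(lines,
                 format_genbank_record(cid, contigs$seq[i], full_lab, co))
    }
    writeLines(lines, path)
    out[g] <- path
  }
  out
}
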