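#' @title Seeded synthetic communities, phages and read sets
#'
#' @description
#' Generators for every input the toolkit consumes: multi-genome
#' communities with skewed (log-normal) abundances, phage genomes with
#' modular gene architecture, substitution-error short reads with exact
#' truth tables, mother-infant pairs sharing near-identical phage
#' genotypes, and cross-sample contaminant spiking. Every generator is a
#' pure function of its seed and arguments: reruns are byte-identical.
#' The error model is substitution-only, matching the ~1% substitution
#' error of short-read sequencing that the 99% identity thresholds are
#' built around.
#' @name synthetic_fixtures
NULL

#' Generate a random genome
#'
#' I.i.d. bases with P(G) + P(C) = `gc`.
#'
#' @param length genome length in nt (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return a single nucleotide string.
#' @export
make_genome <- function(length, gc, seed) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, TRUE,
                               prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                        (1 - gc) / 2)), collapse = ""))
}

#' Apply random substitutions to a sequence
#'
#' Each base is substituted (to a different base) independently with
#' probability `rate`; no indels.
#'
#' @param seq nucleotide string.
#' @param rate per-base substitution probability.
#' @param seed RNG seed.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  if (rate <= 0) return(seq)
  with_seed(seed, {
    n <- nchar(seq)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(seq)
    pos <- sample.int(n, k)
    chars <- strsplit(seq, "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, chars[p])
      chars[p] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  })
}

random_codons <- function(n) {
  # random sense codons (no stop) as one string
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   STOP_CODONS)
  paste(sample(sense, n, TRUE), collapse = "")
}

# stop codons in all three frames on both strands; contains no start codon
SPACER_MOTIF <- "TTAATTAATTAA"

MODULE_PRODUCTS <- list(
  replication = c("DNA polymerase", "replicative helicase",
                  "primase", "single-stranded DNA binding protein"),
  packaging = c("terminase large subunit", "portal protein",
                "terminase small subunit", "HNH endonuclease"),
  head = c("major capsid protein", "head scaffolding protein",
           "capsid maturation protease", "head-tail connector protein"),
  tail = c("tail fiber protein", "tape measure protein",
           "major tail protein", "baseplate protein"),
  lysis = c("endolysin", "holin", "spanin", "lysozyme"),
  lysogeny = c("integrase", "CI-like repressor", "excisionase",
               "anti-repressor"))

#' Generate a synthetic phage marker protein set
#'
#' One nucleotide gene (ATG + random sense codons + TAA) and its
#' translation per marker, organized into the six canonical phage
#' modules.
#'
#' @param seed RNG seed.
#' @param genes_per_module markers per module (<= 4).
#' @param len_aa protein length per marker (default 80).
#' @param modules which modules to include (default all six).
#' @return list: marker_set (a [phage_marker_set()]), genes_nt (named
#'   nucleotide gene vector), entries (protein entries data.frame).
#' @export
make_marker_set <- function(seed, genes_per_module = 2L, len_aa = 80L,
                            modules = PHAGE_MODULES) {
  stopifnot(genes_per_module <= 4L)
  with_seed(seed, {
    rows <- list(); genes <- character(0)
    for (mod in modules) {
      for (g in seq_len(genes_per_module)) {
        acc <- sprintf("MRK_%s_%02d", toupper(mod), g)
        nt <- paste0("ATG", random_codons(len_aa - 1L), "TAA")
        cpos <- seq(1L, nchar(nt) - 3L, by = 3L)
        aa <- translate_codons(substring(nt, cpos, cpos + 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, organism = "synthetic phage",
          seq = aa, product = MODULE_PRODUCTS[[mod]][g], module = mod,
          stringsAsFactors = FALSE)
        genes[acc] <- nt
      }
    }
    tab <- do.call(rbind, rows)
    entries <- cbind(tab[, c("accession", "organism", "seq", "product")],
                     lineage("viral", family = "Synthviridae"))
    list(marker_set = phage_marker_set(entries,
                                       tab[, c("accession", "module")]),
         genes_nt = genes, entries = entries)
  })
}

#' Assemble a synthetic phage genome from marker genes
#'
#' Module-ordered marker genes plus `n_filler` random (unannotatable)
#' genes, all on the plus strand, separated by intergenic spacers that
#' carry stop codons in every frame on both strands so each gene is
#' recovered exactly by [find_orfs()].
#'
#' @param markers result of [make_marker_set()].
#' @param seed RNG seed (for spacers and filler genes).
#' @param modules modules to include, in genome order.
#' @param n_filler number of random filler genes appended.
#' @param filler_len_aa filler protein length (default 80).
#' @return list: genome (records row), truth (data.frame gene_id, start,
#'   end, strand, module, product; coordinates 0-based half-open).
#' @export
make_phage <- function(markers, seed, modules = PHAGE_MODULES,
                       n_filler = 0L, filler_len_aa = 80L) {
  ents <- markers$entries
  mm <- markers$marker_set$module_map
  with_seed(seed, {
    parts <- SPACER_MOTIF
    truth <- list()
    add_gene <- function(parts, gid, nt, module, product) {
      spacer <- paste0(paste(sample(c("A", "C", "G", "T"),
                                    sample(6:24, 1L), TRUE),
                             collapse = ""), SPACER_MOTIF)
      start <- sum(nchar(parts))
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = gid, start = start, end = start + nchar(nt),
        strand = "+", module = module, product = product,
        stringsAsFactors = FALSE)
      c(parts, nt, spacer)
    }
    for (mod in modules) {
      for (acc in names(mm)[mm == mod]) {
        parts <- add_gene(parts, acc, markers$genes_nt[[acc]], mod,
                          ents$product[ents$accession == acc])
      }
    }
    for (g in seq_len(n_filler)) {
      nt <- paste0("ATG", random_codons(filler_len_aa - 1L), "TAA")
      parts <- add_gene(parts, sprintf("filler_%02d", g), nt, "",
                        "hypothetical protein")
    }
    list(genome = seq_records("synthetic_phage",
                              paste(parts, collapse = "")),
         truth = do.call(rbind, truth))
  })
}

#' Specify a synthetic community
#'
#' @param genomes data.frame: label, realm, family, genus, species,
#'   length, gc (one row per genome). Sequences are generated here.
#' @param abundances optional positive weights (named by label); default
#'   log-normal with sdlog 1, the skewed-abundance regime typical of
#'   viral metagenomes.
#' @param read_length read length in nt (default 150).
#' @param error_rate per-base substitution error (default 0.01).
#' @param seed RNG seed.
#' @return list of class `community_spec`: genomes (records), lineages,
#'   abundances (normalized), read_length, error_rate, seed.
#' @export
community_spec <- function(genomes, abundances = NULL, read_length = 150L,
                           error_rate = 0.01, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.25,
            all(genomes$length >= read_length))
  seqs <- character(nrow(genomes))
  with_seed(seed, {
    for (i in seq_len(nrow(genomes)))
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), genomes$length[i],
                              TRUE,
                              prob = c((1 - genomes$gc[i]) / 2,
                                       genomes$gc[i] / 2,
                                       genomes$gc[i] / 2,
                                       (1 - genomes$gc[i]) / 2)),
                       collapse = "")
    if (is.null(abundances))
      abundances <- stats::setNames(rlnorm(nrow(genomes), 0, 1),
                                    genomes$label)
  })
  if (any(abundances <= 0)) stopf("abundance weights must be > 0")
  structure(list(genomes = seq_records(genomes$label, seqs),
                 lineages = cbind(data.frame(label = genomes$label,
                                             stringsAsFactors = FALSE),
                                  genomes[, RANKS]),
                 abundances = abundances / sum(abundances),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = seed),
            class = "community_spec")
}

#' Simulate shotgun reads from a community
#'
#' Sources drawn by abundance weight, positions uniform, strands fair,
#' substitutions i.i.d. at the community error rate, constant Q30
#' qualities. The truth table is exhaustive: every read appears exactly
#' once.
#'
#' @param spec a `community_spec`.
#' @param n_reads number of reads (>= 1).
#' @param seed RNG seed.
#' @param prefix read-id prefix (default "read").
#' @return list: reads (records with qualities), truth (data.frame
#'   read_id, source, pos (0-based), strand, n_errors).
#' @export
simulate_reads <- function(spec, n_reads, seed, prefix = "read") {
  rl <- spec$read_length
  g <- spec$genomes
  w <- spec$abundances[g$id]
  with_seed(seed, {
    src <- sample.int(nrow(g), n_reads, TRUE, prob = w)
    glen <- nchar(g$seq)[src]
    pos <- floor(stats::runif(n_reads) * (glen - rl + 1))
    strand <- sample(c("+", "-"), n_reads, TRUE)
    seqs <- substr(g$seq[src], pos + 1L, pos + rl)
    minus <- which(strand == "-")
    if (length(minus))
      seqs[minus] <- vapply(seqs[minus], cpp_revcomp, "",
                            USE.NAMES = FALSE)
    nerr <- stats::rbinom(n_reads, rl, spec$error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nerr > 0L)) {
      chars <- strsplit(seqs[i], "")[[1]]
      for (p in sample.int(rl, nerr[i])) {
        alt <- setdiff(bases, chars[p])
        chars[p] <- alt[sample.int(3L, 1L)]
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    ids <- sprintf("%s%06d", prefix, seq_len(n_reads))
    list(reads = seq_records(ids, seqs,
                             qual = strrep(rawToChar(as.raw(63L)), rl)),
         truth = data.frame(read_id = ids, source = g$id[src], pos = pos,
                            strand = strand, n_errors = nerr,
                            stringsAsFactors = FALSE))
  })
}

#' Build the four-tier reference cascade from a community
#'
#' One nucleotide entry per genome, placed in its realm's tier (viral
#' priority 1, archaeal 2, bacterial 3, whole/eukaryote 4) with a
#' RefSeq-style accession. Empty tiers are kept so the cascade always
#' has four steps.
#'
#' @param spec a `community_spec`.
#' @return named list of four nucleotide `reference_tier`s in priority
#'   order.
#' @export
make_reference_tiers <- function(spec) {
  tier_of <- c(viral = "viral", archaeal = "archaeal",
               bacterial = "bacterial", eukaryote = "whole")
  prio <- c(viral = 1L, archaeal = 2L, bacterial = 3L, whole = 4L)
  entries <- cbind(data.frame(
    accession = spec$genomes$id, organism = spec$lineages$species,
    seq = spec$genomes$seq, product = "genome",
    stringsAsFactors = FALSE), spec$lineages[, RANKS])
  out <- list()
  for (tn in names(prio)) {
    sel <- tier_of[entries$realm] == tn
    out[[tn]] <- reference_tier(tn, prio[[tn]],
                                entries[sel, , drop = FALSE])
  }
  out
}

#' Write a tier as FASTA + taxonomy TSV
#' @param tier a `reference_tier`.
#' @param fasta_path,taxonomy_path output paths.
#' @export
write_tier <- function(tier, fasta_path, taxonomy_path) {
  e <- tier$entries
  desc <- ifelse(nzchar(e$organism),
                 paste0(e$product, " [", e$organism, "]"), e$product)
  write_fasta(seq_records(e$accession, e$seq, desc), fasta_path)
  write_taxonomy(cbind(data.frame(accession = e$accession,
                                  stringsAsFactors = FALSE), e[, RANKS]),
                 taxonomy_path)
  invisible(fasta_path)
}

#' Generate a mother-infant sample pair with shared phage genotypes
#'
#' Shared phages appear in both samples with per-base divergence
#' `(100 - shared_identity) / 100` between the mother and infant copies;
#' mother-only and infant-only phages are sample-private. Infant contigs
#' are emitted directly from the infant genomes (assembly is out of
#' band), together with their truth classifications.
#'
#' @param spec a `community_spec` holding all phage genomes (realm
#'   viral).
#' @param shared,mother_only,infant_only label sets partitioning the
#'   community.
#' @param shared_identity percent identity between the two copies of
#'   each shared genome (default 99.5).
#' @param n_mother,n_infant reads per sample.
#' @param seed RNG seed.
#' @return list: mother_reads, infant_reads, mother_truth, infant_truth,
#'   infant_contigs, classifications (truth table for
#'   [detect_transmission()]), truth_shared (contig ids of shared phages
#'   above the 5000 nt gate).
#' @export
make_pair <- function(spec, shared, mother_only = character(0),
                      infant_only = character(0), shared_identity = 99.5,
                      n_mother = 5000L, n_infant = 5000L, seed = 1L) {
  labs <- c(shared, mother_only, infant_only)
  if (!all(labs %in% spec$genomes$id))
    stopf("unknown label: %s", setdiff(labs, spec$genomes$id)[1L])
  rate <- (100 - shared_identity) / 100
  sub_spec <- function(labels, seqs) {
    g <- spec$genomes[match(labels, spec$genomes$id), , drop = FALSE]
    if (!is.null(seqs)) g$seq <- seqs[g$id]
    w <- spec$abundances[labels]
    structure(list(genomes = g,
                   lineages = spec$lineages[
                     match(labels, spec$lineages$label), , drop = FALSE],
                   abundances = w / sum(w),
                   read_length = spec$read_length,
                   error_rate = spec$error_rate, seed = spec$seed),
              class = "community_spec")
  }
  infant_seqs <- stats::setNames(spec$genomes$seq, spec$genomes$id)
  for (i in seq_along(shared))
    infant_seqs[shared[i]] <- mutate_sequence(infant_seqs[[shared[i]]],
                                              rate, seed + 100L + i)
  mother <- sub_spec(c(shared, mother_only), NULL)
  infant <- sub_spec(c(shared, infant_only), infant_seqs)
  mr <- simulate_reads(mother, n_mother, seed + 1L, prefix = "m")
  ir <- simulate_reads(infant, n_infant, seed + 2L, prefix = "i")
  ig <- infant$genomes
  contigs <- seq_records(paste0("contig_", ig$id), ig$seq)
  lin <- infant$lineages
  cls <- data.frame(contig_id = contigs$id, length = nchar(contigs$seq),
                    realm = lin$realm, family = lin$family,
                    genus = lin$genus, species = lin$species,
                    label = taxon_label(lin[, RANKS], "family"),
                    stringsAsFactors = FALSE)
  list(mother_reads = mr$reads, infant_reads = ir$reads,
       mother_truth = mr$truth, infant_truth = ir$truth,
       infant_contigs = contigs, classifications = cls,
       truth_shared = paste0("contig_", shared)[
         nchar(infant_seqs[shared]) > 5000L])
}

#' Spike a reagent contaminant into several samples
#'
#' Each sample receives `floor(fraction * n)` reads drawn error-free
#' from its own copy of the contaminant genome; copies are mutated at
#' `divergence / 2` from the master so that copies from different
#' samples differ by about `divergence` (between-lab/kit-lot variation).
#' Error-free reads mirror scrubbing against contigs assembled from the
#' same datasets, where the assembly consensus removes per-read error.
#'
#' @param read_sets named list (sample_id -> records) of clean reads.
#' @param contaminant_genome nucleotide string (the master contaminant).
#' @param fraction spiked fraction of each sample's read count (0-1).
#' @param divergence between-sample per-base divergence (default 0.005).
#' @param read_length spiked read length (default 150).
#' @param seed RNG seed.
#' @return list: spiked (named list of records), contaminant_contigs
#'   (per-sample copies as records, ids `<sample>_contaminant`), truth
#'   (named list of spiked read-id vectors).
#' @export
spike_contaminant <- function(read_sets, contaminant_genome, fraction,
                              divergence = 0.005, read_length = 150L,
                              seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  spiked <- list(); contigs <- list(); truth <- list()
  for (i in seq_along(read_sets)) {
    sid <- names(read_sets)[i]
    copy <- mutate_sequence(contaminant_genome, divergence / 2,
                            seed + 10L * i)
    n_spike <- floor(fraction * nrow(read_sets[[i]]))
    cspec <- structure(list(
      genomes = seq_records(paste0(sid, "_contaminant"), copy),
      lineages = cbind(data.frame(label = paste0(sid, "_contaminant"),
                                  stringsAsFactors = FALSE),
                       lineage("bacterial", genus = "Contaminans",
                               species = "Contaminans synthetica")),
      abundances = stats::setNames(1, paste0(sid, "_contaminant")),
      read_length = as.integer(read_length), error_rate = 0,
      seed = seed), class = "community_spec")
    sp <- simulate_reads(cspec, n_spike, seed + 10L * i + 1L,
                         prefix = paste0(sid, "_contam"))
    spiked[[sid]] <- rbind(read_sets[[i]], sp$reads)
    contigs[[sid]] <- seq_records(paste0(sid, "_contaminant"), copy)
    truth[[sid]] <- sp$reads$id
  }
  list(spiked = spiked, contaminant_contigs = do.call(rbind, contigs),
       truth = truth)
}
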