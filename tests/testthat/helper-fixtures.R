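# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms/libraries than the implementation they check.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# five-genome community spanning all four realms
demo_community <- function(seed = 42L, error_rate = 0.01) {
  g <- data.frame(
    label = c("phageA", "phageB", "bactA", "archA", "eukA"),
    realm = c("viral", "viral", "bacterial", "archaeal", "eukaryote"),
    family = c("Myoviridae", "Siphoviridae", "", "", ""),
    genus = c("", "", "Escherichia", "Methanobrevibacter", "Candida"),
    species = c("Escherichia virus T4s", "Lactococcus phage Xs",
                "Escherichia coli s", "Methanobrevibacter smithii s",
                "Candida albicans s"),
    length = c(8000L, 7000L, 12000L, 9000L, 9000L), gc = 0.45,
    stringsAsFactors = FALSE)
  community_spec(g, read_length = 150L, error_rate = error_rate,
                 seed = seed)
}

nt_entries <- function(accession, seq, realm = "viral", family = "Fam",
                       genus = "", species = "Sp") {
  cbind(data.frame(accession = accession, organism = species, seq = seq,
                   product = "gene", stringsAsFactors = FALSE),
        lineage(realm, family, genus, species))
}

# Smith-Waterman oracle via Biostrings (full DP, both strands); returns
# the optimum score and whether the returned optimal path carries an
# exact k-mer match run
sw_oracle_nt <- function(a, b, k) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = TRUE)
  best <- 0; seeded <- FALSE
  for (qs in c(a, revcomp(a))) {
    pa <- tryCatch(
      Biostrings::pairwiseAlignment(qs, b, type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 5, gapExtension = 2),
      error = function(e) NULL)
    if (is.null(pa)) next
    sc <- Biostrings::score(pa)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    su <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    cols <- ap == su & ap != "-"
    r <- rle(cols)
    sd <- any(r$values & r$lengths >= k)
    if (sc > best) { best <- sc; seeded <- sd }
    else if (sc == best && sd) seeded <- TRUE
  }
  list(score = best, seeded = seeded)
}

# independent six-frame ORF scanner: regex-driven, structured differently
# from find_orfs
orf_oracle <- function(id, seq, min_len_aa = 60L) {
  seq <- toupper(seq); L <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      n <- (nchar(s) - f) %/% 3
      if (n < 2) next
      cod <- substring(s, f + 3 * (0:(n - 1)) + 1, f + 3 * (0:(n - 1)) + 3)
      prot <- paste(ifelse(cod %in% c("TAA", "TAG", "TGA"), "*", "c"),
                    collapse = "")
      stops <- c(0L, which(strsplit(prot, "")[[1]] == "*"))
      for (si in seq_len(length(stops) - 1L)) {
        lo <- stops[si] + 1L; hi <- stops[si + 1L]
        if (hi <= lo) next
        starts <- which(cod[lo:(hi - 1L)] %in% c("ATG", "GTG", "TTG"))
        if (!length(starts)) next
        first <- lo + starts[1L] - 1L
        if (hi - first < min_len_aa) next
        nt0 <- f + 3L * (first - 1L); nt1 <- f + 3L * hi
        if (strand == "-") { tmp <- nt0; nt0 <- L - nt1; nt1 <- L - tmp }
        res[[length(res) + 1L]] <- c(nt0, nt1,
                                     if (strand == "+") 1L else -1L)
      }
    }
  }
  if (!length(res)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, res)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# minimal independent GenBank feature parser (regex-based)
parse_genbank_cds <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  out <- list()
  for (r in recs) {
    if (!length(r) || !grepl("^LOCUS", r[1])) next
    id <- strsplit(trimws(sub("^LOCUS", "", r[1])), "[[:space:]]+")[[1]][1]
    cds <- grep("^     CDS             ", r, value = TRUE)
    for (cd in cds) {
      loc <- trimws(sub("^     CDS", "", cd))
      comp <- grepl("^complement", loc)
      nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc),
                                  "\\.\\.")[[1]])
      out[[length(out) + 1L]] <- data.frame(
        contig = id, from = nums[1], to = nums[2],
        strand = if (comp) "-" else "+", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
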