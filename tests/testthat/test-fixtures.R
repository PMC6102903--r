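test_that("genome generation is seeded, GC-faithful and supports length 1", {
  expect_identical(make_genome(1000, 0.5, 7L), make_genome(1000, 0.5, 7L))
  g <- make_genome(1e5, 0.7, 8L)
  gc_obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.7), 4 * sqrt(0.7 * 0.3 / 1e5))
  expect_equal(nchar(make_genome(1, 0.5, 9L)), 1L)
})

test_that("mutation is substitution-only at the requested rate", {
  s <- make_genome(2e4, 0.5, 10L)
  m <- mutate_sequence(s, 0.01, 11L)
  expect_equal(nchar(m), nchar(s))
  d <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(d - 0.01), 4 * sqrt(0.01 * 0.99 / 2e4))
  expect_identical(mutate_sequence(s, 0, 1L), s)
})

test_that("simulated reads honor abundances, error model and truth tables", {
  spec <- demo_community(seed = 12L, error_rate = 0)
  sim <- simulate_reads(spec, 500L, 13L)
  expect_identical(sim, simulate_reads(spec, 500L, 13L))  # pure in seed
  # truth is exhaustive: every read exactly once
  expect_equal(sort(sim$truth$read_id), sort(sim$reads$id))
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
  # error-free reads are exact substrings of their (oriented) source
  for (i in sample(500, 30)) {
    src <- spec$genomes$seq[spec$genomes$id == sim$truth$source[i]]
    r <- sim$reads$seq[i]
    ori <- if (sim$truth$strand[i] == "-") revcomp(r) else r
    expect_equal(substr(src, sim$truth$pos[i] + 1,
                        sim$truth$pos[i] + 150), ori)
  }

  # two-genome community with 0.9/0.1 weights: share within 4 sigma
  g2 <- data.frame(label = c("A", "B"), realm = "viral",
                   family = "Myoviridae", genus = "",
                   species = c("vA", "vB"), length = 4000L, gc = 0.5,
                   stringsAsFactors = FALSE)
  spec2 <- community_spec(g2, abundances = c(A = 0.9, B = 0.1),
                          error_rate = 0, seed = 14L)
  sim2 <- simulate_reads(spec2, 10000L, 15L)
  shareA <- mean(sim2$truth$source == "A")
  expect_lt(abs(shareA - 0.9), 0.012)

  # observed per-read error count matches the binomial model
  spec_e <- demo_community(seed = 16L, error_rate = 0.01)
  sim_e <- simulate_reads(spec_e, 800L, 17L)
  expect_lt(abs(mean(sim_e$truth$n_errors) - 1.5),
            4 * sqrt(150 * 0.01 * 0.99 / 800))
})

test_that("spike-in series are recovered by read profiling within sampling error", {
  # decreasing spike fractions of a marked phage into a background
  g <- data.frame(label = c("bg", "spike"),
                  realm = c("bacterial", "viral"),
                  family = c("", "Siphoviridae"),
                  genus = c("Escherichia", ""),
                  species = c("E coli b", "Lactococcus phage c2s"),
                  length = 9000L, gc = 0.45, stringsAsFactors = FALSE)
  for (frac in c(0.05, 0.01, 0.002)) {
    spec <- community_spec(g, abundances = c(bg = 1 - frac, spike = frac),
                           error_rate = 0, seed = 18L)
    n <- 5000L
    sim <- simulate_reads(spec, n, 19L)
    tiers <- make_reference_tiers(spec)
    cls <- classify_reads(sim$reads, tiers)
    obs <- mean(cls$realm == "viral")
    expect_lt(abs(obs - frac), 3 * sqrt(frac * (1 - frac) / n) + 1e-9)
  }
})

test_that("reference tiers place each genome in its realm and round-trip to disk", {
  spec <- demo_community(seed = 20L)
  tiers <- make_reference_tiers(spec)
  expect_equal(names(tiers), c("viral", "archaeal", "bacterial", "whole"))
  expect_equal(tiers$viral$entries$accession, c("phageA", "phageB"))
  expect_equal(tiers$whole$entries$accession, "eukA")  # eukaryote tier
  fa <- withr::local_tempfile(fileext = ".fasta")
  tx <- withr::local_tempfile(fileext = ".tsv")
  write_tier(tiers$viral, fa, tx)
  back <- load_reference_tier(fa, tx, "viral", 1L)
  expect_equal(back$entries$accession, tiers$viral$entries$accession)
  expect_equal(back$entries$seq, tiers$viral$entries$seq)
  expect_equal(back$entries$species, tiers$viral$entries$species)
  # headers parse RefSeq-style
  h <- parse_refseq_header(paste(read_fasta(fa)$id[1],
                                 read_fasta(fa)$desc[1]))
  expect_equal(h$accession, "phageA")
  expect_equal(h$organism, "Escherichia virus T4s")
})

test_that("pairs with sub-threshold shared identity are negative controls", {
  g <- data.frame(label = c("P1", "P2"), realm = "viral",
                  family = "Myoviridae", genus = "",
                  species = c("v1", "v2"), length = 6000L, gc = 0.45,
                  stringsAsFactors = FALSE)
  spec <- community_spec(g, read_length = 150L, error_rate = 0.01,
                         seed = 21L)
  pair <- make_pair(spec, shared = "P1", infant_only = "P2",
                    shared_identity = 95, n_mother = 600L,
                    n_infant = 600L, seed = 22L)
  rep <- detect_transmission(pair$infant_contigs, pair$classifications,
                             pair$mother_reads)
  expect_equal(rep$shared_contigs, character(0))
})

test_that("generated phages expose their marker genes to the ORF caller", {
  mk <- make_marker_set(23L, genes_per_module = 2L)
  ph <- make_phage(mk, seed = 24L,
                   modules = c("replication", "packaging", "tail",
                               "lysis"))
  expect_equal(nrow(ph$truth), 8L)
  orfs <- find_orfs(stats::setNames(ph$genome$seq, ph$genome$id))
  found <- paste(orfs$start, orfs$end, orfs$strand)
  expect_true(all(paste(ph$truth$start, ph$truth$end, "+") %in% found))
  expect_identical(make_phage(mk, seed = 24L)$genome$seq,
                   make_phage(mk, seed = 24L)$genome$seq)
})
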