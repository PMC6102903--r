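make_sample_contigs <- function(n_samples, planted, seed) {
  # unique per-sample contigs plus one planted contig in every sample
  with_seed <- function(s, code) { set.seed(s); code }
  set.seed(seed)
  sets <- list()
  for (i in seq_len(n_samples)) {
    sets[[sprintf("S%d", i)]] <- seq_records(
      c(sprintf("uniq%d", i), "shared"),
      c(rand_seq(6000), planted))
  }
  sets
}

test_that("identical planted contigs cluster across all samples", {
  set.seed(40)
  planted <- rand_seq(8000)
  sets <- make_sample_contigs(5L, planted, 41L)
  cl <- find_shared_contigs(sets)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$n_samples, 5L)
  expect_equal(cl[[1]]$pairwise_identity, 100)
  expect_setequal(cl[[1]]$members$contig_id, rep("shared", 5))
  expect_error(find_shared_contigs(sets[1]), ">= 2 samples")
})

test_that("contigs below the identity threshold are not linked", {
  set.seed(42)
  base <- rand_seq(6000)
  far <- mutate_sequence(base, 0.05, 43L)  # ~95% identity
  sets <- list(S1 = seq_records("a", base), S2 = seq_records("b", far))
  expect_equal(length(find_shared_contigs(sets, min_identity = 99)), 0L)
  near <- mutate_sequence(base, 0.002, 44L)
  sets2 <- list(S1 = seq_records("a", base), S2 = seq_records("b", near))
  cl <- find_shared_contigs(sets2, min_identity = 99)
  expect_equal(length(cl), 1L)
})

test_that("cluster detection is invariant under sample relabeling", {
  set.seed(45)
  planted <- rand_seq(7000)
  sets <- make_sample_contigs(3L, planted, 46L)
  cl1 <- find_shared_contigs(sets)
  perm <- sets[c(3, 1, 2)]
  names(perm) <- names(sets)[c(1, 2, 3)]
  cl2 <- find_shared_contigs(perm)
  expect_equal(length(cl1), length(cl2))
  expect_equal(cl1[[1]]$n_samples, cl2[[1]]$n_samples)
  expect_setequal(cl1[[1]]$members$contig_id, cl2[[1]]$members$contig_id)
})

test_that("read scrubbing applies the inclusive 99% boundary", {
  set.seed(47)
  contam <- rand_seq(5000)
  contigs <- seq_records("k", contam)
  read <- substr(contam, 1001, 1100)  # 100 nt
  one_mm <- read; substr(one_mm, 50, 50) <-
    if (substr(one_mm, 50, 50) == "A") "C" else "A"
  two_mm <- one_mm; substr(two_mm, 20, 20) <-
    if (substr(two_mm, 20, 20) == "G") "T" else "G"
  reads <- seq_records(c("exact", "mm1", "mm2"), c(read, one_mm, two_mm))
  sc <- scrub_reads(reads, contigs)
  # 99.0% (1 mismatch in 100) is removed; 98.0% is kept
  expect_setequal(sc$removed$id, c("exact", "mm1"))
  expect_equal(sc$kept$id, "mm2")
  expect_equal(nrow(sc$kept) + nrow(sc$removed), nrow(reads))
  expect_equal(sc$removed_count, 2L)
})

test_that("scrubbing removes fewer reads as the identity threshold rises", {
  set.seed(48)
  contam <- rand_seq(4000)
  contigs <- seq_records("k", contam)
  spec <- structure(list(
    genomes = seq_records("k", contam),
    lineages = cbind(data.frame(label = "k"), lineage("bacterial")),
    abundances = c(k = 1), read_length = 100L, error_rate = 0.02,
    seed = 1L), class = "community_spec")
  reads <- simulate_reads(spec, 300L, seed = 49L)$reads
  removed <- vapply(c(90, 95, 99, 100), function(th)
    scrub_reads(reads, contigs, min_identity = th)$removed_count, 1L)
  expect_true(all(diff(removed) <= 0))
  # empty contaminant set keeps everything
  none <- scrub_reads(reads, contigs[0, ])
  expect_equal(none$removed_count, 0L)
  expect_equal(nrow(none$kept), 300L)
})

test_that("spiked contaminants are found as a cross-sample cluster and scrubbed out", {
  set.seed(50)
  g <- data.frame(label = c("P1", "P2", "P3"), realm = "viral",
                  family = c("Myoviridae", "Siphoviridae", "Podoviridae"),
                  genus = "", species = paste("virus", 1:3),
                  length = 7000L, gc = 0.45, stringsAsFactors = FALSE)
  spec <- community_spec(g, read_length = 150L, error_rate = 0.01,
                         seed = 51L)
  clean <- lapply(1:3, function(i)
    simulate_reads(structure(list(genomes = spec$genomes[i, ],
                                  lineages = spec$lineages[i, ],
                                  abundances = stats::setNames(1, g$label[i]),
                                  read_length = 150L, error_rate = 0.01,
                                  seed = 51L), class = "community_spec"),
                   1500L, seed = 52L + i, prefix = sprintf("s%d_", i))$reads)
  names(clean) <- sprintf("S%d", 1:3)
  contam_genome <- make_genome(6000L, 0.5, 53L)
  sp <- spike_contaminant(clean, contam_genome, fraction = 0.05,
                          divergence = 0.005, seed = 54L)
  # exact spiked count: floor(0.05 * 1500)
  expect_equal(nrow(sp$spiked$S1) - nrow(clean$S1), 75L)

  # per-sample contig sets: each sample's own phage contig + its
  # contaminant copy; only the contaminant clusters across samples
  sets <- lapply(1:3, function(i)
    rbind(seq_records(paste0("phage", i), spec$genomes$seq[i]),
          sp$contaminant_contigs[i, ]))
  names(sets) <- names(clean)
  cl <- find_shared_contigs(sets)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$n_samples, 3L)
  expect_true(all(grepl("contaminant", cl[[1]]$members$contig_id)))

  # scrubbing against the cluster members removes >= 99% of spiked
  # reads and <= 0.1% of clean reads
  members <- cluster_contigs(cl, sets)
  for (i in 1:3) {
    sc <- scrub_reads(sp$spiked[[i]], members)
    spiked_ids <- sp$truth[[i]]
    expect_gte(mean(spiked_ids %in% sc$removed$id), 0.99)
    clean_removed <- setdiff(sc$removed$id, spiked_ids)
    expect_lte(length(clean_removed) / nrow(clean[[i]]), 0.001)
  }
})

test_that("sham controls report depth adequacy and a background verdict", {
  asm_none <- function(reads) reads[0, c("id", "desc", "seq", "qual")]
  empty <- seq_records("x", "ACGT")[0, ]
  rep0 <- sham_report(empty, 1e6, asm_none)
  expect_equal(rep0$n_filtered, 0L)
  expect_equal(rep0$n_contigs, 0L)
  expect_equal(rep0$verdict, "background")
  expect_equal(rep0$depth_adequacy_pct, 0)

  # a real genome at high coverage through the mock assembler is
  # anything but background
  set.seed(55)
  g <- seq_records("gen", rand_seq(4000))
  spec <- structure(list(genomes = g,
                         lineages = cbind(data.frame(label = "gen"),
                                          lineage("bacterial")),
                         abundances = c(gen = 1), read_length = 100L,
                         error_rate = 0, seed = 1L),
                    class = "community_spec")
  sim <- simulate_reads(spec, 2000L, 56L)  # 50x coverage
  asm <- mock_assembler(g, sim$truth, min_coverage = 5)
  rep1 <- sham_report(sim$reads, 1e6, asm)
  expect_equal(rep1$verdict, "non-background")
  expect_equal(rep1$depth_adequacy_pct, 0.2)
})
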