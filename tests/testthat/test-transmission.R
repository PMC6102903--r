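test_that("stringent mapping honors identity, coverage, and one-read-one-contig", {
  set.seed(60)
  contig <- rand_seq(8000)
  contigs <- seq_records("c1", contig)
  exact <- substr(contig, 2001, 2150)
  mm2 <- exact
  substr(mm2, 40, 40) <- if (substr(mm2, 40, 40) == "A") "C" else "A"
  substr(mm2, 90, 90) <- if (substr(mm2, 90, 90) == "A") "C" else "A"
  reads <- seq_records(c("hit", "far"), c(exact, mm2))
  mp <- map_reads_stringent(reads, contigs)
  expect_equal(mp$mapped_reads, 1L)
  expect_equal(mp$read_ids[[1]], "hit")
  # breadth contribution equals the read length
  expect_equal(mp$breadth_pct, 100 * 150 / 8000)

  # a read maps to at most one contig even when two contigs carry it
  two <- seq_records(c("a1", "a2"), c(contig, contig))
  mp2 <- map_reads_stringent(seq_records("r", exact), two)
  expect_equal(sum(mp2$mapped_reads), 1L)
  expect_equal(mp2$mapped_reads[mp2$contig_id == "a1"], 1L)  # tie: accession
  expect_equal(nrow(map_reads_stringent(reads, contigs[0, ])), 0L)
})

test_that("transmission detection flags exactly the truth-shared contigs", {
  g <- data.frame(label = c("P1", "P2", "P3", "P4"), realm = "viral",
                  family = c("Myoviridae", "Siphoviridae", "Podoviridae",
                             "Myoviridae"),
                  genus = "", species = paste("virus", 1:4),
                  length = c(8000L, 7000L, 6500L, 7500L), gc = 0.45,
                  stringsAsFactors = FALSE)
  spec <- community_spec(g, read_length = 150L, error_rate = 0.01,
                         seed = 61L)
  pair <- make_pair(spec, shared = "P1", mother_only = "P2",
                    infant_only = "P3", shared_identity = 99.5,
                    n_mother = 2000L, n_infant = 2000L, seed = 62L)
  rep <- detect_transmission(pair$infant_contigs, pair$classifications,
                             pair$mother_reads)
  expect_equal(rep$shared_contigs, pair$truth_shared)
  expect_equal(rep$n_backbones, 2L)  # shared + infant-only backbones
  # the mapped fraction of mother reads drawn from the shared phage
  # follows P(Bin(150, 0.005 + error interplay) <= 1 mismatch); check the
  # pure-divergence bound within a wide band
  src <- pair$mother_truth$source
  n_p1 <- sum(src == "P1")
  mapped <- length(rep$per_contig$read_ids[[
    which(rep$per_contig$contig_id == "contig_P1")]])
  # mother reads carry 1% sequencing error on top of 0.5% divergence:
  # expected pass rate P(Bin(150, ~0.0149) <= 1) ~ 0.33
  p_pass <- pbinom(1, 150, 0.005 + 0.01 * (1 - 0.005))
  expect_gt(mapped / n_p1, p_pass - 4 * sqrt(p_pass * (1 - p_pass) / n_p1))
  expect_lt(mapped / n_p1, p_pass + 4 * sqrt(p_pass * (1 - p_pass) / n_p1))

  # zero mother reads mapping anywhere -> nothing shared
  unrelated <- simulate_reads(spec, 100L, 63L)$reads
  unrelated$seq <- vapply(nchar(unrelated$seq),
                          function(n) rand_seq(n), "")
  rep0 <- detect_transmission(pair$infant_contigs, pair$classifications,
                              unrelated)
  expect_equal(rep0$shared_contigs, character(0))
})

test_that("one mapped read suffices at min_reads = 1 and the backbone gate is strict", {
  set.seed(64)
  contig <- rand_seq(5500)
  contigs <- seq_records("v1", contig)
  cls <- data.frame(contig_id = "v1", length = 5500L, realm = "viral",
                    family = "Myoviridae", genus = "", species = "v",
                    label = "Myoviridae", stringsAsFactors = FALSE)
  one <- seq_records("r1", substr(contig, 100, 249))
  rep <- detect_transmission(contigs, cls, one)
  expect_equal(rep$shared_contigs, "v1")
  # 5000 nt exactly does not pass the "> 5000" gate
  cls2 <- cls; cls2$length <- 5000L
  rep2 <- detect_transmission(contigs, cls2, one)
  expect_equal(rep2$n_backbones, 0L)
  expect_match(rep2$reason, "no viral contigs")
})

test_that("cross-pair controls are zero off-diagonal and contaminant-sensitive", {
  g <- data.frame(label = sprintf("P%d", 1:4), realm = "viral",
                  family = rep(c("Myoviridae", "Siphoviridae"), 2),
                  genus = "", species = paste("virus", 1:4),
                  length = 6500L, gc = 0.45, stringsAsFactors = FALSE)
  spec <- community_spec(g, read_length = 150L, error_rate = 0.01,
                         seed = 65L)
  pair1 <- make_pair(spec, shared = "P1", infant_only = "P2",
                     n_mother = 800L, n_infant = 800L, seed = 66L)
  pair2 <- make_pair(spec, shared = "P3", infant_only = "P4",
                     n_mother = 800L, n_infant = 800L, seed = 67L)
  pairs <- list(
    pairA = list(mother_reads = pair1$mother_reads,
                 infant_contigs = pair1$infant_contigs,
                 classifications = pair1$classifications),
    pairB = list(mother_reads = pair2$mother_reads,
                 infant_contigs = pair2$infant_contigs,
                 classifications = pair2$classifications))
  mat <- cross_pair_control(pairs)
  expect_true(all(diag(mat) > 0))
  expect_equal(mat[1, 2], 0L)
  expect_equal(mat[2, 1], 0L)

  # a contaminant spiked into both mothers lights up the off-diagonal;
  # scrubbing restores it to zero
  contam <- make_genome(6000L, 0.5, 68L)
  spiked <- spike_contaminant(list(mA = pair1$mother_reads,
                                   mB = pair2$mother_reads),
                              contam, fraction = 0.05, seed = 69L)
  pairs_sp <- pairs
  pairs_sp$pairA$mother_reads <- spiked$spiked$mA
  pairs_sp$pairB$mother_reads <- spiked$spiked$mB
  # contaminant contig also ends up among each infant's backbones
  for (p in c("pairA", "pairB")) {
    cc <- spiked$contaminant_contigs[1, ]
    cc$id <- "contig_kit"
    pairs_sp[[p]]$infant_contigs <- rbind(pairs_sp[[p]]$infant_contigs, cc)
    pairs_sp[[p]]$classifications <- rbind(
      pairs_sp[[p]]$classifications,
      data.frame(contig_id = "contig_kit", length = nchar(cc$seq),
                 realm = "viral", family = "Kitviridae", genus = "",
                 species = "kit phage", label = "Kitviridae",
                 stringsAsFactors = FALSE))
  }
  mat_sp <- cross_pair_control(pairs_sp)
  expect_gt(mat_sp[1, 2], 0L)
  expect_gt(mat_sp[2, 1], 0L)
  for (p in c("pairA", "pairB"))
    pairs_sp[[p]]$mother_reads <- scrub_reads(
      pairs_sp[[p]]$mother_reads, spiked$contaminant_contigs)$kept
  mat_cl <- cross_pair_control(pairs_sp)
  expect_equal(mat_cl[1, 2], 0L)
  expect_equal(mat_cl[2, 1], 0L)
})

test_that("lowering the identity threshold never unmaps reads", {
  set.seed(70)
  contig <- rand_seq(6000)
  contigs <- seq_records("c", contig)
  spec <- structure(list(genomes = seq_records("c", contig),
                         lineages = cbind(data.frame(label = "c"),
                                          lineage("viral", "F", "", "s")),
                         abundances = c(c = 1), read_length = 150L,
                         error_rate = 0.02, seed = 1L),
                    class = "community_spec")
  reads <- simulate_reads(spec, 400L, 71L)$reads
  mapped <- vapply(c(100, 99, 97, 95), function(th)
    sum(map_reads_stringent(reads, contigs,
                            min_identity = th)$mapped_reads), 1L)
  expect_true(all(diff(mapped) >= 0))
})
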