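toy_curve <- function(depths, taxa) {
  structure(list(depths = depths, taxa_counts = taxa,
                 replicates = matrix(taxa, ncol = 1), mode = "read",
                 n_replicates = 1L, full_pool_taxa = max(taxa),
                 fit = NULL), class = "rarefaction_curve")
}

test_that("log-trend fitting exactly recovers noiseless inputs", {
  x <- c(500, 1000, 2000, 4000, 8000, 16000)
  fit <- fit_log_trend(toy_curve(x, 2 * log(x) + 1))
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- fit_log_trend(toy_curve(x, rep(7, 6)))
  expect_equal(flat$a, 0, tolerance = 1e-12)
  expect_equal(flat$b, 7, tolerance = 1e-12)
  expect_error(fit_log_trend(toy_curve(x[1:2], c(1, 2))), ">= 3 depths")
})

test_that("noisy log-trend estimates are unbiased within Monte-Carlo error", {
  set.seed(80)
  x <- round(exp(seq(log(500), log(64000), length.out = 8)))
  a_hat <- b_hat <- numeric(100)
  for (i in 1:100) {
    y <- 3 * log(x) + 5 + rnorm(8, 0, 1)
    f <- fit_log_trend(toy_curve(x, y))
    a_hat[i] <- f$a; b_hat[i] <- f$b
  }
  expect_lt(abs(mean(a_hat) - 3), 3 * sd(a_hat) / 10)
  expect_lt(abs(mean(b_hat) - 5), 3 * sd(b_hat) / 10)
})

test_that("doubling gain matches its closed form and the finite difference", {
  expect_equal(doubling_gain(list(a = 0, b = 5), 1000), 0)
  expect_equal(doubling_gain(list(a = 10, b = 0), exp(1)),
               100 * 10 * log(2) / 10, tolerance = 1e-12)
  fit <- list(a = 4.2, b = 3.3)
  x <- 20000
  y <- function(z) fit$a * log(z) + fit$b
  expect_equal(doubling_gain(fit, x), 100 * (y(2 * x) - y(x)) / y(x),
               tolerance = 1e-9)
  expect_error(doubling_gain(list(a = 1, b = -100), 2), "nonpositive")
})

test_that("coverage fraction reports the share of full-pool richness", {
  cu <- toy_curve(c(1000, 2000, 4000), c(7, 9, 10))
  expect_equal(coverage_fraction(cu, 1000), 70)
  expect_equal(coverage_fraction(cu, 4000), 100)
  expect_error(coverage_fraction(cu, 3000), "not in curve")
  cu0 <- cu; cu0$full_pool_taxa <- 0L
  expect_error(coverage_fraction(cu0, 1000), "zero taxa")
})

test_that("read rarefaction is depth-monotone in the mean and hits the full pool", {
  g <- data.frame(label = sprintf("V%02d", 1:12), realm = "viral",
                  family = "Myoviridae", genus = "",
                  species = sprintf("virus %02d", 1:12), length = 3000L,
                  gc = 0.45, stringsAsFactors = FALSE)
  spec <- community_spec(g, read_length = 120L, error_rate = 0,
                         seed = 81L)
  tiers <- make_reference_tiers(spec)
  sim <- simulate_reads(spec, 1200L, 82L)
  cls <- classify_reads(sim$reads, tiers)
  depths <- c(20L, 60L, 150L, 400L, 800L, 1200L)
  cu <- read_rarefaction(sim$reads, depths, seed = 83L,
                         n_replicates = 4L, classifications = cls)
  # full-depth subsample equals the full-pool count
  expect_equal(cu$taxa_counts[length(depths)], cu$full_pool_taxa)
  expect_equal(coverage_fraction(cu, 1200L), 100)
  # replicate means non-decreasing within 2 SE
  se <- apply(cu$replicates, 1, sd) / sqrt(cu$n_replicates)
  for (i in seq_len(length(depths) - 1L))
    expect_gte(cu$taxa_counts[i + 1] - cu$taxa_counts[i],
               -2 * sqrt(se[i]^2 + se[i + 1]^2))
  expect_error(read_rarefaction(sim$reads, c(0L, 10L), 1L,
                                classifications = cls), "positive")
  expect_error(read_rarefaction(sim$reads, c(10L, 5000L), 1L,
                                classifications = cls), "exceeds")
})

test_that("contig rarefaction counts only taxa assembled past the gate", {
  g <- data.frame(label = sprintf("V%d", 1:3), realm = "viral",
                  family = "Myoviridae", genus = "",
                  species = sprintf("virus %d", 1:3), length = 6000L,
                  gc = 0.45, stringsAsFactors = FALSE)
  spec <- community_spec(g, abundances = c(V1 = .5, V2 = .3, V3 = .2),
                         read_length = 150L, error_rate = 0, seed = 84L)
  sim <- simulate_reads(spec, 2400L, 85L)  # 20x total coverage
  asm <- mock_assembler(spec$genomes, sim$truth, min_coverage = 5)
  lookup <- function(contigs) {
    lab <- sub("^contig_", "", contigs$id)
    m <- match(lab, spec$lineages$label)
    data.frame(contig_id = contigs$id, length = nchar(contigs$seq),
               realm = spec$lineages$realm[m],
               family = spec$lineages$family[m],
               genus = spec$lineages$genus[m],
               species = spec$lineages$species[m],
               stringsAsFactors = FALSE)
  }
  # tiny depths: no genome reaches 5x -> zero taxa
  cu <- contig_rarefaction(sim$reads, c(20L, 2400L), seed = 86L,
                           assembler = asm, classifier = lookup,
                           min_len_nt = 5000L)
  expect_equal(cu$replicates[1, 1], 0L)
  expect_equal(cu$replicates[2, 1], 3L)  # all three covered at full depth
  expect_equal(cu$full_pool_taxa, 3L)

  # contig-mode richness never exceeds read-mode richness
  tiers <- make_reference_tiers(spec)
  cls <- classify_reads(sim$reads, tiers)
  cur <- read_rarefaction(sim$reads, c(20L, 2400L), seed = 86L,
                          n_replicates = 1L, classifications = cls)
  expect_true(all(cu$taxa_counts <= cur$taxa_counts))
})

test_that("curve averaging equals the per-depth arithmetic mean", {
  c1 <- toy_curve(c(100, 200, 400), c(2, 4, 6))
  c2 <- toy_curve(c(100, 200, 400), c(4, 6, 10))
  av <- average_curves(list(c1, c2))
  expect_equal(av$taxa_counts, c(3, 5, 8))
  expect_error(average_curves(list(c1, toy_curve(c(1, 2, 3), c(1, 1, 1)))),
               "same depth grid")
})

test_that("curve tables and fit summaries are written as TSV", {
  cu <- toy_curve(c(500, 1000, 2000, 4000), 2 * log(c(500, 1000, 2000, 4000)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cu, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 4L)
  fit <- read.delim(paste0(p, ".fit.tsv"))
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$doubling_gain_at_max_pct,
               doubling_gain(list(a = 2, b = 0), 4000), tolerance = 1e-9)
})
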