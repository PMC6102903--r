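test_that("quality filter applies inclusive length and mean-Q thresholds", {
  reads <- seq_records(
    c("short", "ok", "q20", "q19"),
    c(rand_seq(49), rand_seq(50), rand_seq(50), rand_seq(50)),
    qual = c(phred_string(rep(30L, 49)), phred_string(rep(30L, 50)),
             phred_string(rep(20L, 50)), phred_string(rep(19L, 50))))
  qf <- quality_filter(reads, 50L, 20)
  expect_equal(qf$kept$id, c("ok", "q20"))  # boundaries are inclusive
  expect_equal(qf$n_removed, 2L)

  # independent one-line recount on a larger synthetic set
  set.seed(10)
  n <- 300
  lens <- sample(40:160, n, TRUE)
  reads2 <- seq_records(sprintf("r%03d", 1:n),
                        vapply(lens, rand_seq, ""),
                        qual = vapply(lens, function(L)
                          phred_string(sample(5:40, L, TRUE)), ""))
  qf2 <- quality_filter(reads2, 50L, 20)
  oracle <- sum(lens >= 50 &
                  vapply(reads2$qual,
                         function(q) mean(utf8ToInt(q) - 33) >= 20, TRUE))
  expect_equal(nrow(qf2$kept), oracle)

  noq <- seq_records("nq", rand_seq(60))
  expect_warning(qf3 <- quality_filter(noq, 50L, 20), "lack qualities")
  expect_equal(nrow(qf3$kept), 1L)
})

test_that("subsampling is uniform, seeded and order-preserving", {
  reads <- seq_records(sprintf("r%02d", 1:10),
                       replicate(10, rand_seq(60)))
  expect_equal(subsample_reads(reads, 10L, 1L), reads)
  expect_equal(subsample_reads(reads, 3L, 7L), subsample_reads(reads, 3L, 7L))
  expect_error(subsample_reads(reads, 11L, 1L), "10")
  s <- subsample_reads(reads, 5L, 3L)
  expect_equal(s$id, sort(s$id))  # pool order preserved (ids are sorted)
  # selection frequency ~ Binomial(n_rep, 3/10), 4-sigma band
  n_rep <- 2000
  counts <- integer(10)
  for (r in seq_len(n_rep)) {
    sel <- subsample_reads(reads, 3L, 1000L + r)$id
    counts[match(sel, reads$id)] <- counts[match(sel, reads$id)] + 1L
  }
  freq <- counts / n_rep
  tol <- 4 * sqrt(0.3 * 0.7 / n_rep)
  expect_true(all(abs(freq - 0.3) < tol))
})

test_that("iterative classification gives the highest-priority tier precedence", {
  set.seed(11)
  shared <- rand_seq(400)  # present in both viral and bacterial tiers
  bact_only <- rand_seq(400)
  vt <- reference_tier("viral", 1L,
                       nt_entries("V1", shared, "viral", "Myoviridae", "",
                                  "Escherichia virus T4s"))
  bt <- reference_tier("bacterial", 2L, rbind(
    nt_entries("B1", shared, "bacterial", "", "Escherichia",
               "Escherichia coli s"),
    nt_entries("B2", bact_only, "bacterial", "", "Salmonella",
               "Salmonella enterica s")))
  reads <- seq_records(c("both", "bonly"),
                       c(substr(shared, 50, 200),
                         substr(bact_only, 50, 200)))
  cls <- classify_reads(reads, list(vt, bt))
  # passing hits in both tiers: the viral tier wins
  expect_equal(cls$tier_name, c("viral", "bacterial"))
  expect_equal(cls$family[1], "Myoviridae")
  expect_equal(cls$species[1], "Escherichia virus T4s")
  # cellular assignment populates genus + species, not family
  expect_equal(cls$genus[2], "Salmonella")
  expect_equal(cls$family[2], "")

  # priority monotonicity: growing a lower tier never changes reads
  # already assigned by a higher tier
  for (rep in 1:5) {
    extra <- nt_entries(sprintf("B9%d", rep),
                        mutate_sequence(shared, 0.02, rep),
                        "bacterial", "", "Klebsiella", "K sp")
    bt2 <- reference_tier("bacterial", 2L, rbind(bt$entries, extra))
    cls2 <- classify_reads(reads, list(vt, bt2))
    expect_equal(cls2$tier_name[1], "viral")
    expect_equal(cls2$species[1], cls$species[1])
  }
  expect_error(classify_reads(reads, list()), "empty tier list")
})

test_that("classification conserves reads and recovers truth exactly at zero error", {
  spec <- demo_community(seed = 21L, error_rate = 0)
  tiers <- make_reference_tiers(spec)
  sim <- simulate_reads(spec, 400L, seed = 22L)
  cls <- classify_reads(sim$reads, tiers)
  expect_equal(nrow(cls), 400L)  # classified + unclassified == input
  expect_true(all(cls$tier_name != "unclassified"))
  truth_species <- spec$lineages$species[match(sim$truth$source,
                                               spec$lineages$label)]
  expect_equal(cls$species, truth_species)
  # species-level profile equals the true read-origin table
  pr <- profile_taxa(cls, "species")
  expect_equal(pr$counts[sort(unique(truth_species))],
               stats::setNames(as.integer(table(truth_species)),
                               sort(unique(truth_species))))
  expect_equal(sum(pr$relative_abundance), 100, tolerance = 1e-9)
})

test_that("profiles aggregate counts with unclassified outside the denominator", {
  cls <- data.frame(read_id = sprintf("r%d", 1:6),
                    tier_name = c(rep("viral", 4), "unclassified",
                                  "unclassified"),
                    realm = c(rep("viral", 4), "", ""),
                    family = c("A", "A", "A", "B", "", ""),
                    genus = "", species = "", stringsAsFactors = FALSE)
  pr <- profile_taxa(cls, "family")
  expect_equal(unname(pr$counts[c("A", "B")]), c(3L, 1L))
  expect_equal(unname(pr$relative_abundance[c("A", "B")]), c(75, 25))
  expect_equal(pr$unclassified_count, 2L)

  all_un <- cls; all_un$tier_name <- "unclassified"; all_un$family <- ""
  all_un$realm <- ""
  pr0 <- profile_taxa(all_un, "family")
  expect_equal(length(pr0$counts), 0L)
  expect_equal(pr0$unclassified_count, 6L)
})

test_that("shared-taxa rule is strictly greater-than in both profiles", {
  mk <- function(ab) {
    counts <- stats::setNames(as.integer(round(ab * 1e6)), names(ab))
    structure(list(rank = "species", counts = counts,
                   total_classified = sum(counts),
                   relative_abundance = 100 * counts / sum(counts),
                   unclassified_count = 0L),
              class = "taxonomic_profile")
  }
  # A sits exactly at 0.01% in profile b -> excluded by strict >
  a <- mk(c(A = 0.0002, B = 0.5, C = 0.4998))
  b <- mk(c(A = 0.0001, B = 0.3, C = 0.6999))
  expect_equal(shared_taxa(a, b), c("B", "C"))
  # both above the floor -> shared
  a2 <- mk(c(A = 0.0002, Z = 0.9998))
  b2 <- mk(c(A = 0.0003, Z = 0.9997))
  expect_equal(shared_taxa(a2, b2), c("A", "Z"))
  # disjoint profiles
  expect_equal(shared_taxa(mk(c(X = 1)), mk(c(Y = 1))), character(0))
})

test_that("depth adequacy reproduces the sham-control arithmetic", {
  expect_equal(depth_adequacy(46269, 1000000), 4.6)
  expect_equal(depth_adequacy(0, 1e6), 0)
  expect_equal(depth_adequacy(1e6, 1e6), 100)
  expect_error(depth_adequacy(10, 0), "target_depth")
})
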