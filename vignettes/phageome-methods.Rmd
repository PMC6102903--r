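---
title: "Methods: read- and assembly-based phageome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read- and assembly-based phageome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageome)
```

# The analytical model

Shotgun sequencing of a virus-like-particle (VLP) enriched stool sample
yields a read pool that mixes phage DNA with residual bacterial,
archaeal and eukaryotic DNA, plus reagent contamination. `phageome`
implements a read-first, assembly-second analysis of such data built
around four ideas:

1. **Iterative priority classification.** Each read is searched against
   an ordered cascade of reference tiers — by default viral, archaeal,
   bacterial, then a whole/eukaryote tier. A read with at least one
   passing hit in a tier is assigned that tier's best hit and lower
   tiers are never consulted for it. The viral-first order protects
   sensitivity for viruses and archaea: a prophage region present in a
   bacterial genome would otherwise absorb genuinely viral reads.
   Viruses are reported at family + species rank; cellular organisms at
   genus + species.

2. **ORF-vote contig taxonomy.** Contigs longer than 5000 nt (strict
   `>`) have their ORFs called, translated, and classified through the
   same cascade at protein level; the contig takes the most frequent
   taxonomy among its classified ORFs (viral-family / cellular-genus
   rank), with ties broken by summed best-hit score and then
   lexicographically. Shorter contigs are reported unclassified with an
   explicit reason, never silently dropped.

3. **The 99% identity rule.** Both contaminant scrubbing and
   mother-infant transmission mapping accept a read-to-contig alignment
   only at identity >= 99% covering >= 90% of the read. The threshold is
   inclusive by design: it admits reads identical to the backbone while
   tolerating the ~1% substitution error of short-read sequencing — a
   100 nt read with exactly one mismatch passes, with two it does not.

4. **Rarefaction for depth sizing.** Distinct viral taxon counts at
   increasing subsample depths are fitted with `y = a·ln(x) + b`; the
   doubling gain `100·a·ln(2) / y(x)` quantifies how little richness
   another doubling of sequencing would buy, and coverage fractions
   report the share of full-pool richness recovered at a given depth.

# The homology engine

All homology steps run through one built-in engine so every module sees
the same hit contract (`query_id, subject_accession, percent_identity,
alignment_length, ..., query_coverage, tier_name`). The engine is a
deterministic seed-and-extend local aligner:

* exact k-mer seeds (k = 11 nucleotide, 4 protein) against a
  plus-strand-only index; minus-strand hits come from searching the
  reverse-complemented query, with coordinates mapped back to the
  forward query and `subject_start > subject_end` marking the strand;
* seeds sharing a reference entry are clustered by diagonal and each
  cluster is extended with a banded (band 15) affine-gap Smith-Waterman
  under unit scores (match +1, mismatch −1, gap of length L scores
  −5 − 2L);
* percent identity is `100 · matches / alignment columns`, gap columns
  counting as non-matches;
* ties are broken everywhere by score desc → e-value proxy asc →
  accession asc, so identical inputs give byte-identical outputs.

The e-value proxy `N_db · L_query · 2^(−score/2)` is an explicit,
uncalibrated screening statistic — not a Karlin-Altschul e-value — and
every cutoff is a configuration key. Under unit scoring a short exact
protein hit carries far fewer bits than a same-length nucleotide hit,
so the default cutoffs differ by alphabet: nucleotide searches use
minimum alignment length 30 and proxy cutoff 1e-5, protein searches 15
and 0.05. The test suite bounds the engine against a full
Smith-Waterman oracle (computed with an independent dynamic-programming
implementation): on random pairs the engine's score never exceeds the
optimum and equals it whenever an exact seed lies on the optimal path.
Externally computed hit tables in the 12/14-column tabular dialect can
be imported in place of the built-in engine.

The ORF caller is a stop-to-stop six-frame scanner (starts ATG/GTG/TTG,
longest ORF per stop, codons containing N never start/stop and
translate to X). It is a deliberate stand-in for a trained gene finder,
chosen because downstream contracts only need coordinates, strands and
translations; it is cross-checked against an independently written
six-frame oracle.

# Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| tier order | viral, archaeal, bacterial, whole | — | viral-first sensitivity |
| `min_identity` (scrub/mapping) | 99 | % | tolerate 1% sequencing error, nothing more |
| `min_read_cov` | 90 | % of read | a short seed must not delete a read |
| contig gate | 5000 (strict >) | nt | classification below this is vote-starved |
| `min_len_aa` | 60 | aa | suppress random-ORF noise |
| shared-taxa floor | 0.01 (strict >) | % abundance | excludes single-read noise taxa |
| word size | 11 nt / 4 aa | — | sensitivity/speed balance |
| `min_samples` (contaminant cluster) | 2 | samples | any cross-sample recurrence is suspect |
| `min_modules` (novel phage) | 3 | modules | one stray tail gene is not a phage |
| `max_mismatches` (spacers) | 1 | subst. | spacers are short; indels not allowed |
| rarefaction replicates | 3 | — | statistical honesty of curve means |

Related samples (e.g. a mother-infant pair) must never be cross-checked
for contaminants against each other: shared sequence within such a pair
is the transmission signal, while sequence shared across *unrelated*
samples is the contamination signal. The pipeline preset therefore runs
decontamination before transmission detection.

# The synthetic-data generators

Fixtures emulate the statistical structure the analyses assume:
multi-genome communities with log-normal (sdlog 1) abundance skew;
phage genomes with module-ordered genes (replication, packaging, head,
tail, lysis, lysogeny) separated by spacers carrying stop codons in all
six frames, so gene coordinates are recovered exactly; 150 nt reads
with i.i.d. substitutions at 1% and constant Q30 qualities;
mother-infant pairs whose shared phage copies differ by a configurable
per-base divergence (default 0.5%, i.e. 99.5% identity); and
contaminant spiking at a fixed read fraction with between-sample copy
divergence.

Two generator choices deserve explanation. First, spiked contaminant
reads are drawn error-free from their sample's own contaminant copy:
scrubbing in practice runs against contigs assembled from the same
datasets, and assembly consensus removes per-read error. With 1%
per-read error on top of a 0.5%-diverged backbone, a >= 99% cut-off
would pass only ~56% of 150 nt reads (binomially), confounding the
threshold property under test; read error's interaction with the
threshold is exercised separately by the one-vs-two-mismatch boundary
checks. Second, for the same binomial reason, a mother read with 1%
error maps to a 99.5%-identity shared contig with probability ~0.33 per
read — transmission detection is still exact because a shared 7 kb
contig attracts hundreds of candidate reads while disjoint contigs
attract none; tests assert the binomially correct per-read rate rather
than an unattainable one.

What the fixtures do **not** model: indels, PCR duplicates, quality
degradation along the read, ssDNA/MDA amplification bias, strain-level
mosaicism, and real assembler behavior (a documented mock assembler
emits a genome iff its mean read coverage reaches 5x; real assemblers
plug in through the same adapter). Passing tests therefore demonstrate
the correctness of the decision rules and their boundaries, not
end-to-end performance on real viromes.

# Numerical and design choices

* Internal coordinates are 0-based half-open; GenBank output and
  tabular hit files keep their native 1-based inclusive conventions,
  with minus-strand features in `complement(a..b)` notation.
* Taxonomy is a separate TSV (`accession, realm, family, genus,
  species`) rather than parsed from organism names; unknown ranks print
  as `Unclassified__<nearest-known>`.
* Contig votes are realm-qualified before counting so that identical
  labels from different realms cannot collide; species is reported only
  when consistent with the winning upper rank.
* A read counts toward at most one mapping backbone (best score, then
  accession) so per-contig read counts partition the mapped reads.
* Read-mode rarefaction classifies the full pool once and subsamples
  the classifications. Per-read classification does not depend on which
  other reads are present, so this is exactly equivalent to
  classify-after-subsample at a fraction of the cost; replicate r of
  any depth uses derived seed `seed + r − 1`.
* Merging reference databases is a non-redundant union on accessions
  (e.g. a 7485-entry curated tier plus 5530 unique archival additions
  totals 13,015 entries).
* GenBank LOCUS lines carry a fixed date so pipeline reruns are
  byte-identical.
* Test and acceptance problem sizes (hundreds to tens of thousands of
  reads, genomes of 3-12 kb, databases of a few hundred kb) were chosen
  as the smallest scales at which every statistical contract is
  informative; all thresholds hold unchanged at larger scales.

# Worked example

```{r example}
g <- data.frame(
  label   = c("phageA", "phageB", "bactA"),
  realm   = c("viral", "viral", "bacterial"),
  family  = c("Myoviridae", "Siphoviridae", ""),
  genus   = c("", "", "Escherichia"),
  species = c("Escherichia virus T4s", "Lactococcus phage Xs",
              "Escherichia coli s"),
  length  = c(8000L, 7000L, 12000L), gc = 0.45)
spec <- community_spec(g, read_length = 150, error_rate = 0.01, seed = 1)
tiers <- make_reference_tiers(spec)
sim <- simulate_reads(spec, 1000, seed = 2)
cls <- classify_reads(sim$reads, tiers)
profile_taxa(cls, "species")
```

```{r transmission}
pair <- make_pair(spec, shared = "phageA", infant_only = "phageB",
                  shared_identity = 99.5, n_mother = 2000,
                  n_infant = 2000, seed = 3)
detect_transmission(pair$infant_contigs, pair$classifications,
                    pair$mother_reads)
```

# Known limitations

* The engine trades heuristic acceleration for determinism; it is meant
  for desk-scale reference sets, not for full RefSeq.
* Read-based profiles cannot distinguish free phage from prophage; only
  upstream VLP enrichment can.
* Abundances are read-count based, uncorrected for genome length.
* The e-value proxy is not calibrated across scoring schemes; compare
  values only under one scheme.
* Low-abundance non-viral contamination that never assembles into
  contigs evades the cross-sample screen; sham controls (see
  `sham_report()`) remain essential for low-biomass samples.
```
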