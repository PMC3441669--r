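test_that("plant_hairpin builds the canonical duplex geometry", {
  hp <- plant_hairpin(FIX_MATURE, loop_len = 8)
  expect_equal(nchar(hp$precursor), 21 + 8 + 21)
  expect_equal(hp$mature_interval, c(1L, 21L))
  expect_equal(hp$star_interval, c(30L, 50L))
  # star core is the reverse complement of the mature minus its overhang
  star <- substr(hp$precursor, 30, 50)
  expect_equal(substr(star, 1, 19), revcomp(substr(FIX_MATURE, 1, 19)))
  # deterministic
  expect_identical(hp, plant_hairpin(FIX_MATURE, loop_len = 8))
  expect_error(plant_hairpin(strrep("A", 17)), "18")
  expect_error(plant_hairpin(FIX_MATURE, loop_len = 2), "loop_len")
})

test_that("an all-U mature yields a U:A stem with 19 pairs", {
  hp <- plant_hairpin(strrep("U", 21), loop_len = 8)
  f <- fold(hp$precursor)
  ev <- evaluate_candidate(f, hp$mature_interval,
                           mireap_params(max_precursor_mfe = -1))
  expect_gte(ev$duplex_pairs, 19)
})

test_that("GC-rich random matures fold below the precursor MFE ceiling", {
  set.seed(11)
  for (i in 1:100) {
    repeat {
      m <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
      if (nchar(gsub("[^GC]", "", m)) / 21 >= 0.4) break
    }
    hp <- plant_hairpin(m, 8)
    expect_lte(fold(hp$precursor)$mfe, -18)
  }
})

test_that("make_genome embeds features at their coordinates, both strands", {
  spec <- genome_spec(c(cA = 10000L), seed = 2)
  g0 <- make_genome(spec)
  expect_equal(nchar(g0$genome[["cA"]]), 10000)
  expect_equal(nrow(g0$truth), 0)
  expect_equal(length(g0$annotation), 0)

  feats <- rbind(
    planted_feature("mirna_hairpin", "cA", 1001, "+", mature_seq = FIX_MATURE),
    planted_feature("mirna_hairpin", "cA", 2001, "-", mature_seq = FIX_MATURE),
    planted_feature("rrna", "cA", 3001),
    planted_feature("sirna_locus", "cA", 4001))
  ds <- make_genome(spec, feats)
  expect_equal(nrow(ds$truth), 4)
  hp <- plant_hairpin(FIX_MATURE, 8)
  expect_equal(substr(ds$genome[["cA"]], 1001, 1050), hp$precursor)
  expect_equal(revcomp(substr(ds$genome[["cA"]], 2001, 2050)), hp$precursor)
  # re-extracting every interval reproduces the recorded sequence
  for (i in seq_len(nrow(ds$truth))) {
    s <- substr(ds$genome[[ds$truth$chrom[i]]], ds$truth$start[i], ds$truth$end[i])
    if (ds$truth$strand[i] == "-") s <- revcomp(s)
    expect_equal(s, ds$truth$seq[i])
  }
  # siRNA locus tags respect the 2-nt offset geometry
  si <- ds$truth[ds$truth$kind == "sirna_locus", ]
  expect_equal(nchar(si$tag_seq), 23)
  expect_equal(si$tag_seq_minus,
               revcomp(substr(ds$genome[["cA"]], si$start, si$end - 2)))
})

test_that("overlapping or out-of-bounds features are rejected", {
  spec <- genome_spec(c(cA = 2000L), seed = 1)
  expect_error(make_genome(spec, rbind(
    planted_feature("rrna", "cA", 100),
    planted_feature("trna", "cA", 150))), "overlap")
  expect_error(make_genome(spec, planted_feature("rrna", "cA", 1990)),
               "beyond")
  expect_error(make_genome(spec, planted_feature("rrna", "cZ", 100)),
               "unknown chromosome")
  expect_error(genome_spec(c(500)), "chromosome_lengths")
})

test_that("simulated libraries have exact totals and honest feature counts", {
  spec <- genome_spec(c(cA = 5000L), seed = 4)
  ds <- make_genome(spec, planted_feature(
    "mirna_hairpin", "cA", 1001, mature_seq = FIX_MATURE,
    base_tpm_plus = 1e5, base_tpm_minus = 4e5))
  sim <- read_sim_spec(10000, 10000, seed = 9)
  reads <- simulate_reads(ds, sim)
  expect_equal(nrow(reads$reads_plus), 10000)
  expect_equal(nrow(reads$reads_minus), 10000)
  # expected counts 1000 / 4000; binomial 4-sigma band
  for (lib in c("plus", "minus")) {
    k <- reads$truth[[paste0("count_", lib)]]
    mu <- c(plus = 1000, minus = 4000)[[lib]]
    expect_lt(abs(k - mu), 4 * sqrt(mu))
  }
  # every expressed mature appears as mature+adapter in the raw reads
  expect_true(any(startsWith(reads$reads_plus$seq,
                             paste0(as_dna(FIX_MATURE), substr(sim$adapter3, 1, 6)))))
})

test_that("a fixed seed reproduces the read files byte for byte", {
  spec <- genome_spec(c(cA = 3000L), seed = 6)
  ds <- make_genome(spec, planted_feature(
    "mirna_hairpin", "cA", 500, mature_seq = FIX_MATURE,
    base_tpm_plus = 5e4, base_tpm_minus = 5e4))
  sim <- read_sim_spec(800, 800, contaminant_fractions = c(polyA = 0.01),
                       seed = 13)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_reads(ds, sim, dir = d1)
  simulate_reads(ds, sim, dir = d2)
  for (f in c("reads_plus.fastq", "reads_minus.fastq"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("contaminant fractions are validated", {
  expect_error(read_sim_spec(10, 10, contaminant_fractions = c(bogus = 0.1)),
               "unknown contaminant")
  expect_error(read_sim_spec(10, 10, contaminant_fractions = c(
    polyA = 0.6, adaptor3_null = 0.5)))
})
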