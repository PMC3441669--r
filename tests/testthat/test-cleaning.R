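A3 <- "TCGTATGCCGTCTTCTGCTTG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

mk <- function(insert, pad = 36) substr(paste0(insert, A3, strrep("A", pad)), 1, pad)

test_that("the published +S accounting is reproduced by the report arithmetic", {
  s <- libstats_plus
  rep <- cleaning_report(
    total_reads = s$total, high_quality = s$high_quality,
    adaptor3_null = s$adaptor3_null, insert_null = s$insert_null,
    adaptor5_contaminants = s$adaptor5, smaller_than_18nt = s$smaller,
    polyA = s$polyA)
  expect_equal(rep$counters[["clean_reads"]], 10029992)
  expect_equal(rep$percentages[["clean_reads"]], 93.19)
})

test_that("supplying an inconsistent clean count is an error", {
  expect_error(cleaning_report(100, 100, adaptor3_null = 10, clean_reads = 91),
               "accounting violated")
})

test_that("each contaminant class is charged to the right counter, exactly", {
  reads <- c(rep(mk("GCGTGCATGCATGCATGCATA"), 20),           # clean 21-mer
             rep(mk(""), 4),                                  # insert null
             rep(paste0(A5, mk("GCGTGCATGCATGCATGCATA", 10)), 3),  # 5' contaminated
             rep(strrep("GA", 18), 5),                        # no 3' adapter
             rep(mk(strrep("A", 20)), 2),                     # polyA
             rep(mk("CGCGT"), 6))                             # < 18 nt
  res <- clean_reads(reads, A3, A5)
  ct <- res$report$counters
  expect_equal(unname(ct[c("adaptor3_null", "insert_null",
                           "adaptor5_contaminants", "smaller_than_18nt",
                           "polyA", "clean_reads")]),
               c(5, 4, 3, 6, 2, 20))
  expect_equal(ct[["high_quality"]], 40)
  expect_equal(nrow(res$tags), 1)
  expect_equal(res$tags$count, 20)
})

test_that("low-quality reads are removed before the high-quality baseline", {
  df <- data.frame(seq = c(mk("GCGTGCATGCATGCATGCATA"),
                           mk("GCGTGCATGCATGCATGCATA")),
                   qual = c(strrep("I", 36),
                            paste0(strrep("#", 22), strrep("I", 14))),
                   stringsAsFactors = FALSE)
  res <- clean_reads(df, A3, A5)
  expect_equal(res$report$counters[["total_reads"]], 2)
  expect_equal(res$report$counters[["high_quality"]], 1)
  expect_equal(res$report$counters[["clean_reads"]], 1)
})

test_that("empty input yields zeroed report and no tags", {
  res <- clean_reads(character(0), A3, A5)
  expect_equal(sum(res$report$counters), 0)
  expect_equal(nrow(res$tags), 0)
})

test_that("inserts longer than 30 nt are set aside, not truncated", {
  res <- clean_reads(substr(paste0(strrep("GCAT", 9), A3), 1, 50), A3, A5)
  expect_equal(res$report$counters[["over_30nt"]], 1)
  expect_equal(nrow(res$tags), 0)
})

test_that("conservation holds on random simulated libraries", {
  for (seed in 1:5) {
    ds <- make_genome(genome_spec(c(c1 = 2000), seed = seed))
    sim <- read_sim_spec(500, 500, contaminant_fractions = c(
      adaptor3_null = 0.05, insert_null = 0.02, polyA = 0.01,
      smaller_than_18nt = 0.1, adaptor5_contaminants = 0.03,
      low_quality = 0.04), seed = seed)
    reads <- simulate_reads(ds, sim)
    res <- clean_reads(reads$reads_plus[, c("seq", "qual")], sim$adapter3,
                       sim$adapter5)
    ct <- res$report$counters
    expect_equal(ct[["total_reads"]], 500)
    expect_equal(ct[["high_quality"]],
                 sum(ct[c("adaptor3_null", "insert_null",
                          "adaptor5_contaminants", "smaller_than_18nt",
                          "polyA", "over_30nt", "clean_reads")]))
    # generator truth: each removal class matches its planted count
    planted <- table(reads$reads_plus$class)
    for (cl in c("adaptor3_null", "insert_null", "adaptor5_contaminants",
                 "smaller_than_18nt", "polyA"))
      expect_equal(ct[[cl]], as.integer(planted[cl]), info = cl)
    expect_equal(ct[["total_reads"]] - ct[["high_quality"]],
                 as.integer(planted["low_quality"]))
    # collapsing preserves the clean read total
    expect_equal(sum(res$tags$count), ct[["clean_reads"]])
  }
})

test_that("length histogram sums match unique and total tag counts", {
  tags <- tag_table(c("GCGTGCATGCATGCATGCATA", "ACGTACGTACGTACGTACGTACG",
                      "ACGTACGTACGTACGTACGTACT"), count = c(5L, 2L, 3L))
  h <- length_histogram(tags)
  expect_equal(sum(h$unique), 3)
  expect_equal(sum(h$total), 10)
  expect_equal(h$total[h$length == 21], 5)
  expect_equal(h$unique[h$length == 23], 2)
  h0 <- length_histogram(tag_table(character(0), count = integer(0)))
  expect_true(all(h0$unique == 0) && all(h0$total == 0))
})

test_that("library overlap percentages follow the dual-denominator scheme", {
  a <- tag_table(c("A1", "A2", "S1"), count = c(1L, 1L, 98L))
  b <- tag_table(c("B1", "B2", "S1"), count = c(1L, 1L, 98L))
  names(a$sequence) <- NULL
  ov <- library_overlap(a, b)
  expect_equal(ov$total_pct[ov$component == "common"], 98)
  expect_equal(ov$unique_pct[ov$component == "common"], round(1 / 3 * 100, 2))
  # identical libraries are 100% common; disjoint are 0%
  expect_equal(library_overlap(a, a)$total_pct, c(100, 0, 0))
  expect_equal(library_overlap(a, tag_table("ZZ", count = 5L))$total_pct[1], 0)
})
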