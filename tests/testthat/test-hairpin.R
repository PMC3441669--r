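test_that("constructed hairpins are accepted with the expected duplex stats", {
  hp <- plant_hairpin(FIX_MATURE, loop_len = 8)
  f <- fold(hp$precursor)
  ev <- evaluate_candidate(f, hp$mature_interval)
  expect_true(ev$accepted)
  expect_length(ev$reasons, 0)
  expect_equal(ev$duplex_pairs, 19)
  expect_equal(ev$max_bulge, 0)
  expect_equal(ev$asymmetry, 0)
  expect_equal(ev$star_interval, hp$star_interval)
})

test_that("MFE threshold is inclusive: exactly -18 accepts, above rejects", {
  hp <- plant_hairpin(FIX_MATURE, loop_len = 8)
  f <- fold(hp$precursor)
  at <- evaluate_candidate(f, hp$mature_interval,
                           mireap_params(max_precursor_mfe = f$mfe))
  expect_true(at$accepted)
  above <- evaluate_candidate(f, hp$mature_interval,
                              mireap_params(max_precursor_mfe = f$mfe - 0.1))
  expect_false(above$accepted)
  expect_true("mfe" %in% above$reasons)
})

test_that("a mature with no pairing partner is rejected with reason no_star", {
  # mature region placed over unpairable poly-A: nothing to pair with
  seq <- paste0(strrep("A", 25), "GGGGGCCCCC", strrep("A", 10))
  f <- fold(seq)
  ev <- evaluate_candidate(f, c(1, 21))
  expect_false(ev$accepted)
  expect_true("no_star" %in% ev$reasons)
  expect_error(evaluate_candidate(f, c(40, 60)), "outside")
})

test_that("accepted candidates satisfy every predicate on independent recheck", {
  set.seed(55)
  p <- mireap_params()
  n_checked <- 0
  for (i in 1:30) {
    m <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    if (nchar(gsub("[^GC]", "", m)) / 21 < 0.4) next
    hp <- plant_hairpin(m, 8)
    f <- fold(hp$precursor)
    ev <- evaluate_candidate(f, hp$mature_interval, p)
    if (!ev$accepted) next
    n_checked <- n_checked + 1
    # recheck from the raw structure, independently of duplex_stats
    pt <- pair_table(f$structure)
    mpos <- hp$mature_interval[1]:hp$mature_interval[2]
    expect_lte(f$mfe, p$max_precursor_mfe)
    expect_gte(sum(pt[mpos] > 0), p$min_duplex_pairs)
    expect_equal(ev$duplex_pairs, sum(pt[mpos] > 0))
    partners <- pt[mpos][pt[mpos] > 0]
    expect_true(all(partners > max(mpos)) || all(partners < min(mpos)))
  }
  expect_gte(n_checked, 15)
})

test_that("candidate windows follow the flank/space arithmetic and clip", {
  p <- mireap_params()
  hit <- data.frame(chromosome = "c", start = 1000L, end = 1020L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- candidate_windows(hit, p, 5000L)
  expect_equal(w$start[w$role == "5p"], 980)
  expect_equal(w$end[w$role == "5p"], 1340)
  expect_equal(w$start[w$role == "3p"], 680)
  expect_equal(w$end[w$role == "3p"], 1040)
  hit$start <- 5L; hit$end <- 25L
  w2 <- candidate_windows(hit, p, 5000L)
  expect_true(all(w2$start >= 1))
})

test_that("planted hairpins are recovered and structural loci are not called", {
  spec <- genome_spec(c(cH = 40000L), gc_fraction = 0.6, seed = 17)
  set.seed(18)
  matures <- character(10)
  for (i in 1:10) {
    repeat {
      m <- random_dna(21, gc = 0.6)
      hp <- plant_hairpin(m, 8)
      if (nchar(gsub("[^GC]", "", m)) / 21 >= 0.4 &&
          evaluate_candidate(fold(hp$precursor), hp$mature_interval)$accepted)
        break
    }
    matures[i] <- m
  }
  feats <- do.call(rbind, c(
    lapply(1:10, function(i) planted_feature(
      "mirna_hairpin", "cH", 1500L * i, strand = if (i %% 2) "+" else "-",
      mature_seq = matures[i])),
    list(planted_feature("rrna", "cH", 30000L),
         planted_feature("trna", "cH", 32000L))))
  ds <- make_genome(spec, feats)
  tr <- ds$truth
  rr <- tr[tr$kind %in% c("rrna", "trna"), ]
  tags <- tag_table(c(matures, rr$tag_seq),
                    count_plus = rep(60L, 12), count_minus = rep(60L, 12))
  idx <- build_genome_index(ds$genome)
  ml <- map_library(idx, tags)
  db <- build_annotation_db(ds$annotation)
  cats <- annotate_tags(ml, db)$category
  expect_true(all(cats[11:12] %in% c("rRNA", "tRNA")))
  novel <- predict_novel(tags, ml, ds$genome, categories = cats)
  found <- as_dna(matures) %in% as_dna(novel$sequence)
  expect_gte(sum(found), 9)  # >= 90% recovery
  # structural loci never yield candidates
  expect_false(any(as_dna(rr$tag_seq) %in% as_dna(novel$sequence)))
  # reported precursor contains the mature at its genomic location
  for (r in seq_len(nrow(novel))) {
    loc <- strsplit(novel$location[r], ":")[[1]]
    s <- substr(ds$genome[[loc[1]]], as.integer(loc[2]), as.integer(loc[3]))
    if (loc[4] == "-") s <- revcomp(s)
    expect_true(grepl(as_dna(novel$sequence[r]), s, fixed = TRUE))
  }
})

test_that("tags with too many genomic copies are excluded", {
  unit <- "GCGTGCATGCATGCATGCATA"
  g <- c(cR = paste0(strrep("T", 1000),
                     paste(rep(paste0(unit, strrep("T", 30)), 25), collapse = ""),
                     strrep("T", 1000)))
  idx <- build_genome_index(g)
  tags <- tag_table(unit, count_plus = 50L, count_minus = 50L)
  ml <- map_library(idx, tags)
  expect_gt(nrow(ml$hits[[1]]), 20)
  novel <- predict_novel(tags, ml, g)
  expect_equal(nrow(novel), 0)
})

test_that("empty tag list yields an empty candidate table", {
  g <- tiny_genome(1000)
  tags <- tag_table(character(0), count_plus = integer(0),
                    count_minus = integer(0))
  ml <- map_library(build_genome_index(g), tags[0, , drop = FALSE])
  out <- predict_novel(tags, ml, g)
  expect_equal(nrow(out), 0)
  expect_true(all(c("name", "sequence", "location", "mfe") %in% names(out)))
})

test_that("known miRNA quantification matches mature and precursor exactly", {
  hp <- plant_hairpin(FIX_MATURE, 8)
  star_frag <- substr(hp$precursor, 31, 52)  # inside precursor only
  other <- "AAAACCCCGGGGTTTTAAAACC"
  tags <- tag_table(c(FIX_MATURE, star_frag, other),
                    count_plus = c(28L, 5L, 9L), count_minus = c(68L, 7L, 2L))
  q <- quantify_known(tags, mature = c(mirX = FIX_MATURE),
                      precursor = c(mirX = hp$precursor))
  expect_equal(q$count_plus[q$mirna == "mirX"], 33)
  expect_equal(q$count_minus[q$mirna == "mirX"], 75)
  expect_false(q$multi_assigned)
  # no matching tags -> zero counts
  q0 <- quantify_known(tags[3, , drop = FALSE], mature = c(mirX = FIX_MATURE))
  expect_equal(q0$count_plus, 0)
  # a tag inside two precursors is counted for both and flagged
  q2 <- quantify_known(tags, mature = c(a = FIX_MATURE),
                       precursor = c(b = hp$precursor))
  expect_equal(q2$count_plus[q2$mirna == "a"], 28)
  expect_equal(q2$count_plus[q2$mirna == "b"], 33)
  expect_true(all(q2$multi_assigned))
})
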