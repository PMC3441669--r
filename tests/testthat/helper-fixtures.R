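# Small in-code fixtures shared across tests.

# A well-behaved 21-nt mature: >=40% GC, and termini whose overhang bases
# leave an inert loop/filler base available, so the constructed hairpin
# folds into the intended 19-pair duplex exactly.
FIX_MATURE <- "GCGTGCATGCATGCATGCATA"

# tiny deterministic genome with one planted tag at a known locus
tiny_genome <- function(len = 3000, seed = 42) {
  spec <- genome_spec(c(chrT = max(len, 1000)), gc_fraction = 0.5, seed = seed)
  make_genome(spec)$genome
}

# collapsed tag table
tag_table <- function(seqs, count_plus = NULL, count_minus = NULL, count = NULL) {
  df <- data.frame(sequence = srnapipe::as_dna(seqs), stringsAsFactors = FALSE)
  if (!is.null(count)) df$count <- count
  if (!is.null(count_plus)) df$count_plus <- count_plus
  if (!is.null(count_minus)) df$count_minus <- count_minus
  df
}

# GRanges annotation fixture
anno_gr <- function(chrom, start, end, strand, category, tier = "genbank") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         category = category, tier = tier)
}

# published library-statistics counters (control / +S and treatment / -S)
libstats_plus <- list(total = 11284767, high_quality = 10762852,
                      adaptor3_null = 3304, insert_null = 2815,
                      adaptor5 = 63608, smaller = 663116, polyA = 17,
                      clean = 10029992)
libstats_minus <- list(total = 11080539, high_quality = 10572756,
                       adaptor3_null = 3499, insert_null = 3575,
                       adaptor5 = 58280, smaller = 588466, polyA = 6,
                       clean = 9918931)

# one shared end-to-end demo run, built lazily and reused across files
demo_cache <- new.env()
get_demo <- function() {
  if (is.null(demo_cache$demo)) {
    d <- file.path(tempdir(), "srnapipe-demo")
    demo_cache$demo <- demo_simulation(d, seed = 5, total_reads = 12000)
    demo_cache$res <- suppressMessages(run_all(demo_cache$demo$config))
  }
  list(demo = demo_cache$demo, res = demo_cache$res)
}

ref_known_table <- function() {
  p <- system.file("extdata", "known_mirna_sulfur_response.tsv",
                   package = "srnapipe")
  utils::read.delim(p, check.names = FALSE)
}

ref_novel_table <- function() {
  p <- system.file("extdata", "novel_mirna_sulfur_response.tsv",
                   package = "srnapipe")
  utils::read.delim(p, check.names = FALSE)
}
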