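# Pipeline orchestration: one configuration object drives
# clean -> map -> annotate -> siRNA -> predict -> diffexp, with every
# intermediate written to the output directory and a manifest recording
# parameters, so identical configurations reproduce identical outputs.

#' Pipeline configuration
#'
#' @param genome path to the genome FASTA (or a named character vector).
#' @param reads_plus,reads_minus paths to the +S (control) and -S
#'   (treatment) read files (FASTQ or collapsed FASTA).
#' @param annotation optional GFF3 of categorized intervals.
#' @param known_mature,known_precursor optional FASTA of known mature
#'   miRNA / precursor sequences.
#' @param adapter3,adapter5 adapter sequences.
#' @param quality_threshold Phred threshold of the low-quality filter.
#' @param map_k mapping seed length (default 18).
#' @param mireap list of [mireap_params()] overrides.
#' @param fc_threshold,p_threshold,specific_floor significance settings
#'   of [diff_table()].
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed drives simulation).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome, reads_plus, reads_minus,
                            annotation = NULL, known_mature = NULL,
                            known_precursor = NULL,
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            quality_threshold = 20, map_k = 18L,
                            mireap = list(), fc_threshold = 1,
                            p_threshold = 0.05, specific_floor = 10,
                            outdir = "srnapipe_out", seed = 1L) {
  structure(list(genome = genome, reads_plus = reads_plus,
                 reads_minus = reads_minus, annotation = annotation,
                 known_mature = known_mature,
                 known_precursor = known_precursor,
                 adapter3 = adapter3, adapter5 = adapter5,
                 quality_threshold = quality_threshold,
                 map_k = as.integer(map_k),
                 mireap = do.call(mireap_params, mireap),
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 specific_floor = specific_floor,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("genome", "reads_plus", "reads_minus", "annotation",
              "known_mature", "known_precursor")) {
    if (!is.null(y[[f]]) && !startsWith(y[[f]], "/"))
      y[[f]] <- file.path(base, y[[f]])
  }
  do.call(pipeline_config, y)
}

check_inputs <- function(config) {
  for (f in c("genome", "reads_plus", "reads_minus", "annotation",
              "known_mature", "known_precursor")) {
    p <- config[[f]]
    if (is.character(p) && length(p) == 1 && !is.null(p) &&
        f != "genome" && !file.exists(p))
      stop(sprintf("missing input file for '%s': %s", f, p), call. = FALSE)
  }
}

#' Run the full analysis
#'
#' Stages run in order: clean both libraries, map the merged tags,
#' annotate by the priority rule, detect siRNA duplexes, predict novel
#' miRNAs, quantify known miRNAs, and compute the differential expression
#' tables. Every intermediate is written under `config$outdir` together
#' with a `manifest.json` of parameters.
#'
#' @param config a [pipeline_config()].
#' @return the result bundle (list), invisibly; see the written files for
#'   the report formats.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_inputs(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  message("[clean] +S library")
  cl_p <- clean_reads(config$reads_plus, config$adapter3, config$adapter5,
                      quality_threshold = config$quality_threshold)
  message("[clean] -S library")
  cl_m <- clean_reads(config$reads_minus, config$adapter3, config$adapter5,
                      quality_threshold = config$quality_threshold)
  for (nm in c("plus", "minus")) {
    cl <- if (nm == "plus") cl_p else cl_m
    write_cleaning_report(cl$report, file.path(out, sprintf("cleaning_%s.tsv", nm)))
    write_collapsed_fasta(cl$tags, file.path(out, sprintf("tags_%s.fa", nm)))
    write_tsv_file(length_histogram(cl$tags),
                   file.path(out, sprintf("length_hist_%s.tsv", nm)))
  }
  write_tsv_file(library_overlap(cl_p$tags, cl_m$tags),
                 file.path(out, "library_overlap.tsv"))
  report_counters(cl_p$report, "+S")
  report_counters(cl_m$report, "-S")

  merged <- merge_libraries(cl_p$tags, cl_m$tags)
  genome <- load_genome(config$genome)
  message(sprintf("[map] %d unique tags against %d chromosome(s)",
                  nrow(merged), length(genome)))
  index <- build_genome_index(genome, k = config$map_k)
  ml <- map_library(index, merged)
  write_tsv_file(ml$tally, file.path(out, "mapping_tally.tsv"))

  db <- if (!is.null(config$annotation)) build_annotation_db(config$annotation)
        else build_annotation_db(empty_annotation())
  categories <- annotate_tags(ml, db)$category

  message("[sirna] duplex detection")
  pairs <- find_sirna_duplexes(merged, ml)
  categories <- assign_sirna(categories, merged, pairs)
  write_tsv_file(pairs, file.path(out, "sirna_pairs.tsv"))

  for (nm in c("plus", "minus")) {
    cc <- paste0("count_", nm)
    present <- merged[[cc]] > 0
    summ <- category_summary(merged[present, , drop = FALSE],
                             categories[present], count_col = cc)
    write_tsv_file(summ, file.path(out, sprintf("composition_%s.tsv", nm)))
    message(sprintf("[annotate] %s library: %d distinct tags, %d reads",
                    nm, sum(present), sum(merged[[cc]])))
  }

  message("[predict] novel miRNA candidates")
  novel <- predict_novel(merged, ml, genome, config$mireap, categories)
  write_tsv_file(novel, file.path(out, "novel_mirna.tsv"))

  known <- NULL
  N1 <- cl_p$report$counters[["clean_reads"]]
  N2 <- cl_m$report$counters[["clean_reads"]]
  diff_known <- NULL
  if (!is.null(config$known_mature)) {
    mat <- as.character(Biostrings::readDNAStringSet(config$known_mature))
    prec <- if (!is.null(config$known_precursor))
      as.character(Biostrings::readDNAStringSet(config$known_precursor)) else NULL
    known <- quantify_known(merged, mat, prec)
    write_tsv_file(known, file.path(out, "known_mirna_counts.tsv"))
    diff_known <- diff_table(
      stats::setNames(known$count_plus, known$mirna),
      stats::setNames(known$count_minus, known$mirna),
      N1 = N1, N2 = N2, fc_threshold = config$fc_threshold,
      p_threshold = config$p_threshold,
      specific_floor = config$specific_floor)
    write_diff_table(diff_known, file.path(out, "diff_known.tsv"))
  }
  diff_novel <- NULL
  if (nrow(novel) > 0 && all(c("count_plus", "count_minus") %in% names(novel))) {
    diff_novel <- diff_table(
      stats::setNames(novel$count_plus, novel$name),
      stats::setNames(novel$count_minus, novel$name),
      N1 = N1, N2 = N2, fc_threshold = config$fc_threshold,
      p_threshold = config$p_threshold,
      specific_floor = config$specific_floor)
    write_diff_table(diff_novel, file.path(out, "diff_novel.tsv"))
  }

  manifest <- list(
    package = "srnapipe",
    version = as.character(utils::packageVersion("srnapipe")),
    seed = config$seed,
    parameters = list(
      adapter3 = config$adapter3, adapter5 = config$adapter5,
      quality_threshold = config$quality_threshold, map_k = config$map_k,
      mireap = unclass(config$mireap), fc_threshold = config$fc_threshold,
      p_threshold = config$p_threshold,
      specific_floor = config$specific_floor))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cleaning = list(plus = cl_p, minus = cl_m),
                 tags = merged, hits = ml, categories = categories,
                 sirna = pairs, novel = novel, known = known,
                 diff_known = diff_known, diff_novel = diff_novel,
                 totals = c(N1 = N1, N2 = N2)))
}

report_counters <- function(report, label) {
  ct <- report$counters
  message(sprintf(
    "[clean] %s: total %d, high quality %d, clean %d (%.2f%%)",
    label, ct[["total_reads"]], ct[["high_quality"]], ct[["clean_reads"]],
    report$percentages[["clean_reads"]]))
}

#' Write a cleaning report as TSV with the standard row labels
#'
#' @param report a [cleaning_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  lab <- c(total_reads = "Total reads", high_quality = "High quality",
           adaptor3_null = "Adaptor3 null", insert_null = "Insert null",
           adaptor5_contaminants = "Adaptor5 contaminants",
           smaller_than_18nt = "Smaller than 18 nt", polyA = "PolyA",
           over_30nt = "Larger than 30 nt", clean_reads = "Clean reads")
  df <- data.frame(
    category = unname(lab[names(report$counters)]),
    reads = unname(report$counters),
    percent = c("", sprintf("%.2f%%", report$percentages)),
    stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Build and write the bundled demo dataset
#'
#' A three-chromosome toy genome carrying novel and known miRNA hairpins,
#' siRNA duplex loci, structural RNA genes, an exon, an intron and a
#' repeat, with condition-dependent abundances (several features induced
#' under sulfur deprivation, some -S-specific), plus simulated raw read
#' sets with every contaminant class.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param total_reads reads per library (default 50000).
#' @return list with the dataset (`genome`, `truth`, ...), the simulated
#'   reads, and a ready-to-run [pipeline_config()].
#' @export
demo_simulation <- function(dir, seed = 1L, total_reads = 50000L) {
  spec <- genome_spec(c(chrA = 60000L, chrB = 40000L, chrC = 30000L),
                      gc_fraction = 0.6, seed = seed)
  adapter3 <- read_sim_spec(0, 0)$adapter3
  # an expressed tag must not contain the adapter seed, or trimming would
  # shorten it: the leftmost seed in tag+adapter must sit right after the tag
  seed6 <- substr(adapter3, 1, 6)
  adapter_safe <- function(tag)
    regexpr(seed6, paste0(tag, seed6), fixed = TRUE) == nchar(tag) + 1L
  # sample matures until the constructed precursor is a bona fide hairpin
  # under the package's energy model (a planted miRNA must BE a miRNA)
  matures <- with_seed(seed + 1L, {
    out <- character(12)
    for (i in seq_along(out)) {
      repeat {
        m <- random_dna(21, gc = 0.6)
        gc <- nchar(gsub("[^GC]", "", m)) / 21
        if (gc < 0.4 || !adapter_safe(m)) next
        hp <- plant_hairpin(m, 8)
        if (evaluate_candidate(fold(hp$precursor), hp$mature_interval)$accepted)
          break
      }
      out[i] <- m
    }
    out
  })
  # background-derived tags (siRNA duplex strands, structural RNA
  # fragments) must be adapter-safe too: nudge each locus start along the
  # background until its expressed tags are clean
  bg <- make_genome(spec)$genome
  safe_start <- function(start0, tag_fn) {
    for (s in start0 + 0:500) {
      if (all(vapply(tag_fn(s), adapter_safe, logical(1)))) return(s)
    }
    start0
  }
  sirna_tags <- function(chrom) function(s)
    c(substr(bg[[chrom]], s + 2L, s + 24L),
      revcomp(substr(bg[[chrom]], s, s + 22L)))
  frag_tags <- function(chrom, strand) function(s) {
    t0 <- substr(bg[[chrom]], s, s + 23L)
    if (strand == "-") revcomp(t0) else t0
  }
  # expression design: features 1-6 induced under -S (fold 4), 7-9 equal,
  # 10-12 -S-specific; at the default library size every expressed
  # hairpin receives at least ~50 reads
  tpm_plus <- c(rep(1000, 6), rep(1500, 3), rep(0, 3))
  tpm_minus <- c(rep(4000, 6), rep(1500, 3), rep(2000, 3))
  feats <- list()
  for (i in seq_len(12)) {
    feats[[length(feats) + 1L]] <- planted_feature(
      "mirna_hairpin", "chrA", start = 2000L * i, strand = if (i %% 2) "+" else "-",
      mature_seq = matures[i], known = i %in% c(5, 6, 9),
      base_tpm_plus = tpm_plus[i], base_tpm_minus = tpm_minus[i])
  }
  for (i in seq_len(5)) {
    feats[[length(feats) + 1L]] <- planted_feature(
      "sirna_locus", "chrB",
      start = safe_start(3000L * i, sirna_tags("chrB")),
      length = 23L, base_tpm_plus = 500, base_tpm_minus = 500)
  }
  kinds <- c("rrna", "trna", "snrna", "snorna", "exon", "intron", "repeat")
  for (i in seq_along(kinds)) {
    feats[[length(feats) + 1L]] <- planted_feature(
      kinds[i], "chrC",
      start = safe_start(2500L * i, frag_tags("chrC", "+")),
      base_tpm_plus = 300, base_tpm_minus = 300)
  }
  features <- do.call(rbind, feats)
  ds <- make_genome(spec, features, dir = dir)
  sim <- read_sim_spec(
    total_reads_plus = total_reads, total_reads_minus = total_reads,
    contaminant_fractions = c(low_quality = 0.02, adaptor5_contaminants = 0.01,
                              adaptor3_null = 0.01, insert_null = 0.005,
                              polyA = 0.002, smaller_than_18nt = 0.05),
    seed = seed + 2L)
  reads <- simulate_reads(ds, sim, dir = dir)
  config <- pipeline_config(
    genome = file.path(dir, "genome.fa"),
    reads_plus = file.path(dir, "reads_plus.fastq"),
    reads_minus = file.path(dir, "reads_minus.fastq"),
    annotation = file.path(dir, "annotation.gff3"),
    known_mature = if (file.exists(file.path(dir, "known_mature.fa")))
      file.path(dir, "known_mature.fa") else NULL,
    outdir = file.path(dir, "results"), seed = seed)
  list(dataset = ds, reads = reads, config = config, sim = sim)
}

#' Configuration pointing at a simulated dataset directory
#'
#' @param dir a directory written by [demo_simulation()] /
#'   [write_genome_dataset()].
#' @param seed integer seed recorded in the manifest.
#' @return a [pipeline_config()] with results under `dir/results`.
#' @export
demo_config_from_dir <- function(dir, seed = 1L) {
  km <- file.path(dir, "known_mature.fa")
  pipeline_config(
    genome = file.path(dir, "genome.fa"),
    reads_plus = file.path(dir, "reads_plus.fastq"),
    reads_minus = file.path(dir, "reads_minus.fastq"),
    annotation = file.path(dir, "annotation.gff3"),
    known_mature = if (file.exists(km)) km else NULL,
    outdir = file.path(dir, "results"), seed = as.integer(seed))
}

#' Compare pipeline output against the generator's ground truth
#'
#' @param result a [run_all()] bundle.
#' @param truth truth table with simulated counts
#'   ([simulate_reads()]`$truth`).
#' @return list with `hairpin_recovery` (fraction of expressed planted
#'   novel hairpins recovered among the predicted matures),
#'   `sirna_recovery` (fraction of expressed planted duplex loci found),
#'   and the corresponding counts.
#' @export
compare_truth <- function(result, truth) {
  hp <- truth[truth$kind == "mirna_hairpin" & !truth$known &
                (truth$count_plus + truth$count_minus) > 0, , drop = FALSE]
  pred_mat <- as_dna(result$novel$sequence)
  hp_found <- as_dna(hp$tag_seq) %in% pred_mat
  si <- truth[truth$kind == "sirna_locus" &
                (truth$count_plus + truth$count_minus) > 0, , drop = FALSE]
  si_found <- logical(nrow(si))
  if (nrow(si) && nrow(result$sirna)) {
    key <- sprintf("%s:%d", result$sirna$chromosome, result$sirna$plus_start)
    si_found <- sprintf("%s:%d", si$chrom, si$start + 2L) %in% key
  }
  list(hairpin_recovery = if (nrow(hp)) mean(hp_found) else NA_real_,
       hairpins_expressed = nrow(hp), hairpins_found = sum(hp_found),
       sirna_recovery = if (nrow(si)) mean(si_found) else NA_real_,
       sirna_expressed = nrow(si), sirna_found = sum(si_found))
}
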