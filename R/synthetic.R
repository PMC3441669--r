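# Synthetic two-condition small RNA experiment: a toy genome with planted,
# ground-truthed loci (miRNA hairpins, siRNA duplexes, structural RNA genes,
# exons/introns, repeats) and simulated raw read sets carrying the adapter
# and contaminant classes the cleaning stage must remove.

#' Specification of a toy genome
#'
#' @param chromosome_lengths integer vector of chromosome lengths (each
#'   >= 1000); names become chromosome names (default `chr1`, `chr2`, ...).
#' @param gc_fraction background GC content in \[0, 1\].
#' @param seed integer seed for the background sequence.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(chromosome_lengths, gc_fraction = 0.5, seed = 1L) {
  stopifnot(all(chromosome_lengths >= 1000),
            gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  structure(list(chromosome_lengths = chromosome_lengths,
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

FEATURE_KINDS <- c("mirna_hairpin", "sirna_locus", "rrna", "trna", "snrna",
                   "snorna", "exon", "intron", "repeat")

DEFAULT_FEATURE_LENGTH <- c(rrna = 120L, trna = 80L, snrna = 100L,
                            snorna = 90L, exon = 200L, intron = 150L,
                            "repeat" = 100L)

#' Declare one feature to plant in the toy genome
#'
#' For `mirna_hairpin` the precursor is built from `mature_seq` by
#' [plant_hairpin()] and its length determines `end`. For `sirna_locus`
#' the interval covers a duplex whose two strands overhang each other by
#' 2 nt at their 3' ends (`length` is the strand length, 22-24). All other
#' kinds annotate a stretch of background sequence of the given `length`.
#'
#' @param kind one of `r paste(FEATURE_KINDS, collapse = ", ")`.
#' @param chrom chromosome name.
#' @param start 1-based start coordinate.
#' @param strand `"+"` or `"-"`.
#' @param length feature length in nt (ignored for `mirna_hairpin`).
#' @param mature_seq mature miRNA sequence, 18-25 nt (`mirna_hairpin` only).
#' @param loop_len hairpin loop length (`mirna_hairpin` only).
#' @param known logical; a known (annotated) miRNA rather than a novel one.
#' @param base_tpm_plus,base_tpm_minus expected abundance, reads per
#'   million, in the +S (control) and -S (treatment) libraries.
#' @return one-row data.frame; rbind rows to form a feature table.
#' @export
planted_feature <- function(kind, chrom, start, strand = "+", length = NULL,
                            mature_seq = NA_character_, loop_len = 8L,
                            known = FALSE,
                            base_tpm_plus = 0, base_tpm_minus = 0) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(start >= 1, strand %in% c("+", "-"),
            base_tpm_plus >= 0, base_tpm_minus >= 0)
  if (kind == "mirna_hairpin") {
    if (is.na(mature_seq) || !nchar(mature_seq) %in% 18:25)
      stop("mirna_hairpin requires a mature_seq of 18-25 nt", call. = FALSE)
    length <- 0L  # resolved by make_genome from the built precursor
  } else if (kind == "sirna_locus") {
    if (is.null(length)) length <- 23L
    if (!length %in% 22:24)
      stop("sirna_locus strand length must be 22-24 nt", call. = FALSE)
  } else if (is.null(length)) {
    length <- DEFAULT_FEATURE_LENGTH[[kind]]
  }
  data.frame(kind = kind, chrom = chrom, start = as.integer(start),
             length = as.integer(length), strand = strand,
             mature_seq = if (is.na(mature_seq)) NA_character_ else as_dna(mature_seq),
             loop_len = as.integer(loop_len), known = known,
             base_tpm_plus = base_tpm_plus, base_tpm_minus = base_tpm_minus,
             stringsAsFactors = FALSE)
}

#' Build a hairpin precursor around a mature miRNA
#'
#' Constructs `mature + loop + star` where the star arm is the reverse
#' complement of the mature offset so that the mature/star duplex carries a
#' 2-nt 3' overhang on each strand (the canonical Dicer product geometry).
#' For a mature of length L the duplex has L - `overhang` Watson-Crick
#' pairs. Loop and overhang filler bases are chosen from A/C so they cannot
#' pair with each other, and are picked to avoid pairing with the bases
#' flanking the loop where the alphabet permits. Deterministic.
#'
#' @param mature_seq mature sequence, 18-25 nt.
#' @param loop_len loop length, >= 3 (default 8).
#' @param overhang 3' overhang in nt (default 2).
#' @return list with `precursor` (DNA alphabet), `mature_interval` and
#'   `star_interval` (1-based inclusive positions within the precursor).
#' @export
plant_hairpin <- function(mature_seq, loop_len = 8L, overhang = 2L) {
  m <- as_dna(mature_seq)
  L <- nchar(m)
  if (!L %in% 18:25) stop("mature length must be in [18, 25]", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  bases <- strsplit(m, "")[[1]]

  # a filler base that cannot pair (WC or GU wobble) with any of `avoid`
  safe_base <- function(avoid) {
    partners <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
    for (b in c("A", "C", "G", "T"))
      if (!any(avoid %in% partners[[b]])) return(b)
    "A"
  }
  loop_base <- safe_base(bases[(L - overhang + 1):L])
  loop <- strrep(loop_base, loop_len)
  star_core <- revcomp(substr(m, 1, L - overhang))
  tail_base <- safe_base(bases[1:overhang])
  star <- paste0(star_core, strrep(tail_base, overhang))
  precursor <- paste0(m, loop, star)
  list(precursor = precursor,
       mature_interval = c(1L, L),
       star_interval = c(L + loop_len + 1L, L + loop_len + nchar(star)))
}

#' Assemble the toy genome and its ground-truth table
#'
#' Generates random background chromosomes, embeds every planted feature's
#' sequence at its coordinates on its strand (miRNA precursors are built by
#' [plant_hairpin()]; other kinds annotate background sequence), and
#' records the full ground truth. Features must not overlap.
#'
#' @param spec a [genome_spec()].
#' @param features data.frame of [planted_feature()] rows (may be empty).
#' @param dir optional output directory; if given, writes `genome.fa`,
#'   `annotation.gff3`, `known_mature.fa` and `truth.tsv`.
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `truth` (data.frame, one row per feature with resolved
#'   coordinates, sequences and simulated tag sequences) and `annotation`
#'   (a `GRanges` of the non-novel-miRNA features with a `category`
#'   metadata column).
#' @export
make_genome <- function(spec, features = NULL, dir = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  genome <- with_seed(spec$seed, {
    vapply(spec$chromosome_lengths, random_dna, "", gc = spec$gc_fraction)
  })

  if (is.null(features) || nrow(features) == 0) {
    truth <- empty_truth()
  } else {
    truth <- resolve_features(features, genome)
    # embed sequences that carry their own construction (miRNA precursors)
    for (i in which(truth$kind == "mirna_hairpin")) {
      s <- truth$seq[i]
      emb <- if (truth$strand[i] == "+") s else revcomp(s)
      substr(genome[[truth$chrom[i]]], truth$start[i], truth$end[i]) <- emb
    }
    # background-derived sequences are extracted after embedding
    truth <- extract_truth_seqs(truth, genome)
  }

  anno <- truth_annotation(truth, spec$chromosome_lengths)
  ds <- list(genome = genome, truth = truth, annotation = anno,
             chromosome_lengths = spec$chromosome_lengths)
  if (!is.null(dir)) write_genome_dataset(ds, dir)
  ds
}

empty_truth <- function() {
  data.frame(kind = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), seq = character(),
             tag_seq = character(), tag_seq_minus = character(),
             mature_start = integer(), mature_end = integer(),
             star_start = integer(), star_end = integer(),
             known = logical(), base_tpm_plus = numeric(),
             base_tpm_minus = numeric(), stringsAsFactors = FALSE)
}

resolve_features <- function(features, genome) {
  n <- nrow(features)
  truth <- empty_truth()[rep(1, 0), ]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- features[i, ]
    row <- list(kind = f$kind, chrom = f$chrom, start = f$start,
                strand = f$strand, seq = NA_character_,
                tag_seq = NA_character_, tag_seq_minus = NA_character_,
                mature_start = NA_integer_, mature_end = NA_integer_,
                star_start = NA_integer_, star_end = NA_integer_,
                known = f$known, base_tpm_plus = f$base_tpm_plus,
                base_tpm_minus = f$base_tpm_minus)
    if (f$kind == "mirna_hairpin") {
      hp <- plant_hairpin(f$mature_seq, f$loop_len)
      row$seq <- hp$precursor
      row$end <- f$start + nchar(hp$precursor) - 1L
      mi <- hp$mature_interval
      if (f$strand == "+") {
        row$mature_start <- f$start + mi[1] - 1L
        row$mature_end <- f$start + mi[2] - 1L
        row$star_start <- f$start + hp$star_interval[1] - 1L
        row$star_end <- f$start + hp$star_interval[2] - 1L
      } else {
        row$mature_start <- row$end - mi[2] + 1L
        row$mature_end <- row$end - mi[1] + 1L
        row$star_start <- row$end - hp$star_interval[2] + 1L
        row$star_end <- row$end - hp$star_interval[1] + 1L
      }
      row$tag_seq <- as_dna(f$mature_seq)
    } else if (f$kind == "sirna_locus") {
      # plus tag on [start+2, start+length+1], minus tag on [start, start+length-1]
      row$end <- f$start + f$length + 1L
    } else {
      row$end <- f$start + f$length - 1L
    }
    if (!row$chrom %in% names(genome))
      stop(sprintf("feature %d: unknown chromosome '%s'", i, row$chrom), call. = FALSE)
    if (row$end > nchar(genome[[row$chrom]]))
      stop(sprintf("feature %d extends beyond the end of %s", i, row$chrom),
           call. = FALSE)
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  # overlap check, per chromosome
  for (ch in unique(truth$chrom)) {
    t <- truth[truth$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1 && any(t$start[-1] <= t$end[-nrow(t)]))
      stop(sprintf("planted features overlap on %s", ch), call. = FALSE)
  }
  truth
}

extract_slice <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start, end)
  if (strand == "-") revcomp(s) else s
}

extract_truth_seqs <- function(truth, genome) {
  for (i in seq_len(nrow(truth))) {
    if (is.na(truth$seq[i]))
      truth$seq[i] <- extract_slice(genome, truth$chrom[i], truth$start[i],
                                    truth$end[i], truth$strand[i])
    if (truth$kind[i] == "sirna_locus") {
      a <- truth$start[i]; b <- truth$end[i]
      truth$tag_seq[i] <- extract_slice(genome, truth$chrom[i], a + 2L, b, "+")
      truth$tag_seq_minus[i] <- extract_slice(genome, truth$chrom[i], a, b - 2L, "-")
    } else if (is.na(truth$tag_seq[i])) {
      # a representative expressed fragment of the locus, on its strand
      w <- min(24L, truth$end[i] - truth$start[i] + 1L)
      truth$tag_seq[i] <- extract_slice(genome, truth$chrom[i], truth$start[i],
                                        truth$start[i] + w - 1L, truth$strand[i])
    }
  }
  truth
}

KIND_CATEGORY <- c(rrna = "rRNA", trna = "tRNA", snrna = "snRNA",
                   snorna = "snoRNA", exon = "exon", intron = "intron",
                   "repeat" = "repeat", mirna_hairpin = "miRNA")

truth_annotation <- function(truth, chrom_lengths) {
  keep <- truth$kind %in% names(KIND_CATEGORY) &
    !(truth$kind == "mirna_hairpin" & !truth$known)
  t <- truth[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(t)) t$chrom else character(),
    ranges = IRanges::IRanges(start = t$start, end = t$end),
    strand = if (nrow(t)) t$strand else character(),
    category = if (nrow(t)) unname(KIND_CATEGORY[t$kind]) else character(),
    tier = if (nrow(t)) rep("genbank", nrow(t)) else character(),
    seqlengths = chrom_lengths)
  gr
}

#' Write a synthetic genome dataset to disk
#'
#' @param ds result of [make_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome),
                              file.path(dir, "genome.fa"))
  gr <- ds$annotation
  if (length(gr)) {
    S4Vectors::mcols(gr)$type <- S4Vectors::mcols(gr)$category
    S4Vectors::mcols(gr)$source <- S4Vectors::mcols(gr)$tier
  }
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  known <- ds$truth[ds$truth$kind == "mirna_hairpin" & ds$truth$known, , drop = FALSE]
  mt <- known$tag_seq
  names(mt) <- sprintf("known-mir-%d", seq_len(nrow(known)))
  if (nrow(known))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(mt),
                                file.path(dir, "known_mature.fa"))
  write_tsv_file(ds$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Specification of a simulated read set
#'
#' Contaminant fractions use the accounting vocabulary of the cleaning
#' report: `low_quality`, `adaptor5_contaminants`, `adaptor3_null`,
#' `insert_null`, `polyA`, `smaller_than_18nt`. Fractions are of total
#' reads and must sum to < 1; per-class read counts are `round(fraction *
#' total)` so the generator's truth is exact.
#'
#' @param total_reads_plus,total_reads_minus library sizes.
#' @param adapter3,adapter5 adapter sequences.
#' @param contaminant_fractions named numeric vector (missing classes are 0).
#' @param seed integer seed.
#' @param read_length raw read length (default 36).
#' @return a `read_sim_spec` list.
#' @export
read_sim_spec <- function(total_reads_plus, total_reads_minus,
                          adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                          adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                          contaminant_fractions = c(),
                          seed = 1L, read_length = 36L) {
  classes <- c("low_quality", "adaptor5_contaminants", "adaptor3_null",
               "insert_null", "polyA", "smaller_than_18nt")
  cf <- stats::setNames(numeric(length(classes)), classes)
  if (length(contaminant_fractions)) {
    bad <- setdiff(names(contaminant_fractions), classes)
    if (length(bad)) stop("unknown contaminant class: ", bad[1], call. = FALSE)
    cf[names(contaminant_fractions)] <- contaminant_fractions
  }
  stopifnot(all(cf >= 0), all(cf <= 1), sum(cf) < 1,
            total_reads_plus >= 0, total_reads_minus >= 0,
            nchar(adapter3) >= 6, nchar(adapter5) >= 6)
  structure(list(total_reads_plus = as.integer(total_reads_plus),
                 total_reads_minus = as.integer(total_reads_minus),
                 adapter3 = as_dna(adapter3), adapter5 = as_dna(adapter5),
                 contaminant_fractions = cf, seed = as.integer(seed),
                 read_length = as.integer(read_length)),
            class = "read_sim_spec")
}

#' Simulate two-condition raw small RNA read sets
#'
#' Clean-class reads are feature tag sequences with the 3' adapter
#' appended; contaminant reads are generated per class (see
#' [read_sim_spec()]). Per-feature counts are drawn multinomially with
#' expectation `base_tpm * total / 1e6`; the remaining clean reads are
#' random genomic background fragments. The number of reads per library
#' equals the requested total exactly, and a fixed seed reproduces the
#' same reads byte for byte.
#'
#' @param ds result of [make_genome()].
#' @param sim a [read_sim_spec()].
#' @param dir optional output directory; if given, writes
#'   `reads_plus.fastq` / `reads_minus.fastq`.
#' @return list with per-library read tables (`reads_plus`, `reads_minus`:
#'   data.frames of id, seq, qual, class, feature) and `truth`: the genome
#'   truth table with sampled `count_plus` / `count_minus` columns.
#' @export
simulate_reads <- function(ds, sim, dir = NULL) {
  stopifnot(inherits(sim, "read_sim_spec"))
  truth <- ds$truth
  out <- with_seed(sim$seed, {
    plus <- simulate_library(ds, sim, sim$total_reads_plus, truth$base_tpm_plus, "p")
    minus <- simulate_library(ds, sim, sim$total_reads_minus, truth$base_tpm_minus, "m")
    list(plus = plus, minus = minus)
  })
  truth$count_plus <- out$plus$feature_counts
  truth$count_minus <- out$minus$feature_counts
  res <- list(reads_plus = out$plus$reads, reads_minus = out$minus$reads,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(res$reads_plus, file.path(dir, "reads_plus.fastq"))
    write_fastq(res$reads_minus, file.path(dir, "reads_minus.fastq"))
    write_tsv_file(truth, file.path(dir, "truth_counts.tsv"))
  }
  res
}

simulate_library <- function(ds, sim, total, base_tpm, prefix) {
  truth <- ds$truth
  cf <- sim$contaminant_fractions
  n_cont <- round(cf * total)
  n_clean <- total - sum(n_cont)

  # per-feature counts: multinomial with expectation base_tpm * total / 1e6
  p_feat <- base_tpm * total / 1e6 / max(n_clean, 1)
  if (sum(p_feat) > 1)
    stop("planted abundances exceed the clean read budget", call. = FALSE)
  if (nrow(truth) > 0 && n_clean > 0) {
    counts <- as.vector(stats::rmultinom(1, n_clean, c(p_feat, 1 - sum(p_feat))))
    feature_counts <- counts[seq_len(nrow(truth))]
    n_bg <- counts[length(counts)]
  } else {
    feature_counts <- rep(0L, nrow(truth))
    n_bg <- n_clean
  }

  seed6 <- substr(sim$adapter3, 1, 6)
  mk_read <- function(insert) {
    r <- paste0(insert, sim$adapter3)
    r <- substr(paste0(r, strrep("A", sim$read_length)), 1, sim$read_length)
    r
  }

  seqs <- character(0); classes <- character(0); feats <- character(0)
  for (i in seq_len(nrow(truth))) {
    k <- feature_counts[i]
    if (k == 0) next
    if (truth$kind[i] == "sirna_locus") {
      # both duplex strands are expressed; each receives the feature count
      seqs <- c(seqs, rep(mk_read(truth$tag_seq[i]), k),
                rep(mk_read(truth$tag_seq_minus[i]), k))
      classes <- c(classes, rep("clean", 2 * k))
      feats <- c(feats, rep(sprintf("feat%03d", i), 2 * k))
    } else {
      seqs <- c(seqs, rep(mk_read(truth$tag_seq[i]), k))
      classes <- c(classes, rep("clean", k))
      feats <- c(feats, rep(sprintf("feat%03d", i), k))
    }
  }
  # siRNA minus-strand copies inflate the library beyond `total`; trim the
  # background budget to compensate so the total stays exact
  n_extra <- length(seqs) - sum(feature_counts)
  n_bg <- max(0L, n_bg - n_extra)

  if (n_bg > 0) {
    seqs <- c(seqs, mk_read(background_fragments(ds, n_bg, seed6)))
    classes <- c(classes, rep("clean", n_bg))
    feats <- c(feats, rep("background", n_bg))
  }

  add <- function(n, class, gen) {
    if (n == 0) return()
    s <- vapply(seq_len(n), function(i) gen(), "")
    seqs <<- c(seqs, s)
    classes <<- c(classes, rep(class, n))
    feats <<- c(feats, rep(NA_character_, n))
  }
  add(n_cont[["adaptor5_contaminants"]], "adaptor5_contaminants", function()
    mk_read(paste0(sim$adapter5, random_dna(21))))
  add(n_cont[["adaptor3_null"]], "adaptor3_null", function() {
    repeat {
      r <- random_dna(sim$read_length)
      if (!grepl(seed6, r, fixed = TRUE)) return(r)
    }
  })
  add(n_cont[["insert_null"]], "insert_null", function() mk_read(""))
  add(n_cont[["polyA"]], "polyA", function() mk_read(strrep("A", sample(18:25, 1))))
  add(n_cont[["smaller_than_18nt"]], "smaller_than_18nt", function()
    mk_read(paste0("C", random_dna(sample(4:16, 1), gc = 0.8))))
  add(n_cont[["low_quality"]], "low_quality", function() mk_read(random_dna(21)))

  # exact conservation: the library holds precisely `total` reads
  if (length(seqs) > total)
    stop("planted abundances exceed the read budget", call. = FALSE)
  if (length(seqs) < total) {
    n_pad <- total - length(seqs)
    pad <- mk_read(background_fragments(ds, n_pad, seed6))
    seqs <- c(seqs, pad)
    classes <- c(classes, rep("clean", n_pad))
    feats <- c(feats, rep("background", n_pad))
  }

  ord <- sample.int(length(seqs))
  seqs <- seqs[ord]; classes <- classes[ord]; feats <- feats[ord]
  w <- nchar(seqs)
  n_bad <- ceiling(w * 0.6)
  qual <- ifelse(classes == "low_quality",
                 paste0(strrep("#", n_bad), strrep("I", w - n_bad)),
                 strrep("I", w))
  reads <- data.frame(
    id = sprintf("%s%07d", prefix, seq_along(seqs)),
    seq = seqs, qual = qual, class = classes, feature = feats,
    stringsAsFactors = FALSE)
  list(reads = reads, feature_counts = feature_counts)
}

# Random genomic fragments for the unannotated background. Fragments
# that happen to contain the 3' adapter seed (they would be trimmed
# short downstream) or that qualify as poly-A are resampled, so the
# generator's read-class truth stays exact.
background_fragments <- function(ds, n, adapter_seed = NULL) {
  draw <- function(k) {
    ch <- sample(names(ds$genome), k, replace = TRUE)
    w <- sample(20:24, k, replace = TRUE)
    maxpos <- nchar(ds$genome)[ch] - w + 1L
    pos <- floor(stats::runif(k) * maxpos) + 1L
    s <- substring(ds$genome[ch], pos, pos + w - 1L)
    flip <- stats::runif(k) < 0.5
    if (any(flip)) s[flip] <- revcomp(s[flip])
    unname(s)
  }
  if (n == 0) return(character(0))
  s <- draw(n)
  repeat {
    a_frac <- nchar(gsub("[^A]", "", s)) / nchar(s)
    bad <- a_frac >= 0.8
    if (!is.null(adapter_seed)) {
      # the seed must first occur exactly at the fragment/adapter
      # boundary, or trimming would shorten the insert
      first <- regexpr(adapter_seed, paste0(s, adapter_seed), fixed = TRUE)
      bad <- bad | first != nchar(s) + 1L
    }
    if (!any(bad)) return(s)
    s[bad] <- draw(sum(bad))
  }
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Write collapsed tags as FASTA with `id_xCOUNT` headers
#'
#' @param tags data.frame with `sequence` and count columns.
#' @param path output path.
#' @param count_col which count column to embed in headers.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, count_col = "count") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(tags))
    writeLines(paste0(">t", seq_len(nrow(tags)), "_x", tags[[count_col]], "\n",
                      tags$sequence), con)
  invisible(path)
}
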