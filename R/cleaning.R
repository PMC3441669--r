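# Read cleaning: the seven-step elimination cascade that turns raw reads
# into clean 18-30 nt tags, with exact first-failure-wins accounting.

#' Build a cleaning report from category counters
#'
#' The report mirrors the standard library-statistics table: total reads,
#' high-quality reads (the 100% baseline), the five removal categories,
#' the out-of-range (>30 nt) inserts, and clean reads. If `clean_reads` is
#' omitted it is computed as the remainder, so the conservation identity
#' `high_quality = removals + clean_reads` holds exactly by construction;
#' if supplied, the identity is asserted.
#'
#' @param total_reads,high_quality,adaptor3_null,insert_null,
#'   adaptor5_contaminants,smaller_than_18nt,polyA,over_30nt non-negative
#'   integer counters.
#' @param clean_reads optional; computed as the remainder when `NULL`.
#' @return a `cleaning_report` list with counters and `percentages`
#'   (of `high_quality`, rounded to 2 decimals).
#' @export
cleaning_report <- function(total_reads, high_quality, adaptor3_null = 0,
                            insert_null = 0, adaptor5_contaminants = 0,
                            smaller_than_18nt = 0, polyA = 0, over_30nt = 0,
                            clean_reads = NULL) {
  removed <- adaptor3_null + insert_null + adaptor5_contaminants +
    smaller_than_18nt + polyA + over_30nt
  if (is.null(clean_reads)) clean_reads <- high_quality - removed
  counters <- c(total_reads = total_reads, high_quality = high_quality,
                adaptor3_null = adaptor3_null, insert_null = insert_null,
                adaptor5_contaminants = adaptor5_contaminants,
                smaller_than_18nt = smaller_than_18nt, polyA = polyA,
                over_30nt = over_30nt, clean_reads = clean_reads)
  if (any(counters < 0)) stop("negative counter in cleaning report", call. = FALSE)
  if (high_quality != removed + clean_reads)
    stop(sprintf(paste0("cleaning accounting violated: high_quality (%d) != ",
                        "removals (%d) + clean_reads (%d)"),
                 high_quality, removed, clean_reads), call. = FALSE)
  pct_of <- function(x) if (high_quality > 0) round(x / high_quality * 100, 2) else 0
  structure(list(
    counters = counters,
    percentages = vapply(counters[-1], pct_of, numeric(1))
  ), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  lab <- c(total_reads = "Total reads", high_quality = "High quality",
           adaptor3_null = "Adaptor3 null", insert_null = "Insert null",
           adaptor5_contaminants = "Adaptor5 contaminants",
           smaller_than_18nt = "Smaller than 18 nt", polyA = "PolyA",
           over_30nt = "Larger than 30 nt", clean_reads = "Clean reads")
  for (nm in names(x$counters)) {
    pc <- if (nm == "total_reads") "" else sprintf("\t%.2f%%", x$percentages[[nm]])
    cat(sprintf("%s\t%d%s\n", lab[[nm]], x$counters[[nm]], pc))
  }
  invisible(x)
}

read_raw_reads <- function(input) {
  if (is.data.frame(input)) {
    stopifnot("seq" %in% names(input))
    if (is.null(input$qual)) input$qual <- NA_character_
    if (is.null(input$count)) input$count <- 1L
    return(input[, c("seq", "qual", "count")])
  }
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    lines <- readLines(input)
    if (length(lines) == 0)
      return(data.frame(seq = character(), qual = character(),
                        count = integer(), stringsAsFactors = FALSE))
    if (startsWith(lines[1], "@")) {  # FASTQ
      if (length(lines) %% 4 != 0)
        stop(sprintf("truncated FASTQ record at line %d", length(lines)), call. = FALSE)
      return(data.frame(seq = lines[seq(2, length(lines), 4)],
                        qual = lines[seq(4, length(lines), 4)],
                        count = 1L, stringsAsFactors = FALSE))
    }
    if (startsWith(lines[1], ">")) {  # collapsed FASTA, counts in "_xN" headers
      hdr <- grepl("^>", lines)
      cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", lines[hdr])))
      cnt[is.na(cnt)] <- 1L
      return(data.frame(seq = lines[!hdr], qual = NA_character_,
                        count = cnt, stringsAsFactors = FALSE))
    }
    stop("unrecognized read file format: ", input, call. = FALSE)
  }
  data.frame(seq = as.character(input),
             qual = rep(NA_character_, length(input)),
             count = rep(1L, length(input)), stringsAsFactors = FALSE)
}

#' Clean raw small RNA reads
#'
#' Applies the elimination cascade in order, each read being charged to
#' the first filter it fails (first-failure-wins, which makes the report's
#' conservation identity exact): (1) low quality — more than
#' `max_low_quality_frac` of base calls below Phred `quality_threshold`;
#' (2) 5' adapter contaminant — the read begins with the 5' adapter;
#' (3) no 3' adapter — the adapter's leading `min_adapter_match`-mer is
#' absent; (4) empty insert; (5) poly-A insert (>= `polyA_frac` A);
#' (6) insert shorter than 18 nt. Inserts longer than 30 nt are set aside
#' in their own counter rather than truncated. Survivors are collapsed to
#' unique tags with read counts.
#'
#' @param input FASTQ/collapsed-FASTA path, character vector of read
#'   sequences, or data.frame with `seq` (and optionally `qual`, `count`).
#' @param adapter3,adapter5 adapter sequences (non-empty).
#' @param quality_threshold Phred score below which a base call counts as
#'   low quality (default 20; only applied when qualities are present).
#' @param max_low_quality_frac fraction of low-quality calls above which a
#'   read is discarded (default 0.5).
#' @param min_adapter_match length of the exact 3' adapter seed (>= 6).
#' @param adapter5_match length of the 5'-adapter prefix compared at the
#'   read start (default 8).
#' @param polyA_frac adenine fraction at or above which an insert is
#'   called poly-A (default 0.8).
#' @return list with `tags` (data.frame `sequence`, `count`, sorted by
#'   sequence) and `report` (a [cleaning_report()]).
#' @export
clean_reads <- function(input, adapter3, adapter5,
                        quality_threshold = 20, max_low_quality_frac = 0.5,
                        min_adapter_match = 6, adapter5_match = 8,
                        polyA_frac = 0.8) {
  stopifnot(nzchar(adapter3), nzchar(adapter5), min_adapter_match >= 6)
  reads <- read_raw_reads(input)
  adapter3 <- as_dna(adapter3); adapter5 <- as_dna(adapter5)
  n <- nrow(reads)
  if (n == 0) {
    return(list(tags = data.frame(sequence = character(), count = integer(),
                                  stringsAsFactors = FALSE),
                report = cleaning_report(0, 0)))
  }
  seqs <- as_dna(reads$seq)
  cnt <- reads$count
  total_reads <- sum(cnt)

  # (1) low quality -> everything downstream is relative to high quality
  low_q <- rep(FALSE, n)
  has_q <- !is.na(reads$qual)
  if (any(has_q)) {
    cutoff <- 33L + as.integer(quality_threshold)
    frac_low <- vapply(reads$qual[has_q], function(q) {
      v <- utf8ToInt(q)
      sum(v < cutoff) / length(v)
    }, numeric(1), USE.NAMES = FALSE)
    low_q[has_q] <- frac_low > max_low_quality_frac
  }
  hq <- !low_q
  high_quality <- sum(cnt[hq])

  category <- rep(NA_character_, n)
  category[!hq] <- "low_quality"
  idx <- which(hq)

  # (2) 5' adapter contaminant
  m5 <- min(adapter5_match, nchar(adapter5))
  is_a5 <- substr(seqs[idx], 1, m5) == substr(adapter5, 1, m5)
  category[idx[is_a5]] <- "adaptor5_contaminants"
  idx <- idx[!is_a5]

  # (3) locate the 3' adapter seed; leftmost exact occurrence
  seed <- substr(adapter3, 1, min_adapter_match)
  pos <- regexpr(seed, seqs[idx], fixed = TRUE)
  no_a3 <- pos < 0
  category[idx[no_a3]] <- "adaptor3_null"
  insert <- substr(seqs[idx], 1, pos - 1)
  idx <- idx[!no_a3]; insert <- insert[!no_a3]

  # (4) empty insert
  empty <- nchar(insert) == 0
  category[idx[empty]] <- "insert_null"
  idx <- idx[!empty]; insert <- insert[!empty]

  # (5) poly-A insert
  a_frac <- nchar(gsub("[^A]", "", insert)) / nchar(insert)
  pa <- a_frac >= polyA_frac
  category[idx[pa]] <- "polyA"
  idx <- idx[!pa]; insert <- insert[!pa]

  # (6) length filters
  short <- nchar(insert) < 18
  category[idx[short]] <- "smaller_than_18nt"
  long <- !short & nchar(insert) > 30
  category[idx[long]] <- "over_30nt"
  keep <- !short & !long
  idx <- idx[keep]; insert <- insert[keep]
  category[idx] <- "clean"

  tally <- function(cl) sum(cnt[category == cl])
  report <- cleaning_report(
    total_reads = total_reads, high_quality = high_quality,
    adaptor3_null = tally("adaptor3_null"), insert_null = tally("insert_null"),
    adaptor5_contaminants = tally("adaptor5_contaminants"),
    smaller_than_18nt = tally("smaller_than_18nt"), polyA = tally("polyA"),
    over_30nt = tally("over_30nt"), clean_reads = tally("clean"))

  if (length(idx)) {
    counts <- tapply(cnt[idx], insert, sum)
    tags <- data.frame(sequence = names(counts),
                       count = as.integer(counts), stringsAsFactors = FALSE)
  } else {
    tags <- data.frame(sequence = character(), count = integer(),
                       stringsAsFactors = FALSE)
  }
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, report = report)
}

#' Length distribution of clean tags
#'
#' @param tags data.frame with `sequence` and a count column.
#' @param count_col name of the count column (default `"count"`).
#' @return data.frame with `length` (18-30), `unique` (distinct tags) and
#'   `total` (read-count weighted) columns.
#' @export
length_histogram <- function(tags, count_col = "count") {
  lens <- 18:30
  w <- nchar(tags$sequence)
  data.frame(
    length = lens,
    unique = vapply(lens, function(l) sum(w == l), integer(1)),
    total = vapply(lens, function(l) sum(tags[[count_col]][w == l]), numeric(1)))
}

#' Common and specific tags between two libraries
#'
#' Overlap in the two-pie style used for library comparisons: the
#' denominator is the sum over both libraries (distinct tags for the
#' unique weighting, read counts for the total weighting) and the common
#' component is counted from both libraries, so the three percentages sum
#' to 100.
#'
#' @param tags_plus,tags_minus collapsed tag tables (`sequence`, `count`).
#' @return data.frame with rows `common`, `plus_specific`,
#'   `minus_specific` and columns `unique_count`, `unique_pct`,
#'   `total_count`, `total_pct`.
#' @export
library_overlap <- function(tags_plus, tags_minus) {
  shared <- intersect(tags_plus$sequence, tags_minus$sequence)
  u1 <- nrow(tags_plus); u2 <- nrow(tags_minus)
  t1 <- sum(tags_plus$count); t2 <- sum(tags_minus$count)
  uc <- 2L * length(shared)
  tc <- sum(tags_plus$count[tags_plus$sequence %in% shared]) +
    sum(tags_minus$count[tags_minus$sequence %in% shared])
  u_den <- max(u1 + u2, 1L); t_den <- max(t1 + t2, 1)
  res <- data.frame(
    component = c("common", "plus_specific", "minus_specific"),
    unique_count = c(uc, u1 - length(shared), u2 - length(shared)),
    total_count = c(tc,
                    t1 - sum(tags_plus$count[tags_plus$sequence %in% shared]),
                    t2 - sum(tags_minus$count[tags_minus$sequence %in% shared])),
    stringsAsFactors = FALSE)
  res$unique_pct <- round(res$unique_count / u_den * 100, 2)
  res$total_pct <- round(res$total_count / t_den * 100, 2)
  res[, c("component", "unique_count", "unique_pct", "total_count", "total_pct")]
}

#' Merge the collapsed tag tables of the two libraries
#'
#' @param tags_plus,tags_minus collapsed tag tables (`sequence`, `count`).
#' @return data.frame `sequence`, `count_plus`, `count_minus` over the
#'   union of sequences, sorted by sequence.
#' @export
merge_libraries <- function(tags_plus, tags_minus) {
  m <- merge(tags_plus, tags_minus, by = "sequence", all = TRUE,
             suffixes = c("_plus", "_minus"))
  m$count_plus[is.na(m$count_plus)] <- 0L
  m$count_minus[is.na(m$count_minus)] <- 0L
  m <- m[order(m$sequence), , drop = FALSE]
  rownames(m) <- NULL
  m
}
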