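# Exact-match (zero-mismatch) mapping of 18-30 nt tags to both genome
# strands via a k-mer seed hash, reporting all hit loci. Coordinates are
# 1-based inclusive in plus-strand space; minus-strand hits carry a strand
# flag with start < end always.

#' Build a k-mer seed index over the genome
#'
#' Hashes every plus-strand k-mer to its positions; minus-strand matches
#' are found by looking up the reverse complement of the query, so a
#' single-strand index covers both strands.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param k seed length (default 18; must be >= 8 and no longer than the
#'   shortest tag that will be mapped).
#' @return a `genome_index` object.
#' @export
build_genome_index <- function(genome, k = 18L) {
  k <- as.integer(k)
  if (k < 8) stop("seed length k < 8 would give a degenerate index", call. = FALSE)
  genome <- load_genome(genome)
  if (length(genome) == 0 || all(nchar(genome) == 0))
    stop("empty genome", call. = FALSE)
  env <- new.env(hash = TRUE, parent = emptyenv())
  chrom_of <- integer(0); pos_of <- integer(0); kmers <- character(0)
  for (ci in seq_along(genome)) {
    s <- genome[[ci]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- c(kmers, substring(s, starts, starts + k - 1L))
    chrom_of <- c(chrom_of, rep(ci, length(starts)))
    pos_of <- c(pos_of, starts)
  }
  list2env(split(seq_along(kmers), kmers), envir = env)
  structure(list(env = env, k = k, genome = genome,
                 chrom_names = names(genome),
                 chrom_lengths = stats::setNames(nchar(genome), names(genome)),
                 chrom_of = chrom_of, pos_of = pos_of),
            class = "genome_index")
}

load_genome <- function(genome) {
  if (length(genome) == 0)
    return(stats::setNames(character(0), character(0)))
  if (inherits(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- as.character(Biostrings::readDNAStringSet(genome))
  } else {
    g <- genome
  }
  if (is.null(names(g))) names(g) <- paste0("chr", seq_along(g))
  names(g) <- sub("\\s.*$", "", names(g))
  vapply(g, as_dna, "")
}

empty_hits <- function() {
  data.frame(chromosome = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Map one tag to the genome, zero mismatches, both strands
#'
#' @param index a [build_genome_index()] result.
#' @param tag nucleotide string (length >= the index seed length).
#' @return data.frame of hits (`chromosome`, `start`, `end`, `strand`;
#'   1-based inclusive, plus-strand space), sorted by chromosome, start,
#'   strand. Zero rows when the tag does not match anywhere.
#' @export
map_tag <- function(index, tag) {
  stopifnot(inherits(index, "genome_index"))
  assert_alphabet(tag, "tag")
  tag <- as_dna(tag)
  w <- nchar(tag)
  if (w < index$k)
    stop(sprintf("tag shorter (%d) than index seed (%d)", w, index$k), call. = FALSE)
  hits <- rbind(seed_hits(index, tag, "+"),
                seed_hits(index, revcomp(tag), "-"))
  hits <- hits[order(hits$chromosome, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

seed_hits <- function(index, oriented_tag, strand) {
  w <- nchar(oriented_tag)
  ids <- index$env[[substr(oriented_tag, 1, index$k)]]
  if (is.null(ids)) return(empty_hits())
  ci <- index$chrom_of[ids]; pos <- index$pos_of[ids]
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    s <- index$genome[[ci[i]]]
    e <- pos[i] + w - 1L
    ok[i] <- e <= nchar(s) && substr(s, pos[i], e) == oriented_tag
  }
  if (!any(ok)) return(empty_hits())
  data.frame(chromosome = index$chrom_names[ci[ok]],
             start = pos[ok], end = pos[ok] + w - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

#' Map a collapsed tag library
#'
#' Bulk, vectorized equivalent of calling [map_tag()] on every tag.
#'
#' @param index a [build_genome_index()] result.
#' @param tags data.frame with `sequence` and one or more count columns.
#' @return list with `hits` (one hit data.frame per tag), `flat` (all
#'   hits in one data.frame with a `tag` index column), `unmapped`
#'   (logical vector), and `tally` (per-chromosome per-strand read-count
#'   weighted hit tallies; each hit of a multi-hit tag contributes the
#'   tag's full count).
#' @export
map_library <- function(index, tags) {
  n <- nrow(tags)
  seqs <- as_dna(tags$sequence)
  assert_alphabet(seqs, "tags")
  if (any(nchar(seqs) < index$k))
    stop("tag shorter than the index seed length", call. = FALSE)
  rc <- revcomp(seqs)
  flat <- rbind(bulk_seed_hits(index, seqs, "+"),
                bulk_seed_hits(index, rc, "-"))
  flat <- flat[order(flat$tag, flat$chromosome, flat$start, flat$strand), ,
               drop = FALSE]
  rownames(flat) <- NULL
  hits <- split(flat[, c("chromosome", "start", "end", "strand")],
                factor(flat$tag, levels = seq_len(n)))
  hits <- lapply(hits, function(h) { rownames(h) <- NULL; h })
  names(hits) <- NULL
  unmapped <- !(seq_len(n) %in% flat$tag)
  count_cols <- grep("^count", names(tags), value = TRUE)
  weight <- if (length(count_cols)) Reduce(`+`, tags[count_cols]) else
    rep(1, n)
  tally <- if (nrow(flat) == 0) {
    data.frame(chromosome = character(), strand = character(),
               reads = numeric(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(
      list(reads = weight[flat$tag]),
      by = list(chromosome = flat$chromosome, strand = flat$strand), FUN = sum)
    agg[order(agg$chromosome, agg$strand), , drop = FALSE]
  }
  rownames(tally) <- NULL
  list(hits = hits, flat = flat, unmapped = unmapped, tally = tally)
}

# vectorized seed lookup + full-length verification for one orientation
bulk_seed_hits <- function(index, oriented, strand) {
  keys <- substr(oriented, 1, index$k)
  cand <- mget(keys, envir = index$env, ifnotfound = list(NULL))
  nc <- lengths(cand)
  if (sum(nc) == 0)
    return(data.frame(tag = integer(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  tag_i <- rep(seq_along(oriented), nc)
  ids <- unlist(cand, use.names = FALSE)
  ci <- index$chrom_of[ids]; pos <- index$pos_of[ids]
  w <- nchar(oriented)[tag_i]
  ends <- pos + w - 1L
  inb <- ends <= unname(index$chrom_lengths[ci])
  ok <- inb
  ok[inb] <- substring(index$genome[ci[inb]], pos[inb], ends[inb]) ==
    oriented[tag_i[inb]]
  data.frame(tag = tag_i[ok], chromosome = index$chrom_names[ci[ok]],
             start = pos[ok], end = ends[ok], strand = strand,
             stringsAsFactors = FALSE)
}

# normalize "hits" arguments: either a per-tag list of hit data.frames or
# a map_library() result carrying the flat table
hits_flat <- function(hits, n = NULL) {
  if (is.list(hits) && !is.null(hits$flat)) return(hits$flat)
  nh <- vapply(hits, nrow, integer(1))
  if (sum(nh) == 0)
    return(data.frame(tag = integer(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  flat <- do.call(rbind, hits[nh > 0])
  flat <- data.frame(tag = rep(seq_along(hits), nh), flat,
                     stringsAsFactors = FALSE)
  rownames(flat) <- NULL
  flat
}

hits_list <- function(hits) {
  if (is.list(hits) && !is.null(hits$hits)) hits$hits else hits
}

#' Export hits as BED6 (0-based half-open) or location strings
#'
#' @param hits a hit data.frame from [map_tag()].
#' @param name feature name for the BED name column.
#' @return `hits_to_bed`: data.frame in BED6 column order;
#'   `hits_to_location`: character vector of `chrom:start:end:strand`
#'   strings (1-based inclusive).
#' @export
hits_to_bed <- function(hits, name = ".") {
  data.frame(chrom = hits$chromosome, chromStart = hits$start - 1L,
             chromEnd = hits$end, name = name, score = 0L,
             strand = hits$strand, stringsAsFactors = FALSE)
}

#' @rdname hits_to_bed
#' @export
hits_to_location <- function(hits) {
  location_string(hits$chromosome, hits$start, hits$end, hits$strand)
}
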