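# siRNA duplex detection. A duplex is two tags of 22-24 nt mapping to
# opposite strands of the same locus such that each strand is 2 nt longer
# than the other on its 3' end: for a plus-strand tag spanning [a, b], the
# partner minus-strand tag spans exactly [a-2, b-2] in plus-strand space
# (which forces equal lengths). Evaluated in genome-coordinate space —
# equivalent to sequence-space duplex alignment for exact-match tags.

#' Find siRNA duplex pairs among mapped tags
#'
#' @param tags tag table with `sequence` and count columns.
#' @param hits a [map_library()] result, or a per-tag hit list aligned
#'   with `tags`.
#' @param min_len,max_len allowed strand lengths (default 22-24 nt).
#' @param overhang 3' overhang in nt (default 2).
#' @return data.frame of deduplicated pairs: `chromosome`, `plus_start`,
#'   `plus_end`, `minus_start`, `minus_end`, `plus_tag`, `minus_tag`,
#'   plus the tags' count columns (suffixed `_p`/`_m`).
#' @export
find_sirna_duplexes <- function(tags, hits, min_len = 22L, max_len = 24L,
                                overhang = 2L) {
  count_cols <- grep("^count", names(tags), value = TRUE)
  flat <- hits_flat(hits)
  w <- nchar(tags$sequence)
  flat <- flat[w[flat$tag] >= min_len & w[flat$tag] <= max_len, , drop = FALSE]
  pl <- flat[flat$strand == "+", , drop = FALSE]
  mi <- flat[flat$strand == "-", , drop = FALSE]
  empty <- data.frame(chromosome = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), plus_tag = character(),
                      minus_tag = character(), stringsAsFactors = FALSE)
  if (nrow(pl) == 0 || nrow(mi) == 0) return(empty)
  minus_key <- sprintf("%s:%d:%d", mi$chromosome, mi$start, mi$end)
  want <- sprintf("%s:%d:%d", pl$chromosome,
                  pl$start - overhang, pl$end - overhang)
  m <- match(want, minus_key)
  found <- !is.na(m)
  if (!any(found)) return(empty)
  pl <- pl[found, , drop = FALSE]
  mt <- mi$tag[m[found]]
  pairs <- data.frame(chromosome = pl$chromosome,
                      plus_start = pl$start, plus_end = pl$end,
                      minus_start = pl$start - overhang,
                      minus_end = pl$end - overhang,
                      plus_tag = tags$sequence[pl$tag],
                      minus_tag = tags$sequence[mt],
                      stringsAsFactors = FALSE)
  for (cc in count_cols) {
    pairs[[paste0(cc, "_p")]] <- tags[[cc]][pl$tag]
    pairs[[paste0(cc, "_m")]] <- tags[[cc]][mt]
  }
  key <- sprintf("%s:%d:%d", pairs$chromosome, pairs$plus_start, pairs$plus_end)
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  pairs <- pairs[order(pairs$chromosome, pairs$plus_start), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
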