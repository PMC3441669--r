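# Shared sequence helpers. Tags are stored internally in the DNA alphabet
# (T, upper case); miRNA-facing reports render them as RNA (U).

DNA_BASES <- c("A", "C", "G", "T")

#' Convert sequences to the internal DNA alphabet
#'
#' Upper-cases and replaces U with T.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in `ACGT`.
#' @export
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Convert sequences to the RNA alphabet
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in `ACGU` (upper case).
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse-complement DNA sequences
#'
#' @param x character vector in the DNA alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

assert_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", as_dna(x))
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGTU symbols (first offender: '%s')",
                 what, x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

# 1-based inclusive "chrom:start:end:strand" location string
location_string <- function(chrom, start, end, strand) {
  sprintf("%s:%d:%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

# Seeded RNG scope; keeps caller's RNG state untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
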