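# Independent oracles, deliberately naive: exhaustive enumeration for the
# folding DP and a sliding-window scan for the exact mapper.

oracle_pair_energy <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(-3)
  if (p %in% c("AU", "UA")) return(-2)
  if (p %in% c("GU", "UG")) return(-1)
  NA_real_
}

# Minimum energy over ALL nested structures by unmemoized recursive
# enumeration (brute force; practical for sequences up to ~20 nt).
oracle_fold_mfe <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      e <- oracle_pair_energy(ch[i], ch[k])
      if (is.na(e)) next
      inner <- rec(i + 1, k - 1)
      rest <- if (k + 1 <= j) rec(k + 1, j) else 0
      best <- min(best, e + inner + rest)
    }
    best
  }
  rec(1, length(ch))
}

# All exact-match loci of a tag on both strands by naive scanning,
# cross-checked through Biostrings pattern matching.
oracle_map_tag <- function(genome, tag) {
  tag <- srnapipe::as_dna(tag)
  hits <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else srnapipe::revcomp(tag)
      m <- Biostrings::matchPattern(q, subj)
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          chromosome = ch, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$chromosome, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All siRNA duplex pairs by brute-force all-pairs checking of hit loci.
oracle_sirna_pairs <- function(tags, hits, min_len = 22, max_len = 24) {
  found <- character(0)
  w <- nchar(tags$sequence)
  for (i in seq_along(hits)) {
    if (w[i] < min_len || w[i] > max_len) next
    hp <- hits[[i]][hits[[i]]$strand == "+", , drop = FALSE]
    for (j in seq_along(hits)) {
      if (w[j] < min_len || w[j] > max_len) next
      hm <- hits[[j]][hits[[j]]$strand == "-", , drop = FALSE]
      if (nrow(hp) == 0 || nrow(hm) == 0) next
      for (a in seq_len(nrow(hp))) for (b in seq_len(nrow(hm))) {
        if (hp$chromosome[a] == hm$chromosome[b] &&
            hm$start[b] == hp$start[a] - 2L && hm$end[b] == hp$end[a] - 2L)
          found <- c(found, sprintf("%s:%d:%d", hp$chromosome[a],
                                    hp$start[a], hp$end[a]))
      }
    }
  }
  sort(unique(found))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
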