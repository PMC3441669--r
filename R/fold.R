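#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Computes the minimum free energy (MFE) secondary structure of a single
#' RNA sequence under a simple base-pair energy model by interval dynamic
#' programming (Nussinov-style, energy-weighted): GC pairs contribute
#' -3.0 kcal/mol, AU pairs -2.0, GU wobble pairs -1.0, and a hairpin loop
#' must span at least `min_loop` unpaired bases. The model is deterministic:
#' on ties, pairing the 5'-most open position wins, and among equal-energy
#' partners the 3'-most partner wins (which keeps stem-loop helices
#' contiguous).
#'
#' The default engine is intentionally simple so that it can be verified
#' exhaustively; `engine = "vienna"` delegates to the ViennaRNA `RNAfold`
#' binary (thermodynamic nearest-neighbour model) when it is on the PATH,
#' behind the same contract. MFE values from the two engines are on
#' different scales and must not be mixed within one analysis.
#'
#' @param sequence a single nucleotide string (RNA or DNA alphabet; T and U
#'   are equivalent on input).
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param engine `"nussinov"` (default, built in) or `"vienna"`.
#' @return an object of class `fold_result`: a list with elements
#'   `sequence` (RNA alphabet), `structure` (dot-bracket) and `mfe`
#'   (kcal/mol, always <= 0 for the built-in engine).
#' @examples
#' fold("GGGAAACCC")  # three GC pairs: mfe -9
#' @export
fold <- function(sequence, min_loop = 3, engine = c("nussinov", "vienna")) {
  engine <- match.arg(engine)
  stopifnot(length(sequence) == 1L)
  assert_alphabet(sequence, "fold() input")
  rna <- as_rna(sequence)
  if (engine == "vienna") {
    res <- fold_vienna(rna)
  } else {
    res <- .fold_dp(rna, as.integer(min_loop))
  }
  structure(list(sequence = rna, structure = res$structure, mfe = res$mfe),
            class = "fold_result")
}

fold_vienna <- function(rna) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("RNAfold not found on PATH", call. = FALSE)
  out <- system2(exe, c("--noPS"), input = rna, stdout = TRUE)
  line <- out[2]
  db <- sub("^([().]+).*$", "\\1", line)
  mfe <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, mfe = mfe)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$mfe), " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; `p[i]` is the partner of position `i`, or 0 if
#'   unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket structure", call. = FALSE)
  p
}

#' Re-score a dot-bracket structure under the built-in energy model
#'
#' Independent of the folding recursion: simply sums the pair energies of
#' the annotated pairs (GC -3, AU -2, GU -1 kcal/mol).
#'
#' @param sequence nucleotide string.
#' @param structure dot-bracket string of the same length.
#' @return total energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure) {
  rna <- strsplit(as_rna(sequence), "")[[1]]
  if (nchar(structure) != length(rna))
    stop("sequence and structure lengths differ", call. = FALSE)
  p <- pair_table(structure)
  e <- 0
  for (i in which(p > seq_along(p))) {
    pr <- paste0(rna[p[i]], rna[i])
    e <- e + switch(pr,
      GC = , CG = -3,
      AU = , UA = -2,
      GU = , UG = -1,
      stop(sprintf("non-canonical pair %s at %d:%d", pr, p[i], i), call. = FALSE))
  }
  e
}
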