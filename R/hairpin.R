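# Novel miRNA prediction from unannotated mapped tags: excise candidate
# precursor windows around each hit, fold them, locate the star arm, and
# accept hairpins that satisfy the Mireap-style thresholds. Also
# quantification of known miRNAs by exact alignment to mature/precursor
# sequences.

#' Mireap-style acceptance parameters
#'
#' Defaults follow the standard parameterization for plant/algal miRNA
#' discovery: miRNA length 18-25 nt, star (reference) length 20-23 nt, at
#' most 20 genomic copies, precursor MFE at most -18 kcal/mol, at most
#' 300 nt between miRNA and star, at least 16 base pairs in the
#' miRNA/star duplex, bulges of at most 4 nt, duplex asymmetry of at most
#' 4 nt, and 20 nt of precursor flank. All thresholds are inclusive: an
#' MFE of exactly -18 and a duplex of exactly 16 pairs are accepted.
#'
#' @param min_mirna_len,max_mirna_len mature length bounds (nt).
#' @param min_ref_len,max_ref_len star length bounds (nt; recorded on
#'   candidates, not an acceptance filter).
#' @param max_copies maximum genomic locus count of a candidate mature.
#' @param max_precursor_mfe acceptance MFE ceiling (kcal/mol, negative).
#' @param max_space maximum nt between miRNA and star.
#' @param min_duplex_pairs minimum paired mature positions.
#' @param max_bulge maximum unpaired run on one duplex strand (nt).
#' @param max_asymmetry maximum |unpaired mature - unpaired star| (nt).
#' @param flank precursor flank length (nt).
#' @return a `mireap_params` list.
#' @export
mireap_params <- function(min_mirna_len = 18L, max_mirna_len = 25L,
                          min_ref_len = 20L, max_ref_len = 23L,
                          max_copies = 20L, max_precursor_mfe = -18,
                          max_space = 300L, min_duplex_pairs = 16L,
                          max_bulge = 4L, max_asymmetry = 4L, flank = 20L) {
  stopifnot(max_precursor_mfe < 0, min_mirna_len <= max_mirna_len,
            max_space > 0, flank >= 0)
  structure(list(min_mirna_len = min_mirna_len, max_mirna_len = max_mirna_len,
                 min_ref_len = min_ref_len, max_ref_len = max_ref_len,
                 max_copies = max_copies, max_precursor_mfe = max_precursor_mfe,
                 max_space = max_space, min_duplex_pairs = min_duplex_pairs,
                 max_bulge = max_bulge, max_asymmetry = max_asymmetry,
                 flank = flank), class = "mireap_params")
}

#' Candidate precursor windows around a genomic hit
#'
#' Two windows per hit, treating the tag as the 5' arm
#' (`[start - flank, end + max_space + flank]`) or as the 3' arm
#' (`[start - max_space - flank, end + flank]`), clipped to the
#' chromosome.
#'
#' @param hit one-row hit data.frame (`chromosome`, `start`, `end`,
#'   `strand`).
#' @param params a [mireap_params()].
#' @param chrom_length length of the hit's chromosome.
#' @return data.frame with `role` (`"5p"`, `"3p"`), `start`, `end`.
#' @export
candidate_windows <- function(hit, params, chrom_length) {
  data.frame(
    role = c("5p", "3p"),
    start = pmax(1L, c(hit$start - params$flank,
                       hit$start - params$max_space - params$flank)),
    end = pmin(as.integer(chrom_length),
               c(hit$end + params$max_space + params$flank,
                 hit$end + params$flank)),
    stringsAsFactors = FALSE)
}

# Duplex statistics of a mature interval within a folded sequence: the
# star arm is the region pairing with the mature, extended by 2 nt so each
# strand of the duplex carries a 2-nt 3' overhang.
duplex_stats <- function(fold_res, mature, overhang = 2L, max_bulge = 4L) {
  pt <- pair_table(fold_res$structure)
  n <- length(pt)
  m1 <- mature[1]; m2 <- mature[2]
  mpos <- m1:m2
  paired_all <- mpos[pt[mpos] > 0 & !(pt[mpos] >= m1 & pt[mpos] <= m2)]
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (length(paired_all) == 0) return(fail("no_star"))
  # the star arm is the side carrying the majority of the mature's
  # partners; stray pairs to the other side count as unpaired
  n3 <- sum(pt[paired_all] > m2); n5 <- sum(pt[paired_all] < m1)
  paired <- if (n3 >= n5) paired_all[pt[paired_all] > m2]
            else paired_all[pt[paired_all] < m1]
  # the star arm is one contiguous partner region: keep the largest
  # cluster of partner positions (a gap implying a bulge beyond
  # max_bulge splits clusters) and treat mature positions pairing
  # outside it as unpaired
  ps <- sort(pt[paired])
  cl <- cumsum(c(0L, diff(ps) > max_bulge + 1L))
  sizes <- table(cl)
  best_cl <- as.integer(names(sizes)[which.max(sizes)])
  keep_partners <- ps[cl == best_cl]
  paired <- paired[pt[paired] %in% keep_partners]
  partners <- pt[paired]
  star5 <- pt[max(paired)]
  star3 <- min(pt[min(paired)] + overhang, if (n3 >= n5) n else m1 - 1L)
  star <- c(min(star5, star3), max(star5, star3))
  # unpaired counts inside the duplex, per side; a position paired to
  # anything outside the duplex counts as unpaired here
  dm <- min(paired):max(paired)
  ds <- min(partners):max(partners)
  un_m <- !(dm %in% paired)
  un_s <- !(ds %in% partners)
  run_max <- function(un) {
    if (!any(un)) return(0L)
    r <- rle(un)
    max(r$lengths[r$values])
  }
  spacing <- if (n3 >= n5) star[1] - m2 - 1L else m1 - star[2] - 1L
  list(ok = TRUE, reason = NA_character_,
       star_interval = star,
       star_length = star[2] - star[1] + 1L,
       duplex_pairs = length(paired),
       max_bulge = max(run_max(un_m), run_max(un_s)),
       asymmetry = abs(sum(un_m) - sum(un_s)),
       spacing = spacing)
}

#' Evaluate a folded precursor window as a miRNA hairpin candidate
#'
#' Locates the star arm from the structure (the partner region of the
#' mature, offset for a 2-nt 3' overhang on each duplex strand) and
#' accepts the candidate iff the MFE is at or below the ceiling, the
#' mature/star duplex has at least the minimum base pairs, bulges and
#' asymmetry are within bounds, mature and star sit on opposite arms of a
#' single stem-loop, and their spacing does not exceed the maximum. All
#' rejection reasons are recorded.
#'
#' @param fold_res a [fold()] result for the (excised) precursor.
#' @param mature integer pair: 1-based mature interval within the folded
#'   sequence.
#' @param params a [mireap_params()].
#' @return a `hairpin_candidate` list: `accepted`, `reasons` (character,
#'   empty when accepted), `mfe`, `structure`, `duplex_pairs`,
#'   `max_bulge`, `asymmetry`, `spacing`, `star_interval`, `star_length`.
#' @export
evaluate_candidate <- function(fold_res, mature, params = mireap_params()) {
  n <- nchar(fold_res$sequence)
  if (mature[1] < 1 || mature[2] > n || mature[1] > mature[2])
    stop("mature interval outside the folded window", call. = FALSE)
  st <- duplex_stats(fold_res, mature, max_bulge = params$max_bulge)
  reasons <- character(0)
  if (!st$ok) {
    reasons <- st$reason
    st <- c(st, list(star_interval = c(NA_integer_, NA_integer_),
                     star_length = NA_integer_, duplex_pairs = 0L,
                     max_bulge = NA_integer_, asymmetry = NA_integer_,
                     spacing = NA_integer_))
  } else {
    if (st$duplex_pairs < params$min_duplex_pairs) reasons <- c(reasons, "duplex_pairs")
    if (st$max_bulge > params$max_bulge) reasons <- c(reasons, "bulge")
    if (st$asymmetry > params$max_asymmetry) reasons <- c(reasons, "asymmetry")
    if (st$spacing > params$max_space) reasons <- c(reasons, "spacing")
  }
  if (fold_res$mfe > params$max_precursor_mfe) reasons <- c(reasons, "mfe")
  structure(list(accepted = length(reasons) == 0, reasons = reasons,
                 mfe = fold_res$mfe, structure = fold_res$structure,
                 duplex_pairs = st$duplex_pairs, max_bulge = st$max_bulge,
                 asymmetry = st$asymmetry, spacing = st$spacing,
                 star_interval = st$star_interval,
                 star_length = st$star_length),
            class = "hairpin_candidate")
}

# window-relative <-> genomic coordinate transforms (strand-aware)
rel_from_genomic <- function(gstart, gend, wstart, wend, strand) {
  if (strand == "+") c(gstart - wstart + 1L, gend - wstart + 1L)
  else c(wend - gend + 1L, wend - gstart + 1L)
}
genomic_from_rel <- function(rstart, rend, wstart, wend, strand) {
  if (strand == "+") c(wstart + rstart - 1L, wstart + rend - 1L)
  else c(wend - rend + 1L, wend - rstart + 1L)
}

#' Predict novel miRNAs from unannotated mapped tags
#'
#' For each unannotated tag of mature length with at most `max_copies`
#' genomic loci: around each hit, both candidate windows are extracted
#' (strand-aware) and folded to locate a star arm; the precursor spanning
#' mature and star plus `flank` nt is then excised, refolded, and
#' evaluated by [evaluate_candidate()]. Per tag, the best accepted
#' candidate is kept (lowest MFE, then shortest precursor, then leftmost
#' coordinate); the output is sorted by genomic location and named
#' `n001`, `n002`, ...
#'
#' @param tags tag table (`sequence` plus `count_plus`/`count_minus` or
#'   `count` columns).
#' @param hits aligned per-tag hit list from [map_library()].
#' @param genome named character vector of chromosome sequences.
#' @param params a [mireap_params()].
#' @param categories optional per-tag category vector; only `unann` tags
#'   are considered when supplied.
#' @param min_reads minimum summed read depth for a tag to be considered
#'   a candidate mature (default 2: singleton tags carry no expression
#'   evidence and dominate the unannotated fraction).
#' @return data.frame of accepted candidates: `name`, `sequence` (mature,
#'   RNA alphabet), `length`, `location` (precursor
#'   `chrom:start:end:strand`, stem-loop core plus flanks),
#'   `precursor_length`, `mfe` and `structure` (of the stem-loop core),
#'   `duplex_pairs`, `max_bulge`, `asymmetry`, `copies`, and the tag
#'   count columns.
#' @export
predict_novel <- function(tags, hits, genome, params = mireap_params(),
                          categories = NULL, min_reads = 2) {
  count_cols <- grep("^count", names(tags), value = TRUE)
  keep <- nchar(tags$sequence) >= params$min_mirna_len &
    nchar(tags$sequence) <= params$max_mirna_len
  if (length(count_cols)) {
    depth <- Reduce(`+`, tags[count_cols])
    keep <- keep & depth >= min_reads
  }
  if (!is.null(categories)) keep <- keep & categories == "unann"
  hl <- hits_list(hits)
  rows <- list()
  for (i in which(keep)) {
    h <- hl[[i]]
    if (nrow(h) == 0 || nrow(h) > params$max_copies) next
    best <- NULL
    for (j in seq_len(nrow(h))) {
      hit <- h[j, ]
      chrom_seq <- genome[[hit$chromosome]]
      # scan a ladder of window extents up to max_space for each arm role:
      # short precursors are found in short windows whose fold is not
      # confounded by flanking sequence
      for (ext in window_extents(params)) {
        wins <- data.frame(
          role = c("5p", "3p"),
          start = pmax(1L, c(hit$start - params$flank,
                             hit$start - ext - params$flank)),
          end = pmin(nchar(chrom_seq),
                     c(hit$end + ext + params$flank,
                       hit$end + params$flank)),
          stringsAsFactors = FALSE)
        for (k in seq_len(nrow(wins))) {
          cand <- evaluate_window(hit, wins[k, ], chrom_seq, params)
          if (is.null(cand) || !cand$eval$accepted) next
          if (is.null(best) || better_candidate(cand, best)) best <- cand
        }
      }
    }
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- c(
      list(sequence = as_rna(tags$sequence[i]),
           length = nchar(tags$sequence[i]),
           chromosome = best$chromosome,
           precursor_start = best$prec[1], precursor_end = best$prec[2],
           strand = best$strand,
           precursor_length = best$prec[2] - best$prec[1] + 1L,
           mfe = best$eval$mfe, structure = best$eval$structure,
           duplex_pairs = best$eval$duplex_pairs,
           max_bulge = best$eval$max_bulge,
           asymmetry = best$eval$asymmetry,
           copies = nrow(h)),
      stats::setNames(as.list(tags[i, count_cols]), count_cols))
  }
  if (length(rows) == 0) {
    out <- data.frame(name = character(), sequence = character(),
                      length = integer(), location = character(),
                      precursor_length = integer(), mfe = numeric(),
                      structure = character(), duplex_pairs = integer(),
                      max_bulge = integer(), asymmetry = integer(),
                      copies = integer(), stringsAsFactors = FALSE)
    for (cc in count_cols) out[[cc]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  out <- out[order(out$chromosome, out$precursor_start, out$strand), , drop = FALSE]
  out$location <- location_string(out$chromosome, out$precursor_start,
                                  out$precursor_end, out$strand)
  out$name <- sprintf("n%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", "sequence", "length", "location", "precursor_length",
          "mfe", "structure", "duplex_pairs", "max_bulge", "asymmetry",
          "copies", count_cols)]
}

window_extents <- function(params) {
  unique(pmin(c(40L, 70L, 110L, 160L, 220L, params$max_space),
              params$max_space))
}

# Fold one window, locate the star, excise the stem-loop core
# (mature + loop + star), refold it and evaluate. The candidate's
# statistics and MFE come from the core fold — flanking sequence would
# otherwise compete with the star for mature pairing — while the
# reported precursor span extends `flank` nt beyond the core. Returns
# NULL when no star can be located in the window.
evaluate_window <- function(hit, win, chrom_seq, params) {
  wseq <- substr(chrom_seq, win$start, win$end)
  if (hit$strand == "-") wseq <- revcomp(wseq)
  mrel <- rel_from_genomic(hit$start, hit$end, win$start, win$end, hit$strand)
  wf <- fold(wseq)
  st <- duplex_stats(wf, mrel, max_bulge = params$max_bulge)
  if (!st$ok) return(NULL)
  p1 <- min(mrel[1], st$star_interval[1])
  p2 <- max(mrel[2], st$star_interval[2])
  core <- fold(substr(wseq, p1, p2))
  ev <- evaluate_candidate(core, c(mrel[1] - p1 + 1L, mrel[2] - p1 + 1L), params)
  # reported precursor: core plus flank, mapped back through the window
  f1 <- max(1L, p1 - params$flank)
  f2 <- min(nchar(wseq), p2 + params$flank)
  grel <- genomic_from_rel(f1, f2, win$start, win$end, hit$strand)
  list(eval = ev, chromosome = hit$chromosome, strand = hit$strand,
       prec = grel)
}

better_candidate <- function(a, b) {
  if (a$eval$mfe != b$eval$mfe) return(a$eval$mfe < b$eval$mfe)
  la <- a$prec[2] - a$prec[1]; lb <- b$prec[2] - b$prec[1]
  if (la != lb) return(la < lb)
  if (a$chromosome != b$chromosome) return(a$chromosome < b$chromosome)
  a$prec[1] < b$prec[1]
}

#' Quantify known miRNAs by exact alignment
#'
#' A tag counts toward a known miRNA when it equals the mature sequence
#' exactly or lies exactly within the precursor. A tag matching several
#' known miRNAs is counted for each and the records are flagged
#' multi-assigned.
#'
#' @param tags tag table (`sequence` plus count columns).
#' @param mature named character vector of mature sequences.
#' @param precursor optional named character vector of precursor
#'   sequences (names matching `mature` where available).
#' @return data.frame with `mirna`, one summed column per tag count
#'   column, and `multi_assigned`.
#' @export
quantify_known <- function(tags, mature, precursor = NULL) {
  count_cols <- grep("^count", names(tags), value = TRUE)
  mature <- vapply(mature, as_dna, "")
  precursor <- if (is.null(precursor)) character(0) else vapply(precursor, as_dna, "")
  ids <- union(names(mature), names(precursor))
  seqs <- as_dna(tags$sequence)
  assign_n <- integer(nrow(tags))
  out <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  for (cc in count_cols) out[[cc]] <- 0
  out$multi_assigned <- FALSE
  match_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    hit <- rep(FALSE, nrow(tags))
    if (id %in% names(mature)) hit <- hit | seqs == mature[[id]]
    if (id %in% names(precursor)) {
      inprec <- vapply(seqs, function(s)
        grepl(s, precursor[[id]], fixed = TRUE), logical(1), USE.NAMES = FALSE)
      hit <- hit | inprec
    }
    match_rows[[i]] <- which(hit)
    assign_n[hit] <- assign_n[hit] + 1L
    for (cc in count_cols) out[[cc]][i] <- sum(tags[[cc]][hit])
  }
  out$multi_assigned <- vapply(match_rows, function(r)
    any(assign_n[r] > 1L), logical(1))
  out
}
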