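# Priority-rule annotation: every unique tag maps to exactly one category.
# Structural RNA (Genbank tier before Rfam tier) beats known miRNA, which
# beats repeats, exons, then introns; tags matching nothing are "unann".
# siRNA membership is assigned afterwards by the duplex detector.

STRUCTURAL_CATEGORIES <- c("rRNA", "scRNA", "snRNA", "snoRNA", "tRNA")
ANNOTATION_CATEGORIES <- c(STRUCTURAL_CATEGORIES, "miRNA", "repeat",
                           "exon", "intron")
SUMMARY_CATEGORIES <- c("exon_antisense", "exon_sense", "intron_antisense",
                        "intron_sense", "miRNA", "rRNA", "scRNA", "siRNA",
                        "snRNA", "snoRNA", "tRNA", "unann")

#' Build an annotation database of categorized intervals
#'
#' @param x a `GRanges` with a `category` metadata column (values among
#'   `r paste(ANNOTATION_CATEGORIES, collapse = ", ")`) and an optional
#'   `tier` column (`"genbank"` or `"rfam"`, structural RNA only; default
#'   genbank), or a GFF3 path whose feature-type column holds the
#'   category and whose source column holds the tier.
#' @return an `annotation_db` object.
#' @export
build_annotation_db <- function(x) {
  if (is.character(x) && length(x) == 1) {
    gr <- rtracklayer::import(x, format = "gff3")
    S4Vectors::mcols(gr)$category <- as.character(S4Vectors::mcols(gr)$type)
    src <- as.character(S4Vectors::mcols(gr)$source)
    S4Vectors::mcols(gr)$tier <- ifelse(!is.na(src) & src == "rfam",
                                        "rfam", "genbank")
  } else {
    gr <- x
    if (is.null(S4Vectors::mcols(gr)$tier))
      S4Vectors::mcols(gr)$tier <- "genbank"
  }
  cat <- S4Vectors::mcols(gr)$category
  bad <- setdiff(unique(cat), ANNOTATION_CATEGORIES)
  if (length(bad))
    stop("unknown annotation category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(gr = gr), class = "annotation_db")
}

# Priority rank of a (category, tier) pair; smaller wins. Structural RNA
# categories tie-break among themselves in a fixed order for determinism.
category_rank <- function(category, tier) {
  base <- match(category, STRUCTURAL_CATEGORIES)
  structural <- !is.na(base)
  rank <- numeric(length(category))
  rank[structural] <- ifelse(tier[structural] == "rfam", 100, 0) + base[structural]
  rank[category == "miRNA"] <- 200
  rank[category == "repeat"] <- 300
  rank[category == "exon"] <- 400
  rank[category == "intron"] <- 500
  rank
}

#' Annotate mapped tags by the priority rule
#'
#' A hit claims a category only when it is fully contained in the
#' interval (strict containment; partial overlaps do not count). Across
#' all hits of a tag the highest-priority category wins; exon and intron
#' assignments record sense/antisense from strand agreement between the
#' hit and the interval. Tags whose hits fall outside every interval (or
#' with no hits) are `unann`. The result is independent of hit order.
#'
#' @param hits a [map_library()] result, or a list of per-tag hit
#'   data.frames.
#' @param db an [build_annotation_db()] result.
#' @param n number of tags (defaults to the length of the per-tag hit
#'   list; required precision only when passing a bare flat table).
#' @return data.frame with `category` (one of
#'   `r paste(setdiff(SUMMARY_CATEGORIES, "siRNA"), collapse = ", ")` or
#'   `repeat`) and `winning_hit` (row index into the tag's hit table, NA
#'   for unann), one row per tag.
#' @export
annotate_tags <- function(hits, db, n = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  flat <- hits_flat(hits)
  if (is.null(n))
    n <- if (!is.null(hits$hits)) length(hits$hits) else length(hits)
  out <- data.frame(category = rep("unann", n),
                    winning_hit = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (nrow(flat) == 0 || length(db$gr) == 0) return(out)
  tag_idx <- flat$tag
  hit_idx <- stats::ave(seq_len(nrow(flat)), flat$tag, FUN = seq_along)
  hg <- GenomicRanges::GRanges(flat$chromosome,
                               IRanges::IRanges(flat$start, flat$end),
                               strand = flat$strand)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hg, db$gr, type = "within", ignore.strand = TRUE))
  if (length(ov) == 0) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  cat <- S4Vectors::mcols(db$gr)$category[s]
  tier <- S4Vectors::mcols(db$gr)$tier[s]
  rank <- category_rank(cat, tier)
  sense <- as.character(GenomicRanges::strand(hg))[q] ==
    as.character(GenomicRanges::strand(db$gr))[s]
  label <- ifelse(cat %in% c("exon", "intron"),
                  paste0(cat, ifelse(sense, "_sense", "_antisense")), cat)
  # within each tag: minimal rank; ties broken by label then hit index so
  # the assignment is independent of input hit order
  o <- order(tag_idx[q], rank, label, hit_idx[q])
  first <- !duplicated(tag_idx[q][o])
  w <- o[first]
  out$category[tag_idx[q][w]] <- label[w]
  out$winning_hit[tag_idx[q][w]] <- hit_idx[q][w]
  out
}

empty_annotation <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$category <- character(0)
  S4Vectors::mcols(gr)$tier <- character(0)
  gr
}

#' Annotate a single tag
#'
#' @param tag_hits hit data.frame of one tag.
#' @param db an [build_annotation_db()] result.
#' @return the tag's category string.
#' @export
annotate_tag <- function(tag_hits, db) {
  annotate_tags(list(tag_hits), db)$category
}

#' Promote duplex members to the siRNA category
#'
#' siRNA membership is decided after priority annotation and claims only
#' tags that would otherwise be unannotated or exon/intron fragments, so
#' structural RNA and known miRNA assignments stay stable.
#'
#' @param categories character vector of per-tag categories.
#' @param tags tag table whose rows align with `categories`.
#' @param pairs [find_sirna_duplexes()] result.
#' @return updated category vector.
#' @export
assign_sirna <- function(categories, tags, pairs) {
  if (nrow(pairs) == 0) return(categories)
  members <- unique(c(pairs$plus_tag, pairs$minus_tag))
  claimable <- categories %in% c("unann", "exon_sense", "exon_antisense",
                                 "intron_sense", "intron_antisense")
  categories[claimable & tags$sequence %in% members] <- "siRNA"
  categories
}

#' Category composition summary
#'
#' @param tags tag table with `sequence` and one or two count columns.
#' @param categories per-tag category vector ([annotate_tags()], possibly
#'   after [assign_sirna()]).
#' @param count_col count column for the total weighting.
#' @return data.frame with one row per category (standard row order,
#'   plus `repeat` when present): `unique`, `unique_pct`, `total`,
#'   `total_pct`. Unique counts sum to the number of distinct tags and
#'   total counts to the clean read count, exactly.
#' @export
category_summary <- function(tags, categories, count_col = "count") {
  rows <- SUMMARY_CATEGORIES
  if (any(categories == "repeat")) rows <- c(rows, "repeat")
  uniq <- vapply(rows, function(cc) sum(categories == cc), integer(1))
  tot <- vapply(rows, function(cc) sum(tags[[count_col]][categories == cc]),
                numeric(1))
  u_den <- max(nrow(tags), 1L)
  t_den <- max(sum(tags[[count_col]]), 1)
  data.frame(category = rows, unique = uniq,
             unique_pct = round(uniq / u_den * 100, 2),
             total = tot, total_pct = round(tot / t_den * 100, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
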