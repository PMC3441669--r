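# Digital differential expression between two small RNA libraries:
# tags-per-million normalization, log2 fold changes, and the
# Audic-Claverie conditional test on raw counts.
#
# With x reads of a miRNA among N1 clean reads in the control (+S)
# library and y among N2 in the treatment (-S) library, the conditional
# probability of y given x is
#
#   p(y|x) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1)
#
# a negative binomial in y with size x+1 and success probability
# N2/(N1+N2). The reported p-value conditions on the treatment count and
# doubles the tail of the control count in the direction of the observed
# change (a two-sided test): p = 2*C(x' <= x | y) for up-regulation,
# 2*D(x' >= x | y) for down-regulation, capped at 1. This convention
# reproduces published p-values of this test digit for digit. All sums
# run in log space.

#' Tags-per-million normalization
#'
#' `count / total * 1e6`; report rendering rounds to 4 decimals.
#'
#' @param count raw read count (>= 0).
#' @param total library total of clean reads (>= 1).
#' @return normalized expression, reads per million.
#' @examples
#' tpm(28, 10029992)  # 2.7916 at 4 decimals
#' @export
tpm <- function(count, total) {
  if (any(total < 1)) stop("library total must be >= 1", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / total * 1e6
}

#' Log2 fold change, treatment over control
#'
#' @param tpm_treatment,tpm_control normalized expressions, both > 0.
#' @return `log2(treatment / control)`; antisymmetric under swap.
#' @export
log2_fc <- function(tpm_treatment, tpm_control) {
  if (any(tpm_treatment <= 0) || any(tpm_control <= 0))
    stop("fold change undefined for zero expression; use specificity calls",
         call. = FALSE)
  log2(tpm_treatment / tpm_control)
}

#' Log of the Audic-Claverie conditional probability p(y|x)
#'
#' Evaluated via log-gamma, so counts up to 1e7 and totals up to 1e8 are
#' handled without overflow.
#'
#' @param x,y non-negative integer counts in the control and treatment
#'   libraries (vectorized over `y`).
#' @param N1,N2 library totals (>= 1).
#' @return log probability (the probability itself lies in (0, 1\]).
#' @export
ac_log_pmf <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("negative counts", call. = FALSE)
  stopifnot(N1 >= 1, N2 >= 1)
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Audic-Claverie p-value
#'
#' Conditions on the treatment count `y` and doubles the tail of the
#' control count in the direction of the observed change: for
#' up-regulation (`y/N2 >= x/N1`) the p-value is `2 * C(x' <= x | y)`,
#' for down-regulation `2 * D(x' >= x | y)`, capped at 1 — the two-sided
#' convention that reproduces published values of this test exactly.
#' Tails are summed in log space until the running terms are negligible
#' (relative contribution below `tol`).
#'
#' @param x,y observed counts (control, treatment).
#' @param N1,N2 library totals (control, treatment).
#' @param tol relative convergence cutoff for the infinite tail
#'   (default 1e-15).
#' @return p-value in (0, 1\].
#' @export
ac_pvalue <- function(x, y, N1, N2, tol = 1e-15) {
  pmin(1, 2 * ac_one_tail(y, x, N2, N1, tol = tol))
}

# single conditional tail: D(y' >= y | x) when the second library's
# frequency is at or above the first's, else C(y' <= y | x)
ac_one_tail <- function(x, y, N1, N2, tol = 1e-15) {
  if (length(x) == 0) return(numeric(0))
  if (length(x) > 1 || length(y) > 1)
    return(mapply(ac_one_tail, x, y,
                  MoreArgs = list(N1 = N1, N2 = N2, tol = tol)))
  if (y / N2 >= x / N1) {
    # upper tail D(y' >= y | x): sum in blocks until terms vanish
    acc <- -Inf
    y0 <- y
    block <- 256L
    repeat {
      ys <- y0:(y0 + block - 1L)
      lp <- ac_log_pmf(x, ys, N1, N2)
      acc <- log_sum_exp(c(acc, lp))
      # terms are eventually strictly decreasing; stop once the whole
      # last block is negligible against the accumulated mass
      if (max(lp) < acc + log(tol) && ys[1] > (x + 1) * N2 / N1) break
      y0 <- y0 + block
    }
    min(exp(acc), 1)
  } else {
    min(exp(log_sum_exp(ac_log_pmf(x, 0:y, N1, N2))), 1)
  }
}

#' Significance label from a p-value
#'
#' `"**"` below 0.01, `"*"` in `[0.01, 0.05)`, `""` otherwise.
#'
#' @param pvalue numeric vector in \[0, 1\].
#' @return character vector of labels.
#' @export
sig_label <- function(pvalue) {
  stopifnot(all(pvalue >= 0 & pvalue <= 1, na.rm = TRUE))
  ifelse(is.na(pvalue), "",
         ifelse(pvalue < 0.01, "**", ifelse(pvalue < 0.05, "*", "")))
}

#' Differential expression table of two count sets
#'
#' Records present in both libraries get a log2 fold change and an
#' Audic-Claverie p-value; records with zero count in exactly one library
#' get a condition-specificity call (`plus_only` / `minus_only`) and no
#' fold change. The significant subset is |log2 FC| >= `fc_threshold`
#' with p < `p_threshold`, or a condition-specific record whose nonzero
#' count reaches `specific_floor` reads.
#'
#' @param counts_plus,counts_minus named numeric vectors of raw counts
#'   (control +S and treatment -S); ids missing from one library are
#'   treated as zero there.
#' @param N1,N2 clean-read totals of the two libraries.
#' @param fc_threshold minimum |log2 FC| (default 1, i.e. linear fold 2).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param specific_floor minimum reads for a condition-specific call to
#'   be significant (default 10).
#' @return data.frame with `mirna`, `x`, `y`, `tpm_plus`, `tpm_minus`,
#'   `log2fc`, `pvalue`, `sig`, `specificity`, `significant`.
#' @export
diff_table <- function(counts_plus, counts_minus, N1, N2,
                       fc_threshold = 1, p_threshold = 0.05,
                       specific_floor = 10) {
  ids <- union(names(counts_plus), names(counts_minus))
  x <- ifelse(ids %in% names(counts_plus), counts_plus[ids], 0)
  y <- ifelse(ids %in% names(counts_minus), counts_minus[ids], 0)
  tp <- tpm(x, N1); tm <- tpm(y, N2)
  both <- x > 0 & y > 0
  log2fc <- rep(NA_real_, length(ids))
  pval <- rep(NA_real_, length(ids))
  log2fc[both] <- log2_fc(tm[both], tp[both])
  pval[both] <- ac_pvalue(x[both], y[both], N1, N2)
  specificity <- ifelse(both | (x == 0 & y == 0), "both",
                        ifelse(x > 0, "plus_only", "minus_only"))
  significant <- (both & !is.na(log2fc) & abs(log2fc) >= fc_threshold &
                    pval < p_threshold) |
    (specificity != "both" & pmax(x, y) >= specific_floor)
  data.frame(mirna = ids, x = unname(x), y = unname(y),
             tpm_plus = unname(tp), tpm_minus = unname(tm),
             log2fc = log2fc, pvalue = pval, sig = sig_label(pval),
             specificity = specificity, significant = significant,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Render a differential expression table with report headers
#'
#' TPM columns are rounded to 4 decimals and the fold change to 8, the
#' standard printed precision of such reports.
#'
#' @param dt a [diff_table()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(dt, path) {
  out <- data.frame(
    "miR-name" = dt$mirna,
    "+S-std" = sprintf("%.4f", dt$tpm_plus),
    "-S-std" = sprintf("%.4f", dt$tpm_minus),
    "fold-change (log2 -S/+S)" = ifelse(is.na(dt$log2fc), "-",
                                        sprintf("%.8f", dt$log2fc)),
    "p-value" = ifelse(is.na(dt$pvalue), "-", format(dt$pvalue)),
    "sig-lable" = dt$sig,
    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}
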