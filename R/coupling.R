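# Tail/TE coupling statistics: Spearman correlations, binned-median TE
# summaries, change-coupling on relative or absolute tail scales, and the
# poly(A)-selection-bias diagnostic.

#' Spearman rank correlation with typed degeneracy errors
#'
#' Spearman's rho with average-rank tie handling (ranks, then Pearson).
#' Undefined correlations (fewer than 3 pairs, or zero variance in either
#' input) raise an error of class `tailTE_error_undefined_correlation`
#' rather than propagating `NA`.
#'
#' @param x,y paired numeric vectors over the same gene set.
#' @return list with `r_s` and `n`.
#' @export
rank_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must be paired",
              "tailTE_error_invalid")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::var(x) == 0 || stats::var(y) == 0) {
    abort_tailTE("rank correlation undefined (n < 3 or zero variance)",
                 "tailTE_error_undefined_correlation")
  }
  list(r_s = stats::cor(x, y, method = "spearman"), n = n)
}

#' Median TE within poly(A)-tail length bins
#'
#' Genes are binned by mean tail length into half-open bins
#' `[0, w), [w, 2w), ...` anchored at 0; the median centred log2 TE is
#' reported per bin, together with the linear-fold ratio of the median TE
#' between two named bins (default `[70, 80)` over `[30, 40)`, the
#' "steepness" summary). Bins with fewer than `min_bin_n` genes are
#' reported but flagged; if either named bin is empty or flagged thin, the
#' ratio is `NA` and flagged.
#'
#' @param tails named vector of mean tail lengths (nt).
#' @param te named vector of centred log2 TE (same genes).
#' @param bin_width bin width in nt (default 10).
#' @param ratio_bins numeric length-2: lower edges of the numerator and
#'   denominator bins (default `c(70, 30)`).
#' @param min_bin_n minimum genes per bin before flagging (default 10).
#' @return list with `bin_medians` (data frame: `bin_lo`, `bin_hi`,
#'   `median_te`, `n`, `flagged`), `bin_ratio`, `ratio_flagged`.
#' @export
binned_median_te <- function(tails, te, bin_width = 10,
                             ratio_bins = c(70, 30), min_bin_n = 10) {
  genes <- intersect(names(tails), names(te))
  assert_that(length(genes) > 0, "no shared genes", "tailTE_error_invalid")
  tl <- tails[genes]; v <- te[genes]
  lo <- floor(tl / bin_width) * bin_width
  grp <- split(v, lo)
  bin_lo <- as.numeric(names(grp))
  bm <- data.frame(
    bin_lo = bin_lo, bin_hi = bin_lo + bin_width,
    median_te = vapply(grp, median_midpoint, numeric(1)),
    n = lengths(grp))
  bm$flagged <- bm$n < min_bin_n
  bm <- bm[order(bm$bin_lo), ]
  rownames(bm) <- NULL
  med_at <- function(edge) {
    i <- which(bm$bin_lo == edge)
    if (!length(i)) NA_real_ else bm$median_te[i]
  }
  m_num <- med_at(ratio_bins[1])
  m_den <- med_at(ratio_bins[2])
  ratio <- 2^(m_num - m_den)
  flagged <- is.na(ratio) ||
    any(bm$flagged[bm$bin_lo %in% ratio_bins])
  list(bin_medians = bm, bin_ratio = ratio, ratio_flagged = flagged)
}

#' Coupling between TE changes and tail-length changes
#'
#' Spearman correlation between centred log2 TE change and either the
#' tail log2 fold change (`scale = "relative"`) or the absolute
#' difference of mean tails in nt (`scale = "absolute"`).
#'
#' @param changes data frame from [compute_fold_changes()] (restricted to
#'   genes passing pairwise cutoffs).
#' @param scale `"relative"` or `"absolute"`.
#' @param drop_unreliable drop genes flagged `tail_unreliable`
#'   (default `FALSE`).
#' @return list with `r_s`, `n`, `scale`.
#' @export
change_coupling <- function(changes, scale = c("relative", "absolute"),
                            drop_unreliable = FALSE) {
  scale <- match.arg(scale)
  need <- c("log2_fc_te",
            if (scale == "relative") "log2_fc_tail" else "delta_tail_nt")
  missing <- setdiff(need, names(changes))
  assert_that(!length(missing),
              sprintf("change table missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "tailTE_error_schema")
  if (drop_unreliable && "tail_unreliable" %in% names(changes)) {
    changes <- changes[!changes$tail_unreliable, , drop = FALSE]
  }
  x <- if (scale == "relative") changes$log2_fc_tail else changes$delta_tail_nt
  rc <- rank_correlation(x, changes$log2_fc_te)
  c(rc, list(scale = scale))
}

#' Poly(A)-selection-bias diagnostic
#'
#' Correlates measured RNA abundance (RPM) with mean poly(A)-tail length.
#' Under unbiased RNA-seq these should be essentially uncorrelated before
#' zygotic transcription; a materially positive correlation indicates
#' that poly(A) selection depleted short-tailed mRNAs from the RNA-seq
#' library (and hence inflated their apparent TEs).
#'
#' @param rna_rpm named vector of RNA RPM.
#' @param tails named vector of mean tail lengths (nt), same genes.
#' @return list with `r_s` and `n`.
#' @export
abundance_tail_bias <- function(rna_rpm, tails) {
  genes <- intersect(names(rna_rpm), names(tails))
  rank_correlation(rna_rpm[genes], tails[genes])
}
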