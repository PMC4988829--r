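# Genotype-contrast analyses: dependent regulated-set definition,
# tail-shortening census, Wilcoxon rank-sum set-shift tests, and
# footprint concordance between genotypes.

#' Define up/down regulated sets dependent on a factor
#'
#' A gene is called dependent-upregulated when its centred log2 TE change
#' is at least `threshold_log2` in both comparisons (and symmetrically for
#' downregulated). With the default threshold of 2 this is the ">= 4-fold
#' in both comparisons" rule. Comparison A is typically mutant-affected
#' transition in wild type; comparison B wild type vs mutant.
#'
#' @param fc_pair_a,fc_pair_b named vectors of centred log2 TE changes
#'   from the two comparisons (genes passing the pairwise cutoffs of
#'   each). Mismatched universes are restricted to the intersection.
#' @param threshold_log2 linear 4-fold = 2 (default).
#' @return list with `up_ids`, `down_ids` (sorted, disjoint),
#'   `threshold_log2`, `n_universe`, `n_dropped`.
#' @export
define_dependent_sets <- function(fc_pair_a, fc_pair_b, threshold_log2 = 2) {
  genes <- intersect(names(fc_pair_a), names(fc_pair_b))
  n_dropped <- length(union(names(fc_pair_a), names(fc_pair_b))) -
    length(genes)
  a <- fc_pair_a[genes]; b <- fc_pair_b[genes]
  list(up_ids = sort(genes[a >= threshold_log2 & b >= threshold_log2]),
       down_ids = sort(genes[a <= -threshold_log2 & b <= -threshold_log2]),
       threshold_log2 = threshold_log2,
       n_universe = length(genes), n_dropped = n_dropped)
}

#' Census of genes with substantially shortened tails
#'
#' Counts genes whose mutant mean tail is at least `fraction` shorter
#' than wild type (`mut <= (1 - fraction) * wt`, boundary inclusive),
#' over the universe of genes with at least `min_tags` tail measurements
#' in both samples. Raw (un-floored) means are used.
#'
#' @param wt,mut tail-summary data frames from [summarize_tails()], one
#'   sample each.
#' @param fraction shortening threshold (default 0.5).
#' @param min_tags universe tag cutoff (default 100).
#' @return list with `n_measured`, `n_shortened`, and a per-gene data
#'   frame `tails` (`gene_id`, `wt_mean`, `mut_mean`, `shortened`).
#' @export
fraction_tail_shortened <- function(wt, mut, fraction = 0.5, min_tags = 100) {
  wt_ok <- wt[wt$tag_count >= min_tags, ]
  mut_ok <- mut[mut$tag_count >= min_tags, ]
  genes <- intersect(wt_ok$gene_id, mut_ok$gene_id)
  if (!length(genes)) {
    return(list(n_measured = 0L, n_shortened = 0L,
                tails = data.frame(gene_id = character(0),
                                   wt_mean = numeric(0),
                                   mut_mean = numeric(0),
                                   shortened = logical(0))))
  }
  wtm <- stats::setNames(wt_ok$mean_tail_nt, wt_ok$gene_id)[genes]
  mtm <- stats::setNames(mut_ok$mean_tail_nt, mut_ok$gene_id)[genes]
  shortened <- mtm <= (1 - fraction) * wtm
  list(n_measured = length(genes), n_shortened = sum(shortened),
       tails = data.frame(gene_id = genes, wt_mean = as.numeric(wtm),
                          mut_mean = as.numeric(mtm),
                          shortened = as.logical(shortened),
                          stringsAsFactors = FALSE))
}

# Exact or approximate Wilcoxon rank-sum p-value for the sum of set ranks.
# Exact: full enumeration over all assignments of the observed values
# (handles ties exactly); used when the enumeration is small. Otherwise a
# normal approximation with tie correction and continuity correction.
ranksum_p <- function(values, in_set, alternative, max_enum = 1e5) {
  n <- length(values)
  m <- sum(in_set)
  r <- rank(values)
  w_obs <- sum(r[in_set])
  n_comb <- choose(n, m)
  if (min(m, n - m) <= 8 && n_comb <= max_enum) {
    combs <- utils::combn(n, m)
    w_all <- colSums(matrix(r[combs], nrow = m))
    eps <- 1e-9
    p_greater <- mean(w_all >= w_obs - eps)
    p_less <- mean(w_all <= w_obs + eps)
    method <- "exact enumeration"
  } else {
    mu <- m * (n + 1) / 2
    ties <- table(r)
    sigma2 <- m * (n - m) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((w_obs - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((w_obs + 0.5 - mu) / sigma)
    method <- "normal approximation (tie + continuity corrected)"
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  list(p_value = min(1, p), statistic = w_obs, method = method)
}

#' Gene-set shift test (Wilcoxon rank sum)
#'
#' Tests whether the metric values of a gene set are shifted relative to
#' the complement, with average-rank tie handling. For small problems the
#' null is enumerated exactly; otherwise a tie- and continuity-corrected
#' normal approximation is used. Reports the set median and cohort
#' median, and the set median relative to the cohort median (the
#' "relative to the median of all mRNAs" descriptive statistic).
#'
#' @param values named numeric vector over the cohort.
#' @param set_ids gene ids in the set (non-empty proper subset).
#' @param alternative `"greater"`, `"less"` (one-tailed: set values
#'   greater/less than the complement) or `"two.sided"`.
#' @return list of class `set_shift_result`: `p_value`, `statistic`,
#'   `set_median`, `cohort_median`, `set_shift` (set median minus cohort
#'   median), `n_set`, `n_rest`, `alternative`, `method`.
#' @export
set_shift_test <- function(values, set_ids,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  assert_that(!is.null(names(values)), "values must be named by gene id",
              "tailTE_error_invalid")
  in_set <- names(values) %in% set_ids
  assert_that(any(in_set) && !all(in_set),
              "set must be a non-empty proper subset of the cohort",
              "tailTE_error_invalid")
  rs <- ranksum_p(values, in_set, alternative)
  structure(list(
    p_value = rs$p_value, statistic = rs$statistic,
    set_median = median_midpoint(values[in_set]),
    cohort_median = median_midpoint(values),
    set_shift = median_midpoint(values[in_set]) - median_midpoint(values),
    n_set = sum(in_set), n_rest = sum(!in_set),
    alternative = alternative, method = rs$method
  ), class = "set_shift_result")
}

#' Gene-set tail-length ratio test
#'
#' Per-gene metric `log2(mut_mean / wt_mean)` over the universe of genes
#' with enough tags in both samples; a one-tailed rank-sum test of
#' whether the gene set's ratios exceed the rest (i.e. the set is less
#' shortened than other genes). Genes with a zero wild-type mean are
#' excluded (undefined ratio).
#'
#' @inheritParams fraction_tail_shortened
#' @param geneset_ids gene ids of interest (e.g. ribosomal proteins).
#' @param alternative default `"greater"` (set less shortened).
#' @return a `set_shift_result` (see [set_shift_test()]) with an
#'   additional `n_excluded` field.
#' @export
geneset_tail_ratio_test <- function(wt, mut, geneset_ids, min_tags = 100,
                                    alternative = "greater") {
  census <- fraction_tail_shortened(wt, mut, min_tags = min_tags)
  tl <- census$tails
  bad <- tl$wt_mean == 0
  tl <- tl[!bad, , drop = FALSE]
  ratios <- stats::setNames(log2(tl$mut_mean / tl$wt_mean), tl$gene_id)
  res <- set_shift_test(ratios, geneset_ids, alternative = alternative)
  res$n_excluded <- sum(bad)
  res
}

#' Footprint concordance between two samples
#'
#' Spearman correlation of ribosome-footprint RPM between two samples
#' over the union of genes with at least `min_rpm` in either, after
#' giving any gene with 0 reads in either sample a pseudocount of 1 read.
#' Genes with reads in exactly one sample are listed as dropouts
#' (candidate strongly factor-dependent mRNAs).
#'
#' @param expr_a,expr_b expression tables from [normalize_expression()],
#'   one sample each (need `rpf_count`, `rpf_total`, `rpf_rpm`).
#' @param min_rpm inclusion cutoff in RPF RPM (default 10).
#' @return list with `r_s`, `n`, `dropouts` (data frame: `gene_id`,
#'   `rpm_a`, `rpm_b`, `zero_in`).
#' @export
rpf_concordance <- function(expr_a, expr_b, min_rpm = 10) {
  genes <- union(expr_a$gene_id, expr_b$gene_id)
  get <- function(df, col) {
    v <- stats::setNames(df[[col]], df$gene_id)[genes]
    v[is.na(v)] <- 0
    v
  }
  rpm_a <- get(expr_a, "rpf_rpm"); rpm_b <- get(expr_b, "rpf_rpm")
  cnt_a <- get(expr_a, "rpf_count"); cnt_b <- get(expr_b, "rpf_count")
  tot_a <- expr_a$rpf_total[1]; tot_b <- expr_b$rpf_total[1]
  keep <- pmax(rpm_a, rpm_b) >= min_rpm
  genes <- genes[keep]
  rpm_a <- rpm_a[keep]; rpm_b <- rpm_b[keep]
  cnt_a <- cnt_a[keep]; cnt_b <- cnt_b[keep]
  zero_a <- cnt_a == 0; zero_b <- cnt_b == 0
  rpm_a[zero_a] <- 1 / tot_a * 1e6
  rpm_b[zero_b] <- 1 / tot_b * 1e6
  rc <- rank_correlation(rpm_a, rpm_b)
  drop_sel <- xor(zero_a, zero_b)
  dropouts <- data.frame(
    gene_id = genes[drop_sel],
    rpm_a = as.numeric(rpm_a[drop_sel]), rpm_b = as.numeric(rpm_b[drop_sel]),
    zero_in = ifelse(zero_a[drop_sel], "a", "b"),
    stringsAsFactors = FALSE)
  rownames(dropouts) <- NULL
  c(rc, list(dropouts = dropouts))
}
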