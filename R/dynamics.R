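# Short time-series model-profile clustering of TE trajectories.
#
# Gene trajectories (centred log2 TE normalised to the first stage) are
# assigned to an exhaustively enumerated set of integer model profiles
# with bounded per-step change; profile enrichment is assessed against a
# per-gene permutation null with a binomial upper tail and Bonferroni
# correction. The permutation/binomial enrichment computation is this
# package's defined surrogate for the clustering method it emulates, and
# is labelled as such in outputs.

#' Enumerate integer model profiles
#'
#' All integer sequences of length `T_points` starting at 0 with per-step
#' changes in `{-c, ..., c}`; there are `(2c+1)^(T-1)` of them. Ordering
#' is deterministic (lexicographic in the step vector, steps `-c` first).
#'
#' @param T_points number of time points (>= 2).
#' @param c maximum per-step change (default 1).
#' @return data frame with `profile_id` and a `values` list-column;
#'   attribute `profile_matrix` holds the same as a matrix (profiles x
#'   time points).
#' @export
enumerate_model_profiles <- function(T_points, c = 1) {
  assert_that(T_points >= 2, "T_points must be >= 2", "tailTE_error_config")
  assert_that(c >= 1, "c must be >= 1", "tailTE_error_config")
  steps <- -c:c
  grids <- rep(list(steps), T_points - 1)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # ordering on the step vector itself
  g <- do.call(expand.grid, rev(grids))
  g <- as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
  cum <- if (ncol(g) == 1) g else t(apply(g, 1, cumsum))
  mat <- cbind(0, cum)
  colnames(mat) <- paste0("t", seq_len(T_points))
  rownames(mat) <- NULL
  out <- data.frame(profile_id = seq_len(nrow(mat)))
  out$values <- I(lapply(seq_len(nrow(mat)), function(i) as.numeric(mat[i, ])))
  attr(out, "profile_matrix") <- mat
  out
}

#' Normalise TE trajectories to the first stage
#'
#' Subtracts each gene's first-stage value so every trajectory starts at
#' 0. Genes with any missing stage value are excluded (recorded in the
#' `dropped` attribute). Idempotent.
#'
#' @param te matrix of centred log2 TE values (genes x stages, ordered).
#' @return matrix of normalised trajectories.
#' @export
normalize_trajectories <- function(te) {
  assert_that(is.matrix(te) && ncol(te) >= 2,
              "te must be a genes x stages matrix with >= 2 stages",
              "tailTE_error_invalid")
  complete <- stats::complete.cases(te)
  dropped <- rownames(te)[!complete]
  te <- te[complete, , drop = FALSE]
  out <- te - te[, 1]
  attr(out, "dropped") <- dropped
  out
}

# Pearson correlation of each row of `vec_mat` against each row of
# `prof_mat`; returns genes x profiles matrix. Rows of prof_mat must have
# nonzero variance.
profile_correlations <- function(vec_mat, prof_mat) {
  vz <- vec_mat - rowMeans(vec_mat)
  pz <- prof_mat - rowMeans(prof_mat)
  vs <- sqrt(rowSums(vz^2))
  ps <- sqrt(rowSums(pz^2))
  (vz %*% t(pz)) / outer(vs, ps)
}

#' Assign gene trajectories to model profiles
#'
#' Genes are eligible when the spread of their normalised trajectory
#' (max - min, i.e. the largest log2 fold change between any two stages)
#' is at least `eligibility`. Each eligible gene is assigned to the
#' profile maximising the Pearson correlation between its trajectory and
#' the profile values; ties go to the lowest profile id. The constant
#' all-zero profile has undefined correlation and is unassignable.
#'
#' @param normalized matrix from [normalize_trajectories()].
#' @param profiles from [enumerate_model_profiles()] (same number of time
#'   points).
#' @param eligibility minimum max-pairwise |log2 difference| (default 0.5).
#' @return data frame with `gene_id`, `eligible`, `profile_id`,
#'   `correlation` (NA for ineligible genes).
#' @export
assign_profiles <- function(normalized, profiles, eligibility = 0.5) {
  pm <- attr(profiles, "profile_matrix")
  assert_that(!is.null(pm) && ncol(pm) == ncol(normalized),
              "profiles and trajectories must share the time axis",
              "tailTE_error_invalid")
  gene_id <- rownames(normalized) %||% as.character(seq_len(nrow(normalized)))
  spread <- apply(normalized, 1, max) - apply(normalized, 1, min)
  eligible <- spread >= eligibility
  out <- data.frame(gene_id = gene_id, eligible = eligible,
                    profile_id = NA_integer_, correlation = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(eligible)) return(out)
  assignable <- which(apply(pm, 1, stats::var) > 0)
  cors <- profile_correlations(normalized[eligible, , drop = FALSE],
                               pm[assignable, , drop = FALSE])
  best <- apply(cors, 1, which.max)   # first maximum = lowest profile id
  out$profile_id[eligible] <- profiles$profile_id[assignable][best]
  out$correlation[eligible] <- cors[cbind(seq_along(best), best)]
  out
}

# all T! orderings of 1..T (T <= 8 expected here)
permutations_of <- function(T_points) {
  if (T_points == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(T_points - 1L)
  out <- vector("list", T_points)
  for (k in seq_len(T_points)) {
    rest <- seq_len(T_points)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), T_points - 1L))
  }
  do.call(rbind, out)
}

#' Permutation-based profile enrichment
#'
#' For every eligible gene, all `T!` orderings of its stage values
#' (exhaustive for `T <= max_exhaustive_T`, otherwise `n_sampled`
#' sampled orderings using the current RNG state) are re-normalised to
#' their first element and re-assigned; the expected size of a profile is
#' the summed per-gene fraction of permutations landing on it. The raw
#' p-value is the upper-tail binomial probability of observing at least
#' the actual count among the eligible genes, and Bonferroni correction
#' is over the number of assignable profiles. Eligibility (max - min of
#' the values) is permutation-invariant, so permuted trajectories of an
#' eligible gene remain eligible.
#'
#' @param assignments from [assign_profiles()].
#' @param normalized the trajectory matrix used for the assignments.
#' @param profiles from [enumerate_model_profiles()].
#' @param max_exhaustive_T exhaustive-permutation limit (default 6).
#' @param n_sampled sampled permutations per gene beyond that (default 200).
#' @param alpha familywise significance level (default 0.05).
#' @return data frame with `profile_id`, `observed`, `expected`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
profile_significance <- function(assignments, normalized, profiles,
                                 max_exhaustive_T = 6, n_sampled = 200,
                                 alpha = 0.05) {
  pm <- attr(profiles, "profile_matrix")
  eligible_genes <- assignments$gene_id[assignments$eligible]
  assignable <- which(apply(pm, 1, stats::var) > 0)
  n_prof <- length(assignable)
  if (!length(eligible_genes)) {
    return(data.frame(profile_id = integer(0), observed = integer(0),
                      expected = numeric(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  }
  T_points <- ncol(normalized)
  if (T_points <= max_exhaustive_T) {
    perms <- permutations_of(T_points)
  } else {
    perms <- t(replicate(n_sampled, sample.int(T_points)))
  }
  pmat <- pm[assignable, , drop = FALSE]
  n_elig <- length(eligible_genes)
  expected <- numeric(nrow(pm))
  vmat <- normalized[eligible_genes, , drop = FALSE]
  for (g in seq_len(n_elig)) {
    v <- vmat[g, ]
    # all orderings, re-normalised to their first element
    pv <- matrix(v[perms], nrow(perms), T_points)
    pv <- pv - pv[, 1]
    cors <- profile_correlations(pv, pmat)
    best <- apply(cors, 1, which.max)
    tab <- tabulate(best, nbins = nrow(pmat))
    expected[assignable] <- expected[assignable] + tab / nrow(perms)
  }
  observed <- tabulate(
    factor(assignments$profile_id[assignments$eligible],
           levels = profiles$profile_id),
    nbins = nrow(pm))
  p_raw <- rep(NA_real_, nrow(pm))
  for (j in assignable) {
    p_raw[j] <- stats::pbinom(observed[j] - 1, n_elig,
                              min(1, expected[j] / n_elig),
                              lower.tail = FALSE)
  }
  res <- data.frame(profile_id = profiles$profile_id,
                    observed = observed, expected = expected,
                    p_raw = p_raw)
  res$p_adjusted <- pmin(1, res$p_raw * n_prof)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res[res$profile_id %in% profiles$profile_id[assignable], ,
      drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Per-profile cluster membership report
#'
#' @param assignments from [assign_profiles()].
#' @param enrichments from [profile_significance()].
#' @return data frame ordered by profile id with member gene lists
#'   (comma-separated), sizes, expected sizes, adjusted p-values and
#'   significance flags. Regenerating from the same inputs is
#'   byte-identical.
#' @export
cluster_report <- function(assignments, enrichments) {
  if (!nrow(enrichments)) {
    return(data.frame(profile_id = integer(0), n_genes = integer(0),
                      expected = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0), genes = character(0)))
  }
  members <- split(assignments$gene_id[assignments$eligible],
                   factor(assignments$profile_id[assignments$eligible],
                          levels = enrichments$profile_id))
  out <- data.frame(
    profile_id = enrichments$profile_id,
    n_genes = enrichments$observed,
    expected = enrichments$expected,
    p_adjusted = enrichments$p_adjusted,
    significant = enrichments$significant,
    genes = vapply(members, function(g) paste(sort(g), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  out[order(out$profile_id), ]
}
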