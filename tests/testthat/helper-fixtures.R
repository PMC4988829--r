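# Shared builders for small in-code fixtures.

# Tiny three-stage config: strong coupling at the first two stages, none
# at the last. Depths scaled down for test speed.
small_config <- function(n_genes = 300, seed = 1, ...) {
  sim_config(n_genes = n_genes, stages = c("early", "mid", "late"),
             coupling_beta = c(1.2, 1.0, 0),
             depth_tags = 2e5, depth_rna = 1e6, depth_rpf = 1e6,
             seed = seed, ...)
}

# Two-stage config around an egg-activation-like transition with png/smg
# genotypes and planted regulons.
activation_config <- function(n_genes = 1000, seed = 1,
                              genotypes = c("wildtype", "png", "smg"),
                              depth = 5e6, ...) {
  n_set <- max(2L, round(0.05 * n_genes))
  sim_config(n_genes = n_genes, stages = c("oocyte", "egg"),
             coupling_beta = c(0.3, 1.2),
             genotypes = genotypes, activation_transition = 1,
             depth_tags = 5e5, depth_rna = depth, depth_rpf = depth,
             genotype_specs = list(png = list(n_up = n_set, n_down = n_set)),
             seed = seed, ...)
}

# A plus-strand single-gene model row for site-calling tests.
toy_model <- function(strand = "+", stop_codon = if (strand == "+") 50
                      else 950, chrom = "chr1") {
  data.frame(gene_id = "gX", tx_id = "txX", chrom = chrom, strand = strand,
             tx_start = if (strand == "+") 0 else 500,
             tx_end = if (strand == "+") 500 else 1000,
             cds_start = if (strand == "+") 10 else 950,
             cds_end = if (strand == "+") 50 else 990,
             stop_codon = stop_codon,
             ref_3p_end = if (strand == "+") 500 else 500,
             final_3p_end = if (strand == "+") 500 else 500,
             excluded = FALSE, exclude_reason = NA_character_,
             stringsAsFactors = FALSE)
}

toy_tags <- function(sites, strand = "+", chrom = "chr1", tail = 50,
                     sample = "s1") {
  data.frame(chrom = chrom, site = sites, strand = strand,
             tail_length = tail, sample = sample, stringsAsFactors = FALSE)
}

# Independent naive implementation of the greedy collapse rule, used as
# an oracle: repeatedly pick max support (tie -> distal), absorb +/- window.
naive_collapse <- function(positions, supports, strand, stop_codon,
                           window = 60, max_utr = 4100) {
  utr <- if (strand == "+") positions - stop_codon else stop_codon - positions
  keep <- utr <= max_utr
  positions <- positions[keep]; supports <- supports[keep]
  kept <- list()
  while (length(positions)) {
    best_sup <- max(supports)
    cand <- which(supports == best_sup)
    if (strand == "+") {
      best <- cand[which.max(positions[cand])]
    } else {
      best <- cand[which.min(positions[cand])]
    }
    absorb <- abs(positions - positions[best]) <= window
    kept[[length(kept) + 1]] <- c(pos = positions[best],
                                  sup = sum(supports[absorb]))
    positions <- positions[!absorb]
    supports <- supports[!absorb]
  }
  if (!length(kept)) {
    return(data.frame(position = numeric(0), tag_support = integer(0)))
  }
  df <- do.call(rbind, kept)
  ord <- order(if (strand == "+") df[, "pos"] else -df[, "pos"])
  data.frame(position = as.numeric(df[ord, "pos"]),
             tag_support = as.integer(df[ord, "sup"]))
}

# Rank-then-Pearson Spearman oracle (explicit formula, not cor()).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact rank-sum p by enumeration of all set assignments of the values.
ranksum_oracle <- function(values, set_idx, alternative) {
  n <- length(values); m <- length(set_idx)
  r <- rank(values)
  w_obs <- sum(r[set_idx])
  combs <- utils::combn(n, m)
  w_all <- colSums(matrix(r[combs], nrow = m))
  eps <- 1e-9
  pg <- mean(w_all >= w_obs - eps)
  pl <- mean(w_all <= w_obs + eps)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}
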