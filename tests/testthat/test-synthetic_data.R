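test_that("sample_tail_lengths draws a unimodal positive family with the right mean", {
  expect_identical(sample_tail_lengths(50, 8, 0), integer(0))
  set.seed(11)
  x <- sample_tail_lengths(50, 8, 1e5)
  expect_true(all(x >= 1))
  expect_true(abs(mean(x) - 50) < 1)
  # variance -> 0 limit
  set.seed(12)
  y <- sample_tail_lengths(50, 1e6, 1000)
  expect_true(all(y %in% 49:51))
  expect_error(sample_tail_lengths(0.5, 8, 10), class = "tailTE_error_config")
  expect_error(sample_tail_lengths(50, 0, 10), class = "tailTE_error_config")
})

test_that("sample_counts matches its Poisson construction", {
  set.seed(5)
  one <- replicate(200, sample_counts(1, 1, 1000, 1000)$rna_counts)
  expect_true(abs(mean(one) - 1000) < 3 * sqrt(1000 / 200))
  # expected RPF ratio follows abundance x TE
  set.seed(6)
  reps <- replicate(400, sample_counts(c(1, 1), c(1, 4), 1e4, 1e4)$rpf_counts)
  expect_true(abs(mean(reps[2, ]) / mean(reps[1, ]) - 4) < 0.2)
  expect_error(sample_counts(c(0, 0), c(1, 1), 10, 10),
               class = "tailTE_error_config")
  # overdispersion knob inflates the variance beyond Poisson
  set.seed(9)
  od <- replicate(500, sample_counts(1, 1, 100, 100,
                                     overdispersion = 0.5)$rna_counts)
  expect_gt(var(od), 3 * 100)
  # goodness of fit against the stated Poisson means at depth 1e6
  set.seed(7)
  a <- rlnorm(1000); te <- rlnorm(1000, sdlog = 0.5)
  cts <- sample_counts(a, te, 1e6, 1e6)
  mu <- 1e6 * a / sum(a)
  keep <- mu >= 10
  chi <- sum((cts$rna_counts[keep] - mu[keep])^2 / mu[keep])
  p <- pchisq(chi, df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("simulate_dataset is byte-deterministic for a fixed seed", {
  cfg <- small_config(n_genes = 50, seed = 7)
  cfg$depth_tags <- 1e4
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$tags, d2$tags)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth$tail_te, d2$truth$tail_te)
  # different seed changes the data
  cfg2 <- small_config(n_genes = 50, seed = 8)
  cfg2$depth_tags <- 1e4
  expect_false(identical(simulate_dataset(cfg2)$counts, d1$counts))
})

test_that("simulate_dataset respects its structural invariants", {
  ds <- simulate_dataset(small_config(n_genes = 100, seed = 3))
  # library size equals the per-gene sum for every sample
  for (s in ds$samples$sample) {
    sub <- ds$counts[ds$counts$sample == s, ]
    ls <- ds$library_sizes[ds$library_sizes$sample == s, ]
    expect_identical(sum(sub$rna_count), as.integer(ls$rna_total))
    expect_identical(sum(sub$rpf_count), as.integer(ls$rpf_total))
    expect_identical(sum(ds$tags$sample == s), as.integer(ls$tag_total))
  }
  # tables reference only manifest genes
  expect_true(all(ds$tags$gene_id %in% ds$truth$genes$gene_id))
  expect_true(all(ds$counts$gene_id %in% ds$truth$genes$gene_id))
  # every gene appears once per (sample) in the truth
  tt <- ds$truth$tail_te
  expect_identical(unname(table(tt$sample)),
                   unname(table(rep(ds$samples$sample, 100))))
})

test_that("coupling_beta = 0 decouples tails from TE in the truth", {
  cfg <- small_config(n_genes = 2000, seed = 2)
  ds <- simulate_dataset(cfg)
  tt <- ds$truth$tail_te
  late <- tt[tt$sample == "wildtype_late", ]
  early <- tt[tt$sample == "wildtype_early", ]
  r_late <- rank_correlation(log2(late$true_mean_tail_nt),
                             late$true_log2_te)$r_s
  r_early <- rank_correlation(log2(early$true_mean_tail_nt),
                              early$true_log2_te)$r_s
  expect_lt(abs(r_late), 0.1)
  expect_gt(r_early, 0.4)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(n_genes = 0), "n_genes",
               class = "tailTE_error_config")
  expect_error(sim_config(stages = c("a", "a"), coupling_beta = c(1, 1)),
               "stages", class = "tailTE_error_config")
  expect_error(sim_config(coupling_beta = c(1, 2)), "coupling_beta",
               class = "tailTE_error_config")
  expect_error(sim_config(depth_rna = 0), "depth_rna",
               class = "tailTE_error_config")
  expect_error(sim_config(genotypes = c("wildtype", "nonsense")),
               "genotypes", class = "tailTE_error_config")
  expect_error(sim_config(genotypes = c("wildtype", "png")),
               "activation_transition", class = "tailTE_error_config")
  expect_error(
    sim_config(profile_classes = list(list(profile = rep(0, 8),
                                           fraction = 1.2, effect = 1))),
    "profile_classes", class = "tailTE_error_config")
})

test_that("apply_genotype implements the three mutant designs", {
  ds <- simulate_dataset(activation_config(n_genes = 200, seed = 4,
                                           depth = 1e6))
  truth <- ds$truth$per_genotype$wildtype

  # wispy with a degenerate shrink range: every tail exactly halves
  spec <- list(shrink_range = c(0.5, 0.5), spared_fraction = 0,
               spared_shrink_range = c(1, 1))
  tr_no_spared <- truth
  tr_no_spared$sets$wispy_spared <- character(0)
  wm <- apply_genotype(tr_no_spared, "wispy", spec)
  expect_equal(2^wm$log2_tail, 2^truth$log2_tail / 2, tolerance = 1e-12)
  expect_equal(cor(2^wm$log2_tail[, 1], 2^truth$log2_tail[, 1],
                   method = "spearman"), 1)

  # png with empty target sets is the identity
  tr_empty <- truth
  tr_empty$sets$png_up <- character(0)
  tr_empty$sets$png_down <- character(0)
  expect_identical(apply_genotype(tr_empty, "png"), tr_empty)

  # png nulls the planted transition change to the cohort median
  pm <- apply_genotype(truth, "png")
  d_wt <- truth$log2_tail[, 2] - truth$log2_tail[, 1]
  d_mut <- pm$log2_tail[, 2] - pm$log2_tail[, 1]
  idx <- match(truth$sets$png_down, truth$genes$gene_id)
  expect_true(all(abs(d_mut[idx] - median(d_wt)) < 1e-12))

  # smg multiplier 0.5 halves the wild-type change for responsive genes
  sm <- apply_genotype(truth, "smg", list(responsive_fraction = 0.7,
                                          multiplier = 0.5))
  ridx <- match(truth$sets$smg_responsive, truth$genes$gene_id)
  expect_equal(unname((sm$log2_tail[, 2] - sm$log2_tail[, 1])[ridx]),
               unname(0.5 * d_wt[ridx]), tolerance = 1e-12)

  expect_error(apply_genotype(truth, "zld"),
               class = "tailTE_error_genotype")
})

test_that("wild-type / mutant contrast datasets preserve tail-change rank order", {
  cfg <- sim_config(n_genes = 500, stages = c("st13", "egg"),
                    coupling_beta = c(1, 1.2),
                    genotypes = c("wildtype", "wispy"),
                    depth_tags = 3e5, depth_rna = 2e6, depth_rpf = 2e6,
                    seed = 9)
  ds <- simulate_dataset(cfg)
  wt <- ds$truth$per_genotype$wildtype
  mu <- ds$truth$per_genotype$wispy
  d_wt <- wt$log2_tail[, 2] - wt$log2_tail[, 1]
  d_mu <- mu$log2_tail[, 2] - mu$log2_tail[, 1]
  expect_gte(cor(d_wt, d_mu, method = "spearman"), 0.8)
})

test_that("fixtures round-trip field for field", {
  cfg <- activation_config(n_genes = 60, seed = 12, depth = 1e5)
  cfg$depth_tags <- 2e4
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  manifest_path <- write_fixture(ds, dir)
  expect_true(file.exists(manifest_path))
  back <- read_fixture(dir)
  for (tab in c("tags", "counts", "samples", "library_sizes")) {
    expect_equal(back[[tab]], ds[[tab]], ignore_attr = TRUE)
  }
  expect_equal(back$truth$genes, ds$truth$genes, ignore_attr = TRUE)
  expect_equal(back$truth$tail_te, ds$truth$tail_te, ignore_attr = TRUE)
  expect_identical(back$truth$sets$png_up, ds$truth$sets$png_up)
  expect_identical(back$manifest$seed, ds$manifest$seed)
  expect_identical(back$manifest$config_hash, ds$manifest$config_hash)
  # truth gene universe == tag-table gene universe (at these depths every
  # gene receives tags)
  expect_setequal(unique(back$tags$gene_id), back$truth$genes$gene_id)
})
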