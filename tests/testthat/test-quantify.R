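tag_df <- function(gene, tails, sample = "s1") {
  data.frame(gene_id = gene, tail_length = tails, sample = sample,
             stringsAsFactors = FALSE)
}

test_that("tail summaries pool isoform measurements and floor reported means", {
  ts <- summarize_tails(tag_df("gA", c(10, 20, 30)))
  expect_equal(ts$mean_tail_nt, 20)
  expect_identical(ts$tag_count, c(gA = 3L), ignore_attr = TRUE)
  # floor applies to the reported field only
  ts2 <- summarize_tails(tag_df("gA", c(2, 2)))
  expect_equal(ts2$mean_tail_nt, 2)
  expect_equal(ts2$reported_mean_nt, 4)
  # pooled mean across tandem isoforms: [10] and [30, 30] -> 70/3
  ts3 <- summarize_tails(tag_df("gA", c(10, 30, 30)))
  expect_equal(ts3$mean_tail_nt, 70 / 3)
  # histogram total equals the tag count; zero-tag genes yield no record
  expect_identical(sum(ts3$histogram[[1]]), 3L)
  empty <- data.frame(gene_id = character(0), tail_length = numeric(0),
                      sample = character(0))
  expect_identical(nrow(summarize_tails(empty)), 0L)
  # pooled-mean property: pooling equals the weighted mean of parts
  set.seed(8)
  a <- rpois(20, 40); b <- rpois(35, 70)
  pooled <- summarize_tails(tag_df("g", c(a, b)))$mean_tail_nt
  expect_equal(pooled, (sum(a) + sum(b)) / 55)
})

test_that("RPM and RPKM follow their definitions and conserve totals", {
  counts <- data.frame(gene_id = c("g1", "g2"), sample = "s1",
                       rna_count = c(5, 15), rpf_count = c(2, 18))
  totals <- data.frame(sample = "s1", rna_total = 20, rpf_total = 20)
  expr <- normalize_expression(counts, totals,
                               orf_lengths = c(g1 = 2000, g2 = 500))
  expect_equal(expr$rna_rpm[1], 250000)
  expect_equal(expr$rna_rpkm[1], 250000 * 1e3 / 2000)
  # when per-gene counts sum to the totals, RPM sums to 1e6
  expect_equal(sum(expr$rna_rpm), 1e6, tolerance = 1e-6)
  expect_equal(sum(expr$rpf_rpm), 1e6, tolerance = 1e-6)
  expect_error(normalize_expression(counts,
                                    data.frame(sample = "s1", rna_total = 0,
                                               rpf_total = 10)),
               class = "tailTE_error_invalid")
})

test_that("TE uses log2 RPF/RNA with the zero-RPF pseudocount rule", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"), sample = "s1",
                     rna_rpm = c(10, 10, 8), rpf_rpm = c(20, 0, 4),
                     rpf_count = c(50, 0, 10), rpf_total = 1e6)
  te <- compute_te(expr)
  expect_equal(te$log2_te[1], 1)
  # zero RPF: rpm recomputed from one read (1e6 total -> rpm 1)
  expect_equal(te$log2_te[2], log2(1 / 10))
  expect_true(te$pseudocount_used[2])
  expect_identical(te$low_evidence, c(FALSE, TRUE, TRUE))
  # hybrid mode: mutant RPF over wild-type RNA
  expect_equal(te$log2_te[3], -1)
  expect_error(compute_te(transform(expr, rna_rpm = c(1, 0, 1))),
               class = "tailTE_error_invalid")
})

test_that("hybrid expression reduces to standard when RNA tables are identical", {
  counts <- data.frame(gene_id = c("g1", "g2"), sample = "s1",
                       rna_count = c(10, 20), rpf_count = c(5, 10))
  expr <- normalize_expression(counts)
  hyb <- hybrid_expression(expr, expr)
  expect_equal(compute_te(hyb)$log2_te, compute_te(expr)$log2_te)
})

test_that("median centring zeroes the centring-set median with midpoint convention", {
  v <- c(a = 0.6, b = 1.0, c = 3.0)
  mc <- median_center(v)
  expect_equal(mc$constant, 1.0)
  expect_equal(unname(mc$centered), c(-0.4, 0, 2.0))
  expect_equal(unname(median_center(c(a = 2, b = 2, c = 2))$centered),
               c(0, 0, 0))
  # even n: midpoint convention
  mc4 <- median_center(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(mc4$constant, 2.5)
  expect_equal(median(mc4$centered), 0)
  # idempotence
  again <- median_center(mc$centered)
  expect_equal(again$constant, 0)
  expect_equal(again$centered, mc$centered)
  # restricted centring set
  sub <- median_center(v, c("a", "b"))
  expect_equal(sub$constant, 0.8)
  expect_error(median_center(v, character(0)),
               class = "tailTE_error_invalid")
})

make_cutoff_tables <- function(df) {
  # df columns: gene_id, tags1, rna1, rpf1, tags2, rna2, rpf2
  tails <- rbind(
    data.frame(gene_id = df$gene_id, sample = "s1", tag_count = df$tags1,
               mean_tail_nt = 50, reported_mean_nt = 50),
    data.frame(gene_id = df$gene_id, sample = "s2", tag_count = df$tags2,
               mean_tail_nt = 50, reported_mean_nt = 50))
  expr <- rbind(
    data.frame(gene_id = df$gene_id, sample = "s1", rna_rpm = df$rna1,
               rpf_rpm = df$rpf1),
    data.frame(gene_id = df$gene_id, sample = "s2", rna_rpm = df$rna2,
               rpf_rpm = df$rpf2))
  list(tails = tails, expr = expr)
}

test_that("cutoffs implement the per-mode conjunctions at their boundaries", {
  df <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    tags1 = c(99, 100, 100, 100, 100),
    rna1 = c(10, 10, 9.9, 10, 10),
    rpf1 = c(5, 0.1, 5, 12, 12),
    tags2 = c(100, 100, 100, 100, 100),
    rna2 = c(10, 10, 10, 10, 10),
    rpf2 = c(5, 5, 5, 0.0, 0.5))
  tb <- make_cutoff_tables(df)
  # single: g1 fails tags; g2 passes with rpf > 0; g3 fails RNA
  expect_identical(apply_cutoffs(tb$tails, tb$expr, "single", "s1"),
                   c("g2", "g4", "g5"))
  # pairwise: g4 fails (second rpf not > 0), g5 passes (12 >= 10, 0.5 > 0)
  pw <- apply_cutoffs(tb$tails, tb$expr, "pairwise", c("s1", "s2"))
  expect_identical(pw, "g5")
  # multistage has no tag requirement: g1 rejoins if rpf qualifies
  ms <- apply_cutoffs(NULL, tb$expr, "multistage", c("s1", "s2"))
  expect_identical(ms, "g5")
  expect_error(apply_cutoffs(tb$tails, tb$expr, "single", "missing"),
               class = "tailTE_error_invalid")
})

test_that("cutoffs equal a brute-force row scan on random tables", {
  set.seed(21)
  n <- 500
  df <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    tags1 = rpois(n, 100), rna1 = runif(n, 0, 20), rpf1 = runif(n, 0, 20),
    tags2 = rpois(n, 100), rna2 = runif(n, 0, 20), rpf2 = runif(n, 0, 20))
  tb <- make_cutoff_tables(df)
  got <- apply_cutoffs(tb$tails, tb$expr, "pairwise", c("s1", "s2"))
  want <- df$gene_id[df$tags1 >= 100 & df$tags2 >= 100 &
                       df$rna1 >= 10 & df$rna2 >= 10 &
                       ((df$rpf1 >= 10 & df$rpf2 > 0) |
                          (df$rpf2 >= 10 & df$rpf1 > 0))]
  expect_identical(got, sort(want))
  got_s <- apply_cutoffs(tb$tails, tb$expr, "single", "s1")
  expect_identical(got_s,
                   sort(df$gene_id[df$tags1 >= 100 & df$rna1 >= 10 &
                                     df$rpf1 > 0]))
})

test_that("fold-change tables centre TE but not tail changes", {
  te_a <- c(g1 = 1, g2 = 0, g3 = 2)
  te_b <- c(g1 = 3, g2 = 0.5, g3 = 2)
  tails_a <- c(g1 = 40, g2 = 50, g3 = 6)
  tails_b <- c(g1 = 60, g2 = 50, g3 = 12)
  ch <- compute_fold_changes(te_a, te_b, tails_a, tails_b,
                             genes = c("g1", "g2", "g3"))
  cc <- attr(ch, "te_centering_constant")
  expect_equal(cc, 0.5)   # median of (2, 0.5, 0)
  expect_equal(ch$log2_fc_te[ch$gene_id == "g1"], 1.5)
  expect_equal(ch$log2_fc_tail[ch$gene_id == "g1"], log2(1.5))
  expect_equal(ch$delta_tail_nt[ch$gene_id == "g1"], 20)
  expect_equal(median(ch$log2_fc_te), 0)
  # raw tail fold changes are not centred; cohort median is recorded
  expect_equal(attr(ch, "tail_fc_median"), log2(1.5))
  # short-tail reliability flag (raw mean < 8 nt)
  expect_identical(ch$tail_unreliable, c(FALSE, FALSE, TRUE))
  # identical stages: all centred fcs zero-median, tail fcs zero
  same <- compute_fold_changes(te_a, te_a, tails_a, tails_a,
                               genes = names(te_a))
  expect_equal(median(same$log2_fc_te), 0)
  expect_equal(same$log2_fc_tail, c(0, 0, 0))
  # genes missing in one stage are excluded with a record
  part <- compute_fold_changes(te_a, te_b[c("g1", "g2")], tails_a, tails_b,
                               genes = names(te_a))
  expect_identical(attr(part, "dropped_genes"), "g3")
})
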