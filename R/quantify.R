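# Per-gene tail summaries, RPM/RPKM normalisation, log2 TE with
# pseudocount and median centring, quantification cutoffs, and
# between-stage change tables.

#' Summarise poly(A)-tail measurements per gene
#'
#' Tags must already carry a `gene_id` (either generated directly or
#' assigned with [assign_tags_to_genes()]); measurements from all tandem
#' 3'-UTR isoforms of a gene are pooled. Genes with zero tags yield no
#' record. The reported mean is floored at 4 nt (a display convention for
#' very short tails, which cannot be measured accurately); all arithmetic
#' downstream uses the raw mean.
#'
#' @param tags data frame with `gene_id`, `tail_length` and (unless
#'   `sample_id` is given) a `sample` column.
#' @param sample_id restrict to / label a single sample. If `NULL`,
#'   summaries are computed per (gene, sample).
#' @param bin_width histogram bin width in nt (bins `[0, w), [w, 2w), ...`).
#' @return data frame with `gene_id`, `sample`, `tag_count`,
#'   `mean_tail_nt`, `reported_mean_nt`, and a `histogram` list-column of
#'   named bin counts.
#' @export
summarize_tails <- function(tags, sample_id = NULL, bin_width = 5) {
  assert_that(all(c("gene_id", "tail_length") %in% names(tags)),
              "tags must have gene_id and tail_length columns",
              "tailTE_error_schema")
  if (!is.null(sample_id)) {
    if ("sample" %in% names(tags)) {
      tags <- tags[tags$sample == sample_id, , drop = FALSE]
    }
    tags$sample <- sample_id
  } else {
    assert_that("sample" %in% names(tags),
                "tags must have a sample column when sample_id is NULL",
                "tailTE_error_schema")
  }
  if (!nrow(tags)) {
    return(data.frame(gene_id = character(0), sample = character(0),
                      tag_count = integer(0), mean_tail_nt = numeric(0),
                      reported_mean_nt = numeric(0)))
  }
  key <- paste(tags$sample, tags$gene_id, sep = "\r")
  grp <- split(tags$tail_length, key)
  ids <- strsplit(names(grp), "\r", fixed = TRUE)
  res <- data.frame(
    gene_id = vapply(ids, `[[`, character(1), 2),
    sample = vapply(ids, `[[`, character(1), 1),
    tag_count = lengths(grp),
    mean_tail_nt = vapply(grp, mean, numeric(1)),
    stringsAsFactors = FALSE)
  res$reported_mean_nt <- pmax(res$mean_tail_nt, 4)
  res$histogram <- I(lapply(grp, function(x) {
    b <- floor(x / bin_width)
    tab <- table(factor(b, levels = 0:max(b)))
    stats::setNames(as.integer(tab),
                    paste0("[", bin_width * as.integer(names(tab)), ",",
                           bin_width * (as.integer(names(tab)) + 1), ")"))
  }))
  res <- res[order(res$sample, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Normalise counts to RPM and RPKM
#'
#' RPM = count / mapped total x 1e6; RPKM = RPM x 1e3 / ORF length. The
#' mapped totals are the supplied library sizes (not per-gene sums) and
#' are carried along in `rna_total` / `rpf_total` columns so that
#' pseudocount TEs can be recomputed downstream.
#'
#' @param counts data frame with `gene_id`, `sample`, `rna_count`,
#'   `rpf_count`.
#' @param totals data frame with `sample`, `rna_total`, `rpf_total`; if
#'   `NULL`, per-sample column sums are used.
#' @param orf_lengths named numeric vector of ORF lengths (nt) per gene
#'   (after excluding the first 50 nt of each ORF upstream); optional,
#'   needed for `rna_rpkm`.
#' @return `counts` with `rna_rpm`, `rpf_rpm`, `rna_total`, `rpf_total`
#'   (and `rna_rpkm` when lengths are given) columns added.
#' @export
normalize_expression <- function(counts, totals = NULL, orf_lengths = NULL) {
  need <- c("gene_id", "sample", "rna_count", "rpf_count")
  missing <- setdiff(need, names(counts))
  assert_that(!length(missing),
              sprintf("count table missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "tailTE_error_schema")
  if (is.null(totals)) {
    rna_tot <- tapply(counts$rna_count, counts$sample, sum)
    rpf_tot <- tapply(counts$rpf_count, counts$sample, sum)
    totals <- data.frame(sample = names(rna_tot),
                         rna_total = as.numeric(rna_tot),
                         rpf_total = as.numeric(rpf_tot[names(rna_tot)]),
                         stringsAsFactors = FALSE)
  }
  assert_that(all(totals$rna_total > 0) && all(totals$rpf_total > 0),
              "mapped-read totals must be > 0", "tailTE_error_invalid")
  m <- match(counts$sample, totals$sample)
  assert_that(!anyNA(m), "every sample needs a mapped-read total",
              "tailTE_error_invalid")
  counts$rna_total <- totals$rna_total[m]
  counts$rpf_total <- totals$rpf_total[m]
  counts$rna_rpm <- counts$rna_count / counts$rna_total * 1e6
  counts$rpf_rpm <- counts$rpf_count / counts$rpf_total * 1e6
  if (!is.null(orf_lengths)) {
    len <- orf_lengths[counts$gene_id]
    assert_that(all(len > 0, na.rm = TRUE), "ORF lengths must be > 0",
                "tailTE_error_invalid")
    counts$rna_rpkm <- counts$rna_rpm * 1e3 / len
  }
  counts
}

#' Compute log2 translational efficiency per gene
#'
#' `log2_te = log2(rpf_rpm / rna_rpm)`. Genes with zero footprint reads
#' have their RPF RPM recomputed from a pseudocount of 1 read (and are
#' flagged `pseudocount_used`); genes with fewer than `min_rpf` footprint
#' reads are flagged `low_evidence` but retained. For hybrid TEs (e.g.
#' mutant footprints over wild-type RNA-seq) pass an expression table
#' built with [hybrid_expression()].
#'
#' @param expr expression table from [normalize_expression()] (needs
#'   `rpf_rpm`, `rna_rpm`, `rpf_count`, `rpf_total`).
#' @param min_rpf low-evidence threshold in footprint reads (default 25).
#' @return `expr` with `log2_te`, `pseudocount_used`, `low_evidence`
#'   columns added. Genes with `rna_rpm == 0` raise an error: apply RNA
#'   cutoffs first.
#' @export
compute_te <- function(expr, min_rpf = 25) {
  need <- c("rpf_rpm", "rna_rpm", "rpf_count", "rpf_total")
  missing <- setdiff(need, names(expr))
  assert_that(!length(missing),
              sprintf("expression table missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "tailTE_error_schema")
  assert_that(all(expr$rna_rpm > 0),
              "rna_rpm must be > 0 for TE (apply RNA cutoffs first)",
              "tailTE_error_invalid")
  rpf_rpm <- expr$rpf_rpm
  pseudo <- expr$rpf_count == 0
  rpf_rpm[pseudo] <- 1 / expr$rpf_total[pseudo] * 1e6
  expr$log2_te <- log2(rpf_rpm / expr$rna_rpm)
  expr$pseudocount_used <- pseudo
  expr$low_evidence <- expr$rpf_count < min_rpf
  expr
}

#' Combine mutant footprints with wild-type RNA-seq
#'
#' Builds a hybrid expression table whose RPF columns come from
#' `expr_rpf` and RNA columns from `expr_rna`, matched by gene. Used when
#' the mutant's own RNA-seq is suspected of poly(A)-selection bias. When
#' both inputs are the same table the result reduces to the standard
#' single-sample table.
#'
#' @param expr_rpf,expr_rna expression tables from
#'   [normalize_expression()], each restricted to one sample.
#' @return hybrid expression table (sample label from `expr_rpf`).
#' @export
hybrid_expression <- function(expr_rpf, expr_rna) {
  m <- match(expr_rpf$gene_id, expr_rna$gene_id)
  out <- expr_rpf[!is.na(m), , drop = FALSE]
  mm <- m[!is.na(m)]
  out$rna_count <- expr_rna$rna_count[mm]
  out$rna_total <- expr_rna$rna_total[mm]
  out$rna_rpm <- expr_rna$rna_rpm[mm]
  if ("rna_rpkm" %in% names(expr_rna)) out$rna_rpkm <- expr_rna$rna_rpkm[mm]
  out
}

#' Median-centre log2 quantities
#'
#' Subtracts the median over the centring gene set from every value, so
#' that samples (or comparisons) are on a common relative scale. Even-n
#' medians use the midpoint convention; the median of the centred values
#' over the centring set is exactly 0. Centring is idempotent.
#'
#' @param values named numeric vector (names = gene ids).
#' @param centering_set gene ids over which the median is taken; default
#'   all of `values`.
#' @return list with `centered` (named vector) and `constant`.
#' @export
median_center <- function(values, centering_set = names(values)) {
  assert_that(length(centering_set) > 0,
              "centering set must be non-empty", "tailTE_error_invalid")
  assert_that(all(centering_set %in% names(values)),
              "centering set must be a subset of the value names",
              "tailTE_error_invalid")
  constant <- median_midpoint(values[centering_set])
  list(centered = values - constant, constant = constant)
}

#' Apply quantification cutoffs
#'
#' Returns the gene ids passing the read-support cutoffs for a given
#' analysis mode:
#' \describe{
#'   \item{single}{>= `min_tags` tail measurements, >= `min_rna_rpm` RNA
#'     RPM, and > 0 RPF RPM in the one sample.}
#'   \item{pairwise}{>= `min_tags` tags and >= `min_rna_rpm` RNA RPM in
#'     both samples, >= `min_rpf_rpm` RPF RPM in one of the two and > 0 in
#'     the other. Set `require_tags = FALSE` for TE-only comparisons.}
#'   \item{multistage}{>= `min_rna_rpm` RNA RPM in all samples, >=
#'     `min_rpf_rpm` RPF RPM in at least one and > 0 in the others (no
#'     tag requirement).}
#' }
#'
#' @param tail_summary data frame from [summarize_tails()] (may be `NULL`
#'   when tags are not required).
#' @param expr expression table from [normalize_expression()] covering all
#'   `samples`.
#' @param mode `"single"`, `"pairwise"` or `"multistage"`.
#' @param samples character vector of sample ids (1, 2, or >= 2 depending
#'   on mode).
#' @param min_tags,min_rna_rpm,min_rpf_rpm cutoff values (defaults 100,
#'   10.0, 10.0).
#' @param require_tags whether pairwise mode demands the tag cutoff
#'   (default `TRUE`).
#' @return character vector of passing gene ids (sorted).
#' @export
apply_cutoffs <- function(tail_summary, expr, mode, samples,
                          min_tags = 100, min_rna_rpm = 10,
                          min_rpf_rpm = 10, require_tags = TRUE) {
  assert_that(mode %in% c("single", "pairwise", "multistage"),
              "mode must be single, pairwise or multistage",
              "tailTE_error_config")
  missing_s <- setdiff(samples, unique(expr$sample))
  assert_that(!length(missing_s),
              sprintf("sample(s) missing from expression table: %s",
                      paste(missing_s, collapse = ", ")),
              "tailTE_error_invalid")
  genes <- sort(unique(expr$gene_id[expr$sample %in% samples]))
  get_vec <- function(df, col, sample_id) {
    sub <- df[df$sample == sample_id, ]
    stats::setNames(sub[[col]], sub$gene_id)[genes]
  }
  tag_ok <- function(sample_id) {
    v <- get_vec(tail_summary, "tag_count", sample_id)
    !is.na(v) & v >= min_tags
  }
  rna <- vapply(samples, function(s) get_vec(expr, "rna_rpm", s),
                numeric(length(genes)))
  rpf <- vapply(samples, function(s) get_vec(expr, "rpf_rpm", s),
                numeric(length(genes)))
  if (length(genes) == 1) {
    rna <- matrix(rna, nrow = 1); rpf <- matrix(rpf, nrow = 1)
  }
  rna[is.na(rna)] <- 0
  rpf[is.na(rpf)] <- 0
  ok <- switch(mode,
    single = {
      assert_that(length(samples) == 1, "single mode needs one sample",
                  "tailTE_error_config")
      tag_ok(samples) & rna[, 1] >= min_rna_rpm & rpf[, 1] > 0
    },
    pairwise = {
      assert_that(length(samples) == 2, "pairwise mode needs two samples",
                  "tailTE_error_config")
      base <- rna[, 1] >= min_rna_rpm & rna[, 2] >= min_rna_rpm &
        pmax(rpf[, 1], rpf[, 2]) >= min_rpf_rpm &
        pmin(rpf[, 1], rpf[, 2]) > 0
      if (require_tags) base & tag_ok(samples[1]) & tag_ok(samples[2])
      else base
    },
    multistage = {
      assert_that(length(samples) >= 2, "multistage mode needs >= 2 samples",
                  "tailTE_error_config")
      apply(rna >= min_rna_rpm, 1, all) &
        apply(rpf, 1, max) >= min_rpf_rpm &
        apply(rpf, 1, min) > 0
    })
  genes[ok]
}

#' Compute between-stage change records
#'
#' log2 TE fold changes are median-centred over the passing gene set (the
#' centring constant is recorded as an attribute); tail log2 fold changes
#' are reported raw, with the cohort median alongside. The absolute
#' difference of mean tails is also emitted. Genes whose raw mean tail is
#' below `min_reliable_tail_nt` in either stage are flagged
#' `tail_unreliable` (very short tails cannot be measured accurately).
#'
#' @param te_a,te_b named vectors of raw (uncentred) log2 TE for stages A
#'   and B.
#' @param tails_a,tails_b named vectors of raw mean tail lengths (nt).
#' @param genes passing gene set (from [apply_cutoffs()], pairwise mode);
#'   genes missing a value in any input are excluded.
#' @param min_reliable_tail_nt reliability floor for tail fold changes
#'   (default 8 nt).
#' @return data frame with `gene_id`, `log2_fc_te` (centred),
#'   `log2_fc_tail`, `delta_tail_nt`, `tail_unreliable`; attributes
#'   `te_centering_constant` and `tail_fc_median`.
#' @export
compute_fold_changes <- function(te_a, te_b, tails_a = NULL, tails_b = NULL,
                                 genes = NULL, min_reliable_tail_nt = 8) {
  if (is.null(genes)) {
    genes <- intersect(names(te_a), names(te_b))
  }
  have <- genes %in% names(te_a) & genes %in% names(te_b)
  if (!is.null(tails_a)) {
    have <- have & genes %in% names(tails_a) & genes %in% names(tails_b)
  }
  dropped <- genes[!have]
  genes <- genes[have]
  assert_that(length(genes) > 0, "no genes with values in both stages",
              "tailTE_error_invalid")
  fc_te <- te_b[genes] - te_a[genes]
  cc <- median_center(fc_te)
  out <- data.frame(gene_id = genes, log2_fc_te = as.numeric(cc$centered),
                    stringsAsFactors = FALSE)
  if (!is.null(tails_a)) {
    ta <- tails_a[genes]; tb <- tails_b[genes]
    out$log2_fc_tail <- log2(tb / ta)
    out$delta_tail_nt <- tb - ta
    out$tail_unreliable <- ta < min_reliable_tail_nt |
      tb < min_reliable_tail_nt
    attr(out, "tail_fc_median") <- median_midpoint(out$log2_fc_tail)
  }
  attr(out, "te_centering_constant") <- cc$constant
  attr(out, "dropped_genes") <- dropped
  out
}
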