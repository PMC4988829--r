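# Representative gene-model selection and 3'-end re-annotation from
# poly(A)-anchored tags.
#
# Coordinates are 0-based, half-open throughout ([start, end)), the native
# refFlat convention. "Distal" is strand-aware: larger coordinates on the
# plus strand, smaller on the minus strand.

required_tx_cols <- c("gene_id", "tx_id", "chrom", "strand", "tx_start",
                      "tx_end", "cds_start", "cds_end", "coding")

validate_transcripts <- function(tx) {
  missing <- setdiff(required_tx_cols, names(tx))
  assert_that(!length(missing),
              sprintf("transcript table missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "tailTE_error_schema")
  assert_that(all(tx$tx_start < tx$tx_end),
              "transcripts must satisfy tx_start < tx_end",
              "tailTE_error_invalid")
  assert_that(all(tx$strand %in% c("+", "-")),
              "strand must be '+' or '-'", "tailTE_error_invalid")
  invisible(tx)
}

strand_distal <- function(positions, strand) {
  if (strand == "+") max(positions) else min(positions)
}

is_distal_to <- function(pos, ref, strand) {
  if (strand == "+") pos > ref else pos < ref
}

#' Select one representative transcript model per gene
#'
#' Per gene the longest transcript is chosen (genomic span `tx_end -
#' tx_start` by default; summed exon length with `longest_by =
#' "exon_sum"`, which requires `exon_starts`/`exon_ends` comma-string
#' columns). Genes whose representative is non-coding are excluded, and
#' pairs of genes whose representative spans overlap on the same strand
#' are both excluded. Exclusions are retained in the output with their
#' reason.
#'
#' @param transcripts data frame with columns `gene_id, tx_id, chrom,
#'   strand, tx_start, tx_end, cds_start, cds_end, coding` (0-based,
#'   half-open).
#' @param longest_by `"span"` (default) or `"exon_sum"`.
#' @return data frame of gene models, one row per gene: representative
#'   transcript coordinates plus `stop_codon` (strand-aware genomic
#'   boundary of the CDS 3' end), `ref_3p_end`, `final_3p_end`
#'   (initialised to the reference end), `excluded`, `exclude_reason`.
#' @export
select_representative_models <- function(transcripts,
                                         longest_by = c("span", "exon_sum")) {
  longest_by <- match.arg(longest_by)
  if (!nrow(transcripts)) {
    return(data.frame(gene_id = character(0)))
  }
  validate_transcripts(transcripts)
  tx <- transcripts
  if (longest_by == "span") {
    tx$.len <- tx$tx_end - tx$tx_start
  } else {
    exon_len <- function(starts, ends) {
      s <- as.integer(strsplit(starts, ",")[[1]])
      e <- as.integer(strsplit(ends, ",")[[1]])
      sum(e - s)
    }
    tx$.len <- mapply(exon_len, tx$exon_starts, tx$exon_ends)
  }
  # deterministic tie-break: longest, then lexicographically first tx_id
  tx <- tx[order(tx$gene_id, -tx$.len, tx$tx_id), ]
  rep_tx <- tx[!duplicated(tx$gene_id), ]
  rep_tx <- rep_tx[order(rep_tx$gene_id), ]

  models <- data.frame(
    gene_id = rep_tx$gene_id, tx_id = rep_tx$tx_id, chrom = rep_tx$chrom,
    strand = rep_tx$strand, tx_start = rep_tx$tx_start,
    tx_end = rep_tx$tx_end, cds_start = rep_tx$cds_start,
    cds_end = rep_tx$cds_end,
    stop_codon = ifelse(rep_tx$strand == "+", rep_tx$cds_end,
                        rep_tx$cds_start),
    ref_3p_end = ifelse(rep_tx$strand == "+", rep_tx$tx_end,
                        rep_tx$tx_start),
    excluded = FALSE, exclude_reason = NA_character_,
    stringsAsFactors = FALSE)
  models$final_3p_end <- models$ref_3p_end

  noncoding <- !rep_tx$coding
  models$excluded[noncoding] <- TRUE
  models$exclude_reason[noncoding] <- "non-coding"

  # same-strand span overlap among still-included genes: both removed
  keep <- which(!models$excluded)
  if (length(keep) > 1) {
    overlapping <- logical(nrow(models))
    for (grp in split(keep, paste(models$chrom[keep], models$strand[keep]))) {
      if (length(grp) < 2) next
      ord <- grp[order(models$tx_start[grp])]
      max_end <- models$tx_end[ord[1]]
      prev <- ord[1]
      for (i in ord[-1]) {
        if (models$tx_start[i] < max_end) {
          overlapping[i] <- TRUE
          overlapping[prev] <- TRUE
        }
        if (models$tx_end[i] > max_end) {
          max_end <- models$tx_end[i]
          prev <- i
        }
      }
    }
    models$excluded[overlapping] <- TRUE
    models$exclude_reason[overlapping] <- "overlapping-same-strand"
  }
  models
}

#' Filter poly(A) tags by minimum tail length
#'
#' Tags with short tails may derive from internal priming rather than
#' genuine cleavage-and-polyadenylation sites; only tags with
#' `tail_length >= min_tail_nt` (default 20 nt) are retained for 3'-end
#' annotation. Row order is preserved.
#'
#' @param tags data frame with a `tail_length` column.
#' @param min_tail_nt minimum tail length in nt.
#' @return filtered data frame.
#' @export
filter_polya_tags <- function(tags, min_tail_nt = 20) {
  assert_that("tail_length" %in% names(tags),
              "tags must have a 'tail_length' column", "tailTE_error_schema")
  out <- tags[tags$tail_length >= min_tail_nt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call cleavage-and-polyadenylation sites from tag pileups
#'
#' Sites supported by at least two tags at the exact same position,
#' lying strictly between the gene's stop codon and the neighbouring
#' same-strand gene's transcription start site, are reported as candidate
#' 3'-end isoforms.
#'
#' @param tags data frame with `chrom`, `site`, `strand`, `tail_length`
#'   columns (pre-filtered with [filter_polya_tags()]).
#' @param model single gene-model row (as from
#'   [select_representative_models()]).
#' @param next_tss genomic coordinate of the neighbouring same-strand
#'   gene's TSS (use `Inf` / `-Inf` when there is none).
#' @param min_support minimum tags at a position (default 2).
#' @return data frame with `position`, `tag_support`, ordered
#'   proximal-to-distal.
#' @export
call_cleavage_sites <- function(tags, model, next_tss, min_support = 2) {
  stop_codon <- model$stop_codon
  strand <- model$strand
  if (strand == "+") {
    assert_that(next_tss > stop_codon,
                "next_tss must be downstream of the stop codon",
                "tailTE_error_interval")
  } else {
    assert_that(next_tss < stop_codon,
                "next_tss must be downstream of the stop codon",
                "tailTE_error_interval")
  }
  sel <- tags$chrom == model$chrom & tags$strand == strand
  sites <- tags$site[sel]
  if (strand == "+") {
    sites <- sites[sites > stop_codon & sites < next_tss]
  } else {
    sites <- sites[sites < stop_codon & sites > next_tss]
  }
  if (!length(sites)) {
    return(data.frame(position = numeric(0), tag_support = integer(0)))
  }
  tab <- table(sites)
  tab <- tab[tab >= min_support]
  pos <- as.numeric(names(tab))
  out <- data.frame(position = pos, tag_support = as.integer(tab))
  out[order(if (strand == "+") out$position else -out$position), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

utr_length <- function(position, model) {
  if (model$strand == "+") position - model$stop_codon
  else model$stop_codon - position
}

#' Collapse tandem 3'-end isoform sites
#'
#' Sites implying a 3'-UTR longer than `max_utr_nt` are discarded. The
#' remaining sites are collapsed greedily: repeatedly take the unconsumed
#' site with the highest support (ties broken strand-distal-most), absorb
#' every site within `window_nt` nt of it (inclusive), and sum the
#' absorbed support into the kept site. The result is sorted
#' proximal-to-distal. Total support is conserved (minus cap-discarded
#' sites), and the operation is idempotent.
#'
#' @param sites data frame from [call_cleavage_sites()].
#' @param model single gene-model row.
#' @param window_nt absorption half-window (nt), default 60.
#' @param max_utr_nt maximum allowed 3'-UTR length (nt), default 4100
#'   (about the 99th percentile of annotated fly 3' UTRs).
#' @return data frame with `position`, `tag_support`.
#' @export
collapse_tandem_isoforms <- function(sites, model, window_nt = 60,
                                     max_utr_nt = 4100) {
  assert_that(window_nt >= 0, "window_nt must be >= 0", "tailTE_error_config")
  if (!nrow(sites)) return(sites)
  keep <- utr_length(sites$position, model) <= max_utr_nt
  sites <- sites[keep, , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(position = numeric(0), tag_support = integer(0)))
  }
  pos <- sites$position
  sup <- sites$tag_support
  consumed <- rep(FALSE, length(pos))
  kept_pos <- numeric(0)
  kept_sup <- integer(0)
  distal_sign <- if (model$strand == "+") 1 else -1
  while (!all(consumed)) {
    open <- which(!consumed)
    best <- open[order(-sup[open], -distal_sign * pos[open])][1]
    absorb <- open[abs(pos[open] - pos[best]) <= window_nt]
    kept_pos <- c(kept_pos, pos[best])
    kept_sup <- c(kept_sup, sum(sup[absorb]))
    consumed[absorb] <- TRUE
  }
  ord <- order(distal_sign * kept_pos)
  data.frame(position = kept_pos[ord], tag_support = kept_sup[ord])
}

#' Finalise a gene model's 3' end from collapsed isoform sites
#'
#' If any collapsed site is strand-distal to the reference 3' end, the
#' model is extended to the most distal site; otherwise the reference end
#' stands. Models whose selected end overlaps a snoRNA/snRNA interval are
#' flagged `excluded_from_figures` but retained.
#'
#' @param model single gene-model row.
#' @param collapsed data frame from [collapse_tandem_isoforms()].
#' @param sno_intervals optional data frame with `chrom`, `start`, `end`
#'   (0-based half-open) of snoRNA/snRNA annotations.
#' @return the model row with `final_3p_end`, an `isoform_ends`
#'   list-column, and `excluded_from_figures` set.
#' @export
finalize_3p_end <- function(model, collapsed, sno_intervals = NULL) {
  final <- model$ref_3p_end
  if (nrow(collapsed)) {
    cand <- c(final, collapsed$position)
    distal <- strand_distal(cand, model$strand)
    if (is_distal_to(distal, final, model$strand)) final <- distal
  }
  model$final_3p_end <- final
  model$isoform_ends <- I(list(collapsed))
  model$excluded_from_figures <- FALSE
  if (!is.null(sno_intervals) && nrow(sno_intervals)) {
    hit <- sno_intervals$chrom == model$chrom &
      final >= sno_intervals$start & final < sno_intervals$end
    model$excluded_from_figures <- any(hit)
  }
  model
}

# Neighbouring same-strand TSS for each included model. On the plus strand
# the TSS of a gene is its tx_start; on the minus strand its tx_end.
next_tss_table <- function(models) {
  res <- rep(NA_real_, nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    same <- models$chrom == m$chrom & models$strand == m$strand &
      models$gene_id != m$gene_id & !models$excluded
    if (m$strand == "+") {
      cand <- models$tx_start[same]
      cand <- cand[cand > m$stop_codon]
      res[i] <- if (length(cand)) min(cand) else Inf
    } else {
      cand <- models$tx_end[same]
      cand <- cand[cand < m$stop_codon]
      res[i] <- if (length(cand)) max(cand) else -Inf
    }
  }
  res
}

#' Build re-annotated gene models from transcripts and poly(A) tags
#'
#' Convenience wrapper running the full re-annotation path: representative
#' selection, tag filtering (tails >= 20 nt), per-gene site calling
#' between the stop codon and the neighbouring same-strand TSS, tandem
#' isoform collapsing, and 3'-end finalisation.
#'
#' @inheritParams select_representative_models
#' @param tags poly(A)-tag data frame (all samples combined).
#' @param min_tail_nt,window_nt,max_utr_nt,min_support rule parameters.
#' @param sno_intervals optional snoRNA/snRNA intervals.
#' @return gene-model data frame with `isoform_ends` list-column.
#' @export
build_gene_models <- function(transcripts, tags, min_tail_nt = 20,
                              window_nt = 60, max_utr_nt = 4100,
                              min_support = 2, sno_intervals = NULL,
                              longest_by = "span") {
  models <- select_representative_models(transcripts, longest_by = longest_by)
  if (!nrow(models)) return(models)
  tags <- filter_polya_tags(tags, min_tail_nt)
  tss <- next_tss_table(models)
  out <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    if (m$excluded) {
      m$isoform_ends <- I(list(data.frame(position = numeric(0),
                                          tag_support = integer(0))))
      m$excluded_from_figures <- FALSE
      out[[i]] <- m
      next
    }
    sites <- call_cleavage_sites(tags, m, tss[i], min_support = min_support)
    collapsed <- collapse_tandem_isoforms(sites, m, window_nt = window_nt,
                                          max_utr_nt = max_utr_nt)
    out[[i]] <- finalize_3p_end(m, collapsed, sno_intervals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign poly(A) tags to genes via annotated isoform ends
#'
#' A tag is assigned to a gene when its site lies within `tolerance` nt of
#' any of that gene's annotated 3'-end positions (collapsed isoform ends
#' plus the final end) on the matching chromosome and strand. Tags
#' matching no gene are dropped; in the rare case of multiple matches the
#' nearest end wins.
#'
#' @param tags tag data frame (`chrom`, `site`, `strand`, `tail_length`).
#' @param models gene-model data frame from [build_gene_models()].
#' @param tolerance matching slop in nt (default 10).
#' @return `tags` with a `gene_id` column, unassigned tags removed.
#' @export
assign_tags_to_genes <- function(tags, models, tolerance = 10) {
  ends <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    if (isTRUE(m$excluded)) return(NULL)
    iso <- m$isoform_ends[[1]]
    pos <- unique(c(iso$position, m$final_3p_end))
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               position = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(ends) || !nrow(ends)) {
    tags$gene_id <- character(0)[rep(NA, nrow(tags))]
    return(tags[0, , drop = FALSE])
  }
  gene_id <- rep(NA_character_, nrow(tags))
  best_d <- rep(Inf, nrow(tags))
  key_tags <- paste(tags$chrom, tags$strand)
  key_ends <- paste(ends$chrom, ends$strand)
  for (k in unique(key_ends)) {
    ti <- which(key_tags == k)
    ei <- which(key_ends == k)
    if (!length(ti)) next
    for (j in ei) {
      d <- abs(tags$site[ti] - ends$position[j])
      hit <- d <= tolerance & d < best_d[ti]
      gene_id[ti[hit]] <- ends$gene_id[j]
      best_d[ti[hit]] <- d[hit]
    }
  }
  out <- tags[!is.na(gene_id), , drop = FALSE]
  out$gene_id <- gene_id[!is.na(gene_id)]
  rownames(out) <- NULL
  out
}
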