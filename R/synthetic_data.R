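# Synthetic multi-stage, multi-genotype cohort generator.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes: per-gene mean poly(A)-tail lengths with unimodal per-molecule
# tail distributions, stage-dependent coupling between (log2) tail length
# and log2 TE that can be switched off stage by stage, planted temporal TE
# profiles, and genotype effects (global tail shortening with preserved
# rank order; nulled activation-transition changes for planted target
# sets; partial derepression of a subset). Ground truth is recorded for
# parameter-recovery tests.

#' Default genotype parameterisations
#'
#' Parameters for the three mutant genotypes the generator understands:
#' \describe{
#'   \item{wispy}{loss of the cytoplasmic poly(A) polymerase: every gene's
#'     mean tail is multiplied by a per-gene shrink factor drawn from
#'     `shrink_range`, except a spared set (emulating ribosomal-protein
#'     mRNAs) whose factors come from `spared_shrink_range`.}
#'   \item{png}{loss of the PAN GU kinase: the planted up/down target
#'     sets have their egg-activation tail and TE changes replaced by the
#'     cohort-median change. `te_effect_log2`/`tail_effect_log2` are the
#'     wild-type planted effect sizes; 3 log2 units = 8 fold.}
#'   \item{smg}{loss of the Smaug repressor: a `responsive_fraction` of
#'     the png-down set retains only `multiplier` times the wild-type
#'     activation-transition change (partial derepression); all other
#'     genes behave as in wild type.}
#' }
#'
#' @return named list of per-genotype parameter lists.
#' @export
default_genotype_specs <- function() {
  list(
    wispy = list(shrink_range = c(0.3, 0.7),
                 spared_fraction = 0.05,
                 spared_shrink_range = c(0.9, 1.0)),
    png = list(n_up = 100L, n_down = 100L,
               te_effect_log2 = 3, tail_effect_log2 = 1),
    smg = list(responsive_fraction = 0.7, multiplier = 0.4)
  )
}

#' Construct and validate a simulation configuration
#'
#' The defaults describe a wild-type-like eight-stage cohort spanning
#' oocyte maturation through gastrulation: tail/TE coupling is strong in
#' maturing oocytes and cleavage-stage embryos, weak at the end of
#' maturation, and absent at gastrulation. Effect sizes and depths are of
#' the same order as a single bulk profiling library per stage.
#'
#' @param n_genes number of genes.
#' @param stages ordered character vector of stage labels.
#' @param coupling_beta per-stage coupling coefficient (log2-TE units per
#'   log2-nt of tail for `coupling_scale = "relative"`; per nt for
#'   `"absolute"`). 0 switches coupling off at that stage.
#' @param coupling_scale whether coupling acts on log2 tail (default) or
#'   on absolute tail length in nt.
#' @param tail_base_mean_nt cohort-typical mean tail length (nt).
#' @param tail_log2_sd between-gene SD of log2 mean tail at the first stage.
#' @param tail_drift_sd per-transition per-gene SD of log2 mean-tail drift.
#' @param tail_shape gamma shape parameter for per-molecule tail lengths
#'   (larger = tighter unimodal distribution).
#' @param alpha_sd between-gene SD of baseline log2 TE.
#' @param noise_sd_log2te per-gene per-stage SD of tail-independent log2 TE
#'   noise.
#' @param depth_rna,depth_rpf,depth_tags expected per-sample totals of
#'   RNA-seq reads, ribosome footprints, and poly(A) tags.
#' @param overdispersion count overdispersion parameter; 0 (default)
#'   gives Poisson counts (one library per stage, no replicate
#'   dispersion), > 0 gives negative binomial with variance
#'   `mu + overdispersion * mu^2`.
#' @param profile_classes list of `list(profile = <integer vector, length
#'   = n stages, first element 0>, fraction = <of genes>, effect =
#'   <log2-TE units per profile unit>)`; fractions must sum to at most 1.
#' @param genotypes subset of `c("wildtype", "wispy", "png", "smg")`;
#'   `"wildtype"` is always required.
#' @param genotype_specs overrides merged over [default_genotype_specs()].
#' @param activation_transition index `t` such that the egg-activation
#'   transition is `stages[t] -> stages[t+1]`; required when png or smg
#'   genotypes (or planted png sets) are simulated.
#' @param rna_selection_bias_tau optional tail-length scale (nt) below
#'   which RNA-seq recovery is attenuated proportionally to tail length,
#'   emulating poly(A)-selection bias; `NULL` (default) disables it.
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       stages = c("stage11", "stage12", "stage13", "stage14",
                                  "activated_egg", "embryo_0_1h",
                                  "embryo_2_3h", "gastrula"),
                       coupling_beta = c(1.0, 1.0, 1.0, 0.3,
                                         1.2, 1.2, 0.4, 0.0),
                       coupling_scale = c("relative", "absolute"),
                       tail_base_mean_nt = 50,
                       tail_log2_sd = 0.6,
                       tail_drift_sd = 0.4,
                       tail_shape = 10,
                       alpha_sd = 0.5,
                       noise_sd_log2te = 0.4,
                       depth_rna = 1e7,
                       depth_rpf = 1e7,
                       depth_tags = 1e6,
                       overdispersion = 0,
                       profile_classes = list(),
                       genotypes = "wildtype",
                       genotype_specs = list(),
                       activation_transition = NULL,
                       rna_selection_bias_tau = NULL,
                       seed = 1L) {
  coupling_scale <- match.arg(coupling_scale)
  specs <- default_genotype_specs()
  for (nm in names(genotype_specs)) {
    specs[[nm]] <- utils::modifyList(specs[[nm]] %||% list(),
                                     genotype_specs[[nm]])
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes), stages = stages,
    coupling_beta = coupling_beta, coupling_scale = coupling_scale,
    tail_base_mean_nt = tail_base_mean_nt, tail_log2_sd = tail_log2_sd,
    tail_drift_sd = tail_drift_sd, tail_shape = tail_shape,
    alpha_sd = alpha_sd, noise_sd_log2te = noise_sd_log2te,
    depth_rna = depth_rna, depth_rpf = depth_rpf, depth_tags = depth_tags,
    overdispersion = overdispersion,
    profile_classes = profile_classes, genotypes = genotypes,
    genotype_specs = specs,
    activation_transition =
      if (is.null(activation_transition)) NULL
      else as.integer(activation_transition),
    rna_selection_bias_tau = rna_selection_bias_tau,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    abort_tailTE(sprintf("invalid configuration field '%s': %s", field, msg),
                 "tailTE_error_config")
  }
  if (!is.numeric(cfg$n_genes) || cfg$n_genes < 1) err("n_genes", "must be >= 1")
  if (!length(cfg$stages) || anyDuplicated(cfg$stages))
    err("stages", "must be a non-empty, duplicate-free stage list")
  S <- length(cfg$stages)
  if (length(cfg$coupling_beta) != S)
    err("coupling_beta", "must supply one coefficient per stage")
  for (d in c("depth_rna", "depth_rpf", "depth_tags")) {
    if (!is.numeric(cfg[[d]]) || cfg[[d]] <= 0) err(d, "must be > 0")
  }
  if (cfg$tail_base_mean_nt < 1) err("tail_base_mean_nt", "must be >= 1 nt")
  if (!is.null(cfg$overdispersion) && cfg$overdispersion < 0)
    err("overdispersion", "must be >= 0")
  if (cfg$tail_shape <= 0) err("tail_shape", "must be > 0")
  if (cfg$noise_sd_log2te < 0) err("noise_sd_log2te", "must be >= 0")
  if (length(cfg$profile_classes)) {
    fr <- vapply(cfg$profile_classes, function(p) p$fraction, numeric(1))
    if (any(fr < 0) || sum(fr) > 1)
      err("profile_classes", "fractions must be >= 0 and sum to <= 1")
    for (p in cfg$profile_classes) {
      if (length(p$profile) != S || p$profile[1] != 0)
        err("profile_classes",
            "each profile must span all stages and start at 0")
    }
  }
  known <- c("wildtype", "wispy", "png", "smg")
  if (!all(cfg$genotypes %in% known))
    err("genotypes", sprintf("must be a subset of {%s}",
                             paste(known, collapse = ", ")))
  if (!"wildtype" %in% cfg$genotypes)
    err("genotypes", "'wildtype' must be included")
  needs_transition <- any(c("png", "smg") %in% cfg$genotypes)
  if (needs_transition &&
      (is.null(cfg$activation_transition) ||
       cfg$activation_transition < 1 || cfg$activation_transition >= S))
    err("activation_transition",
        "must index a stage transition (1 .. n_stages - 1) when png/smg genotypes are simulated")
  if (!is.null(cfg$seed) && is.na(cfg$seed)) err("seed", "must be an integer")
  cfg
}

#' Draw per-molecule poly(A)-tail lengths
#'
#' Tails are drawn from a gamma distribution with the requested mean and
#' shape (a unimodal, strictly positive family), rounded to the nearest
#' integer and floored at 1 nt. Uses the current RNG state.
#'
#' @param mean_nt mean tail length (nt), >= 1.
#' @param shape gamma shape parameter, > 0.
#' @param n number of molecules to draw.
#' @return integer vector of `n` tail lengths (nt).
#' @export
sample_tail_lengths <- function(mean_nt, shape, n) {
  assert_that(is.numeric(mean_nt) && all(mean_nt >= 1),
              "mean_nt must be >= 1", "tailTE_error_config")
  assert_that(is.numeric(shape) && shape > 0,
              "shape must be > 0", "tailTE_error_config")
  assert_that(n >= 0, "n must be >= 0", "tailTE_error_config")
  if (n == 0) return(integer(0))
  draw_tails(rep_len(mean_nt, n), shape)
}

# Vectorised core: one gamma draw per element of `means`.
draw_tails <- function(means, shape) {
  if (!length(means)) return(integer(0))
  x <- stats::rgamma(length(means), shape = shape, rate = shape / means)
  pmax(1L, as.integer(round(x)))
}

#' Draw RNA-seq and ribosome-footprint counts for one sample
#'
#' Counts are independent Poisson draws: RNA counts have means
#' `depth_rna * a_g / sum(a)` and footprint counts
#' `depth_rpf * a_g * te_g / sum(a * te)`, so the expected totals equal
#' the depths and the footprint allocation is proportional to abundance
#' times translational efficiency.
#'
#' @param true_abundance per-gene positive relative abundances.
#' @param true_te per-gene positive linear-scale TEs.
#' @param depth_rna,depth_rpf expected library totals.
#' @param overdispersion 0 for Poisson (default); > 0 for negative
#'   binomial with variance `mu + overdispersion * mu^2`.
#' @return list with integer vectors `rna_counts`, `rpf_counts` and the
#'   realised `rna_total`, `rpf_total`.
#' @export
sample_counts <- function(true_abundance, true_te, depth_rna, depth_rpf,
                          overdispersion = 0) {
  assert_that(all(true_abundance > 0) && sum(true_abundance) > 0,
              "abundances must be > 0", "tailTE_error_config")
  assert_that(all(true_te > 0), "TEs must be > 0", "tailTE_error_config")
  mu_rna <- depth_rna * true_abundance / sum(true_abundance)
  w <- true_abundance * true_te
  mu_rpf <- depth_rpf * w / sum(w)
  draw <- function(mu) {
    if (overdispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  rna <- draw(mu_rna)
  rpf <- draw(mu_rpf)
  list(rna_counts = rna, rpf_counts = rpf,
       rna_total = sum(rna), rpf_total = sum(rpf))
}

# ---- ground truth ----------------------------------------------------------

# A sim_truth carries mean tails, the additive components of log2 TE, and
# the planted set memberships. log2_te = alpha + coupling term + profile
# effect + planted activation effect + per-stage noise. Each genotype's
# dataset gets an independent noise draw (mutant samples are separate
# libraries); mean tails carry no extra noise, so tail-change rank order
# under wispy is preserved exactly in the truth.
new_sim_truth <- function(genes, stages, beta, coupling_scale, log2_tail,
                          alpha, profile_effect, extra_te, noise, sets,
                          activation_transition, genotype = "wildtype") {
  tr <- list(genes = genes, stages = stages, coupling_beta = beta,
             coupling_scale = coupling_scale, log2_tail = log2_tail,
             alpha = alpha, profile_effect = profile_effect,
             extra_te = extra_te, noise = noise, sets = sets,
             activation_transition = activation_transition,
             genotype = genotype)
  tr$log2_te <- compute_true_log2_te(tr)
  class(tr) <- "sim_truth"
  tr
}

compute_true_log2_te <- function(truth) {
  lt <- truth$log2_tail
  te <- matrix(truth$alpha, nrow = nrow(lt), ncol = ncol(lt))
  for (s in seq_len(ncol(lt))) {
    x <- if (truth$coupling_scale == "absolute") 2^lt[, s] else lt[, s]
    te[, s] <- te[, s] + truth$coupling_beta[s] * (x - mean(x))
  }
  te <- te + truth$profile_effect + truth$extra_te + truth$noise
  dimnames(te) <- dimnames(lt)
  te
}

#' Apply a genotype effect to a ground-truth object
#'
#' Transforms the wild-type truth into the corresponding mutant truth.
#' `wispy`: all mean tails multiplied by per-gene shrink factors (spared
#' set near 1); since one factor applies to every stage of a gene, the
#' rank order of between-stage tail changes is preserved by construction.
#' `png`: for the planted up/down sets, the activation-transition tail
#' change and planted TE change are replaced by the cohort-median change.
#' `smg`: responsive png-down genes retain `multiplier` times the
#' wild-type transition change; all other genes behave as in wild type.
#'
#' Draws (wispy shrink factors) use the current RNG state.
#'
#' @param truth a `sim_truth` (wild type).
#' @param genotype one of `"wildtype"`, `"wispy"`, `"png"`, `"smg"`.
#' @param spec parameter list, see [default_genotype_specs()].
#' @return a new `sim_truth` for the mutant.
#' @export
apply_genotype <- function(truth, genotype,
                           spec = default_genotype_specs()[[genotype]]) {
  assert_that(inherits(truth, "sim_truth"), "truth must be a sim_truth",
              "tailTE_error_config")
  if (identical(genotype, "wildtype")) return(truth)
  if (!genotype %in% c("wispy", "png", "smg"))
    abort_tailTE(sprintf("unknown genotype '%s'", genotype),
                 "tailTE_error_genotype")
  n <- nrow(truth$log2_tail)
  S <- ncol(truth$log2_tail)
  tr <- truth
  tr$genotype <- genotype
  if (genotype == "wispy") {
    delta <- stats::runif(n, spec$shrink_range[1], spec$shrink_range[2])
    spared <- truth$sets$wispy_spared
    if (length(spared)) {
      idx <- match(spared, truth$genes$gene_id)
      delta[idx] <- stats::runif(length(idx), spec$spared_shrink_range[1],
                                 spec$spared_shrink_range[2])
    }
    tr$log2_tail <- truth$log2_tail + log2(delta)
    tr$shrink_factor <- delta
  } else {
    t0 <- truth$activation_transition
    assert_that(!is.null(t0) && t0 >= 1 && t0 < S,
                "truth has no activation transition", "tailTE_error_config")
    d_tail_all <- truth$log2_tail[, t0 + 1] - truth$log2_tail[, t0]
    d_extra_all <- truth$extra_te[, t0 + 1] - truth$extra_te[, t0]
    med_tail <- median_midpoint(d_tail_all)
    med_extra <- median_midpoint(d_extra_all)
    later <- (t0 + 1):S
    if (genotype == "png") {
      target <- union(truth$sets$png_up, truth$sets$png_down)
      if (!length(target)) return(truth)
      idx <- match(target, truth$genes$gene_id)
      tr$log2_tail[idx, later] <- tr$log2_tail[idx, later] +
        (med_tail - d_tail_all[idx])
      tr$extra_te[idx, later] <- tr$extra_te[idx, later] +
        (med_extra - d_extra_all[idx])
    } else { # smg
      resp <- truth$sets$smg_responsive
      if (!length(resp)) return(truth)
      m <- spec$multiplier
      idx <- match(resp, truth$genes$gene_id)
      tr$log2_tail[idx, later] <- tr$log2_tail[idx, later] +
        (m - 1) * d_tail_all[idx]
      tr$extra_te[idx, later] <- tr$extra_te[idx, later] +
        (m - 1) * d_extra_all[idx]
    }
  }
  tr$log2_te <- compute_true_log2_te(tr)
  tr
}

# ---- the generator ---------------------------------------------------------

#' Simulate a multi-stage, multi-genotype profiling dataset
#'
#' Generates per-sample poly(A)-tag tables (one row per sequenced tag with
#' its tail length), per-gene RNA-seq and ribosome-footprint counts, and a
#' ground-truth record, for every (genotype, stage) combination in the
#' configuration. Identical configurations (including seed) give
#' byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: list with elements `tags`,
#'   `counts`, `samples`, `library_sizes`, `truth`, `manifest`.
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  stages <- config$stages
  S <- length(stages)
  beta <- config$coupling_beta

  gene_id <- sprintf("g%05d", seq_len(n))
  length_nt <- round(exp(stats::runif(n, log(500), log(10000))))
  abundance <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)

  # mean tails: lognormal base, per-gene random-walk drift across stages
  log2_tail <- matrix(0, n, S, dimnames = list(gene_id, stages))
  log2_tail[, 1] <- log2(config$tail_base_mean_nt) +
    stats::rnorm(n, 0, config$tail_log2_sd)
  if (S > 1) {
    for (s in 2:S) {
      log2_tail[, s] <- log2_tail[, s - 1] +
        stats::rnorm(n, 0, config$tail_drift_sd)
    }
  }

  alpha <- stats::rnorm(n, 0, config$alpha_sd)

  # planted temporal TE profiles
  profile_class <- rep(NA_integer_, n)
  profile_effect <- matrix(0, n, S)
  if (length(config$profile_classes)) {
    pool <- sample.int(n)
    ptr <- 0L
    for (k in seq_along(config$profile_classes)) {
      pc <- config$profile_classes[[k]]
      nk <- round(pc$fraction * n)
      if (nk < 1) next
      idx <- pool[(ptr + 1):(ptr + nk)]
      ptr <- ptr + nk
      profile_class[idx] <- k
      profile_effect[idx, ] <- matrix(pc$profile * pc$effect, nk, S,
                                      byrow = TRUE)
    }
  }

  # planted activation-transition regulons (needed for png/smg genotypes)
  sets <- list(wispy_spared = character(0), png_up = character(0),
               png_down = character(0), smg_responsive = character(0))
  extra_te <- matrix(0, n, S)
  specs <- config$genotype_specs
  if ("wispy" %in% config$genotypes) {
    n_spared <- round(specs$wispy$spared_fraction * n)
    sets$wispy_spared <- sort(sample(gene_id, n_spared))
  }
  if (any(c("png", "smg") %in% config$genotypes)) {
    t0 <- config$activation_transition
    ps <- specs$png
    unassigned <- gene_id[is.na(profile_class)]
    assert_that(ps$n_up + ps$n_down <= length(unassigned),
                "invalid configuration field 'genotype_specs': png target sets exceed the unassigned gene pool",
                "tailTE_error_config")
    picked <- sample(unassigned, ps$n_up + ps$n_down)
    sets$png_up <- sort(picked[seq_len(ps$n_up)])
    sets$png_down <- sort(picked[ps$n_up + seq_len(ps$n_down)])
    later <- (t0 + 1):S
    for (dir in c(1, -1)) {
      set <- if (dir == 1) sets$png_up else sets$png_down
      idx <- match(set, gene_id)
      log2_tail[idx, later] <- log2_tail[idx, later] +
        dir * ps$tail_effect_log2
      # planted TE effect beyond what the coupling term already contributes
      excess <- ps$te_effect_log2 - beta[t0 + 1] * ps$tail_effect_log2
      extra_te[idx, later] <- extra_te[idx, later] + dir * excess
    }
    if ("smg" %in% config$genotypes) {
      n_resp <- round(specs$smg$responsive_fraction * length(sets$png_down))
      sets$smg_responsive <- sort(sample(sets$png_down, n_resp))
    }
  }

  noise <- matrix(stats::rnorm(n * S, 0, config$noise_sd_log2te), n, S)

  genes <- data.frame(gene_id = gene_id, length_nt = length_nt,
                      abundance = abundance, profile_class = profile_class,
                      stringsAsFactors = FALSE)
  truth_wt <- new_sim_truth(genes, stages, beta, config$coupling_scale,
                            log2_tail, alpha, profile_effect, extra_te,
                            noise, sets, config$activation_transition)

  # sub-seeds: one per genotype (mutant draws) + one per (genotype, stage)
  genotypes <- config$genotypes
  G <- length(genotypes)
  sub_seed <- matrix(sample.int(.Machine$integer.max - 1L, G * (S + 1L)),
                     nrow = G)

  per_genotype <- list()
  tag_parts <- list()
  count_parts <- list()
  libsize_parts <- list()
  for (g in seq_len(G)) {
    geno <- genotypes[g]
    set.seed(sub_seed[g, 1])
    tr <- apply_genotype(truth_wt, geno)
    if (geno != "wildtype") {
      # mutant samples are independent libraries: fresh tail-independent
      # TE noise (the deterministic components carry the genotype effects)
      tr$noise <- matrix(stats::rnorm(n * S, 0, config$noise_sd_log2te), n, S)
      tr$log2_te <- compute_true_log2_te(tr)
    }
    per_genotype[[geno]] <- tr
    tail_mean <- 2^tr$log2_tail
    te_lin <- 2^tr$log2_te
    for (s in seq_len(S)) {
      set.seed(sub_seed[g, s + 1])
      sample_id <- paste(geno, stages[s], sep = "_")
      a_eff <- abundance
      tau <- config$rna_selection_bias_tau
      if (!is.null(tau)) a_eff <- abundance * pmin(tail_mean[, s] / tau, 1)
      cts <- sample_counts(a_eff, te_lin[, s],
                           config$depth_rna, config$depth_rpf,
                           overdispersion = config$overdispersion %||% 0)
      count_parts[[sample_id]] <- data.frame(
        gene_id = gene_id, sample = sample_id,
        rna_count = cts$rna_counts, rpf_count = cts$rpf_counts,
        stringsAsFactors = FALSE)
      ntags <- stats::rpois(n, config$depth_tags * abundance / sum(abundance))
      tails <- draw_tails(rep(tail_mean[, s], ntags), config$tail_shape)
      tag_parts[[sample_id]] <- data.frame(
        chrom = "simchr",
        site = rep(1000L + 5000L * seq_len(n), ntags),
        strand = "+",
        tail_length = tails,
        sample = sample_id,
        gene_id = rep(gene_id, ntags),
        stringsAsFactors = FALSE)
      libsize_parts[[sample_id]] <- data.frame(
        sample = sample_id, genotype = geno, stage = stages[s],
        rna_total = cts$rna_total, rpf_total = cts$rpf_total,
        tag_total = sum(ntags), stringsAsFactors = FALSE)
    }
  }

  libsizes <- do.call(rbind, libsize_parts)
  rownames(libsizes) <- NULL
  samples <- libsizes[, c("sample", "genotype", "stage")]
  tags <- do.call(rbind, tag_parts)
  rownames(tags) <- NULL
  counts <- do.call(rbind, count_parts)
  rownames(counts) <- NULL

  tail_te <- do.call(rbind, lapply(names(per_genotype), function(geno) {
    tr <- per_genotype[[geno]]
    data.frame(
      gene_id = rep(gene_id, S),
      sample = rep(paste(geno, stages, sep = "_"), each = n),
      true_mean_tail_nt = as.vector(2^tr$log2_tail),
      true_log2_te = as.vector(tr$log2_te),
      stringsAsFactors = FALSE)
  }))

  truth <- list(genes = genes, tail_te = tail_te, sets = sets,
                coupling_beta = stats::setNames(beta, stages),
                per_genotype = per_genotype)

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   n_genes = n,
                   stages = paste(stages, collapse = ","),
                   coupling_beta = paste(beta, collapse = ","),
                   genotypes = paste(genotypes, collapse = ","),
                   activation_transition =
                     config$activation_transition %||% "")

  structure(list(tags = tags, counts = counts, samples = samples,
                 library_sizes = libsizes[, c("sample", "rna_total",
                                              "rpf_total", "tag_total")],
                 truth = truth, manifest = manifest, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes, %d samples (%s), %d tags, seed %d\n",
    x$config$n_genes, nrow(x$samples),
    paste(unique(x$samples$genotype), collapse = "/"),
    nrow(x$tags), x$manifest$seed))
  invisible(x)
}

# ---- fixture round trip ----------------------------------------------------

#' Write a simulated dataset to a fixture directory
#'
#' Emits the tag and count tables in the pipeline TSV dialects, the truth
#' tables, and a flat key-value manifest. [read_fixture()] reproduces the
#' tables field for field.
#'
#' @param dataset a `sim_dataset`.
#' @param directory output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  assert_that(inherits(dataset, "sim_dataset"),
              "dataset must be a sim_dataset", "tailTE_error_config")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(directory),
              sprintf("cannot create directory: %s", directory),
              "tailTE_error_io")
  prov <- c(generator = "tailTE simulate_dataset",
            seed = as.character(dataset$manifest$seed),
            config_hash = dataset$manifest$config_hash)
  write_tsv_prov(dataset$tags, file.path(directory, "tags.tsv"), prov)
  write_tsv_prov(dataset$counts, file.path(directory, "counts.tsv"), prov)
  write_tsv_prov(dataset$samples, file.path(directory, "samples.tsv"), prov)
  write_tsv_prov(dataset$library_sizes,
                 file.path(directory, "library_sizes.tsv"), prov)
  write_tsv_prov(dataset$truth$genes,
                 file.path(directory, "truth_genes.tsv"), prov)
  write_tsv_prov(dataset$truth$tail_te,
                 file.path(directory, "truth_tail_te.tsv"), prov)
  sets <- dataset$truth$sets
  sets_df <- data.frame(
    set = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_prov(sets_df, file.path(directory, "truth_sets.tsv"), prov)
  manifest_path <- file.path(directory, "manifest.txt")
  m <- dataset$manifest
  writeLines(paste0(names(m), "=", vapply(m, as.character, character(1))),
             manifest_path)
  invisible(manifest_path)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return a `sim_dataset`-like list (the internal per-genotype truth
#'   components are not round-tripped; all tables are).
#' @export
read_fixture <- function(directory) {
  assert_that(dir.exists(directory),
              sprintf("no such fixture directory: %s", directory),
              "tailTE_error_io")
  man_lines <- readLines(file.path(directory, "manifest.txt"))
  kv <- strsplit(man_lines, "=", fixed = TRUE)
  manifest <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1))
  manifest$seed <- as.integer(manifest$seed)
  manifest$n_genes <- as.integer(manifest$n_genes)
  sets_df <- read_tsv_prov(file.path(directory, "truth_sets.tsv"))
  set_names <- c("wispy_spared", "png_up", "png_down", "smg_responsive")
  sets <- stats::setNames(
    lapply(set_names, function(s) sets_df$gene_id[sets_df$set == s]),
    set_names)
  genes <- read_tsv_prov(file.path(directory, "truth_genes.tsv"))
  genes$profile_class <- as.integer(genes$profile_class)
  structure(list(
    tags = read_tsv_prov(file.path(directory, "tags.tsv")),
    counts = read_tsv_prov(file.path(directory, "counts.tsv")),
    samples = read_tsv_prov(file.path(directory, "samples.tsv")),
    library_sizes = read_tsv_prov(file.path(directory, "library_sizes.tsv")),
    truth = list(
      genes = genes,
      tail_te = read_tsv_prov(file.path(directory, "truth_tail_te.tsv")),
      sets = sets),
    manifest = manifest), class = "sim_dataset")
}
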