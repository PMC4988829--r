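# tailTE

Analysis of the coupling between mRNA **poly(A)-tail length** and
**translational efficiency (TE)** across developmental stages and
genotypes, for data of the kind produced by poly(A)-tag sequencing
(PAL-seq-like), ribosome footprint profiling, and RNA-seq on the same
samples — the setting of oocyte maturation, egg activation, and the
maternal-to-zygotic transition, where transcription is silent and
tail-length changes broadly reshape translation until the coupling
switches off around gastrulation.

## Who it is for

Researchers with *processed* per-sample tables — poly(A) tags (3'-end
coordinate + tail length per sequenced molecule), per-gene footprint and
RNA-seq counts, and a refFlat annotation — who want a tested, scriptable
reimplementation of the standard analysis stack for this field, plus a
ground-truth-recording simulator to validate every stage without
touching real data.

## What it computes

For gene $g$ in sample $s$, with reads-per-million (RPM) normalisation:

$$\log_2 \mathrm{TE}_{gs} = \log_2\!\frac{\mathrm{RPF\ RPM}_{gs}}{\mathrm{RNA\ RPM}_{gs}}
 - \operatorname{median}_{g'}\left(\log_2 \mathrm{TE}_{g's}\right)$$

and everywhere the Spearman correlation $R_s$ between per-gene mean tail
length (nt) and centred log2 TE, or between their between-stage changes.
Around that core:

* **Gene models** — representative transcript per gene, 3'-end
  re-annotation from pooled tags (tails ≥ 20 nt, ≥ 2 tags per site,
  60-nt collapse window, 4100-nt UTR cap, distal extension).
* **Quantification** — pooled tandem-isoform tail summaries, RPM/RPKM,
  pseudocount and low-evidence rules, the standard single/pairwise/
  multi-sample read cutoffs, centred TE change tables.
* **Coupling** — per-stage $R_s$, binned-median TE "steepness" ratio
  ([70,80) vs [30,40) nt), change coupling on relative (log2) or
  absolute (nt) tail scales, poly(A)-selection-bias diagnostic.
* **Dynamics** — short time-series clustering of TE trajectories onto
  exhaustively enumerated bounded-step model profiles, with a
  permutation/binomial enrichment surrogate and Bonferroni correction.
* **Contrasts** — ≥ 50%-tail-shortening census, 4-fold-in-both-
  comparisons dependent regulated sets, Wilcoxon rank-sum gene-set shift
  tests (exact for small sets), footprint concordance with dropout
  lists, hybrid TEs (mutant footprints over wild-type RNA-seq).
* **Simulation** — multi-stage, multi-genotype cohorts (global tail
  shortening with a spared set; nulled activation-transition regulons;
  partial derepression) with full ground truth for recovery tests.

See `vignettes/tail-te-methods.Rmd` for the model, parameter defaults,
and design decisions.

## Worked example

Simulate a three-stage cohort in which coupling is on at the first two
stages ($\beta = 1.0, 1.2$) and off at "gastrulation" ($\beta = 0$),
then quantify and measure the coupling per stage:

```r
library(tailTE)

cfg <- sim_config(n_genes = 1000,
                  stages = c("oocyte", "embryo", "gastrula"),
                  coupling_beta = c(1.0, 1.2, 0),
                  depth_tags = 5e5, depth_rna = 5e6, depth_rpf = 5e6,
                  seed = 42)
ds <- simulate_dataset(cfg)
ds
#> <sim_dataset> 1000 genes, 3 samples (wildtype), 1499179 tags, seed 42

st <- stage_tables(ds)   # tail summaries + expression + log2 TE
for (stage in cfg$stages) {
  s <- paste0("wildtype_", stage)
  pass <- apply_cutoffs(st$tails, st$expr, "single", s)
  tails <- setNames(st$tails$mean_tail_nt[st$tails$sample == s],
                    st$tails$gene_id[st$tails$sample == s])[pass]
  te <- median_center(setNames(st$expr$log2_te[st$expr$sample == s],
                               st$expr$gene_id[st$expr$sample == s])[pass])
  rc <- rank_correlation(tails, te$centered)
  bm <- binned_median_te(tails, te$centered)
  cat(sprintf("%-9s R_s = %5.2f  (n = %d)   TE ratio [70,80) vs [30,40) nt = %.1f-fold\n",
              stage, rc$r_s, rc$n, bm$bin_ratio))
}
#> oocyte    R_s =  0.65  (n = 863)   TE ratio [70,80) vs [30,40) nt = 2.0-fold
#> embryo    R_s =  0.78  (n = 872)   TE ratio [70,80) vs [30,40) nt = 2.6-fold
#> gastrula  R_s =  0.02  (n = 867)   TE ratio [70,80) vs [30,40) nt = 1.0-fold
```

Reading the output: at the coupled stages, genes that pass the
quantification cutoffs (≥ 100 tags, ≥ 10 RNA RPM, > 0 RPF RPM — here
~870 of 1000) show a strong positive rank correlation between mean tail
length and relative TE, and mRNAs with 70–80-nt tails are translated
2–2.6-fold better than those with 30–40-nt tails; at the uncoupled
stage both statistics collapse to their null values, recovering the
simulated switch.

The same pipeline runs from the command line on a written fixture:

```sh
Rscript -e 'tailTE::run_cli()' simulate --out fixture --seed 7
Rscript -e 'tailTE::run_cli()' all --fixture fixture --out results_dir
```

Outputs are TSVs with `#`-prefixed provenance headers (centring
constants, cutoffs, seeds); identical inputs give byte-identical output
trees.

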