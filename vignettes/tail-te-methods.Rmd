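---
title: "Methods: poly(A)-tail length and translational efficiency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-tail length and translational efficiency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Maturing oocytes and early embryos are transcriptionally silent, so their
developmental programs run on post-transcriptional control of a stockpile
of maternal mRNAs. One central mechanism is regulation of poly(A)-tail
length: cytoplasmic polyadenylation lengthens tails and deadenylases
shorten them, and — before gastrulation — a gene's mean tail length is
coupled to how efficiently its mRNA is translated. `tailTE` implements a
pipeline for analysing this coupling from three kinds of bulk profiling
data collected on the same samples:

* **poly(A) tags** (e.g. PAL-seq): one record per sequenced mRNA 3' end,
  carrying a genomic cleavage/poly(A)-site coordinate and a measured tail
  length in nucleotides;
* **ribosome footprints (RPFs)**: per-gene counts of ribosome-protected
  fragments;
* **RNA-seq**: per-gene mRNA abundance counts.

Translational efficiency (TE) for gene $g$ in sample $s$ is

$$\mathrm{TE}_{gs} = \frac{\mathrm{RPF\ RPM}_{gs}}{\mathrm{RNA\ RPM}_{gs}},$$

analysed as $\log_2 \mathrm{TE}$ after subtracting the per-sample median
over the quantified gene set ("median centring"), because footprint
profiling measures relative, not absolute, translation. The headline
statistic everywhere is the Spearman correlation $R_s$ between per-gene
mean tail length and centred $\log_2$ TE (or between their between-stage
changes), with average-rank tie handling.

## Pipeline stages and their rules

**Gene models.** Analysis units are one representative transcript model
per protein-coding gene: the longest transcript (genomic span by default;
summed exon length available as a switch), with non-coding genes and
same-strand overlapping gene pairs removed. 3' ends are re-annotated from
pooled poly(A) tags: tags with tails < 20 nt are discarded (likely
internal priming), positions supported by ≥ 2 tags strictly between a
gene's stop codon and the next same-strand TSS become candidate isoform
ends, ends implying a 3' UTR > 4100 nt are discarded, and nearby ends are
collapsed with a 60-nt window. The collapse semantics are fixed as a
deterministic greedy rule — repeatedly keep the unconsumed site with the
highest tag support (ties broken strand-distal-most) and absorb all sites
within ± 60 nt, summing support — because the originally cited procedure
is under-specified; the rule is order-independent, idempotent, conserves
support, and is verified against a naive simulation oracle. If a
re-annotated end is distal to the reference 3' end, the model is
extended. Coordinates are 0-based half-open throughout.

**Quantification.** Tail measurements from all tandem 3'-UTR isoforms of
a gene are pooled into one mean (plus a 5-nt-bin histogram); means ≤ 4 nt
are *reported* as 4 nt but all arithmetic uses raw values, and tail fold
changes involving raw means < 8 nt are flagged unreliable (very short
tails cannot be measured accurately). Read cutoffs reproduce the standard
conjunctions: single-stage analyses require ≥ 100 tags, ≥ 10 RNA RPM and
> 0 RPF RPM; pairwise change analyses require the tag and RNA cutoffs in
both samples and ≥ 10 RPF RPM in one with > 0 in the other; multi-sample
(clustering and TE-only) analyses drop the tag requirement. Genes with
zero footprints get a pseudocount of 1 read, flagged; genes below 25
footprint reads are flagged low-evidence but kept. TE fold changes are
median-centred per comparison; tail fold changes are reported raw with
the cohort median alongside, and the absolute difference in nt is also
emitted (tail–TE change coupling can be computed on either scale; on
log-normal-like tails the two give nearly identical $R_s$).

**Coupling.** Besides $R_s$, the "steepness" of the tail–TE relationship
is summarised by the linear-fold ratio of median centred TE between the
[70, 80) nt and [30, 40) nt tail bins (half-open 10-nt bins anchored at
0; the open/closed convention is not stated in the source legends, so
half-open was chosen and documented). Bins with < 10 genes are flagged.
A diagnostic correlation of RNA RPM against mean tail detects
poly(A)-selection bias in RNA-seq libraries (material positive $R_s$
means short-tailed mRNAs were depleted, inflating their apparent TEs).
Undefined correlations (n < 3, zero variance) raise typed errors rather
than propagating `NA`.

**TE dynamics clustering.** Trajectories of centred log2 TE across 3–4
stages are normalised to the first stage and assigned, by maximal Pearson
correlation, to the exhaustive set of integer model profiles with
per-step changes bounded by 1 ($(2c+1)^{T-1}$ profiles; 27 for four
stages). Only genes whose largest pairwise log2 difference is ≥ 0.5 are
clustered; the all-zero profile is unassignable (undefined correlation) —
its would-be members are exactly the filtered genes. Because the profile
space at $c = 1$ is small, the full enumerated set is used with no
representative-subset reduction. Enrichment is assessed by a permutation
surrogate: each eligible gene's stage values are re-ordered in all $T!$
ways (sampled with a recorded seed above $T = 6$), re-normalised and
re-assigned; a profile's expected size is the summed per-gene assignment
fraction, the raw p-value is the upper binomial tail at that expectation,
and Bonferroni correction is over the assignable profiles (significance
at adjusted p < 0.05). This computation is a defined surrogate for the
short time-series clustering tool it emulates — that tool's exact
significance procedure is not restated in the source — and outputs are
labelled accordingly. The binomial approximation to the
Poisson–binomial null is variance-inflating, hence mildly conservative;
measured familywise error on permuted nulls is ~2–3%.

**Genotype contrasts.** Three mutant archetypes are supported. A
*global-shortening* mutant (loss of the cytoplasmic poly(A) polymerase,
e.g. *wispy*): census of genes whose mutant mean tail is ≥ 50% shorter
(inclusive boundary, raw means, universe = ≥ 100 tags in both samples),
plus a one-tailed rank-sum test for gene sets spared from shortening
(e.g. ribosomal-protein mRNAs). Because its RNA-seq suffers
poly(A)-selection bias, hybrid TEs (mutant footprints over wild-type
RNA-seq) are supported, reducing to standard TEs when the tables
coincide. A *regulator-dependent* set (e.g. PAN GU kinase): genes ≥
4-fold up- or down-regulated in both of two centred TE-change comparisons
(wild-type across egg activation, and wild-type vs mutant after
activation). A *downstream-repressor* mutant (e.g. Smaug): partial,
sign-preserved attenuation of the dependent down-set's shifts. Set-shift
tests compare a set against its complement with a Wilcoxon rank-sum:
exact enumeration of the (tied) null when the smaller group has ≤ 8
members and the enumeration is feasible, otherwise a tie-corrected,
continuity-corrected normal approximation. The set-vs-complement framing
(rather than set-vs-whole-cohort) is the standard two-sample convention;
descriptive "relative to the median of all mRNAs" medians are reported
alongside. Footprint-only concordance between genotypes uses genes ≥ 10
RPF RPM in either sample, a pseudocount of 1 read for zero-count genes,
and reports genes with reads in exactly one sample as dropouts.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the pipeline
assumes, with recorded ground truth so that every stage is testable
without downloads. Per gene: a length (log-uniform 0.5–10 kb), a relative
abundance (log-normal), a base mean tail (log-normal around 50 nt,
between-gene SD 0.6 log2 units), and a per-stage mean-tail random walk
(drift SD 0.4 log2 units per transition). True TE is

$$\log_2 \mathrm{TE}_{gs} = \alpha_g + \beta_s\,(\log_2 \tau_{gs} -
\overline{\log_2 \tau_{\cdot s}}) + \pi_{gs} + \epsilon_{gs},$$

with baseline $\alpha_g \sim N(0, 0.5)$, per-stage coupling $\beta_s$
(set to 0 at "gastrulation"-like stages to switch coupling off; a config
switch couples on absolute nt instead of log2 tail), planted profile and
regulon effects $\pi$, and tail-independent noise $\epsilon \sim N(0,
0.4)$. Per-molecule tails are gamma-distributed (shape 10) around the
gene's stage mean, rounded and floored at 1 nt — unimodal and positive,
without claiming the real data's exact shape, whose per-gene variance the
source does not report. Counts are Poisson allocations of the library
depth proportional to abundance (RNA) and abundance × TE (footprints),
with an optional negative-binomial overdispersion knob (off by default:
one library per stage, no replicate dispersion to emulate). Tags are
Poisson per gene proportional to abundance, and an optional
`rna_selection_bias_tau` attenuates RNA recovery for short-tailed genes
to emulate poly(A)-selection bias.

Genotype effects transform the truth and are re-sampled into counts:
the global-shortening mutant multiplies every gene's mean tail by a
per-gene factor drawn from (0.3, 0.7) — chosen so that about half the
genes cross the 50%-shortening boundary, matching the roughly 50%
fraction the real census found — with a spared set near 1; one factor
per gene across all stages preserves between-stage tail-change rank
order exactly. The kinase mutant replaces the planted activation-
transition tail/TE changes of its up/down target sets (default 100 + 100
genes, 8-fold TE effects with 2-fold tail effects) with the cohort-median
change; the repressor mutant scales the wild-type change of a responsive
subset (70% of the down set) by 0.4. Each genotype's dataset receives an
independent TE-noise draw: mutant samples are separate libraries, and
sharing noise across genotypes was found to leak selection effects from
wild-type comparisons into mutant tables (see the decisions below). All
randomness flows from one seed, with per-sample sub-streams derived from
it, so identical configurations are byte-identical.

### What a green test does and does not establish

The generator reproduces the *assumed statistical structure* — per-gene
unimodal tails, stage-switchable coupling, planted trajectories and
regulons, genotype arithmetic — not real libraries. It omits: sequence-
level artefacts (mapping, internal priming), tail-length measurement
error beyond sampling noise, correlated biological replicate structure,
mRNA decay and zygotic transcription (abundances are constant across
stages), and 3'-end isoform complexity in the tag coordinates (one site
per gene unless gene-model fixtures are built explicitly). Green
recovery tests therefore establish that the pipeline's estimators and
rules are correct and well-calibrated on data satisfying its
assumptions; they do not validate the upstream measurement technology.

## Numerical choices

* Even-length medians use the midpoint convention throughout.
* Tag-to-gene assignment tolerates ± 10 nt around an annotated isoform
  end (configurable); the source maps tags to 3' UTRs without stating a
  quantification slop.
* Tags exactly at the stop codon or the neighbouring TSS are excluded
  (the interval is read strictly).
* Centring sets default to the cutoff-passing gene set of the relevant
  plot/analysis (the legends imply this); any other set can be passed.
* Exact rank-sum enumeration is used when the smaller group has ≤ 8
  members and at most 1e5 combinations exist; ties are handled exactly
  there and by variance correction in the normal branch.
* Floors (4-nt reported means) affect reporting fields only.

## Known limitations

* The per-gene tail-length variance (gamma shape) is a free knob, not an
  estimate from data.
* The clustering enrichment p-values are a defined surrogate; they are
  not numerically comparable to the original tool's p-values.
* Within-gene isoform-resolved TE is out of scope; the unit of analysis
  is the aggregated gene model.
* Real-data mode expects processed tag/count tables in the documented
  TSV dialects; no alignment or download helpers are provided.
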