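---
title: "The PRC2-AgeIndex: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PRC2-AgeIndex: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc2index)
```

## The quantity being measured

Aging methylomes show two opposing genome-wide trends: a slow global
*loss* of methylation across the heavily methylated background, and a
steady *gain* concentrated in a specific compartment — CpG-dense
low-methylated regions (LMRs) that are highly bound by Polycomb
Repressive Complex 2 (PRC2, subunits EZH2/SUZ12) in embryonic stem
cells. The PRC2-AgeIndex is simply the average methylation level over
the CpGs inside the top-k most PRC2-bound LMRs of a tissue. Because the
regions are defined biologically rather than fitted against
chronological age, the index needs no training step, transfers across
assays and tissues, and is interpretable as the magnitude of one
concrete epigenetic change.

The pipeline has four stages, each its own module:

1. **Methylome input** (`read_methylome`, `merge_symmetric`): per-CpG
   records with methylated/total read counts (or array betas), symmetric
   CpG dyads pooled into one strand-less record per dyad.
2. **LMR segmentation** (`call_lmrs`): a two-state HMM partitions each
   chromosome into hypomethylated islands and methylated background.
3. **PRC2 ranking** (`aggregate_binding`, `filter_blacklist`,
   `select_top_k`): ChIP fold-enrichment (or p-value) signal is averaged
   per region across factors, artifact-prone blacklist regions are
   removed, and the k most-bound regions form the high-PRC2 set.
4. **Scoring** (`compute_index` and companions): the average methylation
   over that set, with coverage diagnostics.

## The segmentation model

Each CpG emits its `(meth_count, total_count)` pair from a beta-binomial
distribution whose mean depends on a hidden two-state chain
(hypomethylated vs background). Beta-binomial rather than binomial
emissions absorb the overdispersion of real bisulfite data — biological
variability between molecules makes the per-site counts wider than
binomial at any fixed mean.

Parameters (`hmm_params()`), all deliberately fixed and documented so
that segmentation is deterministic:

| parameter | default | meaning |
|---|---|---|
| `mean_low`, `mean_high` | 0.10 / 0.80 | emission-mean initializations |
| `p_stay` | 0.95 | self-transition initialization |
| `precision` | 15 | beta-binomial precision (alpha+beta), fixed during EM |
| `desert_size` | 1000 bp | inter-CpG gap that breaks the chain |
| `min_cpgs` | 10 | minimum CpGs per reported region |
| `tol`, `max_iter` | 1e-4 / 100 | EM stopping controls (absolute log-likelihood change) |
| `posterior_cut` | 0.5 | decoding threshold on the low-state posterior |

Numerical choices:

- **E-step** runs a scaled forward–backward recursion (compiled, since
  the recursion is inherently sequential) independently within each
  *chain*: a maximal run of CpGs on one chromosome with no gap larger
  than `desert_size`. Regions therefore never bridge assay deserts.
- **M-step**: transition probabilities in closed form from expected
  transition counts; each state mean by 1-D numerical maximization of
  the expected emission log-likelihood at fixed precision. This is a
  generalized EM step, so the log-likelihood is non-decreasing (tested
  to 1e-8). Emission computations are aggregated over unique
  `(meth, coverage)` pairs, making an EM iteration's cost essentially
  independent of genome size.
- **Label symmetry** is resolved after every M-step: the reported low
  state is always the one with the smaller fitted mean, whatever the
  initialization.
- **Degenerate inputs**: a methylome with no covered site returns an
  empty segmentation; if the fitted "low" state is not hypomethylated in
  absolute terms (mean >= 0.5, as happens when the input is uniformly
  methylated and the two states collapse), no regions are reported,
  with a message. Non-convergence at `max_iter` warns and uses the last
  iterate.
- **Decoding** is posterior-based by default (maximal runs with low-state
  posterior >= 0.5, at least `min_cpgs` CpGs long); boundaries are
  smoother than Viterbi's and directly testable against planted truth.
  Viterbi is available as an option. A region's `end` is the last member
  CpG position + 1 (half-open).
- The `min_cpgs` filter plays the role that a significance filter plays
  in segmentation tools of this family; it is the load-bearing control
  for index stability, and its default (10) is declared rather than
  inherited from any external tool.

Array and single-cell methylomes are rejected by `call_lmrs` (no counts,
or too sparse for region inference); the site-level LMC path below
serves them.

## Ranking and selection

A region's per-factor score is the *base-length-weighted* mean of the
signal track over `[start, end)`. Signal tracks customarily omit
zero/background intervals, so uncovered bases contribute 0 under
fold-change semantics and 1 under p-value semantics (an absent p-value
is a null p of 1). The PRC2 score is the unweighted mean across factors:
with p-value semantics this is literally the "average p-value" rule
(no Fisher combination — staying literal to the selection rule keeps
the ranking reproducible); with fold-change semantics it is the average
enrichment. Both semantics exist because both kinds of track are in
common use; the configuration must declare which one it supplies, and
mixing them is an error. Ties are broken by genomic coordinate, making
top-k membership invariant to input order.

The default k = 1000 is the standard size of the high-PRC2 set.

The **LMC variant** (`rank_lmcs`) ranks single CpGs instead of regions
for assays where segmentation is impossible: sites whose baseline beta
(mean across reference samples) is below `low_threshold` are kept and
ranked by the track value *at the site* (no region extent exists for a
probe). The threshold default of 0.3 is our declared operational
definition of "low-methylated" — no published numeric definition
exists, and 0.3 cleanly separates the hypomethylated mode of the
bimodal genome-wide beta distribution from the methylated one. For
single-cell data, `density_filter` (default 10 CpGs/kb) restricts
scoring to CpG-dense elements, compensating for the sparsity of covered
sites.

## The index and its companions

`compute_index` supports two weightings and every result records which
was used:

- `pooled_cpg` (default): unweighted mean beta over all covered CpGs in
  the set. Robust to region-size variation and to splitting or merging
  of regions; this is the weighting used throughout the tests.
- `region_mean`: mean over regions of their per-region means; weights
  every region equally regardless of CpG count.

Regions without coverage in a sample are excluded and *counted* in the
diagnostics (`n_regions_covered`, `n_cpgs_used`), never imputed —
material for sparse single-cell data.

`ranked_profile` reproduces the standard display: regions ordered from
lowest to highest binding, smoothed by a plain moving average (window
100 regions, step 10 by default; a moving average, not a kernel, keeps
each displayed value an interpretable mean of member regions).
`delta_dnam` gives per-region old-minus-young differences;
`fraction_hypermethylated` is the strictly-positive fraction of those.

`gain_share` formalizes "what fraction of the genome-wide methylation
gain falls inside the high-PRC2 set": per-CpG deltas over sites covered
in both samples, positive parts summed inside the set (numerator) and
over a scope (denominator). Two scopes are offered because the positive
part of a symmetric sampling error is itself positive: at modest
coverage, a genome-wide denominator accumulates noise from every
background CpG. Scope `"genome"` (default) is the literal genome-wide
ratio and is the right choice for *group-pooled* methylomes
(`pool_methylomes` sums counts across replicates, shrinking the noise);
scope `"lmrs"` restricts the denominator to the full LMR complement,
where gain is biologically possible at all, and is more stable for
single pairs.

## Group statistics

Group comparisons use a one-sided independent two-sample t-test,
implemented in closed form. The pooled-variance Student's variant is the
default — "simple independent t-test" is read as the textbook pooled
form — with Welch as an option; confidence intervals elsewhere are
normal-theory. Outlier screening is formalized into two named rules so
that sample removals are reproducible rather than case-by-case:
`anchor_range` (flag samples whose global mean methylation falls outside
the interval spanned by two anchor samples, e.g. a neonatal and a
centenarian sample) and `zscore` (|z| > 3 on global means, the rule to
apply within groups for single-cell data).

## What the simulator emulates

`make_layout` + `simulate_methylome` plant the architecture the method
assumes, with defaults chosen as the study conditions:

| parameter | default | rationale |
|---|---|---|
| LMR length | lognormal, mean 3 kb | observed average LMR size |
| LMR count / genome | 50 per 10 Mb | keeps LMRs a small genome fraction |
| CpG spacing | 1/100 bp background, 1/10 bp in LMRs | LMRs are CpG islands |
| `m_bg0`, `m_low0` | 0.85 / 0.05 | bimodal methylome baseline |
| `loss_rate` | 0.001 /year | slow global background loss |
| `gain_rate` | 0.004 /year | target-LMR gain; separates young/old clearly within a lifespan |
| `mean_coverage` | 30 (Poisson) | typical WGBS depth |
| `dispersion` | 0.02 | mild beta-binomial overdispersion |
| `target_fraction` | 0.5 | half the LMRs PRC2-bound |
| ChIP strengths | targets N(8, 1.5), non-targets N(1, 0.3) | well-separated fold enrichments |
| track noise | SD 1 per 200-bp bin | factor-specific noise; two factors share strengths |

Age effects are linear with clamping to `[0.01, 0.99]` — the simplest
structure consistent with monotone aging trends; no saturation curve is
modelled. One global seed drives everything through per-sample derived
substreams (`derive_seed`), so adding a sample to a cohort never
perturbs existing samples. Assay downsamplers emulate arrays (1.5% of
sites, betas only, counts dropped), RRBS (retention proportional to
local CpG density; no in-silico digestion, since no genome sequence is
in scope) and single-cell WGBS (small site fraction, each retained site
binarized to a single Bernoulli read).

What passing tests on this simulator do **not** show: robustness to
cell-type heterogeneity, to batch and conversion-efficiency artifacts,
to non-CpG methylation, to copy-number variation, or to LMR boundaries
shifting with age — none of which are modelled. The simulator validates
the *machinery* (segmentation, ranking, scoring, statistics) against
planted truth, not the biological claim itself.

## Problem sizes used by the test-suite

Unit tests run on 1–2 Mb genomes with ~10 LMRs; the pipeline-level
acceptance tests use one chromosome of 10 Mb with 50 planted LMRs
(~115k CpGs) at coverage 30, three independent genomes for segmentation
recovery, cohorts of 10–12 samples for the age and assay checks, and
10-replicate pooled groups for the gain-share ratio. These sizes give
each check comfortable statistical margin while keeping a full run in
the tens of seconds.

## Known limitations

- The segmentation fixes the beta-binomial precision rather than
  estimating it per state; heavy overdispersion mismatch would blur
  boundaries before it breaks them.
- `gain_share` with a genome-wide denominator is biased downward by
  sampling noise at low coverage (see above); pool replicates or use the
  LMR scope.
- The LMC threshold (0.3) and the single-cell density cutoff (10
  CpGs/kb) are operational conventions, not estimated quantities.
- Coordinates are 0-based half-open throughout; methcounts positions are
  taken as 0-based (the tool convention). BED and bedGraph are native.
  When importing data from 1-based sources, convert first.
- The CLI's configuration comes from flags and defaults only; each run's
  JSON manifest records the merged effective configuration and package
  version, which is the reproducibility contract.
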