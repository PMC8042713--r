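---
title: "Simulation design and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation design and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvbench)
```

# The problem

Bulk RNA-seq profiles heterogeneous tissue: each sample is a weighted sum of
the transcriptomes of its constituent cell types. Deconvolution methods try
to invert that sum and recover the cell-type proportions. Benchmarking such
methods requires mixtures whose composition is known exactly, which in
practice means simulation: the mixture matrix is assembled as

$$M = S \times W + \varepsilon$$

with $S$ the $N \times K$ matrix of purified cell-type expression profiles,
$W$ the $K \times J$ matrix of mixing proportions (each column summing to
1), and $\varepsilon$ sample-to-sample noise. `deconvbench` implements this
assembly under controlled noise structures, noise levels, library sizes,
weight-matrix regimes and unknown-content spike-ins, together with the
scoring scheme used to compare methods against the ground truth.

# Noise models

Three noise models are provided, each driven by a perturbation level
$p_t$ walking a 10-element grid.

**Normal** (`perturb_normal`): $M = 2^{\log_2(SW + 1) + N(0,\, \sigma p_t)}$
— Gaussian noise on the log2 scale around the pseudocounted expected value.
**Log-normal** (`perturb_lognormal`): $M = SW + 2^{N(0,\, \sigma p_t)}$ —
an additive, log-normally distributed error. Both use $\sigma = 10$ by
default and the grid $p_t \in \{0, 0.1, \ldots, 0.9\}$. The $+1$
pseudocount is implemented verbatim, so the zero-noise limit returns
$SW + 1$; a `subtract_pseudocount` flag removes it for users who want the
noise-free matrix back exactly.

**Negative binomial / gamma-Poisson** (`simulate_nb_counts`), the model of
choice for counts, on the grid $p_t \in \{0.1, \ldots, 1\}$:

$$\mu_{i0} = r_{i0} L_j,\qquad
  \mu_{ij} \sim \mathrm{Gamma}\!\left(\tfrac{1}{\sigma_i^2},\,
  \mu_{i0}\sigma_i^2\right),\qquad
  v_{ij} \sim \mathrm{Poisson}(\mu_{ij}),$$

$$\sigma_i = \left(1.8\,p_t + \tfrac{1}{\sqrt{\mu_{i0}}}\right)
  e^{\delta/2},\qquad \delta \sim N(0,\, 0.25).$$

Here $r_{i0}$ is the expected feature proportion of gene $i$, $L_j$ the
library size of sample $j$. The gamma layer models biological variance, the
Poisson layer technical variance; $p_t$ tunes overdispersion on top of the
Poisson floor $1/\sqrt{\mu_{i0}}$.

Two conventions in the printed form of these distributions are ambiguous,
and both are configurable:

* `N(0, s)` is read with $s$ as the **standard deviation** (default
  `normal_scale = "sd"`), matching the sd-parameterized samplers of the
  simulation lineage this model follows; `"var"` switches to the variance
  reading.
* $\delta \sim N(0, 0.25)$ is read as variance $0.25$, i.e. $sd = 0.5$
  (`delta_sd = 0.5`); $\delta$ is drawn **once per gene** by default
  (`delta_per = "gene"`), treating dispersion as a gene-level property,
  with a per-cell option.

When $\sigma_i$ would be zero the gamma draw degenerates to a point mass at
$\mu_{i0}$ rather than producing NaN.

# Mixing modes

For the nb model, noise can be applied at two points
(`apply_noise(mode = ...)`):

* `component_level` (default): each cellular component gets its own
  gamma-Poisson count realization from its normalized profile, and the
  realizations are summed weighted by $W$. This reads the feature
  proportion $r_{i0}$ as a property of a *cellular component* and lets each
  component contribute independent biological noise. Component sums stay
  real-valued; a `round_counts` flag restores strict integer semantics.
* `mixture_level`: the expected mixture column $SW_{\cdot j}$ is normalized
  to a simplex and one count realization is drawn per sample.

Both recover the configured library size in expectation
($\sum_i \mu_{i0} = L_j$); the tests check recovery within 1%.

# Weight regimes

Four regimes span the conditioning spectrum of $W$ (all sampled uniformly,
all columns rescaled to sum to 1):

* **orthog** — 1000 candidate matrices are drawn and the one with the
  smallest 2-norm condition number (largest/smallest singular value; the
  norm is our choice, as none is prescribed) is returned. This is the
  idealized, best-posed regime.
* **real** — components sampled within predefined whole-blood composition
  bands; of 1000 candidate columns those with pre-rescale sums closest to 1
  are kept, and any column whose rescaled entries leave their band is
  resampled (ties on $|{\rm sum}-1|$ break by candidate index). The default
  band table (`real_blood_ranges()`) is a plausible whole-blood
  composition compiled for this package — neutrophil-dominated, with T/B/NK
  subsets at a few percent — and is deliberately config-overridable rather
  than canonical.
* **dominant** — one major component in $[0.9, 0.99]$, minors in
  $[(1-p_{maj})/(K-1),\ (1-p_{maj})/(K-1)+0.01]$.
* **uniform** — all entries in $[1/K,\ 1/K + 0.04]$.

Empirically the mean condition number orders orthog < uniform < dominant,
which is what makes the regimes informative: deconvolution accuracy should
degrade as conditioning worsens, and the built-in NNLS baseline reproduces
that direction.

Tumor spike-ins (`add_tumor_spikein`) add an unknown component with
fraction $t$ drawn from one of three bands: small $[0.2, 0.3]$, large
$[0.7, 0.8]$, mosaic $[0.05, 0.95]$. Two modes are kept because the two
natural readings of "append and rescale" differ: `final_fraction` (default)
scales the known column by $1-t$ so the tumor fraction lands exactly in the
advertised band; `append_rescale` appends $t$ and divides by $1+t$, which
shifts the realized fraction to $t/(1+t)$. Relative (renormalized
immune-only) proportions are identical under both.

# Scenario builders

* `build_sim1` (noise structure): for each model and $p_t$, three
  independent source datasets each yield one mixture set and one reference;
  all $3\times3 = 9$ mixture-reference pairings are enumerated, 6 of which
  cross dataset boundaries. nb runs at a fixed 12M library size.
* `build_sim1_libsize` (library size): nb mixtures with samples 1–10 at 12M
  reads and 11–20 at 24M, emitted in count, countNorm, cpm and tpm.
* `build_sim2` (composition): one mixture set per component number
  $K \in \{5..10\}$ (rosters growing from T/B/monocytes/neutrophils/NK to
  the CD4/CD8 and naive/memory splits) and weight regime, at low nb noise.
  "Low" is taken as $p_t = 0.1$, the first point of the nb grid.
* `build_sim3` (unknown content): each Sim2 set re-mixed in count space
  with a tumor spike-in, emitted in all units, with dual ground truths —
  absolute (immune rows summing with tumor to 1) and relative (immune rows
  renormalized).

# Synthetic source profiles

`generate_source_profiles` stands in for purified immune-cell RNA-seq
datasets. Design choices, and what they do and do not emulate:

* Baseline expression is heavy-tailed log-normal (meanlog $\log 200$,
  sdlog 1.2) with mild per-type variation (sdlog 0.15) on non-marker genes.
* Each type owns a disjoint marker set whose owner-level expression is
  drawn near the top of the baseline distribution (meanlog $\log 3000$,
  sdlog 0.3) and is exactly `marker_fold` lower in every other type. The
  high placement is deliberate: a marker gene is by definition highly
  expressed in its owner, and a generator whose "markers" straddle the
  genome-wide 80th percentile would embed genes that are not markers in
  the selection sense.
* Purified replicates are negative-binomial draws (dispersion size 20)
  around the type means; gene lengths are log-uniform in $[0.5, 10]$ kb,
  present only so the tpm/cpm contrast is exercised.
* `generate_source_datasets` emits several datasets sharing one underlying
  biology (same markers and baseline) with dataset-level log-normal jitter
  (sd 0.1) and independent replicates. This is what makes cross-dataset
  mixture-reference pairs meaningful, as they are for real cohorts.

What the generator does **not** emulate: correlated gene modules, isoform
structure, GC/length bias, batch effects beyond a global jitter, and
realistic marker sparsity patterns. Tests passing on these profiles
demonstrate correctness of the machinery and directional behaviour of
methods, not performance on real tissue.

# Gene selection

`select_markers` implements a rank-based criterion: a gene is a marker of
type $T$ at sample fraction $p$ if it exceeds the per-sample 80th
percentile of expression in at least $p$ of $T$'s samples and falls below
the per-sample 50th percentile in at least $p$ of every other type's
samples; $p$ starts at 0.95 and relaxes by $s = 0.03$ until every type has
at least 2 markers. Percentiles are computed per sample across genes
(column-wise), which makes the criterion invariant to any library-size
normalization; the pooled-across-samples alternative would not be.

`select_signature` filters pairwise DE results at
$p_{adj} \le 0.01$ and $|\log_2 FC| \ge 10$. The union across pairs is the
default (a gene discriminating any pair is informative for a signature
matrix); an intersection rule is available. The built-in DE test
(`de_test_default`, Welch's t on log2-CPM with BH adjustment) is a
deliberate simplification — any external per-gene DE table in the same
schema can be supplied. The 1024-fold default cutoff is extreme and kept
configurable, since synthetic effects are milder.

# Evaluation

Per cell type, across samples: Pearson $r$ and mean absolute deviance
$\mathrm{mAD} = \sum_j |x_j - y_j| / J$. $r$ captures linear concordance
but is blind to systematic offsets — adding a constant to every estimate
leaves $r$ unchanged while raising mAD by exactly that constant — which is
why both metrics are always reported. Any NA, whether returned by a method
or arising from a zero-variance correlation denominator, is replaced by the
worst possible values $r = -1$, $\mathrm{mAD} = 1$, and these penalties
participate in all downstream averages and rankings rather than being
dropped. The `"all"` aggregate is the unweighted mean over cell types.

With unknown content, scoring runs on two scales: absolute (truth = immune
proportions of the whole mixture, summing to $1 - t_j$) and relative
(truth renormalized over known types). Method outputs are scored as-is on
both scales without renormalization, so a method that reports relative
proportions will show an offset on the absolute scale — that discrepancy
is exactly the phenomenon the dual-scale design exposes. With $t = 0$ the
two scales provably coincide.

# Diagnostics

Run in count unit: per-gene mean-variance table with a log-log OLS slope
over genes with mean $\ge 1$ (Poisson data give slope 1, overdispersed nb
data push towards 2); per-gene CV with a density mode count; pairwise
Spearman correlation and Euclidean distance between samples. Unimodality
is operationalized as: number of kernel-density local maxima (512-point
grid) with topographic prominence at least 10% of the peak density. Raw
local-maximum counting was rejected because estimate wiggles in the long
CV tail register as spurious modes on clearly unimodal data; the
prominence filter separates genuinely bimodal from unimodal distributions
in the tests.

# Numerical and design notes

* Low-abundance filtering uses strict inequality ("more than 10 counts in
  at least 5 samples" keeps a gene at counts (11,11,11,11,11,0) and drops
  (11,11,11,11,0,0)); it is monotone in both thresholds, and is applied in
  the ingest unit before any conversion. Per-dataset and concatenated
  filtering are both available to the scenario builders.
* Unit conversions: cpm and tpm columns sum to $10^6$; countNorm columns
  sum to the median library size. All internal simulation runs in count
  space; fpkm is accepted on ingest only.
* The NNLS baseline normalizes mixture and reference to a common
  counts-per-million scale before fitting (estimates are then invariant to
  the input unit at fixed library size, verified to 1e-6), imposes no
  sum-to-one constraint in the solver, and renormalizes post hoc. Singular
  references produce a condition-number warning, and failed per-sample fits
  propagate as NA estimates (which evaluation then penalizes).
* Seeding: every stage derives its stream as `derive_seed(master, label)`
  (a small string hash), so identical configs reproduce byte-identical
  outputs and adding a stage never shifts existing streams.
* Default problem sizes used by the test-suite and worked examples —
  500–5,000 genes, 3–10 cell types, 6–20 samples, 1–3 replicate seeds —
  were chosen as the smallest designs at which the directional claims
  (noise degradation, regime ordering, overdispersion structure) are
  stable; the library-size checks use 10,000 genes and 20 samples.

# Known limitations

* The built-in NNLS baseline is a harness-exercising reference point, not
  a competitive method; published methods are consumed only through the
  estimate-table adapter.
* The "real" composition bands are plausible defaults, not estimates from
  cytometry data.
* Normal/log-normal models operate on any unit and return real values;
  only the nb path yields integer counts.
* No read-level effects (FASTQ, positional/GC bias, isoforms) are
  simulated.

# A minimal session

```{r example, eval = FALSE}
src <- generate_source_profiles(2000, c("T", "B", "mono"), seed = 1)
w   <- make_orthog(3, 20, seed = 1, cell_types = src$cell_types)
spec <- noise_spec("nb", p_t = 0.1, library_size = 12e6, seed = 1)
mix <- apply_noise(mix_expected(src, w), spec,
                   mode = "component_level", w = w, src = src)
est <- nnls_deconvolve(mix, build_reference(src),
                       genes = unlist(select_markers(src$replicates)))
evaluate_celltype(est, w)
```
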