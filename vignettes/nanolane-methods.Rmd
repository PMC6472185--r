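---
title: "Methods: normalization, gene filtering and network inference in nanolane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, gene filtering and network inference in nanolane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolane)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. It covers the per-lane quality flags, the
control-based normalization model, the stability statistic that drives both
housekeeper selection and gene filtering, the heatmap data product, the
tree-ensemble network inference, and the synthetic cartridge generator the
test suite is built on.

## The measurement model

An nCounter cartridge yields up to 12 lanes; each lane's RCC export carries
one non-negative integer count per probe. We model a lane's observed count
for gene *g* as

$$ c_{gl} \approx b_g \cdot e_l \cdot 2^{\varepsilon_{gl}} + \text{background}, $$

where $b_g$ is the gene's expression level, $e_l$ a lane-wide multiplicative
efficiency (hybridization, imaging, input amount), and $\varepsilon_{gl}$
biological plus technical log-scale noise. Normalization estimates and
removes $e_l$ using probes whose $b_g$ is assumed constant across lanes
(housekeeping genes), after flooring counts at a lane-specific background
level estimated from the negative controls. Everything downstream
(z-scores, clustering, network inference) consumes the normalized matrix.

## Per-lane quality flags

Three flags are computed per lane; all three warn and none excludes a lane,
because at clinical cartridge sizes a dropped lane usually means a dropped
patient time point — the analyst should decide, not the pipeline.

* **Binding density** is read from the lane attributes and checked against a
  closed interval, default **0.1–2.25 spots/µm²** — the instrument vendor's
  published operating window for the MAX/FLEX platform. Outside it, spot
  segmentation saturates and counts compress.
* **Positive-control linearity** is the squared Pearson correlation between
  $\log_2(\text{count}+1)$ and $\log_2(\text{concentration})$ over the
  spiked-in dilution ladder. The ladder defaults to the standard six-point
  series POS_A…POS_F = 128, 32, 8, 2, 0.5, 0.125 fM. Log–log is the natural
  scale for a serial dilution; the $+1$ guards zero counts at the bottom of
  the ladder. The pass threshold defaults to $r^2 \ge 0.95$. A
  zero-variance ladder (all counts equal) returns $r^2 = 0$ with a warning
  rather than NaN.
* **Limit of detection** passes when a designated low positive control
  (default POS_E, 0.5 fM) reaches the lane's background threshold (below).

QC is read-only by construction: the report is computed from a cartridge
without touching it, and tests assert that normalization output is identical
whether or not QC ran.

## Background threshold

The per-lane threshold is

$$ T_l = \mathrm{geomean}(\text{negatives}_l) + 2 \cdot \mathrm{SD}(\text{negatives}_l), $$

with zero counts entering the geometric mean as 1 (so $T_l \ge 1$ always)
and SD the sample standard deviation of the raw counts. The phrase "two
standard deviations over the geometric mean" admits two readings
(additive offset vs. a ratio); the additive offset above a central value is
the standard background-thresholding construction in the platform's
normalization guidelines, and it is the one implemented. Correction is
**flooring, not subtraction**: counts below $T_l$ are raised to $T_l$,
which keeps the matrix strictly positive — a requirement for every
log-ratio computation that follows.

## The stability statistic and its two uses

For genes with strictly positive values $x$, define for gene $j$

$$ M_j = \frac{1}{g-1} \sum_{k \neq j} \mathrm{SD}_{\text{samples}}\!\left(\log_2 \frac{x_j}{x_k}\right). $$

$M_j$ is low when gene $j$ moves in lockstep with the rest of the panel and
high when it varies independently. Two properties matter here:

* $M$ is invariant under per-lane rescaling (ratios within a lane are
  untouched), so it can be computed **before** lane normalization — which is
  exactly why it can select the normalization references without circularity.
* It is computable from the sample covariance of the log matrix:
  $\mathrm{SD}(L_j - L_k)^2 = v_j + v_k - 2C_{jk}$, which the implementation
  uses; the tests pin this against a literal double-loop oracle at 1e-9.

**Housekeeper selection** runs the classic elimination loop: compute $M$ on
the housekeeping candidates (background-corrected counts, so positivity is
guaranteed), remove the gene with the largest $M$, recompute, and stop when
`n_keep` genes remain. `n_keep` defaults to 3, the method's minimum for a
meaningful pairwise panel; it is configurable upward. Ties on $M$ remove
the lexicographically **last** gene name first, so selection is
deterministic without any RNG — the whole normalization path is
bit-reproducible by construction. With a single lane the statistic is
undefined (no across-sample SD); the package then keeps all candidates and
scales by 1, which is the only self-consistent degenerate behavior.

**Gene filtering** uses the same statistic in reverse, as a *single pass*:
every gene's $M$ against all others, sorted descending, keep the top $k$ (or
`ceiling(p% · genes)` — the two parameterizations of one operation). No
elimination loop: filtering selects the most variable genes, it does not
search for a stable reference set, and the single pass makes selections
nested in $k$ (a property the tests assert). Ties rank lexicographically
ascending. Filtering runs on normalized (positive) values, not z-scores,
because the statistic needs ratios.

## Scaling factors

With selected housekeepers $H$, let $g_l = \mathrm{geomean}_{h \in H}(x_{hl})$
and $\bar A = \mathrm{mean}_l(g_l)$ (plain arithmetic mean — "average"
unqualified). Then $\mathrm{SF}_l = \bar A / g_l$, and every count in lane
$l$ is multiplied by $\mathrm{SF}_l$. Afterwards the housekeeper geometric
mean is the same constant $\bar A$ in every lane; the tests require this
identity to a relative 1e-9, and on simulated cartridges with planted lane
effects $e_l$ the estimated factors satisfy
$\mathrm{cor}(\mathrm{SF}_l, 1/e_l) > 0.99$ once housekeeper noise is small.

One ordering decision is worth stating: the factors are applied to the
**background-corrected** counts, not the raw flat counts. The geometric
means $g_l$ are computed on corrected values, so only scaling those same
values yields the exact equalization identity above; scaling raw counts
would re-introduce sub-background values into a matrix documented as
strictly positive. Control probes are excluded from the output matrix
(they are not expression measurements) but their corrected counts are kept
on the result object.

## Heatmap data product

`build_heatmap()` chains: gene filter → sample ordering → per-gene z-score →
clustering. Z-scores are computed per gene **across the displayed samples
only** — a comparison of four samples should be scaled by those four
samples' spread, not by every sample ever loaded. Constant genes z-score to
all-zero rows with a warning. Clustering is agglomerative with **average
linkage on Euclidean distances** of the z-scored rows (both configurable);
that is the unremarkable default for expression heatmaps, and average
linkage is what the naive-agglomeration test oracle implements. Merge ties
follow the smaller-index-first convention of the underlying agglomeration.

The four comparison orderings (one patient's time course; every patient's
first sample; every patient's second; all firsts then all seconds) are
*fixed* sample orders — clustering the sample axis would destroy exactly the
comparison they encode, so only genes are clustered in those modes. The
`free` mode clusters both axes. Chronology within a patient comes from
`sample_order` metadata, falling back to `collection_date`, falling back to
input order; the RCC format has no standard field for a time-series
position, so this convention (and its persistence as `SampleOrder` /
`PatientID` attribute rows on round trip) is the package's own.

Rendering (`autoplot`) is a thin tile-plot layer with a diverging scale
symmetric about 0; every contract and test targets the data product
(z-matrix, orders, dendrograms), never pixels.

## Network inference

Both algorithms decompose inference into one regression per target gene:
standardize the target to unit variance, regress it on all candidate
regulators across samples, and score the directed edge regulator → target by
the regulator's **summed variance-reduction importance** (each split's SSE
decrease, divided by the training-set size, averaged over trees). Both are
implemented in the package's own C++ tree grower so the importance
definition is fully specified and identical across variants; all randomness
flows through R's RNG, so a seed fixes the entire edge list bit-for-bit.

* **Random-forest / extra-trees** (GENIE3-style): default 1000 trees per
  target, `mtry = round(sqrt(p))`, trees grown to purity. RF bootstraps the
  samples and searches splits exhaustively; ET uses all samples and one
  uniform random cutpoint per candidate feature.
* **Stochastic gradient boosting** (GRNBoost2-style): default at most 500
  rounds of depth-3 trees, learning rate 0.01, 90% row subsampling, and
  early stopping once the loss on the rows left out of each round has not
  improved on its best value for 25 consecutive rounds. Importances
  accumulate over the rounds actually executed, so a window larger than the
  round budget reduces exactly to fixed-round boosting. These defaults
  follow the original algorithm descriptions' conventions; all are
  arguments.

Candidate regulators default to all genes (immune panels carry no
transcription-factor list); a `regulators` argument restricts them. A
constant target gets zero incoming weights and a warning. Samples are
treated as exchangeable observations — these are steady-state regressors,
and although expression time series motivate the analysis, the temporal
order is not modeled. With fewer than 10 samples the package warns:
a 4-sample patient series supports exploration, not inference.

`top_n_links()` keeps the `min(n, positive-weight edges)` strongest edges,
ties broken lexicographically by (regulator, target); its output is a prefix
of the weight-sorted list and monotone in `n`.

## The synthetic cartridge generator

`simulate_cartridge()` emulates what the pipeline assumes: log-normal counts
around per-gene base levels (`round(b_g · e_l · 2^ε)`, banker's rounding for
cross-platform determinism), multiplicative lane effects (default drawn
with log2-scale SD 0.25 — tens of percent between lanes, typical of real
cartridges), a proportional positive-control ladder (so linearity is ≈ 1 by
construction), truncated-normal negative controls (mean 10, SD 3, counts in
the low tens, as on real lanes), and a 730 + 40 endogenous/housekeeping
split of the 770-gene panel (the panel total is fixed; the split is a
convention). Housekeeper log2 noise defaults to SD 0.15 per gene and can be
set per gene to plant a known stable subset. Optional planted structure
supports the recovery tests: two anti-correlated gene blocks for clustering,
and regulator → target log-scale copies for network inference inside a
cartridge. Because network benchmarks need more samples than 12 lanes,
`simulate_regulatory_matrix()` generates standalone planted-regulator
matrices (default 20 genes × 30 samples, targets = regulator + noise at 10%
of signal SD).

What the generator does **not** emulate: real panel gene names, biological
covariance structure, probe-specific efficiency, saturation at high binding
density, or cross-cartridge batch effects. Passing tests therefore
demonstrate that the algorithms recover the structure they model — not that
any particular biological conclusion from a real cartridge is correct.

## Problem sizes and numerical choices

The test suite exercises full-size 770-gene, 12-lane cartridges where the
operation is cheap (parsing, normalization, filtering) and smaller matrices
(tens of genes, ≤ 40 samples, hundreds of trees) where ensembles are
involved; the network recovery check runs 10 seeds of a 20-gene, 30-sample
system at 500 trees. Oracle comparisons (brute-force stability, threshold,
naive agglomeration, sort) are asserted at 1e-9; the housekeeper
equalization identity at relative 1e-9; exact-arithmetic tie cases are
constructed from powers of two so floating-point noise cannot blur them.

## Known limitations

* No positive-control content normalization and no cross-cartridge batch
  correction: normalization is housekeeper-based within one cartridge.
* QC is advisory; there is no automated lane exclusion.
* The RCC dialect implemented is the common sectioned-CSV export; reporter
  library (RLF) files are out of scope.
* Network edges from cartridge-sized sample counts are exploratory; the
  package warns but does not refuse.
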