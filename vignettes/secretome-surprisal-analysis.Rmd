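---
title: "Surprisal analysis of explant secretomes: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of explant secretomes: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(secretoscope)
```

## The problem

Tumor explants — fresh fragments of a tumor cultured intact for ~24 h —
secrete a panel of cytokines and chemokines into the supernatant, measured
by a multiplex bead assay in pg/mL. The secreted panel is a readout of the
ongoing biology of the intact tumor immune environment: which cell types
are present, how they are polarized, and how they respond to ex vivo
immunotherapy (PD-1/CTLA-4 blockade, OX40 agonism). secretoscope implements
the analysis layer for such experiments: it decomposes the concentration
matrix into a steady state plus a small number of coordinated co-secretion
patterns, asks which immune-cell infiltrates those patterns track, and
tests per-cytokine responses to treatment.

## The model

Let $X_i(k)$ be the measured concentration of cytokine $i$ in sample
(explant) $k$. Surprisal analysis writes

$$\ln X_i(k) = \ln X_i^0(k) - \sum_{\alpha \ge 1} G_{i\alpha}\,\lambda_\alpha(k),$$

where $\ln X_i^0(k)$ is the steady-state level and each term
$G_{i\alpha}\lambda_\alpha(k)$ is the deviation imposed by *unbalanced
process* $\alpha$: a constraint that moves a specific group of cytokines
(those with large $|G_{i\alpha}|$) coherently away from steady state.
$\lambda_\alpha(k)$ is the amplitude of the process in sample $k$; its
sign says in which direction the process acts there, and the signs of
$G_{i\alpha}$ say which cytokines move together and which move opposite.

`surprisal_decompose()` realizes this with an SVD of the completed
$\ln X$ matrix. The leading component (largest singular value) is the
steady-state term $\alpha = 0$; components $\alpha \ge 1$ are the
unbalanced processes, with $G_{\cdot\alpha}$ the left singular vectors
(orthonormal) and $\lambda_\alpha(\cdot)$ the singular value times the
right singular vector. The model equation's minus sign is a labeling
convention absorbed into component signs; we fix each component's sign so
that its largest-$|G|$ cytokine is positive, which makes outputs
reproducible without changing any substantive quantity.

```{r decompose}
truth <- synthetic_truth(seed = 7)   # 30 cytokines x 48 explants, 4 processes
sim <- gen_secretome(truth)
lnX <- log_transform(sim$secretome)
dec <- surprisal_decompose(lnX)
dec
round(dec$singular_values[1:7], 2)   # steady state >> 4 processes >> noise
```

## How many processes are significant?

The number of processes is decided against a Monte-Carlo noise null:
process $\alpha$ is significant when $\max_k |\lambda_\alpha(k)|$ exceeds
the 95th percentile of the same statistic over pure-noise matrices of the
same shape (i.i.d. Gaussian on the log scale at the given or estimated
noise SD). Two details matter:

* The null takes the max over **all** components of each noise matrix.
  The data's steady state absorbs none of the noise, so the full noise
  spectrum — including its largest singular component — leaks into the
  data's deviation components; excluding the noise matrices' leading
  component would make the null anti-conservative.
* With `noise_sd = 0` the threshold falls to a numerical floor
  ($10^{-8}$ of the leading singular value), so exactly the non-degenerate
  components are counted.

The noise SD can be given, or pooled from replicate explant fragments of
the same tumor (`estimate_noise_sd()`): fragments of one animal share
their biology, so their within-group log-scale variance is the noise
floor. Note that the synthetic generator plants per-sample amplitudes
that are *not* shared within an animal, so for simulated data pass the
known `noise_sd` rather than estimating it from replicates.

```{r significance}
dec <- count_significant_processes(dec, noise_sd = truth$noise_sd, seed = 1)
dec$K_significant
```

## Membership and activity calls

A cytokine belongs to process $\alpha$ when its $|G_{i\alpha}|$ is at
least `fold` (default 20) times the mean $|G|$ of the `quantile` (default
20%) of cytokines with the smallest $|G_{i\alpha}|$ — the baseline of
uninvolved cytokines. We rank by absolute value (the only reading under
which the "lowest" cytokines are the uninvolved ones), count
`floor(quantile * n)` of them with a minimum of one, and break ties by
cytokine order. Member weights keep their signs.

A sample is called active for process $\alpha$ when
$|\lambda_\alpha(k)|$ exceeds a threshold — numeric, or `"auto"` to reuse
the Monte-Carlo null 95th percentile, i.e. "larger than noise could make
it". Signs split active calls into `active_positive`/`active_negative`.

```{r processes}
pm <- process_membership(dec, 1)
pa <- process_activity(dec, 1, threshold = "auto", process = pm)
pa
```

## Missing values

Multiplex panels drop out below the detection range. Missing entries are
completed by iterative truncated SVD (`impute_missing_svd()`): initialize
at row means, then alternate truncated reconstruction and re-imputation
until the largest relative change of an imputed entry falls below `tol`.
Defaults are rank `min(5, min(dim) - 1)`, `tol = 1e-6`, `max_iter = 500`;
observed entries are never altered, and non-convergence flags the result
rather than failing. Convergence is linear, so exact low-rank completion
(e.g. reproducing a masked entry of a rank-1 matrix to $10^{-6}$) needs a
tighter `tol` (~$10^{-9}$) than the everyday default. Zeros are distinct
from missing: a zero is floored at `detection_floor` inside
`log_transform()` only.

## Associations with the immune infiltrate

`pearson_matrix()` computes product-moment correlations between two
feature tables over shared samples with pairwise missing removal; cells
with fewer than 3 pairs or zero variance are flagged missing.
`cluster_order()` arranges the report by agglomerative clustering,
defaulting to Chebyshev ("maximum") distance with average linkage — the
vocabulary of the heatmap tools this workflow mirrors; Euclidean and
correlation distance are available. Leaf order is canonicalized (at each
merge the subtree with the lexicographically smallest label comes first)
so results do not depend on input row order.

Because infiltrates are measured once per tumor while the secretome is
measured per fragment, `align_tables()` joins the two through the
metadata's `animal_id`, and fragment values are averaged per animal before
correlating (mean by default, median available). The aggregator is a
design choice: per-tumor means are the least surprising default, and
per-fragment correlation remains available by omitting the alignment.

`amplitude_infiltrate_correlation()` applies the same machinery to the
significant processes' amplitudes — the central question being which
infiltrating populations (CD4, CD8, CD90.2, TAM, ...) track which
co-secretion process.

```{r assoc}
inf <- gen_infiltrates(synthetic_truth(infiltrate_link = list("1" = "CD8"),
                                       seed = 7))
dec2 <- count_significant_processes(
  surprisal_decompose(log_transform(
    gen_secretome(synthetic_truth(infiltrate_link = list("1" = "CD8"),
                                  seed = 7))$secretome)),
  noise_sd = 0.1, seed = 1)
rep <- amplitude_infiltrate_correlation(dec2, inf)
round(rep$r_values[, c("CD8", "TAM")], 2)
```

## Treatment comparisons

`compare_treatments()` is the equal-variance two-sample two-tailed
Student t-test between baseline and treated replicate fragments
($df = n_1 + n_2 - 2$), with the conventional star tiers (*, **, ***) at
0.05 / 0.01 / 0.001 on raw p-values, matching how such panels are
reported. Since a full panel tests dozens of cytokines, a clearly labeled
Benjamini–Hochberg column is emitted alongside, without changing the
starred calls.

## The synthetic generator

No raw multiplex data accompanies this workflow, so every downstream
stage is validated by parameter recovery on synthetic data with planted
structure. `synthetic_truth()` + `gen_secretome()` draw

$$\ln X = b \otimes \mathbf{1}^\top + G_\text{true}\Lambda_\text{true}
  + \varepsilon,\qquad \varepsilon_{ik} \sim N(0, \sigma^2),$$

i.e. log-normal concentrations — the realistic noise model for bead
assays — whose generative form is exactly the decomposition's model. The
default scenario mirrors a four-model murine explant study: 30 analytes
across 48 explants (4 tumor models × 3 animals × 4 treatment arms,
encoded by `gen_metadata()`), $K = 4$ planted processes, log noise
$\sigma = 0.1$, and per-entry process amplitudes 10× noise with a mild
1 → 0.8 decay so singular values stay distinct.

Design choices worth knowing:

* **Orthogonality.** Planted weight columns are drawn orthonormal and
  orthogonal to both the baseline direction and the constant vector;
  amplitude rows are orthogonal to the constant sample vector. This makes
  the noiseless decomposition recover the planted structure exactly, and
  makes a global concentration rescale (which shifts $\ln X$ along the
  constant direction) provably leave the deviation amplitudes unchanged.
  On generic real data that rescale invariance is only approximate.
* **Detection floor.** The generator records a floor of $10^{-4}$ pg/mL,
  below its dynamic range, so taking logs is exact and the planted model
  is unclipped. Real panels floor at ~1 pg/mL (the read-in default);
  censoring at the floor is a feature of real data the generator does not
  emulate.
* **Linked infiltrates.** A population linked to process $\alpha$ is an
  affine transform of $\lambda_\alpha$ plus Gaussian noise with
  $\mathrm{sd} = \mathrm{sd}(\lambda_\alpha)\sqrt{1/r^2 - 1}$, so the
  expected sample correlation is the target $r$; unlinked populations are
  independent log-normal draws, and everything is clipped at zero (with
  count-like location 500 ± 100, making the clip negligible).
* **What passing tests do not show.** The generator plants orthogonal,
  stationary processes with homoscedastic log noise and
  missing-completely-at-random dropout. Real co-secretion programs can be
  correlated, drift with culture time, censor at the detection floor, and
  miss not-at-random; recovery on synthetic data bounds algorithmic
  correctness, not biological validity.

Problem sizes used in the shipped tests — 50-seed replicates of the
30 × 48 scenario, 100-draw Monte-Carlo nulls, 200-sample link
calibrations — were chosen to give stable Monte-Carlo rates while keeping
the whole suite interactive (tens of seconds).

## Numerical choices

* Component signs are fixed by the largest-$|G|$ cytokine; planted-truth
  comparisons are sign- and rotation-agnostic via principal angles.
* `principal_angles()` switches to the sine-based formulation for angles
  with cosine > 0.7: `acos` alone cannot resolve angles below
  ~$2 \cdot 10^{-8}$ rad in double precision.
* Degenerate inputs: all-missing rows/columns are errors for imputation;
  zero-variance features yield flagged missing correlations, not errors;
  single-row tables get identity cluster order; `alpha = 0` (the steady
  state) has no membership or activity by definition.
* The pipeline (`run_pipeline()`) writes every intermediate artifact plus
  a manifest with input/output checksums; two runs from one config and
  seed are byte-identical.

## Known limitations

* The significance call is a Monte-Carlo noise-percentile stand-in for
  the error-calculation procedures cited in the surprisal-analysis
  literature; it is flagged as such in the decomposition JSON.
* Only complete SVD-based decomposition is offered — no censored-data
  likelihood, no multi-omics extension.
* Network edges come from a user-supplied STRING-style export; no live
  database queries are made, and no confidence filtering is applied
  unless requested.
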