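---
title: "Region-size-corrected degree metrics: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-size-corrected degree metrics: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsedegree)
```

## The model

A voxel-wise functional network treats every in-mask voxel as a node, with
an edge between voxels $i$ and $j$ whenever their temporal Pearson
correlation $r(i,j)$ reaches a connectivity threshold $T_d$. Degree
centrality then scales with the sizes of *functional regions* — contiguous
voxel sets sharing one latent signal — in two ways: a voxel in a region of
$m$ voxels collects $m-1$ "self-connections" from its siblings, and every
region it connects to contributes its entire voxel count. The correction
implemented here requires an estimate $C_i$ of the region each voxel
belongs to, and modifies the degree sum with two terms:

$$ U_{RSE}(i) = \sum_j f(i,j)\,\frac{g(i,j)}{s(i,j)}, \qquad
   f(i,j) = \mathbf{1}[r(i,j) \ge T_d], $$

where $g(i,j) = 0$ if $j \in C_i$ (self-connections are disregarded) and
$s(i,j) = |\{k \in C_j \setminus C_i : f(i,k) = 1\}|$ (a connection to $j$
is divided by the effective, threshold-surviving, non-shared size of $j$'s
region). The same $f\,g/s$ factor multiplies the weights $r$, $r^2$ and
$\operatorname{atanh} r$ for the weighted variants. Whenever a term
survives ($f g = 1$), $j$ itself belongs to $C_j \setminus C_i$ and is
connected to $i$, so $s \ge 1$ and the division is always defined; the
implementation asserts this rather than guarding it.

Two structural consequences are useful as sanity checks and are tested
exactly: with singleton clusters the corrected metrics reduce to the
traditional ones, and on an idealized network whose clusters equal the true
regions the corrected unweighted degree of every voxel equals its region's
region-level degree (the six-node `figure1_toy()` network: traditional
degree 3 vs 1 across region sizes, corrected degree 1 everywhere).

## Estimating regions: adaptive threshold and region growing

Regions are estimated per voxel by seed-based growing on two matrices: the
temporal correlations, and the *spatial* correlations — correlations
between whole-brain temporal-correlation rows, with the two self-positions
removed from both rows before correlating (the diagonal 1s and the mutual
entry would otherwise leak agreement into every pair). Growth absorbs any
26-connected neighbour $j$ of the cluster with $r(\text{seed}, j) \ge T_a$;
because the criterion refers only to the seed, the fixed point is
visit-order independent. The temporal and spatial clusters are intersected.

The stop threshold $T_a$ is data driven. Per voxel, the six face-neighbour
correlations are filtered twice — negatives and values below the mean
positive correlation of the whole matrix are dropped, then survivors
strictly below the survivor mean are dropped — and averaged; $T_a$ is the
mean over voxels with a defined value. Ties survive both filters ("lower
than" is read strictly); voxels with no survivor are excluded from the
average rather than imputed, which would bias $T_a$ toward the filler
value. Edge voxels use whatever face neighbours lie in the mask.

Note the second filter only selects upward: each per-voxel threshold is at
least the mean of its first-stage survivors. $T_a$ lands *below* typical
within-region correlations only because the average also includes voxels
with mediocre neighbourhoods. This matters for simulation design (below).

Two quality indices describe the growing. RGER counts voxel pairs with
asymmetric membership ($j \in C_i$ but $i \notin C_j$), one possible error
per unordered pair, divided by $\binom{V}{2}$. The cluster-size maps
compare $M_i = |C_i|$ with $N_i$, the number of clusters containing $i$.
$N_i$ counts *all* containing clusters including $C_i$ itself: the
perfect-growing identity $M = N$ holds only under the inclusive count
(counting only other clusters would force $M = N + 1$), and the identity
$\sum_i M_i = \sum_i N_i$ holds unconditionally. Users comparing against
descriptions that define $N$ exclusively should expect the off-by-one.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `T_d` | sweep 0.15–0.50, step 0.05 | connectivity threshold for degree |
| `T_a` | estimated per matrix | region-growing stop threshold |
| `fwhm_mm` | 8 | Gaussian smoothing FWHM before map comparisons |
| `block_size` | 512 | voxels per block in blocked correlation |
| `zscore ddof` | 0 | population SD in the z-score |
| ICC variant | A1 | two-way, absolute agreement, single measure |

The mean positive correlation used by the first filter is recomputed for
each matrix (temporal and spatial separately), so the filter adapts to each
flavor's correlation scale. Z-scoring uses the population SD because the
standardization formula is written with a plain $\sigma$; the choice is
exposed (`ddof`) and recorded. Degree maps are z-scored first and smoothed
second; smoothing is mask-normalized separable Gaussian convolution
($\sigma = \text{FWHM} / 2\sqrt{2\ln 2}$ per axis in voxel units, kernel
truncated at $4\sigma$), which preserves constants exactly and never lets
out-of-mask (or NaN) voxels dilute in-mask values. ICC(A,1) is the
McGraw–Wong two-way absolute-agreement single-measure form computed from
mean squares, vectorized across voxels; the consistency variant C1 is
available.

## Numerical choices and degenerate inputs

* Zero-variance voxels are kept in the mask with all correlations defined
  as 0 (diagonal included). They can never pass a positive threshold, and
  no NaN propagates.
* Correlation matrices are symmetrized (`(R + t(R))/2`) and clipped to
  $[-1, 1]$ after the blocked product; blocked and single-pass evaluation
  agree to machine precision.
* The spatial matrix is computed from closed-form leave-two-out sums (one
  matrix product plus $O(V^2)$ arithmetic); pairs whose reduced rows have
  zero variance get 0. Tiny negative round-off under the square roots is
  clipped to 0.
* `weight()` with $|r| = 1$ under the Fisher-z metric raises an error
  rather than clamping: a duplicated time series is a data problem the user
  should see.
* The degree sums exclude the self-term $j = i$ (it would add a constant to
  every voxel); a strict-formula mode (`include_self = TRUE`) restores it.
* The ICC of a voxel with zero variance in either measurement is NaN and is
  excluded from summary means.

## What the synthetic data emulate — and what they do not

`make_block_phantom()` builds masked series as variance-share mixtures: a
parcel's voxels share a region signal (`within_share`), linked parcels
share link signals (`between_share`, optionally per link), and every voxel
adds i.i.d. Gaussian noise. Expected correlations follow the share ratios
(e.g. between linked parcels $b/\sqrt{k_p k_q}$ over the total variance,
with $k$ the link counts), which the tests verify against long-series
simulation. Background voxels are pure noise and are their own singleton
ground-truth regions.

The background is not cosmetic. Because the two-step filter only selects
upward, a phantom consisting solely of equicorrelated parcels would put
$T_a$ *above* the median within-parcel sample correlation and growth would
fragment; background voxels contribute low per-voxel thresholds that pull
$T_a$ into the gap between background/cross-region and within-region
correlations, which is precisely the regime in which the adaptive
threshold operates on real data (broad neighbour-correlation distributions
with a long right tail). The recovery simulations use a 8×8×4 grid, four
parcels of 16/16/4/4 voxels, `within_share = 0.8` and $T = 300$ time
points, and recover the parcels exactly (adjusted Rand index 1 against the
ground-truth labels, evaluated with `mclust::adjustedRandIndex`).

`make_multisubject()` emulates a test-retest design: subject-level traits
(which region pairs are linked, and a graded per-link strength) are drawn
once per subject; scan-level variation is fresh per scan — voxel noise and
a jitter of the region extents (±`size_jitter` layers). With size jitter
on, region sizes fluctuate between scans while region-level connectivity is
stable, so region-size variance is the dominant scan-to-scan noise source:
the situation the correction targets. The reliability simulations use four
4×3×1 parcels on a 14×8×2 grid, 10 subjects × 3 scans, $T = 300$,
$T_d = 0.15$, comparing mean ICC over the region voxels.

Two honest limits of this design. First, with 10 subjects the voxel-wise
ICC estimator is noisy and smoothing leaves few spatially independent
voxels, so the corrected-vs-traditional comparison is only resolved for the
*weighted* metrics (W, WS, WF), whose continuous weights carry the subject
trait cleanly; for the unweighted count the same comparison lands within
estimator noise (either sign, ±0.15 across seeds) and is reported but not
asserted. This mirrors the real-data pattern in which the Fisher-z metric
gains the most reliability from the correction and the unweighted count the
least. Second, the ICC point prediction used in the closed-form check,
$\sigma_b^2 / (\sigma_b^2 + 0.75\,\sigma_e^2)$ (measurement B averages two
scans, hence the 0.75), is a population value; the ANOVA estimator is
biased low by about 0.03 at $n = 10$ for the ratio used
($\sigma_b^2 / \sigma_e^2 = 4$, population ICC 0.84), which the ±0.05
tolerance absorbs.

More generally the phantoms are Gaussian white-noise mixtures: no
hemodynamic autocorrelation, no physiological noise, no spatial noise
correlations, no motion, and block-shaped regions. Passing tests
demonstrate the algorithmic properties (exact identities, oracle
equivalence, recovery under the stated SNR), not performance on real BOLD
data, whose preprocessing is out of scope (the pipeline consumes
preprocessed series).

## Design choices where the design was open

* **Growth criterion**: candidates are always correlated against the
  original seed, not the evolving cluster mean — the update rule's
  correlation does not change across iterations, which also makes the
  result order-independent. Clusters from different seeds may overlap and
  disagree; RGER measures exactly that, so no global parcellation is
  enforced and intersected clusters are not re-connected.
* **Whole-matrix mean positive correlation**: upper triangle excluding the
  diagonal, each unordered pair once (diagonal 1s would bias it upward).
* **Mask contract**: any binary mask is accepted; no tissue priors ship
  with the package.
* **Problem sizes**: the shipped simulations use grids of $10^2$–$10^3$
  voxels, where dense $V \times V$ matrices and per-seed growth are
  comfortable; whole-brain use relies on the blocked correlation contract
  and on caching of the $O(V^2)$ intermediates by the pipeline driver.
* **CLI surface**: one `pipeline` subcommand drives all six stages (with
  disk caching keyed by input hash) rather than one subcommand per stage;
  `toy` and `simulate` cover the worked example and phantom export.

## Known limitations

Group statistics (ANOVA/t-test/FDR contrast maps) are out of scope, as is
any preprocessing. The spatial-correlation stage includes negative temporal
correlations in the fingerprints (no clipping). Dataset-dependent values
from real cohorts (e.g. specific $T_a$ ranges or whole-brain RGER/ICC
levels) are not reproduced here; the test suite checks the properties that
do not depend on a particular dataset.
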