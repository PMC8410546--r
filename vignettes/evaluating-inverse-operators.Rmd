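---
title: "Evaluating linear MEG inverse operators: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating linear MEG inverse operators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meginverse)
```

# The model

All methods in this package invert the instantaneous linear forward model
$x = L s + \eta$, where $x \in \mathbb{R}^{N_x \times T}$ is the sensor
recording, $s \in \mathbb{R}^{N_s \times T}$ the dipole currents, $L$ the
leadfield, and $\eta$ sensor noise. Every estimator is a matrix
$\Phi \in \mathbb{R}^{N_s \times N_x}$ with $\hat s = \Phi x$; rows of
$\Phi$ are spatial filters. Two families are covered.

**Minimum-norm (LSMN) family.** $\Phi = W L^\top (L W L^\top +
\lambda^2 C)^{-1}$ with diagonal prior source covariance $W$ and noise
covariance $C$ (identity by default; an empty-room sample covariance is an
opt-in alternative via `empty_room_noise_model()` — which of the two a
given lab uses is rarely reported, so both are exposed). The choice of $W$
distinguishes MNE ($W = I$), wMNE ($W_{jj} \propto \lVert L_j
\rVert^{-\kappa}$, default $\kappa = 1$, configurable to 2), eLORETA
($W$ iterated to a fixed point, below) and sLORETA (MNE rows standardized
by $\sqrt{[\Phi (L L^\top + \lambda^2 C) \Phi^\top]_{jj}}$).

**Beamformer family.** Per-dipole filters from the data covariance
$C_x$: LCMV uses $\Phi_j = (l_j^\top C_{\mathrm{reg}}^{-1} l_j)^{-1}
l_j^\top C_{\mathrm{reg}}^{-1}$ with diagonal loading $C_{\mathrm{reg}} =
C_x + \gamma\,(\mathrm{tr}\,C_x / N_x)\, I$; UNGMV rescales each row to
unit norm. Unit gain ($\Phi_j l_j = 1$) and unit row norm are asserted at
construction.

**One SNR knob.** For comparability every operator is indexed by a
predicted SNR in dB: the LSMN regularizer is $\lambda^2 =
\mathrm{tr}(L W L^\top) / (\mathrm{tr}(C) \cdot 10^{\mathrm{SNR}/10})$
(power-scale convention; the amplitude-scale alternative would simply halve
the dB argument, and the power scale is what the regularization literature
this construction follows uses), and the beamformer loading is $\gamma =
10^{-\mathrm{SNR}/10}$. The default working point is 2.5 dB; `snr_db` is
strictly monotone in $\lambda^2$ over the $-10$ to $10$ dB sweep, so
sweeping it rescales regularization consistently across all six algorithms.

## The eLORETA fixed point

`eloreta_weights()` iterates $M \leftarrow (L W L^\top + \lambda^2
C)^{-1}$, $W_{jj} \leftarrow (l_j^\top M l_j)^{-1/2}$, rescaling $W$ to
mean 1 each pass, until the maximum relative change drops below `tol`
(default 1e-6, cap 100 iterations; non-convergence flags the result rather
than erroring). The rescale fixes the arbitrary overall scale of the fixed
point without affecting the property that matters: at convergence the
standardized point-spread function of any dipole peaks at that dipole
(a Cauchy–Schwarz argument in the $M$-inner product), so peak activity
displacement is exactly zero. The same argument gives sLORETA exact
localization. On desk-scale problems convergence takes 10–30 iterations.

# Resolution metrics

The resolution matrix $R = \Phi L$ maps true to estimated activity; its
columns are point-spread functions (PSF), rows cross-talk functions (CTF).

- **PAD** (peak activity displacement): distance from dipole $i$ to
  $\arg\max_j |{\rm PSF}_{ij}|$. The absolute value is used because a
  sign-flipped peak is still a peak; `absolute = FALSE` restores the signed
  convention. Ties break to the smallest dipole index.
- **SEPS / SECT**: $\sqrt{\sum_j R_{ji}^2 d_{ji}^2 / \sum_j R_{ji}^2}$
  over columns / rows. The square root is applied so the metric carries
  distance units, consistent with the spatial-dispersion convention of the
  resolution-analysis literature; `sqrt_out = FALSE` returns the raw ratio.
  SECT is invariant to positive row rescaling of $\Phi$, which is why LCMV
  and UNGMV have identical SECT by construction.

Dipoles with an all-zero PSF column or CTF row are flagged undefined (NA),
excluded from means and counted — never silently zeroed. All three metrics
are verified against naive double-loop reference implementations.

# Variance explained

Channels are randomly partitioned into balanced folds (sizes differing by
at most one; 27 folds for a 274-channel array, scaled as
`round(n_channels / 10.15)` otherwise). Per fold, the operator is rebuilt
from the training rows of the leadfield, sources are reconstructed from
training channels, forward-mapped to held-out channels, and each test
sensor scored by squared Pearson correlation; the statistic averages over
all sensors. Because it is correlation-based it is invariant to per-channel
affine rescaling, which makes the normalized-unit algorithms (sLORETA,
UNGMV) directly comparable.

The identical code path runs on empty-room recordings (`rER²`), and
`ve_ratio()` forms `rCV²/rER²`: an algorithm that happily explains sensor
noise is penalized. The degenerate anchor is the unregularized MNE on
full-row-rank data: in-sample it explains 100% of the variance of *any*
recording — brain or empty room — hence ratio exactly 1, which is what
makes the normalization meaningful.

Two design points the underlying procedure leaves open, resolved here: the
beamformer training covariance per fold is computed from the training
channels of the same recording being analyzed (resting or empty room), so
both pipelines are treated symmetrically with no test-channel leakage; and
per-sensor scores with a constant (zero-variance) channel or prediction are
excluded from the average with a logged count.

**Parcellated variant.** Before forward mapping, the reconstruction is
compressed to rank 1 per ROI: each ROI's dipole courses are mean-centered,
projected on their first principal component, and back-projected through
the loading vector (sign fixed so the loading sum is positive; a
single-dipole ROI is passed through unchanged). Compression discards
within-ROI information, so parcellated `rCV²` is at most the voxel-wise
value on matched runs — a property the tests check across seeds.

# Parcellated metrics and atlas reduction

- **fPAD**: fraction of a ROI's dipoles whose PSF peak falls outside the
  ROI. Zero PAD implies zero fPAD for every atlas. Both the mean over ROIs
  (the reported summary) and the mean over dipoles are returned.
- **mNC**: mean zero-lag correlation between time courses of adjacent ROIs
  (signed by default, `absolute = TRUE` optional). Adjacency: two ROIs are
  adjacent iff some dipole of one neighbors a dipole of the other in the
  dipole graph.

**Atlas reduction.** ROI influence is the sum of its dipoles' leadfield
column norms, cluster influence the sum over its ROIs (additive by
definition, averaged over subjects when several leadfields are supplied).
A target ROI count is apportioned to clusters proportionally to influence
by largest-remainder apportionment with a floor of one ROI per cluster and
a cap at the cluster's current count — chosen because it is deterministic,
scale-invariant and sums exactly to the target. Within each cluster the
lowest-influence ROI is then repeatedly merged with its lowest-influence
in-cluster neighbor until the allocated count is reached. This automated
greedy rule pursues a more uniform influence distribution (the tests check
that the coefficient of variation of ROI influence never increases); it
deliberately does not replicate any published, anatomy-guided manual
reduction, for which multimodal anatomical criteria are required.

# Robustness and similarity

`add_sensor_noise()` injects i.i.d. Gaussian noise of variance
$\sigma^2 \cdot \mathrm{tr}(C_x)/N_x$. For each level the predicted SNR is
re-derived before rebuilding the operator: with baseline power ratio
$\rho_0$ and total mean channel variance $S + N_0$, the injected variance
$\sigma^2 (S + N_0)$ adds to the noise budget, giving $\rho_{\mathrm{new}}
= \rho_0 / (1 + \sigma^2 (1 + \rho_0))$. The curve correlates each
dipole's time course with the noiseless solution (mean over dipoles); the
standard deviation across the grid (default $\sigma^2 \in \{0, 0.1, 0.25,
0.5, 1, 2, 4\}$) is the single-number sensitivity. At $\sigma^2 = 0$ the
correlation is exactly 1 by construction.

Between-algorithm similarity uses the same spatiotemporal statistic:
per-dipole temporal correlation between two reconstructions, averaged over
dipoles (a flag for the concatenated-vector alternative is deliberately
not provided: averaging is used consistently for both the robustness and
the similarity analyses). Multi-simulation similarity matrices are
median-aggregated before clustering. Clustering is recursive two-way
normalized cuts: nodes with at most 12 items — always the case for six
algorithms — are split by exact minimum-Ncut enumeration; larger nodes use
the Shi–Malik spectral relaxation with a threshold sweep that minimizes
the exact Ncut along the eigenvector ordering. Negative similarities are
floored at zero for clustering only (cut weights must be non-negative);
raw values are retained in outputs. Each split records its exact cost;
disconnected graphs split along components at cost zero first.

# Group statistics

Within-subject comparisons across algorithms use the Friedman rank test
(average ranks for ties, no tie correction — fully tied tables return
$\chi^2 = 0$, $p = 1$; perfectly consistent rankings give $\chi^2 =
n(k-1)$), pairwise two-sided Wilcoxon signed-rank tests (zero differences
dropped; exact $p$ for $n \le 25$ via the convolution of the realized —
possibly tied — ranks, equivalent to enumerating all $2^n$ sign
assignments; normal approximation with tie and continuity corrections
above), and Benjamini–Hochberg correction applied within each metric's
family of pairwise tests. `build_stats_report()` assembles the battery
over arbitrary metric tables.

# The synthetic data generator

The generator provides the study conditions every claim is tested under:

- **Geometry**: radial magnetometers quasi-uniform (Fibonacci lattice) on
  the upper hemisphere of a 0.12 m sphere; dipoles quasi-uniform on a
  concentric 0.08 m sphere. Defaults: 120 sensors, 600 dipoles — a
  desk-scale stand-in for a 274-channel array over a ~10⁴-vertex cortex.
- **Forward model**: the Sarvas closed form for a current dipole in a
  homogeneous spherical conductor. Dipole orientations are seeded random
  tangential unit vectors, because radial dipoles are magnetically silent
  in a sphere and would zero leadfield columns. The implementation is
  checked against the free-space dipole field (whose radial component the
  spherical conductor preserves exactly).
- **Sources**: per-dipole Gaussian noise, ideal (brick-wall FFT) band-pass
  in 1–100 Hz, one spatial-smoothing pass over a 4-nearest-neighbor graph
  for the local correlation that drives leakage metrics. The brick-wall
  filter gives exactly zero out-of-band power, which keeps the band
  contract testable without a filter-design dependency.
- **Recordings**: 30 s epochs at 256 Hz. Sensor noise is scaled against
  the realized signal variance so the dB ratio is exact per realization;
  `snr_db = Inf` disables noise. Default SNR 2.5 dB.
- **Empty room**: white sensor noise plus a rank-3 common-mode component
  (unit spatial patterns, 5× noise amplitude) so empty-room data are not
  perfectly white. Real magnetically-shielded-room noise structure varies
  by site and is not publicly characterized for the array emulated here;
  rank and gain are therefore configuration, not claims.
- **Atlases**: k-means on dipole positions (contiguity via
  nearest-centroid assignment), ROIs clustered the same way, up to 10
  internal reseeds if a ROI comes out empty.

What the generator does *not* emulate: realistic cortical geometry and
orientation constraints, gradiometer arrays and reference-channel noise
cancellation, physiological artifacts, 1/f spectra, or inter-subject
anatomical variability ("subjects" are independent simulations on a shared
head). Passing tests therefore certify the algorithmic claims — exact
localization, SECT invariance, normalization identities, metric
definitions — not empirical performance on any particular real dataset,
whose group-level values depend on the recordings themselves.

# Numerical choices

- Matrix inversion falls back to an SVD pseudo-inverse with relative
  tolerance $10^{-12}$ on the largest singular value, so rank-deficient
  toys and $\lambda^2 = 0$ constructions do not crash.
- PC sign convention: loading sum positive, first nonzero entry positive
  on ties — correlations are sign-invariant but determinism requires a
  rule.
- Every stochastic operation is a pure function of (inputs, seed) and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from one master seed.
- Problem sizes in the shipped tests (600 dipoles × 120 sensors for the
  exact-localization checks, 80 × 32 for the ten-seed robustness design,
  three-subject pipelines elsewhere) were chosen as the smallest
  configurations at which the geometric contrasts between algorithms are
  unambiguous.

# Known limitations

Orientations are scalar (fixed, tangential): free-orientation (vector)
solvers and eigendecomposition-based orientation selection are out of
scope. Nonlinear and Bayesian inverses (MSP, EBB, dSPM), frequency-domain
solvers (DICS), and BEM/FEM head models are likewise excluded by design.
Serialization is plain text (TSV matrices and label tables, JSON plans and
manifests). The empty-room model is a stand-in, exposed as configuration.
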