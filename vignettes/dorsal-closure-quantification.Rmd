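---
title: "Quantifying dorsal closure: models, estimators and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dorsal closure: models, estimators and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcquant)
```

`dcquant` quantifies dorsal closure (DC) in *Drosophila* embryos: the
mid-embryogenesis process in which the lateral epidermal sheets, pulled by
the contracting amnioserosa and their own cell-shape changes, seal the
dorsal hole. This vignette is the package's methods account: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
made where the design was genuinely open.

## Closure kinetics

### Model

The dorsal-hole length *L(t)* — the canthus-to-canthus distance along the
anterior–posterior (AP) axis, in µm — shortens in two phases: a slow early
phase at rate $r_\mathrm{early}$ while $L > L_c$ and a fast late phase at
$r_\mathrm{late}$ below the inflection length $L_c = 190$ µm. Wild-type
presets use 0.64 and 1.88 µm/min; septate-junction mutant presets use
their published early rates (0.52, 0.50, 0.57 µm/min for *cora*, *Mcr*,
*Nrx-IV*) with the fast phase disabled (`enter_fast_phase = FALSE`), since
these mutants generally fail to accelerate.

The generator samples the process at the frame interval (default 10 min,
matching typical acquisition): over each interval it applies
$r_\mathrm{early}$ when the *current sampled length* exceeds $L_c$ and
$r_\mathrm{late}$ otherwise. This discrete-time switch — rather than a
continuous-time breakpoint exactly at $L_c$ — is deliberate: it makes
noiseless trajectories exactly piecewise linear *frame to frame*, so the
endpoint estimator below recovers both preset rates exactly on noiseless
input. A continuous-time breakpoint would leave one straddling frame
interval with a mixture of the two rates and an irreducible estimator
bias even without noise.

Measurement noise is additive Gaussian on the recorded lengths (σ = 2 µm
by default — a fixed estimate of manual canthus-placement error),
clamped at 0; the underlying process is noiseless.

Events: with probability `p_tear` the epidermis tears from the
amnioserosa when the length first drops to a tear length drawn from
N(`tear_length_mean`, `tear_length_sd`) truncated to (0, start length).
The *Nrx-IV* preset tears shortly below 190 µm (mean 180, sd 10 µm);
*cora*/*Mcr* tear later in closure (mean 120, sd 30 µm — a package
choice, as only the ordering is constrained). Tears fall on the anterior
half with probability 0.7 (only "more often anterior" is constrained).
With probability `p_arrest` (0.3 in the mutant presets; unpublished, a
package choice) shortening stops at a length drawn from N(120, 30)
truncated below $L_c$. Tears take precedence over closure within a frame
because the length passes the (positive) tear length before reaching 0.

### Estimation

`fit_phase_rates()` implements the endpoint estimator: with frame *a* the
last with $L > 220$ µm, *b* the first with $L < 190$ µm and *c* the last
before closure (first frame at or below the 5 µm closure threshold),

$$ r_\mathrm{early} = \frac{L_a - L_b}{t_b - t_a}, \qquad
   r_\mathrm{late} = \frac{L_b - L_c}{t_c - t_b}. $$

When no frame exceeds 220 µm the first frame is used; when the series
never drops below $L_c$ the late rate is unset. Trajectories whose first
frame is already below 220 µm are flagged `late_start` and excluded from
cohort rate summaries; late rates are averaged only over embryos that
closed. A least-squares regression variant over the same windows
(`method = "regression"`) is provided and used as a cross-check oracle in
the tests; the endpoint form is the default because the windows are
defined by their endpoints.

**Estimator properties under noise.** Selecting window endpoints on noisy
lengths conditions on the noise (a frame is "the last above 220" partly
because its noise pushed it up), which produces a small bias: at σ = 2 µm,
10-min frames and start length 230 µm, cohort-mean recovery over many
20-embryo cohorts is ≈ +0.03 µm/min for the early rate and ≈ −0.03 for
the late rate (the latter mostly because the frame just above $L_c$ is
occasionally misclassified into the late window, contaminating it with
one slow segment). Both are inside the package's ±0.05 µm/min recovery
tolerance in expectation; they are properties of the window-selection
rule itself, not of the generator.

Outcome classification (`classify_outcome()`) honors tear annotations
first, then calls an embryo closed when the minimum length is at or below
5 µm, and arrested when mean shortening over the final 60 min falls below
0.05 µm/min while still open. Closure threshold and arrest criteria are
package conventions (scoring was visual in practice) and configurable.

## Ablation mechanics

Post-ablation retraction of the tricellular vertices flanking a cut
junction is modelled as a Kelvin–Voigt (spring–dashpot) element:
$\Delta L(t) = D\,(1 - e^{-t/\tau})$, sampled every 3 s for 60 s. The
exponent is negative — the retraction saturates at the asymptotic
distance $D$ — and the fit is on displacement with $\Delta L(0) = 0$
enforced (no offset parameter), since $D$ is defined as the asymptotic
distance retracted. The relaxation time τ is the tissue's
viscosity-to-elasticity ratio.

`fit_kelvin_voigt()` runs Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) from multiple starts ($D_0$ = last observed
displacement; $\tau_0 \in \{5, 15, 45\}$ s, spanning the plausible range)
and keeps the converged fit with the lowest SSE; parameters are bounded
positive. On noiseless input the recovery is exact to well below 10⁻⁶;
with σ = 0.05 µm noise, median relative bias of τ̂ is under 5% (500
replicates), and the fitted SSE is verified in the tests against a dense
grid-search oracle. `recoil_velocity()` is the first-frame displacement
over the pre-cut→post-cut interval (metadata, default 3 s — the sampling
interval, since the actual gap is unrecorded); as the interval shrinks it
approaches $D/\tau$. Group comparisons use two-sided Welch t-tests (the
test used for these comparisons is not named in the source; Welch avoids
the equal-variance assumption).

## Cell-shape morphometrics

Cell outlines are ordered-vertex polygons in µm, x = AP, y = dorsoventral
(DV). The 14 descriptors follow standard particle-analysis conventions
and are computed polygon-exactly (Green's-theorem vertex formulas for
area, centroid and second central moments), not from rasterized masks —
inputs are vector outlines, and a dense-rasterization moment oracle in
the test suite confirms agreement within 1%. Conventions that matter:

- **Equivalent ellipse**: the ellipse with the polygon's second central
  moments, *uniformly rescaled so its area equals the polygon area* (the
  convention of the common particle-analysis tools). Roundness
  ($4A/\pi\,\mathrm{major}^2$) and aspect ratio depend on this choice.
- **Angle**: major-axis orientation, counterclockwise from +AP, in
  [0, 180)°.
- **Feret diameters**: rotating calipers on the convex hull — maximum
  vertex–vertex distance, its angle, and the minimum width across
  parallel supporting lines (attained perpendicular to a hull edge).
- Degenerate inputs (zero area, self-intersection) are rejected by the
  polygon constructor; vertex order may be CW or CCW (normalized to CCW).

PCA (`run_pca()`) centers and scales the descriptor columns — the
eigendecomposition of the correlation matrix. Standardization is the
default because the descriptors carry incommensurate units (µm, µm²,
degrees, ratios), making unscaled PCA dominated by area/perimeter;
`standardize = FALSE` is available. Constant columns are dropped with a
warning; loading signs (arbitrary in PCA) are fixed by making the
largest-magnitude loading of each PC positive. Variance fractions are
$\lambda_k/\sum\lambda$ and the percent contribution of variable *j* to
PC *k* is $100\,\ell_{jk}^2$, summing to 100 per PC. The published
variance split for real segmented cells (45.9%/26.4%) is a property of
that dataset and is not a target for synthetic meshes; the package's PCA
guarantees are property-based (oracle equivalence, sums, separation of
planted defect cells). Per-descriptor comparisons use pooled-variance
Student's t-tests at α = 0.05, matching the original analysis.

## Synthetic epithelium

`simulate_epithelium()` builds a brick-like mesh of simple rectilinear
polygons tiling the rectangle `n_cols·mean_width × n_rows·mean_height`
µm exactly. Rows are laid top-down from the leading edge (topmost row
labelled `DME`, next `row2`): each row draws per-cell widths (lognormal
around 6 µm, rescaled to the common span, cuts jittered by
`boundary_jitter`) and per-cell heights (lognormal around 12 µm —
dorsoventrally elongated cells); a cell's flat bottom edge sits at the
area-weighted mean of its jagged top boundary minus its drawn height, so
*drawn height = realized mean height* exactly. The basal row closes the
mesh at y = 0 and absorbs the accumulated residual (its drawn heights are
not honored) — hence the default `n_rows = 3`, keeping the two analyzed
rows (DME, row2) calibration-exact. Defect cells — a fixed
`round(defect_fraction·n)` subset — model the mutants' "failed
elongation": height × 0.5, width × 2 (similar area, rounder and wider).
Two consequences worth knowing:

- Because the mesh tiles a *fixed* rectangle, whole-mesh mean height is
  conserved; planted height effects exist at the cell level (defect vs
  normal cells), which is the contrast the tests use.
- The bounding-box `height` descriptor of a jagged-topped cell exceeds
  its mean height, so descriptor-level defect ratios (~0.58) sit above
  the mean-height ratio (~0.5); both separations are large relative to
  the 0.2 CV noise.

This construction was chosen over a Voronoi tessellation to keep
polygons simple and the exact-tiling property testable; over a
shared-corner quad mesh because shared corners dilute per-cell defect
factors by averaging with neighbors.

## Fluorescence z-stacks and the bootstrap

`render_junction_stack()` draws cell boundaries as ridges (width 3 px,
intensity 100 counts by default) over background on each of 9 slices
(0.2 µm/px, 0.3 µm z-step), with Gaussian or Poisson noise, and returns a
paired ground-truth label image. "Mutant" mode applies a per-slice decay
of 0.885 to the junction intensity, making the slice-averaged junctional
signal ≈ 0.6× wild type — the ratio implied by the published per-cell
intensity means; only the ratio is used, not the absolute values. The
renderer is deliberately schematic: no point-spread function, photon
physics, amnioserosa pulsation or 3D cell geometry — passing tests show
the *quantification* pipeline is correct, not that the images are
photorealistic.

Quantification follows the original procedure: raw integrated density
(sum of pixel values in the ROI) summed over the selected slices,
normalized by the number of cells covered; ROI areas must match across
compared embryos (error unless explicitly overridden); cell counts are
user-supplied or taken from ground truth — no automatic segmentation.

`bootstrap_compare()` tests $T = |\bar A - \bar B|$ against a null built
by centering each group at its own mean, pooling, and resampling groups
of the original sizes with replacement, B = 10,000 by default;
$p = (1 + \#\{T^* \ge T\})/(B+1)$, reproducible under a seed. The
procedure details are package decisions (unspecified in the source) and
all configurable. One calibration subtlety: plain mean-centering shrinks
each group's spread (n − 1 degrees of freedom in n residuals), making the
test anti-conservative at small n (measured type-I level ≈ 0.086 at
n = 8). The default therefore rescales centered residuals by
$\sqrt{n/(n-1)}$, which brings the level to ≈ 0.064 at n = 8 and ≈ 0.055
at n = 30; the unstudentized mean-difference bootstrap remains mildly
liberal at very small n, which is why the suite's calibration check runs
at n = 30 per group. `center = "plain"` restores the uncorrected variant.

## Penetrance statistics

`two_by_two()` reports both an exact p (Fisher's test, two-sided by the
minimum-likelihood convention — the most common, though alternatives
exist) and an asymptotic p (Pearson chi-square, 1 df, uncorrected),
reproducing the "exact and asymptotic" pairing; the unnamed original test
is thereby bracketed. The odds ratio is the sample $(ad)/(bc)$ with a 0.5
continuity correction when any cell is zero — not the conditional MLE.
Percentages print to two decimals. `penetrance()` gives exact
Clopper–Pearson binomial intervals. The test suite validates the exact p
against a brute-force hypergeometric enumeration oracle and checks
exact/asymptotic agreement (within 20% relative) on large tables away
from the extreme tail (p ≥ 0.01), where multiplicative agreement of the
chi-square approximation is meaningful.

## Reproducibility, problem sizes and limitations

Every generator is a pure function of (params, seed): RNG state is
localized and restored, per-unit seeds are derived deterministically from
the master seed, and the pipeline driver (`run_pipeline()`) writes a
config hash and seed into its summary so outputs are byte-reproducible.

The validation suite uses cohort sizes of 20 embryos (rate recovery, the
scale at which cohort-mean SE ≈ 0.015 µm/min), 200 embryos for outcome
frequencies, 500 replicates for Kelvin–Voigt bias and type-I calibration,
1000 replicates for t-test calibration, and 20 random polygons against
the raster oracle — sizes chosen to keep Monte-Carlo error comfortably
below the tolerances they check.

Known limitations: the closure model is piecewise-linear with additive
Gaussian measurement error (no zippering geometry, no amnioserosa cell
dynamics); tear/arrest parameters for mutants beyond *Nrx-IV*'s timing
are only ordinally constrained and fixed by convention; the mesh is
rectilinear (no junction angles or curvature, so `angle`-type descriptors
carry little signal on synthetic cells); image rendering is schematic;
and real-data quantities that depend on the actual specimens (absolute
intensity means, the PCA variance split, per-stage defect percentages)
are out of reach by design — the package validates its procedures by
parameter recovery and oracle equivalence instead.
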