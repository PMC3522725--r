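---
title: "Quantifying the microtubule pool: models, parameters and design choices"
author: "mtquant maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the microtubule pool: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtquant)
```

# Overview

`mtquant` measures the polymerized microtubule (MT) pool of cultured cells
through four independent readouts — immunofluorescence integrated density,
polymerized/soluble lane densitometry, growth-cone peripheral invasion, and
normalized plate-reader signals — and a statistics layer matched to how such
experiments are analysed (one-way ANOVA, Dunnett's many-to-one post-test,
Student-Newman-Keuls, viability normalization, dose-response shape labels).
Because no public dataset accompanies these procedures, the package's
synthetic-data generators are first-class, tested code: every fixture carries
a `ground_truth()` record, and the test suite scores each estimator against
the truth its generator recorded.

This vignette documents the models, the tunable parameters with their
defaults and units, what the generators do and do not emulate, the numerical
choices, and the design decisions taken where the procedure descriptions left
the design open.

# Integrated density above a positive cutoff (AID)

For an intensity image $I$, a region of interest $R$ and a cutoff $c$,

$$\mathrm{AID}(R, c) \;=\; \sum_{p \in R,\; I(p) > c} I(p)
\;=\; A_{+} \cdot \overline{I}_{+},$$

the product of the positive area $A_{+}$ and the mean gray value
$\overline{I}_{+}$ — an identity `aid_measure()` preserves exactly and the
tests assert on random images.

**Cutoff selection.** The procedure being reproduced says only that positive
cutoffs come from the intensity histogram. The default here is Otsu's
between-class-variance criterion on the 256-bin ROI histogram
(parameter-free, reproducible, verified in tests against an exhaustive
threshold sweep). The alternative `background_k_mad` uses the robust
background estimate $\mathrm{median} + k\,\mathrm{MAD}$ with $k = 3$. In the
assembled cell quantifier (`quantify_cell()`) the Otsu cutoff is additionally
floored at $\mathrm{median} + 3\,\mathrm{MAD}$ of the ROI, standing in for
the autofluorescent background of a control slide: no pixel at or below a
supplied control background is ever counted positive. Without such a floor,
Otsu applied to a signal-free image happily splits the noise distribution and
reports a large spurious positive area; the floor is what makes the
colchicine-like regime register as *below detection*.

**Below-detection rule.** No numeric rule was stated for "below the
threshold level of measurements"; the default flags a measurement when the
positive area is under `min_positive_fraction = 0.5%` of the ROI. This
matches the all-or-nothing character of a depolymerized network without
discarding sparse but real networks. A flagged measurement poisons the
Tyr/Glu ratio: `tyr_glu_ratio()` returns `defined = FALSE` and an `NA` ratio
(never 0, never infinity), and undefined ratios never enter group statistics.

**Per-cell measurements.** AID is computed per cell ROI; field-level values
are means over cells, matching designs that report "n cells per treatment".

# Focal plane and network area

`select_focal_plane()` thresholds one channel per plane (same cutoff rules)
and returns the plane with maximal positive area, ties to the lower index —
the "maximal area on the focal axis" rule. `mt_network_area()` measures the
area inside the outer boundaries of the network as: threshold → morphological
closing (disc, default radius 5 px) → hole fill → largest connected
component. Closing plus hole-fill was chosen over a convex hull because hulls
systematically overestimate star-shaped cells; the area is monotonically
non-decreasing in the closing radius (asserted as a property), and closing is
implemented so it remains extensive at the frame border (out-of-frame pixels
count as foreground during the erosion half-step).

# Lane densitometry and the polymerized fraction

A lane is a 1D profile with a *declared* band window; window auto-detection
is deliberately a non-goal so that quantification stays auditable.
`band_density()` subtracts a background and integrates the window:

* `linear_baseline` (default): straight line through the mean of the three
  positions flanking each side of the window — flank positions strictly
  outside the window, so on noise-free fixtures the recovered P + S integrals
  equal the generated total exactly;
* `rolling_min`: a grayscale opening (rolling minimum then maximum) on the
  flanks, interpolated linearly beneath the band. The baseline under a band
  is unobservable, so both methods interpolate across the window; on linear
  backgrounds they agree to well within 1%.

`percent_polymerized(p, s) = 100\,p/(p+s)` satisfies the complementarity
identity $f(p,s) + f(s,p) = 100$ exactly. Loading-normalized expression
(band / loading-control band) is scale-invariant by construction. The
equal-volume assumption of the paired P/S design is kept; no volume
correction is applied by default.

# Growth-cone invasion

The growth cone is segmented into the total area $T$ (union of
actin-positive and membrane-positive masks, closed with a 2 px disc, filled,
largest component), the proximal Glu-occupied area $P_{gc}$ (Glu-positive
mask dilated by `dilation_px = 3`, intersected with $T$, filled) and the
peripheral region of interest $\mathrm{ROI} = T \setminus P_{gc}$. The
partition $|P_{gc}| + |\mathrm{ROI}| = |T|$ holds exactly for every
segmentation because $P_{gc}$ is intersected with $T$ before differencing.
The three-domain anatomy (central, transitional, peripheral) is collapsed
into this two-set subtraction exactly as the measured procedure does: the
transitional band is absorbed into $P_{gc}$ through the dilation parameter.
Invasion is area coverage, $100\,|{\rm Tyr}^{+} \cap \mathrm{ROI}|/|\mathrm{ROI}|$,
not filament count or length. Raising the Tyr cutoff can only shrink the
positive set, so the invasion percentage is non-increasing in the cutoff
(a property test).

The $T$ closing radius (2 px) differs from the network-area closing radius
(5 px) deliberately: 2 px is about twice the rendering line-spread sigma and
bridges sub-resolution gaps without sealing the concave pockets between
filopodia into the cone area, which a 3 px closing measurably did.

# The synthetic world

**Cells** (`make_cell_image()`). A single elliptical cell; filaments are
smooth random-walk polylines (unit steps, Gaussian heading increments,
sd 0.15 rad) stamped with a Gaussian line-spread (`psf_sigma = 1` px) — the
simplest model preserving the area and intensity statistics the pipeline
measures. Filaments are added until the target `network_extent` (default
0.4 of the cell mask) or the filament cap is reached. The filament signal is
split between the Tyr and Glu channels by `tyr_glu_partition`, so the true
AID ratio is $p/(1-p)$. Defaults: 192×192 px at 0.2 µm/px (a 63× confocal
scale; the source procedure states no pixel size, so this is configurable),
peak filament intensity 3000 AFU, background 60 AFU, Poisson shot noise
(gain 1 count/AFU) plus Gaussian read noise (sd 15 AFU) — levels chosen once
as typical of a well-exposed 16-bit confocal acquisition. The colchicine-like
regime (`below_detection = TRUE`) scales the filament field so every filament
pixel sits below background + `detection_margin` (30 AFU = 2 read-noise sd).

**Z-stacks** (`make_zstack()`). Independent planes whose network extent falls
off linearly (18% per plane, floored at 30%) from the declared maximal
plane — a cell drifting out of focus. Extents are recorded, and the declared
plane is strictly maximal by construction.

**Growth cones** (`make_growthcone_image()`). A fan (100° opening,
central radius 24 px, peripheral width 28 px at 0.1 µm/px) with filopodia
beyond the leading edge; actin and membrane fill the fan. MT filaments here
are *binary ribbons* (a stamped Gaussian accumulator cut at a fixed level,
then set to the saturated plateau intensity): this makes the rendered
coverage mask threshold-invariant, so the ground-truth area and what any
between-modes cutoff measures coincide — with graded filaments the measured
invasion would depend on where Otsu lands on the filament cross-section,
which is a property of the renderer, not of the quantifier under test. Glu
ribbons end 3.8 px inside the central radius so their support can never
touch the band (geometric exclusivity is asserted pixelwise), while the
3 px-dilated proximal mask still reaches the central radius. Invasion
ribbons are added radially, lengths trimmed to the remaining deficit, until
the rendered band coverage reaches the requested fraction; fractions 0 and 1
render the empty and the full band exactly, and the quantifier returns
exactly 0 and 100 on them.

**Cohorts** (`simulate_cone_cohort()`). Per-cone true fractions jitter
around the group mean with CV 0.1. That value is deliberate: the two-group
design this emulates (22 cones per group, true fractions 0.10 vs 0.20)
is required to estimate the group ratio within [1.8, 2.2] in ≥95% of
cohorts, and with $n = 22$ the sampling error of a ratio of means allows a
per-cone CV of at most ≈10–15%. Real growth-cone cohorts scatter
considerably more; a green cohort test therefore establishes the estimator's
calibration, not that real cohorts are this tight.

**Lanes** (`make_lane_profiles()`). Gaussian band (sd = window half-width /3,
truncated to and normalized over the declared window, so noise-free P + S
conserve the total exactly) on a linear background (offset 50 AFU, slope
0.8 AFU/position) with additive Gaussian noise (sd 8 AFU). Default analyte
fractions depict a resting cell: tubulin 0.5, tau 0.95, actin 0.5.

**Plates** (`make_plate_table()`). Raw signal = per-well cell factor ×
condition effect × 1000 AFU + noise; Hoechst = cell factor × 500 AFU +
noise; cell factors are $\max(0.1,\, 1 + \mathcal N(0, 0.2))$ and the noise
sd is 30 AFU, giving a normalized per-well CV of ≈7%, typical of in-cell
westerns. Shapes: `null` (all effects 1), `bimodal` (effect only at the peak
concentrations, default $10^{-15}$ and $10^{-9}$ M at 1.5-fold),
`sigmoid` (Hill curve, midpoint $10^{-12}$ M). Concentrations default to
$10^{-18}\ldots10^{-6}$ M in 3-decade steps with a vehicle group at 0 M.

**What the generators do not emulate:** 3D point-spread functions,
deconvolution, photobleaching, chromatic aberration or channel
misregistration (channels are perfectly registered by design), cell-to-cell
morphological variability beyond the ellipse/fan geometry, gel smiling or
saturated film. Green tests establish that the estimators recover what the
stated world renders — not that these defaults span all real acquisitions.

# Statistics

`one_way_anova()` is the classical equal-variance F test (matching the
defaults of the analysis software the procedures cite); a Welch correction
was considered and left out to keep the reproduced analysis faithful.
Zero within-group variance everywhere raises a degenerate-variance error
rather than returning F = ∞.

**Dunnett.** The many-to-one statistics $T_i = (\bar y_i - \bar y_0)/
\widehat\sigma\sqrt{1/n_i + 1/n_0}$ have the factor-analytic correlation
$\rho_{ij} = \lambda_i \lambda_j$ with $\lambda_i = \sqrt{n_i/(n_i+n_0)}$.
Conditioning on the shared normal factor and on the pooled-SD chi factor
reduces $P(\max_i |T_i| \le q)$ to a smooth 2D integral, evaluated with
48-node Gauss–Hermite × 32-node Gauss–Legendre quadrature (the chi factor
through its probability integral transform); the critical value comes from
`uniroot` and is cached per design. Accuracy is ≈3×10⁻⁴ on the quantile
(cross-checked against `mvtnorm` in the test suite, which also verifies the
k = 1 reduction to the two-sample t quantile); no tables are hard-coded, so
arbitrary group counts and sizes work. Adjusted p-values are
$1 - P(\max|T| \le |t_i|)$, which makes Dunnett provably never less
conservative than the unadjusted t test on the same data (asserted
property). Family-wise type-I error calibrates to 0.05 ± 0.01 in the
acceptance Monte Carlo.

**SNK.** Ordered means, studentized-range tests from span $k$ down to 2
(`ptukey`/`qtukey` from base R), harmonic-mean group size when unbalanced,
and the defining absorption rule: a non-significant span protects every
comparison nested inside it.

**Viability.** Values are scaled by $100/\bar y_{\rm control}$, pinning the
control mean at exactly 100% and making the normalization scale-invariant.

**Dose-response shape.** Concentrations are flagged by Dunnett against the
vehicle; the flag pattern is labelled `flat` (no flags), `monotone` (one
flagged run ending at the top concentration) or `bimodal` otherwise. The
stated rule did not cover a single flagged run that stops short of the top
concentration; it is labelled `bimodal` here because an interior peak is a
non-monotone response, and the three labels partition into
none / monotone / non-monotone. This completion was fixed before any
simulation was scored.

# Numerical and interface conventions

* Indices are 1-based throughout (plane indices, band windows, mask
  indexing) — the R idiom; a 0-based convention was stated in the original
  design notes but would be alien to every downstream R tool.
* Areas are reported in both px and µm² (`pixel_size` in µm/px).
* Ties in focal-plane selection and largest-component selection go to the
  lower index / first label in scan order.
* All randomness flows from one master seed through `derive_seed(master,
  counter)` (multiplicative congruential step modulo $2^{31}-1$), so fixture
  sets are bit-identical across runs and machines with one R version.
* Images are exchanged as uncompressed 16-bit little-endian grayscale TIFF,
  one file per channel (`<fixture>_<channel>.tif`); the package carries its
  own minimal baseline-TIFF reader/writer because no TIFF package is
  available in the supported dependency set. Tables are UTF-8 CSV with a
  header row and `.` decimal; configs are flat `key: value` text.
* Otsu runs on a 256-bin histogram of the ROI; a constant ROI is a
  degenerate-histogram error reporting the constant.
* Band integrals are clipped at zero; a warning is emitted only when the
  negative integral exceeds floating-point dust.

# Known limitations

* The AID sum is not background-subtracted (by definition), so the Tyr/Glu
  ratio carries a small bias toward 1 when the background contribution to
  the positive area is non-negligible; at the default generator settings
  the bias is under 2% and inside the 10% recovery tolerance.
* Otsu assumes a bimodal ROI histogram; networks covering well over half the
  ROI can push the background-floor estimate up. The `background_k_mad`
  method is the escape hatch.
* The SNK procedure controls the family-wise error only under the complete
  null; this is a property of the method, not of the implementation.
* The TIFF reader supports the uncompressed single-sample baseline subset
  (either byte order) — enough for the pipeline's own fixtures and ImageJ
  exports, not for compressed or tiled files.
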