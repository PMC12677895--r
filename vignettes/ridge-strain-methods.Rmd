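---
title: "Measuring sub-surface fingerprint-ridge strain from tracked OCT landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sub-surface fingerprint-ridge strain from tracked OCT landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgestrain)
```

## The measurement problem

Optical coherence tomography (OCT) can film a cross-section of the fingerpad
at a resolution fine enough to see individual papillary ridges and the two
outer skin layers — the stiff stratum corneum (SC) and the softer viable
epidermis (VE) — while a plate indents or slides across the finger. Tracking
nine anatomical landmarks per ridge (three columns: proximal valley, crest,
distal valley; three levels: surface, SC/VE border, epidermis–dermis
junction) turns each ridge into a small triangular mesh whose frame-to-frame
deformation can be quantified as a strain field. This package implements the
full analysis chain from tracked-landmark tables to per-facet
Green–Lagrange strains, and a synthetic-trial generator that provides
analytic ground truth for every stage.

The package deliberately consumes *tracked landmarks* (CSV) rather than raw
video: markerless tracking is a separate, model-based problem. The optional
image stage only reproduces the preprocessing applied before tracking
(histogram equalization, gamma transformation with $\gamma = 5$, bilateral
filter with diameter 5, $\sigma_{color} = 110$, $\sigma_{space} = 190$) and a
renderer for speckled two-band OCT-like frames used as fixtures.

## Mesh model and conventions

All geometry is internally in millimetres. The lateral axis $x$ points
distally; the axial axis $y$ is depth and **increases downward**, matching
the stored image layout (pixel pitch 4.5 µm lateral × 5 µm axial). Each
ridge mesh has 9 nodes and 8 triangular facets: the four quads
(SC/VE × proximal/distal flank) are each split along their
valley-bottom-to-crest-top diagonal, identically in every mesh, so facet
$k$ always spans the same node ids and per-facet comparisons across frames,
phases and ridges are well defined. The split direction is a convention the
imaging itself cannot dictate; fixing it is what makes facet-level
statistics meaningful. Adjacent ridges share their valley landmarks, as a
continuous surface profile implies; whether the original tracking shared
them is not documented, so this is a modelling choice of the generator.

Ridge width is measured between the two valley nodes at the surface level;
layer thickness as the column-mean vertical extent of a layer. Both are
measurement conventions: the source imagery reports the quantities without
defining the measurement line.

## Movement-phase segmentation

Per-ridge velocity is the frame-to-frame displacement of the nine landmarks,
averaged over landmarks and scaled by the frame rate; the first frame is
undefined. For flat-plate trials the *field* trace (mean over all tracked
ridges) is used, as all ridges in contact move together.

**Flat plate.** Each transit starts with the skin sticking to the plate
(ridge velocity equals plate velocity) and ends slipping (ridge
stationary). The stick-to-slip boundary is located at the extremum of the
first derivative of the ridge velocity: negative extremum for distal
transits, positive for proximal. Velocities are smoothed with a centred
3-frame moving average *within* each transit before differencing —
smoothing across a reversal would bleed the large direction-change step
into the neighbouring transit and create a spurious extremum at the transit
edge. Because the same smoothing spreads the true velocity drop over a
plateau of near-equal derivative values, the boundary is taken as the
central frame of the tolerance-plateau of the extremum (the earlier frame
when the plateau has even length). On noise-free synthetic trials this
recovers the true boundary exactly; with 2 px tracking noise it stays
within ±2 frames in well over 95% of seeded runs.

**Feature plates (edge/groove).** Frames where the ridge moves horizontally
(|v_x| above the slip threshold) are discarded as not fully slipping. The
remaining frames of each transit are labelled from the vertical velocity:
`approach` while the skin moves toward the feature (down under an edge, up
into a groove), `withdraw` while it returns, `under_feature` for the
stationary frames in between, and full slip before and after — five phases
per transit, classified per ridge. The sign rule is stated in y-up terms
and flipped automatically for image-convention (y-down) data; hard-coding
one convention silently would invert approach and withdraw.

**Thresholds.** A ridge counts as stationary when its speed is below
`max(0.05 × plate speed, 3 × noise floor)`; an exact zero is unattainable
with tracking noise. With the 0.8 mm/s protocol this is 0.04 mm/s.

**Equal-length windows.** For each phase label, `n_phase` is the minimum
duration among that label's repetitions and every repetition contributes
its central `n_phase` frames (shifted one frame earlier when exact
centering is impossible), so each occurrence enters the phase average with
equal weight. The minimum is taken over *all* repetitions of a label —
four for flat-plate phases, eight per ridge for feature phases — which
generalizes the stated four-repetition rule to the feature protocol.

## Stereotypical ridges and strain

Each complete ridge-frame is centred on its own node centroid (removing
rigid translation), and centred meshes are averaged node-wise over all
ridges and frames of a phase — pooled with equal weight, which the
central-window selection justifies. Incomplete ridge-frames are dropped,
never imputed, with a reported count.

Strain is computed **between phase-averaged meshes**, not as an average of
per-frame strains. For each facet, the unique affine map from the reference
to the deformed triangle (constant-strain-triangle fit, exact for three
vertices) gives the displacement gradient, from which the Green–Lagrange
tensor is formed with its quadratic terms:

$$\varepsilon_{xx} = u_x + \tfrac12(u_x^2 + v_x^2), \quad
  \varepsilon_{yy} = v_y + \tfrac12(u_y^2 + v_y^2), \quad
  \varepsilon_{xy} = \tfrac12(u_y + v_x) + \tfrac12(u_x u_y + v_x v_y),$$

equivalently $E = \tfrac12(F^\top F - I)$, hence exactly invariant under
rigid rotation of the deformed configuration (verified to 1e-10 in the
tests). Eigen-decomposition yields the principal strains $e_1 \ge e_2$
(maximum tension and compression), the area change $e_a = (e_1 + e_2)/2$
and the maximum shear $e_s = (e_1 - e_2)/2$. Note that $e_a$ is the *mean
principal strain*: to first order it equals the per-dimension scale change
$\sqrt{A'/A} - 1$, i.e. half the relative change of facet area. The tests
assert this linearization to 0.01 for strains up to ~5% and assert that the
discrepancy becomes visible at large strain rather than hiding it.

The principal angle $\theta$ is reported for the compressive ($e_2$) axis,
relative to vertical, positive toward distal, as an axial quantity in
$(-90°, 90°]$. Angles within 22.5° of an axis (0 or ±90°) are classified
*cardinal* (tension/compression without appreciable shear), the rest
*diagonal* (horizontal shear), with the 22.5° boundary assigned to
cardinal; diagonal angles are signed by agreement with the plate movement
direction. Axial spread uses the doubled-angle circular standard deviation
(period 180°). Facets whose averaged reference triangle degenerates (area
< 1e-9 mm²) yield flagged `NA` strains rather than infinities.

Reference schemes per protocol: consecutive phases for flat-plate trials
(cyclically stick → slip → stick → slip), the initial full-slip phase for
feature trials, and the unloaded (0 N) stereotypical ridge for static
loading.

## Statistics

All comparisons are non-parametric. The paired Wilcoxon signed-rank test
drops zero differences, requires at least five non-zero pairs, and computes
the exact two-sided p from the full sign-assignment distribution of the
rank sum for up to 15 pairs (this stays exact under tied ranks, where the
classical algorithm must fall back to a normal approximation); larger
samples use the continuity-corrected normal approximation. If every
difference is zero the test is degenerate and reports p = 1 with a warning
— a no-deformation trial should report "no significance", not crash.
Kolmogorov–Smirnov comparisons use the asymptotic two-sided statistic;
Bonferroni correction is `min(1, p·m)`.

Pairing units on single-trial synthetic runs: the flat-plate
stick-to-slip-vs-reversal comparison pairs facet × movement direction
(8 pairs per layer); the feature-plate SC-vs-VE comparisons pair
facet-position × ridge using per-ridge stereotypical meshes, because
pooling all ridges into one mesh leaves only 4 pairs per layer — below the
test's validity threshold. The Bonferroni family for the feature analysis
is the per-phase comparisons within one measure (m = number of phases
compared, 4 by default).

## What the synthetic generator emulates — and what it does not

The generator reproduces the *study conditions*: ridge width 0.47 mm, SC
thickness 0.38 mm, VE thickness 0.12 mm, eight ridges in the ~4 mm field;
7.6 mm transits at 0.8 mm/s, four per direction, imaged at 10 Hz (95 frames
per transit, 760 per trial); static loading 0 → 3.5 N in 0.5 N steps with
20 frames per step; an edge of 1 mm base and 0.4 mm height and a groove of
1 mm base and 0.3 mm depth. Free parameters were fixed once at values a
practitioner would call realistic:

* **Crest height 0.05 mm** — surface undulation of lightly loaded ridged
  skin is a few tens of micrometres.
* **Stick fraction 3.4/7.6** — reproduces the reported mean stick drag
  distance of 3.4 mm per transit.
* **Flat-trial phase states** — sticking in direction $d$ carries a uniform
  horizontal strain $d \cdot 0.04$, slipping $d \cdot (-0.06)$: deformation
  is then concentrated at stick-to-slip transitions (strain change 0.10)
  while reversals change little (0.02) but swap the tension/compression
  axis, giving the 90° principal-angle rotation at reversals.
* **Feature-transit kinematics** — a flat-topped vertical bump (half-cosine
  ramps of half a ridge width on each side, plateau equal to the feature
  base; total support = feature base + ridge width) signed by plate type. A
  peaked bump would make the "under the feature" phase instantaneous; the
  flat top gives it a genuine stationary interval, as required for a
  five-phase ground truth. While a ridge is engaged, its crest column is
  additionally displaced against the valleys (±0.04/0.03 mm), shearing the
  two flanks in opposite senses, and the VE thickness at the crest changes
  (+0.025 mm edge, −0.02 mm groove). The thickness term is a *stylized*
  construct: it reproduces the observed sign pattern (VE area expands
  around an edge, contracts into a groove, SC retains area), not the
  lateral-stretch mechanism behind it.
* **Static flattening** — exponential saturation
  $d(F) = d_{max}(1 - e^{-F/F_0})$ with $d_{max} = 0.06$ mm and
  $F_0 = 0.5$ N, 60% of the depression absorbed by the VE. This yields the
  fast-then-linear strain growth (most deformation by 0.5 N), VE
  compression above 20% and SC below ~10% at full load.
* **Tracking noise** — isotropic i.i.d. Gaussian per physical landmark per
  frame, in pixels, seeded; shared valley landmarks receive a single draw.
  The reported tracker accuracy (a few px) motivates the 1–2 px levels used
  in the tests.

Not emulated: real tissue constitutive behaviour, out-of-plane motion,
participant-to-participant variability, OCT attenuation or refraction
artifacts, or tracker failure modes (drift, label swaps). Passing tests
therefore demonstrate that the *pipeline* recovers known deformation fields
under realistic geometry, protocols and noise — not that real skin behaves
like the generator.

## Numerical choices and problem sizes

Degenerate inputs error early (incomplete ridge-frames, collinear columns,
non-positive facet areas, reference triangles below 1e-12 mm²). The test
suite runs full-size trials (760 frames × 8 ridges), 20-frame phase
averages with 2 px noise for recovery (facet-mean recovery within 10%
relative — per-facet VE components at the 0.12 mm length scale carry ~13%
noise-induced error at these conditions, so the facet mean is the
recoverable quantity), 100-seed robustness runs for boundary detection, and
a 200-replicate null calibration of the stick-vs-reversal test at reduced
trial size (1.6 mm transits, four ridges), which keeps the whole suite
under a minute while leaving every scientific condition at its study value.

## Known limitations

Strains are two-dimensional; out-of-plane deformation is invisible and can
masquerade as apparent thickness change. The mesh stops at the
epidermis–dermis junction (no intermediate ridges). The per-frame strain
mode exists for diagnostics only; all reported strains are between
phase-averaged meshes, so transient within-phase dynamics are averaged
away. The feature-plate generator reproduces sign patterns, not
magnitudes, of layer-differential strain; magnitude-level claims about
real tissue require real recordings.
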