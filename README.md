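# ridgestrain

Sub-surface strain analysis of individual fingerprint ridges from tracked
OCT landmarks.

## What this package is for

When a surface indents or slides across the fingerpad, each papillary ridge
deforms below the skin surface — stretching, compressing, and shearing the
stratum corneum (SC) and viable epidermis (VE) in ways that ultimately
drive the mechanoreceptors at the epidermis–dermis border. Optical
coherence tomography (OCT) makes those deformations visible: a cross-
sectional video of the fingerpad in which nine anatomical landmarks per
ridge (three columns × three depth levels) can be tracked frame by frame.

`ridgestrain` turns those landmark tables into quantitative strain fields.
It is aimed at skin-biomechanics and tactile-neuroscience labs running
plate-stimulation experiments (static indentation, flat-plate sliding with
stick/slip, transit of small edge/groove features) who need a tested,
reproducible path from tracker output to per-facet strain statistics.

The pipeline:

1. **Mesh** — each ridge-frame becomes a fixed-topology triangular mesh:
   9 nodes, 8 facets labelled by layer (SC/VE) and flank (proximal/distal).
2. **Phases** — trials are segmented from per-ridge velocity traces:
   stick/slip per transit for the flat plate (boundaries at the extrema of
   the smoothed velocity derivative), five transit phases per ridge for
   edge/groove plates, load steps for static trials; each phase then
   contributes equal-length central windows (`n_phase` = minimum duration
   among its repetitions).
3. **Stereotypical ridges** — centred meshes are averaged node-wise over
   all ridges and frames of a phase.
4. **Strain** — for every facet, the affine map between phase-averaged
   triangles gives the displacement gradient and the Green–Lagrange tensor

   ε_xx = ∂u/∂x + ½[(∂u/∂x)² + (∂v/∂x)²]
   ε_yy = ∂v/∂y + ½[(∂u/∂y)² + (∂v/∂y)²]
   ε_xy = ½(∂u/∂y + ∂v/∂x) + ½(∂u/∂x·∂u/∂y + ∂v/∂x·∂v/∂y)

   with principal strains e1 ≥ e2, compressive-axis angle θ relative to
   vertical, area change e_a = (e1+e2)/2 and maximum shear
   e_s = (e1−e2)/2.
5. **Statistics** — paired Wilcoxon (exact for ≤ 15 pairs), two-sample KS,
   Bonferroni correction, 22.5° cardinal/diagonal angle classification and
   axial circular spread.

A synthetic-trial generator (`simulate_flat_trial()`,
`simulate_feature_trial()`, `simulate_static_trial()`) reproduces the
study protocols with analytic ground truth — landmark trajectories, true
phase segments, closed-form strains — so every stage is testable without
imaging data, and `render_oct_frame()` produces speckled two-band OCT-like
frames for the preprocessing chain (`equalize_histogram()`,
`gamma_transform()`, `bilateral_filter()`).

## Worked example

Simulate a flat-plate sliding trial (4 transits per direction, 7.6 mm at
0.8 mm/s, 10 Hz) and run the full analysis:

```r
library(ridgestrain)

bundle <- simulate_flat_trial(seed = 1)
res <- run_flat_analysis(bundle)
res
#> Ridge deformation analysis (flat protocol)
#>   16 phase segments, n_phase: 53/53/42/42
#>   maximum shear strain, stick-to-slip vs reversal:
#>             layer mean_es_stick_to_slip mean_es_reversal statistic       p
#>   stratum_corneum                0.0503             0.01        36 0.00781
#>  viable_epidermis                0.0503             0.01        36 0.00781
```

The classifier found the 16 stick/slip segments; maximum shear strain is
five-fold larger at stick-to-slip transitions (0.050) than at movement
reversals (0.010), significant per layer (exact paired Wilcoxon over
facet × direction pairs, p = 0.0078). Reversals swap the tension and
compression axes instead:

```r
aggregate(delta_deg ~ into, res$angle_changes, mean)
#>       into delta_deg
#> 1  to_slip         0
#> 2 to_stick        90
```

Static loading shows the front-loaded flattening of the ridge and the
larger compression of the viable epidermis:

```r
run_static_analysis(simulate_static_trial(seed = 1))
#> Ridge deformation analysis (static protocol)
#>   8 load steps, 0 N reference
#>  load_n            layer mean_e1 mean_e2 mean_e_a
#>     0.5  stratum_corneum  0.0587 -0.0698 -0.00555
#>     0.5 viable_epidermis  0.0266 -0.1097 -0.04154
#>     ...
#>     3.5  stratum_corneum  0.0968 -0.1062 -0.00471
#>     3.5 viable_epidermis  0.0433 -0.1638 -0.06027
```

By 0.5 N the VE already carries two-thirds of its full-load compression
(|e2| = 0.11 of 0.16); the SC compresses much less throughout.

`run_feature_analysis()` does the same for edge/groove trials (strains
relative to the initial full-slip phase, SC-vs-VE comparisons per phase),
and `write_analysis()` writes the per-facet strain CSV plus a JSON run
manifest. A thin command-line front end is installed at
`inst/cli/ridgestrain` (`simulate`, `preprocess`, `phases`, `strain`,
`report` subcommands).

See the methods vignette (`vignettes/ridge-strain-methods.Rmd`) for the
model conventions, thresholds, generator design and limitations.

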