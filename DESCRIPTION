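Package: ridgestrain
Title: Sub-Surface Strain Analysis of Fingerprint Ridges from Tracked OCT Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how individual fingerprint ridges deform
    below the skin surface during tactile interactions. Starting from tables
    of landmarks tracked in optical coherence tomography (OCT) video of the
    fingerpad, the package builds per-ridge triangular meshes spanning the
    stratum corneum and viable epidermis, segments trials into movement
    phases (stick/slip for a flat plate, feature-transit phases for edge and
    groove plates, load steps for static indentation), averages centered
    meshes into stereotypical per-phase ridges, and computes per-facet
    Green-Lagrange strain tensors with principal-strain decompositions,
    area-change and maximum-shear summaries, principal-angle classification
    and axial circular statistics. A synthetic-trial generator produces
    ground-truth ridge geometries, deformation fields, landmark trajectories
    and speckled OCT-like images for all three stimulation protocols, so the
    whole pipeline can be exercised and validated without access to imaging
    data. Also included are the OCT frame preprocessing chain (histogram
    equalization, gamma transformation, bilateral filter) and the
    non-parametric statistical comparisons used in the analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
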