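# Analytic deformation fields applied to ridge meshes. These serve as ground
# truth for the strain pipeline: every field is (piecewise) affine, so its
# deformation gradient F is known in closed form per facet and the exact
# Green-Lagrange tensor E = 0.5 (F'F - I) can be attached to the deformed
# mesh without going through the displacement-gradient estimator under test.

#' Specify an analytic deformation field
#'
#' @param kind One of `"translation"`, `"rotation"`, `"uniform_stretch"`,
#'   `"horizontal_shear"`, `"vertical_shear"`, `"flank_opposed_shear"`,
#'   `"composite"`.
#' @param ... Parameters of the field: `shift` (length-2, mm) for translation;
#'   `phi_deg` for rotation about the mesh centroid; `alpha` (length 1 or 2,
#'   per-axis engineering stretch factors) for uniform_stretch; `gamma` for the
#'   shear kinds (horizontal: u = gamma * (y - cy); vertical: v = gamma *
#'   (x - cx); flank-opposed: v = gamma * |x - x_crest|, so the two flanks
#'   tilt vertically in opposite senses); `specs` (ordered list of
#'   deformation_spec) for composite.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(kind, ...) {
  kinds <- c("translation", "rotation", "uniform_stretch", "horizontal_shear",
             "vertical_shear", "flank_opposed_shear", "composite")
  if (!kind %in% kinds)
    stop("unknown deformation kind: ", kind, call. = FALSE)
  p <- list(...)
  need <- switch(kind,
    translation = "shift", rotation = "phi_deg", uniform_stretch = "alpha",
    horizontal_shear = "gamma", vertical_shear = "gamma",
    flank_opposed_shear = "gamma", composite = "specs")
  if (!need %in% names(p))
    stop("deformation '", kind, "' requires parameter '", need, "'",
         call. = FALSE)
  if (kind == "composite" &&
      !all(vapply(p$specs, inherits, logical(1), "deformation_spec")))
    stop("composite 'specs' must be a list of deformation_spec",
         call. = FALSE)
  if (kind == "uniform_stretch" && length(p$alpha) == 1)
    p$alpha <- c(p$alpha, p$alpha)
  structure(list(kind = kind, params = p), class = "deformation_spec")
}

# Displacement of arbitrary points under one (non-composite) stage.
# `center` and `crest_x` freeze the field's reference frame.
stage_map_points <- function(pts, spec, center, crest_x) {
  p <- spec$params
  switch(spec$kind,
    translation = sweep(pts, 2, p$shift, "+"),
    rotation = {
      a <- p$phi_deg * pi / 180
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      sweep(sweep(pts, 2, center, "-") %*% t(R), 2, center, "+")
    },
    uniform_stretch = {
      d <- sweep(pts, 2, center, "-")
      sweep(cbind(d[, 1] * (1 + p$alpha[1]), d[, 2] * (1 + p$alpha[2])),
            2, center, "+")
    },
    horizontal_shear = cbind(pts[, 1] + p$gamma * (pts[, 2] - center[2]),
                             pts[, 2]),
    vertical_shear   = cbind(pts[, 1],
                             pts[, 2] + p$gamma * (pts[, 1] - center[1])),
    flank_opposed_shear = cbind(pts[, 1],
                                pts[, 2] + p$gamma * abs(pts[, 1] - crest_x)),
    stop("composite handled by caller"))
}

# Deformation gradient F of one stage at a point (side only matters for the
# flank-opposed field, which is affine on each side of the crest).
stage_gradient <- function(spec, at_x = NULL, crest_x = NULL) {
  p <- spec$params
  switch(spec$kind,
    translation = diag(2),
    rotation = {
      a <- p$phi_deg * pi / 180
      matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    },
    uniform_stretch = diag(1 + p$alpha),
    horizontal_shear = matrix(c(1, 0, p$gamma, 1), 2, 2),
    vertical_shear   = matrix(c(1, p$gamma, 0, 1), 2, 2),
    flank_opposed_shear =
      matrix(c(1, p$gamma * sign(at_x - crest_x), 0, 1), 2, 2),
    stop("composite handled by caller"))
}

green_lagrange_from_F <- function(F) {
  E <- 0.5 * (t(F) %*% F - diag(2))
  c(eps_xx = E[1, 1], eps_yy = E[2, 2], eps_xy = E[1, 2])
}

#' Apply an analytic deformation to a ridge mesh
#'
#' Maps the mesh nodes through the specified displacement field and returns
#' both the deformed mesh and the exact per-facet Green-Lagrange strains of
#' the field, computed in closed form from its deformation gradient (not via
#' the strain-estimation pipeline). Composite specs are applied in order;
#' rotation and stretch act about the centroid of their stage-input mesh, the
#' flank-opposed shear about the crest column of its stage input.
#'
#' @param mesh A `ridge_mesh`.
#' @param spec A [deformation_spec()].
#' @return A list with elements `mesh` (deformed `ridge_mesh`) and `strains`
#'   (data frame: facet_id, layer, flank, eps_xx, eps_yy, eps_xy).
#' @export
apply_deformation <- function(mesh, spec) {
  stopifnot(inherits(mesh, "ridge_mesh"), inherits(spec, "deformation_spec"))
  stages <- if (spec$kind == "composite") spec$params$specs else list(spec)
  nodes <- mesh$nodes
  n_f <- nrow(mesh$facets)
  Fs <- replicate(n_f, diag(2), simplify = FALSE)
  for (st in stages) {
    center <- colMeans(nodes)
    crest_x <- nodes["crest.surface", 1]
    cur <- new_ridge_mesh(nodes)
    for (k in seq_len(n_f)) {
      cx <- mean(facet_vertices(cur, k)[, 1])
      Fs[[k]] <- stage_gradient(st, at_x = cx, crest_x = crest_x) %*% Fs[[k]]
    }
    new_nodes <- stage_map_points(nodes, st, center, crest_x)
    rownames(new_nodes) <- rownames(nodes)
    nodes <- new_nodes
  }
  strains <- do.call(rbind, lapply(seq_len(n_f), function(k)
    as.data.frame(as.list(green_lagrange_from_F(Fs[[k]])))))
  out <- cbind(mesh$facets[, c("facet_id", "layer", "flank")], strains)
  rownames(out) <- NULL
  list(mesh = new_ridge_mesh(nodes), strains = out)
}

# Displacement field of a spec evaluated at arbitrary points, with the
# reference frame (centroids, crest abscissa) taken from `mesh`. Used by the
# finite-difference cross-checks of the analytic gradients.
deformation_displacement <- function(spec, pts, mesh) {
  stages <- if (spec$kind == "composite") spec$params$specs else list(spec)
  nodes <- mesh$nodes
  cur <- pts
  for (st in stages) {
    center <- colMeans(nodes)
    crest_x <- nodes["crest.surface", 1]
    cur <- stage_map_points(cur, st, center, crest_x)
    new_nodes <- stage_map_points(nodes, st, center, crest_x)
    rownames(new_nodes) <- rownames(nodes)
    nodes <- new_nodes
  }
  cur - pts
}
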