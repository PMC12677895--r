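# Per-facet Green-Lagrange strain between stereotypical meshes, principal
# decomposition, angle classification and axial circular statistics.

#' Displacement gradient of a triangle pair
#'
#' The unique affine map taking the reference triangle onto the deformed one
#' (constant-strain-triangle fit, exact for three vertices in
#' correspondence) yields the displacement gradient.
#'
#' @param ref,def 3 x 2 matrices of vertex positions (mm), rows in
#'   correspondence.
#' @return Named vector `du_dx`, `du_dy`, `dv_dx`, `dv_dy`.
#' @export
displacement_gradient <- function(ref, def) {
  ref <- as.matrix(ref); def <- as.matrix(def)
  stopifnot(all(dim(ref) == c(3, 2)), all(dim(def) == c(3, 2)))
  E <- rbind(ref[2, ] - ref[1, ], ref[3, ] - ref[1, ])
  area2 <- abs(E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1])
  if (area2 / 2 <= 1e-12)
    stop("degenerate reference triangle", call. = FALSE)
  U <- def - ref
  D <- rbind(U[2, ] - U[1, ], U[3, ] - U[1, ])
  G <- t(solve(E, D))                  # rows: (du_dx, du_dy), (dv_dx, dv_dy)
  c(du_dx = G[1, 1], du_dy = G[1, 2], dv_dx = G[2, 1], dv_dy = G[2, 2])
}

#' Green-Lagrange strain tensor from a displacement gradient
#'
#' Finite-strain components including the quadratic terms:
#' eps_xx = du/dx + 0.5\[(du/dx)^2 + (dv/dx)^2\],
#' eps_yy = dv/dy + 0.5\[(du/dy)^2 + (dv/dy)^2\],
#' eps_xy = 0.5(du/dy + dv/dx) + 0.5(du/dx du/dy + dv/dx dv/dy).
#' Equivalent to E = 0.5 (F'F - I) with F = I + grad u; invariant under
#' rigid rotations of the deformed configuration.
#'
#' @param grad Named vector or list with `du_dx`, `du_dy`, `dv_dx`, `dv_dy`.
#' @return Named vector `eps_xx`, `eps_yy`, `eps_xy`.
#' @export
green_lagrange <- function(grad) {
  g <- as.list(grad)
  if (!all(vapply(g[c("du_dx", "du_dy", "dv_dx", "dv_dy")], is.finite,
                  logical(1))))
    stop("gradient must be finite", call. = FALSE)
  with(g, c(
    eps_xx = du_dx + 0.5 * (du_dx^2 + dv_dx^2),
    eps_yy = dv_dy + 0.5 * (du_dy^2 + dv_dy^2),
    eps_xy = 0.5 * (du_dy + dv_dx) + 0.5 * (du_dx * du_dy + dv_dx * dv_dy)))
}

wrap_axial_deg <- function(theta) {
  out <- ((theta + 90) %% 180) - 90
  ifelse(out == -90, 90, out)
}

#' Principal strains, angle, area change and maximum shear
#'
#' Eigen-decomposes the symmetric 2-D strain tensor. `e1 >= e2` are the
#' maximum tensile and compressive strains; `theta_deg` is the orientation
#' of the compressive (e2) principal axis relative to the vertical, in
#' degrees in (-90, 90], positive when tilted toward distal (+x); the angle
#' is axial (period 180 degrees). `e_a = (e1 + e2) / 2` is the linearized
#' area change and `e_s = (e1 - e2) / 2 >= 0` the maximum shear strain.
#'
#' @param eps Named vector or list with `eps_xx`, `eps_yy`, `eps_xy`
#'   (y measured downward, image convention).
#' @return Named vector `e1`, `e2`, `theta_deg`, `e_a`, `e_s`.
#' @export
principal_strains <- function(eps) {
  e <- as.list(eps)
  M <- matrix(c(e$eps_xx, e$eps_xy, e$eps_xy, e$eps_yy), 2, 2)
  if (!all(is.finite(M))) stop("strain tensor must be finite", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE)
  e1 <- ev$values[1]; e2 <- ev$values[2]
  v2 <- ev$vectors[, 2]                # compressive axis
  theta <- wrap_axial_deg(atan2(v2[1], -v2[2]) * 180 / pi)  # y-up component
  c(e1 = e1, e2 = e2, theta_deg = theta,
    e_a = (e1 + e2) / 2, e_s = (e1 - e2) / 2)
}

#' Per-facet strain between two stereotypical ridges
#'
#' Computes, for every facet of the shared topology, the displacement
#' gradient of the affine map from the reference to the deformed mesh and
#' its Green-Lagrange and principal strains. Facets whose reference area is
#' degenerate (< 1e-9 mm^2) are flagged with `NA` strains rather than
#' producing infinities.
#'
#' @param ref,def `ridge_mesh` / `stereo_ridge` objects with identical
#'   topology (reference and deformed phase).
#' @return Data frame of class `facet_strain`: facet metadata, tensor
#'   components, principal summaries, `phase_from`, `phase_to`, `n_samples`.
#' @export
strain_between_phases <- function(ref, def) {
  stopifnot(inherits(ref, "ridge_mesh"), inherits(def, "ridge_mesh"))
  if (!identical(rownames(ref$nodes), rownames(def$nodes)))
    stop("mesh topology mismatch", call. = FALSE)
  rows <- lapply(ref$facets$facet_id, function(k) {
    rv <- facet_vertices(ref, k); dv <- facet_vertices(def, k)
    if (abs(facet_signed_area(ref, k)) < 1e-9) {
      return(c(du_dx = NA_real_, du_dy = NA, dv_dx = NA, dv_dy = NA,
               eps_xx = NA, eps_yy = NA, eps_xy = NA,
               e1 = NA, e2 = NA, theta_deg = NA, e_a = NA, e_s = NA))
    }
    g <- displacement_gradient(rv, dv)
    eps <- green_lagrange(g)
    c(g, eps, principal_strains(eps))
  })
  out <- cbind(ref$facets[, c("facet_id", "layer", "flank")],
               as.data.frame(do.call(rbind, rows)))
  out$phase_from <- if (!is.null(ref$phase_label)) ref$phase_label else NA
  out$phase_to <- if (!is.null(def$phase_label)) def$phase_label else NA
  out$n_samples <- if (!is.null(def$n_samples)) def$n_samples else NA
  rownames(out) <- NULL
  class(out) <- c("facet_strain", "data.frame")
  out
}

#' Classify a principal angle as cardinal or diagonal
#'
#' An angle within 22.5 degrees of a coordinate axis (0 or +/-90: tension or
#' compression without appreciable shear) is `cardinal`; otherwise it is
#' `diagonal` (within 22.5 degrees of +/-45: horizontal shear). The 22.5
#' degree boundary itself is assigned to `cardinal`. For diagonal angles the
#' shear sign is +1 when the tilt agrees with the plate movement direction
#' and -1 otherwise; cardinal angles get shear sign 0.
#'
#' @param theta Principal angle(s), degrees in (-90, 90].
#' @param movement_direction +1 for distal plate movement, -1 for proximal.
#' @return Data frame with `bin` (`"cardinal"`/`"diagonal"`) and
#'   `shear_sign`.
#' @export
classify_angle <- function(theta, movement_direction = 1) {
  stopifnot(all(theta > -90 & theta <= 90 | is.na(theta)))
  dist_cardinal <- pmin(abs(theta), 90 - abs(theta))
  bin <- ifelse(dist_cardinal <= 22.5, "cardinal", "diagonal")
  shear <- ifelse(bin == "diagonal",
                  sign(theta) * sign(movement_direction), 0)
  data.frame(bin = bin, shear_sign = shear)
}

#' Circular standard deviation of axial data
#'
#' Standard deviation of angles with the given period (180 degrees for
#' axial data such as principal-strain orientations): the angles are mapped
#' onto the full circle by scaling with 360/period, the circular standard
#' deviation sqrt(-2 log R) of the resultant length R is computed, and the
#' result is scaled back.
#'
#' @param angles Angles in degrees.
#' @param period Period in degrees (default 180, axial).
#' @return Circular standard deviation in degrees.
#' @export
circular_std <- function(angles, period = 180) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2) stop("need at least 2 angles", call. = FALSE)
  k <- 360 / period
  a <- angles * k * pi / 180
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- min(R, 1)
  if (R <= 0) return(Inf)
  sqrt(-2 * log(R)) * 180 / pi / k
}

#' Expected deep shear strain from stick drag distance
#'
#' If the skin surface is dragged a distance d while the bone does not move,
#' tissue spanning the surface-to-bone depth h sustains an average simple
#' shear of d / h. Used to contrast the shear expected from the observed
#' stick drag distances with the much smaller shear measured in the
#' epidermis.
#'
#' @param drag_distance Surface drag distance, mm.
#' @param depth Skin-surface-to-bone distance, mm (> 0).
#' @return Dimensionless shear ratio (multiply by 100 for percent).
#' @export
expected_deep_shear <- function(drag_distance, depth) {
  if (any(depth <= 0)) stop("depth must be > 0", call. = FALSE)
  drag_distance / depth
}
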