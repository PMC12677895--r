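# Building, measuring, centering and averaging per-ridge meshes from tracked
# landmark tables.

mm_per_px <- function(pitch_um) pitch_um / 1000

check_landmark_columns <- function(tab) {
  need <- c("frame", "ridge_id", "column", "level", "x_px", "y_px")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("landmark table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(tab)
}

#' Build the triangular mesh of one ridge in one frame
#'
#' Converts the nine tracked landmarks of a single ridge-frame from pixel to
#' mm coordinates (anisotropic pitch) and assembles the fixed 8-facet
#' triangulation (see [facet_topology()]).
#'
#' @param landmarks Data frame with the 9 rows of one (frame, ridge):
#'   columns `column`, `level`, `x_px`, `y_px`.
#' @param pitch_um Pixel pitch in micrometres, `c(lateral, axial)`.
#' @return A `ridge_mesh` (coordinates in mm).
#' @export
build_ridge_mesh <- function(landmarks, pitch_um = c(4.5, 5)) {
  key <- paste(landmarks$column, landmarks$level, sep = ".")
  wanted <- ridge_node_names()
  if (anyDuplicated(key) || !setequal(key, wanted) ||
      any(!is.finite(landmarks$x_px)) || any(!is.finite(landmarks$y_px)))
    stop("incomplete ridge: need exactly the 9 named landmarks, all finite",
         call. = FALSE)
  s <- mm_per_px(pitch_um)
  nodes <- cbind(landmarks$x_px * s[1], landmarks$y_px * s[2])
  rownames(nodes) <- key
  mesh <- new_ridge_mesh(nodes[wanted, ])
  if (any(facet_areas(mesh) <= 1e-12))
    stop("degenerate mesh: facet with non-positive area", call. = FALSE)
  mesh
}

#' Ridge width at the surface
#'
#' Horizontal distance between the two valley landmarks at the surface level.
#'
#' @param mesh A `ridge_mesh`.
#' @return Width in mm.
#' @export
ridge_width <- function(mesh) {
  abs(mesh$nodes["distal_valley.surface", 1] -
      mesh$nodes["proximal_valley.surface", 1])
}

#' Mean thickness of a skin layer
#'
#' Mean over the three mesh columns of the vertical distance between the
#' layer's bounding levels.
#'
#' @param mesh A `ridge_mesh`.
#' @param layer `"stratum_corneum"` or `"viable_epidermis"`.
#' @return Thickness in mm.
#' @export
layer_thickness <- function(mesh,
                            layer = c("stratum_corneum", "viable_epidermis")) {
  layer <- match.arg(layer)
  lv <- if (layer == "stratum_corneum") c("surface", "sc_ve")
        else c("sc_ve", "ed_junction")
  mean(vapply(RIDGE_COLUMNS, function(col) {
    abs(mesh$nodes[paste(col, lv[2], sep = "."), 2] -
        mesh$nodes[paste(col, lv[1], sep = "."), 2])
  }, numeric(1)))
}

#' Center a mesh on the origin
#'
#' Subtracts the mean of the nine node coordinates, so the centered mesh has
#' node centroid exactly (0, 0) while its shape is untouched. Idempotent.
#'
#' @param mesh A `ridge_mesh` (or `stereo_ridge`).
#' @return The centered mesh, same class.
#' @export
center_mesh <- function(mesh) {
  mesh$nodes <- sweep(mesh$nodes, 2, colMeans(mesh$nodes))
  mesh
}

#' Average centered meshes into a stereotypical ridge
#'
#' Node-wise arithmetic mean of a list of (already centered) ridge meshes,
#' as used to form the phase-averaged "stereotypical" ridge.
#'
#' @param meshes Non-empty list of `ridge_mesh` objects.
#' @param phase_label Optional label recorded on the result.
#' @return A `stereo_ridge` (also a `ridge_mesh`) with fields `n_samples`
#'   and `phase_label`.
#' @export
average_meshes <- function(meshes, phase_label = NA_character_) {
  if (length(meshes) == 0) stop("no meshes to average", call. = FALSE)
  stopifnot(all(vapply(meshes, inherits, logical(1), "ridge_mesh")))
  nm <- ridge_node_names()
  acc <- Reduce(`+`, lapply(meshes, function(m) m$nodes[nm, , drop = FALSE]))
  out <- new_ridge_mesh(acc / length(meshes))
  out$n_samples <- length(meshes)
  out$phase_label <- phase_label
  class(out) <- c("stereo_ridge", class(out))
  out
}

#' @export
print.stereo_ridge <- function(x, ...) {
  cat(sprintf("Stereotypical ridge (phase: %s, n = %d samples)\n",
              x$phase_label, x$n_samples))
  NextMethod()
}

#' Stereotypical ridge directly from a landmark table
#'
#' Vectorized equivalent of build -> center -> average over all complete
#' (frame, ridge) combinations in `frames` x `ridge_ids`: each ridge-frame is
#' converted to mm, centered on its own centroid, and the centered meshes are
#' averaged node-wise (ridges and frames pooled with equal weight).
#' Incomplete ridge-frames (missing or non-finite landmarks) are dropped, not
#' imputed; the dropped count is reported via `message()`.
#'
#' @param tab Landmark table (`frame`, `ridge_id`, `column`, `level`, `x_px`,
#'   `y_px`).
#' @param frames Frames to include (default: all in `tab`).
#' @param ridge_ids Ridges to include (default: all).
#' @param pitch_um Pixel pitch, micrometres `c(lateral, axial)`.
#' @param phase_label Label recorded on the result.
#' @return A `stereo_ridge`.
#' @export
stereotypical_ridge <- function(tab, frames = NULL, ridge_ids = NULL,
                                pitch_um = c(4.5, 5),
                                phase_label = NA_character_) {
  check_landmark_columns(tab)
  if (!is.null(frames)) tab <- tab[tab$frame %in% frames, , drop = FALSE]
  if (!is.null(ridge_ids))
    tab <- tab[tab$ridge_id %in% ridge_ids, , drop = FALSE]
  if (nrow(tab) == 0) stop("no landmarks selected", call. = FALSE)
  s <- mm_per_px(pitch_um)
  node <- paste(tab$column, tab$level, sep = ".")
  key <- paste(tab$frame, tab$ridge_id, sep = "\r")
  ok_node <- node %in% ridge_node_names()
  finite <- is.finite(tab$x_px) & is.finite(tab$y_px)
  # a ridge-frame is complete iff it has each of the 9 nodes exactly once
  cnt <- table(key[ok_node & finite])
  dup <- tapply(node[ok_node & finite], key[ok_node & finite],
                function(n) anyDuplicated(n) > 0)
  complete <- names(cnt)[cnt == 9 & !dup[names(cnt)]]
  n_drop <- length(unique(key)) - length(complete)
  if (n_drop > 0)
    message(n_drop, " incomplete ridge-frame(s) dropped from averaging")
  if (length(complete) == 0)
    stop("no complete ridge-frames to average", call. = FALSE)
  keep <- key %in% complete & ok_node & finite
  tab <- tab[keep, ]; node <- node[keep]; key <- key[keep]
  x <- tab$x_px * s[1]
  y <- tab$y_px * s[2]
  xc <- x - stats::ave(x, key)
  yc <- y - stats::ave(y, key)
  nodes <- cbind(tapply(xc, node, mean), tapply(yc, node, mean))
  out <- new_ridge_mesh(nodes[ridge_node_names(), ])
  out$n_samples <- length(complete)
  out$phase_label <- phase_label
  class(out) <- c("stereo_ridge", class(out))
  out
}
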