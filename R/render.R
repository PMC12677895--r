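# Rendering of OCT-like frames from ridge meshes: two tissue bands with
# distinct mean intensities plus multiplicative speckle.

#' Image geometry and intensity specification for rendered frames
#'
#' Defaults match the OCT acquisition format: 895 x 483 px frames with a
#' 4.5 um lateral and 5 um axial pixel pitch and 256 gray levels.
#'
#' @param width,height Frame size in pixels (lateral x axial).
#' @param pitch_um Pixel pitch, um `c(lateral, axial)`.
#' @param origin_mm Physical position of pixel (1, 1), mm `c(x, y)`.
#' @param intensities Mean gray levels: `background` (above the skin),
#'   `stratum_corneum`, `viable_epidermis`, `dermis`.
#' @return An `image_spec` list.
#' @export
image_spec <- function(width = 895, height = 483,
                       pitch_um = c(4.5, 5), origin_mm = c(0, -Y_OFFSET_MM),
                       intensities = c(background = 15,
                                       stratum_corneum = 190,
                                       viable_epidermis = 110,
                                       dermis = 50)) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 pitch_um = pitch_um, origin_mm = origin_mm,
                 intensities = intensities),
            class = "image_spec")
}

# piecewise-linear interface depth y(x) through the three columns of each
# ridge, continued flat outside the meshed field
interface_depth <- function(meshes, level, x_query) {
  cols <- paste(RIDGE_COLUMNS, level, sep = ".")
  pts <- do.call(rbind, lapply(meshes, function(m) m$nodes[cols, ]))
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  pts <- pts[!duplicated(round(pts[, 1], 9)), , drop = FALSE]
  approx(pts[, 1], pts[, 2], xout = x_query, rule = 2)$y
}

#' Render an OCT-like grayscale frame from ridge meshes
#'
#' Produces an 8-bit image with distinct mean intensities for the
#' background, the stratum corneum band (surface to SC/VE border), the
#' viable epidermis band (SC/VE border to epidermis-dermis junction) and
#' the dermis below, with multiplicative log-normal speckle. Meshes
#' extending beyond the frame are clipped with a warning.
#'
#' @param meshes List of `ridge_mesh` objects (mm coordinates).
#' @param spec An [image_spec()].
#' @param speckle_sd Log-sd of the multiplicative speckle (0 disables).
#' @param seed Integer seed; a fixed seed gives a bit-identical image.
#' @return Integer matrix `height x width` with values in `[0, 255]`.
#' @export
render_oct_frame <- function(meshes, spec = image_spec(), speckle_sd = 0.25,
                             seed = NULL) {
  stopifnot(all(vapply(meshes, inherits, logical(1), "ridge_mesh")))
  s <- mm_per_px(spec$pitch_um)
  x_mm <- spec$origin_mm[1] + (seq_len(spec$width) - 1) * s[1]
  y_mm <- spec$origin_mm[2] + (seq_len(spec$height) - 1) * s[2]
  all_nodes <- do.call(rbind, lapply(meshes, `[[`, "nodes"))
  if (min(all_nodes[, 1]) < min(x_mm) || max(all_nodes[, 1]) > max(x_mm) ||
      min(all_nodes[, 2]) < min(y_mm) || max(all_nodes[, 2]) > max(y_mm))
    warning("mesh extends outside the frame; clipped")
  surf <- interface_depth(meshes, "surface", x_mm)
  scve <- interface_depth(meshes, "sc_ve", x_mm)
  edj <- interface_depth(meshes, "ed_junction", x_mm)
  ints <- spec$intensities
  img <- vapply(seq_len(spec$width), function(j) {
    band <- findInterval(y_mm, c(surf[j], scve[j], edj[j]))
    ints[c("background", "stratum_corneum", "viable_epidermis",
           "dermis")][band + 1L]
  }, numeric(spec$height))
  if (speckle_sd > 0) {
    img <- with_seed(seed,
      img * exp(matrix(rnorm(length(img), sd = speckle_sd), nrow(img)) -
                speckle_sd^2 / 2))
  }
  out <- matrix(as.integer(pmax(0, pmin(255, floor(img + 0.5)))), nrow(img))
  out
}
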