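# OCT frame pre-processing chain applied before landmark tracking:
# histogram equalization -> gamma transformation -> bilateral filter.
# Images are integer matrices in [0, 255] (rows = axial, cols = lateral).

check_gray8 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a single-channel numeric matrix", call. = FALSE)
  if (any(img < 0 | img > 255, na.rm = TRUE))
    stop("image values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Histogram equalization of an 8-bit grayscale image
#'
#' Standard cumulative-histogram look-up table: level i maps to
#' `round(255 * (cdf(i) - cdf_min) / (n - cdf_min))`, where `cdf_min` is the
#' first occupied bin's cumulative count, so the darkest occupied level maps
#' to 0 and the brightest to 255. The mapping is monotone non-decreasing. A
#' constant image is returned unchanged.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @return Equalized matrix, same shape, integer values in `[0, 255]`.
#' @export
equalize_histogram <- function(img) {
  check_gray8(img)
  iv <- as.integer(round(img))
  h <- tabulate(iv + 1L, nbins = 256L)
  occupied <- which(h > 0)
  if (length(occupied) <= 1) return(img)
  cdf <- cumsum(h)
  cdf_min <- cdf[occupied[1]]
  lut <- round(255 * (cdf - cdf_min) / (length(iv) - cdf_min))
  out <- matrix(lut[iv + 1L], nrow(img))
  storage.mode(out) <- "integer"
  out
}

#' Gamma transformation of an 8-bit grayscale image
#'
#' Per-pixel `round(255 * (I / 255)^gamma)` (round half away from zero),
#' which fixes 0 and 255 and is strictly monotone for any `gamma > 0`. The
#' tracking pipeline uses `gamma = 5` to suppress background and saturate
#' the bright tissue bands.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param gamma Exponent, > 0.
#' @return Transformed matrix.
#' @export
gamma_transform <- function(img, gamma = 5) {
  check_gray8(img)
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive number", call. = FALSE)
  v <- 255 * (img / 255)^gamma
  out <- matrix(as.integer(floor(v + 0.5)), nrow(img))   # half away from zero
  out
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is the mean of its
#' `diameter` x `diameter` neighbourhood weighted by a spatial Gaussian
#' (`sigma_space`, px) and an intensity-range Gaussian (`sigma_color`, gray
#' levels), so noise in flat regions is averaged while sharp steps are kept.
#' Borders are handled by edge replication.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param diameter Odd neighbourhood diameter, px.
#' @param sigma_color Range Gaussian sd, gray levels.
#' @param sigma_space Spatial Gaussian sd, px.
#' @return Filtered matrix (integer, `[0, 255]`).
#' @export
bilateral_filter <- function(img, diameter = 5, sigma_color = 110,
                             sigma_space = 190) {
  check_gray8(img)
  if (diameter < 1 || diameter %% 2 == 0)
    stop("diameter must be odd and >= 1", call. = FALSE)
  if (sigma_color <= 0 || sigma_space <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  r <- (diameter - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # replicate borders
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  pad <- img[ri, ci, drop = FALSE]
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (dy in -r:r) {
    for (dx in -r:r) {
      shifted <- pad[(1 + r + dy):(nr + r + dy),
                     (1 + r + dx):(nc + r + dx), drop = FALSE]
      w <- exp(-(dy^2 + dx^2) / (2 * sigma_space^2)) *
           exp(-(shifted - img)^2 / (2 * sigma_color^2))
      num <- num + w * shifted
      den <- den + w
    }
  }
  out <- matrix(as.integer(floor(num / den + 0.5)), nr)
  out
}

#' Preprocessing configuration
#'
#' @param gamma Gamma exponent (default 5).
#' @param bilateral_diameter Bilateral neighbourhood diameter, px (odd).
#' @param sigma_color Bilateral range sd, gray levels.
#' @param sigma_space Bilateral spatial sd, px.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(gamma = 5, bilateral_diameter = 5,
                              sigma_color = 110, sigma_space = 190) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (bilateral_diameter < 1 || bilateral_diameter %% 2 == 0)
    stop("bilateral_diameter must be odd and >= 1", call. = FALSE)
  if (sigma_color <= 0 || sigma_space <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  structure(list(gamma = gamma, bilateral_diameter = bilateral_diameter,
                 sigma_color = sigma_color, sigma_space = sigma_space),
            class = "preprocess_config")
}

#' Full preprocessing chain for one frame
#'
#' Applies, in order, histogram equalization, the gamma transformation and
#' the bilateral filter.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param config A [preprocess_config()].
#' @return Preprocessed matrix.
#' @export
preprocess_frame <- function(img, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  img <- equalize_histogram(img)
  img <- gamma_transform(img, config$gamma)
  bilateral_filter(img, config$bilateral_diameter, config$sigma_color,
                   config$sigma_space)
}
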