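# File interfaces: landmark CSV, trial metadata YAML, stereotypical-ridge
# JSON, and 8-bit grayscale PNG/TIFF frames.

#' Read and write landmark tables
#'
#' The landmark CSV has one row per landmark per frame with the mandatory
#' header `frame,time_s,ridge_id,column,level,x_px,y_px`;
#' `column` is one of `distal_valley`, `crest`, `proximal_valley` and
#' `level` one of `surface`, `sc_ve`, `ed_junction`.
#'
#' @param path CSV file path.
#' @return `read_landmarks()`: the landmark data frame.
#' @export
read_landmarks <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_landmark_columns(tab)
  bad_col <- setdiff(unique(tab$column), RIDGE_COLUMNS)
  bad_lev <- setdiff(unique(tab$level), RIDGE_LEVELS)
  if (length(bad_col) || length(bad_lev))
    stop("unknown column/level labels: ",
         paste(c(bad_col, bad_lev), collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_landmarks
#' @param tab Landmark data frame.
#' @export
write_landmarks <- function(tab, path) {
  check_landmark_columns(tab)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trial metadata
#'
#' Trial metadata YAML records the plate type, frame rate, pixel pitch,
#' plate kinematics (protocol constants, or a per-frame velocity CSV) and,
#' for static trials, the load steps.
#'
#' @param path YAML file path.
#' @return `read_trial_meta()`: a named list.
#' @export
read_trial_meta <- function(path) yaml::read_yaml(path)

#' @rdname read_trial_meta
#' @param meta Named list (e.g. from [trial_meta()]).
#' @export
write_trial_meta <- function(meta, path) {
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname read_trial_meta
#' @param bundle A `gt_bundle`.
#' @export
trial_meta <- function(bundle) {
  p <- bundle$protocol
  list(plate = p$plate, frame_rate_hz = p$frame_rate,
       pixel_pitch_um = as.list(setNames(bundle$pitch_um,
                                         c("lateral", "axial"))),
       plate_speed_mm_s = p$plate_speed,
       transit_distance_mm = p$transit_distance,
       n_transits_per_direction = p$n_transits_per_direction,
       feature_base_mm = p$feature_base,
       feature_height_mm = p$feature_height,
       load_steps_n = if (!is.null(bundle$loads)) p$load_steps else NULL,
       seed = bundle$seed)
}

#' Write a stereotypical ridge to JSON
#'
#' Stores the node coordinates (mm), facet labels, sample count and phase
#' label of a [stereotypical_ridge()].
#'
#' @param stereo A `stereo_ridge`.
#' @param path Output path.
#' @export
write_stereo_ridge <- function(stereo, path) {
  stopifnot(inherits(stereo, "stereo_ridge"))
  jsonlite::write_json(
    list(phase_label = stereo$phase_label, n_samples = stereo$n_samples,
         nodes = data.frame(node = rownames(stereo$nodes),
                            x_mm = stereo$nodes[, 1],
                            y_mm = stereo$nodes[, 2]),
         facets = stereo$facets),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_stereo_ridge
#' @export
read_stereo_ridge <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- cbind(obj$nodes$x_mm, obj$nodes$y_mm)
  rownames(nodes) <- obj$nodes$node
  out <- new_ridge_mesh(nodes)
  out$n_samples <- obj$n_samples
  out$phase_label <- obj$phase_label
  class(out) <- c("stereo_ridge", class(out))
  out
}

#' Read and write 8-bit grayscale frames
#'
#' Frames are integer matrices in `[0, 255]`; PNG always available, TIFF
#' when the tiff package is installed. Format is chosen from the file
#' extension.
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @return `read_frame()`: integer matrix.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(v)) == 3) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v))
}

#' @rdname read_frame
#' @param img Integer matrix in `[0, 255]`.
#' @export
write_frame <- function(img, path) {
  check_gray8(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package", call. = FALSE)
    tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}
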