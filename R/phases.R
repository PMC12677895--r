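# Per-ridge velocity traces and movement-phase segmentation.

#' Per-ridge velocity trace from a landmark table
#'
#' Frame-to-frame displacement of each of a ridge's nine tracked points,
#' scaled by the frame rate and averaged over the points. The first frame's
#' velocity is undefined and marked `NA`.
#'
#' @param tab Landmark table.
#' @param ridge_id Ridge to extract.
#' @param pitch_um Pixel pitch, um `c(lateral, axial)`.
#' @param frame_rate Frame rate, Hz.
#' @return A data frame of class `velocity_trace` with columns `frame`,
#'   `vx`, `vy` (mm/s); attribute `dt` holds the frame interval in seconds.
#' @export
compute_ridge_velocity <- function(tab, ridge_id, pitch_um = c(4.5, 5),
                                   frame_rate = 10) {
  check_landmark_columns(tab)
  tab <- tab[tab$ridge_id == ridge_id, , drop = FALSE]
  frames <- sort(unique(tab$frame))
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  if (any(diff(frames) != 1))
    stop("frames must be contiguous", call. = FALSE)
  s <- mm_per_px(pitch_um)
  node <- paste(tab$column, tab$level, sep = ".")
  ord <- order(tab$frame, node)
  tab <- tab[ord, ]
  n_pts <- length(ridge_node_names())
  if (nrow(tab) != length(frames) * n_pts)
    stop("ridge must have all 9 landmarks in every frame", call. = FALSE)
  Xm <- matrix(tab$x_px * s[1], ncol = n_pts, byrow = TRUE)
  Ym <- matrix(tab$y_px * s[2], ncol = n_pts, byrow = TRUE)
  vx <- c(NA, rowMeans(diff(Xm)) * frame_rate)
  vy <- c(NA, rowMeans(diff(Ym)) * frame_rate)
  structure(data.frame(frame = frames, vx = vx, vy = vy),
            class = c("velocity_trace", "data.frame"),
            dt = 1 / frame_rate)
}

#' Field velocity trace averaged over ridges
#'
#' Mean of the per-ridge velocity traces over all ridges in the table, as
#' used for flat-plate phase classification.
#'
#' @inheritParams compute_ridge_velocity
#' @return A `velocity_trace`.
#' @export
compute_field_velocity <- function(tab, pitch_um = c(4.5, 5),
                                   frame_rate = 10) {
  ids <- sort(unique(tab$ridge_id))
  traces <- lapply(ids, compute_ridge_velocity, tab = tab,
                   pitch_um = pitch_um, frame_rate = frame_rate)
  out <- traces[[1]]
  out$vx <- rowMeans(sapply(traces, `[[`, "vx"))
  out$vy <- rowMeans(sapply(traces, `[[`, "vy"))
  out
}

moving_average3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

transits_from_plate <- function(vx_plate) {
  if (any(vx_plate == 0))
    stop("plate velocity must be nonzero throughout the trial",
         call. = FALSE)
  r <- rle(sign(vx_plate))
  data.frame(transit = seq_along(r$lengths),
             start = cumsum(c(1, head(r$lengths, -1))),
             end = cumsum(r$lengths),
             dir = r$values)
}

#' Segment a flat-plate trial into stick and slip phases
#'
#' Within each plate transit the skin first sticks (moves with the plate)
#' and then slips (stays put while the plate slides on). The stick-to-slip
#' boundary is located at the extremum of the first derivative of the
#' smoothed ridge velocity (negative extremum for distal transits, positive
#' for proximal ones), with ties broken toward the earlier frame. Phase
#' labels combine the plate direction with stick/slip.
#'
#' @param trace A `velocity_trace` (typically the field average,
#'   [compute_field_velocity()]).
#' @param vx_plate Per-frame plate velocity, mm/s (same length as the
#'   trace); sign changes delimit transits.
#' @param smooth Width of the centered moving average applied to `vx` before
#'   differencing (frames).
#' @return Data frame of class `phase_segments`: `ridge_id` (NA: field
#'   level), `label`, `transit_index`, `frame_start`, `frame_end`; segments
#'   tile the trial.
#' @export
classify_flat_phases <- function(trace, vx_plate, smooth = 3) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (length(vx_plate) != nrow(trace))
    stop("vx_plate must have one value per frame", call. = FALSE)
  tr <- transits_from_plate(vx_plate)
  if (any(tr$end - tr$start + 1 < 4))
    stop("trace shorter than one transit", call. = FALSE)
  v <- trace$vx
  v[1] <- 0
  segs <- do.call(rbind, lapply(seq_len(nrow(tr)), function(r) {
    fr <- tr$start[r]:tr$end[r]
    # smooth within the transit so the reversal step does not bleed in
    vs <- if (smooth >= 3) moving_average3(v[fr]) else v[fr]
    d <- diff(vs)
    # stick -> slip is the sharpest drop of |vx| toward zero; smoothing
    # spreads the drop over a plateau of near-equal derivative values, whose
    # central frame is the boundary (earlier frame when the tie is even)
    drop <- -tr$dir[r] * d
    cand <- which(drop >= max(drop) - 1e-9 * max(1, abs(max(drop))))
    t_star <- fr[cand[ceiling(length(cand) / 2)]]   # last stick frame
    lab <- if (tr$dir[r] > 0) c("stick_distal", "slip_distal")
           else c("stick_proximal", "slip_proximal")
    data.frame(ridge_id = NA_integer_, label = lab, transit_index = r,
               frame_start = c(fr[1], t_star + 1L),
               frame_end = c(t_star, fr[length(fr)]),
               stringsAsFactors = FALSE)
  }))
  class(segs) <- c("phase_segments", "data.frame")
  segs
}

#' Segment a feature-plate trial into transit phases for one ridge
#'
#' Frames where the ridge moves horizontally (|vx| above the slip threshold)
#' are discarded as not fully slipping. The remaining frames of each transit
#' are labelled from the vertical velocity: `approach` while the ridge moves
#' toward the feature (skin moves down under an edge, up into a groove),
#' `withdraw` while it moves back, `under_feature` for the stationary frames
#' in between, and `full_slip_pre`/`full_slip_post` before and after.
#'
#' @param trace A per-ridge `velocity_trace`.
#' @param plate `"edge"` or `"groove"`.
#' @param vx_plate Per-frame plate velocity (delimits transits).
#' @param plate_speed Plate speed, mm/s (sets the default thresholds).
#' @param noise_floor Estimated velocity noise floor, mm/s; thresholds are
#'   `max(0.05 * plate_speed, 3 * noise_floor)`.
#' @param y_axis Direction of increasing stored y: `"down"` (image
#'   convention, default) or `"up"`. The approach/withdraw sign rules are
#'   stated in the up convention and flipped automatically for image data.
#' @return A `phase_segments` data frame (five phases per transit; a single
#'   `full_slip` segment for transits in which the ridge never moves).
#' @export
classify_feature_phases <- function(trace, plate = c("edge", "groove"),
                                    vx_plate, plate_speed = 0.8,
                                    noise_floor = 0,
                                    y_axis = c("down", "up")) {
  plate <- match.arg(plate)
  y_axis <- match.arg(y_axis)
  stopifnot(inherits(trace, "velocity_trace"))
  thr <- max(0.05 * plate_speed, 3 * noise_floor)
  tr <- transits_from_plate(vx_plate)
  # approach sign rule: groove vy > 0, edge vy < 0, in y-up terms
  approach_sign_up <- if (plate == "groove") 1 else -1
  approach_sign <- if (y_axis == "down") -approach_sign_up else approach_sign_up
  ridge_id <- attr(trace, "ridge_id") %||% NA_integer_
  vx <- trace$vx; vy <- trace$vy
  vx[1] <- 0; vy[1] <- 0
  segs <- do.call(rbind, lapply(seq_len(nrow(tr)), function(r) {
    fr <- tr$start[r]:tr$end[r]
    slipping <- abs(vx[fr]) <= thr
    moving <- abs(vy[fr]) > thr & slipping
    app <- which(moving & sign(vy[fr]) == approach_sign)
    wdr <- which(moving & sign(vy[fr]) == -approach_sign)
    if (!length(app) || !length(wdr)) {
      return(data.frame(ridge_id = ridge_id, label = "full_slip",
                        transit_index = r, frame_start = fr[1],
                        frame_end = fr[length(fr)],
                        stringsAsFactors = FALSE))
    }
    a <- range(app); w <- range(wdr)
    if (a[2] >= w[1])
      stop("approach and withdraw phases overlap; check the sign convention",
           call. = FALSE)
    data.frame(ridge_id = ridge_id,
               label = c("full_slip_pre", "approach", "under_feature",
                         "withdraw", "full_slip_post"),
               transit_index = r,
               frame_start = fr[c(1, a[1], a[2] + 1L, w[1], w[2] + 1L)],
               frame_end = fr[c(a[1] - 1L, a[2], w[1] - 1L, w[2],
                                length(fr))],
               stringsAsFactors = FALSE)
  }))
  class(segs) <- c("phase_segments", "data.frame")
  segs
}

#' Select equal-length central windows for every phase
#'
#' For each phase label, `n_phase` is the minimum duration among the label's
#' repetitions; every repetition contributes its central `n_phase` frames
#' (shifted one frame earlier when exact centering is impossible), so each
#' occurrence of a phase enters subsequent averaging with the same weight.
#'
#' @param segments A `phase_segments` data frame.
#' @return A list of class `phase_plan`: `n_phase` (named vector per label)
#'   and `windows` (the segments with `selected_start`/`selected_end`).
#' @export
select_central_frames <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("no segments", call. = FALSE)
  dur <- segments$frame_end - segments$frame_start + 1L
  if (any(dur < 1)) stop("segment with non-positive duration", call. = FALSE)
  n_phase <- vapply(split(dur, segments$label), min, numeric(1))
  np <- as.integer(unname(n_phase[segments$label]))
  off <- (dur - np) %/% 2L
  segments$selected_start <- segments$frame_start + off
  segments$selected_end <- segments$selected_start + np - 1L
  structure(list(n_phase = setNames(as.integer(n_phase), names(n_phase)),
                 windows = segments),
            class = "phase_plan")
}

#' @export
print.phase_plan <- function(x, ...) {
  cat("Phase plan: central-window selection\n")
  for (lab in names(x$n_phase))
    cat(sprintf("  %-16s n_phase = %d (%d repetition(s))\n", lab,
                x$n_phase[[lab]], sum(x$windows$label == lab)))
  invisible(x)
}

selected_frames <- function(plan, label, ridge_id = NULL) {
  w <- plan$windows
  w <- w[w$label == label, , drop = FALSE]
  if (!is.null(ridge_id)) w <- w[w$ridge_id %in% ridge_id, , drop = FALSE]
  unlist(lapply(seq_len(nrow(w)),
                function(i) w$selected_start[i]:w$selected_end[i]))
}
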