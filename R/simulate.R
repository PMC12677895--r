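# Synthetic trial generators. Each simulator lays out the unique physical
# landmarks of a ridge field (neighbouring ridges share their valley nodes),
# moves them through an analytically known kinematic field frame by frame,
# adds optional i.i.d. Gaussian tracking noise in pixel space, and emits a
# per-ridge landmark table together with ground-truth phase segments and
# the exact noise-free node configurations of every phase.

PITCH_UM_DEFAULT <- c(4.5, 5)   # um per pixel, lateral x axial
Y_OFFSET_MM <- 0.5              # depth of the valley surface in the frame

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Stimulation protocol parameters
#'
#' Describes one stimulation protocol: reciprocating transits of a flat or
#' feature plate, or a stepped static normal load. Defaults follow the study
#' conditions: 7.6 mm transits at 0.8 mm/s, four per direction, imaged at
#' 10 Hz; static loading from contact to 3.5 N in 0.5 N steps with 20 frames
#' per step; a half-circular edge (1 mm base, 0.4 mm height) or groove
#' (1 mm base, 0.3 mm depth).
#'
#' @param plate `"flat"`, `"edge"` or `"groove"`.
#' @param transit_distance Plate travel per transit, mm.
#' @param plate_speed Plate speed, mm/s.
#' @param n_transits_per_direction Transits in each direction.
#' @param frame_rate Imaging frame rate, Hz.
#' @param load_steps Static-protocol loads, N (nondecreasing).
#' @param frames_per_step Frames recorded at each static load step.
#' @param feature_base Feature base width, mm.
#' @param feature_height Feature height (edge) or depth (groove), mm;
#'   defaults to 0.4 for the edge and 0.3 for the groove.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(plate = c("flat", "edge", "groove"),
                          transit_distance = 7.6, plate_speed = 0.8,
                          n_transits_per_direction = 4, frame_rate = 10,
                          load_steps = seq(0, 3.5, by = 0.5),
                          frames_per_step = 20, feature_base = 1,
                          feature_height = NULL) {
  plate <- match.arg(plate)
  if (transit_distance <= 0 || plate_speed <= 0 || frame_rate <= 0 ||
      n_transits_per_direction < 1 || frames_per_step < 1)
    stop("speeds, distances, rates and counts must be positive",
         call. = FALSE)
  if (is.unsorted(load_steps)) stop("load_steps must be nondecreasing",
                                    call. = FALSE)
  if (is.null(feature_height))
    feature_height <- switch(plate, flat = 0, edge = 0.4, groove = 0.3)
  structure(list(plate = plate, transit_distance = transit_distance,
                 plate_speed = plate_speed,
                 n_transits_per_direction = as.integer(n_transits_per_direction),
                 frame_rate = frame_rate, load_steps = load_steps,
                 frames_per_step = as.integer(frames_per_step),
                 feature_base = feature_base,
                 feature_height = feature_height),
            class = "protocol_spec")
}

frames_per_transit <- function(protocol) {
  round(protocol$transit_distance / protocol$plate_speed *
        protocol$frame_rate)
}

# Frame-wise signed plate velocity and transit index for a reciprocating
# trial; the first transit moves in the distal (+x) direction.
plate_motion <- function(protocol) {
  fpt <- frames_per_transit(protocol)
  n_tr <- 2L * protocol$n_transits_per_direction
  dir <- rep(c(1, -1), length.out = n_tr)
  data.frame(frame = seq_len(fpt * n_tr),
             transit = rep(seq_len(n_tr), each = fpt),
             vx_plate = rep(dir, each = fpt) * protocol$plate_speed)
}

# Unique landmark grid of the ridge field: valleys 0..n shared between
# neighbours, plus one crest column per ridge, each at three levels.
unique_grid <- function(geom) {
  w <- geom$ridge_width; n <- geom$n_ridges
  lev_off <- cumsum(c(0, geom$sc_thickness, geom$ve_thickness))
  vx <- (0:n) * w
  cx <- (seq_len(n) - 0.5) * w
  x0 <- c(rep(vx, each = 3), rep(cx, each = 3))
  y0 <- c(rep(lev_off, n + 1), rep(-geom$crest_height + lev_off, n))
  is_crest <- rep(c(FALSE, TRUE), c(3 * (n + 1), 3 * n))
  level <- rep(RIDGE_LEVELS, 2 * n + 1)
  ed_level <- level == "ed_junction"
  # slot order per ridge matches ridge_node_names(): pv, crest, dv x 3 levels
  idx_valley <- function(j) (j * 3) + 1:3          # valley j = 0..n
  idx_crest  <- function(i) (3 * (n + 1)) + (i - 1) * 3 + 1:3
  map <- do.call(rbind, lapply(seq_len(n), function(i)
    c(idx_valley(i - 1), idx_crest(i), idx_valley(i))))
  list(x0 = x0, y0 = y0, is_crest = is_crest, ed_level = ed_level,
       crest_ridge = ifelse(is_crest, rep(seq_len(n), each = 3)[
         cumsum(is_crest)], NA_integer_),
       map = map, n_ridges = n,
       slot_column = rep(RIDGE_COLUMNS, each = 3),
       slot_level = rep(RIDGE_LEVELS, 3))
}

# Expand frame x unique-node coordinate matrices into a per-ridge landmark
# table (one row per landmark per frame), in pixels.
grid_to_landmarks <- function(X, Y, grid, frame_rate,
                              pitch_um = PITCH_UM_DEFAULT,
                              noise_sd_px = 0) {
  s <- mm_per_px(pitch_um)
  Xpx <- X / s[1]
  Ypx <- (Y + Y_OFFSET_MM) / s[2]
  if (noise_sd_px > 0) {
    Xpx <- Xpx + matrix(rnorm(length(Xpx), sd = noise_sd_px), nrow(Xpx))
    Ypx <- Ypx + matrix(rnorm(length(Ypx), sd = noise_sd_px), nrow(Ypx))
  }
  n_frames <- nrow(X); n <- grid$n_ridges
  slots <- as.vector(t(grid$map))               # ridge-major slot order
  x_px <- as.vector(t(Xpx[, slots]))            # frame-major row order
  y_px <- as.vector(t(Ypx[, slots]))
  data.frame(
    frame = rep(seq_len(n_frames), each = n * 9),
    time_s = rep((seq_len(n_frames) - 1) / frame_rate, each = n * 9),
    ridge_id = rep(rep(seq_len(n), each = 9), times = n_frames),
    column = rep(rep(grid$slot_column, n), times = n_frames),
    level = rep(rep(grid$slot_level, n), times = n_frames),
    x_px = x_px, y_px = y_px, stringsAsFactors = FALSE)
}

new_gt_bundle <- function(...) {
  structure(list(...), class = "gt_bundle")
}

#' @export
print.gt_bundle <- function(x, ...) {
  cat(sprintf("Synthetic %s trial: %d frames, %d ridges, %d ground-truth segments\n",
              x$protocol$plate_label %||% x$protocol$plate,
              max(x$landmarks$frame), x$geometry$n_ridges,
              nrow(x$segments)))
  cat(sprintf("  tracking noise sd: %g px, seed: %s\n",
              x$tracking_noise_sd, format(x$seed)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a flat-plate sliding trial with stick/slip kinematics
#'
#' Reciprocating transits of a flat plate: during the stick interval of each
#' transit all landmarks move with the plate (horizontal velocity equal to
#' the plate velocity), during slip they are stationary. A per-phase
#' horizontal strain state is superimposed (uniform x-stretch of the whole
#' field about its centre): sticking in direction d carries strain
#' `d * stick_tension`, slipping `d * slip_tension`, so deformation is
#' concentrated at stick-to-slip transitions and movement reversals swap the
#' tension/compression axis.
#'
#' @param geometry A [ridge_geometry_params()] object.
#' @param protocol A [protocol_spec()] with `plate = "flat"`.
#' @param stick_fraction Fraction of each transit spent sticking, in (0, 1).
#'   The default reproduces a mean stick drag distance of 3.4 mm per 7.6 mm
#'   transit.
#' @param tracking_noise_sd Isotropic landmark noise sd, px (0 disables).
#' @param seed Integer seed; fixed seed gives a bit-identical bundle.
#' @param stick_tension,slip_tension Engineering x-strain of the stick and
#'   slip states (signed by movement direction).
#' @return A `gt_bundle`: `landmarks` (per-ridge landmark table, px),
#'   `segments` (ground-truth phase segments tiling the trial), `plate_vx`
#'   (per-frame plate velocity), `truth` (exact per-label node coordinates
#'   and closed-form transition strains), plus protocol/geometry metadata.
#' @export
simulate_flat_trial <- function(geometry = ridge_geometry_params(),
                                protocol = protocol_spec("flat"),
                                stick_fraction = 3.4 / 7.6,
                                tracking_noise_sd = 0, seed = 1,
                                stick_tension = 0.04,
                                slip_tension = -0.06) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (protocol$plate != "flat") stop("protocol$plate must be 'flat'",
                                     call. = FALSE)
  if (!(stick_fraction > 0 && stick_fraction < 1))
    stop("stick_fraction must be in (0, 1)", call. = FALSE)
  grid <- unique_grid(geometry)
  pm <- plate_motion(protocol)
  fpt <- frames_per_transit(protocol)
  n_frames <- nrow(pm)
  step <- protocol$plate_speed / protocol$frame_rate
  k_stick <- max(1L, min(fpt - 1L, round(stick_fraction * fpt)))

  # ground-truth segments: stick then slip within each transit
  n_tr <- max(pm$transit)
  segs <- do.call(rbind, lapply(seq_len(n_tr), function(r) {
    a <- (r - 1L) * fpt + 1L
    dir <- pm$vx_plate[a] > 0
    lab <- if (dir) c("stick_distal", "slip_distal")
           else c("stick_proximal", "slip_proximal")
    data.frame(ridge_id = NA_integer_, label = lab, transit_index = r,
               frame_start = c(a, a + k_stick),
               frame_end = c(a + k_stick - 1L, a + fpt - 1L),
               stringsAsFactors = FALSE)
  }))

  # per-frame field translation and strain state
  in_stick <- (pm$frame - (pm$transit - 1L) * fpt) <= k_stick
  dirs <- sign(pm$vx_plate)
  move <- ifelse(in_stick & pm$frame > 1, dirs * step, 0)
  trans <- cumsum(move)
  eps_state <- ifelse(in_stick, dirs * stick_tension, dirs * slip_tension)

  xc <- mean(grid$x0)
  X <- outer(1 + eps_state, grid$x0 - xc) + xc + trans
  Y <- matrix(grid$y0, n_frames, length(grid$y0), byrow = TRUE)

  lm <- with_seed(seed,
    grid_to_landmarks(X, Y, grid, protocol$frame_rate,
                      noise_sd_px = tracking_noise_sd))

  labels <- c("stick_distal", "slip_distal", "stick_proximal", "slip_proximal")
  state_eps <- c(stick_tension, slip_tension, -stick_tension, -slip_tension)
  names(state_eps) <- labels
  transition_strain <- function(e_from, e_to) {
    f <- (1 + e_to) / (1 + e_from)
    green_lagrange_from_F(diag(c(f, 1)))
  }
  pairs <- data.frame(from = labels, to = labels[c(2, 3, 4, 1)],
                      type = c("stick_to_slip", "reversal",
                               "stick_to_slip", "reversal"),
                      direction = c("distal", "proximal",
                                    "proximal", "distal"))
  pair_strains <- cbind(pairs, t(mapply(function(f, t)
    transition_strain(state_eps[[f]], state_eps[[t]]),
    pairs$from, pairs$to)))

  phase_nodes <- lapply(state_eps, function(e)
    cbind(x = xc + (grid$x0 - xc) * (1 + e), y = grid$y0))

  new_gt_bundle(landmarks = lm, segments = segs, protocol = protocol,
                geometry = geometry, pitch_um = PITCH_UM_DEFAULT,
                plate_vx = pm$vx_plate,
                tracking_noise_sd = tracking_noise_sd, seed = seed,
                truth = list(state_eps = state_eps,
                             transition_strains = pair_strains,
                             phase_nodes = phase_nodes, grid = grid,
                             stick_frames = k_stick,
                             drag_distance_mm = k_stick * step))
}

# flat-topped vertical bump: plateau of width `base`, half-cosine ramps of
# width `ramp` on each side; total support base + 2 * ramp.
bump_profile <- function(s, base, ramp) {
  a <- abs(s)
  ifelse(a <= base / 2, 1,
  ifelse(a >= base / 2 + ramp, 0,
         0.5 * (1 + cos(pi * (a - base / 2) / ramp))))
}

#' Simulate a feature-plate (edge or groove) transit trial
#'
#' The plate slides over stationary ridges (pure slip: ridge horizontal
#' velocity is identically zero), while its embossed edge or engraved groove
#' sweeps across the field. As the feature passes over a ridge the ridge
#' moves vertically following a flat-topped bump (half-cosine ramps, total
#' support `feature_base + ridge_width`): downward for the edge, upward for
#' the groove (image y grows downward). Two deformation components are
#' superimposed while a ridge is engaged: the crest column is displaced
#' vertically relative to the valleys (`crest_shear_mm`, shearing the two
#' flanks against each other in opposite senses) and the viable epidermis
#' changes thickness at the crest (`ve_thickness_gain_mm`; positive =
#' expansion, as for the edge; negative = contraction, as for the groove).
#'
#' @inheritParams simulate_flat_trial
#' @param protocol A [protocol_spec()] with `plate` `"edge"` or `"groove"`.
#' @param crest_shear_mm Crest-relative vertical displacement while engaged,
#'   mm (down positive). Default +0.04 (edge) / -0.03 (groove).
#' @param ve_thickness_gain_mm Change of viable-epidermis thickness at the
#'   crest while engaged, mm. Default +0.025 (edge) / -0.02 (groove).
#' @param stationary_tol_mm_s Velocity below which the ground truth calls a
#'   ridge stationary when delimiting phases (matches the classifier's
#'   default slip threshold).
#' @return A `gt_bundle` with per-ridge ground-truth segments (five phases
#'   per transit per ridge) and exact engaged/released node coordinates.
#' @export
simulate_feature_trial <- function(geometry = ridge_geometry_params(),
                                   protocol = protocol_spec("edge"),
                                   tracking_noise_sd = 0, seed = 1,
                                   crest_shear_mm = NULL,
                                   ve_thickness_gain_mm = NULL,
                                   stationary_tol_mm_s = 0.04) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (!protocol$plate %in% c("edge", "groove"))
    stop("protocol$plate must be 'edge' or 'groove'", call. = FALSE)
  sgn <- if (protocol$plate == "edge") 1 else -1
  amp <- sgn * protocol$feature_height
  null_feature <- protocol$feature_height == 0
  if (is.null(crest_shear_mm))
    crest_shear_mm <- if (null_feature) 0
      else if (protocol$plate == "edge") 0.04 else -0.03
  if (is.null(ve_thickness_gain_mm))
    ve_thickness_gain_mm <- if (null_feature) 0
      else if (protocol$plate == "edge") 0.025 else -0.02

  grid <- unique_grid(geometry)
  pm <- plate_motion(protocol)
  fpt <- frames_per_transit(protocol)
  n_frames <- nrow(pm)
  step <- protocol$plate_speed / protocol$frame_rate
  move <- ifelse(pm$frame > 1, sign(pm$vx_plate) * step, 0)
  xf <- mean(grid$x0) - protocol$transit_distance / 2 + cumsum(move)

  ramp <- geometry$ridge_width / 2
  # engagement weight of each ridge: mean bump over its nine base nodes
  W <- vapply(seq_len(grid$n_ridges), function(i) {
    xs <- grid$x0[grid$map[i, ]]
    rowMeans(outer(xf, xs, function(f, x) bump_profile(x - f,
                                                       protocol$feature_base,
                                                       ramp)))
  }, numeric(n_frames))                      # n_frames x n_ridges

  B <- outer(xf, grid$x0, function(f, x) bump_profile(x - f,
                                                      protocol$feature_base,
                                                      ramp))
  Y <- matrix(grid$y0, n_frames, length(grid$y0), byrow = TRUE) + amp * B
  crest_cols <- which(grid$is_crest)
  Y[, crest_cols] <- Y[, crest_cols] +
    crest_shear_mm * W[, grid$crest_ridge[crest_cols]]
  crest_ed <- which(grid$is_crest & grid$ed_level)
  Y[, crest_ed] <- Y[, crest_ed] +
    ve_thickness_gain_mm * W[, grid$crest_ridge[crest_ed]]
  X <- matrix(grid$x0, n_frames, length(grid$x0), byrow = TRUE)

  lm <- with_seed(seed,
    grid_to_landmarks(X, Y, grid, protocol$frame_rate,
                      noise_sd_px = tracking_noise_sd))

  # ground-truth segments per ridge from its exact mean vertical motion
  k_mean <- amp + crest_shear_mm / 3 + ve_thickness_gain_mm / 9
  tol_disp <- stationary_tol_mm_s / protocol$frame_rate
  segs <- do.call(rbind, lapply(seq_len(grid$n_ridges), function(i) {
    m <- k_mean * W[, i]
    v <- c(0, diff(m))
    do.call(rbind, lapply(seq_len(max(pm$transit)), function(r) {
      fr <- which(pm$transit == r)
      moving <- abs(v[fr]) > tol_disp
      rising <- moving & (sign(v[fr]) == sign(k_mean) | k_mean == 0)
      if (!any(moving)) {
        return(data.frame(ridge_id = i, label = "full_slip",
                          transit_index = r, frame_start = fr[1],
                          frame_end = fr[length(fr)],
                          stringsAsFactors = FALSE))
      }
      app <- range(which(rising))
      wdr <- range(which(moving & !rising))
      bounds <- c(app[1], app[2] + 1L, wdr[1], wdr[2] + 1L)
      data.frame(ridge_id = i,
                 label = c("full_slip_pre", "approach", "under_feature",
                           "withdraw", "full_slip_post"),
                 transit_index = r,
                 frame_start = fr[c(1, bounds[1], bounds[2], bounds[3],
                                    bounds[4])],
                 frame_end = fr[c(bounds[1] - 1L, bounds[2] - 1L,
                                  bounds[3] - 1L, bounds[4] - 1L,
                                  length(fr))],
                 stringsAsFactors = FALSE)
    }))
  }))

  # exact released / engaged node coordinates per ridge (W = 0 / W = 1)
  engaged_nodes <- lapply(seq_len(grid$n_ridges), function(i) {
    idx <- grid$map[i, ]
    y <- grid$y0[idx] + amp
    y[grid$is_crest[idx]] <- y[grid$is_crest[idx]] + crest_shear_mm
    y[grid$is_crest[idx] & grid$ed_level[idx]] <-
      y[grid$is_crest[idx] & grid$ed_level[idx]] + ve_thickness_gain_mm
    cbind(x = grid$x0[idx], y = y)
  })
  released_nodes <- lapply(seq_len(grid$n_ridges), function(i) {
    idx <- grid$map[i, ]
    cbind(x = grid$x0[idx], y = grid$y0[idx])
  })

  new_gt_bundle(landmarks = lm, segments = segs, protocol = protocol,
                geometry = geometry, pitch_um = PITCH_UM_DEFAULT,
                plate_vx = pm$vx_plate,
                tracking_noise_sd = tracking_noise_sd, seed = seed,
                truth = list(engagement = W, feature_x = xf,
                             engaged_nodes = engaged_nodes,
                             released_nodes = released_nodes,
                             crest_shear_mm = crest_shear_mm,
                             ve_thickness_gain_mm = ve_thickness_gain_mm,
                             amplitude_mm = amp, grid = grid))
}

#' Simulate a static normal-load trial
#'
#' The load increases over the protocol's steps; at each step the crest
#' column of every ridge is depressed by a saturating function of load,
#' `depth(F) = d_max * (1 - exp(-F / F0))`, while the valley columns stay in
#' place (ridge flattening by vertical shear). The depression is shared
#' between the layers: a fraction `ve_share` is absorbed as compression of
#' the viable epidermis and the rest by the stratum corneum; the
#' epidermis-dermis junction stays anchored.
#'
#' @inheritParams simulate_flat_trial
#' @param d_max Saturation depression of the crest surface, mm.
#' @param F0 Load scale of the saturation law, N.
#' @param ve_share Fraction of the crest depression absorbed by the viable
#'   epidermis, in `[0, 1]`.
#' @return A `gt_bundle`; `loads` maps each frame to its load step and
#'   `truth$depression_mm` gives the exact crest depression per step.
#' @export
simulate_static_trial <- function(geometry = ridge_geometry_params(),
                                  protocol = protocol_spec("flat"),
                                  d_max = 0.06, F0 = 0.5, ve_share = 0.6,
                                  tracking_noise_sd = 0, seed = 1) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (length(protocol$load_steps) < 1)
    stop("protocol must provide load_steps", call. = FALSE)
  if (d_max < 0 || F0 <= 0 || ve_share < 0 || ve_share > 1)
    stop("invalid flattening parameters", call. = FALSE)
  grid <- unique_grid(geometry)
  steps <- protocol$load_steps
  fps <- protocol$frames_per_step
  n_frames <- length(steps) * fps
  load_of_frame <- rep(steps, each = fps)
  depth <- d_max * (1 - exp(-steps / F0))
  d_frame <- rep(depth, each = fps)

  Y <- matrix(grid$y0, n_frames, length(grid$y0), byrow = TRUE)
  lev <- rep(RIDGE_LEVELS, 2 * grid$n_ridges + 1)   # level of each unique node
  cs <- which(grid$is_crest & lev == "surface")
  cm <- which(grid$is_crest & lev == "sc_ve")
  Y[, cs] <- Y[, cs] + d_frame
  Y[, cm] <- Y[, cm] + d_frame * ve_share
  X <- matrix(grid$x0, n_frames, length(grid$x0), byrow = TRUE)

  lm <- with_seed(seed,
    grid_to_landmarks(X, Y, grid, protocol$frame_rate,
                      noise_sd_px = tracking_noise_sd))

  labels <- sprintf("load_%.1fN", steps)
  segs <- data.frame(ridge_id = NA_integer_, label = labels,
                     transit_index = seq_along(steps),
                     frame_start = (seq_along(steps) - 1L) * fps + 1L,
                     frame_end = seq_along(steps) * fps,
                     stringsAsFactors = FALSE)
  loads <- data.frame(frame = seq_len(n_frames), load_n = load_of_frame)

  step_nodes <- lapply(seq_along(steps), function(k) {
    y <- grid$y0
    y[cs] <- y[cs] + depth[k]
    y[cm] <- y[cm] + depth[k] * ve_share
    cbind(x = grid$x0, y = y)
  })
  names(step_nodes) <- labels

  new_gt_bundle(landmarks = lm, segments = segs, protocol = protocol,
                geometry = geometry, pitch_um = PITCH_UM_DEFAULT,
                loads = loads, tracking_noise_sd = tracking_noise_sd,
                seed = seed,
                truth = list(depression_mm = setNames(depth, labels),
                             ve_share = ve_share, step_nodes = step_nodes,
                             grid = grid))
}
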