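# End-to-end analyses per protocol plus the non-parametric statistics used
# to summarize them.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped first; if
#' every difference is zero there is no signal and the test returns p = 1
#' with a warning. At least five non-zero pairs are required. For up to 15
#' non-zero pairs the p-value is exact, computed from the full distribution
#' of the rank sum over all sign assignments (valid under tied ranks);
#' beyond that the normal approximation with continuity correction is used.
#'
#' @param a,b Equal-length paired samples.
#' @return Named vector `statistic` (V), `p`.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("samples must be paired", call. = FALSE)
  d <- (a - b)[a != b]
  if (length(d) == 0) {
    warning("all paired differences are zero; test degenerate (p = 1)")
    return(c(statistic = 0, p = 1))
  }
  n <- length(d)
  if (n < 5)
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 15) {
    V_all <- 0
    for (i in seq_len(n))                      # distribution over 2^n signs
      V_all <- c(V_all, V_all + r[i])
    p <- min(1, 2 * min(mean(V_all <= V), mean(V_all >= V)))
  } else {
    res <- suppressWarnings(
      wilcox.test(d, alternative = "two.sided", exact = FALSE,
                  correct = TRUE))
    p <- res$p.value
  }
  c(statistic = V, p = p)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for a family of `m` comparisons.
#'
#' @param p P-values.
#' @param m Family size (must be >= the number of tests).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of tests", call. = FALSE)
  pmin(1, p * m)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS statistic (maximum CDF gap) with the asymptotic p-value.
#'
#' @param a,b Non-empty samples.
#' @return Named vector `statistic` (D), `p`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  c(statistic = unname(res$statistic), p = res$p.value)
}

axial_diff_deg <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

#' Flat-plate sliding analysis
#'
#' Full pipeline for a flat-plate trial: field velocity trace -> stick/slip
#' segmentation -> equal-length central windows -> stereotypical per-phase
#' ridges -> per-facet strains between consecutive phases (cyclic
#' stick -> slip -> stick -> slip order) -> comparison of maximum shear
#' strain between stick-to-slip transitions and movement reversals (paired
#' Wilcoxon per layer, paired by facet x direction), principal-angle
#' classification, axial circular spread, and angle changes at transitions
#' by ridge flank.
#'
#' @param bundle A `gt_bundle` from [simulate_flat_trial()] (or a compatible
#'   list with `landmarks`, `plate_vx`, `protocol`, `pitch_um`).
#' @param use_truth_segments Use the bundle's ground-truth segments instead
#'   of classifying (diagnostics).
#' @return An object of class `ridge_analysis`.
#' @export
run_flat_analysis <- function(bundle, use_truth_segments = FALSE) {
  tab <- bundle$landmarks
  protocol <- bundle$protocol
  trace <- compute_field_velocity(tab, pitch_um = bundle$pitch_um,
                                  frame_rate = protocol$frame_rate)
  segments <- if (use_truth_segments) bundle$segments
              else classify_flat_phases(trace, bundle$plate_vx)
  labels_seq <- unique(segments$label)
  if (length(labels_seq) < 2)
    stop("fewer than 2 phases identified", call. = FALSE)
  plan <- select_central_frames(segments)
  stereo <- lapply(labels_seq, function(lab)
    stereotypical_ridge(tab, frames = selected_frames(plan, lab),
                        pitch_um = bundle$pitch_um, phase_label = lab))
  names(stereo) <- labels_seq

  nlab <- length(labels_seq)
  trans <- data.frame(from = labels_seq,
                      to = labels_seq[c(2:nlab, 1)],
                      stringsAsFactors = FALSE)
  trans$type <- ifelse(grepl("^stick", trans$from) &
                       grepl("^slip", trans$to), "stick_to_slip", "reversal")
  trans$direction <- ifelse(grepl("distal", trans$to), "distal", "proximal")
  strains <- do.call(rbind, lapply(seq_len(nrow(trans)), function(i) {
    st <- strain_between_phases(stereo[[trans$from[i]]],
                                stereo[[trans$to[i]]])
    st$transition <- paste(trans$from[i], trans$to[i], sep = "->")
    st$type <- trans$type[i]
    st$direction <- trans$direction[i]
    st
  }))

  # stick-to-slip vs reversal maximum shear, paired by facet x direction
  es_tests <- do.call(rbind, lapply(
    c("stratum_corneum", "viable_epidermis"), function(lay) {
      sub <- strains[strains$layer == lay, ]
      sub <- sub[order(sub$facet_id, sub$direction), ]
      a <- sub$e_s[sub$type == "stick_to_slip"]
      b <- sub$e_s[sub$type == "reversal"]
      tst <- tryCatch(paired_wilcoxon(a, b), warning = function(w)
        c(statistic = 0, p = 1))
      data.frame(layer = lay, mean_es_stick_to_slip = mean(a),
                 mean_es_reversal = mean(b),
                 statistic = tst[["statistic"]], p = tst[["p"]])
    }))

  # principal-angle bins and axial spread per transition type
  angle_summary <- do.call(rbind, lapply(
    c("stick_to_slip", "reversal"), function(ty) {
      sub <- strains[strains$type == ty & !is.na(strains$theta_deg), ]
      dirs <- ifelse(sub$direction == "distal", 1, -1)
      cls <- classify_angle(sub$theta_deg, dirs)
      data.frame(type = ty,
                 frac_cardinal = mean(cls$bin == "cardinal"),
                 frac_diagonal = mean(cls$bin == "diagonal"),
                 circ_std_deg = if (nrow(sub) >= 2)
                   circular_std(sub$theta_deg) else NA_real_)
    }))

  # angle change relative to the preceding transition, by flank
  idx_prev <- c(nrow(trans), seq_len(nrow(trans) - 1))
  angle_changes <- do.call(rbind, lapply(seq_len(nrow(trans)), function(i) {
    cur <- strains[strains$transition ==
                   paste(trans$from[i], trans$to[i], sep = "->"), ]
    prv <- strains[strains$transition ==
                   paste(trans$from[idx_prev[i]], trans$to[idx_prev[i]],
                         sep = "->"), ]
    data.frame(into = ifelse(trans$type[i] == "stick_to_slip",
                             "to_slip", "to_stick"),
               flank = cur$flank, facet_id = cur$facet_id,
               delta_deg = axial_diff_deg(cur$theta_deg, prv$theta_deg))
  }))

  structure(list(protocol = protocol, trace = trace, segments = segments,
                 plan = plan, stereo = stereo, strains = strains,
                 es_tests = es_tests, angle_summary = angle_summary,
                 angle_changes = angle_changes,
                 kind = "flat", seed = bundle$seed),
            class = "ridge_analysis")
}

#' Feature-plate (edge/groove) analysis
#'
#' Per-ridge pipeline for edge or groove trials: each ridge's trace is
#' segmented into the five transit phases, equal-length central windows are
#' selected, per-ridge stereotypical meshes are averaged per phase, and
#' strains are computed relative to the initial full-slip phase. Layer
#' comparisons (SC vs VE, per phase and measure) use paired Wilcoxon tests
#' over facet-position x ridge pairs with Bonferroni correction over the
#' phases compared.
#'
#' @param bundle A `gt_bundle` from [simulate_feature_trial()].
#' @param use_truth_segments Use ground-truth segments (diagnostics).
#' @param measures Strain summaries compared between layers.
#' @return An object of class `ridge_analysis`.
#' @export
run_feature_analysis <- function(bundle, use_truth_segments = FALSE,
                                 measures = c("e1", "e2", "e_a")) {
  tab <- bundle$landmarks
  protocol <- bundle$protocol
  if (!protocol$plate %in% c("edge", "groove"))
    stop("bundle is not a feature-plate trial", call. = FALSE)
  ids <- sort(unique(tab$ridge_id))
  phase_order <- c("full_slip_pre", "approach", "under_feature", "withdraw",
                   "full_slip_post")
  noise_floor <- if (bundle$tracking_noise_sd > 0)
    sqrt(2) * bundle$tracking_noise_sd * mm_per_px(bundle$pitch_um)[2] *
      protocol$frame_rate / 3 else 0

  per_ridge <- lapply(ids, function(r) {
    trace <- compute_ridge_velocity(tab, r, pitch_um = bundle$pitch_um,
                                    frame_rate = protocol$frame_rate)
    attr(trace, "ridge_id") <- r
    segments <- if (use_truth_segments)
      bundle$segments[bundle$segments$ridge_id == r, ]
    else classify_feature_phases(trace, protocol$plate, bundle$plate_vx,
                                 plate_speed = protocol$plate_speed,
                                 noise_floor = noise_floor)
    segs5 <- segments[segments$label %in% phase_order, , drop = FALSE]
    if (length(unique(segs5$label)) < 2)
      stop("fewer than 2 phases identified for ridge ", r, call. = FALSE)
    plan <- select_central_frames(segs5)
    stereo <- lapply(intersect(phase_order, unique(segs5$label)),
      function(lab) stereotypical_ridge(
        tab, frames = selected_frames(plan, lab), ridge_ids = r,
        pitch_um = bundle$pitch_um, phase_label = lab))
    names(stereo) <- intersect(phase_order, unique(segs5$label))
    ref <- stereo[["full_slip_pre"]]
    if (is.null(ref)) stop("no initial full-slip phase for ridge ", r,
                           call. = FALSE)
    strains <- do.call(rbind, lapply(names(stereo), function(lab) {
      st <- strain_between_phases(ref, stereo[[lab]])
      st$ridge_id <- r
      st
    }))
    list(segments = segments, plan = plan, stereo = stereo,
         strains = strains)
  })
  names(per_ridge) <- as.character(ids)
  strains <- do.call(rbind, lapply(per_ridge, `[[`, "strains"))

  # layer comparison per phase and measure, paired facet-position x ridge
  comp_phases <- setdiff(intersect(phase_order, unique(strains$phase_to)),
                         "full_slip_pre")
  layer_tests <- do.call(rbind, lapply(measures, function(ms) {
    rows <- lapply(comp_phases, function(ph) {
      sub <- strains[strains$phase_to == ph, ]
      sub <- sub[order(sub$ridge_id, sub$facet_id), ]
      a <- sub[sub$layer == "stratum_corneum", ms]
      b <- sub[sub$layer == "viable_epidermis", ms]
      tst <- tryCatch(paired_wilcoxon(a, b), warning = function(w)
        c(statistic = 0, p = 1))
      data.frame(measure = ms, phase = ph, mean_sc = mean(a),
                 mean_ve = mean(b), statistic = tst[["statistic"]],
                 p = tst[["p"]])
    })
    out <- do.call(rbind, rows)
    out$p_corrected <- bonferroni(out$p, m = length(comp_phases))
    out
  }))

  # phase-wise layer means across ridges and facets
  phase_summary <- do.call(rbind, lapply(
    intersect(phase_order, unique(strains$phase_to)), function(ph)
      do.call(rbind, lapply(c("stratum_corneum", "viable_epidermis"),
        function(lay) {
          sub <- strains[strains$phase_to == ph & strains$layer == lay, ]
          data.frame(phase = ph, layer = lay, mean_e1 = mean(sub$e1),
                     mean_e2 = mean(sub$e2), mean_e_a = mean(sub$e_a),
                     mean_e_s = mean(sub$e_s))
        }))))

  # pooled stereotypical meshes for display
  pooled <- lapply(phase_order, function(lab) {
    frames_by_ridge <- lapply(per_ridge, function(pr)
      if (lab %in% names(pr$stereo)) selected_frames(pr$plan, lab) else NULL)
    tabs <- do.call(rbind, lapply(seq_along(ids), function(i) {
      fr <- frames_by_ridge[[i]]
      if (is.null(fr)) return(NULL)
      tab[tab$ridge_id == ids[i] & tab$frame %in% fr, ]
    }))
    if (is.null(tabs) || nrow(tabs) == 0) return(NULL)
    stereotypical_ridge(tabs, pitch_um = bundle$pitch_um, phase_label = lab)
  })
  names(pooled) <- phase_order

  structure(list(protocol = protocol, per_ridge = per_ridge,
                 strains = strains, layer_tests = layer_tests,
                 phase_summary = phase_summary,
                 stereo = pooled[!vapply(pooled, is.null, logical(1))],
                 kind = protocol$plate, seed = bundle$seed),
            class = "ridge_analysis")
}

#' Static normal-load analysis
#'
#' Frames are grouped by load step; per step a stereotypical mesh is
#' averaged over all ridges and frames, and per-facet strains are computed
#' relative to the unloaded (0 N) stereotypical ridge, yielding principal
#' tensile/compressive strain and area-change curves per layer as a
#' function of load.
#'
#' @param bundle A `gt_bundle` from [simulate_static_trial()] (must contain
#'   `loads`, with a 0 N step).
#' @return An object of class `ridge_analysis`.
#' @export
run_static_analysis <- function(bundle) {
  if (is.null(bundle$loads)) stop("bundle has no load-step metadata",
                                  call. = FALSE)
  tab <- bundle$landmarks
  steps <- sort(unique(bundle$loads$load_n))
  if (steps[1] != 0) stop("missing 0 N load step", call. = FALSE)
  stereo <- lapply(steps, function(f) {
    fr <- bundle$loads$frame[bundle$loads$load_n == f]
    stereotypical_ridge(tab, frames = fr, pitch_um = bundle$pitch_um,
                        phase_label = sprintf("load_%.1fN", f))
  })
  names(stereo) <- sprintf("load_%.1fN", steps)
  ref <- stereo[[1]]
  strains <- do.call(rbind, lapply(seq_along(steps), function(i) {
    st <- strain_between_phases(ref, stereo[[i]])
    st$load_n <- steps[i]
    st
  }))
  load_curves <- do.call(rbind, lapply(steps, function(f)
    do.call(rbind, lapply(c("stratum_corneum", "viable_epidermis"),
      function(lay) {
        sub <- strains[strains$load_n == f & strains$layer == lay, ]
        data.frame(load_n = f, layer = lay, mean_e1 = mean(sub$e1),
                   mean_e2 = mean(sub$e2), mean_e_a = mean(sub$e_a))
      }))))
  structure(list(protocol = bundle$protocol, stereo = stereo,
                 strains = strains, load_curves = load_curves,
                 kind = "static", seed = bundle$seed),
            class = "ridge_analysis")
}

#' @export
print.ridge_analysis <- function(x, ...) {
  cat(sprintf("Ridge deformation analysis (%s protocol)\n", x$kind))
  if (x$kind == "flat") {
    cat(sprintf("  %d phase segments, n_phase: %s\n", nrow(x$segments),
                paste(x$plan$n_phase, collapse = "/")))
    cat("  maximum shear strain, stick-to-slip vs reversal:\n")
    print(x$es_tests, row.names = FALSE, digits = 3)
  } else if (x$kind == "static") {
    cat(sprintf("  %d load steps, 0 N reference\n", length(x$stereo)))
    print(x$load_curves, row.names = FALSE, digits = 3)
  } else {
    cat(sprintf("  %d ridges, phases vs initial full slip\n",
                length(x$per_ridge)))
    print(x$phase_summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.ridge_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$angle_summary)) {
    cat("  principal-angle summary:\n")
    print(object$angle_summary, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$layer_tests)) {
    cat("  SC vs VE comparisons (Bonferroni corrected):\n")
    print(object$layer_tests, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
plot.ridge_analysis <- function(x, ...) {
  if (x$kind == "static") {
    lc <- x$load_curves
    sc <- lc[lc$layer == "stratum_corneum", ]
    ve <- lc[lc$layer == "viable_epidermis", ]
    matplot(sc$load_n, cbind(sc$mean_e1, sc$mean_e2, ve$mean_e1, ve$mean_e2),
            type = "b", pch = 16, lty = c(1, 1, 2, 2),
            col = c("#4477AA", "#4477AA", "#CCAA44", "#CCAA44"),
            xlab = "normal load (N)", ylab = "principal strain", ...)
    legend("bottomleft", c("SC e1", "SC e2", "VE e1", "VE e2"),
           lty = c(1, 1, 2, 2), pch = 16,
           col = c("#4477AA", "#4477AA", "#CCAA44", "#CCAA44"), bty = "n")
  } else {
    labs <- names(x$stereo)
    old <- graphics::par(mfrow = c(1, length(labs)), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (lab in labs) plot(x$stereo[[lab]], main = lab)
  }
  invisible(x)
}

#' Write analysis outputs to disk
#'
#' Writes the per-facet strain table as CSV (columns: participant,
#' ridge_scope, phase_from, phase_to, layer, flank, facet_id, tensor and
#' principal components, n_samples) and a machine-readable JSON run
#' manifest (protocol, seed, phase plan, test results).
#'
#' @param x A `ridge_analysis`.
#' @param dir Output directory (created if needed).
#' @param participant Identifier recorded in the tables.
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(x, dir, participant = "synthetic") {
  stopifnot(inherits(x, "ridge_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- x$strains
  st$participant <- participant
  st$ridge_scope <- if (!is.null(st$ridge_id)) st$ridge_id else "pooled"
  if (is.null(st$phase_from)) st$phase_from <- NA
  if (is.null(st$phase_to)) st$phase_to <- NA
  cols <- c("participant", "ridge_scope", "phase_from", "phase_to", "layer",
            "flank", "facet_id", "eps_xx", "eps_yy", "eps_xy", "e1", "e2",
            "theta_deg", "e_a", "e_s", "n_samples")
  strain_path <- file.path(dir, "facet_strains.csv")
  write.csv(st[, intersect(cols, names(st))], strain_path,
            row.names = FALSE)
  manifest <- list(kind = x$kind, seed = x$seed,
                   protocol = unclass(x$protocol),
                   n_phase = as.list(x$plan$n_phase %||% list()),
                   es_tests = x$es_tests, layer_tests = x$layer_tests,
                   load_curves = x$load_curves)
  manifest_path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(c(strain_path, manifest_path))
}
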