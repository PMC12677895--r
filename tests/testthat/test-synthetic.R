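# Synthetic generators: geometry, analytic deformation fields, and the
# three trial simulators.

test_that("reference geometry reproduces the ridge dimensions", {
  meshes <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 3))
  expect_length(meshes, 3)
  for (m in meshes) {
    expect_equal(ridge_width(m), 0.47)
    expect_equal(layer_thickness(m, "stratum_corneum"), 0.38)
    expect_equal(layer_thickness(m, "viable_epidermis"), 0.12)
    # vertical spacing at the crest column
    ys <- m$nodes[paste("crest", c("surface", "sc_ve", "ed_junction"),
                        sep = "."), 2]
    expect_equal(unname(diff(ys)), c(0.38, 0.12))
    # crest elevated above the valleys (y grows downward)
    expect_lt(m$nodes["crest.surface", 2],
              m$nodes["proximal_valley.surface", 2])
    expect_true(all(ridgestrain:::facet_areas(m) > 0))
  }
  # neighbours share their valley landmark
  expect_equal(meshes[[1]]$nodes["distal_valley.surface", ],
               meshes[[2]]$nodes["proximal_valley.surface", ])
  expect_equal(meshes[[2]]$nodes["distal_valley.ed_junction", ],
               meshes[[3]]$nodes["proximal_valley.ed_junction", ])
})

test_that("flat skin (crest_height = 0) has collinear surface nodes", {
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1,
                                                     crest_height = 0))[[1]]
  ys <- m$nodes[paste(c("proximal_valley", "crest", "distal_valley"),
                      "surface", sep = "."), 2]
  expect_equal(unname(diff(ys)), c(0, 0))
})

test_that("invalid geometry parameters are rejected", {
  expect_error(ridge_geometry_params(ridge_width = -1), "lengths")
  expect_error(ridge_geometry_params(sc_thickness = 0), "lengths")
  expect_error(ridge_geometry_params(n_ridges = 0), "n_ridges")
})

test_that("apply_deformation returns closed-form strains", {
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1))[[1]]
  st <- apply_deformation(m, deformation_spec("uniform_stretch",
                                              alpha = c(0.1, 0)))$strains
  expect_equal(st$eps_xx, rep(0.105, 8))
  expect_equal(st$eps_yy, rep(0, 8))
  expect_equal(st$eps_xy, rep(0, 8))

  rot <- apply_deformation(m, deformation_spec("rotation", phi_deg = 30))
  expect_lt(max(abs(as.matrix(rot$strains[, c("eps_xx", "eps_yy",
                                              "eps_xy")]))), 1e-12)

  tra <- apply_deformation(m, deformation_spec("translation",
                                               shift = c(1, 2)))
  expect_equal(tra$mesh$nodes, sweep(m$nodes, 2, c(1, 2), "+"))
  expect_equal(max(abs(as.matrix(tra$strains[, 4:6]))), 0)

  expect_error(deformation_spec("twist", gamma = 1), "unknown")
  expect_error(deformation_spec("uniform_stretch"), "requires")
})

test_that("analytic strains match finite-difference field gradients", {
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1))[[1]]
  specs <- list(
    deformation_spec("uniform_stretch", alpha = c(0.07, -0.03)),
    deformation_spec("horizontal_shear", gamma = 0.12),
    deformation_spec("vertical_shear", gamma = -0.08),
    deformation_spec("rotation", phi_deg = 17),
    deformation_spec("flank_opposed_shear", gamma = 0.1),
    deformation_spec("composite", specs = list(
      deformation_spec("uniform_stretch", alpha = c(0.05, 0.02)),
      deformation_spec("rotation", phi_deg = -11),
      deformation_spec("translation", shift = c(0.3, -0.1)))))
  for (spec in specs) {
    res <- apply_deformation(m, spec)
    for (k in 1:8) {
      centroid <- colMeans(ridgestrain:::facet_vertices(m, k))
      G <- fd_gradient(spec, m, centroid)
      eps_fd <- green_lagrange(G)
      expect_equal(unlist(res$strains[k, c("eps_xx", "eps_yy", "eps_xy")]),
                   eps_fd, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("flat trial produces 16 tiling phases and the set drag distance", {
  b <- simulate_flat_trial(stick_fraction = 0.5, seed = 3)
  expect_equal(nrow(b$segments), 16)
  # segments tile the trial: no gaps, no overlaps
  s <- b$segments[order(b$segments$frame_start), ]
  expect_equal(s$frame_start[1], 1)
  expect_equal(s$frame_end[nrow(s)], max(b$landmarks$frame))
  expect_equal(s$frame_start[-1], head(s$frame_end, -1) + 1L)
  # labels alternate stick -> slip within each transit
  expect_true(all(s$label[c(TRUE, FALSE)] %in%
                  c("stick_distal", "stick_proximal")))
  expect_true(all(s$label[c(FALSE, TRUE)] %in%
                  c("slip_distal", "slip_proximal")))

  # mean-drag default: stick displacement within one frame step of 3.4 mm
  b34 <- simulate_flat_trial(seed = 3)
  expect_lt(abs(b34$truth$drag_distance_mm - 3.4), 0.08)
  expect_error(simulate_flat_trial(stick_fraction = 1.2), "stick_fraction")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(simulate_flat_trial(tracking_noise_sd = 2, seed = 11),
                   simulate_flat_trial(tracking_noise_sd = 2, seed = 11))
  expect_identical(
    simulate_feature_trial(tracking_noise_sd = 1.5, seed = 12),
    simulate_feature_trial(tracking_noise_sd = 1.5, seed = 12))
  expect_identical(simulate_static_trial(tracking_noise_sd = 1, seed = 13),
                   simulate_static_trial(tracking_noise_sd = 1, seed = 13))
})

test_that("feature trial yields 40 tiling phases per ridge", {
  b <- simulate_feature_trial(seed = 5)
  for (r in unique(b$segments$ridge_id)) {
    s <- b$segments[b$segments$ridge_id == r, ]
    s <- s[order(s$frame_start), ]
    expect_equal(nrow(s), 40)
    expect_equal(s$frame_start[1], 1)
    expect_equal(s$frame_end[nrow(s)], max(b$landmarks$frame))
    expect_equal(s$frame_start[-1], head(s$frame_end, -1) + 1L)
  }
  expect_error(
    simulate_feature_trial(protocol = protocol_spec("flat")), "edge")
})

test_that("engaged edge geometry shears the flanks in opposite senses", {
  b <- simulate_feature_trial(protocol = protocol_spec("edge"), seed = 5)
  eng <- b$truth$engaged_nodes[[3]]
  rel <- b$truth$released_nodes[[3]]
  disp <- eng[, "y"] - rel[, "y"]
  nm <- ridge_node_names()
  # crest displaced further down than both valleys (image y down)
  expect_gt(disp[match("crest.surface", nm)],
            disp[match("proximal_valley.surface", nm)])
  expect_gt(disp[match("crest.surface", nm)],
            disp[match("distal_valley.surface", nm)])
  # so the two flanks tilt in opposite senses relative to the crest
  st <- strain_between_phases(
    center_mesh(ridgestrain:::new_ridge_mesh(`rownames<-`(rel, nm))),
    center_mesh(ridgestrain:::new_ridge_mesh(`rownames<-`(eng, nm))))
  sc <- st[st$layer == "stratum_corneum", ]
  expect_true(all(sign(sc$theta_deg[sc$flank == "distal"]) !=
                  sign(sc$theta_deg[sc$flank == "proximal"])))
})

test_that("a zero-height feature degenerates to pure slip", {
  b <- simulate_feature_trial(
    protocol = protocol_spec("edge", feature_height = 0), seed = 6)
  expect_true(all(b$segments$label == "full_slip"))
})

test_that("static trial frames, flattening law and degenerate case", {
  b <- simulate_static_trial(seed = 9)
  expect_equal(max(b$landmarks$frame), 160)   # 8 steps x 20 frames
  expect_equal(nrow(b$segments), 8)
  d <- b$truth$depression_mm
  # saturating law: most flattening happens at initial contact
  expect_lt(d[["load_3.5N"]], 7 * d[["load_0.5N"]])
  expect_gt(d[["load_0.5N"]], 0)

  # zero flattening: every frame identical to the reference configuration
  b0 <- simulate_static_trial(d_max = 0, seed = 9)
  y_by_frame <- matrix(b0$landmarks$y_px, nrow = 160, byrow = TRUE)
  expect_equal(max(apply(y_by_frame, 2, function(z) diff(range(z)))), 0)
  x_by_frame <- matrix(b0$landmarks$x_px, nrow = 160, byrow = TRUE)
  expect_equal(max(apply(x_by_frame, 2, function(z) diff(range(z)))), 0)
})

test_that("rendered frames have the OCT format and are reproducible", {
  meshes <- generate_ridge_geometry()
  img <- render_oct_frame(meshes, seed = 21)
  expect_equal(dim(img), c(483, 895))
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(img, render_oct_frame(meshes, seed = 21))
  flat <- render_oct_frame(meshes, speckle_sd = 0)
  expect_lte(length(unique(as.vector(flat))), 4)
  big <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 12))
  expect_warning(render_oct_frame(big, speckle_sd = 0), "clipped")
})
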