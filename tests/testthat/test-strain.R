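# Strain computation: displacement gradients, Green-Lagrange tensors,
# principal decomposition, angle classification, circular statistics.

test_that("displacement gradient is the exact affine fit", {
  ref <- rbind(c(0, 0), c(1, 0), c(0, 1))
  def <- rbind(c(0, 0), c(1.1, 0), c(0, 1))
  g <- displacement_gradient(ref, def)
  expect_equal(g, c(du_dx = 0.1, du_dy = 0, dv_dx = 0, dv_dy = 0))
  expect_equal(displacement_gradient(ref, ref),
               c(du_dx = 0, du_dy = 0, dv_dx = 0, dv_dy = 0))

  # affine consistency: re-applying the fitted map reproduces the vertices
  set.seed(10)
  for (i in 1:20) {
    ref <- matrix(rnorm(6), 3, 2)
    while (abs(det(rbind(ref[2, ] - ref[1, ], ref[3, ] - ref[1, ]))) < 0.1)
      ref <- matrix(rnorm(6), 3, 2)
    def <- matrix(rnorm(6), 3, 2)
    g <- displacement_gradient(ref, def)
    G <- matrix(g, 2, 2, byrow = TRUE)
    pred <- t(G %*% t(sweep(ref, 2, ref[1, ]))) +
      matrix(def[1, ], 3, 2, byrow = TRUE) + sweep(ref, 2, ref[1, ])
    expect_equal(pred, def, tolerance = 1e-10)
  }
  degen <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(displacement_gradient(degen, degen), "degenerate")
})

test_that("Green-Lagrange strain includes the exact quadratic terms", {
  expect_equal(green_lagrange(c(du_dx = 0.1, du_dy = 0, dv_dx = 0,
                                dv_dy = 0)),
               c(eps_xx = 0.105, eps_yy = 0, eps_xy = 0))
  # rotation: gradient R - I gives exactly zero strain
  a <- 30 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  G <- R - diag(2)
  eps <- green_lagrange(c(du_dx = G[1, 1], du_dy = G[1, 2],
                          dv_dx = G[2, 1], dv_dy = G[2, 2]))
  expect_lt(max(abs(eps)), 1e-12)
  # symmetric small shear: the cross quadratic terms vanish off-diagonal
  gam <- 0.05
  eps <- green_lagrange(c(du_dx = 0, du_dy = gam, dv_dx = gam, dv_dy = 0))
  expect_equal(unname(eps["eps_xy"]), gam)
  expect_equal(unname(eps["eps_xx"]), gam^2 / 2)
  # random gradients: identical to E = 0.5 (F'F - I)
  set.seed(11)
  for (i in 1:50) {
    g <- rnorm(4, sd = 0.2)
    F <- diag(2) + matrix(g, 2, 2, byrow = TRUE)
    E <- 0.5 * (t(F) %*% F - diag(2))
    eps <- green_lagrange(c(du_dx = g[1], du_dy = g[2],
                            dv_dx = g[3], dv_dy = g[4]))
    expect_equal(unname(eps),
                 c(E[1, 1], E[2, 2], E[1, 2]), tolerance = 1e-12)
  }
  expect_error(green_lagrange(c(du_dx = NA, du_dy = 0, dv_dx = 0,
                                dv_dy = 0)), "finite")
})

test_that("principal strains match a quadratic-formula oracle", {
  p <- principal_strains(c(eps_xx = 0.105, eps_yy = 0, eps_xy = 0))
  expect_equal(unname(p[c("e1", "e2")]), c(0.105, 0))
  expect_equal(unname(p["theta_deg"]), 0)   # compressive axis vertical

  ps <- principal_strains(c(eps_xx = 0, eps_yy = 0, eps_xy = 0.05))
  expect_equal(unname(ps[c("e1", "e2")]), c(0.05, -0.05))
  expect_equal(abs(unname(ps["theta_deg"])), 45)

  set.seed(12)
  for (i in 1:1000) {
    exx <- rnorm(1, sd = 0.2); eyy <- rnorm(1, sd = 0.2)
    exy <- rnorm(1, sd = 0.2)
    p <- principal_strains(c(eps_xx = exx, eps_yy = eyy, eps_xy = exy))
    expect_equal(unname(p[c("e1", "e2")]), brute_eigs(exx, eyy, exy),
                 tolerance = 1e-10)
    expect_gte(p[["e1"]], p[["e2"]])
    expect_gte(p[["e_s"]], 0)
    expect_equal(p[["e1"]] + p[["e2"]], exx + eyy, tolerance = 1e-10)
    expect_equal(p[["e_a"]], (p[["e1"]] + p[["e2"]]) / 2)
    expect_true(p[["theta_deg"]] > -90 && p[["theta_deg"]] <= 90)
  }
})

test_that("strains are objective under rigid motion of the deformed state", {
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1))[[1]]
  def <- apply_deformation(m, deformation_spec("composite", specs = list(
    deformation_spec("uniform_stretch", alpha = c(0.08, -0.04)),
    deformation_spec("vertical_shear", gamma = 0.06))))$mesh
  st0 <- strain_between_phases(m, def)
  moved <- apply_deformation(def, deformation_spec("composite", specs = list(
    deformation_spec("rotation", phi_deg = 23),
    deformation_spec("translation", shift = c(1.2, -0.7)))))$mesh
  st1 <- strain_between_phases(m, moved)
  expect_equal(as.matrix(st1[, c("eps_xx", "eps_yy", "eps_xy")]),
               as.matrix(st0[, c("eps_xx", "eps_yy", "eps_xy")]),
               tolerance = 1e-10)
})

test_that("strain between phases recovers imposed deformations per facet", {
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1))[[1]]
  expect_equal(max(abs(as.matrix(
    strain_between_phases(m, m)[, c("eps_xx", "eps_yy", "eps_xy")]))), 0)

  stretched <- apply_deformation(m, deformation_spec("uniform_stretch",
                                                     alpha = c(0.1, 0)))$mesh
  st <- strain_between_phases(m, stretched)
  expect_equal(st$eps_xx, rep(0.105, 8), tolerance = 1e-12)

  flank <- apply_deformation(m, deformation_spec("flank_opposed_shear",
                                                 gamma = 0.1))$mesh
  stf <- strain_between_phases(m, flank)
  expect_true(all(sign(stf$theta_deg[stf$flank == "distal"]) !=
                  sign(stf$theta_deg[stf$flank == "proximal"])))

  bad <- m
  rownames(bad$nodes)[1] <- "other"
  expect_error(strain_between_phases(m, bad), "topology")
})

test_that("area change linearizes the facet scale for small strain", {
  # e_a = (e1 + e2) / 2 is the mean principal strain: for small strain it
  # approximates the per-dimension scale change sqrt(A_def / A_ref) - 1
  # (half the relative area change); the discrepancy grows with strain.
  m <- generate_ridge_geometry(ridge_geometry_params(n_ridges = 1))[[1]]
  for (al in list(c(0.04, 0), c(0, 0.04), c(0.03, 0.02), c(-0.04, 0.01))) {
    def <- apply_deformation(m, deformation_spec("uniform_stretch",
                                                 alpha = al))$mesh
    st <- strain_between_phases(m, def)
    ratio <- ridgestrain:::facet_areas(def) / ridgestrain:::facet_areas(m)
    expect_lte(max(abs(st$e_a - (sqrt(ratio) - 1))), 0.01)
  }
  # at larger strain the linearization error is visible, not hidden
  big <- apply_deformation(m, deformation_spec("uniform_stretch",
                                               alpha = c(0.3, 0)))$mesh
  stb <- strain_between_phases(m, big)
  ratio <- ridgestrain:::facet_areas(big) / ridgestrain:::facet_areas(m)
  expect_gt(max(abs(stb$e_a - (sqrt(ratio) - 1))), 0.01)
})

test_that("angle classification uses the 22.5 degree cardinal band", {
  expect_equal(classify_angle(10)$bin, "cardinal")
  expect_equal(classify_angle(80)$bin, "cardinal")
  expect_equal(classify_angle(45)$bin, "diagonal")
  expect_equal(classify_angle(-45)$bin, "diagonal")
  expect_equal(classify_angle(22.5)$bin, "cardinal")   # boundary rule
  expect_equal(classify_angle(-22.5)$bin, "cardinal")
  expect_equal(classify_angle(30, movement_direction = 1)$shear_sign, 1)
  expect_equal(classify_angle(30, movement_direction = -1)$shear_sign, -1)
  expect_equal(classify_angle(10, movement_direction = 1)$shear_sign, 0)
})

test_that("axial circular standard deviation respects the 180 deg period", {
  expect_equal(circular_std(c(30, 30, 30)), 0)
  spread_wrap <- circular_std(c(-85, 85))
  spread_same <- circular_std(c(-5, 5))
  expect_equal(spread_wrap, spread_same, tolerance = 1e-10)
  set.seed(13)
  ang <- runif(40, -90, 90)
  flip <- ang
  flip[1:17] <- flip[1:17] + 180
  expect_equal(circular_std(ang), circular_std(flip), tolerance = 1e-10)
  # brute-force doubled-angle computation
  a2 <- ang * 2 * pi / 180
  R <- sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  expect_equal(circular_std(ang), sqrt(-2 * log(R)) * 90 / pi,
               tolerance = 1e-12)
  expect_error(circular_std(10), "at least 2")
})

test_that("expected deep shear is drag over depth", {
  expect_equal(expected_deep_shear(3.4, 7.5), 0.45, tolerance = 0.01)
  expect_equal(expected_deep_shear(0.9, 10), 0.09)
  expect_equal(expected_deep_shear(6.3, 5), 1.26)
  expect_error(expected_deep_shear(1, 0), "depth")
})

test_that("pipeline strains recover imposed deformations", {
  geom <- ridge_geometry_params()
  meshes <- generate_ridge_geometry(geom)
  spec <- deformation_spec("uniform_stretch", alpha = c(0.1, 0.1))
  def <- lapply(meshes, function(m) apply_deformation(m, spec)$mesh)

  # noise-free: exact to 1e-8
  ta <- make_phase_table(meshes, frames = 1)
  tb <- make_phase_table(def, frames = 1)
  st <- strain_between_phases(stereotypical_ridge(ta, pitch_um = PX),
                              stereotypical_ridge(tb, pitch_um = PX))
  expect_lt(max(abs(st$eps_xx - 0.105), abs(st$eps_yy - 0.105),
                abs(st$eps_xy)), 1e-8)

  # 2 px tracking noise, 20-frame phase averaging: within 10% relative
  set.seed(20)
  ta <- make_phase_table(meshes, frames = 1:20, noise_sd = 2)
  tb <- make_phase_table(def, frames = 1:20, noise_sd = 2)
  st <- strain_between_phases(stereotypical_ridge(ta, pitch_um = PX),
                              stereotypical_ridge(tb, pitch_um = PX))
  expect_lt(abs(mean(st$eps_xx) - 0.105) / 0.105, 0.10)
  expect_lt(abs(mean(st$eps_yy) - 0.105) / 0.105, 0.10)
})
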