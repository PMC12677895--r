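# Shared fixtures and independent oracles, built in code at test time.

PX <- c(4.5, 5)  # um per px

# landmark table from a list of meshes, one block per frame, i.i.d. noise
# per landmark row (the general tracker-output case)
make_phase_table <- function(meshes, frames = 1, noise_sd = 0) {
  s <- PX / 1000
  do.call(rbind, lapply(frames, function(f)
    do.call(rbind, lapply(seq_along(meshes), function(i) {
      nd <- meshes[[i]]$nodes
      data.frame(frame = f, time_s = (f - 1) / 10, ridge_id = i,
                 column = sub("\\..*", "", rownames(nd)),
                 level = sub("^[^.]*\\.", "", rownames(nd)),
                 x_px = nd[, 1] / s[1] + rnorm(nrow(nd), 0, noise_sd),
                 y_px = nd[, 2] / s[2] + rnorm(nrow(nd), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))))
}

# central finite difference of a deformation field's displacement gradient
fd_gradient <- function(spec, mesh, at, h = 1e-6) {
  num <- function(dim, comp) {
    p1 <- p2 <- matrix(at, 1, 2)
    p1[dim] <- p1[dim] - h; p2[dim] <- p2[dim] + h
    u1 <- ridgestrain:::deformation_displacement(spec, p1, mesh)
    u2 <- ridgestrain:::deformation_displacement(spec, p2, mesh)
    (u2[comp] - u1[comp]) / (2 * h)
  }
  c(du_dx = num(1, 1), du_dy = num(2, 1),
    dv_dx = num(1, 2), dv_dy = num(2, 2))
}

# quadratic-formula eigenvalues of a symmetric 2x2 strain tensor
brute_eigs <- function(exx, eyy, exy) {
  tr <- exx + eyy
  disc <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  c(tr / 2 + disc, tr / 2 - disc)
}

# exact two-sided paired signed-rank p by enumerating all sign assignments
brute_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  V_obs <- sum(r[d > 0])
  p_le <- mean(V_all <= V_obs)
  p_ge <- mean(V_all >= V_obs)
  list(statistic = V_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# brute-force two-sample KS statistic: max CDF gap over pooled values
brute_ks_stat <- function(a, b) {
  x <- sort(unique(c(a, b)))
  max(abs(vapply(x, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}
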