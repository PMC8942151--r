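# MLS divergence, volume change, curvature and surface change.

test_that("MLS divergence is exact for constant and affine fields", {
  dims <- c(48, 48, 48)
  om <- digital_ball(15, n = 48)

  const <- field_from_function(dims, function(g) matrix(0.7, nrow(g), 3))
  sm0 <- mls_divergence(const, om)
  expect_lt(max(abs(sm0$strain[om & sm0$valid])), 1e-12)

  A <- matrix(c(0.05, 0.01, 0, -0.02, 0.04, 0.005, 0.01, 0, 0.03), 3, 3)
  aff <- field_from_function(dims, function(g) g %*% t(A))
  sm <- mls_divergence(aff, om)
  v <- sm$strain[om & sm$valid]
  expect_equal(sum(om & sm$valid), sum(om))  # ball interior is well conditioned
  expect_lt(max(abs(v - sum(diag(A)))), 1e-9)
  expect_error(mls_divergence(aff, array(FALSE, dims)), "empty")
})

test_that("MLS divergence matches the closed form of a radial shell field", {
  dims <- c(48, 48, 48)
  ctr <- (dims + 1) / 2
  shell <- digital_ball(18, n = 48) & !digital_ball(8, n = 48)
  u0 <- 0.4
  fld <- field_from_function(dims, function(g) {
    dx <- sweep(g, 2, ctr)
    r <- pmax(sqrt(rowSums(dx^2)), 1e-9)
    dx * (u0 / r)   # constant radial displacement: div = 2 u0 / r
  })
  sm <- mls_divergence(fld, shell)
  # away from the shell faces (3-voxel band)
  inner <- digital_ball(15, n = 48) & !digital_ball(11, n = 48) & sm$valid
  g <- as.matrix(expand.grid(1:48, 1:48, 1:48))
  r <- sqrt(rowSums(sweep(g, 2, ctr)^2))
  truth <- 2 * u0 / r
  rel <- abs(sm$strain[inner] - truth[inner]) / truth[inner]
  expect_lt(max(rel), 0.05)
})

test_that("volume change tracks the analytic phantom inflation and the label count", {
  spec <- tiny_phantom_spec(amplitude = 0.1, n_steps = 6, noise_sigma = 0)
  ph <- generate_phantom(spec)
  om <- ph$truth$omega0
  kern <- mls_kernel()
  ratios <- sapply(2:4, function(k) {
    sm <- mls_divergence(ph$truth$fields[[k]], om, kern)
    vc <- volume_change(sm, om)
    vc$V / vc$V0
  })
  w <- sapply(1:3, function(s) (1 - cos(2 * pi * s / 6)) / 2)
  expect_lt(max(abs(ratios / (1 + 0.1 * w)^3 - 1)), 0.05)

  # voxel-count oracle at the peak: warped labels vs divergence-based volume
  peak <- 4
  lab_count <- sum(omega_mask(ph$truth$labels[[peak]],
                              c("proximal", "intermediate", "terminal")))
  sm <- mls_divergence(ph$truth$fields[[peak]], om, kern)
  vc <- volume_change(sm, om)
  expect_lt(abs(vc$V - lab_count) / lab_count, 0.05)
})

test_that("zero strain means zero volume change", {
  om <- digital_ball(8)
  dims <- dim(om)
  sm <- mls_divergence(array(0, c(dims, 3)), om)
  vc <- volume_change(sm, om)
  expect_equal(vc$dv, 0)
  expect_equal(vc$V, vc$V0)
})

test_that("curvature estimates match sphere, plane and cylinder references", {
  b <- digital_ball(12, n = 40)
  cv <- mean_curvature(b)
  expect_lt(abs(mean(cv$h_boundary) / (2 / 12) - 1), 0.15)

  hs <- array(FALSE, c(40, 40, 40)); hs[, , 1:20] <- TRUE
  cvp <- mean_curvature(hs)
  expect_lt(mean(abs(cvp$h_boundary)), 0.02)

  cy <- digital_cylinder(10, 28, n = 33)
  cvc <- mean_curvature(cy)
  lateral <- cvc$valid
  lateral[, , ] <- FALSE
  lateral[, , 12:25] <- cvc$valid[, , 12:25]   # away from the caps
  expect_lt(abs(mean(cvc$h[lateral]) / (1 / 10) - 1), 0.15)
})

test_that("surface change reproduces the sphere growth law and the isotropy identity", {
  # ball R = 12 under uniform radial displacement dR
  n <- 40; R <- 12; dR <- 0.5
  b <- digital_ball(R, n = n)
  ctr <- rep((n + 1) / 2, 3)
  fld <- field_from_function(rep(n, 3), function(g) {
    dx <- sweep(g, 2, ctr)
    r <- pmax(sqrt(rowSums(dx^2)), 1e-9)
    dx * (dR / r)
  })
  cv <- mean_curvature(b)
  sc <- surface_change(fld, b, cv)
  expect_lt(abs(sc$ds_voxels / (8 * pi * R * dR) - 1), 0.1)

  # zero field: no change
  sc0 <- surface_change(array(0, c(rep(n, 3), 3)), b, cv)
  expect_equal(sc0$ds, 0)

  # isotropic phantom: S(t)/S(0) tracks (V(t)/V(0))^(2/3)
  spec <- tiny_phantom_spec(amplitude = 0.1, n_steps = 6, noise_sigma = 0)
  ph <- generate_phantom(spec)
  om <- ph$truth$omega0
  kern <- mls_kernel()
  cv2 <- mean_curvature(om)
  S0 <- surface_area(om)
  for (k in c(3, 4)) {
    sm <- mls_divergence(ph$truth$fields[[k]], om, kern)
    vc <- volume_change(sm, om)
    sc <- surface_change(ph$truth$fields[[k]], om, cv2, kern)
    expect_lt(abs(((S0 + sc$ds) / S0) / (vc$V / vc$V0)^(2 / 3) - 1), 0.05)
  }
})

test_that("summed divergence agrees with the boundary flux and is ROI-additive", {
  spec <- tiny_phantom_spec(amplitude = 0.1, n_steps = 5, noise_sigma = 0)
  ph <- generate_phantom(spec)
  om <- ph$truth$omega0
  sm <- mls_divergence(ph$truth$fields[[3]], om)
  total <- sum(sm$strain[om & sm$valid])
  flux <- boundary_flux(ph$truth$fields[[3]], om)
  expect_lt(abs(total - flux) / abs(flux), 0.05)

  # additivity over a disjoint partition
  dims <- dim(om)
  left <- om; left[33:64, , ] <- FALSE
  right <- om & !left
  s_l <- sum(sm$strain[left & sm$valid])
  s_r <- sum(sm$strain[right & sm$valid])
  expect_equal(s_l + s_r, total, tolerance = 1e-12)

  # pure inflation: non-negative mean strain at every phase
  for (k in 2:5) {
    smk <- mls_divergence(ph$truth$fields[[k]], om)
    expect_gte(mean(smk$strain[om & smk$valid]), 0)
  }
})

test_that("ROI series recover uniform and compartment strains", {
  dims <- c(48, 48, 48)
  om <- digital_ball(10, n = 48, center = c(14.5, 24.5, 24.5)) |
    digital_ball(10, n = 48, center = c(34.5, 24.5, 24.5))
  # uniform strain: u = a x with trace 0.27
  fld <- displacement_field(field_from_function(dims, function(g) 0.09 * g),
                            "lagrangian", 0, 1)
  sm <- mls_divergence(fld, om)
  rois <- list(roi_sphere(c(14.5, 24.5, 24.5), 11, "left"),
               roi_sphere(c(34.5, 24.5, 24.5), 11, "right"))
  rs <- roi_series(list(sm), omega = om, rois = rois)
  for (r in rs) {
    expect_equal(r$series$mean_strain, 0.27, tolerance = 1e-9)
    expect_equal(r$series$sd_strain, 0, tolerance = 1e-9)
  }

  # two compartments with different expansion rates about their own centres
  fld2 <- field_from_function(dims, function(g) {
    U <- matrix(0, nrow(g), 3)
    leftish <- g[, 1] < 24.5
    U[leftish, ] <- 0.05 * sweep(g[leftish, , drop = FALSE], 2, c(14.5, 24.5, 24.5))
    U[!leftish, ] <- 0.15 * sweep(g[!leftish, , drop = FALSE], 2, c(34.5, 24.5, 24.5))
    U
  })
  sm2 <- mls_divergence(fld2, om)
  rs2 <- roi_series(list(sm2), omega = om, rois = rois)
  expect_lt(abs(rs2[[1]]$series$mean_strain / 0.15 - 1), 0.1)
  expect_lt(abs(rs2[[2]]$series$mean_strain / 0.45 - 1), 0.1)

  # ROI disjoint from the segmentation is rejected by id
  expect_error(roi_series(list(sm), omega = om,
                          rois = list(roi_sphere(c(44, 44, 44), 2, "nowhere"))),
               "nowhere")
})
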