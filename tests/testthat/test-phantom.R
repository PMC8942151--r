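# Synthetic phantom generator: determinism, analytic series, displacement
# fields and their exact divergence.

test_that("identical specs give bit-identical output and zero-amplitude means identity", {
  spec <- tiny_phantom_spec(amplitude = 0.05, n_steps = 3, seed = 7)
  a <- generate_phantom(spec, with_fields = FALSE)
  b <- generate_phantom(spec, with_fields = FALSE)
  expect_identical(a$series$volumes, b$series$volumes)
  expect_identical(a$truth$labels[[1]]$labels, b$truth$labels[[1]]$labels)

  spec0 <- tiny_phantom_spec(amplitude = 0, n_steps = 3, noise_sigma = 0, seed = 7)
  p0 <- generate_phantom(spec0)
  expect_identical(p0$series$volumes[[1]], p0$series$volumes[[2]])
  expect_identical(p0$series$volumes[[1]], p0$series$volumes[[3]])
  for (f in p0$truth$fields) expect_true(all(f$u == 0))
})

test_that("isotropic analytic volume and surface series follow the scaling laws", {
  eps <- 0.08
  spec <- tiny_phantom_spec(amplitude = eps, n_steps = 6, noise_sigma = 0)
  ph <- generate_phantom(spec, with_fields = FALSE)
  w <- sapply(0:5, function(s) (1 - cos(2 * pi * s / 6)) / 2)
  expect_equal(ph$truth$V_series / ph$truth$V_series[1], (1 + eps * w)^3,
               tolerance = 1e-12)
  expect_equal(ph$truth$S_series / ph$truth$S_series[1], (1 + eps * w)^2,
               tolerance = 1e-12)
  # exact isotropy identity before voxelization
  expect_equal(ph$truth$S_series / ph$truth$S_series[1],
               (ph$truth$V_series / ph$truth$V_series[1])^(2 / 3),
               tolerance = 1e-12)
})

test_that("log-log regression of the analytic isotropic series gives n = 2/3", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 8), with_fields = FALSE)
  # drop duplicated V values (inhale/exhale symmetry) for a clean regression
  fit <- svn_fit(ph$truth$V_series, ph$truth$S_series)
  expect_equal(fit$n, 2 / 3, tolerance = 1e-10)
})

test_that("voxelized labels match analytic volume and surface closely", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3, noise_sigma = 0),
                         with_fields = FALSE)
  v_vox <- sum(ph$truth$labels[[1]]$labels == 3)
  expect_lt(abs(v_vox / ph$truth$V_series[1] - 1), 0.03)

  # surface tolerance checked on a cluster of radius >= 6 alveoli
  spec <- phantom_spec(
    grid_shape = c(64, 64, 64), voxel_size = 1,
    acinar_clusters = list(
      acinar_cluster(center = c(32, 32, 32), duct_radius = 7, duct_length = 26,
                     duct_direction = c(1, 1, 0.6),
                     alveolus_radius = 6, n_alveoli = 6, clearance = 3)),
    deformation = deformation_spec(amplitude = 0.02, n_steps = 3),
    noise_sigma = 0, seed = 1)
  ph2 <- generate_phantom(spec, with_fields = FALSE)
  s_est <- surface_area(ph2$truth$labels[[1]]$labels == 3)
  expect_lt(abs(s_est / ph2$truth$S_series[1] - 1), 0.05)
})

test_that("recruitment events add a connected component at the stated step", {
  spec <- tiny_phantom_spec("recruitment", n_steps = 6)
  k <- spec$deformation$recruitment_events[[1]][2]
  ph <- generate_phantom(spec, with_fields = FALSE)
  n_before <- attr(label_components(omega_mask(ph$truth$labels[[k]]), 26), "n")
  n_at <- attr(label_components(omega_mask(ph$truth$labels[[k + 1]]), 26), "n")
  expect_gt(n_at, n_before)
  expect_equal(ph$truth$recruited_ids, 2)
})

test_that("structures that leave the grid are rejected with the segment named", {
  expect_error(
    phantom_spec(grid_shape = c(32, 32, 32), voxel_size = 1,
                 airway_tree = list(branch_segment(c(16, 16, 2), c(0, 0, 1),
                                                   length = 40, radius = 5,
                                                   name = "runaway")),
                 deformation = deformation_spec(amplitude = 0.2, n_steps = 3)),
    "runaway")
})

test_that("analytic displacement has the stated fixed point, scaling and divergence", {
  def <- deformation_spec("isotropic", amplitude = 0.1, n_steps = 4,
                          waveform = function(f) f * 0 + ifelse(f > 0, 1, 0))
  ctr <- c(20, 20, 20)
  pts <- rbind(ctr, ctr + c(10, 0, 0))
  f <- analytic_displacement(def, pts, step = 1, center = ctr)
  expect_equal(f$u[1, ], c(0, 0, 0))
  expect_equal(f$u[2, ], c(1, 0, 0))
  expect_equal(f$div, rep(0.3, 2))
  expect_error(analytic_displacement(def, pts, step = 17, center = ctr), "step")
})

test_that("local-mode displacement matches a numerical jacobian of the warp", {
  spec <- tiny_phantom_spec("ductal_dominant", amplitude = 0.1, n_steps = 5)
  set.seed(42)
  pts <- matrix(runif(3 * 200, 10, 54), ncol = 3)
  f <- analytic_displacement(spec, pts, step = 2)
  # divergence by central differences of the displacement field
  h <- 1e-4
  div_num <- rep(0, nrow(pts))
  for (c in 1:3) {
    e <- diag(3)[c, ] * h
    up <- analytic_displacement(spec, sweep(pts, 2, -e), step = 2)$u[, c]
    dn <- analytic_displacement(spec, sweep(pts, 2, e), step = 2)$u[, c]
    div_num <- div_num + (up - dn) / (2 * h)
  }
  expect_equal(f$div, div_num, tolerance = 1e-5)
})

test_that("unknown deformation mode is rejected", {
  expect_error(deformation_spec("sideways"), "arg")
})
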