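# B-spline registration, Lagrangian composition and the error metric.

test_that("registering a volume to itself returns a negligible field", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  v <- ph$series$volumes[[1]]
  f <- register_pair(v, v, bspline_model(levels = 1, max_iter = 10))
  expect_lte(max(abs(f$u)), 0.1)
  expect_error(register_pair(v, v[1:32, , ]), "grid")
})

test_that("a known translation is recovered in the interior", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  v <- ph$series$volumes[[1]]
  vt <- v
  vt[4:64, , ] <- v[1:61, , ]   # content shifted by +3 voxels in x
  f <- register_pair(v, vt, bspline_model(levels = 2, max_iter = 30))
  interior <- array(FALSE, c(64, 64, 64)); interior[17:48, 17:48, 17:48] <- TRUE
  expect_lt(abs(mean(f$u[, , , 1][interior]) - 3), 0.5)
  expect_lt(abs(mean(f$u[, , , 2][interior])), 0.5)
  expect_lt(abs(mean(f$u[, , , 3][interior])), 0.5)
})

test_that("phantom inflation is recovered within a voxel on the segmented set", {
  spec <- tiny_phantom_spec(amplitude = 0.05, n_steps = 5)
  ph <- generate_phantom(spec)
  # register baseline to the peak-inflation phase (step 2 of 5)
  f <- register_pair(ph$series$volumes[[1]], ph$series$volumes[[3]],
                     bspline_model(spacing = 4, levels = 2, max_iter = 20),
                     from_step = 0, to_step = 2)
  om_int <- erode_mask(erode_mask(ph$truth$omega0))   # omega interior
  tru <- ph$truth$fields[[3]]$u
  err <- sqrt((f$u[, , , 1] - tru[, , , 1])^2 + (f$u[, , , 2] - tru[, , , 2])^2 +
                (f$u[, , , 3] - tru[, , , 3])^2)
  expect_lt(max(err[om_int]), 1)
  # objective decreases monotonically within every resolution level
  for (tr in attr(f, "trace"))
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
})

test_that("composition obeys the identity and translation laws", {
  dims <- c(24, 24, 24)
  zero <- displacement_field(array(0, c(dims, 3)), "pairwise", 0, 1)
  comp <- compose_lagrangian(list(zero))
  expect_identical(comp[[1]]$u, zero$u)                # single-field identity
  expect_equal(comp[[1]]$kind, "lagrangian")

  a <- displacement_field(array(rep(c(0.5, 1, -0.25), each = prod(dims)),
                                c(dims, 3)), "pairwise", 0, 1)
  b <- displacement_field(array(rep(c(1.5, -0.5, 0.75), each = prod(dims)),
                                c(dims, 3)), "pairwise", 1, 2)
  comp2 <- compose_lagrangian(list(a, b))
  inner <- comp2[[2]]$u[8:16, 8:16, 8:16, ]
  expect_equal(unique(round(as.vector(inner[, , , 1]), 10)), 2)
  expect_equal(unique(round(as.vector(inner[, , , 2]), 10)), 0.5)
  expect_equal(unique(round(as.vector(inner[, , , 3]), 10)), 0.5)
  expect_error(compose_lagrangian(list()), "empty")
})

test_that("composing analytic per-step warps matches the closed-form cumulative warp", {
  dims <- c(48, 48, 48)
  ctr <- (dims + 1) / 2
  n_steps <- 5
  amp <- 0.1
  w <- function(s) (1 - cos(2 * pi * s / n_steps)) / 2
  a <- amp * sapply(0:(n_steps - 1), w)
  pw <- list()
  g <- as.matrix(expand.grid(x = 1:48, y = 1:48, z = 1:48))
  for (k in 2:n_steps) {
    s <- (1 + a[k]) / (1 + a[k - 1])
    U <- (s - 1) * sweep(g, 2, ctr)
    pw[[k - 1]] <- displacement_field(array(c(U[, 1], U[, 2], U[, 3]), c(dims, 3)),
                                      "pairwise", k - 2, k - 1)
  }
  comp <- compose_lagrangian(pw)
  for (k in 2:n_steps) {
    U_true <- a[k] * sweep(g, 2, ctr)
    got <- matrix(comp[[k - 1]]$u, ncol = 3)
    keep <- !comp[[k - 1]]$oob
    err <- sqrt(rowSums((got - U_true)^2))[keep]
    expect_lt(max(err), 0.2)
  }
})

test_that("registration error metric is zero for identical fields and scales with offsets", {
  dims <- c(16, 16, 16)
  set.seed(4)
  u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  direct <- displacement_field(u, "lagrangian", 0, 5)
  composed <- displacement_field(u, "lagrangian", 0, 5)
  e0 <- registration_error(composed, direct)
  expect_true(all(e0$eps == 0))

  m <- max(field_magnitude(direct))
  off <- u
  off[, , , 1] <- off[, , , 1] + 0.1 * m
  e1 <- registration_error(displacement_field(off, "lagrangian", 0, 5), direct)
  expect_equal(e1$mean, 0.1, tolerance = 1e-12)

  zero <- displacement_field(array(0, c(dims, 3)), "lagrangian", 0, 5)
  expect_error(registration_error(composed, zero), "zero")
})

test_that("inverse consistency: A->B then B->A compose to a small field", {
  spec <- tiny_phantom_spec(amplitude = 0.05, n_steps = 5)
  ph <- generate_phantom(spec, with_fields = FALSE)
  A <- ph$series$volumes[[1]]; B <- ph$series$volumes[[3]]
  m <- bspline_model(levels = 1, max_iter = 20)
  fab <- register_pair(A, B, m, 0, 1)
  fba <- register_pair(B, A, m, 0, 1)
  comp <- compose_lagrangian(list(fab, displacement_field(fba$u, "pairwise", 1, 2)))
  om <- ph$truth$omega0
  expect_lt(mean(field_magnitude(comp[[2]])[om]), 0.5)
})
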