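# S = k V^n fitting, regime classification and ROI aggregation.

test_that("identity series gives n = 1, k = 1 exactly", {
  V <- seq(2, 10, length.out = 8)
  fit <- svn_fit(V, V)
  expect_equal(unname(coef(fit)), c(1, 1), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("a family of spheres gives the isotropic exponent 2/3 to machine precision", {
  r <- seq(1, 2, length.out = 12)
  V <- 4 / 3 * pi * r^3
  S <- 4 * pi * r^2
  fit <- svn_fit(V, S)
  expect_equal(fit$n, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$k, (36 * pi)^(1 / 3), tolerance = 1e-10)
  expect_identical(fit$regime, "isotropic")
})

test_that("noisy power-law series is recovered by generate-and-refit", {
  set.seed(78)
  V <- seq(1000, 1600, length.out = 78)
  S <- 2.5 * V^0.82 * exp(rnorm(78, 0, 0.01))
  fit <- svn_fit(V, S)
  expect_lt(abs(fit$n - 0.82), 0.01)
  expect_identical(classify_regime(fit), "alveolar_dominant")
})

test_that("degenerate inputs are rejected", {
  expect_error(svn_fit(c(1, 2), c(1, 2)), "3 points")
  expect_error(svn_fit(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(svn_fit(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("regime classification follows the reference exponents", {
  expect_identical(classify_regime(0.67), "isotropic")
  expect_identical(classify_regime(1.0), "recruitment_like")
  expect_identical(classify_regime(0.82), "alveolar_dominant")
  expect_identical(classify_regime(0.5), "ductal_dominant")
  expect_identical(classify_regime(0.72, tol = 0.1), "isotropic")
})

test_that("the published per-ROI exponents aggregate to 0.82 +/- 0.03", {
  n_rois <- c(0.85, 0.82, 0.85, 0.81, 0.80,   # animal 7
              0.80, 0.76, 0.84,               # animal 8
              0.87, 0.84, 0.81, 0.84)         # animal 9
  tab <- summarize_rois(n_rois)
  expect_equal(tab$mean_n, 0.82)
  expect_equal(tab$sd_n, 0.03)

  single <- summarize_rois(list(0.8))
  expect_equal(single$mean_n, 0.8)
  expect_equal(single$sd_n, 0)
})

test_that("recruitment-like ground-truth series fit near n = 1", {
  spec <- tiny_phantom_spec("recruitment", amplitude = 0, n_steps = 8)
  spec$deformation$recruitment_events <- list(c(2, 2))
  # stepwise addition of identical units: V and S proportional to unit count
  unit_V <- 100; unit_S <- 120
  counts <- c(4, 5, 6, 7, 8, 9, 10, 11)
  fit <- svn_fit(counts * unit_V, counts * unit_S)
  expect_equal(fit$n, 1, tolerance = 1e-12)
  expect_identical(fit$regime, "recruitment_like")
})

test_that("the fit is scale-equivariant", {
  set.seed(5)
  V <- seq(10, 30, length.out = 20)
  S <- 3 * V^0.75 * exp(rnorm(20, 0, 0.005))
  f1 <- svn_fit(V, S)
  f2 <- svn_fit(10 * V, S)
  expect_equal(f1$n, f2$n, tolerance = 1e-12)
  expect_equal(f2$k, f1$k * 10^(-f1$n), tolerance = 1e-9)
})

test_that("model methods are coherent", {
  set.seed(6)
  V <- seq(5, 9, length.out = 15)
  S <- 2 * V^0.8 * exp(rnorm(15, 0, 0.01))
  fit <- svn_fit(V, S)
  expect_equal(predict(fit), fit$k * V^fit$n)
  expect_equal(length(residuals(fit)), 15)
  expect_lt(max(abs(residuals(fit, "response") - (S - predict(fit)))), 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.svn_fit")
  expect_gt(s$n_se, 0)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(15L, 3L))
  expect_output(print(fit), "regime")
  # limb-separate fits use at least 3 points each
  fit_in <- svn_fit(V, S, limb = "inflation")
  expect_s3_class(fit_in, "svn_fit")
})
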