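# Otsu partitioning, erosion profiles and structure classification.

test_that("otsu threshold separates an ideal two-level image strictly between modes", {
  v <- array(rep(c(0, 1), each = 500), c(10, 10, 10))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 1)
  mask <- otsu_partition(v)
  expect_identical(as.vector(mask), as.vector(v == 0))
  expect_error(otsu_threshold(array(0.5, c(4, 4, 4))), "constant")
})

test_that("otsu threshold equals an exhaustive between-class variance sweep", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3, noise_sigma = 0.05),
                         with_fields = FALSE)
  v <- ph$series$volumes[[1]]
  thr <- otsu_threshold(v, nbins = 256)
  # brute force over all 256 bin edges
  edges <- seq(min(v), max(v), length.out = 257)
  best <- -Inf; best_thr <- NA
  for (k in 1:255) {
    lo <- v[v <= edges[k + 1]]; hi <- v[v > edges[k + 1]]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_thr <- edges[k + 1] }
  }
  # same histogram bin (the sweep uses exact means, so allow one bin width)
  expect_lt(abs(thr - best_thr), 2 * diff(edges[1:2]))
})

test_that("phantom air mask is recovered accurately under noise", {
  spec <- phantom_spec(
    grid_shape = c(64, 64, 64), voxel_size = 1,
    airway_tree = list(branch_segment(c(18, 18, 8), c(0, 0, 1), 48, 10,
                                      name = "bronchus")),
    acinar_clusters = list(
      acinar_cluster(center = c(40, 40, 32), duct_radius = 6, duct_length = 30,
                     alveolus_radius = 6, n_alveoli = 6, clearance = 1.5)),
    deformation = deformation_spec(amplitude = 0.02, n_steps = 3),
    noise_sigma = 0.1, seed = 3)
  ph <- generate_phantom(spec, with_fields = FALSE)
  truth <- omega_mask(ph$truth$labels[[1]], c("proximal", "intermediate", "terminal"))
  air <- otsu_partition(smooth_volume(ph$series$volumes[[1]], 0.8))
  expect_gte(2 * sum(air & truth) / (sum(air) + sum(truth)), 0.98)
})

test_that("erosion profiles behave like the analytic shapes", {
  # one-voxel sheet vanishes after a single step
  sheet <- array(FALSE, c(16, 16, 16)); sheet[, , 8] <- TRUE
  expect_equal(erosion_profile(sheet)$depth, 1L)

  # a ball of radius r survives ~r steps
  for (r in c(5, 10)) {
    p <- erosion_profile(digital_ball(r))
    expect_lte(abs(p$depth - r), 1)
  }

  # slender cylinder decays linearly; equal-radius ball does not
  pc <- erosion_profile(digital_cylinder(20, 120, n = 49))
  pb <- erosion_profile(digital_ball(20))
  expect_true(pc$linear)
  expect_false(pb$linear)
  expect_true(all(diff(pc$volumes) <= 0))
})

test_that("erosion survival depth equals the distance-transform maximum", {
  set.seed(8)
  for (r in c(4, 7)) {
    m <- digital_ball(r)
    p <- erosion_profile(m)
    edt_max <- max(distance_transform(!m)$dist)
    expect_equal(p$depth, ceiling(edt_max))
  }
})

test_that("cylinder with attached alveoli classifies into proximal and terminal", {
  n <- c(56, 56, 128)
  cy <- digital_cylinder(20, 120, n = 56, pad = 4)
  truth <- array(0L, n); truth[cy] <- 1L
  m <- cy
  g <- expand.grid(x = 1:n[1], y = 1:n[2], z = 1:n[3])
  centers <- list(c(28.5 + 24.5, 28.5, 30), c(28.5 - 24.5, 28.5, 60),
                  c(28.5, 28.5 + 24.5, 90))
  for (ctr in centers) {
    b <- array((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= 25, n)
    truth[b & truth == 0L] <- 3L
    m <- m | b
  }
  seg <- classify_structures(m)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice(seg$labels == 1, truth == 1), 0.9)
  expect_gte(dice(seg$labels == 3, truth == 3), 0.9)
})

test_that("an isolated sphere is terminal and emits the no-tube warning", {
  b <- digital_ball(6)
  expect_warning(seg <- classify_structures(b), "linearity")
  expect_true(all(seg$labels[b] == 3))
})

test_that("a three-generation tree with acinar clusters classifies by generation", {
  dims <- c(96, 96, 96)
  g <- expand.grid(x = 1:96, y = 1:96, z = 1:96)
  ballm <- function(c0, r) array((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r^2, dims)
  truth <- array(0L, dims)
  gen1 <- oriented_cylinder(c(48, 48, 4), c(0, 0, 1), 52, 10, dims)
  d2a <- c(1, 1, 1) / sqrt(3); d2b <- c(-1, -1, 1) / sqrt(3)
  gen2 <- oriented_cylinder(c(48, 48, 54), d2a, 30, 7, dims) |
    oriented_cylinder(c(48, 48, 54), d2b, 30, 7, dims)
  t2a <- c(48, 48, 54) + d2a * 30; t2b <- c(48, 48, 54) + d2b * 30
  d3a <- c(1, -0.5, 0.3); d3a <- d3a / sqrt(sum(d3a^2))
  d3b <- c(-1, 0.5, 0.3); d3b <- d3b / sqrt(sum(d3b^2))
  gen3 <- oriented_cylinder(t2a, d3a, 20, 5, dims) |
    oriented_cylinder(t2b, d3b, 20, 5, dims)
  truth[gen1] <- 1L
  truth[(gen2 | gen3) & truth == 0] <- 2L
  clus <- array(FALSE, dims)
  for (i in 1:2) {
    tip <- list(t2a + d3a * 20, t2b + d3b * 20)[[i]]
    dd <- list(d3a, d3b)[[i]]
    for (k in 1:5) {
      ang <- 2 * pi * k / 5
      ctr <- tip + dd * 2 + c(8 * cos(ang), 8 * sin(ang), 4.5 * ((k %% 2) * 2 - 1))
      clus <- clus | ballm(ctr, 4)
    }
  }
  truth[clus & truth == 0] <- 3L
  seg <- classify_structures(truth > 0)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice(seg$labels == 1, truth == 1), 0.9)
  expect_gte(dice(seg$labels == 2, truth == 2), 0.9)
  expect_gte(dice(seg$labels == 3, truth == 3), 0.9)
})

test_that("classification is a partition and invariant to 90-degree rotation", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  m <- omega_mask(ph$truth$labels[[1]], c("proximal", "intermediate", "terminal"))
  seg <- classify_structures(m)
  expect_equal(sum(seg$labels > 0), sum(m))
  expect_true(all((seg$labels > 0) == m))

  rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ] # 90 degrees about z
  seg_rot <- classify_structures(rot)
  lab_rot_back <- aperm(seg_rot$labels[dim(m)[2]:1, , ], c(2, 1, 3))
  expect_identical(lab_rot_back, seg$labels)
})

test_that("vessel segmentation finds the blood-contrast tree", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  seg <- segment_volume(ph$series$volumes[[1]], kind = "vessel")
  truth <- ph$truth$labels[[1]]$labels == 4
  dice <- 2 * sum((seg$labels > 0) & truth) / (sum(seg$labels > 0) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("watershed editing splits touching spheres and validates markers", {
  n <- 40
  m <- digital_ball(8, n = 40, center = c(14.5, 20.5, 20.5)) |
    digital_ball(8, n = 40, center = c(28.5, 20.5, 20.5))
  expect_equal(attr(label_components(m, 26), "n"), 1L) # touching: one blob
  markers <- rbind(c(14, 20, 20, 1), c(29, 20, 20, 2))
  lab <- watershed_edit(m, markers)
  expect_equal(attr(lab, "n"), 2L)
  left <- lab[1:21, , ]; right <- lab[22:40, , ]
  expect_gte(mean(left[left > 0] == 1), 0.95)
  expect_gte(mean(right[right > 0] == 2), 0.95)

  # zero markers: identity partition into components
  lab0 <- watershed_edit(m, NULL)
  expect_equal(attr(lab0, "n"), 1L)
  expect_identical(lab0 > 0, m)

  # marker outside the mask is rejected with its coordinates
  expect_error(watershed_edit(m, rbind(c(2, 2, 2, 1))), "2, 2, 2")
})
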