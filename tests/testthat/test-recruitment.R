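# Skeletonization, skeleton advection and recruitment detection.

test_that("a one-voxel line is its own skeleton (thinning idempotence)", {
  m <- array(FALSE, c(32, 32, 32)); m[5:28, 16, 16] <- TRUE
  sk <- skeletonize(m)
  expect_identical(sk$mask, m)
  sk2 <- skeletonize(sk)
  expect_identical(sk2$mask, sk$mask)
  expect_error(skeletonize(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("a solid cylinder thins to a centreline near the axis", {
  cy <- digital_cylinder(8, 40, n = 25)
  sk <- skeletonize(cy)
  idx <- which(sk$mask, arr.ind = TRUE)
  mid <- idx[idx[, 3] >= 5 + 16 & idx[, 3] <= 44 - 16, , drop = FALSE]
  expect_gt(nrow(mid), 0)
  expect_lt(max(sqrt((mid[, 1] - 13)^2 + (mid[, 2] - 13)^2)), 1.5)
})

test_that("skeletonization preserves the component count of the phantom", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  om <- omega_mask(ph$truth$labels[[1]], c("proximal", "intermediate", "terminal"))
  sk <- skeletonize(om)
  expect_true(all(om[sk$mask]))
  expect_equal(attr(label_components(sk$mask, 26), "n"),
               attr(label_components(om, 26), "n"))
})

test_that("skeleton advection obeys zero and uniform-translation fields", {
  m <- array(FALSE, c(32, 32, 32)); m[5:25, 16, 16] <- TRUE
  sk <- skeleton3d(m)
  dims <- c(32, 32, 32)
  zero <- displacement_field(array(0, c(dims, 3)), "lagrangian", 0, 1)
  expect_identical(deform_skeleton(sk, zero)$mask, m)

  u <- array(0, c(dims, 3)); u[, , , 2] <- 5
  tr <- displacement_field(u, "lagrangian", 0, 1)
  moved <- deform_skeleton(sk, tr)$mask
  expect_identical(which(moved, arr.ind = TRUE)[, 2], rep(21L, 21))
})

test_that("deformed baseline skeleton stays close to the phase skeleton under pure inflation", {
  spec <- tiny_phantom_spec(amplitude = 0.05, n_steps = 5, noise_sigma = 0)
  ph <- generate_phantom(spec)
  base <- skeletonize(ph$truth$labels[[1]])
  peak <- skeletonize(ph$truth$labels[[3]])
  def <- deform_skeleton(base, ph$truth$fields[[3]])
  # the matched bulk of the deformed baseline lies within 2 voxels of the
  # phase skeleton (branch points jitter under re-thinning)
  dmap <- distance_transform(peak$mask)$dist
  expect_lte(median(dmap[def$mask]), 1.5)
  expect_lt(quantile(dmap[def$mask], 0.9), 2.0)
})

test_that("pure inflation yields no recruitment seeds", {
  spec <- tiny_phantom_spec(amplitude = 0.05, n_steps = 5)
  ph <- generate_phantom(spec)
  segs <- ph$truth$labels
  lagr <- ph$truth$fields[-1]
  reports <- recruitment_screen(segs, lagr)
  expect_true(all(vapply(reports, function(r) r$n_components, integer(1)) == 0L))
})

test_that("identical skeletons imply d_s of zero and no seeds", {
  ph <- generate_phantom(tiny_phantom_spec(n_steps = 3), with_fields = FALSE)
  seg <- ph$truth$labels[[1]]
  sk <- skeletonize(seg)
  rep0 <- recruitment_detect(sk, sk, seg)
  expect_true(all(rep0$d_s == 0))
  expect_true(all(rep0$d_s <= rep0$d_omega | rep0$d_omega == 0))
  expect_equal(rep0$n_components, 0L)
  expect_true(all(rep0$d_omega >= 0))
})

test_that("an appearing structure is reported from its appearance step with its volume", {
  spec <- tiny_phantom_spec("recruitment", amplitude = 0.05, n_steps = 6)
  k <- spec$deformation$recruitment_events[[1]][2]
  ph <- generate_phantom(spec)
  segs <- ph$truth$labels
  lagr <- ph$truth$fields[-1]
  reports <- recruitment_screen(segs, lagr)
  found <- vapply(reports, function(r) r$n_components > 0, logical(1))
  expect_false(any(found[seq_len(k - 1)]))
  expect_true(all(found[k:length(found)]))
  # ground-truth recruited voxels: components of omega(k) disjoint from the
  # (generously dilated) baseline omega
  omk <- omega_mask(segs[[k + 1]])
  comp <- label_components(omk, 26)
  grown <- omega_mask(segs[[1]])
  for (i in 1:3) grown <- dilate_mask(grown)
  old_ids <- unique(comp[grown & omk])
  truth_rec <- sum(comp > 0 & !(comp %in% old_ids))
  rec_vox <- sum(reports[[k]]$recruited > 0)
  expect_gt(truth_rec, 0)
  expect_lt(abs(rec_vox - truth_rec) / truth_rec, 0.1)
})

test_that("recruitment detection is translation-equivariant", {
  spec <- tiny_phantom_spec("recruitment", amplitude = 0.05, n_steps = 6)
  ph <- generate_phantom(spec)
  k <- spec$deformation$recruitment_events[[1]][2]
  seg <- ph$truth$labels[[k + 1]]
  base <- skeletonize(ph$truth$labels[[1]])
  def <- deform_skeleton(base, ph$truth$fields[[k + 1]])
  ph_sk <- skeletonize(seg)
  r0 <- recruitment_detect(ph_sk, def, seg, min_seed_size = 2)

  shift <- function(a, s) {
    out <- array(if (is.logical(a)) FALSE else 0L, dim(a))
    out[(1 + s):dim(a)[1], , ] <- a[1:(dim(a)[1] - s), , ]
    out
  }
  s <- 4L
  seg_t <- segmented_volume(shift(seg$labels, s), "airspace", 1, seg$phase)
  def_t <- skeleton3d(shift(def$mask, s), def$phase)
  sk_t <- skeleton3d(shift(ph_sk$mask, s), ph_sk$phase)
  r1 <- recruitment_detect(sk_t, def_t, seg_t, min_seed_size = 2)
  expect_equal(r1$n_components, r0$n_components)
  expect_equal(sort(r1$volumes), sort(r0$volumes))
})
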