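# Voxel-wise biomechanics: moving-least-squares corrected divergence of the
# Lagrangian field (volumetric strain), volume change by the divergence
# theorem, curvature-weighted divergence for internal surface-area change,
# and aggregation into ROI time series.

#' Compact-support kernel for the MLS divergence operator
#'
#' Cubic B-spline radial profile with support radius `h` voxels; only the
#' kernel gradient enters the corrected operator (the MLS matrix makes the
#' result invariant to the kernel normalisation).
#'
#' @param h support radius in voxels.
#' @return object of class `mls_kernel`: integer `offsets` (m x 3) and the
#'   kernel gradient `grad` (m x 3) at each offset.
#' @export
mls_kernel <- function(h = 2.5) {
  assert_that(h >= 1.5, "kernel support must cover at least the face neighbours")
  r <- floor(h)
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  d <- sqrt(rowSums(off^2))
  keep <- d > 0 & d < h
  off <- off[keep, , drop = FALSE]
  d <- d[keep]
  q <- 2 * d / h
  # d/dq of the cubic spline profile
  dwdq <- ifelse(q <= 1, -3 * q + 2.25 * q^2, -0.75 * (2 - q)^2)
  dwdr <- dwdq * 2 / h
  grad <- off * (dwdr / d)
  structure(list(offsets = off, grad = grad, h = h), class = "mls_kernel")
}

#' MLS-corrected divergence of a displacement field over the segmented set
#'
#' Estimates the divergence at every voxel of Omega using only Omega voxels
#' in the kernel support, with a per-voxel 3 x 3 moving-least-squares
#' correction matrix that restores exactness for affine fields despite the
#' truncated support (linear consistency). Voxels whose neighbourhood is too
#' degenerate to invert (condition number above `cond_max`) are masked
#' invalid instead of extrapolated.
#'
#' @param field a [displacement_field()] (or a raw nx x ny x nz x 3 array,
#'   voxel units).
#' @param omega logical 3D array or [segmented_volume()]: the voxel set the
#'   operator both evaluates on and draws neighbours from.
#' @param kernel an [mls_kernel()].
#' @param cond_max condition-number guard for the correction matrix.
#' @param classes label classes forming Omega when `omega` is a segmentation.
#' @return object of class `strain_map`: `strain` (3D array, dimensionless
#'   divergence, 0 outside the valid set), `valid` (logical 3D array),
#'   `phase`.
#' @export
mls_divergence <- function(field, omega, kernel = mls_kernel(),
                           cond_max = 1e6,
                           classes = c("proximal", "intermediate", "terminal")) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  om <- if (inherits(omega, "segmented_volume")) omega_mask(omega, classes) else {
    m <- as.logical(omega); dim(m) <- dim(omega); m
  }
  d <- vol_dims(om)
  assert_that(identical(d, dim(u)[1:3]), "field and omega must share one grid")
  assert_that(any(om), "empty segmentation")
  res <- mls_div_cpp(as.numeric(u), om, d,
                     kernel$offsets, kernel$grad, cond_max)
  structure(
    list(strain = array(res$div, dim = d),
         valid = array(res$valid, dim = d),
         phase = if (inherits(field, "displacement_field")) field$to_step else NA_integer_),
    class = "strain_map"
  )
}

#' @export
print.strain_map <- function(x, ...) {
  v <- x$strain[x$valid]
  cat(sprintf("<strain_map> phase %s: %d valid voxels, mean strain %.4g (sd %.3g)\n",
              x$phase, length(v), mean(v), sd(v)))
  invisible(x)
}

#' Volume change from the strain map (divergence theorem)
#'
#' The total volume change at phase n is the divergence of the Lagrangian
#' field summed over the baseline segmented voxels; strain itself is the
#' divergence. Reported both as a voxel count and in physical units.
#'
#' @param strain a [mls_divergence()] result.
#' @param omega baseline segmentation mask (t = 0), logical array or
#'   [segmented_volume()].
#' @param voxel_size voxel edge, micrometres.
#' @param classes see [mls_divergence()].
#' @return list: `dv_voxels`, `dv` (physical), `V0_voxels`, `V0`, `V`,
#'   `n_invalid`.
#' @export
volume_change <- function(strain, omega, voxel_size = 1,
                          classes = c("proximal", "intermediate", "terminal")) {
  om <- if (inherits(omega, "segmented_volume")) omega_mask(omega, classes) else {
    m <- as.logical(omega); dim(m) <- dim(omega); m
  }
  sel <- om & strain$valid
  dv_vox <- sum(strain$strain[sel])
  V0_vox <- sum(om)
  list(dv_voxels = dv_vox, dv = dv_vox * voxel_size^3,
       V0_voxels = V0_vox, V0 = V0_vox * voxel_size^3,
       V = (V0_vox + dv_vox) * voxel_size^3,
       n_invalid = sum(om & !strain$valid))
}

#' Mean curvature field of a segmentation boundary
#'
#' Estimates h = k1 + k2 (the sum of principal curvatures: 2/R on a sphere
#' of radius R, 1/R on a cylinder, 0 on a plane) as the divergence of the
#' normalised gradient of a Gaussian-smoothed signed distance function, and
#' extends the boundary values into the interior of Omega by nearest-boundary
#' lookup so curvature-weighted volume sums are well defined everywhere.
#'
#' @param omega logical 3D array or [segmented_volume()].
#' @param sigma smoothing bandwidth (voxels) for the signed distance.
#' @param classes see [mls_divergence()].
#' @return object of class `curvature_field`: `h` (3D array, units 1/voxel,
#'   NA outside Omega), `h_boundary` (values on the boundary band),
#'   `boundary` (logical array), `valid` (boundary voxels away from the grid
#'   edge).
#' @export
mean_curvature <- function(omega, sigma = 1.5,
                           classes = c("proximal", "intermediate", "terminal")) {
  om <- if (inherits(omega, "segmented_volume")) omega_mask(omega, classes) else {
    m <- as.logical(omega); dim(m) <- dim(omega); m
  }
  d <- vol_dims(om)
  boundary <- array(boundary6_cpp(om, d, FALSE), dim = d)
  assert_that(any(boundary), "segmentation has no boundary")
  dist_out <- distance_transform(om)$dist
  dist_in <- distance_transform(!om)$dist
  phi <- smooth_volume(dist_out - dist_in, sigma)   # increases outward
  g <- array_gradient(phi)
  mag <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  mag[mag < 1e-8] <- 1e-8
  nx <- g$gx / mag; ny <- g$gy / mag; nz <- g$gz / mag
  h <- array_gradient(nx)$gx + array_gradient(ny)$gy + array_gradient(nz)$gz

  # voxels on the grid edge have one-sided distance information: mask them
  edge <- array(FALSE, dim = d)
  edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE; edge[, , c(1, d[3])] <- TRUE
  valid_boundary <- boundary & !edge

  # extend boundary curvature into the interior by nearest boundary voxel
  ft <- distance_transform(valid_boundary)$nearest
  h_omega <- array(NA_real_, dim = d)
  idx <- which(om)
  h_omega[idx] <- h[ft[idx]]
  structure(
    list(h = h_omega, h_boundary = h[valid_boundary], boundary = boundary,
         valid = valid_boundary, sigma = sigma, convention = "k1_plus_k2"),
    class = "curvature_field"
  )
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("<curvature_field> h = k1+k2, boundary mean %.4g per voxel (%d boundary voxels)\n",
              mean(x$h_boundary), sum(x$valid)))
  invisible(x)
}

#' Internal surface-area change by curvature-weighted divergence
#'
#' Computes the MLS divergence of the curvature-weighted field h * u over
#' Omega and sums it: on a sphere of radius R under radial displacement dR
#' this reproduces the exact surface growth 8 * pi * R * dR, which fixes the
#' curvature convention (h = k1 + k2).
#'
#' @param field Lagrangian [displacement_field()] (or raw array, voxel units).
#' @param omega baseline segmentation (logical array or [segmented_volume()]).
#' @param curvature a [mean_curvature()] result on `omega`.
#' @param kernel an [mls_kernel()].
#' @param voxel_size voxel edge, micrometres.
#' @param classes see [mls_divergence()].
#' @return list: `ds_voxels` (voxel^2), `ds` (physical), `map` (per-voxel
#'   contribution, a `strain_map`-like object), `n_invalid`.
#' @export
surface_change <- function(field, omega, curvature, kernel = mls_kernel(),
                           voxel_size = 1,
                           classes = c("proximal", "intermediate", "terminal")) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  om <- if (inherits(omega, "segmented_volume")) omega_mask(omega, classes) else {
    m <- as.logical(omega); dim(m) <- dim(omega); m
  }
  d <- vol_dims(om)
  hmap <- curvature$h
  hfill <- ifelse(is.na(hmap), 0, hmap)
  hu <- u
  for (c in 1:3) hu[, , , c] <- u[, , , c] * hfill
  sm <- mls_divergence(hu, om, kernel)
  sel <- om & sm$valid
  ds_vox <- sum(sm$strain[sel])
  list(ds_voxels = ds_vox, ds = ds_vox * voxel_size^2, map = sm,
       n_invalid = sum(om & !sm$valid))
}

#' Discrete boundary flux of a displacement field
#'
#' Sums u . n over the voxel faces of the boundary of Omega (outward
#' normals); by the divergence theorem this should match the summed
#' divergence over Omega.
#'
#' @param field [displacement_field()] or raw array.
#' @param omega logical 3D array.
#' @return scalar flux in voxel^3.
#' @export
boundary_flux <- function(field, omega) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  om <- as.logical(omega); dim(om) <- dim(omega)
  d <- vol_dims(om)
  pad <- function(a) {
    out <- array(FALSE, dim = d + 2L)
    out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    out
  }
  p <- pad(om)
  shift_arr <- function(a, s) {
    out <- array(0, dim = d + 2L)
    out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    out[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2], (2:(d[3] + 1)) + s[3]]
  }
  flux <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- p[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2], (2:(d[3] + 1)) + s[3]]
    faces <- om & !nb
    comp <- which(s != 0)
    sign <- s[comp]
    # face-centred normal component: average of the two voxels sharing the face
    uc <- u[, , , comp]
    u_face <- (uc + shift_arr(uc, s)) / 2
    flux <- flux + sign * sum(u_face[faces])
  }
  flux
}

#' Spherical region of interest
#'
#' @param center voxel coordinates (1-based) of the ROI centre.
#' @param radius radius in voxels.
#' @param id label used in outputs and error messages.
#' @return object of class `roi`.
#' @export
roi_sphere <- function(center, radius, id = "roi") {
  structure(list(center = as.numeric(center), radius = radius, id = id),
            class = "roi")
}

roi_mask <- function(roi, dims) {
  if (is.array(roi)) {
    m <- as.logical(roi); dim(m) <- dim(roi); return(m)
  }
  dx2 <- (seq_len(dims[1]) - roi$center[1])^2
  dy2 <- (seq_len(dims[2]) - roi$center[2])^2
  dz2 <- (seq_len(dims[3]) - roi$center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= roi$radius^2
}

#' Regional time series of strain, volume and surface change
#'
#' Aggregates per-phase strain maps and surface-change maps over regions of
#' interest: within-ROI mean and standard deviation of voxel strain, plus
#' volume and surface series restricted to the ROI, excluding voxels masked
#' invalid by the MLS operator.
#'
#' @param strain_maps list of [mls_divergence()] results (phases 1..N).
#' @param surface_maps optional list of [surface_change()] results of the
#'   same length.
#' @param omega baseline segmentation mask.
#' @param rois list of [roi_sphere()]s (or logical arrays).
#' @param voxel_size voxel edge, micrometres.
#' @param times optional phase times, seconds.
#' @return list of `roi_series` objects, each with `id` and a data.frame
#'   `series` (`phase`, `time`, `mean_strain`, `sd_strain`, `dv`, `V`, `ds`,
#'   `S`).
#' @export
roi_series <- function(strain_maps, surface_maps = NULL, omega, rois,
                       voxel_size = 1, times = NULL) {
  om <- if (inherits(omega, "segmented_volume")) omega_mask(omega) else {
    m <- as.logical(omega); dim(m) <- dim(omega); m
  }
  d <- vol_dims(om)
  n_ph <- length(strain_maps)
  if (is.null(times)) times <- seq_len(n_ph)
  out <- vector("list", length(rois))
  for (ri in seq_along(rois)) {
    roi <- rois[[ri]]
    id <- if (is.array(roi)) paste0("roi", ri) else roi$id
    rm <- roi_mask(roi, d)
    base_sel <- rm & om
    if (!any(base_sel)) stop_("ROI '%s' does not intersect the segmentation", id)
    V0 <- sum(base_sel) * voxel_size^3
    S0 <- surface_area(base_sel, voxel_size)
    rows <- vector("list", n_ph)
    for (pi in seq_len(n_ph)) {
      sm <- strain_maps[[pi]]
      sel <- base_sel & sm$valid
      if (!any(sel)) stop_("ROI '%s' lies entirely in the invalid set at phase %d", id, pi)
      vals <- sm$strain[sel]
      dv <- sum(vals) * voxel_size^3
      ds <- if (!is.null(surface_maps)) {
        smap <- surface_maps[[pi]]$map
        sum(smap$strain[base_sel & smap$valid]) * voxel_size^2
      } else NA_real_
      rows[[pi]] <- data.frame(
        phase = sm$phase %||% pi, time = times[pi],
        mean_strain = mean(vals), sd_strain = if (length(vals) > 1) sd(vals) else 0,
        dv = dv, V = V0 + dv, ds = ds, S = if (is.na(ds)) NA_real_ else S0 + ds)
    }
    out[[ri]] <- structure(
      list(id = id, V0 = V0, S0 = S0, series = do.call(rbind, rows)),
      class = "roi_series")
  }
  out
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> '%s': V0 = %.4g, S0 = %.4g, %d phases, peak mean strain %.4g\n",
              x$id, x$V0, x$S0, nrow(x$series), max(x$series$mean_strain)))
  invisible(x)
}
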