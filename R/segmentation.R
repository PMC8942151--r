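# Airspace / vessel segmentation: Otsu partitioning and erosion-profile
# classification of connected structures into proximal, intermediate and
# terminal classes.

#' Otsu threshold of a greyscale volume
#'
#' Picks the threshold maximising the between-class variance of the
#' intensity histogram. Ties (flat plateaus of the criterion, as in ideal
#' two-level images) resolve to the middle of the tied range so the
#' threshold falls strictly between the modes.
#'
#' @param volume numeric array (any shape).
#' @param nbins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(volume, nbins = 256) {
  v <- as.numeric(volume)
  rng <- range(v)
  assert_that(rng[1] < rng[2], "volume is constant: no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins),
                     nbins = nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  cum_w <- cumsum(w)
  cum_mu <- cumsum(w * mids)
  mu_T <- cum_mu[nbins]
  # between-class variance for a cut after bin k
  valid <- cum_w > 0 & cum_w < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_T * cum_w[valid] - cum_mu[valid])^2 /
    (cum_w[valid] * (1 - cum_w[valid]))
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  k <- best[ceiling(length(best) / 2)]
  edges[k + 1]
}

#' Otsu air/non-air partition
#'
#' Air is dark on attenuation-like contrast, so the air mask is the set of
#' voxels below the Otsu threshold.
#'
#' @param volume numeric 3D array.
#' @param nbins histogram bins for the threshold search.
#' @return logical 3D array (TRUE = air) with attribute `threshold`.
#' @export
otsu_partition <- function(volume, nbins = 256) {
  thr <- otsu_threshold(volume, nbins)
  mask <- array(volume < thr, dim = vol_dims(volume))
  attr(mask, "threshold") <- thr
  mask
}

#' Stepwise 3D erosion profile of a structure
#'
#' Erodes the mask with a Euclidean ball of increasing radius (realised by
#' thresholding the exact Euclidean distance transform at 1, 2, ... voxels),
#' recording the remaining volume at each step, and fits a line to the early
#' part of the profile. Slender quasi-cylindrical structures lose a
#' near-constant volume per step (linear decay); blob-like structures decay
#' faster than linearly. The erosion survival depth of a voxel is exactly
#' its distance-transform value, so tube radii can be read off the profile.
#'
#' @param mask logical 3D array (one connected structure).
#' @param fit_window fraction of the survival depth used for the linear fit.
#' @param rel_rmse_tol acceptance threshold: the fit's RMSE divided by the
#'   initial volume must not exceed this for the structure to count as
#'   linear (quasi-cylindrical).
#' @param min_elongation additional guard: initial volume divided by depth^3
#'   must reach this value (a tube of aspect ratio L/r = a scores pi * a; a
#'   ball scores 4.19), so compact blobs with short profiles cannot pass.
#' @return an object of class `erosion_profile`: `steps`, `volumes`, `depth`
#'   (erosion steps until empty), `slope`, `intercept`, `rmse`, `rel_rmse`,
#'   `linear`.
#' @export
erosion_profile <- function(mask, fit_window = 0.6, rel_rmse_tol = 0.06,
                            min_elongation = 8) {
  assert_that(any(mask), "empty component")
  d <- vol_dims(mask)
  dist <- distance_transform(!array(as.logical(mask), dim = d))$dist
  depth <- as.integer(ceiling(max(dist)))
  volumes <- vapply(0:(depth - 1), function(k) sum(dist > k), numeric(1))
  volumes <- volumes[volumes > 0]
  depth <- length(volumes)
  steps <- seq_len(depth) - 1
  n_fit <- min(depth, max(3L, ceiling(depth * fit_window)))
  slope <- intercept <- rmse <- NA_real_
  linear <- FALSE
  if (n_fit >= 3) {
    fit <- lm(volumes[seq_len(n_fit)] ~ steps[seq_len(n_fit)])
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    rmse <- sqrt(mean(fit$residuals^2))
    # a quasi-cylinder must also be elongated: a tube of radius ~depth and
    # length L has volume pi * L * depth^2, i.e. volume / depth^3 = pi * L/r,
    # whereas a ball gives only 4.19 regardless of size
    elongation <- volumes[1] / depth^3
    linear <- depth >= 5 &&
      (rmse / volumes[1]) <= rel_rmse_tol && elongation >= min_elongation
  }
  structure(
    list(steps = steps, volumes = volumes, depth = depth, slope = slope,
         intercept = intercept, rmse = rmse,
         rel_rmse = if (is.na(rmse)) NA_real_ else rmse / volumes[1],
         linear = linear, n_fit = n_fit,
         elongation = volumes[1] / depth^3),
    class = "erosion_profile"
  )
}

#' @export
print.erosion_profile <- function(x, ...) {
  cat(sprintf("<erosion_profile> depth %d, v0 = %d, rel RMSE = %.3g (%s)\n",
              x$depth, x$volumes[1], x$rel_rmse,
              if (isTRUE(x$linear)) "linear" else "non-linear"))
  invisible(x)
}

# unconstrained Euclidean dilation of a core, intersected with the mask;
# together with the preceding erosion this is a morphological opening, which
# recovers the tube body without bleeding into attached blobs.
ball_dilate_within <- function(core, mask, radius) {
  d <- vol_dims(mask)
  dist_to_core <- distance_transform(core)$dist
  array(dist_to_core <= radius & mask, dim = d)
}

#' Classify an air (or vessel) mask into proximal / intermediate / terminal
#'
#' Proximal conducting structures are recovered as the deepest erosion
#' survivors whose reconstructed body loses volume linearly with erosion
#' step (quasi-cylindrical); intermediate structures are the remaining
#' quasi-cylindrical structures with survival depth of at least `theta_term`;
#' everything else in the mask (alveolar ducts and clusters, isolated blobs)
#' is terminal.
#'
#' @param mask logical 3D array from [otsu_partition()] (or ground truth).
#' @param theta_term minimum erosion survival depth (steps to vanish) for a
#'   structure to qualify as intermediate rather than terminal.
#' @param rel_rmse_tol,fit_window,min_elongation linearity acceptance, see
#'   [erosion_profile()].
#' @param recover_slack extra dilation radius (voxels) when recovering the
#'   full body of an eroded core, compensating the half-voxel quantisation of
#'   digital distances.
#' @param kind passed through to [segmented_volume()].
#' @param voxel_size,phase metadata for the result.
#' @return a [segmented_volume()].
#' @export
classify_structures <- function(mask, theta_term = 3, rel_rmse_tol = 0.06,
                                fit_window = 0.6, recover_slack = 1.5,
                                min_elongation = 8, kind = "airspace",
                                voxel_size = 1, phase = 0L) {
  d <- vol_dims(mask)
  mask <- array(as.logical(mask), dim = d)
  lab <- array(0L, dim = d)
  if (!any(mask))
    return(segmented_volume(lab, kind, voxel_size, phase))
  dist <- distance_transform(!mask)$dist
  dm <- max(dist)
  d_max <- ceiling(dm)

  proximal <- array(FALSE, dim = d)
  found_linear <- FALSE
  if (d_max >= 3) {
    cores <- label_components(dist > dm - 1, connectivity = 26)
    for (ci in seq_len(attr(cores, "n"))) {
      rec <- ball_dilate_within(cores == ci, mask, dm - 1 + recover_slack)
      prof <- erosion_profile(rec, fit_window, rel_rmse_tol, min_elongation)
      if (isTRUE(prof$linear)) {
        proximal <- proximal | rec
        found_linear <- TRUE
      }
    }
  }
  if (!found_linear && d_max >= 3)
    warning("no structure passed the linearity test; all voxels classified terminal",
            call. = FALSE)

  # intermediate structures: peel the remaining mask by descending erosion
  # depth, testing the reconstructed body of each core; non-tube cores are
  # excluded from further candidacy so depth levels below them get their turn
  rest <- mask & !proximal
  intermediate <- array(FALSE, dim = d)
  excluded <- array(FALSE, dim = d)
  repeat {
    if (!any(rest)) break
    dist2 <- distance_transform(!rest)$dist
    cand <- dist2 > theta_term - 1 & !excluded
    if (!any(cand)) break
    dm2 <- max(dist2[cand])
    cores2 <- label_components(dist2 > dm2 - 1 & !excluded, connectivity = 26)
    progressed <- FALSE
    for (ci in seq_len(attr(cores2, "n"))) {
      core <- cores2 == ci
      depth_c <- max(dist2[core])
      rec <- ball_dilate_within(core, rest, depth_c - 1 + recover_slack)
      prof <- erosion_profile(rec, fit_window, rel_rmse_tol, min_elongation)
      if (isTRUE(prof$linear)) {
        intermediate <- intermediate | rec
        rest <- rest & !rec
        progressed <- TRUE
      } else {
        excluded <- excluded | core
      }
    }
    if (!progressed && !any((dist2 > theta_term - 1) & !excluded & rest)) break
  }

  lab[mask] <- LABELS[["terminal"]]
  lab[intermediate] <- LABELS[["intermediate"]]
  lab[proximal] <- LABELS[["proximal"]]

  # thin residues of the opening-based recovery (skin fragments of erosion
  # depth <= 2 stuck to a recovered tube) are reassigned to the touching class
  if (any(proximal) || any(intermediate)) {
    resid <- lab == LABELS[["terminal"]]
    if (any(resid)) {
      dist3 <- distance_transform(!resid)$dist
      comp <- label_components(resid, connectivity = 26)
      grown <- array(dilate6_cpp(proximal | intermediate, d), dim = d)
      for (ci in seq_len(attr(comp, "n"))) {
        sel <- comp == ci
        depth_r <- max(dist3[sel])
        # shells: shallow but extensive residues of the opening (cap rims,
        # outer skins); compact leftovers (e.g. truncated alveoli) stay
        if (depth_r > 3 || sum(sel) / ceiling(depth_r)^3 < 40) next
        touching <- sel & grown
        if (!any(touching)) next
        # majority label among adjacent recovered voxels
        nb_lab <- if (sum(proximal & array(dilate6_cpp(sel, d), dim = d)) >=
                      sum(intermediate & array(dilate6_cpp(sel, d), dim = d)))
          LABELS[["proximal"]] else LABELS[["intermediate"]]
        lab[sel] <- nb_lab
      }
    }
  }
  segmented_volume(lab, kind, voxel_size, phase)
}

#' Segment a greyscale phase volume
#'
#' Otsu air partition followed by erosion-profile classification. For
#' `kind = "vessel"` the air voxels are first removed and Otsu is re-run on
#' the remaining (tissue + blood) intensities, selecting the darker blood
#' class.
#'
#' @param volume numeric 3D array.
#' @param kind "airspace" or "vessel".
#' @param voxel_size,phase metadata.
#' @param smooth_sigma Gaussian denoising (voxels) applied before the
#'   threshold search; 0 disables.
#' @param ... passed to [classify_structures()].
#' @return a [segmented_volume()].
#' @export
segment_volume <- function(volume, kind = c("airspace", "vessel"),
                           voxel_size = 1, phase = 0L, smooth_sigma = 0.8,
                           ...) {
  kind <- match.arg(kind)
  if (smooth_sigma > 0) volume <- smooth_volume(volume, smooth_sigma)
  air <- otsu_partition(volume)
  if (kind == "airspace") {
    seg <- classify_structures(air, kind = "airspace",
                               voxel_size = voxel_size, phase = phase, ...)
  } else {
    # exclude air and its partial-volume shell before splitting blood/tissue
    excl <- dilate_mask(dilate_mask(air))
    rest <- volume[!excl]
    thr <- otsu_threshold(rest)
    vess <- array(volume < thr & !excl, dim = vol_dims(volume))
    seg <- classify_structures(vess, kind = "vessel",
                               voxel_size = voxel_size, phase = phase, ...)
    seg$labels[seg$labels > 0L] <- LABELS[["vessel"]]
    seg <- segmented_volume(seg$labels, "vessel", voxel_size, phase)
  }
  attr(seg, "air_threshold") <- attr(air, "threshold")
  seg
}

#' Marker-based watershed editing of a segmentation mask
#'
#' Splits touching structures by flooding the inverted Euclidean distance
#' transform from user-supplied markers (the manual-editing step of the
#' segmentation workflow). With no markers the mask is returned partitioned
#' into its connected components (identity edit).
#'
#' @param mask logical 3D array (the region to edit).
#' @param markers either an integer array of marker labels (0 = none) on the
#'   same grid, or an n x 4 matrix of rows `(x, y, z, label)` in 1-based
#'   voxel indices.
#' @return integer array: marker label per mask voxel (0 outside mask), with
#'   attribute `n` regions.
#' @export
watershed_edit <- function(mask, markers = NULL) {
  d <- vol_dims(mask)
  mask <- array(as.logical(mask), dim = d)
  if (is.null(markers) || (is.matrix(markers) && nrow(markers) == 0)) {
    return(label_components(mask, connectivity = 26))
  }
  if (is.matrix(markers)) {
    m <- array(0L, dim = d)
    for (i in seq_len(nrow(markers))) {
      p <- markers[i, 1:3]
      if (any(p < 1) || any(p > d))
        stop_("marker %d at (%g, %g, %g) is outside the grid", i, p[1], p[2], p[3])
      if (!mask[p[1], p[2], p[3]])
        stop_("marker %d at (%d, %d, %d) lies outside the segmented region",
              i, p[1], p[2], p[3])
      m[p[1], p[2], p[3]] <- as.integer(markers[i, 4])
    }
    markers <- m
  } else {
    markers <- array(as.integer(markers), dim = d)
    bad <- which(markers > 0L & !mask)
    if (length(bad) > 0) {
      p <- arrayInd(bad[1], d)
      stop_("marker at (%d, %d, %d) lies outside the segmented region",
            p[1], p[2], p[3])
    }
  }
  edt <- distance_transform(!mask)  # distance to background, high at cores
  lab <- marker_flood_cpp(as.numeric(-edt$dist), mask, markers, d)
  out <- array(lab, dim = d)
  attr(out, "n") <- length(setdiff(unique(as.integer(markers[markers > 0])), 0L))
  out
}
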