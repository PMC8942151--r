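# Skeleton-based detection of recruited (newly inflated) airspaces: the
# baseline skeleton is advected by the Lagrangian field and compared with
# each phase's skeleton through two distances - skeleton-to-boundary (d_omega)
# and skeleton-to-deformed-baseline-skeleton (d_s). Voxels where d_s exceeds
# d_omega cannot be explained by deformation of structures present at
# baseline and seed the recruited-structure segmentation.

#' Topology-preserving 3D skeletonization
#'
#' Iterative thinning to a one-voxel-wide centreline, preserving connected
#' components and tunnels (only simple points are removed; endpoints are
#' kept). Skeletonizing a skeleton returns it unchanged.
#'
#' @param x a [segmented_volume()], logical 3D array, or [skeleton3d()].
#' @param classes which label classes form the object when `x` is a
#'   segmentation.
#' @param phase,voxel_size metadata (taken from `x` when available).
#' @return a [skeleton3d()].
#' @export
skeletonize <- function(x, classes = c("proximal", "intermediate", "terminal"),
                        phase = NULL, voxel_size = NULL) {
  if (inherits(x, "skeleton3d")) {
    mask <- x$mask
    phase <- phase %||% x$phase
    voxel_size <- voxel_size %||% x$voxel_size
  } else if (inherits(x, "segmented_volume")) {
    mask <- omega_mask(x, classes)
    phase <- phase %||% x$phase
    voxel_size <- voxel_size %||% x$voxel_size
  } else {
    mask <- as.logical(x)
    dim(mask) <- dim(x)
  }
  assert_that(any(mask), "cannot skeletonize an empty segmentation")
  d <- vol_dims(mask)
  sk <- array(skeletonize3d_cpp(as.logical(mask), d), dim = d)
  skeleton3d(sk, phase = phase %||% 0L, voxel_size = voxel_size %||% 1)
}

#' Advect a baseline skeleton by a Lagrangian displacement field
#'
#' Each skeleton voxel at x moves to x + u(x; 0, n), rounded to the nearest
#' voxel; collisions keep a single marked voxel and points advected outside
#' the grid are clamped to the boundary and counted.
#'
#' @param baseline a [skeleton3d()] at the reference phase.
#' @param field a Lagrangian [displacement_field()].
#' @return a [skeleton3d()] at the field's target phase, with attribute
#'   `n_clamped`.
#' @export
deform_skeleton <- function(baseline, field) {
  d <- vol_dims(baseline$mask)
  assert_that(identical(d, dim(field$u)[1:3]), "field must cover the skeleton grid")
  idx <- which(baseline$mask)
  if (length(idx) == 0) return(baseline)
  pos <- arrayInd(idx, d)
  u <- matrix(c(field$u[, , , 1][idx], field$u[, , , 2][idx], field$u[, , , 3][idx]),
              ncol = 3)
  adv <- pos + u
  rounded <- round(adv)
  clamped <- sum(rounded < 1 | rounded > matrix(d, nrow(rounded), 3, byrow = TRUE))
  for (c in 1:3) rounded[, c] <- pmin(pmax(rounded[, c], 1), d[c])
  out <- array(FALSE, dim = d)
  out[rounded] <- TRUE
  res <- skeleton3d(out, phase = field$to_step, voxel_size = baseline$voxel_size)
  attr(res, "n_clamped") <- clamped
  res
}

#' Detect recruited airspaces at one phase
#'
#' For every voxel of the phase-n skeleton, computes d_omega (Euclidean
#' distance to the segmentation boundary of phase n) and d_s (Euclidean
#' distance to the nearest voxel of the deformed baseline skeleton). Voxels
#' with d_s > d_omega seed recruited structures, which are grown within the
#' phase segmentation by a marker watershed against the deformed baseline
#' skeleton.
#'
#' @param phase_skeleton [skeleton3d()] of the phase-n segmentation.
#' @param deformed_baseline [skeleton3d()] from [deform_skeleton()].
#' @param segmented the phase-n [segmented_volume()] (or logical mask).
#' @param min_seed_size discard seed components smaller than this many voxels
#'   (suppresses single-voxel skeleton jitter).
#' @param classes label classes forming the airspace set.
#' @return object of class `recruitment_report`: `seeds` (logical array),
#'   `recruited` (integer label array), `n_components`, `volumes` (voxels per
#'   recruited component), `d_omega`, `d_s` (values at phase-skeleton voxels).
#' @export
recruitment_detect <- function(phase_skeleton, deformed_baseline, segmented,
                               min_seed_size = 5L,
                               classes = c("proximal", "intermediate", "terminal")) {
  omega <- if (inherits(segmented, "segmented_volume"))
    omega_mask(segmented, classes) else {
      m <- as.logical(segmented); dim(m) <- dim(segmented); m
    }
  d <- vol_dims(omega)
  assert_that(identical(d, vol_dims(phase_skeleton$mask)) &&
                identical(d, vol_dims(deformed_baseline$mask)),
              "skeletons and segmentation must share one grid")
  sk <- phase_skeleton$mask
  idx <- which(sk)
  boundary <- array(boundary6_cpp(omega, d, FALSE), dim = d)
  d_om_grid <- distance_transform(boundary)$dist
  d_s_grid <- if (any(deformed_baseline$mask))
    distance_transform(deformed_baseline$mask)$dist
  else array(Inf, dim = d)
  d_omega <- d_om_grid[idx]
  d_s <- d_s_grid[idx]

  seeds <- array(FALSE, dim = d)
  seeds[idx[d_s > d_omega]] <- TRUE
  if (any(seeds) && min_seed_size > 1) {
    comp <- label_components(seeds, connectivity = 26)
    sizes <- tabulate(comp[comp > 0], nbins = attr(comp, "n"))
    keep <- which(sizes >= min_seed_size)
    seeds <- array(comp %in% keep & seeds, dim = d)
  }

  recruited <- array(0L, dim = d)
  n_comp <- 0L
  volumes <- integer(0)
  if (any(seeds)) {
    seed_comp <- label_components(seeds, connectivity = 26)
    n_comp <- attr(seed_comp, "n")
    # grow seeds within omega, competing against the deformed baseline
    markers <- array(0L, dim = d)
    markers[deformed_baseline$mask & omega] <- n_comp + 1L
    markers[seeds] <- seed_comp[seeds]
    edt <- distance_transform(!omega)
    grown <- array(marker_flood_cpp(as.numeric(-edt$dist), omega, markers, d), dim = d)
    grown[grown == n_comp + 1L] <- 0L
    recruited <- grown
    volumes <- tabulate(recruited[recruited > 0], nbins = n_comp)
  }
  structure(
    list(seeds = seeds, recruited = recruited, n_components = n_comp,
         volumes = volumes, d_omega = d_omega, d_s = d_s,
         phase = phase_skeleton$phase),
    class = "recruitment_report"
  )
}

#' @export
print.recruitment_report <- function(x, ...) {
  cat(sprintf("<recruitment_report> phase %d: %d recruited component(s), %s voxels\n",
              x$phase, x$n_components,
              if (x$n_components) paste(x$volumes, collapse = "+") else "0"))
  invisible(x)
}

#' Recruitment screen over a whole breath
#'
#' Convenience driver: skeletonizes the baseline and each later phase,
#' advects the baseline skeleton by the corresponding Lagrangian field and
#' runs [recruitment_detect()] per phase.
#'
#' @param segmentations list of [segmented_volume()]s, one per phase.
#' @param lagrangian list of Lagrangian fields for phases 1..N (from
#'   [compose_lagrangian()]).
#' @param ... passed to [recruitment_detect()].
#' @return list of `recruitment_report`s (phases 1..N).
#' @export
recruitment_screen <- function(segmentations, lagrangian, ...) {
  assert_that(length(segmentations) == length(lagrangian) + 1,
              "need one segmentation per phase including baseline")
  base_sk <- skeletonize(segmentations[[1]])
  out <- vector("list", length(lagrangian))
  for (i in seq_along(lagrangian)) {
    ph_sk <- skeletonize(segmentations[[i + 1]])
    def_sk <- deform_skeleton(base_sk, lagrangian[[i]])
    out[[i]] <- recruitment_detect(ph_sk, def_sk, segmentations[[i + 1]], ...)
  }
  out
}
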