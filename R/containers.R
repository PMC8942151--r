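# S3 containers shared by all pipeline stages.

#' Ordered series of 3D greyscale volumes on a shared voxel grid
#'
#' @param volumes list of numeric 3D arrays, one per respiratory phase bin,
#'   all with identical dimensions.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @param times acquisition phase times in seconds (one per volume).
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(volumes, voxel_size, times = NULL) {
  assert_that(is.list(volumes) && length(volumes) >= 1, "need at least one volume")
  d <- vol_dims(volumes[[1]])
  for (v in volumes) assert_that(identical(vol_dims(v), d), "volumes must share one grid")
  assert_that(is.numeric(voxel_size) && voxel_size > 0, "voxel_size must be positive")
  if (is.null(times)) times <- seq_along(volumes) - 1
  assert_that(length(times) == length(volumes), "one time per volume required")
  structure(
    list(volumes = volumes, voxel_size = voxel_size, times = as.numeric(times)),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- vol_dims(x$volumes[[1]])
  cat(sprintf("<volume_series> %d phases, grid %dx%dx%d, voxel %.3g um\n",
              length(x$volumes), d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' @export
length.volume_series <- function(x) length(x$volumes)

#' Per-voxel 3-vector displacement field
#'
#' Displacements are stored in voxel units in an `nx x ny x nz x 3` array;
#' multiply by `voxel_size` for physical displacements. A field is either
#' `pairwise` (step n-1 to n) or `lagrangian` (reference step 0 to n).
#'
#' @param u numeric 4D array, last dimension of extent 3 (x, y, z components).
#' @param kind "pairwise" or "lagrangian".
#' @param from_step,to_step phase indices (0-based, matching the series).
#' @param voxel_size voxel edge length in micrometres.
#' @param oob optional logical array flagging voxels whose value came from a
#'   clamped out-of-domain lookup.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, kind = c("pairwise", "lagrangian"),
                               from_step = 0L, to_step = 1L,
                               voxel_size = 1, oob = NULL) {
  kind <- match.arg(kind)
  d <- dim(u)
  assert_that(length(d) == 4 && d[4] == 3, "u must be an nx x ny x nz x 3 array")
  assert_that(all(is.finite(u)), "displacement field must be finite everywhere")
  if (kind == "pairwise")
    assert_that(to_step == from_step + 1, "pairwise fields link consecutive steps")
  if (kind == "lagrangian")
    assert_that(from_step == 0, "lagrangian fields start at the reference step 0")
  structure(
    list(u = u, kind = kind, from_step = as.integer(from_step),
         to_step = as.integer(to_step), voxel_size = voxel_size, oob = oob),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  mx <- max(sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2))
  cat(sprintf("<displacement_field> %s %d->%d, grid %dx%dx%d, max |u| = %.3g vox\n",
              x$kind, x$from_step, x$to_step, d[1], d[2], d[3], mx))
  invisible(x)
}

#' Magnitude of a displacement field
#' @param field a [displacement_field()].
#' @return 3D array of voxel-unit magnitudes.
#' @export
field_magnitude <- function(field) {
  sqrt(field$u[, , , 1]^2 + field$u[, , , 2]^2 + field$u[, , , 3]^2)
}

# label codes shared across the package
LABELS <- c(background = 0L, proximal = 1L, intermediate = 2L, terminal = 3L, vessel = 4L)

#' Labelled segmentation of one phase volume
#'
#' @param labels integer 3D array with codes 0 = background, 1 = proximal,
#'   2 = intermediate, 3 = terminal, 4 = vessel.
#' @param kind "airspace" or "vessel" - which contrast the segmentation
#'   machinery ran on.
#' @param voxel_size voxel edge length in micrometres.
#' @param phase phase index (0-based).
#' @return an object of class `segmented_volume`.
#' @export
segmented_volume <- function(labels, kind = c("airspace", "vessel"),
                             voxel_size = 1, phase = 0L) {
  kind <- match.arg(kind)
  d <- vol_dims(labels)
  labels <- array(as.integer(labels), dim = d)
  assert_that(all(labels %in% LABELS), "unknown label code")
  structure(
    list(labels = labels, kind = kind, voxel_size = voxel_size,
         phase = as.integer(phase), label_map = LABELS),
    class = "segmented_volume"
  )
}

#' @export
print.segmented_volume <- function(x, ...) {
  tb <- table(factor(x$labels, levels = LABELS, labels = names(LABELS)))
  cat(sprintf("<segmented_volume> %s, phase %d\n", x$kind, x$phase))
  print(tb)
  invisible(x)
}

#' Non-background mask of a segmentation
#' @param seg a [segmented_volume()] or a logical/integer array.
#' @param classes optional subset of class names to include.
#' @return logical 3D array.
#' @export
omega_mask <- function(seg, classes = c("proximal", "intermediate", "terminal", "vessel")) {
  labels <- if (inherits(seg, "segmented_volume")) seg$labels else seg
  codes <- LABELS[classes]
  array(labels %in% codes, dim = vol_dims(labels))
}

#' One-voxel-wide centreline representation of a segmentation
#'
#' @param mask logical 3D array of skeleton voxels.
#' @param phase phase index.
#' @param voxel_size voxel edge length in micrometres.
#' @return an object of class `skeleton3d`.
#' @export
skeleton3d <- function(mask, phase = 0L, voxel_size = 1) {
  d <- vol_dims(mask)
  structure(
    list(mask = array(as.logical(mask), dim = d), phase = as.integer(phase),
         voxel_size = voxel_size),
    class = "skeleton3d"
  )
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> phase %d, %d voxels\n", x$phase, sum(x$mask)))
  invisible(x)
}
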