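# Synthetic 4D micro-CT phantom with analytic ground truth.
#
# The phantom emulates the morphology the pipeline targets: quasi-cylindrical
# conducting airways feeding clusters of quasi-spherical terminal airspaces
# (alveoli around an alveolar duct), plus a vessel tree, deformed over a
# breath by analytic fields so that displacement, divergence, labels, volume
# and surface area are all known in closed form.

#' Deformation specification for the phantom breath
#'
#' @param mode deformation regime: `isotropic` (uniform linear scaling about
#'   the grid centre - the balloon-like regime), `ductal_dominant` (airway
#'   duct radii expand, alveoli fixed), `alveolar_dominant` (alveolar radii
#'   expand, ducts fixed), `recruitment` (isotropic base plus acinar units
#'   that appear partway through the breath), or `custom_analytic`
#'   (user-supplied field).
#' @param amplitude peak fractional linear expansion (dimensionless, in
#'   (0, 0.5]; 0 is accepted and means no motion).
#' @param n_steps number of phase bins over one breath (>= 3).
#' @param waveform function mapping phase fraction in `[0, 1)` to inflation
#'   fraction in `[0, 1]`; must be 0 at 0. Default is a raised cosine
#'   (inhale half, exhale half).
#' @param recruitment_events list of `c(unit, step)` pairs: acinar cluster
#'   `unit` (index into the spec's cluster list) first appears at phase
#'   `step` (0-based).
#' @param taper width of the smooth falloff shell around locally deforming
#'   structures, as a fraction of the structure radius.
#' @param custom for `mode = "custom_analytic"`: a list with functions
#'   `displacement(points, w)` and `divergence(points, w)` taking an n x 3
#'   matrix of physical coordinates and the inflation fraction `w`.
#' @return an object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("isotropic", "ductal_dominant",
                                      "alveolar_dominant", "recruitment",
                                      "custom_analytic"),
                             amplitude = 0.05, n_steps = 10L,
                             waveform = NULL, recruitment_events = list(),
                             taper = 0.3, custom = NULL) {
  mode <- match.arg(mode)
  assert_that(amplitude >= 0 && amplitude <= 0.5, "amplitude must lie in [0, 0.5]")
  assert_that(n_steps >= 3, "need at least 3 phase steps")
  if (is.null(waveform)) waveform <- function(f) (1 - cos(2 * pi * f)) / 2
  assert_that(abs(waveform(0)) < 1e-12, "waveform must vanish at phase 0")
  if (mode == "custom_analytic")
    assert_that(is.list(custom) && is.function(custom$displacement) &&
                  is.function(custom$divergence),
                "custom_analytic mode needs displacement and divergence functions")
  structure(
    list(mode = mode, amplitude = amplitude, n_steps = as.integer(n_steps),
         waveform = waveform, recruitment_events = recruitment_events,
         taper = taper, custom = custom),
    class = "deformation_spec"
  )
}

#' One quasi-cylindrical branch segment of an airway or vessel tree
#'
#' @param start physical coordinates (micrometres) of the branch base.
#' @param direction axis direction (normalised internally).
#' @param length,radius branch length and radius in micrometres.
#' @param class "proximal" or "intermediate".
#' @param name segment identifier used in error messages.
#' @return a list describing the segment.
#' @export
branch_segment <- function(start, direction, length, radius,
                           class = c("proximal", "intermediate"),
                           name = "branch") {
  class <- match.arg(class)
  direction <- direction / sqrt(sum(direction^2))
  list(start = as.numeric(start), direction = as.numeric(direction),
       length = length, radius = radius, class = class, name = name)
}

#' A cluster of quasi-spherical terminal airspaces around an alveolar duct
#'
#' Alveoli are placed deterministically in rings around the duct axis at a
#' radial clearance chosen so that locally deforming alveoli never collide
#' with the duct or with each other at peak inflation.
#'
#' @param center cluster centre, physical coordinates (micrometres).
#' @param duct_radius,duct_length alveolar duct dimensions (micrometres).
#' @param duct_direction duct axis.
#' @param alveolus_radius radius of each alveolus (micrometres).
#' @param n_alveoli number of alveoli.
#' @param clearance gap between the duct surface and alveolar surfaces at
#'   rest (micrometres); default 0.45 times the alveolar radius, which keeps
#'   the influence shell of a locally inflating alveolus off the duct wall.
#' @param attached if TRUE, alveoli are embedded into the duct wall (the
#'   cluster is one connected object; volumes and surfaces are then not
#'   additive and no analytic series should be relied on).
#' @param name cluster identifier.
#' @return a list describing the cluster.
#' @export
acinar_cluster <- function(center, duct_radius, duct_length,
                           duct_direction = c(0, 0, 1),
                           alveolus_radius, n_alveoli,
                           clearance = NULL, attached = FALSE,
                           name = "cluster") {
  duct_direction <- duct_direction / sqrt(sum(duct_direction^2))
  if (is.null(clearance)) clearance <- 0.45 * alveolus_radius
  if (attached) clearance <- -0.5 * alveolus_radius
  list(center = as.numeric(center), duct_radius = duct_radius,
       duct_length = duct_length, duct_direction = duct_direction,
       alveolus_radius = alveolus_radius, n_alveoli = as.integer(n_alveoli),
       clearance = clearance, attached = attached, name = name)
}

#' Full phantom specification
#'
#' @param grid_shape voxels per axis (3 integers, each >= 32).
#' @param voxel_size isotropic voxel edge in micrometres.
#' @param airway_tree list of [branch_segment()]s.
#' @param acinar_clusters list of [acinar_cluster()]s.
#' @param vessel_tree list of [branch_segment()]s rendered at blood contrast.
#' @param deformation a [deformation_spec()].
#' @param noise_sigma additive Gaussian greyscale noise (tissue = 1, air = 0).
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size = 6,
                         airway_tree = list(), acinar_clusters = list(),
                         vessel_tree = list(),
                         deformation = deformation_spec(),
                         noise_sigma = 0.05, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 32),
              "grid_shape must be three integers >= 32")
  assert_that(inherits(deformation, "deformation_spec"), "deformation must be a deformation_spec")
  assert_that(noise_sigma >= 0 && noise_sigma <= 0.2,
              "noise_sigma must keep air at least 5 sigma below tissue")
  spec <- structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         airway_tree = airway_tree, acinar_clusters = acinar_clusters,
         vessel_tree = vessel_tree, deformation = deformation,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

# ---- internal geometry ------------------------------------------------------

# expand the spec into primitive structures:
# type: "sphere" (center, r) or "cylinder" (base, dir, L, r)
# role: "conducting", "terminal_duct", "alveolus", "vessel"
# class: label class name; unit: cluster index or NA
build_structures <- function(spec) {
  structs <- list()
  for (br in spec$airway_tree) {
    structs[[length(structs) + 1L]] <- list(
      type = "cylinder", base = br$start, dir = br$direction, L = br$length,
      r = br$radius, role = "conducting", class = br$class, unit = NA_integer_,
      name = br$name)
  }
  for (ci in seq_along(spec$acinar_clusters)) {
    cl <- spec$acinar_clusters[[ci]]
    d <- cl$duct_direction
    base <- cl$center - d * cl$duct_length / 2
    structs[[length(structs) + 1L]] <- list(
      type = "cylinder", base = base, dir = d, L = cl$duct_length,
      r = cl$duct_radius, role = "terminal_duct", class = "terminal",
      unit = ci, name = paste0(cl$name, "/duct"))
    # two unit vectors orthogonal to the duct axis
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    ring_r <- cl$duct_radius + cl$alveolus_radius + cl$clearance
    # ring layout: fill rings of up to k_max alveoli spaced along the axis
    min_sep <- 2 * cl$alveolus_radius * (1 + 0.6)  # surfaces + taper clearance
    k_max <- max(3L, floor(pi / asin(pmin(1, min_sep / (2 * ring_r)))))
    n_rings <- ceiling(cl$n_alveoli / k_max)
    margin <- cl$alveolus_radius
    zpos <- if (n_rings == 1) 0 else
      seq(-cl$duct_length / 2 + margin, cl$duct_length / 2 - margin,
          length.out = n_rings)
    placed <- 0L
    for (ri in seq_len(n_rings)) {
      k <- min(k_max, cl$n_alveoli - placed)
      for (j in seq_len(k)) {
        ang <- 2 * pi * (j - 1) / k + (ri - 1) * pi / k_max
        ctr <- cl$center + d * zpos[ri] +
          ring_r * (cos(ang) * e1 + sin(ang) * e2)
        structs[[length(structs) + 1L]] <- list(
          type = "sphere", center = ctr, r = cl$alveolus_radius,
          role = "alveolus", class = "terminal", unit = ci,
          name = sprintf("%s/alv%02d", cl$name, placed + j))
      }
      placed <- placed + k
    }
  }
  for (br in spec$vessel_tree) {
    structs[[length(structs) + 1L]] <- list(
      type = "cylinder", base = br$start, dir = br$direction, L = br$length,
      r = br$radius, role = "vessel", class = "vessel", unit = NA_integer_,
      name = br$name)
  }
  structs
}

recruitment_step <- function(def, unit) {
  for (ev in def$recruitment_events)
    if (ev[1] == unit) return(ev[2])
  0L
}

structure_active <- function(st, def, step) {
  if (def$mode != "recruitment" || is.na(st$unit)) return(TRUE)
  step >= recruitment_step(def, st$unit)
}

# geometric parameters of a structure at inflation fraction a, per mode
transform_structure <- function(st, def, a, center) {
  mode <- def$mode
  s <- st
  if (mode %in% c("isotropic", "recruitment")) {
    f <- 1 + a
    if (s$type == "sphere") {
      s$center <- center + f * (s$center - center); s$r <- f * s$r
    } else {
      s$base <- center + f * (s$base - center); s$L <- f * s$L; s$r <- f * s$r
    }
  } else if (mode == "alveolar_dominant") {
    if (s$role == "alveolus") s$r <- (1 + a) * s$r
  } else if (mode == "ductal_dominant") {
    if (s$type == "cylinder" && s$role %in% c("conducting", "terminal_duct"))
      s$r <- (1 + a) * s$r
  }
  s
}

structure_bbox <- function(st) {
  if (st$type == "sphere") {
    rbind(st$center - st$r, st$center + st$r)
  } else {
    mid <- st$base + st$dir * st$L / 2
    half <- abs(st$dir) * st$L / 2 + st$r * sqrt(pmax(0, 1 - st$dir^2))
    rbind(mid - half, mid + half)
  }
}

# fraction of each voxel inside the structure, on the structure's sub-grid
voxelize_structure <- function(st, dims, h, supersample = 2L) {
  bb <- structure_bbox(st)
  lo <- pmax(1L, floor(bb[1, ] / h) + 1L - 1L)
  hi <- pmin(dims, ceiling(bb[2, ] / h) + 1L + 1L)
  if (any(lo > hi)) return(NULL)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  xs <- (ix - 1) * h; ys <- (iy - 1) * h; zs <- (iz - 1) * h
  offs <- if (supersample > 1L) {
    o <- (seq_len(supersample) - 0.5) / supersample - 0.5
    as.matrix(expand.grid(o, o, o)) * h
  } else matrix(0, 1, 3)
  frac <- array(0, dim = c(nx, ny, nz))
  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  for (k in seq_len(nrow(offs))) {
    px <- X + offs[k, 1]; py <- Y + offs[k, 2]; pz <- Z + offs[k, 3]
    inside <- if (st$type == "sphere") {
      (px - st$center[1])^2 + (py - st$center[2])^2 + (pz - st$center[3])^2 <= st$r^2
    } else {
      dx <- px - st$base[1]; dy <- py - st$base[2]; dz <- pz - st$base[3]
      t <- dx * st$dir[1] + dy * st$dir[2] + dz * st$dir[3]
      rho2 <- dx^2 + dy^2 + dz^2 - t^2
      t >= 0 & t <= st$L & rho2 <= st$r^2
    }
    frac <- frac + inside
  }
  list(ix = ix, iy = iy, iz = iz, frac = frac / nrow(offs))
}

structure_volume <- function(st) {
  if (st$type == "sphere") 4 / 3 * pi * st$r^3 else pi * st$r^2 * st$L
}

structure_surface <- function(st) {
  if (st$type == "sphere") 4 * pi * st$r^2 else 2 * pi * st$r * st$L + 2 * pi * st$r^2
}

validate_phantom_spec <- function(spec) {
  h <- spec$voxel_size
  structs <- build_structures(spec)
  assert_that(length(structs) > 0, "phantom has no structures")
  ext <- (spec$grid_shape - 1) * h
  amax <- spec$deformation$amplitude
  for (st in structs) {
    r_vox <- st$r / h
    assert_that(r_vox >= 2, "radius of '%s' is below 2 voxels", st$name)
    worst <- transform_structure(st, spec$deformation, amax, ext / 2)
    bb <- structure_bbox(worst)
    local_mode <- spec$deformation$mode %in% c("ductal_dominant", "alveolar_dominant")
    pad <- h + if (local_mode) spec$deformation$taper * worst$r else 0
    if (any(bb[1, ] < pad) || any(bb[2, ] > ext - pad))
      stop_("structure '%s' exceeds the grid at maximal deformation", st$name)
  }
  invisible(TRUE)
}

# ---- analytic displacement --------------------------------------------------

# quintic smoothstep falloff: q(0) = 1, q(1) = 0, q' = 0 at both ends
taper_fun <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  1 - (10 * s^3 - 15 * s^4 + 6 * s^5)
}
taper_deriv <- function(s) {
  inside <- s > 0 & s < 1
  out <- numeric(length(s))
  out[inside] <- -(30 * s[inside]^2 - 60 * s[inside]^3 + 30 * s[inside]^4)
  out
}

# radial field about a point with unit response inside R1, tapering to 0 at R2
sphere_local_field <- function(points, q, a, R1, R2) {
  dx <- sweep(points, 2, q)
  r <- sqrt(rowSums(dx^2))
  s <- (r - R1) / (R2 - R1)
  tau <- ifelse(r <= R1, 1, taper_fun(s))
  dtau <- ifelse(r <= R1, 0, taper_deriv(s) / (R2 - R1))
  u <- dx * (a * tau)
  div <- a * (3 * tau + r * dtau)
  list(u = u, div = div)
}

# radial field about a cylinder axis (base b, unit dir d, length L)
cylinder_local_field <- function(points, b, d, L, a, R1, R2) {
  dx <- sweep(points, 2, b)
  t <- as.vector(dx %*% d)
  ax <- outer(t, d)
  rad <- dx - ax
  rho <- sqrt(rowSums(rad^2))
  s <- (rho - R1) / (R2 - R1)
  tau <- ifelse(rho <= R1, 1, taper_fun(s))
  dtau <- ifelse(rho <= R1, 0, taper_deriv(s) / (R2 - R1))
  # axial window: full response along the segment, smooth 0 beyond one radius
  w_ax <- R1
  eta <- taper_fun(pmax(pmax(-t, t - L), 0) / w_ax)
  u <- rad * (a * tau * eta)
  div <- a * eta * (2 * tau + rho * dtau)
  # axial falloff contributes u . grad(eta) = 0 since u is normal to the axis
  list(u = u, div = div)
}

#' Analytic phantom displacement field
#'
#' Evaluates the exact deformation field of a phantom at arbitrary physical
#' points and phase step, along with its exact divergence (with respect to
#' the reference coordinates), so downstream operators can be validated
#' without numerical differentiation.
#'
#' @param spec a [phantom_spec()] (geometry is needed for the locally
#'   deforming modes) or a [deformation_spec()] for `isotropic` /
#'   `custom_analytic` modes (then `center` must be given).
#' @param points n x 3 matrix of physical coordinates (micrometres).
#' @param step phase index, 0-based.
#' @param center expansion centre for `isotropic` mode when `spec` is a bare
#'   [deformation_spec()].
#' @return list with `u` (n x 3 displacement, micrometres) and `div`
#'   (exact divergence, dimensionless).
#' @export
analytic_displacement <- function(spec, points, step, center = NULL) {
  points <- as.matrix(points)
  assert_that(ncol(points) == 3, "points must be an n x 3 matrix")
  if (inherits(spec, "phantom_spec")) {
    def <- spec$deformation
    if (is.null(center)) center <- (spec$grid_shape - 1) * spec$voxel_size / 2
    structs <- build_structures(spec)
  } else if (inherits(spec, "deformation_spec")) {
    def <- spec
    structs <- NULL
  } else stop_("spec must be a phantom_spec or deformation_spec")
  assert_that(step >= 0 && step < def$n_steps, "step out of range")
  w <- def$waveform(step / def$n_steps)
  a <- def$amplitude * w

  if (def$mode == "custom_analytic") {
    return(list(u = def$custom$displacement(points, w),
                div = def$custom$divergence(points, w)))
  }
  if (def$mode %in% c("isotropic", "recruitment")) {
    assert_that(!is.null(center), "isotropic mode needs an expansion centre")
    u <- sweep(points, 2, center) * a
    return(list(u = u, div = rep(3 * a, nrow(points))))
  }
  assert_that(!is.null(structs),
              "mode '%s' needs the phantom geometry: pass the phantom_spec", def$mode)
  u <- matrix(0, nrow(points), 3)
  div <- numeric(nrow(points))
  for (st in structs) {
    if (def$mode == "alveolar_dominant" && st$role == "alveolus") {
      R1 <- st$r * (1 + def$amplitude)
      R2 <- R1 + def$taper * st$r
      f <- sphere_local_field(points, st$center, a, R1, R2)
    } else if (def$mode == "ductal_dominant" &&
               st$type == "cylinder" && st$role %in% c("conducting", "terminal_duct")) {
      R1 <- st$r * (1 + def$amplitude)
      R2 <- R1 + def$taper * st$r
      f <- cylinder_local_field(points, st$base, st$dir, st$L, a, R1, R2)
    } else next
    u <- u + f$u
    div <- div + f$div
  }
  list(u = u, div = div)
}

# dense Lagrangian field over the voxel grid, in voxel units
dense_truth_field <- function(spec, step) {
  dims <- spec$grid_shape
  h <- spec$voxel_size
  g <- coord_grid(dims, h)
  pts <- cbind(
    rep(g$x, times = dims[2] * dims[3]),
    rep(rep(g$y, each = dims[1]), times = dims[3]),
    rep(g$z, each = dims[1] * dims[2])
  )
  f <- analytic_displacement(spec, pts, step)
  u <- array(f$u / h, dim = c(dims, 3))
  attr(u, "div") <- array(f$div, dim = dims)
  u
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic 4D micro-CT series with ground truth
#'
#' Produces one greyscale volume per phase step (tissue = 1, air = 0,
#' blood = 0.8, additive Gaussian noise, supersampled partial-volume
#' edges) together with exact ground truth: per-step label volumes, exact
#' Lagrangian displacement fields, analytic volume and surface-area series of
#' the terminal airspaces, and the set of recruited units.
#'
#' @param spec a [phantom_spec()].
#' @param with_fields materialise the dense ground-truth Lagrangian fields
#'   (one per step); disable to save memory when only images are needed.
#' @param supersample linear supersampling factor for partial-volume
#'   greyscale and majority-occupancy labels (1 disables anti-aliasing; odd
#'   values avoid occupancy ties and give the least volume bias).
#' @param breath_duration breath length in seconds used for the phase times.
#' @return list with `series` (a [volume_series()]) and `truth` (class
#'   `phantom_truth`: `labels`, `fields`, `V_series`, `S_series`,
#'   `recruited_ids`, `omega0`).
#' @export
generate_phantom <- function(spec, with_fields = TRUE, supersample = 3L,
                             breath_duration = 0.76) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  validate_phantom_spec(spec)
  def <- spec$deformation
  dims <- spec$grid_shape
  h <- spec$voxel_size
  n <- def$n_steps
  center <- (dims - 1) * h / 2
  structs <- build_structures(spec)
  class_code <- c(proximal = 1L, intermediate = 2L, terminal = 3L, vessel = 4L)

  volumes <- vector("list", n)
  labels <- vector("list", n)
  fields <- if (with_fields) vector("list", n) else NULL
  V_series <- numeric(n)
  S_series <- numeric(n)

  noise <- with_seed(spec$seed, {
    lapply(seq_len(n), function(i)
      if (spec$noise_sigma > 0)
        array(rnorm(prod(dims), sd = spec$noise_sigma), dim = dims)
      else array(0, dim = dims))
  })

  for (si in seq_len(n)) {
    step <- si - 1L
    a <- def$amplitude * def$waveform(step / n)
    grey <- array(1, dim = dims)
    lab <- array(0L, dim = dims)
    air_frac <- array(0, dim = dims)
    vess_frac <- array(0, dim = dims)
    for (st in structs) {
      if (!structure_active(st, def, step)) next
      ts <- transform_structure(st, def, a, center)
      vx <- voxelize_structure(ts, dims, h, supersample)
      if (is.null(vx)) next
      sl <- list(vx$ix, vx$iy, vx$iz)
      if (st$role == "vessel") {
        cur <- vess_frac[sl[[1]], sl[[2]], sl[[3]]]
        vess_frac[sl[[1]], sl[[2]], sl[[3]]] <- pmax(cur, vx$frac)
      } else {
        cur <- air_frac[sl[[1]], sl[[2]], sl[[3]]]
        air_frac[sl[[1]], sl[[2]], sl[[3]]] <- pmax(cur, vx$frac)
      }
      # majority-occupancy labels, first structure wins at junctions
      curlab <- lab[sl[[1]], sl[[2]], sl[[3]]]
      hit <- vx$frac >= 0.5 & curlab == 0L
      curlab[hit] <- class_code[[ts$class]]
      lab[sl[[1]], sl[[2]], sl[[3]]] <- curlab

      if (st$role %in% c("terminal_duct", "alveolus")) {
        V_series[si] <- V_series[si] + structure_volume(ts)
        S_series[si] <- S_series[si] + structure_surface(ts)
      }
    }
    grey <- grey - air_frac - 0.2 * vess_frac + noise[[si]]
    volumes[[si]] <- grey
    labels[[si]] <- segmented_volume(lab, "airspace", voxel_size = h, phase = step)
    if (with_fields) {
      u <- dense_truth_field(spec, step)
      dv <- attr(u, "div"); attr(u, "div") <- NULL
      fld <- displacement_field(u, "lagrangian", 0L, step, voxel_size = h)
      fld$div <- dv
      fields[[si]] <- fld
    }
  }

  times <- (seq_len(n) - 1) / n * breath_duration
  truth <- structure(
    list(labels = labels, fields = fields,
         V_series = V_series, S_series = S_series,
         recruited_ids = vapply(def$recruitment_events, function(e) e[1], numeric(1)),
         omega0 = omega_mask(labels[[1]], c("proximal", "intermediate", "terminal")),
         center = center, structures = structs),
    class = "phantom_truth"
  )
  list(series = volume_series(volumes, voxel_size = h, times = times),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d steps, V0 = %.4g, S0 = %.4g, %d recruited unit(s)\n",
              length(x$labels), x$V_series[1], x$S_series[1],
              length(x$recruited_ids)))
  invisible(x)
}

#' Canonical study phantom
#'
#' A ready-made specification used throughout the package's examples and
#' validation: one proximal bronchus, one acinar cluster (alveolar duct plus
#' 18 alveoli) sized so that the alveolar-dominant regime has a surface-volume
#' exponent near 0.85, and one vessel branch, on a 64-voxel cube.
#'
#' @param mode deformation mode passed to [deformation_spec()].
#' @param amplitude,n_steps,noise_sigma,seed see [phantom_spec()] /
#'   [deformation_spec()].
#' @param recruitment_events passed through for `mode = "recruitment"`; the
#'   default recruits a second small cluster (unit 2) at step 4.
#' @return a [phantom_spec()].
#' @export
phantom_study_spec <- function(mode = "isotropic", amplitude = 0.05,
                               n_steps = 10L, noise_sigma = 0.05, seed = 1L,
                               recruitment_events = list(c(2, 4))) {
  h <- 1  # geometry in voxel units: voxel_size 1 um for convenience
  clusters <- list(
    acinar_cluster(center = c(38, 38, 31), duct_radius = 6, duct_length = 36,
                   duct_direction = c(0, 0, 1), alveolus_radius = 4,
                   n_alveoli = 18, clearance = 3, name = "acinus1")
  )
  if (mode == "recruitment") {
    clusters[[2]] <- acinar_cluster(
      center = c(14, 50, 46), duct_radius = 3, duct_length = 14,
      duct_direction = c(0, 1, 0), alveolus_radius = 3, n_alveoli = 3,
      clearance = 0.4, name = "acinus2")
  }
  phantom_spec(
    grid_shape = c(64, 64, 64), voxel_size = h,
    airway_tree = list(
      branch_segment(start = c(13, 13, 8), direction = c(0, 0, 1),
                     length = 48, radius = 8, class = "proximal",
                     name = "bronchus")
    ),
    acinar_clusters = clusters,
    vessel_tree = list(
      branch_segment(start = c(52, 14, 10), direction = c(0, 0, 1),
                     length = 40, radius = 4, class = "proximal",
                     name = "artery")
    ),
    deformation = deformation_spec(
      mode = mode, amplitude = amplitude, n_steps = n_steps,
      recruitment_events = if (mode == "recruitment") recruitment_events else list()),
    noise_sigma = noise_sigma, seed = seed
  )
}
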