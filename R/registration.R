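# Pairwise non-rigid registration (cubic B-spline free-form deformation,
# SSD similarity + Laplacian smoothness on the coefficient grid) and
# composition of pairwise fields into Lagrangian displacement fields.

#' B-spline registration model settings
#'
#' @param spacing control-point spacing in voxels (>= 4) at the finest level.
#' @param lambda weight of the Laplacian regularisation of the coefficient
#'   grid (per-axis second differences).
#' @param levels multiresolution levels (1 = single resolution; each coarser
#'   level halves the grid).
#' @param max_iter gradient-descent iterations per level.
#' @param tol relative objective decrease below which iteration stops.
#' @param step0 initial trial step expressed as the coefficient change (in
#'   voxels) granted to the largest gradient component.
#' @param smooth_sigma Gaussian pre-smoothing (voxels) applied to both
#'   volumes at every level before the similarity is evaluated; suppresses
#'   the noise floor of the SSD landscape.
#' @return object of class `bspline_model`.
#' @export
bspline_model <- function(spacing = 8, lambda = 0.05, levels = 2,
                          max_iter = 40, tol = 1e-7, step0 = 1,
                          smooth_sigma = 1.5) {
  assert_that(spacing >= 4, "control spacing must be at least 4 voxels")
  assert_that(lambda >= 0, "lambda must be non-negative")
  structure(
    list(spacing = spacing, lambda = lambda, levels = as.integer(levels),
         max_iter = as.integer(max_iter), tol = tol, step0 = step0,
         smooth_sigma = smooth_sigma),
    class = "bspline_model"
  )
}

n_ctrl <- function(dim, spacing) as.integer(floor((dim - 1) / spacing) + 4)

# value and exact gradient of the per-axis second-difference penalty,
# normalised per coefficient
lap_penalty <- function(coef) {
  d <- dim(coef)
  val <- 0
  grad <- array(0, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 3) next
    r <- switch(ax,
      coef[1:(n - 2), , , , drop = FALSE] - 2 * coef[2:(n - 1), , , , drop = FALSE] + coef[3:n, , , , drop = FALSE],
      coef[, 1:(n - 2), , , drop = FALSE] - 2 * coef[, 2:(n - 1), , , drop = FALSE] + coef[, 3:n, , , drop = FALSE],
      coef[, , 1:(n - 2), , drop = FALSE] - 2 * coef[, , 2:(n - 1), , drop = FALSE] + coef[, , 3:n, , drop = FALSE])
    val <- val + sum(r^2)
    add <- function(g, r, off) {
      switch(ax,
        { g[(1 + off):(n - 2 + off), , , ] <- g[(1 + off):(n - 2 + off), , , ] + r; g },
        { g[, (1 + off):(n - 2 + off), , ] <- g[, (1 + off):(n - 2 + off), , ] + r; g },
        { g[, , (1 + off):(n - 2 + off), ] <- g[, , (1 + off):(n - 2 + off), ] + r; g })
    }
    grad <- add(grad, 2 * r, 0L)
    grad <- add(grad, -4 * r, 1L)
    grad <- add(grad, 2 * r, 2L)
  }
  nc <- prod(d)
  list(value = val / nc, grad = grad / nc)
}

downsample2 <- function(vol) {
  d <- dim(vol)
  d2 <- d %/% 2L
  v <- vol[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3])]
  (v[seq(1, 2 * d2[1], 2), seq(1, 2 * d2[2], 2), seq(1, 2 * d2[3], 2)] +
   v[seq(2, 2 * d2[1], 2), seq(1, 2 * d2[2], 2), seq(1, 2 * d2[3], 2)] +
   v[seq(1, 2 * d2[1], 2), seq(2, 2 * d2[2], 2), seq(1, 2 * d2[3], 2)] +
   v[seq(2, 2 * d2[1], 2), seq(2, 2 * d2[2], 2), seq(1, 2 * d2[3], 2)] +
   v[seq(1, 2 * d2[1], 2), seq(1, 2 * d2[2], 2), seq(2, 2 * d2[3], 2)] +
   v[seq(2, 2 * d2[1], 2), seq(1, 2 * d2[2], 2), seq(2, 2 * d2[3], 2)] +
   v[seq(1, 2 * d2[1], 2), seq(2, 2 * d2[2], 2), seq(2, 2 * d2[3], 2)] +
   v[seq(2, 2 * d2[1], 2), seq(2, 2 * d2[2], 2), seq(2, 2 * d2[3], 2)]) / 8
}

# dense field (array dims x 3) from coefficients at one level
dense_from_coef <- function(coef, dims, spacing) {
  array(bs_dense_cpp(as.numeric(coef), dim(coef)[1:3], spacing, dims),
        dim = c(dims, 3))
}

# single-level solve; returns coefficient array
solve_level <- function(fixed, moving, model, spacing) {
  dims <- vol_dims(fixed)
  nc <- vapply(dims, n_ctrl, integer(1), spacing = spacing)
  coef <- array(0, dim = c(nc, 3))
  g <- array_gradient(moving)
  ssd <- function(cf, want_grad) {
    bs_ssd_cpp(as.numeric(fixed), as.numeric(moving),
               as.numeric(g$gx), as.numeric(g$gy), as.numeric(g$gz),
               dims, as.numeric(cf), nc, spacing, want_grad)
  }
  objective <- function(cf) {
    s <- ssd(cf, FALSE)$value
    s + model$lambda * lap_penalty(cf)$value
  }
  f0 <- NULL
  trace <- numeric(0)
  alpha <- NA_real_
  for (it in seq_len(model$max_iter)) {
    s <- ssd(coef, TRUE)
    lp <- lap_penalty(coef)
    f <- s$value + model$lambda * lp$value
    grad <- array(s$grad, dim = c(nc, 3)) + model$lambda * lp$grad
    gmax <- max(abs(grad))
    if (gmax < 1e-14) break
    if (is.na(alpha)) alpha <- model$step0 / gmax
    gnorm2 <- sum(grad^2)
    # Armijo backtracking with growth on immediate acceptance
    accepted <- FALSE
    grew <- FALSE
    for (ls in 1:30) {
      cand <- coef - alpha * grad
      fc <- objective(cand)
      if (fc <= f - 1e-4 * alpha * gnorm2) { accepted <- TRUE; grew <- ls == 1; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    coef <- cand
    trace <- c(trace, fc)
    if (grew) alpha <- alpha * 2
    if (is.null(f0)) f0 <- f
    else if ((f - fc) < model$tol * max(f0, 1e-12)) break
  }
  attr(coef, "trace") <- trace
  coef
}

#' Register a pair of volumes
#'
#' Estimates the dense displacement field u such that
#' `fixed(x) ~ moving(x + u(x))`: with `fixed` the earlier phase and `moving`
#' the next one, u is the forward motion of material points between the two
#' phases, sampled at the voxels of the earlier phase. Minimises mean SSD
#' plus a Laplacian penalty over cubic B-spline coefficients, coarse-to-fine,
#' by gradient descent with Armijo line search.
#'
#' @param fixed,moving numeric 3D arrays on the same grid.
#' @param model a [bspline_model()].
#' @param from_step,to_step phase bookkeeping for the result.
#' @param voxel_size metadata.
#' @return a [displacement_field()] (kind "pairwise" when
#'   `to_step == from_step + 1`, otherwise kind "lagrangian" if
#'   `from_step == 0`), with attribute `trace`: a list of per-level objective
#'   traces, each monotone non-increasing.
#' @export
register_pair <- function(fixed, moving, model = bspline_model(),
                          from_step = 0L, to_step = 1L, voxel_size = 1) {
  dims <- vol_dims(fixed)
  assert_that(identical(dims, vol_dims(moving)), "fixed and moving must share one grid")
  assert_that(all(is.finite(fixed)) && all(is.finite(moving)),
              "volumes must be finite everywhere")
  total <- array(0, dim = c(dims, 3))
  trace <- list()
  for (lev in seq_len(model$levels)) {
    f <- 2^(model$levels - lev)
    if (any(dims %/% f < 4 * model$spacing) && lev < model$levels) next
    # prewarp moving by the field accumulated so far
    mw <- if (max(abs(total)) > 0)
      array(warp_volume_cpp(as.numeric(moving), as.numeric(total), dims)$warped, dim = dims)
    else moving
    fl <- fixed; ml <- mw
    for (k in seq_len(log2(f))) { fl <- downsample2(fl); ml <- downsample2(ml) }
    if (model$smooth_sigma > 0) {
      fl <- smooth_volume(fl, model$smooth_sigma)
      ml <- smooth_volume(ml, model$smooth_sigma)
    }
    coef <- solve_level(fl, ml, model, model$spacing)
    trace[[length(trace) + 1]] <- attr(coef, "trace")
    ul <- dense_from_coef(coef, vol_dims(fl), model$spacing)
    if (f > 1) {
      # upsample the level field to full resolution (scale values by f)
      pts <- as.matrix(expand.grid(
        x = (seq_len(dims[1]) - 1) / f + 1,
        y = (seq_len(dims[2]) - 1) / f + 1,
        z = (seq_len(dims[3]) - 1) / f + 1))
      up <- field_at_points_cpp(as.numeric(ul), vol_dims(fl), pts)$values * f
      ures <- array(up, dim = c(dims, 3))
    } else ures <- ul
    total <- total + ures
  }
  kind <- if (to_step == from_step + 1) "pairwise" else "lagrangian"
  fld <- displacement_field(total, kind, from_step, to_step, voxel_size)
  attr(fld, "trace") <- trace
  fld
}

#' Register a whole phase series pairwise
#'
#' @param series a [volume_series()].
#' @param model a [bspline_model()].
#' @return list of pairwise [displacement_field()]s (step n-1 to n).
#' @export
register_series <- function(series, model = bspline_model()) {
  n <- length(series$volumes)
  assert_that(n >= 2, "need at least two phases")
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    out[[i]] <- register_pair(series$volumes[[i]], series$volumes[[i + 1]],
                              model, from_step = i - 1L, to_step = i,
                              voxel_size = series$voxel_size)
  }
  out
}

#' Compose pairwise fields into Lagrangian displacement fields
#'
#' Applies the recursion u(x; 0, n) = u(x; 0, n-1) + u*(x + u(x; 0, n-1)),
#' interpolating each pairwise field at the advected position (trilinear).
#' Advected positions that leave the grid are clamped and flagged in the
#' out-of-domain mask.
#'
#' @param pairwise list of consecutive pairwise [displacement_field()]s.
#' @return list of Lagrangian [displacement_field()]s for steps 1..N; each
#'   has an `oob` logical array.
#' @export
compose_lagrangian <- function(pairwise) {
  assert_that(length(pairwise) >= 1, "empty list of pairwise fields")
  dims <- dim(pairwise[[1]]$u)[1:3]
  for (i in seq_along(pairwise)) {
    assert_that(identical(dim(pairwise[[i]]$u)[1:3], dims),
                "pairwise fields must share one grid")
    if (i > 1)
      assert_that(pairwise[[i]]$from_step == pairwise[[i - 1]]$to_step,
                  "pairwise fields must be consecutive")
  }
  out <- vector("list", length(pairwise))
  u <- array(0, dim = c(dims, 3))
  oob <- array(FALSE, dim = dims)
  for (i in seq_along(pairwise)) {
    ustar <- pairwise[[i]]$u
    inc <- array(0, dim = c(dims, 3))
    for (c in 1:3) {
      w <- warp_volume_cpp(as.numeric(ustar[, , , c]), as.numeric(u), dims)
      inc[, , , c] <- array(w$warped, dim = dims)
      oob <- oob | array(w$oob, dim = dims)
    }
    u <- u + inc
    out[[i]] <- displacement_field(u, "lagrangian", 0L, pairwise[[i]]$to_step,
                                   voxel_size = pairwise[[i]]$voxel_size,
                                   oob = oob)
  }
  out
}

#' Registration quality metric: composed versus direct field
#'
#' The error is the voxel-wise magnitude of the difference between the
#' Lagrangian field accumulated through the series and a direct single-pair
#' registration between the same endpoints, normalised by the maximum
#' magnitude of the direct field.
#'
#' @param composed,direct [displacement_field()]s on one grid.
#' @param omega optional logical mask over which summary statistics are taken.
#' @return object of class `registration_error`: `eps` (3D array), `mean`,
#'   `max`, `max_direct`.
#' @export
registration_error <- function(composed, direct, omega = NULL) {
  assert_that(identical(dim(composed$u), dim(direct$u)),
              "fields must share one grid")
  mag_direct <- field_magnitude(direct)
  m <- max(mag_direct)
  assert_that(m > 0, "direct field is identically zero: error metric undefined")
  diff <- composed$u - direct$u
  eps <- sqrt(diff[, , , 1]^2 + diff[, , , 2]^2 + diff[, , , 3]^2) / m
  sel <- if (is.null(omega)) rep(TRUE, length(eps)) else as.logical(omega)
  structure(
    list(eps = eps, mean = mean(eps[sel]), max = max(eps[sel]), max_direct = m),
    class = "registration_error"
  )
}

#' @export
print.registration_error <- function(x, ...) {
  cat(sprintf("<registration_error> mean |eps| = %.4g, max = %.4g (direct max |u| = %.3g vox)\n",
              x$mean, x$max, x$max_direct))
  invisible(x)
}

#' Warp a segmentation by a displacement field (nearest neighbour)
#'
#' @param seg a [segmented_volume()] or integer array.
#' @param field a [displacement_field()]; the label at x is looked up at
#'   the advected source position x + u(x).
#' @return object of the same type as `seg`.
#' @export
warp_segmentation <- function(seg, field) {
  labels <- if (inherits(seg, "segmented_volume")) seg$labels else seg
  d <- vol_dims(labels)
  out <- array(warp_labels_nn_cpp(as.integer(labels), as.numeric(field$u), d), dim = d)
  if (inherits(seg, "segmented_volume")) {
    seg$labels <- out
    seg$phase <- field$to_step
    seg
  } else out
}
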