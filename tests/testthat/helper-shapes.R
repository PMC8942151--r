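# Geometric fixtures shared across tests: digital balls and cylinders with
# half-integer centres (so no voxel centre sits exactly on the surface), and
# small phantom specifications.

digital_ball <- function(r, n = 2 * ceiling(r) + 9, center = rep((n + 1) / 2, 3)) {
  x2 <- (seq_len(n) - center[1])^2
  y2 <- (seq_len(n) - center[2])^2
  z2 <- (seq_len(n) - center[3])^2
  outer(outer(x2, y2, "+"), z2, "+") <= r^2
}

# axis-aligned (z) cylinder with flat caps
digital_cylinder <- function(r, L, n = 2 * ceiling(r) + 9, pad = 4) {
  nz <- L + 2 * pad
  x2 <- (seq_len(n) - (n + 1) / 2)^2
  disc <- outer(x2, x2, "+") <= r^2
  out <- array(FALSE, c(n, n, nz))
  for (z in (pad + 1):(pad + L)) out[, , z] <- disc
  out
}

# cylinder along an arbitrary axis
oriented_cylinder <- function(base, dir, L, r, dims) {
  dir <- dir / sqrt(sum(dir^2))
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  dx <- g$x - base[1]; dy <- g$y - base[2]; dz <- g$z - base[3]
  t <- dx * dir[1] + dy * dir[2] + dz * dir[3]
  array(t >= 0 & t <= L & (dx^2 + dy^2 + dz^2 - t^2) <= r^2, dims)
}

# dense field array from a function of voxel positions (1-based indices)
field_from_function <- function(dims, fn) {
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  U <- fn(g)
  array(c(U[, 1], U[, 2], U[, 3]), c(dims, 3))
}

tiny_phantom_spec <- function(mode = "isotropic", amplitude = 0.05,
                              n_steps = 5, noise_sigma = 0.05, seed = 1) {
  phantom_study_spec(mode, amplitude = amplitude, n_steps = n_steps,
                     noise_sigma = noise_sigma, seed = seed)
}
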