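# Shared fixtures: small geometries, models, and dense test-only oracles.
# Dense-Jacobian oracles are restricted to tiny instances (Nx, Ny <= 64-ish).

tiny_geometry <- function(n = 6, n_angles = 10, n_det = NULL,
                          pixel_size = 1 / n) {
  ct_geometry(
    n,
    angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)],
    n_detector_bins = n_det %||% max(n, ceiling(1.5 * n)),
    pixel_size = pixel_size
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_model <- function(M = 2, B = 3, E = 8, seed = 1) {
  make_spectral_model(M = M, B = B, E = E, e_max = 150, seed = seed)
}

# monochromatic single-material model: H is exactly linear, H(X) = -(AX) mu
mono_model <- function(mu = 2, s = 1.5) {
  spectral_model(60, matrix(mu, 1, 1), matrix(s, 1, 1), materials = "water")
}

random_image <- function(P, M, lo = 0, hi = 0.5) {
  matrix(stats::runif(ncol(P$A) * M, lo, hi), ncol = M)
}

# Dense Jacobian of H at X, columns = dH_apply on unit tangents
dense_jacobian_H <- function(model, P, X) {
  Nx <- nrow(X)
  M <- ncol(X)
  stopifnot(Nx <= 64)
  cols <- lapply(seq_len(Nx * M), function(j) {
    e <- matrix(0, Nx, M)
    e[j] <- 1
    as.vector(dH_apply(model, P, X, e))
  })
  do.call(cbind, cols)
}

# Dense Jacobian of Phi at Z, columns = dPhi_apply on unit perturbations
dense_jacobian_phi <- function(model, Z) {
  Ny <- nrow(Z)
  M <- ncol(Z)
  stopifnot(Ny <= 64)
  cols <- lapply(seq_len(Ny * M), function(j) {
    e <- matrix(0, Ny, M)
    e[j] <- 1
    as.vector(dPhi_apply(model, Z, e))
  })
  do.call(cbind, cols)
}

# Independent ray-length oracle: fraction of finely sampled points of the
# ray segment inside each pixel, times the segment length.
ray_lengths_sampled <- function(n, h, theta, r, n_samples = 2e5) {
  half <- n * h / 2
  ct <- cos(theta)
  st <- sin(theta)
  span <- 2 * sqrt(2) * half
  t <- seq(-span / 2, span / 2, length.out = n_samples)
  px <- r * ct - t * st
  py <- r * st + t * ct
  inside <- px > -half & px < half & py > -half & py < half
  ix <- floor((px[inside] + half) / h)
  iy <- floor((py[inside] + half) / h)
  idx <- iy * n + ix + 1
  dt <- span / (n_samples - 1)
  counts <- tabulate(idx, nbins = n * n)
  counts * dt
}

rel_diff <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}

quiet_log_rescale <- function(model, Y) {
  suppressWarnings(log_rescale_data(model, Y))
}
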