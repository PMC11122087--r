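#' Polychromatic forward model F
#'
#' Evaluates the discrete Beer-Lambert forward map
#' `F(X) = exp(-A X t(Mu)) %*% t(S)` row by row: each ray's material line
#' integrals `A X` are mixed through the attenuation matrix into per-energy
#' optical depths, exponentiated, and integrated against each bin's
#' effective spectrum. Entries lie in `(0, max_b <S_b, 1>]` for nonnegative
#' images.
#'
#' @param model A [spectral_model()].
#' @param projector A [build_projector()] result.
#' @param X `Nx x M` material image matrix.
#' @return `Ny x B` matrix of modelled spectral measurements.
#' @export
forward_F <- function(model, projector, X) {
  Z <- apply_multichannel(projector, as_material_matrix(X, model))
  phi_forward_raw(model, Z)
}

# F restricted to the sinogram domain: exp(-Z Mu^T) S^T, with overflow guard.
phi_forward_raw <- function(model, Z) {
  W <- Z %*% t(model$attenuations)
  W <- clip_exponent(W)
  FX <- exp(-W) %*% t(model$spectra)
  if (any(!is.finite(FX))) {
    bad <- which(!is.finite(rowSums(FX)))[1]
    stop(sprintf("non-finite forward value at ray %d", bad), call. = FALSE)
  }
  FX
}

# Exponent arguments clipped at +/- 700 so exp() stays finite in double
# precision; a warning reports how many entries were affected.
clip_exponent <- function(W, limit = 700) {
  n_clip <- sum(abs(W) > limit)
  if (n_clip > 0) {
    warning(sprintf("clipped %d exponent argument(s) at |%g|", n_clip, limit),
            call. = FALSE)
    W <- pmin(pmax(W, -limit), limit)
  }
  W
}

# Blank (zero-object) measurement: every row is the vector of bin spectrum
# sums <S_b, 1>.
forward_F0 <- function(model, n_ray) {
  matrix(rowSums(model$spectra), nrow = n_ray, ncol = n_bins(model),
         byrow = TRUE)
}

#' Logarithmic forward model H
#'
#' `H(X) = log(F(X) / F(0))` entrywise — the recalibrated log-domain model.
#' `H(0) = 0` exactly, and `H` equals the channel nonlinearity applied to
#' the material sinogram, `H(X) = Phi(A X)`.
#'
#' @inheritParams forward_F
#' @return `Ny x B` matrix of log-domain model values.
#' @export
forward_H <- function(model, projector, X) {
  Z <- apply_multichannel(projector, as_material_matrix(X, model))
  phi_apply(model, Z)
}

#' Channel nonlinearity Phi on a material sinogram
#'
#' `Phi(Z) = log(exp(-Z t(Mu)) %*% t(Sbar))` with row-normalized spectra
#' `Sbar`, acting independently on each sinogram pixel (ray). Satisfies
#' `forward_H(model, P, X) = phi_apply(model, A X)` exactly and
#' `Phi(0) = 0`.
#'
#' @param model A [spectral_model()] (spectra are normalized internally).
#' @param Z `Ny x M` material sinogram.
#' @return `Ny x B` log-domain values.
#' @export
phi_apply <- function(model, Z) {
  nm <- normalize_spectra(model)
  Z <- as_sinogram_matrix(Z, model)
  log(phi_forward_raw(nm, Z))
}

#' Least-squares data-fit functional D
#'
#' `D(X) = ||H(X) - Y_H||^2 / 2` under the Frobenius inner product.
#'
#' @inheritParams forward_F
#' @param Y_H `Ny x B` recalibrated log data (see [log_rescale_data()]).
#' @return A nonnegative scalar.
#' @export
lsq_objective <- function(model, projector, X, Y_H) {
  R <- forward_H(model, projector, X) - check_data_shape(Y_H, projector, model)
  sum(R^2) / 2
}

#' Recalibrate measurements into log-domain data
#'
#' `Y_H = log(Y / F(0))`. Nonpositive measurements (possible under Poisson
#' noise) are floored at `floor_eps` times the smallest bin spectrum sum
#' before the logarithm; the number of floored entries is reported via a
#' warning so unstable rays are visible.
#'
#' @param model A [spectral_model()].
#' @param Y `Ny x B` matrix of measured spectral data.
#' @param floor_eps Relative flooring level (default `1e-12`).
#' @return `Ny x B` matrix `Y_H`.
#' @export
log_rescale_data <- function(model, Y, floor_eps = 1e-12) {
  Y <- as.matrix(Y)
  if (ncol(Y) != n_bins(model)) {
    stop("Y must have one column per energy bin", call. = FALSE)
  }
  floor_val <- floor_eps * min(rowSums(model$spectra))
  n_floored <- sum(Y < floor_val)
  if (n_floored > 0) {
    warning(sprintf("floored %d nonpositive/low measurement(s)", n_floored),
            call. = FALSE)
    Y <- pmax(Y, floor_val)
  }
  if (any(Y <= 0)) stop("nonpositive measurements remain after flooring",
                        call. = FALSE)
  log(Y / forward_F0(model, nrow(Y)))
}

#' Virtual spectrally resolved data Q_X
#'
#' The `E x Ny` matrix `Q_X = exp(-Mu (A X)^T)`: per-energy transmission
#' factors for each ray, the inner factor of the forward model and of every
#' derivative formula. Entries lie in `(0, 1]` for nonnegative images.
#'
#' @inheritParams forward_F
#' @return `E x Ny` matrix.
#' @export
virtual_spectral_data <- function(model, projector, X) {
  Z <- apply_multichannel(projector, as_material_matrix(X, model))
  t(exp(-clip_exponent(Z %*% t(model$attenuations))))
}

as_material_matrix <- function(X, model) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  if (ncol(X) != n_materials(model)) {
    stop(sprintf("image has %d channels but the model has %d materials",
                 ncol(X), n_materials(model)), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

as_sinogram_matrix <- function(Z, model) {
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1L)
  Z <- as.matrix(Z)
  if (ncol(Z) != n_materials(model)) {
    stop(sprintf("sinogram has %d channels but the model has %d materials",
                 ncol(Z), n_materials(model)), call. = FALSE)
  }
  storage.mode(Z) <- "double"
  Z
}

check_data_shape <- function(Y_H, projector, model) {
  Y_H <- as.matrix(Y_H)
  if (nrow(Y_H) != nrow(projector$A) || ncol(Y_H) != n_bins(model)) {
    stop(sprintf("data must be %d x %d, got %d x %d",
                 nrow(projector$A), n_bins(model), nrow(Y_H), ncol(Y_H)),
         call. = FALSE)
  }
  Y_H
}
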