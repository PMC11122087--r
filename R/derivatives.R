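#' Directional derivative of the logarithmic forward model
#'
#' Applies `H'[X]` to a tangent image `xi`:
#' `H'[X](xi) = -((Q * (A xi t(Mu))) %*% t(S)) / F(X)` with `Q` the
#' per-energy transmission factors at `X` (entrywise operations). At
#' `X = 0` this collapses to `-(A xi) t(U)` with the channel matrix `U`.
#'
#' @inheritParams forward_F
#' @param xi Tangent image, `Nx x M`.
#' @return `Ny x B` matrix `H'[X](xi)`.
#' @export
dH_apply <- function(model, projector, X, xi) {
  st <- spectral_state(model, projector, X)
  xi <- as_material_matrix(xi, model)
  Txi <- apply_multichannel(projector, xi) %*% t(model$attenuations)
  -((st$Q * Txi) %*% t(model$spectra)) / st$FX
}

#' Adjoint of the derivative of H
#'
#' Applies `H'[X]*` to cotangent data `eta`:
#' `H'[X]*(eta) = -t(A) %*% ((Q * ((eta / F(X)) %*% S)) %*% Mu)`. At `X = 0`
#' this collapses to `-t(A) %*% eta %*% U`.
#'
#' @inheritParams forward_F
#' @param eta Cotangent data, `Ny x B`.
#' @return `Nx x M` matrix `H'[X]*(eta)`.
#' @export
dH_adjoint <- function(model, projector, X, eta) {
  st <- spectral_state(model, projector, X)
  eta <- check_data_shape(eta, projector, model)
  G <- (eta / st$FX) %*% model$spectra
  -adjoint_multichannel(projector, (st$Q * G) %*% model$attenuations)
}

# Shared forward state: material sinogram Z, ray-wise transmission Q
# (Ny x E) and raw-spectra forward values FX (Ny x B). Q and FX appear in
# every derivative formula; the F(X)/F(0) recalibration cancels in the
# ratio, so raw spectra are used throughout.
spectral_state <- function(model, projector, X) {
  Z <- apply_multichannel(projector, as_material_matrix(X, model))
  Q <- exp(-clip_exponent(Z %*% t(model$attenuations)))
  FX <- Q %*% t(model$spectra)
  stopifnot(all(FX > 0))
  list(Z = Z, Q = Q, FX = FX)
}

#' Gradient of the least-squares functional
#'
#' `grad D[X] = H'[X]*(H(X) - Y_H)`, assembled from [forward_H()] and
#' [dH_adjoint()].
#'
#' @inheritParams lsq_objective
#' @return `Nx x M` gradient image.
#' @export
gradient_D <- function(model, projector, X, Y_H) {
  R <- forward_H(model, projector, X) - check_data_shape(Y_H, projector, model)
  dH_adjoint(model, projector, X, R)
}

#' Derivative of the channel nonlinearity and its adjoint
#'
#' `Phi'[Z]` acts ray by ray on sinogram perturbations; together with the
#' projector it factorizes the full derivative,
#' `H'[X](xi) = Phi'[A X](A xi)`. At `Z = 0`, `Phi'[0](zeta) = -zeta t(U)`
#' and `Phi'[0]*(eta) = -eta U`.
#'
#' @param model A [spectral_model()].
#' @param Z `Ny x M` material sinogram (the linearization point).
#' @param zeta `Ny x M` sinogram perturbation.
#' @param eta `Ny x B` data perturbation.
#' @return `dPhi_apply`: `Ny x B`; `dPhi_adjoint`: `Ny x M`.
#' @export
dPhi_apply <- function(model, Z, zeta) {
  st <- phi_state(model, Z)
  zeta <- as_sinogram_matrix(zeta, model)
  -((st$Q * (zeta %*% t(model$attenuations))) %*% t(st$S)) / st$PF
}

#' @rdname dPhi_apply
#' @export
dPhi_adjoint <- function(model, Z, eta) {
  st <- phi_state(model, Z)
  eta <- as.matrix(eta)
  if (ncol(eta) != n_bins(model)) {
    stop("eta must have one column per energy bin", call. = FALSE)
  }
  -(st$Q * ((eta / st$PF) %*% st$S)) %*% model$attenuations
}

phi_state <- function(model, Z) {
  Z <- as_sinogram_matrix(Z, model)
  S <- normalize_spectra(model)$spectra
  Q <- exp(-clip_exponent(Z %*% t(model$attenuations)))
  PF <- Q %*% t(S)
  list(Q = Q, PF = PF, S = S)
}

#' Channel (zero-linearization) matrix U
#'
#' `U[b, m] = <S_b, Mu_m> / <S_b, 1>`: each entry is the spectrum-weighted
#' mean attenuation of material `m` in bin `b`. `U` is the derivative of
#' the channel nonlinearity at a zero sinogram and the whole of the
#' derivative-free (CP-fast) adjoint model. Requires `B >= M` and full
#' column rank.
#'
#' @param model A [spectral_model()].
#' @param max_condition Condition number above which `U` is rejected as
#'   numerically rank-deficient (default `1e12`).
#' @return An object of class `channel_matrix`: list with `U` (`B x M`),
#'   `pinv` (`M x B`, the Moore-Penrose pseudoinverse
#'   `solve(t(U) U) t(U)`), and `condition`.
#' @export
build_channel_matrix <- function(model, max_condition = 1e12) {
  B <- n_bins(model)
  M <- n_materials(model)
  if (B < M) {
    stop("need at least as many bins as materials (B >= M)", call. = FALSE)
  }
  U <- (model$spectra %*% model$attenuations) / rowSums(model$spectra)
  sv <- svd(U)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(cond) || cond > max_condition) {
    stop(sprintf(
      "channel matrix U is numerically rank-deficient (condition %.3g); degenerate spectra or materials",
      cond
    ), call. = FALSE)
  }
  pinv <- solve(crossprod(U), t(U))
  structure(list(U = U, pinv = pinv, condition = cond),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d bins x %d materials, condition %.3g\n",
              nrow(x$U), ncol(x$U), x$condition))
  print(round(x$U, 6))
  invisible(x)
}

#' Export the channel matrix for inspection
#'
#' @param C A [build_channel_matrix()] result.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_channel_matrix_csv <- function(C, path) {
  df <- data.frame(bin = seq_len(nrow(C$U)), C$U, check.names = FALSE)
  names(df)[-1] <- paste0("material_", seq_len(ncol(C$U)))
  df$condition <- C$condition
  write_full_precision_csv(df, path)
  invisible(path)
}

#' Apply the channel preconditioner
#'
#' Solves `(Phi'[Z]* Phi'[Z]) zeta = Phi'[Z]*(R)` — the Gauss-Newton
#' normal equations of the channel nonlinearity alone. Because `Phi` acts
#' ray by ray, this decouples into `Ny` independent `M x M` symmetric
#' positive-definite solves, carried out as a Cholesky factorization
#' vectorized across rays; no object larger than `Ny x max(E, B, M^2)` is
#' ever formed, so cost and memory are linear in `Ny`.
#'
#' @param model A [spectral_model()].
#' @param Z `Ny x M` material sinogram (linearization point).
#' @param R `Ny x B` data-space residual.
#' @param on_illconditioned `"error"` (default) stops when any ray's normal
#'   matrix has an estimated condition above `cond_limit`; `"damp"` instead
#'   adds `1e-10 * trace/M` to its diagonal and reports the affected count.
#' @param cond_limit Per-ray condition threshold (default `1e12`).
#' @return `Ny x M` preconditioned residual sinogram.
#' @export
channel_precondition <- function(model, Z, R,
                                 on_illconditioned = c("error", "damp"),
                                 cond_limit = 1e12) {
  on_illconditioned <- match.arg(on_illconditioned)
  Z <- as_sinogram_matrix(Z, model)
  R <- as.matrix(R)
  st <- phi_state(model, Z)
  M <- n_materials(model)
  B <- n_bins(model)
  if (ncol(R) != B || nrow(R) != nrow(Z)) {
    stop("residual shape does not match the sinogram", call. = FALSE)
  }
  n_ray <- nrow(Z)
  # Accumulate per-ray normal matrices G = J^T J (stored as Ny x M^2) and
  # right-hand sides J^T R (Ny x M), one bin at a time.
  G <- matrix(0, n_ray, M * M)
  rhs <- matrix(0, n_ray, M)
  for (b in seq_len(B)) {
    Jb <- -((st$Q * rep(st$S[b, ], each = n_ray)) %*% model$attenuations) /
      st$PF[, b]
    rhs <- rhs + Jb * R[, b]
    for (m1 in seq_len(M)) {
      for (m2 in m1:M) {
        k <- (m2 - 1L) * M + m1
        G[, k] <- G[, k] + Jb[, m1] * Jb[, m2]
      }
    }
  }
  # mirror the upper triangle (entry (i, j) lives in column (j-1)*M+i)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i > j) G[, (j - 1L) * M + i] <- G[, (i - 1L) * M + j]
    }
  }
  batched_spd_solve(G, rhs, M, on_illconditioned, cond_limit)
}

# Cholesky solve of Ny independent M x M SPD systems, vectorized across the
# ray dimension. G is Ny x M^2 (column (j-1)*M+i holds entry (i, j)); rhs is
# Ny x M. Rays whose pivot ratio max(diag)/pivot exceeds cond_limit are
# treated as ill-conditioned.
batched_spd_solve <- function(G, rhs, M, on_illconditioned, cond_limit) {
  n_ray <- nrow(G)
  k <- function(i, j) (j - 1L) * M + i
  diag_idx <- k(seq_len(M), seq_len(M))
  max_diag <- do.call(pmax, c(lapply(diag_idx, function(d) G[, d]), list(0)))
  L <- matrix(0, n_ray, M * M)
  bad <- rep(FALSE, n_ray)
  for (j in seq_len(M)) {
    d <- G[, k(j, j)]
    if (j > 1L) {
      prev <- k(j, seq_len(j - 1L))
      d <- d - rowSums(L[, prev, drop = FALSE]^2)
    }
    bad <- bad | !(d > max_diag / cond_limit)
    d <- pmax(d, max_diag / cond_limit, .Machine$double.xmin)
    L[, k(j, j)] <- sqrt(d)
    if (j < M) {
      for (i in (j + 1L):M) {
        s <- G[, k(i, j)]
        if (j > 1L) {
          s <- s - rowSums(L[, k(i, seq_len(j - 1L)), drop = FALSE] *
                             L[, k(j, seq_len(j - 1L)), drop = FALSE])
        }
        L[, k(i, j)] <- s / L[, k(j, j)]
      }
    }
  }
  if (any(bad)) {
    if (on_illconditioned == "error") {
      stop(sprintf(
        "%d ray(s) have an ill-conditioned channel normal matrix (limit %.3g)",
        sum(bad), cond_limit
      ), call. = FALSE)
    }
    warning(sprintf("damped %d ill-conditioned ray(s)", sum(bad)),
            call. = FALSE)
    tr <- Reduce(`+`, lapply(diag_idx, function(d) G[, d]))
    for (d in diag_idx) G[bad, d] <- G[bad, d] + 1e-10 * tr[bad] / M
    return(batched_spd_solve(G, rhs, M, "error", Inf))
  }
  # forward substitution L y = rhs
  y <- matrix(0, n_ray, M)
  for (j in seq_len(M)) {
    s <- rhs[, j]
    if (j > 1L) {
      for (m in seq_len(j - 1L)) s <- s - L[, k(j, m)] * y[, m]
    }
    y[, j] <- s / L[, k(j, j)]
  }
  # back substitution t(L) x = y
  x <- matrix(0, n_ray, M)
  for (j in rev(seq_len(M))) {
    s <- y[, j]
    if (j < M) {
      for (m in (j + 1L):M) s <- s - L[, k(m, j)] * x[, m]
    }
    x[, j] <- s / L[, k(j, j)]
  }
  x
}
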