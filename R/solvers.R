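#' Solver configuration
#'
#' @param variant One of `"landweber"`, `"gauss_newton"`, `"cp_full"`,
#'   `"cp_fast"`.
#' @param step_size Positive step size `omega`, or `"auto"` (default) to use
#'   [auto_step_size()].
#' @param max_iterations Maximum number of iterations (default 500; 0 is
#'   allowed and returns the start iterate untouched).
#' @param positivity Project every iterate onto the nonnegative cone
#'   (default `TRUE`).
#' @param stop_tolerance Stop when the relative iterate change falls below
#'   this (default `1e-6`).
#' @param seed Integer seed controlling the step-size power iteration.
#' @param backtracking If `TRUE`, halve the step (at most 20 times) whenever
#'   the objective would increase.
#' @param divergence_factor Abort when the objective exceeds this multiple
#'   of its initial value (default `1e6`).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(variant = c("cp_fast", "cp_full", "landweber",
                                      "gauss_newton"),
                          step_size = "auto",
                          max_iterations = 500L,
                          positivity = TRUE,
                          stop_tolerance = 1e-6,
                          seed = 1L,
                          backtracking = FALSE,
                          divergence_factor = 1e6) {
  variant <- match.arg(variant)
  if (!identical(step_size, "auto")) {
    if (!is.numeric(step_size) || length(step_size) != 1L ||
        !is.finite(step_size) || step_size <= 0) {
      stop("step_size must be \"auto\" or a positive number", call. = FALSE)
    }
  }
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 0L) {
    stop("max_iterations must be a nonnegative integer", call. = FALSE)
  }
  stopifnot(is.finite(stop_tolerance), stop_tolerance >= 0,
            is.finite(divergence_factor), divergence_factor > 1)
  structure(
    list(
      variant = variant, step_size = step_size,
      max_iterations = max_iterations, positivity = isTRUE(positivity),
      stop_tolerance = stop_tolerance, seed = as.integer(seed),
      backtracking = isTRUE(backtracking),
      divergence_factor = divergence_factor
    ),
    class = "solver_config"
  )
}

#' Project an image onto the nonnegative cone
#'
#' Entrywise `max(X, 0)` — the orthogonal projection used between iterative
#' updates to enforce physical (nonnegative density) solutions.
#'
#' @param X Material image matrix.
#' @return `X` with negative entries set to zero.
#' @export
project_nonnegative <- function(X) {
  pmax(X, 0)
}

#' Single iterative updates
#'
#' One update of each iteration, without positivity projection (the solver
#' loop interleaves [project_nonnegative()]):
#' * `landweber_step`: `X - omega * grad D[X]` (identity preconditioner);
#' * `gauss_newton_step`: `X - omega * solve(H'[X]* H'[X], grad D[X])` via
#'   explicit dense Jacobian assembly — a small-scale baseline, guarded to
#'   `Nx * M <= 4096`;
#' * `cp_full_step`: `X - omega * t(A) %*% channel_precondition(A X, H(X) - Y_H)`
#'   — Gauss-Newton in the channel dimension only, never forming the full
#'   normal operator;
#' * `cp_fast_step`: `X - omega * t(A) %*% (H(X) - Y_H) %*% t(pinv(U))` —
#'   derivative-free: the channel matrix `C` is built once up front.
#'
#' @inheritParams lsq_objective
#' @param omega Positive step size.
#' @param C A [build_channel_matrix()] result (CP-fast only).
#' @return The updated `Nx x M` image.
#' @export
landweber_step <- function(model, projector, X, Y_H, omega) {
  solver_update("landweber", model, projector,
                as_material_matrix(X, model), Y_H, omega)
}

#' @rdname landweber_step
#' @export
gauss_newton_step <- function(model, projector, X, Y_H, omega = 1) {
  X <- as_material_matrix(X, model)
  if (length(X) > 4096) {
    stop("Gauss-Newton baseline is limited to Nx * M <= 4096", call. = FALSE)
  }
  solver_update("gauss_newton", model, projector, X, Y_H, omega)
}

#' @rdname landweber_step
#' @export
cp_full_step <- function(model, projector, X, Y_H, omega) {
  solver_update("cp_full", model, projector,
                as_material_matrix(X, model), Y_H, omega)
}

#' @rdname landweber_step
#' @export
cp_fast_step <- function(model, projector, X, Y_H, omega,
                         C = build_channel_matrix(model)) {
  solver_update("cp_fast", model, projector,
                as_material_matrix(X, model), Y_H, omega, C = C)
}

# One update for any variant. st/R may be supplied to reuse the forward
# state computed for the objective.
solver_update <- function(variant, model, projector, X, Y_H, omega,
                          C = NULL, st = NULL, R = NULL) {
  if (is.null(st)) st <- spectral_state(model, projector, X)
  if (is.null(R)) {
    H <- log(st$FX / forward_F0(model, nrow(st$FX)))
    R <- H - check_data_shape(Y_H, projector, model)
  }
  dir <- switch(variant,
    landweber = {
      G <- (R / st$FX) %*% model$spectra
      -adjoint_multichannel(projector, (st$Q * G) %*% model$attenuations)
    },
    cp_full = adjoint_multichannel(
      projector, channel_precondition(model, st$Z, R)
    ),
    cp_fast = {
      if (is.null(C)) C <- build_channel_matrix(model)
      # zero-sinogram limit of the cp_full direction: Phi'[0]* carries a
      # minus sign, so the descent direction is -(R %*% t(pinv(U)))
      adjoint_multichannel(projector, -R %*% t(C$pinv))
    },
    gauss_newton = gauss_newton_direction(model, projector, X, R, st)
  )
  unname(X - omega * dir)
}

gauss_newton_direction <- function(model, projector, X, R, st) {
  Nx <- nrow(X)
  M <- ncol(X)
  if (Nx * M > 4096) {
    stop("Gauss-Newton baseline is limited to Nx * M <= 4096", call. = FALSE)
  }
  J <- dense_H_jacobian(model, projector, st)
  g <- crossprod(J, as.vector(R))
  N <- crossprod(J)
  step <- tryCatch(solve(N, g), error = function(e) {
    stop("singular Gauss-Newton normal operator: ", conditionMessage(e),
         call. = FALSE)
  })
  matrix(step, Nx, M)
}

# Dense Jacobian of H at the state st, columns ordered like vec(X)
# (pixel index fastest, then material). Used by the Gauss-Newton baseline.
dense_H_jacobian <- function(model, projector, st) {
  A <- projector$A
  Nx <- ncol(A)
  M <- n_materials(model)
  Ny <- nrow(A)
  B <- n_bins(model)
  J <- matrix(0, Ny * B, Nx * M)
  for (m in seq_len(M)) {
    mu_m <- model$attenuations[, m]
    for (p in seq_len(Nx)) {
      a_p <- as.numeric(A[, p])
      col <- -((st$Q * outer(a_p, mu_m)) %*% t(model$spectra)) / st$FX
      J[, (m - 1L) * Nx + p] <- as.vector(col)
    }
  }
  J
}

#' Automatic step size by power iteration
#'
#' Estimates the spectral norm `rho` of the preconditioned linearized
#' normal operator at `X = 0` with a seeded power iteration and returns
#' `omega = 1 / rho`. For Landweber the operator is
#' `xi -> t(A)((A xi) t(U)) U`; for the channel-preconditioned variants the
#' channel factor cancels and the operator is `t(A) A` channel-wise.
#' Gauss-Newton uses `omega = 1`.
#'
#' @param model A [spectral_model()].
#' @param projector A [build_projector()] result.
#' @param variant Solver variant name.
#' @param C Optional precomputed [build_channel_matrix()].
#' @param n_iter Number of power iterations (default 50).
#' @param seed Seed for the random start vector.
#' @return `omega`, with the norm estimate attached as attribute `"rho"`.
#' @export
auto_step_size <- function(model, projector,
                           variant = c("cp_fast", "cp_full", "landweber",
                                       "gauss_newton"),
                           C = NULL, n_iter = 50L, seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "gauss_newton") {
    return(structure(1, rho = 1))
  }
  if (is.null(C)) C <- build_channel_matrix(model)
  U <- C$U
  normal_op <- if (variant == "landweber") {
    function(xi) adjoint_multichannel(
      projector, (apply_multichannel(projector, xi) %*% t(U)) %*% U
    )
  } else {
    function(xi) adjoint_multichannel(
      projector,
      ((apply_multichannel(projector, xi) %*% t(U))) %*% t(C$pinv)
    )
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  xi <- matrix(stats::rnorm(ncol(projector$A) * ncol(U)), ncol = ncol(U))
  rho <- 0
  for (i in seq_len(n_iter)) {
    nxi <- normal_op(xi)
    rho <- sqrt(sum(nxi^2))
    if (rho == 0) stop("power iteration hit the zero operator", call. = FALSE)
    xi <- nxi / rho
  }
  structure(1 / rho, rho = rho)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Run an iterative reconstruction
#'
#' The generic preconditioned fixed-point loop: starting from `X0` (zero by
#' default), repeat the configured update, optionally project onto the
#' nonnegative cone, and record the objective, step size, and — when a
#' ground truth is supplied — the relative reconstruction error of every
#' iterate. Stops at `max_iterations`, when the relative iterate change
#' drops below `stop_tolerance`, or on divergence (with a partial trace).
#'
#' @inheritParams lsq_objective
#' @param config A [solver_config()].
#' @param X0 Start image (`Nx x M`); defaults to zero.
#' @param truth Optional ground-truth image for error tracking and
#'   best-iterate selection.
#' @return An object of class `ct_recon`: list with `X` (final iterate),
#'   `X_best` and `best_iteration` (minimal relative error when `truth` is
#'   given, else minimal objective), `trace` (a tibble: iteration,
#'   objective, rel_error, step), `omega`, `config`, `converged`,
#'   `diverged`.
#' @export
run_solver <- function(model, projector, Y_H, config = solver_config(),
                       X0 = NULL, truth = NULL) {
  stopifnot(inherits(config, "solver_config"))
  Y_H <- check_data_shape(Y_H, projector, model)
  Nx <- ncol(projector$A)
  M <- n_materials(model)
  if (is.null(X0)) X0 <- matrix(0, Nx, M)
  X <- as_material_matrix(X0, model)
  if (nrow(X) != Nx) stop("X0 does not match the geometry", call. = FALSE)
  if (!is.null(truth)) {
    truth <- as_material_matrix(truth, model)
    truth_norm <- sqrt(sum(truth^2))
    if (truth_norm == 0) stop("ground truth has zero norm", call. = FALSE)
  }
  C <- build_channel_matrix(model)
  omega <- if (identical(config$step_size, "auto")) {
    auto_step_size(model, projector, config$variant, C = C,
                   seed = config$seed)
  } else config$step_size
  K <- config$max_iterations
  iters <- objs <- rels <- steps <- numeric(K + 1L)
  rels[] <- NA_real_
  record <- function(k, X, obj, step) {
    iters[k + 1L] <<- k
    objs[k + 1L] <<- obj
    steps[k + 1L] <<- step
    if (!is.null(truth)) {
      rels[k + 1L] <<- sqrt(sum((X - truth)^2)) / truth_norm
    }
  }
  make_trace <- function(n_rows) {
    idx <- seq_len(n_rows)
    tibble::tibble(iteration = iters[idx], objective = objs[idx],
                   rel_error = rels[idx], step = steps[idx])
  }
  objective_of <- function(st) {
    H <- log(st$FX / forward_F0(model, nrow(st$FX)))
    sum((H - Y_H)^2) / 2
  }
  if (K == 0L) {
    return(new_ct_recon(X, X, 0L, make_trace(0L), omega, config,
                        converged = FALSE, diverged = FALSE))
  }
  st <- spectral_state(model, projector, X)
  obj <- objective_of(st)
  obj0 <- obj
  record(0L, X, obj, NA_real_)
  X_best <- X
  best_k <- 0L
  best_val <- if (!is.null(truth)) rels[1L] else obj
  converged <- FALSE
  diverged <- FALSE
  k <- 0L
  while (k < K) {
    H <- log(st$FX / forward_F0(model, nrow(st$FX)))
    R <- H - Y_H
    step_used <- as.numeric(omega)
    X_new <- solver_update(config$variant, model, projector, X, Y_H,
                           step_used, C = C, st = st, R = R)
    if (config$positivity) X_new <- project_nonnegative(X_new)
    st_new <- NULL
    obj_new <- NA_real_
    if (all(is.finite(X_new))) {
      st_new <- spectral_state(model, projector, X_new)
      obj_new <- objective_of(st_new)
    }
    if (config$backtracking) {
      n_halve <- 0L
      while ((!is.finite(obj_new) || obj_new > obj) && n_halve < 20L) {
        step_used <- step_used / 2
        n_halve <- n_halve + 1L
        X_new <- solver_update(config$variant, model, projector, X, Y_H,
                               step_used, C = C, st = st, R = R)
        if (config$positivity) X_new <- project_nonnegative(X_new)
        if (all(is.finite(X_new))) {
          st_new <- spectral_state(model, projector, X_new)
          obj_new <- objective_of(st_new)
        } else {
          obj_new <- NA_real_
        }
      }
    }
    k <- k + 1L
    if (!all(is.finite(X_new)) || !is.finite(obj_new) ||
        obj_new > config$divergence_factor * max(obj0, .Machine$double.eps)) {
      diverged <- TRUE
      warning(sprintf(
        "%s iteration diverged at step %d; try a smaller step size",
        config$variant, k
      ), call. = FALSE)
      record(k, X_new, obj_new, step_used)
      break
    }
    change <- sqrt(sum((X_new - X)^2)) /
      max(sqrt(sum(X^2)), .Machine$double.eps)
    X <- X_new
    st <- st_new
    obj <- obj_new
    record(k, X, obj, step_used)
    val <- if (!is.null(truth)) rels[k + 1L] else obj
    if (val < best_val) {
      best_val <- val
      best_k <- k
      X_best <- X
    }
    if (change < config$stop_tolerance) {
      converged <- TRUE
      break
    }
  }
  new_ct_recon(X, X_best, best_k, make_trace(k + 1L), omega, config,
               converged = converged, diverged = diverged)
}

new_ct_recon <- function(X, X_best, best_k, trace, omega, config,
                         converged, diverged) {
  structure(
    list(X = X, X_best = X_best, best_iteration = best_k, trace = trace,
         omega = as.numeric(omega), rho = attr(omega, "rho"),
         config = config, converged = converged, diverged = diverged),
    class = "ct_recon"
  )
}

#' @export
print.ct_recon <- function(x, ...) {
  cat(sprintf(
    "<ct_recon> %s: %d iteration(s), omega = %.4g, final objective %.6g%s%s\n",
    x$config$variant, max(x$trace$iteration, 0), x$omega,
    utils::tail(x$trace$objective, 1),
    if (x$converged) " [converged]" else "",
    if (x$diverged) " [DIVERGED]" else ""
  ))
  if (!all(is.na(x$trace$rel_error))) {
    cat(sprintf("  best iterate: %d (relative error %.4g)\n",
                x$best_iteration,
                min(x$trace$rel_error, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-iteration floating-point work proxy
#'
#' A deterministic operation count (multiply-add proxy) for one update of
#' each variant, covering the forward evaluation and the variant's adjoint
#' and preconditioning work. Used to compare per-iteration cost between
#' variants independent of wall clock.
#'
#' @param model A [spectral_model()].
#' @param projector A [build_projector()] result.
#' @param variant Solver variant name.
#' @return Number of floating-point operations (a proxy, not a benchmark).
#' @export
per_iteration_cost <- function(model, projector, variant) {
  nnz <- Matrix::nnzero(projector$A)
  Ny <- nrow(projector$A)
  Nx <- ncol(projector$A)
  M <- n_materials(model)
  B <- n_bins(model)
  E <- length(model$energies)
  forward <- 2 * nnz * M + 2 * Ny * M * E + Ny * E + 2 * Ny * E * B
  extra <- switch(variant,
    landweber = 2 * Ny * B * E + Ny * E + 2 * Ny * E * M + 2 * nnz * M,
    cp_fast = 2 * Ny * B * M + 2 * nnz * M,
    cp_full = B * (2 * Ny * E * M + Ny * E + 2 * Ny * M * (M + 1)) +
      Ny * M^3 + 2 * nnz * M,
    gauss_newton = Nx * M * (2 * Ny * E + 2 * Ny * E * B) +
      2 * Ny * B * (Nx * M)^2 + (Nx * M)^3 / 3,
    stop("unknown variant", call. = FALSE)
  )
  forward + extra
}
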