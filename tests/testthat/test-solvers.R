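test_that("solver configuration validates its fields", {
  expect_error(solver_config(step_size = -1), "positive")
  expect_error(solver_config(max_iterations = -1), "nonnegative")
  expect_error(solver_config(variant = "nesterov"))
  cfg <- solver_config("cp_full", step_size = 0.3, max_iterations = 10)
  expect_s3_class(cfg, "solver_config")
})

test_that("nonnegativity projection clips, is idempotent and nonexpansive", {
  X <- matrix(c(-1, 0.5, -0.2, 2), 2, 2)
  P1 <- project_nonnegative(X)
  expect_equal(P1, matrix(c(0, 0.5, 0, 2), 2, 2))
  expect_equal(project_nonnegative(P1), P1)
  expect_equal(project_nonnegative(matrix(-1, 3, 2)), matrix(0, 3, 2))
  set.seed(41)
  for (k in 1:25) {
    x <- rnorm(10)
    y <- rnorm(10)
    expect_lte(sqrt(sum((pmax(x, 0) - pmax(y, 0))^2)),
               sqrt(sum((x - y)^2)) + 1e-15)
  }
})

test_that("zero residual leaves every variant's iterate unchanged", {
  set.seed(42)
  g <- tiny_geometry(4, n_angles = 8, n_det = 6)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X)
  expect_lt(rel_diff(landweber_step(m, P, X, Y_H, 0.5), X), 1e-12)
  expect_lt(rel_diff(cp_full_step(m, P, X, Y_H, 0.5), X), 1e-12)
  expect_lt(rel_diff(cp_fast_step(m, P, X, Y_H, 0.5), X), 1e-12)
  expect_lt(rel_diff(gauss_newton_step(m, P, X, Y_H, 1), X), 1e-10)
})

test_that("landweber equals the generic step with identity preconditioner", {
  set.seed(43)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X * 0.5)
  got <- landweber_step(m, P, X, Y_H, 0.7)
  expect_lt(rel_diff(got, X - 0.7 * gradient_D(m, P, X, Y_H)), 1e-14)
})

test_that("landweber on a monochromatic problem is classical linear Landweber", {
  set.seed(44)
  g <- tiny_geometry(4, n_angles = 8, n_det = 6)
  P <- build_projector(g)
  mu <- 1.6
  m <- mono_model(mu = mu)
  truth <- random_image(P, 1, 0, 1)
  Y_H <- forward_H(m, P, truth)
  omega <- 0.05
  # independent linear Landweber on  -(A x) mu = y
  Ad <- as.matrix(P$A) * mu
  x_lin <- rep(0, ncol(Ad))
  X <- matrix(0, ncol(Ad), 1)
  for (k in 1:25) {
    x_lin <- x_lin - omega * as.numeric(crossprod(Ad, Ad %*% x_lin + as.vector(Y_H)))
    X <- landweber_step(m, P, X, Y_H, omega)
  }
  expect_lt(rel_diff(as.vector(X), x_lin), 1e-10)
})

test_that("gauss-newton solves the linear monochromatic problem in one step", {
  set.seed(45)
  g <- tiny_geometry(4, n_angles = 10, n_det = 6)
  P <- build_projector(g)
  m <- mono_model(mu = 2)
  truth <- random_image(P, 1, 0, 1)
  Y_H <- forward_H(m, P, truth)
  X1 <- gauss_newton_step(m, P, matrix(0, 16, 1), Y_H, 1)
  Ad <- as.matrix(P$A) * 2
  xls <- solve(crossprod(Ad), crossprod(Ad, -as.vector(Y_H)))
  expect_lt(rel_diff(as.vector(X1), as.numeric(xls)), 1e-8)
})

test_that("gauss-newton agrees with an independent dense normal solve", {
  set.seed(46)
  g <- tiny_geometry(4, n_angles = 8, n_det = 6)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X * 0.6)
  got <- gauss_newton_step(m, P, X, Y_H, 1)
  J <- dense_jacobian_H(m, P, X)
  r <- as.vector(forward_H(m, P, X) - Y_H)
  ref <- X - matrix(solve(crossprod(J), crossprod(J, r)), 16, 2)
  expect_lt(rel_diff(got, ref), 1e-8)
  expect_error(
    gauss_newton_step(tiny_model(M = 3, B = 5),
                      build_projector(tiny_geometry(48)),
                      matrix(0.1, 48^2, 3), NULL, 1),
    "Nx \\* M <= 4096"
  )
})

test_that("cp_full matches a brute-force dense evaluation of its update", {
  set.seed(47)
  g <- tiny_geometry(4, n_angles = 8, n_det = 6)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X * 0.4)
  omega <- 0.3
  got <- cp_full_step(m, P, X, Y_H, omega)
  Z <- apply_multichannel(P, X)
  R <- forward_H(m, P, X) - Y_H
  J <- dense_jacobian_phi(m, Z)
  zeta <- matrix(solve(crossprod(J), crossprod(J, as.vector(R))),
                 nrow(Z), 2)
  ref <- X - omega * adjoint_multichannel(P, zeta)
  expect_lt(rel_diff(got, ref), 1e-8)
})

test_that("cp_fast and cp_full coincide at a zero start", {
  set.seed(48)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 3, B = 5)
  truth <- random_image(P, 3)
  Y_H <- forward_H(m, P, truth)
  X0 <- matrix(0, 25, 3)
  s_full <- cp_full_step(m, P, X0, Y_H, 0.8)
  s_fast <- cp_fast_step(m, P, X0, Y_H, 0.8)
  expect_lt(max(abs(s_full - s_fast)), 1e-11 * max(abs(s_full)))
})

test_that("cp_fast with a square invertible U uses its plain inverse", {
  set.seed(49)
  g <- tiny_geometry(4, n_angles = 8, n_det = 6)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 2)
  C <- build_channel_matrix(m)
  expect_lt(rel_diff(C$pinv, solve(C$U)), 1e-10)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X * 0.5)
  got <- cp_fast_step(m, P, X, Y_H, 0.4)
  R <- forward_H(m, P, X) - Y_H
  ref <- X + 0.4 * adjoint_multichannel(P, R %*% t(solve(C$U)))
  expect_lt(rel_diff(got, ref), 1e-12)
})

test_that("auto step size inverts a known operator norm", {
  # mono model with mu = 2 on a 1x1 image with two identical rays:
  # normal operator = mu^2 * t(A) A with known largest eigenvalue
  g <- ct_geometry(1, angles = c(0, pi / 2), n_detector_bins = 1,
                   pixel_size = 1)
  P <- build_projector(g)
  m <- mono_model(mu = 2)
  om <- auto_step_size(m, P, "landweber", seed = 3)
  # A = [1; 1], t(A)A = 2, times U^2 = 4 -> rho = 8
  expect_lt(abs(attr(om, "rho") - 8) / 8, 0.01)
  expect_lt(abs(om - 1 / 8) / (1 / 8), 0.01)
})

test_that("auto step size for cp variants scales inversely with A^2", {
  m <- tiny_model(M = 2, B = 3)
  g1 <- tiny_geometry(4, pixel_size = 0.25)
  g2 <- tiny_geometry(4, pixel_size = 0.75)  # A scaled by 3
  om1 <- auto_step_size(m, build_projector(g1), "cp_fast", seed = 5)
  om2 <- auto_step_size(m, build_projector(g2), "cp_fast", seed = 5)
  expect_lt(abs(om1 / om2 - 9) / 9, 1e-6)
})

test_that("auto step size yields monotone objective decrease early on", {
  set.seed(50)
  g <- tiny_geometry(8)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  truth <- make_phantom(phantom_spec(8, list(
    list(center = c(0, 0), radii = 0.35, material = 1L, density = 1),
    list(center = c(0.1, 0), radii = 0.12, material = 2L, density = 0.5)
  ), n_materials = 2L))
  Y_H <- forward_H(m, P, truth)
  for (v in c("landweber", "cp_fast", "cp_full")) {
    fit <- run_solver(m, P, Y_H, solver_config(v, max_iterations = 10,
                                               stop_tolerance = 0),
                      truth = truth)
    expect_true(all(diff(fit$trace$objective) <= 1e-12), info = v)
  }
})

test_that("run_solver contract: zero iterations, traces, reproducibility", {
  set.seed(51)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  truth <- random_image(P, 2)
  Y_H <- forward_H(m, P, truth)
  fit0 <- run_solver(m, P, Y_H, solver_config(max_iterations = 0),
                     X0 = truth)
  expect_equal(fit0$X, truth)
  expect_equal(nrow(fit0$trace), 0L)
  cfg <- solver_config("cp_fast", max_iterations = 30, stop_tolerance = 0)
  f1 <- run_solver(m, P, Y_H, cfg, truth = truth)
  f2 <- run_solver(m, P, Y_H, cfg, truth = truth)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$X, f2$X)
  expect_equal(f1$trace$iteration, 0:30)
  expect_equal(f1$best_iteration,
               f1$trace$iteration[which.min(f1$trace$rel_error)])
  # tidy/glance accessors
  expect_identical(tidy(f1), f1$trace)
  gl <- glance(f1)
  expect_equal(gl$variant, "cp_fast")
  expect_equal(gl$best_rel_error, min(f1$trace$rel_error))
})

test_that("divergence is detected and reported with a partial trace", {
  set.seed(52)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  truth <- random_image(P, 2)
  Y_H <- forward_H(m, P, truth)
  om <- auto_step_size(m, P, "landweber")
  expect_warning(
    fit <- run_solver(m, P, Y_H,
                      solver_config("landweber", step_size = 500 * om,
                                    positivity = FALSE,
                                    max_iterations = 50)),
    "diverged"
  )
  expect_true(fit$diverged)
  expect_lt(nrow(fit$trace), 52)
})

test_that("backtracking halves the step until the objective decreases", {
  set.seed(53)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  truth <- random_image(P, 2)
  Y_H <- forward_H(m, P, truth)
  om <- auto_step_size(m, P, "cp_fast")
  fit <- run_solver(m, P, Y_H,
                    solver_config("cp_fast", step_size = 40 * om,
                                  backtracking = TRUE, max_iterations = 10,
                                  stop_tolerance = 0))
  expect_false(fit$diverged)
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
  expect_true(any(fit$trace$step[-1] < 40 * om))
})

test_that("per-iteration cost proxy ranks the variants as expected", {
  g <- tiny_geometry(16)
  P <- build_projector(g)
  m <- tiny_model(M = 3, B = 5, E = 12)
  costs <- vapply(c("cp_fast", "landweber", "cp_full", "gauss_newton"),
                  function(v) per_iteration_cost(m, P, v), numeric(1))
  expect_lt(costs[["cp_fast"]], costs[["cp_full"]])
  expect_lt(costs[["cp_full"]], costs[["gauss_newton"]])
})
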