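test_that("directional derivative of H matches central differences", {
  set.seed(21)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  xi <- matrix(rnorm(50), 25, 2)
  d <- dH_apply(m, P, X, xi)
  expect_equal(dH_apply(m, P, X, xi * 0), d * 0)
  hs <- 1e-3 / 2^(0:3)
  errs <- vapply(hs, function(h) {
    fd <- (forward_H(m, P, X + h * xi) - forward_H(m, P, X - h * xi)) / (2 * h)
    sqrt(sum((fd - d)^2))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("H'[X] and its adjoint satisfy the inner-product identity", {
  set.seed(22)
  for (k in 1:10) {
    g <- tiny_geometry(sample(3:6, 1))
    P <- build_projector(g)
    m <- tiny_model(M = 2, B = 3, seed = k)
    X <- random_image(P, 2)
    xi <- matrix(rnorm(length(X)), nrow(X))
    eta <- matrix(rnorm(nrow(P$A) * 3), ncol = 3)
    d <- dH_apply(m, P, X, xi)
    a <- dH_adjoint(m, P, X, eta)
    expect_lt(abs(sum(d * eta) - sum(xi * a)),
              1e-10 * sqrt(sum(d^2)) * sqrt(sum(eta^2)))
    expect_equal(dH_adjoint(m, P, X, eta * 0), a * 0)
  }
})

test_that("adjoint action equals the dense Jacobian transpose", {
  set.seed(23)
  g <- tiny_geometry(4, n_angles = 6, n_det = 6)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  J <- dense_jacobian_H(m, P, X)
  eta <- matrix(rnorm(nrow(P$A) * 3), ncol = 3)
  expect_lt(rel_diff(as.vector(dH_adjoint(m, P, X, eta)),
                     as.numeric(crossprod(J, as.vector(eta)))), 1e-12)
})

test_that("derivatives at zero collapse to the channel matrix", {
  set.seed(24)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  U <- build_channel_matrix(m)$U
  X0 <- matrix(0, 25, 2)
  xi <- matrix(rnorm(50), 25, 2)
  eta <- matrix(rnorm(nrow(P$A) * 3), ncol = 3)
  expect_lt(rel_diff(dH_apply(m, P, X0, xi),
                     -apply_multichannel(P, xi) %*% t(U)), 1e-12)
  expect_lt(rel_diff(dH_adjoint(m, P, X0, eta),
                     -adjoint_multichannel(P, eta) %*% U), 1e-12)
  Z0 <- matrix(0, nrow(P$A), 2)
  zeta <- matrix(rnorm(length(Z0)), nrow(Z0))
  expect_lt(rel_diff(dPhi_apply(m, Z0, zeta), -zeta %*% t(U)), 1e-12)
  expect_lt(rel_diff(dPhi_adjoint(m, Z0, eta), -eta %*% U), 1e-12)
})

test_that("linearization error at zero vanishes superlinearly", {
  set.seed(25)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  xi <- matrix(abs(rnorm(50)), 25, 2)
  X0 <- matrix(0, 25, 2)
  d0 <- dH_apply(m, P, X0, xi)
  hs <- c(1e-1, 1e-2, 1e-3)
  errs <- vapply(hs, function(h) {
    sqrt(sum((forward_H(m, P, h * xi) - h * d0)^2)) / h
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / errs[1], 0.02)
})

test_that("gradient of D matches finite differences and the residual rule", {
  set.seed(26)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  Y_H <- forward_H(m, P, X * 0.8)
  gr <- gradient_D(m, P, X, Y_H)
  R <- forward_H(m, P, X) - Y_H
  expect_lt(rel_diff(gr, dH_adjoint(m, P, X, R)), 1e-14)
  expect_equal(gradient_D(m, P, X, forward_H(m, P, X)),
               gr * 0)
  xi <- matrix(rnorm(50), 25, 2)
  hs <- 1e-3 / 2^(0:2)
  errs <- vapply(hs, function(h) {
    fd <- (lsq_objective(m, P, X + h * xi, Y_H) -
             lsq_objective(m, P, X - h * xi, Y_H)) / (2 * h)
    abs(fd - sum(gr * xi))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("channel derivative obeys the chain rule through A", {
  set.seed(27)
  g <- tiny_geometry(5)
  P <- build_projector(g)
  m <- tiny_model(M = 2, B = 3)
  X <- random_image(P, 2)
  xi <- matrix(rnorm(50), 25, 2)
  lhs <- dPhi_apply(m, apply_multichannel(P, X), apply_multichannel(P, xi))
  expect_lt(rel_diff(lhs, dH_apply(m, P, X, xi)), 1e-12)
})

test_that("Phi' adjoint matches its dense Jacobian", {
  set.seed(28)
  m <- tiny_model(M = 2, B = 3)
  Z <- matrix(runif(20 * 2, 0, 1.5), 20, 2)
  J <- dense_jacobian_phi(m, Z)
  eta <- matrix(rnorm(20 * 3), 20, 3)
  expect_lt(rel_diff(as.vector(dPhi_adjoint(m, Z, eta)),
                     as.numeric(crossprod(J, as.vector(eta)))), 1e-10)
})

test_that("channel matrix holds spectrum-weighted mean attenuations", {
  m <- spectral_model(c(1, 2), matrix(c(1, 3), 2, 1), matrix(c(1, 1), 1, 2))
  C <- build_channel_matrix(m)
  expect_equal(unname(C$U), matrix(2, 1, 1))
  # all-ones attenuation column gives an all-ones U column
  m2 <- spectral_model(1:4, cbind(rep(1, 4), c(1, 2, 3, 4)),
                       matrix(runif(8, 0.5, 1), 2, 4))
  expect_equal(unname(build_channel_matrix(m2)$U[, 1]), c(1, 1))
})

test_that("pseudoinverse is a left inverse of U", {
  set.seed(29)
  for (k in 1:10) {
    m <- tiny_model(M = 3, B = 5, seed = k)
    C <- build_channel_matrix(m)
    expect_lt(max(abs(C$pinv %*% C$U - diag(3))), 1e-10)
    # oracle: explicit normal-equation solve
    ref <- solve(t(C$U) %*% C$U) %*% t(C$U)
    expect_lt(rel_diff(C$pinv, ref), 1e-12)
  }
})

test_that("degenerate materials are rejected with a condition report", {
  e <- 1:10
  att <- cbind(2 + 1 / e, 2 + 1 / e)  # two identical materials
  s <- matrix(runif(30, 0.5, 1), 3, 10)
  m <- spectral_model(e, att, s)
  expect_error(build_channel_matrix(m), "rank-deficient")
  expect_error(build_channel_matrix(tiny_model(M = 3, B = 2)), "B >= M")
})

test_that("channel preconditioner equals the brute-force dense solve", {
  set.seed(30)
  m <- tiny_model(M = 2, B = 3)
  Ny <- 12
  Z <- matrix(runif(Ny * 2, 0, 1.2), Ny, 2)
  R <- matrix(rnorm(Ny * 3), Ny, 3)
  zeta <- channel_precondition(m, Z, R)
  J <- dense_jacobian_phi(m, Z)
  ref <- matrix(solve(crossprod(J), crossprod(J, as.vector(R))), Ny, 2)
  expect_lt(rel_diff(zeta, ref), 1e-8)
})

test_that("preconditioning inverts the channel derivative on its range", {
  set.seed(31)
  m <- tiny_model(M = 2, B = 3)
  Z <- matrix(runif(30, 0, 1), 15, 2)
  zeta <- matrix(rnorm(30), 15, 2)
  R <- dPhi_apply(m, Z, zeta)
  expect_lt(rel_diff(channel_precondition(m, Z, R), zeta), 1e-8)
})

test_that("preconditioner at a zero sinogram uses the channel pseudoinverse", {
  set.seed(32)
  m <- tiny_model(M = 3, B = 5)
  C <- build_channel_matrix(m)
  R <- matrix(rnorm(40 * 5), 40, 5)
  got <- channel_precondition(m, matrix(0, 40, 3), R)
  # Phi'[0] = -(.) t(U), so the least-squares channel solve is -R t(pinv)
  expect_lt(rel_diff(got, -R %*% t(C$pinv)), 1e-12)
})

test_that("ill-conditioned rays fail loudly or are damped on request", {
  e <- 1:6
  att <- cbind(1 + 1 / e, 1 + 1 / e + 1e-9)  # nearly identical materials
  s <- matrix(runif(12, 0.5, 1), 2, 6)
  m <- spectral_model(e, att, s)
  R <- matrix(rnorm(8 * 2), 8, 2)
  Z <- matrix(0.2, 8, 2)
  expect_error(channel_precondition(m, Z, R), "ill-conditioned")
  expect_warning(out <- channel_precondition(m, Z, R,
                                             on_illconditioned = "damp"),
                 "damped")
  expect_true(all(is.finite(out)))
})
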