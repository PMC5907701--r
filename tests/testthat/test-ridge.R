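test_that("local quadratic fit is exact on degree-<=2 surfaces", {
  L <- 15
  # constant surface
  q <- fit_local_quadratic(matrix(0.3, L, L), 8, 8)
  expect_equal(q$f0, 0.3)
  expect_equal(q$grad, c(0, 0))
  expect_equal(q$hess, matrix(0, 2, 2))

  # linear surface f = 2x
  m <- outer(1:L, 1:L, function(i, j) 2 * (i - 8))
  q2 <- fit_local_quadratic(m, 8, 8)
  expect_equal(q2$grad, c(2, 0), tolerance = 1e-12)
  expect_lt(max(abs(q2$hess)), 1e-9)

  # f = -x^2 + x y
  m3 <- outer(1:L, 1:L, function(i, j) -(i - 8)^2 + (i - 8) * (j - 8))
  q3 <- fit_local_quadratic(m3, 8, 8)
  expect_equal(q3$hess, matrix(c(-2, 1, 1, 0), 2), tolerance = 1e-9)

  expect_error(fit_local_quadratic(matrix(0, 3, 3), 2, 2), "smaller")
})

test_that("Hessian eigendecomposition handles generic and degenerate cases", {
  e <- eigen_decompose(matrix(c(-2, 0, 0, 0), 2))
  expect_equal(e$lam_p, -2)
  expect_equal(e$v_p, c(1, 0))

  e0 <- eigen_decompose(matrix(0, 2, 2))
  expect_equal(c(e0$lam_p, e0$lam_q), c(0, 0))
  expect_equal(e0$v_p, c(1, 0))
  expect_equal(e0$v_q, c(0, 1))

  set.seed(7)
  for (rep in 1:50) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1)
    e <- eigen_decompose(matrix(c(a, b, b, c), 2))
    expect_lte(e$lam_p, e$lam_q)
    expect_equal(sqrt(sum(e$v_p^2)), 1, tolerance = 1e-9)
    expect_lt(abs(sum(e$v_p * e$v_q)), 1e-9)
    # residual of the eigen equation
    H <- matrix(c(a, b, b, c), 2)
    expect_lt(max(abs(H %*% e$v_p - e$lam_p * e$v_p)), 1e-9)
    expect_lt(max(abs(H %*% e$v_q - e$lam_q * e$v_q)), 1e-9)
  }
})

test_that("ridge-point condition requires concavity and vanishing slope", {
  e_neg <- eigen_decompose(matrix(c(-2, 0, 0, 0), 2))
  # a zero-gradient local maximum is a ridge point
  expect_true(is_ridge_point(e_neg, c(0, 0), tol = 0.1))
  # positive lam_p can never be a ridge
  e_pos <- eigen_decompose(matrix(c(1, 0, 0, 2), 2))
  expect_false(is_ridge_point(e_pos, c(0, 0), tol = 0.1))
  # gradient along v_p breaks the condition
  e1 <- eigen_decompose(matrix(c(-1, 0, 0, 0), 2))
  expect_false(is_ridge_point(e1, c(1, 0), tol = 0.05))
  # gradient along the ridge direction is fine
  expect_true(is_ridge_point(e1, c(0, 1), tol = 0.05))
})

test_that("ridge line recovers direction and offset of analytic surfaces", {
  # f = -(x - 1)^2: ridge is the line x = 1, one cell away
  quad <- structure(list(f0 = -1, grad = c(2, 0),
                         hess = matrix(c(-2, 0, 0, 0), 2)),
                    class = "local_quadratic")
  eig <- eigen_decompose(quad)
  rl <- ridge_line(quad, eig)
  expect_equal(unname(rl["d"]), 1)
  expect_equal(unname(rl["phi"]), pi / 2)

  # zero gradient: the ridge passes through the cell
  quad0 <- structure(list(f0 = 0, grad = c(0, 0),
                          hess = matrix(c(-2, 0, 0, 0), 2)),
                     class = "local_quadratic")
  expect_equal(unname(ridge_line(quad0, eig)["d"]), 0)

  # 45-degree rotation: f = -((x - y)/sqrt(2))^2
  L <- 15
  m <- outer(1:L, 1:L, function(i, j) -((i - j) / sqrt(2))^2)
  q45 <- fit_local_quadratic(m, 8, 8)
  e45 <- eigen_decompose(q45)
  rl45 <- ridge_line(q45, e45)
  expect_equal(unname(rl45["phi"]), pi / 4, tolerance = 1e-9)
  expect_equal(unname(rl45["d"]), 0, tolerance = 1e-9)

  e_pos <- eigen_decompose(matrix(c(1, 0, 0, 2), 2))
  expect_error(ridge_line(quad, e_pos), "lam_p")
})

test_that("Gaussian scale space preserves mass and the DC component", {
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- gaussian_scale_space(imp, 1)[[1]]
  expect_equal(sm[17, 17], 1 / (2 * pi), tolerance = 1e-4)

  const <- matrix(0.7, 20, 20)
  for (s in c(0.5, 2)) {
    expect_equal(gaussian_scale_space(const, s)[[1]], const,
                 tolerance = 1e-12)
  }

  set.seed(3)
  m <- matrix(runif(900), 30)
  for (s in c(0.8, 2.5)) {
    expect_equal(sum(gaussian_scale_space(m, s)[[1]]), sum(m),
                 tolerance = 1e-6)
  }
  expect_error(gaussian_scale_space(m, numeric()), "empty")
})

test_that("gamma-normalized response follows sigma^6 (lam_p^2 - lam_q^2)^2", {
  iso <- eigen_decompose(matrix(c(-1, 0, 0, -1), 2))
  expect_equal(nl_gamma_response(iso, 2)$nl_gamma, 0)

  e <- eigen_decompose(matrix(c(-2, 0, 0, 0), 2))
  r1 <- nl_gamma_response(e, 1)
  expect_equal(r1$nl_gamma, r1$nl)    # sigma = 1 is the un-normalized case
  r2 <- nl_gamma_response(e, 2)
  expect_equal(r2$nl, 16)
  expect_equal(r2$nl_gamma, 1024)
})

test_that("ridge fields recover strand-like geometries and reject noise", {
  cfg <- br_config()
  L <- 48
  for (th in c(pi / 4, 3 * pi / 4)) {
    m <- analytic_ridge(L, th, s = 1.5)
    rf <- ridge_fields(m, cfg)
    cells <- on_axis_cells(L, th)
    v <- rf$valid[cells]
    expect_gt(mean(v), 0.9)
    phi <- rf$phi[cells][v]
    dphi <- pmin(abs(phi - th) %% pi, pi - abs(phi - th) %% pi)
    expect_lt(max(dphi) * 180 / pi, 5)
  }

  # flat map: no ridge anywhere
  rf_flat <- ridge_fields(matrix(0.2, 20, 20), cfg)
  expect_false(any(rf_flat$valid))
  expect_true(all(rf_flat$w == -1))
  expect_true(all(rf_flat$d == -1))
  expect_true(all(rf_flat$h == 0))

  # fewer admissible ridge cells in pure noise than with an embedded ridge
  set.seed(9)
  noise <- matrix(abs(rnorm(48 * 48, 0, 0.3)), 48)
  noise <- (noise + t(noise)) / 2
  withridge <- noise + analytic_ridge(48, 3 * pi / 4, A = 1.5)
  rf_n <- ridge_fields(noise, cfg)
  rf_r <- ridge_fields(withridge, cfg)
  expect_lt(mean(rf_n$valid), mean(rf_r$valid) + 0.2)
  cells <- on_axis_cells(48, 3 * pi / 4)
  expect_gt(mean(rf_r$valid[cells]), mean(rf_n$valid))
})

test_that("width/height estimation is calibrated and equivariant", {
  cfg <- br_config()
  L <- 64
  m1 <- analytic_ridge(L, pi / 4, A = 1, s = 1.5)
  m2 <- analytic_ridge(L, pi / 4, A = 2, s = 1.5)
  cells <- on_axis_cells(L, pi / 4)
  rf1 <- ridge_fields(m1, cfg)
  rf2 <- ridge_fields(m2, cfg)
  v <- rf1$valid[cells] & rf2$valid[cells]
  h1 <- median(rf1$h[cells][v]); h2 <- median(rf2$h[cells][v])
  w1 <- median(rf1$w[cells][v]); w2 <- median(rf2$w[cells][v])
  expect_equal(h1, 1, tolerance = 0.1)
  expect_equal(h2 / h1, 2, tolerance = 0.1)    # h linear in amplitude
  expect_equal(w1, 1.5, tolerance = 0.15)
  expect_equal(w2, w1, tolerance = 0.15 * w1)  # w independent of amplitude

  # d invariant, h stable under adding a constant (baseline-corrected fit)
  rf3 <- ridge_fields(m1 + 0.5, cfg)
  expect_equal(rf3$d[cells][v], rf1$d[cells][v], tolerance = 1e-6)
  expect_equal(median(rf3$h[cells][v]), h1, tolerance = 0.1)

  # scalar wrapper agrees with the field computation
  ij <- cells[which(v)[1], ]
  wh <- estimate_width_height(m1, ij[1], ij[2], cfg)
  expect_equal(unname(wh["w"]), rf1$w[ij[1], ij[2]])
  expect_equal(unname(wh["h"]), rf1$h[ij[1], ij[2]])
})

test_that("ridge fields are deterministic for fixed input", {
  set.seed(21)
  m <- matrix(abs(rnorm(625, 0, 0.3)), 25)
  m <- (m + t(m)) / 2
  a <- ridge_fields(m)
  b <- ridge_fields(m)
  expect_identical(a, b)
})
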