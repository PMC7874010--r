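test_that("objective matches the centred form and trivial cases", {
  set.seed(11)
  x <- matrix(rnorm(8), 2, 4)
  y <- apply_centering(matrix(rnorm(8), 2, 4))
  w <- random_stiefel(2, 2, 1)
  expect_equal(fsor_objective(x, y, w, c(0, 0)), sum(y^2))
  # d = k = n = 2, X = I, Y = 0, W = I, phi = 1: value is ||M||_F^2 = 1
  expect_equal(fsor_objective(diag(2), matrix(0, 2, 2), diag(2), c(1, 1)), 1)
  expect_error(fsor_objective(x, y, w, c(-1, 1)), "nonnegative")
})

test_that("objective equals the uncentred loss minimized over the bias", {
  for (i in 1:20) {
    set.seed(i)
    d <- sample(3:8, 1); n <- sample(4:12, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(d * n), d, n)
    y <- matrix(rnorm(k * n), k, n)
    w <- random_stiefel(d, k, i + 100)
    phi <- abs(rnorm(d))
    expect_equal(fsor_objective(x, y, w, phi),
                 objective_profile_b(x, y, w, phi),
                 tolerance = 1e-9)
  }
})

test_that("GPI recovers the Procrustes solution when C = 0", {
  for (i in 1:5) {
    set.seed(i)
    d <- sample(4:10, 1); k <- sample(2:3, 1)
    d_mat <- matrix(rnorm(d * k), d, k)
    w <- solve_w_gpi(matrix(0, d, d), d_mat, random_stiefel(d, k, i + 50))
    sv <- svd(d_mat)
    w_star <- sv$u[, 1:k] %*% t(sv$v)
    # compare objectives (the maximizer is unique up to sign only with
    # distinct singular values)
    expect_lt(abs(sum(w * d_mat) - sum(w_star * d_mat)), 1e-8)
    expect_lt(norm(crossprod(w) - diag(k), "F"), 1e-8)
  }
})

test_that("GPI with D = 0 finds the smallest-eigenvalue direction", {
  w <- solve_w_gpi(diag(c(1, 2)), matrix(0, 2, 1),
                   matrix(c(0.6, 0.8), 2, 1))
  expect_equal(abs(as.numeric(w)), c(1, 0), tolerance = 1e-6)
})

test_that("GPI beats brute-force sphere sampling for k = 1", {
  for (i in 1:10) {
    d <- if (i %% 2) 2L else 3L
    c_mat <- random_psd(d, i)
    set.seed(i + 10)
    d_vec <- matrix(rnorm(d), d, 1)
    w <- solve_w_gpi(c_mat, d_vec, random_stiefel(d, 1, i + 20))
    gpi_obj <- as.numeric(crossprod(w, c_mat %*% w) - 2 * crossprod(w, d_vec))
    expect_lte(gpi_obj, sphere_sample_min(c_mat, d_vec, seed = i) + 1e-6)
  }
})

test_that("GPI relaxed objective is monotonically non-decreasing", {
  d <- 12; k <- 3
  c_mat <- random_psd(d, 3)
  set.seed(4)
  d_mat <- matrix(rnorm(d * k), d, k)
  opts <- fsor_options()
  lam <- max(eigen(c_mat, symmetric = TRUE, only.values = TRUE)$values)
  alpha <- lam * (1 + opts$alpha_margin) + opts$alpha_margin
  ct <- alpha * diag(d) - c_mat
  w <- random_stiefel(d, k, 9)
  prev <- -Inf
  for (it in 1:50) {
    g <- 2 * ct %*% w + 2 * d_mat
    sv <- svd(g, nu = k, nv = k)
    w <- sv$u %*% t(sv$v)
    cur <- sum(diag(crossprod(w, ct %*% w))) + 2 * sum(w * d_mat)
    expect_gte(cur, prev - 1e-10)
    prev <- cur
  }
})

test_that("GPI validates its inputs", {
  expect_error(solve_w_gpi(matrix(c(1, 2, 0, 1), 2, 2), matrix(0, 2, 1),
                           matrix(c(1, 0), 2, 1)), "symmetric")
  expect_error(solve_w_gpi(diag(2), matrix(0, 2, 1), matrix(c(2, 0), 2, 1)),
               "Stiefel")
  expect_error(solve_w_gpi(diag(2), matrix(0, 2, 3),
                           matrix(c(1, 0), 2, 1)), "shape|k must")
})

test_that("ALM solves the simplex QP: closed-form and symmetric cases", {
  phi <- solve_phi_alm(diag(2), c(1, 0))
  expect_equal(as.numeric(phi), c(0.75, 0.25), tolerance = 1e-4)
  for (d in c(3, 7)) {
    phi <- solve_phi_alm(diag(d), rep(0, d))
    expect_equal(as.numeric(phi), rep(1 / d, d), tolerance = 1e-6)
  }
  expect_true(attr(phi, "converged"))
})

test_that("ALM matches a dense simplex grid search for d = 3", {
  for (i in 1:10) {
    h <- random_psd(3, i + 200)
    set.seed(i + 300)
    r <- rnorm(3)
    phi <- as.numeric(solve_phi_alm(h, r))
    expect_gte(min(phi), 0)
    expect_equal(sum(phi), 1, tolerance = 1e-9)
    obj <- sum(phi * (h %*% phi)) - sum(phi * r)
    expect_lte(obj, simplex_grid_min(h, r) + 1e-4)
  }
})

test_that("ALM rejects an indefinite H", {
  expect_error(solve_phi_alm(diag(c(1, -1)), c(0, 0)), "semidefinite")
  expect_error(solve_phi_alm(diag(2), c(1, 2, 3)), "length")
})
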