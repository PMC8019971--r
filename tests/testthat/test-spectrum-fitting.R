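acq <- acq_params()
grid <- t2_grid()

test_that("a noiseless single-species signal is recovered at the right grid node", {
  j <- which.min(abs(grid - 79.6))
  b <- build_basis(grid, 180, acq)
  y <- 2.7 * b$matrix[, j]
  fit <- nnls_fit(y, b)
  near <- seq(max(1, j - 2), min(length(grid), j + 2))
  expect_gte(sum(fit$amplitudes[near]) / sum(fit$amplitudes), 0.99)
  wmean <- sum(fit$amplitudes * grid) / sum(fit$amplitudes)
  expect_lt(abs(wmean - grid[j]) / grid[j], 0.02)
})

test_that("degenerate and invalid signals are handled", {
  b <- build_basis(grid, 180, acq)
  z <- nnls_fit(rep(0, acq$n_echoes), b)
  expect_equal(z$amplitudes, numeric(length(grid)))
  expect_identical(z$residual_norm, 0)
  expect_error(nnls_fit(c(rep(1, 31), NaN), b), "NA/NaN")
  expect_error(nnls_fit(rep(1, 10), b), "length")
  expect_error(fit_flip_angle(rep(0, 32), fit_config(), acq), "zero")
})

test_that("noiseless two-pool mixtures recover the pool split", {
  b <- build_basis(grid, 180, acq)
  j20 <- which.min(abs(grid - 20))
  j90 <- which.min(abs(grid - 90))
  y <- 0.2 * b$matrix[, j20] + 0.8 * b$matrix[, j90]
  fit <- nnls_fit(y, b)
  frac_short <- sum(fit$amplitudes[grid < 40]) / sum(fit$amplitudes)
  expect_equal(frac_short, 0.20, tolerance = 0.02)
})

test_that("the solver agrees with the pracma reference and satisfies KKT", {
  set.seed(42)
  b8 <- build_basis(t2_grid(25), 180, acq_params(n_echoes = 8))
  A <- b8$matrix
  for (rep_i in 1:5) {
    xtrue <- numeric(25)
    xtrue[sample(25, 3)] <- stats::runif(3, 0.1, 1)
    y <- drop(A %*% xtrue) + stats::rnorm(8, 0, 0.005)
    mine <- t2compart:::nnls_solve(A, y)
    ref <- pracma::lsqnonneg(A, y)
    obj_mine <- sum((A %*% mine$x - y)^2)
    obj_ref <- sum((A %*% ref$x - y)^2)
    expect_lt(abs(obj_mine - obj_ref), 1e-6)
    expect_true(nnls_kkt_ok(A, y, as.numeric(mine$x)))
    expect_true(all(mine$x >= 0))
  }
})

test_that("fits are scale equivariant", {
  m <- tissue_model(0.15, 20, 0.85, 85, 0, 1000)
  y <- voxel_signal(m, flip = 155, acq = acq)
  y <- add_rician_noise(y, snr = 150, seed = 3)
  base <- fit_echo_train(y, acq)
  for (c_scale in c(1e-3, 50)) {
    s <- fit_echo_train(c_scale * y, acq)
    expect_equal(s$flip_angle, base$flip_angle)
    expect_lt(max(abs(s$amplitudes - c_scale * base$amplitudes)) /
                max(c_scale * base$amplitudes), 1e-9)
    expect_equal(partition_spectrum(s)$myelin_fraction,
                 partition_spectrum(base)$myelin_fraction, tolerance = 1e-9)
  }
})

test_that("misfit inflation of exactly 1 reduces to the unregularized fit", {
  b <- build_basis(grid, 170, acq)
  y <- voxel_signal(tissue_model(), flip = 170, acq = acq)
  y <- add_rician_noise(y, snr = 100, seed = 5)
  reg <- regularized_fit(y, b, fit_config(misfit_inflation = 1))
  un <- nnls_fit(y, b)
  expect_lt(max(abs(reg$amplitudes - un$amplitudes)), 1e-8)
  expect_equal(reg$mu, 0)
})

test_that("the regularization path is monotone in the penalty weight", {
  b <- build_basis(grid, 170, acq)
  y <- voxel_signal(tissue_model(), flip = 170, acq = acq)
  y <- add_rician_noise(y, snr = 100, seed = 6)
  G0 <- crossprod(b$matrix)
  DtD <- t2compart:::second_diff_gram(length(grid))
  D <- t2compart:::second_diff_matrix(length(grid))
  f <- drop(crossprod(b$matrix, y))
  mus <- 10^seq(-4, 2, by = 1)
  misfit <- curv <- numeric(length(mus))
  for (i in seq_along(mus)) {
    x <- as.numeric(t2compart:::nnls_gram(G0 + mus[i] * DtD, f))
    misfit[i] <- sqrt(sum((b$matrix %*% x - y)^2))
    curv[i] <- sqrt(sum((D %*% x)^2))
  }
  expect_true(all(diff(misfit) >= -1e-10))
  expect_true(all(diff(curv) <= 1e-10))
})

test_that("regularized single-pool fits keep the weighted mean T2", {
  for (t2_true in c(60, 120)) {
    y <- voxel_signal(tissue_model(0, 20, 1, t2_true, 0, 1000),
                      flip = 165, acq = acq)
    b <- build_basis(grid, 165, acq)
    s <- regularized_fit(y, b, fit_config())
    wmean <- sum(s$amplitudes * grid) / sum(s$amplitudes)
    expect_lt(abs(wmean - t2_true) / t2_true, 0.03)
  }
})

test_that("the refocusing flip angle is recovered from noiseless trains", {
  m <- tissue_model(0.15, 20, 0.85, 85, 0, 1000)
  for (fa in c(130, 150, 160)) {
    y <- voxel_signal(m, flip = fa, acq = acq)
    s <- fit_flip_angle(y, fit_config(), acq)
    expect_lt(abs(s$flip_angle - fa), 2, label = sprintf("true flip %g", fa))
  }
  y180 <- voxel_signal(m, flip = 180, acq = acq)
  s180 <- fit_flip_angle(y180, fit_config(), acq)
  expect_gte(s180$flip_angle, 178)
})

test_that("recovered weighted T2 increases monotonically with true T2", {
  wm <- vapply(c(60, 80, 100, 120), function(t2_true) {
    y <- voxel_signal(tissue_model(0, 20, 1, t2_true, 0, 1000),
                      flip = 170, acq = acq)
    s <- fit_echo_train(y, acq)
    partition_spectrum(s)$iew_t2
  }, numeric(1))
  expect_true(all(diff(wm) > 0))
})

test_that("Monte-Carlo recovery of a two-pool model at SNR 200 is unbiased", {
  m <- tissue_model(0.15, 20, 0.85, 85, 0, 1000)
  tr <- phantom_voxels(80, m, flip = 150, snr = 200, acq = acq, seed = 2)
  res <- fit_voxels(tr, acq)
  expect_equal(nrow(res), 80)
  expect_lt(abs(mean(res$myelin_fraction) - 0.15), 0.03)
  expect_lt(abs(mean(res$iew_t2) - 85), 5)
  expect_lt(abs(stats::median(res$flip_angle) - 150), 5)
})

test_that("tidy and glance views of a fitted spectrum are consistent", {
  y <- voxel_signal(tissue_model(), flip = 170, acq = acq)
  s <- fit_echo_train(y, acq)
  td <- tidy(s)
  expect_named(td, c("t2", "amplitude", "compartment"))
  expect_equal(nrow(td), length(grid))
  g <- glance(s)
  expect_equal(g$myelin_fraction + g$iew_fraction + g$csf_fraction, 1,
               tolerance = 1e-9)
  expect_equal(sum(td$amplitude), g$total_amplitude)
})
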