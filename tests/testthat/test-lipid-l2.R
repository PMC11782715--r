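make_L <- function(nf = 128, nc = 20, seed = 7) {
  ax <- spectral_axis(nf, 2326)
  p <- nuisance_params(metab_ref = 1)
  vapply(seq_len(nc), function(k)
    sample_lipid_spectrum(p, ax, seed = seed * 1000 + k)$data, complex(nf))
}

test_that("factored operator matches the dense matrix inverse", {
  L <- make_L(128, 20)
  for (beta in c(1e-4, 0.05, 3)) {
    sub <- lipid_subspace(L, beta)
    D <- mrsiclean:::dense_lipid_operator(L, beta)
    x <- rand_complex(128, seed = 3)
    expect_lt(max(Mod(apply_l2_suppression(x, sub) - D %*% x)), 1e-8)
    expect_lt(max(Mod(lipid_project(x, sub) - (x - D %*% x))), 1e-8)
    expect_lt(abs(mean_abs_diag(sub) - mean(abs(diag(D)))), 1e-10)
  }
})

test_that("operator is Hermitian positive definite with eigenvalues in (0, 1]", {
  L <- make_L(64, 10)
  D <- mrsiclean:::dense_lipid_operator(L, 0.2)
  expect_lt(max(Mod(D - Conj(t(D)))), 1e-10)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0 & ev <= 1 + 1e-12))
})

test_that("projection and suppression sum to the identity", {
  sub <- test_subspace()
  x <- rand_complex(test_axis()$n_points, seed = 9)
  expect_lt(max(Mod(lipid_project(x, sub) + apply_l2_suppression(x, sub) - x)),
            1e-12 * max(Mod(x)))
})

test_that("spectra orthogonal to the subspace pass through unchanged", {
  L <- make_L(128, 10)
  sub <- lipid_subspace(L, 5)
  x <- rand_complex(128, seed = 21)
  # remove the span(L) component to build an orthogonal input
  U <- sub$U
  x_perp <- x - U %*% (Conj(t(U)) %*% x)
  expect_lt(max(Mod(lipid_project(x_perp, sub))), 1e-10 * sqrt(sum(Mod(x_perp)^2)))
  expect_lt(max(Mod(apply_l2_suppression(x_perp, sub) - x_perp)),
            1e-10 * sqrt(sum(Mod(x_perp)^2)))
})

test_that("single-unit-column operator matches the closed form", {
  n <- 32
  e1 <- complex(real = c(1, rep(0, n - 1)))
  beta <- 2.5
  sub <- lipid_subspace(matrix(e1, ncol = 1), beta)
  x <- rand_complex(n, seed = 5)
  # (1 - L_op) x = (beta/(1+beta)) e1 e1^H x
  expect_lt(max(Mod(lipid_project(x, sub) -
                      (beta / (1 + beta)) * e1 * sum(Conj(e1) * x))), 1e-12)
  # diagonal mean: (n - 1 + 1/(1+beta))/n
  expect_lt(abs(mean_abs_diag(sub) - (n - 1 + 1 / (1 + beta)) / n), 1e-12)
})

test_that("beta calibration hits the 0.938 setpoint and the analytic case", {
  L <- make_L(200, 50, seed = 1)
  beta <- calibrate_beta(L, target = 0.938, tol = 1e-3)
  expect_lt(abs(mean_abs_diag(lipid_subspace(L, beta)) - 0.938), 1e-3)
  # closed-form single-column case: solve (n-1+1/(1+b))/n = target
  n <- 64; target <- 0.99
  e1 <- matrix(complex(real = c(1, rep(0, n - 1))), ncol = 1)
  b_hat <- calibrate_beta(e1, target = target, tol = 1e-6)
  b_true <- 1 / (1 - n * (1 - target)) - 1
  expect_lt(abs(b_hat - b_true) / b_true, 1e-2)
  expect_error(calibrate_beta(matrix(0 + 0i, 10, 3)), "zero")
})

test_that("mean |diag| decreases monotonically over six decades of beta", {
  L <- make_L(96, 15, seed = 3)
  sub <- lipid_subspace(L, 0)
  betas <- 10^seq(-6, 0, length.out = 13) / max(sub$s)^2 * 100
  vals <- vapply(betas, function(b) mean_abs_diag(sub, beta = b), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("large beta recovers in-span signal and kills it under suppression", {
  L <- make_L(128, 8, seed = 11)
  l_sig <- as.vector(L %*% rand_complex(8, seed = 2))
  norms <- vapply(10^c(2, 4, 6), function(beta) {
    sub <- lipid_subspace(L, beta / max(Mod(l_sig))^2)
    sqrt(sum(Mod(apply_l2_suppression(l_sig, sub))^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))    # monotone decreasing toward 0
  # projection bound: x = m + l with m orthogonal, large beta
  sub <- lipid_subspace(L, 1e8 / max(sub_s <- svd(L)$d)^2)
  m <- rand_complex(128, seed = 13)
  U <- sub$U
  m <- m - U %*% (Conj(t(U)) %*% m)
  out <- lipid_project(as.vector(m) + l_sig, sub)
  smin <- min(svd(L)$d)
  bound <- 1 / (1 + sub$beta * smin^2)
  relerr <- sqrt(sum(Mod(out - l_sig)^2)) / sqrt(sum(Mod(l_sig)^2))
  expect_lt(relerr, bound + 1e-8)
})

test_that("extract_lipid_basis returns scalp columns in row-major order", {
  ax <- test_axis(64)
  data <- matrix(rand_complex(64 * 16, seed = 8), 64, 16)
  scalp <- matrix(FALSE, 4, 4); scalp[1, 2] <- scalp[3, 4] <- TRUE
  brain <- matrix(FALSE, 4, 4); brain[2, 2] <- TRUE
  vol <- mrsi_volume(data, ax, c(4, 4), "freq", brain, scalp)
  L <- extract_lipid_basis(vol)
  expect_equal(ncol(L), 2)
  expect_equal(L[, 1], data[, 2])    # voxel (1,2) -> row-major column 2
  expect_equal(L[, 2], data[, 12])   # voxel (3,4) -> column 2*4+4
  expect_error(extract_lipid_basis(vol, matrix(FALSE, 4, 4)), "empty")
  data[, 12] <- NaN + 0i
  vol2 <- mrsi_volume(data, ax, c(4, 4), "freq", brain, scalp)
  expect_error(extract_lipid_basis(vol2), "voxel")
})
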