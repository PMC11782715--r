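rand_volume <- function(np = 64, ny = 4, nx = 4, seed = 1) {
  ax <- spectral_axis(np, 2326)
  data <- matrix(rand_complex(np * ny * nx, seed = seed), np, ny * nx)
  mrsi_volume(data, ax, c(ny, nx), "freq",
              brain_mask = matrix(TRUE, ny, nx))
}

test_that("low-rank truncation satisfies Eckart-Young on random matrices", {
  set.seed(2)
  vol <- rand_volume(48, 4, 5)
  K <- 6
  den <- low_rank_denoise(vol, K)
  C <- t(vol$data)
  sv <- svd(C)
  err <- sqrt(sum(Mod(t(den$data) - C)^2))
  tail_err <- sqrt(sum(sv$d[-(1:K)]^2))
  expect_lt(abs(err - tail_err) / tail_err, 1e-10)
  # rank <= K input is reproduced exactly
  lowC <- sv$u[, 1:3] %*% (sv$d[1:3] * Conj(t(sv$v[, 1:3])))
  vol_low <- mrsiclean:::with_volume_data(vol, t(lowC))
  rec <- low_rank_denoise(vol_low, 5)
  expect_lt(max(Mod(rec$data - vol_low$data)) / max(Mod(lowC)), 1e-8)
  # default rank and bounds
  expect_equal(eval(formals(low_rank_denoise)$K), 40L)
  expect_error(low_rank_denoise(vol, 100), "exceeds")
})

test_that("nrmse follows the hand formula and its conventions", {
  ax <- spectral_axis(64, 2326)
  truth <- rand_complex(64, seed = 3)
  expect_equal(nrmse(truth, truth, c(9, 0), axis = ax), 0)
  # perturb one bin inside the lipid range by the reference norm
  ridx <- ppm_window_idx(ax, c(4.2, 1.9))
  ref_norm <- sqrt(sum(Mod(truth[ridx])^2))
  li <- ppm_window_idx(ax, c(1.9, 0.7))
  pred <- truth
  pred[li[1]] <- pred[li[1]] + ref_norm
  expect_equal(nrmse(pred, truth, c(1.9, 0.7), axis = ax), 100)
  # scale invariance
  expect_equal(nrmse(3 * pred, 3 * truth, c(1.9, 0.7), axis = ax),
               nrmse(pred, truth, c(1.9, 0.7), axis = ax))
  # 4-point hand computation with per-range reference
  ax4 <- spectral_axis(4, 400, carrier_ppm = 1, field_mhz = 100)
  tr <- c(1, 0, 0, 0) + 0i; pr <- c(1, 1, 0, 0) + 0i
  expect_equal(nrmse(pr, tr, c(-10, 10), axis = ax4, ref = "range"), 100)
  expect_error(nrmse(pr, tr * 0, c(-10, 10), axis = ax4), "zero")
  # vectorized form agrees with the scalar form
  P <- cbind(pred, truth); Tm <- cbind(truth, truth)
  v <- nrmse_cols(P, Tm, c(1.9, 0.7), ax)
  expect_equal(v[1], nrmse(pred, truth, c(1.9, 0.7), axis = ax))
  expect_equal(v[2], 0)
})

test_that("suppression factor measures fold reduction over mask voxels", {
  vol <- rand_volume(64, 3, 3, seed = 5)
  expect_equal(suppression_factor(vol, vol), 1)
  half <- mrsiclean:::with_volume_data(vol, vol$data / 10)
  expect_equal(suppression_factor(vol, half), 10, tolerance = 1e-12)
  zero <- mrsiclean:::with_volume_data(vol, vol$data * 0)
  sf <- suppression_factor(vol, zero)
  expect_true(isTRUE(attr(sf, "capped")))
  expect_equal(as.numeric(sf), 1e6)
})

test_that("projection-based suppression never amplifies lipid-only input", {
  ax <- test_axis()
  p <- test_nuisance_params()
  sub <- test_subspace()
  for (k in 1:5) {
    l <- sample_lipid_spectrum(p, ax, seed = 400 + k)$data
    out <- apply_l2_suppression(l, sub)
    li <- ppm_window_idx(ax, c(1.9, 0.7))
    expect_lte(sum(Mod(out[li])^2), sum(Mod(l[li])^2) * (1 + 1e-12))
  }
})

test_that("snr and fwhm proxies recover a known Lorentzian", {
  ax <- spectral_axis(4096, 2326)
  t <- (0:4095) / 2326
  gamma_hz <- 8                              # FWHM = damping/pi
  f <- (2.008 - ax$carrier_ppm) * ax$field_mhz
  fid <- exp((2i * pi * f - pi * gamma_hz) * t)
  noise <- 2e-4 * rand_complex(4096, seed = 6)
  sp <- to_freq(mrs_spectrum(fid + noise, ax, "time"))
  res <- snr_fwhm(sp)
  bin_ppm <- ax$bandwidth_hz / ax$n_points / ax$field_mhz
  expect_lt(abs(res$fwhm_ppm - gamma_hz / ax$field_mhz), bin_ppm + 1e-9)
  # doubling amplitude doubles snr
  sp2 <- to_freq(mrs_spectrum(2 * fid + noise, ax, "time"))
  expect_equal(snr_fwhm(sp2)$snr / res$snr, 2, tolerance = 0.05)
  # noiseless input is flagged
  clean <- to_freq(mrs_spectrum(fid, ax, "time"))
  expect_true(snr_fwhm(clean)$flagged)
  expect_error(snr_fwhm(sp, peak_ppm = 30), "outside")
})

test_that("eval report summarizes quartiles per method and range", {
  ax <- spectral_axis(64, 2326)
  truth <- matrix(rand_complex(64 * 10, seed = 8), 64, 10)
  noisy <- truth + 0.01 * matrix(rand_complex(640), 64, 10)
  rep <- eval_report(list(perfect = truth, noisy = noisy), truth, ax)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep), 6)
  perfect <- rep[rep$method == "perfect", ]
  expect_true(all(perfect$nrmse_median == 0))
  expect_true(all(rep$nrmse_q25 <= rep$nrmse_q75))
})
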