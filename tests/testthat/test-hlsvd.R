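three_exp_fid <- function(ax, f = c(-300, 100, 412), d = c(8, 15, 4),
                          a = c(1, 0.5, 2), ph = c(0.3, -1, 2)) {
  t <- (0:(ax$n_points - 1)) / ax$bandwidth_hz
  sig <- complex(length.out = ax$n_points)
  for (k in seq_along(f))
    sig <- sig + a[k] * exp(1i * ph[k]) * exp((-d[k] + 2i * pi * f[k]) * t)
  sig
}

test_that("noiseless damped sinusoids are recovered to 1e-6 relative", {
  ax <- spectral_axis(256, 2000)
  f <- c(-300, 100, 412); d <- c(8, 15, 4); a <- c(1, 0.5, 2); ph <- c(0.3, -1, 2)
  comps <- hankel_decompose(three_exp_fid(ax, f, d, a, ph), 3, axis = ax)
  comps <- comps[order(comps$frequency_hz), ]
  ord <- order(f)
  expect_lt(max(abs(comps$frequency_hz - f[ord]) / abs(f[ord])), 1e-6)
  expect_lt(max(abs(comps$damping - d[ord]) / d[ord]), 1e-6)
  expect_lt(max(abs(comps$amplitude - a[ord]) / a[ord]), 1e-6)
  expect_lt(max(abs(comps$phase - ph[ord])), 1e-6)
})

test_that("model-order adequacy: k components reconstruct exactly for k <= 32", {
  ax <- spectral_axis(200, 2000)
  fid <- three_exp_fid(ax)
  comps <- hankel_decompose(fid, 32, axis = ax)   # request more than present
  expect_lte(nrow(comps), 32)
  rec <- mrsiclean:::components_signal(comps, ax)
  expect_lt(sqrt(sum(Mod(rec - fid)^2) / sum(Mod(fid)^2)), 1e-8)
})

test_that("degenerate inputs are handled per contract", {
  ax <- spectral_axis(128, 2000)
  expect_equal(nrow(hankel_decompose(complex(length.out = 128), 32, axis = ax)), 0)
  expect_error(hankel_decompose(rand_complex(40), 32, axis = ax), "shorter")
  expect_equal(eval(formals(hankel_decompose)$n_components), 32L)
  expect_equal(sort(eval(formals(remove_water)$window_ppm)), c(4.2, 5.2))
})

test_that("water removal clears the window and preserves NAA", {
  ax <- spectral_axis(453, 2326)
  t <- (0:452) / 2326
  f_naa <- (2.008 - ax$carrier_ppm) * ax$field_mhz
  f_wat <- (4.68 - ax$carrier_ppm) * ax$field_mhz
  naa <- exp((2i * pi * f_naa - 6) * t)
  water <- 1000 * exp((2i * pi * f_wat - 30) * t)
  out <- remove_water(naa + water, axis = ax)
  sp_in <- mrsiclean:::fid_to_spec(naa + water)
  sp_out <- mrsiclean:::fid_to_spec(out)
  sp_naa <- mrsiclean:::fid_to_spec(naa)
  wi <- ppm_window_idx(ax, c(4.2, 5.2))
  ni <- ppm_window_idx(ax, c(1.9, 2.1))
  expect_gt(1 - sum(Mod(sp_out[wi])^2) / sum(Mod(sp_in[wi])^2), 0.99)
  expect_lt(abs(max(Mod(sp_out[ni])) / max(Mod(sp_naa[ni])) - 1), 0.01)
})

test_that("FIDs with nothing in the window pass through untouched", {
  ax <- spectral_axis(256, 2000)
  fid <- three_exp_fid(ax, f = c(-300, -150, -400))   # all far below water
  out <- remove_water(fid, axis = ax)
  expect_lt(max(Mod(out - fid)) / max(Mod(fid)), 1e-10)
  expect_error(remove_water(fid, window_ppm = c(30, 40), axis = ax), "outside")
})

test_that("subtraction is linear in the input for in-model signals", {
  ax <- spectral_axis(300, 2326)
  t <- (0:299) / 2326
  fid <- 50 * exp((2i * pi * 0 - 25) * t) +        # water at carrier
    exp((2i * pi * (-700) - 8) * t)
  r1 <- remove_water(fid, axis = ax)
  r2 <- remove_water(3.7 * fid, axis = ax)
  expect_lt(max(Mod(r2 - 3.7 * r1)) / max(Mod(r1)), 1e-6)
})

test_that("energy is conserved between residual and removed components", {
  ax <- spectral_axis(300, 2326)
  t <- (0:299) / 2326
  water <- 50 * exp((2i * pi * 10 - 25) * t)
  met <- exp((2i * pi * (-700) - 8) * t)
  fid <- water + met
  out <- remove_water(fid, axis = ax)
  removed <- fid - out
  # the subtracted part reproduces the known water component
  expect_lt(sqrt(sum(Mod(removed - water)^2) / sum(Mod(water)^2)), 1e-6)
  e_in <- sum(Mod(fid)^2); e_out <- sum(Mod(out)^2); e_rm <- sum(Mod(removed)^2)
  cross <- 2 * Re(sum(out * Conj(removed)))
  expect_lt(abs(e_in - e_out - e_rm - cross) / e_in, 1e-10)
})

test_that("volume-level removal respects masks", {
  ax <- spectral_axis(128, 2326)
  t <- (0:127) / 2326
  water <- 20 * exp((2i * pi * 0 - 30) * t)
  data <- matrix(0 + 0i, 128, 4)
  for (i in 1:4) data[, i] <- water * i
  brain <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  vol <- mrsi_volume(mrsiclean:::fid_to_spec_mat(data), ax, c(2, 2), "freq",
                     brain_mask = brain)
  out <- remove_water_volume(vol, n_components = 8)
  sp <- volume_spectra(out, "freq")
  wi <- ppm_window_idx(ax, c(4.2, 5.2))
  before <- volume_spectra(vol, "freq")
  expect_lt(sum(Mod(sp[wi, 1])^2) / sum(Mod(before[wi, 1])^2), 0.01)
  expect_equal(sp[, 3], before[, 3])   # unmasked voxel untouched
})
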