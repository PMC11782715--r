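test_that("single uncoupled spin gives the closed-form damped exponential", {
  ax <- spectral_axis(453, 2326)
  ss <- spin_system("X", 2.008, t2 = 0.15)
  fid <- simulate_metabolite_fid(ss, ax)
  t <- (0:(ax$n_points - 1)) / ax$bandwidth_hz
  f <- (2.008 - ax$carrier_ppm) * ax$field_mhz
  ref <- exp(2i * pi * f * t - t / 0.15)
  expect_lt(max(Mod(fid$data - ref)), 1e-10)
})

test_that("uncoupled resonances land within half a bin for varied axes", {
  for (ax in list(spectral_axis(453, 2326), spectral_axis(512, 4000))) {
    for (ppm in c(1.3, 3.03, 4.1)) {
      ss <- spin_system("X", ppm, t2 = 0.3)
      fid <- simulate_metabolite_fid(ss, ax)
      pk <- measure_peak_ppm(fid$data, ax)
      half_bin <- ax$bandwidth_hz / ax$n_points / ax$field_mhz / 2
      expect_lt(abs(pk - ppm), half_bin + 1e-12)
    }
  }
})

test_that("AX system shows first-order doublets split by J", {
  ax <- fine_axis()
  J <- 6.9
  ss <- spin_system("AX", c(1.0, 4.0), matrix(c(0, J, J, 0), 2), t2 = 2)
  m <- Mod(to_freq(simulate_metabolite_fid(ss, ax))$data)
  split_of <- function(range) {
    idx <- ppm_window_idx(ax, range)
    o <- idx[order(m[idx], decreasing = TRUE)][1:10]
    grp <- split(sort(o), cumsum(c(1, diff(sort(o)) > 3)))
    locs <- vapply(grp, function(g) g[which.max(m[g])], integer(1))
    abs(diff(ax$freq_hz[locs[1:2]]))
  }
  expect_lt(abs(split_of(c(0.8, 1.2)) - J), 0.1)
  expect_lt(abs(split_of(c(3.8, 4.2)) - J), 0.1)
})

test_that("lactate shows its 1.3 ppm doublet and 4.1 ppm resonance", {
  ax <- test_axis()
  lac <- test_catalog()$Lac
  m <- Mod(to_freq(simulate_metabolite_fid(lac, ax))$data)
  i13 <- ppm_window_idx(ax, c(1.0, 1.6))
  i41 <- ppm_window_idx(ax, c(3.9, 4.3))
  centroid <- sum(ax$ppm[i13] * m[i13]) / sum(m[i13])
  expect_lt(abs(centroid - 1.31), 0.05)
  expect_gt(max(m[i41]), 0.1 * max(m[i13]))   # quartet present
})

test_that("peak integral scales with multiplicity for uncoupled groups", {
  ax <- test_axis()
  one <- simulate_metabolite_fid(spin_system("s1", 2.0, t2 = 0.2), ax)
  three <- simulate_metabolite_fid(spin_system("s3", 2.0, multiplicities = 3L,
                                               t2 = 0.2), ax)
  expect_lt(max(Mod(three$data - 3 * one$data)), 1e-10)
})

test_that("component cap raises a resource error suggesting decomposition", {
  J <- matrix(1, 9, 9); diag(J) <- 0
  ss <- spin_system("big", seq(1, 3, length.out = 9), J)
  expect_error(simulate_metabolite_fid(ss, test_axis()), "subgroup")
})

test_that("basis construction enforces unique names and reproducibility", {
  ax <- test_axis()
  expect_error(build_basis(list(), ax), "nonempty")
  sys <- test_catalog()
  expect_error(build_basis(c(sys, sys[1]), ax), "duplicate")
  b <- test_basis()
  expect_gte(length(b$names), 10)
  expect_true(all(c("NAA", "Cr", "Cho", "Glu", "Ins", "Lac") %in% b$names))
  b2 <- build_basis(sys, ax)
  expect_identical(b$fids, b2$fids)    # byte-identical rebuild
})

test_that("spin system validation catches malformed inputs", {
  expect_error(spin_system("x", 11), "ppm")
  expect_error(spin_system("x", c(1, 2), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(spin_system("x", 1, matrix(1, 1, 1)), "diagonal")
  expect_error(spin_system("x", 1, multiplicities = 0L), "multiplicities")
})

test_that("sampled spectra are linear, deterministic and correctly broadened", {
  b <- test_basis()
  nm <- b$names[1]
  # null case
  p0 <- metabolite_sample_params(stats::setNames(numeric(0), character(0)))
  expect_equal(max(Mod(sample_metabolite_spectrum(b, p0)$data)), 0)
  # linearity in concentration
  p1 <- metabolite_sample_params(stats::setNames(1, nm))
  p2 <- metabolite_sample_params(stats::setNames(2, nm))
  s1 <- sample_metabolite_spectrum(b, p1)$data
  s2 <- sample_metabolite_spectrum(b, p2)$data
  expect_lt(max(Mod(s2 - 2 * s1)) / max(Mod(s1)), 1e-12)
  # mixture linearity across metabolites
  conc <- stats::setNames(c(0.8, 1.7), b$names[1:2])
  mix <- sample_metabolite_spectrum(b, metabolite_sample_params(conc))$data
  parts <- conc[1] * sample_metabolite_spectrum(
    b, metabolite_sample_params(conc[1] / conc[1] * stats::setNames(1, b$names[1])))$data +
    conc[2] * sample_metabolite_spectrum(
      b, metabolite_sample_params(stats::setNames(1, b$names[2])))$data
  expect_lt(max(Mod(mix - parts)) / max(Mod(mix)), 1e-10)
  # unknown names rejected
  expect_error(sample_metabolite_spectrum(
    b, metabolite_sample_params(stats::setNames(1, "nosuch"))), "unknown")
  # seed determinism
  pn <- metabolite_sample_params(stats::setNames(1, nm), noise_sigma = 0.1,
                                 seed = 42)
  expect_identical(sample_metabolite_spectrum(b, pn)$data,
                   sample_metabolite_spectrum(b, pn)$data)
})

test_that("Lorentzian broadening adds the requested FWHM to a singlet", {
  ax <- fine_axis()
  sys <- list(spin_system("s", 2.0, t2 = 1e6))   # negligible intrinsic width
  b <- build_basis(sys, ax)
  g <- 10
  p <- metabolite_sample_params(c(s = 1), linewidth_hz = g)
  sp <- mrs_spectrum(sample_metabolite_spectrum(b, p)$data, ax, "freq")
  fw <- snr_fwhm(sp, peak_ppm = 2.0)$fwhm_ppm * ax$field_mhz
  expect_lt(abs(fw - g) / g, 0.1)
})

test_that("discrete spectrum of a damped exponential matches the analytic form", {
  # DFT of exp((i w0 - 1/t2) t) has closed form via the finite geometric sum;
  # check the simulator's spectrum against it
  ax <- spectral_axis(2048, 2326)
  ss <- spin_system("X", 3.0, t2 = 0.08)
  sp <- to_freq(simulate_metabolite_fid(ss, ax))$data
  n <- ax$n_points; dt <- 1 / ax$bandwidth_hz
  w0 <- 2 * pi * (3.0 - ax$carrier_ppm) * ax$field_mhz
  r <- exp((1i * w0 - 1 / 0.08) * dt)
  k <- mrsiclean:::fft_perm(n) - 1L
  analytic <- (1 - (r * exp(-2i * pi * k / n))^n) / (1 - r * exp(-2i * pi * k / n))
  expect_lt(sqrt(sum(Mod(sp - analytic)^2) / sum(Mod(analytic)^2)), 1e-6)
})
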