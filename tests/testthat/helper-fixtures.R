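# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# default 7T axis used by most tests (smaller than the acquisition default
# to keep the suite fast)
test_axis <- function(n = 256L, bw = 2326) spectral_axis(n, bw)

# fine axis for frequency-resolution-sensitive checks
fine_axis <- function() spectral_axis(16384L, 2326)

test_catalog <- function() fixture("catalog", load_spin_catalog)

test_basis <- function() fixture("basis", function()
  build_basis(test_catalog(), test_axis()))

test_nuisance_params <- function() fixture("nparams", function()
  nuisance_params(metab_ref = metab_reference(test_basis())))

# a small calibrated lipid subspace shared across tests
test_subspace <- function() fixture("subspace", function() {
  ax <- test_axis()
  p <- test_nuisance_params()
  L <- vapply(1:30, function(k) sample_lipid_spectrum(p, ax, seed = 100 + k)$data,
              complex(ax$n_points))
  lipid_subspace(L, calibrate_beta(L), ax)
})

# Peak chemical shift of a time-domain signal, measured on a zero-padded
# grid so leakage of the truncated FID does not quantize the estimate to a
# whole (possibly second-nearest) bin.
measure_peak_ppm <- function(fid, axis, pad = 4L) {
  n <- length(fid)
  sp <- stats::fft(c(fid, rep(0 + 0i, (pad - 1L) * n)))
  f <- (seq_len(pad * n) - 1L) / (pad * n) * axis$bandwidth_hz
  f[f > axis$bandwidth_hz / 2] <- f[f > axis$bandwidth_hz / 2] - axis$bandwidth_hz
  axis$carrier_ppm + f[which.max(Mod(sp))] / axis$field_mhz
}

rand_complex <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}
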