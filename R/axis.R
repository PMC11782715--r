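#' Spectral axis of an MRSI acquisition
#'
#' Describes the sampling of one voxel's spectrum: number of complex points,
#' spectral bandwidth, the chemical-shift position of the carrier (transmitter)
#' frequency, and the proton Larmor frequency of the scanner. The frequency
#' axis runs from +bandwidth/2 down to -bandwidth/2 (exclusive), so index 1
#' corresponds to the highest ppm and ppm decreases with index.
#'
#' @param n_points number of complex FID/spectral points (> 0)
#' @param bandwidth_hz spectral bandwidth in Hz (> 0)
#' @param carrier_ppm chemical shift at the carrier frequency; water (4.68 ppm)
#'   by convention
#' @param field_mhz proton Larmor frequency in MHz (297.22 at 7 T)
#' @return an object of class `spectral_axis`
#' @export
spectral_axis <- function(n_points, bandwidth_hz, carrier_ppm = 4.68,
                          field_mhz = 297.22) {
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points <= 0L)
    stop("n_points must be a single positive integer")
  if (!is.numeric(bandwidth_hz) || bandwidth_hz <= 0)
    stop("bandwidth_hz must be positive")
  if (!is.numeric(field_mhz) || field_mhz <= 0)
    stop("field_mhz must be positive")
  df <- bandwidth_hz / n_points
  freq_hz <- bandwidth_hz / 2 - (seq_len(n_points) - 1L) * df
  structure(
    list(n_points = n_points,
         bandwidth_hz = as.numeric(bandwidth_hz),
         carrier_ppm = as.numeric(carrier_ppm),
         field_mhz = as.numeric(field_mhz),
         freq_hz = freq_hz,
         ppm = carrier_ppm + freq_hz / field_mhz,
         dwell_s = 1 / bandwidth_hz),
    class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.1f Hz bandwidth, carrier %.2f ppm, %.2f MHz\n",
              x$n_points, x$bandwidth_hz, x$carrier_ppm, x$field_mhz))
  cat(sprintf("  ppm range [%.3f, %.3f], resolution %.3f Hz (%.4f ppm)\n",
              max(x$ppm), min(x$ppm), x$bandwidth_hz / x$n_points,
              x$bandwidth_hz / x$n_points / x$field_mhz))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$bandwidth_hz - b$bandwidth_hz) < tol &&
    abs(a$carrier_ppm - b$carrier_ppm) < tol &&
    abs(a$field_mhz - b$field_mhz) < tol
}

#' Convert chemical shift to spectral index
#'
#' Returns the index of the spectral bin nearest the requested chemical shift.
#'
#' @param axis a [spectral_axis()]
#' @param ppm chemical shift(s) in ppm
#' @return integer index (1-based, index 1 = highest ppm)
#' @export
ppm_to_index <- function(axis, ppm) {
  df <- axis$bandwidth_hz / axis$n_points
  f <- (ppm - axis$carrier_ppm) * axis$field_mhz
  i <- round((axis$bandwidth_hz / 2 - f) / df) + 1L
  i <- as.integer(pmin(pmax(i, 1L), axis$n_points))
  i
}

#' Convert spectral index to chemical shift
#' @param axis a [spectral_axis()]
#' @param i index (1-based)
#' @return ppm value(s)
#' @export
index_to_ppm <- function(axis, i) axis$ppm[i]

#' Indices of a closed ppm interval
#'
#' @param axis a [spectral_axis()]
#' @param range_ppm numeric length-2, interval bounds in ppm (any order);
#'   closed on both ends
#' @return integer vector of indices whose bin centre lies inside the interval
#' @export
ppm_window_idx <- function(axis, range_ppm) {
  lo <- min(range_ppm); hi <- max(range_ppm)
  which(axis$ppm >= lo & axis$ppm <= hi)
}

#' A single voxel's spectrum or FID
#'
#' Thin container pairing a complex data vector with its [spectral_axis()] and
#' a domain flag. `to_freq()`/`to_time()` convert between the time-domain FID
#' and the frequency-domain spectrum using the axis convention (index 1 of the
#' spectrum = highest ppm).
#'
#' @param data complex vector of length `axis$n_points`
#' @param axis a [spectral_axis()]
#' @param domain `"time"` (FID) or `"freq"` (spectrum)
#' @return an object of class `mrs_spectrum`
#' @export
mrs_spectrum <- function(data, axis, domain = c("freq", "time")) {
  domain <- match.arg(domain)
  if (!inherits(axis, "spectral_axis")) stop("axis must be a spectral_axis")
  if (length(data) != axis$n_points)
    stop(sprintf("data length %d does not match axis n_points %d",
                 length(data), axis$n_points))
  structure(list(data = as.complex(data), axis = axis, domain = domain),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %s domain, %d points, max |.| = %.4g\n",
              x$domain, x$axis$n_points, max(Mod(x$data))))
  invisible(x)
}

# Permutation mapping FFT bin order (0..N-1 cyclic in frequency) to the
# descending-ppm axis order: spectrum[i] <- FFT(fid)[perm[i]].
fft_perm <- function(n) {
  half <- n %/% 2L
  ((half - seq_len(n) + 1L) %% n) + 1L
}

#' Convert a spectrum object to the frequency domain
#' @param x an [mrs_spectrum()]
#' @return an `mrs_spectrum` in the frequency domain
#' @export
to_freq <- function(x) {
  stopifnot(inherits(x, "mrs_spectrum"))
  if (x$domain == "freq") return(x)
  mrs_spectrum(fid_to_spec(x$data), x$axis, "freq")
}

#' Convert a spectrum object to the time domain
#' @param x an [mrs_spectrum()]
#' @return an `mrs_spectrum` in the time domain
#' @export
to_time <- function(x) {
  stopifnot(inherits(x, "mrs_spectrum"))
  if (x$domain == "time") return(x)
  mrs_spectrum(spec_to_fid(x$data), x$axis, "time")
}

# Vector-level transforms shared by everything that manipulates raw arrays.
fid_to_spec <- function(fid) {
  n <- length(fid)
  stats::fft(fid)[fft_perm(n)]
}

spec_to_fid <- function(spec) {
  n <- length(spec)
  raw <- complex(length.out = n)
  raw[fft_perm(n)] <- spec
  stats::fft(raw, inverse = TRUE) / n
}

# Matrix variants: columns are spectra (n_points x n_spectra).
fid_to_spec_mat <- function(fids) {
  n <- nrow(fids)
  stats::mvfft(fids)[fft_perm(n), , drop = FALSE]
}

spec_to_fid_mat <- function(specs) {
  n <- nrow(specs)
  raw <- matrix(complex(length.out = n * ncol(specs)), n, ncol(specs))
  raw[fft_perm(n), ] <- specs
  stats::mvfft(raw, inverse = TRUE) / n
}

# Time samples of the FID grid (dwell time spacing, starting at t = 0).
axis_times <- function(axis) (seq_len(axis$n_points) - 1L) * axis$dwell_s
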