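#' Damped-sinusoid decomposition of an FID (HLSVD, state-space method)
#'
#' Models the FID as a sum of exponentially damped complex sinusoids using
#' the Kung state-space variant of Hankel SVD: a near-square Hankel matrix of
#' the FID (ceil(N/2) rows) is truncated to the `n_components` largest
#' singular values, signal poles are estimated from the shift-invariance of
#' the left singular vectors by least squares, and complex amplitudes follow
#' from a linear fit of the FID onto the estimated exponentials. Components
#' are returned sorted by decreasing energy.
#'
#' @param fid time-domain [mrs_spectrum()] or complex vector
#' @param n_components number of retained singular values (default 32)
#' @param axis optional [spectral_axis()] (required when `fid` is a bare
#'   vector and ppm output is wanted)
#' @param reject_growing drop components with |pole| > 1 (growing
#'   exponentials) instead of flagging them
#' @return data.frame with columns `frequency_hz`, `damping` (1/s, >= 0 for
#'   decaying), `amplitude`, `phase`, `energy`, `growing`; zero rows for an
#'   all-zero FID
#' @export
hankel_decompose <- function(fid, n_components = 32L, axis = NULL,
                             reject_growing = FALSE) {
  if (inherits(fid, "mrs_spectrum")) {
    axis <- fid$axis
    fid <- to_time(fid)$data
  }
  if (is.null(axis)) stop("an axis is required to interpret the FID timing")
  x <- as.complex(fid)
  N <- length(x)
  n_components <- as.integer(n_components)
  if (N < 2L * n_components)
    stop(sprintf("FID length %d is shorter than 2*n_components = %d",
                 N, 2L * n_components))
  empty <- data.frame(frequency_hz = numeric(0), damping = numeric(0),
                      amplitude = numeric(0), phase = numeric(0),
                      energy = numeric(0), growing = logical(0))
  if (max(Mod(x)) == 0) return(empty)
  dt <- axis$dwell_s
  M <- ceiling(N / 2)
  K <- N - M + 1L
  H <- matrix(0 + 0i, M, K)
  for (j in seq_len(K)) H[, j] <- x[(j):(j + M - 1L)]
  sv <- svd(H, nu = min(M, n_components), nv = 0)
  # rank is additionally capped at M-1 so the shift-invariance system below
  # stays overdetermined
  kmax <- min(n_components, length(sv$d), M - 1L)
  keep <- which(sv$d[seq_len(kmax)] > 1e-10 * sv$d[1])
  if (!length(keep)) return(empty)
  U <- sv$u[, keep, drop = FALSE]
  # shift invariance: U[2:M,] ~= U[1:M-1,] %*% F; poles = eig(F)
  U1 <- U[-nrow(U), , drop = FALSE]
  U2 <- U[-1, , drop = FALSE]
  F <- lstsq_complex(U1, U2)
  z <- eigen(F, only.values = TRUE)$values
  # numerical safety: clamp runaway growing poles (|z| slightly above 1 is
  # common in practice and kept; far above 1 would overflow the basis)
  zmod <- Mod(z)
  z[zmod > 1.05] <- z[zmod > 1.05] / zmod[zmod > 1.05] * 1.05
  lz <- log(z)
  freq <- Im(lz) / (2 * pi * dt)
  damp <- -Re(lz) / dt
  # complex amplitudes by least squares on the Vandermonde basis
  tt <- 0:(N - 1L)
  Z <- exp(outer(tt, lz))
  c_amp <- as.vector(lstsq_complex(Z, matrix(x, ncol = 1)))
  amp <- Mod(c_amp)
  phase <- Arg(c_amp)
  energy <- amp^2 * colSums(Mod(Z)^2)
  growing <- Mod(z) > 1 + 1e-12
  out <- data.frame(frequency_hz = freq, damping = damp, amplitude = amp,
                    phase = phase, energy = energy, growing = growing)
  if (reject_growing) out <- out[!out$growing, , drop = FALSE]
  out <- out[order(-out$energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# complex least squares via the SVD pseudo-inverse (robust to rank
# deficiency from coalescing poles)
lstsq_complex <- function(A, B, rtol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * (Conj(t(sv$u)) %*% B))
}

# time-domain signal of a set of components on an axis grid
components_signal <- function(comps, axis) {
  t <- axis_times(axis)
  sig <- complex(length.out = axis$n_points)
  for (r in seq_len(nrow(comps))) {
    sig <- sig + comps$amplitude[r] * exp(1i * comps$phase[r]) *
      exp((-comps$damping[r] + 2i * pi * comps$frequency_hz[r]) * t)
  }
  sig
}

#' HLSVD water removal
#'
#' Decomposes the FID into damped sinusoids and subtracts the components
#' whose frequency falls inside the water window (4.7 +/- 0.5 ppm by
#' default). Components outside the window are untouched, so metabolite
#' signal is preserved.
#'
#' @param fid time-domain [mrs_spectrum()] (or complex vector with `axis`)
#' @param window_ppm closed ppm interval to clear (default `c(4.2, 5.2)`)
#' @param n_components retained Hankel singular values (default 32)
#' @param axis [spectral_axis()] when `fid` is a bare vector
#' @return residual in the same form as the input (time domain)
#' @export
remove_water <- function(fid, window_ppm = c(4.7 - 0.5, 4.7 + 0.5),
                         n_components = 32L, axis = NULL) {
  was_spec <- inherits(fid, "mrs_spectrum")
  if (was_spec) {
    axis <- fid$axis
    in_domain <- fid$domain
    x <- to_time(fid)$data
  } else {
    if (is.null(axis)) stop("axis is required for ppm conversion")
    x <- as.complex(fid)
  }
  lo <- min(window_ppm); hi <- max(window_ppm)
  if (hi < min(axis$ppm) || lo > max(axis$ppm))
    stop("water window lies outside the spectral range")
  comps <- hankel_decompose(x, n_components = n_components, axis = axis)
  if (nrow(comps)) {
    ppm <- axis$carrier_ppm + comps$frequency_hz / axis$field_mhz
    inwin <- ppm >= lo & ppm <= hi
    if (any(inwin))
      x <- x - components_signal(comps[inwin, , drop = FALSE], axis)
  }
  if (was_spec) {
    out <- mrs_spectrum(x, axis, "time")
    if (in_domain == "freq") out <- to_freq(out)
    out
  } else x
}

#' HLSVD water removal over a whole volume
#'
#' Applies [remove_water()] voxel-by-voxel; voxels outside the union of
#' brain and scalp masks (if any mask is set) are passed through unchanged.
#'
#' @param volume an [mrsi_volume()]
#' @inheritParams remove_water
#' @param mask_only restrict processing to brain/scalp voxels
#' @return an [mrsi_volume()] in the volume's original domain
#' @export
remove_water_volume <- function(volume, window_ppm = c(4.2, 5.2),
                                n_components = 32L, mask_only = TRUE) {
  stopifnot(inherits(volume, "mrsi_volume"))
  fids <- volume_spectra(volume, "time")
  any_mask <- any(volume$brain_mask) || any(volume$scalp_mask)
  act <- if (mask_only && any_mask)
    rowmajor_indices(volume$brain_mask | volume$scalp_mask)
  else seq_len(ncol(fids))
  for (c0 in act) {
    fids[, c0] <- remove_water(fids[, c0], window_ppm = window_ppm,
                               n_components = n_components,
                               axis = volume$axis)
  }
  out <- with_volume_data(volume, fids, "time")
  if (volume$domain == "freq")
    out <- with_volume_data(volume, fid_to_spec_mat(fids), "freq")
  out
}
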