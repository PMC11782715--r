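#' Truncate a high-resolution image (or image stack) in k-space
#'
#' Fourier-transforms each high-resolution plane, retains only the central
#' (ny, nx) block of k-space, and reconstructs on the low-resolution grid.
#' This reproduces the Gibbs-ringing mechanism by which scalp lipid signal
#' leaks into brain voxels of an MRSI acquisition with a small matrix size.
#' No apodization is applied by default (worst-case ringing); `hamming = TRUE`
#' applies a 2D Hamming window to the retained k-space block.
#'
#' @param plane complex/numeric matrix (nyh x nxh), the high-resolution image
#' @param shape integer (ny, nx) target grid; must divide into the input shape
#' @param hamming apply Hamming apodization to the truncated k-space
#' @return complex (ny, nx) matrix, amplitude-preserving (a constant image
#'   stays constant)
#' @export
kspace_truncate <- function(plane, shape, hamming = FALSE) {
  nyh <- nrow(plane); nxh <- ncol(plane)
  ny <- shape[1]; nx <- shape[2]
  if (ny > nyh || nx > nxh) stop("target shape exceeds input shape")
  ks <- stats::fft(plane)
  # retain frequencies ky in [-ny/2, ny/2), kx in [-nx/2, nx/2)
  kyi <- c(seq_len(ceiling(ny / 2)), nyh - floor(ny / 2) + seq_len(floor(ny / 2)))
  kxi <- c(seq_len(ceiling(nx / 2)), nxh - floor(nx / 2) + seq_len(floor(nx / 2)))
  kept <- ks[kyi, kxi, drop = FALSE]
  if (hamming) {
    wy <- 0.54 - 0.46 * cos(2 * pi * (0:(ny - 1)) / ny)
    wx <- 0.54 - 0.46 * cos(2 * pi * (0:(nx - 1)) / nx)
    # windows indexed in wrapped k-order
    wy <- wy[c(seq(ceiling(ny / 2) + 1L, ny), seq_len(ceiling(ny / 2)))]
    wx <- wx[c(seq(ceiling(nx / 2) + 1L, nx), seq_len(ceiling(nx / 2)))]
    kept <- kept * outer(wy, wx)
  }
  stats::fft(kept, inverse = TRUE) / (nyh * nxh)
}

# smoothed uniform random field in [0,1], used for tissue-texture maps
smooth_field <- function(ny, nx, smooth = 4) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  ks <- stats::fft(z)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  filt <- exp(-(outer(fy^2, rep(1, nx)) + outer(rep(1, ny), fx^2)) * (smooth * 10)^2)
  s <- Re(stats::fft(ks * filt, inverse = TRUE)) / (ny * nx)
  s <- s - min(s)
  if (max(s) > 0) s <- s / max(s)
  s
}

ellipse_mask <- function(ny, nx, ry, rx) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  y <- matrix(seq_len(ny), ny, nx)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ((y - cy) / (ry * ny))^2 + ((x - cx) / (rx * nx))^2 <= 1
}

#' Build a 2D MRSI phantom with scalp-lipid ringing
#'
#' Constructs a high-resolution digital phantom (elliptical brain with
#' textured metabolite concentration maps, scalp annulus carrying lipid and
#' water signal), synthesizes its spatio-spectral data, and truncates k-space
#' to the acquisition matrix so that brain voxels are contaminated by
#' scalp-lipid Gibbs ringing -- the mechanism that makes lipid removal
#' necessary in vivo.
#'
#' @param shape integer (ny, nx) acquisition grid
#' @param params a [nuisance_params()]
#' @param basis a [build_basis()] result
#' @param seed integer seed
#' @param highres_factor integer >= 2, high-resolution oversampling factor
#' @param linewidth_hz extra broadening of the metabolite spectra
#' @param lipid_on,water_on switch the nuisance sources on/off
#' @param noise_sigma thermal noise std added per low-res voxel/point
#' @param hamming apply Hamming apodization during truncation
#' @return list with elements `phantom` (high-res maps and masks), `volume`
#'   (contaminated [mrsi_volume()]), `metab_volume` (metabolite-only truth on
#'   the same grid), and `nuisance_volume` (lipid+water only)
#' @export
build_phantom <- function(shape, params, basis, seed = 1L,
                          highres_factor = 4L, linewidth_hz = 12,
                          lipid_on = TRUE, water_on = TRUE,
                          noise_sigma = 0, hamming = FALSE) {
  stopifnot(inherits(params, "nuisance_params"),
            inherits(basis, "metabolite_basis"))
  h <- as.integer(highres_factor)
  if (h < 2L) stop("highres_factor must be >= 2")
  ny <- shape[1]; nx <- shape[2]
  nyh <- ny * h; nxh <- nx * h
  axis <- basis$axis
  np <- axis$n_points

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  brain_hr <- ellipse_mask(nyh, nxh, 0.32, 0.36)
  outer_hr <- ellipse_mask(nyh, nxh, 0.46, 0.50)
  inner_hr <- ellipse_mask(nyh, nxh, 0.40, 0.44)
  scalp_hr <- outer_hr & !inner_hr
  if (any(brain_hr & scalp_hr)) stop("internal error: phantom masks overlap")

  ratios <- default_concentration_ratios(basis$names)
  conc_maps <- lapply(seq_along(basis$names), function(k) {
    m <- (0.6 + 0.8 * smooth_field(nyh, nxh)) * ratios[k]
    m[!brain_hr] <- 0
    m
  })
  names(conc_maps) <- basis$names

  lipid_amp <- matrix(0, nyh, nxh)
  if (lipid_on) lipid_amp[scalp_hr] <- stats::runif(sum(scalp_hr), 0.5, 1.5)
  water_amp <- matrix(0, nyh, nxh)
  if (water_on) {
    water_amp[brain_hr] <- stats::runif(sum(brain_hr), 0.8, 1.2)
    water_amp[scalp_hr] <- stats::runif(sum(scalp_hr), 0.4, 0.8)
  }

  # spectral building blocks
  bp <- metabolite_sample_params(concentrations = stats::setNames(
    rep(1, length(basis$names)), basis$names), linewidth_hz = linewidth_hz,
    seed = seed)
  t <- axis_times(axis)
  decay <- exp(-pi * linewidth_hz * t)
  met_spec <- fid_to_spec_mat(basis$fids * decay)   # np x n_met
  water_shape <- sample_water_spectrum(params, axis, seed = seed + 1L)$data
  scalp_idx <- which(scalp_hr)
  lipid_shapes <- NULL
  if (lipid_on && length(scalp_idx)) {
    # a handful of distinct scalp-lipid profiles reused across the annulus
    nprof <- min(24L, length(scalp_idx))
    lipid_shapes <- vapply(seq_len(nprof), function(k)
      sample_lipid_spectrum(params, axis, seed = seed * 131L + k)$data,
      complex(np))
    prof_of <- (seq_along(scalp_idx) - 1L) %% nprof + 1L
  }

  # high-resolution spatio-spectral data, nonzero voxels only
  hr <- matrix(0 + 0i, np, nyh * nxh)
  bidx <- which(brain_hr)
  if (length(bidx)) {
    C <- do.call(rbind, lapply(conc_maps, function(m) m[bidx]))  # n_met x nb
    hr[, bidx] <- met_spec %*% C
  }
  if (!is.null(lipid_shapes)) {
    hr[, scalp_idx] <- hr[, scalp_idx] +
      lipid_shapes[, prof_of, drop = FALSE] *
        matrix(lipid_amp[scalp_idx], np, length(scalp_idx), byrow = TRUE)
  }
  widx <- which(water_amp > 0)
  if (length(widx)) {
    hr[, widx] <- hr[, widx] +
      outer(water_shape, water_amp[widx])
  }

  truncate_stack <- function(cols_select = NULL) {
    out <- matrix(0 + 0i, np, ny * nx)
    src <- if (is.null(cols_select)) hr else {
      tmp <- matrix(0 + 0i, np, nyh * nxh)
      tmp[, cols_select] <- hr[, cols_select]
      tmp
    }
    for (p in seq_len(np)) {
      plane <- matrix(src[p, ], nyh, nxh)
      lo <- kspace_truncate(plane, c(ny, nx), hamming = hamming)
      out[p, ] <- as.vector(t(lo))     # row-major voxel order
    }
    out
  }

  data_full <- truncate_stack()
  data_met <- truncate_stack(bidx)
  data_nuis <- data_full - data_met

  if (noise_sigma > 0) {
    nvals <- np * ny * nx
    data_full <- data_full +
      matrix(complex(real = stats::rnorm(nvals, 0, noise_sigma),
                     imaginary = stats::rnorm(nvals, 0, noise_sigma)),
             np, ny * nx)
  }

  # low-res masks by sub-voxel occupancy
  frac_of <- function(mask_hr) {
    m <- matrix(0, ny, nx)
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      m[iy, ix] <- mean(mask_hr[((iy - 1) * h + 1):(iy * h),
                                ((ix - 1) * h + 1):(ix * h)])
    }
    m
  }
  brain_lo <- frac_of(brain_hr) >= 0.5
  scalp_lo <- frac_of(scalp_hr) >= 0.25 & !brain_lo

  mk_vol <- function(d) mrsi_volume(d, axis, c(ny, nx), "freq",
                                    brain_lo, scalp_lo)
  phantom <- structure(
    list(shape = c(ny, nx), highres_factor = h,
         brain_mask_hr = brain_hr, scalp_mask_hr = scalp_hr,
         conc_maps = conc_maps, lipid_amp = lipid_amp,
         water_amp = water_amp, seed = seed),
    class = "phantom_volume")
  list(phantom = phantom,
       volume = mk_vol(data_full),
       metab_volume = mk_vol(data_met),
       nuisance_volume = mk_vol(data_nuis))
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %dx%d grid (x%d high-res), %d scalp / %d brain high-res voxels\n",
              x$shape[1], x$shape[2], x$highres_factor,
              sum(x$scalp_mask_hr), sum(x$brain_mask_hr)))
  invisible(x)
}
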