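#' Spatial grid of spectra with tissue masks
#'
#' Container for 2D MRSI data: one complex spectrum (or FID) per voxel of an
#' (ny, nx) grid plus disjoint brain and scalp masks. Voxels are stored in
#' row-major order (voxel (iy, ix) maps to column (iy-1)*nx + ix, 0-based
#' indexing in the user-facing CLI).
#'
#' @param data complex matrix, n_points x n_voxels, row-major voxel order
#' @param axis a [spectral_axis()]
#' @param shape integer length-2 grid shape (ny, nx)
#' @param domain `"time"` or `"freq"`, the domain of `data`
#' @param brain_mask,scalp_mask logical (ny x nx) matrices; must be disjoint
#' @return object of class `mrsi_volume`
#' @export
mrsi_volume <- function(data, axis, shape, domain = c("freq", "time"),
                        brain_mask = NULL, scalp_mask = NULL) {
  domain <- match.arg(domain)
  shape <- as.integer(shape)
  if (length(shape) != 2L) stop("shape must be (ny, nx)")
  nv <- prod(shape)
  if (ncol(data) != nv)
    stop(sprintf("data has %d columns; grid %dx%d needs %d",
                 ncol(data), shape[1], shape[2], nv))
  if (nrow(data) != axis$n_points)
    stop("data rows do not match axis n_points")
  if (is.null(brain_mask)) brain_mask <- matrix(FALSE, shape[1], shape[2])
  if (is.null(scalp_mask)) scalp_mask <- matrix(FALSE, shape[1], shape[2])
  if (any(brain_mask & scalp_mask))
    stop("brain and scalp masks must be disjoint")
  structure(list(data = data, axis = axis, shape = shape, domain = domain,
                 brain_mask = brain_mask, scalp_mask = scalp_mask),
            class = "mrsi_volume")
}

#' @export
print.mrsi_volume <- function(x, ...) {
  cat(sprintf("<mrsi_volume> %dx%d grid, %d-point %s-domain spectra, %d brain / %d scalp voxels\n",
              x$shape[1], x$shape[2], x$axis$n_points, x$domain,
              sum(x$brain_mask), sum(x$scalp_mask)))
  invisible(x)
}

# Row-major linear indices (into the volume's columns) of TRUE mask voxels.
rowmajor_indices <- function(mask) which(t(mask))

#' All voxel spectra of a volume in a given domain
#' @param volume an [mrsi_volume()]
#' @param domain `"freq"` or `"time"`
#' @return complex matrix n_points x n_voxels
#' @export
volume_spectra <- function(volume, domain = c("freq", "time")) {
  domain <- match.arg(domain)
  if (volume$domain == domain) return(volume$data)
  if (domain == "freq") fid_to_spec_mat(volume$data)
  else spec_to_fid_mat(volume$data)
}

#' Extract one voxel's spectrum from a volume
#' @param volume an [mrsi_volume()]
#' @param iy,ix 1-based grid coordinates
#' @return an [mrs_spectrum()] in the volume's domain
#' @export
voxel_spectrum <- function(volume, iy, ix) {
  nx <- volume$shape[2]
  col <- (iy - 1L) * nx + ix
  mrs_spectrum(volume$data[, col], volume$axis, volume$domain)
}

# Replace the data matrix, preserving masks and axis.
with_volume_data <- function(volume, data, domain = volume$domain) {
  mrsi_volume(data, volume$axis, volume$shape, domain,
              volume$brain_mask, volume$scalp_mask)
}
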