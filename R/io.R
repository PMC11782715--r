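#' Write / read the MRSI container
#'
#' Self-describing single-file container for the package's objects
#' ([mrsi_volume()], [assemble_training_set()] datasets, [build_basis()]
#' bases, [lipid_subspace()] operators). The payload holds the axis
#' parameters, the complex data with its domain flag, any masks, and a
#' provenance record (seed, configuration hash, package version, creation
#' time); a human-readable JSON sidecar `<path>.json` duplicates the
#' provenance. Round trips are lossless.
#'
#' @param obj the object to store
#' @param path file path (conventionally `.mrsi`)
#' @param provenance optional named list merged into the provenance record
#' @return `path` invisibly
#' @export
write_container <- function(obj, path, provenance = list()) {
  kind <- if (inherits(obj, "mrsi_volume")) "volume"
  else if (inherits(obj, "mrsi_dataset")) "dataset"
  else if (inherits(obj, "metabolite_basis")) "basis"
  else if (inherits(obj, "lipid_subspace")) "subspace"
  else stop("unsupported object type for the container")
  prov <- utils::modifyList(list(
    package = "mrsiclean",
    version = as.character(utils::packageVersion("mrsiclean")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    kind = kind,
    config_hash = config_hash(provenance)), provenance)
  payload <- list(format = "mrsiclean-container", format_version = 1L,
                  kind = kind, object = obj, provenance = prov)
  saveRDS(payload, path)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("container not found: %s", path))
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("malformed container: unreadable payload"))
  for (grp in c("format", "kind", "object", "provenance")) {
    if (is.null(payload[[grp]]))
      stop(sprintf("malformed container: missing group '%s'", grp))
  }
  if (!identical(payload$format, "mrsiclean-container"))
    stop("malformed container: wrong format tag")
  obj <- payload$object
  if (payload$kind %in% c("volume", "basis") && is.null(obj$axis))
    stop("malformed container: missing /axis")
  attr(obj, "provenance") <- payload$provenance
  obj
}

#' Hash of a canonical configuration serialization
#'
#' Any change to any configuration field changes the hash; used to stamp
#' generated artifacts so they can be traced to the exact settings that
#' produced them.
#'
#' @param config a named list (nested lists allowed)
#' @return hex md5 string
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  canonical <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                force = TRUE)
  writeLines(canonical, tf)
  unname(tools::md5sum(tf))
}

#' Export / import a volume in NIfTI-MRS style
#'
#' Writes the complex time-domain data as a NIfTI image with dimensions
#' (nx, ny, 1, n_points, 2) -- the last dimension separating real and
#' imaginary parts -- with the spectral dwell time (1/bandwidth) in the
#' 4th pixdim slot, plus a JSON sidecar carrying SpectrometerFrequency,
#' ResonantNucleus, the carrier position, and the grid shape. Masks are
#' written alongside when present.
#'
#' @param volume an [mrsi_volume()]
#' @param path output `.nii.gz` path
#' @return `path` invisibly
#' @export
export_nifti_mrs <- function(volume, path) {
  stopifnot(inherits(volume, "mrsi_volume"))
  fids <- volume_spectra(volume, "time")
  ny <- volume$shape[1]; nx <- volume$shape[2]; np <- volume$axis$n_points
  arr <- array(0, c(nx, ny, 1, np, 2))
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    col <- (iy - 1L) * nx + ix
    arr[ix, iy, 1, , 1] <- Re(fids[, col])
    arr[ix, iy, 1, , 2] <- Im(fids[, col])
  }
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, volume$axis$dwell_s, 1))
  RNifti::writeNifti(img, path)
  meta <- list(SpectrometerFrequency = volume$axis$field_mhz,
               ResonantNucleus = "1H",
               dwell_time_s = volume$axis$dwell_s,
               bandwidth_hz = volume$axis$bandwidth_hz,
               carrier_ppm = volume$axis$carrier_ppm,
               n_points = volume$axis$n_points,
               grid = list(ny = ny, nx = nx))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (any(volume$brain_mask))
    RNifti::writeNifti(RNifti::asNifti(array(
      as.numeric(t(volume$brain_mask)), c(nx, ny, 1))),
      sub("\\.nii(\\.gz)?$", "_brainmask.nii\\1", path))
  if (any(volume$scalp_mask))
    RNifti::writeNifti(RNifti::asNifti(array(
      as.numeric(t(volume$scalp_mask)), c(nx, ny, 1))),
      sub("\\.nii(\\.gz)?$", "_scalpmask.nii\\1", path))
  invisible(path)
}

#' @rdname export_nifti_mrs
#' @export
import_nifti_mrs <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("non-conforming file: missing JSON sidecar")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("SpectrometerFrequency", "dwell_time_s", "carrier_ppm",
            "n_points", "grid")
  if (!all(need %in% names(meta)))
    stop("non-conforming sidecar: missing required fields")
  arr <- RNifti::readNifti(path)
  dm <- dim(arr)
  if (length(dm) != 5 || dm[5] != 2)
    stop("non-conforming file: expected (nx, ny, 1, n_points, 2) layout")
  nx <- dm[1]; ny <- dm[2]; np <- dm[4]
  axis <- spectral_axis(np, 1 / meta$dwell_time_s, meta$carrier_ppm,
                        meta$SpectrometerFrequency)
  fids <- matrix(0 + 0i, np, ny * nx)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    col <- (iy - 1L) * nx + ix
    fids[, col] <- complex(real = arr[ix, iy, 1, , 1],
                           imaginary = arr[ix, iy, 1, , 2])
  }
  bm_path <- sub("\\.nii(\\.gz)?$", "_brainmask.nii\\1", path)
  sm_path <- sub("\\.nii(\\.gz)?$", "_scalpmask.nii\\1", path)
  read_mask <- function(p) {
    if (!file.exists(p)) return(NULL)
    m <- as.array(RNifti::readNifti(p))
    if (length(dim(m)) > 2) m <- m[, , 1]
    t(matrix(as.logical(m > 0.5), nx, ny))
  }
  mrsi_volume(fids, axis, c(ny, nx), "time",
              brain_mask = read_mask(bm_path),
              scalp_mask = read_mask(sm_path))
}

#' Resample a spectrum onto a different spectral axis
#'
#' Frequency-domain linear interpolation of real and imaginary parts onto
#' the target ppm grid; ppm positions of spectral features are preserved
#' across acquisitions with different bandwidths and point counts (e.g. a
#' network trained on a 453-point/2326 Hz axis applied to 512-point/4 kHz
#' data). Target bins outside the source coverage are set to zero.
#'
#' @param x frequency-domain [mrs_spectrum()]
#' @param target_axis a [spectral_axis()]
#' @return an [mrs_spectrum()] on `target_axis`
#' @export
resample_to_grid <- function(x, target_axis) {
  stopifnot(inherits(x, "mrs_spectrum"), inherits(target_axis, "spectral_axis"))
  xf <- to_freq(x)
  src <- xf$axis
  if (axes_equal(src, target_axis)) return(xf)
  lo <- max(min(src$ppm), min(target_axis$ppm))
  hi <- min(max(src$ppm), max(target_axis$ppm))
  if (lo >= hi) stop("no ppm overlap between the source and target axes")
  if (lo > 0 || hi < 9)
    warning(sprintf("ppm overlap [%.2f, %.2f] does not cover 9.0-0.0 ppm",
                    lo, hi))
  sp <- rev(src$ppm)                     # ascending for approx()
  re <- stats::approx(sp, rev(Re(xf$data)), xout = target_axis$ppm,
                      rule = 1)$y
  im <- stats::approx(sp, rev(Im(xf$data)), xout = target_axis$ppm,
                      rule = 1)$y
  re[is.na(re)] <- 0; im[is.na(im)] <- 0
  mrs_spectrum(complex(real = re, imaginary = im), target_axis, "freq")
}
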