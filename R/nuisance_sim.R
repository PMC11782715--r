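#' Default spectral components of the scalp-lipid model
#'
#' Lipid resonance centres with per-component linewidth and relative-amplitude
#' ranges. Centres follow standard scalp-lipid literature values; the
#' dominant methylene peak sits at 1.3 ppm, with olefinic/allylic components
#' up to 5.3 ppm. Linewidths are kept well above typical metabolite
#' linewidths, reflecting the poor B0 homogeneity of the scalp.
#'
#' @return data.frame with columns center_ppm, lw_lo_hz, lw_hi_hz, amp_lo,
#'   amp_hi
#' @export
default_lipid_components <- function() {
  data.frame(
    center_ppm = c(0.90, 1.30, 1.60, 2.00, 2.25, 2.80, 4.40, 5.10, 5.30),
    lw_lo_hz   = rep(25, 9),
    lw_hi_hz   = rep(120, 9),
    amp_lo     = c(0.30, 0.60, 0.10, 0.15, 0.10, 0.05, 0.05, 0.10, 0.05),
    amp_hi     = c(0.70, 1.00, 0.35, 0.45, 0.30, 0.20, 0.25, 0.30, 0.25))
}

#' Parameters of the lipid/water nuisance generator
#'
#' Scales are expressed in orders of magnitude relative to `metab_ref`, the
#' peak magnitude of a typical unit metabolite spectrum: lipids are drawn 1-2
#' orders above it. Raw water artifacts are 3-4 orders above the metabolites,
#' but MRSI is acquired with WET water suppression, so the residual water the
#' pipeline actually sees is 1-2 orders weaker; the default draws it 1.5-2.5
#' orders above the metabolite reference.
#'
#' @param lipid_components data.frame as [default_lipid_components()]
#' @param water_center residual-water chemical shift (ppm)
#' @param water_components number of superimposed water sub-components of
#'   differing width/phase (asymmetric composite lineshape)
#' @param lipid_scale_orders length-2 interval of log10 total lipid amplitude
#'   relative to `metab_ref`
#' @param water_scale_orders same for water
#' @param sideband_spec optional list(harmonics_hz =, amp_frac =) adding
#'   symmetric sidebands around the water resonance; NULL disables them
#' @param metab_ref reference metabolite peak magnitude (see
#'   [metab_reference()])
#' @param seed integer seed for subject-level draws
#' @return object of class `nuisance_params`
#' @export
nuisance_params <- function(lipid_components = default_lipid_components(),
                            water_center = 4.68, water_components = 3L,
                            lipid_scale_orders = c(1, 2),
                            water_scale_orders = c(1.5, 2.5),
                            sideband_spec = NULL,
                            metab_ref = 1, seed = 1L) {
  lc <- lipid_components
  need <- c("center_ppm", "lw_lo_hz", "lw_hi_hz", "amp_lo", "amp_hi")
  if (!all(need %in% names(lc))) stop("lipid_components is missing columns")
  if (any(lc$center_ppm < 0 | lc$center_ppm > 6))
    stop("lipid centers must lie in [0, 6] ppm")
  if (any(lc$lw_lo_hz < 15))
    stop("lipid linewidths must exceed typical metabolite linewidths (>= 15 Hz)")
  if (any(lc$amp_lo < 0) || any(lc$amp_hi < lc$amp_lo))
    stop("invalid amplitude ranges")
  if (water_center < 0 || water_center > 6)
    stop("water_center must lie in [0, 6] ppm")
  if (metab_ref <= 0) stop("metab_ref must be positive")
  structure(list(lipid_components = lc,
                 water_center = water_center,
                 water_components = as.integer(water_components),
                 lipid_scale_orders = as.numeric(lipid_scale_orders),
                 water_scale_orders = as.numeric(water_scale_orders),
                 sideband_spec = sideband_spec,
                 metab_ref = as.numeric(metab_ref),
                 seed = as.integer(seed)),
            class = "nuisance_params")
}

# Frequency-domain spectrum of a damped complex exponential (Lorentzian of
# FWHM gamma Hz at f0): components are built in the time domain so every
# nuisance signal is an exact sum of damped sinusoids, as physical FIDs are.
lorentz_line_spec <- function(axis, f0, gamma, amp = 1, phase = 0) {
  t <- axis_times(axis)
  fid <- amp * exp(1i * phase) * exp((2i * pi * f0 - pi * gamma) * t)
  fid_to_spec(fid)
}

#' Sample one scalp-lipid spectrum
#'
#' Sum of broad resonances at the configured lipid centres with random
#' per-component amplitude, linewidth, phase jitter around a common global
#' phase, and small frequency jitter. The composite is normalized to unit
#' peak magnitude and scaled by 10^U(lipid_scale_orders) * metab_ref. The
#' drawn overall scale is attached as attribute `"scale"`.
#'
#' @param params a [nuisance_params()]
#' @param axis a [spectral_axis()]
#' @param seed integer seed; identical seed gives identical output
#' @return frequency-domain [mrs_spectrum()]
#' @export
sample_lipid_spectrum <- function(params, axis, seed = params$seed) {
  stopifnot(inherits(params, "nuisance_params"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  lc <- params$lipid_components
  phase0 <- stats::runif(1, 0, 2 * pi)
  spec <- complex(length.out = axis$n_points)
  for (k in seq_len(nrow(lc))) {
    amp <- stats::runif(1, lc$amp_lo[k], lc$amp_hi[k])
    lw <- stats::runif(1, lc$lw_lo_hz[k], lc$lw_hi_hz[k])
    ph <- phase0 + stats::rnorm(1, 0, 0.4)
    jit <- stats::runif(1, -0.05, 0.05)                       # ppm
    f0 <- (lc$center_ppm[k] + jit - axis$carrier_ppm) * axis$field_mhz
    spec <- spec + lorentz_line_spec(axis, f0, lw, amp, ph)
  }
  scale <- 10^stats::runif(1, params$lipid_scale_orders[1],
                           params$lipid_scale_orders[2]) * params$metab_ref
  peak <- max(Mod(spec))
  if (peak > 0) spec <- spec * (scale / peak) else scale <- 0
  out <- mrs_spectrum(spec, axis, "freq")
  attr(out, "scale") <- scale
  out
}

#' Sample one residual-water spectrum
#'
#' Residual water after suppression pulses: a superposition of components of
#' very different widths near the water resonance, with independent phases
#' and centre offsets, producing the characteristic asymmetric lineshape with
#' heavy tails. Optional symmetric sidebands at configured harmonic offsets.
#' Normalized to unit peak magnitude then scaled by
#' 10^U(water_scale_orders) * metab_ref; drawn scale attached as `"scale"`.
#'
#' @inheritParams sample_lipid_spectrum
#' @return frequency-domain [mrs_spectrum()]
#' @export
sample_water_spectrum <- function(params, axis, seed = params$seed) {
  stopifnot(inherits(params, "nuisance_params"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  nc <- max(1L, params$water_components)
  widths <- c(8, 45, 130, 260)[((seq_len(nc) - 1L) %% 4L) + 1L]
  base_amp <- c(1, 0.35, 0.15, 0.08)[((seq_len(nc) - 1L) %% 4L) + 1L]
  phase0 <- stats::runif(1, 0, 2 * pi)
  spec <- complex(length.out = axis$n_points)
  for (k in seq_len(nc)) {
    amp <- base_amp[k] * stats::runif(1, 0.6, 1.4)
    lw <- widths[k] * stats::runif(1, 0.7, 1.4)
    # narrow core stays centred; broad components are offset, which skews
    # the composite lineshape (tails larger than the centre on one side)
    off <- if (k == 1L) stats::rnorm(1, 0, 0.005) else stats::runif(1, -0.04, 0.10)
    ph <- phase0 + if (k == 1L) 0 else stats::rnorm(1, 0, 0.5)
    f0 <- (params$water_center + off - axis$carrier_ppm) * axis$field_mhz
    spec <- spec + lorentz_line_spec(axis, f0, lw, amp, ph)
  }
  if (!is.null(params$sideband_spec)) {
    sb <- params$sideband_spec
    f0 <- (params$water_center - axis$carrier_ppm) * axis$field_mhz
    for (h in sb$harmonics_hz) {
      spec <- spec + lorentz_line_spec(axis, f0 + h, 12, sb$amp_frac, phase0) +
        lorentz_line_spec(axis, f0 - h, 12, sb$amp_frac, phase0)
    }
  }
  scale <- if (all(is.finite(params$water_scale_orders)))
    10^stats::runif(1, params$water_scale_orders[1],
                    params$water_scale_orders[2]) * params$metab_ref
  else 0  # -Inf orders encode "water off"
  if (!is.finite(scale) || scale < 0) scale <- 0
  peak <- max(Mod(spec))
  if (peak > 0 && scale > 0) spec <- spec * (scale / peak) else {
    spec[] <- 0 + 0i; scale <- 0
  }
  out <- mrs_spectrum(spec, axis, "freq")
  attr(out, "scale") <- scale
  out
}

#' Reference metabolite peak magnitude for nuisance scaling
#'
#' Peak magnitude of the basis combined at typical relative concentrations
#' (half of [default_concentration_ratios()]) with 12 Hz broadening; the unit
#' that "1-2 orders of magnitude stronger" is measured against.
#'
#' @param basis a [build_basis()] result
#' @param ratios named concentration ratios
#' @return positive scalar
#' @export
metab_reference <- function(basis, ratios = default_concentration_ratios(basis$names)) {
  p <- metabolite_sample_params(concentrations = 0.5 * ratios,
                                linewidth_hz = 12, seed = 1L)
  max(Mod(sample_metabolite_spectrum(basis, p)$data))
}

#' Physiological relative concentration ratios
#'
#' Relative to NAA = 1; metabolites absent from the table default to 0.2.
#'
#' @param names metabolite names to return ratios for
#' @return named numeric vector
#' @export
default_concentration_ratios <- function(names = NULL) {
  tab <- c(NAA = 1.0, NAAG = 0.15, Cr = 0.7, Cho = 0.25, Glu = 0.8,
           Gln = 0.35, Ins = 0.55, Lac = 0.1, GABA = 0.15, Tau = 0.15,
           Gly = 0.1, Asp = 0.2)
  if (is.null(names)) return(tab)
  out <- tab[names]
  out[is.na(out)] <- 0.2
  names(out) <- names
  out
}
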