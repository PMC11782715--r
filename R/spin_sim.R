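#' Define a coupled proton spin system
#'
#' A metabolite is described by its proton groups: chemical shift, number of
#' magnetically equivalent protons per group, and the scalar J-coupling matrix
#' between groups. Equivalent protons within one group share a shift and are
#' mutually uncoupled (intra-group couplings between equivalent spins do not
#' affect the spectrum).
#'
#' @param name metabolite identifier
#' @param shifts numeric vector of group chemical shifts (ppm, in [0, 10])
#' @param couplings symmetric numeric matrix of J-couplings between groups in
#'   Hz (zero diagonal); scalar 0 allowed for uncoupled systems
#' @param multiplicities integer vector, protons per group (>= 1); defaults to
#'   one proton per group
#' @param t2 mono-exponential decay constant in seconds
#' @return an object of class `spin_system`
#' @export
spin_system <- function(name, shifts, couplings = NULL,
                        multiplicities = rep(1L, length(shifts)), t2 = 0.15) {
  shifts <- as.numeric(shifts)
  ng <- length(shifts)
  if (ng < 1L) stop("at least one proton group is required")
  if (any(shifts < 0 | shifts > 10))
    stop("shifts must lie within [0, 10] ppm")
  multiplicities <- as.integer(multiplicities)
  if (length(multiplicities) != ng || any(multiplicities < 1L))
    stop("multiplicities must be >= 1, one per group")
  if (is.null(couplings)) couplings <- matrix(0, ng, ng)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(ng, ng)))
    stop("couplings must be a square matrix over the groups")
  if (max(abs(couplings - t(couplings))) > 1e-9)
    stop("couplings must be symmetric")
  if (any(abs(diag(couplings)) > 1e-12))
    stop("couplings must have zero diagonal")
  if (!is.numeric(t2) || t2 <= 0) stop("t2 must be positive")
  structure(list(name = as.character(name), shifts = shifts,
                 couplings = couplings, multiplicities = multiplicities,
                 t2 = as.numeric(t2)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s: %d group(s), %d proton(s), t2 = %.3g s\n",
              x$name, length(x$shifts), sum(x$multiplicities), x$t2))
  invisible(x)
}

#' Load a spin-system catalog from tab-separated files
#'
#' Reads the bundled (or a user-supplied) plain-text catalog: one file with
#' per-group shifts/multiplicities and one with the inter-group J-couplings.
#'
#' @param systems_file path to the group table (metabolite, group, shift_ppm,
#'   n_protons, t2_s); defaults to the bundled catalog
#' @param couplings_file path to the coupling table (metabolite, group_a,
#'   group_b, j_hz)
#' @return named list of [spin_system()] objects
#' @export
load_spin_catalog <- function(
    systems_file = system.file("extdata", "spin_systems.tsv", package = "mrsiclean"),
    couplings_file = system.file("extdata", "j_couplings.tsv", package = "mrsiclean")) {
  gr <- utils::read.delim(systems_file, comment.char = "#",
                          stringsAsFactors = FALSE)
  jc <- utils::read.delim(couplings_file, comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- list()
  for (met in unique(gr$metabolite)) {
    g <- gr[gr$metabolite == met, , drop = FALSE]
    g <- g[order(g$group), , drop = FALSE]
    ng <- nrow(g)
    J <- matrix(0, ng, ng)
    jj <- jc[jc$metabolite == met, , drop = FALSE]
    if (nrow(jj) > 0) {
      for (r in seq_len(nrow(jj))) {
        a <- jj$group_a[r]; b <- jj$group_b[r]
        J[a, b] <- J[b, a] <- jj$j_hz[r]
      }
    }
    out[[met]] <- spin_system(met, g$shift_ppm, J, g$n_protons,
                              t2 = g$t2_s[1])
  }
  out
}

# Expand proton groups into individual spins and split into connected
# components of the coupling graph; each component is simulated independently
# (couplings between components are zero by construction).
expand_components <- function(system) {
  ng <- length(system$shifts)
  group_of <- rep(seq_len(ng), system$multiplicities)
  n <- length(group_of)
  shifts <- system$shifts[group_of]
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gi <- group_of[i]; gj <- group_of[j]
    if (gi != gj) J[i, j] <- system$couplings[gi, gj]
  }
  # union of singletons and coupled clusters via BFS
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(J[v, ] != 0 & is.na(comp)))
    }
  }
  lapply(seq_len(cur), function(k) {
    idx <- which(comp == k)
    list(shifts = shifts[idx], J = J[idx, idx, drop = FALSE])
  })
}

# Pauli-style spin-1/2 operators on an n-spin product space for spin `pos`.
single_spin_ops <- function(n, pos) {
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  sz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  id <- diag(2)
  build <- function(op) {
    m <- 1
    for (k in seq_len(n)) m <- kronecker(m, if (k == pos) op else id)
    m
  }
  list(x = build(sx), y = build(sy), z = build(sz))
}

# FID of one coupled component: eigendecomposition of the isotropic chemical
# shift + J-coupling Hamiltonian in the rotating frame of the carrier;
# transition amplitudes |<r|I+|s>|^2 normalised so one spin contributes unit
# amplitude.
component_fid <- function(shifts, J, axis, spin_cap = 8L) {
  n <- length(shifts)
  if (n > spin_cap)
    stop(sprintf(paste0("coupled component has %d spins, exceeding the cap of %d; ",
                        "decompose the system into smaller subgroups"),
                 n, spin_cap))
  t <- axis_times(axis)
  omega <- 2 * pi * (shifts - axis$carrier_ppm) * axis$field_mhz  # rad/s
  if (n == 1L) {
    return(exp(1i * omega[1] * t))
  }
  ops <- lapply(seq_len(n), function(p) single_spin_ops(n, p))
  dim2 <- 2^n
  H <- matrix(0 + 0i, dim2, dim2)
  for (i in seq_len(n)) H <- H + omega[i] * ops[[i]]$z
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (J[i, j] != 0) {
      H <- H + 2 * pi * J[i, j] *
        (ops[[i]]$x %*% ops[[j]]$x + ops[[i]]$y %*% ops[[j]]$y +
           ops[[i]]$z %*% ops[[j]]$z)
    }
  }
  eig <- eigen(Re(H), symmetric = TRUE)   # H is real symmetric in this basis
  V <- eig$vectors; E <- eig$values
  Ip <- matrix(0 + 0i, dim2, dim2)
  for (i in seq_len(n)) Ip <- Ip + ops[[i]]$x + 1i * ops[[i]]$y
  A <- t(V) %*% Ip %*% V                  # V real => plain transpose
  amp <- Mod(A)^2 / 2^(n - 1)
  keep <- which(amp > 1e-9 * max(amp), arr.ind = TRUE)
  freqs <- E[keep[, 1]] - E[keep[, 2]]
  amps <- amp[keep]
  # sum of damped complex exponentials over retained transitions
  as.vector(exp(1i * outer(t, freqs)) %*% amps)
}

#' Simulate the unit-concentration FID of a spin system
#'
#' Exact treatment of strong coupling: the isotropic Hamiltonian
#' H = sum_i w_i I_iz + sum_{i<j} 2 pi J_ij I_i . I_j is diagonalised on the
#' full product space of each coupled component (equivalent protons expanded),
#' observable transition amplitudes are taken from the raising operator, and
#' the FID is the amplitude-weighted sum of complex exponentials damped by
#' exp(-t/t2). One uncoupled proton yields unit amplitude, so peak integrals
#' scale with proton count.
#'
#' @param system a [spin_system()]
#' @param axis a [spectral_axis()]
#' @param spin_cap maximum spins per coupled component (default 8); larger
#'   components raise an error asking for subgroup decomposition
#' @return time-domain [mrs_spectrum()]
#' @export
simulate_metabolite_fid <- function(system, axis, spin_cap = 8L) {
  stopifnot(inherits(system, "spin_system"), inherits(axis, "spectral_axis"))
  comps <- expand_components(system)
  t <- axis_times(axis)
  fid <- complex(length.out = axis$n_points)
  # identical singleton components (equivalent uncoupled protons) are
  # simulated once and weighted by their count
  keys <- vapply(comps, function(cc)
    paste(signif(cc$shifts, 12), collapse = ","), character(1))
  for (key in unique(keys)) {
    members <- comps[keys == key]
    fid <- fid + length(members) *
      component_fid(members[[1]]$shifts, members[[1]]$J, axis, spin_cap)
  }
  fid <- fid * exp(-t / system$t2)
  mrs_spectrum(fid, axis, "time")
}

#' Build a metabolite basis set
#'
#' Simulates every system on a shared axis at unit concentration.
#'
#' @param systems named or unnamed list of [spin_system()] objects with unique
#'   names
#' @param axis a [spectral_axis()]
#' @return object of class `metabolite_basis` with fields `axis`, `names`, and
#'   `fids` (complex matrix, one time-domain FID per column)
#' @export
build_basis <- function(systems, axis) {
  if (length(systems) == 0) stop("systems list must be nonempty")
  nms <- vapply(systems, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate metabolite names in basis")
  fids <- vapply(systems, function(s) simulate_metabolite_fid(s, axis)$data,
                 complex(axis$n_points))
  fids <- matrix(fids, nrow = axis$n_points,
                 dimnames = list(NULL, nms))
  if (!all(is.finite(Re(fids))) || !all(is.finite(Im(fids))))
    stop("non-finite values in simulated basis")
  structure(list(axis = axis, names = nms, fids = fids,
                 t2 = vapply(systems, function(s) s$t2, numeric(1))),
            class = "metabolite_basis")
}

#' @export
print.metabolite_basis <- function(x, ...) {
  cat(sprintf("<metabolite_basis> %d metabolites on %d-point axis: %s\n",
              length(x$names), x$axis$n_points,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Parameters of one randomized metabolite spectrum
#'
#' @param concentrations named nonnegative vector; names must exist in the
#'   basis the parameters are applied to
#' @param linewidth_hz extra Lorentzian broadening (FWHM, Hz) applied on top of
#'   the simulated t2 decay
#' @param baseline_coeffs numeric vector of amplitudes for the broad smooth
#'   baseline bumps (empty = no baseline)
#' @param noise_sigma per-point standard deviation of circular complex
#'   Gaussian noise added in the frequency domain
#' @param seed integer seed making the draw reproducible
#' @param gauss_frac fraction of the extra broadening applied as Gaussian
#'   rather than Lorentzian decay (Voigt-like lineshape); 0 = pure Lorentzian
#' @return object of class `metabolite_sample_params`
#' @export
metabolite_sample_params <- function(concentrations, linewidth_hz = 0,
                                     baseline_coeffs = numeric(0),
                                     noise_sigma = 0, seed = 1L,
                                     gauss_frac = 0) {
  if (linewidth_hz < 0) stop("linewidth_hz must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(concentrations) && is.null(names(concentrations)))
    stop("concentrations must be a named vector")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (gauss_frac < 0 || gauss_frac > 1) stop("gauss_frac must be in [0, 1]")
  structure(list(concentrations = concentrations,
                 linewidth_hz = as.numeric(linewidth_hz),
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed),
                 gauss_frac = as.numeric(gauss_frac)),
            class = "metabolite_sample_params")
}

# Smooth baseline: very broad (> 100 Hz) Gaussian bumps whose centres/widths
# are derived deterministically from the bump index, scaled by the
# caller-supplied coefficients.
baseline_profile <- function(axis, coeffs) {
  if (!length(coeffs)) return(complex(length.out = axis$n_points))
  f <- axis$freq_hz
  nb <- length(coeffs)
  centers <- seq(min(f) * 0.8, max(f) * 0.8, length.out = nb)
  widths <- 150 + 80 * (seq_len(nb) %% 3)         # 150-310 Hz, all > 100 Hz
  out <- numeric(axis$n_points)
  for (b in seq_len(nb))
    out <- out + coeffs[b] * exp(-(f - centers[b])^2 / (2 * widths[b]^2))
  as.complex(out)
}

#' Sample a randomized metabolite spectrum from a basis
#'
#' Forms the concentration-weighted basis combination, applies Voigt-like
#' broadening of the requested linewidth in the time domain, transforms to the
#' frequency domain, and adds a smooth baseline plus circular complex Gaussian
#' noise. Identical seeds give identical output.
#'
#' @param basis a [build_basis()] result
#' @param params a [metabolite_sample_params()]
#' @return frequency-domain [mrs_spectrum()]
#' @export
sample_metabolite_spectrum <- function(basis, params) {
  stopifnot(inherits(basis, "metabolite_basis"),
            inherits(params, "metabolite_sample_params"))
  conc <- params$concentrations
  unknown <- setdiff(names(conc), basis$names)
  if (length(unknown))
    stop(sprintf("unknown metabolite name(s): %s",
                 paste(unknown, collapse = ", ")))
  axis <- basis$axis
  fid <- complex(length.out = axis$n_points)
  if (length(conc)) {
    cols <- match(names(conc), basis$names)
    fid <- as.vector(basis$fids[, cols, drop = FALSE] %*% as.complex(conc))
  }
  if (params$linewidth_hz > 0) {
    t <- axis_times(axis)
    gl <- params$linewidth_hz * params$gauss_frac
    ll <- params$linewidth_hz - gl
    decay <- exp(-pi * ll * t)
    if (gl > 0) decay <- decay * exp(-(pi * gl * t)^2 / (4 * log(2)))
    fid <- fid * decay
  }
  spec <- fid_to_spec(fid)
  spec <- spec + baseline_profile(axis, params$baseline_coeffs)
  if (params$noise_sigma > 0) {
    withr_seed <- params$seed
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(withr_seed)
    n <- axis$n_points
    spec <- spec + complex(real = stats::rnorm(n, 0, params$noise_sigma),
                           imaginary = stats::rnorm(n, 0, params$noise_sigma))
  }
  mrs_spectrum(spec, axis, "freq")
}

# Save/restore the global RNG stream so seeded helpers do not perturb callers.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
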