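#' Assemble a synthetic training set of nuisance-removal examples
#'
#' Generates `n` training triplets (x1, x2, y): x1 = m + l (+ w) is a
#' contaminated spectrum, x2 = (1 - L_op) x1 its lipid-subspace projection,
#' and the target y is the nuisance signal the network must identify (lipid +
#' water in `"walinet"` mode, lipid only in `"lipnet"` mode). Examples are
#' grouped into synthetic subjects: each subject has its own lipid basis
#' realization with a beta-calibrated projection operator (mirroring the
#' per-subject operator used in vivo) and its own nuisance statistics, so
#' train/validation splits can be made subject-wise.
#'
#' @param n number of examples (> 0)
#' @param basis a [build_basis()] result
#' @param mode `"walinet"` (lipid + water) or `"lipnet"` (lipid only)
#' @param params a [nuisance_params()]; its `metab_ref` is overridden by the
#'   basis-derived reference when `metab_ref_auto` is TRUE
#' @param n_subjects number of synthetic subjects to spread examples over
#' @param n_lipid_cols scalp spectra per subject lipid basis
#' @param beta_target setpoint for the operator diagonal calibration
#' @param seed master seed; the full dataset is reproducible from it
#' @param metab_ref_auto derive `metab_ref` from the basis (see
#'   [metab_reference()])
#' @return object of class `mrsi_dataset` with complex matrices `x1`, `x2`,
#'   `y`, `truth` (n_points x n), integer vector `subject`, and the
#'   per-subject `subspaces`
#' @export
assemble_training_set <- function(n, basis, mode = c("walinet", "lipnet"),
                                  params = NULL,
                                  n_subjects = max(2L, ceiling(n / 1000)),
                                  n_lipid_cols = 50L, beta_target = 0.938,
                                  seed = 1L, metab_ref_auto = TRUE) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  stopifnot(inherits(basis, "metabolite_basis"))
  axis <- basis$axis
  np <- axis$n_points
  if (is.null(params)) params <- nuisance_params(seed = seed)
  if (metab_ref_auto) params$metab_ref <- metab_reference(basis)
  ref <- params$metab_ref
  ratios <- default_concentration_ratios(basis$names)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n_subjects <- max(1L, min(as.integer(n_subjects), n))
  subj_seed <- sample.int(2^30, n_subjects)
  subject <- sort(rep_len(seq_len(n_subjects), n))

  subspaces <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    L <- vapply(seq_len(n_lipid_cols), function(k)
      sample_lipid_spectrum(params, axis, seed = subj_seed[j] + k)$data,
      complex(np))
    beta <- calibrate_beta(L, target = beta_target)
    subspaces[[j]] <- lipid_subspace(L, beta, axis)
  }

  x1 <- matrix(0 + 0i, np, n)
  y <- matrix(0 + 0i, np, n)
  truth <- matrix(0 + 0i, np, n)
  for (i in seq_len(n)) {
    j <- subject[i]
    conc <- stats::runif(length(ratios)) * ratios
    names(conc) <- basis$names
    nb <- sample(3:6, 1)
    mp <- metabolite_sample_params(
      concentrations = conc,
      linewidth_hz = stats::runif(1, 4, 20),
      baseline_coeffs = stats::rnorm(nb, 0, 0.15) * ref,
      noise_sigma = 10^stats::runif(1, -3, -1) * ref,
      seed = sample.int(2^30, 1),
      gauss_frac = stats::runif(1, 0, 0.5))
    m <- sample_metabolite_spectrum(basis, mp)$data
    l <- sample_lipid_spectrum(params, axis,
                               seed = subj_seed[j] + 10000L + i)$data
    w <- if (mode == "walinet")
      sample_water_spectrum(params, axis,
                            seed = subj_seed[j] + 20000L + i)$data
    else complex(length.out = np)
    x1[, i] <- m + l + w
    y[, i] <- if (mode == "walinet") l + w else l
    truth[, i] <- m
  }
  x2 <- matrix(0 + 0i, np, n)
  for (j in seq_len(n_subjects)) {
    cols <- which(subject == j)
    x2[, cols] <- lipid_project(x1[, cols, drop = FALSE], subspaces[[j]])
  }
  structure(list(axis = axis, mode = mode, x1 = x1, x2 = x2, y = y,
                 truth = truth, subject = subject, subspaces = subspaces,
                 params = params, seed = as.integer(seed)),
            class = "mrsi_dataset")
}

#' @export
print.mrsi_dataset <- function(x, ...) {
  cat(sprintf("<mrsi_dataset> %d examples (%s mode), %d subjects, %d-point axis\n",
              ncol(x$x1), x$mode, length(x$subspaces), x$axis$n_points))
  invisible(x)
}

#' Subject-wise train/validation split
#'
#' Assigns whole subjects to the validation partition so that no synthetic
#' subject contributes examples to both partitions.
#'
#' @param dataset an [assemble_training_set()] result
#' @param val_frac fraction of subjects held out for validation
#' @return list with integer index vectors `train` and `val`
#' @export
split_by_subject <- function(dataset, val_frac = 0.2) {
  stopifnot(inherits(dataset, "mrsi_dataset"))
  subs <- sort(unique(dataset$subject))
  nv <- if (val_frac <= 0) 0L else max(1L, floor(length(subs) * val_frac))
  if (nv >= length(subs)) nv <- length(subs) - 1L
  val_subs <- utils::tail(subs, nv)
  list(train = which(!dataset$subject %in% val_subs),
       val = which(dataset$subject %in% val_subs))
}

#' Select a subset of a dataset by example index
#' @param dataset an `mrsi_dataset`
#' @param idx integer indices
#' @return an `mrsi_dataset` restricted to `idx`
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  for (f in c("x1", "x2", "y", "truth"))
    out[[f]] <- dataset[[f]][, idx, drop = FALSE]
  out$subject <- dataset$subject[idx]
  out
}
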