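#' Lipid subspace operator
#'
#' Builds the lipid suppression operator L_op = (1 + beta * L L^H)^-1 from a
#' basis matrix `L` whose columns are frequency-domain scalp-voxel spectra.
#' The operator is kept in factored form via the thin SVD of `L`
#' (L = U diag(s) V^H), for which
#'   L_op     = I - U diag(beta s^2 / (1 + beta s^2)) U^H,
#'   1 - L_op =     U diag(beta s^2 / (1 + beta s^2)) U^H,
#' so applying either costs O(n_freq * rank) and the dense inverse is never
#' formed. Singular values below 1e-8 of the largest are truncated.
#'
#' @param L complex matrix, n_freq x n_lipid (one column per scalp voxel)
#' @param beta nonnegative regularization parameter
#' @param axis optional [spectral_axis()] the spectra live on
#' @return object of class `lipid_subspace`
#' @export
lipid_subspace <- function(L, beta, axis = NULL) {
  L <- as.matrix(L)
  if (!is.complex(L)) L <- matrix(as.complex(L), nrow(L), ncol(L))
  if (any(!is.finite(Re(L)) | !is.finite(Im(L)))) {
    bad <- which(apply(!is.finite(Re(L)) | !is.finite(Im(L)), 2, any))
    stop(sprintf("non-finite values in lipid basis column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (beta < 0) stop("beta must be nonnegative")
  sv <- svd(L, nu = min(dim(L)), nv = 0)
  keep <- sv$d > 1e-8 * max(sv$d, 0)
  structure(list(L = L, beta = as.numeric(beta),
                 U = sv$u[, keep, drop = FALSE], s = sv$d[keep],
                 axis = axis),
            class = "lipid_subspace")
}

#' @export
print.lipid_subspace <- function(x, ...) {
  cat(sprintf("<lipid_subspace> %d freq points, %d columns, rank %d, beta = %.4g\n",
              nrow(x$L), ncol(x$L), length(x$s), x$beta))
  cat(sprintf("  mean |diag| of operator = %.4f\n", mean_abs_diag(x)))
  invisible(x)
}

# shrinkage weights beta s^2 / (1 + beta s^2) for the current beta
subspace_weights <- function(sub, beta = sub$beta) {
  s2 <- sub$s^2
  beta * s2 / (1 + beta * s2)
}

#' Mean absolute diagonal of the lipid suppression operator
#'
#' diag(L_op)_i = 1 - sum_k w_k |U_ik|^2 with w_k the shrinkage weights;
#' computed from the factorization without densifying the operator.
#'
#' @param sub a [lipid_subspace()]
#' @param beta optionally evaluate at a different beta than stored
#' @return scalar in (0, 1]
#' @export
mean_abs_diag <- function(sub, beta = sub$beta) {
  w <- subspace_weights(sub, beta)
  d <- 1 - as.vector(Mod(sub$U)^2 %*% w)
  mean(abs(d))
}

#' Extract the lipid basis matrix from scalp voxels of a volume
#'
#' @param volume an [mrsi_volume()] (frequency or time domain; converted to
#'   frequency domain)
#' @param scalp_mask logical matrix of the volume's grid shape; defaults to
#'   the volume's own scalp mask
#' @return complex matrix with one frequency-domain spectrum per scalp voxel,
#'   columns in row-major voxel order
#' @export
extract_lipid_basis <- function(volume, scalp_mask = volume$scalp_mask) {
  stopifnot(inherits(volume, "mrsi_volume"))
  if (is.null(scalp_mask) || !any(scalp_mask))
    stop("scalp mask is empty; cannot extract a lipid basis")
  if (!all(dim(scalp_mask) == dim(volume$brain_mask)))
    stop("scalp mask shape does not match the volume grid")
  specs <- volume_spectra(volume, domain = "freq")
  idx <- rowmajor_indices(scalp_mask)    # voxels in row-major order
  L <- specs[, idx, drop = FALSE]
  bad <- which(apply(!is.finite(Re(L)) | !is.finite(Im(L)), 2, any))
  if (length(bad))
    stop(sprintf("NaN/Inf spectrum at scalp voxel index(es): %s",
                 paste(idx[bad], collapse = ", ")))
  L
}

#' Calibrate beta to a target mean absolute diagonal
#'
#' The mean absolute diagonal of (1 + beta L L^H)^-1 decreases monotonically
#' from 1 (beta = 0) towards its large-beta limit; bisection on log10(beta)
#' finds the beta attaining the requested setpoint (0.938 by default, the
#' standard trade-off between lipid suppression and metabolite preservation).
#'
#' @param L complex lipid basis matrix, or a [lipid_subspace()]
#' @param target requested mean absolute diagonal, in (reachable minimum, 1)
#' @param tol absolute tolerance on the achieved diagonal mean
#' @return calibrated beta (scalar)
#' @export
calibrate_beta <- function(L, target = 0.938, tol = 1e-3) {
  sub <- if (inherits(L, "lipid_subspace")) L else lipid_subspace(L, beta = 0)
  if (length(sub$s) == 0 || max(sub$s) == 0)
    stop("lipid basis is zero; the operator diagonal is identically 1")
  if (target <= 0 || target >= 1)
    stop("target must lie strictly between 0 and 1")
  f <- function(l10) mean_abs_diag(sub, beta = 10^l10)
  # the natural scale of beta is 1/s_max^2; bracket around it
  center <- -2 * log10(max(sub$s))
  lo <- center - 12; hi <- center + 12
  if (f(lo) < target)
    stop("target unreachable: diagonal already below target at tiny beta")
  if (f(hi) > target + tol)
    stop(sprintf("target %.4f unreachable: large-beta limit is %.4f",
                 target, f(hi)))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target) <= tol * 0.5) break
    if (v > target) lo <- mid else hi <- mid
  }
  10^mid
}

#' Project a spectrum onto the lipid subspace
#'
#' Returns (1 - L_op) x = U diag(w) U^H x, the lipid-subspace component of the
#' input. This is the second input of the dual-encoder network.
#'
#' @param x frequency-domain [mrs_spectrum()], complex vector, or complex
#'   matrix with one spectrum per column
#' @param sub a [lipid_subspace()]
#' @return same shape/class as `x`
#' @export
lipid_project <- function(x, sub) {
  apply_subspace(x, sub, mode = "project")
}

#' Conventional L2 lipid suppression
#'
#' Returns L_op x = x - (1 - L_op) x, the lipid-suppressed spectrum used as
#' the classical baseline method.
#'
#' @inheritParams lipid_project
#' @return same shape/class as `x`
#' @export
apply_l2_suppression <- function(x, sub) {
  apply_subspace(x, sub, mode = "suppress")
}

apply_subspace <- function(x, sub, mode) {
  stopifnot(inherits(sub, "lipid_subspace"))
  if (inherits(x, "mrs_spectrum")) {
    if (!is.null(sub$axis) && !axes_equal(x$axis, sub$axis))
      stop("spectrum axis does not match the lipid subspace axis")
    xf <- to_freq(x)
    out <- apply_subspace(xf$data, sub, mode)
    res <- mrs_spectrum(out, x$axis, "freq")
    return(if (x$domain == "time") to_time(res) else res)
  }
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(v) != nrow(sub$L))
    stop("input length does not match the lipid basis frequency grid")
  w <- subspace_weights(sub)
  proj <- sub$U %*% (w * (Conj(t(sub$U)) %*% v))
  out <- if (mode == "project") proj else v - proj
  if (is.matrix(x)) out else as.vector(out)
}

# Dense-oracle form, used in tests only: directly inverts (I + beta L L^H).
dense_lipid_operator <- function(L, beta) {
  L <- as.matrix(L)
  n <- nrow(L)
  solve(diag(n) + beta * L %*% Conj(t(L)))
}
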