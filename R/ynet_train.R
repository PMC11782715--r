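#' Energy normalization of an input pair
#'
#' The divisor E = ||x1 - x2||_2 (root-sum-squared difference of the two
#' network inputs) approximates the energy of the underlying metabolite
#' signal, because x1 - x2 = L_op x1 is the lipid-suppressed spectrum. Both
#' inputs are divided by max(E, eps); E is returned so predictions can be
#' de-normalized.
#'
#' @param x1,x2 complex vectors, or complex matrices with one spectrum per
#'   column (normalized per column)
#' @param eps floor preventing division by zero when x1 == x2
#' @return list with `x1`, `x2` (normalized) and `energy` (one value per
#'   spectrum)
#' @export
normalize_pair <- function(x1, x2, eps = 1e-12) {
  m1 <- if (is.matrix(x1)) x1 else matrix(x1, ncol = 1)
  m2 <- if (is.matrix(x2)) x2 else matrix(x2, ncol = 1)
  if (!all(dim(m1) == dim(m2))) stop("x1 and x2 must have the same shape")
  energy <- sqrt(colSums(Mod(m1 - m2)^2))
  div <- pmax(energy, eps)
  m1 <- sweep(m1, 2, div, "/")
  m2 <- sweep(m2, 2, div, "/")
  if (!is.matrix(x1)) { m1 <- as.vector(m1); m2 <- as.vector(m2) }
  list(x1 = m1, x2 = m2, energy = energy)
}

#' One training example
#'
#' @param x1 contaminated spectrum (complex vector)
#' @param x2 its lipid-subspace projection
#' @param y nuisance target (lipid + water, or lipid only)
#' @return object of class `training_example`
#' @export
training_example <- function(x1, x2, y) {
  stopifnot(length(x1) == length(x2), length(x1) == length(y))
  structure(list(x1 = as.complex(x1), x2 = as.complex(x2),
                 y = as.complex(y), omega = 0, energy = NA_real_),
            class = "training_example")
}

#' Random global phase augmentation
#'
#' Multiplies x1, x2 and the target by the same random phase factor
#' exp(i*omega) with omega ~ Uniform[0, 2*pi]; pointwise magnitudes are
#' unchanged. The drawn omega is stored on the example.
#'
#' @param example a [training_example()]
#' @param seed optional seed; NULL draws from the current RNG stream
#' @param omega force a specific phase (radians) instead of drawing one
#' @return the phase-rotated `training_example`
#' @export
augment_phase <- function(example, seed = NULL, omega = NULL) {
  stopifnot(inherits(example, "training_example"))
  if (is.null(omega)) {
    if (!is.null(seed)) {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
      set.seed(seed)
    }
    omega <- stats::runif(1, 0, 2 * pi)
  }
  ph <- exp(1i * omega)
  example$x1 <- example$x1 * ph
  example$x2 <- example$x2 * ph
  example$y <- example$y * ph
  example$omega <- omega
  example
}

# ---- tensor helpers --------------------------------------------------------

# next multiple of m
pad_length <- function(L, m) as.integer(ceiling(L / m) * m)

# complex matrix (np x B) -> real array (2, P, B), zero-padded along length
complex_to_tensor <- function(X, P = nrow(X)) {
  np <- nrow(X); B <- ncol(X)
  arr <- array(0, c(2, P, B))
  arr[1, seq_len(np), ] <- Re(X)
  arr[2, seq_len(np), ] <- Im(X)
  arr
}

# real array (2, P, B) -> complex matrix (np x B), crop pad
tensor_to_complex <- function(arr, np) {
  matrix(complex(real = arr[1, seq_len(np), , drop = TRUE],
                 imaginary = arr[2, seq_len(np), , drop = TRUE]),
         nrow = np)
}

# ---- training --------------------------------------------------------------

#' Train a Y-Net on a synthetic dataset
#'
#' Per minibatch: global-phase augmentation, energy normalization, forward
#' pass, MSE loss on the separated real/imaginary channels of the normalized
#' prediction and target, Adam update with the step-decayed learning rate.
#' Validation loss is computed on the held-out subjects (no dropout, no
#' augmentation). Fully reproducible from `config$seed`.
#'
#' @param net a [build_ynet()] result
#' @param dataset an [assemble_training_set()] result
#' @param config a [train_config()]
#' @param verbose print one line per epoch
#' @return list with `net` (trained), `history` (data.frame epoch/lr/
#'   train_loss/val_loss)
#' @export
train_ynet <- function(net, dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "ynet"), inherits(dataset, "mrsi_dataset"),
            inherits(config, "train_config"))
  if (ncol(dataset$x1) == 0) stop("dataset is empty")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  np <- dataset$axis$n_points
  cfg <- net$config
  P <- pad_length(np, cfg$pool_factor^cfg$depth)
  split <- split_by_subject(dataset, config$val_frac)
  tr_idx <- split$train; va_idx <- split$val
  B <- config$batch_size
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0))
  net$axis <- dataset$axis
  if (config$epochs == 0L) return(list(net = net, history = history))

  run_batch <- function(net, idx, train) {
    x1 <- dataset$x1[, idx, drop = FALSE]
    x2 <- dataset$x2[, idx, drop = FALSE]
    y <- dataset$y[, idx, drop = FALSE]
    if (train) {
      ph <- exp(1i * stats::runif(length(idx), 0, 2 * pi))
      x1 <- sweep(x1, 2, ph, "*")
      x2 <- sweep(x2, 2, ph, "*")
      y <- sweep(y, 2, ph, "*")
    }
    nrm <- normalize_pair(x1, x2, config$eps_norm)
    div <- pmax(nrm$energy, config$eps_norm)
    yn <- sweep(y, 2, div, "/")
    t1 <- complex_to_tensor(nrm$x1, P)
    t2 <- complex_to_tensor(nrm$x2, P)
    ty <- complex_to_tensor(yn, P)
    fw <- ynet_forward(net, t1, t2, training = train)
    sel <- seq_len(np)
    resid <- fw$out[, sel, , drop = FALSE] - ty[, sel, , drop = FALSE]
    loss <- mean(resid^2)
    if (!train) return(list(loss = loss))
    dOut <- array(0, dim(fw$out))
    dOut[, sel, ] <- 2 * resid / length(resid)
    grads <- ynet_backward(net, fw$caches, dOut)
    list(loss = loss, grads = grads)
  }

  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / B))
    tl <- 0
    for (bt in batches) {
      rb <- run_batch(net, bt, train = TRUE)
      if (!is.finite(rb$loss))
        stop(sprintf("non-finite training loss at epoch %d; lr too high or data degenerate",
                     epoch))
      grads <- clip_gradients(rb$grads, config$clip_norm)
      net <- adam_step(net, grads, lr, config$adam_beta1, config$adam_beta2)
      tl <- tl + rb$loss * length(bt)
    }
    tl <- tl / length(tr_idx)
    vl <- NA_real_
    if (length(va_idx)) {
      vbs <- split(va_idx, ceiling(seq_along(va_idx) / B))
      vl <- sum(vapply(vbs, function(bt) run_batch(net, bt, FALSE)$loss *
                         length(bt), numeric(1))) / length(va_idx)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = tl, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train %.4e  val %.4e",
                      epoch, lr, tl, vl))
  }
  list(net = net, history = history)
}

#' Predict and subtract the nuisance signal
#'
#' Computes x2 = (1 - L_op) x1, normalizes the pair, runs the network, and
#' de-normalizes the predicted nuisance spectrum y by the same per-spectrum
#' energy; the cleaned metabolite estimate is m = x1 - y.
#'
#' @param net a trained [build_ynet()] (with `axis` set by training)
#' @param x1 an [mrs_spectrum()], complex vector, or complex matrix of
#'   spectra (frequency domain, columns = spectra)
#' @param sub the subject's [lipid_subspace()]
#' @param resample allow resampling of inputs living on a different axis onto
#'   the network's training axis (and back)
#' @param eps_norm floor for the energy divisor
#' @return list with `y` (predicted nuisance) and `m` (x1 - y), same shape as
#'   the input
#' @export
infer_nuisance <- function(net, x1, sub, resample = TRUE, eps_norm = 1e-12) {
  stopifnot(inherits(net, "ynet"))
  if (inherits(x1, "mrs_spectrum")) {
    ax <- x1$axis
    if (!is.null(net$axis) && !axes_equal(ax, net$axis)) {
      if (!resample)
        stop("input axis differs from the network's training axis")
      xr <- resample_to_grid(to_freq(x1), net$axis)
      # the subject operator must live on the same grid as the spectra it
      # projects: resample its basis columns and recalibrate nothing (beta
      # is grid-independent to first order)
      Lr <- vapply(seq_len(ncol(sub$L)), function(j)
        resample_to_grid(mrs_spectrum(sub$L[, j], ax, "freq"),
                         net$axis)$data, complex(net$axis$n_points))
      sub_r <- lipid_subspace(Lr, sub$beta, net$axis)
      res <- infer_nuisance(net, xr, sub_r, resample = FALSE,
                            eps_norm = eps_norm)
      y <- resample_to_grid(res$y, ax)
      m <- mrs_spectrum(to_freq(x1)$data - y$data, ax, "freq")
      return(list(y = y, m = m))
    }
    xf <- to_freq(x1)
    r <- infer_nuisance(net, matrix(xf$data, ncol = 1), sub,
                        resample = FALSE, eps_norm = eps_norm)
    return(list(y = mrs_spectrum(as.vector(r$y), ax, "freq"),
                m = mrs_spectrum(as.vector(r$m), ax, "freq")))
  }
  X <- if (is.matrix(x1)) x1 else matrix(x1, ncol = 1)
  x2 <- lipid_project(X, sub)
  nrm <- normalize_pair(X, x2, eps_norm)
  div <- pmax(nrm$energy, eps_norm)
  np <- nrow(X)
  cfg <- net$config
  P <- pad_length(np, cfg$pool_factor^cfg$depth)
  # batch in manageable chunks
  nb <- ncol(X)
  y <- matrix(0 + 0i, np, nb)
  chunk <- 256L
  for (s in seq(1L, nb, by = chunk)) {
    cols <- s:min(nb, s + chunk - 1L)
    t1 <- complex_to_tensor(nrm$x1[, cols, drop = FALSE], P)
    t2 <- complex_to_tensor(nrm$x2[, cols, drop = FALSE], P)
    fw <- ynet_forward(net, t1, t2, training = FALSE)
    y[, cols] <- tensor_to_complex(fw$out, np)
  }
  y <- sweep(y, 2, div, "*")
  m <- X - y
  if (!is.matrix(x1)) { y <- as.vector(y); m <- as.vector(m) }
  list(y = y, m = m)
}

#' Apply a trained network to every voxel of a volume
#'
#' @param net trained [build_ynet()]
#' @param volume an [mrsi_volume()] (any domain)
#' @param sub the volume's [lipid_subspace()]
#' @param mask_only process only brain/scalp voxels
#' @return an [mrsi_volume()] of cleaned spectra in the volume's domain
#' @export
infer_volume <- function(net, volume, sub, mask_only = TRUE) {
  stopifnot(inherits(volume, "mrsi_volume"))
  specs <- volume_spectra(volume, "freq")
  any_mask <- any(volume$brain_mask) || any(volume$scalp_mask)
  act <- if (mask_only && any_mask)
    rowmajor_indices(volume$brain_mask | volume$scalp_mask)
  else seq_len(ncol(specs))
  res <- infer_nuisance(net, specs[, act, drop = FALSE], sub)
  specs[, act] <- res$m
  out <- with_volume_data(volume, specs, "freq")
  if (volume$domain == "time")
    out <- with_volume_data(volume, spec_to_fid_mat(specs), "time")
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file holding all parameters and optimizer state,
#' with a JSON sidecar (`<path>.json`) describing the architecture, training
#' axis and parameter count.
#'
#' @param net a [build_ynet()] result
#' @param path checkpoint path
#' @return `path` (invisibly) for `save_ynet`; the network for `load_ynet`
#' @export
save_ynet <- function(net, path) {
  stopifnot(inherits(net, "ynet"))
  saveRDS(net, path)
  sidecar <- list(config = unclass(net$config),
                  axis = if (!is.null(net$axis))
                    net$axis[c("n_points", "bandwidth_hz", "carrier_ppm",
                               "field_mhz")] else NULL,
                  n_parameters = count_parameters(net),
                  step = net$step)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ynet
#' @export
load_ynet <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "ynet")) stop("file does not contain a ynet checkpoint")
  net
}
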