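toy_cfg <- function() ynet_config(depth = 2, base_channels = 4,
                                  kernel_size = 3, dropout_rate = 0)

test_that("config validation and channel progression", {
  expect_error(ynet_config(depth = 0), "depth")
  expect_error(ynet_config(base_channels = 0), "base_channels")
  expect_error(ynet_config(kernel_size = 4), "odd")
  cfg <- ynet_config()
  expect_equal(mrsiclean:::enc_channels(cfg), c(16, 32, 64, 128))
  net <- build_ynet(cfg, seed = 1)
  for (i in 1:4)
    expect_equal(nrow(net$layers[[paste0("enc1_b", i)]]$conv1$W),
                 c(16, 32, 64, 128)[i])
})

test_that("parameter count of a toy config matches the hand-computed sum", {
  cfg <- toy_cfg()            # depth 2, base 4, kernel 3, in/out 2 channels
  net <- build_ynet(cfg, seed = 1)
  conv_p <- function(ci, co, k) co * ci * k + co + co   # W + b + PReLU slope
  out_p <- function(ci, co, k) co * ci * k + co         # linear final conv
  expected <-
    2 * (conv_p(2, 4, 3) + conv_p(4, 4, 3) +       # two encoders, block 1
         conv_p(4, 8, 3) + conv_p(8, 8, 3)) +      # block 2
    (conv_p(16, 16, 3) + conv_p(16, 16, 3)) +      # bottleneck on concat
    (conv_p(16 + 16, 8, 3) + conv_p(8, 8, 3)) +    # decoder level 2
    (conv_p(8 + 8, 4, 3) + conv_p(4, 4, 3)) +      # decoder level 1
    (conv_p(4, 4, 3) + conv_p(4, 4, 3)) +          # final block
    out_p(4, 2, 3)
  expect_equal(count_parameters(net), expected)
})

test_that("forward pass preserves shape and finiteness; padding round-trips", {
  net <- build_ynet(toy_cfg(), seed = 3)
  for (L in c(16, 32, 64)) {
    x1 <- array(0, c(2, L, 3)); x2 <- array(0, c(2, L, 3))
    out <- ynet_forward(net, x1, x2)$out
    expect_equal(dim(out), c(2, L, 3))
    expect_true(all(is.finite(out)))
  }
  expect_error(ynet_forward(net, array(0, c(2, 10, 1)),
                            array(0, c(2, 10, 1))), "divisible")
})

test_that("normalize_pair implements the root-sum-squared energy", {
  r <- normalize_pair(c(1 + 0i, 0), c(0 + 0i, 0))
  expect_equal(r$energy, 1)
  x1 <- rand_complex(32, seed = 1); x2 <- rand_complex(32)
  r <- normalize_pair(x1, x2)
  expect_equal(r$energy, sqrt(sum(Mod(x1 - x2)^2)))
  # degenerate equality: eps floor keeps outputs finite
  rd <- normalize_pair(x1, x1)
  expect_equal(rd$energy, 0)
  expect_true(all(is.finite(Mod(rd$x1))))
  # homogeneity: scaling both inputs scales E, not the normalized outputs
  rc <- normalize_pair(3 * x1, 3 * x2)
  expect_equal(rc$energy, 3 * r$energy)
  expect_lt(max(Mod(rc$x1 - r$x1)), 1e-12)
})

test_that("phase augmentation rotates all parts jointly, magnitudes fixed", {
  ex <- training_example(rand_complex(16, seed = 2), rand_complex(16),
                         rand_complex(16))
  id <- augment_phase(ex, omega = 0)
  expect_equal(id$x1, ex$x1)
  set.seed(7)
  aug <- augment_phase(ex)
  expect_gte(aug$omega, 0); expect_lte(aug$omega, 2 * pi)
  expect_equal(Mod(aug$x1), Mod(ex$x1))
  expect_equal(Mod(aug$y), Mod(ex$y))
  expect_lt(max(Mod(aug$x1 * Conj(aug$x2) - ex$x1 * Conj(ex$x2))), 1e-12)
})

test_that("learning-rate schedule quarters every step interval", {
  cfg <- train_config(lr = 0.01, lr_factor = 0.25, lr_step_epochs = 50)
  expect_equal(lr_at_epoch(cfg, 0), 0.01)
  expect_equal(lr_at_epoch(cfg, 49), 0.01)
  expect_equal(lr_at_epoch(cfg, 50), 0.0025)
  expect_equal(lr_at_epoch(cfg, 100), 0.000625)
})

tiny_dataset <- function(n = 12, seed = 5) {
  ax <- spectral_axis(64, 2326)
  sys <- test_catalog()[c("NAA", "Cr")]
  b <- build_basis(sys, ax)
  assemble_training_set(n, b, mode = "walinet", n_subjects = 2,
                        n_lipid_cols = 6, seed = seed)
}

test_that("zero-epoch training returns the initial weights unchanged", {
  ds <- tiny_dataset()
  net <- build_ynet(toy_cfg(), seed = 11)
  fit <- train_ynet(net, ds, train_config(epochs = 0, seed = 1))
  expect_identical(fit$net$layers, net$layers)
  expect_equal(nrow(fit$history), 0)
})

test_that("training is deterministic and overfits a tiny subset", {
  # 10 examples, 2 steps/epoch for 100 epochs = 200 optimizer steps
  ds <- tiny_dataset(n = 10)
  cfg <- train_config(epochs = 100, seed = 3, batch_size = 5, val_frac = 0,
                      lr_step_epochs = 40)
  net <- build_ynet(toy_cfg(), seed = 3)
  f1 <- train_ynet(net, ds, cfg)
  f2 <- train_ynet(net, ds, cfg)
  expect_lt(max(abs(f1$history$train_loss - f2$history$train_loss)), 1e-6)
  first <- f1$history$train_loss[1]
  last <- min(utils::tail(f1$history$train_loss, 5))
  expect_gt(first / last, 10)    # >= 10-fold loss reduction
})

test_that("inference subtracts an oracle prediction exactly", {
  # if the network output were exactly the normalized target, m = x1 - y
  # recovers the metabolite signal by construction; verify the arithmetic
  # of de-normalization with the true target in place of the network
  ds <- tiny_dataset(n = 4)
  nrm <- normalize_pair(ds$x1, ds$x2)
  div <- pmax(nrm$energy, 1e-12)
  y_back <- sweep(sweep(ds$y, 2, div, "/"), 2, div, "*")
  m <- ds$x1 - y_back
  expect_lt(max(Mod(m - (ds$truth))), 1e-9 * max(Mod(ds$x1)))
})

test_that("inference is homogeneous thanks to energy normalization", {
  ds <- tiny_dataset(n = 6)
  net <- build_ynet(toy_cfg(), seed = 2)
  net$axis <- ds$axis
  sub <- ds$subspaces[[1]]
  cols <- which(ds$subject == 1)
  x <- ds$x1[, cols, drop = FALSE]
  base <- infer_nuisance(net, x, sub)
  for (c0 in c(0.1, 10)) {
    sc <- infer_nuisance(net, c0 * x, sub)
    dev <- max(Mod(sc$y - c0 * base$y)) / max(Mod(c0 * base$y))
    expect_lt(dev, 0.05)
  }
})

test_that("inference resamples foreign-axis inputs onto the training grid", {
  ds <- tiny_dataset(n = 4)
  net <- build_ynet(toy_cfg(), seed = 8)
  net$axis <- ds$axis                       # 64-point training grid
  src <- spectral_axis(96, 3000)            # different acquisition
  # the subject operator is built from the subject's own (source-axis) scalp
  # spectra, as in a cross-protocol application
  p <- test_nuisance_params()
  L <- vapply(1:12, function(k) sample_lipid_spectrum(p, src, seed = 700 + k)$data,
              complex(96))
  sub <- lipid_subspace(L, 0.01, src)
  x <- mrs_spectrum(rand_complex(96, seed = 31), src, "freq")
  res <- suppressWarnings(infer_nuisance(net, x, sub))
  expect_s3_class(res$m, "mrs_spectrum")
  expect_equal(res$m$axis$n_points, 96)     # result back on the input grid
  expect_lt(max(Mod((x$data - res$y$data) - res$m$data)), 1e-10)
  net2 <- net
  expect_error(infer_nuisance(net2, x, sub, resample = FALSE), "axis")
})

test_that("checkpoints round-trip through save/load with sidecar", {
  net <- build_ynet(toy_cfg(), seed = 6)
  tmp <- tempfile(fileext = ".rds")
  save_ynet(net, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- load_ynet(tmp)
  expect_identical(back$layers, net$layers)
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(side$n_parameters, count_parameters(net))
  unlink(c(tmp, paste0(tmp, ".json")))
})
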