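#' Y-Net architecture configuration
#'
#' Dual-encoder 1D convolutional encoder-decoder: each encoder and the decoder
#' contain `depth` convolutional blocks (two conv layers, each followed by
#' PReLU and dropout), with MaxPooling after every encoder block and linear
#' Upsampling before every decoder block. Channels start at `base_channels`
#' and double after every pooling (halve after every upsampling). One extra
#' block sits at the bottleneck (on the concatenated encoder outputs) and one
#' after the decoder. Skip connections from both encoders are concatenated
#' into the decoder at matching scales.
#'
#' @param depth number of encoder/decoder levels (default 4)
#' @param base_channels channels of the first block (default 16)
#' @param kernel_size convolution kernel size (default 7, odd)
#' @param dropout_rate dropout probability after each activation
#' @param pool_factor pooling/upsampling factor (default 2)
#' @param in_channels input channels per encoder (2: real, imaginary)
#' @param out_channels output channels (2: real, imaginary)
#' @return object of class `ynet_config`
#' @export
ynet_config <- function(depth = 4L, base_channels = 16L, kernel_size = 7L,
                        dropout_rate = 0.01, pool_factor = 2L,
                        in_channels = 2L, out_channels = 2L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  kernel_size <- as.integer(kernel_size)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be a positive odd integer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(depth = depth, base_channels = base_channels,
                 kernel_size = kernel_size, dropout_rate = dropout_rate,
                 pool_factor = as.integer(pool_factor),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "ynet_config")
}

#' Training hyperparameters
#'
#' Mirrors the published optimization recipe: Adam with learning rate 0.01
#' quartered every 50 epochs (the full 400-epoch schedule); the scaled preset
#' used for desk-scale experiments shortens the schedule proportionally via
#' `lr_step_epochs`.
#'
#' @param epochs training epochs
#' @param lr initial learning rate (0.01)
#' @param lr_factor multiplicative decay (0.25)
#' @param lr_step_epochs epochs between decays (50 in the full schedule)
#' @param adam_beta1,adam_beta2 Adam momentum decay rates
#' @param batch_size minibatch size
#' @param seed RNG seed controlling init, data order, augmentation, dropout
#' @param mode `"walinet"` (lipid + water target) or `"lipnet"` (lipid only)
#' @param val_frac subject fraction held out for validation
#' @param eps_norm floor for the energy normalization divisor
#' @param clip_norm global gradient-norm clip (stabilizes the early epochs
#'   at the aggressive initial learning rate); `Inf` disables clipping
#' @return object of class `train_config`
#' @export
train_config <- function(epochs = 30L, lr = 0.01, lr_factor = 0.25,
                         lr_step_epochs = 50L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, batch_size = 64L, seed = 1L,
                         mode = c("walinet", "lipnet"), val_frac = 0.2,
                         eps_norm = 1e-12, clip_norm = 5) {
  mode <- match.arg(mode)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_factor = lr_factor,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 mode = mode, val_frac = val_frac, eps_norm = eps_norm,
                 clip_norm = clip_norm),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#' @param config a [train_config()]
#' @param epoch 0-based epoch index
#' @return learning rate
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$lr_factor^(floor(epoch / config$lr_step_epochs))
}

# ---- network construction --------------------------------------------------

enc_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

new_conv <- function(c_in, c_out, k, act = TRUE) {
  W <- matrix(stats::rnorm(c_out * c_in * k, 0, sqrt(2 / (c_in * k))),
              c_out, c_in * k)
  list(W = W, b = numeric(c_out),
       a = if (act) rep(0.25, c_out) else NULL,
       c_in = c_in, c_out = c_out, k = k, act = act)
}

# a conv block = two conv+PReLU(+dropout) layers
new_block <- function(c_in, c_out, k) {
  list(conv1 = new_conv(c_in, c_out, k), conv2 = new_conv(c_out, c_out, k))
}

#' Build a Y-Net
#'
#' Initializes all parameters (He initialization for weights, 0.25 for PReLU
#' slopes) for the architecture described by the config.
#'
#' @param config a [ynet_config()]
#' @param seed RNG seed for the initialization
#' @return object of class `ynet`
#' @export
build_ynet <- function(config = ynet_config(), seed = 1L) {
  stopifnot(inherits(config, "ynet_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ch <- enc_channels(config)
  k <- config$kernel_size
  d <- config$depth
  layers <- list()
  for (enc in c("enc1", "enc2")) {
    c_prev <- config$in_channels
    for (i in seq_len(d)) {
      layers[[paste0(enc, "_b", i)]] <- new_block(c_prev, ch[i], k)
      c_prev <- ch[i]
    }
  }
  cb <- 2L * ch[d]                       # concatenated encoder channels
  layers[["bottleneck"]] <- new_block(cb, cb, k)
  c_prev <- cb
  for (i in rev(seq_len(d))) {
    layers[[paste0("dec_b", i)]] <- new_block(c_prev + 2L * ch[i], ch[i], k)
    c_prev <- ch[i]
  }
  layers[["final"]] <- new_block(ch[1], ch[1], k)
  layers[["out"]] <- list(conv1 = new_conv(ch[1], config$out_channels, k,
                                           act = FALSE))
  structure(list(config = config, layers = layers, seed = as.integer(seed),
                 adam = NULL, step = 0L, axis = NULL),
            class = "ynet")
}

#' Total number of trainable parameters
#' @param net a [build_ynet()] result
#' @return integer parameter count (weights, biases, PReLU slopes)
#' @export
count_parameters <- function(net) {
  tot <- 0L
  for (bl in net$layers) for (cv in bl)
    tot <- tot + length(cv$W) + length(cv$b) + length(cv$a)
  tot
}

#' @export
print.ynet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ynet> depth %d, base %d channels, kernel %d: %d parameters\n",
              cfg$depth, cfg$base_channels, cfg$kernel_size,
              count_parameters(x)))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

conv_fwd <- function(cv, X, training, drop_rate) {
  Y <- .conv1d_fwd(X, cv$W, cv$b, cv$k)
  cache <- list(X = X)
  if (cv$act) {
    cache$pre <- Y
    Y <- .prelu_fwd(Y, cv$a)
    if (training && drop_rate > 0) {
      mask <- array((stats::runif(length(Y)) >= drop_rate) / (1 - drop_rate),
                    dim = dim(Y))
      Y <- Y * mask
      cache$mask <- mask
    }
  }
  list(Y = Y, cache = cache)
}

conv_bwd <- function(cv, cache, dY) {
  if (cv$act) {
    if (!is.null(cache$mask)) dY <- dY * cache$mask
    pb <- .prelu_bwd(cache$pre, cv$a, dY)
    dY <- pb$dX
    da <- pb$da
  } else da <- NULL
  cb <- .conv1d_bwd(cache$X, cv$W, dY, cv$k)
  list(dX = cb$dX, grads = list(dW = cb$dW, db = cb$db, da = da))
}

block_fwd <- function(bl, X, training, drop_rate) {
  r1 <- conv_fwd(bl$conv1, X, training, drop_rate)
  r2 <- conv_fwd(bl$conv2, r1$Y, training, drop_rate)
  list(Y = r2$Y, cache = list(c1 = r1$cache, c2 = r2$cache))
}

block_bwd <- function(bl, cache, dY) {
  b2 <- conv_bwd(bl$conv2, cache$c2, dY)
  b1 <- conv_bwd(bl$conv1, cache$c1, b2$dX)
  list(dX = b1$dX, grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

cat_channels <- function(...) {
  parts <- list(...)
  C <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(C, dim(parts[[1]])[2], dim(parts[[1]])[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Forward pass of the Y-Net
#'
#' @param net a [build_ynet()] result
#' @param x1,x2 input tensors: arrays (in_channels, L, batch) with L
#'   divisible by pool_factor^depth
#' @param training enable dropout and keep caches for the backward pass
#' @return list with `out` (out_channels, L, batch) and, when training,
#'   `caches`
#' @export
ynet_forward <- function(net, x1, x2, training = FALSE) {
  cfg <- net$config
  d <- cfg$depth; pf <- cfg$pool_factor; dr <- cfg$dropout_rate
  L <- dim(x1)[2]
  if (L %% pf^d != 0)
    stop(sprintf("input length %d not divisible by %d", L, pf^d))
  caches <- list()
  skips <- list(enc1 = list(), enc2 = list())
  outs <- list()
  for (enc in c("enc1", "enc2")) {
    cur <- if (enc == "enc1") x1 else x2
    for (i in seq_len(d)) {
      nm <- paste0(enc, "_b", i)
      bf <- block_fwd(net$layers[[nm]], cur, training, dr)
      caches[[nm]] <- bf$cache
      skips[[enc]][[i]] <- bf$Y
      mp <- .maxpool_fwd(bf$Y, pf)
      caches[[paste0(nm, "_pool")]] <- mp$idx
      cur <- mp$Y
    }
    outs[[enc]] <- cur
  }
  cur <- cat_channels(outs$enc1, outs$enc2)
  bf <- block_fwd(net$layers$bottleneck, cur, training, dr)
  caches$bottleneck <- bf$cache
  cur <- bf$Y
  for (i in rev(seq_len(d))) {
    up <- .upsample_fwd(cur)
    caches[[paste0("dec_b", i, "_in_ch")]] <- c(dim(cur)[1],
                                                dim(skips$enc1[[i]])[1],
                                                dim(skips$enc2[[i]])[1])
    cur <- cat_channels(up, skips$enc1[[i]], skips$enc2[[i]])
    bf <- block_fwd(net$layers[[paste0("dec_b", i)]], cur, training, dr)
    caches[[paste0("dec_b", i)]] <- bf$cache
    cur <- bf$Y
  }
  bf <- block_fwd(net$layers$final, cur, training, dr)
  caches$final <- bf$cache
  of <- conv_fwd(net$layers$out$conv1, bf$Y, training, 0)
  caches$out <- of$cache
  list(out = of$Y, caches = if (training) caches else NULL)
}

# Backward pass; returns gradients keyed like net$layers.
ynet_backward <- function(net, caches, dOut) {
  cfg <- net$config
  d <- cfg$depth; pf <- cfg$pool_factor
  grads <- list()
  ob <- conv_bwd(net$layers$out$conv1, caches$out, dOut)
  grads$out <- list(conv1 = ob$grads)
  fb <- block_bwd(net$layers$final, caches$final, ob$dX)
  grads$final <- fb$grads
  dcur <- fb$dX
  dskips <- list(enc1 = vector("list", d), enc2 = vector("list", d))
  for (i in seq_len(d)) {
    nm <- paste0("dec_b", i)
    bb <- block_bwd(net$layers[[nm]], caches[[nm]], dcur)
    chs <- caches[[paste0(nm, "_in_ch")]]
    dX <- bb$dX
    grads[[nm]] <- bb$grads
    dup <- dX[seq_len(chs[1]), , , drop = FALSE]
    dskips$enc1[[i]] <- dX[chs[1] + seq_len(chs[2]), , , drop = FALSE]
    dskips$enc2[[i]] <- dX[chs[1] + chs[2] + seq_len(chs[3]), , , drop = FALSE]
    dcur <- .upsample_bwd(dup)
  }
  bb <- block_bwd(net$layers$bottleneck, caches$bottleneck, dcur)
  grads$bottleneck <- bb$grads
  half <- dim(bb$dX)[1] %/% 2L
  denc <- list(enc1 = bb$dX[seq_len(half), , , drop = FALSE],
               enc2 = bb$dX[half + seq_len(half), , , drop = FALSE])
  for (enc in c("enc1", "enc2")) {
    dcur <- denc[[enc]]
    for (i in rev(seq_len(d))) {
      nm <- paste0(enc, "_b", i)
      Lfull <- dim(caches[[nm]]$c2$X)[2]
      dpool <- .maxpool_bwd(dcur, caches[[paste0(nm, "_pool")]], pf, Lfull)
      dpool <- dpool + dskips[[enc]][[i]]
      bb <- block_bwd(net$layers[[nm]], caches[[nm]], dpool)
      grads[[nm]] <- bb$grads
      dcur <- bb$dX
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

# Global gradient-norm clipping: rescales the whole gradient tree so its
# Euclidean norm does not exceed `max_norm`.
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- 0
  for (l in grads) for (cv in l) for (g in cv)
    if (!is.null(g)) total <- total + sum(g^2)
  total <- sqrt(total)
  if (total <= max_norm) return(grads)
  scale <- max_norm / total
  for (ln in names(grads)) for (cn in names(grads[[ln]]))
    for (gn in names(grads[[ln]][[cn]])) {
      if (!is.null(grads[[ln]][[cn]][[gn]]))
        grads[[ln]][[cn]][[gn]] <- grads[[ln]][[cn]][[gn]] * scale
    }
  grads
}

# Applies one Adam update on the layer tree. The gradient tree `grads`
# mirrors the layer tree with dW/db/da leaves.
adam_step <- function(net, grads, lr, b1, b2, eps = 1e-8) {
  if (is.null(net$adam)) net$adam <- list(m = list(), v = list())
  net$step <- net$step + 1L
  t <- net$step
  corr <- sqrt(1 - b2^t) / (1 - b1^t)
  for (lname in names(grads)) {
    for (cname in names(grads[[lname]])) {
      g <- grads[[lname]][[cname]]
      for (p in c("W", "b", "a")) {
        gv <- g[[paste0("d", p)]]
        if (is.null(gv)) next
        key <- paste(lname, cname, p, sep = ".")
        m <- net$adam$m[[key]]; v <- net$adam$v[[key]]
        if (is.null(m)) { m <- gv * 0; v <- gv * 0 }
        m <- b1 * m + (1 - b1) * gv
        v <- b2 * v + (1 - b2) * gv^2
        net$adam$m[[key]] <- m; net$adam$v[[key]] <- v
        net$layers[[lname]][[cname]][[p]] <-
          net$layers[[lname]][[cname]][[p]] - lr * corr * m / (sqrt(v) + eps)
      }
    }
  }
  net
}
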