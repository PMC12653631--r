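# Binary lesion masks: the attackable region M and its complement 1 - M,
# combined with images by Hadamard product, plus a small U-Net segmenter
# that predicts masks from images.

check_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be an H x W matrix")
  if (any(mask != 0 & mask != 1)) stop("mask values must be exactly {0,1}")
  invisible(mask)
}

#' Complement of a binary mask
#'
#' The non-attackable region: `1 - mask` elementwise.
#' @param mask H x W matrix in {0,1}.
#' @export
complement <- function(mask) {
  check_binary_mask(mask)
  1 - mask
}

#' Hadamard product of an image and a binary mask
#'
#' The mask is broadcast across channels; pixels where the mask is 0 come
#' out exactly 0.
#' @param image H x W matrix or H x W x C array.
#' @param mask H x W matrix in {0,1} on the same pixel grid.
#' @export
apply_mask <- function(image, mask) {
  check_binary_mask(mask)
  d <- dim(image)
  if (!all(d[1:2] == dim(mask))) stop("image and mask grids differ")
  if (length(d) == 2L) return(image * mask)
  image * array(mask, d)
}

#' Dice coefficient between two binary masks
#'
#' `2|a n b| / (|a| + |b|)`; when both masks are empty the overlap is
#' perfect by convention and 1.0 is returned (avoids 0/0).
#' @param a,b H x W matrices in {0,1} on the same grid.
#' @export
dice <- function(a, b) {
  check_binary_mask(a); check_binary_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask grids differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a * b) / (sa + sb)
}

#' Intersection-over-union between two binary masks
#'
#' `|a n b| / |a u b|`, with the both-empty case defined as 1.0.
#' @inheritParams dice
#' @export
iou <- function(a, b) {
  check_binary_mask(a); check_binary_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask grids differ")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1.0)
  inter / uni
}

#' Segmenter configuration
#'
#' A symmetric encoder-decoder (U-Net) with `depth` downsampling and
#' `depth` upsampling stages, ReLU activations, skip connections at every
#' resolution, and a sigmoid head producing a per-pixel lesion probability.
#'
#' @param depth Down/upsampling stages (default 4); input side length must
#'   be divisible by `2^depth`.
#' @param base_channels Channels of the first encoder stage; doubled per
#'   stage.
#' @param binarize_threshold Probability threshold used by
#'   [predict_mask()]; must lie in (0,1).
#' @param seed Weight-initialisation seed.
#' @export
segmenter_config <- function(depth = 4L, base_channels = 4L,
                             binarize_threshold = 0.5, seed = 1L) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop("binarize_threshold must be in (0,1)")
  }
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 binarize_threshold = binarize_threshold,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

#' Build a U-Net style segmenter
#'
#' @param config A [segmenter_config()].
#' @param in_channels Input channels.
#' @return An object of class `unet_segmenter`.
#' @export
build_unet <- function(config = segmenter_config(), in_channels = 3L) {
  stopifnot(inherits(config, "segmenter_config"))
  d <- config$depth
  ch <- config$base_channels * 2L^(0:(d - 1L))
  params <- list()
  with_seed(config$seed, {
    cin <- in_channels
    for (s in seq_len(d)) {
      p <- init_conv(3L, cin, ch[s])
      params[[paste0("enc", s, ".W")]] <- p$W
      params[[paste0("enc", s, ".b")]] <- p$b
      cin <- ch[s]
    }
    p <- init_conv(3L, cin, 2L * ch[d])
    params[["bott.W"]] <- p$W
    params[["bott.b"]] <- p$b
    cin <- 2L * ch[d]
    for (s in rev(seq_len(d))) {
      p <- init_upconv(cin, ch[s])
      params[[paste0("up", s, ".W")]] <- p$W
      params[[paste0("up", s, ".b")]] <- p$b
      p <- init_conv(3L, 2L * ch[s], ch[s])
      params[[paste0("dec", s, ".W")]] <- p$W
      params[[paste0("dec", s, ".b")]] <- p$b
      cin <- ch[s]
    }
    p <- init_conv(1L, ch[1], 1L, gain = 1)
    params[["head.W"]] <- p$W
    params[["head.b"]] <- p$b
  })
  structure(list(params = params, config = config, in_channels = in_channels),
            class = "unet_segmenter")
}

check_divisible <- function(H, W, depth) {
  f <- 2L^depth
  if (H %% f != 0L || W %% f != 0L) {
    stop(sprintf(
      "input size %dx%d is not divisible by 2^depth = %d; pad or resize the image",
      H, W, f))
  }
}

# Shared encoder-decoder forward for U-Net shaped nets. `head_act` is
# "sigmoid" (segmenter) or "tanh" (generator). Returns output and caches.
ed_forward <- function(params, depth, x, head_act, keep = FALSE,
                       skip_connections = TRUE) {
  d <- dim(x)
  check_divisible(d[1], d[2], depth)
  cache <- list(skips = vector("list", depth),
                enc_in = vector("list", depth),
                enc_out = vector("list", depth),
                pools = vector("list", depth))
  h <- x
  if (keep) cache$patches <- list()
  for (s in seq_len(depth)) {
    if (keep) cache$enc_in[[s]] <- h
    cv <- conv_fw(h, params[[paste0("enc", s, ".W")]],
                  params[[paste0("enc", s, ".b")]], return_patches = keep)
    if (keep) cache$patches[[paste0("enc", s)]] <- cv$patches
    a <- relu(if (keep) cv$y else cv)
    if (keep) cache$enc_out[[s]] <- a
    cache$skips[[s]] <- a
    pc <- pool_fw(a)
    if (keep) cache$pools[[s]] <- pc[c("w1", "w2", "dim")]
    h <- pc$y
  }
  if (keep) cache$bott_in <- h
  cv <- conv_fw(h, params[["bott.W"]], params[["bott.b"]],
                return_patches = keep)
  if (keep) cache$patches[["bott"]] <- cv$patches
  h <- relu(if (keep) cv$y else cv)
  if (keep) cache$bott_out <- h
  if (keep) {
    cache$up_in <- vector("list", depth)
    cache$cc <- vector("list", depth)
    cache$dec_out <- vector("list", depth)
  }
  for (s in rev(seq_len(depth))) {
    if (keep) cache$up_in[[s]] <- h
    u <- upconv_fw(h, params[[paste0("up", s, ".W")]],
                   params[[paste0("up", s, ".b")]])
    sk <- if (skip_connections) cache$skips[[s]] else cache$skips[[s]] * 0
    du <- dim(u)
    cc <- array(0, c(du[1], du[2], du[3] + dim(sk)[3], du[4]))
    cc[, , seq_len(du[3]), ] <- u
    cc[, , du[3] + seq_len(dim(sk)[3]), ] <- sk
    if (keep) cache$cc[[s]] <- cc
    cv <- conv_fw(cc, params[[paste0("dec", s, ".W")]],
                  params[[paste0("dec", s, ".b")]], return_patches = keep)
    if (keep) cache$patches[[paste0("dec", s)]] <- cv$patches
    h <- relu(if (keep) cv$y else cv)
    if (keep) cache$dec_out[[s]] <- h
  }
  if (keep) cache$head_in <- h
  cv <- conv_fw(h, params[["head.W"]], params[["head.b"]],
                return_patches = keep)
  if (keep) cache$patches[["head"]] <- cv$patches
  out <- if (keep) cv$y else cv
  out <- if (head_act == "sigmoid") sigmoid(out) else tanh(out)
  if (keep) cache$out <- out
  list(out = out, cache = if (keep) cache else NULL)
}

# Backward through ed_forward given dL/d(output). Returns parameter grads.
ed_backward <- function(params, depth, fw, dout, head_act,
                        skip_connections = TRUE, need_dx = FALSE) {
  cache <- fw$cache
  grads <- lapply(params, function(p) p * 0)
  g <- if (head_act == "sigmoid") sigmoid_bw(cache$out, dout)
       else tanh_bw(cache$out, dout)
  bw <- conv_bw(cache$head_in, params[["head.W"]], g,
                patches = cache$patches[["head"]])
  grads[["head.W"]] <- bw$dW; grads[["head.b"]] <- bw$db
  g <- bw$dx
  dskips <- vector("list", depth)
  for (s in seq_len(depth)) {
    g <- relu_bw(cache$dec_out[[s]], g)
    bw <- conv_bw(cache$cc[[s]], params[[paste0("dec", s, ".W")]], g,
                  patches = cache$patches[[paste0("dec", s)]])
    grads[[paste0("dec", s, ".W")]] <- bw$dW
    grads[[paste0("dec", s, ".b")]] <- bw$db
    dcc <- bw$dx
    cu <- ncol(params[[paste0("up", s, ".W")]]) %/% 4L
    du <- dcc[, , seq_len(cu), , drop = FALSE]
    if (skip_connections) {
      dskips[[s]] <- dcc[, , cu + seq_len(dim(dcc)[3] - cu), , drop = FALSE]
    }
    bw <- upconv_bw(cache$up_in[[s]], params[[paste0("up", s, ".W")]], du)
    grads[[paste0("up", s, ".W")]] <- bw$dW
    grads[[paste0("up", s, ".b")]] <- bw$db
    g <- bw$dx
  }
  g <- relu_bw(cache$bott_out, g)
  bw <- conv_bw(cache$bott_in, params[["bott.W"]], g,
                patches = cache$patches[["bott"]])
  grads[["bott.W"]] <- bw$dW; grads[["bott.b"]] <- bw$db
  g <- bw$dx
  for (s in rev(seq_len(depth))) {
    pc <- cache$pools[[s]]
    g <- pool_bw(pc, g)
    if (skip_connections && !is.null(dskips[[s]])) g <- g + dskips[[s]]
    g <- relu_bw(cache$enc_out[[s]], g)
    bw <- conv_bw(cache$enc_in[[s]], params[[paste0("enc", s, ".W")]], g,
                  need_dx = need_dx || s > 1L,
                  patches = cache$patches[[paste0("enc", s)]])
    grads[[paste0("enc", s, ".W")]] <- bw$dW
    grads[[paste0("enc", s, ".b")]] <- bw$db
    g <- bw$dx
  }
  list(grads = grads, dinput = g)
}

# Lesion probability maps for a batch: H x W x 1 x B in [0,1].
segmenter_probs <- function(segmenter, x, keep = FALSE) {
  ed_forward(segmenter$params, segmenter$config$depth, x, "sigmoid",
             keep = keep)
}

#' Predict a binary lesion mask for one image
#'
#' Runs the segmenter and thresholds the probability map; raising the
#' threshold can only shrink the predicted area.
#' @param segmenter A trained `unet_segmenter`.
#' @param image H x W x 3 array in [0,1]; side lengths divisible by
#'   `2^depth`.
#' @param threshold Binarisation threshold; defaults to the config value.
#' @return H x W matrix in {0,1}.
#' @export
predict_mask <- function(segmenter, image, threshold = NULL) {
  stopifnot(inherits(segmenter, "unet_segmenter"))
  stopifnot_image(image)
  if (is.null(threshold)) threshold <- segmenter$config$binarize_threshold
  x <- array(image, c(dim(image), 1L))
  p <- segmenter_probs(segmenter, x)$out[, , 1L, 1L]
  (p >= threshold) * 1
}

#' @export
predict.unet_segmenter <- function(object, image, threshold = NULL, ...) {
  predict_mask(object, image, threshold)
}

#' @export
print.unet_segmenter <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("unet_segmenter: depth %d, base %d channels, %d parameters\n",
              x$config$depth, x$config$base_channels, np))
  invisible(x)
}

#' Train the segmenter with a Dice loss
#'
#' Minimises the soft Dice loss `1 - (2*sum(p*m)+s)/(sum(p)+sum(m)+s)`
#' against ground-truth masks; reports mean hard Dice on a deterministic
#' held-out split. The default schedule (24 epochs, batch 8) gives the
#' small U-Net enough optimiser steps to move past the mean-lesion-shape
#' optimum on a couple of hundred synthetic samples.
#'
#' @param segmenter A `unet_segmenter`.
#' @param data Manifest data.frame or in-memory dataset (must carry masks).
#' @param epochs Training epochs.
#' @param seed Split/shuffle seed.
#' @param lr,weight_decay,batch_size Adam hyperparameters.
#' @param holdout_frac Held-out fraction.
#' @return A list: `segmenter` (trained), `mean_dice`.
#' @export
train_segmenter <- function(segmenter, data, epochs = 24L, seed = 1L,
                            lr = 2e-3, weight_decay = 1e-5,
                            batch_size = 8L, holdout_frac = 0.2) {
  stopifnot(inherits(segmenter, "unet_segmenter"))
  ds <- as_dataset(data)
  if (is.null(ds$masks)) stop("dataset carries no ground-truth masks")
  n <- dim(ds$images)[4]
  depth <- segmenter$config$depth
  with_seed(derive_seed(seed, 0L, salt = 13L), {
    perm <- sample(n)
    n_hold <- max(1L, floor(holdout_frac * n))
    hold <- perm[seq_len(n_hold)]
    train <- perm[-seq_len(n_hold)]
    state <- adam_init(segmenter$params)
    smooth <- 1
    for (ep in seq_len(epochs)) {
      order <- sample(train)
      for (start in seq(1L, length(order), by = batch_size)) {
        idx <- order[start:min(start + batch_size - 1L, length(order))]
        xb <- ds$images[, , , idx, drop = FALSE]
        mb <- ds$masks[, , idx, drop = FALSE]
        B <- length(idx)
        fw <- segmenter_probs(segmenter, xb, keep = TRUE)
        p <- fw$out
        dout <- array(0, dim(p))
        for (bb in seq_len(B)) {
          pb <- p[, , 1L, bb]
          m <- mb[, , bb]
          A <- sum(pb * m)
          U <- sum(pb) + sum(m)
          # d(1 - (2A+s)/(U+s))/dp = -(2m(U+s) - (2A+s)) / (U+s)^2
          dout[, , 1L, bb] <- -(2 * m * (U + smooth) - (2 * A + smooth)) /
            (U + smooth)^2 / B
        }
        bw <- ed_backward(segmenter$params, depth, fw, dout, "sigmoid")
        upd <- adam_step(segmenter$params, bw$grads, state, lr, weight_decay)
        segmenter$params <- upd$params
        state <- upd$state
      }
    }
    th <- segmenter$config$binarize_threshold
    dices <- vapply(hold, function(i) {
      pm <- predict_mask(segmenter, ds$images[, , , i])
      dice(pm, ds$masks[, , i])
    }, 0)
    list(segmenter = segmenter, mean_dice = mean(dices))
  })
}
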