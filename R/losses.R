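# Loss terms of the attack objective: the class-activation (Grad-CAM)
# discrepancy that drives transferability, the local-binary-pattern (LBP)
# texture discrepancy that preserves concealment, and the adversarial
# cross-entropy. The composed objective is
#   L = -L_adv - lambda_cam * L_cam + lambda_lbp * L_lbp,
# minimised by gradient descent: this maximises classification loss and
# CAM disruption while keeping the texture code maps close.

#' Convert an RGB image to grayscale (BT.601 luma)
#'
#' Fixed weights 0.299 R + 0.587 G + 0.114 B.
#' @param image H x W x 3 array in [0,1].
#' @return H x W matrix.
#' @export
to_grayscale <- function(image) {
  stopifnot_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Neighbor offsets for the 3x3 LBP window, clockwise from top-left;
# bit q (q = 1..8) carries weight 2^(q-1).
.lbp_offsets <- cbind(di = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
                      dj = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L))

# Shifted interior views: neighbour value matrix for offset q.
lbp_shift <- function(gray, q) {
  H <- nrow(gray); W <- ncol(gray)
  o <- .lbp_offsets[q, ]
  gray[(2L + o[1]):(H - 1L + o[1]), (2L + o[2]):(W - 1L + o[2]), drop = FALSE]
}

#' Hard local-binary-pattern codes
#'
#' For every interior pixel of the grayscale image, bit q is 1 iff the
#' q-th neighbour (clockwise from top-left) is >= the centre value (the
#' sign convention s(a) = 1 for a >= 0, so a constant image codes to 255
#' everywhere), and the code is the 8-bit integer with bit weights
#' 2^0..2^7. Codes depend only on intensity differences, so adding a
#' constant to the image leaves them unchanged.
#'
#' @param gray H x W matrix with H, W >= 3.
#' @return (H-2) x (W-2) integer matrix with values in [0, 255].
#' @export
lbp_codes <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L) {
    stop("lbp_codes needs an H x W matrix with H, W >= 3")
  }
  H <- nrow(gray); W <- ncol(gray)
  centre <- gray[2:(H - 1L), 2:(W - 1L), drop = FALSE]
  code <- matrix(0, H - 2L, W - 2L)
  for (q in 1:8) {
    code <- code + (lbp_shift(gray, q) >= centre) * 2^(q - 1L)
  }
  code
}

#' Soft LBP configuration
#' @param temperature Logistic temperature (> 0) on the [0,1] intensity
#'   scale; as it tends to 0 the soft map converges to the hard codes
#'   wherever no neighbour-centre difference is exactly zero.
#' @export
soft_lbp_config <- function(temperature = 0.1) {
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(temperature = temperature), class = "soft_lbp_config")
}

#' Differentiable (soft) LBP map
#'
#' The hard step in the LBP code has zero gradient almost everywhere, so
#' gradient-based training uses a logistic relaxation: each bit becomes
#' `logistic((I(q) - I(c)) / temperature)` and the map is the 2^q-weighted
#' sum, a real value in [0, 255].
#'
#' @inheritParams lbp_codes
#' @param cfg A [soft_lbp_config()].
#' @export
soft_lbp <- function(gray, cfg = soft_lbp_config()) {
  stopifnot(inherits(cfg, "soft_lbp_config"))
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L) {
    stop("soft_lbp needs an H x W matrix with H, W >= 3")
  }
  H <- nrow(gray); W <- ncol(gray)
  centre <- gray[2:(H - 1L), 2:(W - 1L), drop = FALSE]
  s <- matrix(0, H - 2L, W - 2L)
  for (q in 1:8) {
    s <- s + sigmoid((lbp_shift(gray, q) - centre) / cfg$temperature) *
      2^(q - 1L)
  }
  s
}

#' Texture-preservation loss between two images
#'
#' Mean of squared elementwise differences between the LBP maps of the two
#' images' grayscales. `mode = "hard"` uses integer codes (reporting);
#' `mode = "soft"` uses the differentiable relaxation (training).
#'
#' @param x_adv,x H x W x 3 images on the same grid.
#' @param mode `"hard"` or `"soft"`.
#' @param cfg Soft-LBP configuration (soft mode only).
#' @param reduce `"mean"` (default, scale-stable across image sizes) or
#'   `"sum"`.
#' @return Non-negative scalar.
#' @export
lbp_loss <- function(x_adv, x, mode = c("hard", "soft"),
                     cfg = soft_lbp_config(), reduce = c("mean", "sum")) {
  mode <- match.arg(mode)
  reduce <- match.arg(reduce)
  if (!all(dim(x_adv) == dim(x))) stop("image grids differ")
  ga <- to_grayscale(x_adv)
  gx <- to_grayscale(x)
  ma <- if (mode == "hard") lbp_codes(ga) else soft_lbp(ga, cfg)
  mx <- if (mode == "hard") lbp_codes(gx) else soft_lbp(gx, cfg)
  d2 <- (ma - mx)^2
  if (reduce == "mean") mean(d2) else sum(d2)
}

# Gradient of the soft-LBP loss w.r.t. the adversarial image (the clean
# image's map is a fixed reference). Returns an H x W x 3 array.
lbp_loss_grad <- function(x_adv, ref_soft_map, cfg) {
  ga <- to_grayscale(x_adv)
  H <- nrow(ga); W <- ncol(ga)
  centre <- ga[2:(H - 1L), 2:(W - 1L), drop = FALSE]
  sa <- matrix(0, H - 2L, W - 2L)
  sig <- vector("list", 8L)
  for (q in 1:8) {
    sig[[q]] <- sigmoid((lbp_shift(ga, q) - centre) / cfg$temperature)
    sa <- sa + sig[[q]] * 2^(q - 1L)
  }
  rres <- 2 * (sa - ref_soft_map) / length(sa)   # dL/dS, mean reduction
  dgray <- matrix(0, H, W)
  for (q in 1:8) {
    gq <- rres * sig[[q]] * (1 - sig[[q]]) / cfg$temperature * 2^(q - 1L)
    o <- .lbp_offsets[q, ]
    ri <- (2L + o[1]):(H - 1L + o[1]); rj <- (2L + o[2]):(W - 1L + o[2])
    dgray[ri, rj] <- dgray[ri, rj] + gq
    dgray[2:(H - 1L), 2:(W - 1L)] <- dgray[2:(H - 1L), 2:(W - 1L)] - gq
  }
  lw <- c(0.299, 0.587, 0.114)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- dgray * lw[ch]
  out
}

#' Grad-CAM class-activation map
#'
#' Channel weights are the spatial means of the gradient of the true
#' label's pre-softmax logit with respect to the hooked layer's feature
#' maps; the map is the rectified weighted sum of those feature maps at
#' the layer's native resolution (no upsampling, no min-max scaling).
#'
#' @param model A `tiny_classifier` (or any model usable with the
#'   sequential-network executor).
#' @param image H x W x 3 array.
#' @param label True class label (0-based).
#' @param layer_name Hooked layer; defaults to [last_conv_layer()].
#' @return h x w matrix of non-negative values.
#' @export
gradcam <- function(model, image, label, layer_name = NULL) {
  if (is.null(layer_name)) layer_name <- model$last_conv
  if (length(dim(image)) == 3L) image <- array(image, c(dim(image), 1L))
  cam_batch(model, image, as.integer(label), layer_name)[, , 1L]
}

# Batched Grad-CAM. labels is a 0-based integer vector of length B.
# Returns h x w x B. The channel weights a_c are computed by a dedicated
# backward pass from the label logits to the hooked layer.
cam_batch <- function(model, x, labels, layer_name, fw = NULL) {
  if (is.null(fw)) fw <- classifier_logits(model, x, keep = TRUE)
  li <- match(layer_name, vapply(model$layers, `[[`, "", "name"))
  if (is.na(li)) stop("unknown layer: ", layer_name)
  K <- nrow(fw$out); B <- ncol(fw$out)
  if (any(labels < 0L | labels >= K)) stop("label out of range")
  onehot <- matrix(0, K, B)
  onehot[cbind(labels + 1L, seq_len(B))] <- 1
  dl <- net_backward(model, fw, onehot, upto = layer_name,
                     want_params = FALSE)$dlayer
  A <- fw$caches[[li]]$out
  d <- dim(A)
  a <- matrix(colMeans(matrix(dl, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  cam <- array(0, c(d[1], d[2], B))
  for (bb in seq_len(B)) {
    m <- matrix(A[, , , bb], d[1] * d[2], d[3]) %*% a[, bb]
    cam[, , bb] <- relu(matrix(m, d[1], d[2]))
  }
  cam
}

#' Class-activation discrepancy between a clean and an adversarial image
#'
#' Mean of squared elementwise differences between the two Grad-CAM maps
#' at the hooked layer's native resolution. The clean image's map is a
#' fixed reference; during training, gradient flows only through the
#' adversarial branch.
#'
#' @inheritParams gradcam
#' @param x,x_adv Images on the same grid.
#' @param reduce `"mean"` or `"sum"`.
#' @return Non-negative scalar.
#' @export
cam_loss <- function(model, x, x_adv, label, layer_name = NULL,
                     reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (!all(dim(x) == dim(x_adv))) stop("image grids differ")
  c1 <- gradcam(model, x, label, layer_name)
  c2 <- gradcam(model, x_adv, label, layer_name)
  d2 <- (c1 - c2)^2
  if (reduce == "mean") mean(d2) else sum(d2)
}

#' Adversarial classification loss
#'
#' Cross-entropy between the model's logits on the adversarial image and
#' the true label. The attack maximises this term.
#'
#' @inheritParams gradcam
#' @param x_adv Adversarial image (H x W x 3) or batch.
#' @param label True label(s), 0-based.
#' @export
adv_loss <- function(model, x_adv, label) {
  if (length(dim(x_adv)) == 3L) x_adv <- array(x_adv, c(dim(x_adv), 1L))
  logits <- classifier_logits(model, x_adv)$out
  cross_entropy(logits, as.integer(label))
}

# Mean cross-entropy of K x B logits against 0-based labels.
cross_entropy <- function(logits, labels) {
  softmax_ce(logits, labels)$loss
}

#' Loss weights of the composed objective
#' @param lambda_cam Weight of the class-activation term (default 1).
#' @param lambda_lbp Weight of the texture term (default 0.5).
#' @export
loss_weights <- function(lambda_cam = 1, lambda_lbp = 0.5) {
  if (lambda_cam < 0 || lambda_lbp < 0) stop("loss weights must be >= 0")
  structure(list(lambda_cam = lambda_cam, lambda_lbp = lambda_lbp),
            class = "loss_weights")
}

#' Composed attack objective
#'
#' `-l_adv - lambda_cam * l_cam + lambda_lbp * l_lbp`: minimising this
#' maximises the adversarial and class-activation terms while minimising
#' the texture discrepancy.
#'
#' @param l_adv,l_cam,l_lbp Component scalars (finite).
#' @param weights A [loss_weights()].
#' @export
total_loss <- function(l_adv, l_cam, l_lbp, weights = loss_weights()) {
  comps <- c(l_adv, l_cam, l_lbp)
  if (any(!is.finite(comps))) {
    stop("non-finite loss component (training divergence): ",
         paste(signif(comps, 4), collapse = ", "))
  }
  -l_adv - weights$lambda_cam * l_cam + weights$lambda_lbp * l_lbp
}
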