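#' Generator configuration
#'
#' The perturbation generator is an encoder-decoder with 3x3 convolutions
#' and ReLU activations, 2x2 max pooling on the way down, 2x2 transposed
#' convolutions on the way up, skip connections concatenating each encoder
#' stage into the matching decoder stage, and a 1x1 convolution + Tanh
#' head. The Tanh head strictly bounds the raw perturbation field to
#' [-1, 1] for any weights; epsilon-scaling and mask restriction happen
#' later, in the attack engine.
#'
#' @param depth Encoder/decoder stages (default 3: a 64-px input keeps an
#'   8x8 bottleneck). Input side lengths must be divisible by `2^depth`.
#' @param base_channels First-stage channel count; doubled per stage.
#' @param skip_connections Debug flag; when off the encoder features are
#'   replaced by zeros in the decoder concatenation (weight shapes and the
#'   output shape are unchanged).
#' @param seed Weight-initialisation seed.
#' @export
generator_config <- function(depth = 3L, base_channels = 4L,
                             skip_connections = TRUE, seed = 1L) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 skip_connections = isTRUE(skip_connections),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Build a perturbation generator
#'
#' @param config A [generator_config()].
#' @param in_channels Input (and output) channels; 3 for RGB.
#' @return An object of class `perturbation_generator`.
#' @export
build_generator <- function(config = generator_config(), in_channels = 3L) {
  stopifnot(inherits(config, "generator_config"))
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
    # near-zero head init: the generator starts from an (almost) null
    # perturbation field, so early training follows the adversarial
    # gradient instead of first un-learning random texture damage
    p <- init_conv(1L, ch[1], in_channels, gain = 1e-6)
    params[["head.W"]] <- p$W
    params[["head.b"]] <- p$b
  })
  structure(list(params = params, config = config, in_channels = in_channels),
            class = "perturbation_generator")
}

# Raw perturbation field for a batch: H x W x C x B in [-1, 1].
generator_forward <- function(G, x, keep = FALSE) {
  ed_forward(G$params, G$config$depth, x, "tanh", keep = keep,
             skip_connections = G$config$skip_connections)
}

generator_backward <- function(G, fw, dout) {
  ed_backward(G$params, G$config$depth, fw, dout, "tanh",
              skip_connections = G$config$skip_connections)
}

#' Generate the raw perturbation field for one image
#'
#' Deterministic given the generator weights and the input; the Tanh head
#' guarantees values in [-1, 1] elementwise for any weights.
#'
#' @param G A `perturbation_generator`.
#' @param image H x W x 3 array on a grid divisible by `2^depth`.
#' @return H x W x 3 array in [-1, 1].
#' @export
generate_perturbation <- function(G, image) {
  stopifnot(inherits(G, "perturbation_generator"))
  stopifnot_image(image)
  x <- array(image, c(dim(image), 1L))
  generator_forward(G, x)$out[, , , 1L]
}

#' @export
print.perturbation_generator <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "perturbation_generator: depth %d, base %d channels, %d parameters, Tanh head\n",
    x$config$depth, x$config$base_channels, np))
  invisible(x)
}
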