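# Shared fixtures and the memoised end-to-end desk run.

tiny_spec <- function(seed = 7, size = 32L) {
  synthetic_spec(image_size = size, lesion_radius_range = c(5, 9), seed = seed)
}

rand_image <- function(H = 16L, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "latatk")
  with_seed(seed, array(runif(H * H * 3), c(H, H, 3)))
}

rand_mask <- function(H = 16L, seed = 1, p = 0.3) {
  with_seed <- getFromNamespace("with_seed", "latatk")
  with_seed(seed, matrix(as.numeric(runif(H * H) < p), H, H))
}

# Hand-built 1-feature-map toy model: a 1x1 identity conv ("feat"), global
# average pooling, and a dense head with weight 4*w, so the logit equals
# w * sum(A) for the 2x2 map A. Chain rule by hand: d logit / d A = w
# everywhere, channel weight a = w, CAM = relu(w * A).
toy_cam_model <- function(w = 0.7) {
  structure(list(
    layers = list(list(type = "conv", name = "feat"),
                  list(type = "gap", name = "gap"),
                  list(type = "dense", name = "fc")),
    params = list(feat.W = matrix(1, 1, 1), feat.b = 0,
                  fc.W = matrix(4 * w, 1, 1), fc.b = 0),
    normalize = "none", n_classes = 1L, last_conv = "feat"),
    class = "tiny_classifier")
}

# Independent brute-force LBP oracle: explicit loop over the 8 documented
# neighbour positions (clockwise from top-left, weights 2^0..2^7).
lbp_oracle <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0, H - 2, W - 2)
  for (i in 2:(H - 1)) {
    for (j in 2:(W - 1)) {
      code <- 0
      for (q in 1:8) {
        ni <- i + off[[q]][1]; nj <- j + off[[q]][2]
        if (gray[ni, nj] - gray[i, j] >= 0) code <- code + 2^(q - 1)
      }
      out[i - 1, j - 1] <- code
    }
  }
  out
}

# ---- End-to-end desk run (shared by the acceptance tests) ----------------
#
# Conditions, fixed once: default 64-px two-class fixtures (n = 400, spec
# seed 101); classifiers A and B trained 20 epochs (seeds 1, 2); generator
# depth 3 / base 4 (seed 3); attack = 10 epochs, eps = 0.1, batch 32,
# Adam lr 1e-2 / weight decay 1e-5, lambda = (1, 0.5), soft-LBP
# temperature 0.1, per-image normalization, ground-truth masks (seed 4);
# noise baseline seed 5.

.run6_cache <- new.env(parent = emptyenv())

run6_attack_config <- function(...) {
  attack_config(epsilon = 0.1, learning_rate = 1e-2, weight_decay = 1e-5,
                batch_size = 32L, epochs = 10L, seed = 4L, ...)
}

run6_base <- function() {
  if (is.null(.run6_cache$base)) {
    spec <- synthetic_spec(seed = 101)
    ds <- generate_samples(spec, 400)
    resA <- train_classifier(build_tiny_classifier("A", 2, seed = 1),
                             ds, epochs = 20, seed = 1)
    resB <- train_classifier(build_tiny_classifier("B", 2, seed = 2),
                             ds, epochs = 20, seed = 2)
    .run6_cache$base <- list(spec = spec, ds = ds, resA = resA, resB = resB)
  }
  .run6_cache$base
}

run6_train <- function(cfg) {
  base <- run6_base()
  G <- build_generator(generator_config(seed = 3))
  train_attack(G, base$resA$model, base$ds$masks, base$ds, cfg)
}

run6_metrics <- function(att) {
  base <- run6_base()
  ds <- base$ds
  advs <- craft(att, ds$masks, ds)
  asr <- attack_success_rate(base$resA$model, base$resA$model,
                             ds$images, advs, ds$labels)
  ssims <- vapply(seq_along(advs), function(i) {
    ssim(ds$images[, , , i], advs[[i]]$image)
  }, 0)
  list(advs = advs, asr = asr, mean_ssim = mean(ssims))
}

run6_full <- function() {
  if (is.null(.run6_cache$full)) {
    att <- run6_train(run6_attack_config())
    .run6_cache$full <- c(list(attack = att), run6_metrics(att))
  }
  .run6_cache$full
}
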