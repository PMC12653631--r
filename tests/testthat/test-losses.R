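test_that("grayscale conversion uses BT.601 luma weights", {
  gray <- array(0.42, c(4, 4, 3))
  expect_equal(to_grayscale(gray), matrix(0.42, 4, 4))
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.299, 4, 4))
  px <- array(rep(c(0.2, 0.4, 0.6), each = 4), c(2, 2, 3))
  expect_equal(to_grayscale(px), matrix(0.363, 2, 2))
  expect_error(to_grayscale(matrix(0, 4, 4)), "image")
})

test_that("hard LBP codes follow the documented bit layout", {
  expect_true(all(lbp_codes(matrix(0.5, 5, 5)) == 255))

  patch <- rbind(c(1, 2, 3), c(9, 5, 4), c(8, 7, 6)) / 10
  expect_equal(lbp_codes(patch)[1, 1], 240)
  expect_equal(lbp_oracle(patch)[1, 1], 240)

  g <- matrix(runif(64), 8, 8)
  expect_identical(lbp_codes(g), lbp_codes(g + 0.1))   # shift invariance
  expect_error(lbp_codes(matrix(0, 2, 2)), ">= 3")
})

test_that("soft LBP interpolates between 127.5 and the hard codes", {
  expect_true(all(abs(soft_lbp(matrix(0.3, 5, 5)) - 127.5) < 1e-12))

  set.seed(42)
  g <- matrix(sample(1:49) / 50, 7, 7)
  # all values distinct, so every neighbour-centre difference is at least
  # 0.02 in magnitude and a cold relaxation saturates every bit
  hard <- lbp_codes(g)
  soft_cold <- soft_lbp(g, soft_lbp_config(1e-4))
  expect_lt(max(abs(soft_cold - hard)), 1e-3)

  s <- soft_lbp(matrix(runif(36), 6, 6), soft_lbp_config(0.05))
  expect_true(all(s >= 0 & s <= 255))
  expect_error(soft_lbp_config(0), "temperature")
})

test_that("the texture loss is a mean of squared code differences", {
  x <- rand_image(8, seed = 1)
  expect_equal(lbp_loss(x, x, mode = "hard"), 0)
  expect_equal(lbp_loss(x, x, mode = "soft"), 0)

  # two constant images at different levels share the all-255 code map
  a <- array(0.3, c(6, 6, 3)); b <- array(0.7, c(6, 6, 3))
  expect_equal(lbp_loss(a, b, mode = "hard"), 0)

  # against the independent oracle on arbitrary images
  y <- rand_image(8, seed = 2)
  o <- mean((lbp_oracle(to_grayscale(x)) - lbp_oracle(to_grayscale(y)))^2)
  expect_equal(lbp_loss(x, y, mode = "hard"), o)
  expect_equal(lbp_loss(x, y, mode = "hard", reduce = "sum"), o * 36)
  expect_error(lbp_loss(x, rand_image(10, seed = 3)), "grid")
})

test_that("gradcam reproduces the hand-differentiated toy model", {
  w <- 0.7
  m <- toy_cam_model(w)
  A <- matrix(c(0.5, -0.2, 0.1, 0.8), 2, 2)
  img <- array(A, c(2, 2, 1))
  cam <- gradcam(m, img, 0, "feat")
  manual <- pmax(w * A, 0)
  expect_lt(max(abs(cam - manual)), 1e-6)

  # logit constant in the activations -> zero gradients -> zero map
  m0 <- toy_cam_model(0)
  expect_true(all(gradcam(m0, img, 0, "feat") == 0))
  expect_error(gradcam(m, img, 0, "nope"), "unknown layer")
  expect_error(gradcam(m, img, 5, "feat"), "label")
})

test_that("cam maps are non-negative and cam_loss vanishes at identity", {
  cls <- build_tiny_classifier("A", 2, seed = 3)
  img <- rand_image(32, seed = 4)
  cam <- gradcam(cls, img, 1)
  expect_true(all(cam >= 0))
  expect_equal(cam_loss(cls, img, img, 1), 0)
  expect_gte(cam_loss(cls, img, rand_image(32, seed = 5), 1), 0)

  # constant offset over all cells of the toy map -> squared offset
  w <- 1
  m <- toy_cam_model(w)
  A <- matrix(c(1, 2, 3, 4), 2, 2)
  d <- 0.25
  l <- cam_loss(m, array(A, c(2, 2, 1)), array(A + d, c(2, 2, 1)), 0, "feat")
  expect_equal(l, d^2, tolerance = 1e-10)
})

test_that("adversarial cross-entropy matches its closed forms", {
  ce <- latatk:::cross_entropy
  expect_equal(ce(matrix(c(1, 1), 2, 1), 0L), log(2))
  expect_equal(ce(matrix(log(c(0.9, 0.1)), 2, 1), 0L), -log(0.9))
  expect_lt(ce(matrix(c(30, 0), 2, 1), 0L), 1e-10)

  cls <- build_tiny_classifier("A", 2, seed = 6)
  img <- rand_image(32, seed = 7)
  lg <- latatk:::classifier_logits(cls, array(img, c(32, 32, 3, 1)))$out
  expect_equal(adv_loss(cls, img, 0), ce(lg, 0L))
})

test_that("the composed objective has the documented sign structure", {
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(2, 3, 4), -2 - 3 + 2)
  w <- loss_weights(lambda_cam = 2, lambda_lbp = 0.25)
  expect_equal(total_loss(1, 1, 4, w), -1 - 2 + 1)
  expect_gt(total_loss(1, 1, 2), total_loss(1, 1, 1))     # increasing in l_lbp
  expect_lt(total_loss(2, 1, 1), total_loss(1, 1, 1))     # decreasing in l_adv
  expect_lt(total_loss(1, 2, 1), total_loss(1, 1, 1))     # decreasing in l_cam
  expect_error(total_loss(NaN, 0, 0), "non-finite")
  expect_error(loss_weights(-1, 0), ">= 0")
})

test_that("backward passes agree with finite differences end to end", {
  # the full differentiable chain: generator -> eps-scale + mask -> clip ->
  # per-image normalization -> classifier CE + detached-weight CAM term +
  # soft LBP term. Central finite differences on a handful of generator
  # parameters.
  spec <- synthetic_spec(image_size = 16, lesion_radius_range = c(3, 5),
                         seed = 9)
  ds <- generate_samples(spec, 2)
  cls <- build_tiny_classifier("A", 2, seed = 11)
  G <- build_generator(generator_config(depth = 2, base_channels = 2, seed = 6))
  cfg <- attack_config(epsilon = 0.05, seed = 3)
  lcfg <- soft_lbp_config(0.1)

  objective <- function(params) {
    GG <- G; GG$params <- params
    tot <- 0
    for (k in 1:2) {
      x <- ds$images[, , , k]; mk <- ds$masks[, , k]; y <- ds$labels[k]
      adv <- compose_adversarial(x, generate_perturbation(GG, x), mk, cfg)$image
      la <- adv_loss(cls, adv, y)
      lc <- cam_loss(cls, x, adv, y)
      ref <- soft_lbp(to_grayscale(x), lcfg)
      ll <- mean((soft_lbp(to_grayscale(adv), lcfg) - ref)^2)
      tot <- tot + total_loss(la, lc, ll)
    }
    tot / 2
  }

  grads <- latatk:::attack_step_grads(G, cls, ds, cfg)
  set.seed(1)
  h <- 1e-5
  for (nm in c("enc1.W", "bott.W", "up2.W", "dec1.W", "head.W")) {
    i <- sample(length(G$params[[nm]]), 1)
    pp <- G$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- G$params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (objective(pp) - objective(pm)) / (2 * h)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
  }
})
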