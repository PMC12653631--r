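test_that("clip_to_ball clamps into the intersected box", {
  x <- rand_image(8, seed = 1) * 0.5 + 0.25
  expect_identical(clip_to_ball(x, x, 0.1), x)
  expect_equal(clip_to_ball(array(0.9, c(2, 2, 3)),
                            array(0.5, c(2, 2, 3)), 0.1),
               array(0.6, c(2, 2, 3)))
  expect_equal(clip_to_ball(array(-0.2, c(2, 2, 3)),
                            array(0.005, c(2, 2, 3)), 0.01),
               array(0, c(2, 2, 3)))
  expect_error(clip_to_ball(x, rand_image(10, seed = 2), 0.1), "grid")
})

test_that("masked composition preserves non-attackable pixels bit-exactly", {
  cfg <- attack_config(epsilon = 0.1)
  x <- rand_image(16, seed = 3) * 0.6 + 0.2     # interior-valued
  raw <- with(list(), {
    ws <- getFromNamespace("with_seed", "latatk")
    ws(4, array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3)))
  })

  zeros <- matrix(0, 16, 16)
  s0 <- compose_adversarial(x, raw, zeros, cfg)
  expect_identical(s0$image, x)

  ones <- matrix(1, 16, 16)
  s1 <- compose_adversarial(x, array(1, dim(x)), ones, cfg)
  expect_equal(s1$image, x + 0.1, tolerance = 1e-12)

  m <- rand_mask(16, seed = 5)
  sm <- compose_adversarial(x, raw, m, cfg)
  keep <- array(m == 0, dim(x))
  expect_identical(sm$image[keep], x[keep])
  expect_lte(max(abs(sm$image - x)), cfg$epsilon + 1e-12)

  # the "attack everywhere" ablation ignores the supplied mask
  cfg_nomask <- attack_config(epsilon = 0.1, use_mask = FALSE)
  sn <- compose_adversarial(x, raw, zeros, cfg_nomask)
  expect_gt(max(abs(sn$image - x)), 0)
  expect_true(all(sn$applied_mask == 1))

  expect_error(compose_adversarial(x, raw * 2, m, cfg), "\\[-1,1\\]")
  expect_error(compose_adversarial(x, raw, rand_mask(8, seed = 1), cfg),
               "mask grid")
})

test_that("per-channel standardisation has the documented fixed points", {
  z <- per_channel_normalize(rand_image(12, seed = 6))
  z2 <- per_channel_normalize(z)
  expect_lt(max(abs(z2 - z)), 1e-6)             # idempotent once standardised

  const <- array(0.4, c(6, 6, 3))
  expect_true(all(per_channel_normalize(const) == 0))

  half <- array(rep(c(0, 1), each = 2), c(4, 4, 3))   # equal frequency 0/1
  zh <- per_channel_normalize(half)
  expect_equal(sort(unique(round(as.vector(zh), 6))), c(-1, 1))
})

test_that("attack configuration validates its fields", {
  expect_error(attack_config(epsilon = -1), "epsilon")
  expect_error(attack_config(learning_rate = 0), "learning_rate")
  cfg <- attack_config()
  expect_equal(cfg$epsilon, 0.01)
  expect_equal(cfg$learning_rate, 5e-5)
  expect_equal(cfg$weight_decay, 1e-5)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$weights$lambda_cam, 1)
  expect_equal(cfg$weights$lambda_lbp, 0.5)
})

test_that("attack training is deterministic, frozen-surrogate and ablatable", {
  spec <- tiny_spec(seed = 23)
  ds <- generate_samples(spec, 16)
  res <- train_classifier(build_tiny_classifier("A", 2, seed = 2), ds,
                          epochs = 2, seed = 5)
  cls <- res$model
  cls_before <- cls$params
  cfg <- attack_config(epsilon = 0.1, learning_rate = 1e-2, epochs = 2,
                       batch_size = 8, seed = 6)
  mkG <- function() build_generator(generator_config(seed = 7))

  a1 <- train_attack(mkG(), cls, ds$masks, ds, cfg)
  a2 <- train_attack(mkG(), cls, ds$masks, ds, cfg)
  expect_identical(a1$generator$params, a2$generator$params)
  expect_identical(a1$history, a2$history)
  expect_identical(cls$params, cls_before)
  expect_named(a1$history,
               c("step", "epoch", "l_adv", "l_cam", "l_lbp", "total"))

  # adversarial-only ablation: no cam / lbp columns in the history
  cfg_adv <- attack_config(epsilon = 0.1, learning_rate = 1e-2, epochs = 1,
                           batch_size = 8, seed = 6,
                           use_lbp = FALSE, use_cam = FALSE)
  a3 <- train_attack(mkG(), cls, ds$masks, ds, cfg_adv)
  expect_named(a3$history, c("step", "epoch", "l_adv", "total"))
  expect_equal(a3$history$total, -a3$history$l_adv)
})

test_that("crafted samples satisfy the adversarial-sample invariants", {
  spec <- tiny_spec(seed = 25)
  ds <- generate_samples(spec, 6)
  G <- build_generator(generator_config(seed = 8))
  cfg <- attack_config(epsilon = 0.1)
  att <- structure(list(generator = G, config = cfg), class = "latatk_attack")
  advs <- craft(att, ds$masks, ds)
  for (i in seq_along(advs)) {
    a <- advs[[i]]
    keep <- array(a$applied_mask == 0, dim(a$image))
    expect_identical(a$image[keep], ds$images[, , , i][keep])
    expect_lte(max(abs(a$image - ds$images[, , , i])), cfg$epsilon + 1e-12)
    expect_true(all(a$image >= 0 & a$image <= 1))
  }

  # degenerate bound: eps = 0 reproduces the inputs exactly
  att0 <- structure(list(generator = G, config = attack_config(epsilon = 0)),
                    class = "latatk_attack")
  advs0 <- craft(att0, ds$masks, ds)
  for (i in seq_along(advs0)) {
    expect_identical(advs0[[i]]$image, ds$images[, , , i])
  }

  # writing: PNG quantisation moves pixels by at most one level
  dir <- withr::local_tempdir()
  craft(att, ds$masks, ds, out_dir = dir)
  expect_true(file.exists(file.path(dir, "attack_meta.json")))
  back <- read_image_png(file.path(dir, "adv_0000.png"))
  expect_lte(max(abs(back - advs[[1]]$image)), 1 / 255)
})

test_that("attack training lifts the adversarial loss on fixtures", {
  spec <- tiny_spec(seed = 27)
  ds <- generate_samples(spec, 32)
  res <- train_classifier(build_tiny_classifier("A", 2, seed = 3), ds,
                          epochs = 12, seed = 5, batch_size = 8)
  cfg <- attack_config(epsilon = 0.1, learning_rate = 1e-2, epochs = 6,
                       batch_size = 8, seed = 9,
                       use_lbp = FALSE, use_cam = FALSE)
  att <- train_attack(build_generator(generator_config(seed = 4)),
                      res$model, ds$masks, ds, cfg)
  h <- att$history
  expect_gt(mean(h$l_adv[h$epoch == max(h$epoch)]),
            mean(h$l_adv[h$epoch == 1]))
})
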