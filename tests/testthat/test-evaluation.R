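test_that("attack success rate counts per the printed definition", {
  asr <- latatk:::asr_count
  expect_equal(asr(rep(TRUE, 10), rep(TRUE, 10)), 100)
  expect_equal(asr(rep(TRUE, 10), rep(FALSE, 10)), 0)

  # 10 samples, 8 surrogate-correct, 5 of those fooled: the printed
  # formula divides by the full set
  correct <- c(rep(TRUE, 8), rep(FALSE, 2))
  fooled <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(asr(correct, fooled), 50)
  expect_equal(asr(correct, fooled, denominator = "surrogate_correct"),
               100 * 5 / 8)

  # monotone: flipping one more surrogate-correct sample never lowers it
  fooled2 <- fooled; fooled2[6] <- TRUE
  expect_gte(asr(correct, fooled2), asr(correct, fooled))
  expect_error(asr(TRUE, logical(0)), "length")
  expect_error(asr(logical(0), logical(0)), "empty")
})

test_that("global SSIM matches closed forms and its invariants", {
  img <- generate_lesion_sample(tiny_spec(seed = 29), 0)$image
  expect_identical(ssim(img, img), 1)

  # constant images: variance terms cancel to c2/c2, luminance term remains
  a <- matrix(0.5, 8, 8); b <- matrix(0.25, 8, 8)
  p <- ssim_params(c1 = 1e-4)
  expect_equal(ssim(a, b, p), (2 * 0.5 * 0.25 + 1e-4) / (0.5^2 + 0.25^2 + 1e-4))
  expect_equal(ssim(a, b, p), 0.800064, tolerance = 1e-6)

  x <- rand_image(16, seed = 30)
  y <- rand_image(16, seed = 31)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_gte(ssim(x, y), -1)
  expect_lte(ssim(x, y), 1)

  # global statistics are permutation invariant under a shared shuffle
  set.seed(7)
  perm <- sample(16 * 16)
  xp <- x; yp <- y
  for (ch in 1:3) {
    xp[, , ch] <- matrix(as.vector(x[, , ch])[perm], 16, 16)
    yp[, , ch] <- matrix(as.vector(y[, , ch])[perm], 16, 16)
  }
  expect_equal(ssim(xp, yp), ssim(x, y), tolerance = 1e-12)

  # windowed mode: exact identity at equality, penalises local structure loss
  pw <- ssim_params(mode = "windowed")
  expect_equal(ssim(x, x, pw), 1)
  expect_lt(ssim(x, y, pw), 1)
  expect_error(ssim(x, rand_image(8, seed = 1)), "grid")
  expect_error(ssim_params(c1 = 0), "c1")
})

test_that("cam heatmaps are rendered at image resolution", {
  cls <- build_tiny_classifier("A", 2, seed = 5)
  img <- generate_lesion_sample(tiny_spec(seed = 33), 0)$image
  f <- withr::local_tempfile(fileext = ".png")
  export_cam_heatmap(cls, img, 1, out_path = f)
  out <- png::readPNG(f)
  expect_equal(dim(out)[1:2], dim(img)[1:2])

  # an all-zero map blends to the pure original image
  m0 <- toy_cam_model(0)
  img2 <- array(matrix(runif(4), 2, 2), c(2, 2, 1))
  f2 <- withr::local_tempfile(fileext = ".png")
  export_cam_heatmap(m0, img2, 0, "feat", out_path = f2)
  # grayscale single-channel toy: the writer saw identical content
  expect_lte(max(abs(png::readPNG(f2) - img2[, , 1])), 1 / 255)
})

test_that("transfer evaluation aggregates per-target rates", {
  spec <- tiny_spec(seed = 35)
  ds <- generate_samples(spec, 12)
  resA <- train_classifier(build_tiny_classifier("A", 2, seed = 1), ds,
                           epochs = 2, seed = 2)
  resB <- train_classifier(build_tiny_classifier("B", 2, seed = 3), ds,
                           epochs = 2, seed = 2)
  G <- build_generator(generator_config(seed = 5))
  cfg <- attack_config(epsilon = 0.1, learning_rate = 1e-2, epochs = 1,
                       batch_size = 8, seed = 6)
  att <- train_attack(G, resA$model, ds$masks, ds, cfg)

  dir <- withr::local_tempdir()
  rep <- evaluate_transfer(att, ds$masks,
                           list(A = resA$model, B = resB$model), ds,
                           out_dir = dir)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$table), 3)                 # A, B, Ensemble
  expect_equal(rep$table$asr[rep$table$target == "Ensemble"],
               mean(rep$table$asr[rep$table$target != "Ensemble"]))
  expect_equal(rep$avg_asr,
               mean(rep$table$asr[rep$table$target != "Ensemble"]))
  expect_true(all(rep$table$asr >= 0 & rep$table$asr <= 100))
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))

  # independent recomputation of the white-box row from per-sample records
  ps <- rep$per_sample
  expect_equal(rep$table$asr[rep$table$target == "A"],
               100 * mean(ps$surrogate_correct & ps$fooled_A))

  # self-transfer only: a single target row equals the white-box rate
  rep1 <- evaluate_transfer(att, ds$masks, list(A = resA$model), ds)
  expect_equal(nrow(rep1$table), 2)
  expect_equal(rep1$avg_asr, rep1$table$asr[1])
  expect_error(evaluate_transfer(att, ds$masks, list(), ds), "empty")

  # the degenerate eps = 0 attack fools nothing and is invisible
  att0 <- att
  att0$config <- attack_config(epsilon = 0, learning_rate = 1e-2)
  rep0 <- evaluate_transfer(att0, ds$masks, list(A = resA$model), ds)
  expect_equal(rep0$table$asr[1], 0)
  expect_equal(rep0$mean_ssim, 1)
})

test_that("a trained masked attack beats epsilon-matched masked noise", {
  spec <- tiny_spec(seed = 37)
  ds <- generate_samples(spec, 48)
  res <- train_classifier(build_tiny_classifier("A", 2, seed = 2), ds,
                          epochs = 12, seed = 3, batch_size = 8)
  cfg <- attack_config(epsilon = 0.1, learning_rate = 1e-2, epochs = 6,
                       batch_size = 8, seed = 4,
                       use_lbp = FALSE, use_cam = FALSE)
  att <- train_attack(build_generator(generator_config(seed = 5)),
                      res$model, ds$masks, ds, cfg)
  advs <- craft(att, ds$masks, ds)
  noise <- craft_noise_baseline(ds$masks, ds, cfg, seed = 6)
  asr_att <- attack_success_rate(res$model, res$model, ds$images, advs,
                                 ds$labels)
  asr_noise <- attack_success_rate(res$model, res$model, ds$images, noise,
                                   ds$labels)
  expect_gt(asr_att, asr_noise)
})
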