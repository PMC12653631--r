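test_that("sample generation is a pure function of spec and index", {
  spec <- tiny_spec(seed = 3)
  s1 <- generate_lesion_sample(spec, 0)
  s2 <- generate_lesion_sample(spec, 0)
  expect_identical(s1, s2)
  s3 <- generate_lesion_sample(spec, 1)
  expect_false(identical(s1$image, s3$image))
})

test_that("labels follow the masked-mean intensity rule", {
  spec <- tiny_spec(seed = 5)
  for (i in 0:7) {
    s <- generate_lesion_sample(spec, i)
    inside <- s$mask == 1
    mm <- mean(vapply(1:3, function(ch) mean(s$image[, , ch][inside]), 0))
    expect_identical(s$label, as.integer(mm > 0.55))
  }
})

test_that("samples satisfy the image and mask invariants", {
  spec <- tiny_spec(seed = 9)
  for (i in 0:4) {
    s <- generate_lesion_sample(spec, i)
    expect_true(all(s$mask %in% c(0, 1)))
    expect_gte(sum(s$mask), 1)
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(s$label %in% 0:1)
  }
})

test_that("infeasible lesion radii are rejected at spec construction", {
  expect_error(synthetic_spec(image_size = 16, lesion_radius_range = c(4, 10)),
               "radius")
  expect_error(synthetic_spec(image_size = 8), "image_size")
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
})

test_that("written datasets are balanced and round-trip losslessly", {
  spec <- tiny_spec(seed = 11)
  dir <- withr::local_tempdir()
  man <- generate_dataset(spec, 8, dir)
  expect_equal(nrow(man), 8)
  expect_equal(as.integer(table(man$label)), c(4L, 4L))
  expect_true(file.exists(file.path(dir, "spec.json")))

  s1 <- generate_lesion_sample(spec, 0)
  reread <- read_mask_png(file.path(dir, man$mask_filename[1]))
  expect_identical(reread, s1$mask)
  img_back <- read_image_png(file.path(dir, man$filename[1]))
  expect_lte(max(abs(img_back - s1$image)), 1 / 255)

  man2 <- read_manifest(dir)
  expect_equal(man2$label, man$label)
  ds <- latatk:::as_dataset(man2)
  expect_equal(dim(ds$images), c(32, 32, 3, 8))

  man1 <- generate_dataset(spec, 1, withr::local_tempdir())
  expect_equal(nrow(man1), 1)
})

test_that("tiny classifier architectures are distinct and expose CAM hooks", {
  A <- build_tiny_classifier("A", 3, seed = 1)
  B <- build_tiny_classifier("B", 3, seed = 1)
  npar <- function(m) sum(vapply(m$params, length, 0L))
  expect_false(npar(A) == npar(B))
  expect_error(build_tiny_classifier("C"), "arg")

  x <- rand_image(32, seed = 2)
  la <- latatk:::classifier_logits(A, array(x, c(32, 32, 3, 1)))$out
  lb <- latatk:::classifier_logits(B, array(x, c(32, 32, 3, 1)))$out
  expect_equal(dim(la), c(3L, 1L))
  expect_equal(dim(lb), c(3L, 1L))

  for (m in list(A, B)) {
    hook <- last_conv_layer(m)
    act <- latatk:::net_activation(m, array(x, c(32, 32, 3, 1)), hook)
    expect_length(dim(act), 4)
  }
})

test_that("an untrained classifier sits at chance on a balanced holdout", {
  spec <- tiny_spec(seed = 13)
  ds <- generate_samples(spec, 40)
  m <- build_tiny_classifier("A", 2, seed = 3)
  acc <- mean(predict(m, ds$images) == ds$labels)
  expect_gte(acc, 0.5 - 0.15)
  expect_lte(acc, 0.5 + 0.15)
})

test_that("classifier training is deterministic and rejects one-class data", {
  spec <- tiny_spec(seed = 15)
  ds <- generate_samples(spec, 48)
  r1 <- train_classifier(build_tiny_classifier("A", 2, seed = 2), ds,
                         epochs = 2, seed = 5)
  r2 <- train_classifier(build_tiny_classifier("A", 2, seed = 2), ds,
                         epochs = 2, seed = 5)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$holdout_accuracy, r2$holdout_accuracy)

  ds0 <- ds
  keep <- ds0$labels == 0
  ds0$images <- ds0$images[, , , keep, drop = FALSE]
  ds0$masks <- ds0$masks[, , keep, drop = FALSE]
  ds0$labels <- ds0$labels[keep]
  m <- build_tiny_classifier("A", 2, seed = 2)
  expect_error(train_classifier(m, ds0, epochs = 1, seed = 1), "2 classes")
})

test_that("shuffling pixels outside the mask leaves the rule label unchanged", {
  spec <- tiny_spec(seed = 17)
  for (i in 0:3) {
    s <- generate_lesion_sample(spec, i)
    out <- s$mask == 0
    img <- s$image
    set.seed(100 + i)
    perm <- sample(sum(out))
    for (ch in 1:3) {
      v <- img[, , ch][out]
      img[, , ch][out] <- v[perm]
    }
    expect_identical(latatk:::compute_rule_label(spec, img, s$mask), s$label)
  }
})
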