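#' Specification for synthetic lesion images
#'
#' Describes a reproducible synthetic dermoscopy-like dataset: a textured
#' elliptical lesion on a lower-frequency textured background, with the
#' class label carried entirely by a lesion property. The defaults give a
#' learnable, mask-localised decision signal: lesion mean intensity falls
#' in disjoint per-class bands around a midpoint threshold, so the label is
#' recoverable from the masked mean alone.
#'
#' @param image_size Side length of the square image in pixels (>= 16).
#' @param lesion_radius_range Numeric length-2, min and max ellipse radius
#'   in pixels; the maximum must be below `image_size / 2`.
#' @param lesion_texture_freq Sinusoidal lesion texture frequency in
#'   cycles per image.
#' @param background_texture_freq Background texture frequency in cycles
#'   per image (lower than the lesion's by default).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on
#'   the [0,1] intensity scale.
#' @param n_classes Number of classes (>= 2).
#' @param class_rule How the label is derived from the lesion:
#'   `"by_mean_intensity"` (mean image intensity inside the mask falls into
#'   one of `n_classes` disjoint bands) or `"by_texture_freq"` (the lesion
#'   texture frequency falls into per-class bands).
#' @param seed Integer seed; identical spec + seed yields a bit-identical
#'   dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 64L,
                           lesion_radius_range = c(8, 16),
                           lesion_texture_freq = 12,
                           background_texture_freq = 3,
                           noise_sd = 0.05,
                           n_classes = 2L,
                           class_rule = c("by_mean_intensity", "by_texture_freq"),
                           seed = 1L) {
  class_rule <- match.arg(class_rule)
  image_size <- as.integer(image_size)
  n_classes <- as.integer(n_classes)
  if (image_size < 16L) stop("image_size must be >= 16")
  if (length(lesion_radius_range) != 2L ||
      lesion_radius_range[1] > lesion_radius_range[2]) {
    stop("lesion_radius_range must be c(min, max) with min <= max")
  }
  if (max(lesion_radius_range) >= image_size / 2) {
    stop("maximum lesion radius must be < image_size / 2")
  }
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(image_size = image_size,
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_texture_freq = lesion_texture_freq,
                 background_texture_freq = background_texture_freq,
                 noise_sd = noise_sd,
                 n_classes = n_classes,
                 class_rule = class_rule,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Per-class lesion intensity bands on [0.30, 0.80], with an inner margin so
# texture + noise cannot move the masked mean across a band edge. The rule
# thresholds are the band boundaries; for 2 classes the threshold is the
# midpoint 0.55.
class_intensity_bands <- function(n_classes, margin = 0.03) {
  edges <- seq(0.30, 0.80, length.out = n_classes + 1L)
  list(edges = edges,
       lo = edges[-length(edges)] + margin,
       hi = edges[-1L] - margin)
}

# Rule thresholds used to recover the label from the masked mean.
rule_thresholds <- function(spec) {
  class_intensity_bands(spec$n_classes)$edges[2:spec$n_classes]
}

#' Generate one synthetic lesion sample
#'
#' A pure function of (spec, index): the same arguments always return a
#' bit-identical sample. The lesion is an ellipse with sinusoidal texture;
#' the background carries a lower-frequency texture; Gaussian noise is
#' added and the image clipped to [0, 1]. The label is computed from the
#' finished image via the spec's class rule, never assigned directly.
#'
#' @param spec A [synthetic_spec()].
#' @param index Sample index (>= 0); `index %% n_classes` selects the
#'   target class band so that sequential indices yield balanced classes.
#' @return A list with elements `image` (H x W x 3 in [0,1]), `mask`
#'   (H x W in {0,1}, the lesion support) and `label` (integer in
#'   `[0, n_classes)`).
#' @export
generate_lesion_sample <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size
  target <- as.integer(index) %% spec$n_classes
  bands <- class_intensity_bands(spec$n_classes)
  with_seed(derive_seed(spec$seed, index), {
    ii <- matrix(seq_len(H), H, H)
    jj <- matrix(seq_len(H), H, H, byrow = TRUE)

    # lesion geometry
    cx <- H / 2 + runif(1, -H / 8, H / 8)
    cy <- H / 2 + runif(1, -H / 8, H / 8)
    ra <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    rb <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    ang <- runif(1, 0, pi)
    dx <- ii - cx
    dy <- jj - cy
    u <- (dx * cos(ang) + dy * sin(ang)) / ra
    v <- (-dx * sin(ang) + dy * cos(ang)) / rb
    mask <- (u * u + v * v <= 1) * 1

    # class-carrying lesion properties
    les_base <- runif(1, bands$lo[target + 1L], bands$hi[target + 1L])
    les_freq <- if (spec$class_rule == "by_texture_freq") {
      spec$lesion_texture_freq * (1 + target)
    } else {
      spec$lesion_texture_freq
    }

    # textures (zero-mean sinusoids so the masked mean stays in its band)
    th_b <- runif(1, 0, pi); ph_b <- runif(1, 0, 2 * pi)
    th_l <- runif(1, 0, pi); ph_l <- runif(1, 0, 2 * pi)
    bg_tex <- 0.07 * sin(2 * pi * spec$background_texture_freq *
                           (ii * cos(th_b) + jj * sin(th_b)) / H + ph_b)
    les_tex <- 0.10 * sin(2 * pi * les_freq *
                            (ii * cos(th_l) + jj * sin(th_l)) / H + ph_l)

    bg <- 0.55 + bg_tex
    les <- les_base + les_tex
    field <- bg * (1 - mask) + les * mask

    tint <- c(0.03, 0, -0.03)    # mild reddish cast, zero-sum across channels
    img <- array(0, c(H, H, 3))
    for (ch in 1:3) {
      img[, , ch] <- field + tint[ch] * mask +
        rnorm(H * H, sd = spec$noise_sd)
    }
    img <- clip01(img)

    label <- compute_rule_label(spec, img, mask, les_freq)
    list(image = img, mask = mask, label = label)
  })
}

# Label from the class rule. For by_mean_intensity this is the mean image
# intensity (all channels) inside the mask against the band thresholds; for
# by_texture_freq it is the generated lesion frequency against the
# midpoints between per-class frequencies.
compute_rule_label <- function(spec, image, mask, les_freq = NULL) {
  if (spec$class_rule == "by_mean_intensity") {
    inside <- mask == 1
    m <- mean(vapply(1:3, function(ch) mean(image[, , ch][inside]), 0))
    as.integer(findInterval(m, rule_thresholds(spec)))
  } else {
    freqs <- spec$lesion_texture_freq * seq_len(spec$n_classes)
    mids <- (freqs[-1L] + freqs[-length(freqs)]) / 2
    as.integer(findInterval(les_freq, mids))
  }
}

#' Generate an in-memory synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of samples (indices `0:(n-1)`, so classes are balanced
#'   whenever `n` is divisible by `n_classes`).
#' @return A dataset list: `images` (H x W x 3 x n), `masks` (H x W x n),
#'   `labels` (integer vector, 0-based), `spec`.
#' @export
generate_samples <- function(spec, n) {
  stopifnot(n >= 1)
  samples <- lapply(0:(n - 1L), function(i) generate_lesion_sample(spec, i))
  list(images = stack_images(lapply(samples, `[[`, "image")),
       masks = stack_masks(lapply(samples, `[[`, "mask")),
       labels = vapply(samples, `[[`, integer(1), "label"),
       spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Writes `n` 8-bit RGB PNG images, `n` single-channel 0/255 mask PNGs, a
#' CSV manifest (`filename`, `mask_filename`, `label`) and a JSON sidecar
#' holding the spec.
#'
#' @inheritParams generate_samples
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame, invisibly carrying the directory
#'   in attribute `"dir"`.
#' @export
generate_dataset <- function(spec, n, out_dir) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_lesion_sample(spec, i - 1L)
    fn <- sprintf("img_%04d.png", i - 1L)
    mfn <- sprintf("mask_%04d.png", i - 1L)
    write_image_png(s$image, file.path(out_dir, fn))
    write_mask_png(s$mask, file.path(out_dir, mfn))
    rows[[i]] <- data.frame(filename = fn, mask_filename = mfn,
                            label = s$label, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path Path to the manifest CSV (or the directory containing
#'   `manifest.csv`).
#' @return Manifest data.frame with attribute `"dir"`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(manifest, "dir") <- dirname(path)
  manifest
}

# Coerce a manifest data.frame or in-memory dataset list to the internal
# dataset form (images/masks/labels arrays).
as_dataset <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$images)) return(x)
  if (is.data.frame(x)) {
    dir <- attr(x, "dir")
    if (is.null(dir)) stop("manifest lacks a 'dir' attribute; use read_manifest()")
    imgs <- lapply(x$filename, function(f) read_image_png(file.path(dir, f)))
    masks <- lapply(x$mask_filename, function(f) read_mask_png(file.path(dir, f)))
    return(list(images = stack_images(imgs),
                masks = stack_masks(masks),
                labels = as.integer(x$label)))
  }
  stop("expected a manifest data.frame or an in-memory dataset list")
}
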