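# Evaluation: attack success rate (strength/transferability), SSIM
# (concealment), CAM heatmap export, and transfer-table aggregation.

#' SSIM parameters
#'
#' Stabilisers default to `(0.01 L)^2` and `(0.03 L)^2` with dynamic range
#' L = 1 (images on the [0,1] scale). `mode = "global"` computes one
#' statistic set over the whole image; `"windowed"` averages the index
#' over 11x11 Gaussian-weighted sliding windows (sigma 1.5), the
#' conventional mean-SSIM.
#'
#' @param c1,c2 Positive stabilising constants.
#' @param mode `"global"` or `"windowed"`.
#' @export
ssim_params <- function(c1 = 0.01^2, c2 = 0.03^2,
                        mode = c("global", "windowed")) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be > 0")
  structure(list(c1 = c1, c2 = c2, mode = match.arg(mode)),
            class = "ssim_params")
}

ssim_stat <- function(a, b, c1, c2) {
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2)
  vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable same-size Gaussian filtering of a matrix (edge-replicated).
gauss_filter <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(rep(1L, r), seq_len(H), rep(H, r)),
           c(rep(1L, r), seq_len(W), rep(W, r))]
  tmp <- matrix(0, H, ncol(pad))
  for (t in seq_along(k)) tmp <- tmp + k[t] * pad[(t):(t + H - 1L), ]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * tmp[, (t):(t + W - 1L)]
  out
}

ssim_windowed <- function(a, b, c1, c2) {
  k <- gaussian_kernel_1d()
  mu_a <- gauss_filter(a, k)
  mu_b <- gauss_filter(b, k)
  va <- gauss_filter(a * a, k) - mu_a^2
  vb <- gauss_filter(b * b, k) - mu_b^2
  cab <- gauss_filter(a * b, k) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Structural similarity index between two images
#'
#' Single-channel signals are compared directly; colour images are
#' compared per channel and the channel SSIMs averaged. The result lies in
#' [-1, 1], with 1 attained iff the images are identical.
#'
#' @param a,b Matrices or H x W x C arrays on the same grid, [0,1] scale.
#' @param params An [ssim_params()].
#' @export
ssim <- function(a, b, params = ssim_params()) {
  if (!all(dim(a) == dim(b))) stop("image grids differ")
  f <- if (params$mode == "global") {
    function(x, y) ssim_stat(x, y, params$c1, params$c2)
  } else {
    function(x, y) ssim_windowed(x, y, params$c1, params$c2)
  }
  if (length(dim(a)) == 2L) return(f(a, b))
  mean(vapply(seq_len(dim(a)[3]),
              function(ch) f(a[, , ch], b[, , ch]), 0))
}

# Eq-style counting: percentage of samples that are surrogate-correct AND
# target-fooled, over the chosen denominator.
asr_count <- function(surrogate_correct, target_fooled,
                      denominator = c("all", "surrogate_correct")) {
  denominator <- match.arg(denominator)
  if (length(surrogate_correct) != length(target_fooled)) {
    stop("flag vectors differ in length")
  }
  if (length(surrogate_correct) == 0L) stop("empty sample set")
  num <- sum(surrogate_correct & target_fooled)
  den <- if (denominator == "all") length(target_fooled)
         else sum(surrogate_correct)
  if (den == 0L) return(0)
  100 * num / den
}

#' Attack success rate
#'
#' Percentage of adversarial samples whose clean original is classified
#' correctly by the surrogate F while the adversarial version fools the
#' target H: `100 * |{i: F(x_i) = y_i and H(x_adv_i) != y_i}| / n`. The
#' denominator is the full adversarial set, following the printed
#' definition; the alternative convention (only F-correct samples) is
#' available via `denominator = "surrogate_correct"`. H = F measures
#' white-box strength, H != F transferability.
#'
#' @param F_model Surrogate classifier.
#' @param H_model Target classifier.
#' @param originals H x W x 3 x n array (or list of images).
#' @param adversarials List of `adversarial_sample` objects, list of
#'   images, or an H x W x 3 x n array.
#' @param labels True labels (0-based), length n.
#' @param denominator `"all"` (printed definition) or
#'   `"surrogate_correct"`.
#' @return Percentage in [0, 100].
#' @export
attack_success_rate <- function(F_model, H_model, originals, adversarials,
                                labels,
                                denominator = c("all", "surrogate_correct")) {
  xo <- as_image_batch(originals)
  xa <- as_image_batch(adversarials)
  n <- dim(xo)[4]
  if (dim(xa)[4] != n || length(labels) != n) stop("length mismatch")
  pf <- predict(F_model, xo)
  ph <- predict(H_model, xa)
  asr_count(pf == labels, ph != labels, match.arg(denominator))
}

as_image_batch <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (is.list(x)) {
    imgs <- lapply(x, function(e) {
      if (inherits(e, "adversarial_sample")) e$image else e
    })
    return(stack_images(imgs))
  }
  if (is.array(x) && length(dim(x)) == 3L) return(array(x, c(dim(x), 1L)))
  stop("cannot interpret images")
}

#' Export a Grad-CAM heatmap overlay as a PNG
#'
#' The CAM is min-max normalised to [0,1] (an all-constant map becomes
#' all-zero weight, leaving the pure image), upsampled to the image grid,
#' mapped through a red-hot colormap and alpha-blended over the image.
#'
#' @inheritParams gradcam
#' @param out_path PNG output path.
#' @param alpha Global overlay opacity in (0,1].
#' @return `out_path`, invisibly.
#' @export
export_cam_heatmap <- function(model, image, label, layer_name = NULL,
                               out_path, alpha = 0.5) {
  cam <- gradcam(model, image, label, layer_name)
  rng <- range(cam)
  v <- if (diff(rng) < 1e-12) cam * 0 else (cam - rng[1]) / diff(rng)
  fac <- nrow(image) / nrow(v)
  vup <- kronecker(v, matrix(1, fac, fac))
  ramp <- grDevices::colorRamp(c("black", "red", "yellow", "white"))
  cols <- ramp(as.vector(vup)) / 255
  out <- array(0, dim(image))
  w <- alpha * vup
  for (ch in seq_len(dim(image)[3])) {
    heat <- matrix(cols[, min(ch, 3L)], nrow(vup), ncol(vup))
    out[, , ch] <- (1 - w) * image[, , ch] + w * heat
  }
  png::writePNG(clip01(if (dim(out)[3] == 1L) out[, , 1L] else out), out_path)
  invisible(out_path)
}

#' Transfer evaluation report
#'
#' Crafts adversarials once with the trained attack, then scores every
#' surrogate-to-target pair by attack success rate plus an "Ensemble" row
#' (the mean of the per-target ASRs), and the mean SSIM over
#' (original, adversarial) pairs. Optionally writes the report as CSV and
#' JSON.
#'
#' @param attack A `latatk_attack`.
#' @param mask_source As in [train_attack()].
#' @param targets Named list of target classifiers.
#' @param data Manifest or in-memory dataset.
#' @param out_dir Optional report directory.
#' @param ssim_pars An [ssim_params()].
#' @return An `eval_report` list: `table` (one row per target + Ensemble),
#'   `avg_asr`, `mean_ssim`, `per_sample`.
#' @export
evaluate_transfer <- function(attack, mask_source, targets, data,
                              out_dir = NULL, ssim_pars = ssim_params()) {
  stopifnot(inherits(attack, "latatk_attack"))
  if (length(targets) == 0L) stop("empty target list")
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  ds <- as_dataset(data)
  n <- dim(ds$images)[4]
  advs <- craft(attack, mask_source, ds)
  xa <- as_image_batch(advs)
  surrogate <- attack$surrogate
  pf <- predict(surrogate, ds$images)
  correct <- pf == ds$labels
  ssims <- vapply(seq_len(n), function(i) {
    ssim(ds$images[, , , i], xa[, , , i], ssim_pars)
  }, 0)
  rows <- list()
  per_sample <- data.frame(index = seq_len(n), label = ds$labels,
                           surrogate_correct = correct, ssim = ssims)
  asrs <- numeric(0)
  for (nm in names(targets)) {
    ph <- predict(targets[[nm]], xa)
    fooled <- ph != ds$labels
    a <- asr_count(correct, fooled)
    asrs[nm] <- a
    per_sample[[paste0("fooled_", nm)]] <- fooled
    rows[[nm]] <- data.frame(surrogate = surrogate$arch, target = nm,
                             asr = a, mean_ssim = mean(ssims))
  }
  rows[["Ensemble"]] <- data.frame(surrogate = surrogate$arch,
                                   target = "Ensemble",
                                   asr = mean(asrs),
                                   mean_ssim = mean(ssims))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  report <- structure(list(table = tab, avg_asr = mean(asrs),
                           mean_ssim = mean(ssims),
                           per_sample = per_sample),
                      class = "eval_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(per_sample, file.path(out_dir, "per_sample.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(avg_asr = report$avg_asr,
                              mean_ssim = report$mean_ssim),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Transfer evaluation\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Avg_ASR %.2f%%, mean SSIM %.4f over %d samples\n",
              x$avg_asr, x$mean_ssim, nrow(x$per_sample)))
  invisible(x)
}
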