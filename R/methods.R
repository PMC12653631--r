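# S3 methods for the fitted attack object.

#' @export
print.latatk_attack <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "latatk_attack: generator trained %d epochs on %d samples (eps = %g)\n",
    cfg$epochs, x$n_samples, cfg$epsilon))
  cat(sprintf("  flags: mask %s, cam %s, lbp %s; lambda = (%g, %g)\n",
              cfg$use_mask, cfg$use_cam, cfg$use_lbp,
              cfg$weights$lambda_cam, cfg$weights$lambda_lbp))
  invisible(x)
}

#' @export
summary.latatk_attack <- function(object, ...) {
  h <- object$history
  first <- h[h$epoch == min(h$epoch), , drop = FALSE]
  last <- h[h$epoch == max(h$epoch), , drop = FALSE]
  out <- list(config = object$config,
              steps = nrow(h),
              l_adv_first_epoch = mean(first$l_adv),
              l_adv_last_epoch = mean(last$l_adv),
              total_last_epoch = mean(last$total))
  class(out) <- "summary.latatk_attack"
  out
}

#' @export
print.summary.latatk_attack <- function(x, ...) {
  cat(sprintf("Attack training: %d optimiser steps\n", x$steps))
  cat(sprintf("  adversarial CE, first -> last epoch: %.4f -> %.4f\n",
              x$l_adv_first_epoch, x$l_adv_last_epoch))
  cat(sprintf("  composed objective, last epoch: %.4f\n",
              x$total_last_epoch))
  invisible(x)
}

#' Craft adversarial samples from a fitted attack
#'
#' @param object A `latatk_attack`.
#' @param mask_source As in [train_attack()].
#' @param data Manifest or in-memory dataset.
#' @param ... Passed to [craft()] (e.g. `out_dir`).
#' @export
predict.latatk_attack <- function(object, mask_source, data, ...) {
  craft(object, mask_source, data, ...)
}

#' Loss-history curves of a fitted attack
#'
#' @param x A `latatk_attack`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.latatk_attack <- function(x, ...) {
  h <- x$history
  cols <- intersect(c("l_adv", "l_cam", "l_lbp", "total"), names(h))
  graphics::matplot(h$step, as.matrix(h[cols]), type = "l", lty = 1,
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Generator parameters of a fitted attack as a flat vector
#' @param object A `latatk_attack`.
#' @param ... Unused.
#' @export
coef.latatk_attack <- function(object, ...) {
  unlist(object$generator$params)
}
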