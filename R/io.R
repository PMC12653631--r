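# PNG and checkpoint I/O.

#' Write an RGB image as an 8-bit PNG
#' @param image H x W x 3 array in [0,1].
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  stopifnot_image(image)
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' Read an RGB PNG as an H x W x 3 array in [0,1]
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3]
  }
  img
}

#' Write a binary mask as a single-channel 0/255 PNG
#' @param mask H x W matrix with values in {0,1}; 1 marks the attackable
#'   (lesion) region.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a {0,1} matrix
#'
#' Rejects files containing any value other than 0 or 255.
#' @param path PNG path.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (any(m != 0 & m != 1)) {
    stop("mask PNG contains values other than 0 and 255: ", path)
  }
  m * 1
}

#' Save network weights to a checkpoint file
#'
#' Single-file checkpoint holding the configuration and all parameters;
#' [load_checkpoint()] validates that the stored object kind matches.
#' @param object A classifier, segmenter, generator or attack object.
#' @param path Output path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint path.
#' @param expect_class Optional class the object must have.
#' @export
load_checkpoint <- function(path, expect_class = NULL) {
  obj <- readRDS(path)
  if (!is.null(expect_class) && !inherits(obj, expect_class)) {
    stop("checkpoint at ", path, " is not a ", expect_class, " object")
  }
  obj
}
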