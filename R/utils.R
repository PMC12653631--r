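# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`; restores the
# caller's .Random.seed so fixture generation stays a pure function.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a per-item seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) + as.double(index) * 10007 + as.double(salt) * 7919) %%
               .Machine$integer.max)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 image array", call. = FALSE)
  }
  invisible(image)
}

# Stack a list of HxWx3 images into an H x W x 3 x N batch array.
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

stack_masks <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0, c(d, length(masks)))
  for (i in seq_along(masks)) out[, , i] <- masks[[i]]
  out
}
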