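# Generic sequential network: an ordered list of layers over H x W x C x B
# batches, ending in a dense head on pooled features. Used by the tiny
# classifiers; supports gradient extraction/injection at named layers,
# which is what Grad-CAM and the class-activation loss need.
#
# Layer entries: list(type, name) with type one of
#   "conv" (weights <name>.W/.b), "relu", "pool", "gap", "dense".

net_forward <- function(model, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(model$layers)) else NULL
  h <- x
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    entry <- NULL
    if (layer$type == "conv") {
      W <- model$params[[paste0(layer$name, ".W")]]
      b <- model$params[[paste0(layer$name, ".b")]]
      if (keep) {
        entry <- list(x = h)
        cv <- conv_fw(h, W, b, return_patches = TRUE)
        entry$patches <- cv$patches
        h <- cv$y
      } else {
        h <- conv_fw(h, W, b)
      }
    } else if (layer$type == "relu") {
      h <- relu(h)
      if (keep) entry <- list(y = h)
    } else if (layer$type == "pool") {
      pc <- pool_fw(h)
      h <- pc$y
      if (keep) entry <- pc
    } else if (layer$type == "gap") {
      if (keep) entry <- list(xdim = dim(h))
      h <- gap_fw(h)
    } else if (layer$type == "dense") {
      W <- model$params[[paste0(layer$name, ".W")]]
      b <- model$params[[paste0(layer$name, ".b")]]
      if (keep) entry <- list(z = h)
      h <- dense_fw(h, W, b)
    } else {
      stop("unknown layer type: ", layer$type)
    }
    if (keep) {
      entry$out <- h
      caches[[li]] <- entry
    }
  }
  list(out = h, caches = caches)
}

# Backward pass from dL/d(logits). `inject` is a named list adding extra
# gradient at the OUTPUT of the named layers; `upto` stops the walk and
# returns dL/d(output of that layer) without descending further.
net_backward <- function(model, fw, dtop, inject = NULL, upto = NULL,
                         want_params = TRUE, want_input = TRUE) {
  grads <- if (want_params) {
    lapply(model$params, function(p) p * 0)
  } else NULL
  g <- dtop
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    if (!is.null(inject) && !is.null(inject[[layer$name]])) {
      g <- g + inject[[layer$name]]
    }
    if (!is.null(upto) && identical(layer$name, upto)) {
      return(list(dlayer = g, grads = grads))
    }
    cache <- fw$caches[[li]]
    if (layer$type == "conv") {
      W <- model$params[[paste0(layer$name, ".W")]]
      bw <- conv_bw(cache$x, W, g, need_dx = want_input || li > 1L,
                    patches = if (want_params) cache$patches)
      if (want_params) {
        grads[[paste0(layer$name, ".W")]] <- grads[[paste0(layer$name, ".W")]] + bw$dW
        grads[[paste0(layer$name, ".b")]] <- grads[[paste0(layer$name, ".b")]] + bw$db
      }
      g <- bw$dx
      if (li == 1L && !want_input) g <- NULL
    } else if (layer$type == "relu") {
      g <- relu_bw(cache$y, g)
    } else if (layer$type == "pool") {
      g <- pool_bw(cache, g)
    } else if (layer$type == "gap") {
      g <- gap_bw(cache$xdim, g)
    } else if (layer$type == "dense") {
      W <- model$params[[paste0(layer$name, ".W")]]
      bw <- dense_bw(cache$z, W, g)
      if (want_params) {
        grads[[paste0(layer$name, ".W")]] <- grads[[paste0(layer$name, ".W")]] + bw$dW
        grads[[paste0(layer$name, ".b")]] <- grads[[paste0(layer$name, ".b")]] + bw$db
      }
      g <- bw$dz
    }
  }
  list(dinput = g, grads = grads)
}

# Activations at a named layer for a batch (forward hook).
net_activation <- function(model, x, layer_name) {
  fw <- net_forward(model, x, keep = TRUE)
  li <- match(layer_name, vapply(model$layers, `[[`, "", "name"))
  if (is.na(li)) stop("unknown layer: ", layer_name)
  fw$caches[[li]]$out
}
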