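# Minimal convolutional-network primitives in base R.
#
# All layer inputs/outputs are H x W x C x B arrays (column-major, batch
# last). Convolutions use im2col with cached index tables so the inner loop
# is a single BLAS matrix multiplication per image. Every primitive has a
# matching backward pass; gradients were validated against central finite
# differences (see tests).

.idx_cache <- new.env(parent = emptyenv())

# Linear indices into the zero-padded (Hp x Wp x C) array such that
# matrix(xp[idx], H*W, k*k*C) is the im2col patch matrix. Patch columns are
# ordered di fastest, then dj, then channel; this must match conv weight
# layout (k*k*Cin rows, same ordering).
im2col_idx <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  iv <- rep.int(seq_len(H), W)
  jv <- rep(seq_len(W), each = H)
  cols <- vector("list", k * k * C)
  n <- 0L
  for (cc in seq_len(C)) {
    for (dj in 0:(k - 1L)) {
      for (di in 0:(k - 1L)) {
        n <- n + 1L
        cols[[n]] <- (iv + di) + (jv + dj - 1L) * Hp + (cc - 1L) * Hp * Wp
      }
    }
  }
  idx <- unlist(cols, use.names = FALSE)
  .idx_cache[[key]] <- idx
  idx
}

init_conv <- function(k, cin, cout, gain = 2) {
  fan_in <- k * k * cin
  W <- matrix(rnorm(fan_in * cout, sd = sqrt(gain / fan_in)), fan_in, cout)
  list(W = W, b = numeric(cout))
}

init_upconv <- function(cin, cout, gain = 2) {
  W <- matrix(rnorm(cin * 4L * cout, sd = sqrt(gain / cin)), cin, 4L * cout)
  list(W = W, b = numeric(cout))
}

init_dense <- function(cin, cout, gain = 2) {
  W <- matrix(rnorm(cin * cout, sd = sqrt(gain / cin)), cin, cout)
  list(W = W, b = numeric(cout))
}

# (H*W*B) x (k*k*C) patch matrix for a whole batch; compiled kernel.
im2col_batch <- function(x, k) {
  im2col_batch_cpp(x, as.integer(k))
}

# Same-padding convolution, stride 1, odd square kernel (k inferred from
# W); one BLAS multiplication for the whole batch. With
# `return_patches = TRUE` the im2col matrix is returned too, so a
# training-mode caller can hand it back to conv_bw and skip the second
# gather.
conv_fw <- function(x, W, b, return_patches = FALSE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  k <- as.integer(round(sqrt(nrow(W) / C)))
  Fc <- ncol(W)
  patches <- im2col_batch(x, k)
  ym <- patches %*% W                            # (H*W*B) x F
  ym <- ym + rep(b, each = H * Wd * B)
  dim(ym) <- c(H * Wd, B, Fc)
  y <- aperm(ym, c(1L, 3L, 2L))
  dim(y) <- c(H, Wd, Fc, B)
  if (return_patches) list(y = y, patches = patches) else y
}

conv_bw <- function(x, W, dy, need_dx = TRUE, patches = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  k <- as.integer(round(sqrt(nrow(W) / C)))
  Fc <- ncol(W)
  p <- (k - 1L) %/% 2L
  if (is.null(patches)) patches <- im2col_batch(x, k)
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))            # rows (pixel, image)
  dim(dym) <- c(H * Wd * B, Fc)
  dW <- crossprod(patches, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    # input gradient of a stride-1 same-padding conv = conv of dy with the
    # spatially flipped, in/out-transposed kernel
    Wr <- W
    dim(Wr) <- c(k, k, C, Fc)
    Wr <- aperm(Wr[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dim(Wr) <- c(k * k * Fc, C)
    dx <- conv_fw(dy, Wr, numeric(C))
  }
  list(dx = dx, dW = dW, db = db)
}

# 2x2 max pooling, stride 2. Ties route to the first (top/left) element so
# the backward pass is deterministic.
pool_fw <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  Hh <- H %/% 2L; Wh <- Wd %/% 2L
  xm <- matrix(x, nrow = 2L)
  w1 <- xm[1L, ] >= xm[2L, ]
  r <- pmax(xm[1L, ], xm[2L, ])
  a2 <- array(r, c(Hh, 2L, length(r) %/% (2L * Hh)))
  w2 <- a2[, 1L, ] >= a2[, 2L, ]
  y <- pmax(a2[, 1L, ], a2[, 2L, ])
  list(y = array(y, c(Hh, Wh, d[3], d[4])), w1 = w1, w2 = w2, dim = d)
}

pool_bw <- function(cache, dy) {
  d <- cache$dim
  Hh <- d[1] %/% 2L
  rest <- length(dy) %/% Hh
  dym <- matrix(dy, Hh, rest)
  d2 <- array(0, c(Hh, 2L, rest))
  s1 <- d2[, 1L, ]; s1[cache$w2] <- dym[cache$w2]; d2[, 1L, ] <- s1
  s2 <- d2[, 2L, ]; s2[!cache$w2] <- dym[!cache$w2]; d2[, 2L, ] <- s2
  r2 <- as.vector(d2)
  dxm <- matrix(0, 2L, length(r2))
  dxm[1L, cache$w1] <- r2[cache$w1]
  dxm[2L, !cache$w1] <- r2[!cache$w1]
  array(dxm, d)
}

# 2x2 transposed convolution, stride 2 (no output overlap). Weight matrix
# is Cin x (4*Cout); the 4 kernel cells are ordered row-offset fastest.
# Batched: one BLAS multiplication plus an aperm scatter.
upconv_fw <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  Fc <- ncol(W) %/% 4L
  xm <- aperm(x, c(1L, 2L, 4L, 3L))              # rows (pixel, image)
  dim(xm) <- c(H * Wd * B, C)
  res <- xm %*% W                                # rows (i,j,b), cols (r,s,f)
  dim(res) <- c(H, Wd, B, 2L, 2L, Fc)
  y <- aperm(res, c(4L, 1L, 5L, 2L, 6L, 3L))     # (r,i,s,j,f,b)
  dim(y) <- c(2L * H, 2L * Wd, Fc, B)
  y + rep(rep(b, each = 4L * H * Wd), times = B)
}

upconv_bw <- function(x, W, dy, need_dx = TRUE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  Fc <- ncol(W) %/% 4L
  dy6 <- dy
  dim(dy6) <- c(2L, H, 2L, Wd, Fc, B)
  dres <- aperm(dy6, c(2L, 4L, 6L, 1L, 3L, 5L))  # (i,j,b,r,s,f)
  dim(dres) <- c(H * Wd * B, 4L * Fc)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(H * Wd * B, C)
  dW <- crossprod(xm, dres)
  dbm <- dy
  dim(dbm) <- c(4L * H * Wd, Fc, B)
  db <- rowSums(colSums(dbm))
  dx <- NULL
  if (need_dx) {
    dxm <- tcrossprod(dres, W)                   # rows (i,j,b), cols C
    dim(dxm) <- c(H, Wd, B, C)
    dx <- aperm(dxm, c(1L, 2L, 4L, 3L))
  }
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) (x > 0) * x

relu_bw <- function(y, dy) (y > 0) * dy

tanh_bw <- function(y, dy) dy * (1 - y * y)

sigmoid <- function(x) 1 / (1 + exp(-x))

sigmoid_bw <- function(y, dy) dy * y * (1 - y)

# Global average pooling: H x W x C x B -> C x B.
gap_fw <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[3], d[4])
}

gap_bw <- function(xdim, dy) {
  hw <- xdim[1] * xdim[2]
  array(rep(as.vector(dy) / hw, each = hw), xdim)
}

# Dense layer on C x B feature matrices; W is Cin x Cout.
dense_fw <- function(z, W, b) crossprod(W, z) + b

dense_bw <- function(z, W, dy) {
  list(dz = W %*% dy, dW = z %*% t(dy), db = rowSums(dy))
}

# Softmax cross-entropy, mean-reduced over the batch. `labels` are 0-based.
softmax_ce <- function(logits, labels) {
  B <- ncol(logits)
  lm <- apply(logits, 2L, max)
  p <- exp(sweep(logits, 2L, lm))
  p <- sweep(p, 2L, colSums(p), "/")
  sel <- cbind(as.integer(labels) + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  dlogits <- p
  dlogits[sel] <- dlogits[sel] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam with L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
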