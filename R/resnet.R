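## Small residual convolutional encoder for grayscale images. Residual
## units compute f(h(x) + F(x, W)): F is conv-normalize-ReLU-conv-normalize,
## h is the identity (identity block) or a strided 1x1 projection
## (convolutional block), f is ReLU. Convolution is computed by im2col;
## normalization uses per-channel statistics of the current map in
## training mode and running statistics in evaluation mode, so evaluation
## is deterministic.

relu <- function(x) pmax(x, 0)

pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), ] <- x
  out
}

## im2col patch matrix: rows index output positions (column-major over the
## Ho x Wo grid), columns index (ki, kj, c) in array-flattening order.
im2col <- function(xp, kh, kw, stride, Ho, Wo) {
  C <- dim(xp)[3L]
  P <- matrix(0, Ho * Wo, kh * kw * C)
  for (c in seq_len(C)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    col <- ki + (kj - 1L) * kh + (c - 1L) * kh * kw
    i0 <- seq.int(ki, by = stride, length.out = Ho)
    j0 <- seq.int(kj, by = stride, length.out = Wo)
    P[, col] <- xp[i0, j0, c]
  }
  P
}

## 2-D convolution. x: H x W x Cin array; W: kh x kw x Cin x Cout; b: Cout.
conv2d <- function(x, W, b, stride = 1L, pad = 0L) {
  dW <- dim(W)
  xp <- pad_spatial(x, pad)
  H <- dim(xp)[1L]; Wd <- dim(xp)[2L]
  Ho <- (H - dW[1L]) %/% stride + 1L
  Wo <- (Wd - dW[2L]) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop_value("image smaller than receptive minimum")
  P <- im2col(xp, dW[1L], dW[2L], stride, Ho, Wo)
  Wmat <- matrix(W, dW[1L] * dW[2L] * dW[3L], dW[4L])
  out <- P %*% Wmat
  out <- sweep(out, 2L, b, "+")
  array(out, c(Ho, Wo, dW[4L]))
}

## gradient of conv2d w.r.t. its input (evaluation-path backward)
conv2d_grad_x <- function(dy, x_dim, W, stride = 1L, pad = 0L) {
  dW <- dim(W)
  Ho <- dim(dy)[1L]; Wo <- dim(dy)[2L]
  Wmat <- matrix(W, dW[1L] * dW[2L] * dW[3L], dW[4L])
  dy_mat <- matrix(dy, Ho * Wo, dW[4L])
  dP <- dy_mat %*% t(Wmat)
  dxp <- array(0, c(x_dim[1L] + 2L * pad, x_dim[2L] + 2L * pad, x_dim[3L]))
  for (c in seq_len(dW[3L])) for (kj in seq_len(dW[2L]))
    for (ki in seq_len(dW[1L])) {
      col <- ki + (kj - 1L) * dW[1L] + (c - 1L) * dW[1L] * dW[2L]
      i0 <- seq.int(ki, by = stride, length.out = Ho)
      j0 <- seq.int(kj, by = stride, length.out = Wo)
      dxp[i0, j0, c] <- dxp[i0, j0, c] + matrix(dP[, col], Ho, Wo)
    }
  if (pad > 0L)
    dxp <- dxp[pad + seq_len(x_dim[1L]), pad + seq_len(x_dim[2L]), ,
               drop = FALSE]
  dxp
}

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

## per-channel normalization over spatial positions
bn_forward <- function(x, bn, training = FALSE, eps = 1e-5) {
  C <- dim(x)[3L]
  y <- x
  for (c in seq_len(C)) {
    if (training) {
      mu <- mean(x[, , c]); v <- mean((x[, , c] - mu)^2)
    } else {
      mu <- bn$run_mean[c]; v <- bn$run_var[c]
    }
    y[, , c] <- bn$gamma[c] * (x[, , c] - mu) / sqrt(v + eps) + bn$beta[c]
  }
  y
}

bn_grad_x <- function(dy, bn, eps = 1e-5) {
  C <- dim(dy)[3L]
  dx <- dy
  for (c in seq_len(C))
    dx[, , c] <- dy[, , c] * bn$gamma[c] / sqrt(bn$run_var[c] + eps)
  dx
}

maxpool2 <- function(x) {
  d <- dim(x)
  Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
  out <- array(0, c(Ho, Wo, d[3L]))
  for (c in seq_len(d[3L])) {
    m <- x[seq_len(2L * Ho), seq_len(2L * Wo), c]
    out[, , c] <- pmax(m[seq(1L, 2L * Ho, 2L), seq(1L, 2L * Wo, 2L)],
                       m[seq(2L, 2L * Ho, 2L), seq(1L, 2L * Wo, 2L)],
                       m[seq(1L, 2L * Ho, 2L), seq(2L, 2L * Wo, 2L)],
                       m[seq(2L, 2L * Ho, 2L), seq(2L, 2L * Wo, 2L)])
  }
  out
}

conv_init <- function(kh, kw, c_in, c_out, zero = FALSE) {
  fan <- kh * kw * c_in
  W <- if (zero) array(0, c(kh, kw, c_in, c_out))
       else array(stats::rnorm(kh * kw * c_in * c_out, 0, sqrt(2 / fan)),
                  c(kh, kw, c_in, c_out))
  list(W = W, b = numeric(c_out))
}

#' Initialize the weights of one residual unit
#'
#' @param c_in,c_out input/output channel counts.
#' @param stride spatial stride of the unit.
#' @param seed integer seed.
#' @param zero_residual if TRUE the residual branch's conv weights are
#'   zero, making the unit an identity map on nonnegative input (when the
#'   shortcut is the identity).
#' @return a weight list with `conv1`, `bn1`, `conv2`, `bn2` and, when the
#'   shape changes, a projected shortcut `proj`, `bnp`.
#' @export
residual_weights <- function(c_in, c_out, stride = 1L, seed = 1L,
                             zero_residual = FALSE) {
  with_seed(seed, {
    w <- list(conv1 = conv_init(3L, 3L, c_in, c_out, zero_residual),
              bn1 = bn_init(c_out),
              conv2 = conv_init(3L, 3L, c_out, c_out, zero_residual),
              bn2 = bn_init(c_out),
              stride = as.integer(stride))
    if (stride != 1L || c_in != c_out) {
      w$proj <- conv_init(1L, 1L, c_in, c_out)
      w$bnp <- bn_init(c_out)
    }
    w
  })
}

#' Apply one residual unit: f(h(x) + F(x, W))
#'
#' The residual branch F is conv(3x3) -> normalize -> ReLU -> conv(3x3) ->
#' normalize; the shortcut h is the identity, or a strided 1x1 projection
#' when the weights carry one; the outer activation f is ReLU. With zero
#' residual weights and an identity shortcut the unit reproduces
#' nonnegative input exactly, and a stack of such units telescopes to the
#' identity through any depth.
#'
#' @param x H x W x C input array (a matrix is treated as H x W x 1).
#' @param weights a [residual_weights()] list.
#' @param training logical; use current-map normalization statistics
#'   (TRUE) or running statistics (FALSE, deterministic).
#' @return output feature map array.
#' @export
residual_unit <- function(x, weights, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stride <- weights$stride %||% 1L
  a1 <- conv2d(x, weights$conv1$W, weights$conv1$b, stride = stride, pad = 1L)
  r1 <- relu(bn_forward(a1, weights$bn1, training))
  a2 <- conv2d(r1, weights$conv2$W, weights$conv2$b, stride = 1L, pad = 1L)
  f <- bn_forward(a2, weights$bn2, training)
  s <- if (!is.null(weights$proj))
    bn_forward(conv2d(x, weights$proj$W, weights$proj$b, stride = stride,
                      pad = 0L), weights$bnp, training)
  else x
  if (!all(dim(s) == dim(f)))
    stop_value("shape error: shortcut and residual branch shapes differ")
  relu(s + f)
}

#' Analytic input gradient of a residual unit (evaluation mode)
#'
#' Backpropagates `dy` through `f(h(x) + F(x, W))` with running-statistic
#' normalization; the returned gradient contains the shortcut's additive
#' identity path plus the residual branch's contribution.
#'
#' @param x input array (or matrix).
#' @param weights a [residual_weights()] list.
#' @param dy upstream gradient, same shape as the unit's output.
#' @return gradient of the scalar loss w.r.t. `x`.
#' @export
residual_unit_grad_x <- function(x, weights, dy) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stride <- weights$stride %||% 1L
  a1 <- conv2d(x, weights$conv1$W, weights$conv1$b, stride = stride, pad = 1L)
  n1 <- bn_forward(a1, weights$bn1, FALSE)
  r1 <- relu(n1)
  a2 <- conv2d(r1, weights$conv2$W, weights$conv2$b, stride = 1L, pad = 1L)
  f <- bn_forward(a2, weights$bn2, FALSE)
  s <- if (!is.null(weights$proj))
    bn_forward(conv2d(x, weights$proj$W, weights$proj$b, stride = stride,
                      pad = 0L), weights$bnp, FALSE)
  else x
  pre <- s + f
  dpre <- dy * (pre > 0)
  ## residual branch
  df <- bn_grad_x(dpre, weights$bn2)
  dr1 <- conv2d_grad_x(df, dim(r1), weights$conv2$W, stride = 1L, pad = 1L)
  dn1 <- dr1 * (n1 > 0)
  da1 <- bn_grad_x(dn1, weights$bn1)
  dx <- conv2d_grad_x(da1, dim(x), weights$conv1$W, stride = stride, pad = 1L)
  ## shortcut branch: identity passes dpre through unchanged
  if (!is.null(weights$proj)) {
    ds <- bn_grad_x(dpre, weights$bnp)
    dx <- dx + conv2d_grad_x(ds, dim(x), weights$proj$W, stride = stride,
                             pad = 0L)
  } else dx <- dx + dpre
  dx
}

#' Identity block and convolutional block
#'
#' An identity block is a residual unit whose shortcut is the identity, so
#' input and output shapes must match; a convolutional block changes
#' channels and/or stride through a projected (strided 1x1 convolution)
#' shortcut.
#'
#' @inheritParams residual_unit
#' @return output feature map.
#' @export
identity_block <- function(x, weights, training = FALSE) {
  if (!is.null(weights$proj) || (weights$stride %||% 1L) != 1L)
    stop_value("shape error: identity block cannot change shape")
  cx <- if (is.matrix(x)) 1L else dim(x)[3L]
  if (dim(weights$conv1$W)[3L] != cx)
    stop_value("shape error: channel mismatch in identity block")
  residual_unit(x, weights, training)
}

#' @rdname identity_block
#' @export
conv_block <- function(x, weights, training = FALSE) {
  if (is.null(weights$proj))
    stop_value("conv block requires a projected shortcut")
  residual_unit(x, weights, training)
}

#' Build a small residual image encoder
#'
#' Stem convolution -> normalize -> ReLU -> max-pool, then stages of one
#' convolutional block plus one identity block each, then global average
#' pooling to the feature vector.
#'
#' @param stem_channels channels after the stem convolution.
#' @param stage_channels channel count per stage (one conv block + one
#'   identity block each, stride 2).
#' @param feature_dim output feature dimension; when it differs from the
#'   last stage's channels a seeded linear head maps onto it.
#' @param seed integer seed for weight initialization.
#' @return object of class `resnet_encoder`.
#' @export
resnet <- function(stem_channels = 8L, stage_channels = c(16L, 32L),
                   feature_dim = 32L, seed = 1L) {
  stopifnot(length(stage_channels) >= 1L, feature_dim >= 1L)
  with_seed(derive_seed(seed, "resnet"), {
    stem <- conv_init(3L, 3L, 1L, stem_channels)
    bn_stem <- bn_init(stem_channels)
    stages <- list()
    c_in <- stem_channels
    for (s in seq_along(stage_channels)) {
      c_out <- stage_channels[s]
      stages[[s]] <- list(
        conv_block = residual_weights(c_in, c_out, stride = 2L,
                                      seed = stats::runif(1, 1, 2^30)),
        identity_block = residual_weights(c_out, c_out, stride = 1L,
                                          seed = stats::runif(1, 1, 2^30)))
      c_in <- c_out
    }
    head <- if (feature_dim != c_in)
      rand_mat(c_in, feature_dim) else NULL
    structure(list(stem = stem, bn_stem = bn_stem, stages = stages,
                   head = head, feature_dim = as.integer(feature_dim),
                   seed = as.integer(seed)),
              class = "resnet_encoder")
  })
}

#' Encode a grayscale image as a feature vector
#'
#' @param image 2-D numeric matrix (finite values).
#' @param model a [resnet()] encoder.
#' @param training logical; evaluation mode (default) is deterministic.
#' @return numeric vector of length `model$feature_dim`.
#' @export
encode_image <- function(image, model, training = FALSE) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop_value("image must be a finite 2-D matrix")
  if (min(dim(image)) < 8L)
    stop_value("image smaller than receptive minimum (8)")
  x <- array(image, c(dim(image), 1L))
  x <- conv2d(x, model$stem$W, model$stem$b, stride = 1L, pad = 1L)
  x <- relu(bn_forward(x, model$bn_stem, training))
  x <- maxpool2(x)
  for (st in model$stages) {
    x <- conv_block(x, st$conv_block, training)
    x <- identity_block(x, st$identity_block, training)
  }
  feat <- apply(x, 3L, mean)                 # global average pool
  if (!is.null(model$head)) feat <- drop(feat %*% model$head)
  feat
}

#' Encode a set of entity images
#'
#' @param images named list of matrices.
#' @inheritParams encode_image
#' @return matrix, one row per image key.
#' @export
encode_images <- function(images, model, training = FALSE) {
  out <- t(vapply(images, encode_image, numeric(model$feature_dim),
                  model = model, training = training))
  rownames(out) <- names(images)
  out
}

#' @export
print.resnet_encoder <- function(x, ...) {
  cat("Residual image encoder\n")
  cat("  stem: ", dim(x$stem$W)[4L], " channels; stages: ",
      paste(vapply(x$stages, function(s) dim(s$conv_block$conv1$W)[4L],
                   integer(1)), collapse = ", "),
      "; feature dim: ", x$feature_dim, "\n", sep = "")
  invisible(x)
}
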