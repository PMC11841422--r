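# Numerical primitives for the network modules.
#
# Feature maps are plain 4-D arrays indexed (batch, channel, row, col).
# Everything here is implemented with vectorized base-R linear algebra
# (im2col + matrix products); each forward op has a matching backward op
# so the reference detector can be trained without an external autograd.

#' Construct and validate a feature map
#'
#' A feature map is a 4-D numeric array indexed `(batch, channel, row, col)`.
#' All entries must be finite and every dimension at least 1.
#'
#' @param values Numeric array with 4 dimensions, or an object coercible to
#'   one (a matrix is promoted to `(1, 1, nrow, ncol)`).
#' @return The validated array, invisibly classed as `featuremap`.
#' @export
featuremap <- function(values) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, 1L, nrow(values), ncol(values)))
  }
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop("a feature map must be a 4-D (batch, channel, row, col) array")
  }
  if (!is.numeric(values)) stop("feature map values must be numeric")
  if (!all(is.finite(values))) {
    stop("non-finite values in feature map (", sum(!is.finite(values)),
         " entries); refusing to propagate NaN/Inf")
  }
  class(values) <- c("featuremap", class(values))
  values
}

#' @rdname featuremap
#' @param x Object to test.
#' @export
is_featuremap <- function(x) {
  is.array(x) && length(dim(x)) == 4L && is.numeric(x)
}

check_featuremap <- function(x, what = "input") {
  if (!is_featuremap(x)) stop(what, " must be a 4-D (batch,channel,h,w) array")
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}

# zero-padding of the two spatial dims
pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  out[, , (p + 1L):(p + d[3]), (p + 1L):(p + d[4])] <- x
  out
}

conv_out_dim <- function(n, k, stride, padding) {
  (n + 2L * padding - k) %/% stride + 1L
}

# Unroll one padded sample (C, H, W) into the im2col matrix
# (C*kh*kw) x (oh*ow).  Block order is (kj outer, ki inner), channels fastest,
# and must match flatten_kernel().
im2col_one <- function(xp, kh, kw, stride, oh, ow) {
  cdim <- dim(xp)[1]
  blocks <- vector("list", kh * kw)
  b <- 1L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      rows <- seq.int(ki, by = stride, length.out = oh)
      cols <- seq.int(kj, by = stride, length.out = ow)
      sub <- xp[, rows, cols, drop = FALSE]
      dim(sub) <- c(cdim, oh * ow)
      blocks[[b]] <- sub
      b <- b + 1L
    }
  }
  do.call(rbind, blocks)
}

# (Cout, Cin, kh, kw) kernel -> Cout x (Cin*kh*kw) matrix, same block order
flatten_kernel <- function(w) {
  d <- dim(w)
  cout <- d[1]; cin <- d[2]; kh <- d[3]; kw <- d[4]
  blocks <- vector("list", kh * kw)
  b <- 1L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      blocks[[b]] <- matrix(w[, , ki, kj], nrow = cout, ncol = cin)
      b <- b + 1L
    }
  }
  do.call(cbind, blocks)
}

#' 2-D convolution forward pass
#'
#' Cross-correlation (the deep-learning convention) of a
#' `(batch, Cin, H, W)` array with a `(Cout, Cin, kh, kw)` kernel.
#'
#' @param x Input feature map array.
#' @param w Kernel array `(Cout, Cin, kh, kw)`.
#' @param b Bias vector of length `Cout` (or NULL for zero bias).
#' @param stride,padding Integer stride and symmetric zero padding.
#' @param keep_cache Keep intermediates needed by [conv2d_backward()].
#' @return Output array `(batch, Cout, oh, ow)`; with `keep_cache = TRUE`,
#'   a list `list(out, cache)`.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, padding = 0L,
                   keep_cache = FALSE) {
  dx <- dim(x); dw <- dim(w)
  if (length(dw) != 4L) stop("kernel must be 4-D (Cout, Cin, kh, kw)")
  if (dx[2] != dw[2]) {
    stop("channel mismatch: input has ", dx[2], " channels, kernel expects ",
         dw[2])
  }
  if (is.null(b)) b <- numeric(dw[1])
  stride <- as.integer(stride); padding <- as.integer(padding)
  kh <- dw[3]; kw <- dw[4]
  oh <- conv_out_dim(dx[3], kh, stride, padding)
  ow <- conv_out_dim(dx[4], kw, stride, padding)
  if (oh < 1L || ow < 1L) stop("kernel larger than padded input")
  xp <- pad_spatial(x, padding)
  wm <- flatten_kernel(w)
  out <- array(0, dim = c(dx[1], dw[1], oh, ow))
  cols <- if (keep_cache) vector("list", dx[1]) else NULL
  for (bi in seq_len(dx[1])) {
    xc <- im2col_one(array(xp[bi, , , ], dim = dim(xp)[2:4]), kh, kw,
                     stride, oh, ow)
    om <- wm %*% xc + b
    out[bi, , , ] <- array(om, dim = c(dw[1], oh, ow))
    if (keep_cache) cols[[bi]] <- xc
  }
  if (!keep_cache) return(out)
  list(out = out,
       cache = list(cols = cols, dim_x = dx, dim_w = dw, stride = stride,
                    padding = padding, wm = wm, oh = oh, ow = ow))
}

#' 2-D convolution backward pass
#'
#' @param grad_out Gradient w.r.t. the convolution output.
#' @param cache Cache from `conv2d(..., keep_cache = TRUE)`.
#' @return `list(dx, dw, db)` gradients for input, kernel and bias.
#' @export
conv2d_backward <- function(grad_out, cache) {
  dxd <- cache$dim_x; dwd <- cache$dim_w
  stride <- cache$stride; padding <- cache$padding
  kh <- dwd[3]; kw <- dwd[4]; oh <- cache$oh; ow <- cache$ow
  cin <- dxd[2]
  hp <- dxd[3] + 2L * padding; wp <- dxd[4] + 2L * padding
  dwm <- matrix(0, nrow = dwd[1], ncol = cin * kh * kw)
  db <- numeric(dwd[1])
  dxp <- array(0, dim = c(dxd[1], cin, hp, wp))
  wmT <- t(cache$wm)
  for (bi in seq_len(dxd[1])) {
    gm <- matrix(array(grad_out[bi, , , ], dim = c(dwd[1], oh * ow)),
                 nrow = dwd[1])
    db <- db + rowSums(gm)
    dwm <- dwm + gm %*% t(cache$cols[[bi]])
    dxc <- wmT %*% gm                       # (Cin*kh*kw) x (oh*ow)
    blk <- 1L
    acc <- array(dxp[bi, , , ], dim = c(cin, hp, wp))
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        rows <- seq.int(ki, by = stride, length.out = oh)
        cols <- seq.int(kj, by = stride, length.out = ow)
        piece <- array(dxc[((blk - 1L) * cin + 1L):(blk * cin), ],
                       dim = c(cin, oh, ow))
        acc[, rows, cols] <- array(acc[, rows, cols],
                                   dim = c(cin, oh, ow)) + piece
        blk <- blk + 1L
      }
    }
    dxp[bi, , , ] <- acc
  }
  dw <- array(0, dim = dwd)
  blk <- 1L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      dw[, , ki, kj] <- dwm[, ((blk - 1L) * cin + 1L):(blk * cin)]
      blk <- blk + 1L
    }
  }
  dx <- if (padding > 0L) {
    dxp[, , (padding + 1L):(padding + dxd[3]),
        (padding + 1L):(padding + dxd[4]), drop = FALSE]
  } else dxp
  list(dx = dx, dw = dw, db = db)
}

#' Bilinear interpolation matrix
#'
#' Row-stochastic matrix mapping a length-`n_in` axis to `n_out` samples
#' under the half-pixel-center convention, so constants are preserved and
#' `n_out == n_in` yields the identity.
#'
#' @param n_out,n_in Output and input lengths.
#' @return `n_out x n_in` matrix.
#' @export
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, nrow = n_out, ncol = n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    i1 <- min(i0 + 1, n_in - 1)
    wt <- src - i0
    A[i, i0 + 1] <- A[i, i0 + 1] + (1 - wt)
    A[i, i1 + 1] <- A[i, i1 + 1] + wt
  }
  A
}

#' Bilinear spatial resize of a feature map
#'
#' @param x `(batch, C, H, W)` array.
#' @param out_h,out_w Target spatial size.
#' @return Resized `(batch, C, out_h, out_w)` array.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  if (d[3] == out_h && d[4] == out_w) return(x)
  A <- bilinear_matrix(out_h, d[3])
  Bt <- t(bilinear_matrix(out_w, d[4]))
  out <- array(0, dim = c(d[1], d[2], out_h, out_w))
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    out[bi, ci, , ] <- A %*% matrix(x[bi, ci, , ], d[3], d[4]) %*% Bt
  }
  out
}

#' Backward pass of [resize_bilinear()] (transpose of the linear map)
#'
#' @param grad Gradient w.r.t. the resized output.
#' @param in_h,in_w Original spatial size.
#' @return Gradient array at the original size.
#' @export
resize_bilinear_backward <- function(grad, in_h, in_w) {
  d <- dim(grad)
  if (d[3] == in_h && d[4] == in_w) return(grad)
  At <- t(bilinear_matrix(d[3], in_h))
  B <- bilinear_matrix(d[4], in_w)
  out <- array(0, dim = c(d[1], d[2], in_h, in_w))
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    out[bi, ci, , ] <- At %*% matrix(grad[bi, ci, , ], d[3], d[4]) %*% B
  }
  out
}

relu <- function(x) pmax(x, 0)
relu_backward <- function(grad, x) grad * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_backward <- function(grad, s) grad * s * (1 - s)

# channel concatenation of feature maps with identical batch/spatial dims
concat_channels <- function(maps) {
  d1 <- dim(maps[[1]])
  for (m in maps) {
    dm <- dim(m)
    if (!all(dm[c(1, 3, 4)] == d1[c(1, 3, 4)])) {
      stop("concat_channels: batch/spatial dims differ")
    }
  }
  ctot <- sum(vapply(maps, function(m) dim(m)[2], integer(1)))
  out <- array(0, dim = c(d1[1], ctot, d1[3], d1[4]))
  at <- 0L
  for (m in maps) {
    cm <- dim(m)[2]
    out[, (at + 1L):(at + cm), , ] <- m
    at <- at + cm
  }
  out
}

split_channels <- function(grad, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- grad[, (at + 1L):(at + sizes[i]), , , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# global average pool: (b, C, H, W) -> (b, C)
global_avg_pool <- function(x) {
  d <- dim(x)
  apply(x, c(1, 2), mean)
}

# broadcast per-(batch,channel) scalars over the spatial grid
broadcast_channel <- function(v, h, w) {
  d <- dim(v)  # (b, C)
  array(rep(as.vector(v), h * w), dim = c(d[1], d[2], h, w))
}
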