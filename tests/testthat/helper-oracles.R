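# Independent brute-force oracles, written before the vectorized
# implementations they check.  Everything here is scalar-loop arithmetic:
# slow, obvious, and sharing no code with R/.

# plain nested-loop cross-correlation, zero padding, (b, c, h, w) arrays
oracle_conv2d <- function(x, w, b = NULL, stride = 1, padding = 0) {
  dx <- dim(x); dw <- dim(w)
  if (is.null(b)) b <- numeric(dw[1])
  oh <- (dx[3] + 2 * padding - dw[3]) %/% stride + 1
  ow <- (dx[4] + 2 * padding - dw[4]) %/% stride + 1
  out <- array(0, dim = c(dx[1], dw[1], oh, ow))
  for (bi in seq_len(dx[1])) for (oc in seq_len(dw[1])) {
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- b[oc]
      for (ic in seq_len(dx[2])) for (ki in seq_len(dw[3])) {
        for (kj in seq_len(dw[4])) {
          ri <- (i - 1) * stride + ki - padding
          rj <- (j - 1) * stride + kj - padding
          if (ri >= 1 && ri <= dx[3] && rj >= 1 && rj <= dx[4]) {
            acc <- acc + x[bi, ic, ri, rj] * w[oc, ic, ki, kj]
          }
        }
      }
      out[bi, oc, i, j] <- acc
    }
  }
  out
}

# scalar-loop bilinear resize, half-pixel-center convention
oracle_resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], out_h, out_w))
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
      si <- min(max((i - 0.5) * d[3] / out_h - 0.5, 0), d[3] - 1)
      sj <- min(max((j - 0.5) * d[4] / out_w - 0.5, 0), d[4] - 1)
      i0 <- floor(si); i1 <- min(i0 + 1, d[3] - 1); wi <- si - i0
      j0 <- floor(sj); j1 <- min(j0 + 1, d[4] - 1); wj <- sj - j0
      out[bi, ci, i, j] <-
        (1 - wi) * (1 - wj) * x[bi, ci, i0 + 1, j0 + 1] +
        (1 - wi) * wj       * x[bi, ci, i0 + 1, j1 + 1] +
        wi       * (1 - wj) * x[bi, ci, i1 + 1, j0 + 1] +
        wi       * wj       * x[bi, ci, i1 + 1, j1 + 1]
    }
  }
  out
}

# rscconv forward composed purely from the oracles above
oracle_rscconv <- function(x, p) {
  d <- dim(x)
  b2 <- oracle_conv2d(x, p$refine_kernel, p$refine_bias,
                      stride = p$stride, padding = p$padding)
  up <- oracle_resize_bilinear(x, 2 * d[3], 2 * d[4])
  b3 <- oracle_conv2d(up, p$calib_kernel, p$calib_bias,
                      stride = 1, padding = p$padding)
  do <- dim(b2)
  b3 <- oracle_resize_bilinear(b3, do[3], do[4])
  if (isTRUE(p$gate_calibration)) b3 <- 1 / (1 + exp(-b3))
  b1 <- if (p$stride == 1 && all(dim(x)[3:4] == do[3:4])) x else
    oracle_resize_bilinear(x, do[3], do[4])
  b1 * b2 * b3
}

# scalar-loop channel-then-spatial attention (reduction r, spatial kernel k)
oracle_sc_attention <- function(x, params) {
  d <- dim(x)
  n_hidden <- nrow(params$fc1_w)
  ch_w <- matrix(0, d[1], d[2])
  for (bi in seq_len(d[1])) {
    s <- numeric(d[2])
    for (ci in seq_len(d[2])) s[ci] <- mean(x[bi, ci, , ])
    z1 <- numeric(n_hidden)
    for (h in seq_len(n_hidden)) {
      z1[h] <- params$fc1_b[h] + sum(params$fc1_w[h, ] * s)
      if (z1[h] < 0) z1[h] <- 0
    }
    for (ci in seq_len(d[2])) {
      z2 <- params$fc2_b[ci] + sum(params$fc2_w[ci, ] * z1)
      ch_w[bi, ci] <- 1 / (1 + exp(-z2))
    }
  }
  xc <- x
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    xc[bi, ci, , ] <- x[bi, ci, , ] * ch_w[bi, ci]
  }
  pooled <- array(0, dim = c(d[1], 2, d[3], d[4]))
  for (bi in seq_len(d[1])) for (i in seq_len(d[3])) for (j in seq_len(d[4])) {
    pooled[bi, 1, i, j] <- mean(xc[bi, , i, j])
    pooled[bi, 2, i, j] <- max(xc[bi, , i, j])
  }
  k <- dim(params$spatial_w)[3]
  sm <- oracle_conv2d(pooled, params$spatial_w, params$spatial_b,
                      stride = 1, padding = (k - 1) / 2)
  sp_map <- 1 / (1 + exp(-sm))
  out <- xc
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    out[bi, ci, , ] <- xc[bi, ci, , ] * sp_map[bi, 1, , ]
  }
  list(channel_weights = ch_w, spatial_map = sp_map, out = out)
}

# all-pairs quadratic duplicate suppression: keep a box iff no higher-scored
# *kept* box overlaps it above the threshold
oracle_suppress <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- logical(length(scores))
  for (idx in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (oracle_iou(boxes[idx, ], boxes[j, ]) > iou_thr) { ok <- FALSE; break }
    }
    keep[idx] <- ok
  }
  which(keep)
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

# greedy score-ordered matcher, scalar loops (mirrors the COCO convention)
oracle_match <- function(truth, det_boxes, det_scores, iou_thr) {
  ord <- order(det_scores, decreasing = TRUE)
  nt <- nrow(truth)
  t_used <- logical(nt)
  tp <- 0; fp <- 0
  for (di in ord) {
    best <- 0; best_t <- 0
    for (ti in seq_len(nt)) {
      if (t_used[ti]) next
      v <- oracle_iou(det_boxes[di, ], truth[ti, ])
      if (v > best) { best <- v; best_t <- ti }
    }
    if (best >= iou_thr && best_t > 0) { tp <- tp + 1; t_used[best_t] <- TRUE }
    else fp <- fp + 1
  }
  list(TP = tp, FP = fp, FN = nt - tp)
}

# finite-difference gradient of a scalar function of an array
fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_array <- function(dims) array(stats::rnorm(prod(dims)), dim = dims)
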