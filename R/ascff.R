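# Adaptive spatial-channel feature fusion (ASCFF) neck.
#
# Three backbone levels (strides 8/16/32) are mapped to a common width by
# 1x1 convolutions, bilinearly resized to a target level's resolution,
# concatenated, passed through channel-then-spatial attention, reduced back
# to the common width by a 1x1 convolution and refined by a final 3x3
# feature-extraction convolution.  Fusion is repeated once per output scale;
# a stride-2 3x3 convolution of the fused deepest level provides the fourth
# (stride 64) output, mirroring the baseline channel-mapper layout.

#' Parameters of the channel-then-spatial attention block
#'
#' Channel branch: global average pool, two-layer bottleneck (`reduction`),
#' logistic. Spatial branch: per-position mean and max over channels, one
#' `spatial_kernel` x `spatial_kernel` convolution, logistic.
#'
#' @param channels Number of input channels.
#' @param reduction Bottleneck reduction ratio (hidden width is
#'   `max(1, channels / reduction)`).
#' @param spatial_kernel Odd kernel size of the spatial branch (default 7).
#' @return Object of class `attention_params`.
#' @export
attention_params <- function(channels, reduction = 16L, spatial_kernel = 7L) {
  stopifnot(channels >= 1, spatial_kernel %% 2 == 1)
  hidden <- max(1L, channels %/% as.integer(reduction))
  structure(list(
    fc1_w = matrix(stats::rnorm(hidden * channels, sd = sqrt(2 / channels)),
                   hidden, channels),
    fc1_b = numeric(hidden),
    fc2_w = matrix(stats::rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                   channels, hidden),
    # gates start open (sigmoid(2) ~ 0.88) so the freshly inserted block is
    # near-transparent and does not shrink feature magnitudes at step 0
    fc2_b = rep(2, channels),
    spatial_w = he_init(1L, 2L, spatial_kernel, spatial_kernel),
    spatial_b = 2,
    channels = as.integer(channels), spatial_kernel = as.integer(spatial_kernel)),
    class = "attention_params")
}

#' Spatial-channel attention forward pass
#'
#' Applies per-channel logistic weights (squeeze-excite style) followed by a
#' logistic spatial map; both weight sets lie strictly inside (0, 1).
#'
#' @param x `(batch, C, H, W)` feature map.
#' @param params [attention_params()] for `C` channels.
#' @param keep_cache Keep intermediates for [spatial_channel_attention_backward()].
#' @return `list(weights = list(channel_weights, spatial_map), out)`;
#'   with `keep_cache = TRUE` also `$cache`.
#' @export
spatial_channel_attention <- function(x, params, keep_cache = FALSE) {
  check_featuremap(x)
  d <- dim(x)
  if (d[2] != params$channels) {
    stop("attention expects ", params$channels, " channels, got ", d[2])
  }
  s <- global_avg_pool(x)                             # (b, C)
  z1 <- s %*% t(params$fc1_w) + matrix(params$fc1_b, d[1],
                                       length(params$fc1_b), byrow = TRUE)
  a1 <- relu(z1)
  z2 <- a1 %*% t(params$fc2_w) + matrix(params$fc2_b, d[1], d[2], byrow = TRUE)
  cw <- sigmoid(z2)                                   # (b, C)
  xc <- x * broadcast_channel(cw, d[3], d[4])

  pm <- apply(xc, c(1, 3, 4), mean)                   # (b, H, W)
  amax <- apply(xc, c(1, 3, 4), which.max)
  px <- apply(xc, c(1, 3, 4), max)
  pooled <- array(0, dim = c(d[1], 2L, d[3], d[4]))
  pooled[, 1, , ] <- pm
  pooled[, 2, , ] <- px
  k <- params$spatial_kernel
  fs <- conv2d(pooled, params$spatial_w, params$spatial_b, stride = 1L,
               padding = (k - 1L) %/% 2L, keep_cache = keep_cache)
  spre <- if (keep_cache) fs$out else fs
  smap <- sigmoid(spre)                               # (b, 1, H, W)
  sb <- array(smap[, 1, , ], dim = c(d[1], d[3], d[4]))
  out <- xc * aperm(array(sb, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  res <- list(weights = list(channel_weights = cw,
                             spatial_map = smap),
              out = out)
  if (keep_cache) {
    res$cache <- list(x = x, s = s, z1 = z1, a1 = a1, cw = cw, xc = xc,
                      amax = amax, conv = fs$cache, smap = smap, dim = d)
  }
  res
}

#' Spatial-channel attention backward pass
#'
#' @param grad Gradient w.r.t. the attention output.
#' @param cache Cache from `spatial_channel_attention(..., keep_cache = TRUE)`.
#' @param params The [attention_params()] used in the forward pass.
#' @return `list(dx, grads)` with `grads` named like the parameter fields.
#' @export
spatial_channel_attention_backward <- function(grad, cache, params) {
  d <- cache$dim
  sb <- array(cache$smap[, 1, , ], dim = c(d[1], d[3], d[4]))
  smap_b <- aperm(array(sb, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  d_xc <- grad * smap_b
  d_smap <- array(apply(grad * cache$xc, c(1, 3, 4), sum),
                  dim = c(d[1], 1L, d[3], d[4]))
  d_spre <- d_smap * cache$smap * (1 - cache$smap)
  bwc <- conv2d_backward(d_spre, cache$conv)
  d_pooled <- bwc$dx
  # mean branch
  d_xc <- d_xc + aperm(array(array(d_pooled[, 1, , ] / d[2],
                                   dim = c(d[1], d[3], d[4])),
                             dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  # max branch: gradient routes to the (first) argmax channel
  dmax <- array(d_pooled[, 2, , ], dim = c(d[1], d[3], d[4]))
  for (ci in seq_len(d[2])) {
    mask <- cache$amax == ci
    if (any(mask)) {
      d_xc[, ci, , ] <- array(d_xc[, ci, , ], dim = c(d[1], d[3], d[4])) +
        dmax * mask
    }
  }
  # xc = x * cw
  cw_b <- broadcast_channel(cache$cw, d[3], d[4])
  dx <- d_xc * cw_b
  d_cw <- apply(d_xc * cache$x, c(1, 2), sum)         # (b, C)
  d_z2 <- d_cw * cache$cw * (1 - cache$cw)
  d_fc2_w <- t(d_z2) %*% cache$a1
  d_fc2_b <- colSums(d_z2)
  d_a1 <- d_z2 %*% params$fc2_w
  d_z1 <- d_a1 * (cache$z1 > 0)
  d_fc1_w <- t(d_z1) %*% cache$s
  d_fc1_b <- colSums(d_z1)
  d_s <- d_z1 %*% params$fc1_w                        # (b, C)
  dx <- dx + broadcast_channel(d_s / (d[3] * d[4]), d[3], d[4])
  list(dx = dx,
       grads = list(fc1_w = d_fc1_w, fc1_b = d_fc1_b,
                    fc2_w = d_fc2_w, fc2_b = d_fc2_b,
                    spatial_w = bwc$dw, spatial_b = bwc$db))
}

#' Build an adaptive spatial-channel fusion neck
#'
#' @param in_channels Channel counts of the three pyramid levels.
#' @param out_channels Common width after lateral 1x1 convolutions
#'   (256 in the full-scale design; reduce for desk-scale work).
#' @param reduction,spatial_kernel Attention hyper-parameters.
#' @return Object of class `ascff_neck_params`.
#' @export
build_ascff_neck <- function(in_channels, out_channels = 256L,
                             reduction = 16L, spatial_kernel = 7L) {
  stopifnot(length(in_channels) == 3L)
  out_channels <- as.integer(out_channels)
  lateral <- lapply(in_channels, function(ci)
    conv_layer(ci, out_channels, k = 1L, stride = 1L, padding = 0L))
  structure(list(
    lateral = lateral,
    attention = attention_params(3L * out_channels, reduction, spatial_kernel),
    reduce = conv_layer(3L * out_channels, out_channels, k = 1L, stride = 1L,
                        padding = 0L),
    extract = conv_layer(out_channels, out_channels, k = 3L, stride = 1L),
    extra = conv_layer(out_channels, out_channels, k = 3L, stride = 2L),
    in_channels = as.integer(in_channels), out_channels = out_channels),
    class = "ascff_neck_params")
}

#' Align three pyramid levels to a common width and resolution
#'
#' Each level is passed through its lateral 1x1 convolution and bilinearly
#' resized to the spatial size of the target level.
#'
#' @param pyramid List of three `(b, C_l, H_l, W_l)` maps (strides 8/16/32).
#' @param target_index Which level's resolution to harmonize to (1, 2 or 3).
#' @param neck `ascff_neck_params`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List of three aligned `(b, out_channels, H_t, W_t)` maps (with
#'   `$cache` attached when requested).
#' @export
align_levels <- function(pyramid, target_index, neck, keep_cache = FALSE) {
  if (!target_index %in% 1:3) stop("target_index must be 1, 2 or 3")
  check_pyramid(pyramid)
  td <- dim(pyramid[[target_index]])
  mapped <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (l in 1:3) {
    fw <- layer_forward(neck$lateral[[l]], pyramid[[l]], keep_cache)
    m <- if (keep_cache) fw$out else fw
    caches[[l]] <- list(conv = if (keep_cache) fw$cache, pre_dim = dim(m))
    mapped[[l]] <- resize_bilinear(m, td[3], td[4])
  }
  if (keep_cache) attr(mapped, "cache") <- caches
  mapped
}

check_pyramid <- function(pyramid) {
  if (!is.list(pyramid) || length(pyramid) != 3L) {
    stop("feature pyramid must be a list of exactly three levels")
  }
  for (l in 1:3) check_featuremap(pyramid[[l]], paste0("pyramid level ", l))
  for (l in 2:3) {
    a <- dim(pyramid[[l - 1]])[3:4]; b <- dim(pyramid[[l]])[3:4]
    if (!all(b == ceiling(a / 2))) {
      stop("pyramid level ", l, " must halve the previous level's spatial dims")
    }
  }
  invisible(pyramid)
}

#' Fuse three aligned feature maps
#'
#' Concatenation, spatial-channel attention, 1x1 channel reduction and a
#' final 3x3 feature-extraction convolution.
#'
#' @param aligned List of three `(b, out_channels, H, W)` maps.
#' @param neck `ascff_neck_params`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return Fused `(b, out_channels, H, W)` map; `list(out, weights, cache)`
#'   when `keep_cache = TRUE` (weights are the attention weights used).
#' @export
ascff_fuse <- function(aligned, neck, keep_cache = FALSE) {
  dims <- lapply(aligned, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("aligned maps must share an identical shape")
  }
  cc <- concat_channels(aligned)
  att <- spatial_channel_attention(cc, neck$attention, keep_cache = keep_cache)
  fr <- layer_forward(neck$reduce, att$out, keep_cache)
  red <- if (keep_cache) fr$out else fr
  fe <- layer_forward(neck$extract, red, keep_cache)
  out <- if (keep_cache) fe$out else fe
  if (!keep_cache) return(out)
  list(out = out, weights = att$weights,
       cache = list(att = att$cache, reduce = fr$cache, extract = fe$cache,
                    c_sizes = vapply(aligned, function(m) dim(m)[2], integer(1))))
}

ascff_fuse_backward <- function(grad, cache, neck) {
  bwe <- conv2d_backward(grad, cache$extract)
  bwr <- conv2d_backward(bwe$dx, cache$reduce)
  bwa <- spatial_channel_attention_backward(bwr$dx, cache$att, neck$attention)
  d_aligned <- split_channels(bwa$dx, cache$c_sizes)
  list(d_aligned = d_aligned,
       grads = list(extract = list(w = bwe$dw, b = bwe$db),
                    reduce = list(w = bwr$dw, b = bwr$db),
                    attention = bwa$grads))
}

#' Adaptive spatial-channel fusion neck forward pass
#'
#' Runs align + fuse once per pyramid level and appends a stride-2 3x3
#' convolution of the fused deepest level, giving four outputs at strides
#' 8/16/32/64, all `out_channels` wide — the same shape contract as the
#' baseline channel-mapper neck.
#'
#' @param pyramid List of three backbone maps (strides 8/16/32).
#' @param neck `ascff_neck_params`.
#' @param keep_cache Keep intermediates for [ascff_neck_backward()].
#' @return `list(outputs = list of 4 maps, attention = per-level weights)`;
#'   with `keep_cache = TRUE` also `$cache`.
#' @export
ascff_neck <- function(pyramid, neck, keep_cache = FALSE) {
  check_pyramid(pyramid)
  outputs <- vector("list", 4L)
  weights <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (t in 1:3) {
    aligned <- align_levels(pyramid, t, neck, keep_cache = keep_cache)
    fz <- ascff_fuse(aligned, neck, keep_cache = keep_cache)
    if (keep_cache) {
      outputs[[t]] <- fz$out
      weights[[t]] <- fz$weights
      caches[[t]] <- list(align = attr(aligned, "cache"), fuse = fz$cache,
                          pyr_dims = lapply(pyramid, dim))
    } else {
      outputs[[t]] <- fz
    }
  }
  fx <- layer_forward(neck$extra, outputs[[3]], keep_cache)
  outputs[[4]] <- if (keep_cache) fx$out else fx
  res <- list(outputs = outputs, attention = if (keep_cache) weights)
  if (keep_cache) res$cache <- list(levels = caches, extra = fx$cache)
  res
}

#' Adaptive neck backward pass
#'
#' @param grads List of 4 gradients matching the neck outputs (`NULL` entries
#'   allowed for outputs not touched by the loss).
#' @param cache Cache from `ascff_neck(..., keep_cache = TRUE)`.
#' @param neck `ascff_neck_params`.
#' @return `list(d_pyramid, grads)`; `grads` mirrors the parameter structure.
#' @export
ascff_neck_backward <- function(grads, cache, neck) {
  acc <- function(a, b) if (is.null(a)) b else a + b
  g_fused <- grads[1:3]
  g_extra <- NULL
  if (!is.null(grads[[4]])) {
    bw4 <- conv2d_backward(grads[[4]], cache$extra)
    g_fused[[3]] <- acc(g_fused[[3]], bw4$dx)
    g_extra <- list(w = bw4$dw, b = bw4$db)
  }
  pg <- list(lateral = vector("list", 3L), attention = NULL, reduce = NULL,
             extract = NULL, extra = g_extra)
  d_mapped <- vector("list", 3L)   # grads w.r.t. post-lateral maps, per level
  add_param <- function(a, b) {
    if (is.null(a)) return(b)
    mapply(function(x, y) x + y, a, b, SIMPLIFY = FALSE)
  }
  for (t in 1:3) {
    if (is.null(g_fused[[t]])) next
    lc <- cache$levels[[t]]
    bwf <- ascff_fuse_backward(g_fused[[t]], lc$fuse, neck)
    pg$attention <- add_param(pg$attention, bwf$grads$attention)
    pg$reduce <- add_param(pg$reduce, bwf$grads$reduce)
    pg$extract <- add_param(pg$extract, bwf$grads$extract)
    for (l in 1:3) {
      pd <- lc$align[[l]]$pre_dim
      g <- resize_bilinear_backward(bwf$d_aligned[[l]], pd[3], pd[4])
      d_mapped[[l]] <- acc(d_mapped[[l]], g)
    }
  }
  d_pyramid <- vector("list", 3L)
  for (l in 1:3) {
    if (is.null(d_mapped[[l]])) next
    # all targets share one lateral conv per level; its cache is identical
    # across targets, so any non-NULL copy works
    lcache <- NULL
    for (t in 1:3) {
      cand <- cache$levels[[t]]$align[[l]]$conv
      if (!is.null(cand)) { lcache <- cand; break }
    }
    bwl <- conv2d_backward(d_mapped[[l]], lcache)
    pg$lateral[[l]] <- list(w = bwl$dw, b = bwl$db)
    d_pyramid[[l]] <- bwl$dx
  }
  list(d_pyramid = d_pyramid, grads = pg)
}

#' Build the baseline channel-mapper neck
#'
#' Per-level 1x1 convolution to a common width plus a stride-2 3x3
#' convolution of the mapped deepest level. Same output shapes as
#' [ascff_neck()]; no cross-scale fusion, no attention.
#'
#' @inheritParams build_ascff_neck
#' @return Object of class `mapper_neck_params`.
#' @export
build_mapper_neck <- function(in_channels, out_channels = 256L) {
  stopifnot(length(in_channels) == 3L)
  out_channels <- as.integer(out_channels)
  structure(list(
    lateral = lapply(in_channels, function(ci)
      conv_layer(ci, out_channels, k = 1L, stride = 1L, padding = 0L)),
    extra = conv_layer(out_channels, out_channels, k = 3L, stride = 2L),
    in_channels = as.integer(in_channels), out_channels = out_channels),
    class = "mapper_neck_params")
}

#' Baseline neck forward pass
#' @param pyramid List of three backbone maps.
#' @param neck `mapper_neck_params`.
#' @param keep_cache Keep intermediates for [mapper_neck_backward()].
#' @return As [ascff_neck()] (attention slot is `NULL`).
#' @export
mapper_neck <- function(pyramid, neck, keep_cache = FALSE) {
  check_pyramid(pyramid)
  outputs <- vector("list", 4L)
  caches <- vector("list", 4L)
  for (l in 1:3) {
    fw <- layer_forward(neck$lateral[[l]], pyramid[[l]], keep_cache)
    outputs[[l]] <- if (keep_cache) fw$out else fw
    if (keep_cache) caches[[l]] <- fw$cache
  }
  fx <- layer_forward(neck$extra, outputs[[3]], keep_cache)
  outputs[[4]] <- if (keep_cache) fx$out else fx
  if (keep_cache) caches[[4]] <- fx$cache
  res <- list(outputs = outputs, attention = NULL)
  if (keep_cache) res$cache <- caches
  res
}

#' Baseline neck backward pass
#' @inheritParams ascff_neck_backward
#' @param neck `mapper_neck_params`.
#' @export
mapper_neck_backward <- function(grads, cache, neck) {
  acc <- function(a, b) if (is.null(a)) b else a + b
  pg <- list(lateral = vector("list", 3L), extra = NULL)
  g3_extra <- NULL
  if (!is.null(grads[[4]])) {
    bw4 <- conv2d_backward(grads[[4]], cache[[4]])
    pg$extra <- list(w = bw4$dw, b = bw4$db)
    g3_extra <- bw4$dx
  }
  d_pyramid <- vector("list", 3L)
  for (l in 1:3) {
    g <- grads[[l]]
    if (l == 3L) g <- acc(g, g3_extra)
    if (is.null(g)) next
    bw <- conv2d_backward(g, cache[[l]])
    pg$lateral[[l]] <- list(w = bw$dw, b = bw$db)
    d_pyramid[[l]] <- bw$dx
  }
  list(d_pyramid = d_pyramid, grads = pg)
}

neck_n_params <- function(neck) {
  n <- sum(vapply(neck$lateral, layer_n_params, numeric(1))) +
    layer_n_params(neck$extra)
  if (inherits(neck, "ascff_neck_params")) {
    ap <- neck$attention
    n <- n + length(ap$fc1_w) + length(ap$fc1_b) + length(ap$fc2_w) +
      length(ap$fc2_b) + length(ap$spatial_w) + length(ap$spatial_b) +
      layer_n_params(neck$reduce) + layer_n_params(neck$extract)
  }
  n
}
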