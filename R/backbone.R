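# Compact residual backbone hosting plain or self-calibrated convolutions.
#
# Layout (desk-scale analogue of a ResNet-style feature extractor):
#   stem:    3x3 stride-2 convolution, 3 -> widths[1] channels
#   stage i: 3x3 stride-2 transition (widths[i-1] -> widths[i]) followed by
#            n_blocks channel-preserving residual blocks, each containing
#            exactly one 3x3 convolution:  y = relu(x + conv3x3(x)).
# With four stages the stage outputs sit at strides 4 / 8 / 16 / 32; stages
# 2..4 form the three-level feature pyramid consumed by the neck.
# Residual-block convolutions are the ones eligible for replacement by the
# self-calibrated block; stem and transition layers are left untouched.

he_init <- function(cout, cin, kh, kw) {
  array(stats::rnorm(cout * cin * kh * kw, sd = sqrt(2 / (cin * kh * kw))),
        dim = c(cout, cin, kh, kw))
}

conv_layer <- function(cin, cout, k = 3L, stride = 1L, padding = (k - 1L) %/% 2L) {
  structure(list(w = he_init(cout, cin, k, k), b = numeric(cout),
                 stride = as.integer(stride), padding = as.integer(padding)),
            class = "conv_spec")
}

layer_forward <- function(layer, x, keep_cache = FALSE) {
  if (inherits(layer, "rscconv_params")) {
    rscconv_forward(x, layer, keep_cache = keep_cache)
  } else {
    conv2d(x, layer$w, layer$b, stride = layer$stride, padding = layer$padding,
           keep_cache = keep_cache)
  }
}

layer_backward <- function(layer, grad, cache) {
  if (inherits(layer, "rscconv_params")) {
    bw <- rscconv_backward(grad, cache, layer)
    list(dx = bw$dx,
         grads = list(refine_kernel = bw$drefine_kernel,
                      refine_bias = bw$drefine_bias,
                      calib_kernel = bw$dcalib_kernel,
                      calib_bias = bw$dcalib_bias))
  } else {
    bw <- conv2d_backward(grad, cache)
    list(dx = bw$dx, grads = list(w = bw$dw, b = bw$db))
  }
}

layer_n_params <- function(layer) {
  if (inherits(layer, "rscconv_params")) rscconv_n_params(layer)
  else length(layer$w) + length(layer$b)
}

#' Build a compact residual backbone specification
#'
#' @param widths Channel widths of the four stages (stage outputs sit at
#'   strides 4/8/16/32 relative to the input image).
#' @param n_blocks Residual blocks per stage (each block holds exactly one
#'   3x3 convolution).
#' @param in_channels Input image channels (3 for RGB).
#' @return An object of class `backbone_spec`.
#' @export
build_backbone <- function(widths = c(8L, 16L, 24L, 32L), n_blocks = 1L,
                           in_channels = 3L) {
  stopifnot(length(widths) == 4L, n_blocks >= 1L)
  widths <- as.integer(widths)
  stem <- conv_layer(in_channels, widths[1], k = 3L, stride = 2L)
  stages <- vector("list", 4L)
  prev <- widths[1]
  for (s in 1:4) {
    trans <- conv_layer(prev, widths[s], k = 3L, stride = 2L)
    blocks <- lapply(seq_len(n_blocks), function(i) {
      list(conv = conv_layer(widths[s], widths[s], k = 3L, stride = 1L))
    })
    stages[[s]] <- list(transition = trans, blocks = blocks)
    prev <- widths[s]
  }
  structure(list(stem = stem, stages = stages, widths = widths,
                 n_blocks = as.integer(n_blocks),
                 in_channels = as.integer(in_channels)),
            class = "backbone_spec")
}

#' Swap residual-block 3x3 convolutions for self-calibrated blocks
#'
#' Every residual block's 3x3 convolution is replaced by a self-calibrated
#' block initialised from that layer's current weights via
#' [inherit_pretrained()]. Already-replaced blocks are left as they are, so
#' the operation is idempotent. Stem and stage-transition convolutions are
#' not inside residual blocks and are never touched.
#'
#' @param backbone `backbone_spec` from [build_backbone()].
#' @param use_rscconv If `FALSE` the spec is returned unchanged (with an
#'   empty report).
#' @param gate_calibration Passed to the new blocks.
#' @return `list(backbone, report)` where `report` is a data.frame with one
#'   row per replaced layer (stage, block, channels, stride, added_params).
#' @export
patch_backbone <- function(backbone, use_rscconv = TRUE,
                           gate_calibration = FALSE) {
  stopifnot(inherits(backbone, "backbone_spec"))
  rows <- list()
  if (use_rscconv) {
    for (s in seq_along(backbone$stages)) {
      for (bl in seq_along(backbone$stages[[s]]$blocks)) {
        lay <- backbone$stages[[s]]$blocks[[bl]]$conv
        if (inherits(lay, "rscconv_params")) next   # already patched
        d <- dim(lay$w)
        if (d[3] != 3L || d[4] != 3L || d[1] != d[2]) {
          warning("stage ", s, " block ", bl,
                  " has no square 3x3 convolution; skipped")
          next
        }
        new <- inherit_pretrained(lay$w, lay$b, stride = lay$stride,
                                  padding = lay$padding,
                                  gate_calibration = gate_calibration)
        backbone$stages[[s]]$blocks[[bl]]$conv <- new
        rows[[length(rows) + 1L]] <- data.frame(
          stage = s, block = bl, channels = d[1], stride = lay$stride,
          added_params = length(lay$w) + length(lay$b))
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = integer(), block = integer(), channels = integer(),
               stride = integer(), added_params = integer())
  list(backbone = backbone, report = report)
}

#' Scale-preserving calibration of patched blocks
#'
#' A freshly inserted self-calibrated block multiplies three feature maps,
#' so its output magnitude is roughly the cube of the input magnitude; when
#' features are small (e.g. after a warm-up) this crushes the signal and
#' the downstream network trains on noise. This routine runs one forward
#' pass on a sample input and rescales each block's kernels so the block
#' output RMS matches its input RMS — the same idea as data-dependent
#' (LSUV-style) initialisation. Pretrained filters are preserved up to a
#' positive scalar.
#'
#' @param backbone A (possibly patched) `backbone_spec`.
#' @param x_sample `(1, C, H, W)` sample input (e.g. one training image).
#' @return The rescaled backbone.
#' @export
calibrate_backbone_scales <- function(backbone, x_sample) {
  cur <- relu(layer_forward(backbone$stem, x_sample))
  for (s in seq_along(backbone$stages)) {
    st <- backbone$stages[[s]]
    cur <- relu(layer_forward(st$transition, cur))
    for (bl in seq_along(st$blocks)) {
      lay <- backbone$stages[[s]]$blocks[[bl]]$conv
      if (inherits(lay, "rscconv_params")) {
        out <- rscconv_forward(cur, lay)
        r_in <- sqrt(mean(cur^2)); r_out <- sqrt(mean(out^2))
        if (r_out > 1e-12 && r_in > 1e-12) {
          g <- r_in / r_out
          if (lay$gate_calibration) {
            # gated branch is bounded; put the whole factor on the
            # refinement branch
            lay$refine_kernel <- lay$refine_kernel * g
            lay$refine_bias <- lay$refine_bias * g
          } else {
            lay$refine_kernel <- lay$refine_kernel * sqrt(g)
            lay$refine_bias <- lay$refine_bias * sqrt(g)
            lay$calib_kernel <- lay$calib_kernel * sqrt(g)
            lay$calib_bias <- lay$calib_bias * sqrt(g)
          }
          backbone$stages[[s]]$blocks[[bl]]$conv <- lay
          out <- rscconv_forward(cur, lay)
        }
        cur <- relu(cur + out)
      } else {
        cur <- relu(cur + layer_forward(lay, cur))
      }
    }
  }
  backbone
}

#' Total trainable parameter count of a backbone
#' @param backbone `backbone_spec`.
#' @return Integer.
#' @export
backbone_n_params <- function(backbone) {
  n <- layer_n_params(backbone$stem)
  for (st in backbone$stages) {
    n <- n + layer_n_params(st$transition)
    for (bl in st$blocks) n <- n + layer_n_params(bl$conv)
  }
  n
}

#' Backbone forward pass
#'
#' @param backbone `backbone_spec`.
#' @param x `(batch, in_channels, H, W)` image batch.
#' @param keep_cache Keep intermediates for [backbone_backward()].
#' @return `list(pyramid = list(level1, level2, level3), stage_outputs)`;
#'   the pyramid holds stage 2..4 outputs (strides 8/16/32). With
#'   `keep_cache = TRUE` also `$cache`.
#' @export
backbone_forward <- function(backbone, x, keep_cache = FALSE) {
  check_featuremap(x)
  fw <- layer_forward(backbone$stem, x, keep_cache)
  pre <- if (keep_cache) fw$out else fw
  cur <- relu(pre)
  cache <- if (keep_cache) {
    list(stem = list(cache = fw$cache, pre = pre), stages = list())
  } else NULL
  stage_outputs <- vector("list", length(backbone$stages))
  for (s in seq_along(backbone$stages)) {
    st <- backbone$stages[[s]]
    fw <- layer_forward(st$transition, cur, keep_cache)
    pre <- if (keep_cache) fw$out else fw
    cur <- relu(pre)
    scache <- list(transition = if (keep_cache) list(cache = fw$cache, pre = pre),
                   blocks = list())
    for (bl in seq_along(st$blocks)) {
      fw <- layer_forward(st$blocks[[bl]]$conv, cur, keep_cache)
      convo <- if (keep_cache) fw$out else fw
      pre <- cur + convo
      if (keep_cache) {
        scache$blocks[[bl]] <- list(cache = fw$cache, pre = pre)
      }
      cur <- relu(pre)
    }
    if (keep_cache) cache$stages[[s]] <- scache
    stage_outputs[[s]] <- cur
  }
  out <- list(pyramid = stage_outputs[2:4], stage_outputs = stage_outputs)
  if (keep_cache) out$cache <- cache
  out
}

#' Backbone backward pass
#'
#' @param backbone `backbone_spec`.
#' @param cache Cache from `backbone_forward(..., keep_cache = TRUE)`.
#' @param grad_stages List of 4 gradients (one per stage output); entries may
#'   be `NULL` when no loss touches that stage.
#' @return `list(grads, dx)`: `grads` mirrors the backbone structure.
#' @export
backbone_backward <- function(backbone, cache, grad_stages) {
  g_next <- NULL   # gradient flowing into the *output* of the current stage
  grads <- list(stages = vector("list", length(backbone$stages)))
  for (s in rev(seq_along(backbone$stages))) {
    st <- backbone$stages[[s]]
    g <- grad_stages[[s]]
    if (is.null(g)) g <- 0
    if (!is.null(g_next)) g <- g + g_next
    sgr <- list(blocks = vector("list", length(st$blocks)))
    for (bl in rev(seq_along(st$blocks))) {
      bc <- cache$stages[[s]]$blocks[[bl]]
      g <- relu_backward(g, bc$pre)
      bw <- layer_backward(st$blocks[[bl]]$conv, g, bc$cache)
      sgr$blocks[[bl]] <- list(conv = bw$grads)   # mirror the param tree
      g <- g + bw$dx                       # residual skip
    }
    tc <- cache$stages[[s]]$transition
    g <- relu_backward(g, tc$pre)
    bw <- layer_backward(st$transition, g, tc$cache)
    sgr$transition <- bw$grads
    grads$stages[[s]] <- sgr
    g_next <- bw$dx
  }
  g <- relu_backward(g_next, cache$stem$pre)
  bw <- layer_backward(backbone$stem, g, cache$stem$cache)
  grads$stem <- bw$grads
  list(grads = grads, dx = bw$dx)
}
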