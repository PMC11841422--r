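# Compact single-class reference detector.
#
# The detector hosts the patched backbone and the fusion neck so the three
# ablation axes (pretrained warm-up / self-calibrated convolution / adaptive
# fusion) can be exercised end to end on a CPU.  The head is deliberately
# not a transformer decoder: a center-heatmap + box-size head is single
# class, anchor free and cheap, and the components under study live in the
# backbone and neck, not the head.

#' Reference detector configuration
#'
#' @param widths Backbone stage widths.
#' @param n_blocks Residual blocks per backbone stage.
#' @param neck_channels Common neck width.
#' @param use_pretrained Warm-start the backbone by a brief image
#'   reconstruction task before detection training (the desk-scale stand-in
#'   for large-corpus pretrained weights).
#' @param use_rscconv Replace residual-block 3x3 convolutions by
#'   self-calibrated blocks (weights inherited from the current kernels).
#' @param use_ascff Use the adaptive fusion neck instead of the baseline
#'   channel mapper.
#' @param learning_rate Initial learning rate (default 0.002).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param epochs Training epochs (default 12).
#' @param batch_size Scenes per optimizer step (default 8).
#' @param backbone_lr_multiplier Backbone learning-rate factor (default 0.1).
#' @param input_size Square input size the model is trained at.
#' @param pretrain_epochs Epochs of the warm-up task when `use_pretrained`.
#' @param reduction,spatial_kernel Attention hyper-parameters of the neck.
#' @param gate_calibration Logistic gate on the calibration branch.
#' @param seed Master seed; fans out to initialisation, pretraining and
#'   shuffling.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(widths = c(8L, 12L, 16L, 24L), n_blocks = 1L,
                            neck_channels = 16L,
                            use_pretrained = FALSE, use_rscconv = FALSE,
                            use_ascff = FALSE,
                            learning_rate = 0.002, weight_decay = 1e-4,
                            epochs = 12L, batch_size = 8L,
                            backbone_lr_multiplier = 0.1,
                            input_size = 256L, pretrain_epochs = 2L,
                            reduction = 16L, spatial_kernel = 7L,
                            gate_calibration = FALSE, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be at least 1")
  if (backbone_lr_multiplier <= 0 || backbone_lr_multiplier > 1) {
    stop("backbone_lr_multiplier must lie in (0, 1]")
  }
  structure(list(widths = as.integer(widths), n_blocks = as.integer(n_blocks),
                 neck_channels = as.integer(neck_channels),
                 use_pretrained = isTRUE(use_pretrained),
                 use_rscconv = isTRUE(use_rscconv),
                 use_ascff = isTRUE(use_ascff),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 backbone_lr_multiplier = backbone_lr_multiplier,
                 input_size = as.integer(input_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 gate_calibration = isTRUE(gate_calibration),
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Build the reference detector
#'
#' Assembly order matters for the transfer-learning semantics: residual
#' blocks are patched first (the self-calibrated blocks inherit the current
#' 3x3 kernels) and the resulting backbone is then warmed up on the donor
#' corpus, so the transferred weights are native to the architecture being
#' fine-tuned. (Patching a backbone *after* warm-up was tried and rejected:
#' the three-factor product cannot reproduce the donor convolution's
#' function, so patching destroys exactly what the warm-up learned, and the
#' throttled backbone learning rate then prevents repair.)
#'
#' @param cfg A [detector_config()].
#' @param pretrain_scenes Scenes for the warm-up task; required when
#'   `cfg$use_pretrained` is set.
#' @return Object of class `detector_model`.
#' @export
build_model <- function(cfg, pretrain_scenes = NULL) {
  stopifnot(inherits(cfg, "detector_config"))
  set.seed(cfg$seed)
  backbone <- build_backbone(cfg$widths, cfg$n_blocks)
  patch_report <- NULL
  if (cfg$use_rscconv) {
    pr <- patch_backbone(backbone, use_rscconv = TRUE,
                         gate_calibration = cfg$gate_calibration)
    patch_report <- pr$report
    sample <- if (length(pretrain_scenes)) {
      image_to_tensor(pretrain_scenes[[1]]$image)
    } else {
      array(stats::runif(3 * cfg$input_size^2),
            dim = c(1, 3, cfg$input_size, cfg$input_size))
    }
    backbone <- calibrate_backbone_scales(pr$backbone, sample)
  }
  if (cfg$use_pretrained) {
    if (is.null(pretrain_scenes) || length(pretrain_scenes) == 0) {
      stop("use_pretrained requires pretrain_scenes for the warm-up task")
    }
    backbone <- pretrain_backbone(backbone, pretrain_scenes,
                                  epochs = cfg$pretrain_epochs,
                                  learning_rate = cfg$learning_rate)
  }
  in_ch <- cfg$widths[2:4]
  neck <- if (cfg$use_ascff) {
    build_ascff_neck(in_ch, out_channels = cfg$neck_channels,
                     reduction = cfg$reduction,
                     spatial_kernel = cfg$spatial_kernel)
  } else {
    build_mapper_neck(in_ch, out_channels = cfg$neck_channels)
  }
  head <- list(
    conv1 = conv_layer(cfg$neck_channels, cfg$neck_channels, k = 3L),
    conv2 = conv_layer(cfg$neck_channels, 5L, k = 1L, padding = 0L))
  # start the heatmap at a low prior probability so early training is not
  # dominated by the negative cells
  head$conv2$b[1] <- -3
  structure(list(cfg = cfg, backbone = backbone, neck = neck, head = head,
                 stride = 8L, patch_report = patch_report),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model>",
      sprintf("pretrained=%s rscconv=%s ascff=%s, %d parameters\n",
              x$cfg$use_pretrained, x$cfg$use_rscconv, x$cfg$use_ascff,
              model_n_params(x)))
  invisible(x)
}

#' Total trainable parameter count of a detector
#' @param model `detector_model`.
#' @return Integer.
#' @export
model_n_params <- function(model) {
  backbone_n_params(model$backbone) + neck_n_params(model$neck) +
    layer_n_params(model$head$conv1) + layer_n_params(model$head$conv2)
}

# (H, W, 3) image array in [0,1] -> (1, 3, H, W) tensor
image_to_tensor <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("expected an (H, W, 3) image array")
  }
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(1L, dim(x))
  x
}

neck_forward <- function(model, pyramid, keep_cache = FALSE) {
  if (inherits(model$neck, "ascff_neck_params")) {
    ascff_neck(pyramid, model$neck, keep_cache = keep_cache)
  } else {
    mapper_neck(pyramid, model$neck, keep_cache = keep_cache)
  }
}

neck_backward_any <- function(model, grads, cache) {
  if (inherits(model$neck, "ascff_neck_params")) {
    ascff_neck_backward(grads, cache, model$neck)
  } else {
    mapper_neck_backward(grads, cache, model$neck)
  }
}

# full forward to head output (1, 5, gh, gw); channel 1 = heat logit,
# channels 2:3 = sub-cell center offsets (clamped to half a cell at decode
# time), channels 4:5 = log box width/height in stride units
model_forward <- function(model, x, keep_cache = FALSE) {
  bb <- backbone_forward(model$backbone, x, keep_cache = keep_cache)
  nk <- neck_forward(model, bb$pyramid, keep_cache = keep_cache)
  f <- nk$outputs[[1]]
  h1 <- layer_forward(model$head$conv1, f, keep_cache)
  h1o <- if (keep_cache) h1$out else h1
  a1 <- relu(h1o)
  h2 <- layer_forward(model$head$conv2, a1, keep_cache)
  out <- if (keep_cache) h2$out else h2
  res <- list(out = out)
  if (keep_cache) {
    res$cache <- list(backbone = bb$cache, neck = nk$cache, h1 = h1$cache,
                      h1_pre = h1o, h2 = h2$cache)
  }
  res
}

# backward from head-output gradient to all parameter gradients
model_backward <- function(model, grad_out, cache) {
  bw2 <- conv2d_backward(grad_out, cache$h2)
  g <- relu_backward(bw2$dx, cache$h1_pre)
  bw1 <- conv2d_backward(g, cache$h1)
  nk <- neck_backward_any(model, list(bw1$dx, NULL, NULL, NULL), cache$neck)
  gs <- list(NULL, nk$d_pyramid[[1]], nk$d_pyramid[[2]], nk$d_pyramid[[3]])
  bb <- backbone_backward(model$backbone, cache$backbone, gs)
  list(backbone = bb$grads, neck = nk$grads,
       head = list(conv1 = list(w = bw1$dw, b = bw1$db),
                   conv2 = list(w = bw2$dw, b = bw2$db)))
}

#' Decode a center heatmap, offset and size maps into detections
#'
#' Peaks are grid cells that are local maxima of the heatmap over their 3x3
#' neighbourhood with probability strictly above the threshold; each peak
#' becomes a box centered at the cell center plus the predicted sub-cell
#' offset (clamped to half a cell), with width/height `exp(size) * stride`,
#' clipped to the image. Overlapping decoded boxes are de-duplicated by
#' greedy suppression at IoU 0.5.
#'
#' @param heat Matrix of heatmap probabilities (grid rows x cols).
#' @param off_x,off_y Matrices of sub-cell center offsets (cell units).
#' @param size_w,size_h Matrices of log-size predictions (stride units).
#' @param stride Grid stride in pixels.
#' @param score_threshold Strict lower bound on returned scores.
#' @param image_width,image_height Clipping bounds in pixels.
#' @return A [detection_set()].
#' @export
decode_detections <- function(heat, off_x, off_y, size_w, size_h, stride = 8L,
                              score_threshold = 0.5,
                              image_width = ncol(heat) * stride,
                              image_height = nrow(heat) * stride) {
  gh <- nrow(heat); gw <- ncol(heat)
  padded <- matrix(-Inf, gh + 2, gw + 2)
  padded[2:(gh + 1), 2:(gw + 1)] <- heat
  is_peak <- matrix(TRUE, gh, gw)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    is_peak <- is_peak & heat >= padded[(1 + di):(gh + di), (1 + dj):(gw + dj)]
  }
  sel <- which(is_peak & heat > score_threshold, arr.ind = TRUE)
  if (nrow(sel) == 0) return(detection_set())
  cx <- (sel[, 2] - 0.5 + pmin(0.5, pmax(-0.5, off_x[sel]))) * stride
  cy <- (sel[, 1] - 0.5 + pmin(0.5, pmax(-0.5, off_y[sel]))) * stride
  bw <- exp(size_w[sel]) * stride
  bh <- exp(size_h[sel]) * stride
  boxes <- cbind(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
  boxes <- clip_boxes(boxes, image_width, image_height)
  # half-pixel minimum: sub-pixel slivers are numerically fragile and never
  # meaningful detections
  ok <- is.finite(boxes[, 1] + boxes[, 2] + boxes[, 3] + boxes[, 4]) &
    boxes[, 3] - boxes[, 1] >= 0.5 & boxes[, 4] - boxes[, 2] >= 0.5
  boxes <- boxes[ok, , drop = FALSE]
  scores <- heat[sel][ok]
  if (nrow(boxes) == 0) return(detection_set())
  keep <- greedy_suppress(boxes, scores, 0.5)
  detection_set(boxes[keep, , drop = FALSE], scores[keep])
}

#' Run the detector on one image
#'
#' @param model A trained `detector_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`. Images whose size differs
#'   from the training input size are bilinearly resized for inference and
#'   the boxes mapped back to the original pixel grid.
#' @param score_threshold Strict confidence threshold (default 0.5, the
#'   counting rule; use a small value when computing PR curves).
#' @return A [detection_set()] in the original image coordinates.
#' @export
detect <- function(model, image, score_threshold = 0.5) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("detect() expects an (H, W, 3) image array")
  }
  h0 <- dim(image)[1]; w0 <- dim(image)[2]
  n <- model$cfg$input_size
  img <- if (h0 != n || w0 != n) resize_image(image, n, n) else image
  fw <- model_forward(model, image_to_tensor(img))
  out <- fw$out
  heat <- sigmoid(out[1, 1, , ])
  dets <- decode_detections(heat, out[1, 2, , ], out[1, 3, , ],
                            out[1, 4, , ], out[1, 5, , ],
                            stride = model$stride,
                            score_threshold = score_threshold,
                            image_width = n, image_height = n)
  if ((h0 != n || w0 != n) && length(dets) > 0) {
    b <- dets$boxes
    b[, c(1, 3)] <- b[, c(1, 3)] * w0 / n
    b[, c(2, 4)] <- b[, c(2, 4)] * h0 / n
    dets <- detection_set(clip_boxes(b, w0, h0), dets$scores)
  }
  dets
}

#' A detector closure suitable for [run_counting()]
#'
#' @param model A trained `detector_model`.
#' @param score_threshold Passed to [detect()].
#' @return `function(image) -> detection_set`.
#' @export
as_detector <- function(model, score_threshold = 0.5) {
  function(image) detect(model, image, score_threshold)
}
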