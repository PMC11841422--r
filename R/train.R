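# Training: loss, decoupled-weight-decay Adam, warm-up pretraining,
# the main training loop and the ablation harness.

# --- targets and loss --------------------------------------------------------

# build heatmap + offset + size targets on the stride grid for one scene
make_targets <- function(annotations, grid_h, grid_w, stride) {
  heat <- matrix(0, grid_h, grid_w)
  off_x <- matrix(0, grid_h, grid_w)
  off_y <- matrix(0, grid_h, grid_w)
  size_w <- matrix(0, grid_h, grid_w)
  size_h <- matrix(0, grid_h, grid_w)
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      a <- annotations[i, ]
      cx <- (a$x_min + a$x_max) / 2; cy <- (a$y_min + a$y_max) / 2
      j <- min(grid_w, max(1L, floor(cx / stride) + 1L))
      r <- min(grid_h, max(1L, floor(cy / stride) + 1L))
      heat[r, j] <- 1
      off_x[r, j] <- cx / stride - (j - 0.5)
      off_y[r, j] <- cy / stride - (r - 0.5)
      size_w[r, j] <- log(max(a$x_max - a$x_min, 2) / stride)
      size_h[r, j] <- log(max(a$y_max - a$y_min, 2) / stride)
    }
  }
  list(heat = heat, off_x = off_x, off_y = off_y,
       size_w = size_w, size_h = size_h)
}

huber <- function(e, delta = 1) {
  ifelse(abs(e) <= delta, 0.5 * e^2, delta * (abs(e) - 0.5 * delta))
}
huber_grad <- function(e, delta = 1) {
  ifelse(abs(e) <= delta, e, delta * sign(e))
}

# loss on the raw head output (1, 5, gh, gw); returns value and gradient
detector_loss <- function(out, targets, size_weight = 0.1,
                          offset_weight = 0.2) {
  z <- out[1, 1, , ]
  p <- sigmoid(z)
  t <- targets$heat
  n_pos <- sum(t); n_cells <- length(t)
  w_pos <- if (n_pos > 0) min(50, (n_cells - n_pos) / n_pos) else 1
  wts <- ifelse(t > 0, w_pos, 1)
  eps <- 1e-12
  bce <- -(t * log(p + eps) + (1 - t) * log(1 - p + eps))
  loss_heat <- sum(wts * bce) / sum(wts)
  d_z <- wts * (p - t) / sum(wts)
  grad <- array(0, dim = dim(out))
  grad[1, 1, , ] <- d_z
  loss_reg <- 0
  if (n_pos > 0) {
    pos <- t > 0
    reg_t <- list(targets$off_x, targets$off_y, targets$size_w, targets$size_h)
    reg_w <- c(offset_weight, offset_weight, size_weight, size_weight)
    for (k in 1:4) {
      e <- out[1, k + 1, , ] - reg_t[[k]]
      loss_reg <- loss_reg + reg_w[k] * sum(huber(e[pos])) / n_pos
      g <- matrix(0, nrow(t), ncol(t))
      g[pos] <- huber_grad(e[pos]) / n_pos
      grad[1, k + 1, , ] <- reg_w[k] * g
    }
  }
  list(loss = loss_heat + loss_reg, grad = grad)
}

# --- generic parameter-tree arithmetic --------------------------------------

# walk a gradient tree and apply f(param_leaf, grad_leaf, state_leaf) at every
# numeric leaf of the gradient; returns updated (params, state)
tree_map <- function(params, grads, state, f) {
  if (is.null(grads)) return(list(params = params, state = state))
  if (is.numeric(grads)) {
    res <- f(params, grads, state)
    return(list(params = res$param, state = res$state))
  }
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    key <- nm
    sub <- tree_map(params[[key]], grads[[nm]],
                    if (is.null(state)) NULL else state[[key]], f)
    params[[key]] <- sub$params
    if (is.null(state)) state <- list()
    state[[key]] <- sub$state
  }
  # unnamed list nodes (stages, blocks, lateral)
  if (is.null(names(grads)) && is.list(grads)) {
    for (i in seq_along(grads)) {
      if (is.null(grads[[i]])) next
      sub <- tree_map(params[[i]], grads[[i]],
                      if (is.null(state) || length(state) < i) NULL
                      else state[[i]], f)
      params[[i]] <- sub$params
      if (is.null(state)) state <- vector("list", length(grads))
      if (length(state) < length(grads)) {
        length(state) <- length(grads)
      }
      state[[i]] <- sub$state
    }
  }
  list(params = params, state = state)
}

# elementwise sum of two structurally identical gradient trees
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(b)) {
    v <- tree_add(a[[i]], b[[i]])
    if (!is.null(v)) out[i] <- list(v)
  }
  out
}

# AdamW update of one parameter subtree
adamw_update <- function(params, grads, state, lr, weight_decay, step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  f <- function(p, g, s) {
    if (is.null(s)) s <- list(m = 0 * g, v = 0 * g)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^step)
    vh <- s$v / (1 - beta2^step)
    list(param = p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p),
         state = s)
  }
  tree_map(params, grads, state, f)
}

# --- warm-up pretraining -----------------------------------------------------

# per-layer pre-activation RMS profile of a backbone on one sample input
backbone_scale_profile <- function(backbone, x) {
  rms <- function(a) sqrt(mean(a^2))
  prof <- list(stages = vector("list", length(backbone$stages)))
  z <- layer_forward(backbone$stem, x)
  prof$stem <- rms(z)
  cur <- relu(z)
  for (s in seq_along(backbone$stages)) {
    st <- backbone$stages[[s]]
    z <- layer_forward(st$transition, cur)
    pr <- list(transition = rms(z), blocks = numeric(length(st$blocks)))
    cur <- relu(z)
    for (bl in seq_along(st$blocks)) {
      z <- layer_forward(st$blocks[[bl]]$conv, cur)
      pr$blocks[bl] <- rms(z)
      cur <- relu(cur + z)
    }
    prof$stages[[s]] <- pr
  }
  prof
}

# rescale a backbone's layers (positively homogeneous, so this is exact for
# conv layers) until its scale profile matches `ref`; used after warm-up,
# whose regression objective systematically shrinks trunk activations while
# the readout grows -- the classic scale drift of normalization-free nets
match_scale_profile <- function(backbone, ref, x) {
  rms <- function(a) sqrt(mean(a^2))
  rescale <- function(layer, g) {
    layer$w <- layer$w * g; layer$b <- layer$b * g
    layer
  }
  z <- layer_forward(backbone$stem, x)
  g <- if (rms(z) > 1e-12) ref$stem / rms(z) else 1
  backbone$stem <- rescale(backbone$stem, g)
  cur <- relu(z * g)
  for (s in seq_along(backbone$stages)) {
    st <- backbone$stages[[s]]
    z <- layer_forward(st$transition, cur)
    g <- if (rms(z) > 1e-12) ref$stages[[s]]$transition / rms(z) else 1
    backbone$stages[[s]]$transition <- rescale(st$transition, g)
    cur <- relu(z * g)
    for (bl in seq_along(st$blocks)) {
      z <- layer_forward(st$blocks[[bl]]$conv, cur)
      g <- if (rms(z) > 1e-12) ref$stages[[s]]$blocks[bl] / rms(z) else 1
      backbone$stages[[s]]$blocks[[bl]]$conv <-
        rescale(st$blocks[[bl]]$conv, g)
      cur <- relu(cur + z * g)
    }
  }
  backbone
}

#' Warm up a backbone on a donor detection corpus
#'
#' Desk-scale stand-in for large-corpus pretrained weights: train a donor
#' detector (plain convolutions, baseline neck) on a disjoint set of
#' scenes, keep its backbone, discard its neck and head.
#'
#' @param backbone A `backbone_spec`.
#' @param scenes List of donor `synthetic_scene` objects (annotated,
#'   disjoint from the fine-tuning data).
#' @param epochs Warm-up epochs.
#' @param learning_rate Adam learning rate for the warm-up.
#' @return The warmed-up backbone.
#' @export
#' @details
#' The warm-up mirrors real transfer learning: a donor detector (plain
#' convolutions, baseline neck) is trained on a disjoint corpus of scenes
#' and its backbone weights are carried over; the donor's 3x3 kernels are
#' what the self-calibrated blocks later inherit. A self-supervised
#' image-reconstruction warm-up was tried first and rejected: with no
#' normalisation layers the regression objective systematically shrinks
#' trunk activations and frequently leaves the backbone in a basin the
#' throttled (0.1 x learning rate) fine-tuning cannot escape.
pretrain_backbone <- function(backbone, scenes, epochs = 2L,
                              learning_rate = 0.002) {
  img0 <- if (is.list(scenes[[1]])) scenes[[1]]$image else scenes[[1]]
  neck_ch <- max(8L, backbone$widths[2])
  neck <- build_mapper_neck(backbone$widths[2:4], out_channels = neck_ch)
  head <- list(conv1 = conv_layer(neck_ch, neck_ch, k = 3L),
               conv2 = conv_layer(neck_ch, 5L, k = 1L, padding = 0L))
  head$conv2$b[1] <- -3
  donor <- structure(list(backbone = backbone, neck = neck, head = head,
                          stride = 8L),
                     class = "detector_model")
  opt <- NULL
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (sc in scenes) {
      sg <- scene_loss_and_grads(donor, sc)
      if (!is.finite(sg$loss)) stop("warm-up diverged: non-finite loss")
      step <- step + 1L
      up <- adamw_update(list(backbone = donor$backbone, neck = donor$neck,
                              head = donor$head),
                         sg$grads, opt, learning_rate, 1e-4, step)
      donor$backbone <- up$params$backbone
      donor$neck <- up$params$neck
      donor$head <- up$params$head
      opt <- up$state
    }
  }
  donor$backbone
}

# --- training loop -----------------------------------------------------------

scene_loss_and_grads <- function(model, scene) {
  x <- image_to_tensor(scene$image)
  fw <- model_forward(model, x, keep_cache = TRUE)
  gh <- dim(fw$out)[3]; gw <- dim(fw$out)[4]
  tg <- make_targets(scene$annotations, gh, gw, model$stride)
  ls <- detector_loss(fw$out, tg)
  grads <- model_backward(model, ls$grad, fw$cache)
  list(loss = ls$loss, grads = grads)
}

#' Validation AP at IoU 0.5
#'
#' Detections at a low score threshold are pooled over the scene set
#' (boxes offset per scene so images do not interact) and scored against
#' the pooled ground truth.
#'
#' @param model `detector_model`.
#' @param scenes List of `synthetic_scene` objects.
#' @param score_threshold Floor for candidate detections.
#' @return AP at IoU 0.5 (numeric).
#' @export
evaluate_ap50 <- function(model, scenes, score_threshold = 0.05) {
  all_t <- NULL; all_b <- NULL; all_s <- numeric(0)
  off <- 0
  for (sc in scenes) {
    dets <- detect(model, sc$image, score_threshold = score_threshold)
    tb <- as.matrix(sc$annotations[, c("x_min", "y_min", "x_max", "y_max")])
    if (nrow(tb)) all_t <- rbind(all_t, tb + off)
    if (length(dets)) {
      all_b <- rbind(all_b, dets$boxes + off)
      all_s <- c(all_s, dets$scores)
    }
    off <- off + max(dim(sc$image)[1:2]) + 64
  }
  if (is.null(all_t)) return(NA_real_)
  dets <- if (is.null(all_b)) detection_set() else detection_set(all_b, all_s)
  pr_and_ap(all_t, dets, 0.5)$ap
}

#' Train the reference detector
#'
#' Decoupled-weight-decay Adam with a separate backbone parameter group at
#' `learning_rate * backbone_lr_multiplier`. Per-epoch mean training loss
#' and validation AP50 are logged; the checkpoint with the best validation
#' AP50 is retained.
#'
#' @param model A `detector_model` from [build_model()].
#' @param train_scenes,val_scenes Lists of `synthetic_scene` objects
#'   (`val_scenes` may be empty; then the final model is returned as best).
#' @param cfg Optional [detector_config()]; defaults to `model$cfg`.
#' @return `list(model, final, history)`: `model` is the best-by-validation
#'   checkpoint, `history` a data.frame with one row per epoch.
#' @export
train_detector <- function(model, train_scenes, val_scenes = list(),
                           cfg = model$cfg) {
  if (length(train_scenes) == 0) stop("empty training set")
  n_ann <- sum(vapply(train_scenes,
                      function(s) nrow(s$annotations), integer(1)))
  if (n_ann == 0) stop("training set contains no annotations")
  set.seed(cfg$seed + 1L)
  opt_bb <- NULL; opt_rest <- NULL
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_ap50 = numeric())
  best <- list(ap = -Inf, model = model)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(train_scenes))
    ep_losses <- numeric(0)
    batch_grads <- NULL; batch_n <- 0L
    flush <- function() {
      step <<- step + 1L
      gb <- batch_grads
      scale <- 1 / batch_n
      up <- adamw_update(model$backbone, scale_tree(gb$backbone, scale),
                         opt_bb,
                         cfg$learning_rate * cfg$backbone_lr_multiplier,
                         cfg$weight_decay, step)
      model$backbone <<- up$params; opt_bb <<- up$state
      rest_p <- list(neck = model$neck, head = model$head)
      rest_g <- list(neck = scale_tree(gb$neck, scale),
                     head = scale_tree(gb$head, scale))
      up2 <- adamw_update(rest_p, rest_g, opt_rest, cfg$learning_rate,
                          cfg$weight_decay, step)
      model$neck <<- up2$params$neck; model$head <<- up2$params$head
      opt_rest <<- up2$state
      batch_grads <<- NULL; batch_n <<- 0L
    }
    for (i in ord) {
      sg <- scene_loss_and_grads(model, train_scenes[[i]])
      if (!is.finite(sg$loss)) {
        stop("training diverged at epoch ", ep, ": non-finite loss")
      }
      ep_losses <- c(ep_losses, sg$loss)
      batch_grads <- if (is.null(batch_grads)) sg$grads else
        tree_add(batch_grads, sg$grads)
      batch_n <- batch_n + 1L
      if (batch_n >= cfg$batch_size) flush()
    }
    if (batch_n > 0) flush()
    val_ap <- if (length(val_scenes)) evaluate_ap50(model, val_scenes)
    else NA_real_
    history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_losses),
                                         val_ap50 = val_ap))
    if (!is.na(val_ap) && val_ap >= best$ap) {
      best <- list(ap = val_ap, model = model)
    }
  }
  if (!length(val_scenes)) best$model <- model
  list(model = best$model, final = model, history = history)
}

scale_tree <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.numeric(g)) return(g * s)
  lapply(g, scale_tree, s = s)
}

#' Save / load a detector checkpoint
#'
#' Checkpoints are plain RDS serialisations of the model object and restore
#' losslessly.
#'
#' @param model `detector_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# --- ablation harness --------------------------------------------------------

#' Desk-scale ablation: full variant versus all-off baseline
#'
#' For each seed, generates a small synthetic benchmark, trains (a) the
#' baseline detector (no warm-up, plain convolutions, channel-mapper neck)
#' and (b) the full variant (warm-up + self-calibrated convolution +
#' adaptive fusion), and records the validation AP50 of both.
#'
#' @param seeds Integer vector of run seeds.
#' @param n_train,n_val Scenes per split.
#' @param image_size Scene edge in pixels.
#' @param epochs Training epochs per run.
#' @param widths,neck_channels,n_blocks Model size knobs.
#' @param verbose Print one line per run.
#' @return data.frame with columns `seed, ap_baseline, ap_full`.
#' @export
run_ablation <- function(seeds = 1:10, n_train = 8L, n_val = 4L,
                         image_size = 64L, epochs = 8L,
                         widths = c(6L, 8L, 12L, 16L), neck_channels = 8L,
                         n_blocks = 1L, learning_rate = 0.01,
                         batch_size = 1L, verbose = FALSE) {
  res <- data.frame(seed = integer(), ap_baseline = numeric(),
                    ap_full = numeric())
  for (sd in seeds) {
    scenes <- lapply(seq_len(2L * n_train + n_val), function(i) {
      suppressWarnings(generate_scene(field_config(
        image_size = image_size,
        n_rows = max(2L, image_size %/% 32L),
        plants_per_row = max(3L, image_size %/% 24L),
        small_fraction = 1, seed = sd * 10000L + i)))
    })
    tr <- scenes[seq_len(n_train)]
    va <- scenes[n_train + seq_len(n_val)]
    # disjoint donor corpus for the transfer-learning warm-up
    donor <- scenes[n_train + n_val + seq_len(n_train)]
    mk_cfg <- function(full) {
      detector_config(widths = widths, n_blocks = n_blocks,
                      neck_channels = neck_channels,
                      use_pretrained = full, use_rscconv = full,
                      use_ascff = full, epochs = epochs,
                      batch_size = batch_size,
                      learning_rate = learning_rate,
                      input_size = image_size, pretrain_epochs = 4L,
                      reduction = 4L, spatial_kernel = 3L, seed = sd)
    }
    ap <- vapply(c(FALSE, TRUE), function(full) {
      model <- build_model(mk_cfg(full), pretrain_scenes = if (full) donor)
      fit <- train_detector(model, tr, va)
      # converged validation score: mean over the last 3 epochs (less
      # sensitive to single-epoch spikes than the max)
      mean(utils::tail(fit$history$val_ap50, 3))
    }, numeric(1))
    if (verbose) {
      message(sprintf("seed %d: baseline AP50 %.3f, full AP50 %.3f",
                      sd, ap[1], ap[2]))
    }
    res <- rbind(res, data.frame(seed = sd, ap_baseline = ap[1],
                                 ap_full = ap[2]))
  }
  res
}
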