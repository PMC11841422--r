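# Shared fixtures built in code at test time.

# A perfect detector: emits the ground-truth boxes of the scene being
# processed, clipped to the objects fully contained in the current tile,
# at score 1.0.  Uses the window/image_index context run_counting provides.
make_mock_detector <- function(scenes, score = 1.0) {
  function(image, window, image_index) {
    ann <- scenes[[image_index]]$annotations
    if (nrow(ann) == 0) return(detection_set())
    b <- as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])
    inside <- b[, 1] >= window$x0 & b[, 2] >= window$y0 &
      b[, 3] <= window$x0 + window$width & b[, 4] <= window$y0 + window$height
    if (!any(inside)) return(detection_set())
    b <- b[inside, , drop = FALSE]
    b[, c(1, 3)] <- b[, c(1, 3)] - window$x0
    b[, c(2, 4)] <- b[, c(2, 4)] - window$y0
    detection_set(b, rep(score, nrow(b)))
  }
}

# tiny scenes for pipeline tests (fast to render)
make_tiny_scenes <- function(n, image_size = 96, seed0 = 5000) {
  lapply(seq_len(n), function(i) {
    suppressWarnings(generate_scene(field_config(
      image_size = image_size, n_rows = 2, plants_per_row = 3,
      seed = seed0 + i)))
  })
}

ann_boxes_for_test <- function(scene) {
  as.matrix(scene$annotations[, c("x_min", "y_min", "x_max", "y_max")])
}

# jittered detections derived from truth: drop some, shift others, add FPs
make_noisy_detections <- function(truth_boxes, drop = 0.2, fp = 3,
                                  jitter = 2, seed = 1) {
  set.seed(seed)
  keep <- stats::runif(nrow(truth_boxes)) > drop
  b <- truth_boxes[keep, , drop = FALSE]
  b <- b + matrix(stats::rnorm(length(b), sd = jitter), nrow(b))
  bad <- which(b[, 3] <= b[, 1] | b[, 4] <= b[, 2])
  if (length(bad)) b[bad, 3:4] <- b[bad, 1:2] + 2
  scores <- stats::runif(nrow(b), 0.5, 1)
  if (fp > 0) {
    fx <- stats::runif(fp, 0, 400); fy <- stats::runif(fp, 0, 400)
    b <- rbind(b, cbind(fx, fy, fx + stats::runif(fp, 5, 20),
                        fy + stats::runif(fp, 5, 20)))
    scores <- c(scores, stats::runif(fp, 0.1, 0.6))
  }
  detection_set(b, scores)
}
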