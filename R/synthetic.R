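# Synthetic UAV field scenes.
#
# The generator emulates the statistics that matter for exercising the
# detection and counting pipeline -- tile size, ground-sampling distance,
# row structure, and a small/medium object-size mix dominated by small
# objects -- not photorealism.  Soil is low-frequency correlated brown
# noise; each seedling is a rosette of elongated green lobes around a
# center point, with two axis-aligned blades that pin the tight bounding
# box to the sampled object size.  Every scene carries its full provenance
# (config + seed) and a per-pixel instance mask, so geometric invariants
# can be asserted after any transformation.

#' Configuration for the synthetic field-scene generator
#'
#' @param image_size Square scene edge in pixels (default 512, the tile size
#'   cropped from orthomosaics; must be at least 64).
#' @param gsd_cm_per_px Ground-sampling distance in cm per pixel. The three
#'   canonical capture altitudes (12, 20, 24 m) correspond to 0.32, 0.54 and
#'   0.64 cm/px.
#' @param n_rows,plants_per_row Crop-row geometry; defaults are derived from
#'   60 cm row spacing and 25 cm in-row plant spacing at the configured GSD.
#' @param position_jitter Positional noise (standard deviation, px) applied
#'   to each plant center; default 8% of the plant spacing.
#' @param small_fraction Target fraction of small objects (area <= 1024 px^2);
#'   the remainder is medium (1024 < area <= 9216 px^2), never large.
#' @param seed Integer seed fixing all randomness of the scene.
#' @return Object of class `field_config`.
#' @export
field_config <- function(image_size = 512L, gsd_cm_per_px = 0.32,
                         n_rows = NULL, plants_per_row = NULL,
                         position_jitter = NULL, small_fraction = 0.89,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be at least 64")
  if (small_fraction < 0 || small_fraction > 1) {
    stop("small_fraction must lie in [0, 1]")
  }
  if (gsd_cm_per_px <= 0) stop("gsd_cm_per_px must be positive")
  row_px <- 60 / gsd_cm_per_px
  plant_px <- 25 / gsd_cm_per_px
  if (is.null(n_rows)) n_rows <- max(1L, floor(image_size / row_px))
  if (is.null(plants_per_row)) {
    plants_per_row <- max(1L, floor(image_size / plant_px))
  }
  if (is.null(position_jitter)) position_jitter <- 0.08 * plant_px
  structure(list(image_size = image_size, gsd_cm_per_px = gsd_cm_per_px,
                 n_rows = as.integer(n_rows),
                 plants_per_row = as.integer(plants_per_row),
                 position_jitter = position_jitter,
                 small_fraction = small_fraction, seed = as.integer(seed)),
            class = "field_config")
}

# correlated low-frequency noise field (h x w), zero mean, unit-ish scale
low_freq_noise <- function(h, w, cell = 16L) {
  gh <- max(2L, ceiling(h / cell)); gw <- max(2L, ceiling(w / cell))
  coarse <- array(stats::rnorm(gh * gw), dim = c(1, 1, gh, gw))
  resize_bilinear(coarse, h, w)[1, 1, , ]
}

# render one plant; returns updated image/mask and the tight box, or NULL
# when the plant could not be placed
render_plant <- function(image, mask, plant_id, cx, cy, side) {
  n <- dim(image)[1]
  half <- side / 2
  x0 <- max(1L, floor(cx - half)); x1 <- min(n, ceiling(cx + half))
  y0 <- max(1L, floor(cy - half)); y1 <- min(n, ceiling(cy + half))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  px <- outer(rep(1, length(ys)), xs) - 0.5      # pixel centers, 0-based
  py <- outer(ys, rep(1, length(xs))) - 0.5
  dx <- px - cx; dy <- py - cy
  inside <- matrix(FALSE, length(ys), length(xs))
  # two axis-aligned blades pin the box extents to ~side x ~side
  bw <- max(1, 0.10 * side)
  inside <- inside | (abs(dx) <= half & abs(dy) <= bw / 2)
  inside <- inside | (abs(dy) <= half & abs(dx) <= bw / 2)
  # 3-6 elongated lobes at random angles
  n_lobes <- sample(3:6, 1)
  for (l in seq_len(n_lobes)) {
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.55, 1) * half
    wid <- max(0.75, 0.28 * len)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- inside | ((u / len)^2 + (v / wid)^2 <= 1)
  }
  # clip strictly to the sampled extent so the box never exceeds side x side
  inside <- inside & abs(dx) <= half & abs(dy) <= half
  if (!any(inside)) return(NULL)
  idx <- which(inside, arr.ind = TRUE)
  rr <- ys[idx[, 1]]; cc <- xs[idx[, 2]]
  shade <- 1 - 0.5 * sqrt((dx[idx]^2 + dy[idx]^2)) / max(half, 1)
  base <- c(0.20, 0.46, 0.16) + stats::rnorm(3, sd = 0.02)
  for (ch in 1:3) {
    image[cbind(rr, cc, ch)] <-
      pmin(1, pmax(0, base[ch] * (0.7 + 0.6 * shade) +
                     stats::rnorm(length(rr), sd = 0.015)))
  }
  mask[cbind(rr, cc)] <- plant_id
  # tight half-open box around rendered pixels
  box <- c(min(cc) - 1, min(rr) - 1, max(cc), max(rr))
  list(image = image, mask = mask, box = box)
}

# sample a box side so the realized tight-box area falls in the target class
sample_side <- function(small, image_size) {
  if (small) {
    a <- exp(stats::runif(1, log(49), log(1024)))
  } else {
    hi <- min(4096, (image_size / 3)^2)
    if (hi <= 1089) return(NA_real_)        # medium cannot fit in this scene
    a <- exp(stats::runif(1, log(1089), log(hi)))
  }
  max(7, round(sqrt(a)))
}

#' Generate one synthetic field scene
#'
#' @param cfg A [field_config()].
#' @return Object of class `synthetic_scene`: `list(image, annotations, mask,
#'   config)`. `image` is an `(H, W, 3)` array in `[0, 1]`; `annotations` a
#'   data.frame with columns `id, x_min, y_min, x_max, y_max, area,
#'   size_class` (0-based half-open boxes tight to rendered pixels); `mask`
#'   an `(H, W)` integer matrix of plant ids (0 = soil).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "field_config"))
  set.seed(cfg$seed)
  n <- cfg$image_size
  soil <- c(0.42, 0.32, 0.22)
  lf <- low_freq_noise(n, n)
  image <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    image[, , ch] <- pmin(1, pmax(0, soil[ch] + 0.06 * lf +
                                    stats::rnorm(n * n, sd = 0.015)))
  }
  mask <- matrix(0L, n, n)
  rows_y <- (seq_len(cfg$n_rows) - 0.5) * n / cfg$n_rows
  anns <- list()
  plant_id <- 0L
  n_dropped <- 0L
  placed <- NULL
  for (r in seq_len(cfg$n_rows)) {
    xs <- (seq_len(cfg$plants_per_row) - 0.5) * n / cfg$plants_per_row
    for (x in xs) {
      small <- stats::runif(1) < cfg$small_fraction
      side <- sample_side(small, n)
      if (is.na(side)) { side <- sample_side(TRUE, n); small <- TRUE }
      ok <- FALSE
      for (attempt in 1:5) {
        cx <- x + stats::rnorm(1, sd = cfg$position_jitter)
        cy <- rows_y[r] + stats::rnorm(1, sd = cfg$position_jitter)
        cx <- min(max(cx, side / 2 + 1), n - side / 2 - 1)
        cy <- min(max(cy, side / 2 + 1), n - side / 2 - 1)
        cand <- c(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
        if (is.null(placed) ||
            all(box_iou(matrix(cand, 1), placed) < 0.25)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) { n_dropped <- n_dropped + 1L; next }
      res <- render_plant(image, mask, plant_id + 1L, cx, cy, side)
      if (is.null(res)) { n_dropped <- n_dropped + 1L; next }
      plant_id <- plant_id + 1L
      image <- res$image; mask <- res$mask
      placed <- rbind(placed, matrix(res$box, 1))
      anns[[plant_id]] <- res$box
    }
  }
  if (n_dropped > 0) {
    warning("overcrowding: ", n_dropped, " plant(s) could not be placed")
  }
  ann <- if (plant_id > 0) {
    b <- do.call(rbind, anns)
    data.frame(id = seq_len(plant_id), x_min = b[, 1], y_min = b[, 2],
               x_max = b[, 3], y_max = b[, 4],
               area = (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]))
  } else {
    data.frame(id = integer(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric(), area = numeric())
  }
  ann$size_class <- if (nrow(ann)) size_class(ann$area) else
    factor(character(), levels = c("small", "medium", "large"))
  structure(list(image = image, annotations = ann, mask = mask, config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>", dim(x$image)[1], "x", dim(x$image)[2], "px,",
      nrow(x$annotations), "objects (",
      sum(x$annotations$size_class == "small"), "small /",
      sum(x$annotations$size_class == "medium"), "medium )\n")
  invisible(x)
}

ann_boxes <- function(scene) {
  as.matrix(scene$annotations[, c("x_min", "y_min", "x_max", "y_max")])
}

# nearest-neighbour resize of an integer mask
resize_mask <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(h, pmax(1, round((seq_len(out_h) - 0.5) * h / out_h - 0.5) + 1))
  ci <- pmin(w, pmax(1, round((seq_len(out_w) - 0.5) * w / out_w - 0.5) + 1))
  mask[ri, ci, drop = FALSE]
}

resize_image <- function(image, out_h, out_w) {
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(1, dim(x))
  y <- resize_bilinear(x, out_h, out_w)
  aperm(array(y, dim = dim(y)[2:4]), c(2, 3, 1))
}

#' Rescale a scene between ground-sampling distances
#'
#' Simulates capturing the same field at a different altitude: going from
#' 0.32 to 0.64 cm/px halves linear object size, quartering areas and
#' pushing objects toward the small class.
#'
#' @param scene A `synthetic_scene`.
#' @param gsd_from,gsd_to Positive ground-sampling distances (cm/px).
#' @return The rescaled scene; objects shrunk below 2 px in either dimension
#'   are dropped with a warning.
#' @export
altitude_rescale <- function(scene, gsd_from, gsd_to) {
  if (gsd_from <= 0 || gsd_to <= 0) stop("gsd values must be positive")
  f <- gsd_from / gsd_to
  if (f == 1) return(scene)
  h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
  nh <- max(8L, round(h * f)); nw <- max(8L, round(w * f))
  image <- resize_image(scene$image, nh, nw)
  mask <- resize_mask(scene$mask, nh, nw)
  ann <- scene$annotations
  if (nrow(ann)) {
    for (col in c("x_min", "y_min", "x_max", "y_max")) {
      ann[[col]] <- ann[[col]] * f
    }
    keep <- (ann$x_max - ann$x_min >= 2) & (ann$y_max - ann$y_min >= 2)
    if (any(!keep)) {
      warning(sum(!keep), " object(s) below 2 px after rescale; dropped")
      mask[mask %in% ann$id[!keep]] <- 0L
      ann <- ann[keep, , drop = FALSE]
    }
    ann$area <- (ann$x_max - ann$x_min) * (ann$y_max - ann$y_min)
    ann$size_class <- size_class(pmax(ann$area, 1e-9))
  }
  cfg <- scene$config
  cfg$gsd_cm_per_px <- gsd_to
  cfg$image_size <- nh
  structure(list(image = image, annotations = ann, mask = mask, config = cfg),
            class = "synthetic_scene")
}

#' Augment a scene (flip, rescale, crop, resize)
#'
#' Pipeline: horizontal flip (p = 0.5), vertical flip (p = 0.5), resize by a
#' scale drawn from `scales`, random crop, resize to `out_size`. Boxes are
#' transformed consistently; boxes falling entirely outside the crop are
#' removed (partially visible boxes are clipped).
#'
#' @param scene A `synthetic_scene`.
#' @param scales Candidate resize scales (the "predefined list").
#' @param crop_fraction_range Range of the crop edge as a fraction of the
#'   current image.
#' @param out_size Final square size (default: the input scene size).
#' @param seed Seed for the augmentation draws.
#' @param decisions Optional list forcing individual draws (`flip_h`,
#'   `flip_v`, `scale`, `crop = c(x0, y0, size)`), used for reproducibility
#'   and testing.
#' @return The augmented `synthetic_scene`.
#' @export
augment_scene <- function(scene, scales = c(0.8, 0.9, 1.0, 1.1, 1.2),
                          crop_fraction_range = c(0.6, 1.0),
                          out_size = NULL, seed = NULL, decisions = list()) {
  if (!is.null(seed)) set.seed(seed)
  image <- scene$image; mask <- scene$mask
  ann <- scene$annotations
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(out_size)) out_size <- h
  draw <- function(name, rexpr) {
    if (!is.null(decisions[[name]])) decisions[[name]] else rexpr
  }
  flip_h <- draw("flip_h", stats::runif(1) < 0.5)
  flip_v <- draw("flip_v", stats::runif(1) < 0.5)
  if (flip_h) {
    image <- image[, w:1, , drop = FALSE]
    mask <- mask[, w:1, drop = FALSE]
    if (nrow(ann)) {
      x0 <- ann$x_min; ann$x_min <- w - ann$x_max; ann$x_max <- w - x0
    }
  }
  if (flip_v) {
    image <- image[h:1, , , drop = FALSE]
    mask <- mask[h:1, , drop = FALSE]
    if (nrow(ann)) {
      y0 <- ann$y_min; ann$y_min <- h - ann$y_max; ann$y_max <- h - y0
    }
  }
  sc <- draw("scale", sample(scales, 1))
  if (sc != 1) {
    nh <- max(8L, round(h * sc)); nw <- max(8L, round(w * sc))
    image <- resize_image(image, nh, nw)
    mask <- resize_mask(mask, nh, nw)
    if (nrow(ann)) {
      fx <- nw / w; fy <- nh / h
      ann$x_min <- ann$x_min * fx; ann$x_max <- ann$x_max * fx
      ann$y_min <- ann$y_min * fy; ann$y_max <- ann$y_max * fy
    }
    h <- nh; w <- nw
  }
  crop <- draw("crop", {
    cs <- round(stats::runif(1, crop_fraction_range[1],
                             crop_fraction_range[2]) * min(h, w))
    cs <- max(8L, min(cs, min(h, w)))
    c(sample.int(w - cs + 1L, 1) - 1L, sample.int(h - cs + 1L, 1) - 1L, cs)
  })
  cx0 <- crop[1]; cy0 <- crop[2]; cs <- crop[3]
  image <- image[(cy0 + 1):(cy0 + cs), (cx0 + 1):(cx0 + cs), , drop = FALSE]
  mask <- mask[(cy0 + 1):(cy0 + cs), (cx0 + 1):(cx0 + cs), drop = FALSE]
  if (nrow(ann)) {
    ann$x_min <- pmax(0, ann$x_min - cx0); ann$x_max <- pmin(cs, ann$x_max - cx0)
    ann$y_min <- pmax(0, ann$y_min - cy0); ann$y_max <- pmin(cs, ann$y_max - cy0)
    keep <- ann$x_max - ann$x_min >= 1 & ann$y_max - ann$y_min >= 1
    ann <- ann[keep, , drop = FALSE]
  }
  if (out_size != cs) {
    f <- out_size / cs
    image <- resize_image(image, out_size, out_size)
    mask <- resize_mask(mask, out_size, out_size)
    if (nrow(ann)) {
      for (col in c("x_min", "y_min", "x_max", "y_max")) {
        ann[[col]] <- ann[[col]] * f
      }
    }
  }
  if (nrow(ann)) {
    ann$area <- (ann$x_max - ann$x_min) * (ann$y_max - ann$y_min)
    ann$size_class <- size_class(pmax(ann$area, 1e-9))
  }
  cfg <- scene$config
  cfg$image_size <- as.integer(out_size)
  structure(list(image = image, annotations = ann, mask = mask, config = cfg),
            class = "synthetic_scene")
}

#' Split scenes into train/validation/test sets
#'
#' Seeded shuffle followed by floor allocation with the remainder assigned
#' to the training set, so e.g. 1233 scenes at 7:2:1 give 864/246/123.
#'
#' @param scenes List of scenes (any objects).
#' @param ratios Positive weights, default `c(7, 2, 1)`.
#' @param seed Shuffle seed.
#' @return `list(train, val, test)`; the shuffled index assignment is
#'   attached as attribute `"indices"`.
#' @export
split_dataset <- function(scenes, ratios = c(7, 2, 1), seed = 1L) {
  n <- length(scenes)
  if (n < length(ratios)) stop("fewer scenes than ratio parts")
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- floor(n * ratios / sum(ratios))
  sizes[1] <- sizes[1] + (n - sum(sizes))   # remainder to train
  ends <- cumsum(sizes)
  parts <- list(train = idx[seq_len(ends[1])],
                val = idx[(ends[1] + 1):ends[2]],
                test = idx[(ends[2] + 1):ends[3]])
  out <- lapply(parts, function(ii) scenes[ii])
  attr(out, "indices") <- parts
  out
}
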