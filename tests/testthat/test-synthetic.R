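test_that("scene generation is a pure function of config + seed", {
  cfg <- field_config(image_size = 128, n_rows = 2, plants_per_row = 3,
                      seed = 42)
  s1 <- suppressWarnings(generate_scene(cfg))
  s2 <- suppressWarnings(generate_scene(cfg))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- suppressWarnings(generate_scene(field_config(image_size = 128,
                                                     n_rows = 2,
                                                     plants_per_row = 3,
                                                     seed = 43)))
  expect_false(identical(s1$image, s3$image))
})

test_that("requested plant grid is fully placed when there is room", {
  cfg <- field_config(image_size = 512, n_rows = 3, plants_per_row = 10,
                      small_fraction = 1, seed = 7)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$annotations), 30)
  # every annotated object is visibly rendered: mask pixels inside its box
  for (i in seq_len(nrow(sc$annotations))) {
    a <- sc$annotations[i, ]
    sub <- sc$mask[(a$y_min + 1):a$y_max, (a$x_min + 1):a$x_max]
    expect_true(any(sub == a$id))
  }
  # boxes are tight: the object's pixels span the whole box extent
  px <- which(sc$mask == sc$annotations$id[1], arr.ind = TRUE)
  a <- sc$annotations[1, ]
  expect_equal(min(px[, 2]) - 1, a$x_min)
  expect_equal(max(px[, 2]), a$x_max)
  # all boxes inside the image
  expect_true(all(sc$annotations$x_min >= 0 & sc$annotations$y_min >= 0 &
                    sc$annotations$x_max <= 512 &
                    sc$annotations$y_max <= 512))
})

test_that("realized size mix tracks the configured small fraction (200 scenes)", {
  counts <- c(small = 0, medium = 0, large = 0)
  for (i in 1:200) {
    sc <- suppressWarnings(generate_scene(field_config(
      image_size = 256, n_rows = 3, plants_per_row = 5,
      small_fraction = 0.89, seed = 20000 + i)))
    tab <- table(sc$annotations$size_class)
    counts <- counts + as.numeric(tab[c("small", "medium", "large")])
  }
  share <- counts["small"] / sum(counts)
  expect_gt(share, 0.86)
  expect_lt(share, 0.92)
  expect_equal(unname(counts["large"]), 0)
})

test_that("altitude rescale halves boxes exactly for a 0.32 -> 0.64 change", {
  # hand-built scene: one 40x40 object at a known position in a 128px image
  img <- array(0.4, dim = c(128, 128, 3))
  mask <- matrix(0L, 128, 128)
  mask[41:80, 31:70] <- 1L
  ann <- data.frame(id = 1L, x_min = 30, y_min = 40, x_max = 70, y_max = 80,
                    area = 1600)
  ann$size_class <- size_class(ann$area)
  sc <- structure(list(image = img, annotations = ann, mask = mask,
                       config = field_config(image_size = 128,
                                             gsd_cm_per_px = 0.32)),
                  class = "synthetic_scene")
  expect_equal(as.character(sc$annotations$size_class), "medium")
  out <- altitude_rescale(sc, 0.32, 0.64)
  a <- out$annotations[1, ]
  expect_equal(c(a$x_min, a$y_min, a$x_max, a$y_max), c(15, 20, 35, 40))
  expect_equal(a$area, 400)
  expect_equal(as.character(a$size_class), "small")
  expect_equal(dim(out$image)[1:2], c(64, 64))
  # identity rescale is pixel-equal
  expect_identical(altitude_rescale(sc, 0.5, 0.5), sc)
  # shrinking far enough drops the object with a warning
  expect_warning(tiny <- altitude_rescale(sc, 0.32, 12), "dropped")
  expect_equal(nrow(tiny$annotations), 0)
  expect_error(altitude_rescale(sc, 0, 1), "positive")
})

test_that("flips transform boxes by the coordinate identity and are involutive", {
  sc <- suppressWarnings(generate_scene(field_config(
    image_size = 128, n_rows = 2, plants_per_row = 3, seed = 11)))
  w <- dim(sc$image)[2]
  no_crop <- list(flip_v = FALSE, scale = 1, crop = c(0, 0, w))
  fl <- augment_scene(sc, decisions = c(list(flip_h = TRUE), no_crop))
  a0 <- sc$annotations; a1 <- fl$annotations
  expect_equal(a1$x_min, w - a0$x_max)
  expect_equal(a1$x_max, w - a0$x_min)
  expect_equal(a1$y_min, a0$y_min)
  # flipping twice recovers the original scene
  fl2 <- augment_scene(fl, decisions = c(list(flip_h = TRUE), no_crop))
  expect_equal(fl2$image, sc$image)
  expect_equal(fl2$annotations, sc$annotations, ignore_attr = TRUE)
})

test_that("horizontal-flip frequency is a fair coin over 1000 seeded draws", {
  sc <- suppressWarnings(generate_scene(field_config(
    image_size = 64, n_rows = 1, plants_per_row = 2, seed = 12)))
  w <- dim(sc$image)[2]
  flipped <- 0L
  set.seed(77)
  for (i in 1:1000) {
    out <- augment_scene(sc, decisions = list(flip_v = FALSE, scale = 1,
                                              crop = c(0, 0, w)))
    if (!identical(out$image, sc$image)) flipped <- flipped + 1L
  }
  expect_gt(flipped / 1000, 0.45)
  expect_lt(flipped / 1000, 0.55)
})

test_that("augmented boxes still enclose their object's rendered pixels", {
  set.seed(78)
  for (trial in 1:5) {
    sc <- suppressWarnings(generate_scene(field_config(
      image_size = 160, n_rows = 2, plants_per_row = 3,
      seed = 30000 + trial)))
    out <- augment_scene(sc, seed = trial)
    a <- out$annotations
    for (i in seq_len(nrow(a))) {
      px <- which(out$mask == a$id[i], arr.ind = TRUE)
      if (nrow(px) == 0) next   # object may be cropped to nothing
      inside <- px[, 2] - 1 >= a$x_min[i] - 1.5 & px[, 2] <= a$x_max[i] + 1.5 &
        px[, 1] - 1 >= a$y_min[i] - 1.5 & px[, 1] <= a$y_max[i] + 1.5
      expect_gt(mean(inside), 0.95)
    }
  }
})

test_that("dataset split follows the floor + remainder-to-train rule", {
  sizes <- function(n) {
    sp <- split_dataset(as.list(seq_len(n)), seed = 3)
    vapply(sp, length, integer(1))
  }
  expect_equal(unname(sizes(10)), c(7, 2, 1))
  expect_equal(unname(sizes(1233)), c(864, 246, 123))
  sp <- split_dataset(as.list(1:57), seed = 9)
  all_idx <- sort(unname(unlist(attr(sp, "indices"))))
  expect_equal(all_idx, 1:57)                       # exhaustive and disjoint
  expect_error(split_dataset(as.list(1:2)), "fewer scenes")
})

test_that("LabelMe conversion produces exact COCO boxes and itemized errors", {
  path <- system.file("extdata", "labelme_example.json",
                      package = "maizecount")
  if (path == "") path <- file.path("../../inst/extdata/labelme_example.json")
  coco <- convert_annotations(path)
  expect_length(coco$annotations, 5)
  expect_equal(vapply(coco$annotations, function(a) a$id, numeric(1)), 1:5)
  a1 <- coco$annotations[[1]]
  expect_equal(a1$bbox, c(10, 20, 32, 32))
  expect_equal(a1$area, 1024)
  a2 <- coco$annotations[[2]]                       # triangle -> extrema
  expect_equal(a2$bbox, c(0, 0, 10, 8))

  bad <- list(shapes = list(
    list(label = "x", points = list(list(0, 0), list(5, 5)),
         shape_type = "circle"),
    list(label = "y", points = list(list(3, 3), list(3, 9)),
         shape_type = "rectangle")),
    imageHeight = 10, imageWidth = 10)
  expect_error(convert_annotations(bad), "unsupported shape_type")
  expect_error(convert_annotations(bad), "degenerate")
  expect_error(convert_annotations(list(a = 1)), "no 'shapes'")
})

test_that("COCO round-trip is lossless for boxes", {
  scenes <- make_tiny_scenes(2, image_size = 96)
  coco <- scenes_to_coco(scenes)
  tmp <- tempfile(fileext = ".json")
  write_coco(coco, tmp)
  back <- read_coco(tmp)
  for (i in 1:2) {
    expect_equal(coco_boxes(back, i), ann_boxes_for_test(scenes[[i]]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("PPM image files round-trip to 8-bit precision", {
  sc <- make_tiny_scenes(1, image_size = 64)[[1]]
  tmp <- tempfile(fileext = ".ppm")
  write_ppm(sc$image, tmp)
  back <- read_ppm(tmp)
  expect_equal(dim(back), dim(sc$image))
  expect_lt(max(abs(back - sc$image)), 1 / 255 + 1e-9)
})
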