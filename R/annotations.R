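# Annotation interchange: LabelMe JSON, COCO detection JSON, manifests.
#
# Internal convention everywhere: 0-based half-open (x_min, y_min, x_max,
# y_max) boxes.  COCO stores [x, y, width, height]; the two agree on x/y and
# differ only in the width/height encoding, so conversion is exact.

#' Convert a LabelMe document to COCO detection ground truth
#'
#' Rectangle shapes become their box; polygon shapes become their tight
#' bounding box. One category ("seedling") is emitted. Malformed shapes are
#' collected and reported together rather than failing one at a time.
#'
#' @param labelme A file path to a LabelMe JSON document or an equivalent
#'   parsed list (fields `shapes`, `imagePath`, `imageHeight`, `imageWidth`).
#' @param image_id Numeric id for the image entry (default 1).
#' @return COCO ground-truth list with `images`, `annotations`, `categories`.
#' @export
convert_annotations <- function(labelme, image_id = 1L) {
  if (is.character(labelme)) {
    labelme <- jsonlite::fromJSON(labelme, simplifyVector = FALSE)
  }
  if (is.null(labelme$shapes)) stop("not a LabelMe document: no 'shapes' field")
  errors <- character(0)
  anns <- list()
  for (i in seq_along(labelme$shapes)) {
    sh <- labelme$shapes[[i]]
    pts <- try(do.call(rbind, lapply(sh$points, unlist)), silent = TRUE)
    if (inherits(pts, "try-error") || is.null(pts) || ncol(pts) != 2) {
      errors <- c(errors, paste0("shape ", i, ": malformed points"))
      next
    }
    st <- if (is.null(sh$shape_type)) "polygon" else sh$shape_type
    if (!st %in% c("rectangle", "polygon")) {
      errors <- c(errors, paste0("shape ", i, ": unsupported shape_type '",
                                 st, "'"))
      next
    }
    if (st == "rectangle" && nrow(pts) != 2) {
      errors <- c(errors, paste0("shape ", i, ": rectangle needs 2 points"))
      next
    }
    x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
    y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
    if (x1 <= x0 || y1 <= y0) {
      errors <- c(errors, paste0("shape ", i, ": degenerate extent"))
      next
    }
    anns[[length(anns) + 1L]] <- list(
      id = length(anns) + 1L, image_id = image_id, category_id = 1L,
      bbox = c(x0, y0, x1 - x0, y1 - y0),
      area = (x1 - x0) * (y1 - y0), iscrowd = 0L)
  }
  if (length(errors)) {
    stop("LabelMe conversion failed:\n  ", paste(errors, collapse = "\n  "))
  }
  list(
    images = list(list(
      id = image_id,
      file_name = if (is.null(labelme$imagePath)) "" else labelme$imagePath,
      height = labelme$imageHeight, width = labelme$imageWidth)),
    annotations = anns,
    categories = list(list(id = 1L, name = "seedling")))
}

#' COCO ground truth for a list of synthetic scenes
#'
#' @param scenes List of `synthetic_scene` objects.
#' @param file_names Optional character vector of image file names.
#' @return COCO ground-truth list (serialise with [write_coco()]).
#' @export
scenes_to_coco <- function(scenes, file_names = NULL) {
  if (is.null(file_names)) {
    file_names <- sprintf("scene_%04d.ppm", seq_along(scenes))
  }
  images <- list(); anns <- list()
  aid <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    d <- dim(sc$image)
    images[[i]] <- list(id = i, file_name = file_names[i],
                        height = d[1], width = d[2])
    a <- sc$annotations
    for (j in seq_len(nrow(a))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        bbox = c(a$x_min[j], a$y_min[j],
                 a$x_max[j] - a$x_min[j], a$y_max[j] - a$y_min[j]),
        area = a$area[j], iscrowd = 0L)
    }
  }
  list(images = images, annotations = anns,
       categories = list(list(id = 1L, name = "seedling")))
}

#' Extract the box matrix for one image from a COCO ground-truth list
#'
#' @param coco COCO ground-truth list.
#' @param image_id Image id.
#' @return `n x 4` matrix of `(x_min, y_min, x_max, y_max)` boxes.
#' @export
coco_boxes <- function(coco, image_id) {
  rows <- Filter(function(a) a$image_id == image_id, coco$annotations)
  if (!length(rows)) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(rows, function(a) {
    b <- unlist(a$bbox)
    c(b[1], b[2], b[1] + b[3], b[2] + b[4])
  }))
}

#' Write / read COCO JSON
#'
#' @param coco COCO list (ground truth or results).
#' @param path Output file.
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Detections as COCO results entries
#'
#' @param dets A [detection_set()].
#' @param image_id Image id the detections belong to.
#' @return List of COCO detection-results entries
#'   (`image_id, category_id, bbox, score`).
#' @export
detections_to_coco <- function(dets, image_id = 1L) {
  lapply(seq_len(length(dets)), function(i) {
    b <- dets$boxes[i, ]
    list(image_id = image_id, category_id = 1L,
         bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
         score = dets$scores[i])
  })
}

#' Dataset manifest for generated scenes
#'
#' @param scenes List of `synthetic_scene` objects.
#' @return data.frame with one row per scene: object counts by size class
#'   and the ground-sampling distance.
#' @export
scene_manifest <- function(scenes) {
  do.call(rbind, lapply(seq_along(scenes), function(i) {
    a <- scenes[[i]]$annotations
    data.frame(scene = i, n_objects = nrow(a),
               n_small = sum(a$size_class == "small"),
               n_medium = sum(a$size_class == "medium"),
               gsd = scenes[[i]]$config$gsd_cm_per_px)
  }))
}

#' Write / read an image as binary PPM (P6)
#'
#' PPM is used because it is a trivial, dependency-free raster format;
#' any image viewer or converter understands it.
#'
#' @param image `(H, W, 3)` array with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(d[2], d[1]), "255"), con, sep = "\n")
  # channel fastest, then column, then row
  writeBin(as.integer(round(pmin(1, pmax(0, aperm(image, c(3, 2, 1)))) * 255)),
           con, size = 1)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 3)
  if (magic[1] != "P6") stop("not a binary PPM file")
  wh <- as.integer(strsplit(magic[2], " ")[[1]])
  raw <- readBin(con, "integer", n = 3 * wh[1] * wh[2], size = 1,
                 signed = FALSE)
  aperm(array(raw / 255, dim = c(3, wh[1], wh[2])), c(3, 2, 1))
}
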