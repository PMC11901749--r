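# On-disk dataset format: 8-bit RGB PNGs, one COCO-style JSON annotation file,
# and one long-format sensor CSV. Boxes are kept 0-based half-open
# (x0, y0, x1, y1) in memory and converted to COCO [x, y, w, h] on disk by a
# single tested conversion function.

#' Convert between internal and COCO box conventions
#'
#' Internal boxes are 0-based half-open `(x0, y0, x1, y1)`; COCO stores
#' `[x, y, width, height]`. The two carry identical information, so the
#' conversion is exact both ways.
#'
#' @param box numeric length-4 vector in the source convention.
#' @return numeric length-4 vector in the target convention.
#' @export
box_to_coco <- function(box) {
  c(box[1], box[2], box[3] - box[1], box[4] - box[2])
}

#' @rdname box_to_coco
#' @export
coco_to_box <- function(box) {
  c(box[1], box[2], box[1] + box[3], box[2] + box[4])
}

#' Write a multimodal dataset to disk
#'
#' Writes `images/<image_id>.png` (8-bit RGB), `annotations.json` (COCO-style
#' `images`/`annotations`/`categories` arrays) and `sensors.csv` (columns
#' `image_id,timestamp_hour,channel,value`). The result round-trips losslessly
#' through [read_dataset()].
#'
#' @param samples an `mm_dataset` or a non-empty list of multimodal samples.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(samples, out_dir) {
  if (inherits(samples, "mm_dataset")) samples <- samples$samples
  if (length(samples) == 0) stop("samples must be non-empty")
  ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "images"))) {
    stop("cannot create output directory: ", out_dir)
  }

  classes <- disease_classes()
  images <- list(); annos <- list(); sens <- list()
  ann_id <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img <- s$image
    H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
    fn <- paste0(img$image_id, ".png")
    png::writePNG(img$pixels / 255, file.path(out_dir, "images", fn))
    images[[i]] <- data.frame(id = i, file_name = fn, width = W, height = H,
                              stringsAsFactors = FALSE)
    for (b in img$boxes) {
      ann_id <- ann_id + 1L
      annos[[ann_id]] <- data.frame(
        id = ann_id, image_id = i, category_id = img$class_id,
        bbox = I(list(box_to_coco(b))),
        area = (b[3] - b[1]) * (b[4] - b[2]), iscrowd = 0L)
    }
    r <- s$sensors$readings
    sens[[i]] <- data.table::data.table(
      image_id = img$image_id,
      timestamp_hour = rep(seq_len(ncol(r)), each = nrow(r)),
      channel = rep(rownames(r), ncol(r)),
      value = as.vector(r))
  }
  coco <- list(images = do.call(rbind, images),
               annotations = do.call(rbind, annos),
               categories = data.frame(id = classes$id, name = classes$name,
                                       supercategory = "eggplant_disease",
                                       stringsAsFactors = FALSE))
  jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.table::rbindlist(sens),
                     file.path(out_dir, "sensors.csv"))
  invisible(out_dir)
}

#' Read a multimodal dataset from disk
#'
#' Reads a directory produced by [write_dataset()] (or conforming external
#' data), validating every image/sensor invariant: well-formed boxes inside
#' the image, humidity within `[0, 100]`, one reading per channel per hour,
#' and consistent ids between annotations, images and sensor rows.
#'
#' @param dir dataset directory.
#' @return list of multimodal samples.
#' @export
read_dataset <- function(dir) {
  ann_path <- file.path(dir, "annotations.json")
  sen_path <- file.path(dir, "sensors.csv")
  if (!file.exists(ann_path)) stop("missing annotation file: ", ann_path)
  if (!file.exists(sen_path)) stop("missing sensor file: ", sen_path)
  coco <- jsonlite::fromJSON(ann_path, simplifyDataFrame = TRUE)
  sens <- as.data.frame(data.table::fread(sen_path))

  imgs <- coco$images
  annos <- coco$annotations
  bad <- setdiff(annos$image_id, imgs$id)
  if (length(bad) > 0) {
    stop("annotation references missing image_id: ", paste(bad, collapse = ", "))
  }
  value <- channel <- image_id <- NULL # NSE note for R CMD check
  samples <- vector("list", nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    row <- imgs[i, ]
    id_str <- sub("\\.png$", "", row$file_name)
    px <- png::readPNG(file.path(dir, "images", row$file_name))
    pixels <- array(as.integer(round(px * 255)), dim = dim(px))

    sel <- annos[annos$image_id == row$id, , drop = FALSE]
    if (nrow(sel) == 0) stop("image '", id_str, "' has no annotations")
    cid <- unique(sel$category_id)
    if (length(cid) != 1) stop("inconsistent category ids for image '", id_str, "'")
    boxes <- lapply(seq_len(nrow(sel)), function(j) {
      coco_to_box(as.numeric(sel$bbox[[j]]))
    })
    img <- new_labeled_image(pixels, cid, boxes, id_str)
    validate_labeled_image(img)

    sw <- sens[sens$image_id == id_str, , drop = FALSE]
    if (nrow(sw) == 0) stop("no sensor rows for image '", id_str, "'")
    hours <- sort(unique(sw$timestamp_hour))
    readings <- matrix(NA_real_, length(CHANNELS), length(hours),
                       dimnames = list(CHANNELS, NULL))
    for (ch in CHANNELS) {
      v <- sw[sw$channel == ch, , drop = FALSE]
      if (nrow(v) != length(hours)) {
        stop("sensor channel '", ch, "' for image '", id_str,
             "' must have one reading per hour")
      }
      readings[ch, ] <- v$value[order(v$timestamp_hour)]
    }
    w <- new_sensor_window(readings, length(hours))
    validate_sensor_window(w, id_str)
    samples[[i]] <- structure(list(image = img, sensors = w, class_id = cid),
                              class = "mm_sample")
  }
  samples
}
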