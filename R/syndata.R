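# Synthetic multimodal dataset generator: leaf-like images with class-specific
# parametric lesions plus class-conditional hourly sensor windows. The point is
# analytic control, not realism: two ambiguities are planted so the Bayes
# ceiling of each single modality is known in closed form while the joint
# ceiling stays near 1.

CHANNELS <- c("temperature", "humidity", "light", "co2")

#' The five disease classes
#'
#' Fixed registry of disease classes, their lesion morphology descriptors and
#' the per-channel sensor regime each class is generated under. Humidity-linked
#' fungal classes (leaf mold, fusarium wilt) draw from a high-humidity regime.
#'
#' @return data.frame with columns `id` (0..4), `name`, `lesion_style`, and the
#'   per-channel generating means.
#' @export
disease_classes <- function() {
  data.frame(
    id = 0:4,
    name = c("brown_spot", "brown_stripe", "fusarium_wilt",
             "leaf_mold", "bacterial_leaf_spot"),
    lesion_style = c("round-sharp-border", "elongated-streak", "white-patch",
                     "yellow-to-gray-patch", "wet-blurred-halo"),
    temperature = c(26, 32, 30, 21, 24),
    humidity    = c(52, 38, 84, 92, 76),
    light       = c(650, 800, 700, 450, 530),
    co2         = c(420, 380, 460, 520, 420),
    stringsAsFactors = FALSE
  )
}

# Between-window spread (one draw per window) and within-window hourly jitter,
# per channel, in channel units. Diurnal amplitude adds a 24 h sinusoid to
# temperature and light.
sensor_spread <- function() {
  list(
    between = c(temperature = 1.5, humidity = 3, light = 60, co2 = 30),
    within  = c(temperature = 0.6, humidity = 1.5, light = 25, co2 = 12),
    diurnal = c(temperature = 1.5, humidity = 0, light = 120, co2 = 0)
  )
}

# Sensor regime used for the planted leaf_mold/fusarium_wilt ambiguity:
# identical for both classes, separated from every other class.
shared_wilt_mold_profile <- function() {
  c(temperature = 25.5, humidity = 88, light = 575, co2 = 490)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed below 2^31 from a base seed and a stream name.
derive_seed <- function(seed, stream) {
  h <- digest::digest(list(as.integer(seed), stream), algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

new_labeled_image <- function(pixels, class_id, boxes, image_id) {
  structure(list(pixels = pixels, class_id = as.integer(class_id),
                 boxes = boxes, image_id = image_id),
            class = "labeled_image")
}

new_sensor_window <- function(readings, window_hours) {
  structure(list(readings = readings, channel_names = CHANNELS,
                 window_hours = as.integer(window_hours)),
            class = "sensor_window")
}

validate_labeled_image <- function(img) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  for (b in img$boxes) {
    if (!(b[1] >= 0 && b[1] < b[3] && b[3] <= W &&
          b[2] >= 0 && b[2] < b[4] && b[4] <= H)) {
      stop("invalid box in image '", img$image_id, "': (",
           paste(b, collapse = ", "), ") for ", W, "x", H, " image")
    }
  }
  invisible(img)
}

validate_sensor_window <- function(w, image_id = "<unknown>") {
  if (!all(rownames(w$readings) == CHANNELS)) {
    stop("sensor window for '", image_id, "' must have channels ",
         paste(CHANNELS, collapse = ", "))
  }
  if (ncol(w$readings) != w$window_hours) {
    stop("sensor window for '", image_id, "' must hold one reading per ",
         "channel per hour (expected ", w$window_hours, " columns)")
  }
  hum <- w$readings["humidity", ]
  if (any(hum < 0 | hum > 100)) {
    stop("humidity out of [0, 100] in sensor window for '", image_id, "'")
  }
  invisible(w)
}

# --- lesion rendering ------------------------------------------------------

leaf_background <- function(H, W) {
  grad <- matrix(rep(seq(-12, 12, length.out = H), W), H, W)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 60 + rnorm(H * W, sd = 7)
  px[, , 2] <- 138 + grad + rnorm(H * W, sd = 8)
  px[, , 3] <- 68 + rnorm(H * W, sd = 7)
  clip255(px)
}

# Renders one lesion of the given style onto `px`, returning the updated pixels
# and the logical mask of every pixel the lesion touched.
render_lesion <- function(px, style) {
  H <- dim(px)[1]; W <- dim(px)[2]
  X <- matrix(rep(seq_len(W), each = H), H, W)   # column index
  Y <- matrix(rep(seq_len(H), W), H, W)          # row index
  margin <- 16
  cx <- runif(1, margin, W - margin)
  cy <- runif(1, margin, H - margin)
  dx <- X - cx; dy <- Y - cy
  d <- sqrt(dx^2 + dy^2)
  alpha <- matrix(0, H, W)
  col <- c(120, 120, 120)

  if (style == "round-sharp-border") {
    r <- runif(1, 6, 10)
    alpha[d <= r] <- 1
    col <- c(135, 85, 45)
  } else if (style == "elongated-streak") {
    len <- runif(1, 0.45, 0.7) * min(H, W)
    wd <- runif(1, 2.2, 4)
    th <- runif(1, 0, pi)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    alpha[abs(u) <= len / 2 & abs(v) <= wd / 2] <- 1
    col <- c(110, 72, 48)
  } else if (style == "white-patch") {
    r <- runif(1, 7, 11)
    ph <- runif(1, 0, 2 * pi)
    rb <- r * (1 + 0.3 * sin(3 * atan2(dy, dx) + ph))
    alpha[d <= rb] <- 1
    col <- c(228, 228, 218)
  } else if (style == "yellow-to-gray-patch") {
    r <- runif(1, 7, 11)
    ph <- runif(1, 0, 2 * pi)
    rb <- r * (1 + 0.25 * sin(4 * atan2(dy, dx) + ph))
    alpha[d <= rb] <- 1
    col <- c(205, 185, 80)
  } else if (style == "wet-blurred-halo") {
    r <- runif(1, 5, 8)
    core <- d <= r
    halo <- exp(-(pmax(d - r, 0)^2) / (2 * 2.2^2))
    alpha <- halo
    alpha[core] <- 1
    alpha[alpha < 0.05] <- 0
    col <- c(95, 100, 45)
  } else if (style == "ambiguous-spot") {
    # shared appearance for the planted brown_spot / bacterial_leaf_spot
    # ambiguity: same distribution regardless of the true class
    r <- runif(1, 6, 9)
    alpha <- clip01((r + 1.5 - d) / 1.5)
    alpha[alpha < 0.05] <- 0
    col <- c(115, 90, 45)
  } else {
    stop("unknown lesion style: ", style)
  }

  mask <- alpha > 0
  noise <- rnorm(sum(mask), sd = 6)
  for (ch in 1:3) {
    base <- px[, , ch]
    lesion_val <- col[ch] + noise
    if (style == "yellow-to-gray-patch") {
      # gray speckle within the patch
      speck <- runif(sum(mask)) < 0.3
      lesion_val[speck] <- 158 + noise[speck]
    }
    base[mask] <- alpha[mask] * clip255(lesion_val) + (1 - alpha[mask]) * base[mask]
    px[, , ch] <- base
  }
  list(px = clip255(px), mask = mask)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  # 0-based, half-open (x0, y0, x1, y1); x runs along the width (columns)
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

# --- sensor window ---------------------------------------------------------

gen_sensor_window <- function(means, window_hours) {
  sp <- sensor_spread()
  phase <- runif(1, 0, 24)
  hours <- seq_len(window_hours)
  readings <- matrix(0, length(CHANNELS), window_hours,
                     dimnames = list(CHANNELS, NULL))
  for (ch in CHANNELS) {
    offset <- rnorm(1, 0, sp$between[[ch]])
    diurnal <- sp$diurnal[[ch]] * sin(2 * pi * (hours + phase) / 24)
    vals <- means[[ch]] + offset + diurnal + rnorm(window_hours, 0, sp$within[[ch]])
    if (ch == "humidity") vals <- pmin(pmax(vals, 0), 100)
    # quantize to sensor resolution so on-disk CSVs round-trip exactly
    readings[ch, ] <- round(vals, 3)
  }
  readings
}

# --- generator -------------------------------------------------------------

#' Generate a synthetic multimodal disease dataset
#'
#' Produces `5 * n_per_class` paired samples (leaf image with lesion bounding
#' boxes + hourly sensor window), balanced across the five disease classes.
#' `confusability` plants two ambiguities: (a) a fraction of brown spot and
#' bacterial leaf spot images are rendered with an identical "ambiguous spot"
#' appearance (only the humidity regime separates them), and (b) the same
#' fraction of leaf mold and fusarium wilt samples draw their sensor window
#' from one shared regime (only lesion appearance separates them). As a result
#' the image-only and sensor-only Bayes accuracies are both bounded by
#' `1 - confusability/5`, while the joint Bayes accuracy is unaffected.
#'
#' @param n_per_class samples per class (>= 1).
#' @param image_size `c(H, W)`, both >= 64.
#' @param window_hours sensor window length in hours (>= 1); default one day.
#' @param confusability fraction in `[0, 1]` of planted ambiguous samples.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param n_lesions lesions (and boxes) per image; default 1 keeps the
#'   detection head single-box.
#' @return an object of class `mm_dataset`: a list with `samples` (list of
#'   multimodal samples), `manifest` (data.frame of ids, labels and planted
#'   latents), `classes` and `params`. Each sample holds a `labeled_image`
#'   (with a `lesion_mask` attribute), a `sensor_window` and `class_id`.
#' @export
generate_dataset <- function(n_per_class, image_size = c(64, 64),
                             window_hours = 24, confusability = 0,
                             seed = 1, n_lesions = 1) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (length(image_size) != 2 || any(image_size < 64)) {
    stop("image_size must be c(H, W) with H, W >= 64")
  }
  if (window_hours < 1) stop("window_hours must be >= 1")
  if (confusability < 0 || confusability > 1) {
    stop("confusability must be in [0, 1]")
  }
  classes <- disease_classes()
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])

  with_seed(derive_seed(seed, "data"), {
    samples <- vector("list", 5L * n_per_class)
    man <- vector("list", length(samples))
    k <- 0L
    for (cid in 0:4) {
      cls <- classes[classes$id == cid, ]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        image_id <- sprintf("img_%05d", k)

        amb_image <- cid %in% c(0L, 4L) && runif(1) < confusability
        amb_sensor <- cid %in% c(2L, 3L) && runif(1) < confusability

        style <- if (amb_image) "ambiguous-spot" else cls$lesion_style
        px <- leaf_background(H, W)
        boxes <- list(); mask_all <- matrix(FALSE, H, W)
        for (l in seq_len(n_lesions)) {
          les <- render_lesion(px, style)
          px <- les$px
          boxes[[l]] <- mask_bbox(les$mask)
          mask_all <- mask_all | les$mask
        }
        pixels <- array(as.integer(round(px)), c(H, W, 3))
        img <- new_labeled_image(pixels, cid, boxes, image_id)
        attr(img, "lesion_mask") <- mask_all
        validate_labeled_image(img)

        profile_name <- if (amb_sensor) "shared_wilt_mold" else cls$name
        means <- if (amb_sensor) shared_wilt_mold_profile() else
          c(temperature = cls$temperature, humidity = cls$humidity,
            light = cls$light, co2 = cls$co2)
        w <- new_sensor_window(gen_sensor_window(means, window_hours),
                               window_hours)
        validate_sensor_window(w, image_id)

        samples[[k]] <- structure(
          list(image = img, sensors = w, class_id = cid),
          class = "mm_sample")
        man[[k]] <- data.frame(
          image_id = image_id, class_id = cid,
          image_style = style, sensor_profile = profile_name,
          n_boxes = length(boxes), stringsAsFactors = FALSE)
      }
    }
    structure(list(samples = samples, manifest = do.call(rbind, man),
                   classes = classes,
                   params = list(n_per_class = n_per_class,
                                 image_size = c(H, W),
                                 window_hours = window_hours,
                                 confusability = confusability,
                                 seed = seed, n_lesions = n_lesions)),
              class = "mm_dataset")
  })
}

#' @export
print.mm_dataset <- function(x, ...) {
  cat("<mm_dataset> ", length(x$samples), " samples, ",
      nrow(x$classes), " classes, ",
      x$params$image_size[1], "x", x$params$image_size[2], " px, ",
      x$params$window_hours, " h sensor windows, confusability = ",
      x$params$confusability, "\n", sep = "")
  invisible(x)
}

#' Bayes-optimal prediction from the generator's planted latents
#'
#' The generator's own Bayes rule: it reads the planted latent assignment for
#' the requested modality from the dataset manifest and maps it back to a
#' class. For ambiguous latents (shared appearance or shared sensor regime)
#' the posterior is uniform over the two confusable classes, so the rule
#' resolves them by a fair seeded coin flip — no classifier can do better.
#'
#' @param dataset an `mm_dataset`.
#' @param modality `"image"`, `"sensor"`, or `"both"`.
#' @param seed seed for the tie-breaking coin flips.
#' @return integer vector of predicted class ids (0..4), one per sample.
#' @export
bayes_predict <- function(dataset, modality = c("image", "sensor", "both"),
                          seed = 1) {
  modality <- match.arg(modality)
  man <- dataset$manifest
  classes <- dataset$classes
  style_map <- setNames(classes$id, classes$lesion_style)
  name_map <- setNames(classes$id, classes$name)
  with_seed(derive_seed(seed, "bayes"), {
    vapply(seq_len(nrow(man)), function(i) {
      img_pred <- if (man$image_style[i] == "ambiguous-spot") {
        sample(c(0L, 4L), 1L)
      } else unname(style_map[man$image_style[i]])
      sen_pred <- if (man$sensor_profile[i] == "shared_wilt_mold") {
        sample(c(2L, 3L), 1L)
      } else unname(name_map[man$sensor_profile[i]])
      switch(modality,
        image = img_pred,
        sensor = sen_pred,
        both = {
          # each modality is unambiguous about the pair the other is blind to
          if (man$image_style[i] == "ambiguous-spot") sen_pred
          else if (man$sensor_profile[i] == "shared_wilt_mold") img_pred
          else img_pred
        })
    }, integer(1))
  })
}
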