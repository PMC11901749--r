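# Box-aware augmentation operators. All three are seeded and deterministic;
# CutMix and GridMask can be constrained so lesion boxes survive bit-identical.

one_hot5 <- function(class_id) {
  y <- numeric(5)
  y[class_id + 1] <- 1
  y
}

boxes_intersect <- function(a, b) {
  # half-open boxes: positive-area overlap
  max(a[1], b[1]) < min(a[3], b[3]) && max(a[2], b[2]) < min(a[4], b[4])
}

box_contains <- function(outer, inner) {
  outer[1] <= inner[1] && outer[2] <= inner[2] &&
    outer[3] >= inner[3] && outer[4] >= inner[4]
}

#' CutMix two labeled images
#'
#' In `"region"` mode a rectangular region of `b` replaces the corresponding
#' region of `a`; the mixing ratio `lam` is the *realized* fraction of pixels
#' retained from `a` and the label is `lam * y_a + (1 - lam) * y_b`. In
#' `"blend"` mode the literal pixel-wise form `X = lam*X_a + (1-lam)*X_b` is
#' used with `lam ~ Beta(beta_alpha, beta_alpha)`.
#'
#' With `preserve_lesions = TRUE` (region mode) the pasted rectangle is
#' re-sampled (up to 100 attempts) so that it neither covers any lesion box of
#' `a` nor truncates the first lesion box of `b`; if no placement is found the
#' operator falls back to a no-op mix (`lam = 1`) with a warning. Output boxes
#' are the surviving boxes of `a` plus the boxes of `b` translated into the
#' pasted region.
#'
#' @param a,b `labeled_image` objects of equal dimensions.
#' @param beta_alpha shape of the symmetric Beta distribution for `lam`.
#' @param mode `"region"` (default) or `"blend"`.
#' @param preserve_lesions keep all lesion boxes intact (region mode only).
#' @param seed integer seed.
#' @param rect optional explicit paste rectangle `(x0, y0, x1, y1)` (0-based
#'   half-open) overriding random placement in region mode; a zero-area
#'   rectangle yields the identity mix.
#' @return a `mix_result`: list with `pixels`, `label` (length-5 probability
#'   vector), `boxes`, `lam`, `source_ids`.
#' @export
cutmix <- function(a, b, beta_alpha = 1, mode = c("region", "blend"),
                   preserve_lesions = TRUE, seed = 1, rect = NULL) {
  mode <- match.arg(mode)
  da <- dim(a$pixels); db <- dim(b$pixels)
  if (!identical(da, db)) stop("cutmix: images must have equal dimensions")
  H <- da[1]; W <- da[2]
  ya <- one_hot5(a$class_id); yb <- one_hot5(b$class_id)

  with_seed(derive_seed(seed, "cutmix"), {
    if (mode == "blend") {
      lam <- rbeta(1, beta_alpha, beta_alpha)
      px <- lam * a$pixels + (1 - lam) * b$pixels
      return(new_mix_result(px, lam * ya + (1 - lam) * yb,
                            c(a$boxes, b$boxes), lam,
                            c(a$image_id, b$image_id)))
    }
    b_lesion <- if (length(b$boxes) > 0) b$boxes[[1]] else NULL
    place <- NULL
    if (!is.null(rect)) {
      if ((rect[3] - rect[1]) * (rect[4] - rect[2]) <= 0) {
        return(new_mix_result(a$pixels, ya, a$boxes, 1,
                              c(a$image_id, b$image_id)))
      }
      place <- rect
    } else {
      for (attempt in seq_len(100L)) {
        # fresh Beta draw per attempt: a single unlucky paste size must not
        # doom every placement
        lam0 <- rbeta(1, beta_alpha, beta_alpha)
        target <- sqrt(1 - lam0)   # paste area (1 - lam0), square-ish aspect
        rw <- max(1L, round(target * W)); rh <- max(1L, round(target * H))
        if (preserve_lesions && !is.null(b_lesion)) {
          # the paste must be able to contain b's lesion box
          rw <- min(W, max(rw, ceiling(b_lesion[3] - b_lesion[1]) + 2L))
          rh <- min(H, max(rh, ceiling(b_lesion[4] - b_lesion[2]) + 2L))
        }
        if (preserve_lesions && !is.null(b_lesion)) {
          # sample only placements that contain b's lesion box
          xlo <- max(0L, ceiling(b_lesion[3]) - rw)
          xhi <- floor(b_lesion[1])
          ylo <- max(0L, ceiling(b_lesion[4]) - rh)
          yhi <- floor(b_lesion[2])
          x0 <- if (xhi >= xlo) sample(xlo:xhi, 1L) else 0L
          y0 <- if (yhi >= ylo) sample(ylo:yhi, 1L) else 0L
        } else {
          x0 <- sample.int(W - rw + 1L, 1L) - 1L
          y0 <- sample.int(H - rh + 1L, 1L) - 1L
        }
        cand <- c(x0, y0, min(x0 + rw, W), min(y0 + rh, H))
        if (!preserve_lesions) { place <- cand; break }
        clear_a <- !any(vapply(a$boxes, boxes_intersect, logical(1), b = cand))
        keeps_b <- is.null(b_lesion) || box_contains(cand, b_lesion)
        if (clear_a && keeps_b) { place <- cand; break }
      }
    }
    if (is.null(place)) {
      warning("cutmix: no lesion-preserving placement found after 100 ",
              "attempts; falling back to identity mix (lam = 1)")
      return(new_mix_result(a$pixels, ya, a$boxes, 1,
                            c(a$image_id, b$image_id)))
    }
    px <- a$pixels
    xs <- (place[1] + 1L):place[3]; ys <- (place[2] + 1L):place[4]
    px[ys, xs, ] <- b$pixels[ys, xs, ]
    lam <- 1 - length(xs) * length(ys) / (H * W)
    boxes <- a$boxes[!vapply(a$boxes, boxes_intersect, logical(1), b = place)]
    b_in <- b$boxes[vapply(b$boxes, function(bb) box_contains(place, bb),
                           logical(1))]
    new_mix_result(px, lam * ya + (1 - lam) * yb, c(boxes, b_in), lam,
                   c(a$image_id, b$image_id))
  })
}

new_mix_result <- function(pixels, label, boxes, lam, source_ids) {
  stopifnot(abs(sum(label) - 1) < 1e-9, lam >= 0, lam <= 1)
  structure(list(pixels = pixels, label = label, boxes = boxes, lam = lam,
                 source_ids = source_ids),
            class = "mix_result")
}

# nearest-neighbor resize of an H x W x 3 array
resize_nearest <- function(px, H2, W2) {
  H <- dim(px)[1]; W <- dim(px)[2]
  ri <- pmin(H, floor((seq_len(H2) - 0.5) / H2 * H) + 1L)
  ci <- pmin(W, floor((seq_len(W2) - 0.5) / W2 * W) + 1L)
  px[ri, ci, , drop = FALSE]
}

#' Mosaic four labeled images onto one canvas
#'
#' Tiles four images into quadrants split at `(h1, w1)`: image 1 top-left,
#' image 2 top-right, image 3 bottom-left, image 4 bottom-right. Each source
#' is resized (nearest neighbor) to its quadrant; boxes are scaled, translated
#' and clipped to quadrant bounds, dropping boxes whose clipped area falls
#' below `min_box_frac` of their scaled area. The composite label is the
#' area-weighted mixture of the four one-hot labels.
#'
#' @param imgs list of exactly four `labeled_image` objects.
#' @param canvas `c(H, W)` of the composite.
#' @param split `c(h1, w1)` interior split point, or `"random"`.
#' @param seed integer seed (used when `split = "random"`).
#' @param min_box_frac drop threshold for clipped boxes (default 0.2).
#' @return a `mix_result`-like composite; `label` mixes all four classes and
#'   `lam` is the weight of image 1's quadrant.
#' @export
mosaic <- function(imgs, canvas, split = "random", seed = 1,
                   min_box_frac = 0.2) {
  if (length(imgs) != 4) stop("mosaic requires exactly four images")
  H <- canvas[1]; W <- canvas[2]
  with_seed(derive_seed(seed, "mosaic"), {
    if (identical(split, "random")) {
      split <- c(sample(seq(round(0.3 * H), round(0.7 * H)), 1L),
                 sample(seq(round(0.3 * W), round(0.7 * W)), 1L))
    }
    h1 <- split[1]; w1 <- split[2]
    if (h1 <= 0 || w1 <= 0 || h1 >= H || w1 >= W) {
      stop("mosaic: degenerate quadrant (split must be interior to the canvas)")
    }
    quads <- list(c(0, 0, w1, h1), c(w1, 0, W, h1),
                  c(0, h1, w1, H), c(w1, h1, W, H))
    px <- array(0L, c(H, W, 3))
    boxes <- list(); weights <- numeric(4); label <- numeric(5)
    for (q in 1:4) {
      img <- imgs[[q]]
      qb <- quads[[q]]
      qh <- qb[4] - qb[2]; qw <- qb[3] - qb[1]
      px[(qb[2] + 1):qb[4], (qb[1] + 1):qb[3], ] <-
        resize_nearest(img$pixels, qh, qw)
      sh <- dim(img$pixels)[1]; sw <- dim(img$pixels)[2]
      sx <- qw / sw; sy <- qh / sh
      for (bb in img$boxes) {
        nb <- c(qb[1] + bb[1] * sx, qb[2] + bb[2] * sy,
                qb[1] + bb[3] * sx, qb[2] + bb[4] * sy)
        scaled_area <- (nb[3] - nb[1]) * (nb[4] - nb[2])
        cl <- c(max(nb[1], qb[1]), max(nb[2], qb[2]),
                min(nb[3], qb[3]), min(nb[4], qb[4]))
        area <- max(0, cl[3] - cl[1]) * max(0, cl[4] - cl[2])
        if (scaled_area > 0 && area / scaled_area >= min_box_frac) {
          boxes[[length(boxes) + 1]] <- cl
        }
      }
      weights[q] <- qh * qw / (H * W)
      label <- label + weights[q] * one_hot5(img$class_id)
    }
    new_mix_result(px, label, boxes, weights[1],
                   c(imgs[[1]]$image_id, imgs[[2]]$image_id))
  })
}

#' Build a GridMask specification
#'
#' The binary mask tiles the image with period `unit`; within each cell a
#' square block of side `round(unit * sqrt(1 - ratio))` is zeroed, so the kept
#' fraction per cell is approximately `ratio`. `offset` shifts the grid phase.
#'
#' @param unit grid period in pixels (>= 2).
#' @param ratio kept fraction per cell, in (0, 1).
#' @param offset integer `c(dx, dy)` phase.
#' @param size image `c(H, W)`.
#' @return a `gridmask_spec`: list with `unit`, `ratio`, `offset`, `mask`
#'   (H x W 0/1 matrix) and the analytic `kept_fraction`.
#' @export
gridmask_spec <- function(unit, ratio, offset = c(0, 0), size) {
  if (unit < 2) stop("gridmask: unit must be >= 2")
  if (ratio <= 0 || ratio >= 1) stop("gridmask: ratio must be in (0, 1)")
  H <- size[1]; W <- size[2]
  blk <- round(unit * sqrt(1 - ratio))
  # phase position of each pixel within its grid cell (0-based)
  py <- (seq_len(H) - 1 + offset[2]) %% unit
  px <- (seq_len(W) - 1 + offset[1]) %% unit
  zy <- py < blk
  zx <- px < blk
  mask <- 1 - outer(zy, zx, "&")
  structure(list(unit = as.integer(unit), ratio = ratio,
                 offset = as.integer(offset), mask = mask,
                 kept_fraction = 1 - (blk / unit)^2),
            class = "gridmask_spec")
}

#' Apply GridMask occlusion to a labeled image
#'
#' Multiplies the image element-wise by a periodic binary mask. With
#' `preserve_lesions = TRUE` the mask is forced to 1 inside every lesion box
#' after grid generation, so annotated symptoms are never occluded. Label and
#' boxes are unchanged.
#'
#' @param img a `labeled_image`.
#' @param spec a [gridmask_spec()] or `"random"` (unit sampled uniformly from
#'   `[min_side/8, min_side/4]`, ratio from `[0.3, 0.6]`).
#' @param preserve_lesions exempt lesion boxes from occlusion.
#' @param seed integer seed (used when `spec = "random"`).
#' @return a `labeled_image` with masked pixels; a `gridmask_spec` attribute
#'   carries the realized mask.
#' @export
gridmask <- function(img, spec = "random", preserve_lesions = TRUE, seed = 1) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  with_seed(derive_seed(seed, "gridmask"), {
    if (identical(spec, "random")) {
      ms <- min(H, W)
      unit <- sample(seq(max(2L, floor(ms / 8)), max(2L, floor(ms / 4))), 1L)
      spec <- gridmask_spec(unit, runif(1, 0.3, 0.6),
                            offset = c(sample.int(unit, 1L) - 1L,
                                       sample.int(unit, 1L) - 1L),
                            size = c(H, W))
    }
    mask <- spec$mask
    if (preserve_lesions) {
      for (b in img$boxes) {
        mask[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- 1
      }
    }
    out <- img
    storage_int <- is.integer(img$pixels)
    masked <- img$pixels * as.vector(mask)
    out$pixels <- if (storage_int) {
      array(as.integer(masked), dim(img$pixels))
    } else masked
    spec$mask <- mask
    attr(out, "gridmask_spec") <- spec
    out
  })
}
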