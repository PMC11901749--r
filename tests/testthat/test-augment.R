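test_that("cutmix label mixing follows lam * y_a + (1 - lam) * y_b", {
  # lam = 0.7 over a 10x10 image: paste 30 pixels (3x10 block)
  a <- solid_image(10, 10, 10L, class_id = 0L, id = "a")
  b <- solid_image(10, 10, 200L, class_id = 1L, id = "b")
  mx <- cutmix(a, b, mode = "region", preserve_lesions = FALSE,
               rect = c(0, 0, 10, 3))
  expect_equal(mx$lam, 0.7)
  expect_equal(mx$label, c(0.7, 0.3, 0, 0, 0))
  expect_equal(sum(mx$pixels[, , 1] == 200L), 30)
})

test_that("cutmix region arithmetic: 5x4 paste on 10x10 gives lam 0.8", {
  a <- solid_image(10, 10, 10L, class_id = 2L, id = "a")
  b <- solid_image(10, 10, 200L, class_id = 4L, id = "b")
  mx <- cutmix(a, b, mode = "region", preserve_lesions = FALSE,
               rect = c(2, 3, 7, 7))  # 5 wide x 4 tall = 20 px
  expect_equal(mx$lam, 1 - 20 / 100)
  expect_equal(mx$label, 0.8 * c(0, 0, 1, 0, 0) + 0.2 * c(0, 0, 0, 0, 1))
})

test_that("cutmix zero-area paste is the identity", {
  a <- solid_image(8, 8, 50L, class_id = 1L, id = "a")
  b <- solid_image(8, 8, 90L, class_id = 3L, id = "b")
  mx <- cutmix(a, b, mode = "region", rect = c(4, 4, 4, 4))
  expect_identical(mx$pixels, a$pixels)
  expect_equal(mx$lam, 1)
  expect_equal(mx$label, c(0, 1, 0, 0, 0))
})

test_that("cutmix blend mode matches the literal pixel-wise formula", {
  a <- solid_image(6, 6, 100L, class_id = 0L, id = "a")
  b <- solid_image(6, 6, 200L, class_id = 1L, id = "b")
  mx <- cutmix(a, b, mode = "blend", beta_alpha = 1, seed = 5)
  expect_equal(unique(as.vector(mx$pixels)),
               mx$lam * 100 + (1 - mx$lam) * 200)
  expect_equal(mx$label, c(mx$lam, 1 - mx$lam, 0, 0, 0))
  expect_identical(cutmix(a, b, mode = "blend", seed = 5)$lam, mx$lam)
})

test_that("cutmix preservation keeps lesion-box pixels bit-identical", {
  set.seed(3)
  ds <- tiny_dataset()
  for (k in c(1, 6, 11)) {
    a <- ds$samples[[k]]$image
    b <- ds$samples[[k + 1]]$image
    mx <- suppressWarnings(
      cutmix(a, b, mode = "region", preserve_lesions = TRUE, seed = k))
    # every surviving a-box must be untouched
    for (bb in a$boxes) {
      kept <- any(vapply(mx$boxes, function(x) identical(as.numeric(x),
                                                         as.numeric(bb)),
                         logical(1)))
      if (kept) {
        xs <- (bb[1] + 1):bb[3]; ys <- (bb[2] + 1):bb[4]
        expect_identical(mx$pixels[ys, xs, ], a$pixels[ys, xs, ])
      }
    }
    expect_equal(sum(mx$label), 1)
  }
})

test_that("cutmix errors on size mismatch and falls back when infeasible", {
  a <- solid_image(8, 8, 1L)
  b <- solid_image(10, 10, 1L)
  expect_error(cutmix(a, b), "equal dimensions")
  # a box covering everything makes preservation infeasible
  big <- solid_image(8, 8, 1L, boxes = list(c(0, 0, 8, 8)), id = "big")
  other <- solid_image(8, 8, 2L, class_id = 1L,
                       boxes = list(c(0, 0, 8, 8)), id = "o")
  expect_warning(mx <- cutmix(big, other, mode = "region",
                              preserve_lesions = TRUE, seed = 1),
                 "no lesion-preserving placement")
  expect_equal(mx$lam, 1)
  expect_identical(mx$pixels, big$pixels)
})

test_that("mosaic places quadrants in the prescribed order", {
  imgs <- lapply(0:3, function(k) {
    solid_image(2, 2, as.integer(50 * (k + 1)), class_id = k,
                id = paste0("m", k))
  })
  mx <- mosaic(imgs, canvas = c(4, 4), split = c(2, 2))
  expect_equal(mx$pixels[1, 1, 1], 50)    # top-left     = image 1
  expect_equal(mx$pixels[1, 4, 1], 100)   # top-right    = image 2
  expect_equal(mx$pixels[4, 1, 1], 150)   # bottom-left  = image 3
  expect_equal(mx$pixels[4, 4, 1], 200)   # bottom-right = image 4
  expect_equal(mx$label, rep(0.25, 4)[1] * c(1, 1, 1, 1, 0))
})

test_that("mosaic label weights are quadrant areas over canvas area", {
  imgs <- lapply(0:3, function(k) {
    solid_image(4, 4, 10L, class_id = k, id = paste0("m", k))
  })
  mx <- mosaic(imgs, canvas = c(4, 4), split = c(1, 1))
  expect_equal(mx$label, c(1 / 16, 3 / 16, 3 / 16, 9 / 16, 0))
  expect_equal(sum(mx$label), 1)

  # identical inputs: label collapses to the shared one-hot
  same <- lapply(1:4, function(k) solid_image(4, 4, 10L, class_id = 2L,
                                              id = paste0("s", k)))
  expect_equal(mosaic(same, canvas = c(4, 4), split = c(2, 2))$label,
               c(0, 0, 1, 0, 0))
})

test_that("mosaic conserves pixels (nearest-neighbor: no invented colors)", {
  set.seed(8)
  imgs <- lapply(0:3, function(k) {
    img <- solid_image(6, 6, 0L, class_id = k, id = paste0("m", k))
    img$pixels <- array(as.integer(sample(0:255, 6 * 6 * 3, TRUE)), c(6, 6, 3))
    img
  })
  mx <- mosaic(imgs, canvas = c(8, 8), split = c(3, 5), seed = 2)
  src_vals <- unique(unlist(lapply(imgs, function(i) i$pixels)))
  expect_true(all(mx$pixels %in% src_vals))
})

test_that("mosaic remaps and clips boxes, dropping small remnants", {
  img_box <- solid_image(4, 4, 10L, class_id = 0L,
                         boxes = list(c(0, 0, 2, 2)), id = "b0")
  plain <- lapply(1:3, function(k) solid_image(4, 4, 10L, class_id = k,
                                               id = paste0("p", k)))
  mx <- mosaic(c(list(img_box), plain), canvas = c(8, 8), split = c(4, 4))
  # image 1's quadrant is 4x4 (scale 1): the box maps onto itself
  expect_equal(mx$boxes[[1]], c(0, 0, 2, 2))
  expect_error(mosaic(c(list(img_box), plain), canvas = c(8, 8),
                      split = c(0, 4)), "degenerate")
})

test_that("gridmask identity, forced exemption, and analytic fraction", {
  img <- solid_image(8, 8, 100L, boxes = list(c(2, 2, 5, 5)), id = "g")

  spec1 <- gridmask_spec(4, 0.5, c(0, 0), c(8, 8))
  spec1$mask[] <- 1
  out <- gridmask(img, spec1, preserve_lesions = FALSE)
  expect_identical(out$pixels, img$pixels)

  spec0 <- gridmask_spec(4, 0.5, c(0, 0), c(8, 8))
  spec0$mask[] <- 0
  out0 <- gridmask(img, spec0, preserve_lesions = TRUE)
  inside <- out0$pixels[3:5, 3:5, ]
  expect_true(all(inside == 100L))
  outside <- out0$pixels
  outside[3:5, 3:5, ] <- NA
  expect_true(all(outside == 0L, na.rm = TRUE))
  expect_identical(out0$boxes, img$boxes)

  # unit 4, ratio 0.5 on 8x8: enumerate the mask cells independently
  spec <- gridmask_spec(4, 0.5, c(0, 0), c(8, 8))
  blk <- round(4 * sqrt(1 - 0.5))
  manual <- matrix(1, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    if ((r - 1) %% 4 < blk && (c - 1) %% 4 < blk) manual[r, c] <- 0
  }
  expect_equal(unname(spec$mask), manual)
  out2 <- gridmask(img, spec, preserve_lesions = FALSE)
  expect_equal(mean(out2$pixels == 0L), (blk / 4)^2)
  expect_equal(mean(spec$mask), spec$kept_fraction)
})

test_that("gridmask preserves lesion pixels bit-identically", {
  ds <- tiny_dataset()
  s <- ds$samples[[3]]$image
  out <- gridmask(s, "random", preserve_lesions = TRUE, seed = 4)
  for (b in s$boxes) {
    xs <- (b[1] + 1):b[3]; ys <- (b[2] + 1):b[4]
    expect_identical(out$pixels[ys, xs, ], s$pixels[ys, xs, ])
  }
  expect_identical(gridmask(s, "random", TRUE, seed = 4)$pixels, out$pixels)
  expect_error(gridmask_spec(1, 0.5, size = c(8, 8)), "unit")
})

test_that("mask mean stays within 0.05 of the analytic kept fraction", {
  for (unit in c(8, 12, 16)) {
    for (ratio in c(0.3, 0.45, 0.6)) {
      spec <- gridmask_spec(unit, ratio, c(3, 5), c(64, 64))
      expect_lt(abs(mean(spec$mask) - spec$kept_fraction), 0.05)
    }
  }
})
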