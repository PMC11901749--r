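test_that("vectorized attention matches the double-loop oracle on 100 instances", {
  set.seed(11)
  for (i in 1:100) {
    N <- sample(1:8, 1); D <- sample(1:4, 1)
    x <- matrix(rnorm(N * D), N, D)
    layer <- attention_layer_init(D)
    got <- phytofuse:::attention_layer_forward(x, layer, norm = FALSE)$y
    ref <- x + oracle_attention(x, layer$Wq, layer$Wk, layer$Wv, layer$scale)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("singleton token: weight matrix [[1]] and residual V-transform", {
  D <- 3
  layer <- attention_layer_init(D)
  x <- matrix(rnorm(D), 1, D)
  out <- embedding_attention(x, list(layer), norm = FALSE,
                             return_weights = TRUE)
  expect_equal(attr(out, "weights")[[1]], matrix(1, 1, 1))
  expect_equal(unclass(out)[1, ], as.vector(x + x %*% layer$Wv),
               ignore_attr = TRUE)
})

test_that("zero Wq/Wk degenerates to uniform token averaging", {
  set.seed(2)
  x <- matrix(rnorm(5 * 4), 5, 4)
  stack <- attention_stack_init(1, 4, zero_qk = TRUE)
  out <- embedding_attention(x, stack, norm = FALSE, return_weights = TRUE)
  A <- attr(out, "weights")[[1]]
  expect_equal(A, matrix(1 / 5, 5, 5))
  avg <- colMeans(x %*% stack[[1]]$Wv)
  expect_equal(unclass(out),
               x + matrix(avg, 5, 4, byrow = TRUE), ignore_attr = TRUE)
})

test_that("hand-computed N=2, D=1 case", {
  # Q = [1, 2], K = [1, 2], d = 1, V = [10, 20]
  x <- matrix(c(1, 2), 2, 1)
  layer <- list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(10),
                ln_g = 1, ln_b = 0, scale = 1)
  out <- phytofuse:::attention_layer_forward(x, layer, norm = FALSE)$y
  r1 <- (exp(1) * 10 + exp(2) * 20) / (exp(1) + exp(2))
  r2 <- (exp(2) * 10 + exp(4) * 20) / (exp(2) + exp(4))
  expect_equal(as.vector(out), c(1 + r1, 2 + r2), tolerance = 1e-9)
})

test_that("softmax rows sum to 1 and permutation equivariance holds", {
  set.seed(7)
  for (i in 1:20) {
    N <- sample(2:9, 1); D <- sample(2:5, 1)
    x <- matrix(rnorm(N * D), N, D)
    stack <- attention_stack_init(2, D)
    out <- embedding_attention(x, stack, return_weights = TRUE)
    for (A in attr(out, "weights")) {
      expect_equal(rowSums(A), rep(1, N), tolerance = 1e-6)
    }
    perm <- sample(N)
    out_p <- embedding_attention(x[perm, , drop = FALSE], stack)
    expect_equal(unclass(out_p), unclass(out)[perm, , drop = FALSE],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(embedding_attention(matrix(c(1, NA), 1), list()), "non-finite")
})

test_that("channel attention pools and rescales per channel", {
  # constant map: z_c recovers the constant exactly
  fmap <- array(0, c(2, 2, 3))
  fmap[, , 1] <- 5; fmap[, , 2] <- -1; fmap[, , 3] <- 0.25
  out <- channel_attention(fmap, cbam_init(3, seed = 1))
  expect_equal(attr(out, "z"), c(5, -1, 0.25))

  # 2x2 single-channel map [[1,2],[3,4]]: z = 2.5
  m <- array(matrix(c(1, 3, 2, 4), 2, 2), c(2, 2, 1))
  expect_equal(attr(channel_attention(m, cbam_init(1, seed = 1)), "z"), 2.5)

  # forced s = 1: identity (zero the MLP and push the bias high)
  p <- cbam_init(3, seed = 1)
  p$fc2_W[] <- 0; p$fc2_b[] <- 1e4
  expect_equal(unclass(channel_attention(fmap, p)), fmap,
               ignore_attr = TRUE, tolerance = 1e-12)
  s <- attr(channel_attention(fmap, p), "s")
  expect_true(all(s > 0 & s <= 1))
})

test_that("spatial attention: zero kernel gives uniform 0.5 gating", {
  set.seed(3)
  fmap <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  p <- cbam_init(3, seed = 1)
  p$conv_W[] <- 0; p$conv_b <- 0
  out <- spatial_attention(fmap, p)
  expect_equal(unclass(out), 0.5 * fmap, ignore_attr = TRUE)

  # single channel: mean map = max map = the input itself
  one <- array(rnorm(9), c(3, 3, 1))
  p2 <- cbam_init(1, seed = 2)
  out1 <- spatial_attention(one, p2)
  w <- attr(out1, "weights")
  stacked <- array(c(one[, , 1], one[, , 1]), c(3, 3, 2))
  expect_equal(w, 1 / (1 + exp(-phytofuse:::conv2d_same2(stacked, p2$conv_W,
                                                         p2$conv_b))))

  # 1x1 spatial map: scalar weight checked by hand
  tiny <- array(c(2, -1), c(1, 1, 2))
  p3 <- cbam_init(2, seed = 3)
  s <- sum(p3$conv_W[4, 4, 1] * mean(tiny)) + p3$conv_W[4, 4, 2] * max(tiny) +
    p3$conv_b
  expect_equal(as.vector(spatial_attention(tiny, p3)),
               as.vector(tiny) / (1 + exp(-s)))
})

test_that("cbam composes channel then spatial and ordering matters", {
  set.seed(9)
  fmap <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  p <- cbam_init(3, seed = 4)
  expect_equal(cbam(fmap, p),
               unclass(spatial_attention(channel_attention(fmap, p), p)),
               ignore_attr = TRUE)
  # constructed asymmetric input: spatial-then-channel differs
  swapped <- channel_attention(spatial_attention(fmap, p), p)
  expect_false(isTRUE(all.equal(cbam(fmap, p), unclass(swapped),
                                check.attributes = FALSE)))
})

test_that("cbam backward matches finite differences", {
  set.seed(21)
  fmap <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  p <- cbam_init(4, kernel = 3, seed = 5)
  dy <- array(rnorm(length(fmap)), dim(fmap))
  fwd <- phytofuse:::cbam_fwd(fmap, p)
  bk <- phytofuse:::cbam_bwd(fwd, p, dy)
  loss <- function(fm) sum(phytofuse:::cbam_fwd(array(fm, dim(fmap)), p)$y * dy)
  fd <- numeric_grad(loss, as.vector(fmap), h = 1e-5)
  expect_equal(as.vector(bk$dx), fd, tolerance = 1e-5)
  for (nm in c("fc1_W", "fc2_W", "conv_W", "conv_b")) {
    lp <- function(v) {
      pp <- p; pp[[nm]][] <- v
      sum(phytofuse:::cbam_fwd(fmap, pp)$y * dy)
    }
    fdp <- numeric_grad(lp, as.vector(p[[nm]]), h = 1e-5)
    expect_equal(as.vector(bk$grads[[nm]]), fdp, tolerance = 1e-4)
  }
})
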