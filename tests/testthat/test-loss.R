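rand_batch <- function(n = 6, C = 5) {
  logits <- matrix(rnorm(n * C), n, C)
  labels <- t(vapply(sample.int(C, n, TRUE), function(k) {
    y <- numeric(C); y[k] <- 1; y
  }, numeric(C)))
  list(logits = logits, probs = softmax_rows(logits), labels = labels)
}

test_that("cross-entropy hand cases", {
  onehot <- diag(5)[c(1, 3), ]
  expect_equal(cross_entropy(onehot, onehot), 0)

  p <- matrix(c(1 / exp(1), rep((1 - 1 / exp(1)) / 4, 4)), 1)
  y <- matrix(c(1, 0, 0, 0, 0), 1)
  expect_equal(cross_entropy(p, y), 1)

  soft <- matrix(c(0.7, 0.3, 0, 0, 0), 1)
  expect_equal(cross_entropy(soft, soft),
               -(0.7 * log(0.7) + 0.3 * log(0.3)))

  expect_error(cross_entropy(matrix(c(0.5, 0.2, 0, 0, 0), 1), y), "sum to 1")
})

test_that("focal loss reduces to CE at gamma 0 and hits its hand value", {
  set.seed(13)
  for (i in 1:50) {
    b <- rand_batch()
    expect_equal(focal_loss(b$probs, b$labels, gamma = 0, alpha = 1),
                 cross_entropy(b$probs, b$labels), tolerance = 1e-9)
  }
  perfect <- diag(5)[2, , drop = FALSE]
  expect_equal(focal_loss(perfect, perfect, gamma = 3), 0)
  half <- matrix(c(0.5, 0.5, 0, 0, 0), 1)
  y <- matrix(c(1, 0, 0, 0, 0), 1)
  expect_equal(focal_loss(half, y, gamma = 2, alpha = 1), 0.25 * log(2))
})

test_that("focal <= cross-entropy elementwise for gamma > 0, alpha = 1", {
  set.seed(17)
  for (i in 1:25) {
    b <- rand_batch()
    expect_lte(focal_loss(b$probs, b$labels, gamma = 2, alpha = 1),
               cross_entropy(b$probs, b$labels) + 1e-12)
  }
})

test_that("alignment loss analytic extremes and scale invariance", {
  v <- matrix(rnorm(12), 3, 4)
  expect_equal(alignment_loss(v, v), 0, tolerance = 1e-7)
  expect_equal(alignment_loss(v, -v), 2, tolerance = 1e-7)
  u <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  w <- matrix(c(0, 1, 1, 0, 0, -1), 3, 2)
  expect_equal(alignment_loss(u, w), 1, tolerance = 1e-7)

  set.seed(19)
  a <- matrix(rnorm(20), 4, 5); b <- matrix(rnorm(20), 4, 5)
  sc <- runif(4, 0.1, 10)
  expect_equal(alignment_loss(a * sc, b), alignment_loss(a, b),
               tolerance = 1e-6)
  expect_error(alignment_loss(a, b[1:2, ]), "equal dimensions")
})

test_that("embedding loss composes CE and alignment with lambda", {
  set.seed(23)
  b <- rand_batch(4)
  fv <- matrix(rnorm(4 * 3), 4, 3); ft <- matrix(rnorm(4 * 3), 4, 3)
  u <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  w <- matrix(c(0, 1, 1, 0, 0, -1), 3, 2)

  lb <- embedding_loss(b$probs, b$labels, fv, ft,
                       loss_config("embedding", lambda_align = 0.5))
  expect_equal(lb$total, lb$ce + 0.5 * lb$align, tolerance = 1e-9)
  expect_equal(lb$ce, cross_entropy(b$probs, b$labels))
  expect_equal(lb$align, alignment_loss(fv, ft))
  expect_gte(lb$align, 0); expect_lte(lb$align, 2)

  for (i in 1:50) {
    b2 <- rand_batch()
    l0 <- embedding_loss(b2$probs, b2$labels, fv[1:2, ], ft[1:2, ],
                         loss_config("embedding", lambda_align = 0))
    expect_equal(l0$total, cross_entropy(b2$probs, b2$labels),
                 tolerance = 1e-9)
  }
  # perfect prediction and fv = ft: total exactly 0
  perfect <- diag(5)[c(2, 4), ]
  lp <- embedding_loss(perfect, perfect, fv[1:2, ], fv[1:2, ],
                       loss_config("embedding", lambda_align = 0.7))
  expect_equal(lp$total, 0, tolerance = 1e-7)
  # the worked composition: CE = H(0.7, 0.3), align = 1, lambda = 0.5
  soft <- matrix(c(0.7, 0.3, 0, 0, 0), 1)
  lw <- embedding_loss(soft, soft, u[1, , drop = FALSE], w[1, , drop = FALSE],
                       loss_config("embedding", lambda_align = 0.5))
  expect_equal(lw$total, -(0.7 * log(0.7) + 0.3 * log(0.3)) + 0.5,
               tolerance = 1e-6)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(29)
  for (i in 1:5) {
    b <- rand_batch(4)
    gce <- phytofuse:::cross_entropy_grad_logits(b$logits, b$labels)
    fd <- numeric_grad(function(z) {
      cross_entropy(softmax_rows(matrix(z, 4, 5)), b$labels)
    }, as.vector(b$logits))
    expect_equal(as.vector(gce), fd, tolerance = 1e-4)

    gfl <- phytofuse:::focal_grad_logits(b$logits, b$labels, 2, 0.8)
    fdf <- numeric_grad(function(z) {
      focal_loss(softmax_rows(matrix(z, 4, 5)), b$labels, 2, 0.8)
    }, as.vector(b$logits))
    expect_equal(as.vector(gfl), fdf, tolerance = 1e-4)

    fv <- matrix(rnorm(12), 3, 4); ft <- matrix(rnorm(12), 3, 4)
    ga <- phytofuse:::alignment_grad(fv, ft)
    fda <- numeric_grad(function(v) alignment_loss(matrix(v, 3, 4), ft),
                        as.vector(fv))
    expect_equal(as.vector(ga$dfv), fda, tolerance = 1e-4)
    fdb <- numeric_grad(function(v) alignment_loss(fv, matrix(v, 3, 4)),
                        as.vector(ft))
    expect_equal(as.vector(ga$dft), fdb, tolerance = 1e-4)
  }
})

test_that("inverse-frequency weights satisfy sum_c w_c n_c = N", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    labels <- t(vapply(sample.int(5, n, TRUE, prob = runif(5)), function(k) {
      y <- numeric(5); y[k] <- 1; y
    }, numeric(5)))
    w <- inverse_frequency_weights(labels)
    expect_equal(sum(w * colSums(labels)), n)
    expect_true(all(w > 0))
  }
  expect_error(cross_entropy(diag(5), diag(5), weights = c(1, 2)), "length 5")
})

test_that("loss_config validates its fields", {
  expect_error(loss_config(lambda_align = -1), "lambda_align")
  expect_error(loss_config(focal_gamma = -0.1), "focal_gamma")
  expect_error(loss_config(focal_alpha = 0), "focal_alpha")
  expect_equal(loss_config("ce")$kind, "ce")
})
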