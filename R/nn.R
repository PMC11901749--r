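# Minimal neural-network primitives: forward passes paired with hand-written
# backward passes. Everything operates on plain matrices/arrays; a "parameter
# set" is a named list of numeric matrices/vectors and a gradient is a list of
# the same shapes. No external framework is involved.

nn_eps <- 1e-8

#' Numerically stable row-wise softmax
#'
#' @param x numeric matrix; softmax is applied independently to each row.
#' @return matrix of the same shape with non-negative rows summing to 1.
#' @export
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Backward of row softmax: given output p and upstream dp, return dx.
softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# --- dense layer -----------------------------------------------------------

# y = x %*% W + b  (x: N x Din, W: Din x Dout, b: length Dout)
dense_forward <- function(x, W, b) {
  sweep(x %*% W, 2L, b, "+")
}

dense_backward <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# --- layer normalization (per row) ----------------------------------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, istd = istd)
}

layernorm_backward <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  istd <- cache$istd
  D <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  # dx = istd/D * (D*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)) per row
  dx <- (dxhat * D - rowSums(dxhat) - xhat * rowSums(dxhat * xhat)) * istd / D
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- scaled dot-product self-attention block -------------------------------
# One layer: Q = X Wq, K = X Wk, V = X Wv, A = softmax(Q K' / sqrt(d)),
# out = layernorm(X + A V). Residual + layer normalization stabilize the
# stack; d is the feature dimension unless overridden.

attention_layer_init <- function(d, scale = NULL, init_sd = 0.2) {
  list(
    Wq = matrix(rnorm(d * d, sd = init_sd), d, d),
    Wk = matrix(rnorm(d * d, sd = init_sd), d, d),
    Wv = matrix(rnorm(d * d, sd = init_sd), d, d),
    ln_g = rep(1, d),
    ln_b = rep(0, d),
    scale = if (is.null(scale)) d else scale
  )
}

attention_layer_forward <- function(x, layer, norm = TRUE) {
  Q <- x %*% layer$Wq
  K <- x %*% layer$Wk
  V <- x %*% layer$Wv
  S <- tcrossprod(Q, K) / sqrt(layer$scale)
  A <- softmax_rows(S)
  O <- A %*% V
  H <- x + O
  if (norm) {
    ln <- layernorm_forward(H, layer$ln_g, layer$ln_b)
    list(y = ln$y, x = x, Q = Q, K = K, V = V, A = A, ln = ln, norm = TRUE)
  } else {
    list(y = H, x = x, Q = Q, K = K, V = V, A = A, norm = FALSE)
  }
}

attention_layer_backward <- function(cache, layer, dy) {
  if (cache$norm) {
    ln <- layernorm_backward(cache$ln, layer$ln_g, dy)
    dH <- ln$dx
    dgamma <- ln$dgamma
    dbeta <- ln$dbeta
  } else {
    dH <- dy
    dgamma <- NULL
    dbeta <- NULL
  }
  x <- cache$x
  dx <- dH                 # residual path
  dO <- dH
  dA <- tcrossprod(dO, cache$V)
  dV <- crossprod(cache$A, dO)
  dS <- softmax_rows_backward(cache$A, dA) / sqrt(layer$scale)
  dQ <- dS %*% cache$K
  dK <- crossprod(dS, cache$Q)
  dx <- dx + dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  grads <- list(
    Wq = crossprod(x, dQ),
    Wk = crossprod(x, dK),
    Wv = crossprod(x, dV)
  )
  if (cache$norm) {
    grads$ln_g <- dgamma
    grads$ln_b <- dbeta
  }
  list(dx = dx, grads = grads)
}

# --- 3x3 stride-2 convolution via im2col -----------------------------------
# Input x: H x W x Cin array; kernel K: (9*Cin) x Cout matrix whose rows are
# ordered offset-major (dy, dx) with Cin columns per offset; padding 1.

conv3x3_out_dim <- function(n, stride = 2L, pad = 1L) {
  as.integer(floor((n + 2L * pad - 3L) / stride) + 1L)
}

conv_im2col <- function(x, stride = 2L) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- conv3x3_out_dim(H, stride); Wo <- conv3x3_out_dim(W, stride)
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  rows <- 1L + stride * (seq_len(Ho) - 1L)
  cols <- 1L + stride * (seq_len(Wo) - 1L)
  blocks <- vector("list", 9L)
  k <- 1L
  for (dj in 0:2) {      # column offset varies slower than row offset
    for (di in 0:2) {
      sl <- xp[rows + di, cols + dj, , drop = FALSE]
      blocks[[k]] <- matrix(sl, nrow = Ho * Wo, ncol = C)
      k <- k + 1L
    }
  }
  list(mat = do.call(cbind, blocks), Ho = Ho, Wo = Wo, H = H, W = W, C = C,
       rows = rows, cols = cols)
}

conv3x3_forward <- function(x, K, b, stride = 2L) {
  ic <- conv_im2col(x, stride)
  out <- sweep(ic$mat %*% K, 2L, b, "+")
  list(y = array(out, c(ic$Ho, ic$Wo, ncol(K))), ic = ic)
}

conv3x3_backward <- function(cache, K, dy) {
  ic <- cache$ic
  Cout <- ncol(K)
  dy_mat <- matrix(dy, nrow = ic$Ho * ic$Wo, ncol = Cout)
  dK <- crossprod(ic$mat, dy_mat)
  db <- colSums(dy_mat)
  dcol <- dy_mat %*% t(K)
  # fold columns back into a padded gradient array
  dxp <- array(0, c(ic$H + 2L, ic$W + 2L, ic$C))
  k <- 1L
  for (dj in 0:2) {
    for (di in 0:2) {
      blk <- array(dcol[, ((k - 1L) * ic$C + 1L):(k * ic$C)],
                   c(ic$Ho, ic$Wo, ic$C))
      dxp[ic$rows + di, ic$cols + dj, ] <-
        dxp[ic$rows + di, ic$cols + dj, , drop = FALSE] + blk
      k <- k + 1L
    }
  }
  list(dx = dxp[2:(ic$H + 1L), 2:(ic$W + 1L), , drop = FALSE], dK = dK, db = db)
}

# --- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip_decay = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !(nm %in% skip_decay)) {
      g <- g + weight_decay * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Cosine-annealed learning rate
#'
#' Schedules the learning rate over `epochs` epochs:
#' `lr(e) = 0.5 * (1 + cos(pi * e / epochs)) * lr0` with `e` counted from 0,
#' so the first epoch trains at `lr0` and the rate decays towards 0.
#'
#' @param lr0 initial learning rate.
#' @param epoch current epoch, 1-based.
#' @param epochs total number of epochs.
#' @return the learning rate for `epoch`.
#' @export
cosine_lr <- function(lr0, epoch, epochs) {
  0.5 * (1 + cos(pi * (epoch - 1) / epochs)) * lr0
}

# Elementwise accumulation of two same-shaped gradient lists.
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# Flatten nested parameter lists into a named list of leaves (used by the
# compression module and parameter counting). Names are dot-joined paths.
flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p)) {
      out <- c(out, flatten_params(p, key))
    } else if (is.numeric(p)) {
      out[[key]] <- p
    }
  }
  out
}

count_params <- function(params) {
  sum(vapply(flatten_params(params), length, integer(1)))
}
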