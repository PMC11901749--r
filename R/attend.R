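# Attention operators: the joint embedding attention stack over fused
# multimodal tokens, plus the ablation baselines (channel attention, spatial
# attention, and their CBAM composition on convolutional feature maps).

#' Build a stack of attention layers
#'
#' @param n_layers number of layers.
#' @param dim token dimension D.
#' @param seed integer seed (NULL = current RNG stream).
#' @param zero_qk zero-initialize Wq and Wk (yields uniform attention).
#' @return list of attention layers (each with `Wq`, `Wk`, `Wv`, layer-norm
#'   parameters and the scaling factor `scale = dim`).
#' @export
attention_stack_init <- function(n_layers = 2, dim = 32, seed = NULL,
                                 zero_qk = FALSE) {
  make <- function() {
    lapply(seq_len(n_layers), function(i) {
      l <- attention_layer_init(dim)
      if (zero_qk) {
        l$Wq[] <- 0
        l$Wk[] <- 0
      }
      l
    })
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Joint embedding attention over multimodal tokens
#'
#' Applies a stack of scaled dot-product self-attention layers
#' (`Q = Wq F, K = Wk F, V = Wv F`; `softmax(Q K' / sqrt(d)) V` added
#' residually, then layer-normalized) to a token matrix that concatenates
#' image-derived and sensor-derived tokens. Attention spans *both* modalities'
#' tokens jointly — this is what distinguishes it from per-modality
#' self-attention. Mean-pool the result for the classification head.
#'
#' @param tokens N x D numeric matrix of fused multimodal tokens.
#' @param layers attention stack from [attention_stack_init()].
#' @param norm apply residual layer normalization (default TRUE; turn off to
#'   inspect the raw attention algebra).
#' @param return_weights also return each layer's N x N attention matrix.
#' @return N x D matrix, with attribute `"weights"` when requested.
#' @export
embedding_attention <- function(tokens, layers, norm = TRUE,
                                return_weights = FALSE) {
  tokens <- as.matrix(tokens)
  if (!all(is.finite(tokens))) stop("embedding_attention: non-finite inputs")
  wts <- list()
  h <- tokens
  for (l in seq_along(layers)) {
    cache <- attention_layer_forward(h, layers[[l]], norm = norm)
    if (return_weights) wts[[l]] <- cache$A
    h <- cache$y
  }
  if (return_weights) attr(h, "weights") <- wts
  h
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize channel/spatial attention parameters
#'
#' @param C channels of the feature map.
#' @param reduction bottleneck reduction for the channel MLP.
#' @param kernel spatial convolution kernel size (odd; default 7).
#' @param seed integer seed (NULL = current RNG stream).
#' @return parameter list for [channel_attention()], [spatial_attention()]
#'   and [cbam()].
#' @export
cbam_init <- function(C, reduction = 4, kernel = 7, seed = NULL) {
  make <- function() {
    Cr <- max(1L, C %/% reduction)
    list(
      fc1_W = matrix(rnorm(C * Cr, sd = sqrt(2 / C)), Cr, C),
      fc1_b = rep(0, Cr),
      fc2_W = matrix(rnorm(Cr * C, sd = sqrt(2 / Cr)), C, Cr),
      fc2_b = rep(0, C),
      conv_W = array(rnorm(kernel * kernel * 2, sd = 0.1), c(kernel, kernel, 2)),
      conv_b = 0,
      kernel = as.integer(kernel)
    )
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Channel attention over a feature map
#'
#' Pools each channel spatially (`z_c` = mean over H x W), passes `z` through
#' a two-layer bottleneck MLP with sigmoid output, and rescales each channel
#' by its score `s_c`.
#'
#' @param fmap H x W x C numeric array.
#' @param params from [cbam_init()].
#' @return H x W x C array; attributes `"z"` and `"s"` carry the pooled
#'   activations and channel scores.
#' @export
channel_attention <- function(fmap, params = NULL) {
  C <- dim(fmap)[3]
  if (is.null(params)) params <- cbam_init(C, seed = 1)
  z <- apply(fmap, 3, mean)
  h <- relu(as.vector(params$fc1_W %*% z + params$fc1_b))
  s <- sigmoid(as.vector(params$fc2_W %*% h + params$fc2_b))
  out <- fmap * rep(s, each = prod(dim(fmap)[1:2]))
  attr(out, "z") <- z
  attr(out, "s") <- s
  out
}

# "same" 2D convolution of a H x W x 2 stack with a k x k x 2 kernel
conv2d_same2 <- function(x, W, b) {
  k <- dim(W)[1]
  p <- (k - 1L) %/% 2L
  H <- dim(x)[1]; Wd <- dim(x)[2]
  xp <- array(0, c(H + 2L * p, Wd + 2L * p, 2L))
  xp[(p + 1):(p + H), (p + 1):(p + Wd), ] <- x
  out <- matrix(b, H, Wd)
  for (c in 1:2) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        out <- out + W[i, j, c] * xp[i:(i + H - 1L), j:(j + Wd - 1L), c]
      }
    }
  }
  out
}

#' Spatial attention over a feature map
#'
#' Stacks the channel-wise mean and max maps, convolves them with a single
#' `kernel x kernel` filter (padding preserves H x W), squashes through a
#' sigmoid and multiplies the resulting H x W weight map into every channel.
#'
#' @inheritParams channel_attention
#' @return H x W x C array; attribute `"weights"` carries the spatial map.
#' @export
spatial_attention <- function(fmap, params = NULL) {
  C <- dim(fmap)[3]
  if (is.null(params)) params <- cbam_init(C, seed = 1)
  avg <- apply(fmap, c(1, 2), mean)
  mx <- apply(fmap, c(1, 2), max)
  stacked <- array(c(avg, mx), c(dim(fmap)[1], dim(fmap)[2], 2))
  wmap <- sigmoid(conv2d_same2(stacked, params$conv_W, params$conv_b))
  out <- fmap * as.vector(wmap)
  attr(out, "weights") <- wmap
  out
}

# --- CBAM with gradients (used by the training loop) ----------------------

channel_attention_fwd <- function(fmap, params) {
  z <- apply(fmap, 3, mean)
  pre1 <- as.vector(params$fc1_W %*% z + params$fc1_b)
  h <- relu(pre1)
  s <- sigmoid(as.vector(params$fc2_W %*% h + params$fc2_b))
  out <- fmap * rep(s, each = prod(dim(fmap)[1:2]))
  list(y = out, x = fmap, z = z, h = h, s = s)
}

channel_attention_bwd <- function(cache, params, dy) {
  P <- prod(dim(cache$x)[1:2])
  s_b <- rep(cache$s, each = P)
  dx <- dy * s_b
  ds <- apply(dy * cache$x, 3, sum)
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- tcrossprod(dpre2, cache$h)
  db2 <- dpre2
  dh <- as.vector(crossprod(params$fc2_W, dpre2))
  dpre1 <- dh * (cache$h > 0)
  dW1 <- tcrossprod(dpre1, cache$z)
  db1 <- dpre1
  dz <- as.vector(crossprod(params$fc1_W, dpre1))
  dx <- dx + rep(dz / P, each = P)
  list(dx = dx, grads = list(fc1_W = dW1, fc1_b = db1,
                             fc2_W = dW2, fc2_b = db2))
}

spatial_attention_fwd <- function(fmap, params) {
  C <- dim(fmap)[3]
  avg <- apply(fmap, c(1, 2), mean)
  mx <- apply(fmap, c(1, 2), max)
  amax <- apply(fmap, c(1, 2), which.max)
  stacked <- array(c(avg, mx), c(dim(fmap)[1], dim(fmap)[2], 2))
  m <- conv2d_same2(stacked, params$conv_W, params$conv_b)
  w <- sigmoid(m)
  out <- fmap * as.vector(w)
  list(y = out, x = fmap, stacked = stacked, w = w, amax = amax, C = C)
}

spatial_attention_bwd <- function(cache, params, dy) {
  H <- dim(cache$x)[1]; W <- dim(cache$x)[2]; C <- cache$C
  dx <- dy * as.vector(cache$w)
  dw <- apply(dy * cache$x, c(1, 2), sum)
  dm <- dw * cache$w * (1 - cache$w)
  k <- dim(params$conv_W)[1]
  p <- (k - 1L) %/% 2L
  dconv_W <- array(0, dim(params$conv_W))
  xp <- array(0, c(H + 2L * p, W + 2L * p, 2L))
  xp[(p + 1):(p + H), (p + 1):(p + W), ] <- cache$stacked
  for (c in 1:2) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        dconv_W[i, j, c] <- sum(dm * xp[i:(i + H - 1L), j:(j + W - 1L), c])
      }
    }
  }
  # scatter dm back through the "same" convolution to the stacked maps
  dstacked <- array(0, dim(cache$stacked))
  for (c in 1:2) {
    acc <- matrix(0, H + 2L * p, W + 2L * p)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        acc[i:(i + H - 1L), j:(j + W - 1L)] <- acc[i:(i + H - 1L), j:(j + W - 1L)] +
          params$conv_W[i, j, c] * dm
      }
    }
    dstacked[, , c] <- acc[(p + 1):(p + H), (p + 1):(p + W)]
  }
  dx <- dx + array(rep(dstacked[, , 1] / C, C), dim(cache$x))
  dmx <- dstacked[, , 2]
  for (pos in which(dmx != 0)) {
    ij <- arrayInd(pos, c(H, W))
    ch <- cache$amax[ij[1], ij[2]]
    dx[ij[1], ij[2], ch] <- dx[ij[1], ij[2], ch] + dmx[pos]
  }
  list(dx = dx, grads = list(conv_W = dconv_W, conv_b = sum(dm)))
}

cbam_fwd <- function(fmap, params) {
  ca <- channel_attention_fwd(fmap, params)
  sa <- spatial_attention_fwd(ca$y, params)
  list(y = sa$y, ca = ca, sa = sa)
}

cbam_bwd <- function(cache, params, dy) {
  sb <- spatial_attention_bwd(cache$sa, params, dy)
  cb <- channel_attention_bwd(cache$ca, params, sb$dx)
  list(dx = cb$dx, grads = c(cb$grads, sb$grads))
}

#' Convolutional block attention (CBAM)
#'
#' Channel attention followed by spatial attention, the standard ordering.
#'
#' @inheritParams channel_attention
#' @return H x W x C array.
#' @export
cbam <- function(fmap, params = NULL) {
  C <- dim(fmap)[3]
  if (is.null(params)) params <- cbam_init(C, seed = 1)
  out <- spatial_attention(channel_attention(fmap, params), params)
  attributes(out)[c("z", "s")] <- NULL
  out
}
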