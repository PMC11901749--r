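# Modality encoders. The image encoder is a three-block stride-2 CNN
# ("tinycnn", ~50k parameters) producing an Hv x Wv x Cv feature map; the
# sensor encoder bins each channel's hourly stream, standardizes it with
# frozen training-set statistics, embeds each (channel, bin) average as a
# token and runs a small transformer-style self-attention stack over the
# tokens. Both are trained from scratch; no pretrained weights are involved.

#' Initialize tinycnn parameters
#'
#' Three 3x3 stride-2 convolution blocks with ReLU, channels
#' `3 -> channels[1] -> channels[2] -> channels[3]`. A 64x64 input yields an
#' 8x8 feature map.
#'
#' @param channels per-block output channels; the last entry is `Cv`.
#' @param seed integer seed for He-style initialization (ignored when NULL,
#'   in which case the current RNG stream is used).
#' @param zero initialize all weights and biases to zero (diagnostics).
#' @return named list of kernels/biases usable by [encode_image()].
#' @export
tinycnn_init <- function(channels = c(8, 16, 32), seed = NULL, zero = FALSE) {
  make <- function() {
    cin <- c(3, channels[1], channels[2])
    p <- list()
    for (l in 1:3) {
      fan_in <- 9 * cin[l]
      sdv <- if (zero) 0 else sqrt(2 / fan_in)
      p[[paste0("K", l)]] <- matrix(
        if (zero) 0 else rnorm(fan_in * channels[l], sd = sdv),
        fan_in, channels[l])
      p[[paste0("b", l)]] <- rep(0, channels[l])
    }
    p$channels <- channels
    p
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

tinycnn_forward <- function(x, params) {
  caches <- vector("list", 3)
  h <- x
  for (l in 1:3) {
    cv <- conv3x3_forward(h, params[[paste0("K", l)]], params[[paste0("b", l)]])
    caches[[l]] <- cv
    h <- relu(cv$y)
    caches[[l]]$act <- h
  }
  list(map = h, caches = caches)
}

tinycnn_backward <- function(fwd, params, dmap) {
  grads <- list()
  dh <- dmap
  for (l in 3:1) {
    cv <- fwd$caches[[l]]
    dh <- dh * (cv$act > 0)
    bk <- conv3x3_backward(cv, params[[paste0("K", l)]], dh)
    grads[[paste0("K", l)]] <- bk$dK
    grads[[paste0("b", l)]] <- bk$db
    dh <- bk$dx
  }
  grads
}

#' Encode an image into a convolutional feature map
#'
#' @param img a `labeled_image` (or bare H x W x 3 array).
#' @param backbone `"tinycnn"` (default). `"resnet50"` is recognized but not
#'   runnable offline (pretrained weights are an external download) and raises
#'   an informative error.
#' @param params tinycnn parameters from [tinycnn_init()]; freshly initialized
#'   (seed 1) when omitted.
#' @return an `image_feature`: list with `map` (Hv x Wv x Cv) and `pooled`
#'   (spatial mean, length Cv).
#' @export
encode_image <- function(img, backbone = c("tinycnn", "resnet50"),
                         params = NULL) {
  backbone <- match.arg(backbone)
  if (backbone == "resnet50") {
    stop("backbone 'resnet50' requires pretrained weights that are not ",
         "available offline; use 'tinycnn'")
  }
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  if (dim(px)[1] < 8 || dim(px)[2] < 8) {
    stop("image too small for tinycnn (needs >= 8x8)")
  }
  if (is.null(params)) params <- tinycnn_init(seed = 1)
  x <- array(as.numeric(px) / 255 - 0.5, dim(px))
  fwd <- tinycnn_forward(x, params)
  m <- fwd$map
  structure(list(map = m,
                 pooled = apply(m, 3, mean)),
            class = "image_feature")
}

# --- sensor encoder --------------------------------------------------------

#' Initialize sensor-encoder parameters
#'
#' @param bins time bins per channel.
#' @param layers self-attention encoder layers.
#' @param dim token embedding dimension.
#' @param seed integer seed (NULL = current RNG stream).
#' @return named parameter list for [encode_sensors()].
#' @export
sensor_encoder_init <- function(bins = 6, layers = 2, dim = 32, seed = NULL) {
  make <- function() {
    p <- list(
      v_emb = rnorm(dim, sd = 0.5),
      E_ch = matrix(rnorm(4 * dim, sd = 0.2), 4, dim),
      E_bin = matrix(rnorm(bins * dim, sd = 0.2), bins, dim),
      layers = lapply(seq_len(layers), function(i) attention_layer_init(dim)),
      bins = bins, dim = dim
    )
    p
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

# Average each channel into `bins` equal time bins. Pads the tail by repeating
# the last reading when window_hours is not divisible by bins.
bin_sensor_window <- function(readings, bins) {
  T <- ncol(readings)
  per <- ceiling(T / bins)
  need <- per * bins
  if (need > T) {
    readings <- cbind(readings, readings[, rep(T, need - T), drop = FALSE])
  }
  out <- matrix(0, nrow(readings), bins, dimnames = list(rownames(readings), NULL))
  for (b in seq_len(bins)) {
    out[, b] <- rowMeans(readings[, ((b - 1) * per + 1):(b * per), drop = FALSE])
  }
  out
}

#' Compute sensor standardization statistics
#'
#' Per-channel, per-bin mean and standard deviation computed on a set of
#' (training) sensor windows. These statistics must be frozen and reused for
#' validation/test windows — never recomputed on them.
#'
#' @param windows list of `sensor_window` objects.
#' @param bins time bins per channel.
#' @return list with matrices `mean` and `sd` (4 x bins).
#' @export
sensor_stats <- function(windows, bins = 6) {
  binned <- lapply(windows, function(w) bin_sensor_window(w$readings, bins))
  arr <- simplify2array(binned)               # 4 x bins x n
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), sd)
  sdv[!is.finite(sdv) | sdv < 1e-6] <- 1
  list(mean = mu, sd = sdv, bins = bins)
}

sensor_tokens <- function(readings, params, stats) {
  binned <- bin_sensor_window(readings, params$bins)
  z <- (binned - stats$mean) / stats$sd        # 4 x bins standardized
  # token (c, b): z * v_emb + E_ch[c, ] + E_bin[b, ]
  n_ch <- nrow(z); nb <- ncol(z)
  zvec <- as.vector(z)                         # channel-major within bin
  tok <- outer(zvec, params$v_emb) +
    params$E_ch[rep(seq_len(n_ch), nb), , drop = FALSE] +
    params$E_bin[rep(seq_len(nb), each = n_ch), , drop = FALSE]
  list(tokens = tok, z = zvec, n_ch = n_ch, nb = nb)
}

sensor_encoder_forward <- function(readings, params, stats) {
  emb <- sensor_tokens(readings, params, stats)
  caches <- vector("list", length(params$layers))
  h <- emb$tokens
  for (l in seq_along(params$layers)) {
    caches[[l]] <- attention_layer_forward(h, params$layers[[l]])
    h <- caches[[l]]$y
  }
  list(tokens = h, emb = emb, caches = caches)
}

sensor_encoder_backward <- function(fwd, params, dtokens) {
  grads <- list(layers = vector("list", length(params$layers)))
  dh <- dtokens
  for (l in rev(seq_along(params$layers))) {
    bk <- attention_layer_backward(fwd$caches[[l]], params$layers[[l]], dh)
    grads$layers[[l]] <- bk$grads
    dh <- bk$dx
  }
  emb <- fwd$emb
  grads$v_emb <- colSums(dh * emb$z)
  grads$E_ch <- rowsum(dh, rep(seq_len(emb$n_ch), emb$nb))
  grads$E_bin <- rowsum(dh, rep(seq_len(emb$nb), each = emb$n_ch))
  # gradient wrt the standardized inputs (unused upstream; inputs are data)
  grads
}

#' Encode a sensor window into tokens and a pooled embedding
#'
#' Each channel is averaged within `bins` equal time bins, standardized by
#' frozen training-set statistics, embedded as one token per (channel, bin)
#' with channel and bin positional encodings, and passed through a stack of
#' self-attention encoder layers. `pooled` is the mean over tokens.
#'
#' @param w a `sensor_window`.
#' @param bins,layers,dim architecture hyperparameters (used when `params` is
#'   omitted).
#' @param params parameters from [sensor_encoder_init()].
#' @param stats standardization statistics from [sensor_stats()]; identity
#'   standardization (mean 0, sd 1 on raw bin averages) when omitted.
#' @return a `sensor_feature`: list with `tokens` (`N_t x dim`,
#'   `N_t = channels * bins`) and `pooled` (length `dim`).
#' @export
encode_sensors <- function(w, bins = 6, layers = 2, dim = 32, params = NULL,
                           stats = NULL) {
  if (ncol(w$readings) < 1) stop("empty sensor window")
  if (is.null(params)) {
    params <- sensor_encoder_init(bins = bins, layers = layers, dim = dim,
                                  seed = 1)
  }
  if (is.null(stats)) {
    stats <- list(mean = matrix(0, 4, params$bins),
                  sd = matrix(1, 4, params$bins), bins = params$bins)
  }
  fwd <- sensor_encoder_forward(w$readings, params, stats)
  structure(list(tokens = fwd$tokens, pooled = colMeans(fwd$tokens)),
            class = "sensor_feature")
}
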