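# Model assembly: encoders -> token-level weighted fusion -> attention ->
# fully connected head -> class logits + single-box regression. Forward and
# backward passes are written out explicitly; parameters live in one flat
# named list so the optimizer and the compression module can treat them
# uniformly.

sigmoid_scalar <- function(x) 1 / (1 + exp(-x))

model_dims <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  Hv <- H; Wv <- W
  for (i in 1:3) { Hv <- conv3x3_out_dim(Hv); Wv <- conv3x3_out_dim(Wv) }
  list(Hv = Hv, Wv = Wv, Cv = cfg$cnn_channels[3],
       Nv = Hv * Wv, Nt = 4L * cfg$sensor_bins, D = cfg$fusion_dim,
       Do = cfg$head_dim)
}

#' Initialize a full model parameter set
#'
#' @param cfg a [run_config()].
#' @return flat named list of parameter arrays (a `pf_params`).
#' @keywords internal
model_init <- function(cfg) {
  dims <- model_dims(cfg)
  D <- dims$D
  with_seed(derive_seed(cfg$seed, "init"), {
    p <- list()
    if (cfg$modality != "sensor") {
      cnn <- tinycnn_init(cfg$cnn_channels)
      p$K1 <- cnn$K1; p$b1 <- cnn$b1
      p$K2 <- cnn$K2; p$b2 <- cnn$b2
      p$K3 <- cnn$K3; p$b3 <- cnn$b3
      p$img_proj_W <- matrix(rnorm(dims$Cv * D, sd = sqrt(1 / dims$Cv)),
                             dims$Cv, D)
      p$img_proj_b <- rep(0, D)
      # layer-normalize projected image tokens so both modalities enter
      # fusion on the same scale (sensor tokens are normalized by their
      # encoder layers)
      p$img_ln_g <- rep(1, D)
      p$img_ln_b <- rep(0, D)
      if (cfg$attention_kind == "cbam") {
        cb <- cbam_init(dims$Cv)
        p$cbam_fc1_W <- cb$fc1_W; p$cbam_fc1_b <- cb$fc1_b
        p$cbam_fc2_W <- cb$fc2_W; p$cbam_fc2_b <- cb$fc2_b
        p$cbam_conv_W <- cb$conv_W; p$cbam_conv_b <- cb$conv_b
      }
    }
    if (cfg$modality != "image") {
      senc <- sensor_encoder_init(cfg$sensor_bins, cfg$sensor_layers, D)
      p$v_emb <- senc$v_emb; p$E_ch <- senc$E_ch; p$E_bin <- senc$E_bin
      for (l in seq_len(cfg$sensor_layers)) {
        for (nm in c("Wq", "Wk", "Wv", "ln_g", "ln_b")) {
          p[[sprintf("senc%d_%s", l, nm)]] <- senc$layers[[l]][[nm]]
        }
      }
    }
    if (cfg$modality == "both") p$alpha_raw <- cfg$fusion_alpha_init_raw
    if (cfg$attention_kind %in% c("embedding", "self")) {
      att <- attention_stack_init(cfg$attention_layers, D)
      for (l in seq_len(cfg$attention_layers)) {
        for (nm in c("Wq", "Wk", "Wv", "ln_g", "ln_b")) {
          p[[sprintf("att%d_%s", l, nm)]] <- att[[l]][[nm]]
        }
      }
    }
    # final layer normalization on the pooled fused feature keeps the head
    # well-conditioned regardless of token count
    p$lnf_g <- rep(1, D)
    p$lnf_b <- rep(0, D)
    p$Wf <- matrix(rnorm(dims$Do * D, sd = sqrt(2 / D)), dims$Do, D)
    p$bf <- rep(0, dims$Do)
    p$Wcls <- matrix(rnorm(5 * dims$Do, sd = sqrt(1 / dims$Do)), 5, dims$Do)
    p$bcls <- rep(0, 5)
    p$Wbox <- matrix(rnorm(4 * dims$Do, sd = sqrt(1 / dims$Do)), 4, dims$Do)
    p$bbox <- rep(0, 4)
    structure(p, class = "pf_params")
  })
}

layer_view <- function(params, prefix, D) {
  list(Wq = params[[paste0(prefix, "_Wq")]],
       Wk = params[[paste0(prefix, "_Wk")]],
       Wv = params[[paste0(prefix, "_Wv")]],
       ln_g = params[[paste0(prefix, "_ln_g")]],
       ln_b = params[[paste0(prefix, "_ln_b")]],
       scale = D)
}

layer_grads_store <- function(grads, prefix, g) {
  for (nm in names(g)) grads[[paste0(prefix, "_", nm)]] <- g[[nm]]
  grads
}

cbam_view <- function(params) {
  list(fc1_W = params$cbam_fc1_W, fc1_b = params$cbam_fc1_b,
       fc2_W = params$cbam_fc2_W, fc2_b = params$cbam_fc2_b,
       conv_W = params$cbam_conv_W, conv_b = params$cbam_conv_b,
       kernel = dim(params$cbam_conv_W)[1])
}

# Forward pass for one sample. `pixels` may be integer or double (augmented);
# `readings` is the raw sensor matrix. Returns logits, box prediction, pooled
# projections and every cache needed for the backward pass.
model_forward <- function(params, cfg, pixels, readings, stats) {
  dims <- model_dims(cfg)
  D <- dims$D
  cache <- list(dims = dims)
  tokens_v <- NULL; tokens_t <- NULL

  if (cfg$modality != "sensor") {
    x <- array(as.numeric(pixels) / 255 - 0.5, dim(pixels))
    cnn <- tinycnn_forward(x, params)
    cache$cnn <- cnn
    fmap <- cnn$map
    if (cfg$attention_kind == "cbam") {
      cache$cbam <- cbam_fwd(fmap, cbam_view(params))
      fmap <- cache$cbam$y
    }
    flat <- matrix(fmap, dims$Nv, dims$Cv)
    cache$flat <- flat
    proj <- dense_forward(flat, params$img_proj_W, params$img_proj_b)
    cache$proj <- proj
    cache$img_ln <- layernorm_forward(proj, params$img_ln_g, params$img_ln_b)
    tokens_v <- cache$img_ln$y
    cache$tokens_v <- tokens_v
  }
  if (cfg$modality != "image") {
    sp <- list(v_emb = params$v_emb, E_ch = params$E_ch, E_bin = params$E_bin,
               bins = cfg$sensor_bins, dim = D,
               layers = lapply(seq_len(cfg$sensor_layers), function(l) {
                 layer_view(params, sprintf("senc%d", l), D)
               }))
    cache$sp <- sp
    senc <- sensor_encoder_forward(readings, sp, stats)
    cache$senc <- senc
    tokens_t <- senc$tokens
  }

  if (cfg$modality == "both") {
    a <- sigmoid_scalar(params$alpha_raw)
    cache$alpha <- a
    tokens <- rbind(a * tokens_v, (1 - a) * tokens_t)
  } else if (cfg$modality == "image") {
    tokens <- tokens_v
  } else {
    tokens <- tokens_t
  }
  cache$tokens_in <- tokens
  cache$n_img_tokens <- if (is.null(tokens_v)) 0L else nrow(tokens_v)

  if (cfg$attention_kind %in% c("embedding", "self")) {
    att_rows <- if (cfg$attention_kind == "self" && cache$n_img_tokens > 0) {
      seq_len(cache$n_img_tokens)          # image tokens only
    } else {
      seq_len(nrow(tokens))                # joint over both modalities
    }
    cache$att_rows <- att_rows
    h <- tokens[att_rows, , drop = FALSE]
    cache$att <- vector("list", cfg$attention_layers)
    for (l in seq_len(cfg$attention_layers)) {
      lv <- layer_view(params, sprintf("att%d", l), D)
      cache$att[[l]] <- attention_layer_forward(h, lv)
      h <- cache$att[[l]]$y
    }
    tokens_out <- tokens
    tokens_out[att_rows, ] <- h
  } else {
    tokens_out <- tokens
  }
  cache$tokens_out <- tokens_out

  fm <- colMeans(tokens_out)
  cache$fm <- fm
  lnf <- layernorm_forward(matrix(fm, 1), params$lnf_g, params$lnf_b)
  cache$lnf <- lnf
  fm_n <- as.vector(lnf$y)
  cache$fm_n <- fm_n
  pre <- as.vector(params$Wf %*% fm_n + params$bf)
  fmp <- relu(pre)
  cache$pre <- pre; cache$fmp <- fmp
  logits <- as.vector(params$Wcls %*% fmp + params$bcls)
  boxp <- as.vector(params$Wbox %*% fmp + params$bbox)
  list(logits = logits, box = boxp,
       fv_pool = if (is.null(tokens_v)) NULL else colMeans(tokens_v),
       ft_pool = if (is.null(tokens_t)) NULL else colMeans(tokens_t),
       cache = cache)
}

# Backward pass for one sample given upstream gradients. dfv_pool/dft_pool
# carry the alignment-loss contribution to the pooled pre-fusion projections.
model_backward <- function(params, cfg, fwd, dlogits, dbox,
                           dfv_pool = NULL, dft_pool = NULL) {
  cache <- fwd$cache
  dims <- cache$dims
  D <- dims$D
  g <- list()

  g$Wcls <- tcrossprod(dlogits, cache$fmp)
  g$bcls <- dlogits
  g$Wbox <- tcrossprod(dbox, cache$fmp)
  g$bbox <- dbox
  dfmp <- as.vector(crossprod(params$Wcls, dlogits)) +
    as.vector(crossprod(params$Wbox, dbox))
  dpre <- dfmp * (cache$pre > 0)
  g$Wf <- tcrossprod(dpre, cache$fm_n)
  g$bf <- dpre
  dfm_n <- as.vector(crossprod(params$Wf, dpre))
  lnb <- layernorm_backward(cache$lnf, params$lnf_g, matrix(dfm_n, 1))
  g$lnf_g <- lnb$dgamma
  g$lnf_b <- lnb$dbeta
  dfm <- as.vector(lnb$dx)

  n_tok <- nrow(cache$tokens_out)
  dtokens <- matrix(rep(dfm / n_tok, each = n_tok), n_tok, D)

  if (cfg$attention_kind %in% c("embedding", "self")) {
    rows <- cache$att_rows
    dh <- dtokens[rows, , drop = FALSE]
    for (l in rev(seq_len(cfg$attention_layers))) {
      lv <- layer_view(params, sprintf("att%d", l), D)
      bk <- attention_layer_backward(cache$att[[l]], lv, dh)
      g <- layer_grads_store(g, sprintf("att%d", l), bk$grads)
      dh <- bk$dx
    }
    dtokens[rows, ] <- dh
  }

  ni <- cache$n_img_tokens
  if (cfg$modality == "both") {
    a <- cache$alpha
    dTv_s <- dtokens[seq_len(ni), , drop = FALSE]
    dTt_s <- dtokens[(ni + 1):n_tok, , drop = FALSE]
    tv <- cache$tokens_v
    tt <- cache$senc$tokens
    da <- sum(dTv_s * tv) - sum(dTt_s * tt)
    g$alpha_raw <- da * a * (1 - a)
    dtokens_v <- a * dTv_s
    dtokens_t <- (1 - a) * dTt_s
  } else if (cfg$modality == "image") {
    dtokens_v <- dtokens
    dtokens_t <- NULL
  } else {
    dtokens_v <- NULL
    dtokens_t <- dtokens
  }

  if (!is.null(dtokens_v)) {
    if (!is.null(dfv_pool)) {
      dtokens_v <- dtokens_v +
        matrix(rep(dfv_pool / ni, each = ni), ni, D)
    }
    lnb_img <- layernorm_backward(cache$img_ln, params$img_ln_g, dtokens_v)
    g$img_ln_g <- lnb_img$dgamma
    g$img_ln_b <- lnb_img$dbeta
    dtokens_v <- lnb_img$dx
    dn <- dense_backward(cache$flat, params$img_proj_W, dtokens_v)
    g$img_proj_W <- dn$dW
    g$img_proj_b <- dn$db
    dmap <- array(dn$dx, c(dims$Hv, dims$Wv, dims$Cv))
    if (cfg$attention_kind == "cbam") {
      cb <- cbam_bwd(cache$cbam, cbam_view(params), dmap)
      g$cbam_fc1_W <- cb$grads$fc1_W; g$cbam_fc1_b <- cb$grads$fc1_b
      g$cbam_fc2_W <- cb$grads$fc2_W; g$cbam_fc2_b <- cb$grads$fc2_b
      g$cbam_conv_W <- cb$grads$conv_W; g$cbam_conv_b <- cb$grads$conv_b
      dmap <- cb$dx
    }
    g <- c(g, tinycnn_backward(cache$cnn, params, dmap))
  }
  if (!is.null(dtokens_t)) {
    nt <- nrow(cache$senc$tokens)
    if (!is.null(dft_pool)) {
      dtokens_t <- dtokens_t +
        matrix(rep(dft_pool / nt, each = nt), nt, D)
    }
    sb <- sensor_encoder_backward(cache$senc, cache$sp, dtokens_t)
    g$v_emb <- sb$v_emb; g$E_ch <- sb$E_ch; g$E_bin <- sb$E_bin
    for (l in seq_len(cfg$sensor_layers)) {
      g <- layer_grads_store(g, sprintf("senc%d", l), sb$layers[[l]])
    }
  }
  g
}

smooth_l1 <- function(pred, target, beta = 1) {
  d <- pred - target
  ad <- abs(d)
  sum(ifelse(ad < beta, 0.5 * d^2 / beta, ad - 0.5 * beta))
}

smooth_l1_grad <- function(pred, target, beta = 1) {
  d <- pred - target
  pmin(pmax(d / beta, -1), 1)
}
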