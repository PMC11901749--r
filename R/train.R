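# Training/evaluation harness: run configuration, stratified splits and
# cross-validation folds, the Adam + cosine-annealing optimization loop with
# named RNG substreams, and the ablation grid runner.

#' Build a run configuration
#'
#' Defaults follow the optimization protocol the framework is built around:
#' Adam with initial learning rate 0.001 and cosine annealing, weight decay
#' 1e-4, batch size 32, stratified 70/15/15 holdout split. Epoch count (15)
#' and the architecture sizes are desk-scale choices.
#'
#' @param lr initial learning rate.
#' @param weight_decay decoupled L2 coefficient.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param schedule `"cosine"` or `"none"`.
#' @param split `"holdout_70_15_15"` or `"cv5"`.
#' @param seed master seed; all RNG substreams (data, augmentation, init,
#'   shuffle) derive from it.
#' @param modality `"both"`, `"image"`, or `"sensor"`. Unimodal runs disable
#'   the other encoder and the alignment loss.
#' @param attention_kind `"embedding"`, `"self"`, `"cbam"`, or `"none"`.
#' @param loss_kind `"embedding"`, `"ce"`, or `"focal"`.
#' @param augmentation subset of `c("cutmix", "mosaic", "gridmask")` applied
#'   to training images (empty by default).
#' @param lambda_align weight of the alignment term (embedding loss).
#' @param lambda_box weight of the smooth-L1 box-regression term.
#' @param focal_gamma,focal_alpha focal-loss parameters.
#' @param class_weights `"inverse_frequency"` (computed on the training
#'   split), `NULL`, or a positive length-5 vector.
#' @param image_size expected image size `c(H, W)`.
#' @param cnn_channels tinycnn block channels.
#' @param fusion_dim shared token/projection dimension D.
#' @param fusion_alpha_init initial modality weight alpha in (0, 1).
#' @param fusion_mode fusion mode (token-level weighted concatenation is the
#'   trained default; see [fuse()] for the vector-level variants).
#' @param head_dim output dimension of the post-fusion FC layer.
#' @param sensor_bins,sensor_layers sensor-encoder architecture.
#' @param attention_layers attention stack depth.
#' @param augment_prob probability a training sample is augmented per epoch.
#' @return validated `run_config` list.
#' @export
run_config <- function(lr = 0.001, weight_decay = 1e-4, batch_size = 32,
                       epochs = 15, schedule = c("cosine", "none"),
                       split = c("holdout_70_15_15", "cv5"), seed = 1,
                       modality = c("both", "image", "sensor"),
                       attention_kind = c("embedding", "self", "cbam", "none"),
                       loss_kind = c("embedding", "ce", "focal"),
                       augmentation = character(0),
                       lambda_align = 0.5, lambda_box = 1,
                       focal_gamma = 2, focal_alpha = 1,
                       class_weights = "inverse_frequency",
                       image_size = c(64, 64), cnn_channels = c(8, 16, 32),
                       fusion_dim = 32, fusion_alpha_init = 0.5,
                       fusion_mode = "weighted_concat",
                       head_dim = 32, sensor_bins = 6, sensor_layers = 2,
                       attention_layers = 2, augment_prob = 0.5) {
  schedule <- match.arg(schedule)
  split <- match.arg(split)
  modality <- match.arg(modality)
  attention_kind <- match.arg(attention_kind)
  loss_kind <- match.arg(loss_kind)
  if (!is.numeric(lr) || lr < 0) stop("lr must be a non-negative number")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  bad <- setdiff(augmentation, c("cutmix", "mosaic", "gridmask"))
  if (length(bad) > 0) stop("unknown augmentation: ", paste(bad, collapse = ", "))
  if (fusion_alpha_init <= 0 || fusion_alpha_init >= 1) {
    stop("fusion_alpha_init must be in (0, 1)")
  }
  structure(list(
    lr = lr, weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), schedule = schedule, split = split,
    seed = as.integer(seed), modality = modality,
    attention_kind = attention_kind, loss_kind = loss_kind,
    augmentation = augmentation, lambda_align = lambda_align,
    lambda_box = lambda_box, focal_gamma = focal_gamma,
    focal_alpha = focal_alpha, class_weights = class_weights,
    image_size = as.integer(image_size), cnn_channels = as.integer(cnn_channels),
    fusion_dim = as.integer(fusion_dim),
    fusion_alpha_init = fusion_alpha_init,
    fusion_alpha_init_raw = log(fusion_alpha_init / (1 - fusion_alpha_init)),
    fusion_mode = fusion_mode,
    head_dim = as.integer(head_dim), sensor_bins = as.integer(sensor_bins),
    sensor_layers = as.integer(sensor_layers),
    attention_layers = as.integer(attention_layers),
    augment_prob = augment_prob
  ), class = "run_config")
}

#' Stratified data splits
#'
#' `holdout_70_15_15` assigns each sample to train/val/test with per-class
#' proportions within one sample of 70/15/15; `cv5` assigns disjoint,
#' covering, class-stratified folds 1..5.
#'
#' @param dataset an `mm_dataset` or list of samples.
#' @param mode `"holdout_70_15_15"` or `"cv5"`.
#' @param seed integer seed.
#' @return character vector (`"train"/"val"/"test"`) or integer fold vector,
#'   one entry per sample.
#' @export
split_cv <- function(dataset, mode = c("holdout_70_15_15", "cv5"), seed = 1) {
  mode <- match.arg(mode)
  samples <- if (inherits(dataset, "mm_dataset")) dataset$samples else dataset
  cls <- vapply(samples, function(s) s$class_id, integer(1))
  n <- length(samples)
  with_seed(derive_seed(seed, "split"), {
    if (mode == "holdout_70_15_15") {
      out <- character(n)
      for (c in unique(cls)) {
        idx <- sample(which(cls == c))
        k <- length(idx)
        n_tr <- round(0.70 * k)
        n_va <- round(0.15 * k)
        out[idx[seq_len(n_tr)]] <- "train"
        out[idx[n_tr + seq_len(n_va)]] <- "val"
        if (n_tr + n_va < k) out[idx[(n_tr + n_va + 1):k]] <- "test"
      }
      out
    } else {
      out <- integer(n)
      for (c in unique(cls)) {
        idx <- sample(which(cls == c))
        out[idx] <- rep_len(1:5, length(idx))
      }
      out
    }
  })
}

normalized_box <- function(img) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  b <- img$boxes[[which.max(vapply(img$boxes, function(x) {
    (x[3] - x[1]) * (x[4] - x[2])
  }, numeric(1)))]]
  c(b[1] / W, b[2] / H, b[3] / W, b[4] / H)
}

# Apply one randomly chosen enabled augmentation op to a training sample.
# Returns list(pixels, label, box_norm). Sensor windows pass through
# unchanged; partners are drawn from the training pool.
augment_sample <- function(s, pool, ops, canvas) {
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  img <- s$image
  if (op == "gridmask") {
    out <- gridmask(img, "random", preserve_lesions = TRUE,
                    seed = sample.int(2^30, 1))
    return(list(pixels = out$pixels, label = one_hot5(img$class_id),
                box = normalized_box(out)))
  }
  if (op == "cutmix") {
    partner <- pool[[sample.int(length(pool), 1)]]$image
    # infeasible preserving placements fall back to identity mixes; that is
    # expected at this rate and not worth a warning per sample during training
    mx <- suppressWarnings(
      cutmix(img, partner, mode = "region", preserve_lesions = TRUE,
             seed = sample.int(2^30, 1)))
  } else {
    partners <- lapply(sample.int(length(pool), 3, replace = TRUE),
                       function(i) pool[[i]]$image)
    mx <- mosaic(c(list(img), partners), canvas = canvas, split = "random",
                 seed = sample.int(2^30, 1))
  }
  if (length(mx$boxes) == 0) {
    return(list(pixels = mx$pixels, label = mx$label,
                box = c(0.25, 0.25, 0.75, 0.75)))
  }
  fake <- list(pixels = mx$pixels, boxes = mx$boxes)
  list(pixels = mx$pixels, label = mx$label, box = normalized_box(fake))
}

#' Train a multimodal disease-detection model
#'
#' Assembles the configured model (encoders, fusion, attention, FC head,
#' class logits and a single-box regressor), then optimizes it with Adam
#' (cosine-annealed learning rate, weight decay) on the stratified training
#' split. The objective is the configured classification loss plus
#' `lambda_box` times a smooth-L1 box term, plus `lambda_align` times the
#' cosine alignment term when `loss_kind = "embedding"` and both modalities
#' are present. Sensor standardization statistics and inverse-frequency class
#' weights are computed on the training portion only and frozen.
#'
#' @param dataset an `mm_dataset` (or list of multimodal samples).
#' @param cfg a [run_config()].
#' @param verbose print per-epoch progress.
#' @return a `pf_model`: list with `params`, `cfg`, frozen `stats`,
#'   `class_weights`, per-epoch `log` (data.frame of loss components and
#'   validation accuracy), and the `split` assignment used.
#' @export
train_model <- function(dataset, cfg = run_config(), verbose = FALSE) {
  samples <- if (inherits(dataset, "mm_dataset")) dataset$samples else dataset
  split <- split_cv(samples, if (cfg$split == "cv5") "cv5" else
    "holdout_70_15_15", cfg$seed)
  if (cfg$split == "cv5") {
    # fold 1 plays validation; folds 2-5 train (single-fold convenience; the
    # full rotation is driven externally)
    split <- ifelse(split == 1L, "val", "train")
  }
  train_idx <- which(split == "train")
  val_idx <- which(split == "val")

  stats <- if (cfg$modality != "image") {
    sensor_stats(lapply(samples[train_idx], `[[`, "sensors"), cfg$sensor_bins)
  } else NULL
  train_labels <- t(vapply(samples[train_idx],
                           function(s) one_hot5(s$class_id), numeric(5)))
  cw <- if (identical(cfg$class_weights, "inverse_frequency")) {
    inverse_frequency_weights(train_labels)
  } else cfg$class_weights

  params <- model_init(cfg)
  opt <- adam_init(params)
  log_rows <- list()

  with_seed(derive_seed(cfg$seed, "trainloop"), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- if (cfg$schedule == "cosine") {
        cosine_lr(cfg$lr, epoch, cfg$epochs)
      } else cfg$lr
      order_idx <- sample(train_idx)
      ep_loss <- c(cls = 0, align = 0, box = 0, total = 0)
      n_batches <- 0L
      for (start in seq(1, length(order_idx), by = cfg$batch_size)) {
        bidx <- order_idx[start:min(start + cfg$batch_size - 1, length(order_idx))]
        batch <- samples[bidx]
        N <- length(batch)

        pixels <- vector("list", N); labels <- matrix(0, N, 5)
        boxes <- matrix(0, N, 4)
        for (i in seq_len(N)) {
          s <- batch[[i]]
          if (length(cfg$augmentation) > 0 && runif(1) < cfg$augment_prob) {
            aug <- augment_sample(s, samples[train_idx], cfg$augmentation,
                                  cfg$image_size)
            pixels[[i]] <- aug$pixels
            labels[i, ] <- aug$label
            boxes[i, ] <- aug$box
          } else {
            pixels[[i]] <- s$image$pixels
            labels[i, ] <- one_hot5(s$class_id)
            boxes[i, ] <- normalized_box(s$image)
          }
        }

        fwd <- vector("list", N)
        logits <- matrix(0, N, 5); boxp <- matrix(0, N, 4)
        for (i in seq_len(N)) {
          fwd[[i]] <- model_forward(params, cfg, pixels[[i]],
                                    batch[[i]]$sensors$readings, stats)
          logits[i, ] <- fwd[[i]]$logits
          boxp[i, ] <- fwd[[i]]$box
        }
        probs <- softmax_rows(logits)

        cls_loss <- switch(cfg$loss_kind,
          ce = cross_entropy(probs, labels, cw),
          embedding = cross_entropy(probs, labels, cw),
          focal = focal_loss(probs, labels, cfg$focal_gamma, cfg$focal_alpha))
        dlogits <- switch(cfg$loss_kind,
          focal = focal_grad_logits(logits, labels, cfg$focal_gamma,
                                    cfg$focal_alpha),
          cross_entropy_grad_logits(logits, labels, cw))

        box_loss <- sum(vapply(seq_len(N), function(i) {
          smooth_l1(boxp[i, ], boxes[i, ])
        }, numeric(1))) / N
        dboxp <- t(vapply(seq_len(N), function(i) {
          smooth_l1_grad(boxp[i, ], boxes[i, ]) * cfg$lambda_box / N
        }, numeric(4)))

        use_align <- cfg$loss_kind == "embedding" && cfg$modality == "both"
        align_loss_v <- 0
        dfv <- dft <- NULL
        if (use_align) {
          fvm <- t(vapply(fwd, function(f) f$fv_pool, numeric(cfg$fusion_dim)))
          ftm <- t(vapply(fwd, function(f) f$ft_pool, numeric(cfg$fusion_dim)))
          align_loss_v <- alignment_loss(fvm, ftm)
          ag <- alignment_grad(fvm, ftm)
          dfv <- ag$dfv * cfg$lambda_align
          dft <- ag$dft * cfg$lambda_align
        }

        total <- cls_loss + cfg$lambda_box * box_loss +
          cfg$lambda_align * align_loss_v * as.numeric(use_align)
        if (!is.finite(total)) {
          stop("NaN/Inf loss at epoch ", epoch, ", batch starting at ", start,
               "; sample ids: ",
               paste(vapply(batch, function(s) s$image$image_id, character(1)),
                     collapse = ", "))
        }

        grads <- NULL
        for (i in seq_len(N)) {
          gi <- model_backward(params, cfg, fwd[[i]], dlogits[i, ], dboxp[i, ],
                               if (use_align) dfv[i, ] else NULL,
                               if (use_align) dft[i, ] else NULL)
          grads <- grads_add(grads, gi)
        }
        st <- adam_step(params, grads, opt, lr, cfg$weight_decay,
                        skip_decay = c("bcls", "bbox", "bf", "alpha_raw"))
        params <- st$params
        opt <- st$state

        ep_loss <- ep_loss + c(cls_loss, align_loss_v, box_loss, total)
        n_batches <- n_batches + 1L
      }
      ep_loss <- ep_loss / n_batches

      val_acc <- NA_real_
      if (length(val_idx) > 0) {
        preds <- vapply(samples[val_idx], function(s) {
          f <- model_forward(params, cfg, s$image$pixels,
                             s$sensors$readings, stats)
          which.max(f$logits) - 1L
        }, integer(1))
        truth <- vapply(samples[val_idx], function(s) s$class_id, integer(1))
        val_acc <- mean(preds == truth)
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, loss_cls = ep_loss[1], loss_align = ep_loss[2],
        loss_box = ep_loss[3], loss_total = ep_loss[4], val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %2d  lr %.5f  loss %.4f  val_acc %s",
                        epoch, lr, ep_loss[4],
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
    }
  })

  structure(list(params = params, cfg = cfg, stats = stats,
                 class_weights = cw,
                 log = do.call(rbind, log_rows), split = split),
            class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat("<pf_model> modality=", x$cfg$modality, " attention=",
      x$cfg$attention_kind, " loss=", x$cfg$loss_kind, " | ",
      count_params(x$params), " parameters, ", nrow(x$log), " epochs\n",
      sep = "")
  invisible(x)
}

#' Evaluate a trained model on a set of samples
#'
#' Runs inference, builds the 5x5 confusion matrix and classification
#' metrics, converts each box prediction to a [detection()] (score = max
#' class probability), and computes mAP at `iou_thresh` against the lesion
#' boxes.
#'
#' @param model a `pf_model`.
#' @param samples list of multimodal samples (e.g. a test split).
#' @param iou_thresh IoU threshold for mAP (default 0.75).
#' @return an `eval_report`: list with `per_class`, `macro` (precision,
#'   recall, accuracy, map75), `confusion`, `detections`.
#' @export
evaluate_model <- function(model, samples, iou_thresh = 0.75) {
  cfg <- model$cfg
  n <- length(samples)
  confusion <- matrix(0L, 5, 5)
  dets <- vector("list", n)
  gts <- list()
  for (i in seq_len(n)) {
    s <- samples[[i]]
    f <- model_forward(model$params, cfg, s$image$pixels,
                       s$sensors$readings, model$stats)
    p <- as.vector(softmax_rows(matrix(f$logits, 1)))
    pred <- which.max(p) - 1L
    confusion[s$class_id + 1L, pred + 1L] <-
      confusion[s$class_id + 1L, pred + 1L] + 1L
    H <- dim(s$image$pixels)[1]; W <- dim(s$image$pixels)[2]
    bx <- f$box * c(W, H, W, H)
    bx[3] <- max(bx[3], bx[1] + 1e-3)
    bx[4] <- max(bx[4], bx[2] + 1e-3)
    dets[[i]] <- detection(s$image$image_id, pred, bx,
                           max(min(max(p), 1), 0))
    for (b in s$image$boxes) {
      gts[[length(gts) + 1]] <- list(image_id = s$image$image_id,
                                     class_id = s$class_id, box = b)
    }
  }
  cm <- classification_metrics(confusion)
  mp <- map_at(dets, gts, iou_thresh)
  structure(list(
    per_class = cbind(cm$per_class, ap = unname(mp$per_class)),
    macro = c(cm$macro, map75 = mp$map),
    confusion = confusion, detections = dets
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(round(x$macro, 4))
  invisible(x)
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per grid cell per seed. Axes map onto
#' [run_config()] fields `modality`, `attention_kind`, `loss_kind` and
#' `augmentation` (the latter given as a list of character vectors). Cell
#' failures are recorded and do not stop the harness.
#'
#' @param grid named list of axes, e.g.
#'   `list(modality = c("image", "sensor", "both"))`.
#' @param cfg base [run_config()] shared by every cell.
#' @param seeds integer vector of seeds.
#' @param dataset an `mm_dataset`; evaluation uses each run's test split.
#' @param verbose print one line per completed cell.
#' @return data.frame with one row per cell x seed (metrics columns
#'   `precision`, `recall`, `accuracy`, `map75`, plus `error` for failed
#'   cells); a `summary` attribute aggregates mean and sd per cell.
#' @export
run_ablation <- function(grid, cfg, seeds, dataset, verbose = FALSE) {
  axes <- names(grid)
  allowed <- c("modality", "attention", "loss", "augmentation")
  if (!all(axes %in% allowed)) {
    stop("grid axes must be among: ", paste(allowed, collapse = ", "))
  }
  cells <- expand.grid(c(lapply(grid, seq_along), list(seed = seeds)),
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    cell_cfg <- cfg
    desc <- list()
    for (ax in axes) {
      v <- grid[[ax]][[cells[r, ax]]]
      desc[[ax]] <- paste(v, collapse = "+")
      if (ax == "modality") cell_cfg$modality <- v
      if (ax == "attention") cell_cfg$attention_kind <- v
      if (ax == "loss") cell_cfg$loss_kind <- v
      if (ax == "augmentation") cell_cfg$augmentation <- v
    }
    cell_cfg$seed <- cells$seed[r]
    res <- tryCatch({
      model <- train_model(dataset, cell_cfg)
      samples <- if (inherits(dataset, "mm_dataset")) dataset$samples else dataset
      rep <- evaluate_model(model, samples[model$split == "test"])
      data.frame(as.list(rep$macro))
    }, error = function(e) {
      data.frame(precision = NA, recall = NA, accuracy = NA, map75 = NA,
                 error = conditionMessage(e))
    })
    if (is.null(res$error)) res$error <- NA_character_
    row <- cbind(as.data.frame(desc, stringsAsFactors = FALSE),
                 seed = cells$seed[r], res)
    rows[[r]] <- row
    if (verbose) {
      message(paste(unlist(desc), collapse = " | "), " seed ", cells$seed[r],
              "  acc ", round(row$accuracy, 3))
    }
  }
  out <- do.call(rbind, rows)
  cell_key <- apply(out[, axes, drop = FALSE], 1, paste, collapse = " | ")
  parts <- split(out, cell_key)
  agg <- do.call(rbind, lapply(names(parts), function(k) {
    d <- parts[[k]]
    data.frame(cell = k, mean_accuracy = mean(d$accuracy),
               sd_accuracy = sd(d$accuracy), mean_map75 = mean(d$map75),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- agg
  out
}
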