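# Training-harness contracts on deliberately tiny configurations; the full
# desk-scale runs live in test-acceptance.R.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(modality = "sensor", loss_kind = "ce", epochs = 2,
         sensor_layers = 1, attention_layers = 1, fusion_dim = 8,
         head_dim = 8, batch_size = 8),
    list(...))
  do.call(run_config, args)
}

test_that("cosine annealing closed form (half-way epoch gives lr0/2)", {
  E <- 10; lr0 <- 0.02
  # epoch at fraction 1/2 of the schedule: 0.5 * (1 + cos(pi/2)) = 0.5
  expect_equal(cosine_lr(lr0, E / 2 + 1, E), 0.5 * lr0)
  expect_equal(cosine_lr(lr0, 1, E), lr0)
  expect_lt(cosine_lr(lr0, E, E), 0.05 * lr0)
})

test_that("holdout split is stratified 70/15/15 within one sample per class", {
  ds <- generate_dataset(20, seed = 2)
  sp <- split_cv(ds, "holdout_70_15_15", seed = 4)
  cls <- vapply(ds$samples, `[[`, integer(1), "class_id")
  for (c in 0:4) {
    tab <- table(factor(sp[cls == c], levels = c("train", "val", "test")))
    expect_lte(abs(tab[["train"]] - 14), 1)
    expect_lte(abs(tab[["val"]] - 3), 1)
    expect_lte(abs(tab[["test"]] - 3), 1)
  }
  expect_equal(length(sp), 100)
  expect_identical(split_cv(ds, "holdout_70_15_15", seed = 4), sp)
})

test_that("cv5 folds are disjoint, covering, and class-balanced", {
  ds <- generate_dataset(11, seed = 3)
  folds <- split_cv(ds, "cv5", seed = 9)
  expect_setequal(unique(folds), 1:5)
  expect_equal(length(folds), 55)
  cls <- vapply(ds$samples, `[[`, integer(1), "class_id")
  for (c in 0:4) {
    per_fold <- table(factor(folds[cls == c], levels = 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("lr = 0 leaves parameters unchanged after an epoch", {
  ds <- tiny_dataset()
  cfg <- small_cfg(lr = 0, weight_decay = 0, epochs = 1)
  m <- train_model(ds, cfg)
  init <- phytofuse:::model_init(cfg)
  deltas <- vapply(names(init), function(nm) {
    if (!is.numeric(init[[nm]])) return(0)
    max(abs(m$params[[nm]] - init[[nm]]))
  }, numeric(1))
  expect_lt(max(deltas), 1e-12)
})

test_that("one-epoch smoke run completes quickly with a one-row log", {
  ds <- tiny_dataset()
  t0 <- Sys.time()
  m <- train_model(ds, small_cfg(epochs = 1))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_equal(nrow(m$log), 1)
  expect_true(all(c("loss_cls", "loss_box", "loss_total", "val_acc")
                  %in% names(m$log)))
})

test_that("training and evaluation are deterministic given the seed", {
  ds <- tiny_dataset()
  m1 <- train_model(ds, small_cfg(seed = 11))
  m2 <- train_model(ds, small_cfg(seed = 11))
  expect_equal(m1$params, m2$params)
  test <- ds$samples[m1$split == "test"]
  expect_equal(evaluate_model(m1, test)$macro, evaluate_model(m2, test)$macro)
  m3 <- train_model(ds, small_cfg(seed = 12))
  expect_false(isTRUE(all.equal(m1$params, m3$params)))
})

test_that("standardization stats and class weights use the training split only", {
  ds <- generate_dataset(10, confusability = 0.3, seed = 6)
  cfg <- small_cfg(epochs = 1)
  m <- train_model(ds, cfg)
  train_samples <- ds$samples[m$split == "train"]
  recomputed <- sensor_stats(lapply(train_samples, `[[`, "sensors"),
                             cfg$sensor_bins)
  expect_equal(m$stats$mean, recomputed$mean)
  expect_equal(m$stats$sd, recomputed$sd)
  # recomputing on train + validation gives different statistics, proving the
  # frozen ones could not have used validation data
  tv <- ds$samples[m$split != "test"]
  leaky <- sensor_stats(lapply(tv, `[[`, "sensors"), cfg$sensor_bins)
  expect_false(isTRUE(all.equal(m$stats$mean, leaky$mean)))
  labels <- t(vapply(train_samples, function(s) phytofuse:::one_hot5(s$class_id),
                     numeric(5)))
  expect_equal(m$class_weights, inverse_frequency_weights(labels))
})

test_that("evaluate_model: constant and oracle-like predictors", {
  ds <- tiny_dataset()
  cfg <- small_cfg(epochs = 1)
  m <- train_model(ds, cfg)
  # force a constant class-0 predictor through the head bias
  m0 <- m
  m0$params$Wcls[] <- 0
  m0$params$bcls <- c(100, 0, 0, 0, 0)
  rep0 <- suppressMessages(evaluate_model(m0, ds$samples))
  expect_equal(unname(rep0$macro["accuracy"]), 0.2)
  expect_true(all(rep0$confusion[, 1] == 6))
  expect_equal(sum(rep0$confusion), 30)
})

test_that("training objective decreases on the default synthetic run", {
  ds <- generate_dataset(10, confusability = 0.2, seed = 8)
  m <- train_model(ds, small_cfg(epochs = 8, batch_size = 16))
  loss <- m$log$loss_total
  q <- length(loss) %/% 4
  expect_lt(median(tail(loss, q)), median(head(loss, q)))
})

test_that("augmented training accepts soft labels end to end", {
  ds <- tiny_dataset()
  cfg <- small_cfg(epochs = 1, modality = "both",
                   augmentation = c("cutmix", "gridmask"), augment_prob = 1)
  m <- train_model(ds, cfg)
  expect_true(all(is.finite(m$log$loss_total)))
})

test_that("ablation harness cardinality, determinism and failure capture", {
  ds <- tiny_dataset()
  cfg <- small_cfg(epochs = 1)
  res <- run_ablation(list(modality = c("image", "sensor", "both")), cfg,
                      seeds = c(1, 2), ds)
  expect_equal(nrow(res), 6)
  expect_true(all(c("modality", "seed", "accuracy") %in% names(res)))
  expect_equal(nrow(attr(res, "summary")), 3)

  res2 <- run_ablation(list(modality = "sensor"), cfg, seeds = 1, ds)
  res3 <- run_ablation(list(modality = "sensor"), cfg, seeds = 1, ds)
  expect_equal(res2$accuracy, res3$accuracy)

  expect_error(run_ablation(list(bogus = 1), cfg, 1, ds), "axes")
})
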