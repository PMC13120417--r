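test_that("metric formulas match hand-computed values", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2)   # rows = truth, cols = prediction
  m <- compute_metrics(cm)
  expect_equal(m$oa, 0.85)
  expect_equal(m$recall, c(0.90, 0.80))
  expect_equal(m$aa, 0.85)
  expect_equal(m$kappa, 0.70)
  expect_equal(m$precision[1], 45 / 55)
  expect_equal(round(m$precision[1], 4), 0.8182)

  dm <- compute_metrics(diag(c(5, 8, 2)))
  expect_equal(dm$oa, 1); expect_equal(dm$aa, 1); expect_equal(dm$kappa, 1)
  expect_true(all(dm$f1 == 1))

  # prediction independent of truth: chance-level agreement
  chance <- matrix(rep(c(30, 20), each = 2), 2, 2, byrow = TRUE)
  expect_equal(compute_metrics(t(chance))$kappa, 0)

  expect_error(compute_metrics(matrix(1, 2, 3)),
               class = "sstfpo_invalid_argument")
  expect_error(compute_metrics(matrix(-1, 2, 2)),
               class = "sstfpo_invalid_argument")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(20)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, lambda = 8), K, K)
    if (sum(cm) == 0) next
    m <- compute_metrics(cm)
    # OA is the class-frequency-weighted mean of recalls
    wts <- rowSums(cm) / sum(cm)
    expect_equal(m$oa, sum(wts * m$recall), tolerance = 1e-12)
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (pe > 0) expect_lte(m$kappa, m$oa + 1e-12)
    expect_true(all(m$recall >= 0 & m$recall <= 1))
    expect_true(all(m$precision >= 0 & m$precision <= 1))
    expect_lte(m$kappa, 1)
  }
  # confusion_matrix agrees with table() on random label vectors
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  cm <- confusion_matrix(truth, pred, 4)
  expect_equal(cm, unclass(table(truth, pred)), ignore_attr = TRUE)
})

test_that("training learns a separable two-material scene", {
  tc <- two_class_cube()
  ds <- patch_dataset(tc$cube, tc$mask, patch_size = 3)
  sp <- make_splits(ds, 60, 20, seed = 1)
  cfg <- tiny_cfg(n_classes = 2L)
  fit <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg,
                     train_config(epochs = 8, patience = 8, seed = 1))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_gt(fit$best_val_oa, 0.9)
  m <- evaluate_model(ds_subset(ds, sp$test), fit$model)
  expect_gt(m$oa, 0.9)
})

test_that("training is bitwise reproducible under a fixed seed", {
  tc <- two_class_cube()
  ds <- patch_dataset(tc$cube, tc$mask, patch_size = 3)
  sp <- make_splits(ds, 20, 10, seed = 2)
  cfg <- tiny_cfg(n_classes = 2L)
  tcfg <- train_config(epochs = 2, patience = 2, seed = 7)
  f1 <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg, tcfg)
  f2 <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg, tcfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
  f3 <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg,
                    train_config(epochs = 2, patience = 2, seed = 8))
  expect_false(identical(f1$model$params, f3$model$params))
})

test_that("zero patience stops at the first non-improving epoch", {
  tc <- two_class_cube()
  ds <- patch_dataset(tc$cube, tc$mask, patch_size = 3)
  sp <- make_splits(ds, 20, 10, seed = 2)
  cfg <- tiny_cfg(n_classes = 2L)
  # zero learning rate: validation accuracy can never improve after epoch 1
  fit <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg,
                     train_config(epochs = 6, patience = 0, lr = 0, seed = 1))
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
  expect_error(train_model(ds_subset(ds, integer()), ds_subset(ds, sp$val),
                           cfg, train_config(seed = 1)),
               class = "sstfpo_configuration_error")
})

test_that("prediction maps cover exactly the target pixels", {
  tc <- two_class_cube()
  cfg <- tiny_cfg(n_classes = 2L)
  model <- init_params(cfg, seed = 3)

  single <- matrix(0L, 20, 20); single[7, 5] <- 2L
  map1 <- predict_map(tc$cube, label_mask(single, 2L), model)
  expect_equal(sum(map1$values > 0), 1L)
  expect_gt(map1$values[7, 5], 0L)

  # two-path consistency: map class totals equal batched predictions
  ds <- patch_dataset(tc$cube, tc$mask, patch_size = 3)
  map <- predict_map(tc$cube, tc$mask, model)
  pred <- predict_classes(ds, model)
  expect_equal(tabulate(map$values[map$values > 0], 2),
               tabulate(pred, 2))

  # a well-trained model reproduces the mask at its training pixels
  sp <- make_splits(ds, 60, 20, seed = 1)
  fit <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg,
                     train_config(epochs = 15, patience = 15, seed = 1))
  mapt <- predict_map(tc$cube, tc$mask, fit$model)
  tr <- ds$targets[sp$train, ]
  agree <- mean(mapt$values[cbind(tr$row, tr$col)] == tr$label)
  expect_gt(agree, 0.95)
})

test_that("multi-seed evaluation reports per-run metrics and sample spread", {
  tc <- two_class_cube()
  ds <- patch_dataset(tc$cube, tc$mask, patch_size = 3)
  sp <- make_splits(ds, 20, 10, seed = 2)
  cfg <- tiny_cfg(n_classes = 2L)
  res <- multi_seed_evaluate(ds_subset(ds, sp$train), ds_subset(ds, sp$val),
                             ds_subset(ds, sp$test), cfg,
                             train_config(epochs = 2, patience = 2, seed = 1),
                             n_runs = 2, base_seed = 5)
  expect_equal(nrow(res$runs), 2L)
  expect_equal(res$runs$seed, c(5L, 6L))
  expect_equal(res$summary$mean[res$summary$metric == "oa"],
               mean(res$runs$oa))
  expect_equal(res$summary$sd[res$summary$metric == "oa"],
               sd(res$runs$oa))
  expect_error(multi_seed_evaluate(ds, ds, ds, cfg, n_runs = 1),
               class = "sstfpo_invalid_argument")
})

test_that("relative position encoding does not trail the absolute table", {
  # directional check at reduced scale: same splits and seeds, two encodings
  spec <- scene_spec(height = 96L, width = 96L, n_bands = 25L,
                     n_regions_per_class = 6L, region_size = 5L,
                     fillet = c(9L, 9L, 88L, 88L), margin = 0L,
                     noise_sd = 1.5, seed = 21L)
  sc <- render_small(spec)
  cube <- calibrate_reflectance(sc$raw, sc$white, sc$dark)$cube
  ds <- patch_dataset(cube, sc$mask, patch_size = 5)
  sp <- make_splits(ds, 80, 40, seed = 3)
  base <- list(patch_size = 5L, n_bands = 25L, d_emb = 32L, n_heads = 4L,
               d_bottleneck = 8L, n_layers = 2L, ffn_hidden = 64L,
               classifier_hidden = 32L, n_classes = 13L)
  oa <- sapply(c("rope2d_mixed", "ape"), function(pe) {
    cfg <- do.call(model_config, c(base, list(pos_encoding = pe)))
    mean(sapply(1:2, function(s) {
      fit <- train_model(ds_subset(ds, sp$train), ds_subset(ds, sp$val), cfg,
                         train_config(epochs = 12, patience = 3, seed = s))
      evaluate_model(ds_subset(ds, sp$test), fit$model)$oa
    }))
  })
  expect_gte(oa[["rope2d_mixed"]], oa[["ape"]] - 0.005)
})
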