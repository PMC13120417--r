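#' Training configuration
#'
#' The study-scale protocol trains for up to 200 epochs with early-stopping
#' patience 100, initial learning rate 0.001 and batch size 80; validation
#' overall accuracy is the monitored quantity and the best-validation
#' checkpoint is restored at the end. Optimisation is Adam on the mean
#' cross-entropy.
#'
#' @param epochs maximum epochs.
#' @param patience epochs without validation improvement tolerated before
#'   stopping (`patience = 0` stops at the first non-improving epoch).
#' @param lr initial (and only) learning rate.
#' @param batch_size minibatch size.
#' @param seed seed controlling initialisation, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, patience = 100L, lr = 0.001,
                         batch_size = 80L, seed = 1L) {
  if (patience > epochs) stop_config("patience must be <= epochs")
  if (batch_size < 1L) stop_config("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Subset a patch dataset by item indices
#'
#' @param ds a [patch_dataset()].
#' @param items integer item indices (e.g. one field of [make_splits()]).
#' @return A `patch_dataset` restricted to the given items (the underlying
#'   pixel matrix is shared, not copied).
#' @export
ds_subset <- function(ds, items) {
  ds$index <- ds$index[items, , drop = FALSE]
  ds$targets <- ds$targets[items, , drop = FALSE]
  ds$labels <- ds$labels[items]
  ds
}

#' Train the model
#'
#' Minimises mean cross-entropy with Adam, monitors validation overall
#' accuracy each epoch, keeps the best-validation checkpoint and stops
#' early after `patience` epochs without improvement. Fully seeded: the
#' same datasets, configs and seed reproduce the same parameters.
#'
#' @param train_ds,val_ds [patch_dataset()]s (use [ds_subset()] to carve
#'   splits out of one dataset).
#' @param cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return A list: `model` (params/state/cfg at the best validation epoch),
#'   `history` (data.frame epoch/train_loss/val_oa), `best_epoch`,
#'   `best_val_oa`.
#' @export
train_model <- function(train_ds, val_ds, cfg, tcfg = train_config(),
                        verbose = FALSE) {
  if (length(train_ds) == 0L || length(val_ds) == 0L)
    stop_config("train and validation datasets must be non-empty")
  if (train_ds$n_bands != cfg$n_bands)
    stop_config("dataset band count != model config")
  set.seed(tcfg$seed)
  model <- init_params(cfg, seed = tcfg$seed)
  opt <- adam_init(model$params)
  n <- length(train_ds)
  best <- list(oa = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  bad <- 0L
  hist_loss <- numeric(0); hist_oa <- numeric(0)

  for (epoch in seq_len(tcfg$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      items <- perm[start:min(start + tcfg$batch_size - 1L, n)]
      Pmat <- gather_batch(train_ds, items)
      fw <- sst_forward_batch(Pmat, model, mode = "train", keep_cache = TRUE)
      model$state <- fw$state
      cl <- ce_loss(fw$logits, train_ds$labels[items])
      losses <- c(losses, cl$loss)
      grads <- sst_backward_batch(cl$dlogits, fw$cache, model)
      up <- adam_step(model$params, grads, opt, lr = tcfg$lr)
      model$params <- up$params; opt <- up$opt
    }
    val_pred <- predict_classes(val_ds, model)
    val_oa <- mean(val_pred == val_ds$labels)
    hist_loss <- c(hist_loss, mean(losses)); hist_oa <- c(hist_oa, val_oa)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val OA %.4f", epoch,
                      mean(losses), val_oa))
    if (val_oa > best$oa) {
      best <- list(oa = val_oa, params = model$params, state = model$state,
                   epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > tcfg$patience) break
    }
  }
  model$params <- best$params; model$state <- best$state
  list(model = model,
       history = data.frame(epoch = seq_along(hist_loss),
                            train_loss = hist_loss, val_oa = hist_oa),
       best_epoch = best$epoch, best_val_oa = best$oa)
}

#' Predict class labels for a dataset
#'
#' Batched eval-mode forward passes; prediction is the argmax logit with
#' ties broken toward the lowest class index.
#'
#' @param ds a [patch_dataset()].
#' @param model a model (from [train_model()]'s `$model` or [init_params()]).
#' @param batch_size inference batch size.
#' @return Integer vector of predicted labels in `1..n_classes`.
#' @export
predict_classes <- function(ds, model, batch_size = 512L) {
  n <- length(ds)
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    items <- start:min(start + batch_size - 1L, n)
    Pmat <- gather_batch(ds, items)
    fw <- sst_forward_batch(Pmat, model, mode = "eval")
    out[items] <- max.col(fw$logits, ties.method = "first")
  }
  out
}

#' Evaluate a model on a dataset
#'
#' @inheritParams predict_classes
#' @return An `sst_metrics` object (see [compute_metrics()]).
#' @export
evaluate_model <- function(ds, model, batch_size = 512L) {
  pred <- predict_classes(ds, model, batch_size)
  compute_metrics(confusion_matrix(ds$labels, pred, ds$n_classes))
}

#' Train and evaluate across multiple seeds
#'
#' Repeats the train/evaluate cycle with `n_runs` predefined seeds
#' (`base_seed + 0 .. n_runs-1`; the study protocol uses 10 runs) and
#' reports the sample mean and standard deviation of overall accuracy,
#' average accuracy and kappa.
#'
#' @param train_ds,val_ds,test_ds datasets.
#' @param cfg a [model_config()].
#' @param tcfg a [train_config()]; its seed field is replaced per run.
#' @param n_runs number of runs (>= 2).
#' @param base_seed first seed.
#' @return A list with `runs` (data.frame of per-run metrics) and `summary`
#'   (data.frame metric/mean/sd).
#' @export
multi_seed_evaluate <- function(train_ds, val_ds, test_ds, cfg,
                                tcfg = train_config(), n_runs = 10L,
                                base_seed = 1L) {
  if (n_runs < 2L) stop_invalid("n_runs must be >= 2")
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    tcfg$seed <- as.integer(base_seed + i - 1L)
    fit <- train_model(train_ds, val_ds, cfg, tcfg)
    m <- evaluate_model(test_ds, fit$model)
    rows[[i]] <- data.frame(seed = tcfg$seed, oa = m$oa, aa = m$aa,
                            kappa = m$kappa)
  }
  runs <- do.call(rbind, rows)
  summarise <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sm <- rbind(oa = summarise(runs$oa), aa = summarise(runs$aa),
              kappa = summarise(runs$kappa))
  list(runs = runs,
       summary = data.frame(metric = rownames(sm), mean = sm[, "mean"],
                            sd = sm[, "sd"], row.names = NULL))
}
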