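#' Training configuration
#'
#' Mirrors the experimental protocol: Adam, cross-entropy loss, batch size
#' 128, 10-fold cross-validation, learning rate 1e-3 for DEAP-style runs
#' (1e-4 recommended for SEED-style runs).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (128).
#' @param max_epochs Epoch budget.
#' @param n_folds Cross-validation folds (>= 2).
#' @param seed Master seed controlling fold assignment, parameter
#'   initialisation, shuffling and dropout.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping, or `NULL` to train the full budget on all training data.
#' @param validation_fraction Fraction of the training fold carved out for
#'   early stopping (only used when `early_stop_patience` is set).
#' @param stratified Stratify folds by class (default) or split contiguously.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 128,
                         max_epochs = 100, n_folds = 10, seed = 1L,
                         early_stop_patience = NULL,
                         validation_fraction = 0.1,
                         stratified = TRUE) {
  check_arg(n_folds >= 2, "n_folds must be >= 2")
  check_arg(batch_size >= 1, "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 stratified = isTRUE(stratified)),
            class = "train_config")
}

#' Stratified k-fold assignment
#'
#' Shuffled, near-equal partition at the sample level; with stratification
#' each class is spread evenly over folds so small synthetic runs get stable
#' metrics.
#'
#' @param y Integer class labels (one per sample), or a list of samples
#'   carrying `label$class`.
#' @param n_folds Number of folds.
#' @param seed Seed for the shuffle.
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
kfold_split <- function(y, n_folds, seed = 1L, stratified = TRUE) {
  if (is.list(y)) y <- sample_classes(y)
  n <- length(y)
  check_arg(n >= n_folds, "fewer samples than folds")
  folds <- integer(n)
  local_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    }
  })
  folds
}

#' Train the model on one training fold
#'
#' Fits normalisation statistics on the training samples only, then minimises
#' cross-entropy with Adam. When `early_stop_patience` is set, a stratified
#' validation carve-out monitors generalisation and the best-validation
#' parameters are returned; otherwise the final parameters are.
#'
#' @param train_samples Feature-map samples (un-normalised) with `class`
#'   labels.
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @return A checkpoint: `list(params, model_cfg, stats, loss_curve,
#'   val_curve, epochs_run)`.
#' @export
train_fold <- function(train_samples, model_cfg, cfg = train_config()) {
  stats <- fit_map_stats(train_samples)
  train_n <- normalize_maps(train_samples, stats)
  y_all <- sample_classes(train_n)
  val_idx <- integer(0)
  if (!is.null(cfg$early_stop_patience)) {
    vf <- kfold_split(y_all, max(2L, round(1 / cfg$validation_fraction)),
                      seed = derive_seed(cfg$seed, "valsplit"))
    val_idx <- which(vf == 1L)
  }
  tr_idx <- setdiff(seq_along(train_n), val_idx)
  Xtr <- samples_to_matrix(train_n[tr_idx])
  ytr <- y_all[tr_idx]
  Xval <- if (length(val_idx)) samples_to_matrix(train_n[val_idx]) else NULL
  yval <- y_all[val_idx]
  T <- model_cfg$T
  n_tr <- length(tr_idx)

  params <- model_init(model_cfg, seed = derive_seed(cfg$seed, "init"))
  st <- adam_init(params)
  loss_curve <- numeric(0)
  val_curve <- numeric(0)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  local_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      n_batches <- ceiling(n_tr / cfg$batch_size)
      for (bi in seq_len(n_batches)) {
        sel <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n_tr)]
        cols <- as.vector(outer(seq_len(T), (sel - 1L) * T, `+`))
        lg <- model_loss_grad(params, Xtr[, cols, drop = FALSE], ytr[sel],
                              model_cfg, training = TRUE)
        if (!is.finite(lg$loss)) {
          abort2(sprintf("training diverged (non-finite loss at epoch %d)", ep),
                 "eegcaps_training_error")
        }
        upd <- adam_step(params, lg$grads, st, cfg$learning_rate)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + lg$loss * length(sel)
      }
      loss_curve[ep] <- ep_loss / n_tr
      if (!is.null(Xval)) {
        fv <- model_forward(params, Xval, model_cfg, training = FALSE)
        vl <- -mean(log(pmax(fv$probs[cbind(yval + 1L, seq_along(yval))], 1e-300)))
        val_curve[ep] <- vl
        if (vl < best$val - 1e-6) {
          best <- list(val = vl, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$early_stop_patience) break
        }
      }
    }
  })
  out_params <- if (!is.null(Xval) && best$epoch > 0) best$params else params
  list(params = out_params, model_cfg = model_cfg, stats = stats,
       loss_curve = loss_curve, val_curve = val_curve,
       epochs_run = length(loss_curve))
}

#' Confusion matrix and derived metrics
#'
#' @param truth,pred Integer class vectors (0-based), equal length.
#' @param n_classes Number of classes.
#' @return A list: `confusion` (truth in rows, predictions in columns),
#'   `confusion_norm` (row-normalised), `accuracy`, `precision`, `recall`,
#'   `f1` (macro-averaged, in percent), `per_class` data frame.
#' @export
confusion_metrics <- function(truth, pred, n_classes = max(truth, pred) + 1L) {
  check_arg(length(truth) == length(pred) && length(truth) > 0,
            "truth and pred must be non-empty and equal length")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = seq_len(n_classes) - 1L,
                               pred = seq_len(n_classes) - 1L))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  rn <- rowSums(cm)
  cn <- colSums(cm)
  dg <- diag(cm)
  recall_c <- ifelse(rn > 0, dg / rn, 0)
  precision_c <- ifelse(cn > 0, dg / cn, 0)
  f1_c <- ifelse(precision_c + recall_c > 0,
                 2 * precision_c * recall_c / (precision_c + recall_c), 0)
  list(confusion = cm,
       confusion_norm = sweep(cm, 1, pmax(rn, 1L), "/"),
       accuracy = 100 * sum(dg) / sum(cm),
       precision = 100 * mean(precision_c),
       recall = 100 * mean(recall_c),
       f1 = 100 * mean(f1_c),
       per_class = data.frame(class = seq_len(n_classes) - 1L,
                              precision = 100 * precision_c,
                              recall = 100 * recall_c,
                              f1 = 100 * f1_c,
                              row.names = NULL))
}

#' Evaluate a checkpoint on held-out samples
#'
#' Applies the checkpoint's training normalisation statistics (never fitted
#' on the test data), classifies, and reports accuracy plus macro-averaged
#' precision, recall and F1 with the confusion matrix.
#'
#' @param checkpoint Output of [train_fold()].
#' @param test_samples Held-out feature-map samples (un-normalised).
#' @return A list of metrics (see [confusion_metrics()]) plus `n` and
#'   `pred`.
#' @export
evaluate_model <- function(checkpoint, test_samples) {
  check_arg(length(test_samples) > 0, "empty test set")
  test_n <- normalize_maps(test_samples, checkpoint$stats)
  pr <- model_predict(checkpoint$params, test_n, checkpoint$model_cfg)
  truth <- sample_classes(test_samples)
  m <- confusion_metrics(truth, pr$class, checkpoint$model_cfg$n_classes)
  c(m, list(n = length(truth), pred = pr$class))
}

#' k-fold cross-validated training and evaluation
#'
#' Orchestrates fold assignment, per-fold training and evaluation, and
#' aggregates per-fold accuracy, F1, recall and precision into mean and
#' standard deviation. Fully reproducible from the master seed in `cfg`.
#'
#' @param samples Feature-map samples with `class` labels.
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @return An `eval_report`: list with `per_fold` (data frame), `mean`, `sd`,
#'   `confusion` (summed over folds), `loss_curves`, `n_samples`, `seed`.
#' @export
run_cv <- function(samples, model_cfg, cfg = train_config()) {
  y <- sample_classes(samples)
  folds <- kfold_split(y, cfg$n_folds, seed = derive_seed(cfg$seed, "folds"),
                       stratified = cfg$stratified)
  per_fold <- list()
  conf <- NULL
  loss_curves <- list()
  for (k in seq_len(cfg$n_folds)) {
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0("fold", k))
    ck <- train_fold(samples[folds != k], model_cfg, fold_cfg)
    ev <- evaluate_model(ck, samples[folds == k])
    per_fold[[k]] <- data.frame(fold = k, accuracy = ev$accuracy, f1 = ev$f1,
                                recall = ev$recall, precision = ev$precision,
                                n_test = ev$n)
    conf <- if (is.null(conf)) ev$confusion else conf + ev$confusion
    loss_curves[[k]] <- ck$loss_curve
  }
  pf <- do.call(rbind, per_fold)
  agg <- function(f) c(accuracy = f(pf$accuracy), f1 = f(pf$f1),
                       recall = f(pf$recall), precision = f(pf$precision))
  structure(list(per_fold = pf,
                 mean = agg(mean),
                 sd = agg(stats::sd),
                 confusion = conf,
                 loss_curves = loss_curves,
                 n_samples = length(samples),
                 n_folds = cfg$n_folds,
                 seed = cfg$seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV on %d samples (seed %d)\n",
              x$n_folds, x$n_samples, x$seed))
  cat(sprintf("  accuracy  %6.2f +/- %.2f %%\n", x$mean["accuracy"], x$sd["accuracy"]))
  cat(sprintf("  F1        %6.2f +/- %.2f %%\n", x$mean["f1"], x$sd["f1"]))
  cat(sprintf("  recall    %6.2f +/- %.2f %%\n", x$mean["recall"], x$sd["recall"]))
  cat(sprintf("  precision %6.2f +/- %.2f %%\n", x$mean["precision"], x$sd["precision"]))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Writes a byte-stable JSON rendering (fixed field order, full precision) so
#' identical runs produce identical files.
#'
#' @param report An `eval_report` from [run_cv()].
#' @param path Output file.
#' @export
write_eval_report <- function(report, path) {
  out <- list(n_folds = report$n_folds,
              n_samples = report$n_samples,
              seed = report$seed,
              mean = as.list(report$mean),
              sd = as.list(report$sd),
              per_fold = report$per_fold,
              confusion = unname(apply(report$confusion, 1, as.list)),
              loss_curves = report$loss_curves)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
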