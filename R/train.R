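# Training loop with best-validation-accuracy checkpointing, and evaluation
# producing the confusion matrix and the derived classification metrics
# (accuracy, macro precision / recall / F1 / specificity).

#' Training configuration
#'
#' @param epochs maximum epochs.
#' @param batch_size gradient-accumulation batch size.
#' @param lr base learning rate (cosine-decayed over epochs).
#' @param weight_decay L2 coefficient.
#' @param clip_norm global gradient-norm ceiling (stabilises the early
#'   steps of small-batch training); `Inf` disables clipping.
#' @param seed RNG seed controlling shuffling, dropout and initialisation of
#'   any freshly built model.
#' @param verbose print per-epoch log lines.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-3,
                         weight_decay = 0, clip_norm = 5, seed = 1L,
                         verbose = TRUE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, clip_norm > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, clip_norm = clip_norm,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a model
#'
#' Cross-entropy training with Adam and a cosine learning-rate decay.
#' Logs the training loss and validation accuracy per epoch and returns the
#' weights of the epoch with the highest validation accuracy (ties broken
#' towards the earliest epoch).
#'
#' @param model a `tcsr_model`; its classifier width must match the number
#'   of dataset classes.
#' @param train_set,val_set datasets from [load_dataset()] (or any list with
#'   `images` and `labels`).
#' @param config a [train_config()].
#' @return an object of class `tcsr_fit`: the best model, the full history
#'   (`epoch`, `loss`, `val_accuracy`, `lr`), `best_epoch` and the
#'   validation accuracy of the returned weights.
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "tcsr_model"))
  ntr <- length(train_set$images)
  if (ntr == 0L || length(val_set$images) == 0L)
    stop("train: empty training or validation split")
  K <- model$config$num_classes
  if (max(train_set$labels) + 1L > K)
    stop("train: dataset has more classes than the model head (", K, ")")
  set.seed(config$seed)
  net <- model$net
  ## warm the normalisation statistics: several passes so that each layer's
  ## tracked mean/variance converges to the activation distribution induced
  ## by the (already converged) statistics of the layers before it
  warm <- train_set$images[seq_len(min(32L, ntr))]
  for (pass in 1:3) for (im in warm)
    net <- nn_fwd(net, im, training = TRUE)$layer
  ## statistics are then frozen: the normalisation is a fixed affine map
  ## during optimisation, keeping the objective stationary
  net <- set_bn_frozen(net, TRUE)
  theta <- unlist(nn_params(net), use.names = FALSE)
  opt <- adam_new(length(theta))
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_accuracy = numeric(), lr = numeric())
  best <- list(acc = -Inf, net = net, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config$lr, epoch, config$epochs)
    ord <- sample.int(ntr)
    ep_loss <- 0
    done <- 0L
    while (done < ntr) {
      take <- ord[(done + 1L):min(done + config$batch_size, ntr)]
      done <- done + length(take)
      gacc <- NULL
      bloss <- 0
      for (ix in take) {
        r <- nn_fwd(net, train_set$images[[ix]], training = TRUE)
        net <- r$layer                       # running BN statistics advance
        ce <- softmax_ce(r$y, train_set$labels[ix] + 1L)
        if (!is.finite(ce$loss))
          stop("train: non-finite loss at epoch ", epoch,
               " (sample ", ix, "); try a lower learning rate")
        bloss <- bloss + ce$loss
        bw <- nn_bwd(net, ce$dlogits, r$cache)
        gv <- unlist(nn_grads(net, bw$g), use.names = FALSE)
        gacc <- if (is.null(gacc)) gv else gacc + gv
      }
      ep_loss <- ep_loss + bloss
      gacc <- gacc / length(take)
      gn <- sqrt(sum(gacc * gacc))
      if (is.finite(config$clip_norm) && gn > config$clip_norm)
        gacc <- gacc * (config$clip_norm / gn)
      st <- adam_step(opt, theta, gacc, lr,
                      weight_decay = config$weight_decay)
      opt <- st$state
      theta <- st$theta
      net <- nn_set_flat(net, theta)$layer
    }
    ep_loss <- ep_loss / ntr
    acc <- .dataset_accuracy(net, val_set)
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                         val_accuracy = acc, lr = lr))
    if (config$verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val_acc %.4f  lr %.2e",
                      epoch, config$epochs, ep_loss, acc, lr))
    if (acc > best$acc) best <- list(acc = acc, net = net, epoch = epoch)
  }
  model$net <- best$net
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 val_accuracy = best$acc, config = config,
                 class_names = train_set$class_names),
            class = "tcsr_fit")
}

.dataset_accuracy <- function(net, dset) {
  ok <- 0L
  for (i in seq_along(dset$images)) {
    y <- nn_fwd(net, dset$images[[i]], training = FALSE)$y
    if (which.max(y) - 1L == dset$labels[i]) ok <- ok + 1L
  }
  ok / length(dset$images)
}

# ---------------------------------------------------------------------------
# confusion matrix and metrics

#' Build a confusion matrix from label vectors
#'
#' @param true,pred integer class labels (0-based) or factors.
#' @param class_names optional class names (length K).
#' @return object of class `confusion_matrix`: a K x K integer `counts`
#'   table (rows = true class, columns = predicted class) plus names.
#' @export
confusion_matrix <- function(true, pred, class_names = NULL) {
  if (is.factor(true) || is.factor(pred)) {
    lev <- union(levels(as.factor(true)), levels(as.factor(pred)))
    true <- match(as.character(true), lev) - 1L
    pred <- match(as.character(pred), lev) - 1L
    if (is.null(class_names)) class_names <- lev
  }
  stopifnot(length(true) == length(pred), length(true) > 0L)
  K <- max(true, pred) + 1L
  if (!is.null(class_names)) K <- max(K, length(class_names))
  counts <- matrix(0L, K, K)
  for (i in seq_along(true))
    counts[true[i] + 1L, pred[i] + 1L] <- counts[true[i] + 1L, pred[i] + 1L] + 1L
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest TP/TN/FP/FN give precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2PR/(P+R)` and specificity `TN/(TN+FP)`; macro values
#' are unweighted class means and accuracy is the global diagonal fraction.
#' Degenerate ratios (empty denominators) are defined as 0 so macro means
#' stay total.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `metrics_report` with macro `accuracy`,
#'   `precision`, `recall`, `f1`, `specificity` and a `per_class` table.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- cm$counts
  total <- sum(M)
  if (total == 0L) stop("compute_metrics: empty confusion matrix")
  tp <- diag(M)
  fp <- colSums(M) - tp
  fn <- rowSums(M) - tp
  tn <- total - tp - fp - fn
  sdiv <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- sdiv(tp, tp + fp)
  rec <- sdiv(tp, tp + fn)
  f1 <- sdiv(2 * prec * rec, prec + rec)
  spec <- sdiv(tn, tn + fp)
  per <- data.frame(class = cm$class_names, tp = tp, fp = fp, fn = fn, tn = tn,
                    precision = prec, recall = rec, f1 = f1, specificity = spec,
                    row.names = NULL)
  structure(list(accuracy = sum(tp) / total,
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 specificity = mean(spec), per_class = per, n = total),
            class = "metrics_report")
}

#' Evaluate a model on a dataset
#'
#' Argmax predictions are accumulated into a confusion matrix; metrics are
#' derived with [compute_metrics()]. Optionally writes the matrix as CSV and
#' the metrics as JSON.
#'
#' @param model a `tcsr_model` or `tcsr_fit`.
#' @param test_set dataset from [load_dataset()].
#' @param out_dir if non-NULL, write `confusion_matrix.csv` and
#'   `metrics.json` there.
#' @return list with elements `confusion` and `metrics`.
#' @export
evaluate <- function(model, test_set, out_dir = NULL) {
  if (inherits(model, "tcsr_fit")) model <- model$model
  stopifnot(inherits(model, "tcsr_model"))
  K <- model$config$num_classes
  nk <- length(test_set$class_names)
  if (nk > K)
    stop("evaluate: dataset has ", nk, " classes but the model head has ", K)
  preds <- integer(length(test_set$images))
  for (i in seq_along(test_set$images))
    preds[i] <- which.max(nn_fwd(model$net, test_set$images[[i]], FALSE)$y) - 1L
  cm <- confusion_matrix(test_set$labels, preds,
                         class_names = if (nk == K) test_set$class_names else NULL)
  met <- compute_metrics(cm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cm$counts, file.path(out_dir, "confusion_matrix.csv"))
    jsonlite::write_json(list(accuracy = met$accuracy, precision = met$precision,
                              recall = met$recall, f1 = met$f1,
                              specificity = met$specificity, n = met$n),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(confusion = cm, metrics = met)
}
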