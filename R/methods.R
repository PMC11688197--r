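# S3 methods for models, fits and reports, plus checkpoint I/O.

#' @export
print.tcsr_model <- function(x, ...) {
  cfg <- x$config
  cat("<tcsr_model>", cfg$name, "\n")
  cat("  blocks:", length(cfg$blocks),
      " classes:", cfg$num_classes,
      " input:", cfg$input_size, "x", cfg$input_size, "\n")
  cat(sprintf("  parameters: %d (%.6f M)\n", count_parameters(x),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.tcsr_model <- function(object, ...) {
  cfg <- object$config
  tab <- do.call(rbind, lapply(seq_along(cfg$blocks), function(i) {
    b <- cfg$blocks[[i]]
    data.frame(block = i,`in` = b$in_channels, exp = b$expand_channels,
               out = b$out_channels, k = b$dw_kernel, stride = b$stride,
               expansion = b$expansion_type, projection = b$projection_type,
               attention = b$attention, nl = b$nonlinearity,
               check.names = FALSE)
  }))
  print(object)
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' Predict classes or probabilities for images
#'
#' @param object a `tcsr_model`.
#' @param newdata an `[H, W, 3]` array, a list of such arrays, or a
#'   `tcsr_dataset`.
#' @param type "class" (0-based argmax), "prob" (softmax matrix) or "logit".
#' @param ... unused.
#' @return integer vector, or an n x K numeric matrix.
#' @export
predict.tcsr_model <- function(object, newdata, type = c("class", "prob", "logit"),
                               ...) {
  type <- match.arg(type)
  imgs <- if (inherits(newdata, "tcsr_dataset")) newdata$images
          else if (is.list(newdata)) newdata else list(newdata)
  out <- matrix(0, length(imgs), object$config$num_classes)
  for (i in seq_along(imgs)) {
    z <- nn_fwd(object$net, imgs[[i]], training = FALSE)$y
    out[i, ] <- if (type == "prob") softmax(z) else z
  }
  if (type == "class") apply(out, 1L, which.max) - 1L else out
}

#' @export
print.tcsr_fit <- function(x, ...) {
  cat("<tcsr_fit>", x$model$config$name, "\n")
  cat(sprintf("  epochs run: %d; best epoch: %d (val accuracy %.4f)\n",
              nrow(x$history), x$best_epoch, x$val_accuracy))
  invisible(x)
}

#' @export
summary.tcsr_fit <- function(object, ...) {
  print(object)
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
predict.tcsr_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' Plot training history
#'
#' Training loss and validation accuracy against epoch.
#' @param x a `tcsr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tcsr_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "b", xlab = "epoch",
                 ylab = "validation accuracy", main = "validation", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro precision %.4f recall %.4f f1 %.4f specificity %.4f (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$specificity, x$n))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' @export
print.ghost_spec <- function(x, ...) {
  cat(sprintf("<ghost_spec> %d -> %d channels, s = %d, k = %d, d = %d (r_c = %.3f)\n",
              x$c, x$n, x$s, x$k, x$d, compression_ratio(x)))
  invisible(x)
}

#' @export
print.stage_appearance <- function(x, ...) {
  cat(sprintf("<stage %d> yellowing %.2f drying %.2f vein white %.2f curl %.2f (dry/wet bulb %g/%g C)\n",
              x$stage, x$yellowing_fraction, x$drying_fraction,
              x$vein_whiteness, x$curl_amount, x$dry_bulb_C, x$wet_bulb_C))
  invisible(x)
}

# ---------------------------------------------------------------------------
# checkpoints: flat weights + config + history, rebuildable

#' Save / load a training checkpoint
#'
#' A checkpoint embeds the declarative model config, the flattened weight
#' vector, the batchnorm running statistics and the training history, so a
#' model can be rebuilt exactly.
#'
#' @param fit a `tcsr_fit` (or a bare `tcsr_model`).
#' @param path file path (RDS).
#' @return `load_checkpoint()` returns a `tcsr_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  if (inherits(fit, "tcsr_model")) fit <- list(model = fit, history = NULL,
                                               best_epoch = NA, val_accuracy = NA,
                                               class_names = NULL)
  tmp <- tempfile(fileext = ".yaml")
  write_model_config(fit$model$config, tmp)
  obj <- list(config_yaml = paste(readLines(tmp), collapse = "\n"),
              theta = unlist(nn_params(fit$model$net), use.names = FALSE),
              buffers = .collect_buffers(fit$model$net),
              history = fit$history, best_epoch = fit$best_epoch,
              val_accuracy = fit$val_accuracy, class_names = fit$class_names)
  unlink(tmp)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  tmp <- tempfile(fileext = ".yaml")
  writeLines(obj$config_yaml, tmp)
  cfg <- read_model_config(tmp)
  unlink(tmp)
  model <- new_model(cfg)
  model$net <- nn_set_flat(model$net, obj$theta)$layer
  model$net <- .restore_buffers(model$net, obj$buffers, 1L)$layer
  structure(list(model = model, history = obj$history,
                 best_epoch = obj$best_epoch, val_accuracy = obj$val_accuracy,
                 config = NULL, class_names = obj$class_names),
            class = "tcsr_fit")
}

.collect_buffers <- function(layer) {
  out <- if (length(layer$buf)) list(layer$buf) else list()
  for (ch in layer$children)
    if (!is.null(ch)) out <- c(out, .collect_buffers(ch))
  out
}

.restore_buffers <- function(layer, bufs, pos) {
  if (length(layer$buf)) {
    layer$buf <- bufs[[pos]]
    pos <- pos + 1L
  }
  for (i in seq_along(layer$children)) {
    if (is.null(layer$children[[i]])) next
    r <- .restore_buffers(layer$children[[i]], bufs, pos)
    layer$children[[i]] <- r$layer
    pos <- r$pos
  }
  list(layer = layer, pos = pos)
}
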