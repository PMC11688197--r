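test_that("metrics follow the one-vs-rest formulas on hand-checked cases", {
  # perfect predictions
  cm <- confusion_matrix(rep(0:2, each = 4), rep(0:2, each = 4))
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$f1, 1); expect_equal(m$specificity, 1)
  # two-class counts [[8,2],[3,7]]
  cm2 <- structure(list(counts = matrix(c(8, 3, 2, 7), 2, 2),
                        class_names = c("0", "1")), class = "confusion_matrix")
  m2 <- compute_metrics(cm2)
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$per_class$precision[1], 8 / 11, tolerance = 1e-12)
  expect_equal(m2$per_class$recall[1], 0.8)
  expect_equal(m2$per_class$f1[1], 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8), tolerance = 1e-12)
  expect_equal(m2$per_class$specificity[1], 0.7)
  # all-off-diagonal
  cm3 <- confusion_matrix(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(compute_metrics(cm3)$accuracy, 0)
})

test_that("metrics agree with a per-sample brute-force tally on random vectors", {
  set.seed(70)
  for (trial in 1:200) {
    K <- sample(2:6, 1)
    n <- sample(5:40, 1)
    tru <- sample(0:(K - 1), n, replace = TRUE)
    prd <- sample(0:(K - 1), n, replace = TRUE)
    m <- compute_metrics(confusion_matrix(tru, prd, as.character(1:K)))
    expect_equal(m$accuracy, mean(tru == prd), tolerance = 1e-12)
    # independent tally for a random class
    k <- sample(0:(K - 1), 1)
    tp <- sum(tru == k & prd == k); fp <- sum(tru != k & prd == k)
    fn <- sum(tru == k & prd != k); tn <- sum(tru != k & prd != k)
    i <- k + 1
    expect_equal(m$per_class$tp[i], tp)
    expect_equal(m$per_class$precision[i], if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(m$per_class$specificity[i], if (tn + fp > 0) tn / (tn + fp) else 0)
  }
})

test_that("macro metrics are invariant under class relabelling", {
  set.seed(71)
  tru <- sample(0:3, 60, replace = TRUE)
  prd <- sample(0:3, 60, replace = TRUE)
  m1 <- compute_metrics(confusion_matrix(tru, prd, as.character(1:4)))
  perm <- sample(0:3)
  m2 <- compute_metrics(confusion_matrix(perm[tru + 1], perm[prd + 1],
                                         as.character(1:4)))
  for (f in c("accuracy", "precision", "recall", "f1", "specificity"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
})

test_that("degenerate classes yield zero F1 and total macro means", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 0, 0), class_names = c("a", "b", "c"))
  m <- compute_metrics(cm)   # class c: never true, never predicted
  expect_equal(m$per_class$f1[3], 0)
  expect_true(is.finite(m$f1))
})

test_that("training is seed-deterministic and selects the best epoch", {
  ds <- toy_dataset(3)
  cfgt <- train_config(epochs = 2L, batch_size = 3L, lr = 2e-3, seed = 17,
                       verbose = FALSE)
  set.seed(1); f1 <- train(tiny_model(2), ds, ds, cfgt)
  set.seed(1); f2 <- train(tiny_model(2), ds, ds, cfgt)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$val_accuracy, max(f1$history$val_accuracy))
  expect_equal(f1$best_epoch,
               which(f1$history$val_accuracy == max(f1$history$val_accuracy))[1])
})

test_that("non-finite losses abort with a diagnostic", {
  ds <- toy_dataset(2)
  m <- tiny_model(2)
  th <- unlist(tcsrnet:::nn_params(m$net))
  th[length(th)] <- NaN        # classifier bias: first loss is non-finite
  m$net <- tcsrnet:::nn_set_flat(m$net, th)$layer
  expect_error(suppressMessages(
    train(m, ds, ds, train_config(1L, 2L, 1e-3, seed = 1, verbose = FALSE))),
    "non-finite")
})

test_that("evaluation fills a confusion matrix of the dataset size", {
  set.seed(72)
  ds <- toy_dataset(3)
  m <- tiny_model(2)
  ev <- evaluate(m, ds)
  expect_equal(sum(ev$confusion$counts), 6)
  expect_equal(ev$metrics$n, 6)
  # per-class TP/FP/FN/TN partition the total
  pc <- ev$metrics$per_class
  expect_true(all(pc$tp + pc$fp + pc$fn + pc$tn == 6))
  # class-count mismatch is an error
  ds3 <- ds; ds3$class_names <- c("a", "b", "c")
  expect_error(evaluate(m, ds3), "classes")
})

test_that("evaluation artefacts are written as CSV and JSON", {
  set.seed(73)
  td <- tempfile()
  ev <- evaluate(tiny_model(2), toy_dataset(2), out_dir = td)
  expect_true(file.exists(file.path(td, "confusion_matrix.csv")))
  js <- jsonlite::read_json(file.path(td, "metrics.json"))
  expect_equal(js$accuracy, ev$metrics$accuracy)
  unlink(td, recursive = TRUE)
})

test_that("a tiny model overfits a toy batch (loss collapses, accuracy 1)", {
  ds <- toy_dataset(3)
  fit <- suppressMessages(
    train(tiny_model(2), ds, ds,
          train_config(epochs = 8L, batch_size = 3L, lr = 5e-3, seed = 11,
                       verbose = FALSE)))
  expect_equal(fit$val_accuracy, 1)
  expect_lt(min(fit$history$loss), 0.1 * fit$history$loss[1])
  ev <- evaluate(fit, ds)
  expect_equal(ev$metrics$accuracy, 1)
})
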