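test_that("built models are logit-complete and follow the classifier width", {
  set.seed(40)
  m <- build_tcsrnet(10)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  y <- tcsrnet:::model_forward(m, x)$y
  expect_length(y, 10)
  expect_length(predict(build_baseline(4), x, type = "logit"), 4)
  expect_error(tcsrnet:::model_forward(m, array(0, c(50, 50, 3))), "multiples of 32")
})

test_that("baseline head arithmetic: 1000-class total exceeds 10-class by 990*1024 + 990", {
  p10 <- count_parameters(build_baseline(10))
  p1000 <- count_parameters(build_baseline(1000))
  expect_equal(p1000 - p10, 990 * 1024 + 990)
})

test_that("the conv+SE ablation is structurally identical to the baseline", {
  set.seed(41)
  s1 <- model_shapes(build_baseline(10))
  s2 <- model_shapes(ablation_variant("conv+SE", 10))
  expect_identical(names(s1), names(s2))
  expect_identical(s1, s2)
})

test_that("the full-toggle ablation equals build_tcsrnet in parameters", {
  expect_equal(count_parameters(ablation_variant("inception+ghost+MAAM")),
               count_parameters(build_tcsrnet()))
  expect_error(ablation_variant("ghost-only"), "conv\\+SE")
})

test_that("the five ablation variants have pairwise distinct parameter counts", {
  counts <- vapply(ablation_names(),
                   function(nm) count_parameters(ablation_variant(nm)), numeric(1))
  expect_equal(anyDuplicated(counts), 0L)
})

test_that("configs round-trip through YAML with identical weight shapes", {
  set.seed(42)
  cfg <- tcsrnet:::tcsrnet_config(10)
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  m1 <- tcsrnet:::new_model(cfg)
  m2 <- tcsrnet:::new_model(cfg2)
  expect_identical(model_shapes(m1), model_shapes(m2))
  m3 <- build_preset(f)
  expect_equal(count_parameters(m3), count_parameters(m1))
  unlink(f)
})

test_that("model_config rejects non-chaining blocks and bad input sizes", {
  b1 <- bneck_config(16, 16, 16, 3, 2, "SE")
  b2 <- bneck_config(24, 72, 24, 3, 2)       # 16 -> 24 mismatch
  expect_error(model_config("bad", list(b1, b2)), "chain")
  expect_error(model_config("bad", list(b1), input_size = 100), "multiple of 32")
})

test_that("checkpoints restore weights, buffers and predictions exactly", {
  set.seed(43)
  m <- tiny_model(2)
  ds <- toy_dataset(2)
  fit <- suppressMessages(train(m, ds, ds, train_config(1L, 2L, 1e-3, seed = 3,
                                                        verbose = FALSE)))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  fit2 <- load_checkpoint(f)
  expect_equal(predict(fit2, ds, type = "logit"), predict(fit, ds, type = "logit"),
               tolerance = 1e-12)
  expect_equal(fit2$best_epoch, fit$best_epoch)
  unlink(f)
})

test_that("MAAM placement mirrors SE placement unless overridden", {
  cfg <- tcsrnet:::tcsrnet_config(10)
  att <- vapply(cfg$blocks, function(b) b$attention, "")
  se <- vapply(tcsrnet:::mnv3_small_schedule(), function(r) r$se, logical(1))
  expect_identical(att == "MAAM", se)
  cfg2 <- tcsrnet:::tcsrnet_config(10, attention_everywhere = TRUE)
  expect_true(all(vapply(cfg2$blocks, function(b) b$attention, "")[2:3] == "MAAM"))
})
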