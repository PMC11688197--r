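# The convolution/normalisation/pooling primitives are this package's own
# implementation, so each is checked against a naive reference and against
# finite-difference gradients.

test_that("im2col convolution matches the direct triple-loop reference", {
  set.seed(7)
  cases <- list(list(k = 1, s = 1, p = 0, d = 1), list(k = 3, s = 1, p = 1, d = 1),
                list(k = 3, s = 2, p = 1, d = 1), list(k = 5, s = 2, p = 2, d = 1),
                list(k = 3, s = 1, p = 2, d = 2))
  for (cs in cases) {
    x <- array(rnorm(9 * 9 * 4), c(9, 9, 4))
    W <- array(rnorm(cs$k^2 * 4 * 3), c(cs$k, cs$k, 4, 3))
    b <- rnorm(3)
    got <- tcsrnet:::conv2d_fwd(x, W, b, cs$s, cs$p, cs$d)$y
    want <- naive_conv2d(x, W, b, cs$s, cs$p, cs$d)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("depthwise convolution equals per-channel direct convolution", {
  set.seed(8)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  W <- array(rnorm(9 * 5), c(3, 3, 5))
  got <- tcsrnet:::dwconv_fwd(x, W, stride = 2L, pad = 1L)$y
  for (c in 1:5) {
    Wc <- array(W[, , c], c(3, 3, 1, 1))
    want <- naive_conv2d(x[, , c, drop = FALSE], Wc, stride = 2L, pad = 1L)
    expect_equal(got[, , c], want[, , 1], tolerance = 1e-12)
  }
})

test_that("max pooling matches a window-wise reference and routes gradients to the argmax", {
  set.seed(9)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  r <- tcsrnet:::maxpool_fwd(x, 3L, 1L, 1L)
  xp <- array(-Inf, c(8, 8, 2)); xp[2:7, 2:7, ] <- x
  for (c in 1:2) for (i in 1:6) for (j in 1:6)
    expect_equal(r$y[i, j, c], max(xp[i:(i + 2), j:(j + 2), c]))
  expect_lt(fd_layer_check(tcsrnet:::ly_maxpool(), x), 1e-5)
})

test_that("activations follow their reference formulas", {
  x <- seq(-5, 5, by = 0.25)
  expect_equal(hard_swish(x), x * pmin(pmax(x + 3, 0), 6) / 6)
  expect_equal(hard_sigmoid(-4), 0)
  expect_equal(hard_sigmoid(4), 1)
  expect_equal(hard_sigmoid(0), 0.5)
  expect_equal(tcsrnet:::act_fwd(x, "relu"), pmax(x, 0))
  # hard-swish equals swish's key anchor points
  expect_equal(hard_swish(-3), 0)
  expect_equal(hard_swish(3), 3)
})

test_that("every layer kind passes a finite-difference gradient check", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  layers <- list(
    conv = tcsrnet:::ly_conv(6, 5, 3, stride = 2),
    dilated = tcsrnet:::ly_conv(6, 5, 3, dilation = 2),
    dw = tcsrnet:::ly_dwconv(6, 5, stride = 2),
    bn = tcsrnet:::ly_bn(6),
    ghost = ghost_module(ghost_spec(6, 8, 2, 1, 3, activation = "hswish")),
    ghost_s3 = ghost_module(ghost_spec(6, 9, 3, 1, 3, activation = "relu")),
    se = tcsrnet:::ly_se(6),
    maam = maam_module(6, 2),
    inception = inception_module(inception_spec(6, 6, 12, activation = "hswish")),
    bneck = bneck_module(bneck_config(6, 18, 6, 3, 1, "MAAM", "hswish",
                                      "inception", "ghost", 6)))
  for (nm in names(layers))
    expect_lt(fd_layer_check(layers[[nm]], x, training = TRUE), 1e-5,
              label = paste("max relative gradient error of", nm))
})

test_that("softmax cross-entropy has unit-sum probabilities and correct gradient", {
  z <- c(2, -1, 0.5)
  r <- tcsrnet:::softmax_ce(z, 2L)
  expect_equal(sum(r$probs), 1)
  expect_equal(sum(r$dlogits), 0, tolerance = 1e-12)
  eps <- 1e-6
  for (i in 1:3) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (tcsrnet:::softmax_ce(zp, 2L)$loss - tcsrnet:::softmax_ce(zm, 2L)$loss) / (2 * eps)
    expect_equal(num, r$dlogits[i], tolerance = 1e-5)
  }
})
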