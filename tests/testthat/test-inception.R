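test_that("inception expansion keeps spatial size and reaches expand_channels", {
  set.seed(30)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  sp <- inception_spec(16, 16, 72)
  mod <- inception_module(sp)
  y <- inception_forward(x, mod)
  expect_equal(dim(y), c(8, 8, 72))
  expect_equal(mod$concat, 64)     # 3 conv branches + pass-through pool branch
  expect_error(inception_forward(array(0, c(8, 8, 4)), mod), "channels")
})

test_that("the dilated branch preserves spatial size at any input", {
  set.seed(31)
  for (H in c(3, 7, 12)) {
    x <- array(rnorm(H * H * 4), c(H, H, 4))
    conv <- tcsrnet:::ly_conv(4, 4, 3, dilation = 2)
    expect_equal(dim(tcsrnet:::nn_fwd(conv, x)$y), c(H, H, 4))
  }
})

test_that("branch outputs on a constant map match direct convolution arithmetic", {
  # all-ones weights, pass-through normalisation, constant input
  x <- array(1, c(3, 3, 2))
  check_branch <- function(k, dilation) {
    conv <- tcsrnet:::ly_conv(2, 1, k, dilation = dilation)
    conv$par$W[] <- 1
    got <- tcsrnet:::nn_fwd(conv, x)$y
    want <- naive_conv2d(x, conv$par$W, stride = 1L, pad = conv$pad,
                         dilation = dilation)
    expect_equal(got, want, tolerance = 1e-12)
    got
  }
  y1 <- check_branch(1, 1)
  expect_equal(as.numeric(y1), rep(2, 9))       # 1x1: sums the two channels
  y3 <- check_branch(3, 1)
  expect_equal(y3[2, 2, 1], 18)                 # full 3x3 window, 2 channels
  expect_equal(y3[1, 1, 1], 8)                  # corner sees 2x2 window
  yd <- check_branch(3, 2)
  # dilation 2: taps at {-2, 0, 2}; from the centre of a 3x3 map only the
  # centre tap falls inside, so the sum is the two channel values
  expect_equal(yd[2, 2, 1], 2)
})

test_that("residual blocks are exact identities under zeroed projection", {
  set.seed(32)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  cfg <- bneck_config(8, 24, 8, 3, 1, attention = "none")
  mod <- bneck_module(cfg)
  # zero the projection conv and its normalisation shift
  mod$children[[6]]$children[[1]]$par$W[] <- 0
  mod$children[[6]]$children[[2]]$par$beta[] <- 0
  expect_equal(bneck_forward(x, mod), x, tolerance = 1e-12)
})

test_that("bneck shape contract holds for strided five-kernel blocks", {
  set.seed(33)
  x <- array(rnorm(56 * 56 * 24), c(56, 56, 24))
  y <- bneck_forward(x, bneck_config(24, 96, 40, 5, 2, "SE", "hswish"))
  expect_equal(dim(y), c(28, 28, 40))
})

test_that("block parameter count equals the enumeration of its weight arrays", {
  set.seed(34)
  cfg <- bneck_config(16, 72, 24, 3, 2, "MAAM", "hswish", "inception", "ghost",
                      branch_channels = 22)
  mod <- bneck_module(cfg)
  enum <- sum(vapply(tcsrnet:::nn_params(mod), length, numeric(1)))
  prof <- tcsrnet:::profile_layer(mod, c(16, 16, 16), "b")
  expect_equal(sum(vapply(prof$rows, `[[`, 0, "params")), enum)
})

test_that("forward passes are deterministic given weights and input", {
  set.seed(35)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  mod <- bneck_module(bneck_config(16, 48, 16, 3, 1, "MAAM", "hswish",
                                   "inception", "ghost"))
  expect_identical(bneck_forward(x, mod), bneck_forward(x, mod))
})
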