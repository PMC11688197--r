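test_that("channel descriptor sums avg, max and population std", {
  x <- array(2, c(3, 3, 4))
  expect_equal(channel_descriptor(x), rep(4, 4), tolerance = 1e-5)   # 2v, std 0
  x2 <- array(c(1, 3, 1, 3), c(2, 2, 1))
  expect_equal(channel_descriptor(x2), 6, tolerance = 1e-5)          # 2 + 3 + 1
  expect_equal(channel_descriptor(array(0, c(2, 2, 3))), rep(0, 3),
               tolerance = 1e-5)
})

test_that("spatial descriptor mirrors the channel statistics across channels", {
  x <- array(0.7, c(2, 2, 1))
  expect_equal(spatial_descriptor(x), array(1.4, c(2, 2, 1)), tolerance = 1e-5)
  x2 <- array(0, c(1, 1, 2)); x2[1, 1, ] <- c(0, 4)
  expect_equal(as.numeric(spatial_descriptor(x2)), 8, tolerance = 1e-5) # 2+4+2
  x3 <- array(0.3, c(4, 5, 6))
  expect_equal(spatial_descriptor(x3), array(0.6, c(4, 5, 1)), tolerance = 1e-5)
})

test_that("std pooling of any constant input contributes exactly zero", {
  for (v in c(-2, 0, 5)) {
    x <- array(v, c(3, 4, 2))
    expect_equal(channel_descriptor(x), rep(2 * v, 2), tolerance = 1e-5)
    expect_equal(as.numeric(spatial_descriptor(x)), rep(2 * v, 12), tolerance = 1e-5)
  }
})

test_that("maam preserves shape, annihilates zeros, and bounds its weights in (0,1)", {
  set.seed(20)
  for (dims in list(c(1, 1, 1), c(3, 5, 2), c(6, 6, 8))) {
    x <- array(rnorm(prod(dims)), dims)
    mod <- maam_module(dims[3], reduction = 2)
    y <- maam_forward(x, mod)
    expect_equal(dim(y), dims)
    r <- tcsrnet:::maam_fwd_impl(mod, x, FALSE)
    expect_true(all(r$cache$Ac > 0 & r$cache$Ac < 1))
    expect_true(all(r$cache$As > 0 & r$cache$As < 1))
    expect_true(r$cache$g > 0 && r$cache$g < 1)
    expect_true(all(abs(y) <= 2 * abs(x) + 1e-12))
  }
  expect_equal(maam_forward(array(0, c(4, 4, 3))), array(0, c(4, 4, 3)))
})

test_that("gate extremes select the channel or the spatial pathway", {
  set.seed(21)
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  mod <- maam_module(6, 2)
  r0 <- tcsrnet:::maam_fwd_impl(mod, x, FALSE)$cache
  modc <- mod; modc$children[[4]]$par$b <- 50      # g -> 1: channel attention
  yc <- maam_forward(x, modc)
  expect_equal(yc, x * rep(r0$Ac, each = 16), tolerance = 1e-8)
  mods <- mod; mods$children[[4]]$par$b <- -50     # g -> 0: spatial attention
  ys <- maam_forward(x, mods)
  expect_equal(as.numeric(ys), as.numeric(matrix(x, 16, 6) * r0$As),
               tolerance = 1e-8)
})

test_that("maam output is computable by hand on a toy tensor with g = 1", {
  # identity channel transform: C=2 -> Cr=8, embed then project back
  x <- array(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6), c(2, 2, 2))
  mod <- maam_module(2, reduction = 1)   # Cr = 8
  W1 <- matrix(0, 2, 8); W1[1, 1] <- 1; W1[2, 2] <- 1
  W2 <- matrix(0, 8, 2); W2[1, 1] <- 1; W2[2, 2] <- 1
  mod$children[[1]]$par$W <- W1; mod$children[[1]]$par$b <- rep(0, 8)
  mod$children[[2]]$par$W <- W2; mod$children[[2]]$par$b <- rep(0, 2)
  mod$children[[4]]$par$b <- 50          # force g = 1
  y <- maam_forward(x, mod)
  dc <- channel_descriptor(x)            # descriptors are positive here
  want <- x * rep(1 / (1 + exp(-dc)), each = 4)
  expect_equal(y, want, tolerance = 1e-8)
})

test_that("SE attention reweights channels with hard-sigmoid factors in [0,1]", {
  set.seed(22)
  x <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  se <- tcsrnet:::ly_se(16)
  r <- tcsrnet:::nn_fwd(se, x)
  expect_equal(dim(r$y), dim(x))
  a <- r$cache$a
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(r$y, x * rep(a, each = 16), tolerance = 1e-12)
  expect_equal(se$sq, 8)    # make_divisible(16/4, 8)
})
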