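# Shared helpers: naive reference implementations and small fixtures.

# direct triple-loop 2-d convolution (same weight layout as the package):
# reference oracle for the im2col path
naive_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x); dw <- dim(W)
  k <- dw[1]; cout <- dw[4]
  Hp <- d[1] + 2 * pad; Wp <- d[2] + 2 * pad
  xp <- array(0, c(Hp, Wp, d[3]))
  xp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), ] <- x
  ke <- (k - 1) * dilation + 1
  Ho <- (Hp - ke) %/% stride + 1L
  Wo <- (Wp - ke) %/% stride + 1L
  y <- array(0, c(Ho, Wo, cout))
  for (oc in seq_len(cout)) for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    acc <- 0
    for (ic in seq_len(d[3])) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- (oi - 1) * stride + (ki - 1) * dilation + 1
      jj <- (oj - 1) * stride + (kj - 1) * dilation + 1
      acc <- acc + xp[ii, jj, ic] * W[ki, kj, ic, oc]
    }
    y[oi, oj, oc] <- acc + if (is.null(b)) 0 else b[oc]
  }
  y
}

# central finite-difference check of a layer's backward pass
fd_layer_check <- function(layer, x, training = FALSE, eps = 1e-5, nprobe = 10L) {
  set.seed(99)
  r <- tcsrnet:::nn_fwd(layer, x, training)
  dy <- r$y; dy[] <- stats::rnorm(length(dy))
  b <- tcsrnet:::nn_bwd(layer, dy, r$cache)
  loss <- function(lay, xx) sum(tcsrnet:::nn_fwd(lay, xx, training)$y * dy)
  idx <- sample(length(x), min(nprobe, length(x)))
  dx_err <- max(vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (loss(layer, xp) - loss(layer, xm)) / (2 * eps)
    abs(num - b$dx[i]) / max(1e-4, abs(num))
  }, numeric(1)))
  th <- unlist(tcsrnet:::nn_params(layer))
  gr <- unlist(tcsrnet:::nn_grads(layer, b$g))
  par_err <- if (length(th) == 0) 0 else {
    idx <- sample(length(th), min(nprobe, length(th)))
    max(vapply(idx, function(i) {
      tp <- th; tp[i] <- tp[i] + eps
      tm <- th; tm[i] <- tm[i] - eps
      num <- (loss(tcsrnet:::nn_set_flat(layer, tp)$layer, x) -
              loss(tcsrnet:::nn_set_flat(layer, tm)$layer, x)) / (2 * eps)
      abs(num - gr[i]) / max(1e-4, abs(num))
    }, numeric(1)))
  }
  max(dx_err, par_err)
}

# tiny model: stem + two blocks (one improved, one plain) + standard head,
# cheap enough for training-loop tests at a 32-pixel input
tiny_model <- function(num_classes = 2L) {
  blocks <- list(
    bneck_config(16, 16, 16, 3, 2, attention = "SE", nonlinearity = "relu"),
    bneck_config(16, 24, 16, 3, 1, attention = "MAAM", nonlinearity = "hswish",
                 expansion_type = "inception", projection_type = "ghost",
                 branch_channels = 8))
  tcsrnet:::new_model(model_config("tiny", blocks, num_classes, input_size = 32L))
}

# small in-memory two-class image set with an obvious colour signal
toy_dataset <- function(n_per_class = 4L, size = 32L, seed = 5L) {
  set.seed(seed)
  images <- list(); labels <- integer()
  for (cl in 0:1) for (i in seq_len(n_per_class)) {
    base <- if (cl == 0) c(0.1, 0.6, 0.1) else c(0.6, 0.35, 0.1)
    img <- array(stats::runif(size * size * 3, 0, 0.15), c(size, size, 3))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + base[ch]
    images[[length(images) + 1L]] <- pmin(img, 1)
    labels <- c(labels, cl)
  }
  structure(list(images = images, labels = labels, class_names = c("a", "b")),
            class = "tcsr_dataset")
}
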