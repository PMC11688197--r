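# Low-level tensor primitives. Feature maps are numeric arrays with
# dim = c(H, W, C); convolution weights are arrays dim = c(k, k, cin, cout)
# flattened column-major into (k*k*cin) x cout matrices for BLAS matmul.

#' Round a channel count to a hardware-friendly multiple
#'
#' The channel-rounding rule used throughout the MobileNet family: round to
#' the nearest multiple of `divisor`, never below `divisor`, and never more
#' than 10\% below the requested value.
#'
#' @param v requested (possibly fractional) channel count.
#' @param divisor the multiple to round to (default 8).
#' @return an integer channel count.
#' @export
#' @examples
#' make_divisible(37.5)   # 40
#' make_divisible(12)     # 16 (rounding to 8 would lose > 10%)
make_divisible <- function(v, divisor = 8L) {
  new_v <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

pad_hw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  xp
}

conv_out_dim <- function(H, k, stride, pad, dilation = 1L) {
  ke <- (k - 1L) * dilation + 1L
  as.integer((H + 2L * pad - ke) %/% stride + 1L)
}

# Linear (column-major) gather indices for im2col. Returns an N x (k^2*C)
# integer matrix; row = output position (oi fastest), column = (ki, kj, c).
im2col_idx <- function(Hp, Wp, C, k, stride, dilation, Ho, Wo) {
  base_i <- (0:(Ho - 1L)) * stride
  base_j <- (0:(Wo - 1L)) * stride
  off_i <- (0:(k - 1L)) * dilation
  off_j <- (0:(k - 1L)) * dilation
  rowi <- rep(base_i, times = Wo)
  rowj <- rep(base_j, each = Ho)
  colki <- rep(off_i, times = k)
  colkj <- rep(off_j, each = k)
  lin0 <- outer(rowi, colki, "+") + 1L + (outer(rowj, colkj, "+")) * Hp
  k2 <- k * k
  lin <- matrix(0L, nrow(lin0), k2 * C)
  plane <- Hp * Wp
  for (cc in seq_len(C)) {
    lin[, ((cc - 1L) * k2 + 1L):(cc * k2)] <- lin0 + (cc - 1L) * plane
  }
  lin
}

conv2d_fwd <- function(x, W, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x)
  dw <- dim(W)                     # k, k, cin, cout
  k <- dw[1]; cin <- dw[3]; cout <- dw[4]
  stopifnot(d[3] == cin)
  Ho <- conv_out_dim(d[1], k, stride, pad, dilation)
  Wo <- conv_out_dim(d[2], k, stride, pad, dilation)
  xp <- pad_hw(x, pad)
  dp <- dim(xp)
  lin <- im2col_idx(dp[1], dp[2], cin, k, stride, dilation, Ho, Wo)
  patches <- matrix(xp[lin], nrow(lin), ncol(lin))
  y <- patches %*% matrix(W, k * k * cin, cout)
  if (!is.null(b)) y <- sweep(y, 2L, b, "+")
  list(y = array(y, dim = c(Ho, Wo, cout)),
       cache = list(patches = patches, lin = lin, dp = dp, d = d, pad = pad))
}

conv2d_bwd <- function(dy, W, cache) {
  dw <- dim(W)
  k <- dw[1]; cin <- dw[3]; cout <- dw[4]
  ddy <- dim(dy)
  dym <- matrix(dy, ddy[1] * ddy[2], cout)
  dW <- crossprod(cache$patches, dym)
  db <- colSums(dym)
  dpatch <- tcrossprod(dym, matrix(W, k * k * cin, cout))
  dxp <- numeric(prod(cache$dp))
  lin <- cache$lin
  for (cc in seq_len(ncol(lin))) {
    idx <- lin[, cc]
    dxp[idx] <- dxp[idx] + dpatch[, cc]
  }
  dxp <- array(dxp, dim = cache$dp)
  p <- cache$pad; d <- cache$d
  dx <- if (p > 0L) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE] else dxp
  list(dx = dx, dW = array(dW, dim = dw), db = db)
}

# Depthwise convolution: one k x k filter per channel (weights dim k,k,C).
dwconv_fwd <- function(x, W, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x)
  k <- dim(W)[1]; C <- d[3]
  Ho <- conv_out_dim(d[1], k, stride, pad, dilation)
  Wo <- conv_out_dim(d[2], k, stride, pad, dilation)
  xp <- pad_hw(x, pad)
  y <- array(0, dim = c(Ho, Wo, C))
  sel_i <- seq.int(1L, by = stride, length.out = Ho)
  sel_j <- seq.int(1L, by = stride, length.out = Wo)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    oi <- (ki - 1L) * dilation
    oj <- (kj - 1L) * dilation
    sub <- xp[sel_i + oi, sel_j + oj, , drop = FALSE]
    w <- W[ki, kj, ]
    y <- y + sub * rep(w, each = Ho * Wo)
  }
  list(y = y, cache = list(xp = xp, d = d, k = k, stride = stride, pad = pad,
                           dilation = dilation, Ho = Ho, Wo = Wo))
}

dwconv_bwd <- function(dy, W, cache) {
  k <- cache$k; Ho <- cache$Ho; Wo <- cache$Wo
  C <- dim(cache$xp)[3]
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(cache$xp))
  sel_i <- seq.int(1L, by = cache$stride, length.out = Ho)
  sel_j <- seq.int(1L, by = cache$stride, length.out = Wo)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    oi <- (ki - 1L) * cache$dilation
    oj <- (kj - 1L) * cache$dilation
    sub <- cache$xp[sel_i + oi, sel_j + oj, , drop = FALSE]
    dW[ki, kj, ] <- colSums(matrix(sub * dy, Ho * Wo, C))
    w <- W[ki, kj, ]
    dxp[sel_i + oi, sel_j + oj, ] <- dxp[sel_i + oi, sel_j + oj, , drop = FALSE] +
      dy * rep(w, each = Ho * Wo)
  }
  p <- cache$pad; d <- cache$d
  dx <- if (p > 0L) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE] else dxp
  list(dx = dx, dW = dW)
}

maxpool_fwd <- function(x, k = 3L, stride = 1L, pad = 1L) {
  d <- dim(x)
  Ho <- conv_out_dim(d[1], k, stride, pad)
  Wo <- conv_out_dim(d[2], k, stride, pad)
  xp <- pad_hw(x, pad, value = -Inf)
  C <- d[3]
  y <- array(-Inf, dim = c(Ho, Wo, C))
  arg <- array(1L, dim = c(Ho, Wo, C))
  sel_i <- seq.int(1L, by = stride, length.out = Ho)
  sel_j <- seq.int(1L, by = stride, length.out = Wo)
  t <- 0L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    t <- t + 1L
    sub <- xp[sel_i + ki - 1L, sel_j + kj - 1L, , drop = FALSE]
    upd <- sub > y
    y[upd] <- sub[upd]
    arg[upd] <- t
  }
  list(y = y, cache = list(arg = arg, d = d, k = k, stride = stride, pad = pad,
                           dp = dim(xp), Ho = Ho, Wo = Wo))
}

maxpool_bwd <- function(dy, cache) {
  k <- cache$k
  dxp <- array(0, dim = cache$dp)
  sel_i <- seq.int(1L, by = cache$stride, length.out = cache$Ho)
  sel_j <- seq.int(1L, by = cache$stride, length.out = cache$Wo)
  t <- 0L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    t <- t + 1L
    m <- dy * (cache$arg == t)
    dxp[sel_i + ki - 1L, sel_j + kj - 1L, ] <-
      dxp[sel_i + ki - 1L, sel_j + kj - 1L, , drop = FALSE] + m
  }
  p <- cache$pad; d <- cache$d
  if (p > 0L) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE] else dxp
}

# Batch normalisation over the channel axis. Normalisation always uses the
# exponentially tracked population statistics (updated from the per-image
# spatial statistics while training, before the update is applied). With
# single-image batches this preserves image-level contrasts -- e.g. a
# globally yellower leaf -- that per-image statistics would remove, and it
# makes training and inference behave identically.
bn_fwd <- function(x, gamma, beta, rmean, rvar, training = FALSE,
                   eps = 1e-5, momentum = 0.1) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, n, C)
  istd <- 1 / sqrt(rvar + eps)
  xc <- sweep(xm, 2L, rmean)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va
  }
  list(y = array(y, d),
       cache = list(xhat = xhat, istd = istd, d = d, training = FALSE),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$d; n <- d[1] * d[2]; C <- d[3]
  dym <- matrix(dy, n, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  if (cache$training) {
    # full batch-statistics gradient
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$istd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$istd, "*")
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

#' Hard-swish activation
#'
#' `x * relu6(x + 3) / 6`, the piecewise-polynomial swish approximation used
#' by MobileNetV3.
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
hard_swish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

#' Hard-sigmoid activation (`relu6(x + 3) / 6`)
#' @inheritParams hard_swish
#' @return same shape as `x`.
#' @export
hard_sigmoid <- function(x) pmin(pmax(x + 3, 0), 6) / 6

act_fwd <- function(x, type) {
  switch(type,
         relu = pmax(x, 0),
         hswish = hard_swish(x),
         hsigmoid = hard_sigmoid(x),
         sigmoid = 1 / (1 + exp(-x)),
         identity = x,
         stop("unknown activation: ", type))
}

act_bwd <- function(dy, x, type) {
  g <- switch(type,
              relu = (x > 0) + 0,
              hswish = ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6)),
              hsigmoid = ifelse(x > -3 & x < 3, 1 / 6, 0),
              sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
              identity = 1,
              stop("unknown activation: ", type))
  dy * g
}

gap_fwd <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

gap_bwd <- function(dv, d) {
  array(rep(dv, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

linear_fwd <- function(x, W, b) as.vector(crossprod(W, x)) + b

linear_bwd <- function(dy, x, W) {
  list(dx = as.vector(W %*% dy), dW = outer(x, dy), db = dy)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Cross-entropy loss for one sample; returns loss and d(loss)/d(logits).
softmax_ce <- function(logits, label) {
  p <- softmax(logits)
  dlog <- p
  dlog[label] <- dlog[label] - 1
  list(loss = -log(max(p[label], 1e-12)), dlogits = dlog, probs = p)
}
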