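# Multi-scale Adaptive Attention Module (MAAM). Statistical pooling
# (average + max + population standard deviation) along the spatial axis
# gives a per-channel descriptor and along the channel axis a per-position
# descriptor; each is squashed to a sigmoid attention field, and a scalar
# input-dependent gate g blends them: y = x * (g * A_c + (1 - g) * A_s).

.maam_eps <- 1e-12   # inside the sqrt of the standard-deviation pooling

#' Channel descriptor: avg + max + std pooling over the spatial extent
#'
#' For each channel, the spatial average, spatial maximum and spatial
#' population standard deviation are added elementwise.
#'
#' @param x feature map, array `[H, W, C]`.
#' @return numeric vector of length `C`.
#' @export
#' @examples
#' x <- array(c(1, 3, 1, 3), dim = c(2, 2, 1))
#' channel_descriptor(x)   # avg 2 + max 3 + std 1 = 6
channel_descriptor <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || d[1] * d[2] < 1L)
    stop("channel_descriptor: x must be [H, W, C] with H*W >= 1")
  X <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(X)
  mx <- apply(X, 2L, max)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2) + .maam_eps)
  mu + mx + sdv
}

#' Spatial descriptor: avg + max + std pooling across channels
#'
#' Mirror of [channel_descriptor()] with the statistics taken across the
#' channel axis at every spatial position.
#'
#' @param x feature map, array `[H, W, C]`.
#' @return array `[H, W, 1]`.
#' @export
spatial_descriptor <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || d[3] < 1L) stop("spatial_descriptor: x must be [H, W, C]")
  X <- matrix(x, d[1] * d[2], d[3])
  mu <- rowMeans(X)
  mx <- apply(X, 1L, max)
  sdv <- sqrt(rowMeans((X - mu)^2) + .maam_eps)
  array(mu + mx + sdv, dim = c(d[1], d[2], 1L))
}

#' Build a MAAM attention layer
#'
#' The channel pathway is a bottlenecked two-layer transform
#' `C -> make_divisible(C/reduction, 8) -> C` (ReLU between, sigmoid out);
#' the spatial pathway is a single 1x1 convolution on the one-channel
#' descriptor map; the gate is a linear map of the globally averaged input.
#'
#' @param C number of channels the module attends over.
#' @param reduction channel-bottleneck reduction factor (default 12, the
#'   calibrated value; see the complexity profiler).
#' @return an internal layer object usable with [maam_forward()].
#' @export
maam_module <- function(C, reduction = 12) {
  C <- as.integer(C)
  Cr <- make_divisible(C / reduction)
  new_layer("maam", C = C, Cr = Cr, reduction = reduction,
            .children = list(ly_linear(C, Cr),    # channel squeeze
                            ly_linear(Cr, C),    # channel excite
                            ly_linear(1L, 1L),   # 1x1 conv on spatial descriptor
                            ly_linear(C, 1L)))   # gate
}

#' Apply MAAM attention to a feature map
#'
#' @param x array `[H, W, C]`.
#' @param module a layer from [maam_module()]; built fresh (current RNG) if
#'   omitted.
#' @return array of the same shape as `x`.
#' @export
maam_forward <- function(x, module = NULL) {
  d <- dim(x)
  if (is.null(module)) module <- maam_module(d[3])
  if (d[3] != module$C)
    stop("maam_forward: input has ", d[3], " channels, module expects ", module$C)
  nn_fwd(module, x, training = FALSE)$y
}

maam_fwd_impl <- function(layer, x, training) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  X <- matrix(x, HW, C)

  ## channel descriptor
  mu_c <- colMeans(X)
  arg_c <- max.col(t(X), ties.method = "first")
  mx_c <- X[cbind(arg_c, seq_len(C))]
  sd_c <- sqrt(colMeans(sweep(X, 2L, mu_c)^2) + .maam_eps)
  desc_c <- mu_c + mx_c + sd_c

  fc1 <- layer$children[[1]]; fc2 <- layer$children[[2]]
  sc <- layer$children[[3]]; ga <- layer$children[[4]]
  h_pre <- linear_fwd(desc_c, fc1$par$W, fc1$par$b)
  h <- pmax(h_pre, 0)
  a_pre <- linear_fwd(h, fc2$par$W, fc2$par$b)
  Ac <- 1 / (1 + exp(-a_pre))

  ## spatial descriptor
  mu_s <- rowMeans(X)
  arg_s <- max.col(X, ties.method = "first")
  mx_s <- X[cbind(seq_len(HW), arg_s)]
  sd_s <- sqrt(rowMeans((X - mu_s)^2) + .maam_eps)
  desc_s <- mu_s + mx_s + sd_s
  s_pre <- sc$par$W[1, 1] * desc_s + sc$par$b[1]
  As <- 1 / (1 + exp(-s_pre))          # length HW

  ## gate
  v <- colMeans(X)
  g_pre <- linear_fwd(v, ga$par$W, ga$par$b)
  g <- 1 / (1 + exp(-g_pre))

  fld <- g * rep(Ac, each = HW) + (1 - g) * As   # HW x C by recycling columns
  Y <- X * fld
  list(y = array(Y, d),
       cache = list(X = X, d = d, mu_c = mu_c, arg_c = arg_c, sd_c = sd_c,
                    desc_c = desc_c, h_pre = h_pre, h = h, Ac = Ac,
                    mu_s = mu_s, arg_s = arg_s, sd_s = sd_s, desc_s = desc_s,
                    As = As, v = v, g = g, fld = fld),
       layer = layer)
}

maam_bwd_impl <- function(layer, dy, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]
  X <- cache$X
  dY <- matrix(dy, HW, C)
  fc1 <- layer$children[[1]]; fc2 <- layer$children[[2]]
  sc <- layer$children[[3]]; ga <- layer$children[[4]]
  g <- cache$g; Ac <- cache$Ac; As <- cache$As

  dX <- dY * cache$fld
  dF <- dY * X
  dAc <- g * colSums(dF)
  dAs <- (1 - g) * rowSums(dF)
  dg <- sum(dF * (rep(Ac, each = HW) - As))

  ## channel pathway
  da_pre <- dAc * Ac * (1 - Ac)
  r2 <- linear_bwd(da_pre, cache$h, fc2$par$W)
  dh_pre <- r2$dx * (cache$h_pre > 0)
  r1 <- linear_bwd(dh_pre, cache$desc_c, fc1$par$W)
  ddc <- r1$dx
  dX <- dX + matrix(ddc / HW, HW, C, byrow = TRUE)              # avg part
  dX[cbind(cache$arg_c, seq_len(C))] <-
    dX[cbind(cache$arg_c, seq_len(C))] + ddc                    # max part
  dX <- dX + sweep(sweep(X, 2L, cache$mu_c), 2L,
                   ddc / (HW * cache$sd_c), "*")                # std part

  ## spatial pathway
  ds_pre <- dAs * As * (1 - As)
  dWs <- sum(ds_pre * cache$desc_s)
  dbs <- sum(ds_pre)
  dds <- ds_pre * sc$par$W[1, 1]
  dX <- dX + matrix(dds / C, HW, C)                             # avg part
  dX[cbind(seq_len(HW), cache$arg_s)] <-
    dX[cbind(seq_len(HW), cache$arg_s)] + dds                   # max part
  dX <- dX + (X - cache$mu_s) * (dds / (C * cache$sd_s))        # std part

  ## gate pathway
  dg_pre <- dg * g * (1 - g)
  rg <- linear_bwd(dg_pre, cache$v, ga$par$W)
  dX <- dX + matrix(rg$dx / HW, HW, C, byrow = TRUE)

  list(dx = array(dX, d),
       g = list(par = list(),
                children = list(list(par = list(W = r1$dW, b = r1$db), children = list()),
                                list(par = list(W = r2$dW, b = r2$db), children = list()),
                                list(par = list(W = matrix(dWs, 1, 1), b = dbs), children = list()),
                                list(par = list(W = rg$dW, b = rg$db), children = list()))))
}

# ---------------------------------------------------------------------------
# Squeeze-and-Excitation (baseline attention): global average pooling, a
# bottleneck MLP with make_divisible(C/4, 8) squeeze channels, hard-sigmoid
# scaling.

ly_se <- function(C) {
  sq <- make_divisible(C / 4)
  new_layer("se", C = C, sq = sq,
            .children = list(ly_linear(C, sq), ly_linear(sq, C)))
}

se_fwd_impl <- function(layer, x, training) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  X <- matrix(x, HW, C)
  v <- colMeans(X)
  fc1 <- layer$children[[1]]; fc2 <- layer$children[[2]]
  h_pre <- linear_fwd(v, fc1$par$W, fc1$par$b)
  h <- pmax(h_pre, 0)
  a_pre <- linear_fwd(h, fc2$par$W, fc2$par$b)
  a <- hard_sigmoid(a_pre)
  Y <- X * rep(a, each = HW)
  list(y = array(Y, d),
       cache = list(X = X, d = d, v = v, h_pre = h_pre, h = h,
                    a_pre = a_pre, a = a),
       layer = layer)
}

se_bwd_impl <- function(layer, dy, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]
  dY <- matrix(dy, HW, C)
  fc1 <- layer$children[[1]]; fc2 <- layer$children[[2]]
  dX <- dY * rep(cache$a, each = HW)
  da <- colSums(dY * cache$X)
  da_pre <- act_bwd(da, cache$a_pre, "hsigmoid")
  r2 <- linear_bwd(da_pre, cache$h, fc2$par$W)
  dh_pre <- r2$dx * (cache$h_pre > 0)
  r1 <- linear_bwd(dh_pre, cache$v, fc1$par$W)
  dX <- dX + matrix(r1$dx / HW, HW, C, byrow = TRUE)
  list(dx = array(dX, d),
       g = list(par = list(),
                children = list(list(par = list(W = r1$dW, b = r1$db), children = list()),
                                list(par = list(W = r2$dW, b = r2$db), children = list()))))
}
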