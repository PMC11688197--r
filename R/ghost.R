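# Ghost convolution: a cheap primary convolution produces the m = n/s
# "intrinsic" feature maps; the remaining (s-1)*m "ghost" maps are derived
# from them by depthwise d x d filters. Parameter cost drops from
# n*c*k^2 to (n/s)*c*k^2 + (s-1)*(n/s)*d^2, a ratio approaching s.

#' Specify a Ghost convolution
#'
#' @param c input channels (positive integer).
#' @param n output channels; must be divisible by `s`.
#' @param s ghost ratio (integer >= 1). `s = 1` degenerates to a plain
#'   convolution with no ghost maps.
#' @param k primary-convolution kernel size (odd).
#' @param d cheap-operation (depthwise) kernel size (odd).
#' @param stride 1 or 2; applied in the primary convolution only.
#' @param with_norm add batch normalisation after the primary and cheap paths.
#' @param activation one of "identity", "relu", "hswish".
#' @return an object of class `ghost_spec`.
#' @export
#' @examples
#' sp <- ghost_spec(c = 16, n = 32, s = 2)
#' compression_ratio(sp)   # 32/17, the closed form s*c/(c+s-1) when k == d
ghost_spec <- function(c, n, s = 2L, k = 1L, d = 3L, stride = 1L,
                       with_norm = TRUE, activation = "identity") {
  c <- as.integer(c); n <- as.integer(n); s <- as.integer(s)
  k <- as.integer(k); d <- as.integer(d); stride <- as.integer(stride)
  if (c < 1L || n < 1L) stop("ghost_spec: channel counts must be positive")
  if (s < 1L) stop("ghost_spec: ratio s must be >= 1")
  if (n %% s != 0L) stop("ghost_spec: n (", n, ") must be divisible by s (", s, ")")
  if (k %% 2L == 0L || d %% 2L == 0L) stop("ghost_spec: kernels must be odd")
  if (!stride %in% c(1L, 2L)) stop("ghost_spec: stride must be 1 or 2")
  if (!activation %in% c("identity", "relu", "hswish"))
    stop("ghost_spec: unsupported activation '", activation, "'")
  structure(list(c = c, n = n, s = s, k = k, d = d, stride = stride,
                 with_norm = isTRUE(with_norm), activation = activation),
            class = "ghost_spec")
}

#' Parameter compression ratio of a Ghost convolution
#'
#' Ratio of the weights of a standard convolution producing `n` maps to the
#' weights of the Ghost module:
#' \deqn{r_c = \frac{n c k^2}{(n/s)\,c\,k^2 + (s-1)(n/s)\,d^2}}
#' When `k == d` this collapses to the closed form `s*c / (c + s - 1)`,
#' which tends to `s` for wide inputs.
#'
#' @param spec a [ghost_spec()].
#' @return a numeric ratio >= 1.
#' @export
compression_ratio <- function(spec) {
  stopifnot(inherits(spec, "ghost_spec"))
  m <- spec$n / spec$s
  (spec$n * spec$c * spec$k^2) /
    (m * spec$c * spec$k^2 + (spec$s - 1) * m * spec$d^2)
}

#' Build a Ghost convolution layer
#'
#' Instantiates weights (He initialisation, drawn from the current RNG) for
#' the module described by `spec`.
#'
#' @param spec a [ghost_spec()].
#' @return an internal layer object usable with [ghost_forward()].
#' @export
ghost_module <- function(spec) {
  stopifnot(inherits(spec, "ghost_spec"))
  m <- spec$n %/% spec$s
  ch <- list(ly_conv(spec$c, m, spec$k, stride = spec$stride))
  ch[2] <- list(if (spec$with_norm) ly_bn(m) else NULL)
  if (spec$s > 1L) {
    for (j in seq_len(spec$s - 1L)) {
      ch[2L + 2L * j - 1L] <- list(ly_dwconv(m, spec$d))
      ch[2L + 2L * j] <- list(if (spec$with_norm) ly_bn(m) else NULL)
    }
  }
  new_layer("ghost", spec = spec, m = m, .children = ch)
}

#' Run a Ghost convolution forward
#'
#' @param x input feature map, array `[H, W, c]` (or `[c, H, W]`, detected by
#'   matching `spec$c` against the dimensions).
#' @param spec a [ghost_spec()] (a fresh module is built from the current
#'   RNG) or a module from [ghost_module()].
#' @return array `[H', W', n]`: the intrinsic maps followed by the ghost maps.
#' @export
ghost_forward <- function(x, spec) {
  layer <- if (inherits(spec, "ghost_spec")) ghost_module(spec) else spec
  cin <- layer$spec$c
  d <- dim(x)
  if (length(d) != 3L) stop("ghost_forward: x must be a 3-d array")
  if (d[3] != cin && d[1] == cin) x <- aperm(x, c(2, 3, 1))
  if (dim(x)[3] != cin)
    stop("ghost_forward: input has ", d[3], " channels, spec expects ", cin)
  nn_fwd(layer, x, training = FALSE)$y
}

ghost_fwd_impl <- function(layer, x, training) {
  sp <- layer$spec
  caches <- vector("list", length(layer$children))
  r <- nn_fwd(layer$children[[1]], x, training)
  y1 <- r$y; caches[[1]] <- r$cache; layer$children[[1]] <- r$layer
  if (!is.null(layer$children[[2]])) {
    r <- nn_fwd(layer$children[[2]], y1, training)
    y1 <- r$y; caches[[2]] <- r$cache; layer$children[[2]] <- r$layer
  }
  pre1 <- y1
  y1 <- act_fwd(y1, sp$activation)
  segs <- list(y1)
  pres <- vector("list", max(sp$s - 1L, 0L))
  for (j in seq_len(sp$s - 1L)) {
    ic <- 2L + 2L * j - 1L
    r <- nn_fwd(layer$children[[ic]], y1, training)
    gj <- r$y; caches[[ic]] <- r$cache; layer$children[[ic]] <- r$layer
    if (!is.null(layer$children[[ic + 1L]])) {
      r <- nn_fwd(layer$children[[ic + 1L]], gj, training)
      gj <- r$y; caches[[ic + 1L]] <- r$cache; layer$children[[ic + 1L]] <- r$layer
    }
    pres[[j]] <- gj
    segs[[j + 1L]] <- act_fwd(gj, sp$activation)
  }
  ds <- dim(segs[[1]])
  y <- array(0, dim = c(ds[1], ds[2], sp$n))
  for (j in seq_along(segs))
    y[, , ((j - 1L) * layer$m + 1L):(j * layer$m)] <- segs[[j]]
  list(y = y,
       cache = list(children = caches, pre1 = pre1, pres = pres, y1 = y1),
       layer = layer)
}

ghost_bwd_impl <- function(layer, dy, cache) {
  sp <- layer$spec; m <- layer$m
  gs <- vector("list", length(layer$children))
  dy1a <- dy[, , 1:m, drop = FALSE]            # direct (intrinsic) segment
  for (j in seq_len(sp$s - 1L)) {
    ic <- 2L + 2L * j - 1L
    dg <- dy[, , (j * m + 1L):((j + 1L) * m), drop = FALSE]
    dg <- act_bwd(dg, cache$pres[[j]], sp$activation)
    if (!is.null(layer$children[[ic + 1L]])) {
      r <- nn_bwd(layer$children[[ic + 1L]], dg, cache$children[[ic + 1L]])
      dg <- r$dx; gs[[ic + 1L]] <- r$g
    }
    r <- nn_bwd(layer$children[[ic]], dg, cache$children[[ic]])
    gs[[ic]] <- r$g
    dy1a <- dy1a + r$dx
  }
  d1 <- act_bwd(dy1a, cache$pre1, sp$activation)
  if (!is.null(layer$children[[2]])) {
    r <- nn_bwd(layer$children[[2]], d1, cache$children[[2]])
    d1 <- r$dx; gs[[2]] <- r$g
  }
  r <- nn_bwd(layer$children[[1]], d1, cache$children[[1]])
  gs[[1]] <- r$g
  list(dx = r$dx, g = list(par = list(), children = gs))
}
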