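# Layer graph. A layer is a list(kind, ..., par = <named list of arrays>,
# buf = <running statistics>, children = <list of layers>) of class
# "tcsr_layer". nn_fwd()/nn_bwd() implement forward and reverse-mode
# differentiation per kind; nn_params()/nn_set() give a stable traversal
# order used by the optimiser and the enumeration oracle in the tests.

# dot-prefixed formals so field names like `k` or `C` in ... cannot
# partially match them
new_layer <- function(.kind, ..., .par = list(), .buf = list(), .children = list()) {
  structure(c(list(kind = .kind, par = .par, buf = .buf, children = .children),
              list(...)),
            class = "tcsr_layer")
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)

ly_conv <- function(cin, cout, k = 1L, stride = 1L, pad = (k %/% 2L),
                    dilation = 1L, bias = FALSE) {
  if (dilation > 1L) pad <- ((k - 1L) * dilation) %/% 2L
  par <- list(W = he_init(c(k, k, cin, cout), k * k * cin))
  if (bias) par$b <- numeric(cout)
  new_layer("conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
            dilation = dilation, bias = bias, .par = par)
}

ly_dwconv <- function(C, k = 3L, stride = 1L, dilation = 1L) {
  pad <- ((k - 1L) * dilation) %/% 2L
  new_layer("dwconv", C = C, k = k, stride = stride, pad = pad,
            dilation = dilation,
            .par = list(W = he_init(c(k, k, C), k * k)))
}

ly_bn <- function(C) {
  new_layer("bn", C = C,
            .par = list(gamma = rep(1, C), beta = numeric(C)),
            .buf = list(rmean = numeric(C), rvar = rep(1, C)))
}

ly_act <- function(type) new_layer("act", type = type)

ly_maxpool <- function(k = 3L, stride = 1L, pad = 1L)
  new_layer("maxpool", k = k, stride = stride, pad = pad)

ly_gap <- function() new_layer("gap")

ly_linear <- function(cin, cout) {
  new_layer("linear", cin = cin, cout = cout,
            .par = list(W = he_init(c(cin, cout), cin), b = numeric(cout)))
}

ly_dropout <- function(p) new_layer("dropout", p = p)

ly_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "tcsr_layer"))
    ch <- ch[[1]]
  new_layer("seq", .children = ch)
}

# ---------------------------------------------------------------------------
# forward

nn_fwd <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv = {
      r <- conv2d_fwd(x, layer$par$W, layer$par$b, layer$stride, layer$pad,
                      layer$dilation)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    dwconv = {
      r <- dwconv_fwd(x, layer$par$W, layer$stride, layer$pad, layer$dilation)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    bn = {
      r <- bn_fwd(x, layer$par$gamma, layer$par$beta, layer$buf$rmean,
                  layer$buf$rvar, training && !isTRUE(layer$buf$frozen))
      layer$buf$rmean <- r$rmean
      layer$buf$rvar <- r$rvar
      list(y = r$y, cache = r$cache, layer = layer)
    },
    act = list(y = act_fwd(x, layer$type), cache = list(x = x), layer = layer),
    maxpool = {
      r <- maxpool_fwd(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    gap = list(y = gap_fwd(x), cache = list(d = dim(x)), layer = layer),
    linear = list(y = linear_fwd(x, layer$par$W, layer$par$b),
                  cache = list(x = x), layer = layer),
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else list(y = x, cache = list(mask = NULL), layer = layer)
    },
    seq = {
      caches <- vector("list", length(layer$children))
      for (i in seq_along(layer$children)) {
        r <- nn_fwd(layer$children[[i]], x, training)
        x <- r$y
        caches[[i]] <- r$cache
        layer$children[[i]] <- r$layer
      }
      list(y = x, cache = list(children = caches), layer = layer)
    },
    ghost = ghost_fwd_impl(layer, x, training),
    se = se_fwd_impl(layer, x, training),
    maam = maam_fwd_impl(layer, x, training),
    inception = inception_fwd_impl(layer, x, training),
    bneck = bneck_fwd_impl(layer, x, training),
    stop("nn_fwd: unsupported layer kind '", layer$kind, "'")
  )
}

# ---------------------------------------------------------------------------
# backward: returns list(dx, g) with g mirroring the layer (par + children)

nn_bwd <- function(layer, dy, cache) {
  switch(layer$kind,
    conv = {
      r <- conv2d_bwd(dy, layer$par$W, cache)
      g <- list(par = list(W = r$dW), children = list())
      if (layer$bias) g$par$b <- r$db
      list(dx = r$dx, g = g)
    },
    dwconv = {
      r <- dwconv_bwd(dy, layer$par$W, cache)
      list(dx = r$dx, g = list(par = list(W = r$dW), children = list()))
    },
    bn = {
      r <- bn_bwd(dy, layer$par$gamma, cache)
      list(dx = r$dx,
           g = list(par = list(gamma = r$dgamma, beta = r$dbeta), children = list()))
    },
    act = list(dx = act_bwd(dy, cache$x, layer$type),
               g = list(par = list(), children = list())),
    maxpool = list(dx = maxpool_bwd(dy, cache),
                   g = list(par = list(), children = list())),
    gap = list(dx = gap_bwd(dy, cache$d), g = list(par = list(), children = list())),
    linear = {
      r <- linear_bwd(dy, cache$x, layer$par$W)
      list(dx = r$dx, g = list(par = list(W = r$dW, b = r$db), children = list()))
    },
    dropout = {
      dx <- if (is.null(cache$mask)) dy else dy * cache$mask
      list(dx = dx, g = list(par = list(), children = list()))
    },
    seq = {
      gs <- vector("list", length(layer$children))
      for (i in rev(seq_along(layer$children))) {
        r <- nn_bwd(layer$children[[i]], dy, cache$children[[i]])
        dy <- r$dx
        gs[[i]] <- r$g
      }
      list(dx = dy, g = list(par = list(), children = gs))
    },
    ghost = ghost_bwd_impl(layer, dy, cache),
    se = se_bwd_impl(layer, dy, cache),
    maam = maam_bwd_impl(layer, dy, cache),
    inception = inception_bwd_impl(layer, dy, cache),
    bneck = bneck_bwd_impl(layer, dy, cache),
    stop("nn_bwd: unsupported layer kind '", layer$kind, "'")
  )
}

# ---------------------------------------------------------------------------
# parameter traversal (stable order: own par entries, then children in order)

nn_params <- function(layer, path = "net") {
  out <- list()
  for (nm in names(layer$par)) out[[paste0(path, ".", nm)]] <- layer$par[[nm]]
  for (i in seq_along(layer$children)) {
    ch <- layer$children[[i]]
    if (!is.null(ch))
      out <- c(out, nn_params(ch, paste0(path, ".", i)))
  }
  out
}

# grads aligned with nn_params() order, taken from the mirrored g structure
# (composite backward passes keep g$children index-aligned with layer$children)
nn_grads <- function(layer, g) {
  out <- list()
  for (nm in names(layer$par)) out[[length(out) + 1L]] <- g$par[[nm]]
  for (i in seq_along(layer$children)) {
    ch <- layer$children[[i]]
    if (is.null(ch)) next
    out <- c(out, nn_grads(ch, g$children[[i]]))
  }
  out
}

# write a flat numeric vector back into the layer tree
nn_set_flat <- function(layer, theta, pos = 1L) {
  for (nm in names(layer$par)) {
    n <- length(layer$par[[nm]])
    v <- theta[pos:(pos + n - 1L)]
    if (!is.null(dim(layer$par[[nm]]))) dim(v) <- dim(layer$par[[nm]])
    layer$par[[nm]] <- v
    pos <- pos + n
  }
  for (i in seq_along(layer$children)) {
    if (is.null(layer$children[[i]])) next
    r <- nn_set_flat(layer$children[[i]], theta, pos)
    layer$children[[i]] <- r$layer
    pos <- r$pos
  }
  list(layer = layer, pos = pos)
}

# freeze/unfreeze normalisation statistics across a layer tree
set_bn_frozen <- function(layer, frozen = TRUE) {
  if (identical(layer$kind, "bn")) layer$buf$frozen <- frozen
  for (i in seq_along(layer$children)) {
    if (is.null(layer$children[[i]])) next
    layer$children[[i]] <- set_bn_frozen(layer$children[[i]], frozen)
  }
  layer
}

zero_like_g <- function(layer) {
  list(par = lapply(layer$par, function(a) array(0, dim = if (is.null(dim(a))) length(a) else dim(a))),
       children = lapply(layer$children, function(ch) if (is.null(ch)) NULL else zero_like_g(ch)))
}
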