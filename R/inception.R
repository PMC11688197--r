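# Inception expansion: four parallel branches -- 1x1 conv, 3x3 conv,
# 3x3 dilated conv (rate 2), 3x3 max-pool passthrough -- concatenated and
# fused/expanded by a 1x1 Ghost convolution. Used in place of the 1x1
# expansion convolution of the inverted-residual block.

#' Specify an Inception expansion stage
#'
#' @param in_channels input channels.
#' @param branch_channels output channels of each of the three convolutional
#'   branches (the pooling branch passes `in_channels` through unchanged).
#' @param expand_channels channels after the 1x1 Ghost fuse/expand.
#' @param dilation dilation rate of the dilated branch (default 2).
#' @param pool_kernel max-pool kernel (odd, default 3).
#' @param activation "relu" or "hswish".
#' @param ghost_s ghost ratio of the fusing convolution.
#' @return an object of class `inception_spec`.
#' @export
inception_spec <- function(in_channels, branch_channels, expand_channels,
                           dilation = 2L, pool_kernel = 3L,
                           activation = "relu", ghost_s = 2L) {
  stopifnot(in_channels >= 1L, branch_channels >= 1L, expand_channels >= 1L,
            pool_kernel %% 2L == 1L)
  if (!activation %in% c("relu", "hswish"))
    stop("inception_spec: activation must be 'relu' or 'hswish'")
  structure(list(in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 expand_channels = as.integer(expand_channels),
                 dilation = as.integer(dilation),
                 pool_kernel = as.integer(pool_kernel),
                 activation = activation, ghost_s = as.integer(ghost_s)),
            class = "inception_spec")
}

#' @rdname inception_spec
#' @param spec an `inception_spec`.
#' @return `inception_module()`: an internal layer object.
#' @export
inception_module <- function(spec) {
  stopifnot(inherits(spec, "inception_spec"))
  cin <- spec$in_channels; b <- spec$branch_channels; a <- spec$activation
  concat <- 3L * b + cin
  fuse <- ghost_module(ghost_spec(concat, spec$expand_channels, s = spec$ghost_s,
                                  k = 1L, d = 3L, activation = a))
  new_layer("inception", spec = spec, concat = concat,
            .children = list(
              ly_seq(ly_conv(cin, b, 1L), ly_bn(b), ly_act(a)),
              ly_seq(ly_conv(cin, b, 3L), ly_bn(b), ly_act(a)),
              ly_seq(ly_conv(cin, b, 3L, dilation = spec$dilation), ly_bn(b), ly_act(a)),
              ly_seq(ly_maxpool(spec$pool_kernel, 1L, spec$pool_kernel %/% 2L), ly_act(a)),
              fuse))
}

#' Run an Inception expansion forward
#'
#' @param x array `[H, W, in_channels]`.
#' @param spec an [inception_spec()] (fresh weights from the current RNG) or
#'   a module from [inception_module()].
#' @return array `[H, W, expand_channels]`; spatial size is preserved.
#' @export
inception_forward <- function(x, spec) {
  layer <- if (inherits(spec, "inception_spec")) inception_module(spec) else spec
  if (dim(x)[3] != layer$spec$in_channels)
    stop("inception_forward: input has ", dim(x)[3], " channels, spec expects ",
         layer$spec$in_channels)
  nn_fwd(layer, x, training = FALSE)$y
}

inception_fwd_impl <- function(layer, x, training) {
  caches <- vector("list", 5L)
  outs <- vector("list", 4L)
  for (i in 1:4) {
    r <- nn_fwd(layer$children[[i]], x, training)
    outs[[i]] <- r$y; caches[[i]] <- r$cache; layer$children[[i]] <- r$layer
  }
  d <- dim(outs[[1]])
  widths <- vapply(outs, function(o) dim(o)[3], integer(1))
  cc <- array(0, dim = c(d[1], d[2], sum(widths)))
  at <- 0L
  for (i in 1:4) {
    cc[, , (at + 1L):(at + widths[i])] <- outs[[i]]
    at <- at + widths[i]
  }
  r <- nn_fwd(layer$children[[5]], cc, training)
  caches[[5]] <- r$cache; layer$children[[5]] <- r$layer
  list(y = r$y, cache = list(children = caches, widths = widths), layer = layer)
}

inception_bwd_impl <- function(layer, dy, cache) {
  gs <- vector("list", 5L)
  r <- nn_bwd(layer$children[[5]], dy, cache$children[[5]])
  gs[[5]] <- r$g
  dcc <- r$dx
  dx <- NULL
  at <- 0L
  for (i in 1:4) {
    w <- cache$widths[i]
    seg <- dcc[, , (at + 1L):(at + w), drop = FALSE]
    at <- at + w
    rb <- nn_bwd(layer$children[[i]], seg, cache$children[[i]])
    gs[[i]] <- rb$g
    dx <- if (is.null(dx)) rb$dx else dx + rb$dx
  }
  list(dx = dx, g = list(par = list(), children = gs))
}

# ---------------------------------------------------------------------------
# Improved inverted-residual block

#' Configure one (possibly improved) inverted-residual block
#'
#' @param in_channels,expand_channels,out_channels channel plan.
#' @param dw_kernel depthwise kernel, 3 or 5.
#' @param stride 1 or 2.
#' @param attention "none", "SE" or "MAAM".
#' @param nonlinearity "relu" or "hswish".
#' @param expansion_type "conv1x1" (plain expansion) or "inception".
#' @param projection_type "conv1x1" or "ghost".
#' @param branch_channels width of each Inception conv branch (defaults to
#'   `in_channels`; ignored for conv1x1 expansion).
#' @param ghost_s ghost ratio for ghost fuse/projection.
#' @param maam_reduction MAAM channel-bottleneck reduction.
#' @return an object of class `bneck_config`. A residual connection exists
#'   iff `stride == 1` and `in_channels == out_channels`; when
#'   `expand_channels == in_channels` the block has no expansion stage.
#' @export
bneck_config <- function(in_channels, expand_channels, out_channels,
                         dw_kernel = 3L, stride = 1L, attention = "none",
                         nonlinearity = "relu", expansion_type = "conv1x1",
                         projection_type = "conv1x1",
                         branch_channels = in_channels,
                         ghost_s = 2L, maam_reduction = 12) {
  if (!dw_kernel %in% c(3L, 5L)) stop("bneck_config: dw_kernel must be 3 or 5")
  if (!stride %in% c(1L, 2L)) stop("bneck_config: stride must be 1 or 2")
  if (!attention %in% c("none", "SE", "MAAM"))
    stop("bneck_config: attention must be none/SE/MAAM")
  if (!expansion_type %in% c("conv1x1", "inception"))
    stop("bneck_config: bad expansion_type")
  if (!projection_type %in% c("conv1x1", "ghost"))
    stop("bneck_config: bad projection_type")
  structure(list(in_channels = as.integer(in_channels),
                 expand_channels = as.integer(expand_channels),
                 out_channels = as.integer(out_channels),
                 dw_kernel = as.integer(dw_kernel), stride = as.integer(stride),
                 attention = attention, nonlinearity = nonlinearity,
                 expansion_type = expansion_type,
                 projection_type = projection_type,
                 branch_channels = as.integer(branch_channels),
                 ghost_s = as.integer(ghost_s),
                 maam_reduction = maam_reduction),
            class = "bneck_config")
}

#' @rdname bneck_config
#' @param cfg a `bneck_config`.
#' @return `bneck_module()`: an internal layer object.
#' @export
bneck_module <- function(cfg) {
  stopifnot(inherits(cfg, "bneck_config"))
  cin <- cfg$in_channels; ce <- cfg$expand_channels; co <- cfg$out_channels
  a <- cfg$nonlinearity
  expansion <- NULL
  if (ce != cin) {
    expansion <- if (cfg$expansion_type == "inception") {
      inception_module(inception_spec(cin, cfg$branch_channels, ce,
                                      activation = a, ghost_s = cfg$ghost_s))
    } else {
      ly_seq(ly_conv(cin, ce, 1L), ly_bn(ce), ly_act(a))
    }
  }
  attention <- switch(cfg$attention,
                      none = NULL,
                      SE = ly_se(ce),
                      MAAM = maam_module(ce, cfg$maam_reduction))
  projection <- if (cfg$projection_type == "ghost" && !is.null(expansion) &&
                    co %% cfg$ghost_s == 0L) {
    ghost_module(ghost_spec(ce, co, s = cfg$ghost_s, k = 1L, d = 3L,
                            activation = "identity"))
  } else {
    ly_seq(ly_conv(ce, co, 1L), ly_bn(co))
  }
  new_layer("bneck", cfg = cfg,
            residual = (cfg$stride == 1L && cin == co),
            .children = list(expansion,
                            ly_dwconv(ce, cfg$dw_kernel, cfg$stride),
                            ly_bn(ce), ly_act(a),
                            attention, projection))
}

#' Run an improved inverted-residual block forward
#'
#' @param x array `[H, W, in_channels]`.
#' @param cfg a [bneck_config()] (fresh weights from the current RNG) or a
#'   module from [bneck_module()].
#' @return array `[ceil(H/stride), ceil(W/stride), out_channels]`.
#' @export
bneck_forward <- function(x, cfg) {
  layer <- if (inherits(cfg, "bneck_config")) bneck_module(cfg) else cfg
  if (dim(x)[3] != layer$cfg$in_channels)
    stop("bneck_forward: input has ", dim(x)[3], " channels, config expects ",
         layer$cfg$in_channels)
  nn_fwd(layer, x, training = FALSE)$y
}

bneck_fwd_impl <- function(layer, x, training) {
  caches <- vector("list", 6L)
  y <- x
  for (i in 1:6) {
    ch <- layer$children[[i]]
    if (is.null(ch)) next
    r <- nn_fwd(ch, y, training)
    y <- r$y; caches[[i]] <- r$cache; layer$children[[i]] <- r$layer
  }
  if (layer$residual) y <- y + x
  list(y = y, cache = list(children = caches), layer = layer)
}

bneck_bwd_impl <- function(layer, dy, cache) {
  gs <- vector("list", 6L)
  dres <- if (layer$residual) dy else NULL
  for (i in 6:1) {
    ch <- layer$children[[i]]
    if (is.null(ch)) next
    r <- nn_bwd(ch, dy, cache$children[[i]])
    dy <- r$dx; gs[[i]] <- r$g
  }
  if (!is.null(dres)) dy <- dy + dres
  list(dx = dy, g = list(par = list(), children = gs))
}
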