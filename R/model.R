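# Network presets: the MobileNetV3-Small baseline, TCSRNet (Inception
# expansion + Ghost projection + MAAM), and the ablation grid between them.
# A model is list(config, net) of class "tcsr_model"; the config is the
# single source of truth for the builder and the complexity profiler.

# Published MobileNetV3-Small bottleneck schedule:
# in, expand, out, dw kernel, SE?, nonlinearity, stride.
mnv3_small_schedule <- function() {
  rows <- list(
    c(16, 16, 16, 3, 1, 0, 2),
    c(16, 72, 24, 3, 0, 0, 2),
    c(24, 88, 24, 3, 0, 0, 1),
    c(24, 96, 40, 5, 1, 1, 2),
    c(40, 240, 40, 5, 1, 1, 1),
    c(40, 240, 40, 5, 1, 1, 1),
    c(40, 120, 48, 5, 1, 1, 1),
    c(48, 144, 48, 5, 1, 1, 1),
    c(48, 288, 96, 5, 1, 1, 2),
    c(96, 576, 96, 5, 1, 1, 1),
    c(96, 576, 96, 5, 1, 1, 1))
  lapply(rows, function(r) list(in_ch = r[1], exp_ch = r[2], out_ch = r[3],
                                k = r[4], se = r[5] == 1,
                                nl = if (r[6] == 1) "hswish" else "relu",
                                stride = r[7]))
}

# Input resolution of each block at a 224 x 224 input; indexes the per-stage
# Inception branch-width factors.
.block_res224 <- c(112, 56, 28, 28, 14, 14, 14, 14, 14, 7, 7)

#' Calibrated Inception branch-width factors
#'
#' Branch width of the three convolutional Inception branches as a fraction
#' of the block's input channels, per feature-map resolution stage (at a
#' 224 input). The shipped values are the result of the documented
#' complexity calibration (see [calibrate_defaults()]).
#' @return named numeric vector (names are stage resolutions).
#' @export
default_width_factors <- function() c("56" = 1.375, "28" = 1, "14" = 0.75, "7" = 0.875)

branch_width <- function(cin, factor) max(2L, 2L * as.integer(round(factor * cin / 2)))

#' Declarative model configuration
#'
#' @param name preset name (informational).
#' @param blocks list of [bneck_config()] objects; adjacent blocks must chain
#'   (`out_channels` of block i equals `in_channels` of block i+1).
#' @param num_classes classifier width (default 10 curing stages).
#' @param input_size nominal square input size; must be a multiple of 32.
#' @param dropout classifier dropout rate in `[0, 1)`.
#' @return object of class `model_config`. The stem (3 to 16 channels, 3x3
#'   stride 2, hard-swish) and head (1x1 conv to 576, global pooling, 1024
#'   hidden units, classifier) follow the MobileNetV3-Small design.
#' @export
model_config <- function(name, blocks, num_classes = 10L, input_size = 224L,
                         dropout = 0.2) {
  stopifnot(num_classes >= 2L, dropout >= 0, dropout < 1)
  if (input_size %% 32L != 0L || input_size < 32L)
    stop("model_config: input_size must be a positive multiple of 32")
  for (i in seq_along(blocks)) {
    if (!inherits(blocks[[i]], "bneck_config")) stop("blocks must be bneck_config")
    if (i > 1L && blocks[[i]]$in_channels != blocks[[i - 1L]]$out_channels)
      stop("model_config: block ", i, " does not chain (", blocks[[i]]$in_channels,
           " != ", blocks[[i - 1L]]$out_channels, ")")
  }
  structure(list(name = name, blocks = blocks,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), dropout = dropout,
                 stem_ch = 16L, head_conv_ch = 576L, head_hidden = 1024L),
            class = "model_config")
}

baseline_config <- function(num_classes = 10L) {
  blocks <- lapply(mnv3_small_schedule(), function(r)
    bneck_config(r$in_ch, r$exp_ch, r$out_ch, r$k, r$stride,
                 attention = if (r$se) "SE" else "none",
                 nonlinearity = r$nl))
  model_config("mobilenetv3-small", blocks, num_classes)
}

tcsrnet_config <- function(num_classes = 10L, ghost_s = 2L, maam_reduction = 12,
                           width_factors = default_width_factors(),
                           attention_everywhere = FALSE) {
  sched <- mnv3_small_schedule()
  blocks <- vector("list", length(sched))
  for (i in seq_along(sched)) {
    r <- sched[[i]]
    has_exp <- r$exp_ch != r$in_ch
    att <- if (r$se || (attention_everywhere && has_exp)) "MAAM" else "none"
    blocks[[i]] <- bneck_config(
      r$in_ch, r$exp_ch, r$out_ch, r$k, r$stride,
      attention = att, nonlinearity = r$nl,
      expansion_type = if (has_exp) "inception" else "conv1x1",
      projection_type = if (has_exp) "ghost" else "conv1x1",
      branch_channels = if (has_exp)
        branch_width(r$in_ch, width_factors[[as.character(.block_res224[i])]])
      else r$in_ch,
      ghost_s = ghost_s, maam_reduction = maam_reduction)
  }
  model_config("tcsrnet", blocks, num_classes)
}

ablation_config <- function(name, num_classes = 10L) {
  sched <- mnv3_small_schedule()
  wf <- default_width_factors()
  mk <- function(inception, ghost, att_kind) {
    blocks <- vector("list", length(sched))
    for (i in seq_along(sched)) {
      r <- sched[[i]]
      has_exp <- r$exp_ch != r$in_ch
      blocks[[i]] <- bneck_config(
        r$in_ch, r$exp_ch, r$out_ch, r$k, r$stride,
        attention = if (r$se) att_kind else "none",
        nonlinearity = r$nl,
        expansion_type = if (inception && has_exp) "inception" else "conv1x1",
        projection_type = if (ghost && has_exp) "ghost" else "conv1x1",
        branch_channels = if (inception && has_exp)
          branch_width(r$in_ch, wf[[as.character(.block_res224[i])]])
        else r$in_ch)
    }
    model_config(name, blocks, num_classes)
  }
  switch(name,
         "conv+SE" = mk(FALSE, FALSE, "SE"),
         "ghost+SE" = mk(FALSE, TRUE, "SE"),
         "ghost+MAAM" = mk(FALSE, TRUE, "MAAM"),
         "inception+ghost+SE" = mk(TRUE, TRUE, "SE"),
         "inception+ghost+MAAM" = mk(TRUE, TRUE, "MAAM"),
         stop("unknown ablation variant '", name, "'; valid: ",
              paste(ablation_names(), collapse = ", ")))
}

#' Names of the ablation-grid variants
#'
#' The five component-toggle combinations spanning baseline to TCSRNet.
#' @return character vector.
#' @export
ablation_names <- function() {
  c("conv+SE", "ghost+SE", "ghost+MAAM", "inception+ghost+SE",
    "inception+ghost+MAAM")
}

# ---------------------------------------------------------------------------
# builders

build_net <- function(cfg) {
  layers <- list(ly_conv(3L, cfg$stem_ch, 3L, stride = 2L),
                 ly_bn(cfg$stem_ch), ly_act("hswish"))
  for (b in cfg$blocks) layers[[length(layers) + 1L]] <- bneck_module(b)
  last <- cfg$blocks[[length(cfg$blocks)]]$out_channels
  classifier <- ly_linear(cfg$head_hidden, cfg$num_classes)
  classifier$par$W <- classifier$par$W * 0.1   # small initial logits
  layers <- c(layers, list(
    ly_conv(last, cfg$head_conv_ch, 1L), ly_bn(cfg$head_conv_ch), ly_act("hswish"),
    ly_gap(),
    ly_linear(cfg$head_conv_ch, cfg$head_hidden), ly_act("hswish"),
    ly_dropout(cfg$dropout),
    classifier))
  ly_seq(layers)
}

new_model <- function(cfg) {
  structure(list(config = cfg, net = build_net(cfg)), class = "tcsr_model")
}

#' Build a network preset
#'
#' `build_tcsrnet()` constructs the full improved model: every bottleneck
#' with an expansion stage uses the four-branch Inception expansion and a
#' Ghost projection, and MAAM replaces SE wherever the baseline had it.
#' `build_baseline()` constructs canonical MobileNetV3-Small.
#' `ablation_variant()` builds one of the five component-toggle variants
#' named by [ablation_names()] (the last one equals `build_tcsrnet()`).
#' Weights are drawn from the current RNG; call `set.seed()` first for
#' reproducible initialisation.
#'
#' @param num_classes number of output classes (>= 2).
#' @param ghost_s ghost ratio of fuse and projection convolutions.
#' @param maam_reduction MAAM channel-bottleneck reduction factor.
#' @param width_factors per-stage Inception branch-width factors, see
#'   [default_width_factors()].
#' @param attention_everywhere also place MAAM on the two baseline blocks
#'   that had no SE (off by default, matching the baseline placement).
#' @return an object of class `tcsr_model`.
#' @export
build_tcsrnet <- function(num_classes = 10L, ghost_s = 2L, maam_reduction = 12,
                          width_factors = default_width_factors(),
                          attention_everywhere = FALSE) {
  new_model(tcsrnet_config(num_classes, ghost_s, maam_reduction,
                           width_factors, attention_everywhere))
}

#' @rdname build_tcsrnet
#' @export
build_baseline <- function(num_classes = 10L) new_model(baseline_config(num_classes))

#' @rdname build_tcsrnet
#' @param name ablation variant name, one of [ablation_names()].
#' @export
ablation_variant <- function(name, num_classes = 10L)
  new_model(ablation_config(name, num_classes))

# logits for one image (H, W, 3 array in [0, 1])
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L)
    stop("model_forward: expected an H x W x 3 array")
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("model_forward: spatial dims must be multiples of 32, got ",
         d[1], " x ", d[2])
  nn_fwd(model$net, x, training)
}

#' Per-layer weight shapes of a model
#'
#' Named list (stable traversal order) of the dimensions of every learnable
#' array; useful for structural-equivalence checks between presets.
#' @param model a `tcsr_model`.
#' @return named list of integer vectors.
#' @export
model_shapes <- function(model) {
  lapply(nn_params(model$net), function(a) if (is.null(dim(a))) length(a) else dim(a))
}

# ---------------------------------------------------------------------------
# config (de)serialisation: plain YAML

#' Read or write a model configuration
#'
#' Model configurations round-trip through a structured YAML file; rebuilding
#' from a serialised config yields identical weight shapes.
#'
#' @param cfg a `model_config`.
#' @param path file path.
#' @return `read_model_config()` returns a `model_config`.
#' @export
write_model_config <- function(cfg, path) {
  lst <- list(name = cfg$name, num_classes = cfg$num_classes,
              input_size = cfg$input_size, dropout = cfg$dropout,
              blocks = lapply(cfg$blocks, function(b) unclass(b)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lst <- yaml::read_yaml(path)
  blocks <- lapply(lst$blocks, function(b)
    bneck_config(b$in_channels, b$expand_channels, b$out_channels,
                 b$dw_kernel, b$stride, b$attention, b$nonlinearity,
                 b$expansion_type, b$projection_type, b$branch_channels,
                 b$ghost_s, b$maam_reduction))
  model_config(lst$name, blocks, lst$num_classes, lst$input_size, lst$dropout)
}

#' Build a model from a preset name or config file
#'
#' @param preset one of "tcsrnet", "baseline", an ablation name from
#'   [ablation_names()], or a path to a YAML config.
#' @param num_classes classifier width.
#' @return a `tcsr_model`.
#' @export
build_preset <- function(preset, num_classes = 10L) {
  if (file.exists(preset) && grepl("\\.ya?ml$", preset))
    return(new_model(read_model_config(preset)))
  switch(preset,
         tcsrnet = build_tcsrnet(num_classes),
         baseline = ,
         "mobilenetv3-small" = build_baseline(num_classes),
         ablation_variant(preset, num_classes))
}
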