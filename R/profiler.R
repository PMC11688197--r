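# Parameter and FLOP profiler.
#
# Counting convention (fixed by calibrating the baseline preset against its
# published complexity, then frozen for every model):
#   * one multiply-accumulate = one FLOP (convolutions, linear layers);
#   * bias additions: 1 per output element;
#   * batch normalisation: 2 per element (scale and shift);
#   * ReLU, sigmoid, hard-sigmoid: 1 per element; hard-swish: 2 per element
#     (the clipped shift and the product);
#   * pooling (max, average, global, and each statistical-pooling pass):
#     1 per input element;
#   * elementwise products/additions (attention re-weighting, residual
#     additions, gated fusion): 1 per element.
# Parameters count every learnable array (conv/linear weights and biases,
# normalisation scale and shift); running statistics are excluded.

flop_convention <- function() {
  paste("MACs counted as FLOPs; bias 1/elem; batchnorm 2/elem;",
        "relu/sigmoid/hard-sigmoid 1/elem; hard-swish 2/elem;",
        "pooling 1/input elem; elementwise ops 1/elem")
}

act_cost <- function(type) if (identical(type, "hswish")) 2 else if (identical(type, "identity")) 0 else 1

# Recursive walk. `sh` is c(H, W, C) with H = W = 1 for vectors.
# Returns list(rows = list of (name, params, flops), sh = output shape).
profile_layer <- function(layer, sh, name) {
  H <- sh[1]; W <- sh[2]; C <- sh[3]
  row <- function(p, f, nm = name, out = sh)
    list(rows = list(list(name = nm, params = p, flops = f)), sh = out)
  switch(layer$kind,
    conv = {
      k <- layer$k
      Ho <- conv_out_dim(H, k, layer$stride, layer$pad, layer$dilation)
      Wo <- conv_out_dim(W, k, layer$stride, layer$pad, layer$dilation)
      p <- k * k * layer$cin * layer$cout + if (layer$bias) layer$cout else 0
      f <- k * k * layer$cin * layer$cout * Ho * Wo +
        if (layer$bias) layer$cout * Ho * Wo else 0
      row(p, f, out = c(Ho, Wo, layer$cout))
    },
    dwconv = {
      k <- layer$k
      Ho <- conv_out_dim(H, k, layer$stride, layer$pad, layer$dilation)
      Wo <- conv_out_dim(W, k, layer$stride, layer$pad, layer$dilation)
      row(k * k * layer$C, k * k * layer$C * Ho * Wo, out = c(Ho, Wo, layer$C))
    },
    bn = row(2 * layer$C, 2 * C * H * W),
    act = row(0, act_cost(layer$type) * C * H * W),
    maxpool = {
      Ho <- conv_out_dim(H, layer$k, layer$stride, layer$pad)
      Wo <- conv_out_dim(W, layer$k, layer$stride, layer$pad)
      row(0, C * H * W, out = c(Ho, Wo, C))
    },
    gap = row(0, C * H * W, out = c(1, 1, C)),
    linear = row(layer$cin * layer$cout + layer$cout,
                 layer$cin * layer$cout + layer$cout,
                 out = c(1, 1, layer$cout)),
    dropout = row(0, 0),
    seq = {
      rows <- list()
      for (i in seq_along(layer$children)) {
        r <- profile_layer(layer$children[[i]], sh, paste0(name, ".", i))
        rows <- c(rows, r$rows)
        sh <- r$sh
      }
      list(rows = rows, sh = sh)
    },
    ghost = {
      sp <- layer$spec; m <- layer$m
      rows <- list()
      r <- profile_layer(layer$children[[1]], sh, paste0(name, ".primary"))
      rows <- c(rows, r$rows); shp <- r$sh
      if (!is.null(layer$children[[2]])) {
        r <- profile_layer(layer$children[[2]], shp, paste0(name, ".bn"))
        rows <- c(rows, r$rows)
      }
      fA <- act_cost(sp$activation) * m * shp[1] * shp[2]
      rows <- c(rows, list(list(name = paste0(name, ".act"), params = 0, flops = fA)))
      for (j in seq_len(sp$s - 1L)) {
        ic <- 2L + 2L * j - 1L
        r <- profile_layer(layer$children[[ic]], shp, paste0(name, ".cheap", j))
        rows <- c(rows, r$rows)
        if (!is.null(layer$children[[ic + 1L]])) {
          r <- profile_layer(layer$children[[ic + 1L]], shp, paste0(name, ".cheapbn", j))
          rows <- c(rows, r$rows)
        }
        rows <- c(rows, list(list(name = paste0(name, ".cheapact", j),
                                  params = 0, flops = fA)))
      }
      list(rows = rows, sh = c(shp[1], shp[2], sp$n))
    },
    se = {
      sq <- layer$sq
      f <- C * H * W +                       # global average pool
        (C * sq + sq) + sq +                 # squeeze + relu
        (sq * C + C) + C +                   # excite + hard-sigmoid
        C * H * W                            # re-weighting
      row(C * sq + sq + sq * C + C, f)
    },
    maam = {
      Cr <- layer$Cr; HW <- H * W
      f <- 3 * C * HW + 2 * C +                         # channel pools + adds
        (C * Cr + Cr) + Cr + (Cr * C + C) + C +         # channel MLP
        3 * C * HW + 2 * HW +                           # spatial pools + adds
        HW + HW + HW +                                  # 1x1 conv + bias + sigmoid
        C * HW + C + 1 + 1 +                            # gate
        3 * C * HW + C + HW                             # gated fusion + re-weighting
      p <- (C * Cr + Cr) + (Cr * C + C) + 2 + (C + 1)
      row(p, f)
    },
    inception = {
      rows <- list()
      widths <- integer(4)
      for (i in 1:4) {
        r <- profile_layer(layer$children[[i]], sh, paste0(name, ".branch", i))
        rows <- c(rows, r$rows)
        widths[i] <- r$sh[3]
      }
      r <- profile_layer(layer$children[[5]], c(H, W, sum(widths)),
                         paste0(name, ".fuse"))
      list(rows = c(rows, r$rows), sh = r$sh)
    },
    bneck = {
      rows <- list()
      nm <- c("expand", "dw", "dwbn", "dwact", "attention", "project")
      sh0 <- sh
      for (i in 1:6) {
        ch <- layer$children[[i]]
        if (is.null(ch)) next
        r <- profile_layer(ch, sh, paste0(name, ".", nm[i]))
        rows <- c(rows, r$rows)
        sh <- r$sh
      }
      if (layer$residual)
        rows <- c(rows, list(list(name = paste0(name, ".residual"), params = 0,
                                  flops = sh[1] * sh[2] * sh[3])))
      list(rows = rows, sh = sh)
    },
    stop("profiler: unsupported layer kind '", layer$kind, "' at ", name)
  )
}

#' Count learnable parameters by enumerating weight arrays
#'
#' Sums the lengths of every learnable array in the model (convolution and
#' linear weights and biases, normalisation scale and shift); running
#' statistics are excluded.
#'
#' @param model a `tcsr_model` (or any internal layer object).
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  layer <- if (inherits(model, "tcsr_model")) model$net else model
  sum(vapply(nn_params(layer), length, numeric(1)))
}

#' Count FLOPs for one forward pass
#'
#' Per-layer operation counts under the documented convention (see
#' [profile_model()]), summed over the network at the given square input
#' size. Deterministic: independent of weight values.
#'
#' @param model a `tcsr_model`.
#' @param input_size square input edge in pixels (>= 32, multiple of 32).
#' @return numeric FLOP total.
#' @export
count_flops <- function(model, input_size = model$config$input_size) {
  profile_model(model, input_size)$flops_total
}

#' Profile a model's complexity
#'
#' Computes the parameter count and the per-forward-pass FLOPs with a
#' per-layer breakdown. FLOPs follow a fixed, documented convention
#' (multiply-accumulates counted as FLOPs; batchnorm 2/element; ReLU-family
#' activations 1/element and hard-swish 2/element; pooling 1/input element;
#' elementwise operations 1/element; bias additions counted), calibrated
#' once against the baseline preset's published complexity and frozen.
#'
#' @param model a `tcsr_model`.
#' @param input_size square input edge in pixels (multiple of 32).
#' @return object of class `complexity_report` with fields
#'   `parameters_total`, `parameters_millions`, `flops_total`,
#'   `flops_millions`, `input_size`, `convention` and a `per_layer`
#'   data frame.
#' @export
#' @examples
#' \donttest{
#' rep <- profile_model(build_baseline(10))
#' rep$parameters_millions   # 1.528106
#' }
profile_model <- function(model, input_size = model$config$input_size) {
  stopifnot(inherits(model, "tcsr_model"))
  if (input_size < 32L || input_size %% 32L != 0L)
    stop("profile_model: input_size must be a multiple of 32, >= 32")
  r <- profile_layer(model$net, c(input_size, input_size, 3), "net")
  per <- data.frame(name = vapply(r$rows, `[[`, "", "name"),
                    params = vapply(r$rows, `[[`, 0, "params"),
                    flops = vapply(r$rows, `[[`, 0, "flops"),
                    stringsAsFactors = FALSE)
  pt <- sum(per$params); ft <- sum(per$flops)
  structure(list(parameters_total = pt,
                 parameters_millions = pt / 1e6,
                 flops_total = ft,
                 flops_millions = ft / 1e6,
                 input_size = as.integer(input_size),
                 convention = flop_convention(),
                 per_layer = per,
                 model_name = model$config$name),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Complexity report:", x$model_name, "@", x$input_size, "x", x$input_size, "\n")
  cat(sprintf("  parameters: %d (%.6f M)\n", x$parameters_total, x$parameters_millions))
  cat(sprintf("  FLOPs:      %.0f (%.3f M)\n", x$flops_total, x$flops_millions))
  cat("  convention:", x$convention, "\n")
  invisible(x)
}

#' Calibration of the free architecture hyperparameters
#'
#' The Inception/Ghost/MAAM internals leave a few free hyperparameters
#' (ghost ratio `s`, MAAM reduction `r`, per-stage Inception branch-width
#' factors). This grid search selects the shipped defaults
#' (`s = 2`, `r = 12`, width factors `c(56: 11/8, 28: 1, 14: 3/4, 7: 7/8)`)
#' lexicographically: first the parameter distance beyond the printed
#' precision (three decimals in millions; parameters are convention-free),
#' then the FLOP distance among parameter matches. Rebuilds a model per
#' grid point; run with a reduced grid for a quick check.
#'
#' @param target_params,target_flops calibration targets (absolute counts).
#' @param ghost_s,reductions,widths grid axes.
#' @param input_size profiling input size.
#' @return data frame of grid points, parameters, FLOPs and loss, sorted
#'   best first.
#' @export
calibrate_defaults <- function(target_params = 1749000, target_flops = 158.136e6,
                               ghost_s = c(2L, 3L), reductions = c(8, 12, 16),
                               widths = list(default_width_factors(),
                                             c("56" = 1, "28" = 1, "14" = 1, "7" = 1),
                                             c("56" = 0.5, "28" = 0.5, "14" = 0.5, "7" = 0.5)),
                               input_size = 224L) {
  out <- list()
  for (s in ghost_s) for (r in reductions) for (wi in seq_along(widths)) {
    m <- try(build_tcsrnet(10L, s, r, widths[[wi]]), silent = TRUE)
    if (inherits(m, "try-error")) next
    pr <- profile_model(m, input_size)
    # parameter miss beyond the printed 3-decimal precision, in millions
    par_loss <- max(abs(pr$parameters_total - target_params) / 1e6 - 0.0005, 0)
    flop_loss <- abs(pr$flops_total - target_flops) / 1e6
    out[[length(out) + 1L]] <- data.frame(
      ghost_s = s, reduction = r, width_set = wi,
      params = pr$parameters_total, flops_millions = pr$flops_millions,
      param_loss = par_loss, flop_loss = flop_loss)
  }
  res <- do.call(rbind, out)
  res[order(res$param_loss, res$flop_loss), ]
}
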