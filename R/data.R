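# Dataset I/O, augmentation, and the synthetic curing-stage leaf renderer.
#
# The real curing-barn corpus is not publicly deposited, so the renderer is
# the canonical test fixture: it draws an elliptical leaf with a main vein
# and laterals whose colour tracks the yellowing fraction (green -> yellow
# -> orange), whose desaturation/speckle/shrink track the drying fraction,
# and whose veins lighten with the vein-whiteness parameter, plus
# barn-imaging artefacts (lighting gradients, steam-like blur, sensor
# noise). It is NOT biologically calibrated; it encodes only the quantified
# stage fractions.

# Per-stage appearance standard: yellowing rises through stages 1-4,
# drying through 4-10, dry/wet-bulb temperatures are metadata only.
.stage_table <- data.frame(
  stage = 1:10,
  yellowing = c(0.30, 0.70, 0.95, 1.00, 1, 1, 1, 1, 1, 1),
  drying = c(0.00, 0.05, 0.10, 0.30, 0.50, 0.70, 0.90, 0.95, 0.97, 1.00),
  vein_white = c(0.00, 0.10, 0.30, 0.70, 0.70, 0.75, 0.80, 0.85, 0.90, 1.00),
  curl = c(0.00, 0.05, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80),
  dry_bulb = c(36, 38, 40, 42, 44, 46, 50, 54, 60, 68),
  wet_bulb = c(35, 36, 37, 37, 37, 38, 38, 38, 40, 42))

#' Appearance parameters of a curing stage
#'
#' Quantified rendering parameters distilled from the ten-stage flue-curing
#' standard: the yellowing fraction rises through stages 1-4 (~0.3, 0.7,
#' ~1, 1), the drying fraction through stages 4-10 (~0.3 ... 1), veins
#' whiten in late stages, and the dry/wet-bulb barn temperatures ride along
#' as metadata (not rendered).
#'
#' @param stage integer in 1..10.
#' @return object of class `stage_appearance` with fields `stage`,
#'   `yellowing_fraction`, `drying_fraction`, `vein_whiteness`,
#'   `curl_amount`, `dry_bulb_C`, `wet_bulb_C`.
#' @export
#' @examples
#' stage_appearance(1)$yellowing_fraction   # 0.3
#' stage_appearance(10)$drying_fraction     # 1
stage_appearance <- function(stage) {
  if (length(stage) != 1L || is.na(stage) || stage < 1 || stage > 10 ||
      stage != round(stage))
    stop("stage_appearance: stage must be an integer in 1..10")
  r <- .stage_table[stage, ]
  structure(list(stage = as.integer(stage),
                 yellowing_fraction = r$yellowing,
                 drying_fraction = r$drying,
                 vein_whiteness = r$vein_white,
                 curl_amount = r$curl,
                 dry_bulb_C = r$dry_bulb,
                 wet_bulb_C = r$wet_bulb),
            class = "stage_appearance")
}

#' Render a synthetic leaf image for a curing stage
#'
#' Draws one leaf on a dark background at `size` x `size` pixels. The shape,
#' lighting, speckle and blur are perturbed from the current RNG (or from
#' `seed` if given), so a fixed seed yields a bit-identical image.
#'
#' @param appearance a [stage_appearance()].
#' @param seed optional integer seed.
#' @param size output edge length in pixels (default 224).
#' @return numeric array `[size, size, 3]`, values in `[0, 1]`.
#' @export
render_leaf_image <- function(appearance, seed = NULL, size = 224L) {
  stopifnot(inherits(appearance, "stage_appearance"))
  if (!is.null(seed)) set.seed(seed)
  yf <- appearance$yellowing_fraction
  df <- appearance$drying_fraction
  vw <- appearance$vein_whiteness
  cl <- appearance$curl_amount

  g <- seq(-1, 1, length.out = size)
  X <- matrix(g, size, size, byrow = TRUE)    # x to the right
  Y <- matrix(g, size, size)                  # y downward

  th <- stats::rnorm(1, 0, 0.25)
  cx <- stats::rnorm(1, 0, 0.06); cy <- stats::rnorm(1, 0, 0.06)
  xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
  yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
  a <- 0.74 * (1 - 0.12 * cl) * stats::runif(1, 0.92, 1.05)
  b <- 0.46 * (1 - 0.30 * cl) * stats::runif(1, 0.9, 1.1)
  ang <- atan2(yr, xr)
  wobble <- 1 + 0.05 * sin(5 * ang + stats::runif(1, 0, 2 * pi)) +
    0.04 * df * sin(9 * ang + stats::runif(1, 0, 2 * pi))
  rad <- (xr / a)^2 + (yr / b)^2
  leaf <- rad <= wobble

  ## base colour: green -> yellow with yellowing, then toward brown with drying
  green <- c(0.18, 0.46, 0.12)
  yellow <- c(0.82, 0.70, 0.12)
  brown <- c(0.48, 0.33, 0.16)
  base <- (1 - yf) * green + yf * yellow
  base <- (1 - 0.75 * df) * base + 0.75 * df * brown

  ## veins: main vein along the major axis + lateral veins
  mainv <- abs(yr) < 0.018 & abs(xr) < a
  latv <- matrix(FALSE, size, size)
  nlat <- 6L
  for (i in seq_len(nlat)) {
    x0 <- -a + (2 * a) * i / (nlat + 1)
    slope <- stats::runif(1, 0.45, 0.75) * sample(c(-1, 1), 1)
    latv <- latv | (abs((yr - slope * (xr - x0)) * cos(atan(slope))) < 0.008 &
                    sign(yr) == sign(slope) & abs(yr) < b)
  }
  vein <- (mainv | latv) & leaf
  vcol <- (1 - vw) * (base * 0.85) + vw * c(0.93, 0.90, 0.82)

  img <- array(0, dim = c(size, size, 3))
  bg <- 0.05 + 0.02 * stats::runif(1)
  for (ch in 1:3) {
    plane <- matrix(bg * stats::runif(1, 0.8, 1.2), size, size)
    plane[leaf] <- base[ch]
    plane[vein] <- vcol[ch]
    img[, , ch] <- plane
  }

  ## drying speckle: brown patches appear with the drying fraction
  if (df > 0) {
    sp <- matrix(stats::runif(size * size), size, size)
    blob <- EBImage::gblur(sp, sigma = 3)
    spk <- leaf & (blob > stats::quantile(blob[leaf], 1 - 0.45 * df))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[spk] <- 0.6 * plane[spk] + 0.4 * brown[ch] * stats::runif(1, 0.7, 1)
      img[, , ch] <- plane
    }
  }

  ## lighting gradient and steam-like blur
  gdir <- stats::runif(1, 0, 2 * pi)
  light <- 1 + 0.12 * (cos(gdir) * X + sin(gdir) * Y)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * light
  sig <- stats::runif(1, 0.4, 1.2)
  img <- EBImage::gblur(img, sigma = sig)
  img <- img + array(stats::rnorm(length(img), 0, 0.012), dim = dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic folder-per-class dataset
#'
#' Writes `n_per_stage` PNG renders per requested stage into subfolders
#' named after the stages, plus a `manifest.csv` (filename, stage, seed).
#' Fully reproducible: the per-image seeds are drawn once from `seed`.
#'
#' @param out_dir output directory; must be empty unless `overwrite`.
#' @param n_per_stage images per stage (>= 1).
#' @param seed integer master seed.
#' @param stages which stages to render (default 1:10).
#' @param size image edge length.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest data frame.
#' @export
generate_dataset <- function(out_dir, n_per_stage, seed = 1L, stages = 1:10,
                             size = 224L, overwrite = FALSE) {
  stopifnot(n_per_stage >= 1L, all(stages %in% 1:10))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop("generate_dataset: ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(stages) * n_per_stage)
  manifest <- data.frame(filename = character(), stage = integer(),
                         seed = integer())
  k <- 0L
  for (st in stages) {
    sub <- file.path(out_dir, sprintf("%02d", st))
    dir.create(sub, showWarnings = FALSE)
    app <- stage_appearance(st)
    for (i in seq_len(n_per_stage)) {
      k <- k + 1L
      img <- render_leaf_image(app, seed = seeds[k], size = size)
      fn <- file.path(sprintf("%02d", st), sprintf("leaf_%02d_%04d.png", st, i))
      png::writePNG(img, file.path(out_dir, fn))
      manifest <- rbind(manifest,
                        data.frame(filename = fn, stage = st, seed = seeds[k]))
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a folder-per-class image dataset
#'
#' Classes are the subdirectories of `root` (after descending into `split`
#' if given), ordered lexicographically; images are decoded as RGB and
#' resized to `input_size` x `input_size`. Unreadable files are skipped with
#' a warning naming the path; empty class folders warn; a root with no
#' class folders is an error.
#'
#' @param root dataset root directory.
#' @param split optional subdirectory ("train", "val", "test") under `root`.
#' @param input_size square resize target (default 224).
#' @return object of class `tcsr_dataset`: list with `images` (list of
#'   `[input_size, input_size, 3]` arrays in `[0, 1]`), `labels` (0-based
#'   integer vector), `class_names`, and a `manifest` data frame recording
#'   the file-to-label mapping.
#' @export
load_dataset <- function(root, split = NULL, input_size = 224L) {
  dir <- if (is.null(split)) root else file.path(root, split)
  if (!dir.exists(dir)) stop("load_dataset: no such directory: ", dir)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("load_dataset: no class folders under ", dir)
  images <- list(); labels <- integer(); files <- character()
  for (ci in seq_along(classes)) {
    fl <- sort(list.files(file.path(dir, classes[ci]),
                          pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (length(fl) == 0L) {
      warning("load_dataset: empty class folder ", classes[ci])
      next
    }
    for (f in fl) {
      img <- tryCatch(read_image_rgb(f, input_size), error = function(e) NULL)
      if (is.null(img)) {
        warning("load_dataset: skipping unreadable file ", f)
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci - 1L)
      files <- c(files, f)
    }
  }
  structure(list(images = images, labels = labels, class_names = classes,
                 manifest = data.frame(filename = files, label = labels,
                                       class_name = classes[labels + 1L])),
            class = "tcsr_dataset")
}

# decode any supported image as [H, W, 3] in [0, 1], resized square
read_image_rgb <- function(path, input_size) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 2L) img <- EBImage::rgbImage(img, img, img)
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  if (any(dim(img)[1:2] != input_size))
    img <- EBImage::resize(img, w = input_size, h = input_size)
  # EBImage stores (x, y, channel); transpose to (row, col, channel)
  arr <- aperm(EBImage::imageData(img), c(2, 1, 3))
  pmin(pmax(arr, 0), 1)
}

#' Subset a dataset
#'
#' @param dset a `tcsr_dataset`.
#' @param idx integer indices of samples to keep.
#' @param relabel drop unused classes and renumber labels 0..K'-1.
#' @return a `tcsr_dataset`.
#' @export
dataset_subset <- function(dset, idx, relabel = FALSE) {
  d <- dset
  d$images <- dset$images[idx]
  d$labels <- dset$labels[idx]
  d$manifest <- dset$manifest[idx, , drop = FALSE]
  if (relabel) {
    keep <- sort(unique(d$labels))
    d$class_names <- dset$class_names[keep + 1L]
    d$labels <- match(d$labels, keep) - 1L
    d$manifest$label <- d$labels
  }
  d
}

# ---------------------------------------------------------------------------
# augmentation

#' Augmentation policy
#'
#' Mirrors the barn-imaging augmentation taxonomy: geometric transforms
#' (affine, rotation, flips) for camera placement variation, filtering
#' (noise, blur, median denoise) for steam/dust, and colour jitter
#' (brightness, saturation, contrast) for light-source variation. Each call
#' to [augment()] stacks `compose_depth` randomly chosen transform families.
#'
#' @param p_affine,p_rotate,p_hflip,p_vflip geometric transform probabilities.
#' @param rotate_range max absolute rotation (degrees).
#' @param shear_range,scale_range affine shear (radians) and scale bounds.
#' @param p_noise,noise_sd additive Gaussian noise.
#' @param p_blur,blur_sigma_range Gaussian blur.
#' @param p_denoise median-filter denoising.
#' @param p_color,brightness_range,saturation_range,contrast_range colour jitter.
#' @param compose_depth number of transform families stacked per image (1-3).
#' @return an `augmentation_policy` object.
#' @export
augmentation_policy <- function(p_affine = 0.3, p_rotate = 0.5, p_hflip = 0.5,
                                p_vflip = 0.2, rotate_range = 25,
                                shear_range = 0.15, scale_range = c(0.9, 1.1),
                                p_noise = 0.4, noise_sd = 0.02,
                                p_blur = 0.3, blur_sigma_range = c(0.3, 1.2),
                                p_denoise = 0.1,
                                p_color = 0.8, brightness_range = 0.12,
                                saturation_range = 0.25, contrast_range = 0.2,
                                compose_depth = 2L) {
  p <- c(p_affine, p_rotate, p_hflip, p_vflip, p_noise, p_blur, p_denoise, p_color)
  if (any(p < 0 | p > 1)) stop("augmentation_policy: probabilities must be in [0,1]")
  stopifnot(compose_depth >= 1L, compose_depth <= 3L)
  structure(as.list(environment()), class = "augmentation_policy")
}

#' Apply stacked augmentations to one image
#'
#' Deterministic under a fixed `seed`. A policy with all probabilities zero
#' returns the input unchanged; all transforms preserve image size and mode.
#'
#' @param image array `[H, W, 3]` in `[0, 1]`.
#' @param policy an [augmentation_policy()].
#' @param seed optional integer seed.
#' @return augmented array of identical shape.
#' @export
augment <- function(image, policy = augmentation_policy(), seed = NULL) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!is.null(seed)) set.seed(seed)
  fams <- sample(c("geometric", "filtering", "color"), policy$compose_depth)
  for (f in fams) image <- switch(f,
                                  geometric = .aug_geometric(image, policy),
                                  filtering = .aug_filter(image, policy),
                                  color = .aug_color(image, policy))
  pmin(pmax(image, 0), 1)
}

# EBImage works in (x, y, c); keep (row, col, c) outside
.to_eb <- function(a) EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
.from_eb <- function(img) aperm(EBImage::imageData(img), c(2, 1, 3))

.aug_geometric <- function(a, p) {
  d <- dim(a)
  if (stats::runif(1) < p$p_hflip) a <- a[, d[2]:1, , drop = FALSE]
  if (stats::runif(1) < p$p_vflip) a <- a[d[1]:1, , , drop = FALSE]
  if (stats::runif(1) < p$p_rotate) {
    ang <- stats::runif(1, -p$rotate_range, p$rotate_range)
    img <- EBImage::rotate(.to_eb(a), ang, output.dim = c(d[2], d[1]), bg.col = 0)
    a <- .from_eb(img)
  }
  if (stats::runif(1) < p$p_affine) {
    sc <- stats::runif(1, p$scale_range[1], p$scale_range[2])
    sh <- stats::runif(1, -p$shear_range, p$shear_range)
    m <- matrix(c(sc, sh, 0,
                  0, sc, 0), 3, 2)
    img <- EBImage::affine(.to_eb(a), m, output.dim = c(d[2], d[1]), bg.col = 0)
    a <- .from_eb(img)
  }
  a
}

.aug_filter <- function(a, p) {
  if (stats::runif(1) < p$p_blur) {
    sig <- stats::runif(1, p$blur_sigma_range[1], p$blur_sigma_range[2])
    a <- EBImage::gblur(a, sigma = sig)
  }
  if (stats::runif(1) < p$p_noise)
    a <- a + array(stats::rnorm(length(a), 0, p$noise_sd), dim = dim(a))
  if (stats::runif(1) < p$p_denoise)
    a <- .from_eb(EBImage::medianFilter(.to_eb(pmin(pmax(a, 0), 1)), 2L))
  a
}

.aug_color <- function(a, p) {
  if (stats::runif(1) < p$p_color) {
    br <- stats::runif(1, -p$brightness_range, p$brightness_range)
    sat <- stats::runif(1, 1 - p$saturation_range, 1 + p$saturation_range)
    ct <- stats::runif(1, 1 - p$contrast_range, 1 + p$contrast_range)
    lum <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    for (ch in 1:3)
      a[, , ch] <- ((1 - sat) * lum + sat * a[, , ch] + br - 0.5) * ct + 0.5
  }
  a
}
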