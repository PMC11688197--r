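test_that("stage appearance tracks the ten-stage curing standard", {
  expect_equal(stage_appearance(1)$yellowing_fraction, 0.3)
  expect_equal(stage_appearance(2)$yellowing_fraction, 0.7)
  expect_equal(stage_appearance(4)$drying_fraction, 0.3)
  expect_equal(stage_appearance(10)$drying_fraction, 1.0)
  expect_equal(stage_appearance(1)$dry_bulb_C, 36)
  expect_equal(stage_appearance(10)$dry_bulb_C, 68)
  for (k in 1:3)
    expect_lte(stage_appearance(k)$yellowing_fraction,
               stage_appearance(k + 1)$yellowing_fraction)
  for (k in 1:9)
    expect_lte(stage_appearance(k)$drying_fraction,
               stage_appearance(k + 1)$drying_fraction)
  expect_error(stage_appearance(0), "1..10")
  expect_error(stage_appearance(11), "1..10")
})

test_that("the renderer is seed-deterministic with the contracted geometry", {
  a <- stage_appearance(3)
  i1 <- render_leaf_image(a, seed = 5, size = 64)
  i2 <- render_leaf_image(a, seed = 5, size = 64)
  expect_identical(i1, i2)
  expect_equal(dim(i1), c(64, 64, 3))
  expect_true(all(i1 >= 0 & i1 <= 1))
  expect_false(identical(i1, render_leaf_image(a, seed = 6, size = 64)))
})

test_that("early stages render greener than the yellowed stage 4", {
  gr <- function(stage) mean(vapply(1:10, function(s) {
    im <- render_leaf_image(stage_appearance(stage), seed = s, size = 64)
    mean(im[, , 2]) - mean(im[, , 1])
  }, numeric(1)))
  expect_gt(gr(1), gr(4))
})

test_that("generate_dataset writes a reproducible folder-per-class corpus", {
  td1 <- tempfile(); td2 <- tempfile()
  m1 <- generate_dataset(td1, 3, seed = 9, size = 48)
  m2 <- generate_dataset(td2, 3, seed = 9, size = 48)
  expect_equal(nrow(m1), 30)
  expect_identical(m1, m2)
  expect_identical(sort(unique(m1$stage)), 1:10)
  expect_identical(sort(list.dirs(td1, recursive = FALSE, full.names = FALSE)),
                   sprintf("%02d", 1:10))
  f <- m1$filename[1]
  expect_identical(png::readPNG(file.path(td1, f)), png::readPNG(file.path(td2, f)))
  expect_error(generate_dataset(td1, 1, seed = 1), "not empty")
  unlink(c(td1, td2), recursive = TRUE)
})

test_that("load_dataset resizes to square, skips unreadables, errors on no classes", {
  td <- tempfile()
  dir.create(file.path(td, "a"), recursive = TRUE)
  dir.create(file.path(td, "b"))
  # non-square image: must come out input_size x input_size
  png::writePNG(array(runif(30 * 20 * 3), c(30, 20, 3)), file.path(td, "a", "x.png"))
  png::writePNG(array(runif(48 * 48 * 3), c(48, 48, 3)), file.path(td, "b", "y.png"))
  writeLines("not a png", file.path(td, "b", "broken.png"))
  ds <- suppressWarnings(load_dataset(td, input_size = 32))
  expect_equal(length(ds$images), 2)
  expect_equal(dim(ds$images[[1]]), c(32, 32, 3))
  expect_equal(ds$class_names, c("a", "b"))
  expect_equal(ds$labels, c(0L, 1L))
  expect_warning(load_dataset(td, input_size = 32), "broken")
  empty <- tempfile(); dir.create(empty)
  expect_error(load_dataset(empty), "no class folders")
  unlink(c(td, empty), recursive = TRUE)
})

test_that("dataset counts follow the folder layout", {
  td <- tempfile()
  generate_dataset(td, 2, seed = 3, size = 48)
  ds <- load_dataset(td, input_size = 32)
  expect_equal(length(ds$images), 20)            # 10 classes x 2
  expect_identical(sort(unique(ds$labels)), 0:9)
  sub <- dataset_subset(ds, which(ds$labels %in% c(0L, 9L)), relabel = TRUE)
  expect_identical(sort(unique(sub$labels)), 0:1)
  expect_equal(sub$class_names, c("01", "10"))
  unlink(td, recursive = TRUE)
})

test_that("augmentation honours identity, determinism and flip involution", {
  set.seed(60)
  img <- render_leaf_image(stage_appearance(2), seed = 1, size = 48)
  off <- augmentation_policy(p_affine = 0, p_rotate = 0, p_hflip = 0, p_vflip = 0,
                             p_noise = 0, p_blur = 0, p_denoise = 0, p_color = 0)
  expect_identical(augment(img, off, seed = 2), img)
  pol <- augmentation_policy()
  expect_identical(augment(img, pol, seed = 7), augment(img, pol, seed = 7))
  expect_false(identical(augment(img, pol, seed = 7), augment(img, pol, seed = 8)))
  flip <- augmentation_policy(p_affine = 0, p_rotate = 0, p_hflip = 1, p_vflip = 0,
                              p_noise = 0, p_blur = 0, p_denoise = 0, p_color = 0,
                              compose_depth = 3)
  expect_equal(augment(augment(img, flip, seed = 1), flip, seed = 2), img)
})

test_that("augmentations preserve dimensions and value range", {
  set.seed(61)
  img <- render_leaf_image(stage_appearance(6), seed = 2, size = 48)
  pol <- augmentation_policy(p_affine = 1, p_rotate = 1, p_noise = 1, p_blur = 1,
                             p_color = 1, compose_depth = 3)
  for (s in 1:5) {
    a <- augment(img, pol, seed = s)
    expect_equal(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("probability validation rejects out-of-range policies", {
  expect_error(augmentation_policy(p_hflip = 1.2), "probabilities")
  expect_error(augmentation_policy(compose_depth = 0), "compose_depth")
})
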