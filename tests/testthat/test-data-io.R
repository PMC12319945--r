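test_that("area and length conversions follow the physical definitions", {
  expect_equal(mm2_to_px(1.0, 1000.0), 1.0)
  expect_equal(mm2_to_px(2.0, 1.76), 2e6 / 1.76^2)  # ~645,661 px
  expect_equal(mm2_to_px(0, 123), 0)
  expect_error(mm2_to_px(1, 0), "um_per_px")
  # round trip to within 1e-9 relative error
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.01, 50); u <- runif(1, 0.1, 50)
    expect_equal(px_to_mm2(mm2_to_px(a, u), u), a, tolerance = 1e-9)
    expect_equal(mm_to_px(a, u) * u / 1000, a, tolerance = 1e-9)
  }
  expect_equal(um_to_px(20, 1.76), 20 / 1.76)
})

test_that("read_section round-trips PNG images with metadata attached", {
  img <- random_image(100, 80, seed = 2)
  sec <- fb_section(img, um_per_px = 1.76, section_index = 3L)
  path <- tempfile(fileext = ".png")
  write_section(sec, path)
  back <- read_section(path, um_per_px = 1.76, section_index = 3L)
  expect_equal(dim(back$image), c(100, 80, 3))
  expect_equal(back$um_per_px, 1.76)
  expect_equal(back$section_index, 3L)
  expect_lt(max(abs(back$image - img)), 1 / 255)
})

test_that("downsampling updates the pixel size multiplicatively", {
  img <- random_image(64, 64, seed = 3)
  path <- tempfile(fileext = ".png")
  write_section(fb_section(img, 0.44), path)
  sec <- read_section(path, um_per_px = 0.44, downsample = 4L)
  expect_equal(sec$um_per_px, 1.76)
  expect_equal(dim(sec$image)[1:2], c(16L, 16L))
})

test_that("16-bit TIFF scales to [0,1] and grayscale promotes with a warning", {
  m <- matrix(seq(0, 1, length.out = 48 * 48), 48, 48)
  m[1, 1] <- 1  # ensure full-scale value present
  path <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(t(m)), path, bits.per.sample = 16L)
  expect_warning(sec <- read_section(path, um_per_px = 2), "promoted")
  expect_equal(max(sec$image), 1.0, tolerance = 1e-4)
  expect_equal(dim(sec$image)[3], 3L)
})

test_that("label masks round-trip through PNG", {
  lab <- matrix(0L, 20, 30)
  lab[3:8, 4:9] <- 1L
  lab[12:18, 20:28] <- 2L
  path <- tempfile(fileext = ".png")
  write_label_mask(lab, path)
  expect_identical(read_label_mask(path), lab)
})

test_that("polygon rasterization and vectorization agree on area within 2%", {
  set.seed(9)
  for (i in 1:5) {
    cx <- runif(1, 25, 40); cy <- runif(1, 25, 40)
    rad <- runif(1, 8, 15)
    ang <- seq(0, 2 * pi, length.out = 40)[-40]
    poly <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
    mask <- polygon_to_mask(poly, c(64, 64))
    back <- mask_to_polygon(mask)
    mask2 <- polygon_to_mask(back, c(64, 64))
    expect_lt(abs(sum(mask2) - sum(mask)) / sum(mask), 0.02)
  }
})

test_that("patch sampling is deterministic and labels patches by overlap", {
  cfg <- tiny_synth_cfg()
  s <- generate_section(cfg, 0)
  a <- sample_patches(s$section, s$annotations, n = 8, seed = 4, patch_size = 64)
  b <- sample_patches(s$section, s$annotations, n = 8, seed = 4, patch_size = 64)
  expect_identical(a$centers, b$centers)
  expect_identical(a$patches, b$patches)
  expect_equal(dim(a$patches), c(8, 64, 64, 3))
  expect_false(is.null(a$pixel_labels))
  expect_error(sample_patches(s$section, NULL, n = 0), "n must be")
  # a patch centered inside a bundle is labelled fiber
  reg <- s$annotations$regions[[1]]
  ctr <- round(reg$centroid_rc)
  p <- sample_patches(s$section, s$annotations, seed = 1, patch_size = 64,
                      centers = matrix(ctr, 1, 2))
  expect_identical(p$class_labels, "fiber")
  # unlabeled sections yield NULL pixel labels and NA classes
  u <- sample_patches(s$section, NULL, n = 3, seed = 2, patch_size = 64)
  expect_null(u$pixel_labels)
  expect_true(all(is.na(u$class_labels)))
})

test_that("sections smaller than a patch are padded by reflection", {
  sec <- flat_section(40, 40)
  p <- sample_patches(sec, NULL, n = 2, seed = 1, patch_size = 64)
  expect_equal(dim(p$patches)[2:3], c(64, 64))
  expect_true(all(p$patches == 0.5))
})
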