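test_that("generator validates its configuration", {
  expect_error(synth_config(image_height_px = 0), "dimensions")
  expect_error(synth_config(um_per_px = -1), "um_per_px")
  expect_error(synth_config(fiber_area_fraction_range = c(0.3, 0.2)), "low < high")
  expect_error(generate_section(tiny_synth_cfg(), 99), "out of range")
})

test_that("a bundle-free configuration yields background and confounders only", {
  cfg <- tiny_synth_cfg(n_bundles = 0L)
  s <- generate_section(cfg, 0)
  expect_length(s$annotations$regions, 0)
  expect_gt(sum(s$confounder_mask), 0)
  expect_equal(dim(s$section$image), c(192, 192, 3))
})

test_that("bright-pixel fraction inside every bundle region is in the configured range", {
  cfg <- synth_config(image_height_px = 256L, image_width_px = 256L,
                      um_per_px = 20, n_sections = 2L, n_bundles = 3L,
                      fiber_area_fraction_range = c(0.02, 0.20), seed = 13L)
  for (i in 0:1) {
    s <- generate_section(cfg, i)
    expect_gt(length(s$annotations$regions), 0)
    for (r in s$annotations$regions) {
      bf <- bright_fraction(s$section$image, r$mask)
      expect_gte(bf, 0.02)
      expect_lte(bf, 0.20)
    }
  }
})

test_that("a fixed seed fixes every output byte", {
  cfg <- tiny_synth_cfg(seed = 7L)
  a <- generate_section(cfg, 0)
  b <- generate_section(cfg, 0)
  expect_identical(a$section$image, b$section$image)
  expect_identical(a$white_matter_mask, b$white_matter_mask)
  expect_identical(a$confounder_mask, b$confounder_mask)
  expect_identical(lapply(a$annotations$regions, `[[`, "mask"),
                   lapply(b$annotations$regions, `[[`, "mask"))
})

test_that("confounder and bundle masks are disjoint", {
  cfg <- tiny_synth_cfg(seed = 21L, n_bundles = 3L)
  s <- generate_section(cfg, 0)
  bundles <- Reduce(`|`, lapply(s$annotations$regions, `[[`, "mask"))
  expect_equal(sum(bundles & s$confounder_mask), 0)
})

test_that("stacks keep bundle identity with bounded centroid drift", {
  cfg <- synth_config(image_height_px = 192L, image_width_px = 192L,
                      um_per_px = 20, n_sections = 3L, n_bundles = 2L,
                      drift_mm_per_section = 0.3, seed = 5L)
  stack <- generate_stack(cfg)
  expect_length(stack, 3)
  for (i in 2:3) {
    prev <- stack[[i - 1]]$annotations$regions
    cur <- stack[[i]]$annotations$regions
    ids_prev <- vapply(prev, `[[`, integer(1), "bundle_id")
    for (r in cur) {
      k <- match(r$bundle_id, ids_prev)
      if (is.na(k)) next
      d_mm <- sqrt(sum((r$centroid_rc - prev[[k]]$centroid_rc)^2)) *
        cfg$um_per_px / 1000
      expect_lte(d_mm, 0.3 + 1e-9)
    }
  }
})

test_that("a single-section stack has no continuity pairs", {
  stack <- generate_stack(tiny_synth_cfg(n_sections = 1L))
  expect_length(stack, 1)
})

test_that("bundle count per section follows the termination schedule", {
  cfg <- synth_config(image_height_px = 192L, image_width_px = 192L,
                      um_per_px = 20, n_sections = 5L, n_bundles = 3L, seed = 1L)
  sched <- bundleseg:::synth_schedule(cfg)
  stack <- generate_stack(cfg)
  for (i in seq_along(stack)) {
    expected <- sum(vapply(sched$bundles, function(b) {
      (i - 1) >= b$section_start && (i - 1) <= b$section_end
    }, logical(1)))
    expect_equal(length(stack[[i]]$annotations$regions), expected)
  }
  # the schedule terminates one bundle before the last section
  ends <- vapply(sched$bundles, `[[`, integer(1), "section_end")
  expect_true(any(ends < cfg$n_sections - 1L))
})

test_that("withholding labels keeps images and ground truth", {
  cfg <- tiny_synth_cfg(n_sections = 3L)
  stack <- generate_stack(cfg, labeled_sections = 0L)
  expect_false(is.null(stack[[1]]$annotations))
  expect_null(stack[[2]]$annotations)
  expect_false(is.null(stack[[2]]$truth))
  expect_equal(dim(stack[[2]]$section$image), c(192, 192, 3))
})

test_that("synthetic stacks round-trip through the on-disk layout", {
  dir <- tempfile()
  cfg <- tiny_synth_cfg(n_sections = 2L)
  stack <- generate_stack(cfg)
  man <- write_synthetic_stack(stack, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man2), 2)
  sec <- read_section(man2$image[1], um_per_px = man2$um_per_px[1])
  expect_equal(dim(sec$image), dim(stack[[1]]$section$image))
  lab <- read_label_mask(man2$mask[1])
  expect_identical(lab > 0, annotations_to_labelmask(
    stack[[1]]$annotations, c(192, 192)) > 0)
})
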