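test_that("region extraction computes areas, centroids and border distances", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:19, 10:19] <- TRUE           # 100 px
  mask[30:33, 30:34] <- TRUE           # 20 px
  tissue <- matrix(TRUE, 40, 40)
  rs <- regions_from_mask(mask, um_per_px = 100, tissue_mask = tissue)
  expect_length(rs$regions, 2)
  areas <- sort(vapply(rs$regions, `[[`, numeric(1), "area_mm2"))
  expect_equal(areas, c(px_to_mm2(20, 100), px_to_mm2(100, 100)))
  big <- rs$regions[[which.max(vapply(rs$regions, `[[`, numeric(1), "area_mm2"))]]
  expect_equal(unname(big$centroid_xy_px), c(mean(9:18), mean(9:18)))
})

test_that("morphology filter survivors match brute-force enumeration", {
  for (seed in 1:50) {
    w <- random_regionset(seed)
    min_area <- runif(1, 0.01, 0.12)   # mm^2 at 100 um/px: 1-12k px
    min_bd <- runif(1, 0, 0.4)         # mm
    got <- morphology_filter(w$regions, min_area_mm2 = min_area,
                             min_border_dist_mm = min_bd,
                             tissue_mask = w$tissue)
    keep_brute <- vapply(w$regions$regions, function(r) {
      area_ok <- sum(r$mask) * 100^2 / 1e6 >= min_area
      bd <- brute_min_dist_px(r$mask, !w$tissue) * 100 / 1000
      area_ok && bd >= min_bd
    }, logical(1))
    expect_equal(length(got$regions), sum(keep_brute))
    # survivor masks byte-identical to inputs
    kept_in <- w$regions$regions[keep_brute]
    for (i in seq_along(got$regions)) {
      expect_identical(got$regions[[i]]$mask, kept_in[[i]]$mask)
    }
  }
})

test_that("continuity filter survivors match brute-force distances", {
  for (seed in 1:50) {
    w <- random_regionset(seed + 500)
    ref <- bundleseg:::with_seed(seed + 900, {
      m <- matrix(FALSE, 64, 64)
      if (runif(1) > 0.1) {
        r0 <- sample(1:52, 1); c0 <- sample(1:52, 1)
        m[r0:(r0 + 11), c0:(c0 + 11)] <- TRUE
      }
      m
    })
    max_d <- runif(1, 0.1, 2)  # mm at 100 um/px
    got <- continuity_filter(w$regions, ref, max_dist_mm = max_d)
    keep_brute <- vapply(w$regions$regions, function(r) {
      d <- brute_min_dist_px(r$mask, ref) * 100 / 1000
      is.finite(d) && d <= max_d
    }, logical(1))
    expect_equal(length(got$regions), sum(keep_brute))
  }
})

test_that("an empty reference removes every region with a recorded reason", {
  w <- random_regionset(3)
  got <- continuity_filter(w$regions, matrix(FALSE, 64, 64))
  expect_length(got$regions, 0)
  expect_equal(length(attr(got, "removed")), length(w$regions$regions))
  expect_error(continuity_filter(w$regions, matrix(FALSE, 10, 10)),
               "resolution")
})

test_that("the printed filter rules behave on constructed regions", {
  # areas 1.5 and 2.5 mm^2 at 1000 um/px = 1.5 and 2.5 px... use 100 um/px
  mask <- matrix(FALSE, 80, 80)
  mask[10:24, 10:19] <- TRUE    # 150 px = 1.5 mm^2 at 100 um/px
  mask[40:64, 40:49] <- TRUE    # 250 px = 2.5 mm^2
  tissue <- matrix(TRUE, 80, 80)
  rs <- regions_from_mask(mask, 100, tissue_mask = tissue)
  out <- morphology_filter(rs, min_area_mm2 = 2.0, min_border_dist_mm = 0)
  expect_length(out$regions, 1)
  expect_equal(out$regions[[1]]$area_mm2, 2.5)
  # a region touching the tissue boundary is removed
  tissue2 <- matrix(FALSE, 80, 80); tissue2[5:75, 5:75] <- TRUE
  mask2 <- matrix(FALSE, 80, 80); mask2[5:30, 5:30] <- TRUE
  rs2 <- regions_from_mask(mask2, 100, tissue_mask = tissue2)
  out2 <- morphology_filter(rs2, min_area_mm2 = 0, min_border_dist_mm = 0.5,
                            tissue_mask = tissue2)
  expect_length(out2$regions, 0)
  # empty input stays empty
  rs0 <- regions_from_mask(matrix(FALSE, 20, 20), 100)
  expect_length(morphology_filter(rs0)$regions, 0)
})

test_that("stack building recovers constructed translations", {
  set.seed(8)
  base <- matrix(0.02, 200, 200)
  # tissue block with a dark ventricle-like cavity
  base[30:170, 30:170] <- 0.3
  base[95:105, 95:105] <- 0.01
  img1 <- array(rep(base, 3), c(200, 200, 3))
  shift <- 30L
  base2 <- matrix(0.02, 200, 200)
  base2[(30:170) + shift, 30:170] <- 0.3
  base2[(95:105) + shift, 95:105] <- 0.01
  img2 <- array(rep(base2, 3), c(200, 200, 3))
  s1 <- fb_section(img1, 20, section_index = 0L)
  s2 <- fb_section(img2, 20, section_index = 1L)
  pm <- function(s) structure(list(probs = matrix(0, 200, 200)),
                              class = "fb_probmap")
  stk <- build_stack(list(s1, s2), list(pm(s1), pm(s2)), downsample = 10L)
  expect_equal(unname(stk$offsets[[1]]), c(0, 0))
  expect_lte(abs(unname(stk$offsets[[2]]["row"]) - (-3)), 1)
  # identical sections give zero relative offset
  stk2 <- build_stack(list(s1, s1), list(pm(s1), pm(s1)))
  expect_equal(unname(stk2$offsets[[2]]), c(0, 0))
  expect_error(build_stack(list(s1), list(pm(s1))), ">= 2 sections")
})

test_that("mixed section sizes pad to the maximum padded dimensions", {
  imgA <- array(0.3, c(100, 120, 3)); imgA[50:52, 50:52, ] <- 0.01
  imgB <- array(0.3, c(80, 90, 3)); imgB[40:42, 40:42, ] <- 0.01
  sA <- fb_section(imgA, 20); sB <- fb_section(imgB, 20)
  pmA <- structure(list(probs = matrix(0.5, 100, 120)), class = "fb_probmap")
  pmB <- structure(list(probs = matrix(0.5, 80, 90)), class = "fb_probmap")
  stk <- build_stack(list(sA, sB), list(pmA, pmB), downsample = 10L)
  expect_gte(dim(stk$volume)[2], 10)
  expect_gte(dim(stk$volume)[3], 12)
})

test_that("stack consensus keeps persistent bundles and drops one-section blips", {
  vol <- array(0, c(3, 20, 20))
  vol[1, 5:8, 5:8] <- 0.9; vol[2, 5:8, 5:8] <- 0.9; vol[3, 5:8, 5:8] <- 0.9
  vol[2, 15:16, 15:16] <- 0.9   # isolated blip in one section only
  stk <- structure(list(volume = vol, offsets = rep(list(c(row = 0, col = 0)), 3),
                        downsample = 10L,
                        dims = rep(list(c(200, 200)), 3), um_per_px = 20),
                   class = "fb_stackvolume")
  cons <- stack_consensus(stk, threshold = 0.4, smooth_sigma = 0)
  expect_true(cons[2, 6, 6])
  # blip: mean over z-neighbourhood is 0.3 < 0.4
  expect_false(cons[2, 15, 15])
  empty <- stk; empty$volume[] <- 0
  expect_false(any(stack_consensus(empty)))
  # pluggable segmenter is honoured
  cons2 <- stack_consensus(stk, segmenter = function(v) v > 100)
  expect_false(any(cons2))
})

test_that("filters are order-stable on random region sets", {
  for (seed in c(2, 9, 17)) {
    w <- random_regionset(seed, h = 96, w = 96)
    ref <- matrix(FALSE, 96, 96); ref[40:60, 40:60] <- TRUE
    a <- morphology_filter(continuity_filter(w$regions, ref, 0.6),
                           min_area_mm2 = 0.05, min_border_dist_mm = 0.1,
                           tissue_mask = w$tissue)
    b <- continuity_filter(morphology_filter(w$regions, min_area_mm2 = 0.05,
                                             min_border_dist_mm = 0.1,
                                             tissue_mask = w$tissue),
                           ref, 0.6)
    expect_equal(lapply(a$regions, `[[`, "mask"),
                 lapply(b$regions, `[[`, "mask"))
  }
})
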