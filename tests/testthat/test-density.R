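test_that("percentile binarization follows the rank definition", {
  # 1000 distinct-valued pixels, CLAHE disabled: strictly-above count is the
  # top-5% rank count (+/- 1 for the interpolated threshold)
  set.seed(21)
  vals <- sample(seq(0.001, 0.999, length.out = 1000))
  img <- array(rep(matrix(vals, 25, 40), 3), c(25, 40, 3))
  region <- matrix(TRUE, 25, 40)
  fm <- fiber_binary_map(img, region, clahe_params(enabled = FALSE))
  expect_lte(abs(sum(fm) - 50), 1)
  # constant region: nothing is strictly above its own value
  img2 <- array(0.4, c(10, 10, 3))
  expect_equal(sum(fiber_binary_map(img2, matrix(TRUE, 10, 10),
                                    clahe_params(enabled = FALSE))), 0)
  expect_error(fiber_binary_map(img2, matrix(FALSE, 10, 10)), "empty")
  expect_warning(
    fiber_binary_map(img, rbind(matrix(TRUE, 1, 40),
                                matrix(FALSE, 24, 40))[, 1:40] &
                          cbind(matrix(TRUE, 25, 10),
                                matrix(FALSE, 25, 30)),
    clahe_params(enabled = FALSE)), "20 px")
})

test_that("fiber density is the in-region fraction with its edge cases", {
  region <- matrix(FALSE, 10, 10); region[2:9, 2:9] <- TRUE
  expect_equal(fiber_density(region, region), 1)
  expect_equal(fiber_density(matrix(FALSE, 10, 10), region), 0)
  half <- region; half[2:9, 2:5] <- FALSE
  expect_equal(fiber_density(half, region), 0.5)
  expect_error(fiber_density(region, matrix(FALSE, 10, 10)), "empty")
})

test_that("FD is invariant under monotone intensity transforms when CLAHE is off", {
  set.seed(31)
  base <- matrix(runif(64 * 64, 0.05, 0.95), 64, 64)
  region <- matrix(FALSE, 64, 64); region[10:50, 10:50] <- TRUE
  p <- clahe_params(enabled = FALSE)
  img_of <- function(m) array(rep(m, 3), c(64, 64, 3))
  fd0 <- fiber_density(fiber_binary_map(img_of(base), region, p), region)
  for (f in list(function(x) x^2, function(x) sqrt(x),
                 function(x) 1 / (1 + exp(-4 * (x - 0.5))))) {
    fd1 <- fiber_density(fiber_binary_map(img_of(f(base)), region, p), region)
    expect_equal(fd1, fd0)
  }
})

test_that("the fiber map recovers rendered strokes on synthetic bundles", {
  cfg <- tiny_synth_cfg(seed = 31L, n_bundles = 2L)
  s <- generate_section(cfg, 0)
  lum <- luminance(s$section$image)
  for (r in s$annotations$regions) {
    strokes <- lum > 0.45 & r$mask
    fm <- fiber_binary_map(s$section, r$mask,
                           clahe_params(scope = "section"),
                           tissue_mask = s$tissue_mask)
    recall <- sum(fm & strokes) / sum(strokes)
    expect_gte(recall, 0.8)
    # section-scope FD tracks the generator's bright fraction
    fd <- fiber_density(fm, r$mask)
    expect_gt(fd, 0.01)
    expect_lt(fd, 0.25)
  }
})

test_that("region-scope percentile bounds FD near the top rank fraction", {
  cfg <- tiny_synth_cfg(seed = 32L, n_bundles = 2L)
  s <- generate_section(cfg, 0)
  r <- s$annotations$regions[[1]]
  fm <- fiber_binary_map(s$section, r$mask, clahe_params(enabled = FALSE))
  expect_lte(fiber_density(fm, r$mask), 0.05 + 2 / sum(r$mask))
})

test_that("pathway assignment follows the largest-overlap rule", {
  rois <- matrix(0L, 40, 40)
  rois[, 1:15] <- 1L   # IC
  rois[, 26:40] <- 3L  # UF
  attr(rois, "pathways") <- c("IC", "CC", "UF")
  reg <- matrix(FALSE, 40, 40); reg[10:19, 5:14] <- TRUE  # fully in IC
  expect_equal(assign_pathway(reg, rois), "IC")
  # 30% in IC, 30% in UF: neither exceeds 0.4
  reg2 <- matrix(FALSE, 40, 40)
  reg2[1:10, 13:15] <- TRUE   # 30 px in IC
  reg2[1:10, 26:28] <- TRUE   # 30 px in UF
  reg2[1:10, 17:20] <- TRUE   # 40 px nowhere
  expect_equal(assign_pathway(reg2, rois), "none")
  reg3 <- matrix(FALSE, 40, 40); reg3[30:35, 18:22] <- TRUE
  expect_equal(assign_pathway(reg3, rois), "none")
})

test_that("one-way ANOVA matches a hand-computed sums-of-squares oracle", {
  tbl <- data.frame(pathway = c("a", "a", "a", "b", "b", "b", "c", "c", "c"),
                    fd = c(4, 5, 6, 7, 8, 9, 1, 2, 3) / 100)
  res <- pathway_anova(tbl)
  # textbook decomposition
  gm <- mean(tbl$fd)
  ssb <- sum(tapply(tbl$fd, tbl$pathway, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(tbl$fd, tbl$pathway, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, f_hand, tolerance = 1e-8)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$groups$mean, c(0.05, 0.08, 0.02))
  # two groups holding the same values: zero between-group variance, F = 0
  tbl0 <- data.frame(pathway = rep(c("a", "b"), each = 3),
                     fd = rep(c(0.08, 0.1, 0.12), 2))
  expect_equal(pathway_anova(tbl0)$F, 0)
  expect_error(pathway_anova(data.frame(pathway = "a", fd = 1)), "groups")
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(99)
  rejections <- 0L
  for (i in 1:1000) {
    tbl <- data.frame(pathway = rep(c("IC", "CC", "UF"), each = 6),
                      fd = rnorm(18, 0.1, 0.02))
    # direct F computation (avoids aov overhead in the loop)
    p <- stats::oneway.test(fd ~ pathway, tbl, var.equal = TRUE)$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
  # and oneway.test agrees with the package's aov route on one draw
  tbl <- data.frame(pathway = rep(c("IC", "CC", "UF"), each = 6),
                    fd = rnorm(18, 0.1, 0.02))
  expect_equal(pathway_anova(tbl)$F,
               unname(stats::oneway.test(fd ~ pathway, tbl,
                                         var.equal = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("tightening a region boundary around fixed fibers never decreases FD", {
  set.seed(7)
  fibers <- matrix(FALSE, 60, 60)
  fibers[cbind(sample(20:40, 30, TRUE), sample(20:40, 30, TRUE))] <- TRUE
  loose <- matrix(FALSE, 60, 60); loose[10:50, 10:50] <- TRUE
  tight <- matrix(FALSE, 60, 60); tight[18:42, 18:42] <- TRUE
  expect_gte(fiber_density(fibers, tight), fiber_density(fibers, loose))
})
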