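test_that("bundle matching agrees with the double-loop oracle on random sets", {
  for (seed in 1:50) {
    man <- random_masks(seed, 1:4)
    pred <- random_masks(seed + 1000, 0:4)
    frac <- bundleseg:::with_seed(seed + 2000, runif(1, 0.05, 0.6))
    got <- match_bundles(as_annotations(man), as_regionset(pred), min_frac = frac)
    want <- match_oracle(man, pred, frac)
    expect_equal(got$tpr, want$tpr)
    expect_equal(got$fp_count, want$fp)
  }
})

test_that("matching handles the canonical constructed cases", {
  m1 <- matrix(FALSE, 48, 48); m1[5:14, 5:14] <- TRUE
  m2 <- matrix(FALSE, 48, 48); m2[25:34, 5:14] <- TRUE
  m3 <- matrix(FALSE, 48, 48); m3[5:14, 30:39] <- TRUE
  # identical predictions: perfect detection
  got <- match_bundles(as_annotations(list(m1, m2)), as_regionset(list(m1, m2)))
  expect_equal(got$tpr, 1)
  expect_equal(got$fp_count, 0)
  # no predictions: zero TPR
  expect_equal(match_bundles(as_annotations(list(m1)), as_regionset(list()))$tpr, 0)
  # two of three manual bundles covered, plus one disjoint prediction
  shift <- matrix(FALSE, 48, 48); shift[7:16, 5:14] <- TRUE  # 80% of m1
  disj <- matrix(FALSE, 48, 48); disj[40:45, 40:45] <- TRUE
  got2 <- match_bundles(as_annotations(list(m1, m2, m3)),
                        as_regionset(list(shift, m2, disj)), min_frac = 0.2)
  expect_equal(got2$tpr, 2 / 3)
  expect_equal(got2$fp_count, 1)
  # frame mismatch errors
  small <- matrix(TRUE, 10, 10)
  expect_error(match_bundles(as_annotations(list(m1)),
                             as_regionset(list(small), c(10, 10))), "frames")
})

test_that("FPavg is total false positives over sections", {
  mk <- function(fp) structure(list(fp_count = fp, detected = logical(0),
                                    n_manual = 0L),
                               class = "fb_matchresult")
  expect_equal(fp_avg(list(mk(0), mk(0))), 0)
  expect_equal(fp_avg(list(mk(2), mk(4))), 3)
  expect_equal(fp_avg(list(mk(5))), 5)
  expect_error(fp_avg(list()), ">= 1 section")
})

test_that("delta-FD uses the manual-minus-predicted sign convention", {
  m1 <- matrix(FALSE, 20, 20); m1[5:14, 5:14] <- TRUE
  match <- match_bundles(as_annotations(list(m1)),
                         as_regionset(list(m1), c(20, 20)))
  expect_equal(delta_fd(0.10, 0.10, match), 0)
  expect_equal(delta_fd(0.10, 0.12, match), -2, tolerance = 1e-10)
  # tighter predicted boundary around the same fibers implies negative dFD
  set.seed(3)
  fibers <- matrix(FALSE, 20, 20)
  fibers[cbind(sample(6:13, 12, TRUE), sample(6:13, 12, TRUE))] <- TRUE
  tight <- matrix(FALSE, 20, 20); tight[6:13, 6:13] <- TRUE
  fd_m <- fiber_density(fibers & m1, m1)
  fd_p <- fiber_density(fibers & tight, tight)
  match2 <- match_bundles(as_annotations(list(m1)),
                          as_regionset(list(tight), c(20, 20)))
  expect_lt(delta_fd(fd_m, fd_p, match2), 0)
  expect_error(delta_fd(numeric(0), numeric(0),
                        match_bundles(as_annotations(list()),
                                      as_regionset(list()))), "matched")
})

test_that("FROC is monotone and handles the degenerate top threshold", {
  cfg <- tiny_synth_cfg(seed = 17L, n_sections = 2L)
  stack <- generate_stack(cfg)
  sections <- lapply(stack, `[[`, "section")
  tissue <- lapply(stack, `[[`, "tissue_mask")
  manual <- lapply(stack, `[[`, "annotations")
  # surrogate probability maps: ground truth blurred, plus a fake FP blob
  pmaps <- lapply(stack, function(s) {
    p <- annotations_to_labelmask(s$annotations, c(192, 192)) > 0
    p <- p * 0.9
    p[170:185, 170:185] <- 0.45
    structure(list(probs = p, section_index = s$section$section_index,
                   um_per_px = 20, tile_layout = list(), model_tag = "t"),
              class = "fb_probmap")
  })
  curve <- froc(sections, pmaps, manual, tissue,
                thresholds = c(1.0, 0.8, 0.5, 0.4, 0.2),
                postprocess = FALSE)
  expect_s3_class(curve, "fb_froc")
  # no probability reaches 1: the top threshold contributes (0, 0)
  top <- curve[curve$threshold == 1.0, ]
  expect_equal(top$tpr, 0)
  expect_equal(top$fpavg, 0)
  # TPR non-decreasing as threshold decreases
  ord <- order(-curve$threshold)
  expect_true(all(diff(curve$tpr[ord]) >= 0))
  expect_error(froc(sections, pmaps, manual, tissue, thresholds = 0.4),
               ">= 2 thresholds")
})

test_that("FROC is invariant to region ordering", {
  m1 <- matrix(FALSE, 48, 48); m1[5:14, 5:14] <- TRUE
  m2 <- matrix(FALSE, 48, 48); m2[30:39, 30:39] <- TRUE
  a <- match_bundles(as_annotations(list(m1, m2)), as_regionset(list(m2, m1)))
  b <- match_bundles(as_annotations(list(m2, m1)), as_regionset(list(m1, m2)))
  expect_equal(a$tpr, b$tpr)
  expect_equal(a$fp_count, b$fp_count)
})
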