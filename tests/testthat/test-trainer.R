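test_that("te_target equals threshold(mean of last r maps) against the oracle", {
  cfg <- train_config(pretrain_epochs = 5L, te_history = 3L)
  set.seed(41)
  for (rep in 1:20) {
    h <- prediction_history(3L)
    n_maps <- sample(0:6, 1)
    maps <- lapply(seq_len(n_maps), function(i) matrix(runif(16), 4, 4))
    for (i in seq_along(maps)) history_append(h, "s1", 5L + i - 1L, maps[[i]])
    pre <- matrix(runif(16), 4, 4)
    got <- te_target(h, "s1", 5L + n_maps, pre, cfg)
    want <- te_oracle(maps, pre, 3L, 0.5)
    expect_identical(got, want)
    # ring buffer never exceeds r entries
    expect_lte(bundleseg:::history_depth(h, "s1"), 3L)
  }
})

test_that("te_target handles identical maps, ties, the early fallback, and r = 1", {
  cfg <- train_config(pretrain_epochs = 3L, te_history = 3L, te_threshold = 0.5)
  m <- matrix(c(0.9, 0.1, 0.5, 0.3), 2, 2)
  h <- prediction_history(3L)
  for (e in 3:5) history_append(h, "a", e, m)
  # mean of identical maps is the map; 0.5 maps to 1 under the >= tie rule
  expect_identical(te_target(h, "a", 6L, NULL, cfg),
                   matrix(c(1L, 0L, 1L, 0L), 2, 2))
  # the quoted pixel history {0.2, 0.6, 0.7} averages to 0.5 -> label 1
  h2 <- prediction_history(3L)
  for (v in c(0.2, 0.6, 0.7)) history_append(h2, "b", 3L, matrix(v, 1, 1))
  expect_identical(te_target(h2, "b", 6L, NULL, cfg), matrix(1L, 1, 1))
  # no history at epoch Np: thresholded pretrained prediction
  h3 <- prediction_history(3L)
  pre <- matrix(c(0.8, 0.2), 1, 2)
  expect_identical(te_target(h3, "c", 3L, pre, cfg), matrix(c(1L, 0L), 1, 2))
  expect_error(te_target(h3, "c", 3L, NULL, cfg), "pretrain")
  # r = 1 reduces to the previous epoch's thresholded prediction
  cfg1 <- train_config(pretrain_epochs = 3L, te_history = 1L)
  h4 <- prediction_history(1L)
  history_append(h4, "d", 3L, matrix(0.1, 1, 1))
  history_append(h4, "d", 4L, matrix(0.9, 1, 1))
  expect_identical(te_target(h4, "d", 5L, NULL, cfg1), matrix(1L, 1, 1))
})

test_that("history_append validates probability ranges", {
  h <- prediction_history(2L)
  expect_error(history_append(h, "x", 1L, matrix(1.5, 1, 1)), "\\[0,1\\]")
  expect_error(prediction_history(0L), "r must be")
})

# A tiny two-section training world reused across trainer smoke tests.
trainer_world <- function(seed = 11L) {
  cfg <- synth_config(image_height_px = 96L, image_width_px = 96L,
                      um_per_px = 20, n_sections = 4L, n_bundles = 2L,
                      seed = seed)
  stack <- generate_stack(cfg)
  lapply(stack, function(s) list(section = s$section,
                                 annotations = s$annotations,
                                 tissue_mask = s$tissue_mask))
}

tiny_train_cfg <- function(loss_weights = list(focal = 1, contrastive = 0.1),
                           ...) {
  train_config(pretrain_epochs = 2L, te_epochs = 2L, patches_per_section = 2L,
               patch_size = 32L, batch_size = 4L,
               loss_weights = loss_weights, seed = 3L, ...)
}

test_that("pretraining runs on CPU, returns finite validation losses", {
  world <- trainer_world()
  model <- tiny_model(seed = 2, base_width = 2, depth = 2, fc = c(8L, 4L))
  pt <- pretrain(model, world[1:2], tiny_train_cfg())
  expect_true(all(is.finite(pt$val_curve)))
  expect_lte(length(pt$val_curve), 2)
  expect_true(all(pt$logs$contrastive_evaluated))
  expect_error(pretrain(model, list(), tiny_train_cfg()), "non-empty")
})

test_that("zero contrastive weight disables the contrastive term entirely", {
  world <- trainer_world()
  model <- tiny_model(seed = 2, base_width = 2, depth = 2, fc = c(8L, 4L))
  cfg <- tiny_train_cfg(loss_weights = list(focal = 1, contrastive = 0))
  pt <- pretrain(model, world[1:2], cfg)
  expect_false(any(pt$logs$contrastive_evaluated))
  expect_true(all(pt$logs$train_con == 0))
})

test_that("training is deterministic under a fixed seed", {
  world <- trainer_world()
  model <- tiny_model(seed = 2, base_width = 2, depth = 2, fc = c(8L, 4L))
  a <- pretrain(model, world[1:2], tiny_train_cfg())
  b <- pretrain(model, world[1:2], tiny_train_cfg())
  expect_identical(a$val_curve, b$val_curve)
  expect_identical(a$model$params, b$model$params)
})

test_that("temporal ensembling trains with unlabeled data and logs pseudo-label stats", {
  world <- trainer_world()
  model <- tiny_model(seed = 2, base_width = 2, depth = 2, fc = c(8L, 4L))
  cfg <- tiny_train_cfg()
  pt <- pretrain(model, world[1:2], cfg)
  unl <- lapply(world[3:4], function(s) { s$annotations <- NULL; s })
  te <- train_te(pt$model, world[1:2], unl, cfg)
  expect_true(all(is.finite(te$logs$val_loss)))
  expect_true(all(te$logs$pseudo_pos_frac >= 0 & te$logs$pseudo_pos_frac <= 1))
  # history holds at most r maps per sample, all binary pseudo-labels in range
  for (id in names(te$history$maps)) {
    expect_lte(length(te$history$maps[[id]]), cfg$te_history)
    for (m in te$history$maps[[id]]) {
      expect_true(min(m) >= 0 && max(m) <= 1)
    }
  }
  expect_warning(train_te(pt$model, world[1:2], list(), cfg), "empty")
})
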