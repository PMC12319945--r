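#' Training configuration
#'
#' Defaults follow the training recipe used for the full-scale model: Adam
#' with learning rate 1e-3, batch size 8, 100 pretraining and 100
#' temporal-ensembling epochs, a history of `r = 3` epochs, early stopping
#' with patience 25, and a 90:10 train:validation split. Reduced settings
#' (few epochs, few patches, small model) are used for CPU-scale runs.
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Patches per optimization step (default 8). When
#'   contrastive pairs are used, a batch holds `batch_size/2` anchors plus
#'   their positive partners.
#' @param pretrain_epochs Np, supervised pretraining epochs.
#' @param te_epochs Temporal-ensembling epochs.
#' @param te_history r, number of previous epochs averaged into the
#'   pseudo-label (default 3).
#' @param te_threshold Threshold applied to the averaged map (default 0.5,
#'   ties included as foreground).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 25).
#' @param loss_weights List with `focal` and `contrastive` weights.
#' @param val_fraction Validation fraction of the patch pool (default 0.1).
#' @param patches_per_section Anchor patches sampled per labeled section per
#'   epoch.
#' @param patch_size Training patch side (default 256).
#' @param focal A [focal_params()].
#' @param contrastive A [contrastive_params()].
#' @param pair_policy A [pair_policy()] for contrastive partners.
#' @param geom_policy A [geom_policy()] for segmentation augmentation, or
#'   `NULL` to disable.
#' @param seed Global training seed.
#' @return Object of class `fb_train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 8L, pretrain_epochs = 100L,
                         te_epochs = 100L, te_history = 3L, te_threshold = 0.5,
                         early_stop_patience = 25L,
                         loss_weights = list(focal = 1, contrastive = 0.1),
                         val_fraction = 0.1, patches_per_section = 8L,
                         patch_size = 256L,
                         focal = focal_params(), contrastive = contrastive_params(),
                         pair_policy = bundleseg::pair_policy(),
                         geom_policy = bundleseg::geom_policy(),
                         seed = 1L) {
  if (te_history < 1) stop_cfg("te_history r must be >= 1")
  if (early_stop_patience < 1) stop_cfg("patience must be >= 1")
  if (loss_weights$focal < 0 || loss_weights$contrastive < 0) {
    stop_cfg("loss weights must be >= 0")
  }
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 te_epochs = as.integer(te_epochs),
                 te_history = as.integer(te_history),
                 te_threshold = te_threshold,
                 early_stop_patience = as.integer(early_stop_patience),
                 loss_weights = loss_weights, val_fraction = val_fraction,
                 patches_per_section = as.integer(patches_per_section),
                 patch_size = as.integer(patch_size),
                 focal = focal, contrastive = contrastive,
                 pair_policy = pair_policy, geom_policy = geom_policy,
                 seed = as.integer(seed)),
            class = "fb_train_config")
}

# ---- Adam optimizer ---------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- temporal ensembling ----------------------------------------------------

#' Prediction history for temporal ensembling
#'
#' Ring buffer keeping, per sample, the probability maps predicted in the
#' last `r` epochs.
#'
#' @param r History length, `>= 1`.
#' @return Object of class `fb_prediction_history` (an environment).
#' @export
prediction_history <- function(r = 3L) {
  if (r < 1) stop_cfg("r must be >= 1")
  e <- new.env(parent = emptyenv())
  e$r <- as.integer(r)
  e$maps <- list()
  e$epochs <- list()
  class(e) <- "fb_prediction_history"
  e
}

#' @rdname prediction_history
#' @param history An `fb_prediction_history`.
#' @param sample_id Character key of the sample.
#' @param epoch Epoch at which `map` was predicted.
#' @param map Probability map in `[0, 1]`.
#' @export
history_append <- function(history, sample_id, epoch, map) {
  if (min(map) < 0 || max(map) > 1) stop_cfg("probability maps must lie in [0,1]")
  cur <- history$maps[[sample_id]]
  ep <- history$epochs[[sample_id]]
  if (is.null(cur)) { cur <- list(); ep <- integer(0) }
  cur[[length(cur) + 1L]] <- map
  ep <- c(ep, as.integer(epoch))
  if (length(cur) > history$r) {
    cur <- cur[(length(cur) - history$r + 1L):length(cur)]
    ep <- ep[(length(ep) - history$r + 1L):length(ep)]
  }
  history$maps[[sample_id]] <- cur
  history$epochs[[sample_id]] <- ep
  invisible(history)
}

history_depth <- function(history, sample_id) {
  length(history$maps[[sample_id]])
}

#' Temporal-ensembling pseudo-label for one sample
#'
#' Averages the sample's predictions from the last `r` epochs and thresholds
#' the mean (`>=` convention) to obtain the training target for the current
#' epoch. During the first `r` epochs after pretraining, when fewer than `r`
#' post-pretraining predictions exist, the thresholded pretrained-model
#' prediction is used instead.
#'
#' @param history An [prediction_history()].
#' @param sample_id Sample key.
#' @param current_epoch Current (post-pretraining) epoch; must be `>=` the
#'   number of pretraining epochs.
#' @param pretrain_prediction Probability map from the pretrained model.
#' @param cfg A [train_config()] (uses `te_threshold`, `te_history`).
#' @return Binary label map (matrix of 0/1).
#' @export
te_target <- function(history, sample_id, current_epoch, pretrain_prediction,
                      cfg = train_config()) {
  r <- history$r
  depth <- history_depth(history, sample_id)
  if (depth < r) {
    if (is.null(pretrain_prediction)) {
      stop_cfg("pretrain prediction required during the first %d epochs", r)
    }
    return((pretrain_prediction >= cfg$te_threshold) * 1L)
  }
  maps <- history$maps[[sample_id]]
  avg <- Reduce(`+`, maps) / length(maps)
  (avg >= cfg$te_threshold) * 1L
}

# ---- batch construction -----------------------------------------------------

# Deterministic grid of patch centers covering the image (used for unlabeled
# data so temporal-ensembling histories stay aligned across epochs).
patch_grid_centers <- function(dim_hw, patch_size) {
  s <- patch_size; half <- s %/% 2L
  pos <- function(n) {
    if (n <= s) return(half + 1L)
    k <- ceiling(n / s)
    as.integer(round(seq(half + 1L, n - (s - half) + 1L, length.out = k)))
  }
  rows <- pos(dim_hw[1]); cols <- pos(dim_hw[2])
  as.matrix(expand.grid(rows = rows, cols = cols))
}

# Run one optimization pass over a list of batch descriptors. Each batch is
# list(images = list of HxWx3, labels = list of HxW or NULL, con_order =
# integer vector (1-based) or integer(0)). Returns updated params/state and
# mean losses.
run_batches <- function(params, state, batches, model_cfg, cfg) {
  fl <- cl <- 0; nb <- 0L
  for (b in batches) {
    step <- .nn_train_step_cpp(b$images, b$labels, params,
                               cfg_for_cpp(model_cfg),
                               as.integer(b$con_order - 1L),
                               cfg$focal$alpha, cfg$focal$gamma,
                               cfg$contrastive$tau,
                               cfg$loss_weights$focal,
                               cfg$loss_weights$contrastive,
                               model_cfg$contrastive_features)
    upd <- adam_step(params, step$grads, state, cfg$lr)
    params <- upd$params; state <- upd$state
    fl <- fl + step$focal_loss; cl <- cl + step$con_loss; nb <- nb + 1L
  }
  list(params = params, state = state,
       focal = if (nb) fl / nb else NA_real_,
       con = if (nb) cl / nb else NA_real_)
}

# Sample anchors (+ optional contrastive partners) from labeled sections and
# assemble batches. `use_pairs` adds a positive partner per anchor and marks
# the contrastive ordering.
make_labeled_batches <- function(labeled_data, cfg, epoch_seed, use_pairs) {
  anchors <- list()
  for (i in seq_along(labeled_data)) {
    ld <- labeled_data[[i]]
    sp <- sample_patches(ld$section, ld$annotations,
                         n = cfg$patches_per_section,
                         seed = derive_seed(epoch_seed, i),
                         patch_size = cfg$patch_size,
                         tissue_mask = ld$tissue_mask)
    for (k in seq_len(nrow(sp$centers))) {
      anchors[[length(anchors) + 1L]] <- list(
        img = array(sp$patches[k, , , ], dim = c(cfg$patch_size, cfg$patch_size, 3)),
        lab = if (is.null(sp$pixel_labels)) NULL else sp$pixel_labels[k, , ],
        sec = i, center = sp$centers[k, ])
    }
  }
  ord <- with_seed(derive_seed(epoch_seed, 555L), sample(seq_along(anchors)))
  anchors <- anchors[ord]
  n_anchor_per_batch <- if (use_pairs) max(2L, cfg$batch_size %/% 2L) else cfg$batch_size
  batches <- list()
  i0 <- 1L
  while (i0 <= length(anchors)) {
    idx <- i0:min(i0 + n_anchor_per_batch - 1L, length(anchors))
    images <- list(); labels <- list(); con_order <- integer(0)
    for (j in seq_along(idx)) {
      a <- anchors[[idx[j]]]
      aug_seed <- derive_seed(epoch_seed, 10000L + idx[j])
      if (!is.null(cfg$geom_policy)) {
        ga <- geometric_augment(a$img, a$lab, cfg$geom_policy, seed = aug_seed)
        img <- ga$patch; lab <- ga$pixel_labels
      } else {
        img <- a$img; lab <- a$lab
      }
      images[[length(images) + 1L]] <- img
      labels[length(labels) + 1L] <- if (is.null(lab)) list(NULL) else list(lab * 1.0)
      if (use_pairs && length(idx) >= 2L) {
        ld <- labeled_data[[a$sec]]
        pp <- make_positive_pair(ld$section, a$center, cfg$pair_policy,
                                 wm_mask = ld$white_matter_mask,
                                 seed = derive_seed(epoch_seed, 20000L + idx[j]),
                                 patch_size = cfg$patch_size)
        images[[length(images) + 1L]] <- pp$patch_b
        labels[length(labels) + 1L] <- list(NULL)
        con_order <- c(con_order, length(images) - 1L, length(images))
      }
    }
    batches[[length(batches) + 1L]] <- list(images = images, labels = labels,
                                            con_order = con_order)
    i0 <- i0 + n_anchor_per_batch
  }
  batches
}

# Fixed validation patch set (focal loss only).
make_val_set <- function(labeled_data, cfg) {
  n_val <- max(2L, ceiling(cfg$val_fraction * length(labeled_data) *
                             cfg$patches_per_section))
  per_sec <- max(1L, ceiling(n_val / length(labeled_data)))
  out <- list()
  for (i in seq_along(labeled_data)) {
    ld <- labeled_data[[i]]
    sp <- sample_patches(ld$section, ld$annotations, n = per_sec,
                         seed = derive_seed(cfg$seed, 90000L + i),
                         patch_size = cfg$patch_size,
                         tissue_mask = ld$tissue_mask)
    for (k in seq_len(nrow(sp$centers))) {
      out[[length(out) + 1L]] <- list(
        img = array(sp$patches[k, , , ], dim = c(cfg$patch_size, cfg$patch_size, 3)),
        lab = sp$pixel_labels[k, , ])
    }
  }
  out
}

val_loss <- function(model, params, val_set, cfg) {
  m <- model; m$params <- params
  losses <- vapply(val_set, function(v) {
    out <- nn_forward(m, v$img, with_cls = FALSE)
    focal_loss(out$seg_prob, v$lab, cfg$focal)
  }, numeric(1))
  mean(losses)
}

# ---- training entry points --------------------------------------------------

#' Supervised pretraining on labeled sections
#'
#' Trains the model for up to `pretrain_epochs` epochs on manually charted
#' sections, minimizing focal loss on the segmentation head plus (when the
#' contrastive weight is positive) the weighted NT-Xent loss over
#' anatomy-constrained positive pairs on the classification arm. Early
#' stopping monitors validation focal loss; the best-validation weights are
#' retained.
#'
#' @param model An `fb_model` from [build_model()].
#' @param labeled_data List of labeled samples, each a list with `section`
#'   ([fb_section()]), `annotations` ([fb_annotations()]) and optionally
#'   `white_matter_mask` and `tissue_mask`.
#' @param cfg A [train_config()].
#' @return List with `model` (best weights), `val_curve` (per-epoch
#'   validation loss) and `logs` (per-epoch data frame).
#' @export
pretrain <- function(model, labeled_data, cfg = train_config()) {
  if (length(labeled_data) == 0) stop_cfg("labeled data must be non-empty")
  use_pairs <- cfg$loss_weights$contrastive > 0
  val_set <- make_val_set(labeled_data, cfg)
  if (length(val_set) == 0) stop_cfg("validation split is empty")
  params <- model$params
  state <- adam_new(params)
  best <- list(loss = Inf, params = params)
  curve <- numeric(0)
  logs <- list()
  since_best <- 0L
  for (epoch in seq_len(cfg$pretrain_epochs)) {
    epoch_seed <- derive_seed(cfg$seed, 7000L + epoch)
    batches <- make_labeled_batches(labeled_data, cfg, epoch_seed, use_pairs)
    res <- run_batches(params, state, batches, model$cfg, cfg)
    params <- res$params; state <- res$state
    vl <- val_loss(model, params, val_set, cfg)
    curve <- c(curve, vl)
    logs[[epoch]] <- data.frame(epoch = epoch, phase = "pretrain",
                                train_focal = res$focal, train_con = res$con,
                                val_loss = vl,
                                contrastive_evaluated = use_pairs)
    if (vl < best$loss) {
      best <- list(loss = vl, params = params); since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  list(model = model, val_curve = curve, logs = do.call(rbind, logs))
}

#' Semi-supervised training with temporal ensembling
#'
#' Continues training using unlabeled sections: labeled patches keep their
#' manual labels (focal loss), unlabeled patches are trained against
#' temporal-ensembling pseudo-labels ([te_target()]) on a deterministic
#' patch grid (so per-sample histories stay aligned across epochs), and
#' contrastive pairs are drawn from the unlabeled sections. After each
#' epoch the history ring is updated with the current predictions.
#'
#' @param model A pretrained `fb_model`.
#' @param labeled_data As in [pretrain()].
#' @param unlabeled_data List of unlabeled samples (each with `section` and
#'   optionally `white_matter_mask`, `tissue_mask`; annotations ignored).
#' @param cfg A [train_config()].
#' @return List with `model`, `logs` (per-epoch data frame including the
#'   pseudo-label positive fraction) and `history`.
#' @export
train_te <- function(model, labeled_data, unlabeled_data, cfg = train_config()) {
  if (length(unlabeled_data) == 0) {
    warning("unlabeled set empty; temporal-ensembling phase degenerates to supervised continuation")
  }
  use_pairs <- cfg$loss_weights$contrastive > 0
  val_set <- make_val_set(labeled_data, cfg)
  params <- model$params
  state <- adam_new(params)
  history <- prediction_history(cfg$te_history)
  np <- cfg$pretrain_epochs

  # deterministic unlabeled patch grid + pretrained-model predictions
  upatches <- list()
  for (i in seq_along(unlabeled_data)) {
    ud <- unlabeled_data[[i]]
    centers <- patch_grid_centers(dim(ud$section$image)[1:2], cfg$patch_size)
    sp <- sample_patches(ud$section, NULL, seed = 0L,
                         patch_size = cfg$patch_size, centers = centers)
    for (k in seq_len(nrow(centers))) {
      upatches[[length(upatches) + 1L]] <- list(
        id = sprintf("u%03d_p%03d", i, k),
        img = array(sp$patches[k, , , ], dim = c(cfg$patch_size, cfg$patch_size, 3)),
        sec = i, center = centers[k, ])
    }
  }
  mtmp <- model
  pretrain_preds <- lapply(upatches, function(u) {
    mtmp$params <- params
    nn_forward(mtmp, u$img, with_cls = FALSE)$seg_prob
  })
  names(pretrain_preds) <- vapply(upatches, `[[`, character(1), "id")

  best <- list(loss = if (length(val_set)) val_loss(model, params, val_set, cfg) else Inf,
               params = params)
  since_best <- 0L
  logs <- list()
  for (epoch in seq_len(cfg$te_epochs)) {
    cur_epoch <- np + epoch - 1L
    epoch_seed <- derive_seed(cfg$seed, 40000L + epoch)
    # pseudo-labels for this epoch
    pseudo <- lapply(upatches, function(u) {
      te_target(history, u$id, cur_epoch, pretrain_preds[[u$id]], cfg)
    })
    pos_frac <- if (length(pseudo)) mean(vapply(pseudo, mean, numeric(1))) else NA_real_

    lab_batches <- make_labeled_batches(labeled_data, cfg, epoch_seed, use_pairs)
    # unlabeled batches: pseudo-labeled anchors (+ pairs)
    n_anchor <- if (use_pairs) max(2L, cfg$batch_size %/% 2L) else cfg$batch_size
    ub <- list()
    ord <- with_seed(derive_seed(epoch_seed, 77L), sample(seq_along(upatches)))
    i0 <- 1L
    while (i0 <= length(ord)) {
      idx <- ord[i0:min(i0 + n_anchor - 1L, length(ord))]
      images <- list(); labels <- list(); con_order <- integer(0)
      for (j in idx) {
        u <- upatches[[j]]
        images[[length(images) + 1L]] <- u$img
        labels[[length(labels) + 1L]] <- pseudo[[j]] * 1.0
        if (use_pairs && length(idx) >= 2L) {
          ud <- unlabeled_data[[u$sec]]
          pp <- make_positive_pair(ud$section, u$center, cfg$pair_policy,
                                   wm_mask = ud$white_matter_mask,
                                   seed = derive_seed(epoch_seed, 30000L + j),
                                   patch_size = cfg$patch_size)
          images[[length(images) + 1L]] <- pp$patch_b
          labels[length(labels) + 1L] <- list(NULL)
          con_order <- c(con_order, length(images) - 1L, length(images))
        }
      }
      ub[[length(ub) + 1L]] <- list(images = images, labels = labels,
                                    con_order = con_order)
      i0 <- i0 + n_anchor
    }
    res <- run_batches(params, state, c(lab_batches, ub), model$cfg, cfg)
    params <- res$params; state <- res$state

    # update history with the current model's predictions on the fixed grid
    mtmp$params <- params
    for (u in upatches) {
      pr <- nn_forward(mtmp, u$img, with_cls = FALSE)$seg_prob
      history_append(history, u$id, cur_epoch, clamp(pr, 0, 1))
    }

    vl <- if (length(val_set)) val_loss(model, params, val_set, cfg) else NA_real_
    logs[[epoch]] <- data.frame(epoch = cur_epoch + 1L, phase = "te",
                                train_focal = res$focal, train_con = res$con,
                                val_loss = vl, pseudo_pos_frac = pos_frac)
    if (!is.na(vl) && vl < best$loss) {
      best <- list(loss = vl, params = params); since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  model$params <- if (is.finite(best$loss)) best$params else params
  list(model = model, logs = do.call(rbind, logs), history = history)
}
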