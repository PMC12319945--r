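# Shared fixtures: tiny synthetic configurations, tiny models, and random
# region sets, all built in code at test time.

tiny_synth_cfg <- function(n_sections = 2L, seed = 7L, n_bundles = 2L, ...) {
  synth_config(image_height_px = 192L, image_width_px = 192L, um_per_px = 20,
               n_sections = n_sections, n_bundles = n_bundles, seed = seed, ...)
}

tiny_model <- function(seed = 3L, base_width = 2L, depth = 2L,
                       fc = c(8L, 6L), ...) {
  build_model(model_config(base_width = base_width, depth = depth,
                           fc_sizes = fc, ...), seed = seed)
}

random_image <- function(h, w, seed = 1L) {
  bundleseg:::with_seed(seed, array(runif(h * w * 3), dim = c(h, w, 3)))
}

flat_section <- function(h = 64L, w = 64L, value = 0.5, um_per_px = 20) {
  fb_section(array(value, dim = c(h, w, 3)), um_per_px = um_per_px)
}

# Random rectangular region masks with known geometry, for filter oracles.
random_regionset <- function(seed, h = 64L, w = 64L, um_per_px = 100,
                             n_max = 4L) {
  bundleseg:::with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    n <- sample.int(n_max, 1)
    for (k in seq_len(n)) {
      rh <- sample(2:12, 1); rw <- sample(2:12, 1)
      r0 <- sample(seq_len(h - rh), 1); c0 <- sample(seq_len(w - rw), 1)
      mask[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- TRUE
    }
    tissue <- matrix(FALSE, h, w)
    tissue[5:(h - 4), 5:(w - 4)] <- TRUE
    list(mask = mask, tissue = tissue,
         regions = regions_from_mask(mask, um_per_px, tissue_mask = tissue))
  })
}

# Brute-force minimum Euclidean pixel distance between a mask and a
# reference mask (independent of the package's distance transforms).
brute_min_dist_px <- function(mask, reference) {
  if (!any(reference)) return(Inf)
  a <- which(mask, arr.ind = TRUE)
  b <- which(reference, arr.ind = TRUE)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(min(d2))
}

# ---- independent oracles shared with the acceptance suite ----

focal_oracle <- function(p, y, alpha, gamma) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    if (y[i] == 1) { pt <- pi; at <- alpha } else { pt <- 1 - pi; at <- 1 - alpha }
    total <- total - at * (1 - pt)^gamma * log(pt)
  }
  total / length(p)
}

ntxent_oracle <- function(f, tau) {
  n2 <- nrow(f)
  cossim <- function(x, y) sum(x * y) / (max(sqrt(sum(x^2)), 1e-12) *
                                           max(sqrt(sum(y^2)), 1e-12))
  total <- 0
  for (i in seq_len(n2)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    num <- exp(cossim(f[i, ], f[j, ]) / tau)
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(cossim(f[i, ], f[k, ]) / tau)
    total <- total - log(num / den)
  }
  total / n2
}


# Temporal-ensembling target rule, hand-rolled.
te_oracle <- function(maps, pretrain_map, r, thr) {
  if (length(maps) < r) return((pretrain_map >= thr) * 1L)
  last <- maps[(length(maps) - r + 1):length(maps)]
  ((Reduce(`+`, last) / r) >= thr) * 1L
}

# Brute-force overlap-based matching oracle (double loop over region pairs).
match_oracle <- function(man_masks, pred_masks, min_frac) {
  nm <- length(man_masks); np <- length(pred_masks)
  detected <- logical(nm)
  for (i in seq_len(nm)) {
    for (j in seq_len(np)) {
      if (sum(man_masks[[i]] & pred_masks[[j]]) >= min_frac * sum(man_masks[[i]])) {
        detected[i] <- TRUE
      }
    }
  }
  fp <- 0L
  for (j in seq_len(np)) {
    tp <- FALSE
    for (i in seq_len(nm)) {
      if (sum(man_masks[[i]] & pred_masks[[j]]) >= min_frac * sum(pred_masks[[j]])) {
        tp <- TRUE
      }
    }
    if (!tp) fp <- fp + 1L
  }
  list(tpr = if (nm > 0) mean(detected) else NA_real_, fp = fp)
}

as_annotations <- function(masks) {
  fb_annotations(0L, lapply(masks, function(m) list(mask = m, density = "unknown")))
}

as_regionset <- function(masks, dim_hw = c(48, 48)) {
  structure(list(section_index = 0L, dim_hw = dim_hw, um_per_px = 100,
                 regions = lapply(masks, function(m)
                   list(mask = m, area_mm2 = px_to_mm2(sum(m), 100),
                        centroid_xy_px = c(0, 0),
                        min_border_dist_mm = NA_real_))),
            class = "fb_regionset")
}

random_masks <- function(seed, n_range = 0:4, h = 48, w = 48) {
  bundleseg:::with_seed(seed, {
    n <- sample(n_range, 1)
    lapply(seq_len(n), function(k) {
      m <- matrix(FALSE, h, w)
      rh <- sample(4:14, 1); rw <- sample(4:14, 1)
      r0 <- sample(seq_len(h - rh), 1); c0 <- sample(seq_len(w - rw), 1)
      m[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- TRUE
      m
    })
  })
}

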