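#' Match predicted regions to manual bundles
#'
#' A manual bundle counts as detected (true positive) iff some predicted
#' region's intersection with it covers at least `min_frac` of the manual
#' bundle's area. A predicted region counts as a false positive iff its
#' intersection with every manual bundle covers less than `min_frac` of the
#' prediction's own area. Counting is non-exclusive: one prediction may
#' match several manual bundles and vice versa.
#'
#' @param manual An [fb_annotations()] (or `fb_regionset`) of manual
#'   bundles.
#' @param predicted An `fb_regionset` of predictions for the same section.
#' @param min_frac Matching fraction (default 0.2). The region-level
#'   matching criterion is the single most consequential configurable
#'   choice of the evaluation; a low fraction tolerates the systematic
#'   boundary-tightness difference between predicted and manual outlines.
#' @return Object of class `fb_matchresult`: list with `detected` (logical
#'   per manual bundle), `matched_prediction` (index or NA), `pred_is_tp`
#'   (logical per prediction), `tpr`, `fp_count`, `n_manual`, `pairs`
#'   (data frame of matched manual/predicted index pairs).
#' @export
match_bundles <- function(manual, predicted, min_frac = 0.2) {
  man_masks <- region_masks(manual)
  pred_masks <- region_masks(predicted)
  if (length(man_masks) > 0 && length(pred_masks) > 0) {
    if (!all(dim(man_masks[[1]]) == dim(pred_masks[[1]]))) {
      stop_cfg("manual and predicted masks are in different frames")
    }
  }
  nm <- length(man_masks); np <- length(pred_masks)
  inter <- matrix(0, nrow = max(nm, 1), ncol = max(np, 1))
  if (nm > 0 && np > 0) {
    for (i in seq_len(nm)) {
      for (j in seq_len(np)) {
        inter[i, j] <- sum(man_masks[[i]] & pred_masks[[j]])
      }
    }
  }
  man_area <- vapply(man_masks, sum, numeric(1))
  pred_area <- vapply(pred_masks, sum, numeric(1))
  detected <- logical(nm); matched <- rep(NA_integer_, nm)
  pairs <- list()
  for (i in seq_len(nm)) {
    if (np > 0) {
      cov <- inter[i, ] / man_area[i]
      hits <- which(cov >= min_frac)
      if (length(hits) > 0) {
        detected[i] <- TRUE
        matched[i] <- hits[which.max(inter[i, hits])]
        for (j in hits) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  pred_is_tp <- logical(np)
  for (j in seq_len(np)) {
    if (nm > 0) {
      pred_is_tp[j] <- any(inter[, j] / pred_area[j] >= min_frac)
    }
  }
  structure(list(
    detected = detected, matched_prediction = matched,
    pred_is_tp = pred_is_tp,
    tpr = if (nm > 0) sum(detected) / nm else NA_real_,
    fp_count = sum(!pred_is_tp), n_manual = nm,
    pairs = if (length(pairs)) {
      data.frame(manual = vapply(pairs, `[`, numeric(1), 1),
                 predicted = vapply(pairs, `[`, numeric(1), 2))
    } else data.frame(manual = integer(0), predicted = integer(0))),
    class = "fb_matchresult")
}

region_masks <- function(x) {
  if (inherits(x, "fb_annotations") || inherits(x, "fb_regionset")) {
    lapply(x$regions, `[[`, "mask")
  } else if (is.list(x)) {
    x
  } else {
    stop_cfg("unsupported region container")
  }
}

#' Average false positives per section
#'
#' Total false-positive count over a set of match results divided by the
#' number of sections.
#'
#' @param match_results List of `fb_matchresult` (one per test section).
#' @return Scalar FPavg.
#' @export
fp_avg <- function(match_results) {
  if (length(match_results) == 0) stop_cfg("need >= 1 section")
  sum(vapply(match_results, `[[`, numeric(1), "fp_count")) / length(match_results)
}

#' Pooled true positive rate over sections
#'
#' Detected manual bundles over all manual bundles, pooled across sections.
#'
#' @param match_results List of `fb_matchresult`.
#' @return Scalar TPR in `[0, 1]`.
#' @export
tpr_pooled <- function(match_results) {
  det <- sum(vapply(match_results, function(m) sum(m$detected), numeric(1)))
  tot <- sum(vapply(match_results, `[[`, numeric(1), "n_manual"))
  if (tot == 0) return(NA_real_)
  det / tot
}

#' Mean fiber-density difference over matched bundles
#'
#' Mean over matched manual/predicted pairs of
#' `FD_manual - FD_predicted`, reported as a percentage. A negative value
#' indicates higher density in the predicted bundles, as happens when
#' predicted boundaries fit the fibers more tightly than manual outlines.
#'
#' @param manual_fd Numeric vector of manual-bundle fiber densities (in
#'   `[0, 1]`), indexed like the manual bundles of `matches`.
#' @param predicted_fd Numeric vector of predicted-region fiber densities,
#'   indexed like the predictions of `matches`.
#' @param matches An `fb_matchresult` (or list of them, with `manual_fd` /
#'   `predicted_fd` as lists of vectors).
#' @return Mean difference in percent.
#' @export
delta_fd <- function(manual_fd, predicted_fd, matches) {
  if (inherits(matches, "fb_matchresult")) {
    matches <- list(matches); manual_fd <- list(manual_fd)
    predicted_fd <- list(predicted_fd)
  }
  diffs <- numeric(0)
  for (s in seq_along(matches)) {
    p <- matches[[s]]$pairs
    if (nrow(p) == 0) next
    diffs <- c(diffs, manual_fd[[s]][p$manual] - predicted_fd[[s]][p$predicted])
  }
  if (length(diffs) == 0) stop_cfg("no matched pairs")
  100 * mean(diffs)
}

#' FROC curve for bundle detection
#'
#' For each probability threshold: binarize, postprocess, match against the
#' manual bundles, and record the (FPavg, TPR) operating point. The curve
#' is returned sorted by FPavg. TPR is non-decreasing as the threshold
#' decreases before postprocessing; the elbow is the point closest to
#' (0 FP, TPR 1) after scaling FPavg by its maximum.
#'
#' @param sections List of [fb_section()].
#' @param probability_maps List of `fb_probmap`.
#' @param manual_list List of [fb_annotations()].
#' @param tissue_masks List of tissue masks.
#' @param thresholds Numeric vector of at least 2 thresholds.
#' @param postprocess Logical: run the false-positive filters at each
#'   threshold (default TRUE).
#' @param min_frac Matching fraction (default 0.2).
#' @param ... Passed to [postprocess_stack()].
#' @return Object of class `fb_froc`: data frame with columns `threshold`,
#'   `tpr`, `fpavg`, plus an `elbow` attribute.
#' @export
froc <- function(sections, probability_maps, manual_list, tissue_masks,
                 thresholds = seq(0.9, 0.1, by = -0.1), postprocess = TRUE,
                 min_frac = 0.2, ...) {
  if (length(thresholds) < 2) stop_cfg("need >= 2 thresholds")
  pts <- lapply(thresholds, function(th) {
    rsets <- if (postprocess) {
      postprocess_stack(sections, probability_maps, tissue_masks,
                        threshold = th, ...)
    } else {
      lapply(seq_along(sections), function(i) {
        regions_from_mask(binarize(probability_maps[[i]], th),
                          um_per_px = sections[[i]]$um_per_px,
                          section_index = sections[[i]]$section_index,
                          tissue_mask = tissue_masks[[i]])
      })
    }
    ms <- lapply(seq_along(sections), function(i) {
      match_bundles(manual_list[[i]], rsets[[i]], min_frac = min_frac)
    })
    data.frame(threshold = th, tpr = tpr_pooled(ms), fpavg = fp_avg(ms))
  })
  curve <- do.call(rbind, pts)
  curve <- curve[order(curve$fpavg, curve$threshold), ]
  rownames(curve) <- NULL
  fmax <- max(curve$fpavg, 1e-9)
  d <- sqrt((curve$fpavg / fmax)^2 + (1 - curve$tpr)^2)
  attr(curve, "elbow") <- curve[which.min(d), ]
  class(curve) <- c("fb_froc", "data.frame")
  curve
}

#' Region-level evaluation report
#'
#' Matches predictions to manual bundles on every section and summarizes
#' TPR, FPavg and delta-FD.
#'
#' @param sections List of [fb_section()].
#' @param manual_list List of [fb_annotations()].
#' @param predicted_list List of `fb_regionset`.
#' @param min_frac Matching fraction (default 0.2).
#' @param fd_params A [clahe_params()] used for the delta-FD computation.
#' @param tissue_masks Optional list of tissue masks.
#' @return List with `tpr`, `fpavg`, `delta_fd_pct`, `per_section` (data
#'   frame) and `matches`.
#' @export
evaluate_detection <- function(sections, manual_list, predicted_list,
                               min_frac = 0.2, fd_params = clahe_params(),
                               tissue_masks = NULL) {
  n <- length(sections)
  matches <- vector("list", n)
  man_fd <- vector("list", n); pred_fd <- vector("list", n)
  per_section <- list()
  for (i in seq_len(n)) {
    matches[[i]] <- match_bundles(manual_list[[i]], predicted_list[[i]],
                                  min_frac = min_frac)
    tm <- if (is.null(tissue_masks)) NULL else tissue_masks[[i]]
    man_fd[[i]] <- vapply(region_masks(manual_list[[i]]), function(m) {
      fiber_density(fiber_binary_map(sections[[i]], m, fd_params,
                                     tissue_mask = tm), m)
    }, numeric(1))
    pred_fd[[i]] <- vapply(region_masks(predicted_list[[i]]), function(m) {
      fiber_density(fiber_binary_map(sections[[i]], m, fd_params,
                                     tissue_mask = tm), m)
    }, numeric(1))
    per_section[[i]] <- data.frame(
      section = sections[[i]]$section_index,
      n_manual = matches[[i]]$n_manual,
      n_detected = sum(matches[[i]]$detected),
      fp = matches[[i]]$fp_count)
  }
  dfd <- tryCatch(delta_fd(man_fd, pred_fd, matches), error = function(e) NA_real_)
  list(tpr = tpr_pooled(matches), fpavg = fp_avg(matches),
       delta_fd_pct = dfd, per_section = do.call(rbind, per_section),
       matches = matches)
}
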