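#' Connected regions of a binary segmentation
#'
#' Labels connected components of a binary mask and computes, per region,
#' its area in mm^2, centroid, and minimum distance to the tissue outline
#' in mm. Regions are the unit of detection evaluation and false-positive
#' filtering.
#'
#' @param mask H x W logical (or 0/1) mask.
#' @param um_per_px Pixel size in µm/pixel.
#' @param section_index Section position.
#' @param tissue_mask Optional H x W logical tissue mask; border distances
#'   are `NA` without it.
#' @return Object of class `fb_regionset`: list with `section_index`,
#'   `dim_hw`, `um_per_px` and `regions` (each with `mask`, `area_mm2`,
#'   `centroid_xy_px`, `min_border_dist_mm`).
#' @export
regions_from_mask <- function(mask, um_per_px, section_index = 0L,
                              tissue_mask = NULL) {
  mask <- mask > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1))))
  lab <- t(lab)
  border_dist <- NULL
  if (!is.null(tissue_mask)) {
    # distance of every tissue pixel to the tissue outline (its complement)
    border_dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(tissue_mask * 1))))
    border_dist <- t(border_dist)
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  regions <- lapply(ids, function(id) {
    m <- lab == id
    idx <- which(m, arr.ind = TRUE)
    list(mask = m,
         area_mm2 = px_to_mm2(nrow(idx), um_per_px),
         centroid_xy_px = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
         min_border_dist_mm = if (is.null(border_dist)) NA_real_ else
           min(border_dist[m]) * um_per_px / 1000,
         matched_bundle_id = NA_integer_)
  })
  structure(list(section_index = as.integer(section_index),
                 dim_hw = dim(mask), um_per_px = um_per_px,
                 regions = regions),
            class = "fb_regionset")
}

#' @export
print.fb_regionset <- function(x, ...) {
  cat(sprintf("<fb_regionset> section %d: %d regions\n",
              x$section_index, length(x$regions)))
  invisible(x)
}

#' Build a low-resolution aligned stack volume
#'
#' Downsamples each section's probability map by `downsample`, aligns
#' sections by translation using the centroid of the largest interior dark
#' cavity (ventricle proxy) when one exists, falling back to the lateral
#' edges of the tissue bounding box, and zero-pads all sections to a common
#' size. Offsets are recorded losslessly so results can be mapped back.
#'
#' @param sections List of [fb_section()] in rostro-caudal order (`>= 2`).
#' @param probability_maps List of `fb_probmap` (same order).
#' @param downsample Downsampling factor (default 10).
#' @param dark_quantile Intensity quantile below which tissue pixels count
#'   as cavity candidates (default 0.02 absolute intensity).
#' @return Object of class `fb_stackvolume`: list with `volume`
#'   (sections x h x w array), `offsets` (per-section row/col translation in
#'   low-res pixels), `downsample`, `dims`, `um_per_px`.
#' @export
build_stack <- function(sections, probability_maps, downsample = 10L,
                        dark_quantile = 0.02) {
  if (length(sections) < 2L) stop_cfg("continuity requires >= 2 sections")
  stopifnot(length(sections) == length(probability_maps))
  small <- lapply(probability_maps, function(pm) {
    p <- pm$probs
    h <- max(1L, floor(nrow(p) / downsample))
    w <- max(1L, floor(ncol(p) / downsample))
    t(EBImage::imageData(EBImage::resize(EBImage::Image(t(p)), w = w, h = h)))
  })
  landmarks <- lapply(sections, function(s) section_landmark(s, dark_quantile))
  # translate every section so its landmark matches the first section's
  ref <- landmarks[[1]]
  offsets <- lapply(landmarks, function(lm) {
    c(row = round((ref[1] - lm[1]) / downsample),
      col = round((ref[2] - lm[2]) / downsample))
  })
  hs <- vapply(small, nrow, integer(1)); ws <- vapply(small, ncol, integer(1))
  pad_h <- max(hs + abs(vapply(offsets, `[[`, numeric(1), "row")))
  pad_w <- max(ws + abs(vapply(offsets, `[[`, numeric(1), "col")))
  n <- length(small)
  vol <- array(0, dim = c(n, pad_h, pad_w))
  for (i in seq_len(n)) {
    orow <- offsets[[i]]["row"]; ocol <- offsets[[i]]["col"]
    sh <- nrow(small[[i]]); sw <- ncol(small[[i]])
    # destination index r holds source row r - orow
    rr <- max(1, 1 + orow):min(pad_h, sh + orow)
    cc <- max(1, 1 + ocol):min(pad_w, sw + ocol)
    vol[i, rr, cc] <- small[[i]][rr - orow, cc - ocol]
  }
  structure(list(volume = vol, offsets = offsets,
                 downsample = as.integer(downsample),
                 dims = lapply(probability_maps, function(pm) dim(pm$probs)),
                 um_per_px = sections[[1]]$um_per_px),
            class = "fb_stackvolume")
}

# Alignment landmark of a section: centroid (row, col) of the largest
# connected dark cavity interior to the tissue, else the midpoint of the
# tissue bounding box's lateral edges.
section_landmark <- function(section, dark_quantile = 0.02) {
  lum <- luminance(section$image)
  tissue <- lum > dark_quantile + 1e-6
  tissue_open <- EBImage::imageData(EBImage::opening(
    EBImage::Image(t(tissue * 1)), EBImage::makeBrush(5, "disc")))
  tissue <- t(tissue_open) > 0.5
  # interior dark pixels: dark and not connected to the image border region
  interior <- EBImage::imageData(EBImage::erode(
    EBImage::Image(t(tissue * 1)), EBImage::makeBrush(9, "disc")))
  interior <- t(interior) > 0.5
  cavity <- (!tissue | lum <= dark_quantile) & interior
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(cavity * 1)))))
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) > 0) {
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    if (sizes[big] >= 20) {
      idx <- which(lab == big, arr.ind = TRUE)
      return(c(mean(idx[, 1]), mean(idx[, 2])))
    }
  }
  idx <- which(tissue, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(nrow(lum) / 2, ncol(lum) / 2))
  # lateral edges of the tissue bounding box
  c(mean(range(idx[, 1])), mean(range(idx[, 2])))
}

#' Stack-level consensus of dense bundles
#'
#' Pluggable stage producing a low-resolution 3D mask of the main dense
#' bundles from the aligned stack. The default segmenter averages each
#' voxel's probability with its z-adjacent neighbours, smooths in-plane with
#' a small Gaussian kernel, and thresholds at the inference threshold; any
#' user-supplied 3D segmenter with signature `function(volume)` returning a
#' logical array of the same shape may replace it.
#'
#' @param stack An `fb_stackvolume` from [build_stack()].
#' @param threshold Threshold applied after z-averaging (default 0.4).
#' @param smooth_sigma In-plane Gaussian sigma in low-res pixels (default 1).
#' @param segmenter Optional replacement segmenter.
#' @return Logical array (sections x h x w).
#' @export
stack_consensus <- function(stack, threshold = 0.4, smooth_sigma = 1,
                            segmenter = NULL) {
  vol <- stack$volume
  if (!is.null(segmenter)) {
    out <- segmenter(vol)
    stopifnot(all(dim(out) == dim(vol)))
    return(out > 0)
  }
  n <- dim(vol)[1]
  zavg <- vol
  for (i in seq_len(n)) {
    zs <- max(1, i - 1):min(n, i + 1)
    zavg[i, , ] <- apply(vol[zs, , , drop = FALSE], c(2, 3), mean)
  }
  if (smooth_sigma > 0) {
    for (i in seq_len(n)) {
      zavg[i, , ] <- t(EBImage::imageData(EBImage::gblur(
        EBImage::Image(t(zavg[i, , ])), sigma = smooth_sigma)))
    }
  }
  zavg >= threshold
}

#' Full-resolution neighbour reference mask for one section
#'
#' Averages the consensus bundle masks of the up to two nearest neighbouring
#' sections (rostral and caudal, where available), maps them back through
#' the recorded offsets, upsamples to the section's resolution, and
#' thresholds the average at 0.5.
#'
#' @param consensus Logical array from [stack_consensus()].
#' @param stack The `fb_stackvolume` the consensus was computed from.
#' @param i Section position (1-based within the stack).
#' @return Logical H x W mask at full resolution.
#' @export
neighbor_reference <- function(consensus, stack, i) {
  n <- dim(consensus)[1]
  neigh <- c(i - 1, i + 1)
  neigh <- neigh[neigh >= 1 & neigh <= n]
  if (length(neigh) == 0) stop_cfg("no neighboring sections available")
  avg <- apply(consensus[neigh, , , drop = FALSE] * 1, c(2, 3), mean)
  ref_low <- avg >= 0.5
  # undo this section's offset, crop to its low-res extent, upsample
  orow <- stack$offsets[[i]]["row"]; ocol <- stack$offsets[[i]]["col"]
  dim_full <- stack$dims[[i]]
  h_low <- max(1L, floor(dim_full[1] / stack$downsample))
  w_low <- max(1L, floor(dim_full[2] / stack$downsample))
  out_low <- matrix(FALSE, h_low, w_low)
  for (r in seq_len(h_low)) {
    rr <- r + orow
    if (rr < 1 || rr > nrow(ref_low)) next
    cc <- seq_len(w_low) + ocol
    keep <- cc >= 1 & cc <= ncol(ref_low)
    out_low[r, keep] <- ref_low[rr, cc[keep]]
  }
  up <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(out_low * 1)),
                                             w = dim_full[2], h = dim_full[1])))
  up >= 0.5
}

#' Continuity-prior false-positive filter
#'
#' Removes a detected region when its minimum Euclidean distance (in mm,
#' over all its pixels) to the averaged bundle segmentation of the
#' neighbouring sections exceeds `max_dist_mm`. With an empty reference the
#' distance is infinite and all regions are removed (logged).
#'
#' @param regions An `fb_regionset`.
#' @param reference Logical H x W reference mask at full resolution (e.g.
#'   from [neighbor_reference()]).
#' @param max_dist_mm Distance threshold in mm (default 0.5).
#' @return Filtered `fb_regionset`; removed regions are recorded in
#'   `attr(, "removed")` with reasons.
#' @export
continuity_filter <- function(regions, reference, max_dist_mm = 0.5) {
  if (!all(dim(reference) == regions$dim_hw)) {
    stop_cfg("reference resolution does not match the section")
  }
  if (length(regions$regions) == 0) return(regions)
  dist_px <- distance_to_foreground(reference)
  keep <- logical(length(regions$regions))
  removed <- list()
  for (k in seq_along(regions$regions)) {
    r <- regions$regions[[k]]
    d_mm <- min(dist_px[r$mask]) * regions$um_per_px / 1000
    if (is.finite(d_mm) && d_mm <= max_dist_mm) {
      keep[k] <- TRUE
    } else {
      removed[[length(removed) + 1L]] <- list(
        centroid_xy_px = r$centroid_xy_px, area_mm2 = r$area_mm2,
        reason = "continuity", dist_mm = d_mm)
    }
  }
  out <- regions
  out$regions <- regions$regions[keep]
  attr(out, "removed") <- c(attr(regions, "removed"), removed)
  out
}

#' Morphological false-positive filter
#'
#' Keeps regions with area at least `min_area_mm2` and minimum distance from
#' the tissue outline at least `min_border_dist_mm`. Survivor masks are
#' returned unchanged.
#'
#' @param regions An `fb_regionset`.
#' @param min_area_mm2 Area floor in mm^2 (default 2).
#' @param min_border_dist_mm Border-distance floor in mm (default 0.5).
#' @param tissue_mask H x W logical tissue mask (used when the region set
#'   lacks precomputed border distances).
#' @return Filtered `fb_regionset` with removals recorded as in
#'   [continuity_filter()].
#' @export
morphology_filter <- function(regions, min_area_mm2 = 2.0,
                              min_border_dist_mm = 0.5, tissue_mask = NULL) {
  if (length(regions$regions) == 0) return(regions)
  border_dist <- NULL
  if (!is.null(tissue_mask)) {
    if (!all(dim(tissue_mask) == regions$dim_hw)) {
      stop_cfg("tissue mask size does not match the section")
    }
    border_dist <- t(EBImage::imageData(EBImage::distmap(
      EBImage::Image(t(tissue_mask * 1)))))
  }
  keep <- logical(length(regions$regions))
  removed <- list()
  for (k in seq_along(regions$regions)) {
    r <- regions$regions[[k]]
    bd <- if (!is.null(border_dist)) {
      min(border_dist[r$mask]) * regions$um_per_px / 1000
    } else r$min_border_dist_mm
    ok_area <- r$area_mm2 >= min_area_mm2
    ok_border <- is.na(bd) || bd >= min_border_dist_mm
    if (ok_area && ok_border) {
      keep[k] <- TRUE
    } else {
      removed[[length(removed) + 1L]] <- list(
        centroid_xy_px = r$centroid_xy_px, area_mm2 = r$area_mm2,
        reason = if (!ok_area) "area" else "border", dist_mm = bd)
    }
  }
  out <- regions
  out$regions <- regions$regions[keep]
  attr(out, "removed") <- c(attr(regions, "removed"), removed)
  out
}

#' Postprocess a stack of predictions
#'
#' Convenience wrapper running the full false-positive removal chain for
#' every section: binarize, extract regions, continuity filter against the
#' stack consensus of neighbouring sections (when `>= 2` sections are
#' available), then area/border morphological filtering.
#'
#' @param sections List of [fb_section()].
#' @param probability_maps List of `fb_probmap`.
#' @param tissue_masks List of H x W logical masks.
#' @param threshold Binarization threshold (default 0.4).
#' @param min_area_mm2,min_border_dist_mm,max_dist_mm Filter parameters.
#' @param use_continuity Apply the continuity prior (default TRUE when the
#'   stack has at least 2 sections).
#' @param downsample Stack downsampling factor (default 10).
#' @return List of filtered `fb_regionset`, one per section.
#' @export
postprocess_stack <- function(sections, probability_maps, tissue_masks,
                              threshold = 0.4, min_area_mm2 = 2.0,
                              min_border_dist_mm = 0.5, max_dist_mm = 0.5,
                              use_continuity = length(sections) >= 2,
                              downsample = 10L) {
  n <- length(sections)
  consensus <- NULL; stack <- NULL
  if (use_continuity && n >= 2) {
    stack <- build_stack(sections, probability_maps, downsample = downsample)
    consensus <- stack_consensus(stack, threshold = threshold)
  }
  lapply(seq_len(n), function(i) {
    rs <- regions_from_mask(binarize(probability_maps[[i]], threshold),
                            um_per_px = sections[[i]]$um_per_px,
                            section_index = sections[[i]]$section_index,
                            tissue_mask = tissue_masks[[i]])
    if (!is.null(consensus)) {
      ref <- neighbor_reference(consensus, stack, i)
      rs <- continuity_filter(rs, ref, max_dist_mm = max_dist_mm)
    }
    morphology_filter(rs, min_area_mm2 = min_area_mm2,
                      min_border_dist_mm = min_border_dist_mm,
                      tissue_mask = tissue_masks[[i]])
  })
}
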