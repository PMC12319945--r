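#' CLAHE parameters for fiber-density estimation
#'
#' @param enabled Apply contrast-limited adaptive histogram equalization
#'   before thresholding (default TRUE).
#' @param tiles Number of CLAHE tiles per dimension (default 8).
#' @param clip_limit CLAHE clip limit (default 2).
#' @param percentile Binarization percentile (default 0.95).
#' @param scope Where the percentile is computed: within the `"region"`
#'   (default) or over the tissue of the whole `"section"`. Region scope
#'   bounds the resulting density at `1 - percentile`; section scope lets
#'   dense bundles stand out against the section-wide intensity
#'   distribution and is used for pathway-level comparisons.
#' @return Object of class `fb_clahe_params`.
#' @export
clahe_params <- function(enabled = TRUE, tiles = 8L, clip_limit = 2,
                         percentile = 0.95, scope = c("region", "section")) {
  scope <- match.arg(scope)
  structure(list(enabled = enabled, tiles = as.integer(tiles),
                 clip_limit = clip_limit, percentile = percentile,
                 scope = scope),
            class = "fb_clahe_params")
}

#' Binary fiber map within a bundle region
#'
#' Converts the section to luminance, optionally enhances contrast with
#' CLAHE, computes the binarization threshold as the 95th percentile of the
#' enhanced intensities (within the region by default, or over the section
#' tissue), and marks pixels strictly above the threshold. The map is zero
#' outside the region. A region of constant intensity yields an empty map
#' (no pixel is strictly above its own value).
#'
#' @param section An [fb_section()] (or an H x W x 3 array / H x W matrix).
#' @param region_mask H x W logical mask, nonempty.
#' @param params A [clahe_params()].
#' @param tissue_mask Optional tissue mask used for section-scope
#'   percentiles (defaults to the whole image).
#' @return Logical H x W fiber map.
#' @export
fiber_binary_map <- function(section, region_mask, params = clahe_params(),
                             tissue_mask = NULL) {
  img <- if (inherits(section, "fb_section")) section$image else section
  region_mask <- region_mask > 0
  n_px <- sum(region_mask)
  if (n_px == 0) stop_cfg("region is empty")
  if (n_px < 20) warning("region smaller than 20 px; fiber density unreliable")
  lum <- luminance(img)
  if (params$enabled) {
    # CLAHE needs even tile multiples; pad by reflection and crop back
    h <- nrow(lum); w <- ncol(lum)
    mult <- 2L * params$tiles
    ph <- as.integer(ceiling(h / mult) * mult)
    pw <- as.integer(ceiling(w / mult) * mult)
    lp <- pad_reflect(lum, ph, pw)
    enh <- EBImage::imageData(EBImage::clahe(EBImage::Image(t(lp)),
                                             nx = params$tiles,
                                             ny = params$tiles,
                                             limit = params$clip_limit))
    lum <- t(enh)[seq_len(h), seq_len(w)]
  }
  pool <- if (params$scope == "region") {
    lum[region_mask]
  } else if (!is.null(tissue_mask)) {
    lum[tissue_mask > 0]
  } else {
    as.vector(lum)
  }
  thr <- stats::quantile(pool, params$percentile, names = FALSE, type = 7)
  (lum > thr) & region_mask
}

#' Fiber density of a bundle region
#'
#' Number of fiber-map pixels inside the region over the region's pixel
#' count.
#'
#' @param fiber_map Logical H x W fiber map (e.g. [fiber_binary_map()]).
#' @param region_mask Logical H x W region mask, nonempty.
#' @return Scalar in `[0, 1]`.
#' @export
fiber_density <- function(fiber_map, region_mask) {
  region_mask <- region_mask > 0
  n <- sum(region_mask)
  if (n == 0) stop_cfg("region is empty")
  sum(fiber_map & region_mask) / n
}

#' Assign a region to a white-matter pathway
#'
#' The region is assigned to the pathway with the largest fractional
#' overlap (intersection over region area) provided that fraction exceeds
#' `min_overlap`; otherwise `"none"`. Ties are broken by larger absolute
#' intersection, then by the fixed pathway order of the ROI labels.
#'
#' @param region_mask Logical H x W mask.
#' @param pathway_rois Integer H x W label matrix (0 = background, k = k-th
#'   pathway) with an optional `pathways` attribute naming the labels
#'   (default `c("IC", "CC", "UF")`).
#' @param min_overlap Minimum overlap fraction (default 0.4).
#' @return Pathway name or `"none"`.
#' @export
assign_pathway <- function(region_mask, pathway_rois, min_overlap = 0.4) {
  region_mask <- region_mask > 0
  n <- sum(region_mask)
  if (n == 0) return("none")
  nms <- attr(pathway_rois, "pathways")
  ids <- setdiff(sort(unique(as.vector(pathway_rois))), 0)
  if (length(ids) == 0) return("none")
  if (is.null(nms)) nms <- c("IC", "CC", "UF")
  inter <- vapply(ids, function(id) sum(region_mask & pathway_rois == id),
                  numeric(1))
  frac <- inter / n
  ord <- order(-frac, -inter, seq_along(ids))
  bestk <- ord[1]
  if (frac[bestk] > min_overlap) {
    id <- ids[bestk]
    if (id <= length(nms)) nms[id] else paste0("pathway", id)
  } else "none"
}

#' One-way ANOVA of fiber density across pathways
#'
#' Standard one-way analysis of variance with fiber density as the
#' dependent variable and pathway as the grouping factor, plus per-group
#' mean and standard error.
#'
#' @param fd_table Data frame with columns `pathway` and `fd`.
#' @return List with `F`, `p`, `df`, and `groups` (data frame with
#'   `pathway`, `n`, `mean`, `se`).
#' @export
pathway_anova <- function(fd_table) {
  fd_table <- fd_table[!is.na(fd_table$fd) & fd_table$pathway != "none", ,
                       drop = FALSE]
  counts <- table(fd_table$pathway)
  if (length(counts) < 2 || any(counts < 2)) {
    stop_cfg("need >= 2 groups with >= 2 observations each")
  }
  fd_table$pathway <- factor(fd_table$pathway)
  fit <- stats::aov(fd ~ pathway, data = fd_table)
  an <- summary(fit)[[1]]
  groups <- do.call(rbind, lapply(levels(fd_table$pathway), function(g) {
    v <- fd_table$fd[fd_table$pathway == g]
    data.frame(pathway = g, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]), groups = groups)
}

#' Fiber-density table for a set of regions
#'
#' Computes FD and pathway assignment for every region of every section.
#'
#' @param sections List of [fb_section()].
#' @param regionsets List of `fb_regionset` (or [fb_annotations()]; masks
#'   are taken from either).
#' @param pathway_rois_list List of pathway ROI label matrices (or `NULL`).
#' @param params A [clahe_params()].
#' @param tissue_masks Optional list of tissue masks for section-scope
#'   percentiles.
#' @param min_overlap Pathway assignment threshold (default 0.4).
#' @return Data frame with columns `case`, `section`, `bundle`, `pathway`,
#'   `fd`, `n_px`.
#' @export
fd_table <- function(sections, regionsets, pathway_rois_list = NULL,
                     params = clahe_params(), tissue_masks = NULL,
                     min_overlap = 0.4) {
  rows <- list()
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    rs <- regionsets[[i]]
    masks <- if (inherits(rs, "fb_annotations")) {
      lapply(rs$regions, `[[`, "mask")
    } else if (inherits(rs, "fb_regionset")) {
      lapply(rs$regions, `[[`, "mask")
    } else rs
    for (k in seq_along(masks)) {
      m <- masks[[k]] > 0
      if (!any(m)) next
      fmap <- fiber_binary_map(sec, m, params,
                               tissue_mask = if (is.null(tissue_masks)) NULL
                                             else tissue_masks[[i]])
      pw <- if (is.null(pathway_rois_list) || is.null(pathway_rois_list[[i]])) {
        "none"
      } else {
        assign_pathway(m, pathway_rois_list[[i]], min_overlap)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case = sec$case_id, section = sec$section_index, bundle = k,
        pathway = pw, fd = fiber_density(fmap, m), n_px = sum(m))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(case = character(0), section = integer(0),
                      bundle = integer(0), pathway = character(0),
                      fd = numeric(0), n_px = integer(0)))
  }
  do.call(rbind, rows)
}
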