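#' Configuration for the synthetic dark-field section generator
#'
#' Describes a stack of synthetic coronal sections that emulate dark-field
#' photomicrographs from tracer experiments: a dark, gently graded tissue
#' background, bright curvilinear fiber strokes clustered into elongated
#' bundle regions inside the white matter, and the confounders that drive
#' false positives in real data (isotropic terminal-field speckle, glare
#' blobs, a bright band at the section border). Bundles persist across
#' consecutive sections with a bounded centroid drift, so cross-section
#' continuity holds by construction.
#'
#' @param image_height_px,image_width_px Section dimensions in pixels.
#' @param um_per_px Physical pixel size (µm/pixel), `> 0`.
#' @param n_sections Number of sections in the stack, `>= 1`.
#' @param section_spacing_mm Distance between consecutive annotated sections
#'   (mm); default 1.2.
#' @param n_bundles Number of fiber bundles (0 allowed). The first three are
#'   placed one per white-matter pathway (IC, CC, UF); any further bundles
#'   are placed in free white matter.
#' @param fiber_area_fraction_range Per-bundle target range for the fraction
#'   of bright (stroke) pixels within the bundle region; default
#'   `c(0.02, 0.20)`.
#' @param bundle_axis_ratio_range Range of bundle elongation (long/short
#'   half-axis).
#' @param background_mean Mean background intensity in `[0, 1]`.
#' @param background_gradient_amp Amplitude of the smooth intensity gradient.
#' @param confounder_counts List with `terminal_fields` and `glare` counts
#'   per section.
#' @param drift_mm_per_section Upper bound on per-section bundle centroid
#'   drift (mm).
#' @param terminal_field_brightness Peak brightness of terminal-field
#'   speckle relative to full scale (exposed because its level relative to
#'   bundles is a free parameter of the simulation).
#' @param seed Integer seed; a fixed seed fixes every output byte.
#' @return Object of class `fb_synth_config`.
#' @export
synth_config <- function(image_height_px = 512L, image_width_px = 512L,
                         um_per_px = 20, n_sections = 20L,
                         section_spacing_mm = 1.2, n_bundles = 3L,
                         fiber_area_fraction_range = c(0.02, 0.20),
                         bundle_axis_ratio_range = c(2.2, 3.2),
                         background_mean = 0.08,
                         background_gradient_amp = 0.04,
                         confounder_counts = list(terminal_fields = 2L, glare = 2L),
                         drift_mm_per_section = 0.3,
                         terminal_field_brightness = 0.85,
                         seed = 1L) {
  if (image_height_px <= 0 || image_width_px <= 0) {
    stop_cfg("image dimensions must be positive")
  }
  if (um_per_px <= 0) stop_cfg("um_per_px must be > 0")
  if (n_sections < 1) stop_cfg("n_sections must be >= 1")
  r <- fiber_area_fraction_range
  if (length(r) != 2 || r[1] < 0 || r[2] > 1 || r[1] >= r[2]) {
    stop_cfg("fiber_area_fraction_range must lie in [0,1] with low < high")
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    um_per_px = um_per_px, n_sections = as.integer(n_sections),
    section_spacing_mm = section_spacing_mm, n_bundles = as.integer(n_bundles),
    fiber_area_fraction_range = r,
    bundle_axis_ratio_range = bundle_axis_ratio_range,
    background_mean = background_mean,
    background_gradient_amp = background_gradient_amp,
    confounder_counts = confounder_counts,
    drift_mm_per_section = drift_mm_per_section,
    terminal_field_brightness = terminal_field_brightness,
    seed = as.integer(seed)
  ), class = "fb_synth_config")
}

# Intensity above which a pixel counts as "bright" (stroke) when measuring
# the fiber-area fraction of a synthetic bundle.
SYNTH_BRIGHT_THRESHOLD <- 0.45

#' Measured bright-pixel fraction within a region
#'
#' The generator's own definition of fiber-area fraction: fraction of region
#' pixels whose luminance exceeds the stroke threshold (0.45).
#'
#' @param image H x W x 3 array or H x W matrix.
#' @param region_mask H x W logical mask.
#' @return Scalar fraction.
#' @export
bright_fraction <- function(image, region_mask) {
  lum <- luminance(image)
  mean(lum[region_mask] > SYNTH_BRIGHT_THRESHOLD)
}

# Elliptical mask helper: center (r0, c0) in 1-based pixel rows/cols,
# half-axes (a along orientation theta, b across), theta in radians measured
# in (col, row) coordinates.
ellipse_mask <- function(h, w, r0, c0, a, b, theta = 0) {
  dy <- matrix(seq_len(h) - r0, h, w)
  dx <- matrix(seq_len(w) - c0, h, w, byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Deterministic stack-level schedule: tissue geometry, pathway layout, and
# per-bundle trajectories (centroid path, axes, orientation, target fiber
# fraction, density category, first/last section). Everything downstream of
# the seed; generate_section() renders from this so per-section calls agree
# with generate_stack().
#' @keywords internal
synth_schedule <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  ctr <- c(h / 2, w / 2)
  tissue <- list(r0 = ctr[1], c0 = ctr[2], a = 0.44 * w, b = 0.46 * h)
  wm <- list(r0 = ctr[1], c0 = ctr[2], a = 0.31 * w, b = 0.33 * h)
  vent <- list(r0 = ctr[1] + 0.02 * h, c0 = ctr[2], a = 0.015 * w, b = 0.05 * h)
  # pathway bands inside the white matter: IC left (vertical), CC top
  # (horizontal), UF right (vertical)
  pathways <- list(
    IC = list(r0 = ctr[1], c0 = ctr[2] - 0.19 * w, a = 0.21 * h, b = 0.08 * w,
              theta = pi / 2),
    CC = list(r0 = ctr[1] - 0.23 * h, c0 = ctr[2], a = 0.21 * w, b = 0.08 * h,
              theta = 0),
    UF = list(r0 = ctr[1], c0 = ctr[2] + 0.19 * w, a = 0.21 * h, b = 0.08 * w,
              theta = pi / 2)
  )
  drift_px <- mm_to_px(cfg$drift_mm_per_section, cfg$um_per_px)
  lo <- cfg$fiber_area_fraction_range[1]; hi <- cfg$fiber_area_fraction_range[2]
  # per-pathway fiber-fraction bands (clipped into the configured range):
  # internal-capsule bundles run denser than callosal/uncinate ones
  band_for <- function(p) {
    raw <- switch(p, IC = c(0.11, 0.16), CC = c(0.08, 0.13),
                  UF = c(0.07, 0.12), other = c(lo, hi))
    b <- c(max(raw[1], lo), min(raw[2], min(hi * 0.85, hi - 0.01)))
    if (b[1] >= b[2]) b <- c(lo, lo + 0.85 * (hi - lo))
    b
  }
  with_seed(derive_seed(cfg$seed, 1L), {
    bundles <- list()
    if (cfg$n_bundles > 0) {
      pw_names <- c("IC", "CC", "UF")
      for (k in seq_len(cfg$n_bundles)) {
        pw <- if (k <= 3) pw_names[k] else "other"
        geom <- if (pw == "other") {
          list(r0 = ctr[1] + runif(1, -0.1, 0.1) * h,
               c0 = ctr[2] + runif(1, -0.1, 0.1) * w,
               a = 0.18 * w, b = 0.18 * h, theta = runif(1, 0, pi))
        } else pathways[[pw]]
        ratio <- runif(1, cfg$bundle_axis_ratio_range[1],
                       cfg$bundle_axis_ratio_range[2])
        # long half-axis scaled to the section; area ~ 2.5-4x the 2 mm^2
        # post-processing floor at the default calibration
        a_len <- runif(1, 0.16, 0.19) * min(h, w)
        b_len <- max(a_len / ratio, 6)
        band <- band_for(pw)
        f_target <- runif(1, band[1], band[2])
        sec_start <- 0L
        sec_end <- cfg$n_sections - 1L
        if (k == 3L && cfg$n_sections >= 5L) {
          sec_end <- as.integer(floor(0.7 * (cfg$n_sections - 1L)))
        }
        # random-walk centroid path clamped inside the pathway band
        centers <- matrix(0, cfg$n_sections, 2)
        u_max <- max(geom$a - a_len - 4, 4)  # slack along band axis
        v_max <- 6                            # slack across band axis
        u <- runif(1, -0.5, 0.5) * u_max; v <- runif(1, -v_max, v_max)
        for (i in seq_len(cfg$n_sections)) {
          if (i > 1) {
            ang <- runif(1, 0, 2 * pi)
            step <- runif(1, 0.3, 0.7) * drift_px
            u <- clamp(u + step * cos(ang), -u_max, u_max)
            v <- clamp(v + step * sin(ang), -v_max, v_max)
          }
          th <- geom$theta
          centers[i, ] <- c(geom$r0 + u * sin(th) + v * cos(th),
                            geom$c0 + u * cos(th) - v * sin(th))
        }
        bundles[[k]] <- list(
          id = k, pathway = pw, a = a_len, b = b_len,
          theta = geom$theta + runif(1, -0.1, 0.1),
          fiber_fraction = f_target,
          density = if (f_target >= 0.11) "dense" else "moderate",
          section_start = sec_start, section_end = sec_end,
          centers = centers)
      }
    }
    grad_dir <- runif(1, 0, 2 * pi)
    list(tissue = tissue, wm = wm, ventricle = vent, pathways = pathways,
         bundles = bundles, grad_dir = grad_dir, drift_px = drift_px)
  })
}

# Paint one curvilinear stroke onto `canvas` starting at (r, c) with initial
# direction phi, staying inside the support mask. Core pixels get intensity
# `inten`, 4-neighbors a faint shoulder. Returns the updated canvas.
paint_stroke <- function(canvas, support, r, c, phi, len, inten) {
  h <- nrow(canvas); w <- ncol(canvas)
  for (s in seq_len(len)) {
    ri <- round(r); ci <- round(c)
    if (ri < 2 || ri > h - 1 || ci < 2 || ci > w - 1 || !support[ri, ci]) break
    canvas[ri, ci] <- max(canvas[ri, ci], inten)
    sh <- 0.25 * inten
    canvas[ri - 1, ci] <- max(canvas[ri - 1, ci], sh)
    canvas[ri + 1, ci] <- max(canvas[ri + 1, ci], sh)
    canvas[ri, ci - 1] <- max(canvas[ri, ci - 1], sh)
    canvas[ri, ci + 1] <- max(canvas[ri, ci + 1], sh)
    r <- r + sin(phi); c <- c + cos(phi)
    phi <- phi + rnorm(1, 0, 0.06)
  }
  canvas
}

#' Generate one synthetic section
#'
#' Renders section `section_index` of the stack described by `cfg`: dark
#' graded background with a ventricle cavity, bright oriented fiber strokes
#' within elongated bundle regions (bright-pixel fraction inside each region
#' within the configured range), and confounders placed outside bundle
#' regions. Calling twice with the same config yields identical output.
#'
#' @param cfg A [synth_config()].
#' @param section_index 0-based index in `[0, n_sections)`.
#' @param schedule Optional precomputed [synth_schedule()] (computed from
#'   `cfg` when `NULL`).
#' @return List with elements `section` ([fb_section()]), `annotations`
#'   ([fb_annotations()]), `white_matter_mask`, `pathway_rois` (integer
#'   label matrix: 1 = IC, 2 = CC, 3 = UF), `tissue_mask`,
#'   `confounder_mask`.
#' @export
generate_section <- function(cfg, section_index, schedule = NULL) {
  if (section_index < 0 || section_index >= cfg$n_sections) {
    stop_cfg("section_index out of range [0, %d)", cfg$n_sections)
  }
  if (is.null(schedule)) schedule <- synth_schedule(cfg)
  h <- cfg$image_height_px; w <- cfg$image_width_px
  sc <- schedule
  tissue <- ellipse_mask(h, w, sc$tissue$r0, sc$tissue$c0, sc$tissue$a, sc$tissue$b)
  wm <- ellipse_mask(h, w, sc$wm$r0, sc$wm$c0, sc$wm$a, sc$wm$b)
  vent <- ellipse_mask(h, w, sc$ventricle$r0, sc$ventricle$c0,
                       sc$ventricle$a, sc$ventricle$b)
  pw_rois <- matrix(0L, h, w)
  for (k in seq_along(sc$pathways)) {
    p <- sc$pathways[[k]]
    m <- ellipse_mask(h, w, p$r0, p$c0, p$a, p$b, p$theta) & wm
    pw_rois[m & pw_rois == 0L] <- k
  }

  out <- with_seed(derive_seed(cfg$seed, 100L + section_index), {
    # --- background: mean + smooth gradient + coarse mottle
    gx <- cos(sc$grad_dir); gy <- sin(sc$grad_dir)
    xg <- matrix(seq_len(w) / w - 0.5, h, w, byrow = TRUE)
    yg <- matrix(seq_len(h) / h - 0.5, h, w)
    bg <- cfg$background_mean + cfg$background_gradient_amp * (gx * xg + gy * yg)
    mot <- matrix(runif(ceiling(h / 32) * ceiling(w / 32), -1, 1),
                  ceiling(h / 32), ceiling(w / 32))
    mot <- EBImage::imageData(EBImage::resize(EBImage::Image(t(mot)), w = w, h = h))
    mot <- t(mot)
    bg <- bg + 0.015 * mot
    bg[!tissue] <- 0.02
    bg[vent] <- 0.015

    # --- bundles: strokes painted into elliptical supports
    strokes <- matrix(0, h, w)
    regions <- list()
    bundle_union <- matrix(FALSE, h, w)
    for (bd in sc$bundles) {
      if (section_index < bd$section_start || section_index > bd$section_end) next
      ctr <- bd$centers[section_index + 1L, ]
      reg <- ellipse_mask(h, w, ctr[1], ctr[2], bd$a, bd$b, bd$theta)
      inner <- ellipse_mask(h, w, ctr[1], ctr[2], max(bd$a - 3, 2),
                            max(bd$b - 3, 2), bd$theta)
      n_reg <- sum(reg)
      if (n_reg < 30) next
      target_px <- bd$fiber_fraction * n_reg
      len <- max(12L, min(as.integer(round(1.6 * bd$a)),
                          as.integer(ceiling(target_px / 8))))
      guard <- 0L
      while (sum(reg & strokes > SYNTH_BRIGHT_THRESHOLD) < target_px &&
             guard < 4000L) {
        guard <- guard + 1L
        # start point uniform in the inner ellipse
        uu <- runif(1, -0.95, 0.95) * (bd$a - 3)
        vv <- runif(1, -0.95, 0.95) * (bd$b - 3)
        if ((uu / max(bd$a - 3, 2))^2 + (vv / max(bd$b - 3, 2))^2 > 1) next
        r0 <- ctr[1] + uu * sin(bd$theta) + vv * cos(bd$theta)
        c0 <- ctr[2] + uu * cos(bd$theta) - vv * sin(bd$theta)
        phi <- bd$theta + rnorm(1, 0, 0.15) + sample(c(0, pi), 1)
        strokes <- paint_stroke(strokes, inner, r0, c0, phi, len,
                                runif(1, 0.6, 0.95))
      }
      regions[[length(regions) + 1L]] <-
        list(mask = reg, density = bd$density, bundle_id = bd$id,
             pathway = bd$pathway, centroid_rc = ctr)
      bundle_union <- bundle_union | reg
    }

    # --- confounders, placed outside bundle regions
    conf <- matrix(FALSE, h, w)
    margin_px <- mm_to_px(0.8, cfg$um_per_px)
    bundle_dist <- distance_to_foreground(bundle_union)
    glare_add <- matrix(0, h, w)
    dy <- matrix(seq_len(h), h, w); dx <- matrix(seq_len(w), h, w, byrow = TRUE)
    n_tf <- cfg$confounder_counts$terminal_fields
    if (is.null(n_tf)) n_tf <- 0L
    cortex <- tissue & !ellipse_mask(h, w, sc$wm$r0, sc$wm$c0,
                                     1.12 * sc$wm$a, 1.12 * sc$wm$b)
    cortex_idx <- which(cortex & bundle_dist > margin_px)
    for (j in seq_len(n_tf)) {
      if (length(cortex_idx) == 0) break
      ci <- cortex_idx[sample.int(length(cortex_idx), 1)]
      rr <- (ci - 1) %% h + 1; cc <- (ci - 1) %/% h + 1
      rad <- runif(1, 14, 22)
      disc <- (dy - rr)^2 + (dx - cc)^2 <= rad^2
      disc <- disc & tissue
      idx <- which(disc)
      ndots <- max(8L, round(0.10 * length(idx)))
      dots <- idx[sample.int(length(idx), min(ndots, length(idx)))]
      amp <- cfg$terminal_field_brightness
      strokes[dots] <- pmax(strokes[dots], runif(length(dots), 0.65 * amp, amp))
      conf <- conf | disc
    }
    n_gl <- cfg$confounder_counts$glare
    if (is.null(n_gl)) n_gl <- 0L
    tissue_idx <- which(tissue & bundle_dist > margin_px & !conf)
    for (j in seq_len(n_gl)) {
      if (length(tissue_idx) == 0) break
      ci <- tissue_idx[sample.int(length(tissue_idx), 1)]
      rr <- (ci - 1) %% h + 1; cc <- (ci - 1) %/% h + 1
      rad <- runif(1, 6, 12)
      d2 <- (dy - rr)^2 + (dx - cc)^2
      glare_add <- glare_add + runif(1, 0.55, 0.8) * exp(-d2 / (2 * (rad / 2)^2))
      conf <- conf | (d2 <= rad^2)
    }
    # bright band along the section border (mounting glare)
    un <- ((dx - sc$tissue$c0) / sc$tissue$a)^2 + ((dy - sc$tissue$r0) / sc$tissue$b)^2
    band <- un <= 1 & un >= 0.94 & bundle_dist > margin_px
    bg[band] <- bg[band] + 0.30
    conf <- conf | band

    # --- compose channels with slight correlation
    wch <- c(1.0, 0.95, 0.85)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      img[, , ch] <- clamp(bg * wch[ch] + strokes * wch[ch] + glare_add +
                             matrix(rnorm(h * w, 0, 0.012), h, w), 0, 1)
    }
    list(img = img, regions = regions, conf = conf)
  })

  section <- fb_section(out$img, um_per_px = cfg$um_per_px,
                        case_id = "synthetic", section_index = section_index,
                        spacing_mm = cfg$section_spacing_mm)
  list(section = section,
       annotations = fb_annotations(section_index, out$regions),
       white_matter_mask = wm,
       pathway_rois = structure(pw_rois, pathways = names(sc$pathways)),
       tissue_mask = tissue,
       confounder_mask = out$conf)
}

#' Generate a synthetic section stack
#'
#' Generates all `n_sections` sections of the configured stack. Consecutive
#' sections share bundle identities and bundle centroids drift by at most
#' `drift_mm_per_section` between neighbors. Optionally withholds the
#' annotations of some sections (images kept), emulating unlabeled data.
#'
#' @param cfg A [synth_config()].
#' @param labeled_sections Optional integer vector of 0-based section
#'   indices that keep their annotations; all other sections have
#'   `annotations = NULL` (the generator's ground truth is still returned
#'   under `truth` for evaluation).
#' @return List of per-section outputs as in [generate_section()], each with
#'   an extra `truth` element holding the full annotation set, plus an
#'   attribute `schedule`.
#' @export
generate_stack <- function(cfg, labeled_sections = NULL) {
  schedule <- synth_schedule(cfg)
  out <- lapply(seq_len(cfg$n_sections) - 1L, function(i) {
    s <- generate_section(cfg, i, schedule = schedule)
    s$truth <- s$annotations
    if (!is.null(labeled_sections) && !(i %in% labeled_sections)) {
      s$annotations <- NULL
    }
    s
  })
  attr(out, "schedule") <- schedule
  out
}

#' Write a synthetic stack to disk
#'
#' Sections as PNG, bundle masks / white-matter masks / pathway ROIs as
#' label PNGs, and a stack manifest CSV.
#'
#' @param stack Output of [generate_stack()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_synthetic_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(stack, function(s) {
    i <- s$section$section_index
    img_path <- file.path(dir, sprintf("section_%03d.png", i))
    write_section(s$section, img_path)
    mask_path <- ""
    if (!is.null(s$annotations)) {
      mask_path <- file.path(dir, sprintf("bundles_%03d.png", i))
      write_label_mask(annotations_to_labelmask(s$annotations,
                                                dim(s$section$image)[1:2]),
                       mask_path)
    }
    wm_path <- file.path(dir, sprintf("wm_%03d.png", i))
    write_label_mask(s$white_matter_mask * 1L, wm_path)
    pw_path <- file.path(dir, sprintf("pathways_%03d.png", i))
    write_label_mask(s$pathway_rois, pw_path)
    data.frame(section_index = i, image = img_path, mask = mask_path,
               wm_mask = wm_path, pathway_rois = pw_path,
               um_per_px = s$section$um_per_px,
               spacing_mm = s$section$spacing_mm,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
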