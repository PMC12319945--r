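#' Positive-pair augmentation policy
#'
#' Controls how the contrastive positive partner of an anchor patch is
#' built: a nearby crop (center displaced by less than `max_crop_offset_um`),
#' anatomically constrained to white matter either by an explicit mask or by
#' resampling until the candidate's mean intensity falls in
#' `wm_mean_intensity_range`, followed by noise injection and Gaussian
#' blurring.
#'
#' @param max_crop_offset_um Maximum center displacement in µm (default 20).
#' @param wm_mean_intensity_range Accepted band for the candidate patch's
#'   mean grayscale intensity (used when no white-matter mask is given).
#' @param max_resample_attempts Resampling budget (default 50).
#' @param noise_std Additive Gaussian noise std on full scale (default 0.02).
#' @param blur_sigma_range Range for the blur sigma, default `c(0.05, 0.3)`.
#' @param augment_both Apply noise+blur to both patches of the pair instead
#'   of the second only (default FALSE).
#' @return Object of class `fb_pair_policy`.
#' @export
pair_policy <- function(max_crop_offset_um = 20, wm_mean_intensity_range = c(0, 1),
                        max_resample_attempts = 50L, noise_std = 0.02,
                        blur_sigma_range = c(0.05, 0.3), augment_both = FALSE) {
  if (max_crop_offset_um < 0) stop_cfg("offsets must be >= 0")
  if (blur_sigma_range[1] > blur_sigma_range[2]) stop_cfg("blur range low must be <= high")
  structure(list(max_crop_offset_um = max_crop_offset_um,
                 wm_mean_intensity_range = wm_mean_intensity_range,
                 max_resample_attempts = as.integer(max_resample_attempts),
                 noise_std = noise_std, blur_sigma_range = blur_sigma_range,
                 augment_both = augment_both),
            class = "fb_pair_policy")
}

#' Geometric augmentation policy for segmentation training
#'
#' @param translation_px Range of the translation offset (default
#'   `c(-50, 50)`).
#' @param rotation_deg Rotation range in degrees (default `c(-20, 20)`).
#' @param hflip,vflip Allow horizontal / vertical flips.
#' @param scale Scaling range (default `c(0.9, 1.2)`).
#' @return Object of class `fb_geom_policy`.
#' @export
geom_policy <- function(translation_px = c(-50, 50), rotation_deg = c(-20, 20),
                        hflip = TRUE, vflip = TRUE, scale = c(0.9, 1.2)) {
  structure(list(translation_px = translation_px, rotation_deg = rotation_deg,
                 hflip = hflip, vflip = vflip, scale = scale),
            class = "fb_geom_policy")
}

crop_at <- function(img, r, c, s) {
  half <- s %/% 2L
  img[(r - half):(r - half + s - 1L), (c - half):(c - half + s - 1L), , drop = FALSE]
}

blur_rgb <- function(patch, sigma) {
  # EBImage's Gaussian filter needs an odd kernel covering the sigma
  e <- EBImage::Image(aperm(patch, c(2, 1, 3)), colormode = "Color")
  b <- EBImage::gblur(e, sigma = max(sigma, 0.01))
  aperm(EBImage::imageData(b), c(2, 1, 3))
}

#' Build an anatomy-constrained contrastive positive pair
#'
#' Crops the anchor patch and a partner patch whose center is displaced by
#' at most `max_crop_offset_um` (converted through the section's pixel
#' size). The partner is resampled until it is anatomically plausible white
#' matter: at least 80% of its pixels inside `wm_mask` when given, otherwise
#' mean grayscale intensity within the policy band. The partner then
#' receives additive Gaussian noise and a Gaussian blur with sigma drawn
#' from the policy range. If no candidate passes within the resampling
#' budget, an anchor-centered fallback is used with a warning.
#'
#' @param section An [fb_section()].
#' @param anchor_xy Anchor patch center as `c(row, col)` (1-based pixels).
#' @param policy A [pair_policy()].
#' @param wm_mask Optional H x W logical white-matter mask.
#' @param seed Integer seed; fixed seed gives an identical pair.
#' @param patch_size Patch side in pixels (default 256).
#' @return List with `patch_a`, `patch_b` (S x S x 3 arrays) and
#'   `offset_px` (achieved center displacement).
#' @export
make_positive_pair <- function(section, anchor_xy, policy = pair_policy(),
                               wm_mask = NULL, seed = 1L, patch_size = 256L) {
  img <- section$image
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- as.integer(patch_size)
  half <- s %/% 2L
  r_lo <- half + 1L; r_hi <- h - (s - half) + 1L
  c_lo <- half + 1L; c_hi <- w - (s - half) + 1L
  ar <- anchor_xy[1]; ac <- anchor_xy[2]
  if (ar < r_lo || ar > r_hi || ac < c_lo || ac > c_hi) {
    stop_cfg("anchor patch does not fit in the image")
  }
  max_off_px <- um_to_px(policy$max_crop_offset_um, section$um_per_px)
  with_seed(seed, {
    patch_a <- crop_at(img, ar, ac, s)
    ok <- FALSE; br <- ar; bc <- ac
    for (attempt in seq_len(policy$max_resample_attempts)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, max_off_px)
      cr <- as.integer(round(clamp(ar + rad * sin(ang), r_lo, r_hi)))
      cc <- as.integer(round(clamp(ac + rad * cos(ang), c_lo, c_hi)))
      # respect the physical bound after clamping/rounding
      if (sqrt((cr - ar)^2 + (cc - ac)^2) > max_off_px) next
      cand <- crop_at(img, cr, cc, s)
      accept <- if (!is.null(wm_mask)) {
        mean(wm_mask[(cr - half):(cr - half + s - 1L),
                     (cc - half):(cc - half + s - 1L)]) >= 0.8
      } else {
        m <- mean(luminance(cand))
        m >= policy$wm_mean_intensity_range[1] && m <= policy$wm_mean_intensity_range[2]
      }
      if (accept) { ok <- TRUE; br <- cr; bc <- cc; break }
    }
    if (!ok) {
      warning("no valid positive-pair candidate after max attempts; using anchor-centered fallback")
    }
    patch_b <- crop_at(img, br, bc, s)
    aug <- function(p) {
      if (policy$noise_std > 0) {
        p <- p + array(rnorm(length(p), 0, policy$noise_std), dim = dim(p))
      }
      sigma <- runif(1, policy$blur_sigma_range[1], policy$blur_sigma_range[2])
      clamp(blur_rgb(p, sigma), 0, 1)
    }
    patch_b <- aug(patch_b)
    if (policy$augment_both) patch_a <- aug(patch_a)
    list(patch_a = patch_a, patch_b = patch_b,
         offset_px = sqrt((br - ar)^2 + (bc - ac)^2))
  })
}

#' Geometric augmentation of a patch and its labels
#'
#' Draws translation, rotation, flips and scale uniformly from the policy
#' ranges and applies the identical spatial transform to the image
#' (bilinear) and the label map (nearest neighbour), so labels stay binary.
#'
#' @param patch S x S x 3 array.
#' @param pixel_labels S x S matrix in `{0, 1}` or `NULL`.
#' @param policy A [geom_policy()].
#' @param seed Integer seed.
#' @return List with `patch` and `pixel_labels` after transformation.
#' @export
geometric_augment <- function(patch, pixel_labels = NULL,
                              policy = geom_policy(), seed = 1L) {
  stopifnot(is.null(pixel_labels) ||
              all(dim(pixel_labels) == dim(patch)[1:2]))
  with_seed(seed, {
    tx <- runif(1, policy$translation_px[1], policy$translation_px[2])
    ty <- runif(1, policy$translation_px[1], policy$translation_px[2])
    th <- runif(1, policy$rotation_deg[1], policy$rotation_deg[2]) * pi / 180
    sc <- runif(1, policy$scale[1], policy$scale[2])
    fh <- policy$hflip && runif(1) < 0.5
    fv <- policy$vflip && runif(1) < 0.5
    apply_geom_transform(patch, pixel_labels,
                         list(tx = tx, ty = ty, theta = th, scale = sc,
                              hflip = fh, vflip = fv))
  })
}

# Apply an explicit parameter draw (rotation about the patch center, then
# scale, flips, translation). Exposed internally so tests can exercise
# specific draws such as the identity or +/- rotations.
apply_geom_transform <- function(patch, pixel_labels, par) {
  s <- dim(patch)[1]
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  a <- par$scale * cos(par$theta); b <- par$scale * sin(par$theta)
  sx <- if (isTRUE(par$hflip)) -1 else 1
  sy <- if (isTRUE(par$vflip)) -1 else 1
  # EBImage::affine maps output = input %*% m for homogeneous row vectors
  # (x, y, 1); build forward matrix around the center in EBImage's (x, y)
  # frame, where x runs along our columns (transposed storage).
  m11 <- a * sx; m12 <- b * sx
  m21 <- -b * sy; m22 <- a * sy
  ox <- cx - (m11 * cx + m21 * cy) + par$tx
  oy <- cy - (m12 * cx + m22 * cy) + par$ty
  m <- matrix(c(m11, m21, ox, m12, m22, oy), 3, 2)
  img <- EBImage::Image(aperm(patch, c(2, 1, 3)), colormode = "Color")
  warped <- EBImage::affine(img, m, filter = "bilinear",
                            output.dim = c(s, s), antialias = FALSE)
  out_patch <- clamp(aperm(EBImage::imageData(warped), c(2, 1, 3)), 0, 1)
  out_labels <- NULL
  if (!is.null(pixel_labels)) {
    lab <- EBImage::Image(t(pixel_labels))
    wl <- EBImage::affine(lab, m, filter = "none",
                          output.dim = c(s, s), antialias = FALSE)
    out_labels <- matrix(as.integer(round(t(EBImage::imageData(wl)))), s, s)
  }
  list(patch = out_patch, pixel_labels = out_labels)
}
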