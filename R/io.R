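#' Section container
#'
#' A single coronal photomicrograph with its physical calibration and its
#' position in the rostro-caudal stack of annotated sections.
#'
#' @param image H x W x 3 array in `[0, 1]` (grayscale matrices are promoted
#'   to 3 channels).
#' @param um_per_px Pixel size in micrometers per pixel, `> 0`.
#' @param case_id Case identifier.
#' @param section_index 0-based position in the rostro-caudal stack.
#' @param spacing_mm Distance in mm to the adjacent annotated section, `> 0`.
#' @return Object of class `fb_section`.
#' @export
fb_section <- function(image, um_per_px, case_id = "case", section_index = 0L,
                       spacing_mm = 1.2) {
  if (um_per_px <= 0) stop_cfg("um_per_px must be > 0")
  if (spacing_mm <= 0) stop_cfg("spacing_mm must be > 0")
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (min(image) < 0 || max(image) > 1) stop_cfg("image values must lie in [0,1]")
  structure(list(image = image, um_per_px = um_per_px, case_id = case_id,
                 section_index = as.integer(section_index),
                 spacing_mm = spacing_mm),
            class = "fb_section")
}

#' @export
print.fb_section <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fb_section> case %s, section %d: %d x %d px @ %.3g um/px, spacing %.3g mm\n",
              x$case_id, x$section_index, d[1], d[2], x$um_per_px, x$spacing_mm))
  invisible(x)
}

#' Per-section bundle annotations
#'
#' Holds manually charted (or predicted) bundle regions for one section,
#' each with a visually assessed density category.
#'
#' @param section_index 0-based section position.
#' @param regions List of regions, each a list with elements `mask`
#'   (H x W logical), `density` (one of `"dense"`, `"moderate"`,
#'   `"unknown"`), and optionally `bundle_id`.
#' @return Object of class `fb_annotations`.
#' @export
fb_annotations <- function(section_index, regions = list()) {
  for (r in regions) {
    stopifnot(is.logical(r$mask) || all(r$mask %in% c(0, 1)))
    if (!is.null(r$density)) {
      stopifnot(r$density %in% c("dense", "moderate", "unknown"))
    }
  }
  structure(list(section_index = as.integer(section_index), regions = regions),
            class = "fb_annotations")
}

#' Read a section image from disk
#'
#' Reads a PNG/TIFF/JPEG photomicrograph, rescales intensities to `[0, 1]`
#' (16-bit TIFFs map 65535 to 1), promotes grayscale to RGB with a warning,
#' and optionally applies an in-plane downsampling factor, updating the
#' pixel size multiplicatively.
#'
#' @param path Image file path.
#' @param um_per_px Physical pixel size of the stored image (µm/pixel).
#' @param section_index,spacing_mm,case_id Metadata; see [fb_section()].
#' @param downsample Integer in-plane downsampling factor (default 1).
#' @return An [fb_section()] object.
#' @export
read_section <- function(path, um_per_px, section_index = 0L, spacing_mm = 1.2,
                         case_id = "case", downsample = 1L) {
  if (!file.exists(path)) stop_cfg("cannot read section image: %s", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores x (col) as first dim; transpose to row-major H x W
  if (length(dim(a)) == 2L) {
    warning("grayscale input promoted to 3 channels")
    a <- t(a)
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else {
    a <- a[, , 1:3, drop = FALSE]  # drop alpha if present
    a <- aperm(a, c(2, 1, 3))
  }
  a <- clamp(a, 0, 1)
  if (downsample > 1L) {
    h <- floor(nrow(a) / downsample); w <- floor(ncol(a) / downsample)
    e <- EBImage::resize(EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color"),
                         w = w, h = h)
    a <- aperm(EBImage::imageData(e), c(2, 1, 3))
    a <- clamp(a, 0, 1)
    um_per_px <- um_per_px * downsample
  }
  fb_section(a, um_per_px = um_per_px, case_id = case_id,
             section_index = section_index, spacing_mm = spacing_mm)
}

#' Write a section image
#'
#' @param section An [fb_section()].
#' @param path Output path; format chosen from the extension (png/tiff).
#' @export
write_section <- function(section, path) {
  img <- EBImage::Image(aperm(section$image, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Read / write label-mask images
#'
#' Label masks are single-channel PNGs with value 0 for background and k for
#' bundle (or pathway) k.
#'
#' @param mask Integer H x W matrix with values in `0..255`.
#' @param path File path.
#' @return `read_label_mask` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 255, min(mask) >= 0)
  EBImage::writeImage(EBImage::Image(t(mask / 255)), path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Convert an area in mm^2 to pixels
#'
#' `area_mm2 * 1e6 / um_per_px^2`.
#'
#' @param area_mm2 Area in square millimeters.
#' @param um_per_px Pixel size in µm/pixel, `> 0`.
#' @return Area in pixels (fractional).
#' @export
mm2_to_px <- function(area_mm2, um_per_px) {
  if (any(um_per_px <= 0)) stop_cfg("um_per_px must be > 0")
  area_mm2 * 1e6 / um_per_px^2
}

#' @rdname mm2_to_px
#' @param area_px Area in pixels.
#' @export
px_to_mm2 <- function(area_px, um_per_px) {
  if (any(um_per_px <= 0)) stop_cfg("um_per_px must be > 0")
  area_px * um_per_px^2 / 1e6
}

#' Convert a physical length to pixels
#'
#' @param mm,um Length in millimeters / micrometers.
#' @param um_per_px Pixel size, `> 0`.
#' @return Length in pixels (fractional).
#' @export
mm_to_px <- function(mm, um_per_px) {
  if (any(um_per_px <= 0)) stop_cfg("um_per_px must be > 0")
  mm * 1000 / um_per_px
}

#' @rdname mm_to_px
#' @export
um_to_px <- function(um, um_per_px) {
  if (any(um_per_px <= 0)) stop_cfg("um_per_px must be > 0")
  um / um_per_px
}

#' Rasterize a label image from annotations / vectorize back
#'
#' @param annotations An [fb_annotations()] object.
#' @param dim_hw Image dimensions `c(H, W)`.
#' @return Integer H x W label matrix (0 background, k = k-th region).
#' @export
annotations_to_labelmask <- function(annotations, dim_hw) {
  lab <- matrix(0L, dim_hw[1], dim_hw[2])
  for (k in seq_along(annotations$regions)) {
    lab[annotations$regions[[k]]$mask > 0] <- k
  }
  lab
}

#' @rdname annotations_to_labelmask
#' @param labelmask Integer label matrix.
#' @param section_index Section position for the result.
#' @param densities Optional character vector of density categories per label.
#' @export
labelmask_to_annotations <- function(labelmask, section_index = 0L,
                                     densities = NULL) {
  ids <- sort(setdiff(unique(as.vector(labelmask)), 0L))
  regions <- lapply(seq_along(ids), function(i) {
    list(mask = labelmask == ids[i], bundle_id = ids[i],
         density = if (is.null(densities)) "unknown" else densities[[i]])
  })
  fb_annotations(section_index, regions)
}

#' Rasterize a closed polygon into a mask
#'
#' Polygons use (x, y) pixel coordinates (0-based, pixel centers, half-open
#' image domain); a pixel belongs to the polygon if its center is inside
#' (even-odd rule).
#'
#' @param poly Two-column matrix of (x, y) vertices of a closed simple
#'   polygon (last vertex need not repeat the first).
#' @param dim_hw `c(H, W)`.
#' @return H x W logical mask.
#' @export
polygon_to_mask <- function(poly, dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  mask <- matrix(FALSE, h, w)
  # even-odd scanline fill at pixel centers (cx = col-1, cy = row-1)
  for (row in seq_len(h)) {
    cy <- row - 1
    xcross <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > cy) != (ys[j] > cy)) {
        xcross <- c(xcross, xs[i] + (cy - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i]))
      }
      j <- i
    }
    if (length(xcross)) {
      xcross <- sort(xcross)
      for (k in seq(1, length(xcross) - 1, by = 2)) {
        lo <- ceiling(xcross[k]); hi <- floor(xcross[k + 1])
        lo <- max(lo, 0); hi <- min(hi, w - 1)
        if (hi >= lo) mask[row, (lo:hi) + 1L] <- TRUE
      }
    }
  }
  # include the vertex pixels themselves: contours traced from masks list
  # every boundary pixel as a vertex, so this makes the round trip exact
  px <- round(xs); py <- round(ys)
  ok <- px >= 0 & px < w & py >= 0 & py < h
  mask[cbind(py[ok] + 1L, px[ok] + 1L)] <- TRUE
  mask
}

#' Extract the boundary polygon of a mask
#'
#' Traces the outline of the largest connected component; suitable for
#' round-tripping region masks to closed-contour files.
#'
#' @param mask H x W logical mask.
#' @return Two-column (x, y) matrix of boundary pixel coordinates, ordered.
#' @export
mask_to_polygon <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  if (length(oc) == 0L) return(matrix(numeric(0), 0, 2))
  big <- which.max(vapply(oc, nrow, integer(1)))
  p <- oc[[big]]  # EBImage returns (x, y) in its x-first convention
  cbind(p[, 1], p[, 2])
}

#' Read / write a stack manifest
#'
#' CSV with columns `section_index`, `image`, `mask`, `um_per_px`,
#' `spacing_mm` (mask may be empty for unlabeled sections).
#'
#' @param manifest Data frame with the columns above.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_cfg("manifest not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Sample training patches from a section
#'
#' Samples 256 x 256 x 3 patches uniformly over the tissue (non-border)
#' area. Pixel labels are rasterized from annotations where available; the
#' patch-level class is `fiber` iff the patch overlaps bundle regions by at
#' least `fiber_frac` of its area.
#'
#' @param section An [fb_section()].
#' @param annotations An [fb_annotations()] or `NULL` for unlabeled data.
#' @param n Number of patches, `> 0`.
#' @param seed Integer seed; fixed seed gives identical patch coordinates.
#' @param patch_size Patch side in pixels (default 256).
#' @param fiber_frac Minimum bundle-overlap fraction for the `fiber` class
#'   label (default 0.05).
#' @param tissue_mask Optional H x W logical mask restricting sampling.
#' @param centers Optional matrix of (row, col) 1-based patch centers to use
#'   instead of random sampling (used for deterministic patch grids).
#' @return A list of class `fb_patchbatch` with elements `patches`
#'   (N x S x S x 3), `pixel_labels` (N x S x S or `NULL`), `class_labels`
#'   (character), `centers` (N x 2 matrix of row/col centers).
#' @export
sample_patches <- function(section, annotations = NULL, n = 8L, seed = 1L,
                           patch_size = 256L, fiber_frac = 0.05,
                           tissue_mask = NULL, centers = NULL) {
  if (is.null(centers) && n <= 0) stop_cfg("n must be > 0")
  img <- section$image
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- as.integer(patch_size)
  if (h < s || w < s) {
    img <- pad_reflect(img, max(h, s), max(w, s))
    if (!is.null(tissue_mask)) tissue_mask <- pad_reflect(tissue_mask, max(h, s), max(w, s))
    h <- dim(img)[1]; w <- dim(img)[2]
  }
  labmask <- NULL
  if (!is.null(annotations)) {
    labmask <- annotations_to_labelmask(annotations, c(dim(section$image)[1], dim(section$image)[2])) > 0
    if (nrow(labmask) < h || ncol(labmask) < w) labmask <- pad_reflect(labmask, h, w)
  }
  half <- s %/% 2L
  if (is.null(centers)) {
    # sample from a vector even when it has length one
    pick <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]
    row_range <- seq(half + 1L, h - (s - half) + 1L)
    col_range <- seq(half + 1L, w - (s - half) + 1L)
    centers <- with_seed(seed, {
      rows <- pick(row_range, n)
      cols <- pick(col_range, n)
      if (!is.null(tissue_mask)) {
        # resample centers that fall off tissue (up to 20 tries each)
        for (i in seq_len(n)) {
          tries <- 0L
          while (!tissue_mask[rows[i], cols[i]] && tries < 20L) {
            rows[i] <- pick(row_range, 1L)
            cols[i] <- pick(col_range, 1L)
            tries <- tries + 1L
          }
        }
      }
      cbind(rows, cols)
    })
  }
  n <- nrow(centers)
  patches <- array(0, dim = c(n, s, s, 3))
  plabels <- if (is.null(labmask)) NULL else array(0L, dim = c(n, s, s))
  cls <- character(n)
  for (i in seq_len(n)) {
    r0 <- centers[i, 1] - half; c0 <- centers[i, 2] - half
    patches[i, , , ] <- img[r0:(r0 + s - 1L), c0:(c0 + s - 1L), , drop = FALSE]
    if (!is.null(labmask)) {
      pl <- labmask[r0:(r0 + s - 1L), c0:(c0 + s - 1L)]
      plabels[i, , ] <- pl * 1L
      cls[i] <- if (mean(pl) >= fiber_frac) "fiber" else "background"
    } else {
      cls[i] <- NA_character_
    }
  }
  structure(list(patches = patches, pixel_labels = plabels,
                 class_labels = cls, centers = centers, patch_size = s),
            class = "fb_patchbatch")
}
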