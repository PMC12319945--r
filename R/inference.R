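#' Whole-section probability map via tiled inference
#'
#' Applies the segmentation head to a whole section. Sections that fit in
#' one tile are processed with a single forward pass; larger sections are
#' tiled on a grid of `tile_size` tiles with optional overlap, overlapping
#' pixels are averaged, and the map is cropped back to the original size.
#' Edge tiles are padded by reflection. Tiles are padded internally so any
#' section size is admissible.
#'
#' @param model An `fb_model`.
#' @param section An [fb_section()].
#' @param tile_size Tile side in pixels (default 1024); must be divisible by
#'   `2^(depth - 1)`.
#' @param overlap_px Tile overlap in pixels (default 0).
#' @return Object of class `fb_probmap`: list with `probs` (H x W in
#'   `[0, 1]`), `section_index`, `um_per_px`, `tile_layout`, `model_tag`.
#' @export
predict_section <- function(model, section, tile_size = 1024L, overlap_px = 0L) {
  stride_div <- 2^(model$cfg$depth - 1)
  if (tile_size %% stride_div != 0) {
    stop_cfg("tile_size must be divisible by 2^(depth-1) = %d", stride_div)
  }
  img <- section$image
  h <- dim(img)[1]; w <- dim(img)[2]
  run_tile <- function(tile) {
    th <- dim(tile)[1]; tw <- dim(tile)[2]
    ph <- as.integer(ceiling(th / stride_div) * stride_div)
    pw <- as.integer(ceiling(tw / stride_div) * stride_div)
    tp <- pad_reflect(tile, ph, pw)
    pr <- nn_forward(model, tp, with_cls = FALSE)$seg_prob
    pr[seq_len(th), seq_len(tw), drop = FALSE]
  }
  if (h <= tile_size && w <= tile_size) {
    probs <- run_tile(img)
    layout <- list(list(row = 1L, col = 1L, h = h, w = w))
  } else {
    step <- tile_size - overlap_px
    if (step <= 0) stop_cfg("overlap_px must be smaller than tile_size")
    starts <- function(n) {
      if (n <= tile_size) return(1L)
      s <- seq(1L, n - tile_size + 1L, by = step)
      if (s[length(s)] + tile_size - 1L < n) s <- c(s, n - tile_size + 1L)
      as.integer(s)
    }
    acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
    layout <- list()
    for (r0 in starts(h)) {
      for (c0 in starts(w)) {
        r1 <- min(r0 + tile_size - 1L, h); c1 <- min(c0 + tile_size - 1L, w)
        pr <- run_tile(img[r0:r1, c0:c1, , drop = FALSE])
        acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + pr
        cnt[r0:r1, c0:c1] <- cnt[r0:r1, c0:c1] + 1
        layout[[length(layout) + 1L]] <- list(row = r0, col = c0,
                                              h = r1 - r0 + 1L, w = c1 - c0 + 1L)
      }
    }
    probs <- acc / cnt
  }
  structure(list(probs = clamp(probs, 0, 1),
                 section_index = section$section_index,
                 um_per_px = section$um_per_px,
                 tile_layout = layout,
                 model_tag = sprintf("unet-d%d-w%d", model$cfg$depth,
                                     model$cfg$base_width)),
            class = "fb_probmap")
}

#' Threshold a probability map
#'
#' `mask = probs >= threshold`; a pixel exactly at the threshold is
#' foreground (documented tie rule). Lowering the threshold never removes
#' foreground pixels, which underlies FROC monotonicity.
#'
#' @param map An `fb_probmap` or a plain probability matrix.
#' @param threshold Value in `[0, 1]` (default 0.4, the operating point used
#'   for binary maps).
#' @return Logical H x W mask.
#' @export
binarize <- function(map, threshold = 0.4) {
  if (threshold < 0 || threshold > 1) stop_cfg("threshold must be in [0,1]")
  p <- if (inherits(map, "fb_probmap")) map$probs else map
  p >= threshold
}

#' Write a probability map / read it back
#'
#' Probability maps are stored as 32-bit TIFF.
#'
#' @param map An `fb_probmap`.
#' @param path Output TIFF path.
#' @export
write_probmap <- function(map, path) {
  img <- EBImage::Image(t(map$probs))
  EBImage::writeImage(img, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_probmap
#' @export
read_probmap <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  structure(list(probs = clamp(t(a), 0, 1), section_index = NA_integer_,
                 um_per_px = NA_real_, tile_layout = list(),
                 model_tag = "file"),
            class = "fb_probmap")
}
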