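#' @useDynLib bundleseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
#' @import utils
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic package operations route
# through this so a single seed fixes every output.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert an RGB array to luminance
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`. Grayscale (2D) input is
#' returned unchanged.
#'
#' @param img H x W matrix or H x W x 3 array with values in `[0, 1]`.
#' @return H x W matrix.
#' @export
luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Reflection-pad a 2D matrix or H x W x C array on the bottom/right to the
# target size. Used to make tiles divisible by the network stride.
pad_reflect <- function(x, target_h, target_w) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  stopifnot(target_h >= h, target_w >= w)
  idx_r <- reflect_index(h, target_h)
  idx_c <- reflect_index(w, target_w)
  if (length(d) == 2L) x[idx_r, idx_c, drop = FALSE] else x[idx_r, idx_c, , drop = FALSE]
}

reflect_index <- function(n, target) {
  if (target == n) return(seq_len(n))
  if (n == 1L) return(rep(1L, target))
  # mirror without repeating the edge sample: n-1, n-2, ...
  period <- c(seq_len(n), seq(n - 1L, 2L))
  period[((seq_len(target) - 1L) %% length(period)) + 1L]
}

# Distance (in pixels) from each pixel to the nearest TRUE pixel of `mask`.
# Inf everywhere when the mask is empty.
distance_to_foreground <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  # EBImage::distmap computes, for each ON pixel, distance to nearest OFF
  # pixel; applying it to the complement gives distance to the foreground.
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask)))
  d[mask] <- 0
  d
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
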