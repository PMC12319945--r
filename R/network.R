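#' Model configuration for the dual-head network
#'
#' Describes the U-Net segmentation backbone (FSeg) and the
#' bottleneck-attached classification arm (FClass): a downsampling module of
#' two (max-pool, 3x3 conv, 3x3 conv) blocks, global average pooling, two
#' fully connected layers and a two-node output. Encoder weights are shared
#' between the heads. The model scales down to `base_width = 2`,
#' `depth = 2` so CPU tests run in seconds.
#'
#' @param in_channels Input channels (3 for RGB patches).
#' @param base_width Feature channels at the first encoder level; channels
#'   double per level.
#' @param depth Number of encoder levels including the bottleneck, `>= 2`.
#' @param fc_sizes Sizes of the two fully connected layers of FClass
#'   (default `c(1024, 256)`; the second is the contrastive embedding).
#' @param contrastive_features Which FClass output feeds the contrastive
#'   loss: the 256-d `"embedding"` (default) or the 2-node `"logits"`.
#' @return Object of class `fb_model_config`.
#' @export
model_config <- function(in_channels = 3L, base_width = 16L, depth = 4L,
                         fc_sizes = c(1024L, 256L),
                         contrastive_features = c("embedding", "logits")) {
  if (depth < 2) stop_cfg("depth must be >= 2")
  if (any(fc_sizes <= 0)) stop_cfg("fc_sizes must be positive")
  contrastive_features <- match.arg(contrastive_features)
  structure(list(in_ch = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 fc1 = as.integer(fc_sizes[1]), fc2 = as.integer(fc_sizes[2]),
                 contrastive_features = contrastive_features),
            class = "fb_model_config")
}

# He-style initialization for a conv/fc weight matrix (fan_in x fan_out)
init_w <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Build a dual-head model
#'
#' Allocates and initializes all weights. With a fixed seed the
#' initialization is reproducible.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `fb_model`: list with `cfg` and `params` (a named
#'   list of weight matrices / bias vectors).
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  D <- cfg$depth
  ch <- function(l) cfg$base_width * 2^(l - 1)
  params <- with_seed(seed, {
    p <- list()
    for (l in seq_len(D)) {
      cin <- if (l == 1) cfg$in_ch else ch(l - 1)
      p[[sprintf("enc%d_Wa", l)]] <- init_w(9 * cin, ch(l))
      p[[sprintf("enc%d_ba", l)]] <- numeric(ch(l))
      p[[sprintf("enc%d_Wb", l)]] <- init_w(9 * ch(l), ch(l))
      p[[sprintf("enc%d_bb", l)]] <- numeric(ch(l))
    }
    for (l in seq_len(D - 1)) {
      p[[sprintf("dec%d_Wu", l)]] <- init_w(9 * ch(l + 1), ch(l))
      p[[sprintf("dec%d_bu", l)]] <- numeric(ch(l))
      p[[sprintf("dec%d_Wa", l)]] <- init_w(9 * 2 * ch(l), ch(l))
      p[[sprintf("dec%d_ba", l)]] <- numeric(ch(l))
      p[[sprintf("dec%d_Wb", l)]] <- init_w(9 * ch(l), ch(l))
      p[[sprintf("dec%d_bb", l)]] <- numeric(ch(l))
    }
    p[["out_W"]] <- init_w(ch(1), 2L)
    # bias the output toward the background prior (~10% fiber pixels) so
    # early training does not spend its budget calibrating the base rate
    p[["out_b"]] <- c(1.1, -1.1)
    for (m in 1:2) {
      p[[sprintf("cls%d_Wa", m)]] <- init_w(9 * ch(D), ch(D))
      p[[sprintf("cls%d_ba", m)]] <- numeric(ch(D))
      p[[sprintf("cls%d_Wb", m)]] <- init_w(9 * ch(D), ch(D))
      p[[sprintf("cls%d_bb", m)]] <- numeric(ch(D))
    }
    p[["fc1_W"]] <- init_w(ch(D), cfg$fc1)
    p[["fc1_b"]] <- numeric(cfg$fc1)
    p[["fc2_W"]] <- init_w(cfg$fc1, cfg$fc2)
    p[["fc2_b"]] <- numeric(cfg$fc2)
    p[["fc3_W"]] <- init_w(cfg$fc2, 2L)
    p[["fc3_b"]] <- numeric(2L)
    p
  })
  structure(list(cfg = cfg, params = params), class = "fb_model")
}

cfg_for_cpp <- function(cfg) {
  list(depth = cfg$depth, base_width = cfg$base_width,
       fc1 = cfg$fc1, fc2 = cfg$fc2, in_ch = cfg$in_ch)
}

#' Forward pass
#'
#' Runs one image (or a batch) through the model in inference mode. The
#' segmentation output has the spatial size of the input; inputs must be
#' divisible by `2^(depth - 1)` (and by `2^(depth + 1)` when the
#' classification arm is evaluated).
#'
#' @param model An `fb_model`.
#' @param x H x W x C array (single image) or N x H x W x C array (batch).
#' @param with_cls Evaluate the classification arm too? (default TRUE).
#' @return For a single image, a list with `seg_logits` (H x W x 2),
#'   `seg_prob` (H x W fiber-class probability) and, when `with_cls`,
#'   `cls_logits` (length 2) and `cls_embedding` (length `fc_sizes[2]`).
#'   For a batch, a list of such lists.
#' @export
nn_forward <- function(model, x, with_cls = TRUE) {
  one <- function(img) {
    if (dim(img)[3] != model$cfg$in_ch) stop_cfg("channel mismatch")
    out <- .nn_forward_cpp(img, model$params, cfg_for_cpp(model$cfg), with_cls)
    res <- list(seg_logits = out$seg_logits, seg_prob = out$seg_prob)
    if (with_cls) {
      res$cls_logits <- as.numeric(out$cls_logits)
      res$cls_embedding <- as.numeric(out$embedding)
    }
    res
  }
  if (length(dim(x)) == 3L) return(one(x))
  stopifnot(length(dim(x)) == 4L)
  lapply(seq_len(dim(x)[1]), function(i) one(array(x[i, , , ], dim = dim(x)[-1])))
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the model configuration and a format version tag.
#'
#' @param model An `fb_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "bundleseg-checkpoint", version = 1L,
              cfg = model$cfg, params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "bundleseg-checkpoint")) {
    stop_cfg("not a bundleseg checkpoint: %s", path)
  }
  structure(list(cfg = obj$cfg, params = obj$params), class = "fb_model")
}
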