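#' Focal loss parameters
#'
#' Weighing (`alpha`) and focusing (`gamma`) parameters of the focal loss
#' used to train the segmentation head under heavy fiber/background class
#' imbalance. Defaults follow the training configuration used throughout
#' the package (`alpha = 0.25`, `gamma = 2`).
#'
#' @param alpha Class-balance weight in `[0, 1]` applied to positives;
#'   negatives receive `1 - alpha`.
#' @param gamma Focusing exponent, `>= 0`. `gamma = 0` reduces the loss to
#'   alpha-weighted cross-entropy.
#' @return Object of class `fb_focal_params`.
#' @export
focal_params <- function(alpha = 0.25, gamma = 2.0) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop_cfg("alpha must be in [0,1]")
  if (!is.numeric(gamma) || gamma < 0) stop_cfg("gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma), class = "fb_focal_params")
}

#' Contrastive (NT-Xent) loss parameters
#'
#' @param tau Temperature, `> 0`. Default 0.5.
#' @return Object of class `fb_contrastive_params`.
#' @export
contrastive_params <- function(tau = 0.5) {
  if (!is.numeric(tau) || tau <= 0) stop_cfg("tau must be > 0")
  structure(list(tau = tau), class = "fb_contrastive_params")
}

#' Focal loss for binary segmentation
#'
#' Mean over elements of `-alpha_t (1 - p_t)^gamma log(p_t)` where
#' `p_t = p` for positive pixels and `1 - p` for negative ones, and
#' `alpha_t = alpha` for positives, `1 - alpha` for negatives.
#' Probabilities are clamped to `[eps, 1 - eps]` (`eps = 1e-7`) before the
#' logarithm.
#'
#' @param p Numeric array of predicted fiber-class probabilities.
#' @param y Array of the same shape with labels in `{0, 1}`.
#' @param params A [focal_params()] object.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(p, y, params = focal_params()) {
  if (length(p) != length(y)) stop_cfg("p and y must have the same length")
  if (length(p) == 0L) stop_cfg("empty input")
  eps <- 1e-7
  p <- clamp(as.numeric(p), eps, 1 - eps)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_cfg("y must be binary")
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, params$alpha, 1 - params$alpha)
  mean(-at * (1 - pt)^params$gamma * log(pt))
}

#' NT-Xent contrastive loss over positive pairs
#'
#' Normalized-temperature cross-entropy over a batch of `2N` embeddings
#' arranged so that rows `2m - 1` and `2m` form the m-th positive pair.
#' For an ordered pair `(i, j)`,
#' `l(i, j) = -log( exp(sim(f_i, f_j)/tau) / sum_{k != i} exp(sim(f_i, f_k)/tau) )`
#' with cosine similarity `sim`; the loss is the mean of `l` over all `2N`
#' ordered pairs. Cosine similarity makes the loss invariant to per-vector
#' scaling; vector norms are clamped at `1e-12`.
#'
#' @param features Numeric matrix `2N x D` of embeddings, `N >= 2`.
#' @param params A [contrastive_params()] object.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(features, params = contrastive_params()) {
  features <- as.matrix(features)
  n2 <- nrow(features)
  if (n2 %% 2L != 0L) stop_cfg("batch size must be even (positive pairs)")
  if (n2 < 4L) stop_cfg("need at least two positive pairs (2N >= 4)")
  if (ncol(features) < 1L) stop_cfg("feature dimension must be >= 1")
  nrm <- pmax(sqrt(rowSums(features^2)), 1e-12)
  z <- features / nrm
  s <- tcrossprod(z) / params$tau           # 2N x 2N scaled cosine similarities
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  # log-sum-exp over k != i, row-wise
  losses <- vapply(seq_len(n2), function(i) {
    row <- s[i, -i]
    m <- max(row)
    lse <- m + log(sum(exp(row - m)))
    lse - s[i, partner[i]]
  }, numeric(1))
  mean(losses)
}
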