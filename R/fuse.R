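# Multimodal fusion: combine an image-feature projection Fv and sensor
# embedding Ft into a fused vector Fm, plus the post-fusion fully connected
# head Fm' = ReLU(Wf Fm + bf) and a KL-divergence diagnostic for the gap
# between the two modalities' feature distributions.

#' Fuse image and sensor feature vectors
#'
#' Modes:
#' * `"weighted_sum"`: `Fm = alpha * Fv + (1 - alpha) * Ft` (requires equal
#'   dimensions).
#' * `"weighted_concat"` (default): each modality block is scaled by its
#'   weight and the blocks are concatenated,
#'   `Fm = c(alpha * Fv, (1 - alpha) * Ft)`.
#' * `"concat"`: plain `c(Fv, Ft)`.
#' * `"bilinear"`: `Fv` is a token matrix (N x D); attention weights
#'   `softmax(Fv W Ft)` over the image-token axis pool the tokens,
#'   `Fm = t(Fv) %*% softmax(Fv %*% W %*% Ft)`.
#'
#' `alpha` is produced from the unconstrained `alpha_param` through a sigmoid,
#' so it always lies in (0, 1).
#'
#' @param fv image feature: numeric vector, or N x D token matrix for
#'   `"bilinear"`.
#' @param ft sensor feature vector.
#' @param mode fusion mode.
#' @param alpha_param unconstrained scalar; `alpha = sigmoid(alpha_param)`.
#'   Default 0 gives alpha = 0.5.
#' @param W D x D bilinear weight matrix (bilinear mode only).
#' @return a `fused_feature`: list with `fm`, `alpha`, `mode` and, for
#'   bilinear, the attention `weights` over image tokens.
#' @export
fuse <- function(fv, ft, mode = c("weighted_concat", "weighted_sum",
                                  "concat", "bilinear"),
                 alpha_param = 0, W = NULL) {
  mode <- match.arg(mode)
  alpha <- 1 / (1 + exp(-alpha_param))
  out <- switch(mode,
    weighted_sum = {
      if (length(fv) != length(ft)) {
        stop("weighted_sum: image feature dimension (", length(fv),
             ") must match sensor feature dimension (", length(ft), ")")
      }
      list(fm = alpha * fv + (1 - alpha) * ft)
    },
    weighted_concat = list(fm = c(alpha * fv, (1 - alpha) * ft)),
    concat = list(fm = c(fv, ft)),
    bilinear = {
      fv <- as.matrix(fv)
      if (is.null(W)) stop("bilinear: weight matrix W is required")
      if (ncol(fv) != nrow(W) || ncol(W) != length(ft)) {
        stop("bilinear: W must be ", ncol(fv), " x ", length(ft))
      }
      scores <- as.vector(fv %*% W %*% ft)
      wts <- as.vector(softmax_rows(matrix(scores, nrow = 1)))
      list(fm = as.vector(crossprod(fv, wts)), weights = wts)
    })
  structure(c(out, list(alpha = alpha, mode = mode)), class = "fused_feature")
}

#' Post-fusion fully connected head
#'
#' `Fm' = ReLU(Wf %*% Fm + bf)`: affine map then rectification. Classification
#' logits are a further linear map applied by the model head.
#'
#' @param fm fused feature vector.
#' @param Wf weight matrix with `ncol(Wf) == length(fm)`.
#' @param bf bias vector of length `nrow(Wf)`.
#' @return non-negative numeric vector `fm_prime`.
#' @export
project_and_head <- function(fm, Wf, bf) {
  if (ncol(Wf) != length(fm)) {
    stop("project_and_head: Wf has ", ncol(Wf), " columns but fm has length ",
         length(fm))
  }
  relu(as.vector(Wf %*% fm + bf))
}

#' Divergence between modality feature distributions
#'
#' Diagnostic only (never trained on): the Kullback-Leibler divergence between
#' histogram estimates of the distributions of per-sample feature norms for
#' the two modalities, using shared bin edges over the pooled range and
#' add-one smoothing.
#'
#' @param fv_batch N x D matrix of image features (rows = samples).
#' @param ft_batch N x D matrix of sensor features.
#' @param bins histogram bins.
#' @return non-negative KL divergence, or `NA` with a warning when either
#'   batch has fewer than 30 samples.
#' @export
modality_divergence <- function(fv_batch, ft_batch, bins = 10) {
  nv <- sqrt(rowSums(as.matrix(fv_batch)^2))
  nt <- sqrt(rowSums(as.matrix(ft_batch)^2))
  if (length(nv) < 30 || length(nt) < 30) {
    warning("modality_divergence: fewer than 30 samples per batch; skipped")
    return(NA_real_)
  }
  rng <- range(c(nv, nt))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  cv <- tabulate(findInterval(nv, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + 1
  ct <- tabulate(findInterval(nt, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + 1
  p <- cv / sum(cv); q <- ct / sum(ct)
  sum(p * log(p / q))
}
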