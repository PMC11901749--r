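# Classification and alignment losses. All losses support soft labels (needed
# for CutMix/Mosaic targets) and per-class weights, and each has an analytic
# gradient used by the training loop and verified against finite differences
# in the test suite.

PROB_EPS <- 1e-12

check_probs <- function(probs) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 (within 1e-6)")
  }
  pmin(pmax(probs, PROB_EPS), 1)
}

resolve_weights <- function(weights, labels) {
  C <- ncol(labels)
  if (is.null(weights)) return(rep(1, C))
  if (identical(weights, "inverse_frequency")) return(inverse_frequency_weights(labels))
  if (length(weights) != C || any(weights <= 0)) {
    stop("class_weights must be a positive vector of length ", C)
  }
  weights
}

#' Inverse-frequency class weights
#'
#' Weights `w_c` proportional to `1 / n_c`, normalized so that
#' `sum_c w_c * n_c = N` (a uniformly weighted balanced batch keeps unit
#' average weight). Soft labels contribute fractional counts.
#'
#' @param labels N x C matrix of (possibly soft) label distributions.
#' @return positive length-C weight vector.
#' @export
inverse_frequency_weights <- function(labels) {
  n_c <- colSums(labels)
  pos <- n_c > 0
  w <- numeric(length(n_c))
  w[pos] <- 1 / n_c[pos]
  w[!pos] <- max(w[pos])              # unseen class: treat as rarest seen
  # scale so that the seen classes satisfy sum_c w_c * n_c = N
  w * sum(labels) / sum(w[pos] * n_c[pos])
}

#' Weighted cross-entropy with soft labels
#'
#' `L = -(1/N) * sum_i sum_c w_c * y_ic * log(p_ic)`, with probabilities
#' clipped to `[1e-12, 1]`.
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param labels N x C matrix of true label distributions (one-hot or soft).
#' @param weights `NULL` (uniform), `"inverse_frequency"`, or a positive
#'   length-C vector.
#' @return scalar loss.
#' @export
cross_entropy <- function(probs, labels, weights = NULL) {
  labels <- as.matrix(labels)
  probs <- check_probs(probs)
  w <- resolve_weights(weights, labels)
  -mean(rowSums(sweep(labels, 2L, w, "*") * log(probs)))
}

# gradient of cross_entropy wrt logits z where probs = softmax(z)
cross_entropy_grad_logits <- function(logits, labels, weights = NULL) {
  labels <- as.matrix(labels)
  p <- softmax_rows(logits)
  w <- resolve_weights(weights, labels)
  a <- sweep(labels, 2L, w, "*")
  (p * rowSums(a) - a) / nrow(p)
}

#' Focal loss (batch-mean multi-class extension)
#'
#' `L = -(1/N) * sum_i sum_c alpha * (1 - p_ic)^gamma * y_ic * log(p_ic)`.
#' Reduces exactly to unweighted cross-entropy at `gamma = 0, alpha = 1`.
#'
#' @inheritParams cross_entropy
#' @param gamma focusing parameter (>= 0).
#' @param alpha balancing factor in (0, 1].
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, alpha = 1) {
  labels <- as.matrix(labels)
  probs <- check_probs(probs)
  if (gamma < 0) stop("gamma must be >= 0")
  -mean(rowSums(alpha * (1 - probs)^gamma * labels * log(probs)))
}

focal_grad_logits <- function(logits, labels, gamma = 2, alpha = 1) {
  labels <- as.matrix(labels)
  p <- softmax_rows(logits)
  pc <- pmin(pmax(p, PROB_EPS), 1)
  # dL/dp then through the softmax Jacobian
  dLdp <- -alpha * labels *
    ((1 - pc)^gamma / pc - gamma * (1 - pc)^pmax(gamma - 1, 0) * log(pc))
  softmax_rows_backward(p, dLdp) / nrow(p)
}

#' Cosine alignment loss between paired feature rows
#'
#' `L = (1/N) * sum_i (1 - cos(fv_i, ft_i))`, range `[0, 2]`. Norms are
#' guarded by a small epsilon so zero rows do not produce NaN.
#'
#' @param fv N x D matrix of projected image features.
#' @param ft N x D matrix of projected sensor features.
#' @return scalar loss in `[0, 2]`.
#' @export
alignment_loss <- function(fv, ft) {
  fv <- as.matrix(fv); ft <- as.matrix(ft)
  if (!all(dim(fv) == dim(ft))) stop("fv and ft must have equal dimensions")
  nv <- sqrt(rowSums(fv^2)) + nn_eps
  nt <- sqrt(rowSums(ft^2)) + nn_eps
  mean(1 - rowSums(fv * ft) / (nv * nt))
}

alignment_grad <- function(fv, ft) {
  fv <- as.matrix(fv); ft <- as.matrix(ft)
  nv <- sqrt(rowSums(fv^2)) + nn_eps
  nt <- sqrt(rowSums(ft^2)) + nn_eps
  dotp <- rowSums(fv * ft)
  N <- nrow(fv)
  dfv <- -(ft / (nv * nt) - fv * (dotp / (nv^3 * nt))) / N
  dft <- -(fv / (nv * nt) - ft * (dotp / (nt^3 * nv))) / N
  list(dfv = dfv, dft = dft)
}

#' Loss configuration
#'
#' @param kind `"ce"`, `"focal"` or `"embedding"`.
#' @param lambda_align weight of the alignment term (>= 0).
#' @param focal_gamma focusing parameter for `"focal"`.
#' @param focal_alpha balancing factor for `"focal"`.
#' @param class_weights `NULL`, `"inverse_frequency"`, or a positive length-5
#'   vector.
#' @return a `loss_config` list.
#' @export
loss_config <- function(kind = c("embedding", "ce", "focal"),
                        lambda_align = 0.5, focal_gamma = 2, focal_alpha = 1,
                        class_weights = NULL) {
  kind <- match.arg(kind)
  if (lambda_align < 0) stop("lambda_align must be >= 0")
  if (focal_gamma < 0) stop("focal_gamma must be >= 0")
  if (focal_alpha <= 0 || focal_alpha > 1) stop("focal_alpha must be in (0, 1]")
  structure(list(kind = kind, lambda_align = lambda_align,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 class_weights = class_weights),
            class = "loss_config")
}

#' Composite embedding loss
#'
#' `L = L_CE + lambda_align * L_align`: classification cross-entropy plus the
#' cosine alignment between paired image and sensor feature projections,
#' reported with its components.
#'
#' @inheritParams cross_entropy
#' @param fv,ft N x D paired feature projections (see [alignment_loss()]).
#' @param cfg a [loss_config()].
#' @return a `loss_breakdown`: list with `ce`, `align`, `total`, `n`.
#' @export
embedding_loss <- function(probs, labels, fv, ft, cfg = loss_config()) {
  ce <- cross_entropy(probs, labels, cfg$class_weights)
  al <- alignment_loss(fv, ft)
  structure(list(ce = ce, align = al,
                 total = ce + cfg$lambda_align * al,
                 n = nrow(as.matrix(probs))),
            class = "loss_breakdown")
}
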