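# Post-training compression: magnitude pruning (retain a weight iff |w|
# strictly exceeds the threshold) and uniform quantization with
# round-half-to-even, plus an accuracy-delta report.

#' Magnitude-prune a weight container
#'
#' Sets every entry with `|w| <= epsilon` to exactly 0 and leaves the others
#' bit-identical. Accepts a numeric vector/matrix or a (nested) parameter
#' list; `scope` restricts pruning to matching parameter names.
#'
#' @param weights numeric array or named parameter list.
#' @param epsilon threshold (>= 0); a weight survives iff `|w| > epsilon`.
#' @param scope optional character vector of parameter names to prune
#'   (list input only); others pass through untouched.
#' @return pruned weights with attribute `"sparsity"` (fraction of zeros over
#'   the pruned scope).
#' @export
prune_weights <- function(weights, epsilon, scope = NULL) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  prune_one <- function(w) { w[abs(w) <= epsilon] <- 0; w }
  if (is.numeric(weights)) {
    out <- prune_one(weights)
    attr(out, "sparsity") <- mean(out == 0)
    return(out)
  }
  nz <- 0; tot <- 0
  out <- weights
  nms <- if (is.null(scope)) names(out) else intersect(names(out), scope)
  for (nm in nms) {
    if (!is.numeric(out[[nm]])) next
    out[[nm]] <- prune_one(out[[nm]])
    nz <- nz + sum(out[[nm]] == 0)
    tot <- tot + length(out[[nm]])
  }
  attr(out, "sparsity") <- if (tot > 0) nz / tot else 0
  out
}

#' Uniformly quantize weights
#'
#' `codes = round(w / delta)` using round-half-to-even (R's `round`);
#' `dequantized = codes * delta`, so the reconstruction error of every entry
#' is at most `delta / 2`.
#'
#' @param weights numeric array or named parameter list.
#' @param delta quantization step (> 0).
#' @param scope optional name filter, as in [prune_weights()].
#' @return list with `codes` (integer-valued) and `dequantized` (same
#'   structure as the input).
#' @export
quantize_weights <- function(weights, delta, scope = NULL) {
  if (delta <= 0) stop("delta must be > 0")
  q <- function(w) round(w / delta)
  if (is.numeric(weights)) {
    codes <- q(weights)
    return(list(codes = codes, dequantized = codes * delta))
  }
  codes <- weights; deq <- weights
  nms <- if (is.null(scope)) names(weights) else intersect(names(weights), scope)
  for (nm in names(weights)) {
    if (!is.numeric(weights[[nm]]) || !(nm %in% nms)) {
      codes[[nm]] <- weights[[nm]]
      next
    }
    codes[[nm]] <- q(weights[[nm]])
    deq[[nm]] <- codes[[nm]] * delta
  }
  list(codes = codes, dequantized = deq)
}

#' Compress a trained model and report the accuracy delta
#'
#' Applies pruning then quantization to the model parameters and evaluates
#' before and after on the same split.
#'
#' @param model a `pf_model`.
#' @param samples evaluation samples.
#' @param epsilon pruning threshold.
#' @param delta quantization step.
#' @param scope optional parameter-name filter.
#' @return list with `before`/`after` eval reports, `sparsity`,
#'   `metric_delta` (after - before macro metrics) and `size_estimate`
#'   (nonzero parameter count and a bits-per-weight code-size estimate).
#' @export
report_compression <- function(model, samples, epsilon = 0, delta = 1e-6,
                               scope = NULL) {
  before <- evaluate_model(model, samples)
  pruned <- prune_weights(model$params, epsilon, scope)
  sparsity <- attr(pruned, "sparsity")
  qz <- quantize_weights(pruned, delta, scope)
  compressed <- model
  compressed$params <- qz$dequantized
  after <- evaluate_model(compressed, samples)
  flat <- flatten_params(qz$codes)
  nonzero <- sum(vapply(flat, function(w) sum(w != 0), numeric(1)))
  max_code <- max(vapply(flat, function(w) max(abs(w)), numeric(1)))
  bits <- max(1, ceiling(log2(2 * max_code + 1)))
  list(before = before, after = after, sparsity = sparsity,
       metric_delta = after$macro - before$macro,
       size_estimate = c(nonzero_params = nonzero, bits_per_weight = bits,
                         code_bytes = ceiling(nonzero * bits / 8)),
       model = compressed)
}
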