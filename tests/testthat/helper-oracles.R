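# Independent reference implementations used to cross-check the package.
# These deliberately use naive loops / prefix enumeration and share no code
# with the vectorized implementations they verify.

# Double-loop scaled dot-product attention for one layer (no residual, no
# normalization): out[i, ] = sum_j softmax_i(j) * V[j, ].
oracle_attention <- function(x, Wq, Wk, Wv, scale) {
  N <- nrow(x); D <- ncol(x)
  Q <- x %*% Wq; K <- x %*% Wk; V <- x %*% Wv
  out <- matrix(0, N, D)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(scale)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(N)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Brute-force average precision: enumerate every prefix of the score-ranked
# detection list, compute (precision, recall), and integrate with the
# max-over-suffix precision at each recall increment.
oracle_ap <- function(is_tp, n_gt) {
  n <- length(is_tp)
  if (n == 0) return(0)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    tp <- sum(is_tp[seq_len(k)])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * max(prec[k:n])
      prev_r <- rec[k]
    }
  }
  ap
}

# Naive IoU matcher mirroring greedy matching for oracle mAP runs. Ordering
# ties follow the documented contract: score desc, best-IoU desc, image id.
oracle_match <- function(dets, gts, thr) {
  scores <- vapply(dets, function(d) d$score, numeric(1))
  ids <- vapply(dets, function(d) d$image_id, character(1))
  best_iou <- vapply(dets, function(d) {
    b <- 0
    for (g in gts) {
      if (g$image_id == d$image_id) b <- max(b, iou(d$box, g$box))
    }
    b
  }, numeric(1))
  ord <- order(-scores, -best_iou, ids)
  used <- rep(FALSE, length(gts))
  tp <- logical(length(dets))
  for (k in ord) {
    best <- 0; bj <- 0
    for (j in seq_along(gts)) {
      if (used[j] || gts[[j]]$image_id != dets[[k]]$image_id) next
      ov <- iou(dets[[k]]$box, gts[[j]]$box)
      if (ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0 && best >= thr) { used[bj] <- TRUE; tp[k] <- TRUE }
  }
  tp[ord]
}

# Central finite-difference gradient of f at x (vectorized over entries).
numeric_grad <- function(f, x, h = 1e-4) {
  g <- x
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
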