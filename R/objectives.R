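# Training objectives: supervised contrastive loss over the enhanced
# embedding (raw scaled dot-product similarity, not L2-normalized, with a
# cosine option), intra-class similarity, class-weighted cross-entropy,
# the dual-loss combination, and the MLP classification head.

scaled_similarity <- function(z, tau, cosine = FALSE) {
  stop_if_not(tau > 0, "temperature tau must be > 0")
  if (cosine) {
    nz <- sqrt(rowSums(z * z))
    nz[nz == 0] <- 1
    z <- z / nz
  }
  tcrossprod(z) / tau
}

#' Intra-class similarity
#'
#' For each sample `i`, the mean scaled similarity `S_ij = z_i . z_j /
#' tau` over its positive set `P(i)` (same-label samples, excluding
#' itself).  Samples without any same-label peer get 0 by convention.
#'
#' @param z embedding matrix `N x d`.
#' @param labels 0/1 vector of length `N`.
#' @param tau temperature (> 0).
#' @param cosine use cosine similarity instead of the raw dot product.
#' @return matrix `N x 1`.
#' @export
intra_class_similarity <- function(z, labels, tau = 0.1, cosine = FALSE) {
  n <- nrow(z)
  stop_if_not(n >= 1, "need at least one sample")
  stop_if_not(length(labels) == n, "labels length must match rows of z")
  S <- scaled_similarity(z, tau, cosine)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    out[i] <- if (length(pos) == 0) 0 else mean(S[i, pos])
  }
  matrix(out, ncol = 1L)
}

#' Supervised contrastive loss on pCR labels
#'
#' `L = -(1/N') sum_i (1/|P(i)|) sum_{j in P(i)} log(exp(S_ij) /
#' sum_{k != i} exp(S_ik))` with `S_ij = z_i . z_j / tau`.  Anchors
#' without positives are skipped and `N'` counts the remaining anchors;
#' if every anchor is skipped the loss is 0 with a warning.  Log-sum-exp
#' is computed stably.
#'
#' @inheritParams intra_class_similarity
#' @return scalar loss.
#' @export
supcon_loss <- function(z, labels, tau = 0.1, cosine = FALSE) {
  supcon_loss_grad(z, labels, tau, cosine, want_grad = FALSE)$loss
}

# loss plus (optionally) the analytic gradient wrt z
supcon_loss_grad <- function(z, labels, tau = 0.1, cosine = FALSE,
                             want_grad = TRUE) {
  n <- nrow(z)
  stop_if_not(n >= 2, "need at least two samples")
  stop_if_not(!cosine || !want_grad,
              "analytic gradient implemented for the raw dot-product form only")
  S <- scaled_similarity(z, tau, cosine)
  G <- matrix(0, n, n)   # dL/dS
  loss_terms <- 0
  n_anchors <- 0L
  for (i in seq_len(n)) {
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    if (length(pos) == 0) next
    n_anchors <- n_anchors + 1L
    den_idx <- setdiff(seq_len(n), i)
    srow <- S[i, den_idx]
    m <- max(srow)
    lse <- m + log(sum(exp(srow - m)))
    loss_terms <- loss_terms + (lse - mean(S[i, pos]))
    if (want_grad) {
      G[i, pos] <- G[i, pos] - 1 / length(pos)
      p <- exp(srow - lse)
      G[i, den_idx] <- G[i, den_idx] + p
    }
  }
  if (n_anchors == 0L) {
    warning("no anchor has a same-label peer; contrastive loss is 0")
    return(list(loss = 0, grad = if (want_grad) z * 0 else NULL))
  }
  loss <- loss_terms / n_anchors
  grad <- NULL
  if (want_grad) {
    G <- G / n_anchors
    grad <- (G + t(G)) %*% z / tau
  }
  list(loss = loss, grad = grad)
}

#' Class weights from training-set label counts
#'
#' The pCR class weight `w1` is the count of non-pCR training samples and
#' vice versa, so the minority class is up-weighted proportionally to the
#' imbalance.  Counts are returned raw; divide by their mean (see
#' `normalize_weights` in [run_config()]) to keep loss magnitudes
#' comparable across datasets.
#'
#' @param labels 0/1 training labels (both classes must be present).
#' @return named vector `c(w0 = <pCR count>, w1 = <non-pCR count>)`.
#' @export
class_weights_from_counts <- function(labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stop_if_not(n0 > 0 && n1 > 0, "training labels contain a single class")
  c(w0 = n1, w1 = n0)
}

#' Class-weighted cross-entropy
#'
#' `L = -(1/N) sum_i [w1 y_i log p_i1 + w0 (1-y_i) log p_i0]`.
#' Probabilities are clipped at `eps` to keep the loss finite when a true
#' class receives probability zero.
#'
#' @param probs matrix `N x 2` of class probabilities (rows sum to 1;
#'   column 1 = non-pCR, column 2 = pCR).
#' @param labels 0/1 vector.
#' @param w0,w1 class weights for non-pCR and pCR.
#' @param eps probability floor.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, w0 = 1, w1 = 1,
                                   eps = 1e-12) {
  stop_if_not(nrow(probs) == length(labels), "probs/labels length mismatch")
  p1 <- pmax(probs[, 2], eps)
  p0 <- pmax(probs[, 1], eps)
  -mean(w1 * labels * log(p1) + w0 * (1 - labels) * log(p0))
}

#' Dual-loss combination
#'
#' `L_total = L_cls + lambda * L_CL`.
#'
#' @param lcls classification loss.
#' @param lcl contrastive loss.
#' @param lambda contrastive weight (default 0.9).
#' @return scalar.
#' @export
total_loss <- function(lcls, lcl, lambda = 0.9) {
  stop_if_not(is.finite(lcls) && is.finite(lcl) && lambda >= 0,
              "losses must be finite and lambda >= 0")
  lcls + lambda * lcl
}

# ---- classification head ----------------------------------------------------

init_head <- function(dfuse = 512L, hidden = 128L) {
  list(W1 = init_dense(dfuse, hidden, "he"), b1 = rep(0, hidden),
       W2 = init_dense(hidden, 2L, "xavier"), b2 = rep(0, 2L))
}

head_fwd <- function(ffused, params) {
  l1 <- linear_fwd(ffused, params$W1, params$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, params$W2, params$b2)
  probs <- softmax_rows(l2$out)
  list(out = probs, l1 = l1, r1 = r1, l2 = l2)
}

# upstream gradient arrives already at the logits (see wce_logit_grad)
head_bwd <- function(cache, params, dlogits) {
  g <- tree_zeros_like(params)
  b2 <- linear_bwd(cache$l2, params$W2, dlogits)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- linear_bwd(cache$l1, params$W1, dr1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  list(dx = b1$dx, grads = g)
}

# gradient of the weighted cross-entropy wrt the head logits
wce_logit_grad <- function(probs, labels, w0, w1) {
  n <- length(labels)
  w <- ifelse(labels == 1, w1, w0)
  target <- cbind(1 - labels, labels)
  (w / n) * (probs - target)
}

#' MLP classification head over the fused feature
#'
#' Two-layer perceptron (`dfuse -> hidden -> 2`) with ReLU and a softmax
#' output, producing the two-class pCR probability per sample.
#'
#' @param ffused fused feature matrix `B x dfuse`.
#' @param params head parameters (`W1`, `b1`, `W2`, `b2`).
#' @return matrix `B x 2` of probabilities (rows sum to 1; column 2 is
#'   the pCR probability).
#' @export
classification_head <- function(ffused, params) {
  head_fwd(ffused, params)$out
}
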