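# Shared fixtures and independent oracles used across the suite.

# tiny model configuration for fast end-to-end runs and gradient checks
tiny_config <- function(...) {
  desk_profile(input_shape = c(16L, 16L, 8L), patch_size = 8L,
               chid = 16L, depth = 1L, heads = 2L,
               dmid = 8L, dclin = 12L, dfuse = 16L, fusion_heads = 2L,
               dz = 8L, head_hidden = 8L, seed = 7L, ...)
}

tiny_batch <- function(cfg, B = 4L, d_clin_in = 10L, seed = 99L) {
  pcrfusion:::with_seed(seed, list(
    patches = array(rnorm(B * cfg$img$n_patches * cfg$img$patch_dim),
                    dim = c(B, cfg$img$n_patches, cfg$img$patch_dim)),
    xclin = matrix(rnorm(B * d_clin_in), B, d_clin_in),
    labels = rep_len(c(0, 1), B)))
}

# small separable cohort for training smoke tests
tiny_cohort_data <- function(cfg, n = 40L, seed = 5L) {
  cohort <- generate_cohort(
    cohort_spec(n = n, pcr_rate_target = 0.4, beta_img = 2,
                beta_clin = c(er = -1.5, her2 = 1.5),
                gamma_interaction = 2.5, seed = seed),
    phantom_spec(shape = cfg$img$input_shape,
                 tumor_radii = pmax(2, cfg$img$input_shape / 5)))
  list(patches = prepare_volumes(cohort$volumes, cfg),
       clinical = cohort$clinical, labels = cohort$labels,
       cohort = cohort)
}

# ---- independent brute-force oracles ---------------------------------------

supcon_oracle <- function(z, labels, tau) {
  n <- nrow(z)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) S[i, j] <- sum(z[i, ] * z[j, ]) / tau
  total <- 0
  anchors <- 0
  for (i in 1:n) {
    P <- setdiff(which(labels == labels[i]), i)
    if (length(P) == 0) next
    anchors <- anchors + 1
    term <- 0
    for (j in P) {
      den <- 0
      for (k in setdiff(1:n, i)) den <- den + exp(S[i, k])
      term <- term + log(exp(S[i, j]) / den)
    }
    total <- total + term / length(P)
  }
  if (anchors == 0) return(0)
  -total / anchors
}

sintra_oracle <- function(z, labels, tau) {
  n <- nrow(z)
  out <- numeric(n)
  for (i in 1:n) {
    P <- setdiff(which(labels == labels[i]), i)
    if (length(P) == 0) next
    s <- 0
    for (j in P) s <- s + sum(z[i, ] * z[j, ]) / tau
    out[i] <- s / length(P)
  }
  out
}

wce_oracle <- function(probs, labels, w0, w1) {
  total <- 0
  for (i in seq_along(labels)) {
    total <- total + if (labels[i] == 1) w1 * log(probs[i, 2]) else
      w0 * log(probs[i, 1])
  }
  unname(-total / length(labels))
}

auc_pairs_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# slow structural-components DeLong (direct double loops)
delong_slow <- function(labels, sa, sb) {
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  comp <- function(scores) {
    xs <- scores[labels == 1]
    ys <- scores[labels == 0]
    m <- length(xs); n <- length(ys)
    auc <- 0
    for (x in xs) for (y in ys) auc <- auc + psi(x, y)
    auc <- auc / (m * n)
    v10 <- vapply(xs, function(x) mean(vapply(ys, function(y) psi(x, y),
                                              numeric(1))), numeric(1))
    v01 <- vapply(ys, function(y) mean(vapply(xs, function(x) psi(x, y),
                                              numeric(1))), numeric(1))
    list(auc = auc, v10 = v10, v01 = v01)
  }
  ca <- comp(sa); cb <- comp(sb)
  m <- sum(labels == 1); n <- sum(labels == 0)
  L <- c(1, -1)
  v <- drop(t(L) %*% stats::var(cbind(ca$v10, cb$v10)) %*% L) / m +
       drop(t(L) %*% stats::var(cbind(ca$v01, cb$v01)) %*% L) / n
  diff <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) return(list(diff = diff, var = v, p = 1))
  z <- diff / sqrt(v)
  list(diff = diff, var = v, p = 2 * stats::pnorm(-abs(z)))
}

# single-token multi-head cross-attention, written out literally
cross_attention_oracle <- function(q, k, v, path, heads) {
  dfuse <- ncol(q)
  dh <- dfuse / heads
  B <- nrow(q)
  attended <- matrix(0, B, dfuse)
  pooled <- matrix(0, B, 1)
  for (b in 1:B) {
    heads_out <- NULL
    wsum <- 0
    for (h in 1:heads) {
      cols <- (h - 1) * dh + 1:dh
      qh <- q[b, , drop = FALSE] %*% path$Wq[, cols]
      kh <- k[b, , drop = FALSE] %*% path$Wk[, cols]
      vh <- v[b, , drop = FALSE] %*% path$Wv[, cols]
      logit <- sum(qh * kh) / sqrt(dh)
      w <- exp(logit) / exp(logit)       # softmax over the one-key axis
      heads_out <- cbind(heads_out, w * vh)
      wsum <- wsum + w                   # global average pool of a 1x1 matrix
    }
    attended[b, ] <- heads_out %*% path$Wout
    pooled[b, 1] <- wsum / heads
  }
  list(attended = attended, pooled = pooled)
}
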