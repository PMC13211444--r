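# AdamW over nested parameter trees, with per-module learning-rate groups
# (the image encoder trains at a lower rate than the rest, mirroring the
# layer-wise strategy used for fine-tuned backbones) and a single-cycle
# cosine-annealing schedule over the total number of epochs.

adamw_init <- function(params) {
  list(m = tree_zeros_like(params),
       v = tree_zeros_like(params),
       t = 0L)
}

#' @noRd
#' @param lr_map named numeric: learning rate per top-level module name;
#'   entries missing from `lr_map` fall back to `lr_map[[".default"]]`.
adamw_step <- function(params, grads, state, lr_map, lr_scale = 1,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (mod in names(params)) {
    lr <- lr_map[[mod]]
    if (is.null(lr)) lr <- lr_map[[".default"]]
    lr <- lr * lr_scale
    res <- adamw_update_tree(params[[mod]], grads[[mod]],
                             state$m[[mod]], state$v[[mod]],
                             lr, beta1, beta2, eps, weight_decay, bc1, bc2)
    params[[mod]] <- res$p
    state$m[[mod]] <- res$m
    state$v[[mod]] <- res$v
  }
  list(params = params, state = state)
}

adamw_update_tree <- function(p, g, m, v, lr, beta1, beta2, eps,
                              wd, bc1, bc2) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      res <- adamw_update_tree(p[[i]], g[[i]], m[[i]], v[[i]],
                               lr, beta1, beta2, eps, wd, bc1, bc2)
      p[[i]] <- res$p
      m[[i]] <- res$m
      v[[i]] <- res$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / bc1
    vhat <- v / bc2
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
    list(p = p, m = m, v = v)
  }
}

# CosineAnnealingLR factor for 0-indexed epoch e out of `total` epochs
# (single cycle, annealing to zero).
cosine_lr_factor <- function(epoch0, total) {
  0.5 * (1 + cos(pi * epoch0 / total))
}
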