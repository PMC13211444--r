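# Modality encoders.
#
# Imaging: a patch-based 3D vision transformer built from scratch.  The
# volume is cut into non-overlapping cubic patches, linearly embedded,
# prepended with a learned CLS token, given learned positional embeddings,
# passed through pre-norm transformer blocks (multi-head self-attention +
# GELU MLP), and the final-layer CLS token is LayerNorm-ed into the global
# imaging feature.  There is no pretrained checkpoint; scale is set by the
# config.
#
# Clinical: two stacked stages of Linear -> ReLU -> LayerNorm mapping the
# encoded clinical vector to 128 then 256 dimensions.
#
# Forward functions cache every intermediate needed by the hand-written
# backward passes; gradients are checked against finite differences in the
# test suite.

#' Imaging encoder configuration
#'
#' @param input_shape volume shape (H, W, D) the encoder operates on; each
#'   dimension must be divisible by `patch_size`.
#' @param patch_size cubic patch edge length in voxels.
#' @param chid hidden (token) dimension; divisible by `heads`.  The
#'   paper-scale default is 768; desk-scale tests use much smaller values.
#' @param depth number of transformer blocks.
#' @param heads number of self-attention heads.
#' @param ln_eps layer-norm epsilon.
#' @return list of class `imaging_encoder_config`, including the derived
#'   patch-token count `n_patches`.
#' @export
imaging_encoder_config <- function(input_shape = c(192L, 192L, 112L),
                                   patch_size = 8L,
                                   chid = 768L, depth = 4L, heads = 8L,
                                   ln_eps = 1e-5) {
  for (ax in 1:3) {
    if (input_shape[ax] %% patch_size != 0) {
      stop(sprintf("axis %d (size %d) is not divisible by patch_size %d",
                   ax, input_shape[ax], patch_size), call. = FALSE)
    }
  }
  stop_if_not(chid %% heads == 0, "chid must be divisible by heads")
  n_patches <- prod(as.integer(input_shape) %/% as.integer(patch_size))
  structure(list(input_shape = as.integer(input_shape),
                 patch_size = as.integer(patch_size),
                 chid = as.integer(chid), depth = as.integer(depth),
                 heads = as.integer(heads), ln_eps = ln_eps,
                 n_patches = as.integer(n_patches),
                 patch_dim = as.integer(patch_size^3)),
            class = "imaging_encoder_config")
}

#' Cut a volume into flattened non-overlapping cubic patches
#'
#' @param volume 3D array whose dimensions are divisible by `patch_size`.
#' @param patch_size cubic patch edge in voxels.
#' @return matrix with one row per patch (row count
#'   `prod(dim(volume) / patch_size)`), columns = voxels in array order.
#' @export
volume_to_patches <- function(volume, patch_size) {
  d <- dim(volume)
  for (ax in 1:3) {
    if (d[ax] %% patch_size != 0) {
      stop(sprintf("axis %d (size %d) is not divisible by patch_size %d",
                   ax, d[ax], patch_size), call. = FALSE)
    }
  }
  g <- d %/% patch_size
  n <- prod(g)
  out <- matrix(0, n, patch_size^3)
  idx <- 1L
  for (k in seq_len(g[3])) {
    for (j in seq_len(g[2])) {
      for (i in seq_len(g[1])) {
        out[idx, ] <- volume[(i - 1L) * patch_size + seq_len(patch_size),
                             (j - 1L) * patch_size + seq_len(patch_size),
                             (k - 1L) * patch_size + seq_len(patch_size)]
        idx <- idx + 1L
      }
    }
  }
  out
}

init_image_encoder <- function(cfg) {
  d <- cfg$chid
  blocks <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    blocks[[l]] <- list(
      ln1 = init_ln(d),
      Wqkv = init_dense(d, 3L * d, "xavier"), bqkv = rep(0, 3L * d),
      Wo = init_dense(d, d, "xavier"), bo = rep(0, d),
      ln2 = init_ln(d),
      Wm1 = init_dense(d, 4L * d, "he"), bm1 = rep(0, 4L * d),
      Wm2 = init_dense(4L * d, d, "xavier"), bm2 = rep(0, d))
  }
  list(Wemb = init_dense(cfg$patch_dim, d, "xavier"), bemb = rep(0, d),
       cls = matrix(rnorm(d, sd = 0.02), 1L, d),
       pos = matrix(rnorm((cfg$n_patches + 1L) * d, sd = 0.02),
                    cfg$n_patches + 1L, d),
       blocks = blocks,
       lnf = init_ln(d))
}

# ---- multi-head self-attention over token sequences -------------------------

mhsa_fwd <- function(x, Wqkv, bqkv, Wo, bo, heads) {
  # x: T x d tokens for ONE sample
  d <- ncol(x)
  dh <- d %/% heads
  qkv <- sweep(x %*% Wqkv, 2L, bqkv, `+`)
  q <- qkv[, seq_len(d), drop = FALSE]
  k <- qkv[, d + seq_len(d), drop = FALSE]
  v <- qkv[, 2L * d + seq_len(d), drop = FALSE]
  att <- matrix(0, nrow(x), d)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    att[, cols] <- A[[h]] %*% v[, cols, drop = FALSE]
  }
  out <- sweep(att %*% Wo, 2L, bo, `+`)
  list(out = out, x = x, q = q, k = k, v = v, A = A, att = att)
}

mhsa_bwd <- function(cache, Wqkv, Wo, heads, dout) {
  d <- ncol(cache$x)
  dh <- d %/% heads
  datt <- dout %*% t(Wo)
  dWo <- crossprod(cache$att, dout)
  dbo <- colSums(dout)
  dq <- matrix(0, nrow(cache$x), d)
  dk <- matrix(0, nrow(cache$x), d)
  dv <- matrix(0, nrow(cache$x), d)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A <- cache$A[[h]]
    dA <- datt[, cols, drop = FALSE] %*% t(cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(A, datt[, cols, drop = FALSE])
    dS <- softmax_bwd(A, dA) / sqrt(dh)
    dq[, cols] <- dS %*% cache$k[, cols, drop = FALSE]
    dk[, cols] <- crossprod(dS, cache$q[, cols, drop = FALSE])
  }
  dqkv <- cbind(dq, dk, dv)
  list(dx = dqkv %*% t(Wqkv),
       dWqkv = crossprod(cache$x, dqkv),
       dbqkv = colSums(dqkv),
       dWo = dWo, dbo = dbo)
}

block_fwd <- function(x, p, heads) {
  ln1 <- layernorm_fwd(x, p$ln1$g, p$ln1$b)
  sa <- mhsa_fwd(ln1$out, p$Wqkv, p$bqkv, p$Wo, p$bo, heads)
  h1 <- x + sa$out
  ln2 <- layernorm_fwd(h1, p$ln2$g, p$ln2$b)
  m1 <- linear_fwd(ln2$out, p$Wm1, p$bm1)
  ge <- gelu_fwd(m1$out)
  m2 <- linear_fwd(ge$out, p$Wm2, p$bm2)
  list(out = h1 + m2$out, ln1 = ln1, sa = sa, h1 = h1, ln2 = ln2,
       m1 = m1, ge = ge, m2 = m2)
}

block_bwd <- function(cache, p, heads, dout) {
  g <- tree_zeros_like(p)
  b2 <- linear_bwd(cache$m2, p$Wm2, dout)
  g$Wm2 <- b2$dW; g$bm2 <- b2$db
  dge <- gelu_bwd(cache$ge, b2$dx)
  b1 <- linear_bwd(cache$m1, p$Wm1, dge)
  g$Wm1 <- b1$dW; g$bm1 <- b1$db
  l2 <- layernorm_bwd(cache$ln2, p$ln2$g, b1$dx)
  g$ln2$g <- l2$dg; g$ln2$b <- l2$db
  dh1 <- dout + l2$dx
  sa <- mhsa_bwd(cache$sa, p$Wqkv, p$Wo, heads, dh1)
  g$Wqkv <- sa$dWqkv; g$bqkv <- sa$dbqkv
  g$Wo <- sa$dWo; g$bo <- sa$dbo
  l1 <- layernorm_bwd(cache$ln1, p$ln1$g, sa$dx)
  g$ln1$g <- l1$dg; g$ln1$b <- l1$db
  list(dx = dh1 + l1$dx, grads = g)
}

# patches: array (B, N, patch_dim)
image_encoder_fwd <- function(patches, params, cfg) {
  B <- dim(patches)[1]
  N <- cfg$n_patches
  T <- N + 1L
  # col-major flattening: row index b + (n-1)*B holds patch n of sample b
  emb_in <- matrix(patches, B * N, cfg$patch_dim)
  emb <- linear_fwd(emb_in, params$Wemb, params$bemb)
  tokens <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(N) - 1L) * B
    tok <- rbind(params$cls, emb$out[rows, , drop = FALSE]) + params$pos
    tokens[[b]] <- tok
  }
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    x <- tokens[[b]]
    bl <- vector("list", cfg$depth)
    for (l in seq_len(cfg$depth)) {
      bl[[l]] <- block_fwd(x, params$blocks[[l]], cfg$heads)
      x <- bl[[l]]$out
    }
    caches[[b]] <- list(blocks = bl, final = x)
  }
  cls_last <- do.call(rbind, lapply(caches, function(cc) cc$final[1L, , drop = FALSE]))
  lnf <- layernorm_fwd(cls_last, params$lnf$g, params$lnf$b)
  list(out = lnf$out, emb = emb, caches = caches, lnf = lnf, B = B, N = N)
}

image_encoder_bwd <- function(cache, params, cfg, dout) {
  B <- cache$B
  N <- cache$N
  g <- tree_zeros_like(params)
  lf <- layernorm_bwd(cache$lnf, params$lnf$g, dout)
  g$lnf$g <- lf$dg; g$lnf$b <- lf$db
  demb_out <- matrix(0, B * N, cfg$chid)
  for (b in seq_len(B)) {
    dx <- matrix(0, N + 1L, cfg$chid)
    dx[1L, ] <- lf$dx[b, ]
    for (l in rev(seq_len(cfg$depth))) {
      bb <- block_bwd(cache$caches[[b]]$blocks[[l]], params$blocks[[l]],
                      cfg$heads, dx)
      dx <- bb$dx
      g$blocks[[l]] <- tree_map2(g$blocks[[l]], bb$grads, `+`)
    }
    # dx is the gradient at (tokens + pos)
    g$pos <- g$pos + dx
    g$cls <- g$cls + dx[1L, , drop = FALSE]
    rows <- b + (seq_len(N) - 1L) * B
    demb_out[rows, ] <- dx[-1L, , drop = FALSE]
  }
  be <- linear_bwd(cache$emb, params$Wemb, demb_out)
  g$Wemb <- be$dW; g$bemb <- be$db
  g
}

#' Encode a batch of volumes into global imaging features
#'
#' Runs the 3D vision-transformer encoder: patch embedding, CLS token +
#' positional embeddings, `depth` transformer blocks, and a final
#' LayerNorm of the last-layer CLS token.
#'
#' @param volumes list of 3D arrays (all of `config$input_shape`), or a
#'   pre-patchified array of dimension `(B, n_patches, patch_dim)`.
#' @param params encoder parameters from the model initializer.
#' @param config an [imaging_encoder_config()].
#' @return matrix `B x chid` of imaging features (rows LayerNorm-ed).
#' @export
encode_image <- function(volumes, params, config) {
  patches <- patchify_batch(volumes, config)
  image_encoder_fwd(patches, params, config)$out
}

# volumes (list) or (B,N,pdim) array -> (B,N,pdim) array
patchify_batch <- function(volumes, cfg) {
  if (is.array(volumes) && length(dim(volumes)) == 3L &&
      dim(volumes)[2] == cfg$n_patches && dim(volumes)[3] == cfg$patch_dim) {
    return(volumes)
  }
  stop_if_not(is.list(volumes), "`volumes` must be a list of 3D arrays or a patch array")
  B <- length(volumes)
  out <- array(0, dim = c(B, cfg$n_patches, cfg$patch_dim))
  for (b in seq_len(B)) {
    stop_if_not(all(dim(volumes[[b]]) == cfg$input_shape),
                "volume %d has shape %s, expected %s", b,
                paste(dim(volumes[[b]]), collapse = "x"),
                paste(cfg$input_shape, collapse = "x"))
    out[b, , ] <- volume_to_patches(volumes[[b]], cfg$patch_size)
  }
  out
}

# ---- clinical encoder -------------------------------------------------------

init_clinical_encoder <- function(d_in, dmid = 128L, dclin = 256L) {
  list(W1 = init_dense(d_in, dmid, "he"), b1 = rep(0, dmid),
       ln1 = init_ln(dmid),
       W2 = init_dense(dmid, dclin, "he"), b2 = rep(0, dclin),
       ln2 = init_ln(dclin))
}

clinical_encoder_fwd <- function(x, params) {
  l1 <- linear_fwd(x, params$W1, params$b1)
  r1 <- relu_fwd(l1$out)
  n1 <- layernorm_fwd(r1$out, params$ln1$g, params$ln1$b)
  l2 <- linear_fwd(n1$out, params$W2, params$b2)
  r2 <- relu_fwd(l2$out)
  n2 <- layernorm_fwd(r2$out, params$ln2$g, params$ln2$b)
  list(out = n2$out, z1 = n1$out,
       l1 = l1, r1 = r1, n1 = n1, l2 = l2, r2 = r2, n2 = n2)
}

clinical_encoder_bwd <- function(cache, params, dout) {
  g <- tree_zeros_like(params)
  b2 <- layernorm_bwd(cache$n2, params$ln2$g, dout)
  g$ln2$g <- b2$dg; g$ln2$b <- b2$db
  dr2 <- relu_bwd(cache$r2, b2$dx)
  lb2 <- linear_bwd(cache$l2, params$W2, dr2)
  g$W2 <- lb2$dW; g$b2 <- lb2$db
  b1 <- layernorm_bwd(cache$n1, params$ln1$g, lb2$dx)
  g$ln1$g <- b1$dg; g$ln1$b <- b1$db
  dr1 <- relu_bwd(cache$r1, b1$dx)
  lb1 <- linear_bwd(cache$l1, params$W1, dr1)
  g$W1 <- lb1$dW; g$b1 <- lb1$db
  list(dx = lb1$dx, grads = g)
}

#' Encode clinical vectors through the two-stage clinical encoder
#'
#' Stage one maps the raw encoded vector to a 128-dimensional intermediate
#' (`Linear -> ReLU -> LayerNorm`), stage two refines it to the final
#' 256-dimensional clinical representation by the same pattern.
#'
#' @param x matrix `B x d_clin_in` of encoded clinical vectors.
#' @param params clinical-encoder parameters.
#' @return list with `z1` (`B x 128` intermediate) and `fclin`
#'   (`B x 256` final representation); dimensions follow the parameter
#'   shapes, so scaled-down configs are honoured.
#' @export
encode_clinical_features <- function(x, params) {
  stop_if_not(ncol(x) == nrow(params$W1),
              "input has %d columns, encoder expects %d", ncol(x), nrow(params$W1))
  fw <- clinical_encoder_fwd(x, params)
  list(z1 = fw$z1, fclin = fw$out)
}
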