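# Bidirectional cross-modal attention fusion.
#
# Both modality features are projected into a shared `dfuse`-dimensional
# space, then two parallel multi-head cross-attention pathways run:
# IGC-Attention (imaging queries, clinical keys/values) and CGI-Attention
# (clinical queries, imaging keys/values), each with its own parameter
# set.  Because each modality contributes a single pooled token, the
# softmax over the one-element key axis is exactly 1; the literal pooled
# attention summaries (amri, aclin) are therefore constant 1, and an
# alternative `pooled = "pre_softmax_sigmoid"` mode (sigmoid of the
# head-averaged scaled logit) is provided for sample-dependent
# calibration.  The two attended features are concatenated and linearly
# projected to the fused feature.

init_bicma <- function(chid, dclin, dfuse = 512L, heads = 8L) {
  stop_if_not(dfuse %% heads == 0, "dfuse must be divisible by heads")
  path <- function() list(Wq = init_dense(dfuse, dfuse, "xavier"),
                          Wk = init_dense(dfuse, dfuse, "xavier"),
                          Wv = init_dense(dfuse, dfuse, "xavier"),
                          Wout = init_dense(dfuse, dfuse, "xavier"))
  list(Wimg = init_dense(chid, dfuse, "xavier"), bimg = rep(0, dfuse),
       Wclin = init_dense(dclin, dfuse, "xavier"), bclin = rep(0, dfuse),
       igc = path(), cgi = path(),
       Wfusion = init_dense(2L * dfuse, dfuse, "xavier"),
       bfusion = rep(0, dfuse))
}

#' Project modality features into the shared fusion space
#'
#' Affine maps from the imaging (`chid`) and clinical (256) feature
#' dimensions into the common `dfuse`-dimensional latent space in which
#' the cross-attention pathways operate.
#'
#' @param fimg matrix `B x chid` of imaging features.
#' @param fclin matrix `B x dclin` of clinical features.
#' @param params BiCMA parameter list (`Wimg`, `bimg`, `Wclin`, `bclin`).
#' @return list with `fimgproj` and `fclinproj`, both `B x dfuse`.
#' @export
shared_projection <- function(fimg, fclin, params) {
  stop_if_not(ncol(fimg) == nrow(params$Wimg),
              "fimg has %d columns, projection expects %d",
              ncol(fimg), nrow(params$Wimg))
  stop_if_not(ncol(fclin) == nrow(params$Wclin),
              "fclin has %d columns, projection expects %d",
              ncol(fclin), nrow(params$Wclin))
  list(fimgproj = linear_fwd(fimg, params$Wimg, params$bimg)$out,
       fclinproj = linear_fwd(fclin, params$Wclin, params$bclin)$out)
}

cross_attention_fwd <- function(query, key, value, path, heads,
                                pooled = c("literal", "pre_softmax_sigmoid")) {
  pooled <- match.arg(pooled)
  dfuse <- ncol(query)
  stop_if_not(dfuse %% heads == 0, "dfuse (%d) not divisible by heads (%d)",
              dfuse, heads)
  dh <- dfuse %/% heads
  Q <- query %*% path$Wq
  K <- key %*% path$Wk
  V <- value %*% path$Wv
  # per-head scaled dot-product logits; with a single key token the
  # post-softmax weight is identically 1 and attended_h = V_h
  logits <- matrix(0, nrow(query), heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    logits[, h] <- rowSums(Q[, cols, drop = FALSE] * K[, cols, drop = FALSE]) / sqrt(dh)
  }
  attended <- V %*% path$Wout
  pooled_weight <- if (pooled == "literal") {
    matrix(1, nrow(query), 1L)
  } else {
    matrix(sigmoid(rowMeans(logits)), ncol = 1L)
  }
  list(out = attended, pooled = pooled_weight,
       query = query, key = key, value = value,
       Q = Q, K = K, V = V, logits = logits, mode = pooled, heads = heads)
}

cross_attention_bwd <- function(cache, path, dout, dpooled = NULL) {
  heads <- cache$heads
  dfuse <- ncol(cache$query)
  dh <- dfuse %/% heads
  dV <- dout %*% t(path$Wout)
  g <- list(Wq = matrix(0, dfuse, dfuse), Wk = matrix(0, dfuse, dfuse),
            Wv = crossprod(cache$value, dV),
            Wout = crossprod(cache$V, dout))
  dquery <- matrix(0, nrow(cache$query), dfuse)
  dkey <- matrix(0, nrow(cache$key), dfuse)
  dvalue <- dV %*% t(path$Wv)
  if (!is.null(dpooled) && cache$mode == "pre_softmax_sigmoid" &&
      any(dpooled != 0)) {
    p <- sigmoid(rowMeans(cache$logits))
    dmean <- as.vector(dpooled) * p * (1 - p)
    dQ <- matrix(0, nrow(cache$query), dfuse)
    dK <- matrix(0, nrow(cache$key), dfuse)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      dlog <- dmean / heads
      dQ[, cols] <- dlog * cache$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- dlog * cache$Q[, cols, drop = FALSE] / sqrt(dh)
    }
    g$Wq <- crossprod(cache$query, dQ)
    g$Wk <- crossprod(cache$key, dK)
    dquery <- dQ %*% t(path$Wq)
    dkey <- dK %*% t(path$Wk)
  }
  list(dquery = dquery, dkey = dkey, dvalue = dvalue, grads = g)
}

#' Single-token multi-head cross-attention
#'
#' Treats each sample's query/key/value vectors as one-token sequences.
#' Per head, the scaled dot-product logit is `q . k / sqrt(dhead)`;
#' softmax over the (single-element) key axis gives weight exactly 1, so
#' the attended output reduces to `Wout %*% concat_h(Wv_h v)`.  The
#' pooled summary is the head-average of the global-average-pooled
#' post-softmax weights (identically 1 in the literal mode) or, in
#' `"pre_softmax_sigmoid"` mode, the sigmoid of the head-averaged logit.
#'
#' @param query_vec,key_vec,value_vec matrices `B x dfuse`.
#' @param params pathway parameters: `Wq`, `Wk`, `Wv`, `Wout`
#'   (`dfuse x dfuse`; per-head blocks of `Wq`/`Wk`/`Wv` columns).
#' @param heads number of attention heads (`dfuse` divisible by `heads`).
#' @param pooled `"literal"` or `"pre_softmax_sigmoid"`.
#' @return list with `attended` (`B x dfuse`) and `pooled_weight`
#'   (`B x 1`).
#' @export
multihead_cross_attention <- function(query_vec, key_vec, value_vec, params,
                                      heads = 8L,
                                      pooled = c("literal", "pre_softmax_sigmoid")) {
  fw <- cross_attention_fwd(query_vec, key_vec, value_vec, params, heads,
                            match.arg(pooled))
  list(attended = fw$out, pooled_weight = fw$pooled)
}

bicma_fwd <- function(fimg, fclin, params, heads, pooled) {
  pi_ <- linear_fwd(fimg, params$Wimg, params$bimg)
  pc <- linear_fwd(fclin, params$Wclin, params$bclin)
  igc <- cross_attention_fwd(pi_$out, pc$out, pc$out, params$igc, heads, pooled)
  cgi <- cross_attention_fwd(pc$out, pi_$out, pi_$out, params$cgi, heads, pooled)
  cat_ <- cbind(igc$out, cgi$out)
  fus <- linear_fwd(cat_, params$Wfusion, params$bfusion)
  list(out = fus$out, amri = igc$pooled, aclin = cgi$pooled,
       fimgattn = igc$out, fclinattn = cgi$out,
       proj_img = pi_, proj_clin = pc, igc = igc, cgi = cgi, fus = fus)
}

bicma_bwd <- function(cache, params, dout, damri = NULL, daclin = NULL) {
  g <- tree_zeros_like(params)
  fb <- linear_bwd(cache$fus, params$Wfusion, dout)
  g$Wfusion <- fb$dW; g$bfusion <- fb$db
  dfuse <- ncol(cache$igc$out)
  d_igc <- fb$dx[, seq_len(dfuse), drop = FALSE]
  d_cgi <- fb$dx[, dfuse + seq_len(dfuse), drop = FALSE]
  bi <- cross_attention_bwd(cache$igc, params$igc, d_igc, damri)
  bc <- cross_attention_bwd(cache$cgi, params$cgi, d_cgi, daclin)
  g$igc <- bi$grads
  g$cgi <- bc$grads
  dpimg <- bi$dquery + bc$dkey + bc$dvalue
  dpclin <- bi$dkey + bi$dvalue + bc$dquery
  li <- linear_bwd(cache$proj_img, params$Wimg, dpimg)
  g$Wimg <- li$dW; g$bimg <- li$db
  lc <- linear_bwd(cache$proj_clin, params$Wclin, dpclin)
  g$Wclin <- lc$dW; g$bclin <- lc$db
  list(dfimg = li$dx, dfclin = lc$dx, grads = g)
}

#' Bidirectional cross-modal attention fusion
#'
#' Runs the full fusion: shared projection, IGC-Attention (imaging
#' queries / clinical keys+values), CGI-Attention (the mirror direction,
#' with its own independent parameters), and the joint projection of the
#' concatenated attended features to the fused representation.
#'
#' @param fimg,fclin modality feature matrices.
#' @param params full BiCMA parameter list (see [init_bicma] via the
#'   model constructor).
#' @param heads attention heads per pathway.
#' @param pooled pooled-summary mode, see [multihead_cross_attention()].
#' @return list with `ffused` (`B x dfuse`), pooled summaries `amri`,
#'   `aclin` (`B x 1`), and the attended features `fimgattn`,
#'   `fclinattn`.
#' @export
bicma_fuse <- function(fimg, fclin, params, heads = 8L,
                       pooled = c("literal", "pre_softmax_sigmoid")) {
  fw <- bicma_fwd(fimg, fclin, params, heads, match.arg(pooled))
  list(ffused = fw$out, amri = fw$amri, aclin = fw$aclin,
       fimgattn = fw$fimgattn, fclinattn = fw$fclinattn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
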