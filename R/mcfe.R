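# Multimodal contrast-aware feature enhancement (MCFE).
#
# Four stages operate on the pooled fused feature: (1) modal calibration
# via sigmoid gates on the pooled cross-attention summaries, (2) clinical
# semantic-guided feature selection via a softmax over the fused feature
# slots, (3) dual-path refinement whose activation strength is modulated
# by the intra-class similarity (smaller similarity = harder sample =
# stronger activation), and (4) projection of both paths to the
# contrastive embedding.  The similarity feedback is circular as written
# (the activation needs sintra, which is defined on the embedding the
# activation produces); it is resolved by a two-pass scheme: a provisional
# embedding is computed with sintra = 0, sintra is derived from it and
# detached from gradient flow, then the activation and projections are
# recomputed with that sintra.

init_mcfe <- function(dfuse = 512L, dclin = 256L, dz = 128L) {
  list(gate = list(Wmri = 0, bmri = 0, Wclin = 0, bclin = 0),
       Ws = init_dense(dclin, dfuse, "he"), bs = rep(0, dfuse),
       ln_s = init_ln(dfuse),
       W1 = init_dense(dfuse, dfuse, "he"), b1 = rep(0, dfuse),
       ln1 = init_ln(dfuse),
       W2 = init_dense(dfuse, dfuse, "he"), b2 = rep(0, dfuse),
       ln2 = init_ln(dfuse),
       Wp1 = init_dense(dfuse, dz, "xavier"), bp1 = rep(0, dz),
       lnp1 = init_ln(dz),
       Wp2 = init_dense(dfuse, dz, "xavier"), bp2 = rep(0, dz),
       lnp2 = init_ln(dz),
       alpha = 1.0, beta = 0.1)
}

calibration_fwd <- function(ffused, amri, aclin, params) {
  gm <- params$gate$Wmri * as.vector(amri) + params$gate$bmri
  gc_ <- params$gate$Wclin * as.vector(aclin) + params$gate$bclin
  wmri <- sigmoid(gm)
  wclin <- sigmoid(gc_)
  w <- wmri + wclin
  list(out = w * ffused, wmri = wmri, wclin = wclin, w = w,
       ffused = ffused, amri = as.vector(amri), aclin = as.vector(aclin))
}

calibration_bwd <- function(cache, params, dout) {
  dffused <- cache$w * dout
  dw <- rowSums(dout * cache$ffused)
  dgm <- dw * cache$wmri * (1 - cache$wmri)
  dgc <- dw * cache$wclin * (1 - cache$wclin)
  list(dffused = dffused,
       damri = matrix(dgm * params$gate$Wmri, ncol = 1L),
       daclin = matrix(dgc * params$gate$Wclin, ncol = 1L),
       grads = list(Wmri = sum(dgm * cache$amri), bmri = sum(dgm),
                    Wclin = sum(dgc * cache$aclin), bclin = sum(dgc)))
}

#' Modal calibration of the fused feature
#'
#' Sigmoid gates on the pooled attention summaries produce per-sample
#' modality weights `wmri`, `wclin`; the calibrated feature is
#' `(wmri + wclin) * ffused` (the two gated copies of Eq.-style
#' element-wise products collapse algebraically to a single broadcast
#' scale).  With zero gating parameters both gates are 0.5 and the
#' operation is the identity.
#'
#' @param ffused fused feature `B x dfuse`.
#' @param amri,aclin pooled attention summaries `B x 1`.
#' @param params MCFE parameter list (uses the `gate` scalars).
#' @return list with `fcalibrated`, `wmri`, `wclin`.
#' @export
modal_calibration <- function(ffused, amri, aclin, params) {
  fw <- calibration_fwd(ffused, amri, aclin, params)
  list(fcalibrated = fw$out, wmri = fw$wmri, wclin = fw$wclin)
}

selection_fwd <- function(fcal, fclin, params) {
  u <- linear_fwd(fclin, params$Ws, params$bs)
  n <- layernorm_fwd(u$out, params$ln_s$g, params$ln_s$b)
  r <- relu_fwd(n$out)
  s <- softmax_rows(r$out)
  list(out = fcal * s, s = s, fcal = fcal, u = u, n = n, r = r)
}

selection_bwd <- function(cache, params, dout) {
  dfcal <- dout * cache$s
  ds <- dout * cache$fcal
  dr <- softmax_bwd(cache$s, ds)
  dn <- relu_bwd(cache$r, dr)
  lb <- layernorm_bwd(cache$n, params$ln_s$g, dn)
  ub <- linear_bwd(cache$u, params$Ws, lb$dx)
  list(dfcal = dfcal, dfclin = ub$dx,
       grads = list(Ws = ub$dW, bs = ub$db,
                    ln_s = list(g = lb$dg, b = lb$db)))
}

#' Clinical semantic-guided feature selection
#'
#' A feature-slot attention weight `s = Softmax(ReLU(LayerNorm(Ws fclin +
#' bs)))` (softmax over the `dfuse` slots, summing to 1 per sample)
#' multiplies the calibrated feature element-wise, highlighting the slots
#' the clinical semantics deem pCR-relevant.
#'
#' @param fcalibrated calibrated fused feature `B x dfuse`.
#' @param fclin clinical representation `B x dclin`.
#' @param params MCFE parameter list.
#' @return list with `fselected` and the selection weights `s`.
#' @export
semantic_selection <- function(fcalibrated, fclin, params) {
  fw <- selection_fwd(fcalibrated, fclin, params)
  list(fselected = fw$out, s = fw$s)
}

path_fwd <- function(fsel, W, b, ln) {
  l <- linear_fwd(fsel, W, b)
  n <- layernorm_fwd(l$out, ln$g, ln$b)
  r <- relu_fwd(n$out)
  list(out = r$out, l = l, n = n, r = r)
}

path_bwd <- function(cache, W, ln_g, dout) {
  dn <- relu_bwd(cache$r, dout)
  lb <- layernorm_bwd(cache$n, ln_g, dn)
  lin <- linear_bwd(cache$l, W, lb$dx)
  list(dfsel = lin$dx, dW = lin$dW, db = lin$db,
       dln = list(g = lb$dg, b = lb$db))
}

activation_scale <- function(sintra, alpha, beta, clamp = FALSE) {
  sc <- (1 - beta * as.vector(sintra)) * alpha
  if (clamp) sc <- pmax(sc, 0)
  sc
}

#' Dual-path refinement with contrast-aware dynamic activation
#'
#' Two parallel, independently parameterized paths
#' `f_k = ReLU(LayerNorm(W_k fselected + b_k))` are scaled by
#' `(1 - beta * sintra) * alpha`: samples with low intra-class similarity
#' (hard samples) receive stronger activation.  The scale is not clamped
#' by default (the literal equations allow it to go negative when
#' `beta * sintra > 1`); `clamp = TRUE` floors it at zero.
#'
#' @param fselected selected feature `B x dfuse`.
#' @param sintra intra-class similarity `B x 1` (0 disables the feedback).
#' @param params MCFE parameter list (`W1`, `W2`, `alpha`, `beta`, ...).
#' @param clamp floor the activation scale at zero.
#' @return list with `f1act`, `f2act` (`B x dfuse`).
#' @export
dual_path_refine <- function(fselected, sintra, params, clamp = FALSE) {
  p1 <- path_fwd(fselected, params$W1, params$b1, params$ln1)
  p2 <- path_fwd(fselected, params$W2, params$b2, params$ln2)
  sc <- activation_scale(sintra, params$alpha, params$beta, clamp)
  list(f1act = sc * p1$out, f2act = sc * p2$out)
}

proj_fwd <- function(fact, W, b, ln) {
  l <- linear_fwd(fact, W, b)
  n <- layernorm_fwd(l$out, ln$g, ln$b)
  list(out = n$out, l = l, n = n)
}

proj_bwd <- function(cache, W, ln_g, dout) {
  lb <- layernorm_bwd(cache$n, ln_g, dout)
  lin <- linear_bwd(cache$l, W, lb$dx)
  list(dfact = lin$dx, dW = lin$dW, db = lin$db,
       dln = list(g = lb$dg, b = lb$db))
}

#' Project the refined paths to the contrastive embedding
#'
#' Each path is mapped through `LayerNorm(W_proj f_act + b_proj)` to the
#' embedding dimension and the two projections are averaged.
#'
#' @param f1act,f2act refined path activations `B x dfuse`.
#' @param params MCFE parameter list.
#' @return matrix `B x dz` (`zenhanced`).
#' @export
enhanced_embedding <- function(f1act, f2act, params) {
  p1 <- proj_fwd(f1act, params$Wp1, params$bp1, params$lnp1)
  p2 <- proj_fwd(f2act, params$Wp2, params$bp2, params$lnp2)
  (p1$out + p2$out) / 2
}

# Full MCFE forward with caches.  `sintra_fn` maps a provisional embedding
# to the (detached) intra-class similarity; NULL means inference mode
# (sintra = 0).
mcfe_fwd <- function(ffused, fclin, amri, aclin, params,
                     sintra_fn = NULL, clamp = FALSE) {
  B <- nrow(ffused)
  cal <- calibration_fwd(ffused, amri, aclin, params)
  sel <- selection_fwd(cal$out, fclin, params)
  p1 <- path_fwd(sel$out, params$W1, params$b1, params$ln1)
  p2 <- path_fwd(sel$out, params$W2, params$b2, params$ln2)

  sintra <- matrix(0, B, 1L)
  if (!is.null(sintra_fn)) {
    sc0 <- activation_scale(sintra, params$alpha, params$beta, clamp)
    z_prov <- enhanced_embedding(sc0 * p1$out, sc0 * p2$out, params)
    sintra <- sintra_fn(z_prov)           # detached: treated as a constant
  }
  sc <- activation_scale(sintra, params$alpha, params$beta, clamp)
  clamp_active <- clamp & ((1 - params$beta * as.vector(sintra)) * params$alpha < 0)
  f1act <- sc * p1$out
  f2act <- sc * p2$out
  pr1 <- proj_fwd(f1act, params$Wp1, params$bp1, params$lnp1)
  pr2 <- proj_fwd(f2act, params$Wp2, params$bp2, params$lnp2)
  z <- (pr1$out + pr2$out) / 2
  list(out = z, sintra = sintra,
       cal = cal, sel = sel, p1 = p1, p2 = p2, sc = sc,
       clamp_active = clamp_active,
       f1act = f1act, f2act = f2act, pr1 = pr1, pr2 = pr2)
}

mcfe_bwd <- function(cache, params, dz) {
  g <- tree_zeros_like(params)
  dpr <- dz / 2
  b1 <- proj_bwd(cache$pr1, params$Wp1, params$lnp1$g, dpr)
  b2 <- proj_bwd(cache$pr2, params$Wp2, params$lnp2$g, dpr)
  g$Wp1 <- b1$dW; g$bp1 <- b1$db; g$lnp1 <- b1$dln
  g$Wp2 <- b2$dW; g$bp2 <- b2$db; g$lnp2 <- b2$dln

  sc <- cache$sc
  sintra <- as.vector(cache$sintra)
  df1 <- sc * b1$dfact
  df2 <- sc * b2$dfact
  dsc <- rowSums(b1$dfact * cache$p1$out) + rowSums(b2$dfact * cache$p2$out)
  active <- !cache$clamp_active
  g$alpha <- sum(dsc * (1 - params$beta * sintra) * active)
  g$beta <- sum(dsc * (-sintra) * params$alpha * active)

  pb1 <- path_bwd(cache$p1, params$W1, params$ln1$g, df1)
  pb2 <- path_bwd(cache$p2, params$W2, params$ln2$g, df2)
  g$W1 <- pb1$dW; g$b1 <- pb1$db; g$ln1 <- pb1$dln
  g$W2 <- pb2$dW; g$b2 <- pb2$db; g$ln2 <- pb2$dln
  dfsel <- pb1$dfsel + pb2$dfsel

  sb <- selection_bwd(cache$sel, params, dfsel)
  g$Ws <- sb$grads$Ws; g$bs <- sb$grads$bs; g$ln_s <- sb$grads$ln_s
  cb <- calibration_bwd(cache$cal, params, sb$dfcal)
  g$gate <- cb$grads
  list(dffused = cb$dffused, dfclin = sb$dfclin,
       damri = cb$damri, daclin = cb$daclin, grads = g)
}

#' Full MCFE forward pass
#'
#' Chains calibration, selection, dual-path refinement and embedding
#' projection.  In training mode (labels supplied) the intra-class
#' similarity feedback runs in the two-pass detached scheme: a
#' provisional embedding computed with `sintra = 0` yields `sintra` via
#' [intra_class_similarity()], which then rescales the activation for the
#' second pass.  In inference mode (`labels = NULL`) `sintra` is 0.  A
#' single-sample training batch has no positive peers; it falls back to
#' `sintra = 0` with a warning.
#'
#' @param ffused fused feature `B x dfuse`.
#' @param fclin clinical representation `B x dclin`.
#' @param amri,aclin pooled attention summaries `B x 1`.
#' @param labels optional 0/1 vector of length `B` (training mode).
#' @param tau temperature for the similarity computation.
#' @param params MCFE parameter list.
#' @param clamp floor the activation scale at zero.
#' @return list with `zenhanced` (`B x dz`) and `sintra` (`B x 1`).
#' @export
mcfe_forward <- function(ffused, fclin, amri, aclin, labels = NULL,
                         tau = 0.1, params, clamp = FALSE) {
  sintra_fn <- NULL
  if (!is.null(labels)) {
    if (nrow(ffused) < 2) {
      warning("training batch of size 1: intra-class similarity fixed at 0")
    } else {
      sintra_fn <- function(z) intra_class_similarity(z, labels, tau)
    }
  }
  fw <- mcfe_fwd(ffused, fclin, amri, aclin, params, sintra_fn, clamp)
  list(zenhanced = fw$out, sintra = fw$sintra)
}
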