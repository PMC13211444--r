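# End-to-end model assembly: configuration, parameter initialization, and
# the full forward/backward pass combining encoders, fusion, MCFE and the
# dual loss.  Ablation switches select alternative fusion and enhancement
# paths; unimodal variants reuse the same encoder and head codepaths.

#' Run configuration
#'
#' Collects every tunable of the network and training loop.  Defaults are
#' paper scale (hidden dimension 768, fusion width 512, contrastive
#' embedding 128, temperature 0.1, contrastive weight 0.9, AdamW with
#' weight decay 0.01, encoder learning rate 1e-5 vs 1e-4 elsewhere,
#' cosine annealing, batch 4, 50 epochs); [desk_profile()] supplies a
#' small configuration for CPU-scale experiments.
#'
#' @param input_shape volume shape the imaging encoder consumes.
#' @param patch_size cubic patch edge.
#' @param chid imaging token dimension.
#' @param depth,heads transformer depth and self-attention heads.
#' @param dmid,dclin clinical encoder intermediate/final dimensions.
#' @param dfuse shared fusion dimension (also the fused feature width).
#' @param fusion_heads cross-attention heads in each BiCMA pathway.
#' @param dz contrastive embedding dimension.
#' @param head_hidden classification-head hidden width.
#' @param tau contrastive temperature.
#' @param lambda contrastive loss weight.
#' @param fusion one of `"bicma"`, `"concat"`, `"igc"`, `"cgi"`.
#' @param mcfe one of `"full"`, `"off"`, `"conventional_cl"`,
#'   `"no_calibration"`, `"no_dual_path"`, `"no_dynamic_activation"`.
#' @param modality `"both"`, `"image"` or `"clinical"` (unimodal
#'   baselines built from the same encoder + head codepaths).
#' @param pooled pooled attention-summary mode (see
#'   [multihead_cross_attention()]).
#' @param clamp_activation floor the dynamic-activation scale at zero.
#' @param cosine_similarity use cosine instead of raw dot-product
#'   similarity in the contrastive loss.
#' @param normalize_weights divide class weights by their mean (keeps the
#'   loss scale comparable across cohort sizes; raw counts otherwise).
#' @param lr_encoder,lr_other AdamW learning rates for the imaging
#'   encoder vs all other modules.
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs (cosine schedule spans all of them in a
#'   single cycle).
#' @param seed RNG seed for initialization and batching.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_shape = c(192L, 192L, 112L), patch_size = 8L,
                       chid = 768L, depth = 4L, heads = 8L,
                       dmid = 128L, dclin = 256L,
                       dfuse = 512L, fusion_heads = 8L,
                       dz = 128L, head_hidden = 128L,
                       tau = 0.1, lambda = 0.9,
                       fusion = c("bicma", "concat", "igc", "cgi"),
                       mcfe = c("full", "off", "conventional_cl",
                                "no_calibration", "no_dual_path",
                                "no_dynamic_activation"),
                       modality = c("both", "image", "clinical"),
                       pooled = c("literal", "pre_softmax_sigmoid"),
                       clamp_activation = FALSE,
                       cosine_similarity = FALSE,
                       normalize_weights = TRUE,
                       lr_encoder = 1e-5, lr_other = 1e-4,
                       weight_decay = 0.01,
                       batch_size = 4L, epochs = 50L, seed = 1L) {
  cfg <- list(
    img = imaging_encoder_config(input_shape, patch_size, chid, depth, heads),
    dmid = as.integer(dmid), dclin = as.integer(dclin),
    dfuse = as.integer(dfuse), fusion_heads = as.integer(fusion_heads),
    dz = as.integer(dz), head_hidden = as.integer(head_hidden),
    tau = tau, lambda = lambda,
    fusion = match.arg(fusion), mcfe = match.arg(mcfe),
    modality = match.arg(modality), pooled = match.arg(pooled),
    clamp_activation = clamp_activation,
    cosine_similarity = cosine_similarity,
    normalize_weights = normalize_weights,
    lr_encoder = lr_encoder, lr_other = lr_other,
    weight_decay = weight_decay,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Desk-scale configuration profile
#'
#' A small configuration for CPU experiments and tests: 32x32x16 volumes,
#' patch 8 (32 tokens), token dimension 64, two transformer blocks,
#' reduced fusion/embedding widths, 10 epochs.  Paper-scale dimensions
#' remain reachable through [run_config()].
#'
#' @param ... overrides passed on to [run_config()].
#' @return a `run_config`.
#' @export
desk_profile <- function(...) {
  args <- list(input_shape = c(32L, 32L, 16L), patch_size = 8L,
               chid = 64L, depth = 2L, heads = 4L,
               dmid = 64L, dclin = 128L, dfuse = 128L, fusion_heads = 4L,
               dz = 64L, head_hidden = 64L, epochs = 10L,
               # no pretrained backbone at desk scale, so no reason for the
               # reduced layer-wise encoder rate used with pretrained ViTs
               lr_encoder = 1e-4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}

#' Initialize model parameters
#'
#' @param config a [run_config()].
#' @param d_clin_in encoded clinical vector length (see
#'   [clinical_layout()]); ignored for the image-only modality.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return nested parameter list with one entry per module.
#' @export
init_model <- function(config, d_clin_in = clinical_layout()$length,
                       seed = config$seed) {
  with_seed(seed, {
    p <- list()
    if (config$modality != "clinical") {
      p$img_enc <- init_image_encoder(config$img)
    }
    if (config$modality != "image") {
      p$clin_enc <- init_clinical_encoder(d_clin_in, config$dmid, config$dclin)
    }
    p$fusion <- switch(config$modality,
      both = {
        if (config$fusion == "concat") {
          list(Wcat = init_dense(config$img$chid + config$dclin,
                                 config$dfuse, "xavier"),
               bcat = rep(0, config$dfuse))
        } else {
          init_bicma(config$img$chid, config$dclin, config$dfuse,
                     config$fusion_heads)
        }
      },
      image = list(Wuni = init_dense(config$img$chid, config$dfuse, "xavier"),
                   buni = rep(0, config$dfuse)),
      clinical = list(Wuni = init_dense(config$dclin, config$dfuse, "xavier"),
                      buni = rep(0, config$dfuse)))
    if (config$modality == "both" && config$mcfe != "off") {
      p$mcfe <- if (config$mcfe == "conventional_cl") {
        list(Wz = init_dense(config$dfuse, config$dz, "xavier"),
             bz = rep(0, config$dz))
      } else {
        init_mcfe(config$dfuse, config$dclin, config$dz)
      }
    }
    p$head <- init_head(config$dfuse, config$head_hidden)
    p
  })
}

# Full forward pass.  batch: list(patches = (B,N,pdim) array or NULL,
# xclin = B x d matrix or NULL, labels = 0/1 vector or NULL).
# Returns losses, probabilities, embeddings and every cache needed by
# model_backward().
model_forward <- function(params, batch, config, weights = c(w0 = 1, w1 = 1),
                          training = !is.null(batch$labels)) {
  mod <- config$modality
  fw <- list()

  if (mod != "clinical") {
    fw$img <- image_encoder_fwd(batch$patches, params$img_enc, config$img)
    fimg <- fw$img$out
  }
  if (mod != "image") {
    fw$clin <- clinical_encoder_fwd(batch$xclin, params$clin_enc)
    fclin <- fw$clin$out
  }

  B <- if (mod == "clinical") nrow(batch$xclin) else dim(batch$patches)[1]
  ones <- matrix(1, B, 1L)

  if (mod == "both") {
    if (config$fusion == "concat") {
      fw$cat_in <- cbind(fimg, fclin)
      fw$fus <- linear_fwd(fw$cat_in, params$fusion$Wcat, params$fusion$bcat)
      ffused <- fw$fus$out
      amri <- ones; aclin <- ones
    } else if (config$fusion == "bicma") {
      fw$bicma <- bicma_fwd(fimg, fclin, params$fusion,
                            config$fusion_heads, config$pooled)
      ffused <- fw$bicma$out
      amri <- fw$bicma$amri; aclin <- fw$bicma$aclin
    } else {
      # single-pathway ablations: attended feature of the active pathway
      # concatenated with the passive modality's shared projection
      pi_ <- linear_fwd(fimg, params$fusion$Wimg, params$fusion$bimg)
      pc <- linear_fwd(fclin, params$fusion$Wclin, params$fusion$bclin)
      if (config$fusion == "igc") {
        att <- cross_attention_fwd(pi_$out, pc$out, pc$out,
                                   params$fusion$igc, config$fusion_heads,
                                   config$pooled)
        cat_ <- cbind(att$out, pc$out)
        amri <- att$pooled; aclin <- ones
      } else {
        att <- cross_attention_fwd(pc$out, pi_$out, pi_$out,
                                   params$fusion$cgi, config$fusion_heads,
                                   config$pooled)
        cat_ <- cbind(pi_$out, att$out)
        amri <- ones; aclin <- att$pooled
      }
      fw$single <- list(pi = pi_, pc = pc, att = att)
      fw$fus <- linear_fwd(cat_, params$fusion$Wfusion, params$fusion$bfusion)
      ffused <- fw$fus$out
    }
  } else {
    src <- if (mod == "image") fimg else fclin
    fw$fus <- linear_fwd(src, params$fusion$Wuni, params$fusion$buni)
    ffused <- fw$fus$out
    amri <- ones; aclin <- ones
  }

  fw$head <- head_fwd(ffused, params$head)
  probs <- fw$head$out
  lcls <- NA_real_
  if (!is.null(batch$labels)) {
    lcls <- weighted_cross_entropy(probs, batch$labels,
                                   weights[["w0"]], weights[["w1"]])
  }

  # contrastive branch
  lcl <- 0
  zenh <- NULL
  sintra <- matrix(0, B, 1L)
  cl_on <- mod == "both" && config$mcfe != "off" && !is.null(batch$labels)
  if (mod == "both" && config$mcfe != "off") {
    if (config$mcfe == "conventional_cl") {
      fw$zlin <- linear_fwd(ffused, params$mcfe$Wz, params$mcfe$bz)
      zenh <- fw$zlin$out
    } else {
      sintra_fn <- NULL
      if (training && !is.null(batch$labels) && B >= 2) {
        sintra_fn <- function(z) intra_class_similarity(z, batch$labels,
                                                        config$tau,
                                                        config$cosine_similarity)
      }
      fw$mcfe <- mcfe_variant_fwd(ffused, fclin, amri, aclin, params$mcfe,
                                  config, sintra_fn)
      zenh <- fw$mcfe$out
      sintra <- fw$mcfe$sintra
    }
    if (cl_on && B >= 2 && anyDuplicated(batch$labels) > 0) {
      sc <- supcon_loss_grad(zenh, batch$labels, config$tau,
                             config$cosine_similarity,
                             want_grad = FALSE)
      lcl <- sc$loss
    }
  }

  ltotal <- if (is.na(lcls)) NA_real_ else lcls + config$lambda * lcl
  list(probs = probs, scores = probs[, 2], ffused = ffused,
       zenhanced = zenh, sintra = sintra,
       lcls = lcls, lcl = lcl, ltotal = ltotal,
       fw = fw, B = B, cl_on = cl_on)
}

# MCFE forward honouring the ablation switches
mcfe_variant_fwd <- function(ffused, fclin, amri, aclin, params, config,
                             sintra_fn) {
  variant <- config$mcfe
  if (variant == "no_dynamic_activation") sintra_fn <- NULL
  fw <- mcfe_fwd_variant(ffused, fclin, amri, aclin, params,
                         sintra_fn, config$clamp_activation,
                         skip_calibration = variant == "no_calibration",
                         single_path = variant == "no_dual_path",
                         freeze_beta = variant == "no_dynamic_activation")
  fw
}

# like mcfe_fwd() but with ablation hooks
mcfe_fwd_variant <- function(ffused, fclin, amri, aclin, params, sintra_fn,
                             clamp, skip_calibration = FALSE,
                             single_path = FALSE, freeze_beta = FALSE) {
  B <- nrow(ffused)
  if (skip_calibration) {
    cal <- list(out = ffused, skip = TRUE)
  } else {
    cal <- calibration_fwd(ffused, amri, aclin, params)
  }
  sel <- selection_fwd(cal$out, fclin, params)
  p1 <- path_fwd(sel$out, params$W1, params$b1, params$ln1)
  p2 <- if (single_path) NULL else path_fwd(sel$out, params$W2, params$b2, params$ln2)
  beta <- if (freeze_beta) 0 else params$beta

  sintra <- matrix(0, B, 1L)
  if (!is.null(sintra_fn)) {
    # pass 1: provisional embedding with the feedback disabled
    sc0 <- activation_scale(sintra, params$alpha, beta, clamp)
    z0 <- if (single_path) {
      proj_fwd(sc0 * p1$out, params$Wp1, params$bp1, params$lnp1)$out
    } else {
      enhanced_embedding(sc0 * p1$out, sc0 * p2$out, params)
    }
    sintra <- sintra_fn(z0)   # detached from gradient flow
  }
  sc <- activation_scale(sintra, params$alpha, beta, clamp)
  clamp_active <- clamp & ((1 - beta * as.vector(sintra)) * params$alpha < 0)
  f1act <- sc * p1$out
  pr1 <- proj_fwd(f1act, params$Wp1, params$bp1, params$lnp1)
  if (single_path) {
    z <- pr1$out
    f2act <- NULL; pr2 <- NULL
  } else {
    f2act <- sc * p2$out
    pr2 <- proj_fwd(f2act, params$Wp2, params$bp2, params$lnp2)
    z <- (pr1$out + pr2$out) / 2
  }
  list(out = z, sintra = sintra, cal = cal, sel = sel, p1 = p1, p2 = p2,
       sc = sc, clamp_active = clamp_active, beta_used = beta,
       freeze_beta = freeze_beta, single_path = single_path,
       skip_calibration = skip_calibration,
       f1act = f1act, f2act = f2act, pr1 = pr1, pr2 = pr2)
}

mcfe_bwd_variant <- function(cache, params, dz) {
  g <- tree_zeros_like(params)
  single <- cache$single_path
  sc <- cache$sc
  sintra <- as.vector(cache$sintra)
  beta <- cache$beta_used

  if (single) {
    b1 <- proj_bwd(cache$pr1, params$Wp1, params$lnp1$g, dz)
    g$Wp1 <- b1$dW; g$bp1 <- b1$db; g$lnp1 <- b1$dln
    df1 <- sc * b1$dfact
    dsc <- rowSums(b1$dfact * cache$p1$out)
  } else {
    dpr <- dz / 2
    b1 <- proj_bwd(cache$pr1, params$Wp1, params$lnp1$g, dpr)
    b2 <- proj_bwd(cache$pr2, params$Wp2, params$lnp2$g, dpr)
    g$Wp1 <- b1$dW; g$bp1 <- b1$db; g$lnp1 <- b1$dln
    g$Wp2 <- b2$dW; g$bp2 <- b2$db; g$lnp2 <- b2$dln
    df1 <- sc * b1$dfact
    df2 <- sc * b2$dfact
    dsc <- rowSums(b1$dfact * cache$p1$out) + rowSums(b2$dfact * cache$p2$out)
  }
  active <- !cache$clamp_active
  g$alpha <- sum(dsc * (1 - beta * sintra) * active)
  g$beta <- if (cache$freeze_beta) 0 else sum(dsc * (-sintra) * params$alpha * active)

  pb1 <- path_bwd(cache$p1, params$W1, params$ln1$g, df1)
  g$W1 <- pb1$dW; g$b1 <- pb1$db; g$ln1 <- pb1$dln
  dfsel <- pb1$dfsel
  if (!single) {
    pb2 <- path_bwd(cache$p2, params$W2, params$ln2$g, df2)
    g$W2 <- pb2$dW; g$b2 <- pb2$db; g$ln2 <- pb2$dln
    dfsel <- dfsel + pb2$dfsel
  }

  sb <- selection_bwd(cache$sel, params, dfsel)
  g$Ws <- sb$grads$Ws; g$bs <- sb$grads$bs; g$ln_s <- sb$grads$ln_s
  if (cache$skip_calibration) {
    dffused <- sb$dfcal
    B <- nrow(dffused)
    damri <- matrix(0, B, 1L); daclin <- matrix(0, B, 1L)
  } else {
    cb <- calibration_bwd(cache$cal, params, sb$dfcal)
    g$gate <- cb$grads
    dffused <- cb$dffused
    damri <- cb$damri; daclin <- cb$daclin
  }
  list(dffused = dffused, dfclin = sb$dfclin,
       damri = damri, daclin = daclin, grads = g)
}

# Full backward pass; returns the gradient tree matching `params`.
# `apply_cl_grads = FALSE` drops the contrastive contribution (used to
# verify that lambda = 0 leaves gradients untouched).
model_backward <- function(params, batch, config, forward,
                           weights = c(w0 = 1, w1 = 1)) {
  fw <- forward$fw
  mod <- config$modality
  g <- tree_zeros_like(params)

  # classification branch: gradient at the head logits
  dlogits <- wce_logit_grad(forward$probs, batch$labels,
                            weights[["w0"]], weights[["w1"]])
  hb <- head_bwd(fw$head, params$head, dlogits)
  g$head <- hb$grads
  dffused <- hb$dx
  dfclin <- NULL
  damri <- NULL; daclin <- NULL

  # contrastive branch
  if (forward$cl_on && forward$B >= 2 && config$lambda > 0 &&
      anyDuplicated(batch$labels) > 0) {
    scg <- supcon_loss_grad(forward$zenhanced, batch$labels, config$tau,
                            config$cosine_similarity)
    dz <- config$lambda * scg$grad
    if (config$mcfe == "conventional_cl") {
      zb <- linear_bwd(fw$zlin, params$mcfe$Wz, dz)
      g$mcfe$Wz <- zb$dW; g$mcfe$bz <- zb$db
      dffused <- dffused + zb$dx
    } else {
      mb <- mcfe_bwd_variant(fw$mcfe, params$mcfe, dz)
      g$mcfe <- mb$grads
      dffused <- dffused + mb$dffused
      dfclin <- mb$dfclin
      damri <- mb$damri; daclin <- mb$daclin
    }
  }

  # fusion
  if (mod == "both") {
    if (config$fusion == "concat") {
      cb <- linear_bwd(fw$fus, params$fusion$Wcat, dffused)
      g$fusion$Wcat <- cb$dW; g$fusion$bcat <- cb$db
      chid <- config$img$chid
      dfimg <- cb$dx[, seq_len(chid), drop = FALSE]
      dfc <- cb$dx[, chid + seq_len(config$dclin), drop = FALSE]
    } else if (config$fusion == "bicma") {
      bb <- bicma_bwd(fw$bicma, params$fusion, dffused, damri, daclin)
      g$fusion <- bb$grads
      dfimg <- bb$dfimg
      dfc <- bb$dfclin
    } else {
      fb <- linear_bwd(fw$fus, params$fusion$Wfusion, dffused)
      g$fusion$Wfusion <- fb$dW; g$fusion$bfusion <- fb$db
      dfuse <- config$dfuse
      dleft <- fb$dx[, seq_len(dfuse), drop = FALSE]
      dright <- fb$dx[, dfuse + seq_len(dfuse), drop = FALSE]
      s <- fw$single
      if (config$fusion == "igc") {
        ab <- cross_attention_bwd(s$att, params$fusion$igc, dleft, damri)
        g$fusion$igc <- ab$grads
        dpimg <- ab$dquery
        dpclin <- dright + ab$dkey + ab$dvalue
      } else {
        ab <- cross_attention_bwd(s$att, params$fusion$cgi, dright, daclin)
        g$fusion$cgi <- ab$grads
        dpimg <- dleft + ab$dkey + ab$dvalue
        dpclin <- ab$dquery
      }
      li <- linear_bwd(s$pi, params$fusion$Wimg, dpimg)
      g$fusion$Wimg <- li$dW; g$fusion$bimg <- li$db
      lc <- linear_bwd(s$pc, params$fusion$Wclin, dpclin)
      g$fusion$Wclin <- lc$dW; g$fusion$bclin <- lc$db
      dfimg <- li$dx
      dfc <- lc$dx
    }
    if (!is.null(dfclin)) dfc <- dfc + dfclin
    ib <- image_encoder_bwd(fw$img, params$img_enc, config$img, dfimg)
    g$img_enc <- ib
    cb2 <- clinical_encoder_bwd(fw$clin, params$clin_enc, dfc)
    g$clin_enc <- cb2$grads
  } else {
    ub <- linear_bwd(fw$fus, params$fusion$Wuni, dffused)
    g$fusion$Wuni <- ub$dW; g$fusion$buni <- ub$db
    if (mod == "image") {
      g$img_enc <- image_encoder_bwd(fw$img, params$img_enc, config$img, ub$dx)
    } else {
      dsrc <- ub$dx
      if (!is.null(dfclin)) dsrc <- dsrc + dfclin
      cb2 <- clinical_encoder_bwd(fw$clin, params$clin_enc, dsrc)
      g$clin_enc <- cb2$grads
    }
  }
  g
}
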