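mcfe_params <- function(dfuse = 16L, dclin = 12L, dz = 8L, seed = 1L) {
  pcrfusion:::with_seed(seed, pcrfusion:::init_mcfe(dfuse, dclin, dz))
}

test_that("modal calibration: zero gates are the identity, gates stay in (0,1)", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params()
  ffused <- pf$with_seed(2, matrix(rnorm(4 * 16), 4))
  amri <- matrix(runif(4), 4, 1)
  aclin <- matrix(runif(4), 4, 1)

  # fresh parameters have zero gates: wmri = wclin = 0.5 -> identity
  out <- modal_calibration(ffused, amri, aclin, params)
  expect_equal(out$fcalibrated, ffused, tolerance = 1e-12)
  expect_equal(out$wmri, rep(0.5, 4))

  params$gate <- list(Wmri = 1.7, bmri = -0.3, Wclin = -2.2, bclin = 0.4)
  out2 <- modal_calibration(ffused, amri, aclin, params)
  expect_true(all(out2$wmri > 0 & out2$wmri < 1))
  expect_true(all(out2$wclin > 0 & out2$wclin < 1))
  # the two gated copies collapse to a single (wmri + wclin) broadcast
  expect_equal(out2$fcalibrated, (out2$wmri + out2$wclin) * ffused,
               tolerance = 1e-12)
})

test_that("semantic selection normalizes over feature slots", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 3)
  fcal <- pf$with_seed(4, matrix(rnorm(5 * 16), 5))
  fclin <- pf$with_seed(5, matrix(rnorm(5 * 12), 5))
  out <- semantic_selection(fcal, fclin, params)
  expect_equal(rowSums(out$s), rep(1, 5), tolerance = 1e-6)
  expect_equal(out$fselected, fcal * out$s, tolerance = 1e-12)

  # uniform pre-softmax logits -> fselected = fcalibrated / dfuse
  params$Ws[] <- 0; params$bs[] <- 0
  expect_equal(semantic_selection(fcal, fclin, params)$fselected,
               fcal / 16, tolerance = 1e-12)

  # one dominating logit masks everything else (gain amplifies the gap
  # the row-wise LayerNorm would otherwise compress)
  params$bs <- c(50, rep(0, 15))
  params$ln_s$g[] <- 20; params$ln_s$b[] <- 0
  dom <- semantic_selection(fcal, fclin, params)
  expect_equal(dom$s[, 1], rep(1, 5), tolerance = 1e-6)
  expect_equal(dom$fselected[, 1], fcal[, 1], tolerance = 1e-4)
  expect_lt(max(abs(dom$fselected[, -1])), 1e-4)
})

test_that("dynamic activation scales paths by (1 - beta sintra) alpha", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 6)
  fsel <- pf$with_seed(7, matrix(rnorm(4 * 16), 4))
  zero_s <- matrix(0, 4, 1)

  # beta = 0, alpha = 1: activations pass through unchanged (already >= 0)
  p0 <- params; p0$beta <- 0; p0$alpha <- 1
  ref <- dual_path_refine(fsel, zero_s, p0)
  manual1 <- pf$relu_fwd(pf$layernorm_fwd(
    pf$linear_fwd(fsel, params$W1, params$b1)$out,
    params$ln1$g, params$ln1$b)$out)$out
  expect_equal(ref$f1act, manual1, tolerance = 1e-12)
  expect_true(all(ref$f1act >= 0))

  # all-negative pre-activations give zero output
  pneg <- p0; pneg$ln1$b[] <- -5; pneg$ln2$b[] <- -5
  expect_equal(dual_path_refine(fsel, zero_s, pneg)$f1act,
               matrix(0, 4, 16))

  # activation magnitude is non-increasing in sintra for beta > 0
  pb <- params; pb$beta <- 0.4; pb$alpha <- 1.2
  mags <- sapply(seq(0, 2.4, by = 0.4), function(s) {  # within beta*s <= 1
    sum(abs(dual_path_refine(fsel, matrix(s, 4, 1), pb)$f1act))
  })
  expect_true(all(diff(mags) <= 1e-9))
  # unclamped scale goes negative once beta * sintra > 1; clamping floors it
  big_s <- matrix(5, 4, 1)
  expect_lt(min(dual_path_refine(fsel, big_s, pb)$f1act), 0)
  expect_equal(dual_path_refine(fsel, big_s, pb, clamp = TRUE)$f1act,
               matrix(0, 4, 16))
})

test_that("enhanced embedding averages the two LayerNorm projections", {
  pf <- asNamespace("pcrfusion")
  params <- pf$with_seed(8, pf$init_mcfe(512L, 256L, 128L))
  f1 <- pf$with_seed(9, matrix(abs(rnorm(3 * 512)), 3))
  z <- enhanced_embedding(f1, f1 * 0.3, params)
  expect_equal(dim(z), c(3, 128))    # paper-scale embedding width

  # identical paths and shared projection parameters: average equals either
  shared <- params
  shared$Wp2 <- shared$Wp1; shared$bp2 <- shared$bp1; shared$lnp2 <- shared$lnp1
  one <- pf$proj_fwd(f1, shared$Wp1, shared$bp1, shared$lnp1)$out
  expect_equal(enhanced_embedding(f1, f1, shared), one, tolerance = 1e-12)

  # each projected vector is row-centred by the LayerNorm (bias zero at init)
  expect_true(all(abs(rowMeans(one)) < 1e-10))
})

test_that("mcfe_forward composes its stages and honours the two-pass scheme", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 10)
  params$beta <- 0.3
  B <- 6
  ffused <- pf$with_seed(11, matrix(rnorm(B * 16), B))
  fclin <- pf$with_seed(12, matrix(rnorm(B * 12), B))
  amri <- matrix(runif(B), B, 1); aclin <- matrix(runif(B), B, 1)
  labels <- c(0, 1, 1, 0, 1, 0)

  res <- mcfe_forward(ffused, fclin, amri, aclin, labels, tau = 0.1,
                      params = params)

  # manual chain using the pass-1 sintra reproduces the pass-2 output
  cal <- modal_calibration(ffused, amri, aclin, params)
  sel <- semantic_selection(cal$fcalibrated, fclin, params)
  prov <- dual_path_refine(sel$fselected, matrix(0, B, 1), params)
  z_prov <- enhanced_embedding(prov$f1act, prov$f2act, params)
  sintra <- intra_class_similarity(z_prov, labels, 0.1)
  expect_equal(res$sintra, sintra, tolerance = 1e-10)
  act <- dual_path_refine(sel$fselected, sintra, params)
  expect_equal(res$zenhanced, enhanced_embedding(act$f1act, act$f2act, params),
               tolerance = 1e-10)

  # beta = 0: the feedback is inert and two-pass equals single-pass
  p0 <- params; p0$beta <- 0
  res0 <- mcfe_forward(ffused, fclin, amri, aclin, labels, 0.1, p0)
  act0 <- dual_path_refine(sel$fselected, matrix(0, B, 1), p0)
  expect_equal(res0$zenhanced, enhanced_embedding(act0$f1act, act0$f2act, p0),
               tolerance = 1e-10)

  # inference mode: sintra = 0
  inf <- mcfe_forward(ffused, fclin, amri, aclin, labels = NULL,
                      params = params)
  expect_equal(inf$sintra, matrix(0, B, 1))

  # determinism
  expect_identical(res$zenhanced,
                   mcfe_forward(ffused, fclin, amri, aclin, labels, 0.1,
                                params)$zenhanced)

  # singleton training batch falls back to sintra = 0 with a warning
  expect_warning(
    one <- mcfe_forward(ffused[1, , drop = FALSE], fclin[1, , drop = FALSE],
                        amri[1, , drop = FALSE], aclin[1, , drop = FALSE],
                        labels = 1, params = params),
    "size 1")
  expect_equal(one$sintra, matrix(0, 1, 1))
})

test_that("MCFE backward matches finite differences with sintra detached", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 13)
  params$beta <- 0.25
  B <- 4
  ffused <- pf$with_seed(14, matrix(rnorm(B * 16), B))
  fclin <- pf$with_seed(15, matrix(rnorm(B * 12), B))
  amri <- matrix(runif(B), B, 1); aclin <- matrix(runif(B), B, 1)
  sintra_fixed <- matrix(runif(B, 0, 2), B, 1)
  R <- pf$with_seed(16, matrix(rnorm(B * 8), B))

  loss <- function(p) {
    fw <- pf$mcfe_fwd(ffused, fclin, amri, aclin, p,
                      sintra_fn = function(z) sintra_fixed)
    sum(fw$out * R)
  }
  fw <- pf$mcfe_fwd(ffused, fclin, amri, aclin, params,
                    sintra_fn = function(z) sintra_fixed)
  g <- pf$mcfe_bwd(fw, params, R)$grads

  eps <- 1e-6
  probe <- function(get, set, gval) {
    pp <- set(params, get(params) + eps)
    pm <- set(params, get(params) - eps)
    expect_equal(gval, (loss(pp) - loss(pm)) / (2 * eps), tolerance = 1e-4)
  }
  probe(function(p) p$alpha, function(p, v) { p$alpha <- v; p }, g$alpha)
  probe(function(p) p$beta, function(p, v) { p$beta <- v; p }, g$beta)
  probe(function(p) p$gate$Wmri, function(p, v) { p$gate$Wmri <- v; p },
        g$gate$Wmri)
  probe(function(p) p$Ws[3], function(p, v) { p$Ws[3] <- v; p }, g$Ws[3])
  probe(function(p) p$W1[10], function(p, v) { p$W1[10] <- v; p }, g$W1[10])
  probe(function(p) p$Wp2[5], function(p, v) { p$Wp2[5] <- v; p }, g$Wp2[5])
})

test_that("sintra feedback path carries no gradient (detachment contract)", {
  # gradients of the pass-2 loss must be identical whether sintra was
  # produced by the similarity function or supplied as the same constant
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 17)
  params$beta <- 0.3
  B <- 4
  ffused <- pf$with_seed(18, matrix(rnorm(B * 16), B))
  fclin <- pf$with_seed(19, matrix(rnorm(B * 12), B))
  amri <- matrix(runif(B), B, 1); aclin <- matrix(runif(B), B, 1)
  labels <- c(0, 1, 0, 1)
  R <- pf$with_seed(20, matrix(rnorm(B * 8), B))

  live <- pf$mcfe_fwd(ffused, fclin, amri, aclin, params,
                      sintra_fn = function(z)
                        intra_class_similarity(z, labels, 0.1))
  frozen <- pf$mcfe_fwd(ffused, fclin, amri, aclin, params,
                        sintra_fn = function(z) live$sintra)
  g_live <- pf$mcfe_bwd(live, params, R)$grads
  g_frozen <- pf$mcfe_bwd(frozen, params, R)$grads
  expect_equal(g_live, g_frozen, tolerance = 1e-12)
})

test_that("with inert gates and uniform selection the module is two LN-affine maps", {
  pf <- asNamespace("pcrfusion")
  params <- mcfe_params(seed = 21)
  params$beta <- 0
  params$Ws[] <- 0; params$bs[] <- 0     # uniform selection -> / dfuse
  B <- 3
  ffused <- pf$with_seed(22, matrix(rnorm(B * 16), B))
  fclin <- pf$with_seed(23, matrix(rnorm(B * 12), B))
  ones <- matrix(1, B, 1)
  res <- mcfe_forward(ffused, fclin, ones, ones, labels = NULL,
                      params = params)

  x <- ffused / 16
  path <- function(W, b, ln, Wp, bp, lnp) {
    f <- pf$relu_fwd(pf$layernorm_fwd(pf$linear_fwd(x, W, b)$out,
                                      ln$g, ln$b)$out)$out
    pf$layernorm_fwd(pf$linear_fwd(f, Wp, bp)$out, lnp$g, lnp$b)$out
  }
  manual <- (path(params$W1, params$b1, params$ln1,
                  params$Wp1, params$bp1, params$lnp1) +
             path(params$W2, params$b2, params$ln2,
                  params$Wp2, params$bp2, params$lnp2)) / 2
  expect_equal(res$zenhanced, manual, tolerance = 1e-10)
})
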