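test_that("stratified folds preserve the class balance of a 151-sample cohort", {
  labels <- c(rep(1, 43), rep(0, 108))
  split <- stratified_folds(labels, k = 5, seed = 1)
  sizes <- vapply(split$folds, function(f) length(f$test), integer(1))
  pos <- vapply(split$folds, function(f) sum(labels[f$test]), numeric(1))
  expect_true(all(sizes %in% 30:31))
  expect_true(all(pos %in% 8:9))
  # disjoint test folds covering every sample exactly once
  all_test <- sort(unlist(lapply(split$folds, `[[`, "test")))
  expect_identical(all_test, 1:151)
  # train is the complement
  expect_identical(sort(c(split$folds[[2]]$train, split$folds[[2]]$test)),
                   1:151)
  # deterministic under the seed
  split2 <- stratified_folds(labels, k = 5, seed = 1)
  expect_identical(split$folds, split2$folds)
  expect_false(identical(split$folds,
                         stratified_folds(labels, 5, seed = 2)$folds))
  expect_error(stratified_folds(c(rep(1, 3), rep(0, 20)), k = 5), "fewer than")
})

test_that("fold positive fractions stay within 1/|fold| of the global fraction", {
  for (seed in 1:10) {
    labels <- pcrfusion:::with_seed(seed, rbinom(87, 1, runif(1, 0.2, 0.5)))
    if (min(table(labels)) < 4) next
    split <- stratified_folds(labels, k = 4, seed = seed)
    global <- mean(labels)
    for (f in split$folds) {
      expect_lte(abs(mean(labels[f$test]) - global), 1 / length(f$test))
    }
  }
})

test_that("training reduces the loss on a separable cohort", {
  pf <- asNamespace("pcrfusion")
  # ~200 optimizer steps: 40 samples, batch 4, 20 epochs
  cfg <- tiny_config(epochs = 20L, seed = 3L)
  data <- tiny_cohort_data(cfg, n = 40L)
  pc <- prepare_clinical(data$clinical, 1:40)
  full_loss <- function(params) {
    batch <- list(patches = data$patches, xclin = pc$x, labels = data$labels)
    pf$model_forward(params, batch, cfg, c(w0 = 1, w1 = 1),
                     training = TRUE)$ltotal
  }
  p0 <- init_model(cfg, ncol(pc$x))
  model <- run_training(cfg, data)
  expect_s3_class(model, "pcr_model")
  expect_equal(nrow(model$log), 20)
  # whole-training-set dual loss drops from initialization to convergence
  expect_lt(full_loss(model$params), full_loss(p0))
  # and so does the classification component of the per-epoch log
  expect_lt(model$log$lcls[20], model$log$lcls[1])
  expect_true(all(is.finite(model$log$ltotal)))
  # scores come back as probabilities
  pr <- predict_scores(model, data)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  expect_equal(rowSums(pr$probs), rep(1, 40), tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  cfg <- tiny_config(epochs = 2L, seed = 11L)
  data <- tiny_cohort_data(cfg, n = 24L)
  m1 <- run_training(cfg, data)
  m2 <- run_training(cfg, data)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("lambda = 0 logs the contrastive loss without letting it reach gradients", {
  pf <- asNamespace("pcrfusion")
  cfg <- tiny_config(lambda = 0)
  batch <- tiny_batch(cfg)
  params <- init_model(cfg, ncol(batch$xclin))
  w <- c(w0 = 1, w1 = 1)
  fwd <- pf$model_forward(params, batch, cfg, w, training = TRUE)
  expect_gt(fwd$lcl, 0)                       # logged
  expect_equal(fwd$ltotal, fwd$lcls)          # but not in the total
  g <- pf$model_backward(params, batch, cfg, fwd, w)
  mcfe_norm <- rapply(g$mcfe, function(x) sqrt(sum(x^2)), how = "unlist")
  expect_true(all(mcfe_norm == 0))            # no gradient flows through CL

  # identical non-MCFE gradients to a run with the branch disabled
  cfg_off <- tiny_config(mcfe = "off")
  params_off <- params[names(params) != "mcfe"]
  fwd_off <- pf$model_forward(params_off, batch, cfg_off, w, training = TRUE)
  g_off <- pf$model_backward(params_off, batch, cfg_off, fwd_off, w)
  expect_equal(g$head, g_off$head, tolerance = 1e-12)
  expect_equal(g$img_enc, g_off$img_enc, tolerance = 1e-12)
})

test_that("concat ablation bypasses attention with a plain joint projection", {
  pf <- asNamespace("pcrfusion")
  cfg <- tiny_config(fusion = "concat", mcfe = "off")
  batch <- tiny_batch(cfg)
  params <- init_model(cfg, ncol(batch$xclin))
  fwd <- pf$model_forward(params, batch, cfg, training = FALSE)
  fimg <- pf$image_encoder_fwd(batch$patches, params$img_enc, cfg$img)$out
  fclin <- pf$clinical_encoder_fwd(batch$xclin, params$clin_enc)$out
  manual <- cbind(fimg, fclin) %*% params$fusion$Wcat +
    matrix(params$fusion$bcat, 4, cfg$dfuse, byrow = TRUE)
  expect_equal(fwd$ffused, manual, tolerance = 1e-10)
})

test_that("cross-validation reports have the published table shape", {
  cfg <- tiny_config(epochs = 2L, seed = 13L)
  data <- tiny_cohort_data(cfg, n = 30L, seed = 7L)
  cv <- run_crossval(cfg, data, k = 3)
  expect_equal(nrow(cv$per_fold), 3)
  expect_identical(colnames(cv$per_fold),
                   c("fold", "AUC", "ACC", "SEN", "SPE", "F1", "PPV", "NPV"))
  expect_identical(cv$summary$metric,
                   c("AUC", "ACC", "SEN", "SPE", "F1", "PPV", "NPV"))
  # the summary row is fold_summary() applied to the fold column
  fs <- fold_summary(cv$per_fold$AUC)
  expect_equal(cv$summary$mean[1], fs$mean)
  expect_equal(cv$summary$sd[1], fs$sd)
  expect_equal(cv$summary$ci_lower[1], fs$ci[["lower"]])
  # out-of-fold scores exist for every sample
  expect_true(all(is.finite(cv$scores)))
})

test_that("hyperparameter sweep produces one row per grid cell", {
  cfg <- tiny_config(epochs = 1L, seed = 17L)
  data <- tiny_cohort_data(cfg, n = 20L, seed = 9L)
  grid <- sweep_hyperparams(cfg, data, taus = 0.1, lambdas = c(0.9, 1),
                            k = 2)
  expect_equal(nrow(grid), 2)
  expect_identical(grid$is_default, c(TRUE, FALSE))
  expect_true(all(c("AUC", "ACC") %in% colnames(grid)))
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- tiny_config(epochs = 1L, seed = 19L)
  data <- tiny_cohort_data(cfg, n = 16L, seed = 11L)
  model <- run_training(cfg, data)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_equal(unclass(back$config), unclass(model$config))
  pr1 <- predict_scores(model, data, 1:5)
  pr2 <- predict_scores(back, data, 1:5)
  expect_identical(pr1$scores, pr2$scores)
})

test_that("full-model gradients match finite differences end to end", {
  pf <- asNamespace("pcrfusion")
  # feedback-inert variants make the loss an exact function of parameters
  for (mc in c("off", "conventional_cl", "no_dynamic_activation")) {
    cfg <- tiny_config(mcfe = mc)
    batch <- tiny_batch(cfg)
    params <- init_model(cfg, ncol(batch$xclin))
    w <- c(w0 = 1.3, w1 = 0.8)
    fwd <- pf$model_forward(params, batch, cfg, w, training = TRUE)
    g <- pf$model_backward(params, batch, cfg, fwd, w)
    loss <- function(p) pf$model_forward(p, batch, cfg, w, training = TRUE)$ltotal
    eps <- 1e-5
    probes <- list(c("clin_enc", "W1", 3), c("fusion", "Wfusion", 8),
                   c("head", "W2", 2))
    if (mc == "conventional_cl") probes <- c(probes, list(c("mcfe", "Wz", 4)))
    for (pr in probes) {
      mod <- pr[1]; leaf <- pr[2]; i <- as.integer(pr[3])
      pp <- params; pp[[mod]][[leaf]][i] <- pp[[mod]][[leaf]][i] + eps
      pm <- params; pm[[mod]][[leaf]][i] <- pm[[mod]][[leaf]][i] - eps
      fd <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(g[[mod]][[leaf]][i], fd, tolerance = 1e-4,
                   label = sprintf("%s/%s/%s[%d]", mc, mod, leaf, i))
    }
  }
})
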