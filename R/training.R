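# Training: stratified k-fold splitting, cohort preparation (leakage-free
# per-fold clinical statistics), the AdamW training loop with the cosine
# schedule and dual loss, cross-validation reports, and the tau/lambda
# sweep.

#' Stratified k-fold split
#'
#' Shuffles each class independently and deals samples round-robin into k
#' disjoint test folds, so every fold's class proportion matches the
#' global one to within one sample.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (>= 2; every class must have >= k members).
#' @param seed RNG seed; identical seeds give identical folds.
#' @return list of class `fold_split`: `folds` (list of `train`/`test`
#'   index vectors) and `report` (per-fold class counts).
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stop_if_not(k >= 2, "k must be >= 2")
  n <- length(labels)
  assign_fold <- integer(n)
  with_seed(seed, {
    # deal each class round-robin, carrying the fold rotation across
    # classes so remainder samples spread over different folds and the
    # fold sizes differ by at most one
    start <- 0L
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      stop_if_not(length(idx) >= k,
                  "class %s has %d members, fewer than k = %d",
                  as.character(cls), length(idx), k)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- (start + seq_along(idx) - 1L) %% k + 1L
      start <- (start + length(idx)) %% k
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- which(assign_fold == f)
    list(train = setdiff(seq_len(n), test), test = test)
  })
  report <- do.call(rbind, lapply(seq_len(k), function(f) {
    te <- folds[[f]]$test
    data.frame(fold = f, n_test = length(te),
               pos_test = sum(labels[te] == 1),
               neg_test = sum(labels[te] == 0))
  }))
  structure(list(folds = folds, report = report, k = k, seed = seed),
            class = "fold_split")
}

#' Prepare phantom volumes for the imaging encoder
#'
#' Z-scores each volume (optional), pads/crops to the encoder's input
#' shape and cuts it into flattened patches.
#'
#' @param volumes list of 3D arrays.
#' @param config a [run_config()].
#' @param zscore apply per-volume Z-score normalization.
#' @return array `(n, n_patches, patch_dim)`.
#' @export
prepare_volumes <- function(volumes, config, zscore = TRUE) {
  n <- length(volumes)
  icfg <- config$img
  out <- array(0, dim = c(n, icfg$n_patches, icfg$patch_dim))
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    if (zscore) v <- zscore_volume(v)
    v <- pad_crop_volume(v, icfg$input_shape)
    out[i, , ] <- volume_to_patches(v, icfg$patch_size)
  }
  out
}

#' Encode the clinical table with train-split statistics
#'
#' @param clinical raw clinical data.frame (NA = missing).
#' @param train_idx rows belonging to the training split; age statistics
#'   are fitted on these rows only (no test leakage).
#' @param K_race,K_subtype category counts.
#' @return list with `x` (encoded matrix for ALL rows) and `stats`.
#' @export
prepare_clinical <- function(clinical, train_idx, K_race = 3L,
                             K_subtype = 4L) {
  stats <- fit_clinical_stats(clinical[train_idx, , drop = FALSE])
  list(x = encode_clinical_table(clinical, stats, K_race, K_subtype),
       stats = stats)
}

resolve_weights <- function(train_labels, config) {
  w <- class_weights_from_counts(train_labels)
  if (isTRUE(config$normalize_weights)) w <- w / mean(w)
  w
}

#' Train the model on one split
#'
#' AdamW (weight decay 0.01) with the layer-wise learning rates (imaging
#' encoder `lr_encoder`, everything else `lr_other`) and single-cycle
#' cosine annealing over `config$epochs`.  Logs the classification,
#' contrastive and total loss per epoch.  Aborts with a diagnostic naming
#' the offending term when a loss goes non-finite.
#'
#' @param config a [run_config()].
#' @param data list with `patches` (`(n, N, pdim)` array; optional for
#'   the clinical modality), `clinical` (raw data.frame; optional for the
#'   image modality) and `labels` (0/1 vector).
#' @param train_idx training-row indices (default: all rows).
#' @param verbose print per-epoch losses.
#' @return list of class `pcr_model`: trained `params`, `config`,
#'   per-epoch `log` data.frame, class `weights`, clinical `stats`.
#' @export
run_training <- function(config, data, train_idx = seq_along(data$labels),
                         verbose = FALSE) {
  labels <- data$labels
  weights <- resolve_weights(labels[train_idx], config)

  xclin <- NULL
  stats <- NULL
  if (config$modality != "image") {
    pc <- prepare_clinical(data$clinical, train_idx)
    xclin <- pc$x
    stats <- pc$stats
  }
  d_clin_in <- if (is.null(xclin)) clinical_layout()$length else ncol(xclin)
  params <- init_model(config, d_clin_in)
  opt <- adamw_init(params)
  lr_map <- list(img_enc = config$lr_encoder, .default = config$lr_other)

  log_rows <- vector("list", config$epochs)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr_scale <- cosine_lr_factor(epoch - 1L, config$epochs)
      order_ <- train_idx[sample.int(length(train_idx))]
      n_steps <- 0L
      sums <- c(lcls = 0, lcl = 0, ltotal = 0)
      for (start in seq(1L, length(order_), by = config$batch_size)) {
        idx <- order_[start:min(start + config$batch_size - 1L, length(order_))]
        if (length(idx) < 2L) next  # degenerate singleton batch
        batch <- list(
          patches = if (config$modality != "clinical")
            data$patches[idx, , , drop = FALSE] else NULL,
          xclin = if (!is.null(xclin)) xclin[idx, , drop = FALSE] else NULL,
          labels = labels[idx])
        fwd <- model_forward(params, batch, config, weights, training = TRUE)
        if (!is.finite(fwd$lcls)) {
          stop(sprintf("classification loss became non-finite at epoch %d", epoch))
        }
        if (!is.finite(fwd$lcl)) {
          stop(sprintf("contrastive loss became non-finite at epoch %d", epoch))
        }
        grads <- model_backward(params, batch, config, fwd, weights)
        st <- adamw_step(params, grads, opt, lr_map, lr_scale,
                         weight_decay = config$weight_decay)
        params <- st$params
        opt <- st$state
        sums <- sums + c(fwd$lcls, fwd$lcl, fwd$ltotal)
        n_steps <- n_steps + 1L
      }
      row <- data.frame(epoch = epoch, lr_scale = lr_scale,
                        lcls = sums[["lcls"]] / n_steps,
                        lcl = sums[["lcl"]] / n_steps,
                        ltotal = sums[["ltotal"]] / n_steps)
      log_rows[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  Lcls %.4f  LCL %.4f  Ltotal %.4f",
                        epoch, row$lcls, row$lcl, row$ltotal))
      }
    }
  })
  structure(list(params = params, config = config,
                 log = do.call(rbind, log_rows),
                 weights = weights, stats = stats,
                 train_idx = train_idx),
            class = "pcr_model")
}

#' Predict pCR scores for a set of samples
#'
#' @param model a trained `pcr_model` from [run_training()].
#' @param data the same data list used for training.
#' @param idx rows to score (default: all).
#' @return list with `scores` (pCR probability) and `probs` (`n x 2`).
#' @export
predict_scores <- function(model, data, idx = seq_along(data$labels)) {
  config <- model$config
  xclin <- NULL
  if (config$modality != "image") {
    xclin <- encode_clinical_table(data$clinical, model$stats)
  }
  n <- length(idx)
  probs <- matrix(0, n, 2L)
  bs <- max(2L, config$batch_size)
  for (start in seq(1L, n, by = bs)) {
    rows <- start:min(start + bs - 1L, n)
    sel <- idx[rows]
    batch <- list(
      patches = if (config$modality != "clinical")
        data$patches[sel, , , drop = FALSE] else NULL,
      xclin = if (!is.null(xclin)) xclin[sel, , drop = FALSE] else NULL,
      labels = NULL)
    fwd <- model_forward(model$params, batch, config, training = FALSE)
    probs[rows, ] <- fwd$probs
  }
  list(scores = probs[, 2], probs = probs)
}

metric_row <- function(labels, scores) {
  preds <- as.integer(scores >= 0.5)   # argmax over the two-class softmax
  cm <- confusion_and_metrics(labels, preds)
  m <- cm$metrics
  data.frame(AUC = auc_score(labels, scores), ACC = m[["ACC"]],
             SEN = m[["SEN"]], SPE = m[["SPE"]], F1 = m[["F1"]],
             PPV = m[["PPV"]], NPV = m[["NPV"]])
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold and evaluates it on the held-out fold,
#' producing a per-fold metric table (AUC, ACC, SEN, SPE, F1, PPV, NPV)
#' plus a Mean +/- SD summary row computed with [fold_summary()].
#'
#' @param config a [run_config()].
#' @param data data list (see [run_training()]).
#' @param k number of folds.
#' @param verbose print progress.
#' @return list of class `crossval_report`: `per_fold` (k-row
#'   data.frame), `summary` (mean/sd/CI per metric), `folds`, `models`
#'   (optional), `scores` (per-sample out-of-fold scores).
#' @export
run_crossval <- function(config, data, k = 5L, verbose = FALSE) {
  labels <- data$labels
  split <- stratified_folds(labels, k, config$seed)
  rows <- vector("list", k)
  oof_scores <- rep(NA_real_, length(labels))
  for (f in seq_len(k)) {
    fold <- split$folds[[f]]
    if (verbose) message(sprintf("fold %d/%d: training on %d samples",
                                 f, k, length(fold$train)))
    model <- run_training(config, data, fold$train, verbose = FALSE)
    pr <- predict_scores(model, data, fold$test)
    oof_scores[fold$test] <- pr$scores
    rows[[f]] <- cbind(fold = f, metric_row(labels[fold$test], pr$scores))
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("AUC", "ACC", "SEN", "SPE", "F1", "PPV", "NPV")
  summary_rows <- lapply(metrics, function(m) {
    vals <- per_fold[[m]]
    if (any(is.na(vals))) {
      return(data.frame(metric = m, mean = NA_real_, sd = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_))
    }
    fs <- fold_summary(vals)
    data.frame(metric = m, mean = fs$mean, sd = fs$sd,
               ci_lower = fs$ci[["lower"]], ci_upper = fs$ci[["upper"]])
  })
  structure(list(per_fold = per_fold,
                 summary = do.call(rbind, summary_rows),
                 folds = split, scores = oof_scores, config = config),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Stratified", x$folds$k, "fold cross-validation\n")
  print(cbind(x$per_fold[1], round(x$per_fold[-1], 4)), row.names = FALSE)
  s <- x$summary
  cat("Mean +/- SD:\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.4f +/- %.4f  (95%% CI %.4f, %.4f)\n",
                s$metric[i], s$mean[i], s$sd[i], s$ci_lower[i], s$ci_upper[i]))
  }
  invisible(x)
}

#' Temperature / contrastive-weight sweep
#'
#' Runs one cross-validation per grid cell over the candidate ranges
#' (defaults: tau in 0.1/0.3/0.5, lambda in 0.1-1).  Each cell derives
#' its seed from the base seed plus the cell index, so cells are
#' independent and reproducible.
#'
#' @param config base [run_config()].
#' @param data data list.
#' @param taus,lambdas candidate grids.
#' @param k folds per cell.
#' @param verbose print progress.
#' @return data.frame with one row per cell: tau, lambda, `is_default`
#'   (the tau=0.1 / lambda=0.9 cell), and the mean cross-validated
#'   metrics.
#' @export
sweep_hyperparams <- function(config, data, taus = c(0.1, 0.3, 0.5),
                              lambdas = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                              k = 5L, verbose = FALSE) {
  grid <- expand.grid(lambda = lambdas, tau = taus)[, c("tau", "lambda")]
  stop_if_not(nrow(grid) > 0, "empty sweep grid")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- config
    cell$tau <- grid$tau[i]
    cell$lambda <- grid$lambda[i]
    cell$seed <- config$seed + i
    if (verbose) message(sprintf("sweep cell %d/%d: tau=%.1f lambda=%.1f",
                                 i, nrow(grid), cell$tau, cell$lambda))
    cv <- run_crossval(cell, data, k)
    means <- stats::setNames(cv$summary$mean, cv$summary$metric)
    rows[[i]] <- data.frame(tau = cell$tau, lambda = cell$lambda,
                            is_default = cell$tau == 0.1 && cell$lambda == 0.9,
                            t(means))
  }
  do.call(rbind, rows)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS file containing the parameters and the
#' full configuration (itself serializable to JSON).
#'
#' @param model a `pcr_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config),
               weights = model$weights, stats = model$stats,
               log = model$log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  class(x$config) <- "run_config"
  structure(list(params = x$params, config = x$config, log = x$log,
                 weights = x$weights, stats = x$stats), class = "pcr_model")
}
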