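# Training loop (Adam on mean-squared error over normalised targets, seeded
# and deterministic), MAE/RMSE metrics, and the leave-one-subject-out
# evaluation protocol with sample-weighted aggregation.

#' Mean absolute error
#'
#' @param pred,truth Equal-length numeric vectors (mmHg in the BP setting).
#' @return Mean of `|pred - truth|`.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    pg_stop("pg_shape_error", "pred and truth must have equal nonzero length")
  }
  mean(abs(pred - truth))
}

#' Root mean squared error
#'
#' @inheritParams mae
#' @return Square root of the mean squared difference.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    pg_stop("pg_shape_error", "pred and truth must have equal nonzero length")
  }
  sqrt(mean((pred - truth)^2))
}

#' Training configuration
#'
#' @param epochs Number of passes over the training windows.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param loss Loss name; `"mse"` (regression heads) is the only option, the
#'   stage classifier uses softmax cross-entropy internally.
#' @param seed Integer seed driving shuffling, dropout masks and the
#'   validation split.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; the best-validation parameters are restored.
#' @param val_fraction Fraction of training windows held out for validation
#'   (0 disables early stopping).
#' @param augment_shift Apply a random circular time shift to every training
#'   window each epoch. Beat-synchronous windows are near-periodic, so a
#'   circular shift yields another physiologically plausible window with the
#'   same labels; this removes the network's dependence on absolute beat
#'   positions and is the package's only augmentation.
#' @param weight_decay Decoupled weight-decay coefficient (AdamW style);
#'   regularises against memorising training subjects.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L,
                         learning_rate = 3e-3, loss = "mse", seed = 1L,
                         early_stop_patience = 8L, val_fraction = 0.1,
                         augment_shift = TRUE, weight_decay = 0) {
  check_scalar_number(epochs, "epochs", lower = 0, integer = TRUE)
  check_scalar_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_scalar_number(learning_rate, "learning_rate", lower = 0)
  loss <- match.arg(loss, "mse")
  check_scalar_number(seed, "seed", integer = TRUE)
  check_scalar_number(early_stop_patience, "early_stop_patience", lower = 1,
                      integer = TRUE)
  check_scalar_number(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, loss = loss, seed = as.integer(seed),
         early_stop_patience = as.integer(early_stop_patience),
         val_fraction = val_fraction,
         augment_shift = isTRUE(augment_shift),
         weight_decay = weight_decay),
    class = "train_config"
  )
}

# Targets for a head, as a windows x outputs matrix (classifier: class index).
head_targets <- function(dataset, spec) {
  switch(spec$head,
    direct_sbp_dbp = cbind(sbp = dataset$sbp, dbp = dataset$dbp),
    entire_waveform = dataset$abp,
    stage_classifier = matrix(
      findInterval(dataset$sbp, STAGE_BREAKS[-1], left.open = TRUE) + 1L,
      ncol = 1L)
  )
}

batch_loss_grad <- function(net, xb, yb, spec, training = TRUE) {
  fw <- net_forward(net, xb, training = training)
  out <- fw$y
  B <- ncol(out)
  if (spec$head == "stage_classifier") {
    K <- nrow(out)
    probs <- exp(sweep(out, 2L, apply(out, 2L, max)))
    probs <- sweep(probs, 2L, colSums(probs), `/`)
    onehot <- matrix(0, K, B)
    onehot[cbind(yb, seq_len(B))] <- 1
    loss <- -mean(log(pmax(colSums(probs * onehot), 1e-12)))
    dout <- (probs - onehot) / B
  } else {
    diff <- out - yb
    loss <- mean(diff^2)
    dout <- 2 * diff / length(diff)
  }
  list(loss = loss, dout = dout, caches = fw$caches)
}

#' Train a model on a windowed dataset
#'
#' Minimises mean-squared error on z-scored targets (softmax cross-entropy
#' for the stage head) with Adam. All randomness — parameter shuffling order,
#' dropout masks, the validation split — derives from `config$seed`, so a
#' `(model, dataset, config)` triple trains to identical parameters on a
#' given platform. Validation-based early stopping restores the
#' best-validation parameters.
#'
#' @param model A freshly built (or previously trained) `bp_model`.
#' @param dataset A `bp_dataset` from [make_dataset()].
#' @param config A [train_config()].
#' @param subjects Optional character vector restricting training to these
#'   subject ids (used by the leave-one-out driver).
#' @return The trained `bp_model`, with a `history` data frame of per-epoch
#'   train/validation losses.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        subjects = NULL) {
  stopifnot(inherits(model, "bp_model"), inherits(dataset, "bp_dataset"),
            inherits(config, "train_config"))
  if (config$epochs == 0L) return(model)
  keep <- if (is.null(subjects)) rep(TRUE, length(dataset$subject))
          else dataset$subject %in% subjects
  if (!any(keep)) pg_stop("pg_config_error", "no training windows selected")
  spec <- model$spec
  X <- dataset_inputs(dataset, spec$channels)[keep, , drop = FALSE]
  Y <- head_targets(dataset, spec)[keep, , drop = FALSE]
  xarr <- inputs_to_tensor(X, spec)

  # normalisation statistics from the training windows only; channels are
  # centred and scaled by their max absolute deviation (not the sd) so spiky
  # channels like the ECG do not dwarf smooth ones after scaling
  nch <- dim(xarr)[1]
  x_mean <- numeric(nch); x_sd <- numeric(nch)
  for (c in seq_len(nch)) {
    x_mean[c] <- mean(xarr[c, , ])
    x_sd[c] <- max(max(abs(xarr[c, , ] - x_mean[c])), 1e-8)
  }
  if (spec$head == "stage_classifier") {
    y_mean <- 0; y_sd <- 1
    yt <- t(Y)                                   # 1 x B class indices
  } else if (spec$head == "entire_waveform") {
    y_mean <- mean(Y); y_sd <- max(stats::sd(as.numeric(Y)), 1e-8)
    yt <- t((Y - y_mean) / y_sd)
  } else {
    y_mean <- colMeans(Y); y_sd <- pmax(apply(Y, 2L, stats::sd), 1e-8)
    yt <- t(sweep(sweep(Y, 2L, y_mean), 2L, y_sd, `/`))
  }
  dimnames(yt) <- NULL
  model$norm <- list(x_mean = x_mean, x_sd = x_sd,
                     y_mean = unname(y_mean), y_sd = unname(y_sd))
  xarr <- normalize_inputs(xarr, model$norm)

  n <- dim(xarr)[3]
  rows <- which(keep)                  # dataset row ids of training windows
  net <- model$net
  state <- adam_state_new()
  hist_train <- numeric(config$epochs)
  hist_val <- rep(NA_real_, config$epochs)

  with_seed(config$seed, {
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val >= 1L) sample.int(n, n_val) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    val_rows <- rows[val_idx]
    best_val <- Inf
    best_net <- NULL
    stall <- 0L
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      # step decay: halve the rate twice over the run for stable convergence
      lr <- config$learning_rate *
        0.5^((ep > 0.5 * config$epochs) + (ep > 0.75 * config$epochs))
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        xb <- xarr[, , bi, drop = FALSE]
        if (config$augment_shift) {
          L <- dim(xb)[2]
          for (s in seq_along(bi)) {
            sh <- sample.int(L, 1L) - 1L
            if (sh > 0L) {
              xb[, , s] <- xb[, c((sh + 1L):L, 1L:sh), s]
            }
          }
        }
        yb <- if (spec$head == "stage_classifier") as.integer(yt[, bi])
              else yt[, bi, drop = FALSE]
        r <- batch_loss_grad(net, xb, yb, spec, training = TRUE)
        if (!is.finite(r$loss)) {
          pg_stop("pg_divergence_error",
                  "non-finite training loss at epoch %d", ep)
        }
        bk <- net_backward(net, r$caches, r$dout)
        step <- step + 1L
        net <- adam_step(net, bk$grads, state, lr, step,
                         weight_decay = config$weight_decay)
        ep_loss <- ep_loss + r$loss * length(bi)
        ep_n <- ep_n + length(bi)
      }
      hist_train[ep] <- ep_loss / max(ep_n, 1L)
      if (length(val_idx)) {
        xv <- xarr[, , val_idx, drop = FALSE]
        yv <- if (spec$head == "stage_classifier") as.integer(yt[, val_idx])
              else yt[, val_idx, drop = FALSE]
        vl <- batch_loss_grad(net, xv, yv, spec, training = FALSE)$loss
        hist_val[ep] <- vl
        if (vl < best_val - 1e-9) {
          best_val <- vl
          best_net <- net
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$early_stop_patience) break
        }
      }
    }
    if (!is.null(best_net)) net <- best_net
  })

  model$net <- net
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              train_loss = hist_train, val_loss = hist_val)
  model$val_rows <- val_rows
  model
}

#' Validation MAE of a trained configuration
#'
#' Trains a freshly built model and returns the mean absolute error of its
#' SBP/DBP predictions on its own held-out validation windows (in mmHg).
#' This is the in-distribution generalisation measure used to compare input
#' channel configurations on a common benchmark.
#'
#' @param spec A [model_spec()] with the `direct_sbp_dbp` head.
#' @param dataset A `bp_dataset`.
#' @param config A [train_config()] with a positive `val_fraction`.
#' @return Named numeric vector with `mae_s` and `mae_d` (mmHg).
#' @export
validation_mae <- function(spec, dataset, config) {
  stopifnot(identical(spec$head, "direct_sbp_dbp"))
  if (config$val_fraction <= 0) {
    pg_stop("pg_config_error", "validation_mae needs val_fraction > 0")
  }
  model <- build_model(spec, seed = config$seed)
  model <- train_model(model, dataset, config)
  idx <- model$val_rows
  p <- predict(model, dataset_inputs(dataset, spec$channels)[idx, ,
                                                             drop = FALSE])
  c(mae_s = mae(p[, "sbp"], dataset$sbp[idx]),
    mae_d = mae(p[, "dbp"], dataset$dbp[idx]))
}

# ---- leave-one-out protocol -------------------------------------------------

fit_estimator <- function(estimator, dataset, config, train_subjects,
                          fold_seed) {
  X <- dataset_inputs(
    dataset, if (inherits(estimator, "model_spec")) estimator$channels
             else "ppg")
  keep <- dataset$subject %in% train_subjects
  if (inherits(estimator, "model_spec")) {
    cfg <- config
    cfg$seed <- (config$seed + fold_seed) %% .Machine$integer.max
    model <- build_model(estimator, seed = cfg$seed)
    train_model(model, dataset, cfg, subjects = train_subjects)
  } else if (identical(estimator, "linear")) {
    Y <- cbind(dataset$sbp, dataset$dbp)[keep, , drop = FALSE]
    fit_linear_baseline(X[keep, , drop = FALSE], Y)
  } else if (identical(estimator, "mean")) {
    structure(list(mu = c(mean(dataset$sbp[keep]), mean(dataset$dbp[keep]))),
              class = "mean_baseline")
  } else {
    pg_stop("pg_config_error", "unknown estimator")
  }
}

predict_estimator <- function(fit, dataset, idx) {
  if (inherits(fit, "bp_model")) {
    X <- dataset_inputs(dataset, fit$spec$channels)[idx, , drop = FALSE]
    predict(fit, X)
  } else if (inherits(fit, "linear_baseline")) {
    X <- dataset_inputs(dataset, "ppg")[idx, , drop = FALSE]
    p <- predict(fit, X)
    colnames(p) <- c("sbp", "dbp")
    p
  } else {
    matrix(fit$mu, nrow = length(idx), ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("sbp", "dbp")))
  }
}

# Derive window-level SBP/DBP from a predicted waveform using the window's
# known beat onsets (max/min of the whole window when fewer than two onsets
# fall inside it).
waveform_to_sbp_dbp <- function(wave, onsets) {
  if (length(onsets) >= 2L) {
    ex <- extract_sbp_dbp(wave, onsets)
    c(mean(ex$sbp), mean(ex$dbp))
  } else {
    c(max(wave), min(wave))
  }
}

#' Leave-one-subject-out evaluation
#'
#' For each subject: train on all other subjects, test on the held-out one.
#' `direct` mode scores the head's SBP/DBP outputs against the window labels;
#' `entire` mode scores the predicted pressure waveform (MAE/RMSE) and
#' additionally derives SBP/DBP from the predicted waveform via
#' [extract_sbp_dbp()] before scoring. Aggregate metrics are
#' sample-count-weighted means over folds.
#'
#' @param estimator A [model_spec()] (its `head` selects the mode), or
#'   `"linear"` / `"mean"` for the flattened-window least-squares baseline and
#'   the training-mean predictor (both direct mode).
#' @param dataset A `bp_dataset`.
#' @param config A [train_config()]; ignored by the non-network baselines.
#' @return An object of class `eval_report`.
#' @export
loo_evaluate <- function(estimator, dataset, config = train_config()) {
  stopifnot(inherits(dataset, "bp_dataset"))
  subjects <- unique(dataset$subject)
  if (length(subjects) < 2L) {
    pg_stop("pg_config_error", "leave-one-out needs at least 2 subjects")
  }
  mode <- if (inherits(estimator, "model_spec") &&
              estimator$head == "entire_waveform") "entire" else "direct"
  channels <- if (inherits(estimator, "model_spec")) estimator$channels
              else "ppg"
  folds <- vector("list", length(subjects))
  skipped <- character()
  for (f in seq_along(subjects)) {
    held <- subjects[f]
    test_idx <- which(dataset$subject == held)
    if (length(test_idx) == 0L) {
      warning(sprintf("subject %s has no test windows; fold skipped", held),
              call. = FALSE)
      skipped <- c(skipped, held)
      next
    }
    fit <- fit_estimator(estimator, dataset, config,
                         setdiff(subjects, held), fold_seed = f)
    pred <- predict_estimator(fit, dataset, test_idx)
    if (mode == "entire") {
      wave_true <- dataset$abp[test_idx, , drop = FALSE]
      m_wave <- mae(as.numeric(pred), as.numeric(wave_true))
      r_wave <- rmse(as.numeric(pred), as.numeric(wave_true))
      sd_hat <- t(vapply(seq_along(test_idx), function(i) {
        waveform_to_sbp_dbp(pred[i, ],
                            dataset$beats[[test_idx[i]]]$onsets)
      }, numeric(2)))
      sbp_hat <- sd_hat[, 1]; dbp_hat <- sd_hat[, 2]
    } else {
      m_wave <- NA_real_; r_wave <- NA_real_
      sbp_hat <- pred[, "sbp"]; dbp_hat <- pred[, "dbp"]
    }
    folds[[f]] <- data.frame(
      subject = held, n = length(test_idx),
      mae = m_wave, rmse = r_wave,
      mae_s = mae(sbp_hat, dataset$sbp[test_idx]),
      mae_d = mae(dbp_hat, dataset$dbp[test_idx]),
      rmse_s = rmse(sbp_hat, dataset$sbp[test_idx]),
      rmse_d = rmse(dbp_hat, dataset$dbp[test_idx]),
      stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, folds)
  wmean <- function(v) {
    if (all(is.na(v))) NA_real_
    else sum(v * per_fold$n) / sum(per_fold$n)
  }
  aggregate <- list(mae = wmean(per_fold$mae), rmse = wmean(per_fold$rmse),
                    mae_s = wmean(per_fold$mae_s),
                    mae_d = wmean(per_fold$mae_d),
                    rmse_s = wmean(per_fold$rmse_s),
                    rmse_d = wmean(per_fold$rmse_d))
  structure(
    list(mode = mode, channels = channels, per_fold = per_fold,
         aggregate = aggregate, n_subjects = length(subjects),
         skipped = skipped),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s mode, %s, %d subjects (%d folds)>\n",
              x$mode, x$channels, x$n_subjects, nrow(x$per_fold)))
  a <- x$aggregate
  if (x$mode == "entire") {
    cat(sprintf("  waveform  MAE %.3f  RMSE %.3f mmHg\n", a$mae, a$rmse))
  }
  cat(sprintf("  systolic  MAE %.3f  RMSE %.3f mmHg\n", a$mae_s, a$rmse_s))
  cat(sprintf("  diastolic MAE %.3f  RMSE %.3f mmHg\n", a$mae_d, a$rmse_d))
  invisible(x)
}

#' Export an evaluation report as a one-row data frame
#'
#' Columns follow the conventional LOO result layout: `RMSE`, `MAE`, `MAE D`,
#' `MAE S`, `RMSE D`, `RMSE S` (waveform columns `NA` in direct mode).
#'
#' @param report An `eval_report`.
#' @return A data frame with one aggregate row.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  a <- report$aggregate
  df <- data.frame(a$rmse, a$mae, a$mae_d, a$mae_s, a$rmse_d, a$rmse_s,
                   check.names = FALSE)
  names(df) <- c("RMSE", "MAE", "MAE D", "MAE S", "RMSE D", "RMSE S")
  df
}
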