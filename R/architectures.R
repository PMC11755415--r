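# Model assembly for the five compared families: fully connected, LSTM,
# WaveNet (dilated causal convolutions), WaveNet-LSTM and ResNet-LSTM (the
# hybrid layout: five convolutional blocks holding 12 convolutions in a
# (3,3,2,2,2) split, each block closed by a residual skip, a 2-wide max-pool
# and dropout, followed by one LSTM layer, one fully connected layer and the
# selected head).

FAMILIES <- c("fully_connected", "lstm", "wavenet", "wavenet_lstm",
              "resnet_lstm")
HEADS <- c("direct_sbp_dbp", "entire_waveform", "stage_classifier")

# long display names accepted as family aliases (the model zoo is addressable
# by either form)
FAMILY_LABELS <- c(
  "fully connected" = "fully_connected",
  "long short-term memory" = "lstm",
  "wavenet" = "wavenet",
  "wavenet + long short-term memory" = "wavenet_lstm",
  "resnet + long short-term memory" = "resnet_lstm")

#' Resolve a model family name or display label
#'
#' Accepts either the canonical snake_case family id or the long display
#' name (e.g. `"ResNet + Long Short-Term Memory"`), case-insensitively.
#'
#' @param name Character family name or label.
#' @return The canonical family id.
#' @export
resolve_family <- function(name) {
  if (name %in% FAMILIES) return(name)
  key <- tolower(trimws(name))
  if (key %in% names(FAMILY_LABELS)) return(unname(FAMILY_LABELS[key]))
  pg_stop("pg_config_error", "unknown model family `%s`", name)
}

# Hypertension stages by systolic pressure (ACC/AHA bands, mmHg)
STAGE_BREAKS <- c(-Inf, 120, 130, 140, Inf)
STAGE_LABELS <- c("normal", "elevated", "stage1", "stage2")

#' Declarative model specification
#'
#' Describes one of the five architectures together with its input-channel
#' configuration and prediction head. Layer widths scale with the number of
#' input channels (a PPG+ECG model doubles its conv channels and LSTM hidden
#' size relative to the PPG-only model), which also makes its forward cost
#' roughly four times larger — the quadratic width scaling discussed in the
#' complexity module.
#'
#' @param family One of `"fully_connected"`, `"lstm"`, `"wavenet"`,
#'   `"wavenet_lstm"`, `"resnet_lstm"`.
#' @param channels `"ppg"` (one input channel) or `"ppg_ecg"` (two).
#' @param head `"direct_sbp_dbp"` (two outputs), `"entire_waveform"` (output
#'   length equals the input window) or `"stage_classifier"` (softmax over
#'   hypertension stages).
#' @param hidden_size Base width (conv channels / LSTM hidden units) before
#'   channel scaling.
#' @param depth Layer count for the fully connected stack / WaveNet dilation
#'   stack (ignored by `resnet_lstm`, whose depth is fixed by its layout).
#' @param kernel_size Convolution kernel width (3 in the reference layout).
#' @param dropout_rate Dropout fraction per block, in \[0, 1).
#' @param window_len Input window length in samples.
#' @param n_classes Number of stages for the classifier head.
#' @param frame_size Samples per recurrent time step for the plain LSTM
#'   family.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = FAMILIES, channels = c("ppg", "ppg_ecg"),
                       head = HEADS, hidden_size = 12L, depth = 4L,
                       kernel_size = 3L, dropout_rate = 0.25,
                       window_len = 500L, n_classes = 4L, frame_size = 8L) {
  if (length(family) == 1L && !family %in% FAMILIES) {
    family <- resolve_family(family)
  }
  family <- match.arg(family)
  channels <- match.arg(channels)
  head <- match.arg(head)
  check_scalar_number(hidden_size, "hidden_size", lower = 1, integer = TRUE)
  check_scalar_number(depth, "depth", lower = 1, integer = TRUE)
  check_scalar_number(kernel_size, "kernel_size", lower = 1, integer = TRUE)
  check_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-9)
  check_scalar_number(window_len, "window_len", lower = 8, integer = TRUE)
  check_scalar_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  check_scalar_number(frame_size, "frame_size", lower = 1, integer = TRUE)
  structure(
    list(family = family, channels = channels, head = head,
         hidden_size = as.integer(hidden_size), depth = as.integer(depth),
         kernel_size = as.integer(kernel_size), dropout_rate = dropout_rate,
         window_len = as.integer(window_len), n_classes = as.integer(n_classes),
         frame_size = as.integer(frame_size)),
    class = "model_spec"
  )
}

spec_n_channels <- function(spec) if (spec$channels == "ppg_ecg") 2L else 1L

head_dim <- function(spec) {
  switch(spec$head,
         direct_sbp_dbp = 2L,
         entire_waveform = spec$window_len,
         stage_classifier = spec$n_classes)
}

# Build the head layers given the incoming feature dimension. The stage head
# emits logits; softmax is applied at prediction / in the loss.
build_head <- function(spec, feat_dim) {
  list(layer_dense(feat_dim, head_dim(spec), activation = "linear",
                   role = "output"))
}

#' Instantiate a network from a specification
#'
#' Construction is seeded so identical `(spec, seed)` pairs yield identical
#' parameter tensors.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `bp_model` (untrained).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  nch <- spec_n_channels(spec)
  w <- spec$hidden_size * nch              # width after channel scaling
  L <- spec$window_len
  k <- spec$kernel_size
  net <- with_seed(seed, switch(spec$family,
    fully_connected = {
      layers <- list(layer_flatten())
      d_in <- nch * L
      for (i in seq_len(spec$depth)) {
        layers <- c(layers, list(layer_dense(d_in, w * 4L, "relu")))
        d_in <- w * 4L
      }
      c(layers, build_head(spec, d_in))
    },
    lstm = {
      t_out <- L %/% spec$frame_size
      c(list(layer_frame(spec$frame_size),
             layer_lstm(nch * spec$frame_size, w)),
        build_head(spec, w))
    },
    wavenet = build_wavenet(spec, nch, w, L, k, with_lstm = FALSE),
    wavenet_lstm = build_wavenet(spec, nch, w, L, k, with_lstm = TRUE),
    resnet_lstm = build_resnet_lstm(spec, nch, w, L, k)
  ))
  structure(
    list(spec = spec, net = net, seed = as.integer(seed),
         norm = NULL, trained = FALSE, history = NULL),
    class = "bp_model"
  )
}

# Dilated causal stack; dilation doubles per layer (1, 2, 4, ...). Each layer
# after the channel embedding carries a residual skip.
build_wavenet <- function(spec, nch, w, L, k, with_lstm) {
  layers <- list(layer_conv1d(nch, w, 1L, padding = "causal"))
  for (i in seq_len(spec$depth)) {
    layers <- c(layers, list(layer_res_block(
      list(layer_conv1d(w, w, k, dilation = 2L^(i - 1L), padding = "causal"))
    )))
  }
  if (spec$head == "entire_waveform" && !with_lstm) {
    # length-preserving readout: 1x1 conv to a single channel
    return(c(layers, list(layer_conv1d(w, 1L, 1L, padding = "causal"),
                          layer_flatten())))
  }
  if (with_lstm) {
    pools <- list(layer_pool1d(), layer_pool1d(), layer_pool1d())
    t_out <- L %/% 8L
    layers <- c(layers, pools, list(layer_lstm(w, w)))
    return(c(layers, build_head(spec, w)))
  }
  c(layers, list(layer_meanpool_time()), build_head(spec, w))
}

# The 20-layer hybrid: 5 blocks of (3,3,2,2,2) convolutions (3-wide kernels,
# ReLU, residual skip per block), each closed by a 2-wide max-pool and
# dropout, then one LSTM layer, one FC layer, and the output head.
build_resnet_lstm <- function(spec, nch, w, L, k) {
  conv_split <- c(3L, 3L, 2L, 2L, 2L)
  layers <- list()
  c_in <- nch
  for (b in seq_along(conv_split)) {
    sub <- list()
    cc <- c_in
    for (j in seq_len(conv_split[b])) {
      sub <- c(sub, list(layer_conv1d(cc, w, k, padding = "same")))
      cc <- w
      if (j < conv_split[b]) sub <- c(sub, list(layer_relu()))
    }
    proj <- if (c_in != w) layer_channel_proj(c_in, w) else NULL
    layers <- c(layers, list(layer_res_block(sub, proj = proj),
                             layer_pool1d(),
                             layer_dropout(spec$dropout_rate)))
    c_in <- w
  }
  t_out <- max(L %/% 32L, 1L)
  c(layers,
    list(layer_lstm(w, w, return_sequences = TRUE),
         layer_dense(w * t_out, w, activation = "relu", role = "fc")),
    build_head(spec, w))
}

# ---- introspection ----------------------------------------------------------

walk_layers <- function(net, f) {
  for (l in net) {
    if (l$type == "res_block") {
      walk_layers(l$layers, f)
      if (!is.null(l$proj)) f(l$proj)
      f(l)
    } else {
      f(l)
    }
  }
  invisible(NULL)
}

#' Summarise a built model's layer composition
#'
#' @param model A `bp_model`.
#' @return A list with counts (`n_conv`, `n_pool`, `n_lstm`, `n_fc`,
#'   `n_dropout`), the distinct `dropout_rates` and `kernel_sizes`, the pool
#'   window, the fan-in of the first parameterised layer
#'   (`first_layer_fan_in`), and the total trainable `n_parameters`.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "bp_model"))
  counts <- list(n_conv = 0L, n_pool = 0L, n_lstm = 0L, n_fc = 0L,
                 n_output = 0L, n_dropout = 0L)
  rates <- numeric(); ksz <- integer(); pools <- integer()
  first_fan_in <- NA_integer_
  walk_layers(model$net, function(l) {
    if (l$type == "conv1d") {
      counts$n_conv <<- counts$n_conv + 1L
      ksz <<- c(ksz, l$k)
      if (is.na(first_fan_in)) first_fan_in <<- l$c_in * l$k
    } else if (l$type == "pool1d") {
      counts$n_pool <<- counts$n_pool + 1L
      pools <<- c(pools, l$window)
    } else if (l$type == "lstm") {
      counts$n_lstm <<- counts$n_lstm + 1L
      if (is.na(first_fan_in)) first_fan_in <<- l$n_in
    } else if (l$type == "dense") {
      if (identical(l$role, "output")) counts$n_output <<- counts$n_output + 1L
      else counts$n_fc <<- counts$n_fc + 1L
      if (is.na(first_fan_in)) first_fan_in <<- l$n_in
    } else if (l$type == "dropout") {
      counts$n_dropout <<- counts$n_dropout + 1L
      rates <<- c(rates, l$rate)
    }
  })
  c(counts,
    list(dropout_rates = unique(rates), kernel_sizes = unique(ksz),
         pool_windows = unique(pools), first_layer_fan_in = first_fan_in,
         n_parameters = net_param_count(model$net),
         family = model$spec$family, channels = model$spec$channels,
         head = model$spec$head))
}

#' @export
print.bp_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf(
    "<bp_model %s (%s, %s): %d conv, %d pool, %d lstm, %d fc; %d params%s>\n",
    x$spec$family, x$spec$channels, x$spec$head, s$n_conv, s$n_pool,
    s$n_lstm, s$n_fc, s$n_parameters,
    if (x$trained) ", trained" else ""))
  invisible(x)
}

# ---- prediction -------------------------------------------------------------

# Reshape a windows-by-samples input matrix into the (C, L, B) tensor the
# layer engine expects; for ppg_ecg the matrix holds [ppg | ecg] columns.
inputs_to_tensor <- function(X, spec) {
  nch <- spec_n_channels(spec)
  L <- spec$window_len
  if (ncol(X) != nch * L) {
    pg_stop("pg_shape_error",
            "input windows have %d columns; model expects %d (%d channel(s) x %d samples)",
            ncol(X), nch * L, nch, L)
  }
  B <- nrow(X)
  xarr <- array(0, c(nch, L, B))
  for (c in seq_len(nch)) {
    xarr[c, , ] <- t(X[, (c - 1L) * L + seq_len(L), drop = FALSE])
  }
  xarr
}

normalize_inputs <- function(xarr, norm) {
  for (c in seq_len(dim(xarr)[1])) {
    xarr[c, , ] <- (xarr[c, , ] - norm$x_mean[c]) / norm$x_sd[c]
  }
  xarr
}

#' Run a model forward on input windows
#'
#' @param model A `bp_model` (trained or freshly built; an untrained model
#'   uses identity target scaling).
#' @param X Numeric matrix of input windows (rows = windows, columns =
#'   channel-concatenated samples), or a single window as a vector.
#' @return For `direct_sbp_dbp`: a matrix with columns `sbp`, `dbp` (mmHg).
#'   For `entire_waveform`: a matrix of predicted pressure waveforms (mmHg),
#'   one row per window. For `stage_classifier`: a matrix of class
#'   probabilities with one row per window.
#' @export
predict.bp_model <- function(object, X, ...) {
  model <- object
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  xarr <- inputs_to_tensor(X, model$spec)
  if (!is.null(model$norm)) xarr <- normalize_inputs(xarr, model$norm)
  out <- net_forward(model$net, xarr, training = FALSE)$y   # (K, B)
  if (model$spec$head == "stage_classifier") {
    probs <- apply(out, 2L, softmax)
    res <- t(matrix(probs, nrow = head_dim(model$spec)))
    colnames(res) <- STAGE_LABELS[seq_len(ncol(res))]
    return(res)
  }
  if (!is.null(model$norm)) {
    out <- out * model$norm$y_sd + model$norm$y_mean
  }
  res <- t(out)
  if (model$spec$head == "direct_sbp_dbp") colnames(res) <- c("sbp", "dbp")
  res
}

# ---- linear baseline (y = m.x + b) ------------------------------------------

#' Least-squares linear regression baseline
#'
#' Fits `y = m . x + b` on flattened input windows by least squares. With a
#' rank-deficient design (e.g. constant inputs) a warning is raised and the
#' minimum-norm solution is returned via the pseudoinverse.
#'
#' @param windows Numeric matrix of input windows (rows = samples).
#' @param targets Numeric vector or matrix of targets (one column per output).
#' @return An object of class `linear_baseline` with fields `m` (slope matrix,
#'   inputs x outputs) and `b` (intercept vector).
#' @export
fit_linear_baseline <- function(windows, targets) {
  if (is.vector(windows)) windows <- matrix(windows, ncol = 1L)
  targets <- as.matrix(targets)
  if (nrow(windows) < 2L) {
    pg_stop("pg_config_error", "need at least 2 samples to fit the baseline")
  }
  if (nrow(windows) != nrow(targets)) {
    pg_stop("pg_shape_error", "windows and targets row counts differ")
  }
  X <- cbind(1, windows)
  fit <- tryCatch(qr(X, LAPACK = FALSE), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(X)) {
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(pos, 1 / sv$d, 0)
    coefs <- sv$v %*% (dinv * crossprod(sv$u, targets))
  } else {
    coefs <- qr.coef(fit, targets)
    coefs[is.na(coefs)] <- 0
  }
  coefs <- as.matrix(coefs)
  structure(list(m = coefs[-1L, , drop = FALSE], b = coefs[1L, ]),
            class = "linear_baseline")
}

#' @export
predict.linear_baseline <- function(object, windows, ...) {
  if (is.vector(windows)) windows <- matrix(windows, nrow = 1L)
  sweep(windows %*% object$m, 2L, object$b, `+`)
}
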