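# Model assembly: layout conformance, channel scaling, head contracts, and
# the least-squares baseline.

test_that("the hybrid ResNet-LSTM matches its reference layout", {
  spec <- model_spec("resnet_lstm", "ppg", "direct_sbp_dbp",
                     window_len = 256L)
  s <- model_summary(build_model(spec))
  expect_identical(s$n_conv, 12L)
  expect_identical(s$n_pool, 5L)
  expect_identical(s$n_lstm, 1L)
  expect_identical(s$n_fc, 1L)
  expect_identical(s$dropout_rates, 0.25)
  expect_identical(s$kernel_sizes, 3L)
  expect_identical(s$pool_windows, 2L)
})

test_that("dropout rate propagates to every block", {
  spec <- model_spec("resnet_lstm", "ppg", "direct_sbp_dbp",
                     window_len = 256L, dropout_rate = 0.4)
  s <- model_summary(build_model(spec))
  expect_identical(s$n_dropout, 5L)
  expect_identical(s$dropout_rates, 0.4)
})

test_that("two-channel input doubles the first-layer fan-in for every family", {
  for (fam in c("fully_connected", "lstm", "wavenet", "wavenet_lstm",
                "resnet_lstm")) {
    s1 <- model_summary(build_model(
      model_spec(fam, "ppg", "direct_sbp_dbp", window_len = 64L,
                 hidden_size = 4L, depth = 3L)))
    s2 <- model_summary(build_model(
      model_spec(fam, "ppg_ecg", "direct_sbp_dbp", window_len = 64L,
                 hidden_size = 4L, depth = 3L)))
    expect_identical(s2$first_layer_fan_in, 2L * s1$first_layer_fan_in)
  }
})

test_that("heads emit the contracted output shapes", {
  set.seed(31)
  X <- matrix(rnorm(3 * 64), 3, 64)
  for (fam in c("fully_connected", "lstm", "wavenet", "wavenet_lstm",
                "resnet_lstm")) {
    md <- build_model(model_spec(fam, "ppg", "direct_sbp_dbp",
                                 window_len = 64L, hidden_size = 4L,
                                 depth = 3L))
    expect_identical(dim(predict(md, X)), c(3L, 2L))
    mw <- build_model(model_spec(fam, "ppg", "entire_waveform",
                                 window_len = 64L, hidden_size = 4L,
                                 depth = 3L))
    expect_identical(dim(predict(mw, X)), c(3L, 64L))
    mc <- build_model(model_spec(fam, "ppg", "stage_classifier",
                                 window_len = 64L, hidden_size = 4L,
                                 depth = 3L))
    probs <- predict(mc, X)
    expect_identical(dim(probs), c(3L, 4L))
    expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
    expect_true(all(probs >= 0))
  }
  expect_error(predict(md, matrix(rnorm(10), 1)), class = "pg_shape_error")
})

test_that("a zero-initialised direct head predicts its bias", {
  spec <- model_spec("fully_connected", "ppg", "direct_sbp_dbp",
                     window_len = 32L, hidden_size = 4L, depth = 1L)
  m <- build_model(spec, seed = 2)
  no <- length(m$net)
  m$net[[no]]$W[] <- 0
  m$net[[no]]$b <- c(7, 3)
  p <- predict(m, matrix(rnorm(64), 2, 32))
  expect_equal(unname(p), matrix(c(7, 7, 3, 3), 2), tolerance = 1e-12)
})

test_that("the hybrid has more parameters than the plain LSTM at equal width", {
  sl <- model_summary(build_model(
    model_spec("lstm", "ppg", "direct_sbp_dbp", window_len = 128L,
               hidden_size = 8L)))
  sr <- model_summary(build_model(
    model_spec("resnet_lstm", "ppg", "direct_sbp_dbp", window_len = 128L,
               hidden_size = 8L)))
  expect_gt(sr$n_parameters, sl$n_parameters)
})

test_that("wavenet dilations double per layer giving exponential receptive field", {
  spec <- model_spec("wavenet", "ppg", "direct_sbp_dbp", window_len = 128L,
                     hidden_size = 4L, depth = 6L, kernel_size = 2L)
  m <- build_model(spec)
  dils <- integer()
  pulseguard:::walk_layers(m$net, function(l) {
    if (l$type == "conv1d" && l$k > 1L) dils <<- c(dils, l$dilation)
  })
  expect_identical(dils, as.integer(2^(0:5)))
  # receptive field of the stack: 1 + sum((k-1) * d) = 2^depth for k = 2
  expect_identical(1L + sum((2L - 1L) * dils), 64L)
})

test_that("model construction is deterministic in (spec, seed)", {
  spec <- model_spec("resnet_lstm", "ppg_ecg", "direct_sbp_dbp",
                     window_len = 64L, hidden_size = 4L)
  expect_identical(build_model(spec, 9)$net, build_model(spec, 9)$net)
  expect_false(identical(build_model(spec, 9)$net, build_model(spec, 10)$net))
})

test_that("fit_linear_baseline recovers exact linear relationships", {
  # two points determine the line y = 2x + 1
  fit <- fit_linear_baseline(c(0, 1), c(1, 3))
  expect_equal(as.numeric(fit$m), 2, tolerance = 1e-12)
  expect_equal(as.numeric(fit$b), 1, tolerance = 1e-12)
  # constant targets: zero slope, intercept c
  set.seed(32)
  X <- matrix(rnorm(40), 20, 2)
  fit <- fit_linear_baseline(X, rep(5, 20))
  expect_equal(as.numeric(fit$m), c(0, 0), tolerance = 1e-9)
  expect_equal(as.numeric(fit$b), 5, tolerance = 1e-9)
  # residuals orthogonal to inputs (normal equations)
  y <- rnorm(20)
  fit <- fit_linear_baseline(X, y)
  res <- y - as.numeric(predict(fit, X))
  expect_lt(max(abs(crossprod(cbind(1, X), res))), 1e-8)
  # rank-deficient design warns and still predicts
  Xc <- cbind(X[, 1], X[, 1])
  expect_warning(fitc <- fit_linear_baseline(Xc, y), "rank-deficient")
  expect_length(predict(fitc, Xc), 20)
})

test_that("the model zoo resolves long display labels", {
  expect_identical(resolve_family("ResNet + Long Short-Term Memory"),
                   "resnet_lstm")
  expect_identical(resolve_family("Fully connected"), "fully_connected")
  expect_identical(resolve_family("wavenet"), "wavenet")
  spec <- model_spec("Long Short-Term Memory", "ppg", "direct_sbp_dbp",
                     window_len = 64L)
  expect_identical(spec$family, "lstm")
  expect_error(resolve_family("Perceptron"), class = "pg_config_error")
})
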