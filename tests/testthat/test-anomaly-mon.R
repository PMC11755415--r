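# Model-of-Normality detector: embedding mean, Euclidean scoring, the six
# working-point threshold rules, and detection behaviour on synthetic
# embeddings.

test_that("build_mon averages embeddings elementwise", {
  v <- c(1.5, -2, 7)
  mon <- build_mon(list(v, v, v))
  expect_equal(mon$mon, v)
  expect_identical(mon$n_normals, 3L)
  expect_equal(build_mon(list(c(0, 2), c(2, 0)))$mon, c(1, 1))
  set.seed(61)
  M <- matrix(rnorm(50 * 7), 50, 7)
  expect_equal(build_mon(M)$mon, oracle_colmean(M), tolerance = 1e-12)
  expect_error(build_mon(list()), class = "pg_empty_normals_error")
  expect_error(build_mon(list(c(1, 2), c(1, 2, 3))),
               class = "pg_shape_error")
})

test_that("anomaly_score is the Euclidean distance and a metric", {
  mon <- build_mon(list(c(0, 0)))
  expect_equal(anomaly_score(mon, c(0, 0)), 0)
  expect_equal(anomaly_score(mon, c(3, 4)), 5)
  set.seed(62)
  for (i in 1:30) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    expect_equal(anomaly_score(a, b), oracle_euclid(a, b), tolerance = 1e-10)
    expect_equal(anomaly_score(a, b), anomaly_score(b, a))
    expect_gte(anomaly_score(a, b), 0)
    # triangle inequality
    expect_lte(anomaly_score(a, c),
               anomaly_score(a, b) + anomaly_score(b, c) + 1e-12)
  }
  expect_error(anomaly_score(c(1, 2), c(1, 2, 3)), class = "pg_shape_error")
})

test_that("threshold rules follow their formulas with population std", {
  thr <- function(rule, K1, K2 = K1) compute_threshold(K1, K2, rule)$value
  expect_equal(thr("T1", c(0, 0, 0)), 0)
  expect_equal(thr("T2", c(0, 0, 0)), 0)
  expect_equal(thr("T3", c(0, 0, 0)), 0)
  K <- c(1, 2, 3)                 # mean 2, population std sqrt(2/3)
  expect_equal(thr("T1", K), 3)
  expect_equal(thr("T2", K), 3 - sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(thr("T2", K), 2.183503, tolerance = 1e-6)
  expect_equal(thr("T3", K), 2 + sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(thr("T3", K), 2.816497, tolerance = 1e-6)
  # K2-based rules mirror the K1 rules on the mean-pooled vector
  K2 <- c(4, 6)
  expect_equal(thr("T4", K, K2), 6)
  expect_equal(thr("T5", K, K2), 6 - 1)
  expect_equal(thr("T6", K, K2), 5 + 1)
  expect_error(compute_threshold(numeric(), numeric(), "T1"),
               class = "pg_calibration_error")
})

test_that("threshold orderings hold on random calibration vectors", {
  set.seed(63)
  ok12 <- ok45 <- ok3 <- ok31 <- logical(1000)
  for (i in 1:1000) {
    K <- stats::rlnorm(sample(3:40, 1))
    t <- vapply(c("T1", "T2", "T3", "T4", "T5"),
                function(r) compute_threshold(K, K, r)$value, 1.0)
    psd <- sqrt(mean((K - mean(K))^2))
    ok12[i] <- t["T2"] <= t["T1"]
    ok45[i] <- t["T5"] <= t["T4"]
    ok3[i] <- t["T3"] >= mean(K)
    ok31[i] <- max(K) < mean(K) + psd || t["T3"] <= t["T1"]
  }
  expect_true(all(ok12))
  expect_true(all(ok45))
  expect_true(all(ok3))
  expect_true(all(ok31))
})

test_that("classification is strict: scores at the threshold are normal", {
  thr <- compute_threshold(c(1, 2, 3), rule = "T1")   # value 3
  expect_identical(classify_anomaly(5, thr), "anomaly")
  expect_identical(classify_anomaly(3, thr), "normal")
  expect_identical(classify_anomaly(0, compute_threshold(0, rule = "T1")),
                   "normal")
})

test_that("mon_detect composes the pipeline with a held-out calibration split", {
  # identical deterministic inputs: score 0, normal under every rule
  ident <- function(x) matrix(x, ncol = 1)
  normals <- replicate(10, c(1, 2, 3), simplify = FALSE)
  for (rule in c("T1", "T3", "T4", "T6")) {
    res <- mon_detect(ident, normals, list(c(1, 2, 3)), rule = rule)
    expect_equal(res$decisions$score, 0)
    expect_identical(res$decisions$label, "normal")
  }
  # a mean-shifted test of norm 10 against a tight calibration is anomalous
  set.seed(64)
  normals <- lapply(1:40, function(i) rnorm(8, sd = 0.1))
  shift <- rep(10 / sqrt(8), 8)
  res <- mon_detect(ident, normals, list(shift), rule = "T1")
  expect_lt(res$threshold$value, 5)
  expect_identical(res$decisions$label, "anomaly")
  expect_error(mon_detect(ident, normals[1], list(shift)),
               class = "pg_calibration_error")
})

test_that("detection rate is monotone in the anomaly shift for every rule", {
  set.seed(65)
  d <- 8L
  extractor <- function(x) matrix(x, ncol = 1)
  normals <- lapply(1:200, function(i) rnorm(d))
  tpr <- sapply(c(0, 1, 2, 5), function(shift) {
    tests <- lapply(1:500, function(i) rnorm(d) + shift)
    sapply(THRESHOLD_RULES <- c("T1", "T2", "T3", "T4", "T5", "T6"),
           function(rule) {
      res <- mon_detect(extractor, normals, tests, rule = rule)
      mean(res$decisions$label == "anomaly")
    })
  })
  for (r in seq_len(nrow(tpr))) {
    expect_true(all(diff(tpr[r, ]) >= -1e-12))
  }
  # large shifts are always caught
  expect_true(all(tpr[, 4] > 0.95))
})

test_that("T1 is more conservative than T3 on held-out normals", {
  set.seed(66)
  d <- 8L
  extractor <- function(x) matrix(x, ncol = 1)
  normals <- lapply(1:200, function(i) rnorm(d))
  held_out <- lapply(1:500, function(i) rnorm(d))
  fp <- sapply(c("T1", "T3"), function(rule) {
    res <- mon_detect(extractor, normals, held_out, rule = rule)
    mean(res$decisions$label == "anomaly")
  })
  expect_lte(fp["T1"], fp["T3"])
})

test_that("the bundled random-projection extractor is seeded and pools both ways", {
  ex1 <- random_projection_extractor(10, d = 4, m = 3, seed = 9)
  ex2 <- random_projection_extractor(10, d = 4, m = 3, seed = 9)
  x <- rnorm(10)
  expect_identical(ex1(x), ex2(x))
  fmap <- ex1(x)
  expect_identical(dim(fmap), c(4L, 3L))
  expect_equal(pulseguard:::pool_feature_map(fmap, "max"),
               apply(fmap, 1, max))
  expect_equal(pulseguard:::pool_feature_map(fmap, "mean"), rowMeans(fmap))
  expect_error(ex1(rnorm(3)), class = "pg_shape_error")
})
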