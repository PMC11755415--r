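# Model-of-Normality (MoN) anomaly detection: average the feature embeddings
# of N normal samples, score test embeddings by Euclidean distance to that
# mean, and set the working-point threshold by one of six rules over
# calibration score vectors (max / max - std / mean + std of the max-pooled or
# mean-pooled score vector). A sample is an anomaly iff its score strictly
# exceeds the threshold.

#' Feature vector with provenance
#'
#' @param values Finite numeric vector.
#' @param source_id Character identifier of the originating sample.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(values, source_id = "") {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    pg_stop("pg_shape_error", "`values` must be a non-empty finite vector")
  }
  structure(list(values = as.numeric(values),
                 source_id = as.character(source_id)),
            class = "feature_vector")
}

as_embedding_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "feature_vector")) return(matrix(x$values, nrow = 1L))
  if (is.list(x)) {
    vals <- lapply(x, function(v) {
      if (inherits(v, "feature_vector")) v$values else as.numeric(v)
    })
    d <- unique(vapply(vals, length, 1L))
    if (length(d) != 1L) {
      pg_stop("pg_shape_error", "embeddings have mixed dimensionality")
    }
    return(do.call(rbind, vals))
  }
  if (is.numeric(x)) return(matrix(x, nrow = 1L))
  pg_stop("pg_shape_error", "cannot interpret embeddings input")
}

#' Build a Model of Normality
#'
#' The MoN is the elementwise arithmetic mean of the N normal embeddings; by
#' contract those embeddings are used only for MoN construction and are kept
#' out of any evaluation set.
#'
#' @param normals A matrix (rows = embeddings), a list of numeric vectors, or
#'   a list of [feature_vector()] objects.
#' @param class_label Optional label of the data class this MoN represents
#'   (one MoN is built per class).
#' @return An object of class `mon_model` with fields `mon`, `n_normals`,
#'   `class_label`.
#' @export
build_mon <- function(normals, class_label = "normal") {
  if ((is.list(normals) && length(normals) == 0L) ||
      (is.matrix(normals) && nrow(normals) == 0L)) {
    pg_stop("pg_empty_normals_error",
            "at least one normal embedding is required")
  }
  M <- as_embedding_matrix(normals)
  structure(
    list(mon = colMeans(M), n_normals = nrow(M),
         class_label = as.character(class_label)),
    class = "mon_model"
  )
}

#' Euclidean anomaly score
#'
#' `sqrt(sum_i (mon_i - test_i)^2)` — the distance between the MoN and a test
#' embedding in feature space.
#'
#' @param mon A `mon_model` (or plain numeric vector).
#' @param test A numeric vector or [feature_vector()] of the same
#'   dimensionality.
#' @return Non-negative scalar distance.
#' @export
anomaly_score <- function(mon, test) {
  m <- if (inherits(mon, "mon_model")) mon$mon else as.numeric(mon)
  v <- if (inherits(test, "feature_vector")) test$values else as.numeric(test)
  if (length(m) != length(v)) {
    pg_stop("pg_shape_error",
            "embedding dimensionality %d does not match MoN dimensionality %d",
            length(v), length(m))
  }
  sqrt(sum((m - v)^2))
}

THRESHOLD_RULES <- c("T1", "T2", "T3", "T4", "T5", "T6")

# population standard deviation (divide by n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Working-point threshold from calibration score vectors
#'
#' The six rules operate on two calibration score vectors: `K1`, scores of
#' held-out normal samples under max-pooled embeddings, and `K2`, the same
#' under mean-pooled embeddings.
#' `T1 = max(K1)`, `T2 = max(K1) - std(K1)`, `T3 = mean(K1) + std(K1)`,
#' `T4 = max(K2)`, `T5 = max(K2) - std(K2)`, `T6 = mean(K2) + std(K2)`,
#' where `std` is the population standard deviation.
#'
#' @param K1,K2 Numeric calibration score vectors (the one the rule uses must
#'   be non-empty).
#' @param rule One of `"T1"` .. `"T6"`.
#' @return An object of class `threshold_spec` with the rule, its `value`,
#'   and the stored calibration vectors.
#' @export
compute_threshold <- function(K1, K2 = numeric(), rule = THRESHOLD_RULES) {
  rule <- match.arg(rule)
  K <- if (rule %in% c("T1", "T2", "T3")) K1 else K2
  if (length(K) == 0L || any(!is.finite(K))) {
    pg_stop("pg_calibration_error",
            "calibration vector for rule %s is empty or non-finite", rule)
  }
  value <- switch(rule,
                  T1 = max(K),
                  T2 = max(K) - pop_sd(K),
                  T3 = mean(K) + pop_sd(K),
                  T4 = max(K),
                  T5 = max(K) - pop_sd(K),
                  T6 = mean(K) + pop_sd(K))
  structure(list(rule = rule, value = value, K1 = K1, K2 = K2),
            class = "threshold_spec")
}

#' Classify a score against a working-point threshold
#'
#' Anomalous iff the score strictly exceeds the threshold value; a score
#' exactly at the threshold is normal.
#'
#' @param score Finite numeric score (scalar or vector).
#' @param threshold A `threshold_spec` (or plain numeric threshold value).
#' @return Character vector of `"anomaly"` / `"normal"`.
#' @export
classify_anomaly <- function(score, threshold) {
  thr <- if (inherits(threshold, "threshold_spec")) threshold$value
         else as.numeric(threshold)
  if (any(!is.finite(score))) {
    pg_stop("pg_config_error", "scores must be finite")
  }
  ifelse(score > thr, "anomaly", "normal")
}

#' Seeded random-projection embedding extractor
#'
#' Returns a callable mapping a numeric input vector to a `d x m` feature map
#' (`tanh` of `m` random linear projections per feature dimension), from which
#' max-pooled and mean-pooled embeddings are derived. A lightweight stand-in
#' extractor so the detector runs without any pretrained network; any callable
#' with the same signature can replace it.
#'
#' @param input_dim Length of the raw input vectors.
#' @param d Embedding dimensionality.
#' @param m Number of feature-map columns pooled over.
#' @param seed Integer seed fixing the projection.
#' @return A function `input -> d x m matrix`.
#' @export
random_projection_extractor <- function(input_dim, d = 16L, m = 8L,
                                        seed = 1L) {
  check_scalar_number(input_dim, "input_dim", lower = 1, integer = TRUE)
  check_scalar_number(d, "d", lower = 1, integer = TRUE)
  check_scalar_number(m, "m", lower = 1, integer = TRUE)
  P <- with_seed(seed, array(stats::rnorm(d * m * input_dim) /
                               sqrt(input_dim), c(d * m, input_dim)))
  function(x) {
    x <- as.numeric(x)
    if (length(x) != input_dim) {
      pg_stop("pg_shape_error", "extractor expects input of length %d",
              input_dim)
    }
    matrix(tanh(P %*% x), nrow = d)
  }
}

pool_feature_map <- function(fmap, pooling = c("max", "mean")) {
  pooling <- match.arg(pooling)
  if (!is.matrix(fmap)) fmap <- matrix(fmap, nrow = length(fmap))
  if (pooling == "max") apply(fmap, 1L, max) else rowMeans(fmap)
}

#' End-to-end MoN anomaly detection
#'
#' Splits the normal inputs into a MoN-building set and a disjoint threshold
#' calibration set, builds one MoN per pooling variant, scores the
#' calibration set to obtain `K1` (max pooling) and `K2` (mean pooling),
#' computes the requested working-point threshold, then scores and classifies
#' each test input using the pooling variant the rule refers to.
#'
#' @param extractor A callable mapping a raw input to a feature map (matrix)
#'   or feature vector; see [random_projection_extractor()].
#' @param normals List (or rows of a matrix) of anomaly-free raw inputs.
#' @param tests List (or rows of a matrix) of raw inputs to classify.
#' @param rule Threshold rule, `"T1"` .. `"T6"`.
#' @param calibration_fraction Fraction of normals held out for threshold
#'   calibration (at least one sample each for building and calibration).
#' @return A list with `decisions` (data frame: id, score, rule, threshold,
#'   label), the `mon_model`, the `threshold_spec` and `n_normals`.
#' @export
mon_detect <- function(extractor, normals, tests, rule = "T3",
                       calibration_fraction = 0.5) {
  stopifnot(is.function(extractor))
  if (is.matrix(normals)) {
    normals <- lapply(seq_len(nrow(normals)), function(i) normals[i, ])
  }
  if (is.matrix(tests)) {
    tests <- lapply(seq_len(nrow(tests)), function(i) tests[i, ])
  }
  n <- length(normals)
  n_cal <- max(1L, floor(calibration_fraction * n))
  n_fit <- n - n_cal
  if (n_fit < 1L || n_cal < 1L) {
    pg_stop("pg_calibration_error",
            "need at least 2 normal samples (MoN building + calibration)")
  }
  fit_set <- normals[seq_len(n_fit)]
  cal_set <- normals[n_fit + seq_len(n_cal)]
  pooling <- if (rule %in% c("T1", "T2", "T3")) "max" else "mean"

  embed <- function(xs, p) {
    do.call(rbind, lapply(xs, function(x) pool_feature_map(extractor(x), p)))
  }
  mon_max <- build_mon(embed(fit_set, "max"))
  mon_mean <- build_mon(embed(fit_set, "mean"))
  K1 <- apply(embed(cal_set, "max"), 1L, anomaly_score, mon = mon_max)
  K2 <- apply(embed(cal_set, "mean"), 1L, anomaly_score, mon = mon_mean)
  thr <- compute_threshold(K1, K2, rule = rule)

  mon_used <- if (pooling == "max") mon_max else mon_mean
  scores <- apply(embed(tests, pooling), 1L, anomaly_score, mon = mon_used)
  decisions <- data.frame(
    id = if (!is.null(names(tests))) names(tests)
         else sprintf("test%03d", seq_along(tests)),
    score = scores, rule = rule, threshold = thr$value,
    label = classify_anomaly(scores, thr),
    stringsAsFactors = FALSE)
  list(decisions = decisions, mon = mon_used, threshold = thr,
       n_normals = n_fit)
}
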