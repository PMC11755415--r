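# Heart-rate analytics over wearable CSV exports: time-in-zone distributions,
# distribution summaries with Tukey outlier flagging, and cross-signal
# Pearson correlation matrices.

#' Heart-rate time series
#'
#' @param timestamps Strictly increasing numeric timestamps (seconds) or
#'   POSIXct times.
#' @param bpm Positive heart-rate values, one per timestamp.
#' @param subject_id Character identifier.
#' @return An object of class `heart_rate_series`.
#' @export
heart_rate_series <- function(timestamps, bpm, subject_id = "") {
  if (inherits(timestamps, "POSIXct")) timestamps <- as.numeric(timestamps)
  if (length(timestamps) != length(bpm)) {
    pg_stop("pg_shape_error", "timestamps and bpm must have equal length")
  }
  if (length(timestamps) && any(diff(timestamps) <= 0)) {
    pg_stop("pg_config_error", "timestamps must be strictly increasing")
  }
  if (any(bpm <= 0)) {
    pg_stop("pg_config_error", "bpm values must be positive")
  }
  structure(list(timestamps = as.numeric(timestamps), bpm = as.numeric(bpm),
                 subject_id = as.character(subject_id)),
            class = "heart_rate_series")
}

#' Heart-rate zone definition
#'
#' Ordered intensity bands partitioning the positive bpm axis. The defaults
#' follow the conventional percent-of-maximum-heart-rate bands (max HR
#' `220 - age`): Out of Range below 50%, Fat Burn 50-69%, Cardio 70-84%,
#' Peak 85% and above. Device vendors use their own boundaries, so these are
#' fully overridable.
#'
#' @param boundaries Increasing numeric vector of the three inner bpm cut
#'   points (Fat Burn, Cardio and Peak lower bounds).
#' @param labels Zone names, one more than `boundaries`.
#' @param age Used only to derive default boundaries when none are given.
#' @return An object of class `zone_definition`.
#' @export
zone_definition <- function(boundaries = NULL,
                            labels = c("Out of Range", "Fat Burn",
                                       "Cardio", "Peak"),
                            age = 40) {
  if (is.null(boundaries)) {
    max_hr <- 220 - age
    boundaries <- max_hr * c(0.50, 0.70, 0.85)
  }
  if (any(diff(boundaries) <= 0)) {
    pg_stop("pg_config_error", "zone boundaries must be strictly increasing")
  }
  if (length(labels) != length(boundaries) + 1L) {
    pg_stop("pg_config_error",
            "need exactly one more label than boundary (got %d labels, %d boundaries)",
            length(labels), length(boundaries))
  }
  structure(list(boundaries = as.numeric(boundaries),
                 labels = as.character(labels)),
            class = "zone_definition")
}

zone_of <- function(bpm, zones) {
  zones$labels[findInterval(bpm, zones$boundaries) + 1L]
}

#' Minutes spent per heart-rate zone
#'
#' Each inter-sample interval is attributed to the zone of its leading sample,
#' so per-zone minutes sum exactly to the series duration
#' `(t_last - t_first)`.
#'
#' @param series A [heart_rate_series()] with at least 2 samples.
#' @param zones A [zone_definition()].
#' @return Named numeric vector of minutes, one entry per zone label (zeros
#'   included), in zone order.
#' @export
zone_distribution <- function(series, zones = zone_definition()) {
  stopifnot(inherits(series, "heart_rate_series"),
            inherits(zones, "zone_definition"))
  n <- length(series$bpm)
  if (n < 2L) {
    pg_stop("pg_insufficient_data_error",
            "need at least 2 samples to form intervals")
  }
  mins <- diff(series$timestamps) / 60
  lead_zone <- zone_of(series$bpm[-n], zones)
  out <- stats::setNames(numeric(length(zones$labels)), zones$labels)
  agg <- tapply(mins, factor(lead_zone, levels = zones$labels), sum)
  out[names(agg)] <- ifelse(is.na(agg), 0, agg)
  out
}

#' Distribution summary with Tukey outlier flagging
#'
#' Quartiles use linear interpolation (type-7 quantiles); outliers are values
#' outside the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param series A [heart_rate_series()] with at least 4 samples.
#' @return List with `median`, `q1`, `q3`, `iqr` and the `outliers` values
#'   (order-independent set).
#' @export
summary_stats <- function(series) {
  stopifnot(inherits(series, "heart_rate_series"))
  x <- series$bpm
  if (length(x) < 4L) {
    pg_stop("pg_insufficient_data_error",
            "need at least 4 samples for quartiles")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       outliers = sort(x[x < lo | x > hi]))
}

#' Pearson correlation matrix of physiological channels
#'
#' @param channels Named list (or data frame) of equal-length numeric
#'   sequences, each with at least 3 samples and non-zero variance.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(channels) {
  if (is.data.frame(channels)) channels <- as.list(channels)
  if (!is.list(channels) || length(channels) < 1L) {
    pg_stop("pg_shape_error", "`channels` must be a non-empty named list")
  }
  lens <- vapply(channels, length, 1L)
  if (length(unique(lens)) != 1L || lens[1] < 3L) {
    pg_stop("pg_shape_error",
            "all channels must share one length of at least 3")
  }
  sds <- vapply(channels, stats::sd, 1.0)
  if (any(sds == 0)) {
    pg_stop("pg_undefined_correlation_error",
            "constant channel(s): %s",
            paste(names(channels)[sds == 0], collapse = ", "))
  }
  stats::cor(do.call(cbind, channels))
}

#' Read a wearable heart-rate CSV export
#'
#' Accepts the common deposited layout: a `timestamp` column (ISO date-time or
#' numeric seconds) and a heart-rate value column (named `value`, `bpm`,
#' `heart_rate` or the second column). Rows that fail to parse are dropped.
#'
#' @param path CSV file path.
#' @param subject_id Identifier attached to the series.
#' @return A [heart_rate_series()].
#' @export
read_heart_rate_csv <- function(path, subject_id = basename(path)) {
  header <- tolower(names(utils::read.csv(path, nrows = 1)))
  if (any(grepl("zone|label", header)) && any(grepl("minute", header))) {
    pg_stop("pg_config_error",
            "%s looks like a zone summary; use read_zone_summary_csv()", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    pg_stop("pg_config_error", "expected at least timestamp + value columns")
  }
  nms <- tolower(names(df))
  tcol <- which(nms %in% c("timestamp", "time", "datetime", "date"))[1]
  vcol <- which(nms %in% c("value", "bpm", "heart_rate", "heartrate"))[1]
  if (is.na(tcol)) tcol <- 1L
  if (is.na(vcol)) vcol <- setdiff(seq_len(ncol(df)), tcol)[1]
  tv <- df[[tcol]]
  if (is.character(tv)) {
    parsed <- as.POSIXct(tv, tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                        "%m/%d/%y %H:%M:%S", "%Y-%m-%d %H:%M"))
    tv <- as.numeric(parsed)
  }
  bpm <- suppressWarnings(as.numeric(df[[vcol]]))
  ok <- is.finite(tv) & is.finite(bpm) & bpm > 0
  heart_rate_series(tv[ok], bpm[ok], subject_id = subject_id)
}

#' Read a per-zone summary CSV (zone label + minutes rows)
#'
#' Some wearable exports summarise a day as one row per heart-rate zone with
#' the minutes spent in it, rather than a sample-level series.
#'
#' @param path CSV with a zone/label column and a minutes column.
#' @return Named numeric vector of minutes per zone, in file order.
#' @export
read_zone_summary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nms <- tolower(names(df))
  zcol <- which(grepl("zone|label|name", nms))[1]
  mcol <- which(grepl("minute|duration", nms))[1]
  if (is.na(zcol) || is.na(mcol)) {
    pg_stop("pg_config_error",
            "expected a zone label column and a minutes column in %s", path)
  }
  mins <- suppressWarnings(as.numeric(df[[mcol]]))
  if (any(!is.finite(mins))) {
    pg_stop("pg_config_error", "non-numeric minutes in %s", path)
  }
  stats::setNames(mins, as.character(df[[zcol]]))
}
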