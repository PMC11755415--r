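# Record serialisation: CSV (waveforms) + JSON sidecar (sampling rate, beat
# annotations), model checkpoints as RDS, and a minimal WFDB reader for
# single-segment format-16 records with PLETH/ECG/ABP (or ART) channels.

#' Write a signal record to CSV (+ JSON sidecar)
#'
#' The CSV holds columns `t, ppg, ecg, abp`; beat onsets, per-beat SBP/DBP and
#' the sampling rate go to `<path>.meta.json` so the record round-trips
#' exactly.
#'
#' @param record A `signal_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  n <- length(record$abp)
  df <- data.frame(t = (seq_len(n) - 1) / record$fs,
                   ppg = record$ppg, ecg = record$ecg, abp = record$abp)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = record$subject_id, fs = record$fs,
               beat_onsets = record$beat_onsets,
               sbp_per_beat = record$sbp_per_beat,
               dbp_per_beat = record$dbp_per_beat)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal record written by [write_record_csv()]
#'
#' @param path CSV path (its `.meta.json` sidecar must sit beside it).
#' @return A `signal_record`.
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    pg_stop("pg_config_error", "missing sidecar %s", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  signal_record(meta$subject_id, as.numeric(meta$fs), df$ppg, df$ecg, df$abp,
                meta$beat_onsets, meta$sbp_per_beat, meta$dbp_per_beat)
}

#' Save / load a model checkpoint
#'
#' @param model A `bp_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `bp_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "bp_model")) {
    pg_stop("pg_config_error", "%s is not a bp_model checkpoint", path)
  }
  m
}

# ---- minimal WFDB support ---------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- list(name = top[1], n_sig = as.integer(top[2]),
              fs = if (length(top) >= 3) as.numeric(top[3]) else 250,
              n_samp = if (length(top) >= 4) as.integer(top[4]) else NA)
  # signal line: file format gain(baseline)/units [adc fields ...] description
  rec$signals <- lapply(lines[1 + seq_len(rec$n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain <- 200; baseline <- 0
    if (length(f) >= 3) {
      m <- regmatches(f[3], regexec("^([-0-9.]+)(\\(([-0-9]+)\\))?", f[3]))[[1]]
      if (length(m) >= 2 && nzchar(m[2])) gain <- as.numeric(m[2])
      if (length(m) >= 4 && nzchar(m[4])) baseline <- as.numeric(m[4])
    }
    list(file = f[1], format = f[2],
         gain = if (is.finite(gain) && gain != 0) gain else 200,
         baseline = baseline, desc = f[length(f)])
  })
  rec
}

#' Read a WFDB record into a signal record
#'
#' Minimal reader for single-segment WFDB records in format 16 (16-bit
#' little-endian interleaved samples). Channels whose description contains
#' `PLETH`, `ECG` (or lead names `I`/`II`/`III`/`V`), and `ABP` or `ART` are
#' mapped to the ppg/ecg/abp slots; missing channels become zero traces. No
#' beat annotations are read, so `beat_onsets` and per-beat labels are empty
#' unless `detect_beats = TRUE`, in which case beats are segmented at local
#' ABP minima and labelled via [extract_sbp_dbp()].
#'
#' @param hea_path Path to the `.hea` header file.
#' @param detect_beats Segment beats from the ABP trace.
#' @return A `signal_record`.
#' @export
read_wfdb_record <- function(hea_path, detect_beats = FALSE) {
  hdr <- parse_wfdb_header(hea_path)
  if (any(vapply(hdr$signals, function(s) s$format, "") != "16")) {
    pg_stop("pg_config_error", "only WFDB format 16 is supported")
  }
  dat_path <- file.path(dirname(hea_path), hdr$signals[[1]]$file)
  raw_n <- file.info(dat_path)$size %/% 2L
  v <- readBin(dat_path, "integer", n = raw_n, size = 2L,
               signed = TRUE, endian = "little")
  n <- length(v) %/% hdr$n_sig
  m <- matrix(v[seq_len(n * hdr$n_sig)], nrow = hdr$n_sig)
  phys <- lapply(seq_len(hdr$n_sig), function(i) {
    s <- hdr$signals[[i]]
    (m[i, ] - s$baseline) / s$gain
  })
  descs <- toupper(vapply(hdr$signals, function(s) s$desc, ""))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, descs)
      if (length(hit)) return(phys[[hit[1]]])
    }
    numeric(n)
  }
  ppg <- pick("PLETH")
  ecg <- pick(c("ECG", "^II$", "^I$", "^III$", "^V$"))
  abp <- pick(c("ABP", "ART"))
  onsets <- integer(); sbp <- numeric(); dbp <- numeric()
  if (detect_beats && any(abp != 0)) {
    # beat onsets at local minima separated by at least 0.3 s
    w <- max(3L, round(0.3 * hdr$fs))
    cand <- which(vapply(seq_along(abp), function(i) {
      lo <- max(1L, i - w %/% 2L); hi <- min(length(abp), i + w %/% 2L)
      abp[i] == min(abp[lo:hi])
    }, TRUE))
    onsets <- cand[c(TRUE, diff(cand) > w)]
    if (length(onsets) >= 2L) {
      ex <- extract_sbp_dbp(abp, onsets)
      sbp <- ex$sbp; dbp <- ex$dbp
      onsets <- onsets[seq_along(sbp)]
      keep <- sbp > dbp
      onsets <- onsets[keep]; sbp <- sbp[keep]; dbp <- dbp[keep]
    } else {
      onsets <- integer()
    }
  }
  signal_record(hdr$name, hdr$fs, ppg, ecg, abp, onsets, sbp, dbp)
}
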