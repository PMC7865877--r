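# Waveform input/output: two-column CSV (time_s, amplitude_mV) and a minimal
# single-signal WFDB implementation (format 16: .hea header + little-endian
# 16-bit .dat, gain in ADU/mV).  No WFDB library exists for this R
# environment, so the subset needed for round-tripping package records is
# implemented here.

#' Write a record as CSV
#'
#' Two columns, `time_s,amplitude_mV`, with header.
#'
#' @param record an [ecg_record()].
#' @param path output file.
#' @export
write_ecg_csv <- function(record, path) {
  assert_record(record)
  t_s <- (seq_along(record$samples) - 1L) / record$sampling_rate
  utils::write.csv(data.frame(time_s = t_s, amplitude_mV = record$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a record from CSV
#'
#' Expects columns `time_s` and `amplitude_mV` (header required).  The
#' sampling rate is inferred from the time column; inputs not sampled at
#' `target_rate` are resampled to it with a note.
#'
#' @param path CSV file.
#' @param target_rate canonical rate, Hz.
#' @param record_id identifier for the returned record.
#' @export
read_ecg_csv <- function(path, target_rate = 125, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("CSV parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (nrow(df) < 2L) stop("CSV parse error: need at least 2 rows in ", path, call. = FALSE)
  if (!all(c("time_s", "amplitude_mV") %in% names(df))) {
    stop("CSV parse error: header must be time_s,amplitude_mV (", path, ")",
         call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("CSV parse error: time column must increase", call. = FALSE)
  if (max(dt) / min(dt) > 1.01) {
    stop("CSV parse error: non-uniform sampling interval", call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  fs_round <- round(fs, 6)
  rec <- ecg_record(df$amplitude_mV, sampling_rate = fs_round,
                    record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)))
  if (abs(fs_round - target_rate) > 1e-6) {
    message(sprintf("resampling %s from %g Hz to %g Hz", path, fs_round, target_rate))
    rec <- resample_record(rec, target_rate)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a record to a new rate
#'
#' Anti-alias low-pass (when downsampling) followed by linear interpolation
#' onto the new uniform grid.
#'
#' @param record an [ecg_record()].
#' @param new_rate target rate in Hz.
#' @export
resample_record <- function(record, new_rate) {
  fs <- record$sampling_rate
  x <- record$samples
  if (new_rate < fs) {
    lp <- butter_coeffs(4, 0.45 * new_rate, fs, "low")
    x <- filtfilt_zero_phase(lp$b, lp$a, x, min(length(x) - 1L, 200L))
  }
  t_old <- (seq_along(x) - 1L) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / new_rate)
  record$samples <- stats::approx(t_old, x, xout = t_new)$y
  record$sampling_rate <- new_rate
  record
}

#' Write a record as a WFDB pair
#'
#' Single-signal format-16 record: `<name>.hea` plus `<name>.dat`
#' (little-endian int16, `gain` ADU per mV).
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param name record name (defaults to the record id).
#' @param gain ADU per mV.
#' @export
write_wfdb <- function(record, dir, name = record$record_id, gain = 200) {
  assert_record(record)
  adu <- as.integer(pmin(32767, pmax(-32768, round(record$samples * gain))))
  cksum <- sum(adu) %% 65536L
  if (cksum > 32767L) cksum <- cksum - 65536L
  hea <- c(sprintf("%s 1 %g %d", name, record$sampling_rate, length(adu)),
           sprintf("%s.dat 16 %g 16 0 %d %d 0 %s", name, gain, adu[1], cksum,
                   record$lead_label))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  on.exit(close(con))
  writeBin(adu, con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Read a WFDB record pair
#'
#' Reads the single-signal format-16 subset written by [write_wfdb()].
#'
#' @param path path to the `.hea` file (or its basename without extension).
#' @param target_rate canonical rate; other rates are resampled with a note.
#' @export
read_wfdb <- function(path, target_rate = 125) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path, call. = FALSE)
  lines <- readLines(hea_path, warn = FALSE)
  if (length(lines) < 2L) stop("WFDB parse error: truncated header ", hea_path, call. = FALSE)
  h <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(h) < 4L) stop("WFDB parse error: bad record line in ", hea_path, call. = FALSE)
  name <- h[1]; fs <- as.numeric(h[3]); nsamp <- as.integer(h[4])
  s <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(s) < 3L || s[2] != "16") {
    stop("WFDB parse error: only single-signal format 16 supported (", hea_path, ")",
         call. = FALSE)
  }
  gain <- as.numeric(sub("\\(.*", "", s[3])) # "200" or "200(0)/mV"
  gain <- as.numeric(sub("/.*", "", sub("\\(.*", "", s[3])))
  if (!is.finite(gain) || gain <= 0) gain <- 200
  dat_path <- file.path(dirname(hea_path), s[1])
  if (!file.exists(dat_path)) stop("file not found: ", dat_path, call. = FALSE)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adu <- readBin(con, "integer", n = nsamp, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(adu) != nsamp) {
    stop("WFDB parse error: expected ", nsamp, " samples, read ", length(adu),
         call. = FALSE)
  }
  lead <- if (length(s) >= 9L) s[length(s)] else "I"
  rec <- ecg_record(adu / gain, sampling_rate = fs, record_id = name,
                    lead_label = lead)
  if (abs(fs - target_rate) > 1e-6) {
    message(sprintf("resampling %s from %g Hz to %g Hz", name, fs, target_rate))
    rec <- resample_record(rec, target_rate)
  }
  rec
}

#' Read a record, dispatching on format
#'
#' @param path `.csv` or `.hea` file (or WFDB basename).
#' @param format `"auto"`, `"csv"` or `"wfdb"`.
#' @param target_rate canonical sampling rate.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"),
                        target_rate = 125) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") read_ecg_csv(path, target_rate) else read_wfdb(path, target_rate)
}

#' Export wave annotations as JSON
#'
#' Sample indices are exported 0-based (the R API is 1-based).
#'
#' @param annotations a `wave_annotations` data.frame.
#' @param path optional output file.
#' @export
annotations_to_json <- function(annotations, path = NULL) {
  a <- as.data.frame(annotations)
  idx_cols <- setdiff(names(a), "beat_index")
  a[idx_cols] <- lapply(a[idx_cols], function(v) v - 1L)
  out <- list(schema_version = 1L,
              sampling_rate = attr(annotations, "sampling_rate"),
              index_base = 0L,
              beats = a)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
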