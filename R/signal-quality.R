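#' Filtering configuration for the cleaning chain
#'
#' Collects the parameters of the two cleaning chains and of the flat-line
#' (lead-off) detector.  Defaults follow the acquisition design this package
#' targets: a 50 Hz low-pass joined with a 60 Hz notch against high-frequency
#' noise, and a 0.67 Hz high-pass joined with a moving-average baseline
#' estimator against baseline wander.
#'
#' @param lowpass_cutoff low-pass -3 dB cutoff, Hz.
#' @param notch_freq notch centre frequency, Hz.  If at or above Nyquist for
#'   the record at hand, the notch stage is skipped with a warning.
#' @param highpass_cutoff high-pass cutoff, Hz.
#' @param moving_average_window baseline-estimator window, seconds.
#' @param lowpass_order,highpass_order Butterworth orders of the two stages.
#' @param notch_q quality factor of the notch.
#' @param flatline_std_threshold standard-deviation threshold (mV) below which
#'   a window counts as flat.
#' @param flatline_min_duration minimum flat stretch (s) that flags a record
#'   as empty.
#' @param baseline_first if `TRUE` (default) the baseline chain runs before
#'   the high-frequency chain in [clean_record()].
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(lowpass_cutoff = 50, notch_freq = 60,
                          highpass_cutoff = 0.67, moving_average_window = 1.0,
                          lowpass_order = 4, highpass_order = 2, notch_q = 30,
                          flatline_std_threshold = 0.01,
                          flatline_min_duration = 2.0,
                          baseline_first = TRUE) {
  if (highpass_cutoff <= 0 || lowpass_cutoff <= highpass_cutoff) {
    stop("need 0 < highpass_cutoff < lowpass_cutoff", call. = FALSE)
  }
  structure(list(lowpass_cutoff = lowpass_cutoff, notch_freq = notch_freq,
                 highpass_cutoff = highpass_cutoff,
                 moving_average_window = moving_average_window,
                 lowpass_order = lowpass_order, highpass_order = highpass_order,
                 notch_q = notch_q,
                 flatline_std_threshold = flatline_std_threshold,
                 flatline_min_duration = flatline_min_duration,
                 baseline_first = isTRUE(baseline_first)),
            class = "filter_config")
}

# settling length (samples) of the slowest stage involved; used for the
# too-short guard and the reflection pad
settle_samples <- function(cutoff_hz, sampling_rate, order) {
  max(3L * (as.integer(order) + 1L), as.integer(ceiling(sampling_rate / cutoff_hz)))
}

check_filter_input <- function(record, settle) {
  assert_record(record)
  if (length(record$samples) < 3L * settle) {
    stop(sprintf("record too short for filtering: %d samples, need >= %d",
                 length(record$samples), 3L * settle), call. = FALSE)
  }
  invisible(record)
}

#' Remove high-frequency noise
#'
#' Applies the joint 50 Hz low-pass + 60 Hz notch chain, forward-backward so
#' that filtering is zero phase and QRS peaks are not shifted.  When the notch
#' frequency is at or above Nyquist the notch stage is skipped with a warning
#' (the low-pass alone then defines the chain).
#'
#' @param record an [ecg_record()].
#' @param config a [filter_config()].
#' @return the filtered record, same length, with provenance flag
#'   `"hf_denoised"` added.
#' @export
remove_high_frequency_noise <- function(record, config = filter_config()) {
  fs <- record$sampling_rate
  if (config$lowpass_cutoff >= fs / 2) {
    stop("lowpass cutoff at or above Nyquist", call. = FALSE)
  }
  settle <- settle_samples(config$lowpass_cutoff, fs, config$lowpass_order)
  check_filter_input(record, settle)
  lp <- butter_coeffs(config$lowpass_order, config$lowpass_cutoff, fs, "low")
  x <- filtfilt_zero_phase(lp$b, lp$a, record$samples, settle)
  if (config$notch_freq < fs / 2) {
    nt <- notch_coeffs(config$notch_freq, fs, config$notch_q)
    x <- filtfilt_zero_phase(nt$b, nt$a, x, settle)
  } else {
    warning(sprintf("notch frequency %g Hz >= Nyquist (%g Hz); notch stage skipped",
                    config$notch_freq, fs / 2))
  }
  record$samples <- x
  add_flags(record, "hf_denoised")
}

#' Remove baseline wander
#'
#' Applies the 0.67 Hz high-pass (forward-backward, zero phase) and then
#' subtracts a centred moving-average estimate of any residual baseline.  The
#' moving-average window (default 1 s) is long relative to the QRS complex, so
#' QRS sharpness is preserved.
#'
#' @inheritParams remove_high_frequency_noise
#' @return the filtered record with flag `"baseline_removed"` added.
#' @export
remove_baseline_wander <- function(record, config = filter_config()) {
  fs <- record$sampling_rate
  settle <- settle_samples(config$highpass_cutoff, fs, config$highpass_order)
  check_filter_input(record, settle)
  hp <- butter_coeffs(config$highpass_order, config$highpass_cutoff, fs, "high")
  x <- filtfilt_zero_phase(hp$b, hp$a, record$samples, settle)
  baseline <- moving_average(x, round(config$moving_average_window * fs))
  record$samples <- x - baseline
  add_flags(record, "baseline_removed")
}

#' Detect an empty (lead-off) signal
#'
#' A record is empty when some contiguous stretch of at least
#' `flatline_min_duration` seconds has sample standard deviation below
#' `flatline_std_threshold` mV — the software analogue of the hardware
#' lead-drop detector.
#'
#' @inheritParams remove_high_frequency_noise
#' @return list with `empty` (logical), `intervals` (data.frame of flat
#'   stretches, `start_s`/`end_s`), and `record` (flagged with `"empty"` when
#'   detected).
#' @export
detect_empty_signal <- function(record, config = filter_config()) {
  assert_record(record)
  fs <- record$sampling_rate
  x <- record$samples
  n <- length(x)
  win <- max(2L, as.integer(round(config$flatline_min_duration * fs)))
  if (n < win) {
    return(list(empty = FALSE, intervals = data.frame(start_s = numeric(0), end_s = numeric(0)),
                record = record))
  }
  # rolling standard deviation over the minimum-duration window via cumsums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - win + 1L)
  s <- cs[i + win] - cs[i]
  s2 <- cs2[i + win] - cs2[i]
  v <- pmax(0, (s2 - s^2 / win) / (win - 1L))
  flat <- sqrt(v) < config$flatline_std_threshold
  if (!any(flat)) {
    return(list(empty = FALSE, intervals = data.frame(start_s = numeric(0), end_s = numeric(0)),
                record = record))
  }
  # merge flat window starts into maximal intervals (each window spans win samples)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  intervals <- data.frame(start_s = (starts[keep] - 1L) / fs,
                          end_s = (ends[keep] + win - 1L) / fs)
  list(empty = TRUE, intervals = intervals, record = add_flags(record, "empty"))
}

#' Full cleaning chain
#'
#' Runs baseline-wander removal and high-frequency denoising (order set by
#' `config$baseline_first`), then the empty-signal check; the result of the
#' check is recorded in the provenance flags.
#'
#' @inheritParams remove_high_frequency_noise
#' @return the cleaned record carrying flags `"baseline_removed"`,
#'   `"hf_denoised"` and possibly `"empty"`.
#' @export
clean_record <- function(record, config = filter_config()) {
  assert_record(record)
  if (config$baseline_first) {
    record <- remove_baseline_wander(record, config)
    record <- remove_high_frequency_noise(record, config)
  } else {
    record <- remove_high_frequency_noise(record, config)
    record <- remove_baseline_wander(record, config)
  }
  detect_empty_signal(record, config)$record
}
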