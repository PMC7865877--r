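#' Single-lead ECG recording
#'
#' `ecg_record()` builds the container used throughout the package: a numeric
#' vector of amplitudes in millivolts plus its sampling rate and a set of
#' provenance flags recording what processing has been applied.  Flags only
#' accumulate along the pipeline; no stage removes a flag set by an earlier
#' one.
#'
#' @param samples numeric vector of amplitudes (mV); must be finite and
#'   non-empty.
#' @param sampling_rate sampling frequency in Hz (default 125, the rate of the
#'   thumb-electrode acquisition hardware this package targets).
#' @param record_id opaque identifier string.
#' @param lead_label lead name; the acquisition is Lead-I equivalent.
#' @param provenance character vector of processing flags; one or more of
#'   `"raw"`, `"hf_denoised"`, `"baseline_removed"`, `"reversed_suspected"`,
#'   `"empty"`.
#' @return an object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 10, by = 1 / 125)))
#' rec
#' @export
ecg_record <- function(samples, sampling_rate = 125, record_id = "rec",
                       lead_label = "I", provenance = "raw") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ecg_record: samples must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("ecg_record: all samples must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("ecg_record: sampling_rate must be a single positive number", call. = FALSE)
  }
  known <- c("raw", "hf_denoised", "baseline_removed", "reversed_suspected", "empty")
  if (!all(provenance %in% known)) {
    stop("ecg_record: unknown provenance flag(s): ",
         paste(setdiff(provenance, known), collapse = ", "), call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         record_id = as.character(record_id), lead_label = as.character(lead_label),
         provenance = unique(provenance)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead_label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  cat("  provenance:", paste(x$provenance, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

is_ecg_record <- function(x) inherits(x, "ecg_record")

# add flags without ever dropping existing ones
add_flags <- function(record, flags) {
  record$provenance <- unique(c(record$provenance, flags))
  record
}

has_flag <- function(record, flag) flag %in% record$provenance

# duration in seconds
record_duration <- function(record) length(record$samples) / record$sampling_rate

assert_record <- function(record, what = "record") {
  if (!is_ecg_record(record)) stop(what, " must be an ecg_record", call. = FALSE)
  if (!all(is.finite(record$samples))) {
    stop("rejected input: non-finite samples in ", what, call. = FALSE)
  }
  invisible(record)
}
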