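# QRS detection (Pan-Tompkins style energy detector) and beat-level P/T
# delineation.  Sample indices are 1-based throughout the R API; exporters
# convert to 0-based indices (io.R).

#' Detect QRS complexes
#'
#' Energy-based detector in the Pan-Tompkins style: 5-15 Hz band-pass (zero
#' phase), derivative, squaring, 150 ms moving-window integration, adaptive
#' signal/noise thresholds with a 200 ms refractory period and a search-back
#' pass for long gaps.  Peak positions are refined to the extremum of the
#' cleaned signal, so reversed-polarity records are handled symmetrically.
#'
#' @param record a cleaned [ecg_record()] of at least 3 s.
#' @param min_rr_s refractory period in seconds (default 0.2).
#' @return integer vector of strictly increasing QRS peak sample indices
#'   (1-based).
#' @export
detect_qrs <- function(record, min_rr_s = 0.2) {
  assert_record(record)
  if (has_flag(record, "empty")) stop("no-signal: record is flagged empty", call. = FALSE)
  fs <- record$sampling_rate
  x <- record$samples
  n <- length(x)
  if (n < 3 * fs) stop("record too short for QRS detection (need >= 3 s)", call. = FALSE)

  hp <- butter_coeffs(2, 5, fs, "high")
  lp <- butter_coeffs(2, 15, fs, "low")
  xf <- filtfilt_zero_phase(lp$b, lp$a,
                            filtfilt_zero_phase(hp$b, hp$a, x, round(fs / 2)),
                            round(fs / 2))
  d <- c(0, diff(xf)) * fs
  mwi <- moving_average(d^2, round(0.15 * fs))
  if (max(mwi) <= 0) stop("no-signal: flat detection function", call. = FALSE)

  refr <- as.integer(round(min_rr_s * fs))
  # local maxima of the integrated energy
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) stop("no-signal: no candidate peaks", call. = FALSE)

  init <- mwi[seq_len(min(n, as.integer(2.5 * fs)))]
  spki <- max(init)
  npki <- stats::median(init)
  thr <- function() npki + 0.25 * (spki - npki)

  accepted <- integer(0)
  rejected <- integer(0)
  last <- -Inf
  for (c0 in cand) {
    if (c0 - last < refr) next
    if (mwi[c0] >= thr()) {
      accepted <- c(accepted, c0)
      spki <- 0.125 * mwi[c0] + 0.875 * spki
      last <- c0
    } else {
      rejected <- c(rejected, c0)
      npki <- 0.125 * mwi[c0] + 0.875 * npki
    }
  }
  if (length(accepted) < 1L) stop("no-signal: no QRS found", call. = FALSE)

  # search-back: fill abnormally long gaps from the rejected pool at half
  # threshold
  if (length(accepted) >= 3L && length(rejected)) {
    med_rr <- stats::median(diff(accepted))
    lowthr <- npki + 0.125 * (spki - npki)
    repeat {
      gaps <- diff(accepted)
      gi <- which(gaps > 1.66 * med_rr)
      if (!length(gi)) break
      added <- FALSE
      for (g in gi) {
        inside <- rejected[rejected > accepted[g] + refr &
                           rejected < accepted[g + 1] - refr]
        inside <- inside[mwi[inside] >= lowthr]
        if (length(inside)) {
          best <- inside[which.max(mwi[inside])]
          accepted <- sort(c(accepted, best))
          rejected <- setdiff(rejected, best)
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
  }

  # refine each detection to the extremum of the cleaned signal
  half <- as.integer(round(0.10 * fs))
  peaks <- vapply(accepted, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory after refinement, keeping the larger deflection
  while (length(peaks) > 1L && any(diff(peaks) < refr)) {
    i <- which(diff(peaks) < refr)[1L]
    drop <- if (abs(x[peaks[i]]) >= abs(x[peaks[i + 1L]])) i + 1L else i
    peaks <- peaks[-drop]
  }
  peaks
}

# walk outward from a peak along |slope| until it stays below frac of the
# wave's own maximum slope; the reference slope is taken over the first
# slope_win samples of the walk so a neighbouring wave cannot inflate it.
# Returns the first index of the sustained sub-threshold run.
slope_boundary <- function(d, peak, lim, frac = 0.1, slope_win = NULL, min_thr = 0) {
  if (peak == lim) return(lim)
  rng <- peak:lim
  m <- length(rng)
  k <- if (is.null(slope_win)) m else min(m, as.integer(slope_win))
  v <- abs(d[rng])
  maxslope <- max(v[seq_len(k)])
  if (maxslope <= 0) return(lim)
  thr <- max(frac * maxslope, min_thr)
  # 3-sample forward mean makes the stop robust to single-sample ripple
  vm <- vapply(seq_len(m), function(j) mean(v[j:min(m, j + 2L)]), numeric(1))
  seen_rise <- FALSE
  rise_at <- m
  for (j in seq_len(m)) {
    if (!seen_rise) {
      if (v[j] >= 0.5 * maxslope) {
        seen_rise <- TRUE
        rise_at <- j
      }
      next
    }
    if (vm[j] < thr && v[j] < thr) return(rng[j])
  }
  # waves merged (no quiet stretch): take the flattest point of the transition
  if (seen_rise && rise_at < m) {
    j <- rise_at + which.min(vm[(rise_at + 1L):m])
    return(rng[j])
  }
  lim
}

# tighten a conservative boundary: walk from b back toward the wave while the
# amplitude stays within tol of the boundary level, i.e. while the wave has
# not yet departed from baseline
refine_boundary <- function(x, b, peak, tol = 0.02) {
  if (b == peak) return(b)
  step <- if (peak > b) 1L else -1L
  j <- b
  while (j + step != peak && abs(x[j + step] - x[b]) < tol) j <- j + step
  j
}

#' Delineate P, QRS and T waves beat by beat
#'
#' For each detected QRS peak, the QRS onset/offset are located where the
#' absolute slope falls below 10% of the local maximum slope.  The T peak is
#' searched in a window after the QRS offset and the P peak in a window before
#' the QRS onset; waves whose amplitude does not clear the noise floor are
#' reported absent rather than fabricated.
#'
#' @param record a cleaned [ecg_record()].
#' @param qrs_peaks integer vector from [detect_qrs()].
#' @param p_min_amp minimum |amplitude| (mV) for a P wave to be accepted.
#' @param t_min_amp minimum |amplitude| (mV) for a T wave to be accepted.
#' @return a data.frame of class `wave_annotations`: one row per beat with
#'   1-based sample indices `p_onset, p_peak, p_offset, qrs_onset, qrs_peak,
#'   qrs_offset, t_onset, t_peak, t_offset` (NA when absent) and `beat_index`.
#' @export
delineate_waves <- function(record, qrs_peaks, p_min_amp = 0.08, t_min_amp = 0.08) {
  assert_record(record)
  if (length(qrs_peaks) < 2L) stop("need >= 2 QRS peaks to delineate", call. = FALSE)
  fs <- record$sampling_rate
  x <- record$samples
  n <- length(x)
  # sample-to-sample slope for the boundary criteria (the cleaned signal is
  # already band-limited; smoothing here would blur boundaries by +-1 sample)
  d <- c(0, diff(x)) * fs

  nb <- length(qrs_peaks)
  rr <- diff(qrs_peaks)
  rr_next <- c(rr, rr[length(rr)]) # samples to next beat (last reuses previous)

  out <- data.frame(beat_index = seq_len(nb),
                    p_onset = NA_integer_, p_peak = NA_integer_, p_offset = NA_integer_,
                    qrs_onset = NA_integer_, qrs_peak = as.integer(qrs_peaks),
                    qrs_offset = NA_integer_,
                    t_onset = NA_integer_, t_peak = NA_integer_, t_offset = NA_integer_)

  trough_win <- as.integer(round(0.15 * fs))
  walk_win <- as.integer(round(0.06 * fs))
  ref_win <- as.integer(round(0.04 * fs))
  for (i in seq_len(nb)) {
    pk <- qrs_peaks[i]
    span <- as.integer(round(0.18 * fs))
    qwin <- as.integer(round(0.10 * fs))
    sgn <- if (x[pk] < 0) -1 else 1
    # QRS onset: from the Q trough (if deep enough) using the Q wave's own
    # slope, else directly from the R peak
    qlo <- max(1L, pk - trough_win)
    seg <- sgn * x[qlo:(pk - 1L)]
    qi <- qlo + which.min(seg) - 1L
    on <- if (min(seg) < -0.02) {
      refine_boundary(x, slope_boundary(d, qi, max(1L, qi - walk_win), 0.1, ref_win), qi)
    } else {
      refine_boundary(x, slope_boundary(d, pk, max(1L, pk - span), 0.1, qwin), pk)
    }
    # QRS offset: symmetric, from the S trough
    shi <- min(n, pk + trough_win)
    seg <- sgn * x[(pk + 1L):shi]
    si <- pk + which.min(seg)
    off <- if (min(seg) < -0.02) {
      refine_boundary(x, slope_boundary(d, si, min(n, si + walk_win), 0.1, ref_win), si)
    } else {
      refine_boundary(x, slope_boundary(d, pk, min(n, pk + span), 0.1, qwin), pk)
    }
    out$qrs_onset[i] <- on
    out$qrs_offset[i] <- off

    # T wave: search after the QRS offset, up to 60% of the RR to the next
    # beat; at high rates the T hugs the QRS, so the window opens early
    t_lo <- off + as.integer(round(0.02 * fs))
    t_hi <- min(n, pk + as.integer(round(0.6 * rr_next[i])))
    if (t_hi - t_lo >= as.integer(round(0.05 * fs))) {
      seg <- x[t_lo:t_hi]
      tp <- t_lo + which.max(abs(seg)) - 1L
      if (abs(x[tp]) >= t_min_amp && tp > t_lo && tp < t_hi) {
        w <- as.integer(round(0.16 * fs))
        twin <- as.integer(round(0.08 * fs))
        out$t_peak[i] <- tp
        out$t_onset[i] <- refine_boundary(x, slope_boundary(d, tp, max(off, tp - w), 0.1, twin), tp)
        out$t_offset[i] <- refine_boundary(x, slope_boundary(d, tp, min(n, tp + w), 0.1, twin), tp)
      }
    }

    # P wave: search 240-40 ms before the QRS onset (clipped at the previous
    # beat's territory)
    p_lo <- on - as.integer(round(0.24 * fs))
    if (i > 1L) {
      prev_guard <- qrs_peaks[i - 1L] + as.integer(round(0.12 * fs))
      if (!is.na(out$t_offset[i - 1L])) {
        prev_guard <- max(prev_guard, out$t_offset[i - 1L] + 1L)
      }
      p_lo <- max(p_lo, prev_guard)
    }
    p_hi <- on - as.integer(round(0.04 * fs))
    if (p_lo >= 1L && p_hi - p_lo >= as.integer(round(0.04 * fs))) {
      seg <- x[p_lo:p_hi]
      # baseline from the window edges: the middle may be all P wave
      k <- max(2L, length(seg) %/% 5L)
      base <- stats::median(c(seg[seq_len(k)], seg[seq(length(seg) - k + 1L, length(seg))]))
      pp <- p_lo + which.max(abs(seg - base)) - 1L
      # prominence against the window's own baseline rejects fibrillatory
      # undulation and tails of the previous T wave
      if (abs(x[pp] - base) >= p_min_amp && pp > p_lo && pp < p_hi) {
        w <- as.integer(round(0.08 * fs))
        pwin <- as.integer(round(0.04 * fs))
        out$p_peak[i] <- pp
        out$p_onset[i] <- refine_boundary(x, slope_boundary(d, pp, max(1L, pp - w), 0.1, pwin), pp, tol = 0.015)
        out$p_offset[i] <- refine_boundary(x, slope_boundary(d, pp, min(on, pp + w), 0.1, pwin), pp, tol = 0.015)
      }
    }
    # enforce ordering: p entirely before QRS onset, t after QRS offset
    if (!is.na(out$p_offset[i]) && out$p_offset[i] > on) out$p_offset[i] <- on
    if (!is.na(out$t_onset[i]) && out$t_onset[i] < off) out$t_onset[i] <- off
  }
  class(out) <- c("wave_annotations", "data.frame")
  attr(out, "sampling_rate") <- fs
  out
}

#' Interval measurements from wave annotations
#'
#' Computes the eight standard measurements: P duration, PR interval (P onset
#' to QRS onset), QRS interval, QT interval (QRS onset to T offset), QTc, T
#' duration, atrial rate (from PP intervals) and ventricular rate (from RR
#' intervals).  Durations are index differences times 1000/sampling_rate, in
#' ms; the per-beat values are summarised by the median (configurable).
#'
#' @param annotations a `wave_annotations` data.frame from [delineate_waves()].
#' @param sampling_rate Hz; defaults to the annotation attribute.
#' @param qtc_method `"bazett"` (QT/sqrt(RR)), `"fridericia"` (QT/RR^(1/3)) or
#'   `"none"`.
#' @param summary `"median"` or `"mean"` across beats.
#' @return list of class `measurement_report` with `per_beat` (data.frame) and
#'   `summary` (named numeric: p_duration_ms, pr_interval_ms, qrs_interval_ms,
#'   qt_interval_ms, qtc_interval_ms, t_duration_ms, atrial_rate_bpm,
#'   ventricular_rate_bpm).
#' @export
compute_measurements <- function(annotations, sampling_rate = attr(annotations, "sampling_rate"),
                                 qtc_method = c("bazett", "fridericia", "none"),
                                 summary = c("median", "mean")) {
  qtc_method <- match.arg(qtc_method)
  summary <- match.arg(summary)
  a <- annotations
  if (nrow(a) < 2L) stop("insufficient data: need >= 2 annotated beats", call. = FALSE)
  ms <- 1000 / sampling_rate
  rr_s <- diff(a$qrs_peak) / sampling_rate
  rr_local <- c(rr_s[1], rr_s) # per-beat local RR (first beat uses the next)
  qt <- (a$t_offset - a$qrs_onset) * ms
  qtc <- switch(qtc_method,
                bazett = qt / sqrt(rr_local),
                fridericia = qt / (rr_local^(1 / 3)),
                none = qt)
  per_beat <- data.frame(
    beat_index = a$beat_index,
    p_duration_ms = (a$p_offset - a$p_onset) * ms,
    pr_interval_ms = (a$qrs_onset - a$p_onset) * ms,
    qrs_interval_ms = (a$qrs_offset - a$qrs_onset) * ms,
    qt_interval_ms = qt,
    qtc_interval_ms = qtc,
    t_duration_ms = (a$t_offset - a$t_onset) * ms,
    rr_s = rr_local
  )
  agg <- function(v) if (all(is.na(v))) NA_real_ else {
    if (summary == "median") stats::median(v, na.rm = TRUE) else mean(v, na.rm = TRUE)
  }
  p_peaks <- a$p_peak[!is.na(a$p_peak)]
  atrial <- if (length(p_peaks) >= 2L) 60 / mean(diff(p_peaks) / sampling_rate) else NA_real_
  ventricular <- 60 / mean(rr_s)
  summ <- c(p_duration_ms = agg(per_beat$p_duration_ms),
            pr_interval_ms = agg(per_beat$pr_interval_ms),
            qrs_interval_ms = agg(per_beat$qrs_interval_ms),
            qt_interval_ms = agg(per_beat$qt_interval_ms),
            qtc_interval_ms = agg(per_beat$qtc_interval_ms),
            t_duration_ms = agg(per_beat$t_duration_ms),
            atrial_rate_bpm = atrial,
            ventricular_rate_bpm = ventricular)
  structure(list(per_beat = per_beat, summary = summ, qtc_method = qtc_method),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>", nrow(x$per_beat), "beats\n")
  print(round(x$summary, 1))
  invisible(x)
}

#' Average beat template
#'
#' Sample-wise mean of all complete beats in a fixed window around the QRS
#' peak (-300 ms to +500 ms).
#'
#' @param record a cleaned [ecg_record()].
#' @param qrs_peaks integer QRS peak indices (or a `wave_annotations` frame).
#' @param pre_s,post_s window before/after the peak, seconds.
#' @return list of class `average_beat`: `template` (mV), `time_s` (relative
#'   to the peak), `n_beats`.
#' @export
compute_average_beat <- function(record, qrs_peaks, pre_s = 0.3, post_s = 0.5) {
  assert_record(record)
  if (inherits(qrs_peaks, "wave_annotations")) qrs_peaks <- qrs_peaks$qrs_peak
  fs <- record$sampling_rate
  pre <- as.integer(round(pre_s * fs))
  post <- as.integer(round(post_s * fs))
  n <- length(record$samples)
  ok <- qrs_peaks[qrs_peaks - pre >= 1L & qrs_peaks + post <= n]
  if (length(ok) < 5L) stop("insufficient data: need >= 5 complete beats", call. = FALSE)
  mat <- vapply(ok, function(p) record$samples[(p - pre):(p + post)],
                numeric(pre + post + 1L))
  structure(list(template = rowMeans(mat), time_s = (-pre:post) / fs,
                 n_beats = length(ok)),
            class = "average_beat")
}

#' Heart-rate-variability summary
#'
#' Time-domain HRV statistics of the RR sequence: SDNN (standard deviation of
#' RR), RMSSD (root mean square of successive differences) and pNN50 (fraction
#' of successive differences exceeding 50 ms).
#'
#' @param qrs_peaks integer QRS peak indices; at least 3.
#' @param sampling_rate Hz.
#' @return list of class `hrv_summary`: `mean_rr`, `sdnn`, `rmssd` (s),
#'   `pnn50` (fraction), `n_intervals`.
#' @export
compute_hrv <- function(qrs_peaks, sampling_rate) {
  if (length(qrs_peaks) < 3L) stop("insufficient data: need >= 3 QRS peaks", call. = FALSE)
  rr <- diff(qrs_peaks) / sampling_rate
  drr <- diff(rr)
  structure(list(mean_rr = mean(rr), sdnn = stats::sd(rr),
                 rmssd = sqrt(mean(drr^2)), pnn50 = mean(abs(drr) > 0.05),
                 n_intervals = length(rr)),
            class = "hrv_summary")
}

#' RR scatter (Poincaré) data
#'
#' @inheritParams compute_hrv
#' @return data.frame with columns `rr_s` and `rr_next_s`: each RR interval
#'   against its successor (n_peaks - 2 points).
#' @export
rr_scatter <- function(qrs_peaks, sampling_rate) {
  if (length(qrs_peaks) < 3L) stop("insufficient data: need >= 3 QRS peaks", call. = FALSE)
  rr <- diff(qrs_peaks) / sampling_rate
  data.frame(rr_s = rr[-length(rr)], rr_next_s = rr[-1])
}
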