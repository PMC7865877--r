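# Seeded synthetic single-lead ECG generator.  Each beat is a sum of Gaussian
# deflections (P, Q, R, S, T) placed by an RR-interval process, so every
# fiducial (onset = peak - half width, offset = peak + half width) is known
# analytically and can serve as ground truth for the delineator and the
# classifier.  A wave's "width" is its full duration; the Gaussian sigma is
# width/6 so the bump essentially vanishes outside [onset, offset].

# run code under a temporary RNG state so generators do not clobber the
# caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rhythm classes the generator can synthesize
#' @export
ecg_rhythms <- function() {
  c("normal_sinus", "sinus_tachycardia", "sinus_bradycardia", "sinus_arrhythmia",
    "irregular_af_like", "ectopic_pvc_like", "ectopic_pac_like",
    "long_pr_block_like", "wide_qrs_block_like")
}

rhythm_to_item <- function(rhythm) {
  switch(rhythm,
         normal_sinus = "SN", sinus_tachycardia = "SNT", sinus_bradycardia = "SNB",
         sinus_arrhythmia = "SNA", irregular_af_like = "AF",
         ectopic_pvc_like = "PVC", ectopic_pac_like = "PAC",
         long_pr_block_like = "AVBI", wide_qrs_block_like = "LBBB",
         stop("unknown rhythm: ", rhythm, call. = FALSE))
}

default_wave_params <- function() {
  list(p = c(amp = 0.15, width = 80),
       q = c(amp = -0.10, width = 30),
       r = c(amp = 1.00, width = 40),
       s = c(amp = -0.15, width = 30),
       t = c(amp = 0.30, width = 160))
}

#' Specification of a synthetic ECG recording
#'
#' @param duration recording length, seconds.
#' @param sampling_rate Hz.
#' @param heart_rate mean rate in bpm; default depends on rhythm (75 sinus,
#'   130 tachycardia, 50 bradycardia).
#' @param rhythm one of [ecg_rhythms()].
#' @param hf_noise_amp RMS (mV) of added band-limited (>= 40 Hz) noise.
#' @param baseline_amp amplitude (mV) of an added baseline-wander sinusoid.
#' @param baseline_freq frequency (Hz) of the baseline sinusoid.
#' @param reversed if `TRUE` the whole waveform is negated, emulating swapped
#'   electrode polarity.
#' @param wave_params per-wave `c(amp =, width =)` (mV, ms) for p/q/r/s/t.
#' @param pr_ms,qt_ms target PR (P onset to QRS onset) and QT (QRS onset to T
#'   offset) intervals in ms.
#' @param seed integer; all randomness derives from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration = 30, sampling_rate = 125, heart_rate = NULL,
                           rhythm = "normal_sinus", hf_noise_amp = 0,
                           baseline_amp = 0, baseline_freq = 0.25,
                           reversed = FALSE, wave_params = default_wave_params(),
                           pr_ms = 160, qt_ms = 360, seed = 1L) {
  rhythm <- match.arg(rhythm, ecg_rhythms())
  if (is.null(heart_rate)) {
    heart_rate <- switch(rhythm, sinus_tachycardia = 130, sinus_bradycardia = 50, 75)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (heart_rate < 20 || heart_rate > 250) stop("heart_rate must be in [20, 250]", call. = FALSE)
  wp <- utils::modifyList(default_wave_params(), wave_params)
  if (rhythm == "long_pr_block_like" && pr_ms <= 200) pr_ms <- 240
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 heart_rate = heart_rate, rhythm = rhythm,
                 hf_noise_amp = hf_noise_amp, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, reversed = isTRUE(reversed),
                 wave_params = wp, pr_ms = pr_ms, qt_ms = qt_ms,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# RR interval sequence (s) and ectopic flags for a rhythm
make_rr_sequence <- function(spec) {
  base <- 60 / spec$heart_rate
  n <- ceiling(spec$duration / base) + 8L
  rhythm <- spec$rhythm
  if (rhythm == "irregular_af_like") {
    rr <- base * exp(stats::rnorm(n, 0, 0.2))
    ect <- rep(FALSE, n)
  } else if (rhythm == "sinus_arrhythmia") {
    jit <- stats::rnorm(n, 0, 0.01)
    phase <- cumsum(rep(base, n))
    rr <- base * (1 + 0.12 * sin(2 * pi * 0.25 * phase) + jit)
    ect <- rep(FALSE, n)
  } else {
    rr <- base * (1 + stats::rnorm(n, 0, 0.02))
    ect <- rep(FALSE, n)
    if (rhythm %in% c("ectopic_pvc_like", "ectopic_pac_like")) {
      # ~10% of beats premature, each followed by a compensatory pause
      cand <- which(seq_len(n) > 2 & seq_len(n) < n)
      k <- max(1L, round(0.1 * n))
      pick <- sort(sample(cand, min(k, length(cand))))
      pick <- pick[c(TRUE, diff(pick) > 1)] # no adjacent ectopics
      ect[pick] <- TRUE
      rr[pick] <- rr[pick] * 0.65
      after <- pick + 1L
      rr[after] <- rr[after] * 1.35
    }
  }
  list(rr = pmax(rr, 0.25), ectopic = ect)
}

# rate-adapted effective intervals: QT shortens with RR (Bazett-style) and PR
# shortens moderately at high rates so consecutive beats never overlap
effective_intervals <- function(pr_ms, qt_ms, rr_s) {
  list(pr = pr_ms * (0.6 + 0.4 * min(rr_s, 1)),
       qt = qt_ms * sqrt(min(rr_s, 1.2)))
}

# ground-truth fiducials (seconds) for one beat with R apex at t_r; t_scale
# shrinks the T duration together with the rate-adapted QT
beat_fiducials <- function(t_r, wp, pr_ms, qt_ms, wide, with_p, t_scale = 1) {
  ms <- 1e-3
  wq <- wp$q[["width"]] * ms
  wr <- wp$r[["width"]] * ms
  ws <- wp$s[["width"]] * ms
  if (wide) {
    wq <- wq * 2; wr <- wr * 2; ws <- ws * 2
  }
  qrs_on <- t_r - wr / 2 - wq
  qrs_off <- t_r + wr / 2 + ws
  out <- list(qrs_onset = qrs_on, qrs_peak = t_r, qrs_offset = qrs_off)
  wpv <- wp$p[["width"]] * ms
  if (with_p) {
    out$p_onset <- qrs_on - pr_ms * ms
    out$p_offset <- out$p_onset + wpv
    out$p_peak <- out$p_onset + wpv / 2
  } else {
    out$p_onset <- out$p_peak <- out$p_offset <- NA_real_
  }
  wt <- wp$t[["width"]] * ms * t_scale
  out$t_offset <- qrs_on + qt_ms * ms
  out$t_onset <- out$t_offset - wt
  out$t_peak <- out$t_offset - wt / 2
  out$t_width <- wt
  out
}

gauss_bump <- function(t_grid, center, amp, width_s) {
  sigma <- width_s / 6
  lo <- center - 4 * sigma
  hi <- center + 4 * sigma
  i <- which(t_grid >= lo & t_grid <= hi)
  v <- numeric(length(t_grid))
  if (length(i)) v[i] <- amp * exp(-((t_grid[i] - center)^2) / (2 * sigma^2))
  v
}

#' Generate a labelled synthetic ECG
#'
#' Builds the waveform from the spec, applies artifacts (high-frequency noise,
#' baseline sinusoid) and optional polarity reversal, and returns it together
#' with analytic ground truth: beat times, per-beat wave fiducials, the clean
#' artifact-free waveform, and the diagnosis item label implied by the rhythm.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `ecg_labelled` with elements `record` (an
#'   [ecg_record()]), `clean_samples`, `item_labels`, `ground_truth` (one row
#'   per beat, times in seconds), and `spec`.
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    n <- as.integer(round(spec$duration * fs))
    t_grid <- (seq_len(n) - 1L) / fs
    seq_info <- make_rr_sequence(spec)
    start <- 0.45 + stats::runif(1, 0, 0.1)
    t_beats <- start + cumsum(c(0, seq_info$rr))
    margin <- 0.45
    keep <- t_beats < spec$duration - margin
    t_beats <- t_beats[keep]
    ect <- seq_info$ectopic[seq_along(t_beats)]
    wp <- spec$wave_params
    all_wide <- spec$rhythm == "wide_qrs_block_like"
    no_p_all <- spec$rhythm == "irregular_af_like"
    x <- numeric(n)
    gt <- vector("list", length(t_beats))
    rr_local <- c(60 / spec$heart_rate, diff(t_beats))
    for (i in seq_along(t_beats)) {
      wide <- all_wide || (ect[i] && spec$rhythm == "ectopic_pvc_like")
      with_p <- !no_p_all && !(ect[i] && spec$rhythm == "ectopic_pvc_like")
      eff <- effective_intervals(spec$pr_ms, spec$qt_ms, rr_local[i])
      t_scale <- eff$qt / spec$qt_ms # T duration shortens with the QT
      if (wide) {
        # keep the T wave clear of a widened QRS: QT covers QRS + 40 ms ST + T
        qrs_ms <- 2 * (wp$q[["width"]] + wp$r[["width"]] + wp$s[["width"]])
        eff$qt <- max(eff$qt, qrs_ms + 40 + wp$t[["width"]] * t_scale)
      }
      fid <- beat_fiducials(t_beats[i], wp, eff$pr, eff$qt, wide, with_p, t_scale)
      scale_w <- if (wide) 2 else 1
      amp_r <- wp$r[["amp"]] * (if (wide) 1.15 else 1)
      x <- x + gauss_bump(t_grid, t_beats[i], amp_r, wp$r[["width"]] * 1e-3 * scale_w)
      x <- x + gauss_bump(t_grid, fid$qrs_onset + wp$q[["width"]] * 1e-3 * scale_w / 2,
                          wp$q[["amp"]], wp$q[["width"]] * 1e-3 * scale_w)
      x <- x + gauss_bump(t_grid, fid$qrs_offset - wp$s[["width"]] * 1e-3 * scale_w / 2,
                          wp$s[["amp"]], wp$s[["width"]] * 1e-3 * scale_w)
      if (with_p) {
        x <- x + gauss_bump(t_grid, fid$p_peak, wp$p[["amp"]], wp$p[["width"]] * 1e-3)
      }
      x <- x + gauss_bump(t_grid, fid$t_peak, wp$t[["amp"]], fid$t_width)
      gt[[i]] <- data.frame(beat = i, ectopic = ect[i], wide = wide,
                            p_onset = fid$p_onset, p_peak = fid$p_peak,
                            p_offset = fid$p_offset, qrs_onset = fid$qrs_onset,
                            qrs_peak = fid$qrs_peak, qrs_offset = fid$qrs_offset,
                            t_onset = fid$t_onset, t_peak = fid$t_peak,
                            t_offset = fid$t_offset,
                            pr_ms = if (with_p) eff$pr else NA_real_,
                            qrs_ms = (fid$qrs_offset - fid$qrs_onset) * 1e3,
                            qt_ms = eff$qt)
    }
    # AF-like records get a fine fibrillatory undulation instead of P waves
    if (no_p_all) {
      x <- x + 0.03 * sin(2 * pi * 6 * t_grid + stats::runif(1, 0, 2 * pi))
    }
    clean <- x
    noisy <- add_artifact_samples(x, fs, spec$hf_noise_amp, spec$baseline_amp,
                                  spec$baseline_freq)
    if (spec$reversed) noisy <- -noisy
    rec <- ecg_record(noisy, sampling_rate = fs,
                      record_id = sprintf("syn_%s_%d", spec$rhythm, spec$seed),
                      provenance = "raw")
    structure(list(record = rec, clean_samples = clean,
                   item_labels = rhythm_to_item(spec$rhythm),
                   ground_truth = do.call(rbind, gt),
                   reversed = spec$reversed, spec = spec),
              class = "ecg_labelled")
  })
}

# artifact synthesis shared by generate_ecg() and add_artifacts(); consumes
# the current RNG stream
add_artifact_samples <- function(x, fs, hf_noise_amp, baseline_amp, baseline_freq) {
  n <- length(x)
  if (hf_noise_amp > 0) {
    noise <- stats::rnorm(n)
    if (fs / 2 > 40) {
      hp <- butter_coeffs(4, 40, fs, "high")
      noise <- filtfilt_zero_phase(hp$b, hp$a, noise, min(n - 1L, 200L))
    }
    noise <- noise / sqrt(mean(noise^2)) * hf_noise_amp
    x <- x + noise
  }
  if (baseline_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + baseline_amp * sin(2 * pi * baseline_freq * (seq_len(n) - 1L) / fs + phase)
  }
  x
}

#' Add acquisition artifacts to an existing record
#'
#' Adds band-limited (>= 40 Hz) noise of the requested RMS and a baseline
#' sinusoid of the requested amplitude/frequency.  With both amplitudes zero
#' the record is returned unchanged.
#'
#' @param record an [ecg_record()].
#' @param spec a [synthetic_spec()] providing `hf_noise_amp`, `baseline_amp`,
#'   `baseline_freq`.
#' @param seed integer RNG seed for the noise.
#' @return the contaminated record.
#' @export
add_artifacts <- function(record, spec, seed = spec$seed) {
  assert_record(record)
  if (spec$hf_noise_amp == 0 && spec$baseline_amp == 0) return(record)
  with_seed(seed, {
    record$samples <- add_artifact_samples(record$samples, record$sampling_rate,
                                           spec$hf_noise_amp, spec$baseline_amp,
                                           spec$baseline_freq)
    record
  })
}

#' Generate a labelled dataset of synthetic recordings
#'
#' @param n number of recordings.
#' @param class_mix named numeric vector or list mapping rhythm name to
#'   fraction; fractions must sum to 1.
#' @param seed master seed; per-record seeds are derived from it, so two runs
#'   with the same master seed give identical datasets.
#' @param duration,... forwarded to [synthetic_spec()].
#' @return list with `recordings` (list of `ecg_labelled`) and `manifest`
#'   (data.frame: record_id, rhythm, item_label, seed).
#' @export
make_ecg_dataset <- function(n, class_mix = c(normal_sinus = 1), seed = 1L,
                             duration = 30, ...) {
  mix <- unlist(class_mix)
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix fractions must sum to 1", call. = FALSE)
  if (!all(names(mix) %in% ecg_rhythms())) {
    stop("unknown rhythm in class_mix", call. = FALSE)
  }
  # largest-remainder apportionment of n over classes
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  rhythms <- rep(names(mix), counts)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  recs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- synthetic_spec(duration = duration, rhythm = rhythms[i],
                         seed = seeds[i], ...)
    recs[[i]] <- generate_ecg(sp)
    recs[[i]]$record$record_id <- sprintf("rec%04d", i)
    rows[[i]] <- data.frame(record_id = sprintf("rec%04d", i),
                            rhythm = rhythms[i],
                            item_label = recs[[i]]$item_labels,
                            seed = seeds[i])
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}
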