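## Signal conditioning chain: anti-aliased decimation to 100 Hz, running
## median baseline removal, Christov adaptive-threshold R-peak detection,
## and fixed 50/349-sample beat segmentation.

#' Preprocessing configuration
#'
#' @param target_fs Target sampling rate after decimation (Hz).
#' @param median_window_s Running-median window for baseline estimation, in
#'   seconds; sized to cover one full cardiac cycle at 70 bpm.
#' @param pre_samples,post_samples Samples kept before/after the R sample in
#'   each beat window; with the R sample itself the default window is
#'   50 + 1 + 349 = 400 samples.
#' @param include_r_sample If `FALSE`, the window is pre + post samples
#'   without counting R separately (length 399 at the defaults).
#' @param detection_lead Lead fed to the R-peak detector.
#' @param christov Constants of the Christov detector, see
#'   [christov_config()].
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 100, median_window_s = 0.857,
                              pre_samples = 50, post_samples = 349,
                              include_r_sample = TRUE,
                              detection_lead = "II",
                              christov = christov_config()) {
  stopifnot(pre_samples >= 0, post_samples >= 1, target_fs > 0)
  if (round(median_window_s * target_fs) < 3)
    stop_ecgmi("median window must span at least 3 samples")
  detection_lead <- match.arg(detection_lead, ECG_LEADS)
  structure(list(target_fs = target_fs, median_window_s = median_window_s,
                 pre_samples = as.integer(pre_samples),
                 post_samples = as.integer(post_samples),
                 include_r_sample = isTRUE(include_r_sample),
                 detection_lead = detection_lead, christov = christov),
            class = "preprocess_config")
}

#' Anti-aliased integer-factor downsampling
#'
#' Zero-phase low-pass FIR filtering (symmetric odd-length kernel applied
#' centered, with reflection padding at the edges) followed by decimation.
#' The cutoff sits at 0.8 of the target Nyquist rate (40 Hz for 100 Hz
#' output), preserving the clinically relevant ECG band while attenuating
#' content above the new Nyquist frequency by more than 20 dB.
#'
#' @param x Numeric vector, or a matrix with signals in rows.
#' @param fs_in,fs_out Input/output sampling rates; `fs_in` must be an
#'   integer multiple of `fs_out`.
#' @return Downsampled signal, length `floor(n * fs_out / fs_in)`.
#' @export
antialias_downsample <- function(x, fs_in, fs_out = 100) {
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_ecgmi("fs_in (%g) must be an integer multiple of fs_out (%g)", fs_in, fs_out)
  ratio <- as.integer(round(ratio))
  if (is.matrix(x)) {
    out <- t(apply(x, 1, antialias_downsample, fs_in = fs_in, fs_out = fs_out))
    rownames(out) <- rownames(x)
    return(out)
  }
  n_out <- floor(length(x) / ratio)
  if (ratio == 1L) return(x[seq_len(n_out)])
  ntaps <- 12L * ratio
  if (ntaps %% 2L == 1L) ntaps <- ntaps + 1L        # even order -> odd taps
  h <- signal::fir1(ntaps, 0.8 / ratio)             # cutoff 0.8 * new Nyquist
  h <- h / sum(h)                                   # exact unit DC gain
  half <- (length(h) - 1L) / 2L
  if (length(x) <= half) stop_ecgmi("signal too short for the anti-alias filter")
  padded <- c(x[(half + 1):2], x, x[(length(x) - 1):(length(x) - half)])
  ## zero-phase response evaluated only at the retained samples
  pos <- seq.int(1L, by = ratio, length.out = n_out)
  y <- numeric(n_out)
  for (k in seq_along(h)) y <- y + h[k] * padded[pos + (k - 1L)]
  y
}

#' Baseline wander removal by running median
#'
#' Subtracts a running median whose window (in samples) is
#' `round(window_s * fs)`, forced odd so the median is an observed sample
#' value. Edges are handled by reflecting the signal. A constant signal maps
#' to identically zero.
#'
#' @param x Numeric vector or matrix (signals in rows).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 0.857 s, one cardiac
#'   cycle at 70 bpm).
#' @return Detrended signal, same shape as `x`.
#' @export
remove_baseline <- function(x, fs, window_s = 0.857) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, remove_baseline, fs = fs, window_s = window_s))
    rownames(out) <- rownames(x)
    return(out)
  }
  k <- as.integer(round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) stop_ecgmi("median window (%d) must be shorter than the signal (%d)",
                                 k, length(x))
  half <- (k - 1L) / 2L
  padded <- c(x[(half + 1):2], x, x[(length(x) - 1):(length(x) - half)])
  base <- stats::runmed(padded, k, endrule = "keep")
  x - base[(half + 1):(half + length(x))]
}

#' Christov detector constants
#'
#' Adaptive-threshold constants of the Christov (2004) single-lead QRS
#' detector: the steep-slope component M (initialized from the first
#' seconds, refreshed per QRS, linearly decaying after a refractory hold),
#' the integrating noise component F, and the beat-expectation component R
#' that lowers the threshold when a beat is due. All durations in seconds.
#'
#' @param smooth1_s,smooth2_s Moving-average spans for the complex-lead
#'   construction (pre-difference smoothing and post-rectification
#'   smoothing).
#' @param init_s Initialization span for M.
#' @param m_coef Fraction of the local complex-lead maximum used for M.
#' @param m_hold_s Post-QRS hold (refractory) during which M is constant and
#'   no detection is allowed.
#' @param m_decay_s Span over which M decays linearly to `m_floor` of its
#'   per-beat value.
#' @param m_floor Final fraction of the per-beat M after decay.
#' @param f_update_s,f_window_s,f_gain F-component update geometry and gain.
#' @param r_fraction Fraction of the mean RR after which the expectation
#'   component starts lowering the threshold.
#' @param r_slope_ratio Slope of the R decrease relative to the M decay
#'   slope.
#' @param relocate_s Half-width of the window used to relocate a detection
#'   to the raw-lead absolute maximum.
#' @return Object of class `christov_config`.
#' @export
christov_config <- function(smooth1_s = 0.030, smooth2_s = 0.040,
                            init_s = 5, m_coef = 0.6, m_hold_s = 0.2,
                            m_decay_s = 1.0, m_floor = 0.6,
                            f_update_s = 0.35, f_window_s = 0.05, f_gain = 150,
                            r_fraction = 2 / 3, r_slope_ratio = 1.4,
                            relocate_s = 0.05) {
  structure(as.list(environment()), class = "christov_config")
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(c(rep(x[1], k), x, rep(x[length(x)], k)),
                           rep(1 / k, k), sides = 2))[(k + 1):(k + length(x))]
}

#' Christov adaptive-threshold R-peak detection
#'
#' Single-lead QRS detection on a baseline-removed signal: the lead is
#' smoothed, differenced, rectified and smoothed again into a "complex
#' lead" Y, which is compared against the adaptive threshold M + F + R.
#' M tracks the steep-slope amplitude of recent beats with a post-QRS hold
#' and linear decay; F integrates the recent noise floor; R anticipates the
#' next beat from the running mean RR interval. Each threshold crossing is
#' relocated to the local absolute-amplitude maximum of the raw lead within
#' a small window, so returned indices sit on R peaks.
#'
#' @param x Single-lead numeric vector (baseline removed), microvolt.
#' @param fs Sampling rate, Hz.
#' @param config A [christov_config()].
#' @return Strictly increasing integer sample indices of detected R peaks.
#' @export
detect_r_peaks <- function(x, fs, config = christov_config()) {
  n <- length(x)
  if (n < 2 * fs) stop_ecgmi("signal shorter than 2 s: thresholds cannot initialize")
  cfg <- config
  y <- moving_average(x, max(1L, round(cfg$smooth1_s * fs)))
  y <- abs(c(0, diff(y)))
  y <- moving_average(y, max(1L, round(cfg$smooth2_s * fs)))

  init_n <- min(n, round(cfg$init_s * fs))
  m_base <- cfg$m_coef * max(y[seq_len(init_n)])
  if (m_base <= 0) return(integer(0))
  m_buf <- rep(m_base, 5)

  hold <- round(cfg$m_hold_s * fs)
  decay_n <- round(cfg$m_decay_s * fs)
  f_upd <- round(cfg$f_update_s * fs)
  f_win <- round(cfg$f_window_s * fs)
  reloc <- round(cfg$relocate_s * fs)

  ## running maximum of y over the trailing f_win samples, precomputed
  run_max <- do.call(pmax, lapply(seq_len(f_win) - 1L, function(lag)
    c(rep(y[1], lag), y[seq_len(n - lag)])))

  Fc <- 0
  rr_buf <- rep(fs, 5)            # running RR estimate, samples (init 1 s)
  last_qrs <- -decay_n            # pretend a beat long ago
  peaks <- integer(0)

  for (t in seq_len(n)) {
    since <- t - last_qrs
    m_cur <- sum(m_buf) / 5
    ## M: hold, then linear decay to m_floor of the per-beat level
    M <- if (since <= hold) m_cur
         else if (since <= hold + decay_n)
           m_cur * (1 - (1 - cfg$m_floor) * (since - hold) / decay_n)
         else m_cur * cfg$m_floor
    ## F: slow integration of the difference between the newest and an
    ## older 50 ms maximum
    if (t > f_upd) {
      Fc <- Fc + (run_max[t] - run_max[t - f_upd + f_win]) / cfg$f_gain
      if (Fc < 0) Fc <- 0
    }
    ## R: beat expectation lowers the threshold once 2/3 of the mean RR
    ## has elapsed since the last detection
    rr_m <- sum(rr_buf) / 5
    R <- 0
    if (since > cfg$r_fraction * rr_m) {
      slope_m <- (1 - cfg$m_floor) * m_cur / decay_n
      R <- -(since - cfg$r_fraction * rr_m) * slope_m / cfg$r_slope_ratio
      R <- max(R, -0.5 * m_cur)
    }
    if (since > hold && y[t] > M + Fc + R) {
      ## QRS found: refresh M from the steep-slope region, update RR buffer
      seg_end <- min(n, t + hold)
      m_new <- cfg$m_coef * max(y[t:seg_end])
      m_new <- min(m_new, 1.1 * m_cur)
      m_buf <- c(m_buf[-1], m_new)
      if (length(peaks)) rr_buf <- c(rr_buf[-1], t - last_qrs)
      last_qrs <- t
      peaks <- c(peaks, t)
    }
  }

  ## relocate each crossing to the raw-lead absolute maximum nearby
  out <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p - reloc)); hi <- min(n, as.integer(p + reloc))
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  out <- sort(unique(out))
  ## enforce a refractory spacing after relocation
  if (length(out) > 1) {
    keep <- c(TRUE, diff(out) > hold)
    out <- out[keep]
  }
  out
}

#' Fixed-window beat segmentation
#'
#' Cuts one 12 x L window per R peak, covering `pre` samples before the R
#' sample and `post` samples after it (R sample included at index
#' `pre + 1`, default L = 400). Peaks whose window would cross a record
#' boundary are silently dropped and counted.
#'
#' @param signals 12 x N matrix at the target sampling rate.
#' @param r_indices Integer R-peak sample indices (1-based).
#' @param config A [preprocess_config()].
#' @param patient_id,record_id,class_label Provenance stored with each beat.
#' @return A `beat_set`: list with `x` (array 12 x L x n), `meta`
#'   (data.frame: patient_id, record_id, beat, class) and `n_dropped`.
#' @export
segment_beats <- function(signals, r_indices, config = preprocess_config(),
                          patient_id = NA_character_, record_id = NA_character_,
                          class_label = NA_character_) {
  stopifnot(is.matrix(signals), nrow(signals) == 12)
  n <- ncol(signals)
  pre <- config$pre_samples; post <- config$post_samples
  len <- pre + post + if (config$include_r_sample) 1L else 0L
  ok <- r_indices - pre >= 1L & r_indices + post <= n
  kept <- as.integer(r_indices[ok])
  x <- array(0, dim = c(12L, len, length(kept)),
             dimnames = list(ECG_LEADS, NULL, NULL))
  for (i in seq_along(kept))
    x[, , i] <- signals[, (kept[i] - pre):(kept[i] + post - if (config$include_r_sample) 0L else 1L)]
  meta <- data.frame(patient_id = rep(patient_id, length(kept)),
                     record_id = rep(record_id, length(kept)),
                     beat = seq_along(kept),
                     r_index = kept,
                     class = rep(class_label, length(kept)),
                     stringsAsFactors = FALSE)
  structure(list(x = x, meta = meta, n_dropped = sum(!ok),
                 r_in_segment = pre + 1L), class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set  %d beats x 12 leads x %d samples  (%d dropped at boundaries)>\n",
              dim(x$x)[3], dim(x$x)[2], x$n_dropped))
  invisible(x)
}

## Concatenate beat_sets along the beat axis.
combine_beat_sets <- function(sets) {
  sets <- Filter(function(s) dim(s$x)[3] > 0, sets)
  if (!length(sets)) stop_ecgmi("no beats to combine")
  len <- dim(sets[[1]]$x)[2]
  x <- array(0, dim = c(12L, len, sum(vapply(sets, function(s) dim(s$x)[3], 0L))),
             dimnames = list(ECG_LEADS, NULL, NULL))
  off <- 0L
  for (s in sets) {
    k <- dim(s$x)[3]
    if (k) x[, , (off + 1):(off + k)] <- s$x
    off <- off + k
  }
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  structure(list(x = x, meta = meta,
                 n_dropped = sum(vapply(sets, `[[`, 0L, "n_dropped")),
                 r_in_segment = sets[[1]]$r_in_segment), class = "beat_set")
}

#' Preprocess one record into beats
#'
#' Runs the full chain on an `ecg_record`: downsample to the target rate,
#' remove the baseline on all leads, detect R peaks on the detection lead,
#' segment all 12 leads around each peak.
#'
#' @param record An `ecg_record`.
#' @param config A [preprocess_config()].
#' @return A `beat_set` carrying the record's provenance.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "ecg_record"))
  sig <- antialias_downsample(record$signals, record$fs, config$target_fs)
  sig <- remove_baseline(sig, config$target_fs, config$median_window_s)
  lead <- sig[config$detection_lead, ]
  r <- detect_r_peaks(lead, config$target_fs, config$christov)
  segment_beats(sig, r, config, patient_id = record$patient_id,
                record_id = record$record_id, class_label = record$class_label)
}

#' Generate and preprocess a cohort, streaming record by record
#'
#' Materializes each record of the cohort manifest, preprocesses it, and
#' keeps only the beat windows, so raw signals never accumulate in memory.
#'
#' @param spec A [cohort_spec()].
#' @param config A [preprocess_config()].
#' @return A `beat_set` for the whole cohort.
#' @export
cohort_segments <- function(spec, config = preprocess_config()) {
  man <- cohort_manifest(spec)
  sets <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- generate_record(man$class[i], man$patient_seed[i], man$beat_seed[i],
                           spec, patient_id = man$patient_id[i],
                           record_id = man$record_id[i])
    sets[[i]] <- preprocess_record(rec, config)
  }
  combine_beat_sets(sets)
}

#' Map annotation indices across sampling rates
#'
#' Converts 1-based sample indices recorded at `fs_from` to the nearest
#' sample at `fs_to`.
#'
#' @param idx Integer indices.
#' @param fs_from,fs_to Sampling rates.
#' @return Integer indices at `fs_to`.
#' @export
rescale_indices <- function(idx, fs_from, fs_to) {
  as.integer(round((idx - 1) * fs_to / fs_from)) + 1L
}

#' Match detections against reference annotations
#'
#' Greedy one-to-one matching of detected beat indices to reference indices
#' within a tolerance, as used for detector sensitivity / positive
#' predictivity scoring.
#'
#' @param detected,truth Integer sample indices.
#' @param tol_samples Matching tolerance in samples.
#' @return List with counts `tp`, `fn`, `fp` and rates `sensitivity`,
#'   `ppv` (in percent).
#' @export
match_beats <- function(detected, truth, tol_samples) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (r in truth) {
    d <- which(!used & abs(detected - r) <= tol_samples)
    if (length(d)) { used[d[which.min(abs(detected[d] - r))]] <- TRUE; tp <- tp + 1L }
  }
  fn <- length(truth) - tp
  fp <- length(detected) - tp
  list(tp = tp, fn = fn, fp = fp,
       sensitivity = if (length(truth)) 100 * tp / length(truth) else NA_real_,
       ppv = if (length(detected)) 100 * tp / length(detected) else NA_real_)
}
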