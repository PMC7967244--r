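## Synthetic PTB-like 12-lead ECG cohorts.
##
## The beat model is a sum of Gaussians, one per wave (P, Q, R, S, T), on a
## reference channel, projected through a fixed per-lead amplitude scaling
## vector. MI classes perturb the template only in their affected leads:
## a constant ST-segment offset, Q-wave amplification, and probabilistic
## T-wave inversion. Patient-level variability (RIV) jitters the template
## once per subject; beat-level variability (AIV) jitters every beat.

#' Reference PQRST beat template
#'
#' Wave parameters of the reference beat: amplitude (microvolt), center
#' (seconds relative to the R peak) and Gaussian width (seconds) for each of
#' P, Q, R, S, T, plus the fixed 12-lead amplitude scaling vector. Values are
#' textbook-like magnitudes for a lead II-dominant normal beat.
#'
#' @param amplitude,center,width Named numeric vectors over P, Q, R, S, T.
#' @param lead_scale Dimensionless per-lead scaling, length 12, in the
#'   standard lead order.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(amplitude = c(P = 120, Q = -100, R = 1100, S = -250, T = 300),
                          center    = c(P = -0.22, Q = -0.035, R = 0, S = 0.035, T = 0.30),
                          width     = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.012, T = 0.060),
                          lead_scale = c(I = 0.60, II = 1.00, III = 0.50,
                                         aVR = -0.75, aVL = 0.15, aVF = 0.75,
                                         V1 = -0.40, V2 = 0.50, V3 = 0.80,
                                         V4 = 1.10, V5 = 1.00, V6 = 0.90)) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amplitude), waves), setequal(names(center), waves),
            setequal(names(width), waves))
  amplitude <- amplitude[waves]; center <- center[waves]; width <- width[waves]
  if (any(width <= 0)) stop_ecgmi("wave widths must be > 0")
  if (any(diff(center) <= 0)) stop_ecgmi("wave centers must be ordered P < Q < R < S < T")
  if (length(lead_scale) != 12) stop_ecgmi("lead_scale must have 12 entries")
  names(lead_scale) <- ECG_LEADS
  r_amp <- amplitude["R"] * lead_scale
  if (!any(r_amp[1:6] > 0) || !any(r_amp[7:12] > 0))
    stop_ecgmi("R amplitude must be positive in at least one limb and one precordial lead")
  structure(list(amplitude = amplitude, center = center, width = width,
                 lead_scale = lead_scale), class = "beat_template")
}

#' Class-conditioned MI morphology effects
#'
#' Each MI class perturbs a set of affected leads with an ST-segment shift
#' (microvolt), a Q-wave amplification factor and a probability of T-wave
#' inversion. Healthy control (HC) has no affected leads. Default affected
#' lead sets follow standard ECG territory conventions.
#'
#' @param label Class label, one of `ecg_classes()`.
#' @param leads Affected lead names (empty for HC).
#' @param st_shift ST-segment offset in microvolt applied on the affected leads.
#' @param q_amplification Multiplier (>= 1) on the Q-wave amplitude.
#' @param t_inversion_prob Probability that the T wave is inverted in an
#'   affected lead (drawn once per patient per lead).
#' @return An object of class `class_effect`.
#' @export
class_effect <- function(label, leads, st_shift = 0, q_amplification = 1,
                         t_inversion_prob = 0) {
  label <- match.arg(label, ECG_CLASSES)
  leads <- as.character(leads)
  if (!all(leads %in% ECG_LEADS))
    stop_ecgmi("unknown lead(s): %s", paste(setdiff(leads, ECG_LEADS), collapse = ", "))
  if (label == "HC" && (length(leads) > 0 || st_shift != 0 ||
                        q_amplification != 1 || t_inversion_prob != 0))
    stop_ecgmi("HC must have an empty affected-lead set and zero effects")
  if (label != "HC" && length(leads) == 0)
    stop_ecgmi("MI class %s must have a non-empty affected-lead set", label)
  if (q_amplification < 1) stop_ecgmi("q_amplification must be >= 1")
  if (t_inversion_prob < 0 || t_inversion_prob > 1)
    stop_ecgmi("t_inversion_prob must be in [0, 1]")
  structure(list(label = label, leads = leads, st_shift = st_shift,
                 q_amplification = q_amplification,
                 t_inversion_prob = t_inversion_prob), class = "class_effect")
}

#' Default MI class effects
#'
#' Territory conventions: ALMI (anterolateral) affects I, aVL, V5, V6; AMI
#' (anterior) V1-V4; ASMI (anteroseptal) V1-V3; ILMI (inferolateral) II, III,
#' aVF, V5, V6; IMI (inferior) II, III, aVF. `effect_scale` multiplies the
#' ST shift, the Q amplification excess over 1 and the T-inversion
#' probability, giving a single class-separability dial (0 = no class signal,
#' 1 = default study conditions).
#'
#' @param st_shift,q_amplification,t_inversion_prob Default effect magnitudes
#'   shared by all MI classes.
#' @param effect_scale Separability multiplier applied to all three effects.
#' @return Named list of `class_effect` objects, one per class.
#' @export
default_class_effects <- function(st_shift = 150, q_amplification = 3,
                                  t_inversion_prob = 0.5, effect_scale = 1) {
  stopifnot(effect_scale >= 0)
  s <- st_shift * effect_scale
  q <- 1 + (q_amplification - 1) * effect_scale
  ti <- min(1, t_inversion_prob * effect_scale)
  territory <- list(
    ALMI = c("I", "aVL", "V5", "V6"),
    AMI  = c("V1", "V2", "V3", "V4"),
    ASMI = c("V1", "V2", "V3"),
    ILMI = c("II", "III", "aVF", "V5", "V6"),
    IMI  = c("II", "III", "aVF"))
  out <- list(HC = class_effect("HC", character(0)))
  for (lab in names(territory))
    out[[lab]] <- class_effect(lab, territory[[lab]], s, q, ti)
  out[ECG_CLASSES]
}

#' Cohort specification
#'
#' Defines a synthetic cohort: per-class subject counts, per-class record
#' totals (records are distributed over subjects, so subjects can contribute
#' more than one record), record duration, heart rate distribution,
#' patient-level (RIV) and beat-level (AIV) relative jitter, baseline wander
#' and measurement noise, and the master seed that makes the whole cohort a
#' pure function of this object.
#'
#' @param subjects_per_class Integer scalar or length-6 vector (class order
#'   `ecg_classes()`).
#' @param records_per_class Integer scalar or length-6 vector; must be >=
#'   subjects_per_class.
#' @param duration_s Record duration in seconds. Must allow at least 35 beats
#'   at the slowest plausible heart rate (mean - 3 sd).
#' @param hr_mean,hr_sd Heart rate distribution in beats per minute; patient
#'   rates are clamped to mean +/- 3 sd.
#' @param riv_sd Patient-level relative jitter of template wave parameters.
#' @param aiv_sd Beat-level relative jitter; must be below `riv_sd` by
#'   default, reflecting that within-subject ECG variability is smaller than
#'   between-subject variability.
#' @param wander_amp,wander_band Baseline wander amplitude (microvolt) and
#'   frequency band (Hz, length 2).
#' @param noise_sd Additive white measurement noise, microvolt.
#' @param fs Sampling rate, Hz.
#' @param seed Master seed.
#' @param effects List of `class_effect` objects (default
#'   `default_class_effects()`).
#' @param template `beat_template` for the reference beat.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(subjects_per_class = 5, records_per_class = NULL,
                        duration_s = 40, hr_mean = 70, hr_sd = 5,
                        riv_sd = 0.15, aiv_sd = 0.05,
                        wander_amp = 150, wander_band = c(0.15, 0.40),
                        noise_sd = 15, fs = 1000, seed = 1,
                        effects = default_class_effects(),
                        template = beat_template()) {
  n_sub <- rep_len(as.integer(subjects_per_class), 6)
  if (is.null(records_per_class)) records_per_class <- n_sub
  n_rec <- rep_len(as.integer(records_per_class), 6)
  names(n_sub) <- names(n_rec) <- ECG_CLASSES
  if (any(n_sub < 1) || any(n_rec < 1)) stop_ecgmi("subject and record counts must be >= 1")
  if (any(n_rec < n_sub)) stop_ecgmi("records_per_class must be >= subjects_per_class")
  if (any(c(riv_sd, aiv_sd, wander_amp, noise_sd, hr_sd) < 0))
    stop_ecgmi("all variability magnitudes must be >= 0")
  if (aiv_sd >= riv_sd && riv_sd > 0)
    warning("aiv_sd >= riv_sd: beat-level variability should normally be smaller than patient-level variability")
  hr_slow <- max(40, hr_mean - 3 * hr_sd)
  min_dur <- 35 * 60 / hr_slow
  if (duration_s < min_dur)
    stop_ecgmi("duration_s = %.1f too short: need >= %.1f s for 35 beats at %.0f bpm",
               duration_s, min_dur, hr_slow)
  stopifnot(length(wander_band) == 2, wander_band[1] > 0, diff(wander_band) > 0)
  structure(list(subjects_per_class = n_sub, records_per_class = n_rec,
                 duration_s = duration_s, hr_mean = hr_mean, hr_sd = hr_sd,
                 riv_sd = riv_sd, aiv_sd = aiv_sd, wander_amp = wander_amp,
                 wander_band = wander_band, noise_sd = noise_sd, fs = fs,
                 seed = as.integer(seed), effects = effects,
                 template = template), class = "cohort_spec")
}

#' Cohort presets
#'
#' `"table1"` mirrors the PTB-derived study layout: 25/14/14/13/16/14
#' subjects for HC/ALMI/AMI/ASMI/ILMI/IMI (96 subjects) and 40 records per
#' class (240 records), records distributed unevenly over subjects.
#' `"tiny"` is a small smoke-scale cohort (5 subjects and 10 records per
#' class) for fast end-to-end runs.
#'
#' @param preset `"table1"` or `"tiny"`.
#' @param seed Master seed.
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
preset_cohort <- function(preset = c("table1", "tiny"), seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    table1 = list(subjects_per_class = c(25, 14, 14, 13, 16, 14),
                  records_per_class = 40),
    tiny   = list(subjects_per_class = 5, records_per_class = 10))
  args$seed <- seed
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}

## Patient-level template draw: RIV jitter of amplitudes/centers/widths,
## patient heart rate, and per-lead T-inversion indicator for the class.
draw_patient <- function(class_label, patient_seed, spec) {
  eff <- spec$effects[[class_label]]
  if (is.null(eff)) stop_ecgmi("unknown class label: %s", class_label)
  tpl <- spec$template
  with_seed(derive_seed(patient_seed, "patient"), {
    amp <- tpl$amplitude * (1 + spec$riv_sd * rnorm(5))
    ctr <- tpl$center * (1 + 0.3 * spec$riv_sd * rnorm(5))
    wid <- tpl$width * pmax(0.4, 1 + 0.3 * spec$riv_sd * rnorm(5))
    ## keep the wave ordering even under extreme jitter
    ctr <- sort(ctr); names(ctr) <- names(tpl$center)
    hr <- spec$hr_mean + spec$hr_sd * rnorm(1)
    hr <- min(max(hr, spec$hr_mean - 3 * spec$hr_sd), spec$hr_mean + 3 * spec$hr_sd)
    t_inv <- ECG_LEADS %in% eff$leads & runif(12) < eff$t_inversion_prob
  })
  names(t_inv) <- ECG_LEADS
  list(class_label = class_label, amplitude = amp, center = ctr, width = wid,
       lead_scale = tpl$lead_scale, hr = hr, t_inverted = t_inv, effect = eff)
}

## ST-plateau weight: 1 on [st_start, st_end], 20 ms cosine ramps outside.
st_window <- function(patient) {
  c(start = unname(patient$center["S"] + 2 * patient$width["S"]),
    end   = unname(patient$center["T"] - 2 * patient$width["T"]))
}

st_plateau <- function(t, st) {
  ramp <- 0.020
  w <- numeric(length(t))
  w[t >= st["start"] & t <= st["end"]] <- 1
  lo <- t > st["start"] - ramp & t < st["start"]
  w[lo] <- 0.5 * (1 + cos(pi * (st["start"] - t[lo]) / ramp))
  hi <- t > st["end"] & t < st["end"] + ramp
  w[hi] <- 0.5 * (1 + cos(pi * (t[hi] - st["end"]) / ramp))
  w
}

#' Generate one synthetic 12-lead ECG record
#'
#' Produces a 12 x N signal matrix at `spec$fs` Hz, quantized to 0.5
#' microvolt steps and clipped to the 16-bit range, with ground-truth R-peak
#' sample indices attached. The patient seed scopes template draws (RIV);
#' the beat seed scopes per-beat jitter, baseline wander and noise (AIV).
#' Identical `(class_label, patient_seed, beat_seed, spec)` reproduce the
#' record bit-exactly.
#'
#' @param class_label One of `ecg_classes()`.
#' @param patient_seed,beat_seed Integer seeds.
#' @param spec A [cohort_spec()].
#' @param patient_id,record_id Optional identifiers stored on the record.
#' @return An object of class `ecg_record`: list with `signals` (12 x N,
#'   microvolt), `fs`, `lead_names`, `class_label`, `r_peaks` (1-based sample
#'   indices), `patient_id`, `record_id` and the realized `patient` template.
#' @export
generate_record <- function(class_label, patient_seed, beat_seed, spec,
                            patient_id = sprintf("p%06d", patient_seed %% 1000000L),
                            record_id = sprintf("%s_r%04d", patient_id, beat_seed %% 10000L)) {
  if (!inherits(spec, "cohort_spec")) stop_ecgmi("spec must be a cohort_spec")
  if (!class_label %in% ECG_CLASSES) stop_ecgmi("unknown class label: %s", class_label)
  pat <- draw_patient(class_label, patient_seed, spec)
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  eff <- pat$effect

  with_seed(derive_seed(beat_seed, "beats"), {
    rr_mean <- 60 / pat$hr
    max_beats <- ceiling(spec$duration_s / rr_mean) + 5
    rr <- rr_mean * pmax(0.6, 1 + spec$aiv_sd * rnorm(max_beats))
    r_times <- 0.5 + cumsum(c(0, rr))
    r_times <- r_times[r_times < spec$duration_s - 0.05]
    n_beats <- length(r_times)
    amp_jit <- matrix(1 + spec$aiv_sd * rnorm(5 * n_beats), nrow = 5,
                      dimnames = list(names(pat$amplitude), NULL))
    n_sin <- 2
    wf <- matrix(runif(12 * n_sin, spec$wander_band[1], spec$wander_band[2]), n_sin, 12)
    wp <- matrix(runif(12 * n_sin, 0, 2 * pi), n_sin, 12)
    noise <- if (spec$noise_sd > 0)
      matrix(rnorm(12 * n, sd = spec$noise_sd), nrow = 12) else 0
  })

  sig <- matrix(0, 12, n, dimnames = list(ECG_LEADS, NULL))
  st <- st_window(pat)
  affected <- ECG_LEADS %in% eff$leads
  ## per-lead per-wave amplitude matrix before beat jitter
  A0 <- outer(pat$lead_scale, pat$amplitude)          # 12 x 5
  colnames(A0) <- names(pat$amplitude)
  A0[affected, "Q"] <- A0[affected, "Q"] * eff$q_amplification
  A0[pat$t_inverted, "T"] <- -A0[pat$t_inverted, "T"]

  win_lo <- pat$center["P"] - 4 * pat$width["P"] - 0.02
  win_hi <- pat$center["T"] + 4 * pat$width["T"] + 0.03
  for (b in seq_len(n_beats)) {
    i0 <- max(1L, as.integer(floor((r_times[b] + win_lo) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((r_times[b] + win_hi) * fs)) + 1L)
    t_rel <- ((i0:i1) - 1) / fs - r_times[b]
    G <- vapply(names(pat$amplitude), function(w)
      exp(-0.5 * ((t_rel - pat$center[w]) / pat$width[w])^2),
      numeric(length(t_rel)))                          # len x 5
    beat <- (A0 * rep(amp_jit[, b], each = 12)) %*% t(G)  # 12 x len
    if (eff$st_shift != 0 && any(affected))
      beat[affected, ] <- beat[affected, ] +
        eff$st_shift * rep(st_plateau(t_rel, st), each = sum(affected))
    sig[, i0:i1] <- sig[, i0:i1] + beat
  }

  if (spec$wander_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    for (l in 1:12)
      sig[l, ] <- sig[l, ] + spec$wander_amp / n_sin *
        colSums(sin(outer(2 * pi * wf[, l], tt) + wp[, l]))
  }
  sig <- sig + noise
  sig <- pmin(pmax(round(sig * 2) / 2, -16384), 16383.5)

  r_peaks <- as.integer(round(r_times * fs)) + 1L
  structure(list(patient_id = patient_id, record_id = record_id,
                 signals = sig, fs = fs, lead_names = ECG_LEADS,
                 class_label = class_label, r_peaks = r_peaks,
                 patient = pat), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s  patient %s  class %s  12 x %d @ %g Hz  %d annotated beats>\n",
              x$record_id, x$patient_id, x$class_label, ncol(x$signals),
              x$fs, length(x$r_peaks)))
  invisible(x)
}

#' Cohort manifest
#'
#' Deterministic table of every record in a cohort: patient and record IDs,
#' class, and the patient/beat seeds that reproduce each record. Records are
#' distributed over subjects unevenly (each subject gets at least one; the
#' remainder is spread by a seeded shuffle), so subjects can contribute
#' multiple records, as in clinical archives.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns patient_id, record_id, class,
#'   patient_seed, beat_seed.
#' @export
cohort_manifest <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  pat_counter <- 0L
  for (ci in seq_along(ECG_CLASSES)) {
    cl <- ECG_CLASSES[ci]
    n_sub <- spec$subjects_per_class[ci]
    n_rec <- spec$records_per_class[ci]
    counts <- rep(1L, n_sub)
    extra <- n_rec - n_sub
    if (extra > 0) {
      idx <- with_seed(derive_seed(spec$seed, "alloc", ci),
                       rep_len(sample(n_sub), extra))
      for (i in idx) counts[i] <- counts[i] + 1L
    }
    for (si in seq_len(n_sub)) {
      pat_counter <- pat_counter + 1L
      pid <- sprintf("p%03d", pat_counter)
      pseed <- derive_seed(spec$seed, "pat", ci, si)
      for (ri in seq_len(counts[si])) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid,
          record_id = sprintf("%s_r%02d", pid, ri),
          class = cl,
          patient_seed = pseed,
          beat_seed = derive_seed(spec$seed, "beat", ci, si, ri),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a full cohort
#'
#' Materializes every record in the manifest. For large cohorts prefer
#' [cohort_segments()], which streams records through preprocessing without
#' holding all raw signals in memory.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of `ecg_record`) and `manifest`.
#' @export
generate_cohort <- function(spec) {
  man <- cohort_manifest(spec)
  recs <- lapply(seq_len(nrow(man)), function(i)
    generate_record(man$class[i], man$patient_seed[i], man$beat_seed[i], spec,
                    patient_id = man$patient_id[i], record_id = man$record_id[i]))
  list(records = recs, manifest = man)
}
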