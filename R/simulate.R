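#' Finger-opposition block paradigm
#'
#' Generates the event timeline of one experimental run: a 30 s lead-in
#' rest, sixteen 10 s task blocks (eight left-hand, eight right-hand
#' finger-opposition) each followed by 15 s rest, and a final 30 s rest.
#' The block order is a pseudo-randomised constrained shuffle: the first
#' task is always left-hand and no more than `max_consecutive` consecutive
#' blocks use the same hand (avoiding anticipation and accidental frequency
#' locking to systemic oscillations).
#'
#' @param seed integer seed; the same seed yields the identical sequence.
#' @param n_blocks number of task blocks (even; half left, half right).
#' @param task_s,rest_s,lead_s block durations in seconds.
#' @param max_consecutive maximum run of same-hand blocks.
#' @return a `paradigm`: data.frame (label, onset_s, duration_s) with
#'   attribute `total_duration_s`.
#' @export
make_paradigm <- function(seed = 1L, n_blocks = 16L, task_s = 10,
                          rest_s = 15, lead_s = 30, max_consecutive = 3L) {
  if (n_blocks %% 2 != 0) stopf("n_blocks must be even")
  labels <- with_seed(seed, {
    repeat {
      rest_lab <- sample(c(rep("left", n_blocks / 2 - 1),
                           rep("right", n_blocks / 2)))
      lab <- c("left", rest_lab)
      runs <- rle(lab)$lengths
      if (max(runs) <= max_consecutive) break
    }
    lab
  })
  onset <- lead_s + (seq_len(n_blocks) - 1) * (task_s + rest_s)
  events <- rbind(
    data.frame(label = "rest", onset_s = 0, duration_s = lead_s),
    do.call(rbind, lapply(seq_len(n_blocks), function(k) {
      data.frame(label = c(labels[k], "rest"),
                 onset_s = c(onset[k], onset[k] + task_s),
                 duration_s = c(task_s, rest_s))
    })),
    data.frame(label = "rest",
               onset_s = lead_s + n_blocks * (task_s + rest_s),
               duration_s = lead_s)
  )
  rownames(events) <- NULL
  structure(events, total_duration_s = 2 * lead_s + n_blocks * (task_s + rest_s),
            class = c("paradigm", "data.frame"))
}

paradigm_total_s <- function(paradigm) attr(paradigm, "total_duration_s")

#' Canonical haemodynamic response
#'
#' Double-gamma oxyhaemoglobin impulse response, normalised so its peak
#' equals `amplitude` (micromolar) at approximately `latency_s` seconds, with
#' a late undershoot; the deoxyhaemoglobin response is the inverted, scaled
#' copy `-hb_ratio * HbO` seen in motor-cortex activation.
#'
#' @param t time in seconds (>= 0) after response onset.
#' @param amplitude peak HbO excursion in micromolar.
#' @param latency_s time-to-peak in seconds.
#' @param hb_ratio magnitude of the Hb decrease relative to the HbO increase.
#' @return matrix with columns `HbO`, `Hb` (micromolar), rows matching `t`.
#' @export
canonical_hrf <- function(t, amplitude = 1, latency_s = 6, hb_ratio = 1/3) {
  if (any(t < 0)) stopf("t must be non-negative")
  shape <- hrf_shape(t, latency_s)
  ref <- max(hrf_shape(seq(0, 40, by = 0.02), latency_s))
  hbo <- amplitude * shape / ref
  cbind(HbO = hbo, Hb = -hb_ratio * hbo)
}

hrf_shape <- function(t, latency_s) {
  a1 <- 6
  b1 <- (a1 - 1) / latency_s
  a2 <- 16
  g1 <- (b1 * t)^(a1 - 1) * exp(-b1 * t)
  g2 <- (b1 * t)^(a2 - 1) * exp(-b1 * t) / gamma(a2) * gamma(a1)
  g1 - g2 / 6
}

#' Systemic / noise configuration for the simulator
#'
#' Amplitudes are HbO-equivalent micromolar excursions applied through the
#' superficial compartment of every channel; the cardiac line lies above the
#' 0.5 Hz band edge (removed by filtering) while respiratory and Mayer waves
#' fall inside the pass band and act as realistic confounds.  Measurement
#' noise is multiplicative log-normal with standard deviation
#' `noise_floor * sqrt(A_ref / A)`, i.e. growing for dimmer (longer or worse
#' coupled) channels as in shot-noise-limited detection.
#'
#' @param cardiac_hz,resp_hz,mayer_hz systemic oscillation frequencies.
#' @param cardiac_uM,resp_uM,mayer_uM their HbO-equivalent amplitudes.
#' @param sys_hb_ratio in-phase Hb fraction of the systemic excursion.
#' @param noise_floor multiplicative intensity noise at the reference
#'   (median NN1) amplitude.
#' @param phase_noise_rad phase noise (radians) at the reference amplitude.
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(cardiac_hz = 1.1, resp_hz = 0.25, mayer_hz = 0.1,
                         cardiac_uM = 0.3, resp_uM = 0.2, mayer_uM = 0.2,
                         sys_hb_ratio = 0.3, noise_floor = 0.002,
                         phase_noise_rad = 0.002) {
  structure(as.list(environment()), class = "noise_config")
}

#' Draw per-subject simulator profiles
#'
#' Subject-to-subject variation enters through the haemodynamic amplitude,
#' latency and spatial extent of the activation, a per-hemisphere offset of
#' the activation locus relative to the probe (emulating probe-placement and
#' physiological variability), and per-channel coupling attenuation
#' (hair / contact losses).  The locus offset is the knob that separates
#' positionally invariant models from per-channel models: larger
#' `offset_sd_mm` moves the response to different voxels for different
#' subjects.
#'
#' @param n_subjects number of subjects to draw.
#' @param table a `channel_table` (for per-channel coupling factors).
#' @param seed integer seed.
#' @param amplitude_mean,amplitude_sd peak HbO amplitude distribution (uM).
#' @param latency_mean,latency_sd time-to-peak distribution (s).
#' @param sigma_mm spatial extent (Gaussian sd) of the activation.
#' @param offset_sd_mm sd of the per-hemisphere locus offset (mm).
#' @param coupling_log_sd log-sd of per-channel coupling attenuation.
#' @return list of `subject_profile` lists.
#' @export
subject_profiles <- function(n_subjects, table, seed = 1L,
                             amplitude_mean = 1.0, amplitude_sd = 0.2,
                             latency_mean = 6, latency_sd = 0.8,
                             sigma_mm = 15, offset_sd_mm = 6.5,
                             coupling_log_sd = 0.1) {
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    amp <- max(0.2, rnorm(1, amplitude_mean, amplitude_sd))
    lat <- min(8, max(4, rnorm(1, latency_mean, latency_sd)))
    off <- matrix(rnorm(4, 0, offset_sd_mm), 2, 2,
                  dimnames = list(c("left", "right"), c("x", "y")))
    structure(list(
      subject_id = sprintf("sub%02d", s),
      hrf_amplitude = amp,
      hrf_latency_s = lat,
      activation_sigma_mm = max(8, rnorm(1, sigma_mm, 2)),
      locus_offset_mm = off,
      coupling = exp(rnorm(nrow(table), 0, coupling_log_sd)),
      hb_ratio = 1/3
    ), class = "subject_profile")
  }))
}

# Convolve the task boxcar of one hand with the canonical impulse shape and
# normalise the block response peak to one.
task_regressor <- function(paradigm, hand, t, latency_s) {
  fs <- 1 / (t[2] - t[1])
  box <- rep(0, length(t))
  ev <- paradigm[paradigm$label == hand, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    idx <- which(t >= ev$onset_s[i] & t < ev$onset_s[i] + ev$duration_s[i])
    box[idx] <- 1
  }
  tk <- seq(0, 32, by = 1 / fs)
  kern <- hrf_shape(tk, latency_s)
  kern <- kern / max(kern)
  out <- stats::convolve(box, rev(kern), type = "open")[seq_along(t)]
  pk <- max(out)
  if (pk > 0) out <- out / pk
  out
}

#' Simulate one frequency-domain fNIRS run
#'
#' Forward model: per channel, the baseline amplitude and phase follow the
#' semi-infinite frequency-domain diffusion solution at the channel's
#' source-detector separation, attenuated by the subject's per-channel
#' coupling factor.  Task activation is a contralateral haemodynamic
#' response (left-hand blocks drive right-pad channels and vice versa)
#' weighted by a Gaussian of the subject's activation extent around the pad
#' locus, converted to an absorption perturbation through the haemoglobin
#' extinction spectra and seen with nearest-neighbour-dependent depth
#' weights (deeper NN2 channels carry more cortical signal; NN1 channels
#' more superficial systemic signal).  Systemic cardiac, respiratory and
#' Mayer oscillations with run-specific random phases are added to all
#' channels, and multiplicative log-normal noise scaled inversely with
#' baseline amplitude corrupts the intensities.
#'
#' @param table a `channel_table`.
#' @param paradigm a `paradigm`.
#' @param profile a `subject_profile`.
#' @param noise_cfg a [noise_config()].
#' @param seed integer seed (fixes systemic phases, jitter and noise).
#' @param props an [optical_properties()].
#' @param fs_hz sampling rate (Hz).
#' @param mod_freq_hz modulation frequency (Hz).
#' @param run_id identifier stored with the recording.
#' @param cortical_depth_w,superficial_depth_w per-NN-class weights of the
#'   cortical and superficial compartments.
#' @return a `run_recording`: list with `intensity` and `phase` arrays
#'   `[time, channel, wavelength]`, sampling metadata, the paradigm and ids.
#' @export
simulate_run <- function(table, paradigm, profile,
                         noise_cfg = noise_config(), seed = 1L,
                         props = optical_properties(), fs_hz = 39,
                         mod_freq_hz = 141e6, run_id = "run01",
                         cortical_depth_w = c(0.3, 1.0, 1.0),
                         superficial_depth_w = c(1.0, 0.7, 0.6)) {
  n_ch <- nrow(table)
  if (n_ch == 0) stopf("empty channel table")
  total_s <- paradigm_total_s(paradigm)
  n_t <- round(total_s * fs_hz)
  t <- (seq_len(n_t) - 1) / fs_hz
  wl <- props$wavelengths_nm
  eps10 <- extinction_coefficients(wl)          # log10, mm^-1 uM^-1
  ln10 <- log(10)
  hp <- attr(table, "frame")$half_pitch_mm
  layout <- attr(table, "layout")

  # per-channel, per-wavelength baseline and sensitivities
  base <- lapply(seq_along(wl), function(w)
    fd_semiinfinite_response(table$sds_mm, props$mua_mm[w], props$musp_mm[w],
                             props$n_index, mod_freq_hz))
  sens <- lapply(seq_along(wl), function(w)
    mua_sensitivity(table$sds_mm, props$mua_mm[w], props$musp_mm[w],
                    props$n_index, mod_freq_hz))

  # spatial activation weights: Gaussian around the (offset) pad locus
  cx <- table$vox_col * hp
  cy <- table$vox_row * hp
  w_spatial <- numeric(n_ch)
  for (p in c("left", "right")) {
    sel <- table$pad == p
    opt <- layout$optodes[layout$optodes$pad == p, ]
    locus <- c(mean(opt$x_mm), mean(opt$y_mm)) + profile$locus_offset_mm[p, ]
    d2 <- (cx[sel] - locus[1])^2 + (cy[sel] - locus[2])^2
    w_spatial[sel] <- exp(-d2 / (2 * profile$activation_sigma_mm^2))
  }

  s_left <- task_regressor(paradigm, "left", t, profile$hrf_latency_s)
  s_right <- task_regressor(paradigm, "right", t, profile$hrf_latency_s)
  # contralateral drive: left-hand task -> right pad
  s_contra <- cbind(left = s_right, right = s_left)

  intensity <- array(NA_real_, c(n_t, n_ch, length(wl)))
  phase <- array(NA_real_, c(n_t, n_ch, length(wl)))
  with_seed(seed, {
    cfg <- noise_cfg
    sys_phase <- runif(3, 0, 2 * pi)
    sys_jit <- runif(n_ch, 0.8, 1.2)
    hbo_sys <- cfg$cardiac_uM * sin(2 * pi * cfg$cardiac_hz * t + sys_phase[1]) +
      cfg$resp_uM * sin(2 * pi * cfg$resp_hz * t + sys_phase[2]) +
      cfg$mayer_uM * sin(2 * pi * cfg$mayer_hz * t + sys_phase[3])
    task_by_ch <- s_contra[, match(table$pad, colnames(s_contra)), drop = FALSE] # [T, ch]

    for (w in seq_along(wl)) {
      # uM -> natural-log mua perturbation (mm^-1) for task and systemic parts
      k_task <- ln10 * (eps10[w, "HbO"] - profile$hb_ratio * eps10[w, "Hb"])
      k_sys <- ln10 * (eps10[w, "HbO"] + cfg$sys_hb_ratio * eps10[w, "Hb"])
      coef_task <- k_task * profile$hrf_amplitude * w_spatial *
        cortical_depth_w[table$nn]
      coef_sys <- k_sys * sys_jit * superficial_depth_w[table$nn]

      a0 <- base[[w]]$amplitude * profile$coupling
      a_ref <- stats::median(a0[table$nn == 1])
      sig_i <- cfg$noise_floor * sqrt(a_ref / a0)
      sig_p <- cfg$phase_noise_rad * sqrt(a_ref / a0)
      noise_seed <- as.integer(floor(runif(1, 1, 2^31 - 1)))
      mixed <- cpp_sim_mix(task_by_ch, hbo_sys, coef_task, coef_sys,
                           sens[[w]]$pathlength_mm, sens[[w]]$dphase_dmua,
                           a0, base[[w]]$phase + numeric(n_ch), sig_i, sig_p,
                           noise_seed)
      intensity[, , w] <- mixed$intensity
      phase[, , w] <- mixed$phase
    }
  })

  structure(list(
    intensity = intensity, phase = phase, fs_hz = fs_hz,
    wavelengths_nm = wl, mod_freq_hz = mod_freq_hz, paradigm = paradigm,
    subject_id = profile$subject_id, run_id = run_id,
    channel_ids = table$channel_id
  ), class = "run_recording")
}

#' @export
print.run_recording <- function(x, ...) {
  cat(sprintf("run_recording %s/%s: %d channels x %d wavelengths x %d frames @ %g Hz\n",
              x$subject_id, x$run_id, dim(x$intensity)[2],
              dim(x$intensity)[3], dim(x$intensity)[1], x$fs_hz))
  invisible(x)
}

#' Contaminate channels so they fail quality control
#'
#' Replaces the intensity of a random subset of channels with a
#' spike-contaminated version (rare large positive excursions, as produced
#' by detector popping or loose contact) whose coefficient of variation
#' (std/mean) is guaranteed to reach the poor-quality threshold of 7.5.
#'
#' @param run a `run_recording`.
#' @param fraction proportion of channels to contaminate (0 <= f < 1).
#' @param seed integer seed.
#' @param spike_prob per-sample spike probability.
#' @return the modified run, with the injected channel indices in
#'   attribute `bad_channels`.
#' @export
inject_bad_channels <- function(run, fraction, seed = 1L, spike_prob = 0.005) {
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  n_ch <- dim(run$intensity)[2]
  n_bad <- ceiling(fraction * n_ch)
  if (n_bad == 0) {
    attr(run, "bad_channels") <- integer()
    return(run)
  }
  with_seed(seed, {
    bad <- sample(n_ch, n_bad)
    n_t <- dim(run$intensity)[1]
    for (ch in bad) {
      for (w in seq_len(dim(run$intensity)[3])) {
        x <- run$intensity[, ch, w]
        spikes <- rbinom(n_t, 1, spike_prob)
        s <- 2000
        repeat {
          y <- x * (1 + s * spikes)
          if (sd(y) / mean(y) >= 7.5) break
          s <- s * 2
        }
        run$intensity[, ch, w] <- y
      }
    }
    attr(run, "bad_channels") <- sort(bad)
  })
  run
}
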