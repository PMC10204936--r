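#' Preprocessing configuration
#'
#' All thresholds of the preprocessing chain with their default values:
#' channels with coefficient of variation (std/mean of raw intensity)
#' >= 7.5 are poor; a run is rejected when more than 30% of its channels
#' with source-detector separation below 30 mm are poor; channels beyond
#' 30 mm are discarded; the band-pass is a zero-phase 3rd-order Butterworth
#' at 0.01-0.5 Hz; data are resampled to 2 Hz and z-scored per channel over
#' the whole run; poor channels are replaced by their block-neighbourhood
#' average; examples are 20-frame (10 s) windows.
#'
#' @param cv_threshold poor-channel coefficient-of-variation threshold.
#' @param frac_threshold run-rejection fraction of poor short channels.
#' @param short_sds_mm separation below which a channel counts as short.
#' @param max_sds_mm separation above which channels are discarded.
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order (applied forward and backward).
#' @param target_fs resampling target rate in Hz.
#' @param frames frames per example window.
#' @param mode `"mbll"` for chromophore conversion, `"passthrough"` to
#'   forward optical density and phase unconverted.
#' @param resample_cutoff_hz,resample_transition_hz anti-alias kernel design.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(cv_threshold = 7.5, frac_threshold = 0.30,
                              short_sds_mm = 30, max_sds_mm = 30,
                              band = c(0.01, 0.5), filter_order = 3,
                              target_fs = 2, frames = 20L,
                              mode = c("mbll", "passthrough"),
                              resample_cutoff_hz = 0.8,
                              resample_transition_hz = 0.4) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "preprocess_config")
}

# reshape [ch, plane, T] <-> [T, ch*plane] for the column-wise compiled
# kernels (chromophore-style arrays with time last)
flat_time <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2], d[3]))
}
unflat_time <- function(m, d) {
  array(t(m), c(d[1], d[2], nrow(m)))
}

#' Optical-density change
#'
#' `dOD(t) = -ln(i(t) / mean(i))`, the natural-log attenuation change of
#' each channel/wavelength series relative to its own run mean.
#'
#' @param intensity strictly positive numeric vector, matrix
#'   (time x series), or array `[time, channel, wavelength]`.
#' @return object of the same shape.
#' @export
delta_od <- function(intensity) {
  bad <- which(!(intensity > 0))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(intensity) %||% length(intensity))
    stopf("non-positive intensity sample at index [%s]",
          paste(idx, collapse = ", "))
  }
  if (is.array(intensity) && length(dim(intensity)) == 3) {
    d <- dim(intensity)
    m0 <- matrix(intensity, d[1], d[2] * d[3])
    array(-log(sweep(m0, 2, colMeans(m0), "/")), d)
  } else if (is.matrix(intensity)) {
    -log(sweep(intensity, 2, colMeans(intensity), "/"))
  } else {
    -log(intensity / mean(intensity))
  }
}

#' Phase-shift change
#'
#' `dph(t) = ph(t) - mean(ph)` per channel/wavelength series.
#'
#' @param phase numeric vector, matrix (time x series) or array
#'   `[time, channel, wavelength]` of finite phases (radians).
#' @return mean-centred object of the same shape.
#' @export
delta_phase <- function(phase) {
  if (any(!is.finite(phase))) stopf("non-finite phase sample")
  if (is.array(phase) && length(dim(phase)) == 3) {
    d <- dim(phase)
    m0 <- matrix(phase, d[1], d[2] * d[3])
    array(sweep(m0, 2, colMeans(m0), "-"), d)
  } else if (is.matrix(phase)) {
    sweep(phase, 2, colMeans(phase), "-")
  } else {
    phase - mean(phase)
  }
}

#' Channel quality control
#'
#' Computes the coefficient of variation (std/mean, the inverse
#' signal-to-noise statistic) of every channel's raw intensity, taking the
#' worst (largest) value across wavelengths.  Channels at or above
#' `cv_threshold` are poor; the run is rejected when strictly more than
#' `frac_threshold` of the channels shorter than `short_sds_mm` are poor,
#' which indicates a cap-placement failure.  QC runs on raw intensity,
#' before any filtering.
#'
#' @param run a `run_recording`.
#' @param table the `channel_table` matching the run's channels.
#' @param cv_threshold,frac_threshold,short_sds_mm thresholds (see
#'   [preprocess_config()]).
#' @return a `qc_report`: list(cv, poor, rejected, frac_poor_short), with
#'   `cv` and `poor` named by channel id.
#' @export
qc_flag <- function(run, table, cv_threshold = 7.5, frac_threshold = 0.30,
                    short_sds_mm = 30) {
  stopifnot(nrow(table) == dim(run$intensity)[2])
  n_t <- dim(run$intensity)[1]
  m <- colMeans(run$intensity)                           # [ch, wl]
  v <- colMeans(run$intensity^2) - m^2
  s <- sqrt(pmax(v, 0) * n_t / (n_t - 1))                # sample sd
  cvm <- ifelse(m == 0, Inf, s / m)
  cv <- apply(cvm, 1, max)
  names(cv) <- table$channel_id
  poor <- cv >= cv_threshold
  short <- table$sds_mm < short_sds_mm
  frac <- if (any(short)) mean(poor[short]) else 0
  structure(list(cv = cv, poor = poor, rejected = frac > frac_threshold,
                 frac_poor_short = frac),
            class = "qc_report")
}

#' Discard long-separation channels
#'
#' Removes channels with source-detector separation above `max_sds_mm`
#' (the third-nearest-neighbour class, whose signal-to-noise ratio is
#' consistently poor), from the channel table and, if given, from matching
#' per-channel data arrays.
#'
#' @param table a `channel_table`.
#' @param data optional array whose first dimension indexes channels.
#' @param max_sds_mm separation cutoff in mm.
#' @return if `data` is NULL the reduced table, else
#'   `list(table = , data = )`.
#' @export
discard_long_channels <- function(table, data = NULL, max_sds_mm = 30) {
  keep <- table$sds_mm <= max_sds_mm
  if (!any(keep)) stopf("no channels remain after discarding SDS > %g mm", max_sds_mm)
  out <- subset_channel_table(table, keep)
  if (is.null(data)) return(out)
  d <- dim(data)
  list(table = out,
       data = array(data[keep, , , drop = FALSE], c(sum(keep), d[2], d[3])))
}

subset_channel_table <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, layout = attr(table, "layout"), frame = attr(table, "frame"),
            class = c("channel_table", "data.frame"))
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase
#' distortion, squared magnitude response), with odd-reflection padding of
#' the series ends.
#'
#' @param x numeric vector, matrix (time x series) or array
#'   `[channel, plane, time]`.
#' @param fs_hz sampling rate.
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth order of each pass.
#' @return filtered object of the same shape.
#' @export
bandpass <- function(x, fs_hz, low = 0.01, high = 0.5, order = 3) {
  if (!(low > 0 && high > low && high < fs_hz / 2))
    stopf("invalid band [%g, %g] Hz at fs = %g Hz", low, high, fs_hz)
  bf <- signal::butter(order, c(low, high) / (fs_hz / 2), type = "pass")
  run_filt <- function(m) cpp_filtfilt_mat(m, bf$b, bf$a,
                                           min(nrow(m) - 1L, 300L))
  if (is.array(x) && length(dim(x)) == 3) {
    unflat_time(run_filt(flat_time(x)), dim(x))
  } else if (is.matrix(x)) {
    run_filt(x)
  } else {
    drop(run_filt(matrix(x, ncol = 1)))
  }
}

#' Convert optical density to haemoglobin concentrations
#'
#' Modified Beer-Lambert inversion: for each channel the two-wavelength
#' linear system `dOD_wl = L_wl * ln(10) * (e_HbO,wl dHbO + e_Hb,wl dHb)` is
#' solved for the chromophore changes, with effective pathlengths `L_wl`
#' taken from the semi-infinite frequency-domain model at each channel's
#' separation (the amplitude derivative with respect to absorption) unless
#' supplied.  In `"passthrough"` mode the optical-density and phase-shift
#' series are forwarded unconverted as four planes per channel.
#'
#' @param dod optical-density array `[time, channel, wavelength]`.
#' @param table the matching `channel_table`.
#' @param dphase phase-shift array (required for passthrough mode).
#' @param pathlengths optional effective pathlengths: vector (per
#'   wavelength) or matrix `[channel, wavelength]`, in mm.
#' @param extinction optional decadic extinction matrix
#'   `[wavelength, c(HbO, Hb)]` in mm^-1 uM^-1.
#' @param mode `"mbll"` or `"passthrough"`.
#' @param props,mod_freq_hz forward model used to derive pathlengths.
#' @return a `chromophore_series`: list(conc `[channel, plane, time]`,
#'   planes, fs_hz unset by caller, z_scored = FALSE).
#' @export
to_chromophores <- function(dod, table, dphase = NULL, pathlengths = NULL,
                            extinction = NULL, mode = c("mbll", "passthrough"),
                            props = optical_properties(), mod_freq_hz = 141e6) {
  mode <- match.arg(mode)
  d <- dim(dod)                     # [time, channel, wavelength]
  n_t <- d[1]; n_ch <- d[2]; n_wl <- d[3]
  if (mode == "passthrough") {
    if (is.null(dphase)) stopf("passthrough mode requires dphase")
    conc <- array(NA_real_, c(n_ch, 2 * n_wl, n_t))
    for (w in seq_len(n_wl)) {
      conc[, w, ] <- t(dod[, , w])
      conc[, n_wl + w, ] <- t(dphase[, , w])
    }
    planes <- c(sprintf("OD%d", props$wavelengths_nm),
                sprintf("PH%d", props$wavelengths_nm))
    return(structure(list(conc = conc, planes = planes, z_scored = FALSE,
                          channel_ids = table$channel_id, passthrough = TRUE),
                     class = "chromophore_series"))
  }
  stopifnot(n_wl == 2, nrow(table) == n_ch)
  eps10 <- extinction %||% extinction_coefficients(props$wavelengths_nm)
  if (is.null(pathlengths)) {
    pathlengths <- default_pathlengths(table, props, mod_freq_hz)
  } else if (is.vector(pathlengths)) {
    pathlengths <- matrix(pathlengths, n_ch, 2, byrow = TRUE)
  }
  inv <- mbll_invert(dod[, , 1], dod[, , 2], pathlengths, eps10)
  conc <- array(NA_real_, c(n_ch, 2, n_t))
  conc[, 1, ] <- t(inv$hbo)
  conc[, 2, ] <- t(inv$hb)
  structure(list(conc = conc, planes = c("HbO", "Hb"), z_scored = FALSE,
                 channel_ids = table$channel_id, passthrough = FALSE),
            class = "chromophore_series")
}

# Two-wavelength MBLL inversion on [time x channel] matrices.
mbll_invert <- function(od1, od2, pathlengths, eps10) {
  ln10 <- log(10)
  a <- pathlengths[, 1] * ln10 * eps10[1, "HbO"]
  b <- pathlengths[, 1] * ln10 * eps10[1, "Hb"]
  cc <- pathlengths[, 2] * ln10 * eps10[2, "HbO"]
  dd <- pathlengths[, 2] * ln10 * eps10[2, "Hb"]
  det <- a * dd - b * cc
  if (any(abs(det) < 1e-18)) stopf("singular extinction/pathlength system")
  list(hbo = sweep(od1, 2, dd / det, "*") - sweep(od2, 2, b / det, "*"),
       hb = sweep(od2, 2, a / det, "*") - sweep(od1, 2, cc / det, "*"))
}

default_pathlengths <- function(table, props = optical_properties(),
                                mod_freq_hz = 141e6) {
  vapply(seq_along(props$wavelengths_nm), function(w)
    mua_sensitivity(table$sds_mm, props$mua_mm[w], props$musp_mm[w],
                    props$n_index, mod_freq_hz)$pathlength_mm,
    numeric(nrow(table)))
}

#' Anti-aliased resampling
#'
#' Windowed-sinc interpolation to the target rate with the kernel cutoff
#' below the output Nyquist frequency; the new length is
#' `round(duration * target_fs)`.
#'
#' @param x numeric vector, matrix (time x series), or array
#'   `[channel, plane, time]`.
#' @param fs_in input rate (Hz).
#' @param target_fs output rate (Hz).
#' @param cutoff_hz,transition_hz anti-alias kernel design parameters.
#' @return resampled object of the same kind.
#' @export
resample_series <- function(x, fs_in, target_fs = 2, cutoff_hz = 0.8,
                            transition_hz = 0.4) {
  if (fs_in < target_fs) stopf("fs_in must be >= target_fs")
  rs <- function(m) cpp_resample_mat(m, fs_in, target_fs, cutoff_hz,
                                     transition_hz)
  if (is.array(x) && length(dim(x)) == 3) {
    m <- rs(flat_time(x))
    unflat_time(m, dim(x))
  } else if (is.matrix(x)) {
    rs(x)
  } else {
    drop(rs(matrix(x, ncol = 1)))
  }
}

#' Z-score standardisation
#'
#' `Z(t) = (x(t) - mean(x)) / sd_pop(x)` per series over the whole run,
#' using the population standard deviation.  Constant series yield zeros
#' with a warning.
#'
#' @param x numeric vector, matrix (time x series) or array with time as
#'   the last dimension.
#' @return standardised object of the same shape.
#' @export
zscore_series <- function(x) {
  z <- function(m) {
    mu <- colMeans(m)
    sg <- sqrt(colMeans(sweep(m, 2, mu)^2))
    if (any(sg == 0)) {
      warning("constant series in z-score: returning zeros", call. = FALSE)
      sg[sg == 0] <- Inf
    }
    sweep(sweep(m, 2, mu), 2, sg, "/")
  }
  if (is.array(x) && length(dim(x)) == 3) {
    unflat_time(z(flat_time(x)), dim(x))
  } else if (is.matrix(x)) {
    z(x)
  } else {
    drop(z(matrix(x, ncol = 1)))
  }
}

#' Replace poor channels by their neighbourhood average
#'
#' Each poor channel's series is replaced, plane by plane, with the
#' unweighted mean of its good block-neighbourhood channels (same
#' nearest-neighbour class, same orientation for NN2, adjoining or diagonal
#' midpoints).  A poor channel with no good neighbour is an error.
#'
#' @param series a `chromophore_series`.
#' @param qc a `qc_report` covering the channels in `table`.
#' @param table the `channel_table` matching `series`.
#' @return the repaired `chromophore_series`.
#' @export
interpolate_poor <- function(series, qc, table) {
  poor_ids <- names(qc$poor)[qc$poor]
  poor_ids <- intersect(poor_ids, table$channel_id)
  if (!length(poor_ids)) return(series)
  good <- function(ids) ids[!qc$poor[ids]]
  conc0 <- series$conc
  for (id in poor_ids) {
    nb <- block_neighbourhood(id, table)
    ok <- good(nb$channel_id)
    if (!length(ok))
      stopf("poor channel '%s' has no good neighbour to interpolate from", id)
    i <- match(id, table$channel_id)
    j <- match(ok, table$channel_id)
    sub <- conc0[j, , , drop = FALSE]
    series$conc[i, , ] <- colMeans(array(sub, dim(sub)), dims = 1)
  }
  series
}

#' Split a run into labelled 20-frame windows
#'
#' One window is aligned to the onset of each 10 s task block (labelled
#' `left` or `right`) and one to the onset of each inter-task rest interval
#' (labelled `rest`); the rest following the final task merges into the
#' trailing rest period and is not windowed, giving 31 examples for the
#' default 16-block paradigm.
#'
#' @param series a `chromophore_series` at the windowing rate.
#' @param paradigm the run's `paradigm`.
#' @param fs_hz rate of `series` in Hz.
#' @param frames frames per window.
#' @param subject_id,run_id identifiers stored with the examples.
#' @return a `windowed_dataset`: list(values
#'   `[channel, plane, frame, example]`, labels, subject_id, run_id,
#'   window_index, planes, channel_ids).
#' @export
window_examples <- function(series, paradigm, fs_hz = 2, frames = 20L,
                            subject_id = "sub01", run_id = "run01") {
  n_t <- dim(series$conc)[3]
  is_task <- paradigm$label %in% c("left", "right")
  task_rows <- which(is_task)
  follows_task <- which(paradigm$label == "rest" &
                          c(FALSE, head(is_task, -1)))
  rest_rows <- head(follows_task, -1)           # last rest merges with tail
  rows <- sort(c(task_rows, rest_rows))
  onsets <- paradigm$onset_s[rows]
  labels <- paradigm$label[rows]
  start <- round(onsets * fs_hz) + 1
  if (any(start + frames - 1 > n_t))
    stopf("window extends past end of recording")
  n_ex <- length(rows)
  d <- dim(series$conc)
  values <- array(NA_real_, c(d[1], d[2], frames, n_ex))
  for (k in seq_len(n_ex))
    values[, , , k] <- series$conc[, , start[k]:(start[k] + frames - 1)]
  structure(list(
    values = values,
    labels = factor(labels, levels = c("left", "right", "rest")),
    subject_id = rep(subject_id, n_ex), run_id = rep(run_id, n_ex),
    window_index = seq_len(n_ex), frames_per_example = frames,
    planes = series$planes, channel_ids = series$channel_ids
  ), class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("windowed_dataset: %d examples (%s), %d channels x %d planes x %d frames\n",
              length(x$labels),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Combine windowed datasets
#'
#' @param datasets list of `windowed_dataset` objects over identical
#'   channels and planes.
#' @return one concatenated `windowed_dataset`.
#' @export
bind_windows <- function(datasets) {
  stopifnot(length(datasets) > 0)
  d0 <- dim(datasets[[1]]$values)[1:3]
  for (ds in datasets)
    if (!identical(dim(ds$values)[1:3], d0))
      stopf("windowed datasets have incompatible shapes")
  n <- vapply(datasets, function(d) length(d$labels), integer(1))
  values <- array(NA_real_, c(d0, sum(n)))
  at <- 0
  for (ds in datasets) {
    k <- length(ds$labels)
    values[, , , at + seq_len(k)] <- ds$values
    at <- at + k
  }
  structure(list(
    values = values,
    labels = factor(unlist(lapply(datasets, function(d) as.character(d$labels))),
                    levels = c("left", "right", "rest")),
    subject_id = unlist(lapply(datasets, `[[`, "subject_id")),
    run_id = unlist(lapply(datasets, `[[`, "run_id")),
    window_index = unlist(lapply(datasets, `[[`, "window_index")),
    frames_per_example = datasets[[1]]$frames_per_example,
    planes = datasets[[1]]$planes,
    channel_ids = datasets[[1]]$channel_ids
  ), class = "windowed_dataset")
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: optical density and phase shift, quality control on
#' raw intensity, discarding of long channels, band-pass, chromophore
#' conversion, resampling, z-scoring, neighbour interpolation of poor
#' channels, windowing.  Channel indexing is preserved through every stage.
#'
#' @param run a `run_recording`.
#' @param table the full `channel_table` for the run.
#' @param config a [preprocess_config()].
#' @return list with `windows` (a `windowed_dataset`, or NULL if the run is
#'   rejected), `qc` (the `qc_report`), and `table` (the retained channels).
#' @export
preprocess_run <- function(run, table, config = preprocess_config()) {
  stopifnot(inherits(run, "run_recording"))
  d <- dim(run$intensity)
  n_t <- d[1]
  n_ch <- d[2]
  n_wl <- d[3]
  qc <- qc_flag(run, table, config$cv_threshold, config$frac_threshold,
                config$short_sds_mm)
  keep <- table$sds_mm <= config$max_sds_mm
  if (!any(keep)) stopf("no channels remain after discarding SDS > %g mm",
                        config$max_sds_mm)
  tab <- subset_channel_table(table, keep)
  if (qc$rejected)
    return(list(windows = NULL, qc = qc, table = tab))

  # work in [time x (channel, wavelength)] matrix layout throughout
  cols <- as.vector(outer(which(keep), (seq_len(n_wl) - 1) * n_ch, "+"))
  dod <- delta_od(matrix(run$intensity, n_t, n_ch * n_wl))[, cols,
                                                           drop = FALSE]
  dod <- bandpass(dod, run$fs_hz, config$band[1], config$band[2],
                  config$filter_order)
  nk <- nrow(tab)
  if (config$mode == "passthrough") {
    dph <- delta_phase(matrix(run$phase, n_t, n_ch * n_wl))[, cols,
                                                            drop = FALSE]
    dph <- bandpass(dph, run$fs_hz, config$band[1], config$band[2],
                    config$filter_order)
    m <- cbind(dod, dph)
    planes <- c(sprintf("OD%d", run$wavelengths_nm),
                sprintf("PH%d", run$wavelengths_nm))
    passthrough <- TRUE
  } else {
    inv <- mbll_invert(dod[, seq_len(nk), drop = FALSE],
                       dod[, nk + seq_len(nk), drop = FALSE],
                       default_pathlengths(tab, mod_freq_hz = run$mod_freq_hz),
                       extinction_coefficients(run$wavelengths_nm))
    m <- cbind(inv$hbo, inv$hb)
    planes <- c("HbO", "Hb")
    passthrough <- FALSE
  }
  m <- resample_series(m, run$fs_hz, config$target_fs,
                       config$resample_cutoff_hz,
                       config$resample_transition_hz)
  m <- zscore_series(m)
  series <- structure(list(
    conc = unflat_time(m, c(nk, length(planes), nrow(m))),
    planes = planes, z_scored = TRUE, channel_ids = tab$channel_id,
    passthrough = passthrough
  ), class = "chromophore_series")
  series <- interpolate_poor(series, qc, tab)
  win <- window_examples(series, run$paradigm, config$target_fs,
                         config$frames, run$subject_id, run$run_id)
  list(windows = win, qc = qc, table = tab)
}
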