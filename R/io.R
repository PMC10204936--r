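#' Write a run recording to a plain-text bundle
#'
#' Serialises a `run_recording` as a directory containing a JSON header
#' (sampling metadata, subject/run ids, channel ids), one TSV matrix
#' (time x channel) per measure and wavelength, and a BIDS-style
#' `events.tsv` (onset, duration, trial_type) holding the paradigm.  The
#' format is lossless for the stored values and fully text-based.
#'
#' @param run a `run_recording`.
#' @param dir directory to create (must not exist unless `overwrite`).
#' @param overwrite replace an existing bundle.
#' @return `dir`, invisibly.
#' @export
write_fnirs_run <- function(run, dir, overwrite = FALSE) {
  stopifnot(inherits(run, "run_recording"))
  if (dir.exists(dir)) {
    if (!overwrite) stopf("'%s' already exists", dir)
  } else dir.create(dir, recursive = TRUE)
  header <- list(
    format = "fnirscnn-run-bundle", version = 1L,
    fs_hz = run$fs_hz, wavelengths_nm = run$wavelengths_nm,
    mod_freq_hz = run$mod_freq_hz, subject_id = run$subject_id,
    run_id = run$run_id, channel_ids = run$channel_ids,
    n_frames = dim(run$intensity)[1]
  )
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (w in seq_along(run$wavelengths_nm)) {
    for (meas in c("intensity", "phase")) {
      if (is.null(run[[meas]])) next
      d <- dim(run[[meas]])
      m <- matrix(run[[meas]][, , w], d[1], d[2])  # time x channel
      # 17 significant digits make the decimal text round-trip bit-exact
      m <- matrix(sprintf("%.17g", m), d[1], d[2])
      colnames(m) <- run$channel_ids
      data.table::fwrite(as.data.frame(m),
                         file.path(dir, sprintf("%s_wl%d.tsv", meas,
                                                run$wavelengths_nm[w])),
                         sep = "\t")
    }
  }
  write_events_tsv(run$paradigm, file.path(dir, "events.tsv"))
  invisible(dir)
}

#' Read a run bundle
#'
#' Inverse of [write_fnirs_run()].  A bundle without phase matrices (e.g.
#' continuous-wave data) loads with `phase = NULL` and attribute
#' `phase_absent = TRUE`; a missing header or intensity matrix is an error
#' naming the missing piece.
#'
#' @param dir bundle directory.
#' @return a `run_recording`.
#' @export
read_fnirs_run <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) stopf("not a run bundle: missing %s", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  n_ch <- length(h$channel_ids)
  n_wl <- length(h$wavelengths_nm)
  read_meas <- function(meas, required) {
    out <- array(NA_real_, c(h$n_frames, n_ch, n_wl))
    for (w in seq_len(n_wl)) {
      f <- file.path(dir, sprintf("%s_wl%d.tsv", meas, h$wavelengths_nm[w]))
      if (!file.exists(f)) {
        if (required) stopf("missing data block '%s'", basename(f))
        return(NULL)
      }
      m <- as.matrix(data.table::fread(f, sep = "\t"))
      if (!identical(dim(m), c(as.integer(h$n_frames), as.integer(n_ch))))
        stopf("malformed data block '%s'", basename(f))
      out[, , w] <- m
    }
    out
  }
  intensity <- read_meas("intensity", required = TRUE)
  phase <- read_meas("phase", required = FALSE)
  paradigm <- read_events_tsv(file.path(dir, "events.tsv"))
  run <- structure(list(
    intensity = intensity, phase = phase, fs_hz = h$fs_hz,
    wavelengths_nm = h$wavelengths_nm, mod_freq_hz = h$mod_freq_hz,
    paradigm = paradigm, subject_id = h$subject_id, run_id = h$run_id,
    channel_ids = h$channel_ids
  ), class = "run_recording")
  if (is.null(phase)) attr(run, "phase_absent") <- TRUE
  run
}

#' Write / read a BIDS-style events table
#'
#' @param paradigm a `paradigm`.
#' @param path TSV path.
#' @return `path` / a `paradigm`.
#' @export
write_events_tsv <- function(paradigm, path) {
  ev <- data.frame(onset = paradigm$onset_s, duration = paradigm$duration_s,
                   trial_type = paradigm$label)
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stopf("missing events table '%s'", path)
  ev <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("numeric", "numeric", "character"))
  out <- data.frame(label = ev$trial_type, onset_s = ev$onset,
                    duration_s = ev$duration)
  structure(out, total_duration_s = max(ev$onset + ev$duration),
            class = c("paradigm", "data.frame"))
}

#' Default full configuration
#'
#' One nested list holding every tunable of the pipeline: simulator
#' conditions, preprocessing thresholds and the selected model
#' hyperparameters.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    simulate = list(n_subjects = 7L, n_runs = 5L, offset_sd_mm = 6.5,
                    poor_fraction = 0.03,
                    noise = unclass(noise_config()),
                    optics = unclass(optical_properties())),
    preprocess = unclass(preprocess_config()),
    model_cnn3d = unclass(cnn3d_config()),
    model_cnn1d = unclass(cnn1d_config()),
    experiment = list(scheme = "subject_independent", n_repeats = 10L)
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, rejects unknown keys at top and second level, range
#' checks the values that have hard constraints, and merges the result over
#' [default_config()], so a partial file overrides only what it names.
#'
#' @param path YAML file.
#' @return the merged, validated configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path) %||% list()
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stopf("unknown configuration section(s): %s",
          paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad))
      stopf("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", "))
    base[[sec]] <- modifyList(base[[sec]], user[[sec]])
  }
  for (m in c("model_cnn3d", "model_cnn1d")) {
    dr <- base[[m]]$dropout_rate
    if (!is.numeric(dr) || dr < 0 || dr >= 1)
      stopf("%s$dropout_rate must lie in [0, 1)", m)
    if (base[[m]]$learning_rate <= 0) stopf("%s$learning_rate must be > 0", m)
  }
  if (base$preprocess$cv_threshold <= 0) stopf("cv_threshold must be > 0")
  base
}

#' Write a configuration as YAML
#'
#' @param config configuration list.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Short content hash of a configuration
#'
#' FNV-1a hash of the canonical serialised configuration, used to stamp
#' pipeline products with their provenance.
#'
#' @param config any R object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  # FNV-1a in double arithmetic: xor touches only the low byte, and the
  # 32-bit modular product is split 16/16 to stay within exact-double range
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- (((h %/% 65536) * 16777619) %% 65536) * 65536 + (h %% 65536) * 16777619
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}
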