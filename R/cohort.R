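#' Simulate and preprocess a whole cohort
#'
#' Convenience driver reproducing the emulated study design: `n_subjects`
#' subjects each completing `n_runs` runs of the 16-block finger-opposition
#' paradigm, every run simulated at 39 Hz and pushed through the full
#' preprocessing chain.  Raw recordings are discarded run by run, so memory
#' stays bounded; only the windowed examples are kept.  Specific runs can be
#' contaminated heavily enough to be rejected by quality control (emulating
#' cap-placement failures), and a small fraction of channels in accepted
#' runs can be made poor (they are interpolated, not dropped).
#'
#' @param n_subjects,n_runs cohort size (defaults mirror the emulated
#'   study: 7 subjects, 5 runs each).
#' @param seed base seed; paradigm, profile and noise seeds derive from it.
#' @param table full `channel_table`; defaults to the two-pad motor layout.
#' @param profiles optional list from [subject_profiles()]; drawn with
#'   `offset_sd_mm` if absent.
#' @param offset_sd_mm probe/response locus jitter across subjects (mm).
#' @param config a [preprocess_config()].
#' @param noise_cfg a [noise_config()].
#' @param poor_fraction fraction of channels made poor in accepted runs.
#' @param reject_runs optional data.frame (subject, run) of runs to
#'   contaminate into rejection.
#' @return list with `windows` (a `windowed_dataset` over all accepted
#'   runs), `table` (retained channels), `manifest` (per-run QC summary) and
#'   `n_rejected`.
#' @export
simulate_cohort_windows <- function(n_subjects = 7, n_runs = 5, seed = 1L,
                                    table = NULL, profiles = NULL,
                                    offset_sd_mm = 6.5,
                                    config = preprocess_config(),
                                    noise_cfg = noise_config(),
                                    poor_fraction = 0.03,
                                    reject_runs = NULL) {
  table <- table %||% enumerate_channels(build_motor_layout())
  profiles <- profiles %||% subject_profiles(
    n_subjects, table, seed = child_seed(seed, 1), offset_sd_mm = offset_sd_mm)
  all_windows <- list()
  manifest <- list()
  ret_table <- NULL
  n_rejected <- 0L
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_runs)) {
      run_id <- sprintf("run%02d", r)
      par_seed <- child_seed(seed, 100 * s + r)
      paradigm <- make_paradigm(par_seed)
      run <- simulate_run(table, paradigm, profiles[[s]],
                          noise_cfg = noise_cfg,
                          seed = child_seed(seed, 1000 * s + r),
                          run_id = run_id)
      force_reject <- !is.null(reject_runs) &&
        any(reject_runs$subject == s & reject_runs$run == r)
      frac <- if (force_reject) 0.5 else poor_fraction
      if (frac > 0)
        run <- inject_bad_channels(run, frac,
                                   seed = child_seed(seed, 5000 * s + r))
      res <- preprocess_run(run, table, config)
      ret_table <- res$table
      manifest[[length(manifest) + 1]] <- data.frame(
        subject_id = profiles[[s]]$subject_id, run_id = run_id,
        seed = child_seed(seed, 1000 * s + r),
        n_poor = sum(res$qc$poor),
        frac_poor_short = res$qc$frac_poor_short,
        rejected = res$qc$rejected, stringsAsFactors = FALSE)
      if (is.null(res$windows)) {
        n_rejected <- n_rejected + 1L
        next
      }
      all_windows[[length(all_windows) + 1]] <- res$windows
    }
  }
  if (!length(all_windows)) stopf("all runs were rejected")
  list(windows = bind_windows(all_windows), table = ret_table,
       manifest = do.call(rbind, manifest), n_rejected = n_rejected)
}
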