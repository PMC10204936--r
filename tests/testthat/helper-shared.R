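# Shared fixtures, computed once per test run and cached.
#
# All seeds and cohort sizes here are fixed a priori; tests never retry with
# different seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# full two-pad motor layout and its channel table
full_table <- function() cached("full_table", {
  enumerate_channels(build_motor_layout())
})

# small layout for cheap unit tests (two 3x4 pads)
small_table <- function() cached("small_table", {
  enumerate_channels(build_motor_layout(rows = 3, cols = 4))
})

# one simulated run on the small layout plus its preprocessing products
small_run <- function() cached("small_run", {
  tab <- small_table()
  par <- make_paradigm(seed = 4)
  prof <- subject_profiles(1, tab, seed = 4)[[1]]
  simulate_run(tab, par, prof, seed = 4, run_id = "run01")
})

small_pp <- function() cached("small_pp", {
  preprocess_run(small_run(), small_table())
})

# one preprocessed run on the full layout (used by structure tests)
full_pp <- function() cached("full_pp", {
  tab <- full_table()
  par <- make_paradigm(seed = 6)
  prof <- subject_profiles(1, tab, seed = 6)[[1]]
  run <- simulate_run(tab, par, prof, seed = 6, run_id = "run01")
  preprocess_run(run, tab)
})

# the emulated study cohort: 7 subjects x 5 runs with two runs contaminated
# into rejection, leaving 33 accepted runs (shared by the acceptance tests)
study_cohort <- function() cached("study_cohort", {
  simulate_cohort_windows(
    n_subjects = 7, n_runs = 5, seed = 1,
    reject_runs = data.frame(subject = c(2, 5), run = c(3, 1)))
})

# model-ordering experiment: pooled results over 5 independent jittered
# cohorts (3 subjects x 2 runs each, probe-offset jitter two optode pitches)
# x 2 training repeats = 10 seed replications.  Replicating across cohort
# draws rather than only training seeds keeps run-level sampling noise from
# dominating the scheme comparison on any single tiny cohort.
jitter_comparison <- function() cached("jitter_comparison", {
  loso_all <- list()
  mixed_all <- list()
  for (ci in 1:5) {
    co <- simulate_cohort_windows(n_subjects = 3, n_runs = 2,
                                  seed = child_seed(2, ci),
                                  offset_sd_mm = 26)
    ds <- list("cnn3d+block" = to_block(co$windows, co$table),
               "cnn1d+flat" = to_flat(co$windows, co$table))
    loso <- run_comparison(ds, scheme = "subject_independent",
                           n_repeats = 2, seed = child_seed(200, ci),
                           n_epochs = TEST_EPOCHS)
    mixed <- run_comparison(ds, scheme = "mixed", n_repeats = 2,
                            seed = child_seed(201, ci),
                            n_epochs = TEST_EPOCHS)
    loso$subject <- paste0("c", ci, "_", loso$subject)
    mixed$subject <- paste0("c", ci, "_", mixed$subject)
    loso_all[[ci]] <- loso
    mixed_all[[ci]] <- mixed
  }
  loso <- do.call(rbind, loso_all)
  mixed <- do.call(rbind, mixed_all)
  class(loso) <- c("result_table", "data.frame")
  class(mixed) <- c("result_table", "data.frame")
  list(loso = loso, mixed = mixed)
})

# reduced-epoch training schedule used throughout the tests (training-loss
# plateau is reached by epoch 3 on fold-scale synthetic data; defaults stay
# at the full 60 epochs)
TEST_EPOCHS <- 4L
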