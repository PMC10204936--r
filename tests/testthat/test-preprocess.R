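# Preprocessing chain: dOD/dphase, QC, filtering, resampling, z-scoring,
# interpolation, windowing.

fake_run <- function(intensity, table, fs_hz = 39) {
  structure(list(intensity = intensity, phase = NULL, fs_hz = fs_hz,
                 wavelengths_nm = c(690, 830), mod_freq_hz = 141e6,
                 paradigm = NULL, subject_id = "subX", run_id = "runX",
                 channel_ids = table$channel_id),
            class = "run_recording")
}

test_that("optical-density and phase changes are computed per series", {
  with_seed(41, x <- matrix(exp(rnorm(500)), 100, 5))
  od <- delta_od(x)
  expect_equal(od, -log(sweep(x, 2, colMeans(x), "/")))
  # mean attenuation change over the run is not forced to zero, but the
  # geometric-mean intensity maps to zero attenuation
  expect_equal(colMeans(exp(-od) * rep(colMeans(x), each = 100)), colMeans(x))
  expect_error(delta_od(c(1, 0, 2)), "non-positive intensity")
  expect_error(delta_od(matrix(c(1, 2, -1, 3), 2)), "\\[1, 2\\]")
  ph <- delta_phase(x)
  expect_equal(colMeans(ph), rep(0, 5), tolerance = 1e-12)
  expect_error(delta_phase(c(1, NA)), "non-finite")
  # 3D array form [time, channel, wavelength] agrees with the matrix form
  arr <- array(x, c(100, 5, 1))
  expect_equal(as.vector(delta_od(arr)), as.vector(od))
})

test_that("QC flags exactly at the CV boundary", {
  tab <- small_table()
  n_ch <- nrow(tab)
  n_t <- 400
  with_seed(42, z <- as.vector(scale(rnorm(n_t))))  # mean 0, sample sd 1
  base <- array(1, c(n_t, n_ch, 2))
  run <- fake_run(base, tab)
  # flat channels: cv 0 everywhere, nothing poor
  qc <- qc_flag(run, tab)
  expect_false(any(qc$poor))
  expect_false(qc$rejected)
  # marginally above / below the default threshold
  above <- base; above[, 1, 1] <- 1 + (7.5 + 1e-6) * z
  expect_true(qc_flag(fake_run(above, tab), tab)$poor[1])
  below <- base; below[, 1, 1] <- 1 + (7.5 - 1e-6) * z
  expect_false(qc_flag(fake_run(below, tab), tab)$poor[1])
  # equality semantics: cv exactly equal to the threshold counts as poor
  qc1 <- qc_flag(fake_run(above, tab), tab)
  cv_exact <- unname(qc1$cv[1])
  expect_true(qc_flag(fake_run(above, tab), tab,
                      cv_threshold = cv_exact)$poor[1])
  expect_false(qc_flag(fake_run(above, tab), tab,
                       cv_threshold = cv_exact * (1 + 1e-12))$poor[1])
})

test_that("run rejection triggers strictly above the 30% short fraction", {
  tab <- small_table()
  n_t <- 400
  with_seed(43, z <- as.vector(scale(rnorm(n_t))))
  short_idx <- which(tab$sds_mm < 30)
  n_short <- length(short_idx)
  k_at <- floor(0.30 * n_short)       # largest count with fraction <= 0.30
  make_qc <- function(k) {
    x <- array(1, c(n_t, nrow(tab), 2))
    for (ch in short_idx[seq_len(k)]) x[, ch, 1] <- 1 + 10 * z
    qc_flag(fake_run(x, tab), tab)
  }
  expect_true(k_at / n_short <= 0.30)
  expect_false(make_qc(k_at)$rejected)
  expect_true(make_qc(k_at + 1)$rejected)
  # equality semantics: rejection is strictly above the fraction threshold
  x1 <- array(1, c(n_t, nrow(tab), 2))
  for (ch in short_idx[seq_len(k_at + 1)]) x1[, ch, 1] <- 1 + 10 * z
  qc1 <- qc_flag(fake_run(x1, tab), tab)
  expect_false(qc_flag(fake_run(x1, tab), tab,
                       frac_threshold = qc1$frac_poor_short)$rejected)
  # a rejected run yields no windows but keeps its QC report
  x <- array(1, c(n_t, nrow(tab), 2))
  for (ch in short_idx[seq_len(k_at + 1)]) x[, ch, 1] <- 1 + 10 * z
  run <- fake_run(x, tab)
  run$phase <- array(0, dim(x))
  run$paradigm <- make_paradigm(seed = 1)
  res <- preprocess_run(run, tab)
  expect_null(res$windows)
  expect_true(res$qc$rejected)
})

test_that("the band-pass is zero phase with the specified attenuations", {
  fs <- 39
  t <- seq(0, 460 - 1 / fs, by = 1 / fs)
  amp_out <- function(f_hz) {
    y <- bandpass(sin(2 * pi * f_hz * t), fs)
    core <- y[(length(y) %/% 4):(3 * length(y) %/% 4)]
    max(abs(core))
  }
  expect_lte(-20 * log10(amp_out(0.1)), 1)     # <= 1 dB loss in band
  expect_gte(-20 * log10(amp_out(1.1)), 20)    # >= 20 dB at the cardiac line
  expect_gte(-20 * log10(amp_out(0.001)), 20)  # drift removed
  # zero phase: in-band sinusoid stays aligned with the input
  y <- bandpass(sin(2 * pi * 0.1 * t), fs)
  core <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  lag <- which.max(stats::ccf(y[core], sin(2 * pi * 0.1 * t)[core],
                              lag.max = 20, plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
  expect_error(bandpass(t, fs, low = 0.5, high = 0.01), "invalid band")
})

test_that("resampling preserves duration, constants and in-band amplitude", {
  fs <- 39
  n <- round(460 * fs)
  t <- (seq_len(n) - 1) / fs
  r <- resample_series(rep(2.5, n), fs, 2)
  expect_equal(length(r), 920)
  expect_equal(r, rep(2.5, 920), tolerance = 1e-9)
  s <- resample_series(sin(2 * pi * 0.1 * t), fs, 2)
  t2 <- (seq_len(920) - 1) / 2
  core <- 100:820
  expect_equal(s[core], sin(2 * pi * 0.1 * t2)[core], tolerance = 0.01)
  expect_error(resample_series(rep(1, 10), 1, 2), "fs_in")
})

test_that("z-scoring standardises each series with the population sd", {
  with_seed(44, x <- matrix(rnorm(600, 5, 3), 200, 3))
  z <- zscore_series(x)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(sqrt(200 / 199), 3), tolerance = 1e-9)
  expect_warning(z0 <- zscore_series(cbind(x[, 1], 7)), "constant")
  expect_equal(z0[, 2], rep(0, 200))
})

test_that("poor channels are rebuilt from their neighbourhood", {
  tab <- small_table()
  run <- small_run()
  clean <- small_pp()
  # contaminate one retained NN1 channel with guaranteed good neighbours
  kept <- clean$table
  cand <- kept$channel_id[kept$nn == 1]
  nb_counts <- vapply(cand, function(id)
    nrow(block_neighbourhood(id, kept)), integer(1))
  target <- cand[which.max(nb_counts)]
  ch <- match(target, tab$channel_id)
  bad <- run
  with_seed(45, {
    spikes <- rbinom(dim(run$intensity)[1], 1, 0.005)
    for (w in 1:2)
      bad$intensity[, ch, w] <- run$intensity[, ch, w] * (1 + 5000 * spikes)
  })
  res <- preprocess_run(bad, tab)
  expect_true(res$qc$poor[target])
  expect_false(res$qc$rejected)
  k <- match(target, res$table$channel_id)
  rebuilt <- as.vector(res$windows$values[k, 1, , ])
  original <- as.vector(clean$windows$values[k, 1, , ])
  expect_gt(cor(rebuilt, original), 0.9)
  # interpolation error when a poor channel has no good neighbour
  qc_fake <- res$qc
  nb <- block_neighbourhood(target, kept)
  qc_fake$poor[c(target, nb$channel_id)] <- TRUE
  series <- list(conc = array(0, c(nrow(kept), 2, 10)), planes = c("HbO", "Hb"),
                 channel_ids = kept$channel_id)
  expect_error(interpolate_poor(series, qc_fake, kept), "no good neighbour")
})

test_that("windowing yields 31 labelled examples per accepted run", {
  pp <- small_pp()
  w <- pp$windows
  expect_equal(length(w$labels), 31)
  expect_equal(as.vector(table(w$labels)), c(8, 8, 15))
  expect_equal(dim(w$values)[3], 20)
  expect_equal(w$frames_per_example, 20)
  # windows start exactly at event onsets (2 Hz grid)
  par <- make_paradigm(seed = 4)
  task <- par[par$label %in% c("left", "right"), ]
  expect_equal(as.character(w$labels[seq(1, 31, by = 2)]), task$label)
  expect_true(all(as.character(w$labels[seq(2, 30, by = 2)]) == "rest"))
  # too-short recording errors
  short <- list(conc = array(0, c(4, 2, 30)), planes = c("HbO", "Hb"),
                channel_ids = sprintf("C%03d", 1:4))
  expect_error(window_examples(short, par), "past end")
})

test_that("passthrough mode forwards four optical planes", {
  run <- small_run()
  tab <- small_table()
  res <- preprocess_run(run, tab, preprocess_config(mode = "passthrough"))
  expect_identical(res$windows$planes,
                   c("OD690", "OD830", "PH690", "PH830"))
  expect_equal(dim(res$windows$values)[2], 4)
  expect_equal(length(res$windows$labels), 31)
})

test_that("long-separation channels are discarded before imaging", {
  tab <- small_table()
  pp <- small_pp()
  expect_true(all(pp$table$sds_mm <= 30))
  expect_true(all(pp$table$nn <= 2))
  expect_equal(nrow(pp$table), sum(tab$sds_mm <= 30))
  expect_identical(pp$windows$channel_ids, pp$table$channel_id)
})
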