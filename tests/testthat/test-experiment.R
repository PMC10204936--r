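# Split schemes, scoring, grid search and the statistical comparison.

fake_examples <- function(n_subj = 3, n_run = 2, per = 4) {
  n <- n_subj * n_run * per
  list(subject_id = rep(sprintf("sub%02d", seq_len(n_subj)),
                        each = n_run * per),
       run_id = rep(rep(sprintf("run%02d", seq_len(n_run)), each = per),
                    n_subj),
       labels = factor(rep(c("left", "right", "rest", "rest"),
                           length.out = n),
                       levels = c("left", "right", "rest")))
}

test_that("split schemes separate sessions and subjects correctly", {
  ds <- fake_examples()
  mixed <- make_splits(ds, "mixed")
  expect_length(mixed, 1)
  f <- mixed[[1]]
  expect_setequal(c(f$train, f$test), seq_along(ds$subject_id))
  # test side is the last run of every subject; all subjects appear in both
  expect_setequal(unique(ds$subject_id[f$test]), unique(ds$subject_id))
  expect_true(all(ds$run_id[f$test] == "run02"))
  expect_setequal(unique(ds$subject_id[f$train]), unique(ds$subject_id))

  loso <- make_splits(ds, "subject_independent")
  expect_length(loso, 3)
  for (f in loso) {
    expect_length(unique(ds$subject_id[f$test]), 1)
    expect_false(unique(ds$subject_id[f$test]) %in% ds$subject_id[f$train])
    expect_setequal(c(f$train, f$test), seq_along(ds$subject_id))
  }
  # no session straddles a fold boundary in either scheme
  for (f in c(mixed, loso)) {
    ses <- paste(ds$subject_id, ds$run_id)
    expect_length(intersect(ses[f$train], ses[f$test]), 0)
  }
  one <- list(subject_id = rep("sub01", 4), run_id = rep("run01", 4))
  expect_error(make_splits(one, "subject_independent"), "2 subjects")
})

test_that("macro F1 agrees with a confusion-matrix oracle", {
  oracle <- function(pred, act, classes) {
    mean(vapply(classes, function(cl) {
      tp <- sum(pred == cl & act == cl)
      prec <- if (sum(pred == cl) == 0) NA else tp / sum(pred == cl)
      rec <- if (sum(act == cl) == 0) NA else tp / sum(act == cl)
      if (is.na(prec) && is.na(rec)) return(0)
      p <- if (is.na(prec)) 0 else prec
      r <- if (is.na(rec)) 0 else rec
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }, numeric(1)))
  }
  classes <- c("left", "right", "rest")
  with_seed(71, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      act <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      expect_equal(macro_f1(pred, act), oracle(pred, act, classes))
    }
  })
  expect_equal(macro_f1(classes, classes), 1)
  # all wrong: zero
  expect_equal(macro_f1(c("left", "right"), c("right", "left")), 0)
  # absent class drags the average down instead of being dropped
  expect_equal(macro_f1(c("left", "left"), c("left", "left")), 1 / 3)
  expect_error(macro_f1(character(), character()), "non-empty")
  expect_error(macro_f1("left", c("left", "rest")), "equal length")
})

test_that("grid search scores configurations by grouped cross-validation", {
  ds <- fake_examples(n_subj = 3, n_run = 2, per = 6)
  n <- length(ds$labels)
  with_seed(72, {
    values <- array(rnorm(5 * 8 * n, sd = 0.3), c(5, 8, n))
    # make the task classes separable so training moves the score
    values[1, , ds$labels == "left"] <- values[1, , ds$labels == "left"] + 2
    values[2, , ds$labels == "right"] <-
      values[2, , ds$labels == "right"] + 2
  })
  flat <- structure(list(values = values, labels = ds$labels,
                         subject_id = ds$subject_id, run_id = ds$run_id,
                         structure = "flat"),
                    class = c("flat_dataset", "structured_dataset"))
  grid <- list(cnn1d_config(n_filters = 4L, seed = 1),
               cnn1d_config(n_filters = 8L, seed = 1))
  gs <- grid_search(flat, grid, k = 3, n_epochs = 3)
  expect_equal(dim(gs$fold_scores), c(2, 3))
  expect_true(all(gs$fold_scores >= 0 & gs$fold_scores <= 1))
  expect_true(identical(gs$best_config, grid[[which.max(gs$results$mean_f1)]]))
  expect_error(session_folds(fake_examples(1, 2), k = 5), "at least 5")
})

test_that("ANOVA and post-hoc tests match explicit computations", {
  # balanced two-way layout: 2 models x 3 subjects x 4 repeats
  set.seed(73)
  tbl <- expand.grid(model = c("A", "B"),
                     subject = sprintf("sub%02d", 1:3),
                     repeat_idx = 1:4, stringsAsFactors = FALSE)
  eff_m <- c(A = 0.05, B = -0.05)
  eff_s <- c(sub01 = 0.02, sub02 = 0, sub03 = -0.02)
  tbl$macro_f1 <- 0.7 + eff_m[tbl$model] + eff_s[tbl$subject] +
    rnorm(nrow(tbl), sd = 0.03)
  class(tbl) <- c("result_table", "data.frame")
  rpt <- compare_stats(tbl)

  # explicit sum-of-squares decomposition (orthogonal balanced design)
  y <- tbl$macro_f1
  gm <- mean(y)
  ss <- function(f) sum(tapply(y, f, function(v) length(v) * (mean(v) - gm)^2))
  ss_m <- ss(tbl$model)
  ss_s <- ss(tbl$subject)
  ss_t <- sum((y - gm)^2)
  ss_r <- ss_t - ss_m - ss_s
  df_m <- 1
  df_r <- nrow(tbl) - 2 - 3 + 1
  f_oracle <- (ss_m / df_m) / (ss_r / df_r)
  expect_equal(rpt$anova$F, f_oracle, tolerance = 1e-10)
  expect_equal(rpt$anova$p, pf(f_oracle, df_m, df_r, lower.tail = FALSE),
               tolerance = 1e-10)

  # paired post-hoc t-test against a direct computation
  a <- tbl[tbl$model == "A", ]
  b <- tbl[tbl$model == "B", ]
  key <- function(d) paste(d$subject, d$repeat_idx)
  b <- b[match(key(a), key(b)), ]
  d <- a$macro_f1 - b$macro_f1
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(rpt$posthoc$t, t_oracle, tolerance = 1e-10)
  expect_equal(rpt$posthoc$t_squared, t_oracle^2, tolerance = 1e-10)
  expect_equal(rpt$posthoc$p,
               2 * pt(abs(t_oracle), length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_length(rpt$shapiro, 6)
  expect_true(all(rpt$shapiro > 0 & rpt$shapiro <= 1, na.rm = TRUE))
})

test_that("degenerate and malformed result tables are handled", {
  tbl <- expand.grid(model = c("A", "B"), subject = c("s1", "s2"),
                     repeat_idx = 1:3, stringsAsFactors = FALSE)
  tbl$macro_f1 <- 1   # all identical
  class(tbl) <- c("result_table", "data.frame")
  rpt <- compare_stats(tbl)
  expect_equal(rpt$anova$F, 0)
  expect_equal(rpt$anova$p, 1)
  expect_equal(rpt$posthoc$t, 0)
  expect_equal(rpt$posthoc$p, 1)
  expect_true(all(is.na(rpt$shapiro)))

  unbal <- tbl[-1, ]
  class(unbal) <- c("result_table", "data.frame")
  expect_error(compare_stats(unbal), "unbalanced")
  single <- tbl[tbl$repeat_idx == 1, ]
  class(single) <- c("result_table", "data.frame")
  expect_error(compare_stats(single), "at least 2 repeats")
})
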