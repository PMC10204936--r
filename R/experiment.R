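#' Train/test split plans
#'
#' `mixed`: one fold whose test set is a held-out collection session from
#' every subject (the last run of each subject); the test subjects appear in
#' training through their other sessions.  `subject_independent`: one fold
#' per subject (leave-one-subject-out); no example of the test subject
#' appears in training.  Both schemes guarantee that no (subject, run)
#' session contributes to both sides of a fold.
#'
#' @param dataset any dataset carrying `subject_id` and `run_id` per example.
#' @param scheme `"mixed"` or `"subject_independent"`.
#' @return list of folds, each `list(train, test, fold_id)` of example
#'   indices; attribute `scheme`.
#' @export
make_splits <- function(dataset, scheme = c("mixed", "subject_independent")) {
  scheme <- match.arg(scheme)
  subj <- dataset$subject_id
  run <- dataset$run_id
  stopifnot(length(subj) == length(run), length(subj) > 0)
  session <- paste(subj, run, sep = "/")
  folds <- if (scheme == "mixed") {
    test <- unlist(lapply(split(seq_along(subj), subj), function(ix) {
      last_run <- max(run[ix])
      ix[run[ix] == last_run]
    }), use.names = FALSE)
    list(list(train = setdiff(seq_along(subj), test), test = sort(test),
              fold_id = "held-out-session"))
  } else {
    subjects <- sort(unique(subj))
    if (length(subjects) < 2)
      stopf("subject-independent scheme needs at least 2 subjects")
    lapply(subjects, function(s)
      list(train = which(subj != s), test = which(subj == s), fold_id = s))
  }
  for (f in folds)
    if (length(intersect(session[f$train], session[f$test])))
      stopf("leakage: a session appears in both train and test")
  structure(folds, scheme = scheme)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the per-class F1 scores over the three task states.
#' A class with no true and no predicted instances contributes an F1 of 0,
#' tying the average down rather than silently dropping the class.
#'
#' @param predicted,actual factors or character vectors of equal length.
#' @param classes class set to average over.
#' @return the macro F1 in [0, 1].
#' @export
macro_f1 <- function(predicted, actual,
                     classes = c("left", "right", "rest")) {
  if (length(predicted) == 0 || length(predicted) != length(actual))
    stopf("predicted and actual must be non-empty and of equal length")
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & actual == cl)
    fp <- sum(predicted == cl & actual != cl)
    fn <- sum(predicted != cl & actual == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# deterministic assignment of whole sessions to k folds, balancing the
# number of sessions per fold; every session's class mix is (near) identical
# by paradigm design, so class proportions are preserved.
session_folds <- function(dataset, k = 5) {
  session <- paste(dataset$subject_id, dataset$run_id, sep = "/")
  sessions <- unique(session)
  if (length(sessions) < k)
    stopf("grid search needs at least %d sessions (got %d)", k,
          length(sessions))
  fold_of <- setNames(rep(seq_len(k), length.out = length(sessions)),
                      sessions)
  split(seq_along(session), fold_of[session])
}

#' Session-grouped cross-validated grid search
#'
#' Evaluates candidate hyperparameter configurations by class-stratified,
#' group-based k-fold cross-validation: whole collection sessions are
#' assigned to folds (no session's data appears in both the training and
#' validation side) and each configuration is scored by its mean validation
#' macro F1.  Held-out test sessions must be excluded from `dataset` before
#' calling.
#'
#' @param dataset a structured dataset (Block, Flat or S-by-D).
#' @param grid list of [cnn_config()] candidates.
#' @param k number of folds.
#' @param n_epochs optional override of each candidate's epoch count.
#' @param augment apply [flip_augment()] to Block training folds.
#' @return list with `best_config`, and `results` (one row per
#'   configuration: mean and sd of validation macro F1).
#' @export
grid_search <- function(dataset, grid, k = 5, n_epochs = NULL,
                        augment = FALSE) {
  stopifnot(length(grid) >= 1)
  folds <- session_folds(dataset, k)
  score <- matrix(NA_real_, length(grid), length(folds))
  for (g in seq_along(grid)) {
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      train <- setdiff(seq_along(dataset$labels), val)
      tr <- subset_examples(dataset, train)
      if (augment && inherits(dataset, "block_dataset"))
        tr <- flip_augment(tr)
      fit <- train_cnn(tr, grid[[g]], n_epochs = n_epochs)
      pred <- classify(fit, subset_examples(dataset, val))
      score[g, f] <- macro_f1(pred, dataset$labels[val])
    }
  }
  mean_f1 <- rowMeans(score)
  results <- data.frame(config = seq_along(grid), mean_f1 = mean_f1,
                        sd_f1 = apply(score, 1, sd))
  list(best_config = grid[[which.max(mean_f1)]], results = results,
       fold_scores = score)
}

#' Compare model/structure combinations under a training scheme
#'
#' Trains every supplied model on every fold of the chosen scheme, repeated
#' with `n_repeats` different training seeds, and scores macro F1 per test
#' subject.  Block training folds are flip-augmented (test folds never
#' are); all models see exactly the same example partitions.
#'
#' @param datasets named list of structured datasets built from the same
#'   windowed examples, e.g. `list("cnn3d+block" = ..., "cnn1d+flat" = ...)`.
#' @param scheme `"mixed"` or `"subject_independent"`.
#' @param n_repeats training repetitions (distinct seeds) per fold.
#' @param seed base seed; repeat seeds are derived from it.
#' @param configs optional named list of [cnn_config()] overrides per model.
#' @param n_epochs optional epoch-count override for every model.
#' @param augment_block apply mirror-flip augmentation to Block training
#'   folds.
#' @return a `result_table` data.frame: model, structure, subject,
#'   repeat_idx, seed, macro_f1.
#' @export
run_comparison <- function(datasets, scheme = "subject_independent",
                           n_repeats = 10, seed = 1L, configs = NULL,
                           n_epochs = NULL, augment_block = TRUE) {
  stopifnot(is.list(datasets), length(datasets) >= 1,
            !is.null(names(datasets)))
  lab0 <- datasets[[1]]$labels
  for (ds in datasets)
    if (!identical(as.character(ds$labels), as.character(lab0)))
      stopf("datasets must be built from the same windowed examples")
  splits <- make_splits(datasets[[1]], scheme)
  rows <- list()
  for (m in names(datasets)) {
    ds <- datasets[[m]]
    cfg <- if (!is.null(configs) && m %in% names(configs)) configs[[m]]
           else if (inherits(ds, "flat_dataset")) cnn1d_config()
           else cnn3d_config()
    for (f in seq_along(splits)) {
      tr_idx <- splits[[f]]$train
      te_idx <- splits[[f]]$test
      tr <- subset_examples(ds, tr_idx)
      attr(tr, "split_role") <- "train"
      if (augment_block && inherits(ds, "block_dataset"))
        tr <- flip_augment(tr)
      te <- subset_examples(ds, te_idx)
      attr(te, "split_role") <- "test"
      for (r in seq_len(n_repeats)) {
        cfg_r <- cfg
        cfg_r$seed <- child_seed(seed, 10000 * f + 100 * r +
                                   match(m, names(datasets)))
        fit <- train_cnn(tr, cfg_r, n_epochs = n_epochs)
        pred <- classify(fit, te)
        for (s in sort(unique(te$subject_id))) {
          sel <- te$subject_id == s
          rows[[length(rows) + 1]] <- data.frame(
            model = m, structure = ds$structure, subject = s,
            repeat_idx = r, seed = cfg_r$seed,
            macro_f1 = macro_f1(pred[sel], te$labels[sel]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("result_table", "data.frame")
  attr(out, "scheme") <- scheme
  out
}

#' Summarise a result table
#'
#' @param results a `result_table`.
#' @return data.frame of mean and sd macro F1 per (model, subject).
#' @export
summarise_results <- function(results) {
  agg <- aggregate(macro_f1 ~ model + subject, data = results,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  data.frame(model = agg$model, subject = agg$subject,
             mean_f1 = agg$macro_f1[, "mean"], sd_f1 = agg$macro_f1[, "sd"])
}

#' Statistical comparison of models
#'
#' Shapiro-Wilk normality per (model, subject) cell of the sampled macro-F1
#' scores, a two-way fixed-effects ANOVA with factors model and subject
#' (testing the model effect while controlling for between-subject
#' variation), and pairwise post-hoc t-tests between models, paired over
#' (subject, repeat).  Post-hoc p-values are reported raw (uncorrected);
#' both the t statistic and its square are emitted.  The design must be
#' balanced with at least two repeats per cell.
#'
#' @param results a `result_table` from [run_comparison()].
#' @return a `stats_report`: list(shapiro, anova, posthoc).
#' @export
compare_stats <- function(results) {
  results$model <- factor(results$model)
  results$subject <- factor(results$subject)
  counts <- table(results$model, results$subject)
  if (length(unique(as.vector(counts))) != 1)
    stopf("unbalanced design: unequal repeats per (model, subject) cell")
  if (counts[1] < 2) stopf("need at least 2 repeats per cell")

  cells <- split(results$macro_f1, list(results$model, results$subject))
  shapiro <- vapply(cells, function(v) {
    if (length(unique(v)) < 3) NA_real_ else shapiro.test(v)$p.value
  }, numeric(1))

  if (stats::var(results$macro_f1) == 0) {
    anova_row <- data.frame(F = 0, p = 1)
    models <- levels(results$model)
    pairs <- utils::combn(models, 2)
    posthoc <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                          t = 0, t_squared = 0, p = 1)
  } else {
    fit <- aov(macro_f1 ~ model + subject, data = results)
    tab <- summary(fit)[[1]]
    i <- grep("^model", trimws(rownames(tab)))
    anova_row <- data.frame(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    models <- levels(results$model)
    pairs <- utils::combn(models, 2)
    posthoc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- results[results$model == pairs[1, j], ]
      b <- results[results$model == pairs[2, j], ]
      key <- function(d) paste(d$subject, d$repeat_idx)
      b <- b[match(key(a), key(b)), ]
      diffs <- a$macro_f1 - b$macro_f1
      if (stats::var(diffs) == 0) {
        data.frame(model_a = pairs[1, j], model_b = pairs[2, j],
                   t = 0, t_squared = 0, p = 1)
      } else {
        tt <- t.test(a$macro_f1, b$macro_f1, paired = TRUE)
        data.frame(model_a = pairs[1, j], model_b = pairs[2, j],
                   t = unname(tt$statistic),
                   t_squared = unname(tt$statistic)^2, p = tt$p.value)
      }
    }))
  }
  structure(list(shapiro = shapiro, anova = anova_row, posthoc = posthoc,
                 posthoc_correction = "none (raw p-values)"),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("two-way ANOVA model effect: F = %.3f, p = %.3g\n",
              x$anova$F, x$anova$p))
  print(x$posthoc)
  invisible(x)
}
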