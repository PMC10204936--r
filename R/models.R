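#' CNN hyperparameter configuration
#'
#' The selected hyperparameters of the grid search are the defaults: the
#' spatial-temporal 3D CNN uses one convolutional stage of 16 filters with
#' temporal kernel 4 (and a 3 x 3 spatial kernel, clipped to the input when
#' smaller), two fully connected layers of 100 units with dropout 0.4; the
#' temporal 1D CNN uses 8 filters and dropout 0.8.  Both train for 60
#' epochs with batch size 50 and Adam at learning rate 0.01.
#'
#' @param arch `"cnn3d"` or `"cnn1d"`.
#' @param n_conv_layers number of convolutional stages.
#' @param n_filters filters per stage.
#' @param temporal_kernel convolution extent along time (frames).
#' @param spatial_kernel convolution extent along each spatial axis
#'   (3D architecture only; ignored for `"cnn1d"`).
#' @param n_fc_layers,fc_size hidden fully connected stage.
#' @param dropout_rate dropout on each hidden FC activation, in [0, 1).
#' @param batch_size,n_epochs,learning_rate training schedule (Adam).
#' @param seed integer driving initialisation, shuffling and dropout.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(arch = c("cnn3d", "cnn1d"), n_conv_layers = 1L,
                       n_filters = NULL, temporal_kernel = 4L,
                       spatial_kernel = 3L, n_fc_layers = 2L, fc_size = 100L,
                       dropout_rate = NULL, batch_size = 50L, n_epochs = 60L,
                       learning_rate = 0.01, seed = 1L) {
  arch <- match.arg(arch)
  n_filters <- n_filters %||% if (arch == "cnn3d") 16L else 8L
  dropout_rate <- dropout_rate %||% if (arch == "cnn3d") 0.4 else 0.8
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout must be in [0, 1)")
  if (any(c(n_conv_layers, n_filters, temporal_kernel, spatial_kernel,
            n_fc_layers, fc_size, batch_size, n_epochs) < 1) ||
      learning_rate <= 0)
    stopf("all architecture and schedule parameters must be positive")
  structure(as.list(environment()), class = "cnn_config")
}

#' @rdname cnn_config
#' @param ... overrides passed to [cnn_config()].
#' @export
cnn3d_config <- function(...) cnn_config(arch = "cnn3d", ...)

#' @rdname cnn_config
#' @export
cnn1d_config <- function(...) cnn_config(arch = "cnn1d", ...)

# dataset -> engine input array [C, T, H, W, N]
model_input <- function(dataset) {
  if (inherits(dataset, "flat_dataset")) {
    v <- dataset$values                       # [rows, frames, N]
    d <- dim(v)
    x <- aperm(v, c(2, 1, 3))                 # [frames, rows, N]
    dim(x) <- c(1L, d[2], d[1], 1L, d[3])
    x
  } else if (inherits(dataset, c("block_dataset", "sbyd_dataset"))) {
    dataset$values
  } else stopf("unsupported dataset class for CNN input")
}

engine_cfg <- function(config, input_dim) {
  n <- config$n_conv_layers
  if (config$arch == "cnn1d") {
    kh <- rep(1L, n); kw <- rep(1L, n)
  } else {
    kh <- rep(min(config$spatial_kernel, input_dim[3]), n)
    kw <- rep(min(config$spatial_kernel, input_dim[4]), n)
  }
  list(filters = rep(config$n_filters, n),
       kt = rep(config$temporal_kernel, n), kh = kh, kw = kw,
       fc_sizes = rep(config$fc_size, config$n_fc_layers),
       dropout = config$dropout_rate, batch_size = config$batch_size,
       n_epochs = config$n_epochs, learning_rate = config$learning_rate)
}

#' Train a CNN classifier
#'
#' Minimises softmax cross-entropy with Adam over the configured number of
#' epochs.  The 3D architecture convolves over time and both spatial axes of
#' Block or Source-by-Detector stacks; the 1D architecture applies the same
#' temporal filters to every row of a Flat matrix independently (no
#' cross-row mixing before the fully connected stage).  Training is
#' deterministic given `config$seed`.
#'
#' @param dataset a `block_dataset`, `sbyd_dataset` or `flat_dataset` with
#'   labels.
#' @param config a [cnn_config()]; `arch` must suit the dataset (`"cnn1d"`
#'   for flat, `"cnn3d"` otherwise).
#' @param n_epochs optional override of `config$n_epochs`.
#' @return a `fnirs_cnn` model: parameters, config, training-loss
#'   trajectory, parameter count and the class levels.
#' @export
train_cnn <- function(dataset, config = NULL, n_epochs = NULL) {
  is_flat <- inherits(dataset, "flat_dataset")
  config <- config %||% if (is_flat) cnn1d_config() else cnn3d_config()
  if (is_flat != (config$arch == "cnn1d"))
    stopf("architecture '%s' does not match dataset structure '%s'",
          config$arch, dataset$structure)
  if (!is.null(n_epochs)) config$n_epochs <- as.integer(n_epochs)
  x <- model_input(dataset)
  d <- dim(x)
  if (d[5] == 0) stopf("empty training set")
  y <- as.integer(dataset$labels) - 1L
  if (anyNA(y)) stopf("dataset labels contain NA")
  ec <- engine_cfg(config, d)
  fit <- cpp_train_cnn(as.numeric(x), as.integer(d), y,
                       nlevels(dataset$labels), ec, as.integer(config$seed))
  structure(list(arch = config$arch, structure = dataset$structure,
                 config = config, engine_cfg = ec, params = fit[
                   c("conv_w", "conv_b", "fc_w", "fc_b")],
                 input_dim = d[1:4], loss = as.numeric(fit$loss),
                 n_params = fit$n_params,
                 classes = levels(dataset$labels)),
            class = "fnirs_cnn")
}

#' @export
print.fnirs_cnn <- function(x, ...) {
  cat(sprintf("%s on %s input [%s]: %d parameters, final loss %.4f\n",
              x$arch, x$structure, paste(x$input_dim, collapse = ","),
              x$n_params, tail(x$loss, 1)))
  invisible(x)
}

#' Class probabilities for new examples
#'
#' @param object a trained `fnirs_cnn`.
#' @param dataset a structured dataset of the same kind the model was
#'   trained on.
#' @param ... unused.
#' @return matrix `[example, class]` of probabilities (rows sum to one).
#' @export
predict.fnirs_cnn <- function(object, dataset, ...) {
  x <- model_input(dataset)
  d <- dim(x)
  if (!identical(d[1:4], object$input_dim))
    stopf("input shape [%s] does not match the model contract [%s]",
          paste(d[1:4], collapse = ","),
          paste(object$input_dim, collapse = ","))
  if (d[5] == 0)
    return(matrix(numeric(), 0, length(object$classes),
                  dimnames = list(NULL, object$classes)))
  probs <- cpp_predict_cnn(object$params, as.numeric(x), as.integer(d),
                           object$engine_cfg, length(object$classes), 256L)
  colnames(probs) <- object$classes
  probs
}

#' Hard class assignments
#'
#' @inheritParams predict.fnirs_cnn
#' @param model a trained `fnirs_cnn`.
#' @return factor of predicted labels.
#' @export
classify <- function(model, dataset) {
  probs <- predict(model, dataset)
  factor(model$classes[max.col(probs, ties.method = "first")],
         levels = model$classes)
}

#' Convolutional feature maps
#'
#' Output of the convolutional stage (post-ReLU) for each example, used to
#' inspect the positional invariance of the spatial-temporal features.
#'
#' @param model a trained `fnirs_cnn`.
#' @param dataset matching structured dataset.
#' @return array `[filter, time, height, width, example]`.
#' @export
conv_feature_maps <- function(model, dataset) {
  x <- model_input(dataset)
  d <- dim(x)
  cpp_conv_features(model$params, as.numeric(x), as.integer(d),
                    model$engine_cfg, length(model$classes))
}
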