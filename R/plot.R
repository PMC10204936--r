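#' Task-averaged topographic maps of a Block dataset
#'
#' Averages the examples of one label over time and examples and draws the
#' six voxel-image layers (chromophore x channel group) as heat maps, the
#' visual check that the contralateral haemodynamic response lands where it
#' should.
#'
#' @param block a `block_dataset`.
#' @param label which examples to average (`"left"`, `"right"`, `"rest"`).
#' @param file optional PNG path; when given the plot is written there.
#' @return the `[layer, height, width]` array of averaged images, invisibly.
#' @export
plot_topo <- function(block, label = "left", file = NULL) {
  sel <- which(block$labels == label)
  if (!length(sel)) stopf("no examples labelled '%s'", label)
  v <- block$values[, , , , sel, drop = FALSE]
  img <- apply(v, c(1, 3, 4), mean)            # average time and examples
  for (l in seq_along(block$layers))
    img[l, , ][!block$mask[l, , ]] <- NA
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  old <- graphics::par(mfrow = c(2, 3), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (l in seq_along(block$layers)) {
    m <- t(img[l, dim(img)[2]:1, ])
    graphics::image(m, main = sprintf("%s (%s)", block$layers[l], label),
                    axes = FALSE, col = grDevices::hcl.colors(64, "RdBu",
                                                              rev = TRUE))
  }
  invisible(img)
}
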