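block_layer_names <- function(planes) {
  groups <- c("NN1", "NN2h", "NN2v")
  as.vector(t(outer(planes, groups, paste, sep = "-")))
}

# group key of each channel row: NN1, NN2h, NN2v (NN3 is never imaged)
channel_group <- function(table) {
  ifelse(table$nn == 1, "NN1",
         ifelse(table$orientation == "horizontal", "NN2h", "NN2v"))
}

#' Build Block image tensors
#'
#' Arranges a windowed dataset as stacks of topographic voxel images: one
#' image layer per (plane, channel-group) pair, where the groups are NN1,
#' horizontally oriented NN2 and vertically oriented NN2.  Within a layer
#' every channel's series is placed at its midpoint voxel on the shared
#' half-pitch lattice covering both pads (midline at the central column);
#' voxels carrying no channel are zero and recorded in the validity mask.
#' The two crossing diagonal channels of each NN2 cell share a midpoint, so
#' their voxel holds the mean of the co-located series; NN1 midpoints are
#' unique and recovered exactly by `block_to_series()`.
#'
#' @param windows a `windowed_dataset` restricted to NN1/NN2 channels.
#' @param table the matching `channel_table`.
#' @return a `block_dataset`: list(values `[layer, frame, height, width,
#'   example]`, mask `[layer, height, width]`, channel_map, layers, labels,
#'   subject_id, run_id, frame).
#' @export
to_block <- function(windows, table) {
  frame <- attr(table, "frame")
  if (any(table$nn > 2)) stopf("Block imaging expects NN1/NN2 channels only")
  H <- frame$height
  W <- frame$width
  planes <- windows$planes
  layers <- block_layer_names(planes)
  grp <- channel_group(table)
  d <- dim(windows$values)
  n_f <- d[3]
  n_ex <- d[4]
  idx <- match(table$channel_id, windows$channel_ids)
  if (anyNA(idx)) stopf("channel '%s' missing from windowed dataset",
                        table$channel_id[which(is.na(idx))[1]])
  values <- array(0, c(length(layers), n_f, H, W, n_ex))
  mask <- array(FALSE, c(length(layers), H, W))
  map <- NULL
  for (p in seq_along(planes)) {
    for (g in seq_along(c("NN1", "NN2h", "NN2v"))) {
      gname <- c("NN1", "NN2h", "NN2v")[g]
      l <- (p - 1) * 3 + g
      sel <- which(grp == gname)
      counts <- matrix(0L, H, W)
      for (ch in sel) {
        r <- table$vox_row[ch] + 1L
        cc <- table$vox_col[ch] + 1L
        values[l, , r, cc, ] <- values[l, , r, cc, ] +
          windows$values[idx[ch], p, , ]
        counts[r, cc] <- counts[r, cc] + 1L
        mask[l, r, cc] <- TRUE
      }
      # average channels whose midpoints coincide (crossing NN2 diagonals)
      for (v in which(counts > 1L)) {
        r <- row(counts)[v]; cc <- col(counts)[v]
        values[l, , r, cc, ] <- values[l, , r, cc, ] / counts[v]
      }
      if (length(sel))
        map <- rbind(map, data.frame(
          layer = l, plane = planes[p], group = gname,
          vox_row = table$vox_row[sel], vox_col = table$vox_col[sel],
          channel_id = table$channel_id[sel], stringsAsFactors = FALSE))
    }
  }
  structure(list(values = values, mask = mask, channel_map = map,
                 layers = layers, labels = windows$labels,
                 subject_id = windows$subject_id, run_id = windows$run_id,
                 frame = frame, structure = "block"),
            class = c("block_dataset", "structured_dataset"))
}

#' Recover channel series from a Block tensor
#'
#' Returns the content of the channel's voxel: the original series when the
#' channel owns its midpoint voxel exclusively, or the mean of the
#' co-located series when two crossing NN2 channels share the voxel.
#'
#' @param block a `block_dataset`.
#' @param channel_id,plane which series to extract.
#' @return matrix `[frame, example]`.
#' @export
block_to_series <- function(block, channel_id, plane) {
  m <- block$channel_map
  row <- m[m$channel_id == channel_id & m$plane == plane, ]
  if (nrow(row) != 1) stopf("channel '%s' plane '%s' not mapped", channel_id, plane)
  block$values[row$layer, , row$vox_row + 1L, row$vox_col + 1L, ]
}

#' Build the Flat matrix representation
#'
#' One row per (channel, plane) pair, channels in canonical table order
#' (pad, nearest-neighbour class, row-major midpoint), each row a 20-frame
#' series: the standard channels-by-time input of a temporal CNN.
#'
#' @param windows a `windowed_dataset`.
#' @param table the matching `channel_table`.
#' @return a `flat_dataset`: list(values `[row, frame, example]`, row_key,
#'   labels, subject_id, run_id).
#' @export
to_flat <- function(windows, table) {
  idx <- match(table$channel_id, windows$channel_ids)
  if (anyNA(idx)) stopf("windowed dataset does not cover the channel table")
  d <- dim(windows$values)
  planes <- windows$planes
  n_rows <- nrow(table) * length(planes)
  values <- array(NA_real_, c(n_rows, d[3], d[4]))
  key <- data.frame(channel_id = rep(table$channel_id, each = length(planes)),
                    plane = rep(planes, nrow(table)),
                    stringsAsFactors = FALSE)
  for (ch in seq_len(nrow(table)))
    for (p in seq_along(planes))
      values[(ch - 1) * length(planes) + p, , ] <- windows$values[idx[ch], p, , ]
  structure(list(values = values, row_key = key, labels = windows$labels,
                 subject_id = windows$subject_id, run_id = windows$run_id,
                 structure = "flat"),
            class = c("flat_dataset", "structured_dataset"))
}

#' Build the Source-by-Detector representation
#'
#' Arranges each plane's measurements in a source-index by detector-index
#' grid: cell (s, d) holds the channel formed by source s and detector d, or
#' zero where no such channel is retained.  Adjacent cells are generally not
#' spatially adjacent channels, which is the point: this structure carries
#' the same content as Block with the spatial relationships scrambled.
#'
#' @param windows a `windowed_dataset`.
#' @param table the matching `channel_table`.
#' @return an `sbyd_dataset`: list(values `[plane, frame, source, detector,
#'   example]`, mask `[source, detector]`, sources, detectors, labels, ...).
#' @export
to_sbyd <- function(windows, table) {
  layout <- attr(table, "layout")
  sources <- sort(unique(layout$optodes$optode_id[layout$optodes$role == "source"]))
  detectors <- sort(unique(layout$optodes$optode_id[layout$optodes$role == "detector"]))
  si <- match(table$source_id, sources)
  di <- match(table$detector_id, detectors)
  if (anyDuplicated(cbind(si, di))) stopf("duplicate source-detector pair")
  idx <- match(table$channel_id, windows$channel_ids)
  if (anyNA(idx)) stopf("windowed dataset does not cover the channel table")
  d <- dim(windows$values)
  planes <- windows$planes
  values <- array(0, c(length(planes), d[3], length(sources),
                       length(detectors), d[4]))
  mask <- matrix(FALSE, length(sources), length(detectors))
  for (ch in seq_len(nrow(table))) {
    mask[si[ch], di[ch]] <- TRUE
    for (p in seq_along(planes))
      values[p, , si[ch], di[ch], ] <- windows$values[idx[ch], p, , ]
  }
  structure(list(values = values, mask = mask, sources = sources,
                 detectors = detectors, labels = windows$labels,
                 subject_id = windows$subject_id, run_id = windows$run_id,
                 structure = "sbyd"),
            class = c("sbyd_dataset", "structured_dataset"))
}

#' Mirror a Block dataset about the frame midline
#'
#' Width-reverses every example (and the validity mask) and swaps the
#' left/right labels; rest examples keep their label.  Mirroring twice is
#' the identity.  Requires a mirror-symmetric layout (each layer's mask must
#' equal its own reflection).
#'
#' @param block a `block_dataset`.
#' @param .check_symmetry verify the mask is mirror symmetric (internal).
#' @return the mirrored `block_dataset`.
#' @export
mirror_block <- function(block, .check_symmetry = TRUE) {
  W <- dim(block$values)[4]
  rev_w <- W:1
  if (.check_symmetry) {
    for (l in seq_along(block$layers))
      if (!identical(block$mask[l, , ], block$mask[l, , rev_w]))
        stopf("layout is not mirror symmetric; flip augmentation undefined")
  }
  out <- block
  out$values <- block$values[, , , rev_w, , drop = FALSE]
  out$mask <- block$mask[, , rev_w, drop = FALSE]
  swap <- c(left = "right", right = "left", rest = "rest")
  out$labels <- factor(swap[as.character(block$labels)],
                       levels = levels(block$labels))
  out$channel_map <- NULL   # flipped examples are synthetic mirror copies
  out
}

#' Mirror-flip label-swap augmentation
#'
#' Doubles the left/right-labelled examples of a Block training set: each
#' task example gains a width-reversed copy carrying the opposite hand
#' label, exploiting the mirror symmetry of the probe and the contralateral
#' dominance of the motor response.  Rest examples are not duplicated.
#' Refuses to run on a dataset marked as test data (augmentation must never
#' cross the train/test boundary).
#'
#' @param block a `block_dataset`.
#' @return the augmented `block_dataset`; attribute `augmented` is TRUE.
#' @export
flip_augment <- function(block) {
  if (identical(attr(block, "split_role"), "test"))
    stopf("refusing to augment a test dataset")
  task <- which(block$labels %in% c("left", "right"))
  if (!length(task)) return(block)
  flipped <- mirror_block(subset_examples(block, task))
  out <- bind_structured(list(block, flipped))
  out$channel_map <- block$channel_map
  attr(out, "augmented") <- TRUE
  attr(out, "split_role") <- attr(block, "split_role")
  out
}

#' Subset a structured or windowed dataset by example
#'
#' @param ds a `windowed_dataset`, `block_dataset`, `flat_dataset` or
#'   `sbyd_dataset`.
#' @param idx example indices to keep.
#' @return the subset dataset.
#' @export
subset_examples <- function(ds, idx) {
  nd <- length(dim(example_values(ds)))
  ds_out <- ds
  ds_out$values <- index_last(ds$values, idx)
  for (f in c("labels", "subject_id", "run_id", "window_index"))
    if (!is.null(ds[[f]])) ds_out[[f]] <- ds[[f]][idx]
  ds_out
}

example_values <- function(ds) ds$values

index_last <- function(x, idx) {
  d <- dim(x)
  args <- c(list(x), rep(list(quote(expr = )), length(d) - 1), list(idx),
            list(drop = FALSE))
  do.call(`[`, args)
}

bind_structured <- function(dss) {
  d0 <- dim(dss[[1]]$values)
  nd <- length(d0)
  n <- vapply(dss, function(d) dim(d$values)[nd], integer(1))
  out <- dss[[1]]
  values <- array(0, c(d0[-nd], sum(n)))
  at <- 0
  for (ds in dss) {
    k <- dim(ds$values)[nd]
    args <- c(list(values), rep(list(quote(expr = )), nd - 1),
              list(at + seq_len(k)))
    values <- do.call(`[<-`, c(args, list(value = ds$values)))
    at <- at + k
  }
  out$values <- values
  out$labels <- factor(unlist(lapply(dss, function(d) as.character(d$labels))),
                       levels = levels(dss[[1]]$labels))
  out$subject_id <- unlist(lapply(dss, `[[`, "subject_id"))
  out$run_id <- unlist(lapply(dss, `[[`, "run_id"))
  out
}

#' @export
print.structured_dataset <- function(x, ...) {
  cat(sprintf("%s dataset: %d examples, value dims [%s]\n", x$structure,
              length(x$labels), paste(dim(x$values), collapse = ", ")))
  invisible(x)
}
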