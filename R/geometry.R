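#' High-density checkerboard optode pad
#'
#' Builds one rectangular pad of sources and detectors on a square lattice
#' with the two roles alternating in checkerboard fashion, the arrangement
#' used by standard high-density diffuse-optical-tomography arrays.  Lattice
#' positions may be masked out, e.g. to drop one corner detector and obtain
#' the 16-source / 15-detector pad used over each motor cortex.
#'
#' Coordinates are pad-plane millimetres with x rightward and y downward;
#' optode grid indices and voxel indices are 0-based.  Channel midpoints land
#' on the half-pitch lattice, so all voxel bookkeeping uses units of
#' `pitch_mm / 2`.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param pitch_mm lattice spacing in mm (13 for the motor-cortex array).
#' @param corner_role role of the optode at grid position (0, 0):
#'   `"source"` or `"detector"`.
#' @param pad which hemisphere pad this is: `"left"` or `"right"`.
#' @param mask optional integer matrix with columns (row, col), 0-based,
#'   of lattice positions to leave unpopulated.
#' @return an object of class `optode_layout`: a list with `optodes`
#'   (data.frame: optode_id, role, pad, row, col, x_mm, y_mm), `pitch_mm`,
#'   and `pad_gap_mm` (NA for a single pad).
#' @export
build_checkerboard_pad <- function(rows, cols, pitch_mm = 13,
                                   corner_role = c("source", "detector"),
                                   pad = c("left", "right"), mask = NULL) {
  corner_role <- match.arg(corner_role)
  pad <- match.arg(pad)
  if (rows < 1 || cols < 1) stopf("pad dimensions must be >= 1 (got %dx%d)", rows, cols)
  if (pitch_mm <= 0) stopf("pitch_mm must be positive")
  grid <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  if (!is.null(mask)) {
    mask <- matrix(as.integer(mask), ncol = 2)
    drop <- paste(grid$row, grid$col) %in% paste(mask[, 1], mask[, 2])
    grid <- grid[!drop, , drop = FALSE]
  }
  parity <- (grid$row + grid$col) %% 2L
  role0 <- c(source = 0L, detector = 1L)[[corner_role]]
  role <- ifelse(parity == role0, "source", "detector")
  optodes <- data.frame(
    optode_id = NA_character_,
    role = role,
    pad = pad,
    row = grid$row,
    col = grid$col,
    x_mm = grid$col * pitch_mm,
    y_mm = grid$row * pitch_mm,
    stringsAsFactors = FALSE
  )
  layout <- structure(
    list(optodes = number_optodes(optodes), pitch_mm = pitch_mm,
         pad_gap_mm = NA_real_),
    class = "optode_layout"
  )
  validate_layout(layout)
  layout
}

number_optodes <- function(optodes) {
  ord <- order(optodes$pad, optodes$role, optodes$col, optodes$row)
  optodes <- optodes[ord, , drop = FALSE]
  is_src <- optodes$role == "source"
  optodes$optode_id[is_src] <- sprintf("S%02d", seq_len(sum(is_src)))
  optodes$optode_id[!is_src] <- sprintf("D%02d", seq_len(sum(!is_src)))
  rownames(optodes) <- NULL
  optodes
}

validate_layout <- function(layout) {
  opt <- layout$optodes
  hp <- layout$pitch_mm / 2
  vx <- opt$x_mm / hp
  vy <- opt$y_mm / hp
  if (max(abs(vx - round(vx)), abs(vy - round(vy))) > 1e-6)
    stopf("optode positions do not lie on the half-pitch lattice")
  for (p in unique(opt$pad)) {
    sub <- opt[opt$pad == p, ]
    parity <- (round(sub$x_mm / layout$pitch_mm) +
               round(sub$y_mm / layout$pitch_mm)) %% 2
    tab <- table(parity, sub$role)
    if (any(rowSums(tab > 0) > 1))
      stopf("roles do not alternate in checkerboard fashion within pad '%s'", p)
  }
  invisible(layout)
}

#' Two mirror-image motor-cortex pads
#'
#' Assembles the full high-density layout: one checkerboard pad over the left
#' motor cortex and its mirror image over the right, separated by
#' `pad_gap_mm`.  The default reproduces the printed optode counts of the
#' acquisition system emulated here: two 4 x 8 pads at 13 mm pitch with one
#' corner masked, i.e. 16 sources and 15 detectors per pad.  The gap must be
#' an even multiple of the half pitch so both pads share one voxel lattice.
#'
#' @param rows,cols,pitch_mm,corner_role,mask as [build_checkerboard_pad()].
#' @param pad_gap_mm horizontal clearance between the two pads in mm.
#' @return an `optode_layout` containing both pads; the frame midline lies
#'   halfway across the combined extent.
#' @export
build_motor_layout <- function(rows = 4, cols = 8, pitch_mm = 13,
                               pad_gap_mm = 26, corner_role = "source",
                               mask = matrix(c(0L, 7L), ncol = 2)) {
  hp <- pitch_mm / 2
  if (abs(pad_gap_mm / hp - round(pad_gap_mm / hp)) > 1e-9 ||
      (round(pad_gap_mm / hp) %% 2) != 0)
    stopf("pad_gap_mm must be an even multiple of the half pitch (%g mm)", hp)
  left <- build_checkerboard_pad(rows, cols, pitch_mm, corner_role,
                                 pad = "left", mask = mask)
  lo <- left$optodes
  width_mm <- 2 * (cols - 1) * pitch_mm + pad_gap_mm
  right <- lo
  right$pad <- "right"
  right$x_mm <- width_mm - lo$x_mm
  right$col <- round(right$x_mm / pitch_mm - min(right$x_mm) / pitch_mm)
  opt <- number_optodes(rbind(lo, right))
  layout <- structure(
    list(optodes = opt, pitch_mm = pitch_mm, pad_gap_mm = pad_gap_mm),
    class = "optode_layout"
  )
  validate_layout(layout)
  layout
}

#' Mirror a layout about its vertical midline
#'
#' @param layout an `optode_layout`.
#' @return the reflected layout (x -> max(x) - x, pads swapped).
#' @export
mirror_layout <- function(layout) {
  opt <- layout$optodes
  xmax <- max(opt$x_mm) + min(opt$x_mm)
  opt$x_mm <- xmax - opt$x_mm
  opt$pad <- c(left = "right", right = "left")[opt$pad]
  opt$col <- max(opt$col) - opt$col
  layout$optodes <- number_optodes(opt)
  layout
}

nn_reference_distances <- function(pitch_mm) {
  pitch_mm * c(1, sqrt(5), 3)
}

#' Enumerate measurement channels by nearest-neighbour class
#'
#' Every same-pad source-detector pair whose Euclidean separation matches one
#' of the nearest-neighbour reference distances (13, 13*sqrt(5) ~ 29.07 and
#' 39 mm, scaled by `pitch_mm / 13`) within `tolerance_mm` becomes a channel.
#' Second-nearest-neighbour channels are split by orientation: horizontal
#' when |dx| > |dy|, vertical otherwise.  The channel midpoint (the voxel the
#' measurement is assigned to) is the arithmetic mean of the source and
#' detector positions, expressed on the 0-based half-pitch voxel lattice.
#'
#' @param layout an `optode_layout`.
#' @param max_nn highest nearest-neighbour class to enumerate (1, 2 or 3).
#' @param tolerance_mm distance tolerance for classification.
#' @return a `channel_table`: a data.frame with columns channel_id,
#'   source_id, detector_id, pad, sds_mm, nn, orientation, vox_col, vox_row,
#'   ordered by (pad, nn, row-major midpoint), with the layout and voxel
#'   frame stored as attributes.
#' @export
enumerate_channels <- function(layout, max_nn = 3, tolerance_mm = 0.5) {
  stopifnot(inherits(layout, "optode_layout"), max_nn %in% 1:3)
  opt <- layout$optodes
  src <- opt[opt$role == "source", ]
  det <- opt[opt$role == "detector", ]
  refs <- nn_reference_distances(layout$pitch_mm)[seq_len(max_nn)]
  hp <- layout$pitch_mm / 2

  rows <- list()
  if (nrow(src) > 0 && nrow(det) > 0) {
    for (i in seq_len(nrow(src))) {
      same_pad <- det$pad == src$pad[i]
      if (!any(same_pad)) next
      d <- det[same_pad, , drop = FALSE]
      dx <- d$x_mm - src$x_mm[i]
      dy <- d$y_mm - src$y_mm[i]
      dist <- sqrt(dx^2 + dy^2)
      hits <- abs(outer(dist, refs, "-")) <= tolerance_mm
      n_hits <- rowSums(hits)
      if (any(n_hits > 1))
        stopf("ambiguous channel classification: pair within %g mm of two NN references", tolerance_mm)
      sel <- which(n_hits == 1)
      for (j in sel) {
        nn <- which(hits[j, ])
        orientation <- "none"
        if (nn == 2) orientation <- if (abs(dx[j]) > abs(dy[j])) "horizontal" else "vertical"
        mx <- (src$x_mm[i] + d$x_mm[j]) / 2
        my <- (src$y_mm[i] + d$y_mm[j]) / 2
        vc <- mx / hp
        vr <- my / hp
        if (abs(vc - round(vc)) > 1e-6 || abs(vr - round(vr)) > 1e-6)
          stopf("channel midpoint not representable on the half-pitch lattice")
        rows[[length(rows) + 1]] <- data.frame(
          source_id = src$optode_id[i], detector_id = d$optode_id[j],
          pad = src$pad[i], sds_mm = dist[j], nn = nn,
          orientation = orientation, vox_col = as.integer(round(vc)),
          vox_row = as.integer(round(vr)), stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), detector_id = character(),
               pad = character(), sds_mm = numeric(), nn = integer(),
               orientation = character(), vox_col = integer(),
               vox_row = integer(), stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("source_id", "detector_id")]))
    stopf("duplicate source-detector pair in channel table")
  ord <- order(tab$pad, tab$nn, tab$vox_row, tab$vox_col)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(channel_id = sprintf("C%03d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  all_v <- c(layout$optodes$x_mm, layout$optodes$y_mm)
  frame <- list(
    width = as.integer(round(max(layout$optodes$x_mm) / hp)) + 1L,
    height = as.integer(round(max(layout$optodes$y_mm) / hp)) + 1L,
    half_pitch_mm = hp
  )
  structure(tab, layout = layout, frame = frame,
            class = c("channel_table", "data.frame"))
}

#' @export
print.channel_table <- function(x, ...) {
  cat(sprintf("channel_table: %d channels (NN counts: %s), frame %dx%d voxels\n",
              nrow(x),
              paste(sprintf("NN%d=%d", sort(unique(x$nn)),
                            as.vector(table(x$nn))), collapse = ", "),
              attr(x, "frame")$height, attr(x, "frame")$width))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Voxel-lattice neighbour offsets for each channel group.  NN1 midpoints sit
# on a 45-degree-rotated square lattice (edge midpoints of the optode grid),
# so its 8-neighbourhood is the four diagonal offsets plus the four
# two-voxel axial offsets; NN2/NN3 group midpoints sit on an axis-aligned
# lattice of stride two voxels.
group_neighbour_offsets <- function(nn) {
  if (nn == 1) {
    cbind(c(-1, -1, 1, 1, -2, 2, 0, 0), c(-1, 1, -1, 1, 0, 0, -2, 2))
  } else {
    cbind(c(-2, 2, 0, 0, -2, -2, 2, 2), c(0, 0, -2, 2, -2, 2, -2, 2))
  }
}

#' Surrounding channels of the same class
#'
#' Returns the channels that adjoin `channel_id` in its own group's native
#' midpoint grid: same nearest-neighbour class, same orientation for NN2,
#' same pad, and immediately adjacent or diagonal midpoints (up to eight
#' surrounding voxels; NN2 voxels can carry two crossing channels each, so
#' the result can exceed eight channels).  These are the channels used to
#' patch over a poor-quality channel.
#'
#' @param channel_id a channel id present in `table`.
#' @param table a `channel_table`.
#' @return the subset of `table` containing the neighbours (possibly empty).
#' @export
block_neighbourhood <- function(channel_id, table) {
  i <- match(channel_id, table$channel_id)
  if (is.na(i)) stopf("channel '%s' not found in table", channel_id)
  ref <- table[i, ]
  same <- table$nn == ref$nn & table$orientation == ref$orientation &
    table$pad == ref$pad & table$channel_id != ref$channel_id
  off <- group_neighbour_offsets(ref$nn)
  key <- paste(ref$vox_col + off[, 1], ref$vox_row + off[, 2])
  hit <- same & paste(table$vox_col, table$vox_row) %in% key
  table[hit, , drop = FALSE]
}

#' Write / read a channel table as TSV
#'
#' @param table a `channel_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_channel_tsv <- function(table, path) {
  cols <- c("channel_id", "source_id", "detector_id", "pad", "sds_mm", "nn",
            "orientation", "vox_col", "vox_row")
  write.table(as.data.frame(table)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a layout to JSON
#'
#' @param layout an `optode_layout`.
#' @param path file path ending in .json.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  doc <- list(pitch_mm = layout$pitch_mm, pad_gap_mm = layout$pad_gap_mm,
              optodes = layout$optodes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout from JSON
#'
#' @param path a file written by [write_layout_json()].
#' @return an `optode_layout`.
#' @export
read_layout_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- structure(
    list(optodes = as.data.frame(doc$optodes), pitch_mm = doc$pitch_mm,
         pad_gap_mm = doc$pad_gap_mm %||% NA_real_),
    class = "optode_layout"
  )
  validate_layout(layout)
  layout
}
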