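# Probe geometry: pads, channel enumeration, neighbourhoods, serialisation.

brute_force_channels <- function(layout, max_nn = 3, tolerance_mm = 0.5) {
  opt <- layout$optodes
  src <- opt[opt$role == "source", ]
  det <- opt[opt$role == "detector", ]
  refs <- layout$pitch_mm * c(1, sqrt(5), 3)[seq_len(max_nn)]
  out <- NULL
  for (i in seq_len(nrow(src))) for (j in seq_len(nrow(det))) {
    if (src$pad[i] != det$pad[j]) next
    d <- sqrt((src$x_mm[i] - det$x_mm[j])^2 + (src$y_mm[i] - det$y_mm[j])^2)
    hit <- which(abs(d - refs) <= tolerance_mm)
    if (length(hit) == 1)
      out <- rbind(out, data.frame(source_id = src$optode_id[i],
                                   detector_id = det$optode_id[j],
                                   nn = hit, stringsAsFactors = FALSE))
  }
  out
}

test_that("channel enumeration matches a brute-force oracle on random layouts", {
  with_seed(11, {
    for (trial in 1:12) {
      rows <- sample(2:6, 1)
      cols <- sample(2:6, 1)
      n_mask <- sample(0:2, 1)
      mask <- if (n_mask > 0)
        cbind(sample(0:(rows - 1), n_mask, replace = TRUE),
              sample(0:(cols - 1), n_mask, replace = TRUE)) else NULL
      lay <- build_checkerboard_pad(rows, cols, pitch_mm = 13,
                                    corner_role = sample(c("source",
                                                           "detector"), 1),
                                    pad = "left", mask = mask)
      tab <- enumerate_channels(lay)
      oracle <- brute_force_channels(lay)
      key <- function(d) sort(paste(d$source_id, d$detector_id, d$nn))
      if (is.null(oracle)) {
        expect_equal(nrow(tab), 0)
      } else {
        expect_identical(key(as.data.frame(tab)), key(oracle))
      }
    }
  })
})

test_that("the default motor layout has the expected structure", {
  lay <- build_motor_layout()
  opt <- lay$optodes
  expect_equal(sum(opt$role == "source"), 32)    # 16 per pad
  expect_equal(sum(opt$role == "detector"), 30)  # 15 per pad
  tab <- full_table()
  expect_equal(as.vector(table(tab$nn)), c(100, 124, 52))
  expect_equal(sum(tab$nn == 2 & tab$orientation == "horizontal"), 70)
  expect_equal(sum(tab$nn == 2 & tab$orientation == "vertical"), 54)
  fr <- attr(tab, "frame")
  expect_equal(fr$height, 7)
  expect_equal(fr$width, 33)
  expect_equal(fr$half_pitch_mm, 6.5)
  # separations match the three reference distances
  expect_true(all(abs(tab$sds_mm - c(13, 13 * sqrt(5), 39)[tab$nn]) < 1e-9))
  # channel ordering: pad, nn class, then row-major midpoint
  ord <- order(tab$pad, tab$nn, tab$vox_row, tab$vox_col)
  expect_identical(ord, seq_len(nrow(tab)))
})

test_that("the two pads are mirror images sharing one voxel lattice", {
  lay <- build_motor_layout()
  tab <- full_table()
  W <- attr(tab, "frame")$width
  # reflecting the table about the midline maps it onto itself with pads
  # swapped: same multiset of (nn, orientation, reflected voxel) keys
  key <- function(pad, nn, o, col, row) sort(paste(pad, nn, o, col, row))
  refl <- key(c(left = "right", right = "left")[tab$pad], tab$nn,
              tab$orientation, (W - 1) - tab$vox_col, tab$vox_row)
  expect_identical(refl, key(tab$pad, tab$nn, tab$orientation,
                             tab$vox_col, tab$vox_row))
  # mirror_layout is an involution on positions
  lay2 <- mirror_layout(mirror_layout(lay))
  expect_equal(sort(paste(lay2$optodes$role, lay2$optodes$pad,
                          lay2$optodes$x_mm, lay2$optodes$y_mm)),
               sort(paste(lay$optodes$role, lay$optodes$pad,
                          lay$optodes$x_mm, lay$optodes$y_mm)))
})

test_that("invalid geometries are rejected", {
  expect_error(build_checkerboard_pad(0, 3), "dimensions")
  expect_error(build_motor_layout(pad_gap_mm = 19.5), "even multiple")
  lay <- build_motor_layout()
  # ambiguity: tolerance so large the NN2 distance also matches the NN3
  # reference (39 - 13 * sqrt(5) < 10)
  expect_error(enumerate_channels(lay, tolerance_mm = 10), "ambiguous")
})

test_that("block neighbourhoods stay within group and adjacency", {
  tab <- full_table()
  with_seed(21, ids <- sample(tab$channel_id, 25))
  hp <- attr(tab, "frame")$half_pitch_mm
  for (id in ids) {
    ref <- tab[tab$channel_id == id, ]
    nb <- block_neighbourhood(id, tab)
    # up to 8 surrounding voxels; NN2 voxels can carry 2 crossing channels
    expect_lte(nrow(nb), 16)
    expect_lte(nrow(unique(nb[, c("vox_row", "vox_col")])), 8)
    if (nrow(nb)) {
      expect_true(all(nb$nn == ref$nn))
      expect_true(all(nb$pad == ref$pad))
      expect_true(all(nb$orientation == ref$orientation))
      dv <- pmax(abs(nb$vox_col - ref$vox_col), abs(nb$vox_row - ref$vox_row))
      expect_true(all(dv >= 1 & dv <= 2))
    }
  }
  # every retained (NN1/NN2) channel has at least one neighbour
  kept <- tab[tab$nn <= 2, ]
  n_nb <- vapply(kept$channel_id,
                 function(id) nrow(block_neighbourhood(id, tab)), integer(1))
  expect_true(all(n_nb >= 1))
  expect_error(block_neighbourhood("C999", tab), "not found")
})

test_that("layout JSON and channel TSV round-trip", {
  lay <- build_motor_layout()
  f <- tempfile(fileext = ".json")
  write_layout_json(lay, f)
  lay2 <- read_layout_json(f)
  expect_equal(lay2$pitch_mm, lay$pitch_mm)
  expect_equal(lay2$pad_gap_mm, lay$pad_gap_mm)
  expect_equal(as.data.frame(lay2$optodes), as.data.frame(lay$optodes))
  tab <- full_table()
  tf <- tempfile(fileext = ".tsv")
  write_channel_tsv(tab, tf)
  back <- read.table(tf, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back$channel_id, tab$channel_id)
  expect_equal(back$sds_mm, tab$sds_mm, tolerance = 1e-9)
  unlink(c(f, tf))
})
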