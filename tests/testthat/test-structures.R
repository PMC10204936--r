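# Block / Flat / Source-by-Detector tensors, mirroring and augmentation.

test_that("Block imaging is lossless and mask-consistent", {
  pp <- full_pp()
  blk <- to_block(pp$windows, pp$table)
  expect_s3_class(blk, "block_dataset")
  expect_equal(dim(blk$values), c(6, 20, 7, 33, 31))
  expect_identical(blk$layers,
                   c("HbO-NN1", "HbO-NN2h", "HbO-NN2v",
                     "Hb-NN1", "Hb-NN2h", "Hb-NN2v"))
  # every voxel holds the mean of its co-located channel series (crossing
  # NN2 diagonals share a midpoint; NN1 midpoints are exclusive)
  grp <- with(pp$table, ifelse(nn == 1, "NN1",
                               ifelse(orientation == "horizontal",
                                      "NN2h", "NN2v")))
  with_seed(51, chk <- sample(pp$table$channel_id, 20))
  for (id in chk) {
    j <- match(id, pp$table$channel_id)
    sh <- pp$table$channel_id[grp == grp[j] &
                                pp$table$vox_row == pp$table$vox_row[j] &
                                pp$table$vox_col == pp$table$vox_col[j]]
    expect_lte(length(sh), 2)
    if (pp$table$nn[j] == 1) expect_length(sh, 1)
    ks <- match(sh, pp$windows$channel_ids)
    for (p in 1:2) {
      v <- pp$windows$values[ks, p, , , drop = FALSE]
      expect_equal(block_to_series(blk, id, pp$windows$planes[p]),
                   apply(v, c(3, 4), mean))
    }
  }
  # mask marks exactly the distinct populated voxels; everything else is 0
  map <- blk$channel_map
  expect_equal(sum(blk$mask),
               sum(!duplicated(map[, c("layer", "vox_row", "vox_col")])))
  for (l in 1:6) {
    vmax <- apply(abs(blk$values[l, , , , ]), c(2, 3), max)  # [H, W]
    expect_true(all(vmax[!blk$mask[l, , ]] == 0))
    expect_true(all(vmax[blk$mask[l, , ]] > 0))
  }
  # at most two channels per voxel, and only in the NN2 layers
  cnt <- table(paste(map$layer, map$vox_row, map$vox_col))
  expect_true(all(cnt <= 2))
  nn1_layers <- which(grepl("NN1", blk$layers))
  expect_false(anyDuplicated(
    map[map$layer %in% nn1_layers,
        c("layer", "vox_row", "vox_col")]) > 0)
  # NN3 channels are not imageable
  tab3 <- small_table()
  win <- small_pp()$windows
  expect_error(to_block(win, tab3), "NN1/NN2")
})

test_that("Flat matrices preserve series and canonical row order", {
  pp <- full_pp()
  flt <- to_flat(pp$windows, pp$table)
  expect_s3_class(flt, "flat_dataset")
  expect_equal(dim(flt$values), c(2 * nrow(pp$table), 20, 31))
  expect_equal(nrow(flt$row_key), 2 * nrow(pp$table))
  with_seed(52, rows <- sample(nrow(flt$row_key), 20))
  for (r in rows) {
    id <- flt$row_key$channel_id[r]
    p <- match(flt$row_key$plane[r], pp$windows$planes)
    k <- match(id, pp$windows$channel_ids)
    expect_equal(flt$values[r, , ], pp$windows$values[k, p, , ])
  }
  # rows grouped per channel in table order
  expect_identical(unique(flt$row_key$channel_id), pp$table$channel_id)
})

test_that("Source-by-Detector carries the same content, scrambled", {
  pp <- full_pp()
  sb <- to_sbyd(pp$windows, pp$table)
  expect_s3_class(sb, "sbyd_dataset")
  expect_equal(sum(sb$mask), nrow(pp$table))
  d <- dim(sb$values)
  expect_equal(d[1], 2)      # planes
  expect_equal(d[2], 20)     # frames
  expect_equal(d[5], 31)
  # one spot check: channel series lands at its (source, detector) cell
  ch <- pp$table[5, ]
  si <- match(ch$source_id, sb$sources)
  di <- match(ch$detector_id, sb$detectors)
  k <- match(ch$channel_id, pp$windows$channel_ids)
  expect_equal(sb$values[1, , si, di, ], pp$windows$values[k, 1, , ])
  expect_true(sb$mask[si, di])
})

test_that("mirroring flips geometry and labels and is an involution", {
  pp <- full_pp()
  blk <- to_block(pp$windows, pp$table)
  mir <- mirror_block(blk)
  swap <- c(left = "right", right = "left", rest = "rest")
  expect_identical(as.character(mir$labels),
                   unname(swap[as.character(blk$labels)]))
  expect_equal(mir$values, blk$values[, , , 33:1, , drop = FALSE])
  back <- mirror_block(mir)
  expect_equal(back$values, blk$values)
  expect_identical(as.character(back$labels), as.character(blk$labels))
  # left-task activation moves sides under mirroring (mean over examples)
  sel <- which(blk$labels == "left")
  W <- dim(blk$values)[4]
  right_half <- (W %/% 2 + 2):W
  left_half <- 1:(W %/% 2)
  expect_gt(mean(blk$values[2, , , right_half, sel]),
            mean(blk$values[2, , , left_half, sel]))
  expect_gt(mean(mir$values[2, , , left_half, sel]),
            mean(mir$values[2, , , right_half, sel]))
})

test_that("flip augmentation doubles task examples and guards test data", {
  pp <- full_pp()
  blk <- to_block(pp$windows, pp$table)
  aug <- flip_augment(blk)
  n_task <- sum(blk$labels %in% c("left", "right"))
  expect_equal(length(aug$labels), length(blk$labels) + n_task)
  expect_equal(sum(aug$labels == "left"), 16)   # 8 original + 8 mirrored
  expect_equal(sum(aug$labels == "right"), 16)
  expect_equal(sum(aug$labels == "rest"), sum(blk$labels == "rest"))
  expect_true(attr(aug, "augmented"))
  # originals are untouched, appended examples are the mirrored tasks
  expect_equal(aug$values[, , , , seq_along(blk$labels)], blk$values)
  te <- blk
  attr(te, "split_role") <- "test"
  expect_error(flip_augment(te), "test")
})

test_that("example subsetting and binding are consistent", {
  pp <- full_pp()
  blk <- to_block(pp$windows, pp$table)
  sub <- subset_examples(blk, c(3, 1, 5))
  expect_equal(dim(sub$values)[5], 3)
  expect_equal(sub$values[, , , , 2], blk$values[, , , , 1])
  expect_identical(as.character(sub$labels),
                   as.character(blk$labels[c(3, 1, 5)]))
  expect_identical(sub$subject_id, blk$subject_id[c(3, 1, 5)])
})
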