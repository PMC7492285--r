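test_that("column heights are pixel counts times the spacing", {
  m <- matrix(FALSE, 20, 60)
  m[1:10, 10:55] <- TRUE
  sm <- seg_mask(m, 0.24, piston_center_col = 32)
  ch <- column_heights(sm)
  expect_equal(ch[10:55], rep(2.4, 46))
  expect_equal(ch[5], 0)
})

test_that("the caliper probes the centre and +/- 2 mm and averages", {
  # 0.24 mm spacing: lateral offset = round(2 / 0.24) = 8 columns
  m <- matrix(FALSE, 20, 60)
  m[1:10, 10:55] <- TRUE
  m[11:12, 24] <- TRUE # make the -2 mm column (32 - 8) taller
  sm <- seg_mask(m, 0.24, piston_center_col = 32)
  cal <- caliper_heights(sm)
  expect_equal(unname(cal$heights), c(12, 10, 10) * 0.24)
  expect_equal(cal$mean, mean(c(12, 10, 10) * 0.24))
  # invariant to columns outside the three probed positions
  m2 <- m; m2[11:15, 30] <- TRUE
  cal2 <- caliper_heights(seg_mask(m2, 0.24, piston_center_col = 32))
  expect_equal(cal2$heights, cal$heights)
  # empty probed column is a measurement error naming the position
  m3 <- m; m3[, 40] <- FALSE
  expect_error(caliper_heights(seg_mask(m3, 0.24, piston_center_col = 32)),
               "plus2mm", class = "qc_measurement_error")
})

test_that("boundary exclusion removes the top and bottom pixel per column", {
  m <- matrix(FALSE, 20, 60)
  m[1:10, 10:55] <- TRUE
  m[1:2, 20] <- c(TRUE, TRUE); m[3:10, 20] <- FALSE # height-2 column
  sm <- seg_mask(m, 0.232, piston_center_col = 32)
  er <- exclude_boundaries(sm)
  expect_equal(sum(er$mask[, 15]), 8)
  expect_equal(sum(er$mask[, 20]), 0)
  expect_equal(attr(er, "n_emptied"), 1L)
  # for all-tall columns: removed pixels = 2 x non-empty columns
  m4 <- matrix(FALSE, 20, 60); m4[1:10, 10:55] <- TRUE
  sm4 <- seg_mask(m4, 0.232, piston_center_col = 32)
  er4 <- exclude_boundaries(sm4)
  expect_equal(sum(sm4$mask) - sum(er4$mask), 2 * 46)
})

test_that("the seven-ROI partition satisfies its identities on random masks", {
  for (s in 1:100) {
    sm <- random_mask(s)
    part <- partition_rois(sm)
    cn <- part$counts
    expect_equal(cn[["ECS"]], cn[["SPA"]] + cn[["PPA"]])
    expect_equal(cn[["SPA"]], cn[["SPA_upper"]] + cn[["SPA_lower"]])
    expect_equal(cn[["PPA"]], cn[["PPA_upper"]] + cn[["PPA_lower"]])
    expect_equal(cn[["ECS"]], sum(sm$mask))
    expect_false(any(part$rois$SPA & part$rois$PPA))
    expect_false(any(part$rois$SPA_upper & part$rois$SPA_lower))
    # per column: odd heights put the extra pixel in the upper half
    h <- colSums(sm$mask)
    up <- colSums(part$rois$SPA_upper | part$rois$PPA_upper)
    lo <- colSums(part$rois$SPA_lower | part$rois$PPA_lower)
    expect_equal(up - lo, ifelse(h %% 2 == 1, 1, 0)[seq_along(up)])
  }
})

test_that("the sub-pistonal band is centred with the documented width", {
  # spacing 0.232 mm, 8 mm band: round(8 / 0.232) = 34 columns
  m <- matrix(TRUE, 40, 100)
  sm <- seg_mask(m, 0.232, piston_center_col = 50)
  part <- partition_rois(sm)
  expect_length(part$spa_columns, 34)
  expect_equal(range(part$spa_columns), c(50 - 16, 50 + 17)) # extra right
  # even heights split evenly
  expect_equal(part$counts[["SPA_upper"]], part$counts[["SPA_lower"]])
  # SPA band outside the mask is a geometry error
  m5 <- matrix(FALSE, 40, 100); m5[1:20, 1:8] <- TRUE
  expect_error(partition_rois(seg_mask(m5, 0.232, piston_center_col = 90,
                                       piston_width = 1.5, spa_width = 1)),
               class = "qc_geometry_error")
})

test_that("pixel size follows field of view over matrix size", {
  expect_equal(pixel_size(62, 256), 62 / 256)
})
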