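# small frames keep these tests fast: a 60-um sensor at 0.59 um/px

small_trace <- function(widths = c(60, 56, 53, 51)) {
  deformation_trace((seq_along(widths) - 1) * 30, widths)
}

test_that("segmentation recovers a rendered sensor footprint (IoU > 0.9)", {
  mv <- render_movie(small_trace(60), ring_thickness = 8, blur_sd = 0)
  fr <- mv$stack$frames[[1]]
  mask <- segment_sensor(fr)
  # the pipeline hole-fills the lumen, so the target is the full footprint
  truth <- ellipse_disc_mask(nrow(fr), 0.59, 30, 30)
  iou <- sum(mask$mask & truth) / sum(mask$mask | truth)
  expect_gt(iou, 0.9)
})

test_that("segmentation rejects constant frames and survives speckles", {
  expect_error(segment_sensor(matrix(1, 50, 50)), "no-detection")
  mv <- render_movie(small_trace(60), ring_thickness = 8, blur_sd = 0)
  fr <- mv$stack$frames[[1]]
  set.seed(7)
  idx <- cbind(sample(nrow(fr), 20), sample(ncol(fr), 20))
  fr[idx] <- max(fr) * 1.5
  w_clean <- measure_width(segment_sensor(mv$stack$frames[[1]]), 0.59)
  w_speck <- measure_width(segment_sensor(fr), 0.59)
  expect_equal(w_speck, w_clean, tolerance = 0.02)
})

test_that("width is the bounding-rectangle x extent", {
  m <- matrix(FALSE, 20, 20)
  m[10, 10] <- TRUE
  sm <- structure(list(mask = m, bbox = c(x_min = 10, x_max = 10,
                                          y_min = 10, y_max = 10)),
                  class = "sensor_mask")
  expect_equal(measure_width(sm, 0.59), 0.59)
  # axis convention: a 3-px-wide, 7-px-tall blob has width 3 px, and 7 px
  # after a 90-degree (transpose) rotation
  m2 <- matrix(FALSE, 20, 20)
  m2[5:11, 9:11] <- TRUE
  seg <- segment_sensor(m2 * 1)
  expect_equal(measure_width(seg, 1), 3)
  segT <- segment_sensor(t(m2) * 1)
  expect_equal(measure_width(segT, 1), 7)
})

test_that("intensity gain does not change the measurement", {
  mv <- render_movie(small_trace(60), ring_thickness = 8, blur_sd = 1)
  fr <- mv$stack$frames[[1]]
  w1 <- measure_width(segment_sensor(fr), 0.59)
  w2 <- measure_width(segment_sensor(fr * 2), 0.59)
  expect_equal(w1, w2)
})

test_that("integer drift is recovered exactly and widths are unchanged", {
  tr <- small_trace()
  mv <- render_movie(tr, ring_thickness = 8, blur_sd = 1, drift = c(3, -2))
  reg <- register_stack(mv$stack)
  expect_equal(as.matrix(reg$offsets[, c("dy", "dx")]),
               -mv$truth$drift_px, ignore_attr = TRUE, tolerance = 1e-9)
  w_reg <- extract_trace(mv$stack, method = "fixed")$width
  still <- render_movie(tr, ring_thickness = 8, blur_sd = 1)
  w_still <- extract_trace(still$stack, register = FALSE, method = "fixed")$width
  expect_equal(w_reg, w_still, tolerance = 1e-9)
})

test_that("subpixel drift with noise is recovered within 0.5 px", {
  tr <- small_trace()
  mv <- render_movie(tr, ring_thickness = 8, blur_sd = 1, drift = c(0.4, 0.4),
                     photon_scale = 200, gauss_sd = 0.01, seed = 11)
  reg <- register_stack(mv$stack)
  resid <- as.matrix(reg$offsets[, c("dy", "dx")]) + mv$truth$drift_px
  expect_lt(max(abs(resid)), 0.5)
})

test_that("rigid registration recovers a small in-plane rotation", {
  mv <- render_movie(small_trace(c(60, 58)), ring_thickness = 8, blur_sd = 1)
  fr <- mv$stack$frames[[1]]
  # break the circular symmetry so the angle is observable
  fr[10:14, ] <- fr[10:14, ] + 0.5
  rot <- morphoforce:::.rotate2(fr, -3)
  st <- image_stack(list(fr, pmax(rot, 0)), 0.59, 30)
  reg <- register_stack(st, mode = "rigid")
  expect_lt(abs(reg$offsets$angle[2] - 3), 0.45)
})

test_that("scripted widths are recovered within a pixel", {
  tr <- deformation_trace(c(0, 30, 60, 90), c(180, 172, 166, 162))
  mv <- render_movie(tr, blur_sd = 1)
  est <- extract_trace(mv$stack, register = FALSE, method = "fixed")
  expect_lt(max(abs(est$width - tr$width)), 0.6)
  est2 <- extract_trace(mv$stack, register = FALSE, method = "otsu")
  expect_lt(max(abs(est2$width - tr$width)), 1.2)
})

test_that("measured widths are monotone in scripted widths (noise-free)", {
  widths <- seq(50, 62, by = 2)
  tr <- deformation_trace((seq_along(widths) - 1) * 30, widths)
  mv <- render_movie(tr, ring_thickness = 8, blur_sd = 1)
  est <- extract_trace(mv$stack, register = FALSE, method = "fixed")
  expect_true(all(diff(est$width) >= 0))
})

test_that("single frames, gaps and empty stacks are handled explicitly", {
  mv <- render_movie(small_trace(60), ring_thickness = 8)
  reg <- register_stack(mv$stack)
  expect_equal(nrow(reg$offsets), 0)
  expect_error(image_stack(list(), 0.59), "invalid-input")
  blank <- matrix(0, nrow(mv$stack$frames[[1]]), ncol(mv$stack$frames[[1]]))
  st <- image_stack(c(mv$stack$frames, list(blank)), 0.59, 30)
  expect_warning(tr <- extract_trace(st, register = FALSE), "gap")
  expect_true(is.na(tr$width[2]))
})

test_that("TIFF round-trip preserves the measured widths", {
  tr <- small_trace()
  mv <- render_movie(tr, ring_thickness = 8, blur_sd = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(mv$stack, path)
  rt <- read_image_stack(path, pixel_size = 0.59, time_step = 30)
  w1 <- extract_trace(mv$stack, register = FALSE, method = "fixed")$width
  w2 <- extract_trace(rt, register = FALSE, method = "fixed")$width
  expect_equal(w2, w1, tolerance = 0.01)
})
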