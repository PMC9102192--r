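test_that("registration of an image to itself is the identity", {
  sim <- gen_colony_images(quick_config(seed = 21))
  reg <- register_to_reference(sim$reference, sim$reference,
                               search_radius = 6)
  expect_equal(unname(reg$offset), c(0, 0))
  expect_equal(reg$correlation, 1, tolerance = 1e-12)
  expect_length(reg$flags, 0)
})

test_that("registration recovers a planted (7, -3) shift", {
  cfg <- sim_config(seed = 22, colony = colony_spec(pixel_noise_sd = 0))
  sim <- gen_colony_images(cfg)
  bg <- sim$reference[1, 1, ]  # background colour of the clean render
  shifted <- sim$reference
  for (ch in 1:3) {
    m <- cafcoculture:::shift_matrix(sim$reference[, , ch], 7, -3, fill = NA)
    m[is.na(m)] <- bg[ch]
    shifted[, , ch] <- m
  }
  reg <- register_to_reference(shifted, sim$reference, search_radius = 10)
  expect_equal(unname(reg$offset), c(7, -3))
})

test_that("degenerate uniform images flag poor registration without crashing", {
  sim <- gen_colony_images(quick_config(seed = 23))
  white <- flat_image(dim(sim$reference)[1], dim(sim$reference)[2],
                      c(255, 255, 255))
  reg <- register_to_reference(white, sim$reference, search_radius = 4)
  expect_true("poor registration" %in% reg$flags)
  expect_true(is.finite(reg$correlation))
})

test_that("blue-channel thresholding follows the fixed-threshold contract", {
  blue <- flat_image(64, 64, c(0, 0, 255))
  black <- flat_image(64, 64, c(0, 0, 0))
  expect_true(all(segment_colonies(blue, 128)))
  expect_false(any(segment_colonies(black, 128)))
  expect_error(segment_colonies(blue, 300), "0-255")

  # contrast margin 60 over background 100: threshold 130 recovers the
  # rendered truth mask exactly in the noiseless render
  cfg <- sim_config(seed = 24, colony = colony_spec(pixel_noise_sd = 0))
  sim <- gen_colony_images(cfg)
  m <- segment_colonies(sim$images[[1]], threshold = 130)
  expect_identical(m, sim$clean_masks[[1]])
})

test_that("lowering the threshold never decreases the area fraction", {
  sim <- gen_colony_images(quick_config(seed = 25))
  img <- sim$images[[1]]
  fracs <- vapply(c(200, 160, 130, 90, 40), function(thr) {
    area_fraction(segment_colonies(img, thr), sim$roi)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("area fraction honours the ROI, offsets and bounds", {
  roi <- matrix(FALSE, 50, 50); roi[11:30, 11:30] <- TRUE
  all_true <- matrix(TRUE, 50, 50)
  expect_equal(area_fraction(all_true, roi), 1.0)
  expect_equal(area_fraction(!all_true, roi), 0.0)
  # translation applied to both mask and ROI leaves the fraction unchanged
  mask <- matrix(FALSE, 50, 50); mask[15:20, 12:28] <- TRUE
  f0 <- area_fraction(mask, roi)
  mask_sh <- cafcoculture:::shift_matrix(mask, 4, -2, fill = FALSE)
  expect_equal(area_fraction(mask_sh, roi, offset = c(4, -2)), f0)
  # ROI shifted fully out of bounds is an error
  expect_error(area_fraction(all_true, roi, offset = c(60, 0)), "empty")
})

test_that("end-to-end colony quantification recovers shifts and fractions", {
  cfg <- sim_config(seed = 26)
  sim <- gen_colony_images(cfg)
  res <- quantify_colonies(sim$images, sim$reference, sim$roi,
                           threshold = 130, search_radius = 14)
  expect_equal(res$dy, sim$truth$dy)
  expect_equal(res$dx, sim$truth$dx)
  expect_lte(mean(abs(res$area_fraction - sim$truth$area_fraction)), 0.02)
})

test_that("support test implements the Welch criterion", {
  same <- support_test(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(same$p_value, 1)
  expect_false(same$supporting)

  tr <- c(0.30, 0.31, 0.29); ctl <- c(0.10, 0.11, 0.09)
  st <- support_test(tr, ctl)
  # textbook Welch statistic computed from first principles
  se <- sqrt(var(tr) / 3 + var(ctl) / 3)
  tstat <- (mean(tr) - mean(ctl)) / se
  df <- se^4 / ((var(tr) / 3)^2 / 2 + (var(ctl) / 3)^2 / 2)
  p_hand <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  expect_equal(st$p_value, p_hand, tolerance = 1e-12)
  expect_true(st$supporting)
  expect_false(st$suppressing)

  sup <- support_test(ctl, tr)
  expect_true(sup$suppressing)
  expect_error(support_test(0.3, c(0.1, 0.2)), "2 replicates")
})
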