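test_that("zero shift and zero noise render digits identical to the dorsum", {
  r <- render_tiny(mag = 0, noise_sd = 0)
  px <- extract_roi_pixels(r$image, r$rois)
  dors <- unique(px[px$roi_id == 25, c("R", "G", "B")])
  expect_equal(nrow(dors), 1)
  digs <- unique(px[px$roi_id != 25, c("R", "G", "B")])
  expect_equal(nrow(digs), 1)
  expect_equal(as.matrix(digs), as.matrix(dors), ignore_attr = TRUE)
})

test_that("a pure a* shift on one digit is recovered within 0.5 units", {
  shift <- matrix(0, 8, 2)
  shift[1, ] <- c(10, 0)
  r <- render_hand_image(hand_spec(per_digit_shift = shift, noise_sd = 0,
                                   image_size = tiny_image_size))
  px <- extract_roi_pixels(r$image, r$rois)
  lab <- dplyr::bind_cols(px["roi_id"], srgb_to_lab(px[c("R", "G", "B")]))
  means <- lab |>
    dplyr::group_by(roi_id) |>
    dplyr::summarise(a = mean(a), b = mean(b))
  dors <- means[means$roi_id == 25, ]
  d1 <- means[means$roi_id %in% 1:3, ] # digit 1's three ROIs
  expect_true(all(abs(d1$a - dors$a - 10) < 0.5))
  expect_true(all(abs(d1$b - dors$b) < 0.5))
  d2 <- means[means$roi_id %in% 4:6, ]
  expect_true(all(abs(d2$a - dors$a) < 0.5))
})

test_that("rendering is bit-identical under a fixed seed", {
  a <- render_tiny(mag = 5, seed = 99)
  b <- render_tiny(mag = 5, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  c <- render_tiny(mag = 5, seed = 100)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("ground-truth ROI labels are complete and disjoint by construction", {
  r <- render_tiny(mag = 3)
  ids <- sort(unique(c(r$rois$labels)))
  expect_equal(ids, 0:25)
  expect_equal(nrow(r$rois$n_pixels), 25)
  expect_true(all(r$rois$n_pixels$n_pixels >= 50))
  expect_false(any(r$rois$n_pixels$degenerate))
  # digit ROIs sit inside their digit's mask
  expect_true(all(r$layout$digit[r$rois$labels %in% 1:24] > 0))
})

test_that("invalid hand specs are rejected", {
  expect_error(hand_spec(n_digits = 7))
  expect_error(hand_spec(noise_sd = -1))
  expect_error(hand_spec(per_digit_shift = matrix(0, 4, 2)))
  expect_error(hand_spec(image_size = c(0, 100)))
})

test_that("shifts pushing outside the sRGB gamut set the clip flag", {
  shift <- matrix(rep(c(80, 80), each = 8), 8, 2)
  r <- render_hand_image(hand_spec(per_digit_shift = shift, noise_sd = 0,
                                   image_size = tiny_image_size))
  expect_true(r$gamut_clipped)
  expect_false(render_tiny(mag = 5, noise_sd = 0)$gamut_clipped)
})

test_that("generated folders hold the promised files and records", {
  root <- withr::local_tempdir()
  g <- generate_dataset(root, n_patients = 1, episodes_per_patient = 1,
                        images_per_episode = c(3, 3),
                        image_size = tiny_image_size, seed = 7)
  days <- list.dirs(file.path(root, "P01"), recursive = FALSE)
  expect_length(days, 1)
  expect_length(list.files(days, pattern = "\\.jpg$"), 3)
  expect_true(file.exists(file.path(days, "attacks.txt")))
  expect_true(file.exists(file.path(root, "ground_truth.csv")))
  expect_true(file.exists(file.path(root, "manifest.json")))
  expect_equal(nrow(g$ground_truth), 1)
  expect_equal(g$ground_truth$n_images, 3)
})

test_that("a strictly increasing severity model preserves shift rank order", {
  root <- withr::local_tempdir()
  g <- generate_dataset(root, n_patients = 1, episodes_per_patient = 6,
                        offset_range = 0, severity_noise_sd = 0,
                        image_size = tiny_image_size, seed = 8)
  gt <- g$ground_truth
  expect_true(all(diff(gt$severity[order(gt$shift_mag)]) >= 0))
  expect_gt(max(gt$severity), min(gt$severity))
})

test_that("the ground-truth table is identical under one seed", {
  r1 <- withr::local_tempdir()
  r2 <- withr::local_tempdir()
  g1 <- generate_dataset(r1, n_patients = 1, episodes_per_patient = 2,
                         image_size = tiny_image_size, seed = 5)
  g2 <- generate_dataset(r2, n_patients = 1, episodes_per_patient = 2,
                         image_size = tiny_image_size, seed = 5)
  expect_equal(g1$ground_truth, g2$ground_truth)
  # and the image bytes themselves
  f1 <- list.files(r1, pattern = "\\.jpg$", recursive = TRUE, full.names = TRUE)
  f2 <- list.files(r2, pattern = "\\.jpg$", recursive = TRUE, full.names = TRUE)
  expect_identical(readBin(f1[1], "raw", 1e6), readBin(f2[1], "raw", 1e6))
})

test_that("episode-level simulation responds to its effect switch", {
  null_tbl <- simulate_episode_bd(effect = 0, seed = 1)
  eff_tbl <- simulate_episode_bd(effect = 0.8, seed = 1)
  expect_equal(names(null_tbl),
               c("patient_id", "episode", "true_shift", "severity", "mean_bd"))
  expect_true(all(null_tbl$severity >= 0 & null_tbl$severity <= 10))
  expect_lt(abs(cor(null_tbl$true_shift, null_tbl$mean_bd)), 0.25)
  expect_gt(cor(eff_tbl$true_shift, eff_tbl$mean_bd), 0.8)
  expect_identical(simulate_episode_bd(effect = 0, seed = 1), null_tbl)
})
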