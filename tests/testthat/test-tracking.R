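test_that("binarize handles blank and saturated regions", {
  cfg <- detection_config(blur_kernel = 3)
  white <- matrix(255L, 9, 9)
  expect_equal(count_target_pixels(binarize(white, config = cfg), "black"), 0)
  black <- matrix(0L, 9, 9)
  expect_equal(count_target_pixels(binarize(black, config = cfg), "black"),
               81)
})

test_that("binarize matches the pixelwise median+threshold oracle", {
  cfg <- detection_config(blur_kernel = 3)
  m <- matrix(255L, 9, 9)
  m[3:7, 3:7] <- 0L
  got <- binarize(m, config = cfg)
  expect_identical(got, brute_binarize(m, 3, 127))
  set.seed(5)
  for (k in c(3, 5)) {
    noisy <- matrix(sample(0:255, 20 * 17, replace = TRUE), 20, 17)
    cfgk <- detection_config(blur_kernel = k)
    expect_identical(binarize(noisy, config = cfgk),
                     brute_binarize(noisy, k, 127))
  }
})

test_that("binarize respects ROI bounds and kernel limits", {
  m <- matrix(255L, 10, 10)
  expect_error(binarize(m, roi(5, 5, 10, 10)), "outside the frame")
  expect_error(binarize(m, roi(0, 0, 3, 3), detection_config(blur_kernel = 5)),
               "kernel larger")
  expect_error(detection_config(blur_kernel = 4), "odd")
})

test_that("binarisation is idempotent on binary input with kernel 1", {
  set.seed(3)
  m <- matrix(sample(c(0L, 255L), 64, replace = TRUE), 8, 8)
  cfg <- detection_config(blur_kernel = 1)
  expect_identical(binarize(m, config = cfg), m)
})

test_that("pixel counting is exact and complements to the ROI area", {
  expect_equal(count_target_pixels(matrix(255L, 5, 5), "black"), 0)
  expect_equal(count_target_pixels(matrix(0L, 5, 5), "black"), 25)
  cb <- matrix(c(0L, 255L), 4, 4)
  expect_equal(count_target_pixels(cb, "black"), 8)
  expect_equal(count_target_pixels(cb, "black") +
               count_target_pixels(cb, "white"), 16)
  expect_error(count_target_pixels(matrix(1L, 2, 2)), "not binary")
})

test_that("the light-dark rule reads visibility as the light chamber", {
  expect_equal(classify_light_dark(0, 50), "dark")
  expect_equal(classify_light_dark(500, 50), "light")
  expect_equal(classify_light_dark(50, 50), "light")  # tie counts as in-ROI
})

test_that("the three-chamber rule uses side memory when out of view", {
  r <- classify_three_chamber(300, 10, c(100, 100), "unknown")
  expect_equal(r$chamber, "middle")
  expect_equal(r$side_memory, "left")
  r2 <- classify_three_chamber(5, 8, c(100, 100), "right")
  expect_equal(r2$chamber, "right")
  r3 <- classify_three_chamber(5, 8, c(100, 100), "unknown")
  expect_equal(r3$chamber, "undetermined")
  # both ROIs triggered: the fuller one wins the memory
  r4 <- classify_three_chamber(150, 220, c(100, 100), "left")
  expect_equal(r4$side_memory, "right")
})

test_that("centroids are the mean of target-pixel coordinates", {
  m <- matrix(255L, 8, 8)
  m[5, 4] <- 0L   # row 5 = y 4, col 4 = x 3
  expect_equal(mask_centroid(m), c(x = 3, y = 4))
  blk <- matrix(255L, 8, 8)
  blk[1:4, 1:4] <- 0L
  expect_equal(mask_centroid(blk), c(x = 1.5, y = 1.5))
  expect_true(all(is.na(mask_centroid(matrix(255L, 4, 4)))))
})

test_that("locomotion metrics recover straight-line arithmetic", {
  tr <- trajectory(x = 10 * (0:299), y = rep(0, 300), fps = 30, mm_per_px = 1)
  lm <- locomotion_metrics(tr)
  expect_equal(lm$distance_m, 2.99, tolerance = 1e-12)
  expect_equal(lm$mean_speed_mm_s, 300, tolerance = 1e-12)
  still <- trajectory(rep(3, 10), rep(4, 10), fps = 30, mm_per_px = 1)
  expect_equal(locomotion_metrics(still)$distance_m, 0)
})

test_that("absent centroids are bridged by skipping", {
  x <- c(0, 10, NA, NA, 40, 50)
  tr <- trajectory(x, rep(0, 6), fps = 10, mm_per_px = 1)
  lm <- locomotion_metrics(tr)
  expect_equal(lm$distance_m, 0.05, tolerance = 1e-12)  # 10+30+10 mm
  expect_equal(lm$mean_speed_mm_s, 50 / 0.5, tolerance = 1e-12)
  expect_error(locomotion_metrics(trajectory(c(1, NA), c(1, NA), 10, 1)),
               "two detected")
})

test_that("a sampled circular path approximates its circumference", {
  n <- 360; R <- 50
  th <- 2 * pi * (0:(n - 1)) / n
  tr <- trajectory(R * cos(th), R * sin(th), fps = 30, mm_per_px = 1)
  # polygon perimeter of an inscribed (n-1)-arc path
  expected <- sum(sqrt(diff(R * cos(th))^2 + diff(R * sin(th))^2)) / 1000
  expect_equal(locomotion_metrics(tr)$distance_m, expected,
               tolerance = 1e-12)
  expect_lt(abs(expected * 1000 - 2 * pi * R * (n - 1) / n), 1)
})

test_that("chamber times count frames at 1/fps with undetermined set aside", {
  tl <- chamber_timeline(rep("dark", 40), fps = 20)
  ct <- chamber_times(tl)
  expect_equal(unname(ct$fractions["dark"]), 1)
  labs <- c(rep("dark", 30), rep("light", 70))
  ct2 <- chamber_times(chamber_timeline(labs, fps = 25))
  expect_equal(unname(ct2$fractions["dark"]), 0.30, tolerance = 1e-12)
  expect_equal(unname(ct2$seconds["dark"]), 30 / 25, tolerance = 1e-12)
  labs3 <- c(rep("undetermined", 20), rep("dark", 40), rep("light", 40))
  ct3 <- chamber_times(chamber_timeline(labs3, fps = 20))
  expect_equal(unname(ct3$fractions["dark"]), 0.5, tolerance = 1e-12)
  expect_equal(ct3$undetermined_s, 1)
  expect_equal(ct3$total_s, 5)
})

test_that("PGM images round-trip", {
  set.seed(9)
  m <- matrix(sample(0:255, 30 * 20, replace = TRUE), 20, 30)
  p <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(m, p)
  expect_identical(read_pgm(p), m)
  # P5 (binary) variant
  p5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p5, "wb")
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(m))), con)
  close(con)
  expect_identical(read_pgm(p5), m)
})
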