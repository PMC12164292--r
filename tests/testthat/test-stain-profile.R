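flat_image <- function(h, w, rgb = c(0.96, 0.93, 0.88)) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("sample_line walks the polyline in unit pixel steps", {
  img <- flat_image(60, 200)
  horiz <- rbind(c(10, 30), c(109, 30))  # spans 100 pixels
  s <- sample_line(img, horiz)
  expect_equal(nrow(s), 100)

  # reversing the polyline reverses the sample order
  img[30, 10, ] <- 0  # mark the distal end
  f <- sample_line(img, horiz)
  r <- sample_line(img, horiz[2:1, ])
  expect_equal(f, r[nrow(r):1, ])

  # sample count tracks Euclidean arclength for arbitrary polylines
  set.seed(42)
  for (i in 1:20) {
    pts <- cbind(stats::runif(3, 5, 195), stats::runif(3, 5, 55))
    len <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
    expect_lte(abs(nrow(sample_line(img, pts)) - len), 1)
  }

  expect_error(sample_line(img, rbind(c(-5, 3), c(50, 3))), "bounds")
  expect_error(sample_line(img, rbind(c(4, 4), c(4, 4))), "arclength")
})

test_that("purple_od inverts Beer-Lambert staining", {
  model <- stain_model()
  # background pixels map to zero OD
  expect_equal(purple_od(matrix(model$background_rgb, 1), model), 0)

  # planted OD is recovered through the full image pipeline
  d <- digit_id("forelimb", 2)
  p <- clock_params(d, 3)
  cfg <- render_config(profile_length_px = 150, noise_sd = 0, seed = 2)
  scene <- render_autopod_image(list(p), 36, cfg)
  prof <- extract_profile(scene$image, scene$polylines[[1]], model)
  expect_equal(max(prof$samples), 0.8, tolerance = 0.01)

  # monotone in planted stain amount
  od_at_peak <- sapply(seq(0, 2, by = 0.25), function(a) {
    cfg_a <- render_config(profile_length_px = 120, noise_sd = 0, seed = 2,
                           bump_amp = max(a, 1e-9))
    sc <- render_autopod_image(list(p), 36, cfg_a)
    max(extract_profile(sc$image, sc$polylines[[1]], model)$samples)
  })
  expect_true(all(diff(od_at_peak) >= -1e-6))
})

test_that("extract_profile matches planted ground truth at zero noise", {
  d <- digit_id("forelimb", 3)
  p <- clock_params(d, 5)
  cfg <- render_config(profile_length_px = 400, noise_sd = 0, seed = 6)
  scene <- render_autopod_image(list(p), 36, cfg)
  prof <- extract_profile(scene$image, scene$polylines[[1]], stain_model())
  expect_equal(prof$n_raw, nrow(sample_line(scene$image,
                                            scene$polylines[[1]])))
  dom <- detect_domains(normalize_length(prof, 500))
  centers <- (dom$start + dom$end)[!dom$is_tip] / 2
  truth <- sort(scene$ground_truth[[1]]$joint_centers)
  expect_length(centers, length(truth))
  expect_lt(max(abs(sort(centers) - truth)), 0.01)

  # an all-background image yields an (essentially) all-zero profile
  blank <- flat_image(60, 200)
  prof0 <- extract_profile(blank, rbind(c(10, 30), c(150, 30)))
  expect_lt(max(prof0$samples), 1e-6)
})

test_that("profiles are invariant to joint rotation of image and line", {
  d <- digit_id("forelimb", 1)
  p <- clock_params(d, 4)
  cfg <- render_config(profile_length_px = 150, noise_sd = 0, seed = 8)
  scene <- render_autopod_image(list(p), 36, cfg)
  img <- scene$image
  line <- scene$polylines[[1]]
  prof <- extract_profile(img, line)

  # rotate 90 degrees counterclockwise: (x, y) -> (y, W + 1 - x)
  h <- dim(img)[1]; w <- dim(img)[2]
  rot <- array(0, dim = c(w, h, 3))
  for (ch in 1:3) rot[, , ch] <- t(img[, , ch][, w:1])
  line_rot <- cbind(line[, 2], w + 1 - line[, 1])
  prof_rot <- extract_profile(rot, line_rot)
  expect_equal(prof_rot$n_raw, prof$n_raw)
  expect_lt(max(abs(prof_rot$samples - prof$samples)),
            0.02 * max(prof$samples))
})

test_that("purple_od tolerates joint brightness scaling", {
  d <- digit_id("forelimb", 1)
  p <- clock_params(d, 3)
  cfg <- render_config(profile_length_px = 120, noise_sd = 0, seed = 4)
  scene <- render_autopod_image(list(p), 36, cfg)
  m1 <- stain_model()
  m2 <- stain_model(background_rgb = 0.6 * m1$background_rgb)
  p1 <- extract_profile(scene$image, scene$polylines[[1]], m1)
  img2 <- scene$image * 0.6
  p2 <- extract_profile(img2, scene$polylines[[1]], m2)
  expect_lt(max(abs(p1$samples - p2$samples)), 0.01)
})

test_that("PPM and profile CSV round trips preserve the data", {
  d <- digit_id("forelimb", 2)
  p <- clock_params(d, 2)
  cfg <- render_config(profile_length_px = 100, noise_sd = 0, seed = 3)
  scene <- render_autopod_image(list(p), 36, cfg)
  tmp <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(scene$image, tmp)
  back <- read_ppm(tmp)
  expect_equal(dim(back), dim(scene$image))
  expect_lt(max(abs(back - scene$image)), 1 / 255)

  prof <- extract_profile(scene$image, scene$polylines[[1]], stain_model(),
                          meta = list(specimen = "s1", stage = 36,
                                      limb = "forelimb", digit = "II"))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, tmp2)
  back2 <- read_profile(tmp2)
  expect_equal(back2$samples, prof$samples, tolerance = 1e-9)
  expect_equal(back2$meta$digit, "II")
  expect_equal(back2$meta$stage, 36)
})
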