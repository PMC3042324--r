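test_that("row statistics match a hand-enumerated 1x4 example", {
  lab <- label_image(matrix(c(0L, 1L, 1L, 2L), nrow = 1))
  prof <- row_statistics(lab)
  expect_equal(prof$p_sample, 0.5)
  expect_equal(prof$p_air, 0.25)
  expect_equal(prof$p_holder, 0.25)
  # sample pixels at x = -0.5, +0.5: mean 0, population variance 0.25
  expect_equal(prof$mean_x, 0)
  expect_equal(prof$var_x, 0.25)
  expect_equal(prof$p_sample + prof$p_air + prof$p_holder, 1)
})

test_that("rows without sample pixels have undefined center of mass", {
  lab <- label_image(matrix(0L, 3, 8))
  prof <- row_statistics(lab)
  expect_equal(prof$p_air, rep(1, 3))
  expect_true(all(is.na(prof$mean_x)))
  expect_true(all(is.na(prof$var_x)))
})

test_that("fractions always sum to one across random label images", {
  set.seed(31)
  for (i in 1:5) {
    lab <- label_image(matrix(sample(0:2, 25 * 30, replace = TRUE), 25, 30))
    prof <- row_statistics(lab)
    expect_equal(prof$p_sample + prof$p_air + prof$p_holder, rep(1, 25))
    expect_true(all(prof$var_x >= 0, na.rm = TRUE))
  }
})

make_profiles <- function(y, mean_x, p_sample = 0.5, pix_x = 1, pix_y = 1) {
  n <- length(y)
  out <- data.frame(y = y, p_sample = p_sample, p_air = 1 - p_sample,
                    p_holder = 0, p_sat = 0, n_sample = 10,
                    mean_x = mean_x, var_x = 1, edge_touch = FALSE)
  attr(out, "pix_x") <- pix_x
  attr(out, "pix_y") <- pix_y
  class(out) <- c("row_profiles", "data.frame")
  out
}

test_that("axis fit reproduces closed-form lines", {
  # constant line: c1 = 0, c2 = 1
  f <- fit_axis(make_profiles(y = c(-1, 0, 1), mean_x = c(1, 1, 1)))
  expect_equal(f$c1, 0)
  expect_equal(f$c2, 1)
  expect_equal(f$theta_s, 0)
  # unit diagonal with square pixels: 45 degrees
  f2 <- fit_axis(make_profiles(y = c(-1, 0, 1), mean_x = c(-1, 0, 1)))
  expect_equal(f2$c1, 1)
  expect_equal(f2$c2, 0, tolerance = 1e-12)
  expect_equal(f2$theta_s, 45)
  # anisotropic pixels rescale the angle
  f3 <- fit_axis(make_profiles(y = c(-1, 0, 1), mean_x = c(-1, 0, 1),
                               pix_x = 2, pix_y = 1))
  expect_equal(f3$theta_s, atan(2) * 180 / pi)
})

test_that("axis fit agrees with an explicit normal-equations oracle", {
  set.seed(55)
  for (i in 1:5) {
    y <- sort(runif(50, -100, 100))
    mean_x <- 0.3 * y + 5 + rnorm(50, 0, 2)
    f <- fit_axis(make_profiles(y = y, mean_x = mean_x))
    X <- cbind(1, y)
    beta <- solve(t(X) %*% X, t(X) %*% mean_x)
    expect_equal(f$c2, beta[1], tolerance = 1e-10)
    expect_equal(f$c1, beta[2], tolerance = 1e-10)
  }
})

test_that("the fit ignores air rows and tracks column shifts exactly", {
  det <- clean_det(96)
  smp <- slim_phantom(radius = 0.15, length = 0.9)  # fits inside the FOV
  st <- stage_state(y = -450)
  lab <- segment(render_projection(smp, st, det), thresholds())
  prof <- row_statistics(lab)
  f <- fit_axis(prof)
  # padding with all-air rows above and below changes nothing
  pad <- matrix(0L, 10, 96)
  lab_pad <- label_image(rbind(pad, lab$labels, pad))
  f_pad <- fit_axis(row_statistics(lab_pad))
  expect_equal(f_pad$c1, f$c1, tolerance = 1e-12)
  expect_equal(f_pad$c2, f$c2, tolerance = 1e-12)
  # shifting the image k columns moves c2 by exactly k, c1 unchanged
  k <- 4
  shifted <- cbind(matrix(0L, 96, k), lab$labels[, 1:(96 - k)])
  f_sh <- fit_axis(row_statistics(label_image(shifted)))
  expect_equal(f_sh$c2, f$c2 + k, tolerance = 1e-9)
  expect_equal(f_sh$c1, f$c1, tolerance = 1e-9)
})

test_that("fewer than two qualifying rows is reported as no sample", {
  expect_error(fit_axis(make_profiles(y = c(-1, 0, 1), mean_x = c(0, 0, 0),
                                      p_sample = 0.01)), "no sample found")
  lab <- label_image(matrix(0L, 5, 10))
  expect_error(find_extent(row_statistics(lab)), "no sample found")
})

test_that("vertical extent matches the reference detector convention", {
  # a specimen vertically filling a 2048-row detector: extremes around
  # +/-1024 rows from the center
  det <- detector_config(n_rows = 2048, n_cols = 32, pix_x = 0.74,
                         pix_y = 0.74, noise_sigma = 0, fringe_amplitude = 0)
  smp <- slim_phantom(radius = 0.005, length = 12)
  st <- mid_stage(smp)
  ext <- find_extent(row_statistics(segment(render_projection(smp, st, det),
                                            thresholds(t_sample = 0.005))))
  expect_equal(unname(ext["y_max"]), 1023.5)
  expect_equal(unname(ext["y_min"]), -1023.5)
  # a single qualifying row reports itself as both extremes
  m <- matrix(0L, 15, 10); m[4, ] <- 1L
  ext1 <- find_extent(row_statistics(label_image(m)))
  expect_equal(unname(ext1["y_max"]), unname(ext1["y_min"]))
  expect_equal(unname(ext1["y_max"]), 4)
})

test_that("the top cap of a phantom is located to within the fringe band", {
  det <- detector_config(128, 128, 1500 / 128, 1500 / 128, noise_sigma = 0,
                         fringe_amplitude = 0.4, fringe_width_px = 1)
  smp <- slim_phantom(radius = 0.2, length = 0.9)
  st <- stage_state(y = -450)   # cap at lab y = +450 um
  ext <- find_extent(row_statistics(clean_rows(segment(
    render_projection(smp, st, det), thresholds()), 0.05)))
  cap_row <- 450 / det$pix_y
  expect_lt(abs(ext["y_max"] - cap_row), 1 + det$fringe_width_px * 2)
})

test_that("tilt and offset are recovered from noiseless phantoms", {
  det <- clean_det(256)
  cases <- expand.grid(tilt = c(-3, -1, 0.5, 2), off = c(-200, 0, 150))
  for (i in seq_len(nrow(cases))) {
    tilt <- cases$tilt[i]; off <- cases$off[i]
    smp <- slim_phantom(radius = 0.1, axis_tilt_x = tilt, base_offset_x = off)
    st <- stage_state(y = -3000)
    lab <- clean_rows(segment(render_projection(smp, st, det), thresholds()),
                      0.05)
    f <- fit_axis(row_statistics(lab))
    expect_lt(abs(f$theta_s - tilt), 0.05)
    true_center <- off + 3000 * tan(tilt * pi / 180)
    expect_lt(abs(f$c2 * det$pix_x - true_center), det$pix_x)
  }
})

test_that("out_of_fov flags specimens that vertically fill the detector", {
  det <- clean_det(96)
  long <- slim_phantom(radius = 0.1, length = 12)
  f_long <- fit_axis(row_statistics(segment(
    render_projection(long, mid_stage(long), det), thresholds())))
  expect_true(f_long$out_of_fov)
  short <- slim_phantom(radius = 0.1, length = 0.9)
  f_short <- fit_axis(row_statistics(segment(
    render_projection(short, stage_state(y = -450), det), thresholds())))
  expect_false(f_short$out_of_fov)
})
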