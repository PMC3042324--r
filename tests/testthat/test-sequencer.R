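test_that("the script parser accepts the step grammar and reports bad lines", {
  expect_length(parse_script(""), 0)
  sc <- parse_script("load s1; align; scan a; unload")
  expect_length(sc, 4)
  expect_equal(vapply(sc, `[[`, "", "kind"),
               c("load", "align", "scan", "unload"))
  # repeat blocks nest and keep their line numbers
  sc2 <- parse_script("load s1\nrepeat 3\n  roi 0.56\n  scan t\nend\nunload")
  expect_equal(sc2[[2]]$kind, "repeat")
  expect_equal(sc2[[2]]$n, 3)
  expect_length(sc2[[2]]$body, 2)
  # malformed scripts fail with the offending line number
  expect_error(parse_script("load s1\nfly away"), "line 2.*unknown")
  expect_error(parse_script("load s1\nrepeat 2\nscan a"), "never closed")
  expect_error(parse_script("end"), "without matching")
  expect_error(parse_script("align"), "before any 'load'")
})

test_that("a three-sample batch logs every step once with converged alignments", {
  smp <- phantom_sample(length = 10, radius_x = 0.3, radius_z = 0.3)
  sys <- virtual_system(list(s1 = smp, s2 = smp, s3 = smp), study_det(128),
                        pm = placement_model(max_initial_offset = 400))
  sc <- parse_script(paste(
    "load s1; align; scan a; unload",
    "load s2; align; scan a; unload",
    "load s3; align; scan a; unload", sep = "\n"))
  rep1 <- run_batch(sc, sys, seed = 3)
  expect_equal(nrow(rep1$log), 12)
  expect_true(all(rep1$log$status == "ok"))
  expect_equal(sum(rep1$log$kind == "align"), 3)
  conv <- Filter(function(d) inherits(d, "alignment_result"), rep1$details)
  expect_length(conv, 3)
  expect_true(all(vapply(conv, `[[`, TRUE, "converged")))
  # identical seed, identical report
  rep2 <- run_batch(sc, sys, seed = 3)
  expect_identical(rep1$log, rep2$log)
  rep3 <- run_batch(sc, sys, seed = 4)
  expect_false(identical(rep1$log$x, rep3$log$x))
})

test_that("multi-ROI scripts record scans at distinct stage heights", {
  smp <- phantom_sample(length = 10, radius_x = 0.3, radius_z = 0.3)
  sys <- virtual_system(list(s1 = smp), study_det(128),
                        pm = placement_model(max_initial_offset = 200))
  sc <- parse_script(paste(
    "load s1; align",
    "roi 0.2; scan r1", "roi 0.35; scan r2", "roi 0.5; scan r3",
    "roi 0.65; scan r4", "roi 0.8; scan r5", "unload", sep = "\n"))
  rep1 <- run_batch(sc, sys, seed = 5)
  scans <- rep1$log[rep1$log$kind == "scan", ]
  expect_equal(nrow(scans), 5)
  expect_equal(length(unique(round(scans$y, 3))), 5)
  # fractions map to positions spaced by the measured length
  roi_idx <- which(rep1$log$kind == "roi")[1]
  len_mm <- rep1$details[[roi_idx]]$length_mm
  expect_equal(len_mm, 10, tolerance = 0.05)
  ys <- scans$y
  expect_equal(diff(ys), rep(-0.15 * len_mm * 1000, 4), tolerance = 1e-6)
})

test_that("failed steps follow the configured error policy", {
  smp <- phantom_sample(length = 10, radius_x = 0.3, radius_z = 0.3)
  sys <- virtual_system(list(s1 = smp), study_det(128),
                        pm = placement_model(max_initial_offset = 200))
  sc <- parse_script("load s1; align; scan ok1; load nope; align; scan bad; unload; load s1; align; scan ok2; unload")
  ab <- run_batch(sc, sys, seed = 7, on_error = "abort")
  expect_equal(nrow(ab$log), 4)
  expect_match(ab$log$status[4], "unknown sample")
  sk <- run_batch(sc, sys, seed = 7, on_error = "skip_sample")
  expect_equal(nrow(sk$log), nrow(sk$log))
  expect_equal(sum(sk$log$status == "skipped"), 2)   # align + scan after bad load
  expect_true(any(sk$log$status == "ok" & sk$log$kind == "scan" &
                    sk$log$arg == "ok2"))
})

test_that("repeat blocks execute their body the requested number of times", {
  smp <- phantom_sample(length = 10, radius_x = 0.3, radius_z = 0.3)
  sys <- virtual_system(list(s1 = smp), study_det(96),
                        pm = placement_model(max_initial_offset = 100))
  rep1 <- run_batch(parse_script("load s1; align\nrepeat 3\nscan t; wait 10\nend\nunload"),
                    sys, seed = 2)
  expect_equal(sum(rep1$log$kind == "scan"), 3)
  expect_equal(sum(rep1$log$kind == "wait"), 3)
  # the simulated clock advances through waits without sleeping
  expect_gte(max(rep1$log$clock), 30)
})

test_that("zero placement noise and noiseless imaging give zero precision spread", {
  det <- clean_det(96)
  smp <- phantom_sample(length = 3, radius_x = 0.25, radius_z = 0.25)
  ps <- precision_study(smp, n_reps = 3,
                        pm = placement_model(mount_sigma = 0,
                                             max_initial_offset = 0,
                                             tilt_range = 0),
                        det = det, seed = 1)
  expect_equal(ps$summary$x_sd, 0)
  expect_equal(ps$summary$y_sd, 0)
  expect_equal(ps$summary$z_sd, 0)
  expect_equal(ps$summary$length_sd, 0)
})

test_that("precision spread does not shrink when imaging noise grows", {
  smp <- phantom_sample(length = 6, radius_x = 0.35, radius_z = 0.35)
  # fringe off: at near-zero noise a strong fringe locks the labeled edge to
  # the pixel grid and the aliasing would dominate the noise response
  spread <- vapply(c(0.005, 0.03, 0.08), function(ns) {
    det <- detector_config(128, 128, 1500 / 128, 1500 / 128,
                           noise_sigma = ns, fringe_amplitude = 0,
                           fringe_width_px = 0)
    ps <- precision_study(smp, n_reps = 8,
                          pm = placement_model(mount_sigma = 0,
                                               max_initial_offset = 300),
                          det = det, seed = 42)
    mean(c(ps$summary$x_sd, ps$summary$z_sd))
  }, numeric(1))
  expect_lt(spread[1], spread[3])
})

test_that("precision rows export as a readable summary table", {
  det <- clean_det(96)
  smp <- phantom_sample(length = 3, radius_x = 0.25, radius_z = 0.25)
  ps <- precision_study(smp, n_reps = 2,
                        pm = placement_model(mount_sigma = 0,
                                             max_initial_offset = 50,
                                             tilt_range = 0.5),
                        det = det, seed = 2)
  path <- tempfile(fileext = ".csv")
  out <- write_precision_csv(ps, path)
  expect_true(file.exists(path))
  expect_match(out$length_mm, "±")
  expect_equal(out$n_repetitions, 2)
})
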