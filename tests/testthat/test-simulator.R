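test_that("ray path length: exact chords, misses, and the quadrature oracle", {
  bar <- bar_spec()
  g <- paper_geometry()
  zb <- g$A            # upstream bar depth, cm
  zp <- g$A + g$B + g$C

  # ray through the cross-section center traverses the full diameter
  expect_equal(ray_path_length(0, 0, 0, zb, zp, bar), bar$diameter_cm,
               tolerance = 1e-12)
  # rays far from the bar miss it
  expect_equal(ray_path_length(50, 0, 0, zb, zp, bar), 0)
  expect_equal(ray_path_length(-8, 0, 0, zb, zp, bar), 0)

  # oblique and grazing rays agree with brute-force quadrature to 1e-4 cm
  cases <- expand.grid(x = c(-4.5, -3.3, -1, 0.8, 2.9, 3.4), s = c(-0.8, 0, 1.2))
  for (i in seq_len(nrow(cases))) {
    expect_lt(abs(ray_path_length(cases$x[i], cases$s[i], 0.2, zb, zp, bar) -
                    ray_path_oracle(cases$x[i], cases$s[i], 0.2, zb, zp, bar)),
              1e-4) # cm, absolute
  }
})

test_that("a centered focus gives a profile symmetric about zero", {
  prof <- simulate_profile(source_spec(0, fwhm_mm = 0), "upstream",
                           detector = detector_spec(aperture_mm = 0, noise_cv = 0))
  x <- prof$positions
  expect_equal(x, -rev(x)) # the standard grid is symmetric
  expect_equal(prof$currents, rev(prof$currents), tolerance = 1e-12)
})

test_that("dip-center difference between levels equals a times k", {
  g <- paper_geometry()
  k <- magnification_factor(g)
  up <- simulate_profile(source_spec(0.42), "upstream", detector = noiseless_detector())
  dn <- simulate_profile(source_spec(0.42), "downstream", detector = noiseless_detector())
  diff_centers <- find_dip_center(dn)$center - find_dip_center(up)$center
  expect_lt(abs(diff_centers - 0.42 * k), 0.01)
})

test_that("an opaque bar drives the dip floor to zero current", {
  opaque <- bar_spec(mu_per_cm = 200)
  prof <- simulate_profile(source_spec(0, fwhm_mm = 0), "upstream",
                           detector = detector_spec(aperture_mm = 0, noise_cv = 0),
                           bar = opaque)
  expect_lt(min(prof$currents) / max(prof$currents), 1e-30)
})

test_that("noiseless simulation recovers the injected offset across its range", {
  for (a in c(-1, -0.5, -0.1, 0, 0.1, 0.5, 1)) {
    expect_lt(abs(recover_offset(a) - a), 0.02)
  }
})

test_that("negating the injected offset negates the estimate", {
  for (a in c(0.1, 0.42, 1)) {
    expect_equal(recover_offset(-a), -recover_offset(a), tolerance = 1e-9)
  }
})

test_that("the recovered offset does not depend on the attenuation coefficient", {
  ests <- vapply(c(0.1, 0.5, 2, 5), function(mu) {
    recover_offset(0.42, bar = bar_spec(mu_per_cm = mu))
  }, numeric(1))
  expect_true(all(abs(ests - 0.42) < 0.02))
})

test_that("estimator scatter grows monotonically with reading noise", {
  est_sd <- function(cv) {
    ests <- vapply(1:50, function(i) {
      det <- detector_spec(noise_cv = cv, seed = 5000 + i)
      up <- simulate_profile(source_spec(0.2), "upstream", detector = det)
      det$seed <- 9000 + i
      dn <- simulate_profile(source_spec(0.2), "downstream", detector = det)
      estimate_focal_offset(find_dip_center(up)$center,
                            find_dip_center(dn)$center,
                            paper_geometry())$offset_a
    }, numeric(1))
    sd(ests)
  }
  sds <- vapply(c(0.001, 0.004, 0.012), est_sd, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("seeded profiles are reproducible and spec validation works", {
  det <- detector_spec(seed = 77)
  p1 <- simulate_profile(source_spec(0.3), "upstream", detector = det)
  p2 <- simulate_profile(source_spec(0.3), "upstream", detector = det)
  expect_identical(p1$currents, p2$currents)
  expect_error(detector_spec(noise_cv = -0.1), class = "focalspot_invalid_spec")
  expect_error(bar_spec(diameter_cm = 20), class = "focalspot_invalid_spec")
  expect_error(sampling_schedule(data.frame(start = 0, end = 1, interval = -1)),
               class = "focalspot_invalid_spec")
  expect_error(sampling_schedule(data.frame(start = c(0, 2), end = c(1, 3),
                                            interval = c(0.5, 0.5))),
               class = "focalspot_invalid_spec")
  expect_warning(simulate_profile(
    source_spec(0), "upstream", detector = noiseless_detector(),
    schedule = sampling_schedule(data.frame(start = -40, end = 40, interval = 5))),
    "flat central field")
})

test_that("the standard schedule reproduces the protocol grid", {
  x <- table1_positions()
  expect_equal(range(x), c(-10, 10))
  expect_equal(min_interval(sampling_schedule()), 0.1)
  expect_equal(sort(unique(round(diff(x), 9))), c(0.1, 0.2, 1))
  # 0.1 mm steps only within +/- 1 mm
  fine <- x[x >= -1 & x <= 1]
  expect_equal(diff(fine), rep(0.1, 20), tolerance = 1e-9)
})

test_that("generate_session writes a deterministic, analyzable study", {
  dir_a <- file.path(tempdir(), "fs_sess_a")
  dir_b <- file.path(tempdir(), "fs_sess_b")
  unlink(c(dir_a, dir_b), recursive = TRUE)

  man <- generate_session(dir_a, 0, 0, n_repeats = 1, n_sessions = 1, seed = 3,
                          session_sd_mm = 0,
                          detector = detector_spec(noise_cv = 0))
  expect_equal(nrow(man$files), 4) # 2 axes x 2 levels
  rep0 <- analyze_session(dir_a)
  expect_lt(abs(rep0$axes$IEC_X$result$offset_a), 0.01)
  expect_lt(abs(rep0$axes$IEC_Y$result$offset_a), 0.01)

  # byte-identical rerun from the same arguments/seed
  generate_session(dir_b, 0, 0, n_repeats = 1, n_sessions = 1, seed = 3,
                   session_sd_mm = 0, detector = detector_spec(noise_cv = 0))
  for (f in man$files$file) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }

  # manifest records the ground truth and per-file seeds
  m2 <- jsonlite::read_json(file.path(dir_a, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(m2$truth$offset_x_mm, 0)
  expect_equal(m2$seed, 3)
  expect_equal(nrow(m2$files), 4)

  # rerunning into the same directory is an output collision
  expect_error(generate_session(dir_a, 0, 0, n_repeats = 1, n_sessions = 1),
               class = "focalspot_output_collision")
})
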