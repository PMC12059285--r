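test_that("beam profile validation catches malformed inputs", {
  expect_error(beam_profile(c(1, 2), c(1, 2)), class = "focalspot_invalid_profile")
  expect_error(beam_profile(c(1, 2, 2, 3), c(1, 1, 1, 1)),
               class = "focalspot_invalid_profile")
  expect_error(beam_profile(1:5, c(1, 2, -1, 2, 1)),
               class = "focalspot_invalid_profile")
  expect_error(beam_profile(1:4, 1:5), class = "focalspot_invalid_profile")
})

test_that("central differences are exact for linear data on any grid", {
  x <- c(-3, -1.5, -1, -0.2, 0.3, 1, 2.7)
  dp <- differentiate_profile(beam_profile(x, 2 * x + 15))
  expect_equal(dp$positions, x[2:6])
  expect_equal(dp$derivative, rep(2, 5), tolerance = 1e-12)
  dpc <- differentiate_profile(beam_profile(x, rep(7, 7)))
  expect_equal(dpc$derivative, rep(0, 5))
})

test_that("central differences equal the neighbour secant slope on a nonuniform grid", {
  x <- c(-2, -1, -0.5, 0, 1)
  dp <- differentiate_profile(beam_profile(x, x^2 + 5)) # +5 keeps currents > 0
  # hand-evaluated secants of x^2: at -1: (0.25-4)/1.5; at -0.5: (0-1)/1; at 0: (1-0.25)/1.5
  expect_equal(dp$derivative, c(-2.5, -1, 0.5), tolerance = 1e-12)
})

test_that("a symmetric dip on the symmetric standard grid centers at zero", {
  prof <- gaussian_dip_profile(0)
  expect_equal(find_dip_center(prof, method = "local_linear_fit")$center, 0,
               tolerance = 1e-12)
  expect_equal(find_dip_center(prof, method = "bracket_interp")$center, 0,
               tolerance = 1e-12)
})

test_that("a translated dip is located within the sampling tolerance", {
  for (method in c("local_linear_fit", "bracket_interp")) {
    est <- find_dip_center(gaussian_dip_profile(0.10), method = method)
    expect_lt(abs(est$center - 0.10), 0.05) # half the local 0.1 mm interval
    # dense 1 um resampling oracle: ground truth recovered almost exactly
    dense <- gaussian_dip_profile(0.10, positions = seq(-5, 5, by = 1e-3))
    expect_lt(abs(find_dip_center(dense, method = method)$center - 0.10), 1e-3)
  }
})

test_that("both methods match the continuous model on dense noiseless profiles", {
  # point source, zero aperture: transmission minimum exactly at the
  # projected bar-axis position
  det <- detector_spec(aperture_mm = 0, noise_cv = 0)
  src <- source_spec(offset_mm = 0.42, fwhm_mm = 0)
  sched <- sampling_schedule(data.frame(start = -5, end = 5, interval = 1e-3))
  truth <- shadow_offset(0.42, "upstream", paper_geometry())
  prof <- simulate_profile(src, "upstream", detector = det, schedule = sched)
  for (method in c("local_linear_fit", "bracket_interp")) {
    expect_lt(abs(find_dip_center(prof, method = method)$center - truth), 1e-3)
  }
})

test_that("dip center agrees with the forward projection on simulator profiles", {
  g <- paper_geometry()
  prof <- simulate_profile(source_spec(0.42), "upstream",
                           detector = noiseless_detector(), geometry = g)
  expect_lt(abs(find_dip_center(prof)$center - shadow_offset(0.42, "upstream", g)),
            0.02)
})

test_that("dip center is invariant to current rescaling", {
  prof <- gaussian_dip_profile(0.10)
  base <- find_dip_center(prof)$center
  for (scale in c(1e-3, 7, 1e4)) {
    scaled <- beam_profile(prof$positions, prof$currents * scale)
    expect_equal(find_dip_center(scaled)$center, base, tolerance = 1e-12)
    expect_equal(find_dip_center(scaled, method = "bracket_interp")$center,
                 find_dip_center(prof, method = "bracket_interp")$center,
                 tolerance = 1e-12)
  }
})

test_that("dip center is equivariant under a profile shift", {
  prof <- simulate_profile(source_spec(0.2), "upstream",
                           detector = noiseless_detector())
  base <- find_dip_center(prof)$center
  # exact when the whole grid shifts with the profile
  for (delta in c(-2.5, 0.3, 4)) {
    shifted <- beam_profile(prof$positions + delta, prof$currents,
                            metadata = prof$metadata)
    expect_equal(find_dip_center(shifted)$center, base + delta, tolerance = 1e-9)
  }
  # within the local sampling interval when the dip moves over a fixed grid
  for (delta in c(-0.35, 0.15, 0.6)) {
    moved <- gaussian_dip_profile(delta)
    expect_lt(abs(find_dip_center(moved)$center - delta), 0.1)
  }
})

test_that("the two dip-center methods agree on noiseless simulator profiles", {
  for (a in seq(-1, 1, by = 0.25)) {
    for (level in c("upstream", "downstream")) {
      prof <- simulate_profile(source_spec(a), level,
                               detector = noiseless_detector())
      d_fit <- find_dip_center(prof, method = "local_linear_fit")$center
      d_br <- find_dip_center(prof, method = "bracket_interp")$center
      expect_lt(abs(d_fit - d_br), 0.05)
    }
  }
})

test_that("dip detection fails cleanly when there is no usable dip", {
  # minimum on the boundary: monotone profile
  mono <- beam_profile(seq(-5, 5, by = 1), seq(20, 10, length.out = 11))
  expect_error(find_dip_center(mono), class = "focalspot_no_dip")
  # interior minimum but no negative-to-positive crossing inside the window
  cur <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 1.5)
  tail_dip <- beam_profile(0:10, cur)
  expect_error(find_dip_center(tail_dip, window_halfwidth = 1),
               class = "focalspot_no_dip")
  # window too narrow to hold 4 derivative samples
  expect_error(find_dip_center(gaussian_dip_profile(0), window_halfwidth = 0.15),
               class = "focalspot_no_dip")
  # too-short profile
  expect_error(find_dip_center(beam_profile(1:5, c(3, 2, 1, 2, 3))),
               class = "focalspot_invalid_profile")
})

test_that("repeat aggregation returns mean, SD and SD of the mean", {
  r <- aggregate_repeats(c(0.1, 0.1, 0.1))
  expect_equal(r$mean, 0.1)
  expect_equal(r$sd, 0)
  expect_equal(r$sd_of_mean, 0)

  r2 <- aggregate_repeats(c(0.0, 0.2))
  expect_equal(r2$mean, 0.1)
  expect_equal(r2$sd, sqrt(0.02), tolerance = 1e-12) # 0.14142...
  expect_equal(r2$sd_of_mean, 0.1, tolerance = 1e-12)

  expect_error(aggregate_repeats(0.1), class = "focalspot_too_few_repeats")

  # accepts dip_center_estimate objects
  ests <- lapply(c(-0.1, 0.3), function(center) {
    structure(list(center = center), class = "dip_center_estimate")
  })
  expect_equal(aggregate_repeats(ests)$mean, 0.1)

  # statistical sanity on seeded draws
  set.seed(42)
  draws <- rnorm(10, -0.14, 0.03)
  expect_lt(abs(aggregate_repeats(draws)$mean - (-0.14)), 0.03)
})
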