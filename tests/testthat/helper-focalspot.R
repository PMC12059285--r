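# shared fixtures for the focalspot tests

paper_geometry <- function() measurement_geometry(B = 20.473, C = 3.65, sad = 85)

noiseless_detector <- function() detector_spec(aperture_mm = 2, noise_cv = 0)

# noiseless two-level simulation -> estimated focal offset (stage frame)
recover_offset <- function(a, method = "local_linear_fit",
                           detector = noiseless_detector(),
                           bar = bar_spec(), geometry = paper_geometry()) {
  up <- simulate_profile(source_spec(a), "upstream", detector = detector,
                         geometry = geometry, bar = bar)
  dn <- simulate_profile(source_spec(a), "downstream", detector = detector,
                         geometry = geometry, bar = bar)
  c1 <- find_dip_center(up, method = method)$center
  c2 <- find_dip_center(dn, method = method)$center
  estimate_focal_offset(c1, c2, geometry)$offset_a
}

# analytic Gaussian dip sampled on a given grid
gaussian_dip_profile <- function(center = 0, positions = table1_positions()) {
  beam_profile(positions, 100 * (1 - 0.8 * exp(-(positions - center)^2 / 2)))
}

# globally quadratic dip: derivative exactly linear, so the dip-center
# estimators are exact at any center
quadratic_dip_profile <- function(center, positions = table1_positions(),
                                  metadata = list()) {
  beam_profile(positions, 50 + 10 * (positions - center)^2, metadata = metadata)
}

table1_positions <- function() schedule_positions(sampling_schedule())

# brute-force quadrature oracle for the ray path: integrate the inside-bar
# indicator along the ray at 1 um depth steps near the bar
ray_path_oracle <- function(x_plane_mm, source_x_mm, bar_x_mm,
                            bar_depth_cm, plane_depth_cm, bar = bar_spec()) {
  zb <- bar_depth_cm * 10
  zp <- plane_depth_cm * 10
  r <- bar$diameter_cm * 10 / 2
  step <- 1e-3 # mm
  z <- seq(zb - r - 1, zb + r + 1, by = step)
  x_on_ray <- source_x_mm + (x_plane_mm - source_x_mm) * z / zp
  inside <- (x_on_ray - bar_x_mm)^2 + (z - zb)^2 <= r^2
  sec <- sqrt(1 + ((x_plane_mm - source_x_mm) / zp)^2)
  sum(inside) * step * sec / 10 # cm
}
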