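#' Specification of the suspended metal bar
#'
#' The bar hangs in the beam with its long axis across the field,
#' perpendicular to the chamber scan direction; each scan crosses the bar's
#' short axis, so a ray in the scan plane sees the bar's circular
#' cross-section. The attenuation coefficient is a generic effective value for
#' a metal at 6 MV; the dip *center* is insensitive to it (only the dip depth
#' changes).
#'
#' @param length_cm Bar length (cm), default 14.5.
#' @param diameter_cm Bar diameter (cm), default 0.5.
#' @param mu_per_cm Effective linear attenuation coefficient (1/cm),
#'   default 0.4.
#' @return An object of class `"bar_spec"`.
#' @export
bar_spec <- function(length_cm = 14.5, diameter_cm = 0.5, mu_per_cm = 0.4) {
  stopifnot(is_scalar_number(length_cm), length_cm > 0,
            is_scalar_number(diameter_cm), diameter_cm > 0,
            is_scalar_number(mu_per_cm), mu_per_cm > 0)
  if (diameter_cm >= length_cm) {
    fs_abort("bar diameter must be smaller than its length", "focalspot_invalid_spec")
  }
  structure(list(length_cm = length_cm, diameter_cm = diameter_cm,
                 mu_per_cm = mu_per_cm), class = "bar_spec")
}

#' Specification of the x-ray source for simulation
#'
#' @param offset_mm True lateral focal-spot displacement (mm) in the
#'   chamber-stage frame — the ground truth the analysis should recover.
#' @param fwhm_mm Focal-spot size (FWHM of a Gaussian intensity distribution,
#'   mm) used to blur the shadow; default 1.0. The real focal-spot size of the
#'   machine is not publicly specified; the dip center is first-order
#'   insensitive to this value.
#' @param sad_cm Source-axis distance (cm), default 85.
#' @return An object of class `"source_spec"`.
#' @export
source_spec <- function(offset_mm = 0, fwhm_mm = 1.0, sad_cm = 85) {
  stopifnot(is_scalar_number(offset_mm), is_scalar_number(fwhm_mm), fwhm_mm >= 0,
            is_scalar_number(sad_cm), sad_cm > 0)
  structure(list(offset_mm = offset_mm, fwhm_mm = fwhm_mm, sad_cm = sad_cm),
            class = "source_spec")
}

#' Specification of the scanning ionization chamber
#'
#' @param aperture_mm Lateral averaging width of the chamber (mm), modeled as
#'   a uniform window; default 2.0.
#' @param noise_cv Coefficient of variation of a single electrometer reading;
#'   default 0.002.
#' @param samples_per_point Readings averaged at each stage position,
#'   default 5.
#' @param seed Optional integer seed making a simulated profile reproducible.
#' @return An object of class `"detector_spec"`.
#' @export
detector_spec <- function(aperture_mm = 2.0, noise_cv = 0.002,
                          samples_per_point = 5L, seed = NULL) {
  stopifnot(is_scalar_number(aperture_mm), aperture_mm >= 0)
  if (!is_scalar_number(noise_cv) || noise_cv < 0) {
    fs_abort("noise_cv must be a nonnegative scalar", "focalspot_invalid_spec")
  }
  stopifnot(samples_per_point >= 1)
  structure(list(aperture_mm = aperture_mm, noise_cv = noise_cv,
                 samples_per_point = as.integer(samples_per_point),
                 seed = seed), class = "detector_spec")
}

#' Nonuniform stage sampling schedule
#'
#' Contiguous position ranges with their step sizes. The default reproduces
#' the standard protocol: 1 mm steps from ±10 to ±5 mm, 0.2 mm from ±5 to
#' ±1 mm, and 0.1 mm within ±1 mm of the reference center.
#'
#' @param segments `data.frame` with columns `start`, `end`, `interval` (mm).
#' @return An object of class `"sampling_schedule"`.
#' @export
sampling_schedule <- function(segments = data.frame(
                                start = c(-10, -5, -1, 1, 5),
                                end = c(-5, -1, 1, 5, 10),
                                interval = c(1, 0.2, 0.1, 0.2, 1))) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "interval") %in% names(segments)))
  if (any(segments$interval <= 0) || any(segments$end <= segments$start)) {
    fs_abort("schedule segments need end > start and positive intervals",
             "focalspot_invalid_spec")
  }
  if (nrow(segments) > 1L &&
      any(abs(segments$start[-1L] - segments$end[-nrow(segments)]) > 1e-9)) {
    fs_abort("schedule segments must be contiguous and increasing",
             "focalspot_invalid_spec")
  }
  structure(list(segments = segments), class = "sampling_schedule")
}

#' Stage positions implied by a sampling schedule
#'
#' @param schedule A [sampling_schedule()].
#' @return Sorted unique numeric vector of positions (mm).
#' @export
schedule_positions <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  seg <- schedule$segments
  pos <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    seq(seg$start[i], seg$end[i], by = seg$interval[i])
  }))
  sort(unique(round(pos, 9)))
}

#' Smallest sampling interval of a schedule (mm)
#' @param schedule A [sampling_schedule()].
#' @return The minimum step size, mm.
#' @export
min_interval <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  min(schedule$segments$interval)
}

#' Path length of a ray through the bar
#'
#' Exact chord of the straight ray from the source point to a position on the
#' acquisition plane through the bar's circular cross-section (the scan plane
#' cuts the horizontal bar perpendicular to its axis). Returns 0 when the ray
#' misses the bar. Lateral coordinates are in mm, depths in cm (converted
#' internally); the returned path is in cm.
#'
#' @param x_plane_mm Position(s) on the acquisition plane, mm. Vectorized.
#' @param source_x_mm Lateral source position, mm.
#' @param bar_x_mm Lateral position of the bar axis, mm.
#' @param bar_depth_cm Depth of the bar axis below the source, cm.
#' @param plane_depth_cm Depth of the acquisition plane below the source, cm.
#' @param bar A [bar_spec()].
#' @return Path length(s) inside the bar, cm.
#' @export
ray_path_length <- function(x_plane_mm, source_x_mm = 0, bar_x_mm = 0,
                            bar_depth_cm, plane_depth_cm, bar = bar_spec()) {
  stopifnot(inherits(bar, "bar_spec"),
            is_scalar_number(bar_depth_cm), bar_depth_cm > 0,
            is_scalar_number(plane_depth_cm), plane_depth_cm > bar_depth_cm)
  zb <- bar_depth_cm * 10    # mm
  zp <- plane_depth_cm * 10  # mm
  r <- bar$diameter_cm * 10 / 2
  dx <- x_plane_mm - source_x_mm
  # perpendicular distance from the ray line to the bar axis point (bar_x, zb)
  cross <- dx * zb - zp * (bar_x_mm - source_x_mm)
  dist <- abs(cross) / sqrt(dx^2 + zp^2)
  chord_mm <- 2 * sqrt(pmax(r^2 - dist^2, 0))
  chord_mm / 10
}

bar_depth_for_level <- function(level, geometry) {
  g <- as_geometry(geometry)
  switch(level,
         upstream = g$A,
         downstream = g$A + g$B,
         fs_abort("level must be 'upstream' or 'downstream'", "focalspot_invalid_spec"))
}

#' Simulate one transmission profile through the bar
#'
#' For each stage position the transmission `exp(-mu * path)` is averaged over
#' the focal-spot intensity distribution (Gaussian of the given FWHM, 21-node
#' quadrature) and the chamber aperture (uniform window, 11 nodes), scaled by
#' the open-field level, and then read `samples_per_point` times with
#' multiplicative Gaussian noise of the given coefficient of variation; the
#' per-position mean is recorded as the current. The open field is modeled as
#' flat across the scanned region (the central part of the treatment field);
#' only the bar's shadow imposes lateral structure.
#'
#' @param source A [source_spec()]; its `offset_mm` is the injected focal
#'   displacement in the stage frame.
#' @param level `"upstream"` or `"downstream"` bar position.
#' @param bar_x_mm Lateral position of the bar axis (mm), 0 when perfectly
#'   aligned with the reference center.
#' @param detector A [detector_spec()]; with `noise_cv = 0` the profile is
#'   deterministic.
#' @param schedule A [sampling_schedule()].
#' @param geometry A [measurement_geometry()].
#' @param bar A [bar_spec()].
#' @param open_field_level Open-field current level (arbitrary units).
#' @param metadata Extra metadata stored on the returned profile.
#' @return A [beam_profile()]; metadata records the level, specs and per-point
#'   reading SD.
#' @export
simulate_profile <- function(source = source_spec(),
                             level = c("upstream", "downstream"),
                             bar_x_mm = 0,
                             detector = detector_spec(),
                             schedule = sampling_schedule(),
                             geometry = measurement_geometry(),
                             bar = bar_spec(),
                             open_field_level = 100,
                             metadata = list()) {
  level <- match.arg(level)
  stopifnot(inherits(source, "source_spec"), inherits(detector, "detector_spec"),
            inherits(bar, "bar_spec"))
  g <- as_geometry(geometry)
  x <- schedule_positions(schedule)
  # flat-field model holds only near the field center (5 cm min field width)
  if (max(abs(x)) > 25) {
    warning("schedule extends beyond the flat central field region (+/- 25 mm)")
  }
  zbar <- bar_depth_for_level(level, g)
  zplane <- g$A + g$B + g$C

  if (source$fwhm_mm > 0) {
    sigma <- source$fwhm_mm / (2 * sqrt(2 * log(2)))
    u <- seq(-3, 3, length.out = 21)
    s_nodes <- source$offset_mm + u * sigma
    s_w <- stats::dnorm(u)
    s_w <- s_w / sum(s_w)
  } else {
    s_nodes <- source$offset_mm
    s_w <- 1
  }
  if (detector$aperture_mm > 0) {
    o_nodes <- seq(-detector$aperture_mm / 2, detector$aperture_mm / 2,
                   length.out = 11)
    o_w <- rep(1 / 11, 11)
  } else {
    o_nodes <- 0
    o_w <- 1
  }

  tbar <- numeric(length(x))
  for (i in seq_along(s_nodes)) {
    for (j in seq_along(o_nodes)) {
      path <- ray_path_length(x + o_nodes[j], s_nodes[i], bar_x_mm,
                              zbar, zplane, bar)
      tbar <- tbar + s_w[i] * o_w[j] * exp(-bar$mu_per_cm * path)
    }
  }

  sim_read <- function() {
    if (detector$noise_cv > 0) {
      spp <- detector$samples_per_point
      eps <- matrix(stats::rnorm(length(x) * spp, 0, detector$noise_cv),
                    nrow = length(x))
      reads <- open_field_level * tbar * (1 + eps)
      list(current = pmax(rowMeans(reads), .Machine$double.xmin),
           point_sd = apply(reads, 1, stats::sd))
    } else {
      list(current = open_field_level * tbar, point_sd = rep(0, length(x)))
    }
  }
  r <- if (!is.null(detector$seed)) withr::with_seed(detector$seed, sim_read())
       else sim_read()

  beam_profile(x, r$current,
               n_samples_per_point = detector$samples_per_point,
               metadata = c(list(level = level,
                                 open_field_level = open_field_level,
                                 mu_per_cm = bar$mu_per_cm,
                                 point_sd = r$point_sd),
                            metadata))
}

#' Generate a complete synthetic measurement study
#'
#' Emits profile CSV files for both IEC axes, both bar levels, `n_repeats`
#' consecutive repeats per session and `n_sessions` sessions, plus a
#' `manifest.json` recording every ground-truth parameter and per-file seed.
#' Repeats within a session share the bar alignment and differ only by
#' reading noise (repeatability); each session redraws the bar lateral
#' alignment from `Normal(0, session_sd_mm)` (reproducibility of the weekly
#' set-up). Injected IEC-frame offsets are converted to the stage frame with
#' the per-axis orientation signs, so analyzing the session with the same
#' signs recovers them.
#'
#' Rerunning with identical arguments reproduces byte-identical files.
#'
#' @param out_dir Output directory (created; existing profile files or
#'   manifest are an error).
#' @param offset_x_mm,offset_y_mm True focal-spot offsets (mm) along IEC-X /
#'   IEC-Y.
#' @param n_repeats Consecutive repeats per session (default 10).
#' @param n_sessions Sessions (default 3).
#' @param seed Integer master seed.
#' @param session_sd_mm SD of the per-session bar alignment shift (mm),
#'   default 0.08.
#' @param axis_sign_x,axis_sign_y Stage-to-IEC orientation signs.
#' @param source,detector,schedule,geometry,bar Component specs; the
#'   `offset_mm` of `source` and the `seed` of `detector` are overridden per
#'   file.
#' @return Invisibly, the manifest as a list.
#' @export
generate_session <- function(out_dir, offset_x_mm = 0, offset_y_mm = 0,
                             n_repeats = 10L, n_sessions = 3L, seed = 1L,
                             session_sd_mm = 0.08,
                             axis_sign_x = 1L, axis_sign_y = -1L,
                             source = source_spec(),
                             detector = detector_spec(),
                             schedule = sampling_schedule(),
                             geometry = measurement_geometry(),
                             bar = bar_spec()) {
  stopifnot(n_repeats >= 1, n_sessions >= 1, session_sd_mm >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(out_dir, "manifest.json"))) {
    fs_abort(sprintf("output collision: %s already contains a manifest",
                     out_dir), "focalspot_output_collision")
  }

  axes <- c(IEC_X = axis_sign_x, IEC_Y = axis_sign_y)
  offsets_iec <- c(IEC_X = offset_x_mm, IEC_Y = offset_y_mm)
  levels <- c("upstream", "downstream")
  n_files <- length(axes) * length(levels) * n_repeats * n_sessions

  drawn <- withr::with_seed(as.integer(seed), {
    list(shifts = matrix(stats::rnorm(n_sessions * length(axes), 0, session_sd_mm),
                         nrow = n_sessions,
                         dimnames = list(NULL, names(axes))),
         seeds = sample.int(.Machine$integer.max - 1L, n_files))
  })

  files <- data.frame(file = character(0), axis = character(0),
                      level = character(0), session = integer(0),
                      rep = integer(0), seed = integer(0),
                      stringsAsFactors = FALSE)
  idx <- 0L
  for (axis in names(axes)) {
    a_stage <- axes[[axis]] * offsets_iec[[axis]]
    src <- source
    src$offset_mm <- a_stage
    for (ses in seq_len(n_sessions)) {
      bar_x <- drawn$shifts[ses, axis]
      for (lev in levels) {
        for (rep_i in seq_len(n_repeats)) {
          idx <- idx + 1L
          det <- detector
          det$seed <- drawn$seeds[idx]
          fn <- sprintf("%s_%s_s%02d_r%02d.csv", tolower(axis), lev, ses, rep_i)
          path <- file.path(out_dir, fn)
          if (file.exists(path)) {
            fs_abort(sprintf("output collision: %s exists", path),
                     "focalspot_output_collision")
          }
          prof <- simulate_profile(src, lev, bar_x, det, schedule, geometry, bar,
                                   metadata = list(axis = axis,
                                                   session = ses,
                                                   rep = rep_i))
          write_profile(prof, path)
          files <- rbind(files, data.frame(file = fn, axis = axis, level = lev,
                                           session = ses, rep = rep_i,
                                           seed = drawn$seeds[idx],
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }

  manifest <- list(
    truth = list(offset_x_mm = offset_x_mm, offset_y_mm = offset_y_mm),
    seed = as.integer(seed),
    axis_signs = list(IEC_X = axis_sign_x, IEC_Y = axis_sign_y),
    session_sd_mm = session_sd_mm,
    session_bar_shifts_mm = as.data.frame(drawn$shifts),
    geometry = unclass(geometry),
    bar = unclass(bar),
    source = list(fwhm_mm = source$fwhm_mm, sad_cm = source$sad_cm),
    detector = list(aperture_mm = detector$aperture_mm,
                    noise_cv = detector$noise_cv,
                    samples_per_point = detector$samples_per_point),
    schedule = schedule$segments,
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
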