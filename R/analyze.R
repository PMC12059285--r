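level_stats <- function(centers, sessions) {
  by_s <- split(centers, sessions)
  nrep <- lengths(by_s)
  within <- by_s[nrep >= 2L]
  repeat_sd <- if (length(within)) {
    # pooled within-session SD
    sqrt(sum(vapply(within, function(v) (length(v) - 1) * stats::var(v),
                    numeric(1))) / sum(lengths(within) - 1L))
  } else NA_real_
  session_means <- vapply(by_s, mean, numeric(1))
  repro_sd <- if (length(by_s) >= 2L) stats::sd(session_means) else NA_real_
  list(mean = mean(centers), n = length(centers),
       n_sessions = length(by_s), mean_repeats = mean(nrep),
       repeat_sd = repeat_sd, repro_sd = repro_sd,
       session_means = unname(session_means))
}

axis_budget <- function(stats1, stats2, interval_mm, ucfg) {
  comps <- list()
  add_a <- function(value, n_eff, name) {
    if (!is.finite(value)) return()
    if (ucfg$type_a_mode == "sd_of_mean") value <- value / sqrt(n_eff)
    comps[[length(comps) + 1L]] <<-
      uncertainty_component(name, "A", value,
                            sprintf("%s of dip-center estimates", ucfg$type_a_mode))
  }
  add_a(stats1$repeat_sd, stats1$mean_repeats, "d1 (repeatability)")
  add_a(stats2$repeat_sd, stats2$mean_repeats, "d2 (repeatability)")
  add_a(stats1$repro_sd, stats1$n_sessions, "d1 (reproducibility)")
  add_a(stats2$repro_sd, stats2$n_sessions, "d2 (reproducibility)")
  for (nm in c("d1", "d2")) {
    comps[[length(comps) + 1L]] <-
      type_b_from_resolution(interval_mm, ucfg$type_b_model,
                             given_mm = ucfg$type_b_given_mm,
                             name = sprintf("%s (measurement interval: %g mm)",
                                            nm, interval_mm))
  }
  comps
}

#' Analyze a measurement session into a focal-spot report
#'
#' Runs the full pipeline on a directory (or explicit list) of profile CSV
#' files: read each profile, locate its dip center, aggregate repeats and
#' sessions per axis and bar level, invert the projection geometry into the
#' per-axis focal-spot offset, and assemble the uncertainty budget
#' (repeatability and reproducibility as Type A; the finest sampling interval
#' as Type B; root-sum-square combination).
#'
#' Each profile must carry `axis` (`IEC_X`/`IEC_Y`) and `level`
#' (`upstream`/`downstream`) metadata; `session` defaults to 1. Both levels
#' are required for every axis present.
#'
#' @param path A directory containing profile `.csv` files (a
#'   `manifest.json` is ignored), or a character vector of profile file
#'   paths.
#' @param config Configuration list as from [default_config()] /
#'   [read_config()].
#' @return An object of class `"analysis_report"`.
#' @export
analyze_session <- function(path, config = default_config()) {
  cfg <- merge_config(config)
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) {
    fs_abort("no profile files found", "focalspot_analysis_error")
  }

  profiles <- list()
  problems <- character(0)
  for (f in files) {
    p <- tryCatch(read_profile(f), error = function(e) e)
    if (inherits(p, "error")) {
      problems <- c(problems, sprintf("%s: %s", basename(f), conditionMessage(p)))
      next
    }
    ax <- p$metadata$axis
    lev <- p$metadata$level
    if (is.null(ax) || !ax %in% c("IEC_X", "IEC_Y") ||
        is.null(lev) || !lev %in% c("upstream", "downstream")) {
      problems <- c(problems,
                    sprintf("%s: missing or invalid axis/level metadata", basename(f)))
      next
    }
    profiles[[length(profiles) + 1L]] <- list(file = f, profile = p)
  }
  if (length(problems)) {
    fs_abort(paste(c("profile problems:", problems), collapse = "\n  "),
             "focalspot_analysis_error")
  }
  if (!length(profiles)) {
    fs_abort("no usable profile files", "focalspot_analysis_error")
  }

  geom <- config_geometry(cfg)
  rows <- data.frame(
    file = vapply(profiles, function(p) basename(p$file), character(1)),
    axis = vapply(profiles, function(p) p$profile$metadata$axis, character(1)),
    level = vapply(profiles, function(p) p$profile$metadata$level, character(1)),
    session = vapply(profiles, function(p) {
      s <- p$profile$metadata$session
      if (is.null(s)) 1 else as.numeric(s)
    }, numeric(1)),
    stringsAsFactors = FALSE)

  centers <- numeric(nrow(rows))
  for (i in seq_along(profiles)) {
    est <- tryCatch(
      find_dip_center(profiles[[i]]$profile,
                      window_halfwidth = cfg$analysis$window_halfwidth_mm,
                      method = cfg$analysis$method),
      error = function(e) e)
    if (inherits(est, "error")) {
      problems <- c(problems, sprintf("%s: %s", rows$file[i], conditionMessage(est)))
    } else {
      centers[i] <- est$center
    }
  }
  if (length(problems)) {
    fs_abort(paste(c("dip detection failed:", problems), collapse = "\n  "),
             "focalspot_analysis_error")
  }

  interval_mm <- min(diff(profiles[[1L]]$profile$positions))

  axes_out <- list()
  for (ax in intersect(c("IEC_X", "IEC_Y"), unique(rows$axis))) {
    sel <- rows$axis == ax
    missing_lev <- setdiff(c("upstream", "downstream"), unique(rows$level[sel]))
    if (length(missing_lev)) {
      fs_abort(sprintf("axis %s: missing %s profiles", ax,
                       paste(missing_lev, collapse = " and ")),
               "focalspot_analysis_error")
    }
    s1 <- sel & rows$level == "upstream"
    s2 <- sel & rows$level == "downstream"
    st1 <- level_stats(centers[s1], rows$session[s1])
    st2 <- level_stats(centers[s2], rows$session[s2])
    comps <- axis_budget(st1, st2, interval_mm, cfg$uncertainty)
    budget <- combine_uncertainty(comps,
                                  propagate_to_focus = isTRUE(cfg$uncertainty$propagate_to_focus),
                                  geometry = geom)
    res <- estimate_focal_offset(st1$mean, st2$mean, geom,
                                 axis = config_axis(cfg, ax),
                                 divisor = if (cfg$analysis$divisor_mode == "paper_rounded")
                                   "paper_rounded" else "exact",
                                 combined_uncertainty = budget$combined)
    axes_out[[ax]] <- list(d1 = st1, d2 = st2, result = res, budget = budget)
  }

  structure(list(
    axes = axes_out,
    config = cfg,
    provenance = list(
      files = rows,
      n_profiles = nrow(rows),
      min_interval_mm = interval_mm,
      package_version = as.character(utils::packageVersion("focalspot")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Focal-spot analysis report\n")
  cat(sprintf("  %d profiles; positions are chamber-stage coordinates at the acquisition plane\n",
              x$provenance$n_profiles))
  for (ax in names(x$axes)) {
    a <- x$axes[[ax]]
    cat(sprintf("\n== %s ==\n", ax))
    cat(sprintf("  d1 (upstream):   %+.3f mm  (repeat SD %s, session SD %s, n = %d)\n",
                a$d1$mean, fmt_or_na(a$d1$repeat_sd), fmt_or_na(a$d1$repro_sd), a$d1$n))
    cat(sprintf("  d2 (downstream): %+.3f mm  (repeat SD %s, session SD %s, n = %d)\n",
                a$d2$mean, fmt_or_na(a$d2$repeat_sd), fmt_or_na(a$d2$repro_sd), a$d2$n))
    cat(sprintf("  offset at target height: %+.3f +/- %.3f mm (k = %.5f, %s)\n",
                a$result$offset_a, a$budget$combined, a$result$k, a$result$divisor))
    print(a$budget)
  }
  invisible(x)
}

fmt_or_na <- function(v) if (is.finite(v)) sprintf("%.3f", v) else "n/a"

report_to_list <- function(report) {
  axes <- lapply(report$axes, function(a) {
    list(d1 = a$d1[c("mean", "n", "n_sessions", "repeat_sd", "repro_sd",
                     "session_means")],
         d2 = a$d2[c("mean", "n", "n_sessions", "repeat_sd", "repro_sd",
                     "session_means")],
         offset_mm = a$result$offset_a,
         k = a$result$k,
         divisor = a$result$divisor,
         orientation_sign = a$result$axis$orientation_sign,
         combined_uncertainty_mm = a$budget$combined,
         budget = a$budget$components)
  })
  list(axes = axes, config = report$config, provenance = report$provenance)
}

#' Write an analysis report to disk
#'
#' @param report An [analyze_session()] result.
#' @param path Output file.
#' @param format `"json"` or `"text"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  } else {
    writeLines(utils::capture.output(print(report)), path)
  }
  invisible(path)
}
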