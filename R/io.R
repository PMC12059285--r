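#' Read a beam profile from a delimited-text file
#'
#' The format is a CSV with header `position_mm,current` and one row per
#' stage position, preceded by optional `# key: value` comment lines carrying
#' acquisition metadata (axis, level, session, ...). Tab-delimited files are
#' accepted as well. Rows out of position order are sorted with a warning;
#' duplicated positions and malformed rows are errors naming the offending
#' line or position.
#'
#' @param path File path.
#' @return A [beam_profile()] with the comment metadata attached.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("profile file not found: %s", path), "focalspot_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)

  metadata <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      metadata[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }

  body_idx <- which(!is_comment & !is_blank)
  if (length(body_idx) < 2L) {
    fs_abort(sprintf("no data rows in %s", path), "focalspot_parse_error")
  }
  header_line <- lines[body_idx[1]]
  delim <- if (grepl("\t", header_line)) "\t" else ","
  header <- trimws(strsplit(header_line, delim, fixed = TRUE)[[1]])
  if (length(header) < 2L || header[1] != "position_mm" || header[2] != "current") {
    fs_abort(sprintf("%s: expected header 'position_mm%scurrent', got '%s'",
                     path, delim, header_line),
             "focalspot_parse_error")
  }

  rows_idx <- body_idx[-1L]
  fields <- strsplit(lines[rows_idx], delim, fixed = TRUE)
  pos <- numeric(length(rows_idx))
  cur <- numeric(length(rows_idx))
  for (i in seq_along(rows_idx)) {
    f <- fields[[i]]
    p <- suppressWarnings(as.numeric(f[1]))
    cc <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2L || is.na(p) || is.na(cc)) {
      fs_abort(sprintf("%s: malformed row at line %d: '%s'",
                       path, rows_idx[i], lines[rows_idx[i]]),
               "focalspot_parse_error")
    }
    pos[i] <- p
    cur[i] <- cc
  }

  dup <- pos[duplicated(pos)]
  if (length(dup)) {
    fs_abort(sprintf("%s: duplicated position %g mm", path, dup[1]),
             "focalspot_parse_error")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    warning(sprintf("%s: rows were not in increasing position order; sorted on read",
                    path))
    o <- order(pos)
    pos <- pos[o]
    cur <- cur[o]
  }

  nspp <- metadata[["n_samples_per_point"]]
  metadata[["n_samples_per_point"]] <- NULL
  beam_profile(pos, cur,
               n_samples_per_point = if (!is.null(nspp)) as.integer(nspp) else 5L,
               metadata = metadata)
}

#' Write a beam profile to a delimited-text file
#'
#' Emits `# key: value` comment lines for every scalar metadata entry, the
#' header `position_mm,current`, and comma-separated rows. Values are written
#' with 17 significant digits so that a read/write cycle is lossless.
#'
#' @param profile A [beam_profile()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "beam_profile"))
  md <- profile$metadata
  md <- md[vapply(md, function(v) length(v) == 1L &&
                    (is.character(v) || is.numeric(v)), logical(1))]
  md$n_samples_per_point <- profile$n_samples_per_point
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- vapply(names(md), function(k) {
    v <- md[[k]]
    sprintf("# %s: %s", k, if (is.numeric(v)) num(v) else as.character(v))
  }, character(1))
  rows <- paste(num(profile$positions), num(profile$currents), sep = ",")
  writeLines(c(hdr, "position_mm,current", rows), path)
  invisible(path)
}

#' Default analysis configuration
#'
#' The defaults mirror the reference apparatus, so analyzing a session
#' acquired (or simulated) with that set-up needs no configuration file:
#' geometry SAD 85 cm / B 20.473 cm / C 3.65 cm, orientation signs +1 (IEC-X)
#' and -1 (IEC-Y), dip detection by local linear fit over a +/- 1 mm window,
#' the full-precision divisor, Type A mode `sd`, and the rectangular Type B
#' model on the finest sampling interval.
#'
#' @return Nested named list with blocks `geometry`, `analysis`,
#'   `uncertainty`.
#' @export
default_config <- function() {
  list(
    geometry = list(sad_cm = 85, b_cm = 20.473, c_cm = 3.65,
                    axis_sign_x = 1L, axis_sign_y = -1L),
    analysis = list(method = "local_linear_fit",
                    window_halfwidth_mm = 1.0,
                    divisor_mode = "exact"),
    uncertainty = list(type_a_mode = "sd",
                       type_b_model = "rectangular_half_interval",
                       type_b_given_mm = NULL,
                       propagate_to_focus = FALSE)
  )
}

#' Read an analysis configuration file
#'
#' A flat YAML file with the blocks of [default_config()]; omitted keys take
#' their defaults, unknown keys are rejected with a message naming them.
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(user)
}

merge_config <- function(user) {
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  if (!is.list(user)) {
    fs_abort("config must be a mapping of blocks", "focalspot_config_error")
  }
  bad_block <- setdiff(names(user), names(cfg))
  if (length(bad_block)) {
    fs_abort(sprintf("unknown config block(s): %s",
                     paste(bad_block, collapse = ", ")),
             "focalspot_config_error")
  }
  for (blk in names(user)) {
    bad_key <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad_key)) {
      fs_abort(sprintf("unknown key(s) in config block '%s': %s",
                       blk, paste(bad_key, collapse = ", ")),
               "focalspot_config_error")
    }
    for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
  }
  cfg
}

config_geometry <- function(cfg) {
  measurement_geometry(B = cfg$geometry$b_cm, C = cfg$geometry$c_cm,
                       sad = cfg$geometry$sad_cm)
}

config_axis <- function(cfg, axis_name) {
  sign <- if (axis_name == "IEC_X") cfg$geometry$axis_sign_x else cfg$geometry$axis_sign_y
  scan_axis(axis_name, sign)
}
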