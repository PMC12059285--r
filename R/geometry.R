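#' Measurement geometry of the bar-shadow projection
#'
#' The distance stack that defines the projection magnification: `A` from the
#' focal spot to the upstream bar position, `B` between the two bar positions,
#' and `C` from the downstream bar position to the plane where the chamber
#' profile is acquired. All three are in centimetres. When the downstream bar
#' sits at isocenter, `A + B` equals the source-axis distance (SAD), which is
#' 85 cm on the machine this method was developed for, so the geometry may be
#' given either as `(A, B, C)` or as `(sad, B, C)` with `A = sad - B`.
#'
#' @param B Distance between the upstream and downstream bar positions (cm).
#'   The default 20.473 cm is the bar travel of two roller rotations on the
#'   reference apparatus.
#' @param C Distance from the downstream bar position to the profile
#'   acquisition plane (cm).
#' @param A Distance from the focal spot to the upstream bar position (cm).
#'   If `NULL` (default), computed as `sad - B`.
#' @param sad Source-axis distance (cm); used only when `A` is `NULL`.
#'
#' @return An object of class `"measurement_geometry"`: a list with elements
#'   `A`, `B`, `C` (cm).
#' @examples
#' geom <- measurement_geometry()           # SAD 85, B 20.473, C 3.65
#' magnification_factor(geom)               # ~0.331
#' @export
measurement_geometry <- function(B = 20.473, C = 3.65, A = NULL, sad = 85) {
  if (is.null(A)) {
    if (!is_scalar_number(sad)) {
      fs_abort("'sad' must be a finite numeric scalar", "focalspot_invalid_geometry")
    }
    A <- sad - B
  }
  for (nm in c("A", "B", "C")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      fs_abort(sprintf("geometry distance %s must be a positive finite scalar (got %s)",
                       nm, format(v)),
               "focalspot_invalid_geometry")
    }
  }
  structure(list(A = A, B = B, C = C), class = "measurement_geometry")
}

#' @export
print.measurement_geometry <- function(x, ...) {
  cat(sprintf("Bar-shadow measurement geometry [cm]\n  A (focus -> upstream bar):   %8.3f\n  B (upstream -> downstream):  %8.3f\n  C (downstream bar -> plane): %8.3f\n  magnification factor k:      %8.5f\n",
              x$A, x$B, x$C, magnification_factor(x)))
  invisible(x)
}

as_geometry <- function(geometry) {
  if (!inherits(geometry, "measurement_geometry")) {
    fs_abort("'geometry' must be a measurement_geometry object",
             "focalspot_invalid_geometry")
  }
  geometry
}

#' Geometric magnification factor of the two-height bar measurement
#'
#' The dimensionless sensitivity `k = (B + C)/A - C/(A + B)` converting the
#' difference of dip-center deviations at the two bar heights, `d2 - d1`, into
#' the focal-spot lateral offset `a = (d2 - d1)/k`. For the default geometry
#' (SAD 85 cm, B 20.473 cm, C 3.65 cm) `k` is 0.33090..., commonly rounded to
#' 0.33.
#'
#' @param geometry A [measurement_geometry()].
#' @return The magnification factor `k` (dimensionless, > 0).
#' @export
magnification_factor <- function(geometry) {
  g <- as_geometry(geometry)
  (g$B + g$C) / g$A - g$C / (g$A + g$B)
}

#' Forward shadow projection: dip-center position cast by an offset focus
#'
#' With the bar fixed laterally at the reference center, a focal spot
#' displaced laterally by `a` casts the bar's shadow at the acquisition plane
#' at `-a * (B + C)/A` (bar upstream) or `-a * C/(A + B)` (bar downstream):
#' the shadow moves opposite to the source, scaled by the lever arm between
#' bar and plane over the lever arm between source and bar. The difference of
#' the two equals `a * k` exactly, with `k` from [magnification_factor()].
#'
#' @param a Focal-spot lateral offset(s), mm. Vectorized.
#' @param level `"upstream"` or `"downstream"` bar position.
#' @param geometry A [measurement_geometry()].
#' @return Dip-center position(s) at the acquisition plane, mm.
#' @export
shadow_offset <- function(a, level = c("upstream", "downstream"),
                          geometry = measurement_geometry()) {
  level <- match.arg(level)
  g <- as_geometry(geometry)
  stopifnot(is.numeric(a), all(is.finite(a)))
  if (level == "upstream") {
    -a * (g$B + g$C) / g$A
  } else {
    -a * g$C / (g$A + g$B)
  }
}

#' Scan axis with its orientation sign
#'
#' Maps the chamber-stage coordinate onto a reported IEC 61217 axis. The
#' stage's positive direction need not coincide with the IEC positive
#' direction, so each axis carries an orientation sign. Defaults (+1 for
#' IEC-X, -1 for IEC-Y) reflect the reference apparatus.
#'
#' @param name `"IEC_X"` or `"IEC_Y"`.
#' @param orientation_sign +1 or -1; if `NULL`, the per-axis default.
#' @return An object of class `"scan_axis"`.
#' @export
scan_axis <- function(name = c("IEC_X", "IEC_Y"), orientation_sign = NULL) {
  name <- match.arg(name)
  if (is.null(orientation_sign)) {
    orientation_sign <- if (name == "IEC_X") 1L else -1L
  }
  if (!orientation_sign %in% c(-1, 1)) {
    fs_abort("orientation_sign must be +1 or -1", "focalspot_invalid_axis")
  }
  structure(list(name = name, orientation_sign = as.integer(orientation_sign)),
            class = "scan_axis")
}

#' Invert the projection: focal-spot offset from two dip-center deviations
#'
#' Implements `a = sign * (d2 - d1) / k`, where `d1` and `d2` are the
#' dip-center deviations from the reference center with the bar upstream and
#' downstream respectively, and `k` is the geometric magnification factor.
#' `divisor = "exact"` uses the full-precision `k`;
#' `divisor = "paper_rounded"` uses the two-decimal convenience value 0.33,
#' which reproduces published results computed with the rounded divisor
#' digit-for-digit.
#'
#' @param d1,d2 Dip-center deviations (mm) at the upstream / downstream bar
#'   positions, in the chamber-stage frame at the acquisition plane.
#' @param geometry A [measurement_geometry()].
#' @param axis A [scan_axis()]; its orientation sign maps the stage frame to
#'   the reported IEC axis.
#' @param divisor `"exact"` (default) or `"paper_rounded"`.
#' @param combined_uncertainty Optional combined standard uncertainty (mm) to
#'   attach to the result.
#' @return An object of class `"focal_spot_result"`: list with `axis`, `d1`,
#'   `d2`, `offset_a` (mm, at target height), `k`, `divisor`,
#'   `combined_uncertainty`.
#' @examples
#' geom <- measurement_geometry()
#' estimate_focal_offset(-0.14, 0.00, geom, scan_axis("IEC_X"),
#'                       divisor = "paper_rounded")  # 0.42 mm
#' @export
estimate_focal_offset <- function(d1, d2, geometry = measurement_geometry(),
                                  axis = scan_axis("IEC_X"),
                                  divisor = c("exact", "paper_rounded"),
                                  combined_uncertainty = NA_real_) {
  divisor <- match.arg(divisor)
  g <- as_geometry(geometry)
  if (!inherits(axis, "scan_axis")) {
    fs_abort("'axis' must be a scan_axis object", "focalspot_invalid_axis")
  }
  stopifnot(is_scalar_number(d1), is_scalar_number(d2))
  k <- if (divisor == "paper_rounded") 0.33 else magnification_factor(g)
  if (!is.finite(k) || abs(k) < .Machine$double.eps) {
    fs_abort("degenerate geometry: magnification factor is zero",
             "focalspot_invalid_geometry")
  }
  structure(list(axis = axis, d1 = d1, d2 = d2,
                 offset_a = axis$orientation_sign * (d2 - d1) / k,
                 k = k, divisor = divisor,
                 combined_uncertainty = combined_uncertainty),
            class = "focal_spot_result")
}

#' @export
print.focal_spot_result <- function(x, ...) {
  u <- if (is.finite(x$combined_uncertainty)) {
    sprintf(" +/- %.3f mm (combined std. uncertainty)", x$combined_uncertainty)
  } else ""
  cat(sprintf("Focal-spot offset, %s: %+.3f mm%s\n  d1 = %+.3f mm, d2 = %+.3f mm, divisor k = %.5f (%s), stage->IEC sign %+d\n",
              x$axis$name, x$offset_a, u, x$d1, x$d2, x$k, x$divisor,
              x$axis$orientation_sign))
  invisible(x)
}
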