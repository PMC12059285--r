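#' A single component of the uncertainty budget
#'
#' @param name Component label (e.g. `"d1 (repeatability)"`).
#' @param utype `"A"` (statistically estimated from repeated observations) or
#'   `"B"` (assigned from other knowledge, e.g. instrument resolution).
#' @param value_mm Standard uncertainty, mm (nonnegative).
#' @param provenance Free text stating how the value was obtained.
#' @return An object of class `"uncertainty_component"`.
#' @export
uncertainty_component <- function(name, utype = c("A", "B"), value_mm,
                                  provenance = "") {
  utype <- match.arg(utype)
  if (!is_scalar_number(value_mm) || value_mm < 0) {
    fs_abort("standard uncertainty must be a nonnegative scalar",
             "focalspot_invalid_uncertainty")
  }
  structure(list(name = as.character(name), utype = utype,
                 value_mm = value_mm, provenance = as.character(provenance)),
            class = "uncertainty_component")
}

#' Type A standard uncertainty from repeated observations
#'
#' @param values Numeric vector of repeated measurements (mm), length >= 2.
#' @param mode `"sd"` (default): sample standard deviation (n-1 denominator);
#'   `"sd_of_mean"`: standard deviation of the mean, `sd/sqrt(n)`.
#' @param name,provenance Passed to [uncertainty_component()].
#' @return An `"uncertainty_component"` of type A.
#' @export
type_a_from_repeats <- function(values, mode = c("sd", "sd_of_mean"),
                                name = "repeatability", provenance = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    fs_abort("Type A evaluation needs at least 2 observations",
             "focalspot_too_few_repeats")
  }
  s <- stats::sd(values)
  if (mode == "sd_of_mean") s <- s / sqrt(length(values))
  if (is.null(provenance)) {
    provenance <- sprintf("%s of %d repeated observations", mode, length(values))
  }
  uncertainty_component(name, "A", s, provenance)
}

#' Type B standard uncertainty from an instrument resolution
#'
#' The standard GUM treatment of a resolution `delta` assumes the reading is
#' uniform within `+/- delta/2`, giving a standard uncertainty of
#' `(delta/2)/sqrt(3)` (`"rectangular_half_interval"`). Published budgets
#' sometimes assign a different value whose derivation is not stated; the
#' `"as_given"` model accepts such a value verbatim.
#'
#' @param interval_mm The resolution / smallest sampling interval, mm.
#' @param model `"rectangular_half_interval"` (default) or `"as_given"`.
#' @param given_mm The assigned value, required for `"as_given"`.
#' @param name Component label.
#' @return An `"uncertainty_component"` of type B.
#' @export
type_b_from_resolution <- function(interval_mm,
                                   model = c("rectangular_half_interval", "as_given"),
                                   given_mm = NULL,
                                   name = NULL) {
  model <- match.arg(model)
  if (!is_scalar_number(interval_mm) || interval_mm < 0) {
    fs_abort("interval must be a nonnegative scalar", "focalspot_invalid_uncertainty")
  }
  if (is.null(name)) {
    name <- sprintf("measurement interval: %g mm", interval_mm)
  }
  if (model == "rectangular_half_interval") {
    uncertainty_component(name, "B", (interval_mm / 2) / sqrt(3),
                          "rectangular distribution over half the interval")
  } else {
    if (is.null(given_mm)) {
      fs_abort("model 'as_given' requires 'given_mm'", "focalspot_invalid_uncertainty")
    }
    uncertainty_component(name, "B", given_mm, "assigned value, derivation external")
  }
}

#' Combine uncertainty components by root-sum-square
#'
#' The combined standard uncertainty is `sqrt(sum(value^2))` over all
#' components, treating them as uncorrelated with unit sensitivity — the
#' literal combination used in bar-shadow budget tables, expressed at the
#' profile-acquisition plane. `propagate_to_focus = TRUE` additionally divides
#' by the magnification factor `k`, propagating the plane-level uncertainty
#' through the offset estimator to target height (an extension beyond the
#' literal table).
#'
#' @param components List of [uncertainty_component()] objects (length >= 1).
#' @param propagate_to_focus Logical; divide the combined value by `k`.
#' @param geometry A [measurement_geometry()], needed only when propagating.
#' @return An object of class `"uncertainty_budget"`: list with `components`
#'   (data.frame), `combined` (mm) and `propagated_to_focus`.
#' @examples
#' comps <- c(rep(0.048, 2), rep(0.087, 4))
#' b <- combine_uncertainty(lapply(comps, function(v)
#'   uncertainty_component("c", "A", v)))
#' round(b$combined, 3)  # 0.187
#' @export
combine_uncertainty <- function(components, propagate_to_focus = FALSE,
                                geometry = measurement_geometry()) {
  if (inherits(components, "uncertainty_component")) components <- list(components)
  if (!length(components)) {
    fs_abort("need at least one uncertainty component", "focalspot_invalid_uncertainty")
  }
  if (!all(vapply(components, inherits, logical(1), "uncertainty_component"))) {
    fs_abort("all elements must be uncertainty_component objects",
             "focalspot_invalid_uncertainty")
  }
  df <- data.frame(
    name = vapply(components, `[[`, character(1), "name"),
    utype = vapply(components, `[[`, character(1), "utype"),
    value_mm = vapply(components, `[[`, numeric(1), "value_mm"),
    provenance = vapply(components, `[[`, character(1), "provenance"),
    stringsAsFactors = FALSE)
  combined <- sqrt(sum(df$value_mm^2))
  if (propagate_to_focus) {
    combined <- combined / magnification_factor(geometry)
  }
  structure(list(components = df, combined = combined,
                 propagated_to_focus = propagate_to_focus),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncertainty budget\n")
  df <- x$components
  w <- max(nchar(df$name), nchar("Quantity"))
  cat(sprintf("  %-*s  %-4s  %s\n", w, "Quantity", "Type", "Std. uncertainty [mm]"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-*s  %-4s  %.3f\n", w, df$name[i], df$utype[i], df$value_mm[i]))
  }
  lab <- if (isTRUE(x$propagated_to_focus)) {
    "Combined standard uncertainty (at focus height)"
  } else "Combined standard uncertainty"
  cat(sprintf("  %s: %.3f mm\n", lab, x$combined))
  invisible(x)
}

#' Read / write an uncertainty-component table as CSV
#'
#' Columns: `name,utype,value_mm,provenance`.
#'
#' @param path File path.
#' @return `read_budget_csv` returns a list of [uncertainty_component()].
#' @export
read_budget_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "utype", "value_mm")
  if (!all(need %in% names(df))) {
    fs_abort(sprintf("budget file must have columns %s",
                     paste(need, collapse = ", ")),
             "focalspot_parse_error")
  }
  if (is.null(df$provenance)) df$provenance <- ""
  lapply(seq_len(nrow(df)), function(i) {
    uncertainty_component(df$name[i], df$utype[i], df$value_mm[i],
                          df$provenance[i])
  })
}

#' @rdname read_budget_csv
#' @param components List of [uncertainty_component()] objects.
#' @export
write_budget_csv <- function(components, path) {
  b <- combine_uncertainty(components)
  utils::write.csv(b$components, path, row.names = FALSE)
  invisible(path)
}
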