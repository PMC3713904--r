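#' Linear MET prediction models
#'
#' A calibration model maps a per-minute vertical-axis intensity to
#' metabolic equivalents (METs) through an affine equation
#' `METs = intercept + slope * VT`. Two models ship with the package:
#'
#' * `freedson_actigraph_model()` — the Freedson equation for the research
#'   accelerometer's vertical-axis counts/min:
#'   `METs = 1.439008 + 0.000795 * VT`.
#' * `calfit_model()` — the phone-adapted equation in g/min, obtained by
#'   composing a cross-device unit calibration with the Freedson equation:
#'   `METs = 1.2907087 + 0.4141791 * VT`.
#'
#' `met_model()` builds an arbitrary model, e.g. from a calibration fitted
#' on your own paired data.
#'
#' @param intercept,slope coefficients of the affine equation.
#' @param unit unit of the VT input (`"counts"` or `"g"`).
#' @param source provenance tag.
#' @return An object of class `met_model`.
#' @export
met_model <- function(intercept, slope, unit = c("g", "counts"),
                      source = "fitted") {
  unit <- match.arg(unit)
  if (!is.finite(slope) || !is.finite(intercept))
    stop("model coefficients must be finite", call. = FALSE)
  structure(list(intercept = intercept, slope = slope, unit = unit,
                 source = source),
            class = "met_model")
}

#' @rdname met_model
#' @export
freedson_actigraph_model <- function() {
  met_model(1.439008, 0.000795, unit = "counts",
            source = "actigraph_freedson")
}

#' @rdname met_model
#' @export
calfit_model <- function() {
  met_model(1.2907087, 0.4141791, unit = "g", source = "calfit_adapted")
}

#' @export
print.met_model <- function(x, ...) {
  cat(sprintf("<met_model> METs = %.7g + %.7g * VT %s/min  [%s]\n",
              x$intercept, x$slope, x$unit, x$source))
  invisible(x)
}

#' Predict METs from vertical-axis intensity
#'
#' @param model a [met_model()].
#' @param vt vertical-axis intensity (>= 0, in the model's unit); `NA`
#'   passes through.
#' @return METs, `intercept + slope * vt`, vectorized.
#' @export
predict_mets <- function(model, vt) {
  stopifnot(inherits(model, "met_model"))
  if (any(vt < 0, na.rm = TRUE))
    stop("vertical-axis intensity must be >= 0", call. = FALSE)
  model$intercept + model$slope * vt
}

#' Fit the cross-device unit calibration
#'
#' Ordinary least-squares regression of the reference device's counts/min
#' on the phone's g/min over the pair's jointly worn minutes. Composing
#' this link with the reference device's Freedson MET equation yields a
#' phone-specific MET equation.
#'
#' Accelerometer noise grows with intensity, so the reported standard
#' errors are heteroscedasticity-robust (HC1 sandwich estimates); the
#' coefficients themselves are plain OLS.
#'
#' @param pair an `aligned_pair` (after [apply_wear()] for the jointly
#'   worn restriction; any `aligned_pair` works, the fit uses
#'   `joint_mask`).
#' @return A list of class `unit_calibration`: `intercept`, `slope`,
#'   their standard errors, `r_squared`, `n`, and `met_model` — the phone
#'   MET equation obtained by composition with
#'   [freedson_actigraph_model()].
#' @export
fit_unit_calibration <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  g <- pair$phone_vt[pair$joint_mask]
  cts <- pair$ref_vt[pair$joint_mask]
  ok <- is.finite(g) & is.finite(cts)
  g <- g[ok]; cts <- cts[ok]
  if (length(g) < 3)
    stop("unit calibration needs at least 3 jointly worn minutes",
         call. = FALSE)
  if (stats::var(g) == 0)
    stop("unit calibration undefined: phone VT has zero variance",
         call. = FALSE)
  fit <- stats::lm(cts ~ g)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(sandwich::vcovHC(fit, type = "HC1"))))
  freed <- freedson_actigraph_model()
  comp <- met_model(unname(freed$intercept + freed$slope * cf[1]),
                    unname(freed$slope * cf[2]), unit = "g",
                    source = "fitted")
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 intercept_se = unname(se[1]), slope_se = unname(se[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(g),
                 met_model = comp),
            class = "unit_calibration")
}

#' @export
print.unit_calibration <- function(x, ...) {
  cat(sprintf(
    "<unit_calibration> counts/min = %.4g + %.4g * g/min (n = %d, R2 = %.3f)\n",
    x$intercept, x$slope, x$n, x$r_squared))
  cat("  composed phone MET equation: ")
  print(x$met_model)
  invisible(x)
}

intensity_levels <- c("sedentary", "light", "moderate", "vigorous")

#' Classify per-minute METs into intensity classes
#'
#' Classes partition `[0, Inf)` with lower-bound-inclusive boundaries:
#' sedentary `[0, 1.5)`, light `[1.5, 3)`, moderate `[3, 6)`, vigorous
#' `[6, Inf)`. Any minute at or above the first cutoff counts as physical
#' activity.
#'
#' @param mets numeric MET values (>= 0; `NA` passes through).
#' @param cutpoints the three class boundaries, default `c(1.5, 3, 6)`.
#' @return Factor with levels sedentary/light/moderate/vigorous.
#' @export
classify_intensity <- function(mets, cutpoints = c(1.5, 3, 6)) {
  if (any(mets < 0, na.rm = TRUE))
    stop("MET values must be >= 0", call. = FALSE)
  cut(mets, breaks = c(0, cutpoints, Inf), labels = intensity_levels,
      right = FALSE, include.lowest = TRUE)
}

#' Summarize physical activity over a set of minutes
#'
#' Tabulates a per-minute MET vector over a stated minute set: minutes and
#' percentage in each intensity class, total active minutes, and mean MET
#' intensity. The minute set is whatever comparison is being made —
#' jointly worn minutes for paired comparisons, one device's own worn
#' minutes for solo summaries.
#'
#' @param mets numeric per-minute MET vector.
#' @param minute_set logical or integer selection of minutes to summarize.
#' @param active_min METs at (or above, see `active_inclusive`) which a
#'   minute counts as physical activity (default 1.5).
#' @param active_inclusive if `TRUE` (default) the active rule is
#'   `METs >= active_min`; if `FALSE`, strictly greater.
#' @param cutpoints passed to [classify_intensity()].
#' @return A list of class `activity_summary`: `n`, per-class `minutes`
#'   and `pct`, `active_minutes`, `active_pct`, `mean_mets`, and `empty`
#'   flag (an empty set is flagged, not an error).
#' @export
summarize_activity <- function(mets, minute_set = TRUE, active_min = 1.5,
                               active_inclusive = TRUE,
                               cutpoints = c(1.5, 3, 6)) {
  m <- mets[minute_set]
  m <- m[is.finite(m)]
  n <- length(m)
  if (n == 0L) {
    zero <- stats::setNames(rep(0, 4), intensity_levels)
    return(structure(list(n = 0L, minutes = zero, pct = zero,
                          active_minutes = 0, active_pct = 0,
                          mean_mets = NA_real_, empty = TRUE),
                     class = "activity_summary"))
  }
  cls <- classify_intensity(m, cutpoints)
  minutes <- as.vector(table(cls))
  names(minutes) <- intensity_levels
  active <- if (active_inclusive) sum(m >= active_min) else
    sum(m > active_min)
  structure(list(n = n, minutes = minutes, pct = 100 * minutes / n,
                 active_minutes = active, active_pct = 100 * active / n,
                 mean_mets = mean(m), empty = FALSE),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  if (x$empty) {
    cat("<activity_summary> empty minute set\n")
    return(invisible(x))
  }
  cat(sprintf("<activity_summary> %d min, mean %.2f METs, active %.0f min (%.1f%%)\n",
              x$n, x$mean_mets, x$active_minutes, x$active_pct))
  print(round(rbind(minutes = x$minutes, pct = x$pct), 1))
  invisible(x)
}
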