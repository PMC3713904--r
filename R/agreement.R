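#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurements of the same quantity, penalizing
#' both imprecision (loss of correlation) and location/scale shift:
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' n-denominator moments. It can be read as the share of total variance
#' attributable to the subjects rather than to the measurement method.
#' The 95% confidence interval uses the Fisher z-transformation with
#' Lin's asymptotic variance.
#'
#' @param x,y numeric vectors of equal length (n >= 3 after removing
#'   incomplete pairs).
#' @param conf confidence level.
#' @return A list of class `ccc`: `estimate`, `ci` (lower, upper), `n`,
#'   and the Pearson `r`.
#' @export
ccc <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("concordance needs at least 3 pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0)
    stop("concordance undefined: both inputs constant", call. = FALSE)
  est <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (is.finite(r) && abs(est) < 1 - 1e-12 && r != 0) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    z <- atanh(est)
    vz <- ((1 - r^2) * est^2 / ((1 - est^2) * r^2) +
             2 * est^3 * (1 - est) * u^2 / (r * (1 - est^2)^2) -
             est^4 * u^4 / (2 * r^2 * (1 - est^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(max(vz, 0)))
  } else if (abs(est) >= 1 - 1e-12) {
    ci <- c(est, est)
  }
  structure(list(estimate = est, ci = ci, n = n, r = r, conf = conf),
            class = "ccc")
}

#' @export
print.ccc <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.4f (%g%% CI %.4f to %.4f), n = %d\n",
              x$estimate, 100 * x$conf, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Spearman rank correlation with a confidence interval
#'
#' Rank correlation (average ranks for ties) with a confidence interval
#' from the Fisher z-transformation using variance `1 / (n - 3)`.
#'
#' @param x,y numeric vectors (n >= 4 complete pairs).
#' @param conf confidence level.
#' @return A list: `rho`, `ci`, `n`.
#' @export
spearman_with_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rank correlation undefined for constant input", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1 - 1e-12) {
    ci <- c(rho, rho)
  } else {
    q <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(atanh(rho) + c(-1, 1) * q / sqrt(n - 3))
  }
  list(rho = rho, ci = ci, n = n)
}

#' Bland-Altman agreement analysis with proportional-bias regression
#'
#' Differences `d = x - y` are summarized by their mean (with a t-based
#' confidence interval) and the limits of agreement
#' `mean(d) +/- 1.96 sd(d)`. Proportional bias is assessed by regressing
#' the differences on the pair means `m = (x + y) / 2`; the bias is called
#' significant when the slope's confidence interval excludes zero. The
#' returned `table` (`mean`, `diff`) plus the annotation values are
#' plot-ready for any front end.
#'
#' @param x,y numeric vectors of equal length (n >= 3 complete pairs);
#'   differences are `x - y` (test device minus reference).
#' @param conf confidence level.
#' @return A list of class `bland_altman`: `n`, `mean_diff`,
#'   `mean_diff_ci`, `sd_diff`, `loa` (lower, upper), `bias_slope`,
#'   `bias_slope_ci`, `bias_intercept`, `bias_significant`, `table`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  md <- mean(d); sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  md_ci <- md + c(-1, 1) * tq * sdd / sqrt(n)
  loa <- md + c(-1.96, 1.96) * sdd
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    cf <- suppressWarnings(summary(fit)$coefficients)
    se <- cf[2, 2]
    tq2 <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
    slope <- cf[2, 1]
    slope_ci <- slope + c(-1, 1) * tq2 * se
    intercept <- cf[1, 1]
    significant <- slope_ci[1] > 0 || slope_ci[2] < 0
  } else {
    slope <- NA_real_; slope_ci <- c(NA_real_, NA_real_)
    intercept <- NA_real_; significant <- NA
  }
  structure(list(n = n, mean_diff = md, mean_diff_ci = md_ci,
                 sd_diff = sdd, loa = loa,
                 bias_slope = slope, bias_slope_ci = slope_ci,
                 bias_intercept = intercept,
                 bias_significant = significant,
                 conf = conf,
                 table = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.4f (%g%% CI %.4f to %.4f)\n",
              x$n, x$mean_diff, 100 * x$conf, x$mean_diff_ci[1],
              x$mean_diff_ci[2]))
  cat(sprintf("  limits of agreement %.4f to %.4f\n", x$loa[1], x$loa[2]))
  if (is.finite(x$bias_slope))
    cat(sprintf("  bias slope %.4f (CI %.4f to %.4f)%s\n", x$bias_slope,
                x$bias_slope_ci[1], x$bias_slope_ci[2],
                if (isTRUE(x$bias_significant)) " *significant*" else ""))
  invisible(x)
}

# one full agreement report on a pair of vectors; statistics that are
# undefined for the data at hand come back NA rather than erroring.
# same_unit = FALSE restricts to correlation/association statistics:
# concordance and differences are meaningless across units
agreement_report <- function(x, y, level = c("minute", "day"),
                             conf = 0.95, same_unit = TRUE) {
  level <- match.arg(level)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  sp <- tryCatch(spearman_with_ci(x, y, conf), error = function(e) NULL)
  ar2 <- tryCatch(adjusted_r2(x, y), error = function(e) NA_real_)
  cc <- if (same_unit) tryCatch(ccc(x, y, conf),
                                error = function(e) NULL) else NULL
  ba <- if (same_unit) tryCatch(bland_altman(x, y, conf),
                                error = function(e) NULL) else NULL
  structure(list(
    n = length(x), level = level,
    spearman_rho = if (is.null(sp)) NA_real_ else sp$rho,
    spearman_ci = if (is.null(sp)) c(NA_real_, NA_real_) else sp$ci,
    adjusted_r2 = ar2,
    ccc = if (is.null(cc)) NA_real_ else cc$estimate,
    ccc_ci = if (is.null(cc)) c(NA_real_, NA_real_) else cc$ci,
    mean_difference = if (is.null(ba)) NA_real_ else ba$mean_diff,
    mean_difference_ci = if (is.null(ba)) c(NA_real_, NA_real_) else
      ba$mean_diff_ci,
    loa = if (is.null(ba)) c(NA_real_, NA_real_) else ba$loa,
    bias_slope = if (is.null(ba)) NA_real_ else ba$bias_slope,
    bias_slope_ci = if (is.null(ba)) c(NA_real_, NA_real_) else
      ba$bias_slope_ci,
    bias_significant = if (is.null(ba)) NA else ba$bias_significant,
    bland_altman = ba),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> level %s, n = %d\n", x$level, x$n))
  cat(sprintf("  Spearman rho %.3f (%.3f-%.3f), adj R2 %.3f\n",
              x$spearman_rho, x$spearman_ci[1], x$spearman_ci[2],
              x$adjusted_r2))
  if (is.finite(x$ccc))
    cat(sprintf("  CCC %.3f (%.3f-%.3f)\n", x$ccc, x$ccc_ci[1],
                x$ccc_ci[2]))
  if (is.finite(x$mean_difference)) {
    cat(sprintf("  mean difference %.4f (%.4f-%.4f), LoA %.4f-%.4f\n",
                x$mean_difference, x$mean_difference_ci[1],
                x$mean_difference_ci[2], x$loa[1], x$loa[2]))
    cat(sprintf("  bias slope %.4f (%.4f-%.4f)%s\n", x$bias_slope,
                x$bias_slope_ci[1], x$bias_slope_ci[2],
                if (isTRUE(x$bias_significant)) " *" else ""))
  }
  invisible(x)
}

#' Minute-level between-device comparison for a cohort
#'
#' Restricts every comparison to minutes both devices recorded and both
#' were worn, then computes (i) a pooled vertical-axis report (Spearman
#' correlation and adjusted R-squared over all participants' joint
#' minutes), (ii) per-participant agreement reports (Lin's CCC and
#' Bland-Altman) for active-time percentage, mean MET intensity, and
#' per-class time percentages, and (iii) a within-class intensity
#' comparison: over minutes the *reference* device assigns to each class,
#' each device's MET mean and SD with a two-sided Welch t-test.
#' Participants without joint minutes are excluded and listed.
#'
#' @param participants list; each element a list with `id`, aligned
#'   vectors `phone_vt`, `ref_vt`, `mets_phone`, `mets_ref`, and logical
#'   `joint` marking jointly recorded, jointly worn minutes.
#' @param conf confidence level.
#' @param active_min,active_inclusive,cutpoints see
#'   [summarize_activity()].
#' @return A list of class `minute_comparison`: `vt` (pooled report),
#'   `reports` (named agreement reports across participants),
#'   `per_participant` data frame, `class_intensity` data frame,
#'   `excluded` character vector of participant ids.
#' @export
compare_minutes <- function(participants, conf = 0.95, active_min = 1.5,
                            active_inclusive = TRUE,
                            cutpoints = c(1.5, 3, 6)) {
  keep <- vapply(participants, function(p) sum(p$joint) > 0, TRUE)
  excluded <- vapply(participants[!keep], `[[`, "", "id")
  if (length(excluded))
    message("excluded (no joint minutes): ",
            paste(excluded, collapse = ", "))
  participants <- participants[keep]
  if (!length(participants))
    stop("no participant has jointly worn minutes", call. = FALSE)
  pooled_phone <- unlist(lapply(participants,
                                function(p) p$phone_vt[p$joint]))
  pooled_ref <- unlist(lapply(participants,
                              function(p) p$ref_vt[p$joint]))
  vt <- agreement_report(pooled_phone, pooled_ref, "minute", conf,
                         same_unit = FALSE)
  per <- do.call(rbind, lapply(participants, function(p) {
    sp <- summarize_activity(p$mets_phone, p$joint, active_min,
                             active_inclusive, cutpoints)
    sr <- summarize_activity(p$mets_ref, p$joint, active_min,
                             active_inclusive, cutpoints)
    data.frame(id = p$id, n_joint = sum(p$joint),
               active_pct_phone = sp$active_pct,
               active_pct_ref = sr$active_pct,
               mean_mets_phone = sp$mean_mets,
               mean_mets_ref = sr$mean_mets,
               sedentary_pct_phone = sp$pct[["sedentary"]],
               sedentary_pct_ref = sr$pct[["sedentary"]],
               light_pct_phone = sp$pct[["light"]],
               light_pct_ref = sr$pct[["light"]],
               moderate_pct_phone = sp$pct[["moderate"]],
               moderate_pct_ref = sr$pct[["moderate"]],
               vigorous_pct_phone = sp$pct[["vigorous"]],
               vigorous_pct_ref = sr$pct[["vigorous"]],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  measures <- c(active_pct = "active_pct", mean_mets = "mean_mets",
                sedentary_pct = "sedentary_pct", light_pct = "light_pct",
                moderate_pct = "moderate_pct",
                vigorous_pct = "vigorous_pct")
  reports <- lapply(measures, function(m)
    agreement_report(per[[paste0(m, "_phone")]],
                     per[[paste0(m, "_ref")]], "minute", conf))
  mph <- unlist(lapply(participants, function(p) p$mets_phone[p$joint]))
  mrf <- unlist(lapply(participants, function(p) p$mets_ref[p$joint]))
  ref_cls <- classify_intensity(mrf, cutpoints)
  class_intensity <- do.call(rbind, lapply(levels(ref_cls), function(cl) {
    sel <- which(ref_cls == cl)
    if (length(sel) < 2)
      return(data.frame(class = cl, n = length(sel),
                        mean_phone = NA_real_, sd_phone = NA_real_,
                        mean_ref = NA_real_, sd_ref = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    tt <- tryCatch(stats::t.test(mph[sel], mrf[sel])$p.value,
                   error = function(e) NA_real_)
    data.frame(class = cl, n = length(sel),
               mean_phone = mean(mph[sel]), sd_phone = stats::sd(mph[sel]),
               mean_ref = mean(mrf[sel]), sd_ref = stats::sd(mrf[sel]),
               p_value = tt, stringsAsFactors = FALSE)
  }))
  structure(list(vt = vt, reports = reports, per_participant = per,
                 class_intensity = class_intensity, excluded = excluded),
            class = "minute_comparison")
}

#' Day-level between-device comparison over coinciding valid days
#'
#' Sensitivity analysis without control of the coinciding time periods:
#' only calendar days valid (enough wearing time) on *both* devices
#' enter; per-day class durations in min/day are then compared across all
#' participant-days with Lin's CCC and Bland-Altman. Each device
#' contributes its own worn minutes for the day, so differences reflect
#' nonmeasured periods as well as measurement disagreement.
#'
#' @param participants list; each element a list with `id` and, per
#'   device (`phone`, `ref`), `day` (character day labels per minute),
#'   `worn` (logical per minute), `mets` (numeric per minute) on that
#'   device's own recording.
#' @param valid_day_hours hours of wearing time a day needs (default 10).
#' @param conf confidence level.
#' @param active_min,active_inclusive,cutpoints see
#'   [summarize_activity()].
#' @return A list of class `day_comparison`: `reports` (per class and
#'   active time, min/day), `per_day` data frame, `n_days`, `empty` flag.
#' @export
compare_days <- function(participants, valid_day_hours = 10, conf = 0.95,
                         active_min = 1.5, active_inclusive = TRUE,
                         cutpoints = c(1.5, 3, 6)) {
  day_rows <- function(p, dev) {
    d <- p[[dev]]
    days <- sort(unique(d$day))
    do.call(rbind, lapply(days, function(dy) {
      sel <- d$day == dy & d$worn & is.finite(d$mets)
      s <- summarize_activity(d$mets, sel, active_min, active_inclusive,
                              cutpoints)
      data.frame(id = p$id, day = dy, device = dev,
                 worn_minutes = sum(sel),
                 sedentary = s$minutes[["sedentary"]],
                 light = s$minutes[["light"]],
                 moderate = s$minutes[["moderate"]],
                 vigorous = s$minutes[["vigorous"]],
                 active = s$active_minutes,
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- do.call(rbind, unlist(lapply(participants, function(p)
    list(day_rows(p, "phone"), day_rows(p, "ref"))), recursive = FALSE))
  tab <- tab[tab$worn_minutes >= valid_day_hours * 60, , drop = FALSE]
  ph <- tab[tab$device == "phone", , drop = FALSE]
  rf <- tab[tab$device == "ref", , drop = FALSE]
  key <- function(x) paste(x$id, x$day)
  common <- intersect(key(ph), key(rf))
  if (!length(common)) {
    return(structure(list(reports = list(), per_day = NULL, n_days = 0L,
                          empty = TRUE), class = "day_comparison"))
  }
  ph <- ph[match(common, key(ph)), , drop = FALSE]
  rf <- rf[match(common, key(rf)), , drop = FALSE]
  measures <- c("sedentary", "light", "moderate", "vigorous", "active")
  reports <- stats::setNames(lapply(measures, function(m)
    agreement_report(ph[[m]], rf[[m]], "day", conf)), measures)
  per_day <- data.frame(id = ph$id, day = ph$day,
                        ph[measures], rf[measures])
  names(per_day) <- c("id", "day", paste0(measures, "_phone"),
                      paste0(measures, "_ref"))
  structure(list(reports = reports, per_day = per_day,
                 n_days = length(common), empty = FALSE),
            class = "day_comparison")
}
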