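#' Detect nonwear intervals in an epoch series
#'
#' A device is called not worn during any maximal run of at least
#' `min_run` consecutive *recorded* minutes whose intensity sits at the
#' device's "no movement" level: exactly 0 for a counts/min series, below
#' the `zero_threshold` (default 0.3 g, a level free-living night-time
#' data sit under) for a g/min series. Every other recorded minute is
#' worn. Minutes with no recording break candidate runs and are kept as a
#' third state, `not_recorded`.
#'
#' @param series an [epoch_series()].
#' @param zero_threshold intensity at or below which a minute counts as no
#'   movement. Defaults to 0 for counts series and 0.3 for g series. A
#'   fractional threshold on a counts series is rejected as a
#'   unit/threshold mismatch.
#' @param min_run minimum run length in minutes (default 40).
#' @return An object of class `wear_mask`: per-minute `state` factor
#'   (`worn` / `nonwear` / `not_recorded`), the epoch `time` grid, and an
#'   `episodes` data frame of maximal same-state runs
#'   (`start`, `length`, `state`).
#' @export
detect_nonwear <- function(series, zero_threshold = NULL, min_run = 40) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(zero_threshold))
    zero_threshold <- if (series$unit == "counts") 0 else 0.3
  if (zero_threshold < 0) stop("zero_threshold must be >= 0", call. = FALSE)
  if (series$unit == "counts" && zero_threshold > 0 && zero_threshold < 1)
    stop("fractional g-style threshold supplied for a counts/min series",
         call. = FALSE)
  if (min_run < 1) stop("min_run must be >= 1", call. = FALSE)
  v <- series$values
  still <- if (series$unit == "counts") v <= zero_threshold
           else v < zero_threshold
  still[is.na(still)] <- FALSE
  state <- ifelse(is.na(v), "not_recorded", "worn")
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= min_run))
    state[starts[i]:ends[i]] <- "nonwear"
  state <- factor(state, levels = c("worn", "nonwear", "not_recorded"))
  re <- rle(as.character(state))
  e_end <- cumsum(re$lengths)
  e_start <- e_end - re$lengths + 1L
  times <- epoch_times(series)
  episodes <- data.frame(start = times[e_start],
                         length = re$lengths,
                         state = re$values,
                         stringsAsFactors = FALSE)
  structure(list(state = state, time = times, episodes = episodes,
                 min_run = min_run, zero_threshold = zero_threshold),
            class = "wear_mask")
}

#' @export
print.wear_mask <- function(x, ...) {
  tab <- table(x$state)
  cat(sprintf("<wear_mask> %d min: %d worn, %d nonwear, %d not recorded\n",
              length(x$state), tab[["worn"]], tab[["nonwear"]],
              tab[["not_recorded"]]))
  nw <- x$episodes[x$episodes$state == "nonwear", , drop = FALSE]
  cat(sprintf("  %d nonwear episode(s), min run %d min\n", nrow(nw),
              x$min_run))
  invisible(x)
}

# state at arbitrary timestamps; minutes outside the mask are not_recorded
mask_lookup <- function(mask, times) {
  idx <- match(as.numeric(times), as.numeric(mask$time))
  out <- rep("not_recorded", length(times))
  hit <- !is.na(idx)
  out[hit] <- as.character(mask$state[idx[hit]])
  out
}

#' Per-participant usability summary of one device's recording
#'
#' Aggregates a wear mask over calendar days (midnight to midnight, the
#' series' clock) into the compliance bookkeeping used to judge whether a
#' deployment produced a valid physical-activity assessment: days and
#' minutes recorded, minutes worn, recorded and worn hours per recorded
#' day, percent worn of recorded time, days with enough wearing time, and
#' the valid-assessment flag (at least `min_valid_days` valid days).
#'
#' A recorded day is any calendar day with at least one recorded minute. A
#' valid day has at least `valid_day_hours` hours in the qualifying state
#' (`"worn"` by default; set `valid_day_basis = "recorded"` for the
#' recorded-time variant of the rule).
#'
#' @param series an [epoch_series()].
#' @param mask the [detect_nonwear()] mask derived from `series`.
#' @param protocol_days days the protocol asked for (reported alongside).
#' @param valid_day_hours hours needed for a valid day (default 10).
#' @param valid_day_basis `"worn"` or `"recorded"`.
#' @param min_valid_days valid days needed for a valid assessment
#'   (default 3).
#' @return An object of class `usability_summary` (a one-row data frame of
#'   the metrics with the per-day table in attribute `"per_day"`).
#' @export
usability_summary <- function(series, mask, protocol_days = 5,
                              valid_day_hours = 10,
                              valid_day_basis = c("worn", "recorded"),
                              min_valid_days = 3) {
  valid_day_basis <- match.arg(valid_day_basis)
  stopifnot(inherits(mask, "wear_mask"))
  day <- format(mask$time, "%Y-%m-%d", tz = "UTC")
  rec <- mask$state != "not_recorded"
  worn <- mask$state == "worn"
  per_day <- data.frame(
    day = sort(unique(day)),
    recorded_minutes = as.vector(tapply(rec, day, sum)),
    worn_minutes = as.vector(tapply(worn, day, sum)))
  per_day <- per_day[per_day$recorded_minutes > 0, , drop = FALSE]
  basis <- if (valid_day_basis == "worn") per_day$worn_minutes
           else per_day$recorded_minutes
  per_day$valid <- basis >= valid_day_hours * 60
  days_recorded <- nrow(per_day)
  recorded_minutes <- sum(per_day$recorded_minutes)
  worn_minutes <- sum(per_day$worn_minutes)
  out <- data.frame(
    device = series$device,
    protocol_days = protocol_days,
    days_recorded = days_recorded,
    recorded_minutes = recorded_minutes,
    worn_minutes = worn_minutes,
    recorded_hours_per_recorded_day =
      if (days_recorded) recorded_minutes / 60 / days_recorded else 0,
    worn_hours_per_recorded_day =
      if (days_recorded) worn_minutes / 60 / days_recorded else 0,
    pct_worn_of_recorded =
      if (recorded_minutes) 100 * worn_minutes / recorded_minutes else 0,
    n_valid_days = sum(per_day$valid),
    valid_assessment = sum(per_day$valid) >= min_valid_days,
    stringsAsFactors = FALSE)
  attr(out, "per_day") <- per_day
  class(out) <- c("usability_summary", class(out))
  out
}

usability_metrics <- c(
  "days_recorded", "recorded_minutes", "worn_minutes",
  "recorded_hours_per_recorded_day", "worn_hours_per_recorded_day",
  "pct_worn_of_recorded", "n_valid_days")

# a group may be a usability_summary, a list of them, or a data.frame
as_usability_df <- function(g) {
  if (inherits(g, "usability_summary")) g <- list(g)
  if (is.data.frame(g)) return(g)
  do.call(rbind, lapply(g, function(s) as.data.frame(unclass(s))))
}

#' Compare usability metrics between device groups
#'
#' For each usability metric, runs the (tie-corrected) Kruskal-Wallis rank
#' sum test across the supplied groups and reports the H statistic, its
#' chi-square p-value, and each group's median and IQR. Two groups is the
#' usual phone-vs-reference comparison; any number of groups is accepted.
#' When every value is identical across all groups the test is degenerate
#' and is reported as H = 0, p = 1.
#'
#' @param ... two or more groups, each a list of [usability_summary()]
#'   objects or an equivalent data frame (one row per participant).
#' @param labels optional group labels.
#' @return A data frame with one row per (metric, group) medians plus
#'   columns `H`, `df`, `p` repeated within metric.
#' @export
compare_usability <- function(..., labels = NULL) {
  groups <- lapply(list(...), as_usability_df)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(!vapply(groups, nrow, 1L)))
    stop("every group must be nonempty", call. = FALSE)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  rows <- list()
  for (m in usability_metrics) {
    vals <- lapply(groups, function(df) as.numeric(df[[m]]))
    x <- unlist(vals)
    grp <- factor(rep(labels, vapply(vals, length, 1L)), levels = labels)
    if (stats::var(x) == 0) {
      H <- 0; df_ <- length(groups) - 1L; p <- 1
    } else {
      kt <- stats::kruskal.test(x, grp)
      H <- unname(kt$statistic); df_ <- unname(kt$parameter)
      p <- kt$p.value
    }
    med <- vapply(vals, stats::median, 1)
    q1 <- vapply(vals, function(v) unname(stats::quantile(v, 0.25)), 1)
    q3 <- vapply(vals, function(v) unname(stats::quantile(v, 0.75)), 1)
    rows[[m]] <- data.frame(metric = m, group = labels, n =
                              vapply(vals, length, 1L),
                            median = med, q1 = q1, q3 = q3,
                            H = H, df = df_, p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
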