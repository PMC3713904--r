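#' Adjusted R-squared of a simple linear regression
#'
#' Goodness of fit used by the clock-alignment scan: the coefficient of
#' determination of `y ~ x`, penalized for the single slope parameter,
#' `1 - (1 - R^2) (n - 1) / (n - 2)`. Pairs where either value is missing
#' are dropped first.
#'
#' @param x,y numeric vectors of equal length.
#' @return Adjusted R-squared in `(-Inf, 1]`.
#' @export
adjusted_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("adjusted R-squared needs at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("adjusted R-squared undefined: predictor has zero variance",
         call. = FALSE)
  # exact fits trip summary.lm's "essentially perfect fit" warning;
  # the R^2 it reports is still what we want
  suppressWarnings(summary(stats::lm(y ~ x))$adj.r.squared)
}

#' Align two devices' epoch series by integer-minute offset search
#'
#' Evaluates the adjusted R-squared between the phone's and the reference
#' device's vertical-axis series at every integer offset in
#' `[-max_offset, +max_offset]` over jointly recorded minutes, and merges
#' the pair at the best offset. The reported offset `k` is the shift
#' applied to the phone's clock: the phone value stamped `t + k` minutes is
#' paired with the reference value stamped `t`, so a phone whose clock runs
#' `k` minutes late is recovered as offset `k`.
#'
#' Ties are broken toward the smallest absolute offset, then the negative
#' one, preferring "no shift". If the maximum sits on the scan boundary the
#' result is flagged (`boundary_attained`), since the true offset may lie
#' outside the window.
#'
#' @param phone [epoch_series()] in g/min.
#' @param ref [epoch_series()] in counts/min.
#' @param max_offset half-width of the scan window in minutes.
#' @param min_overlap minimum jointly recorded minutes required at every
#'   candidate offset.
#' @return A list with components `scan` (class `offset_scan`: per-offset
#'   adjusted R-squared, overlap n, chosen offset, boundary flag) and
#'   `pair` (class `aligned_pair`: merged per-minute vectors `phone_vt`,
#'   `ref_vt`, their common `time` grid on the reference clock, and
#'   `joint_mask` marking minutes both devices recorded).
#' @export
align <- function(phone, ref, max_offset = 5, min_overlap = 30) {
  stopifnot(inherits(phone, "epoch_series"), inherits(ref, "epoch_series"))
  offsets <- seq.int(-max_offset, max_offset)
  ref_min <- as.numeric(ref$start) / 60
  phone_min <- as.numeric(phone$start) / 60
  r2 <- rep(NA_real_, length(offsets))
  n_ov <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    k <- offsets[i]
    # phone epoch stamped (ref minute + k) pairs with the ref epoch
    j_ref <- seq_along(ref$values)
    j_ph <- j_ref + as.integer(ref_min - phone_min + k)
    keep <- j_ph >= 1 & j_ph <= length(phone$values)
    pv <- rep(NA_real_, length(ref$values))
    pv[keep] <- phone$values[j_ph[keep]]
    ok <- is.finite(pv) & is.finite(ref$values)
    n_ov[i] <- sum(ok)
    if (n_ov[i] >= 3 && stats::var(pv[ok]) > 0)
      r2[i] <- adjusted_r2(pv[ok], ref$values[ok])
  }
  if (any(n_ov < min_overlap)) {
    msg <- paste(sprintf("%+d: %d", offsets, n_ov), collapse = ", ")
    stop("insufficient overlap for alignment (minutes per offset: ",
         msg, ")", call. = FALSE)
  }
  best <- max(r2, na.rm = TRUE)
  cand <- offsets[!is.na(r2) & r2 == best]
  # smallest |offset|, then the negative one
  cand <- cand[order(abs(cand), cand)]
  chosen <- cand[1]
  scan <- structure(list(offset = offsets, adj_r2 = r2, n = n_ov,
                         chosen = chosen,
                         boundary_attained = abs(chosen) == max_offset),
                    class = "offset_scan")
  j_ref <- seq_along(ref$values)
  j_ph <- j_ref + as.integer(ref_min - phone_min + chosen)
  keep <- j_ph >= 1 & j_ph <= length(phone$values)
  pv <- rep(NA_real_, length(ref$values))
  pv[keep] <- phone$values[j_ph[keep]]
  pair <- structure(list(
    offset = chosen,
    time = epoch_times(ref),
    phone_vt = pv,
    ref_vt = ref$values,
    joint_mask = is.finite(pv) & is.finite(ref$values)),
    class = "aligned_pair")
  list(scan = scan, pair = pair)
}

#' @export
print.offset_scan <- function(x, ...) {
  cat("<offset_scan> chosen offset:", x$chosen, "min",
      if (x$boundary_attained) "(boundary attained)" else "", "\n")
  print(data.frame(offset = x$offset, adj_r2 = round(x$adj_r2, 4),
                   n = x$n), row.names = FALSE)
  invisible(x)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "<aligned_pair> offset %+d min, %d minutes (%d jointly recorded)\n",
    x$offset, length(x$ref_vt), sum(x$joint_mask)))
  invisible(x)
}

#' Restrict an aligned pair's joint mask to minutes worn on both devices
#'
#' @param pair an `aligned_pair` from [align()].
#' @param phone_mask,ref_mask [wear_mask] objects for the two series,
#'   on the phone's own clock and the reference clock respectively.
#' @return The pair with `joint_mask` additionally requiring the worn
#'   state on both devices.
#' @export
apply_wear <- function(pair, phone_mask, ref_mask) {
  worn_ref <- mask_lookup(ref_mask, pair$time) == "worn"
  worn_ph <- mask_lookup(phone_mask, pair$time + 60 * pair$offset) == "worn"
  pair$joint_mask <- pair$joint_mask & worn_ref & worn_ph
  pair
}
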