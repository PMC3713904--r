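#' Configuration for a synthetic paired-device cohort
#'
#' Describes a free-living validation study in which every participant
#' wears two devices — a research accelerometer recording vertical-axis
#' counts/min and a phone recording vertical-axis g/min — over several
#' protocol days. One latent per-minute MET trajectory drives both
#' devices; each device observes it through the inverse of its own MET
#' equation plus device noise, with its own nonwear episodes, recording
#' gaps (battery/power-off), and, for the phone, a clock offset.
#'
#' Defaults emulate the study design this package targets: 36
#' participants, 5 protocol days, phone clock offsets up to +/-5 minutes,
#' overnight both-device nonwear of about 9 hours, extra phone-only
#' nonwear and charging gaps that bring the phone's wear share of
#' recorded time to roughly half, against about 60% for the reference
#' device.
#'
#' @param n_participants,protocol_days cohort size and days per
#'   participant.
#' @param start `POSIXct` midnight starting the first protocol day.
#' @param offset_range integer minutes; each phone's true clock offset is
#'   drawn uniformly from this range.
#' @param night_minutes_mean,night_minutes_sd length of the nightly
#'   both-device nonwear block starting at midnight.
#' @param class_probs bout class probabilities
#'   (sedentary/light/moderate/vigorous), summing to 1.
#' @param met_ranges list of `c(lo, hi)` MET ranges per class; bout
#'   levels are uniform draws within the class range.
#' @param bout_mean_minutes mean bout length (geometric, minimum 2 min).
#' @param met_jitter_sd within-bout per-minute MET jitter SD.
#' @param phone_nonwear_per_day,ref_nonwear_per_day expected
#'   device-specific daytime nonwear episodes per day (Poisson).
#' @param nonwear_extra_mean mean episode length beyond the 40-minute
#'   detection floor (exponential).
#' @param phone_gap_per_day,ref_gap_per_day expected recording gaps per
#'   day (Poisson).
#' @param gap_minutes_mean mean gap length in minutes (exponential,
#'   minimum 30).
#' @param gap_placement `"random"` anywhere in the day, or
#'   `"sedentary"` to drop recording only during sedentary stretches
#'   (phone forgotten while still).
#' @param phone_noise,ref_noise lists `list(mult =, add =)` of
#'   multiplicative and additive gaussian noise scales in the device's
#'   unit; `phone_noise$mult_vigorous`, if set, replaces the phone's
#'   multiplicative scale during minutes at or above 6 METs
#'   (heteroscedastic phone error).
#' @param phone_model,ref_model [met_model()]s inverted to produce each
#'   device's readings.
#' @param seed default random seed used by [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 36,
                          protocol_days = 5,
                          start = as.POSIXct("2013-04-01 00:00:00",
                                             tz = "UTC"),
                          offset_range = c(-5L, 5L),
                          night_minutes_mean = 540,
                          night_minutes_sd = 30,
                          class_probs = c(sedentary = 0.70, light = 0.22,
                                          moderate = 0.065,
                                          vigorous = 0.015),
                          met_ranges = list(sedentary = c(1.44, 1.49),
                                            light = c(1.6, 2.9),
                                            moderate = c(3.1, 5.8),
                                            vigorous = c(6.1, 8.5)),
                          bout_mean_minutes = 15,
                          met_jitter_sd = 0.15,
                          phone_nonwear_per_day = 1.5,
                          ref_nonwear_per_day = 0.5,
                          nonwear_extra_mean = 50,
                          phone_gap_per_day = 1,
                          ref_gap_per_day = 0,
                          gap_minutes_mean = 120,
                          gap_placement = c("random", "sedentary"),
                          phone_noise = list(mult = 0.03, add = 0.01),
                          ref_noise = list(mult = 0.05, add = 3),
                          phone_model = calfit_model(),
                          ref_model = freedson_actigraph_model(),
                          seed = 1L) {
  gap_placement <- match.arg(gap_placement)
  cfg <- list(n_participants = n_participants,
              protocol_days = protocol_days, start = start,
              offset_range = as.integer(offset_range),
              night_minutes_mean = night_minutes_mean,
              night_minutes_sd = night_minutes_sd,
              class_probs = class_probs, met_ranges = met_ranges,
              bout_mean_minutes = bout_mean_minutes,
              met_jitter_sd = met_jitter_sd,
              phone_nonwear_per_day = phone_nonwear_per_day,
              ref_nonwear_per_day = ref_nonwear_per_day,
              nonwear_extra_mean = nonwear_extra_mean,
              phone_gap_per_day = phone_gap_per_day,
              ref_gap_per_day = ref_gap_per_day,
              gap_minutes_mean = gap_minutes_mean,
              gap_placement = gap_placement,
              phone_noise = phone_noise, ref_noise = ref_noise,
              phone_model = phone_model, ref_model = ref_model,
              seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1 || cfg$protocol_days < 1)
    stop("need at least 1 participant and 1 protocol day", call. = FALSE)
  rates <- c(cfg$phone_nonwear_per_day, cfg$ref_nonwear_per_day,
             cfg$phone_gap_per_day, cfg$ref_gap_per_day)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (abs(sum(cfg$class_probs) - 1) > 1e-8 || any(cfg$class_probs < 0))
    stop("class_probs must be nonnegative and sum to 1", call. = FALSE)
  expected_busy <- cfg$night_minutes_mean +
    cfg$phone_nonwear_per_day * (40 + cfg$nonwear_extra_mean) +
    cfg$phone_gap_per_day * max(cfg$gap_minutes_mean, 30)
  if (cfg$night_minutes_mean >= 1440 || expected_busy >= 1440)
    stop("infeasible daily schedule: scheduled minutes exceed day length",
         call. = FALSE)
  invisible(cfg)
}

# inverse of an affine MET equation, clipped to the device's valid range
invert_met <- function(model, mets) {
  pmax(0, (mets - model$intercept) / model$slope)
}

draw_episodes <- function(n_days, per_day, len_fn, day_len = 1440) {
  out <- list()
  for (d in seq_len(n_days)) {
    k <- stats::rpois(1, per_day)
    if (k == 0) next
    for (i in seq_len(k)) {
      len <- min(len_fn(), day_len - 1L)
      s <- sample.int(day_len - len, 1) + (d - 1L) * day_len
      out[[length(out) + 1L]] <- c(start = s, length = len)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Simulate a paired two-device cohort with known ground truth
#'
#' For each participant: draws a latent per-minute MET trajectory from a
#' piecewise-constant bout process with within-bout jitter, inverts the
#' reference device's MET equation to counts/min and the phone's to
#' g/min, applies device noise, inserts both-device (overnight) and
#' single-device nonwear plus recording gaps, and shifts the phone's
#' clock by a true integer offset. Everything drawn is bookkept in the
#' returned ground truth, so pipeline estimates can be checked exactly.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`. A fixed seed
#'   makes the whole cohort bit-reproducible.
#' @return A list of class `actipair_cohort`: `participants` (named list
#'   with `phone` and `ref` [epoch_series()] each), `truth` (named list
#'   per participant: `offset`, per-minute `met`, `phone_state` /
#'   `ref_state` in worn/nonwear/not_recorded, realized wear
#'   percentages, per-day per-class worn minutes per device), `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n_min <- config$protocol_days * 1440L
  cls_names <- names(config$class_probs)
  noiseless <- function(nz) nz$mult == 0 && nz$add == 0
  participants <- list()
  truth <- list()
  for (p in seq_len(config$n_participants)) {
    id <- sprintf("P%02d", p)
    offset <- if (diff(range(config$offset_range)) == 0)
      config$offset_range[1] else
      sample(seq.int(config$offset_range[1], config$offset_range[2]), 1)
    met <- rep(NA_real_, n_min)
    night <- rep(FALSE, n_min)
    for (d in seq_len(config$protocol_days)) {
      L <- round(stats::rnorm(1, config$night_minutes_mean,
                              config$night_minutes_sd))
      L <- min(max(L, 300), 720)
      night[(d - 1L) * 1440L + seq_len(L)] <- TRUE
      # bout process over the waking remainder of the day
      t <- L
      while (t < 1440L) {
        cl <- sample(cls_names, 1, prob = config$class_probs)
        len <- 2L + stats::rgeom(1, 1 / (config$bout_mean_minutes - 1))
        len <- min(len, 1440L - t)
        rng <- config$met_ranges[[cl]]
        level <- stats::runif(1, rng[1], rng[2])
        vals <- level + stats::rnorm(len, 0, config$met_jitter_sd)
        vals <- pmin(pmax(vals, 1.44), 12)
        met[(d - 1L) * 1440L + t + seq_len(len)] <- vals
        t <- t + len
      }
    }
    phone_state <- ifelse(night, "nonwear", "worn")
    ref_state <- phone_state
    mark <- function(state, eps, new) {
      if (is.null(eps)) return(state)
      for (i in seq_len(nrow(eps))) {
        sel <- eps[i, "start"] + seq_len(eps[i, "length"]) - 1L
        sel <- sel[sel <= n_min]
        state[sel] <- new
      }
      state
    }
    nw_len <- function() 40L + round(stats::rexp(1, 1 / config$nonwear_extra_mean))
    gap_len <- function() 30L + round(stats::rexp(1, 1 / max(config$gap_minutes_mean - 30, 1)))
    phone_state <- mark(phone_state,
                        draw_episodes(config$protocol_days,
                                      config$phone_nonwear_per_day, nw_len),
                        "nonwear")
    ref_state <- mark(ref_state,
                      draw_episodes(config$protocol_days,
                                    config$ref_nonwear_per_day, nw_len),
                      "nonwear")
    place_gap <- function(state) {
      eps <- draw_episodes(config$protocol_days,
                           if (identical(state, "phone"))
                             config$phone_gap_per_day else
                             config$ref_gap_per_day, gap_len)
      eps
    }
    apply_gaps <- function(state, eps) {
      if (is.null(eps)) return(state)
      if (config$gap_placement == "sedentary") {
        # relocate each gap onto a sedentary stretch where possible
        sed <- which(!is.na(met) & met < 1.5)
        for (i in seq_len(nrow(eps))) {
          len <- eps[i, "length"]
          starts <- sed[sed + len - 1 <= n_min]
          if (length(starts))
            eps[i, "start"] <- sample(starts, 1)
        }
      }
      mark(state, eps, "not_recorded")
    }
    phone_state <- apply_gaps(phone_state, place_gap("phone"))
    ref_state <- apply_gaps(ref_state, place_gap("ref"))

    reading <- function(model, state, noise, unit) {
      v <- rep(NA_real_, n_min)
      worn <- state == "worn" & !is.na(met)
      # worn minutes with no latent MET (none by construction) stay NA
      base <- invert_met(model, met[worn])
      if (noiseless(noise)) {
        v[worn] <- base
      } else {
        mult <- rep(noise$mult, sum(worn))
        if (!is.null(noise$mult_vigorous))
          mult[met[worn] >= 6] <- noise$mult_vigorous
        v[worn] <- pmax(0, base * (1 + stats::rnorm(sum(worn), 0, mult)) +
                          stats::rnorm(sum(worn), 0, noise$add))
      }
      nw <- state == "nonwear"
      if (unit == "counts") {
        v[nw] <- 0            # the reference device flatlines at exact zero
      } else {
        v[nw] <- if (noiseless(noise)) 0 else
          stats::runif(sum(nw), 0, 0.05)   # residual phone jitter, < 0.3 g
      }
      v[state == "not_recorded"] <- NA_real_
      v
    }
    ref_vals <- reading(config$ref_model, ref_state, config$ref_noise,
                        "counts")
    phone_vals <- reading(config$phone_model, phone_state,
                          config$phone_noise, "g")
    ref <- epoch_series(ref_vals, start = config$start, unit = "counts",
                        device = paste0(id, "_ref"))
    phone <- epoch_series(phone_vals,
                          start = config$start + 60 * offset,
                          unit = "g", device = paste0(id, "_phone"))
    day <- rep(seq_len(config$protocol_days), each = 1440L)
    per_day_class <- do.call(rbind, lapply(
      seq_len(config$protocol_days), function(d) {
        rows <- lapply(list(phone = phone_state, ref = ref_state),
                       function(st) {
          sel <- day == d & st == "worn" & !is.na(met)
          tab <- table(factor(as.character(classify_intensity(met[sel])),
                              levels = intensity_levels))
          as.vector(tab)
        })
        data.frame(day = d,
                   device = c("phone", "ref"),
                   sedentary = c(rows$phone[1], rows$ref[1]),
                   light = c(rows$phone[2], rows$ref[2]),
                   moderate = c(rows$phone[3], rows$ref[3]),
                   vigorous = c(rows$phone[4], rows$ref[4]))
      }))
    truth[[id]] <- list(
      offset = offset,
      met = met,
      phone_state = phone_state,
      ref_state = ref_state,
      wear_pct_phone = 100 * mean(phone_state[phone_state !=
                                  "not_recorded"] == "worn"),
      wear_pct_ref = 100 * mean(ref_state[ref_state !=
                                "not_recorded"] == "worn"),
      per_day_class = per_day_class)
    participants[[id]] <- list(id = id, phone = phone, ref = ref)
  }
  structure(list(participants = participants, truth = truth,
                 config = config, seed = seed),
            class = "actipair_cohort")
}

#' @export
print.actipair_cohort <- function(x, ...) {
  cat(sprintf("<actipair_cohort> %d participants x %d days (seed %d)\n",
              length(x$participants), x$config$protocol_days, x$seed))
  invisible(x)
}

#' Synthesize a raw tri-axial stream matching a participant's phone epochs
#'
#' Emits, for every recorded phone minute, a vertical sinusoid around 1 g
#' whose amplitude is scaled so that [summarize_to_epochs()] reproduces
#' that minute's g/min value: with `R` samples per 1 Hz cycle the
#' discrete grid mean of `|sin|` is `(2/R) cot(pi/R)` (even `R`), and the
#' amplitude compensates for it. Horizontal axes carry small constant
#' offsets. Not-recorded minutes emit no samples.
#'
#' @param cohort an `actipair_cohort` from [simulate_cohort()].
#' @param participant participant id.
#' @param sample_rate whole samples/second, >= 2.
#' @param max_minutes cap on the number of minutes synthesized (from the
#'   start of the recording); `Inf` for all.
#' @return A [raw_stream()] on the phone's (offset) clock, vertical axis
#'   `"y"`.
#' @export
simulate_raw <- function(cohort, participant, sample_rate = 10,
                         max_minutes = Inf) {
  stopifnot(inherits(cohort, "actipair_cohort"))
  if (!participant %in% names(cohort$participants))
    stop("unknown participant: ", participant, call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate < 2 ||
      sample_rate != round(sample_rate))
    stop("sample_rate must be a whole number of samples/second >= 2",
         call. = FALSE)
  series <- cohort$participants[[participant]]$phone
  g <- series$values
  n <- min(length(g), max_minutes)
  g <- g[seq_len(n)]
  R <- as.integer(sample_rate)
  grid <- sin(2 * pi * (0:(R - 1)) / R)
  m <- mean(abs(grid - stats::median(grid)))
  t0 <- as.numeric(series$start)
  times <- list(); vy <- list()
  for (i in seq_len(n)) {
    if (!is.finite(g[i])) next
    tt <- t0 + (i - 1) * 60 + (0:(60L * R - 1)) / R
    amp <- if (m > 0) g[i] / m else 0
    times[[length(times) + 1L]] <- tt
    vy[[length(vy) + 1L]] <- 1 + amp * sin(2 * pi * (tt - tt[1]))
  }
  if (!length(times)) stop("no recorded minutes to synthesize",
                           call. = FALSE)
  tt <- unlist(times)
  vv <- unlist(vy)
  raw_stream(as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"),
             ax = rep(0.02, length(tt)), ay = vv,
             az = rep(-0.01, length(tt)),
             sample_rate = R, device = series$device, vertical = "y")
}

#' Write a simulated cohort to disk as a study directory
#'
#' Emits one epoch CSV per participant and device, a study manifest
#' (YAML) pointing at them, and a ground-truth JSON (true offsets and
#' wear percentages) stamped with the generating seed.
#'
#' @param cohort an `actipair_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort$participants, function(p) {
    pf <- file.path(dir, paste0(p$id, "_phone.csv"))
    rf <- file.path(dir, paste0(p$id, "_ref.csv"))
    write_epoch_csv(p$phone, pf)
    write_epoch_csv(p$ref, rf)
    list(id = p$id, phone = basename(pf), ref = basename(rf),
         phone_unit = "g", ref_unit = "counts")
  })
  manifest <- list(seed = cohort$seed,
                   participants = unname(entries))
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  truth <- lapply(cohort$truth, function(tr)
    list(offset = tr$offset, wear_pct_phone = tr$wear_pct_phone,
         wear_pct_ref = tr$wear_pct_ref))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
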