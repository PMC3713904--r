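#' Analysis options for a paired-device study
#'
#' One block holding every threshold the analysis uses, with the
#' conventional defaults: alignment window +/-5 min, nonwear rule of 40
#' consecutive near-zero minutes (0 counts / below 0.3 g), valid day of
#' 10 wearing hours, valid assessment of 3 valid days, activity at
#' 1.5 METs (inclusive), and class cutpoints 3 and 6 METs. Any knob can
#' be switched without code edits.
#'
#' @param max_offset,min_overlap see [align()].
#' @param nonwear_min_run,g_threshold see [detect_nonwear()].
#' @param valid_day_hours,valid_day_basis,min_valid_days,protocol_days
#'   see [usability_summary()].
#' @param active_min,active_inclusive,cutpoints see
#'   [summarize_activity()].
#' @param phone_met_model `"calfit"` for the shipped phone equation, or
#'   `"fitted"` to re-derive it per participant by composing
#'   [fit_unit_calibration()] with the reference equation.
#' @param conf confidence level for all intervals.
#' @return A list of class `study_options`.
#' @export
study_options <- function(max_offset = 5, min_overlap = 30,
                          nonwear_min_run = 40, g_threshold = 0.3,
                          valid_day_hours = 10,
                          valid_day_basis = "worn",
                          min_valid_days = 3, protocol_days = 5,
                          active_min = 1.5, active_inclusive = TRUE,
                          cutpoints = c(1.5, 3, 6),
                          phone_met_model = c("calfit", "fitted"),
                          conf = 0.95) {
  structure(list(max_offset = max_offset, min_overlap = min_overlap,
                 nonwear_min_run = nonwear_min_run,
                 g_threshold = g_threshold,
                 valid_day_hours = valid_day_hours,
                 valid_day_basis = valid_day_basis,
                 min_valid_days = min_valid_days,
                 protocol_days = protocol_days,
                 active_min = active_min,
                 active_inclusive = active_inclusive,
                 cutpoints = cutpoints,
                 phone_met_model = match.arg(phone_met_model),
                 conf = conf),
            class = "study_options")
}

# full single-participant pipeline: align, wear, METs, day tables
analyze_participant <- function(id, phone, ref, opts) {
  al <- align(phone, ref, max_offset = opts$max_offset,
              min_overlap = opts$min_overlap)
  mask_phone <- detect_nonwear(phone, opts$g_threshold,
                               opts$nonwear_min_run)
  mask_ref <- detect_nonwear(ref, 0, opts$nonwear_min_run)
  us_phone <- usability_summary(phone, mask_phone, opts$protocol_days,
                                opts$valid_day_hours,
                                opts$valid_day_basis,
                                opts$min_valid_days)
  us_ref <- usability_summary(ref, mask_ref, opts$protocol_days,
                              opts$valid_day_hours, opts$valid_day_basis,
                              opts$min_valid_days)
  pair <- apply_wear(al$pair, mask_phone, mask_ref)
  phone_model <- if (opts$phone_met_model == "calfit") calfit_model()
                 else fit_unit_calibration(pair)$met_model
  ref_model <- freedson_actigraph_model()
  mets_phone <- predict_mets(phone_model, pair$phone_vt)
  mets_ref <- predict_mets(ref_model, pair$ref_vt)
  day_block <- function(series, mask, model) {
    list(day = format(epoch_times(series), "%Y-%m-%d", tz = "UTC"),
         worn = as.character(mask$state) == "worn",
         mets = predict_mets(model, series$values))
  }
  list(id = id, scan = al$scan, pair = pair,
       mask_phone = mask_phone, mask_ref = mask_ref,
       usability_phone = us_phone, usability_ref = us_ref,
       phone_model = phone_model,
       minute = list(id = id, phone_vt = pair$phone_vt,
                     ref_vt = pair$ref_vt, mets_phone = mets_phone,
                     mets_ref = mets_ref, joint = pair$joint_mask),
       day = list(id = id,
                  phone = day_block(phone, mask_phone, phone_model),
                  ref = day_block(ref, mask_ref, ref_model)))
}

#' Run the full paired-device study analysis on in-memory series
#'
#' Executes epoch alignment, wear detection, usability accounting, MET
#' conversion, and the minute- and day-level agreement batteries for a
#' cohort. Per-participant failures are isolated: the participant is
#' excluded with a machine-readable reason code, and enrolled =
#' analyzed + excluded always holds. A cohort with no analyzable
#' participant aborts with a diagnostic.
#'
#' @param cohort either an `actipair_cohort` from [simulate_cohort()] or
#'   a named list of elements `list(id, phone, ref)` with
#'   [epoch_series()] values.
#' @param options a [study_options()] block.
#' @return A list of class `study_results`: `usability` (per
#'   participant-device data frame), `usability_tests` (Kruskal-Wallis
#'   table), `minute` ([compare_minutes()] output), `day`
#'   ([compare_days()] output), `offsets` (chosen offset per
#'   participant), `exclusions` (data frame id/code/message), `log`
#'   (character lines).
#' @export
analyze_cohort <- function(cohort, options = study_options()) {
  if (inherits(cohort, "actipair_cohort")) cohort <- cohort$participants
  opts <- options
  results <- list(); exclusions <- list(); log <- character()
  for (p in cohort) {
    res <- tryCatch(
      analyze_participant(p$id, p$phone, p$ref, opts),
      error = function(e) e)
    if (inherits(res, "error")) {
      code <- if (grepl("insufficient overlap", conditionMessage(res)))
        "alignment_error" else "processing_error"
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(id = p$id, code = code,
                   message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      log <- c(log, sprintf("%s excluded code=%s: %s", p$id, code,
                            conditionMessage(res)))
    } else {
      if (sum(res$pair$joint_mask) == 0) {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(id = p$id, code = "no_joint_minutes",
                     message = "no jointly worn minutes",
                     stringsAsFactors = FALSE)
        log <- c(log, sprintf("%s excluded code=no_joint_minutes", p$id))
      } else {
        results[[p$id]] <- res
        log <- c(log, sprintf("%s analyzed offset=%+d joint=%d", p$id,
                              res$pair$offset,
                              sum(res$pair$joint_mask)))
      }
    }
  }
  if (!length(results))
    stop("no participant could be analyzed; see exclusions", call. = FALSE)
  usability <- do.call(rbind, unlist(lapply(results, function(r) {
    up <- as.data.frame(unclass(r$usability_phone))
    ur <- as.data.frame(unclass(r$usability_ref))
    up$id <- r$id; up$device <- "phone"
    ur$id <- r$id; ur$device <- "ref"
    list(up, ur)
  }), recursive = FALSE))
  rownames(usability) <- NULL
  usability <- usability[c("id", "device",
                           setdiff(names(usability), c("id", "device")))]
  usability_tests <- compare_usability(
    usability[usability$device == "phone", ],
    usability[usability$device == "ref", ],
    labels = c("phone", "ref"))
  minute <- compare_minutes(lapply(results, `[[`, "minute"),
                            conf = opts$conf,
                            active_min = opts$active_min,
                            active_inclusive = opts$active_inclusive,
                            cutpoints = opts$cutpoints)
  day <- compare_days(lapply(results, `[[`, "day"),
                      valid_day_hours = opts$valid_day_hours,
                      conf = opts$conf, active_min = opts$active_min,
                      active_inclusive = opts$active_inclusive,
                      cutpoints = opts$cutpoints)
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(id = character(), code = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(
    n_enrolled = length(cohort), n_analyzed = length(results),
    usability = usability, usability_tests = usability_tests,
    minute = minute, day = day,
    offsets = vapply(results, function(r) r$pair$offset, 1L),
    participant_results = results,
    exclusions = exclusions, log = log, options = opts),
    class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d enrolled, %d analyzed, %d excluded\n",
              x$n_enrolled, x$n_analyzed, nrow(x$exclusions)))
  cat("minute-level VT: ")
  print(x$minute$vt)
  invisible(x)
}

report_to_list <- function(r) {
  list(n = r$n, level = r$level,
       spearman_rho = r$spearman_rho, spearman_ci = r$spearman_ci,
       adjusted_r2 = r$adjusted_r2,
       ccc = r$ccc, ccc_ci = r$ccc_ci,
       mean_difference = r$mean_difference,
       mean_difference_ci = r$mean_difference_ci,
       loa = r$loa, bias_slope = r$bias_slope,
       bias_slope_ci = r$bias_slope_ci,
       bias_significant = r$bias_significant)
}

#' Run a paired-device study from a manifest of epoch files
#'
#' Reads every participant's phone and reference epoch CSVs named in the
#' manifest, runs [analyze_cohort()], and writes the report bundle:
#' `usability.csv`, `usability_tests.csv`, `agreement_minute.json`,
#' `agreement_day.json`, `class_intensity.csv`, plot-ready
#' `bland_altman_*.csv` tables, and `run.log` recording every exclusion
#' with its reason code.
#'
#' @param manifest a YAML file path or a list with a `participants`
#'   element: each entry `list(id, phone, ref)` of file paths (relative
#'   paths resolve against the manifest's directory).
#' @param out_dir output directory, created if needed.
#' @param options a [study_options()] block.
#' @return The [analyze_cohort()] results, invisibly.
#' @export
run_study <- function(manifest, out_dir, options = study_options()) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  series <- list(); exclusions <- list(); log <- character()
  for (e in manifest$participants) {
    got <- tryCatch(list(
      id = e$id,
      phone = read_epoch_csv(resolve_path(e$phone, base), unit = "g"),
      ref = read_epoch_csv(resolve_path(e$ref, base), unit = "counts")),
      error = function(err) err)
    if (inherits(got, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(id = e$id, code = "read_error",
                   message = conditionMessage(got),
                   stringsAsFactors = FALSE)
      log <- c(log, sprintf("%s excluded code=read_error: %s", e$id,
                            conditionMessage(got)))
    } else {
      series[[e$id]] <- got
    }
  }
  if (!length(series))
    stop("no participant file pair could be read", call. = FALSE)
  res <- analyze_cohort(series, options)
  res$n_enrolled <- res$n_enrolled + length(exclusions)
  if (length(exclusions))
    res$exclusions <- rbind(do.call(rbind, exclusions), res$exclusions)
  res$log <- c(log, res$log)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  utils::write.csv(res$usability, file.path(out_dir, "usability.csv"),
                   row.names = FALSE)
  utils::write.csv(res$usability_tests,
                   file.path(out_dir, "usability_tests.csv"),
                   row.names = FALSE)
  wj(c(list(vt = report_to_list(res$minute$vt)),
       lapply(res$minute$reports, report_to_list),
       list(excluded = res$minute$excluded)),
     "agreement_minute.json")
  wj(if (res$day$empty) list(empty = TRUE, n_days = 0) else
       c(lapply(res$day$reports, report_to_list),
         list(n_days = res$day$n_days)),
     "agreement_day.json")
  utils::write.csv(res$minute$class_intensity,
                   file.path(out_dir, "class_intensity.csv"),
                   row.names = FALSE)
  for (m in names(res$minute$reports)) {
    ba <- res$minute$reports[[m]]$bland_altman
    if (!is.null(ba))
      utils::write.csv(ba$table,
                       file.path(out_dir,
                                 paste0("bland_altman_", m, ".csv")),
                       row.names = FALSE)
  }
  log_lines <- c(sprintf("enrolled=%d analyzed=%d excluded=%d",
                         res$n_enrolled, res$n_analyzed,
                         nrow(res$exclusions)), res$log)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}

resolve_path <- function(p, base) {
  if (file.exists(p) || grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base, p)
}
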