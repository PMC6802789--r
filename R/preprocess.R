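#' Signed angular error between target and response
#'
#' @param target_colour_deg,response_colour_deg hue angles in degrees.
#' @return signed error in degrees, wrapped to (-180, 180]; the antipode is
#'   assigned +180 by convention.
#' @examples
#' angular_error(350, 10)   # +20
#' angular_error(0, 180)    # +180
#' @export
angular_error <- function(target_colour_deg, response_colour_deg) {
  wrap_deg(response_colour_deg - target_colour_deg)
}

new_exclusion_report <- function(n_input, n_practice_dropped = 0L, n_miss = 0L,
                                 n_false_alarm = 0L, n_pre_target = 0L,
                                 n_madm_outliers = 0L,
                                 n_target_trials = NA_integer_,
                                 n_catch_trials = NA_integer_,
                                 n_before_madm = NA_integer_) {
  r <- list(
    n_input = n_input,
    n_practice_dropped = n_practice_dropped,
    n_miss = n_miss,
    n_false_alarm = n_false_alarm,
    n_pre_target = n_pre_target,
    n_madm_outliers = n_madm_outliers,
    # denominators follow the reporting convention of the emulated papers:
    # misses and pre-target responses as fractions of (post-practice) target
    # trials, false alarms of catch trials, MADM outliers of the trials
    # remaining before the filter
    frac_miss = n_miss / n_target_trials,
    frac_false_alarm = n_false_alarm / n_catch_trials,
    frac_pre_target = n_pre_target / n_target_trials,
    frac_madm = n_madm_outliers / n_before_madm
  )
  class(r) <- "exclusion_report"
  r
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  input trials        %6d\n", x$n_input))
  cat(sprintf("  practice dropped    %6d\n", x$n_practice_dropped))
  fmt <- function(n, f, lab) {
    cat(sprintf("  %-18s %6d%s\n", lab, n,
                if (is.finite(f)) sprintf("  (%.2f%%)", 100 * f) else ""))
  }
  fmt(x$n_miss, x$frac_miss, "misses")
  fmt(x$n_false_alarm, x$frac_false_alarm, "false alarms")
  fmt(x$n_pre_target, x$frac_pre_target, "pre-target")
  fmt(x$n_madm_outliers, x$frac_madm, "MADM outliers")
  invisible(x)
}

#' Drop practice blocks and invalid-response trials
#'
#' Removes practice trials (block 0), misses, false alarms and pre-target
#' responses, tallying each rule separately.  Catch trials with correct
#' rejections are also removed from the analysis set (they carry no colour
#' response) but are not counted as exclusions.
#'
#' @param trials completed trials with `block` and `outcome` populated.
#' @return list with `trials` (retained hit trials) and `report`
#'   (an `exclusion_report`).
#' @export
drop_invalid <- function(trials) {
  if (any(is.na(trials$outcome))) {
    stop("`outcome` must be populated for every trial", call. = FALSE)
  }
  n_input <- nrow(trials)
  test <- trials[trials$block != 0L, ]
  n_practice <- n_input - nrow(test)

  n_target <- sum(test$target_present)
  n_catch <- sum(!test$target_present)
  n_miss <- sum(test$outcome == "miss")
  n_fa <- sum(test$outcome == "false_alarm")
  n_pre <- sum(test$outcome == "pre_target")

  keep <- test[test$outcome == "hit", ]
  report <- new_exclusion_report(
    n_input = n_input, n_practice_dropped = n_practice,
    n_miss = n_miss, n_false_alarm = n_fa, n_pre_target = n_pre,
    n_target_trials = n_target, n_catch_trials = n_catch
  )
  list(trials = keep, report = report)
}

#' Robust outlier filter on log reaction times
#'
#' Within each cell (subject crossed with cue condition, or with SOA x cue
#' condition), computes the median of log RT and the median absolute
#' deviation around it (MADM, unscaled), and drops trials whose log RT
#' deviates from the cell median by strictly more than `multiplier` times
#' the MADM.  Cells whose MADM is zero drop nothing, and empty cells are
#' no-ops.
#'
#' @param trials hit trials with `rt_ms` present.
#' @param cells one of `"cue"` (cells are subject x cue type) or
#'   `"soa-cue"` (subject x SOA x cue type).
#' @param multiplier positive cutoff in MADM units (5 by default).
#' @return list with `trials` (retained) and `report` (an
#'   `exclusion_report` whose `frac_madm` is relative to the input rows).
#' @export
madm_filter <- function(trials, cells = c("cue", "soa-cue"), multiplier = 5) {
  cells <- match.arg(cells)
  stopifnot(multiplier > 0)
  if (nrow(trials) == 0) {
    return(list(trials = trials,
                report = new_exclusion_report(0L, n_before_madm = 0L)))
  }
  if (any(is.na(trials$rt_ms))) {
    stop("`rt_ms` must be present on every trial before MADM filtering",
         call. = FALSE)
  }
  key <- if (cells == "cue") {
    paste(trials$subject_id, trials$cue_type)
  } else {
    paste(trials$subject_id, trials$soa_ms, trials$cue_type)
  }
  lrt <- log(trials$rt_ms)
  med <- stats::ave(lrt, key, FUN = stats::median)
  dev <- abs(lrt - med)
  madm <- stats::ave(dev, key, FUN = stats::median)
  drop <- dev > multiplier * madm          # strict: zero deviation survives MADM 0
  drop[is.na(drop)] <- FALSE               # Inf * 0 guard
  report <- new_exclusion_report(
    n_input = nrow(trials), n_madm_outliers = sum(drop),
    n_before_madm = nrow(trials)
  )
  list(trials = trials[!drop, ], report = report)
}

#' Assemble the modelling dataset
#'
#' One row per retained target trial, with the modelling condition label,
#' log reaction time and signed angular error.
#'
#' @param trials filtered hit trials.
#' @return a `clean_dataset` tibble with columns `subject_id`, `condition`,
#'   `log_rt`, `error_deg`.
#' @export
to_clean <- function(trials) {
  if (nrow(trials) == 0) {
    out <- tibble::tibble(subject_id = character(), condition = character(),
                          log_rt = numeric(), error_deg = numeric())
    class(out) <- c("clean_dataset", class(out))
    return(out)
  }
  needed <- c("subject_id", "rt_ms", "target_colour_deg", "response_colour_deg")
  missing_any <- vapply(needed, function(nm) any(is.na(trials[[nm]])), logical(1))
  if (any(missing_any)) {
    stop("missing fields in retained trials: ",
         paste(needed[missing_any], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = trials$subject_id,
    condition = trial_condition(trials),
    log_rt = log(trials$rt_ms),
    error_deg = angular_error(trials$target_colour_deg,
                              trials$response_colour_deg)
  )
  class(out) <- c("clean_dataset", class(out))
  out
}

#' Run the full preprocessing pipeline
#'
#' Applies [drop_invalid()] then [madm_filter()] (a single pass) and returns
#' the clean dataset together with a merged exclusion report.
#'
#' @inheritParams madm_filter
#' @param trials completed trials (e.g. `sim$trials`).
#' @return list with `clean` (a `clean_dataset`) and `report`.
#' @export
preprocess <- function(trials, cells = c("cue", "soa-cue"), multiplier = 5) {
  cells <- match.arg(cells)
  s1 <- drop_invalid(trials)
  s2 <- madm_filter(s1$trials, cells = cells, multiplier = multiplier)
  report <- s1$report
  report$n_madm_outliers <- s2$report$n_madm_outliers
  report$frac_madm <- s2$report$frac_madm
  list(clean = to_clean(s2$trials), report = report)
}
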