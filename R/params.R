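#' Generative parameters for simulated cueing sessions
#'
#' Bundles the condition-level truth used by the simulator: per-condition
#' median reaction times (modelled as lognormal), encoding probabilities
#' (the mixture weight of the target-centred von Mises component) and
#' encoding fidelities (the von Mises concentration), together with
#' subject-level spreads and contamination rates.
#'
#' Defaults reproduce the regime of the two experiments this package
#' emulates.  Condition-level values are anchored at the published posterior
#' medians, with the reported valid-minus-invalid effects split symmetrically
#' around the intercept (the intercept is treated as the across-condition
#' mean).  Within-subject reaction-time spread and subject-level spreads are
#' not published; the defaults are values typical of speeded detection tasks
#' and are documented in the methods vignette.
#'
#' @param experiment `"E1"` or `"E2"`; selects the default condition set.
#' @param rt_median_ms named numeric: median RT in ms per condition.
#'   Condition names are `valid/invalid/neutral` for E1 and
#'   `soa100.valid`, ..., `soa800.neutral` for E2.
#' @param rho named numeric in (0, 1): encoding probability per condition.
#' @param kappa named numeric > 0: von Mises concentration per condition.
#' @param rt_log_sd_within within-subject SD of log RT.
#' @param subject_sds named numeric: SDs of subject-level intercept
#'   deviations on the latent scales (`rt` log-ms, `rho` logit, `kappa`
#'   log).
#' @param miss_rate,false_alarm_rate,pre_target_rate contamination
#'   probabilities (fractions of target, catch and target trials
#'   respectively).
#' @param timeout_ms detection-response timeout in ms.
#' @return An object of class `generative_params` (a validated list).
#' @examples
#' p <- generative_params("E1")
#' p$rho
#' @export
generative_params <- function(experiment = c("E1", "E2"),
                              rt_median_ms = NULL,
                              rho = NULL,
                              kappa = NULL,
                              rt_log_sd_within = 0.20,
                              subject_sds = c(rt = 0.15, rho = 1.0, kappa = 0.25),
                              miss_rate = NULL,
                              false_alarm_rate = NULL,
                              pre_target_rate = NULL,
                              timeout_ms = 1500) {
  experiment <- match.arg(experiment)
  d <- default_truth(experiment)
  rt_median_ms <- rt_median_ms %||% d$rt_median_ms
  rho <- rho %||% d$rho
  kappa <- kappa %||% d$kappa
  miss_rate <- miss_rate %||% d$miss_rate
  false_alarm_rate <- false_alarm_rate %||% d$false_alarm_rate
  pre_target_rate <- pre_target_rate %||% d$pre_target_rate

  conds <- condition_levels(experiment)
  for (nm in c("rt_median_ms", "rho", "kappa")) {
    v <- get(nm)
    if (!all(conds %in% names(v))) {
      stop(sprintf("`%s` must be named with all conditions: %s",
                   nm, paste(conds, collapse = ", ")), call. = FALSE)
    }
  }
  stopifnot(
    all(rho > 0 & rho < 1), all(kappa > 0), all(rt_median_ms > 0),
    rt_log_sd_within >= 0, all(subject_sds >= 0),
    miss_rate >= 0, miss_rate <= 1,
    false_alarm_rate >= 0, false_alarm_rate <= 1,
    pre_target_rate >= 0, pre_target_rate <= 1,
    timeout_ms > 0
  )
  structure(list(
    experiment = experiment,
    rt_median_ms = rt_median_ms[conds],
    rho = rho[conds],
    kappa = kappa[conds],
    rt_log_sd_within = rt_log_sd_within,
    subject_sds = subject_sds,
    miss_rate = miss_rate,
    false_alarm_rate = false_alarm_rate,
    pre_target_rate = pre_target_rate,
    timeout_ms = timeout_ms
  ), class = "generative_params")
}

#' Condition labels used for modelling
#'
#' E1 conditions are the three cue types; E2 conditions cross SOA with cue
#' type (six cells).
#' @param experiment `"E1"` or `"E2"`.
#' @return character vector of condition labels, reference condition first.
#' @export
condition_levels <- function(experiment) {
  if (experiment == "E1") {
    c("invalid", "valid", "neutral")
  } else {
    c("soa100.invalid", "soa100.valid", "soa100.neutral",
      "soa800.invalid", "soa800.valid", "soa800.neutral")
  }
}

# Published-regime truth.  Intercepts are the reported posterior medians;
# valid-minus-invalid effects are split +-1/2 around them.  E1 neutral sits
# at the intercept.  The E2 neutral fidelity at the short SOA adds the
# reported neutral-vs-spatial benefit (on the kappa scale) to the spatial
# mean; other neutral cells sit at their SOA intercepts.
default_truth <- function(experiment) {
  if (experiment == "E1") {
    rt_eff <- -21.70; rho_eff <- 0.008; kap_eff <- 0.45
    list(
      rt_median_ms = c(invalid = 359.86 - rt_eff / 2,
                       valid   = 359.86 + rt_eff / 2,
                       neutral = 359.86),
      rho   = c(invalid = 0.992 - rho_eff / 2,
                valid   = 0.992 + rho_eff / 2,
                neutral = 0.992),
      kappa = c(invalid = 9.08 - kap_eff / 2,
                valid   = 9.08 + kap_eff / 2,
                neutral = 9.08),
      miss_rate = 0.0032, false_alarm_rate = 0.0302, pre_target_rate = 0.0122
    )
  } else {
    # short (100 ms) and long (800 ms) SOA cells
    rt1 <- 404.02; rt8 <- 393.78
    rt_eff1 <- 6.62; rt_eff8 <- 34.94
    rho1 <- 0.995; rho8 <- 0.995
    rho_eff1 <- 0.003; rho_eff8 <- -0.004
    k1 <- 10.51; k8 <- 9.78
    k_eff1 <- -0.02; k_eff8 <- -0.11
    k1_valid <- k1 + k_eff1 / 2; k1_invalid <- k1 - k_eff1 / 2
    # neutral-vs-spatial fidelity benefit at the short SOA (kappa scale),
    # pooling spatial cells on the log scale
    k1_neutral <- exp(mean(log(c(k1_valid, k1_invalid)))) + 1.26
    list(
      rt_median_ms = c(soa100.invalid = rt1 - rt_eff1 / 2,
                       soa100.valid   = rt1 + rt_eff1 / 2,
                       soa100.neutral = rt1,
                       soa800.invalid = rt8 - rt_eff8 / 2,
                       soa800.valid   = rt8 + rt_eff8 / 2,
                       soa800.neutral = rt8),
      rho   = c(soa100.invalid = rho1 - rho_eff1 / 2,
                soa100.valid   = rho1 + rho_eff1 / 2,
                soa100.neutral = rho1,
                soa800.invalid = rho8 - rho_eff8 / 2,
                soa800.valid   = rho8 + rho_eff8 / 2,
                soa800.neutral = rho8),
      kappa = c(soa100.invalid = k1_invalid,
                soa100.valid   = k1_valid,
                soa100.neutral = k1_neutral,
                soa800.invalid = k8 - k_eff8 / 2,
                soa800.valid   = k8 + k_eff8 / 2,
                soa800.neutral = k8),
      miss_rate = 0.0074, false_alarm_rate = 0.0267, pre_target_rate = 0.0147
    )
  }
}

#' Label a trial with its modelling condition
#' @param trials tibble with `experiment`, `cue_type`, `soa_ms`.
#' @return character vector of condition labels.
#' @export
trial_condition <- function(trials) {
  ifelse(trials$experiment == "E1",
         trials$cue_type,
         paste0("soa", trials$soa_ms, ".", trials$cue_type))
}
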