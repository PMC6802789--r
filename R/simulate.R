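#' Sample one colour-wheel response
#'
#' Draws a reported colour under the two-component encoding model: with
#' probability `rho` the response is the target colour plus von Mises error
#' with concentration `kappa`; otherwise it is a blind guess, uniform on the
#' wheel.
#'
#' @param target_colour_deg target hue angle(s) in degrees, in \[0, 360).
#' @param rho encoding probability in \[0, 1\].
#' @param kappa von Mises concentration, `>= 0`.
#' @param n number of draws per target (recycled against
#'   `target_colour_deg`).
#' @return response hue angle(s) in \[0, 360).
#' @examples
#' set.seed(1)
#' r <- sample_colour_response(90, rho = 0.95, kappa = 9)
#' @export
sample_colour_response <- function(target_colour_deg, rho, kappa, n = length(target_colour_deg)) {
  stopifnot(rho >= 0, rho <= 1)
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  target <- rep_len(target_colour_deg, n)
  encoded <- stats::runif(n) < rho
  err <- numeric(n)
  n_enc <- sum(encoded)
  if (n_enc > 0) err[encoded] <- rad2deg(rvonmises(n_enc, kappa))
  if (n_enc < n) err[!encoded] <- stats::runif(n - n_enc, -180, 180)
  (target + err) %% 360
}

#' Draw von Mises angular errors centred at zero
#'
#' Best-Fisher rejection sampler; falls back to the wrapped-normal limit for
#' very large concentrations.
#'
#' @param n number of draws.
#' @param kappa concentration, `>= 0` (`0` gives circular uniform draws).
#' @return angles in radians in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) {
    # wrapped-normal limit; avoids pathological rejection rates
    return(wrap_rad(stats::rnorm(n, 0, 1 / sqrt(kappa))))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    acc <- theta[ok]
    take <- min(length(acc), m)
    if (take > 0) out[(got + 1L):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  out
}

wrap_rad <- function(x) {
  e <- x %% (2 * pi)
  e[e > pi] <- e[e > pi] - 2 * pi
  e
}

#' Sample reaction times from the lognormal response model
#'
#' `log(rt)` is normal with mean `log(rt_median_ms[condition]) +
#' subject_offset` and SD `rt_log_sd_within`, so `rt_median_ms` is the
#' median RT of the condition for a subject with zero offset.
#'
#' @param condition condition label(s) present in `params$rt_median_ms`.
#' @param params a [generative_params()] object.
#' @param subject_offset additive offset on the log-ms scale.
#' @param n number of draws (recycled against `condition`).
#' @return reaction times in ms.
#' @export
sample_rt <- function(condition, params, subject_offset = 0, n = length(condition)) {
  condition <- rep_len(condition, n)
  bad <- !condition %in% names(params$rt_median_ms)
  if (any(bad)) {
    stop("unknown condition: ", paste(unique(condition[bad]), collapse = ", "),
         call. = FALSE)
  }
  mu <- log(params$rt_median_ms[condition]) + subject_offset
  exp(stats::rnorm(n, mu, params$rt_log_sd_within))
}

#' Simulate one subject's responses over a schedule
#'
#' Fills the response fields of a trial schedule under the generative model.
#' Target trials become pre-target responses with probability
#' `pre_target_rate` (RT drawn uniformly in \[-SOA, 0) relative to target
#' onset, colour click uniform), misses with probability `miss_rate` (no RT,
#' no colour response), and hits otherwise (lognormal RT, mixture colour
#' response).  Catch trials become false alarms with probability
#' `false_alarm_rate` (RT from the condition's RT model, uniform colour
#' click) and correct rejections otherwise.
#'
#' @param schedule a [build_session()]/[build_block()] schedule.
#' @param params a [generative_params()] object.
#' @param subject_id label stored on every trial.
#' @param seed integer seed.
#' @param subject_offsets named numeric (`rt`, `rho`, `kappa`): this
#'   subject's latent intercept deviations.
#' @return the schedule with `subject_id`, responses and `outcome` filled.
#' @export
simulate_subject <- function(schedule, params, subject_id = "s01", seed = 1L,
                             subject_offsets = c(rt = 0, rho = 0, kappa = 0)) {
  stopifnot(inherits(schedule, "data.frame"), nrow(schedule) > 0)
  trials <- schedule
  trials$subject_id <- as.character(subject_id)
  cond <- trial_condition(trials)
  n <- nrow(trials)

  rho_s <- stats::plogis(stats::qlogis(params$rho) + subject_offsets[["rho"]])
  kap_s <- exp(log(params$kappa) + subject_offsets[["kappa"]])

  withr::with_seed(seed, {
    u <- stats::runif(n)
    is_target <- trials$target_present
    outcome <- character(n)
    # catch trials: false alarm or correct rejection
    outcome[!is_target] <- ifelse(u[!is_target] < params$false_alarm_rate,
                                  "false_alarm", "correct_rejection")
    # target trials: pre-target, miss, or hit
    outcome[is_target] <- ifelse(
      u[is_target] < params$pre_target_rate, "pre_target",
      ifelse(u[is_target] < params$pre_target_rate + params$miss_rate,
             "miss", "hit"))

    rt <- rep(NA_real_, n)
    resp <- rep(NA_real_, n)

    hit <- outcome == "hit"
    if (any(hit)) {
      rt[hit] <- sample_rt(cond[hit], params, subject_offsets[["rt"]])
      # timeout censoring: responses slower than the deadline count as misses
      late <- hit & rt > params$timeout_ms
      outcome[late] <- "miss"
      rt[late] <- NA_real_
      resp[late] <- NA_real_
      hit <- outcome == "hit"
      for (cc in unique(cond[hit])) {
        i <- hit & cond == cc
        resp[i] <- sample_colour_response(trials$target_colour_deg[i],
                                          rho_s[[cc]], kap_s[[cc]])
      }
    }
    pre <- outcome == "pre_target"
    if (any(pre)) {
      rt[pre] <- stats::runif(sum(pre), -trials$soa_ms[pre], 0)
      resp[pre] <- stats::runif(sum(pre), 0, 360)
    }
    fa <- outcome == "false_alarm"
    if (any(fa)) {
      rt[fa] <- sample_rt(cond[fa], params, subject_offsets[["rt"]])
      resp[fa] <- stats::runif(sum(fa), 0, 360)
    }
    trials$outcome <- outcome
    trials$rt_ms <- rt
    trials$response_colour_deg <- resp
  })
  trials
}

#' Simulate a full multi-subject experiment
#'
#' Builds one counterbalanced session per subject (E1 counterbalance arms
#' alternate across subjects), draws subject-level intercept deviations from
#' `params$subject_sds`, and simulates every subject's responses.
#'
#' @param n_subjects number of subjects (71 and 40 in the emulated
#'   experiments).
#' @param experiment `"E1"` or `"E2"`.
#' @param params a [generative_params()] object; defaults to
#'   `generative_params(experiment)`.
#' @param seed master integer seed.
#' @param n_blocks test blocks per subject; defaults to the experiment's
#'   published count (7 for E1, 8 for E2).
#' @param practice include a 30-trial practice block per subject.
#' @return An object of class `sim_dataset`: list with `trials` (tibble),
#'   `truth` (the `generative_params` plus realised subject offsets) and
#'   `seed`.
#' @examples
#' sim <- simulate_experiment(2, "E1", seed = 7, n_blocks = 1)
#' table(sim$trials$outcome)
#' @export
simulate_experiment <- function(n_subjects, experiment = c("E1", "E2"),
                                params = NULL, seed = 1L,
                                n_blocks = NULL, practice = TRUE) {
  stopifnot(n_subjects >= 1)
  experiment <- match.arg(experiment)
  params <- params %||% generative_params(experiment)
  stopifnot(identical(params$experiment, experiment))
  n_blocks <- n_blocks %||% if (experiment == "E1") 7L else 8L

  seeds <- child_seeds(seed, 2L * n_subjects + 1L)
  offsets <- withr::with_seed(seeds[2L * n_subjects + 1L], {
    s <- params$subject_sds
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      rt = stats::rnorm(n_subjects, 0, s[["rt"]]),
      rho = stats::rnorm(n_subjects, 0, s[["rho"]]),
      kappa = stats::rnorm(n_subjects, 0, s[["kappa"]])
    )
  })

  arms <- rep(c("2_right", "2_left"), length.out = n_subjects)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sched <- build_session(experiment, n_blocks = n_blocks, practice = practice,
                           seed = seeds[2L * i - 1L], counterbalance_arm = arms[i])
    out[[i]] <- simulate_subject(
      sched, params,
      subject_id = offsets$subject_id[i], seed = seeds[2L * i],
      subject_offsets = c(rt = offsets$rt[i], rho = offsets$rho[i],
                          kappa = offsets$kappa[i]))
  }
  structure(list(
    trials = dplyr::bind_rows(out),
    truth = list(params = params, subject_offsets = offsets),
    seed = as.integer(seed)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %s: %d trials, %d subjects (seed %d)\n",
              x$truth$params$experiment, nrow(x$trials),
              length(unique(x$trials$subject_id)), x$seed))
  print(table(x$trials$outcome))
  invisible(x)
}
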