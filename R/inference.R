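#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws (exact for unimodal empirical distributions).  Ties between equally
#' short windows are broken towards the lowest start.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass probability mass in (0, 1).
#' @return numeric `c(lo, hi)`.
#' @examples
#' hdi(rnorm(10000), 0.95)
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI", call. = FALSE)
  s <- sort(draws)
  k <- ceiling(mass * n)
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)              # which.min takes the first (lowest start)
  c(s[i], s[i + k - 1])
}

#' Classify the credibility of an effect
#'
#' An effect is `highly_credible` when its 95% HDI excludes zero,
#' `weakly_credible` when the 95% HDI contains zero but the 50% HDI does
#' not, and `non_credible` when the 50% HDI contains zero.  Interval
#' endpoints equal to zero count as containing zero.
#'
#' @param draws numeric vector of posterior draws of the effect.
#' @return one of `"highly_credible"`, `"weakly_credible"`,
#'   `"non_credible"`.
#' @export
classify_credibility <- function(draws) {
  stopifnot(all(is.finite(draws)))
  h95 <- hdi(draws, 0.95)
  if (!contains_zero(h95)) return("highly_credible")
  h50 <- hdi(draws, 0.50)
  if (!contains_zero(h50)) return("weakly_credible")
  "non_credible"
}

contains_zero <- function(interval) interval[1] <= 0 && interval[2] >= 0

#' Summarise a vector of effect draws
#'
#' @param draws numeric posterior draws of an effect or parameter.
#' @param name label for the summary row.
#' @param scale unit label (`"ms"`, `"probability"`, `"kappa"`, ...).
#' @return one-row tibble of class `effect_summary` with the median, the
#'   95% and 50% HDIs and the credibility verdict.
#' @export
summarise_effect <- function(draws, name = "effect", scale = "") {
  h95 <- hdi(draws, 0.95)
  h50 <- hdi(draws, 0.50)
  out <- tibble::tibble(
    name = name,
    median = stats::median(draws),
    hdi95_lo = h95[1], hdi95_hi = h95[2],
    hdi50_lo = h50[1], hdi50_hi = h50[2],
    credibility = classify_credibility(draws),
    scale = scale
  )
  class(out) <- c("effect_summary", class(out))
  out
}

#' Posterior contrast between conditions
#'
#' Computes a draw-wise difference on the reported scale of the chosen
#' parameter: condition `a` minus condition `b` for `type = "difference"`
#' (e.g. valid minus invalid), or the neutral condition minus the pooled
#' spatial conditions for `type = "neutral_vs_spatial"`.  Pooling averages
#' the valid and invalid linear predictors (unweighted) before the back
#' transformation, so the spatial reference is the latent-scale mean of the
#' two spatial cells.
#'
#' @param post a `posterior_samples` object from [fit_posterior()].
#' @param param `"rt"` (ms scale), `"rho"` (probability scale) or
#'   `"kappa"` (concentration scale).
#' @param a,b condition names for `type = "difference"`.
#' @param type contrast type.
#' @param neutral,spatial condition names for `type = "neutral_vs_spatial"`
#'   (`spatial` must name two conditions).
#' @param name optional label; a descriptive default is built.
#' @return an `effect_summary` row.
#' @export
contrast <- function(post, param = c("rt", "rho", "kappa"),
                     a = NULL, b = NULL,
                     type = c("difference", "neutral_vs_spatial"),
                     neutral = NULL, spatial = NULL, name = NULL) {
  param <- match.arg(param)
  type <- match.arg(type)
  scale <- switch(param, rt = "ms", rho = "probability", kappa = "kappa")
  if (type == "difference") {
    stopifnot(!is.null(a), !is.null(b))
    cd <- condition_draws(post, param)
    check_conditions(c(a, b), colnames(cd))
    d <- cd[, a] - cd[, b]
    name <- name %||% sprintf("%s: %s - %s", param, a, b)
  } else {
    stopifnot(!is.null(neutral), length(spatial) == 2)
    eta <- latent_condition_draws(post, param)
    check_conditions(c(neutral, spatial), colnames(eta))
    inv <- switch(param, rt = exp, rho = stats::plogis, kappa = exp)
    d <- inv(eta[, neutral]) - inv((eta[, spatial[1]] + eta[, spatial[2]]) / 2)
    name <- name %||% sprintf("%s: %s - pooled(%s)", param, neutral,
                              paste(spatial, collapse = ", "))
  }
  summarise_effect(d, name = name, scale = scale)
}

check_conditions <- function(wanted, have) {
  bad <- setdiff(wanted, have)
  if (length(bad)) {
    stop("unknown condition name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Latent-scale (linear-predictor) draws per condition
#'
#' Like [condition_draws()] but without the back transformation: log-ms for
#' reaction time, logit for encoding probability, log for fidelity.
#'
#' @inheritParams condition_draws
#' @return numeric matrix, one column per condition.
#' @export
latent_condition_draws <- function(post, param = c("rt", "rho", "kappa")) {
  param <- match.arg(param)
  pre <- switch(param, rt = "rt", rho = "p", kappa = "k")
  conds <- post$conditions
  a <- post$draws[, paste0("a_", pre)]
  eta <- sapply(conds, function(cc) {
    if (cc == conds[1]) a else a + post$draws[, paste0("b_", pre, ".", cc)]
  })
  colnames(eta) <- conds
  eta
}

#' Standard effect table for a fitted cueing model
#'
#' For each parameter (RT, encoding probability, fidelity): the posterior
#' of every condition on the reported scale, plus valid-minus-invalid
#' contrasts (per SOA for the six-cell exogenous design) and, for the
#' exogenous design, the neutral-versus-spatial fidelity contrast at each
#' SOA.
#'
#' @param post a `posterior_samples` object.
#' @return an `effect_summary` tibble, one row per parameter/effect.
#' @export
effect_summary <- function(post) {
  conds <- post$conditions
  rows <- list()
  for (param in c("rt", "rho", "kappa")) {
    scale <- switch(param, rt = "ms", rho = "probability", kappa = "kappa")
    cd <- condition_draws(post, param)
    for (cc in conds) {
      rows[[length(rows) + 1]] <-
        summarise_effect(cd[, cc], sprintf("%s[%s]", param, cc), scale)
    }
    if (all(c("valid", "invalid") %in% conds)) {
      rows[[length(rows) + 1]] <-
        contrast(post, param, a = "valid", b = "invalid")
    }
    for (soa in c("soa100", "soa800")) {
      va <- paste0(soa, ".valid"); iv <- paste0(soa, ".invalid")
      if (all(c(va, iv) %in% conds)) {
        rows[[length(rows) + 1]] <- contrast(post, param, a = va, b = iv)
      }
    }
  }
  for (soa in c("soa100", "soa800")) {
    ne <- paste0(soa, ".neutral")
    sp <- paste0(soa, c(".valid", ".invalid"))
    if (all(c(ne, sp) %in% conds)) {
      rows[[length(rows) + 1]] <-
        contrast(post, "kappa", type = "neutral_vs_spatial",
                 neutral = ne, spatial = sp)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("effect_summary", class(out))
  out
}
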