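#' Validate a pipeline configuration
#'
#' A configuration is a named list with blocks `experiment`, `simulation`,
#' `preprocess`, `model` and `report`.  Unknown keys anywhere are rejected
#' so that typos fail loudly before any stage runs.
#'
#' @param config named list (e.g. parsed from JSON or YAML with
#'   [read_config()]).
#' @return the validated config, with defaults filled in, of class
#'   `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    experiment = "E1",
    simulation = list(n_subjects = 10L, seed = 1L, n_blocks = NULL,
                      practice = TRUE, params = list()),
    preprocess = list(madm_multiplier = 5, cells = NULL),
    model = list(chains = 4L, warmup = 1000L, draws = 1000L, seed = 1L,
                 priors = list(), method = "mcmc"),
    report = list(masses = c(0.95, 0.5))
  )
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(config, names(defaults), "config")
  for (blk in c("simulation", "preprocess", "model", "report")) {
    check_keys(config[[blk]], names(defaults[[blk]]), blk)
    defaults[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  if (!is.null(config$experiment)) defaults$experiment <- config$experiment
  defaults$experiment <- match.arg(defaults$experiment, c("E1", "E2"))
  defaults$preprocess$cells <- defaults$preprocess$cells %||%
    if (defaults$experiment == "E1") "cue" else "soa-cue"
  defaults$model$method <- match.arg(defaults$model$method, c("mcmc", "mle"))
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  }
  pipeline_config(raw)
}

#' Simulate an experiment and write its artifacts
#'
#' Writes the completed trial CSV and the generating-truth JSON (parameters
#' and realised subject offsets), both stamped with the config hash.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if missing).
#' @return list with `sim` (the `sim_dataset`), `trials_csv`, `truth_json`.
#' @export
run_simulate <- function(config, dir) {
  config <- pipeline_config(unclass(config))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  sm <- config$simulation
  params <- do.call(generative_params,
                    c(list(experiment = config$experiment), sm$params))
  sim <- simulate_experiment(sm$n_subjects, config$experiment, params,
                             seed = sm$seed, n_blocks = sm$n_blocks,
                             practice = sm$practice)
  trials_csv <- file.path(dir, "trials.csv")
  write_trials(sim$trials, trials_csv, config_hash = h)
  truth_json <- file.path(dir, "truth.json")
  truth <- list(
    config_hash = h,
    # named vectors as JSON objects, so names survive the round trip
    params = lapply(unclass(sim$truth$params),
                    function(x) if (is.null(names(x))) x else as.list(x)),
    subject_offsets = sim$truth$subject_offsets
  )
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message(sprintf("simulate: %d trials, %d subjects (seed %d) -> %s",
                  nrow(sim$trials), sm$n_subjects, sm$seed, trials_csv))
  list(sim = sim, trials_csv = trials_csv, truth_json = truth_json)
}

#' Run the full pipeline: simulate, preprocess, fit, report
#'
#' Stages run in order with intermediate artifacts persisted under `dir`:
#' `trials.csv` and `truth.json` (simulation), `clean.csv` and
#' `exclusions.json` (preprocessing), `draws.csv` and `diagnostics.json`
#' (model, MCMC method only) and `effects.csv` (report).  With
#' `model$method = "mle"` the report contains per-condition
#' maximum-likelihood estimates pooled over subjects instead of posterior
#' summaries — a fast path for smoke runs.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory.
#' @return list with the clean data, exclusion report and the effect table
#'   (plus `post` for the MCMC method).
#' @export
run_pipeline <- function(config, dir) {
  config <- pipeline_config(unclass(config))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)

  sim_out <- run_simulate(config, dir)
  pp <- preprocess(sim_out$sim$trials, cells = config$preprocess$cells,
                   multiplier = config$preprocess$madm_multiplier)
  message(sprintf("preprocess: %d -> %d trials", pp$report$n_input,
                  nrow(pp$clean)))
  readr::write_csv(pp$clean, file.path(dir, "clean.csv"))
  jsonlite::write_json(c(list(config_hash = h), unclass(pp$report)),
                       file.path(dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (config$model$method == "mle") {
    eff <- mle_condition_table(pp$clean)
    readr::write_csv(eff, file.path(dir, "effects.csv"))
    message(sprintf("report (MLE path): %d rows -> %s", nrow(eff),
                    file.path(dir, "effects.csv")))
    return(list(clean = pp$clean, report = pp$report, effects = eff))
  }

  md <- config$model
  spec <- model_spec(priors = md$priors, chains = md$chains,
                     warmup = md$warmup, draws = md$draws, seed = md$seed)
  post <- fit_posterior(pp$clean, spec)
  message(sprintf("fit: max split R-hat %.3f",
                  max(post$diagnostics$rhat, na.rm = TRUE)))
  readr::write_csv(tidy_draws(post), file.path(dir, "draws.csv"))
  jsonlite::write_json(
    c(list(config_hash = h),
      lapply(post$diagnostics, function(x) if (is.numeric(x)) as.list(x) else x)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  eff <- effect_summary(post)
  readr::write_csv(eff, file.path(dir, "effects.csv"))
  message(sprintf("report: %d effect rows -> %s", nrow(eff),
                  file.path(dir, "effects.csv")))
  list(clean = pp$clean, report = pp$report, post = post, effects = eff)
}

# Pooled per-condition MLE table (fast path).
mle_condition_table <- function(clean) {
  conds <- infer_conditions(clean$condition)
  rows <- lapply(conds, function(cc) {
    d <- clean[clean$condition == cc, ]
    f <- fit_mle_cell(deg2rad(d$error_deg))
    tibble::tibble(
      condition = cc, n = nrow(d),
      rho_hat = f$rho, kappa_hat = f$kappa,
      rt_median_ms = exp(stats::median(d$log_rt)),
      mle_converged = f$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare fitted effects with the generating truth
#'
#' Re-derives every condition-level generating value from a truth object
#' (as produced by [run_simulate()]) and checks whether each corresponding
#' posterior 95% HDI covers it; valid-minus-invalid contrasts are checked
#' the same way.
#'
#' @param post a `posterior_samples` object.
#' @param truth either the `truth` element of a `sim_dataset` or the path
#'   of a `truth.json`.
#' @return tibble with one row per checked quantity: truth, posterior
#'   median, 95% HDI and a `covered` flag.
#' @export
run_recover <- function(post, truth) {
  if (is.character(truth)) {
    tj <- jsonlite::read_json(truth, simplifyVector = TRUE)
    params <- tj$params
  } else {
    params <- unclass(truth$params)
  }
  conds <- post$conditions
  truth_by <- list(
    rt = unlist(params$rt_median_ms)[conds],
    rho = unlist(params$rho)[conds],
    kappa = unlist(params$kappa)[conds]
  )
  rows <- list()
  for (param in c("rt", "rho", "kappa")) {
    cd <- condition_draws(post, param)
    for (cc in conds) {
      h <- hdi(cd[, cc], 0.95)
      tv <- truth_by[[param]][[cc]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        quantity = sprintf("%s[%s]", param, cc), truth = tv,
        median = stats::median(cd[, cc]), hdi95_lo = h[1], hdi95_hi = h[2],
        covered = h[1] <= tv & tv <= h[2])
    }
    pairs <- valid_invalid_pairs(conds)
    for (p in pairs) {
      d <- cd[, p[1]] - cd[, p[2]]
      h <- hdi(d, 0.95)
      tv <- truth_by[[param]][[p[1]]] - truth_by[[param]][[p[2]]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        quantity = sprintf("%s[%s - %s]", param, p[1], p[2]), truth = tv,
        median = stats::median(d), hdi95_lo = h[1], hdi95_hi = h[2],
        covered = h[1] <= tv & tv <= h[2])
    }
  }
  dplyr::bind_rows(rows)
}

valid_invalid_pairs <- function(conds) {
  if (all(c("valid", "invalid") %in% conds)) {
    return(list(c("valid", "invalid")))
  }
  out <- list()
  for (soa in c("soa100", "soa800")) {
    va <- paste0(soa, ".valid"); iv <- paste0(soa, ".invalid")
    if (all(c(va, iv) %in% conds)) out[[length(out) + 1]] <- c(va, iv)
  }
  out
}
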