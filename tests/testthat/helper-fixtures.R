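# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; nothing is read from disk except the example CSV
# shipped in inst/extdata.

# A clean_dataset with mixture-distributed errors, built without going
# through the simulator (useful for testing the model in isolation).
make_clean <- function(n, rho, kappa, n_subjects = 5, condition = "invalid",
                       rt_location = log(360), rt_sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    enc <- stats::runif(n) < rho
    err <- ifelse(enc, rvonmises(n, kappa), stats::runif(n, -pi, pi))
    out <- tibble::tibble(
      subject_id = sprintf("s%02d", rep_len(seq_len(n_subjects), n)),
      condition = rep_len(condition, n),
      log_rt = stats::rnorm(n, rt_location, rt_sd),
      error_deg = rad2deg(err)
    )
  })
  class(out) <- c("clean_dataset", class(out))
  out
}

# A minimal posterior_samples object with prescribed latent draws, for
# testing inference operations without running the sampler.
make_fake_post <- function(draws, conditions) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 conditions = conditions, n_subjects = NA, n_trials = NA,
                 diagnostics = list()),
            class = "posterior_samples")
}

# Brute-force MADM decision for a single cell: the double-loop oracle.
madm_drop_oracle <- function(log_rt, multiplier = 5) {
  n <- length(log_rt)
  med <- stats::median(log_rt)
  devs <- abs(log_rt - med)
  madm <- stats::median(devs)
  drop <- logical(n)
  for (i in seq_len(n)) drop[i] <- devs[i] > multiplier * madm
  drop
}

example_trials_path <- function() {
  system.file("extdata", "example_trials.csv", package = "cuewheel")
}
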