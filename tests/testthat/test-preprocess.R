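test_that("angular error wraps to (-180, 180] with +180 at the antipode", {
  expect_equal(angular_error(350, 10), 20)
  expect_equal(angular_error(123.4, 123.4), 0)
  expect_equal(angular_error(0, 180), 180)
  expect_equal(angular_error(10, 350), -20)
  # invariant under common rotation
  t <- c(0, 45, 190, 359); r <- c(10, 30, 200, 1)
  expect_equal(angular_error((t + 77) %% 360, (r + 77) %% 360),
               angular_error(t, r))
})

test_that("drop_invalid removes practice and contaminated trials, tallied", {
  toy <- tibble::tibble(
    subject_id = "s01", experiment = "E1",
    block = c(0L, 0L, rep(1L, 8)),
    cue_type = "valid", soa_ms = 800L,
    target_present = c(rep(TRUE, 9), FALSE),
    outcome = c("hit", "hit", rep("hit", 5), "miss", "pre_target",
                "false_alarm"),
    rt_ms = 350, target_colour_deg = 10, response_colour_deg = 20
  )
  out <- drop_invalid(toy)
  expect_equal(nrow(out$trials), 5)
  expect_equal(out$report$n_practice_dropped, 2)
  expect_equal(out$report$n_miss, 1)
  expect_equal(out$report$n_pre_target, 1)
  expect_equal(out$report$n_false_alarm, 1)
  # denominators: 7 post-practice target trials, 1 catch trial
  expect_equal(out$report$frac_miss, 1 / 7)
  expect_equal(out$report$frac_false_alarm, 1 / 1)

  all_hit <- toy[toy$outcome == "hit" & toy$block > 0, ]
  out2 <- drop_invalid(all_hit)
  expect_equal(out2$trials, all_hit)
  expect_equal(out2$report$n_miss + out2$report$n_false_alarm +
                 out2$report$n_pre_target, 0)

  toy$outcome[1] <- NA
  expect_error(drop_invalid(toy), "outcome")
})

test_that("MADM filter matches the hand-computed six-value cell", {
  # median 6.05, deviations .25 .15 .05 .05 .15 2.95, MADM .15, cutoff .75
  lrt <- c(5.8, 5.9, 6.0, 6.1, 6.2, 9.0)
  tr <- tibble::tibble(subject_id = "s01", cue_type = "valid",
                       soa_ms = 800L, rt_ms = exp(lrt))
  out <- madm_filter(tr, cells = "cue")
  expect_equal(nrow(out$trials), 5)
  expect_equal(out$trials$rt_ms, exp(lrt[1:5]))
  expect_equal(out$report$n_madm_outliers, 1)
})

test_that("degenerate and infinite-multiplier cells drop nothing", {
  tr <- tibble::tibble(subject_id = "s01", cue_type = "valid",
                       soa_ms = 800L, rt_ms = rep(350, 6))
  expect_equal(nrow(madm_filter(tr, "cue")$trials), 6)

  tr2 <- tibble::tibble(subject_id = "s01", cue_type = "valid",
                        soa_ms = 800L, rt_ms = c(rep(350, 6), 5000))
  expect_equal(nrow(madm_filter(tr2, "cue", multiplier = Inf)$trials), 7)
  # empty input is a no-op, not an error
  expect_equal(nrow(madm_filter(tr2[0, ], "cue")$trials), 0)
})

test_that("MADM decisions equal the brute-force oracle on random cells", {
  withr::with_seed(77, {
    for (i in 1:200) {
      n <- sample(3:25, 1)
      lrt <- rnorm(n, 5.9, 0.2)
      if (runif(1) < 0.3) lrt[sample(n, 1)] <- lrt[1] + runif(1, 1, 4)
      tr <- tibble::tibble(subject_id = "sX", cue_type = "valid",
                           soa_ms = 800L, rt_ms = exp(lrt))
      kept <- madm_filter(tr, "cue")$trials$rt_ms
      expect_equal(kept, exp(lrt[!madm_drop_oracle(lrt)]))
    }
  })
})

test_that("exclusion decisions are order-invariant", {
  sim <- simulate_experiment(4, "E1", seed = 31, n_blocks = 2)
  shuffled <- withr::with_seed(1, sim$trials[sample(nrow(sim$trials)), ])
  a <- preprocess(sim$trials)
  b <- preprocess(shuffled)
  expect_equal(a$report$n_madm_outliers, b$report$n_madm_outliers)
  expect_equal(dplyr::arrange(a$clean, subject_id, condition, log_rt),
               dplyr::arrange(b$clean, subject_id, condition, log_rt))
})

test_that("to_clean maps retained trials to condition, log RT and error", {
  tr <- tibble::tibble(
    subject_id = "s01", experiment = "E1", block = 1L,
    cue_type = "valid", soa_ms = 800L, target_present = TRUE,
    rt_ms = 350, target_colour_deg = 10, response_colour_deg = 355,
    outcome = "hit")
  cl <- to_clean(tr)
  expect_equal(cl$condition, "valid")
  expect_equal(cl$log_rt, log(350))
  expect_equal(cl$error_deg, -15)

  tr$experiment <- "E2"
  tr$soa_ms <- 100L
  expect_equal(to_clean(tr)$condition, "soa100.valid")

  expect_equal(nrow(to_clean(tr[0, ])), 0)
  tr$rt_ms <- NA
  expect_error(to_clean(tr), "missing fields")
})

test_that("the shipped example CSV round-trips through preprocessing", {
  tr <- read_trials(example_trials_path())
  expect_equal(nrow(tr), 16)
  pp <- preprocess(tr)
  expect_equal(pp$report$n_practice_dropped, 2)
  expect_equal(pp$report$n_miss, 1)
  expect_equal(pp$report$n_false_alarm, 1)
  expect_equal(nrow(pp$clean), 12)
  expect_setequal(pp$clean$error_deg,
                  c(20, -15, 0, 180, 5, -5, 10, -10, 2, -2, 8, -8))
  expect_equal(unique(pp$clean$log_rt), log(350))
  # the MLE fast path runs on the fixture's single condition
  f <- fit_mle_cell(deg2rad(pp$clean$error_deg))
  expect_true(f$rho >= 0 && f$rho <= 1 && f$kappa > 0)
})
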