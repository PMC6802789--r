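test_that("colour responses degenerate correctly at the rho/kappa limits", {
  withr::with_seed(1, {
    r <- sample_colour_response(rep(90, 200), rho = 1, kappa = 1e6)
    expect_true(all(abs(wrap_deg(r - 90)) < 0.5))
  })
  # pure guessing: errors uniform on the circle
  withr::with_seed(2, {
    tgt <- runif(50000, 0, 360)
    r <- sample_colour_response(tgt, rho = 0, kappa = 5)
    err <- angular_error(tgt, r)
    ks <- suppressWarnings(stats::ks.test(err, "punif", -180, 180))
    expect_gt(ks$p.value, 0.01)
  })
  expect_error(sample_colour_response(0, rho = 0.5, kappa = -1))
})

test_that("mixture draws match the quadrature mass in a central window", {
  rho <- 0.5; kappa <- 9.08; n <- 50000
  vm_mass <- integrate(function(x) exp(vm_logpdf(x, kappa)),
                       -pi / 6, pi / 6, rel.tol = 1e-10)$value
  p_expect <- rho * vm_mass + (1 - rho) * (60 / 360)
  withr::with_seed(3, {
    tgt <- runif(n, 0, 360)
    r <- sample_colour_response(tgt, rho, kappa)
    p_obs <- mean(abs(angular_error(tgt, r)) <= 30)
  })
  mc_sd <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_obs - p_expect), 4 * mc_sd)
})

test_that("mixture sampling matches the density (chi-square on 1e5 draws)", {
  rho <- 0.7; kappa <- 5; n <- 1e5
  withr::with_seed(4, {
    tgt <- runif(n, 0, 360)
    err <- deg2rad(angular_error(tgt, sample_colour_response(tgt, rho, kappa)))
  })
  breaks <- seq(-pi, pi, length.out = 37)
  obs <- table(cut(err, breaks))
  p_bin <- vapply(seq_len(36), function(i) {
    integrate(function(x) exp(mixture_logpdf(x, rho, kappa)),
              breaks[i], breaks[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p_bin,
                                            rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})

test_that("shifting target colours shifts responses, leaving errors alone", {
  tgt <- seq(0, 350, by = 10)
  withr::with_seed(5, r1 <- sample_colour_response(tgt, 0.8, 6))
  withr::with_seed(5, r2 <- sample_colour_response((tgt + 123) %% 360, 0.8, 6))
  expect_equal(wrap_deg(r2 - r1), rep(123, length(tgt)), tolerance = 1e-10)
  expect_equal(angular_error(tgt, r1),
               angular_error((tgt + 123) %% 360, r2), tolerance = 1e-10)
})

test_that("reaction times follow the lognormal identities", {
  p0 <- generative_params("E1", rt_log_sd_within = 0)
  withr::with_seed(6, rt <- sample_rt(rep("neutral", 10), p0))
  expect_equal(rt, rep(359.86, 10))

  p <- generative_params("E1", rt_log_sd_within = 0.25)
  withr::with_seed(7, rt <- sample_rt(rep("neutral", 1e5), p))
  # sample median of a lognormal estimates exp(location)
  expect_equal(median(rt), 359.86, tolerance = 0.01)

  # a -0.06 log-ms offset scales the median by exp(-0.06)
  p2 <- generative_params(
    "E1", rt_median_ms = c(invalid = 360, valid = 360 * exp(-0.06),
                           neutral = 360),
    rt_log_sd_within = 0.25)
  withr::with_seed(8, {
    rti <- sample_rt(rep("invalid", 1e5), p2)
    rtv <- sample_rt(rep("valid", 1e5), p2)
  })
  expect_equal(median(rtv) / median(rti), exp(-0.06), tolerance = 0.015)
  expect_error(sample_rt("nope", p), "unknown condition")
})

test_that("contamination-free simulation yields only hits and rejections", {
  p <- generative_params("E1", miss_rate = 0, false_alarm_rate = 0,
                         pre_target_rate = 0)
  sched <- build_session("E1", 1, practice = FALSE, seed = 9)
  tr <- simulate_subject(sched, p, seed = 10)
  expect_true(all(tr$outcome[tr$target_present] == "hit"))
  expect_true(all(tr$outcome[!tr$target_present] == "correct_rejection"))
  expect_true(all(is.finite(tr$rt_ms[tr$target_present])))
  expect_true(all(tr$rt_ms[tr$target_present] > 0))
})

test_that("simulation is reproducible and respects subject spreads", {
  a <- simulate_experiment(3, "E1", seed = 12, n_blocks = 1)
  b <- simulate_experiment(3, "E1", seed = 12, n_blocks = 1)
  expect_identical(a$trials, b$trials)

  p0 <- generative_params("E1", subject_sds = c(rt = 0, rho = 0, kappa = 0))
  s <- simulate_experiment(4, "E1", params = p0, seed = 13, n_blocks = 1)
  expect_true(all(s$truth$subject_offsets$rt == 0))
  expect_true(all(s$truth$subject_offsets$rho == 0))
  expect_true(all(s$truth$subject_offsets$kappa == 0))
})

test_that("cohort-sized simulations have the published per-subject counts", {
  s <- simulate_experiment(2, "E1", seed = 14)
  expect_equal(nrow(s$trials), 2 * 450)   # 420 test + 30 practice
  s2 <- simulate_experiment(2, "E2", seed = 14)
  expect_equal(nrow(s2$trials), 2 * 510)  # 480 test + 30 practice
  expect_setequal(
    unique(s$trials$outcome[s$trials$target_present]),
    intersect(unique(s$trials$outcome), c("hit", "miss", "pre_target")))
  expect_true(all(s$trials$outcome[!s$trials$target_present] %in%
                    c("correct_rejection", "false_alarm")))
})

test_that("von Mises sampler matches its density", {
  withr::with_seed(15, x <- rvonmises(2e4, 2))
  expect_true(all(x > -pi & x <= pi))
  breaks <- seq(-pi, pi, length.out = 19)
  p_bin <- vapply(seq_len(18), function(i) {
    integrate(function(t) exp(vm_logpdf(t, 2)), breaks[i], breaks[i + 1],
              rel.tol = 1e-10)$value
  }, numeric(1))
  chi <- suppressWarnings(stats::chisq.test(
    as.numeric(table(cut(x, breaks))), p = p_bin, rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})
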