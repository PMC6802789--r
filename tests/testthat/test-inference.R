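test_that("hdi matches brute-force and closed-form references", {
  # constant draws collapse to a point
  expect_equal(hdi(rep(3.2, 150), 0.95), c(3.2, 3.2))

  # uniform grid: shortest window of 500 of 1000 points has width 499 and
  # ties resolve to the lowest start
  d <- 0:999
  expect_equal(hdi(d, 0.5), c(0, 499))
  # exhaustive-scan oracle on a random set
  withr::with_seed(31, x <- rexp(501))
  k <- ceiling(0.8 * length(x))
  s <- sort(x)
  widths <- vapply(seq_len(length(x) - k + 1),
                   function(i) s[i + k - 1] - s[i], numeric(1))
  i_best <- which.min(widths)
  expect_equal(hdi(x, 0.8), c(s[i_best], s[i_best + k - 1]))

  withr::with_seed(32, z <- rnorm(1e6))
  h <- hdi(z, 0.95)
  expect_equal(h[1], -1.95996, tolerance = 0.02)
  expect_equal(h[2], 1.95996, tolerance = 0.02)

  expect_error(hdi(rnorm(50), 0.95), "at least 100")
})

test_that("hdi is monotone in mass", {
  withr::with_seed(33, {
    for (i in 1:20) {
      x <- switch(1 + i %% 3, rnorm(400), rexp(400), rbeta(400, 2, 5))
      h50 <- hdi(x, 0.5); h95 <- hdi(x, 0.95)
      expect_gte(h50[1], h95[1])
      expect_lte(h50[2], h95[2])
    }
  })
})

test_that("credibility taxonomy reproduces the reported interval patterns", {
  # large RT benefit: 95% HDI well below zero
  withr::with_seed(34, d1 <- rnorm(4000, -21.70, 2.72))
  expect_equal(hdi(d1, 0.95), c(-27.15, -16.47), tolerance = 0.05)
  expect_equal(classify_credibility(d1), "highly_credible")

  # fidelity benefit: 95% HDI spans zero, 50% HDI does not
  withr::with_seed(35, d2 <- rnorm(4000, 0.45, 0.31))
  expect_equal(classify_credibility(d2), "weakly_credible")
  h50 <- hdi(d2, 0.5)
  expect_equal(h50, c(0.26, 0.67), tolerance = 0.1)

  # null effect: 50% HDI spans zero
  withr::with_seed(36, d3 <- rnorm(4000, -0.02, 0.29))
  expect_equal(classify_credibility(d3), "non_credible")

  # zero endpoints count as containing zero: 95% HDI is [0, 1] here while
  # the 50% HDI collapses onto the spike at 1
  expect_equal(classify_credibility(c(rep(0, 10), rep(1, 110))),
               "weakly_credible")
})

test_that("credibility is invariant to draw order and positive rescaling", {
  withr::with_seed(37, d <- rnorm(500, 1.2, 1))
  lab <- classify_credibility(d)
  expect_equal(classify_credibility(rev(d)), lab)
  expect_equal(classify_credibility(sample(d)), lab)
  expect_equal(classify_credibility(d * 1000), lab)
  expect_equal(classify_credibility(d * 1e-4), lab)
})

test_that("contrasts difference draws on the reported scale", {
  n <- 400
  withr::with_seed(38, a_k <- rnorm(n, log(9), 0.05))
  # condition B exceeds A by exactly 5 on the kappa scale, every draw
  b_valid <- log(exp(a_k) + 5) - a_k
  draws <- cbind(a_k = a_k, `b_k.valid` = b_valid)
  post <- make_fake_post(draws, c("invalid", "valid"))

  eff <- contrast(post, "kappa", a = "valid", b = "invalid")
  expect_equal(eff$median, 5)
  expect_equal(eff$hdi95_hi - eff$hdi95_lo, 0)
  expect_equal(eff$credibility, "highly_credible")

  # identical conditions: exact zero, non-credible
  draws0 <- cbind(a_k = a_k, `b_k.valid` = rep(0, n))
  post0 <- make_fake_post(draws0, c("invalid", "valid"))
  eff0 <- contrast(post0, "kappa", a = "valid", b = "invalid")
  expect_equal(eff0$median, 0)
  expect_equal(eff0$credibility, "non_credible")

  # antisymmetry
  eff_ab <- contrast(post, "kappa", a = "valid", b = "invalid")
  eff_ba <- contrast(post, "kappa", a = "invalid", b = "valid")
  expect_equal(eff_ab$median, -eff_ba$median)
  expect_equal(eff_ab$hdi95_lo, -eff_ba$hdi95_hi)

  expect_error(contrast(post, "kappa", a = "valid", b = "nope"),
               "unknown condition")
})

test_that("the neutral-vs-spatial contrast pools on the latent scale", {
  n <- 200
  a_k <- rep(log(10), n)
  draws <- cbind(a_k = a_k,
                 `b_k.soa100.valid` = rep(0.2, n),
                 `b_k.soa100.neutral` = rep(0.4, n))
  post <- make_fake_post(draws,
                         c("soa100.invalid", "soa100.valid", "soa100.neutral"))
  eff <- contrast(post, "kappa", type = "neutral_vs_spatial",
                  neutral = "soa100.neutral",
                  spatial = c("soa100.valid", "soa100.invalid"))
  expected <- 10 * exp(0.4) - 10 * exp(0.1)  # pooled latent mean of 0 and 0.2
  expect_equal(eff$median, expected)
})

test_that("effect summaries keep nested HDIs and the median inside", {
  withr::with_seed(39, {
    draws <- cbind(a_rt = rnorm(300, log(360), 0.02),
                   `b_rt.valid` = rnorm(300, -0.05, 0.01),
                   a_p = rnorm(300, 4, 0.3), `b_p.valid` = rnorm(300, 1, 0.4),
                   a_k = rnorm(300, log(9), 0.05),
                   `b_k.valid` = rnorm(300, 0.05, 0.03))
  })
  post <- make_fake_post(draws, c("invalid", "valid"))
  eff <- effect_summary(post)
  expect_true(all(eff$hdi50_lo >= eff$hdi95_lo))
  expect_true(all(eff$hdi50_hi <= eff$hdi95_hi))
  expect_true(all(eff$median >= eff$hdi95_lo & eff$median <= eff$hdi95_hi))
  expect_true(all(c("rt[invalid]", "rt: valid - invalid",
                    "rho[valid]", "kappa[valid]") %in% eff$name))
})
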