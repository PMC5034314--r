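test_that("vb_mean matches hand-computed values and boundary behaviour", {
  # age 0 returns size at age zero exactly, for assorted parameter sets
  for (p in list(c(0.1, 3000, 900), c(0.5, 2000, 500), c(1.2, 400, 10))) {
    expect_identical(vb_mean(0, p[1], p[2], p[3]), p[3])
  }
  # asymptote
  expect_equal(vb_mean(1000, 0.12, 2995, 880), 2995, tolerance = 1e-12)
  # direct evaluation: 2995 - 2115 * exp(-0.6)
  expect_equal(vb_mean(5, 0.12, 2995, 880), 2995 - 2115 * exp(-0.6),
               tolerance = 1e-12)
  expect_equal(vb_mean(5, 0.12, 2995, 880), 1834.2634, tolerance = 1e-4)
})

test_that("vb_mean is strictly increasing in age and bounded by dw_inf", {
  set.seed(101)
  for (i in 1:50) {
    dw0 <- runif(1, 100, 1500)
    dw_inf <- dw0 + runif(1, 100, 3000)
    k <- runif(1, 0.01, 1.5)
    w <- vb_mean(0:50, k, dw_inf, dw0)
    expect_true(all(diff(w) >= 0))
    expect_true(all(w <= dw_inf))      # saturates to within float precision
    expect_true(all(diff(w[1:10]) > 0))  # strictly increasing pre-plateau
    expect_true(all(w >= dw0))
  }
})

test_that("vb_mean and vb_loglik reject invalid parameters", {
  expect_error(vb_mean(5, -0.1, 3000, 900), "positive")
  expect_error(vb_mean(5, 0.1, 900, 3000), "dw_inf > dw0")
  expect_error(vb_mean(-1, 0.1, 3000, 900), "non-negative")
  d <- data.frame(age_years = 1:5, disc_width_mm = seq(1000, 2000, 250))
  expect_error(vb_loglik(d, 0.1, 3000, 900, -1), "sigma2")
})

test_that("vb_loglik equals an independent normal log-density sum", {
  # record exactly on the curve: density of a zero residual
  s2 <- 0.04
  d0 <- data.frame(age_years = 3,
                   disc_width_mm = vb_mean(3, 0.2, 2500, 800))
  expect_equal(vb_loglik(d0, 0.2, 2500, 800, s2),
               -0.5 * log(2 * pi * s2), tolerance = 1e-12)

  # brute-force oracle on fixed records
  d <- data.frame(age_years = c(1, 4, 9),
                  disc_width_mm = c(1100, 1800, 2500))
  mu <- 2995 - (2995 - 880) * exp(-0.12 * d$age_years)
  oracle <- sum(-0.5 * log(2 * pi * 0.01) -
                  (log(d$disc_width_mm) - log(mu))^2 / (2 * 0.01))
  expect_equal(vb_loglik(d, 0.12, 2995, 880, 0.01), oracle,
               tolerance = 1e-10)

  # additivity: duplicating every record doubles the log likelihood
  expect_equal(vb_loglik(rbind(d, d), 0.12, 2995, 880, 0.01),
               2 * vb_loglik(d, 0.12, 2995, 880, 0.01), tolerance = 1e-10)
})

test_that("vb_loglik is maximised at the generating parameters", {
  truth <- c(k = 0.15, dw_inf = 2800, dw0 = 850)
  d <- data.frame(age_years = 0:14,
                  disc_width_mm = vb_mean(0:14, truth["k"],
                                          truth["dw_inf"], truth["dw0"]))
  ll_true <- vb_loglik(d, truth["k"], truth["dw_inf"], truth["dw0"], 0.01)
  for (dk in c(-0.04, -0.02, 0.02, 0.04))
    expect_lt(vb_loglik(d, truth["k"] + dk, truth["dw_inf"],
                        truth["dw0"], 0.01), ll_true)
  for (dw in c(-300, -100, 100, 300))
    expect_lt(vb_loglik(d, truth["k"], truth["dw_inf"] + dw,
                        truth["dw0"], 0.01), ll_true)
})

test_that("prior presets match their tabled distributions", {
  pr <- vb_priors("strong")
  expect_equal(pr$k[c("shape1", "shape2")],
               list(shape1 = 1.05, shape2 = 1.5))
  expect_equal(pr$kappa$shape / pr$kappa$rate, 1000 / 990)
  expect_equal(prior_mean(pr, "kappa"), 1000 / 990)
  expect_equal(c(pr$kappa$lower, pr$kappa$upper), c(0.7, 1.3))
  expect_equal(pr$dw_inf$sd, 100)
  expect_equal(pr$sigma2$scale, 30000)
  expect_equal(prior_mean(pr, "dw_inf"), 3100 * 1000 / 990)

  prw <- vb_priors("weaker")
  expect_equal(prw$kappa$shape / prw$kappa$rate, 200 / 198)
  expect_equal(prw$dw_inf$sd, 400)
  expect_equal(prw$dw0$sd, 300)

  pru <- vb_priors("uninformative")
  for (p in c("k", "dw_inf", "dw0", "kappa"))
    expect_identical(pru[[p]]$dist, "uniform")
  expect_equal(c(pru$k$lower, pru$k$upper), c(0, 2))
  expect_equal(c(pru$dw_inf$lower, pru$dw_inf$upper), c(0, 4000))
  expect_equal(c(pru$dw0$lower, pru$dw0$upper), c(0, 2000))
  expect_equal(c(pru$kappa$lower, pru$kappa$upper), c(0.7, 1.3))
  expect_identical(pru$sigma2$dist, "half_cauchy")

  expect_error(vb_priors("Strong "), "unknown prior preset")
  expect_error(vb_priors("flat"), "unknown prior preset")
})

test_that("posterior_summary computes equal-tailed intervals", {
  # constant draws collapse to a point
  s <- posterior_summary(rep(2.5, 2000))
  expect_equal(unlist(s[c("mean", "ci_low", "ci_high")], use.names = FALSE),
               c(2.5, 2.5, 2.5))

  # uniform grid: closed-form mean and quantiles
  g <- posterior_summary((1:10000) / 10000)
  expect_equal(g$mean, 0.50005, tolerance = 1e-10)
  expect_lt(abs(g$ci_low - 0.025), 2e-4)
  expect_lt(abs(g$ci_high - 0.975), 2e-4)

  # ordering invariant on random draw sets
  set.seed(7)
  for (i in 1:20) {
    x <- rlnorm(500, runif(1, -1, 1), runif(1, 0.1, 2))
    s <- posterior_summary(x)
    expect_lte(s$ci_low, s$mean + 1e-12)
    expect_lte(s$ci_low, s$ci_high)
  }
  expect_error(posterior_summary(numeric(0)), "no draws")
})
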