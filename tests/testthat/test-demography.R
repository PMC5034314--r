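test_that("natural_mortality is the reciprocal of average lifespan", {
  expect_equal(natural_mortality(5.5, 17.5), 2 / 23)
  expect_equal(natural_mortality(5, 15), 0.1)
  expect_equal(natural_mortality(6, 20), 2 / 26)
  expect_error(natural_mortality(0, 10), "alpha_mat")
  expect_error(natural_mortality(10, 5), "alpha_mat")
})

test_that("survival_to_maturity is exponential survivorship", {
  expect_equal(survival_to_maturity(0, 5), 1)
  expect_equal(survival_to_maturity(0.087, 5.5), exp(-0.4785),
               tolerance = 1e-12)
  # decreasing in both arguments over a grid
  grid <- expand.grid(m = seq(0.05, 0.3, 0.05), a = seq(2, 10, 2))
  l <- survival_to_maturity(grid$m, grid$a)
  expect_true(all(l > 0 & l <= 1))
  m_mat <- matrix(l, nrow = 6)  # rows: m increasing; cols: a increasing
  expect_true(all(apply(m_mat, 2, diff) < 0))
  expect_true(all(apply(m_mat, 1, diff) < 0))
  expect_error(survival_to_maturity(-0.1, 5), "m")
})

test_that("solve_rmax returns the Euler-Lotka root to tolerance", {
  # constructed zero-growth case: g(0) = 0 analytically
  m <- 0.1; amat <- 5
  b0 <- (1 - exp(-m)) * exp(m * amat)
  expect_lt(abs(solve_rmax(b0, amat, m)), 1e-8)

  # median life-history inputs
  r <- solve_rmax(0.375, 5.5, 2 / 23)
  expect_equal(r, 0.077, tolerance = 0.01)
  expect_equal(r, bisect_rmax_oracle(0.375, 5.5, 2 / 23),
               tolerance = 1e-8)
  expect_lt(abs(el_residual(r, 0.375, 5.5, 2 / 23)), 1e-10)

  expect_error(solve_rmax(-1, 5, 0.1), "'b'")
  expect_error(solve_rmax(0.3, 0.5, 0.1), "alpha_mat")
})

test_that("r_max is increasing in fecundity and decreasing in mortality", {
  expect_gt(solve_rmax(0.5, 5.5, 2 / 23), solve_rmax(0.375, 5.5, 2 / 23))
  for (b in c(0.3, 0.5, 1, 2)) {
    for (amat in c(3, 5.5, 8)) {
      r_seq <- solve_rmax(b, amat, c(0.05, 0.1, 0.2, 0.3))
      expect_true(all(diff(r_seq) < 0))
    }
    r_b <- vapply(c(0.05, 0.15, 0.25),
                  function(m) solve_rmax(b + 0.1, 5, m) -
                    solve_rmax(b, 5, m), 0)
    expect_true(all(r_b > 0))
  }
})

test_that("solve_rmax agrees with a bisection oracle across a grid", {
  grid <- expand.grid(b = c(0.25, 0.5, 1, 2, 3),
                      amat = c(2, 4, 5.5, 8, 16),
                      m = c(0.04, 0.087, 0.15, 0.3))
  for (i in seq_len(nrow(grid))) {
    r <- solve_rmax(grid$b[i], grid$amat[i], grid$m[i])
    expect_equal(r, bisect_rmax_oracle(grid$b[i], grid$amat[i],
                                       grid$m[i]), tolerance = 1e-8)
    expect_lt(abs(el_residual(r, grid$b[i], grid$amat[i], grid$m[i])),
              1e-10)
  }
})

test_that("rmax_mc draws honour ranges, determinism, and rejection", {
  mc <- rmax_mc(n_draws = 500, seed = 4)
  d <- mc$draws
  expect_true(all(d$b >= 0.25 & d$b <= 0.5))
  expect_true(all(d$alpha_mat >= 5 & d$alpha_mat <= 6))
  expect_true(all(d$alpha_max >= 15 & d$alpha_max <= 20))
  expect_equal(d$omega, (d$alpha_mat + d$alpha_max) / 2)
  expect_equal(d$m, 1 / d$omega)
  expect_equal(d$l_mat, exp(-d$m * d$alpha_mat))
  expect_true(all(abs(el_residual(d$r_max, d$b, d$alpha_mat, d$m)) <
                    1e-10))
  # summaries recomputable from draws
  expect_equal(mc$summary$median[mc$summary$quantity == "r_max"],
               median(d$r_max))

  mc2 <- rmax_mc(n_draws = 500, seed = 4)
  expect_identical(mc$draws, mc2$draws)

  # zero-width ranges collapse to the deterministic solution
  pt <- rmax_mc(b_range = c(0.375, 0.375),
                alpha_mat_range = c(5.5, 5.5),
                alpha_max_range = c(17.5, 17.5), n_draws = 50, seed = 1)
  expect_true(all(pt$draws$r_max == solve_rmax(0.375, 5.5, 2 / 23)))

  # overlapping maturity/longevity ranges force rejections
  ov <- rmax_mc(alpha_mat_range = c(5, 16), alpha_max_range = c(15, 20),
                n_draws = 2000, seed = 2)
  expect_gt(ov$n_rejected, 0)
  expect_true(all(ov$draws$alpha_mat < ov$draws$alpha_max))
  expect_error(rmax_mc(alpha_mat_range = c(25, 30)), "admissible")
})

test_that("rmax_batch reproduces per-row Monte Carlo and flags bad rows", {
  tab <- data.frame(species = c("devil ray", "basking-shark-like"),
                    b_low = c(0.25, 3), b_high = c(0.5, 3),
                    alpha_mat_low = c(5, 16), alpha_mat_high = c(6, 16),
                    alpha_max_low = c(15, 50), alpha_max_high = c(20, 50))
  res <- rmax_batch(tab, n_draws = 400, seed = 100)
  expect_equal(nrow(res), 2L)
  # first row equals a direct rmax_mc call at the derived sub-seed
  direct <- rmax_mc(c(0.25, 0.5), c(5, 6), c(15, 20), n_draws = 400,
                    seed = 100)
  expect_equal(res$rmax_median[1],
               direct$summary$median[direct$summary$quantity == "r_max"])
  # point-value row is deterministic and matches the bisection oracle
  expect_equal(res$rmax_median[2],
               bisect_rmax_oracle(3, 16, 2 / 66), tolerance = 1e-8)

  bad <- rbind(tab, data.frame(species = "broken", b_low = -1, b_high = 1,
                               alpha_mat_low = 5, alpha_mat_high = 6,
                               alpha_max_low = 15, alpha_max_high = 20))
  expect_warning(res2 <- rmax_batch(bad, n_draws = 50, seed = 1),
                 "broken")
  expect_equal(attr(res2, "failed"), "broken")
  expect_equal(nrow(res2), 2L)
})
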