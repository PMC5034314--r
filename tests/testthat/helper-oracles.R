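# Independent oracles used across the suite.

# OLS slope of log(count) on age via stats::lm (independent of the
# closed-form slope used inside catch_curve)
lm_z_oracle <- function(comp) {
  keep <- comp$count > 0
  peak <- comp$age[which.max(comp$count)]
  d <- comp[keep & comp$age >= peak, ]
  -unname(coef(stats::lm(log(count) ~ age, data = d))["age"])
}

# plain bisection root of the Euler-Lotka residual, independent of
# solve_rmax's uniroot path
bisect_rmax_oracle <- function(b, alpha_mat, m, lo = -1, hi = 5,
                               tol = 1e-12) {
  g <- function(r)
    exp(r * alpha_mat) - exp(-m) * exp(r * (alpha_mat - 1)) -
      exp(-m * alpha_mat) * b
  stopifnot(g(lo) * g(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Euler-Lotka residual
el_residual <- function(r, b, alpha_mat, m)
  exp(r * alpha_mat) - exp(-m) * exp(r * (alpha_mat - 1)) -
    exp(-m * alpha_mat) * b

# expand an age-composition table back to one age per individual
comp_to_ages <- function(comp) rep(comp$age, comp$count)
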