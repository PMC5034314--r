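#' Simulate a length-at-age sample
#'
#' Generates aged individuals with the statistical structure the growth
#' model assumes: integer ages uniform over \code{age_range} (band counts
#' carry no mortality signal here, so growth fixtures stay decoupled from
#' the mortality modules) and disc widths with multiplicative lognormal
#' error around the von Bertalanffy mean,
#' \eqn{DW = \exp(\ln \mu_a + \epsilon)}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}.  An optional size window emulates a fishery that never
#' lands the smallest or largest animals: records outside the window are
#' rejected and redrawn (age and width together), and the rejection count
#' is attached as attribute \code{"n_rejected"}.
#'
#' Defaults imitate the published Spinetail Devil Ray sample: about 60
#' animals, ages 0-14, landings restricted to 1100-2400 mm DW, around a
#' curve with slow growth (k = 0.12 year^-1) and an asymptote near the
#' species maximum.
#'
#' @param n sample size (default 60).
#' @param k,dw_inf,dw0 true growth parameters (see [vb_mean()]).
#' @param sigma2 log-scale error variance (default 0.01).
#' @param age_range integer age bounds, inclusive (default \code{c(0, 14)}).
#' @param size_window optional \code{c(min, max)} disc-width truncation in
#'   mm; \code{NULL} for no truncation.
#' @param seed optional integer seed; same seed, same dataset.
#' @return data frame with columns \code{age_years}, \code{disc_width_mm};
#'   attribute \code{"n_rejected"} counts window rejections.
#' @export
sim_length_at_age <- function(n = 60, k = 0.12, dw_inf = 2995, dw0 = 880,
                              sigma2 = 0.01, age_range = c(0, 14),
                              size_window = c(1100, 2400), seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length(age_range) == 2L,
            age_range[1] >= 0, age_range[2] >= age_range[1])
  check_growth_params(k, dw_inf, dw0, sigma2)
  if (!is.null(size_window)) {
    stopifnot(length(size_window) == 2L, size_window[1] < size_window[2])
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ages_grid <- seq.int(age_range[1], age_range[2])
  acc_age <- integer(0); acc_dw <- numeric(0)
  n_rejected <- 0L
  repeat {
    need <- n - length(acc_age)
    if (need == 0L) break
    m <- max(need, 100L)
    a <- ages_grid[sample.int(length(ages_grid), m, replace = TRUE)]
    dw <- exp(log(vb_mean(a, k, dw_inf, dw0)) +
                stats::rnorm(m, 0, sqrt(sigma2)))
    keep <- if (is.null(size_window)) rep(TRUE, m)
            else dw >= size_window[1] & dw <= size_window[2]
    n_rejected <- n_rejected + sum(!keep)
    acc_age <- c(acc_age, a[keep])[seq_len(min(n, length(acc_age) +
                                                 sum(keep)))]
    acc_dw <- c(acc_dw, dw[keep])[seq_len(length(acc_age))]
    if (n_rejected > 100L * n && length(acc_age) < n &&
        n_rejected / (n_rejected + length(acc_age)) > 0.99)
      stop("size window rejects more than 99% of simulated records; ",
           "widen the window or change the growth parameters")
  }
  structure(data.frame(age_years = acc_age[seq_len(n)],
                       disc_width_mm = acc_dw[seq_len(n)]),
            n_rejected = n_rejected)
}

# logistic selectivity reaching exactly 1 at the full-recruitment age;
# steepness = Inf gives a knife edge
selectivity_ogive <- function(age, age_full, steepness) {
  d <- age - age_full
  s <- ifelse(d >= 0, 1, 2 * stats::plogis(steepness * d))
  s[!is.finite(s)] <- 0  # Inf * negative underflow guard
  s
}

#' Simulate an age-composition sample from a fished population
#'
#' Expected catch proportions at age follow
#' \eqn{p_a \propto s(a)\, e^{-(M+F) a}}, with \eqn{s(a)} a logistic
#' selectivity ogive that equals 1 from the full-recruitment age upward
#' (ascending limb below it; \code{steepness = Inf} is knife-edge).
#' \code{n_sampled} individuals are then drawn multinomially, mimicking
#' an opportunistically sampled catch.
#'
#' @param m,f natural and fishing mortality (year^-1), >= 0.
#' @param sel_age_full age at full recruitment to the gear (years).
#' @param sel_steepness logistic steepness of the ascending limb
#'   (default \code{Inf}, knife-edge).
#' @param max_age oldest age class simulated (default 20).
#' @param n_sampled number of individuals drawn (default 60).
#' @param seed optional integer seed.
#' @return an [age_composition()] table whose counts sum to
#'   \code{n_sampled}.
#' @export
sim_age_composition <- function(m = 0.087, f = 0.163, sel_age_full = 2,
                                sel_steepness = Inf, max_age = 20,
                                n_sampled = 60, seed = NULL) {
  stopifnot(m >= 0, f >= 0, max_age >= 1, n_sampled >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ages <- 0:max_age
  p <- selectivity_ogive(ages, sel_age_full, sel_steepness) *
    exp(-(m + f) * ages)
  if (all(p == 0)) stop("all catch proportions are zero")
  counts <- as.integer(stats::rmultinom(1, n_sampled, p))
  structure(data.frame(age = ages, count = counts),
            class = c("age_comp", "data.frame"))
}

#' Simulate a fished population's age structure
#'
#' Deterministic exponential cohort decay: survivorship declines at the
#' natural rate M before recruitment to the gear and at M + F from the
#' full-recruitment age onward (per-age fishing mortality is
#' \eqn{F\, s(a)} under a logistic ogive).  Returns the fished equilibrium
#' age structure, a year-by-age trajectory started from the unfished
#' equilibrium (constant unit recruitment), the noise-free catch-at-age,
#' and a multinomial catch sample.  Fitting a catch curve to the
#' noise-free equilibrium catch recovers M + F exactly under knife-edge
#' selectivity, which is how the package demonstrates that a steep right
#' limb can arise from fishing alone.
#'
#' @inheritParams sim_age_composition
#' @param n_years years of trajectory to record (default 50).
#' @return list with \code{ages}, \code{abundance} (fished equilibrium),
#'   \code{catch} (noise-free catch-at-age), \code{trajectory}
#'   (\code{n_years} x ages matrix), and \code{sample} (an
#'   [age_composition()] of \code{n_sampled} individuals).
#' @export
sim_fished_population <- function(m = 0.087, f = 0.163, sel_age_full = 2,
                                  sel_steepness = Inf, max_age = 20,
                                  n_sampled = 60, n_years = 50,
                                  seed = NULL) {
  stopifnot(m >= 0, f >= 0, max_age >= 1, n_years >= 1, n_sampled >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ages <- 0:max_age
  sel <- selectivity_ogive(ages, sel_age_full, sel_steepness)
  z_at_age <- m + f * sel
  surv_unfished <- exp(-cumsum(c(0, rep(m, max_age))))
  # equilibrium under fishing: survival to age a is the product of
  # year-by-year survival at the total rates experienced along the cohort
  surv_fished <- exp(-cumsum(c(0, z_at_age[-length(z_at_age)])))
  traj <- matrix(NA_real_, n_years, length(ages),
                 dimnames = list(NULL, ages))
  N <- surv_unfished
  for (t in seq_len(n_years)) {
    N <- c(1, (N * exp(-z_at_age))[-length(N)])
    traj[t, ] <- N
  }
  catch <- sel * surv_fished
  sample_comp <- structure(
    data.frame(age = ages,
               count = as.integer(stats::rmultinom(1, n_sampled, catch))),
    class = c("age_comp", "data.frame"))
  list(ages = ages, abundance = surv_fished, catch = catch,
       trajectory = traj, sample = sample_comp)
}
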