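#' Prior presets for the Bayesian von Bertalanffy growth model
#'
#' Builds the prior specification for the five sampled quantities
#' (\code{k}, \code{dw_inf}, \code{dw0}, \code{kappa}, \code{sigma2}) under
#' one of three named presets.  The informative presets encode what is
#' known about the species outside the sample: the prior on the asymptotic
#' width is centred on \code{dw_max * kappa}, where \code{kappa} is a
#' hyperparameter converting the observed maximum size of the species to
#' its asymptotic size, given a gamma hyperprior with mean about 1.01 and
#' hard bounds \eqn{[0.7, 1.3]}; the prior on \code{dw0} is centred on the
#' reported size at birth (880 mm DW); and \code{k} gets a beta prior that
#' gently favours slow growth.  The \code{"uninformative"} preset replaces
#' all of these with bounded uniforms.  In every preset the log-scale error
#' variance \code{sigma2} carries a half-Cauchy(0, 30000) prior.
#'
#' Normal priors are parameterised as (mean, sd); gamma priors as
#' (shape, rate), so the strong-preset \code{kappa} hyperprior
#' Gamma(1000, 990) has mean 1000/990.
#'
#' @param preset one of \code{"strong"}, \code{"weaker"},
#'   \code{"uninformative"} (case sensitive, no padding).
#' @param dw_max observed maximum disc width of the species (mm), used to
#'   centre the \code{dw_inf} prior in the informative presets. Default
#'   3100 mm, the largest reported Spinetail Devil Ray.
#' @return an object of class \code{"vb_priors"}: a list with one entry per
#'   parameter (each a named distribution with its numeric parameters) plus
#'   \code{preset} and \code{dw_max}.
#' @seealso [prior_mean()], [fit_vbgm()]
#' @examples
#' pr <- vb_priors("strong")
#' prior_mean(pr, "kappa")  # 1000/990
#' @export
vb_priors <- function(preset = c("strong", "weaker", "uninformative"),
                      dw_max = 3100) {
  if (!is.character(preset) || length(preset) < 1L ||
      !(preset[1L] %in% c("strong", "weaker", "uninformative")))
    stop("unknown prior preset: ",
         deparse(if (length(preset)) preset[1L] else character()),
         " (expected one of \"strong\", \"weaker\", \"uninformative\")")
  preset <- preset[1L]
  if (!is.finite(dw_max) || dw_max <= 0) stop("'dw_max' must be positive")
  spec <- switch(preset,
    strong = list(
      k      = list(dist = "beta", shape1 = 1.05, shape2 = 1.5),
      dw_inf = list(dist = "normal_kappa", sd = 100),
      dw0    = list(dist = "normal", mean = 880, sd = 200),
      kappa  = list(dist = "gamma", shape = 1000, rate = 990,
                    lower = 0.7, upper = 1.3),
      sigma2 = list(dist = "half_cauchy", scale = 30000)),
    weaker = list(
      k      = list(dist = "beta", shape1 = 1.05, shape2 = 1.1),
      dw_inf = list(dist = "normal_kappa", sd = 400),
      dw0    = list(dist = "normal", mean = 880, sd = 300),
      kappa  = list(dist = "gamma", shape = 200, rate = 198,
                    lower = 0.7, upper = 1.3),
      sigma2 = list(dist = "half_cauchy", scale = 30000)),
    uninformative = list(
      k      = list(dist = "uniform", lower = 0, upper = 2),
      dw_inf = list(dist = "uniform", lower = 0, upper = 4000),
      dw0    = list(dist = "uniform", lower = 0, upper = 2000),
      kappa  = list(dist = "uniform", lower = 0.7, upper = 1.3),
      sigma2 = list(dist = "half_cauchy", scale = 30000)))
  structure(c(spec, list(preset = preset, dw_max = dw_max)),
            class = "vb_priors")
}

#' @export
print.vb_priors <- function(x, ...) {
  cat("von Bertalanffy prior preset:", x$preset,
      sprintf("(dw_max = %g mm)\n", x$dw_max))
  for (p in c("k", "dw_inf", "dw0", "kappa", "sigma2")) {
    e <- x[[p]]
    pars <- e[setdiff(names(e), "dist")]
    cat(sprintf("  %-7s ~ %s(%s)\n", p, e$dist,
                paste(sprintf("%s=%g", names(pars), unlist(pars)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Analytic mean of a marginal prior
#'
#' For the \code{dw_inf} entry of the informative presets (normal centred
#' on \code{dw_max * kappa}) the mean is reported at the \code{kappa}
#' hyperprior mean; truncation of the \code{kappa} gamma to \eqn{[0.7,1.3]}
#' is ignored (the untruncated mass outside the bounds is negligible for
#' the tabled shapes).  The half-Cauchy has no mean and returns \code{NA}.
#'
#' @param priors a \code{"vb_priors"} object.
#' @param param one of \code{"k"}, \code{"dw_inf"}, \code{"dw0"},
#'   \code{"kappa"}, \code{"sigma2"}.
#' @return scalar prior mean (or \code{NA} where undefined).
#' @export
prior_mean <- function(priors, param) {
  stopifnot(inherits(priors, "vb_priors"))
  e <- priors[[match.arg(param, c("k", "dw_inf", "dw0", "kappa", "sigma2"))]]
  switch(e$dist,
    beta         = e$shape1 / (e$shape1 + e$shape2),
    normal       = e$mean,
    normal_kappa = priors$dw_max * prior_mean(priors, "kappa"),
    gamma        = e$shape / e$rate,
    uniform      = (e$lower + e$upper) / 2,
    half_cauchy  = NA_real_)
}

# log prior density (unnormalised where truncated) at a named parameter
# vector; -Inf outside support. The joint support constraint
# dw_inf > dw0 > 0 is part of the model, enforced here as well.
vb_log_prior <- function(theta, priors) {
  k <- theta[["k"]]; dw_inf <- theta[["dw_inf"]]; dw0 <- theta[["dw0"]]
  kappa <- theta[["kappa"]]; sigma2 <- theta[["sigma2"]]
  if (!all(is.finite(c(k, dw_inf, dw0, kappa, sigma2)))) return(-Inf)
  if (k <= 0 || dw0 <= 0 || dw_inf <= dw0 || sigma2 <= 0) return(-Inf)
  lp <- 0
  for (p in c("k", "dw_inf", "dw0", "kappa", "sigma2")) {
    e <- priors[[p]]
    x <- theta[[p]]
    d <- switch(e$dist,
      beta = stats::dbeta(x, e$shape1, e$shape2, log = TRUE),
      normal = stats::dnorm(x, e$mean, e$sd, log = TRUE),
      normal_kappa = stats::dnorm(x, priors$dw_max * kappa, e$sd,
                                  log = TRUE),
      gamma = if (x < e$lower || x > e$upper) -Inf
              else stats::dgamma(x, e$shape, rate = e$rate, log = TRUE),
      uniform = stats::dunif(x, e$lower, e$upper, log = TRUE),
      half_cauchy = if (x < 0) -Inf
                    else stats::dcauchy(x, 0, e$scale, log = TRUE))
    if (!is.finite(d)) return(-Inf)
    lp <- lp + d
  }
  lp
}

# draw one valid initial parameter vector from the priors
vb_prior_init <- function(priors) {
  draw1 <- function(e) switch(e$dist,
    beta = stats::rbeta(1, e$shape1, e$shape2),
    normal = stats::rnorm(1, e$mean, e$sd),
    normal_kappa = NA_real_,  # filled after kappa
    gamma = {
      x <- stats::rgamma(1, e$shape, rate = e$rate)
      min(max(x, e$lower), e$upper)
    },
    uniform = stats::runif(1, e$lower, e$upper),
    half_cauchy = abs(stats::rcauchy(1, 0, e$scale)))
  for (i in 1:200) {
    kappa <- draw1(priors$kappa)
    dw_inf <- if (priors$dw_inf$dist == "normal_kappa")
      stats::rnorm(1, priors$dw_max * kappa, priors$dw_inf$sd)
    else draw1(priors$dw_inf)
    theta <- c(k = draw1(priors$k), dw_inf = dw_inf,
               dw0 = draw1(priors$dw0), kappa = kappa,
               # cap wild half-Cauchy tails: start in a sane variance range
               sigma2 = min(draw1(priors$sigma2), 1))
    if (is.finite(vb_log_prior(theta, priors))) return(theta)
  }
  stop("could not draw a valid initial value from the priors")
}
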