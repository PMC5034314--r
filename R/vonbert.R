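#' von Bertalanffy mean disc width at age
#'
#' Evaluates the three-parameter von Bertalanffy growth function in its
#' size-at-age-zero parameterisation,
#' \deqn{DW_t = DW_\infty - (DW_\infty - DW_0)\, e^{-k t},}
#' the saturating curve conventionally used for elasmobranch size-at-age.
#' Disc width (DW) is used in place of length because it is the standard
#' size measure for batoids.
#'
#' @param age numeric vector of ages in years; must be non-negative.
#' @param k growth coefficient (year^-1), > 0.
#' @param dw_inf asymptotic disc width (mm).
#' @param dw0 disc width at age zero (mm); 0 < \code{dw0} < \code{dw_inf}.
#' @return numeric vector of mean disc widths (mm), strictly increasing in
#'   age and bounded above by \code{dw_inf}.
#' @examples
#' vb_mean(0:14, k = 0.12, dw_inf = 2995, dw0 = 880)
#' @export
vb_mean <- function(age, k, dw_inf, dw0) {
  if (any(!is.finite(age)) || any(age < 0))
    stop("'age' must be finite and non-negative")
  check_growth_params(k, dw_inf, dw0)
  dw_inf - (dw_inf - dw0) * exp(-k * age)
}

# shared domain checks for the growth parameter vector
check_growth_params <- function(k, dw_inf, dw0, sigma2 = NULL) {
  if (!is.finite(k) || k <= 0) stop("'k' must be a positive finite number")
  if (!is.finite(dw_inf) || !is.finite(dw0) || dw0 <= 0 || dw_inf <= dw0)
    stop("growth parameters must satisfy dw_inf > dw0 > 0")
  if (!is.null(sigma2) && (!is.finite(sigma2) || sigma2 <= 0))
    stop("'sigma2' must be a positive finite number")
  invisible(TRUE)
}

#' Log likelihood of length-at-age data under the lognormal error model
#'
#' Observation model: multiplicative error around the growth curve, so that
#' \eqn{\ln DW_t \sim N(\ln \mu_t, \sigma^2)} with \eqn{\mu_t} the
#' von Bertalanffy mean at age \eqn{t}.
#'
#' @param data data frame with columns \code{age_years} and
#'   \code{disc_width_mm} (one aged individual per row).
#' @param k,dw_inf,dw0 growth parameters as in [vb_mean()].
#' @param sigma2 variance of the log-scale error term, > 0.
#' @return scalar log likelihood.
#' @export
vb_loglik <- function(data, k, dw_inf, dw0, sigma2) {
  data <- as_length_at_age(data)
  if (nrow(data) == 0L) stop("'data' must contain at least one record")
  check_growth_params(k, dw_inf, dw0, sigma2)
  mu <- vb_mean(data$age_years, k, dw_inf, dw0)
  if (any(mu <= 0)) stop("predicted mean disc width must be positive")
  sum(stats::dnorm(log(data$disc_width_mm), mean = log(mu),
                   sd = sqrt(sigma2), log = TRUE))
}

#' Validate and coerce a length-at-age table
#'
#' @param data a data frame with columns \code{age_years} (integer band
#'   counts, >= 0) and \code{disc_width_mm} (positive).
#' @return the validated data frame.
#' @export
as_length_at_age <- function(data) {
  data <- as.data.frame(data)
  need <- c("age_years", "disc_width_mm")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_age <- which(!is.finite(data$age_years) | data$age_years < 0)
  if (length(bad_age))
    stop("invalid age_years at row(s) ", paste(bad_age, collapse = ", "),
         ": ages must be finite and >= 0")
  bad_dw <- which(!is.finite(data$disc_width_mm) | data$disc_width_mm <= 0)
  if (length(bad_dw))
    stop("invalid disc_width_mm at row(s) ", paste(bad_dw, collapse = ", "),
         ": disc widths must be finite and > 0")
  data[need]
}
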