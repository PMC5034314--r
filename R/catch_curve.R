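#' Tabulate an age composition
#'
#' Counts individuals per integer age class from age 0 to the oldest
#' retained age.  Intermediate classes with zero individuals are kept in
#' the table (they are dropped only at regression time, where the log of a
#' zero count is undefined); excluded classes are removed outright.
#'
#' @param ages integer vector of ages (years), or a data frame with an
#'   \code{age_years} column.
#' @param exclude_ages integer vector of age classes to remove before
#'   tabulation (e.g. classes known to be unrepresentative).
#' @return an object of class \code{"age_comp"}: data frame with columns
#'   \code{age} and \code{count}.
#' @examples
#' age_composition(c(0, 0, 1, 3))
#' @export
age_composition <- function(ages, exclude_ages = integer()) {
  if (is.data.frame(ages)) ages <- as_length_at_age(ages)$age_years
  ages <- as.integer(round(ages))
  if (length(ages) == 0L) stop("'ages' must be non-empty")
  if (any(ages < 0)) stop("ages must be non-negative")
  max_age <- max(ages)
  ages <- ages[!ages %in% as.integer(exclude_ages)]
  if (length(ages) == 0L) stop("all records excluded from the composition")
  # the grid spans the pre-exclusion maximum so interior zero classes
  # survive even when the oldest class is excluded
  grid <- setdiff(0:max_age, as.integer(exclude_ages))
  counts <- vapply(grid, function(a) sum(ages == a), 0L)
  structure(data.frame(age = grid, count = counts),
            class = c("age_comp", "data.frame"))
}

#' @export
print.age_comp <- function(x, ...) {
  cat("Age composition:", sum(x$count), "individuals in",
      sum(x$count > 0), "non-empty classes\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# validate/coerce a composition given as age_comp, data.frame or counts
as_age_comp <- function(comp) {
  if (inherits(comp, "age_comp")) return(comp)
  comp <- as.data.frame(comp)
  if (!all(c("age", "count") %in% names(comp)))
    stop("composition needs columns 'age' and 'count'")
  if (any(comp$age < 0) || any(comp$count < 0))
    stop("ages and counts must be non-negative")
  if (!any(comp$count > 0)) stop("composition has no individuals")
  structure(comp[order(comp$age), c("age", "count")],
            class = c("age_comp", "data.frame"))
}

#' Catch-curve estimate of total mortality
#'
#' Estimates the instantaneous total mortality rate Z (year^-1) as minus
#' the ordinary-least-squares slope of log count on age over the fully
#' recruited age classes.  The descending limb is selected by the peak
#' rule: the class with the maximum count (earliest age if tied) and all
#' older classes are retained, younger classes — assumed less catchable —
#' are discarded; zero-count classes are then dropped so the log is
#' defined.  At least 3 classes must remain.
#'
#' @param comp an [age_composition()] table (or any data frame with
#'   \code{age} and \code{count} columns).
#' @return an object of class \code{"catch_curve"}: list with \code{z}
#'   (year^-1), \code{slope}, \code{intercept}, \code{peak_age},
#'   \code{used} (the regression table) and the input composition.
#' @examples
#' cc <- catch_curve(data.frame(age = 0:4, count = c(2, 5, 9, 7, 4)))
#' cc$z  # ~ 0.41
#' @export
catch_curve <- function(comp) {
  comp <- as_age_comp(comp)
  peak_age <- comp$age[which.max(comp$count)]  # which.max: earliest tie
  used <- comp[comp$age >= peak_age & comp$count > 0, , drop = FALSE]
  if (nrow(used) < 3L)
    stop("degenerate composition: fewer than 3 usable age classes ",
         "after peak truncation and zero-class removal")
  # closed-form OLS slope of log(count) on age
  x <- used$age; y <- log(used$count)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc * xc)
  intercept <- mean(y) - slope * mean(x)
  structure(list(z = -slope, slope = slope, intercept = intercept,
                 peak_age = peak_age, used = used, comp = comp),
            class = "catch_curve")
}

#' @export
print.catch_curve <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Catch curve: Z = %.*f year^-1 (peak age %d, %d classes used)\n",
    digits, x$z, x$peak_age, nrow(x$used)))
  invisible(x)
}

#' @export
coef.catch_curve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope, z = object$z)

#' @export
plot.catch_curve <- function(x, ...) {
  keep <- x$comp$count > 0
  plot(x$comp$age[keep], log(x$comp$count[keep]),
       xlab = "age (years)", ylab = "ln(count)", ...)
  with(x$used, graphics::points(age, log(count), pch = 16))
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Bootstrap uncertainty in the catch-curve Z estimate
#'
#' Quantifies sampling uncertainty in a small age sample by repeatedly
#' deleting a fixed fraction of the individual records at random (without
#' replacement), rebuilding the age composition, and refitting the
#' peak-truncated catch curve.  Replicates that leave fewer than 3 usable
#' age classes are discarded and counted.  Optionally drops ages at or
#' above a cutoff first (a conservative variant when the oldest classes
#' may be depleted by migration rather than mortality).
#'
#' @param ages integer age vector or data frame with \code{age_years}.
#' @param n_boot number of bootstrap replicates (default 20000).
#' @param drop_fraction fraction of records deleted per replicate, in
#'   \eqn{[0, 1)}; \code{floor(drop_fraction * n)} records are removed
#'   (default 0.2).
#' @param max_age_cutoff optional integer; records with age >=
#'   \code{max_age_cutoff} are excluded from every replicate.
#' @param exclude_ages age classes removed from every composition.
#' @param seed integer seed; all replicate streams derive from it.
#' @return an object of class \code{"z_boot"}: list with \code{z_draws},
#'   \code{median}, \code{ci} (2.5% and 97.5% quantiles),
#'   \code{n_discarded}, and the settings.
#' @export
bootstrap_Z <- function(ages, n_boot = 20000, drop_fraction = 0.2,
                        max_age_cutoff = NULL, exclude_ages = integer(),
                        seed = NULL) {
  if (is.data.frame(ages)) ages <- as_length_at_age(ages)$age_years
  ages <- as.integer(round(ages))
  stopifnot(n_boot >= 1, drop_fraction >= 0, drop_fraction < 1)
  if (!is.null(max_age_cutoff)) ages <- ages[ages < max_age_cutoff]
  if (length(ages) == 0L) stop("no records left after the age cutoff")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(ages)
  n_drop <- floor(drop_fraction * n)
  z <- numeric(n_boot)
  ok <- logical(n_boot)
  for (i in seq_len(n_boot)) {
    keep <- if (n_drop > 0) ages[-sample.int(n, n_drop)] else ages
    fit <- tryCatch(
      catch_curve(age_composition(keep, exclude_ages = exclude_ages)),
      error = function(e) NULL)
    if (!is.null(fit)) { z[i] <- fit$z; ok[i] <- TRUE }
  }
  if (!any(ok))
    stop("all ", n_boot, " bootstrap replicates were discarded ",
         "(fewer than 3 usable age classes each)")
  z <- z[ok]
  structure(list(
    z_draws = z,
    median = stats::median(z),
    ci = stats::quantile(z, c(0.025, 0.975), names = FALSE),
    n_discarded = sum(!ok), n_boot = n_boot,
    drop_fraction = drop_fraction, max_age_cutoff = max_age_cutoff,
    exclude_ages = exclude_ages, seed = seed), class = "z_boot")
}

#' @export
print.z_boot <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bootstrapped catch curve: median Z = %.*f year^-1 [%.*f, %.*f]\n",
    digits, x$median, digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("  %d replicates (%d discarded), drop fraction %.2f%s\n",
              x$n_boot, x$n_discarded, x$drop_fraction,
              if (is.null(x$max_age_cutoff)) ""
              else sprintf(", ages >= %d excluded", x$max_age_cutoff)))
  invisible(x)
}

#' @export
summary.z_boot <- function(object, ...) {
  data.frame(median = object$median, ci_low = object$ci[1],
             ci_high = object$ci[2], n_draws = length(object$z_draws),
             n_discarded = object$n_discarded, row.names = NULL)
}

#' Fishing mortality from total and natural mortality draws
#'
#' Pairs draws of total mortality Z with draws of natural mortality M by
#' independently resampling each vector with replacement to a common
#' length, and computes F = Z - M elementwise.  Negative F draws are
#' retained: they express the possibility that the sampled Z is below the
#' natural mortality rate.  The summary interval uses the 5% and 95%
#' quantiles, matching the convention used for M and r_max.
#'
#' @param z_draws numeric vector of total mortality draws (year^-1).
#' @param m_draws numeric vector of natural mortality draws (year^-1).
#' @param n number of paired draws (default the larger input length).
#' @param seed optional integer seed for the resampling.
#' @return an object of class \code{"f_mort"}: list with \code{f_draws},
#'   \code{median} and \code{ci} (5% / 95% quantiles).
#' @export
fishing_mortality <- function(z_draws, m_draws,
                              n = max(length(z_draws), length(m_draws)),
                              seed = NULL) {
  if (length(z_draws) == 0L || length(m_draws) == 0L)
    stop("'z_draws' and 'm_draws' must be non-empty")
  if (!is.null(seed)) set.seed(as.integer(seed))
  zi <- sample(z_draws, n, replace = TRUE)
  mi <- sample(m_draws, n, replace = TRUE)
  f <- zi - mi
  structure(list(f_draws = f, median = stats::median(f),
                 ci = stats::quantile(f, c(0.05, 0.95), names = FALSE)),
            class = "f_mort")
}

#' @export
print.f_mort <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Fishing mortality: median F = %.*f year^-1 [q05 %.*f, q95 %.*f]\n",
    digits, x$median, digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}
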