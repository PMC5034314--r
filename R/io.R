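#' Read a length-at-age CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' \code{age_years,disc_width_mm} and one aged individual per row.
#' Validation errors name the offending row.
#'
#' @param path file path.
#' @return validated data frame (see [as_length_at_age()]).
#' @export
read_length_at_age <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_years", "disc_width_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("'", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at row(s) ",
           paste(bad, collapse = ", "), " of ", path)
    d[[col]] <- v
  }
  as_length_at_age(d)
}

#' Write a length-at-age CSV
#'
#' @param data validated length-at-age data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_length_at_age <- function(data, path) {
  data <- as_length_at_age(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pre-tabulated age composition CSV
#'
#' Expects header \code{age_class,count}.
#'
#' @param path file path.
#' @return an [age_composition()]-style table.
#' @export
read_age_composition <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_class", "count") %in% names(d)))
    stop("'", path, "' must have columns age_class,count")
  as_age_comp(data.frame(age = d$age_class, count = d$count))
}

#' Read a species life-history table CSV
#'
#' Expects header \code{species,b_low,b_high,alpha_mat_low,alpha_mat_high,
#' alpha_max_low,alpha_max_high}; point values are encoded as
#' \code{low == high}.
#'
#' @param path file path.
#' @return data frame suitable for [rmax_batch()].
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "b_low", "b_high", "alpha_mat_low",
            "alpha_mat_high", "alpha_max_low", "alpha_max_high")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("'", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  d
}

# summary JSON with provenance: every machine-readable artifact embeds
# the seed, settings and package version that produced it
write_summary_json <- function(x, path, seed, config) {
  x$provenance <- list(
    package = "raydemog",
    version = as.character(utils::packageVersion("raydemog")),
    seed = seed, config = config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full demographic pipeline
#'
#' Executes simulate (only when no input data file is given) ->
#' growth fit -> bootstrapped catch curve -> Monte Carlo r_max ->
#' fishing mortality, writing draws as CSV and summaries as JSON under
#' \code{out_dir}.  Every summary JSON embeds the seed, the settings and
#' the package version.  All randomness derives from the single
#' \code{seed}; rerunning with the same configuration reproduces every
#' artifact byte for byte.  The configuration is validated up front: a
#' bad configuration fails before any output is written, and a stage
#' failure stops the downstream stages.
#'
#' @param config a named list, or the path of a YAML file holding one,
#'   with entries: \code{seed} (integer), \code{out_dir}, optional
#'   \code{data} (length-at-age CSV path; omitted means simulate), and
#'   optional stage settings \code{simulate}, \code{growth} (priors,
#'   chains, iter, warmup), \code{catch} (n_boot, drop_fraction,
#'   max_age_cutoff, exclude_ages), \code{rmax} (b_range,
#'   alpha_mat_range, alpha_max_range, n_draws) passed to
#'   [sim_length_at_age()], [fit_vbgm()], [bootstrap_Z()] and
#'   [rmax_mc()].
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    # keep single-letter keys like "n" as strings instead of YAML 1.1
    # booleans
    config <- yaml::read_yaml(config,
                              handlers = list("bool#yes" = identity,
                                              "bool#no" = identity))
  }
  stopifnot(is.list(config))
  if (is.null(config$seed) || !is.finite(config$seed) || config$seed < 0)
    stop("config$seed must be a non-negative integer")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- as.integer(config$seed)
  if (!is.null(config$data) && !file.exists(config$data))
    stop("configured input data file not found: ", config$data)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  pth <- function(f) file.path(config$out_dir, f)

  # stage 1: obtain data (simulate unless a file is configured)
  if (is.null(config$data)) {
    sim_args <- c(config$simulate, list(seed = seed + 1L))
    data <- do.call(sim_length_at_age,
                    sim_args[!duplicated(names(sim_args))])
    paths$data <- write_length_at_age(data, pth("length_at_age.csv"))
  } else {
    data <- read_length_at_age(config$data)
  }

  # stage 2: growth
  g <- config$growth
  fit <- fit_vbgm(data,
                  priors = vb_priors(g$priors %||% "strong"),
                  chains = g$chains %||% 4, iter = g$iter %||% 1000,
                  warmup = g$warmup %||% 1000, seed = seed + 2L)
  gd <- data.frame(parameter = rep(colnames(fit$draws),
                                   each = nrow(fit$draws)),
                   chain = rep(fit$chain, ncol(fit$draws)),
                   iteration = rep(fit$iteration, ncol(fit$draws)),
                   value = as.vector(fit$draws))
  utils::write.csv(gd, pth("growth_draws.csv"), row.names = FALSE,
                   quote = FALSE)
  paths$growth_draws <- pth("growth_draws.csv")
  gs <- posterior_summary(fit)
  paths$growth_summary <- write_summary_json(
    list(summary = gs, converged = fit$diagnostics$converged),
    pth("growth_summary.json"), seed, g)

  # stage 3: catch curve
  cc <- config$catch
  zb <- bootstrap_Z(data, n_boot = cc$n_boot %||% 20000,
                    drop_fraction = cc$drop_fraction %||% 0.2,
                    max_age_cutoff = cc$max_age_cutoff,
                    exclude_ages = cc$exclude_ages %||% integer(),
                    seed = seed + 3L)
  utils::write.csv(data.frame(replicate = seq_along(zb$z_draws),
                              Z = zb$z_draws),
                   pth("z_draws.csv"), row.names = FALSE, quote = FALSE)
  paths$z_draws <- pth("z_draws.csv")

  # stage 4: r_max Monte Carlo
  rx <- config$rmax
  mc <- rmax_mc(b_range = rx$b_range %||% c(0.25, 0.5),
                alpha_mat_range = rx$alpha_mat_range %||% c(5, 6),
                alpha_max_range = rx$alpha_max_range %||% c(15, 20),
                n_draws = rx$n_draws %||% 10000, seed = seed + 4L)
  rd <- mc$draws
  names(rd) <- c("b", "alpha_mat", "alpha_max", "omega", "M", "l_mat",
                 "r_max")
  rd <- cbind(draw = seq_len(nrow(rd)), rd)
  utils::write.csv(rd, pth("rmax_draws.csv"), row.names = FALSE,
                   quote = FALSE)
  paths$rmax_draws <- pth("rmax_draws.csv")
  paths$rmax_summary <- write_summary_json(
    list(summary = mc$summary, n_rejected = mc$n_rejected),
    pth("rmax_summary.json"), seed, rx)

  # stage 5: fishing mortality F = Z - M pairing the two draw sets
  fm <- fishing_mortality(zb$z_draws, mc$draws$m, seed = seed + 5L)
  paths$z_summary <- write_summary_json(
    list(z = summary(zb),
         f = data.frame(median = fm$median, q05 = fm$ci[1],
                        q95 = fm$ci[2], row.names = NULL)),
    pth("z_summary.json"), seed, cc)

  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
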