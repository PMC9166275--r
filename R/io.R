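#' Read a survey series from CSV
#'
#' Expects a header `year,mean,se`; extra columns (e.g. printed confidence
#' limits) are ignored. Thousands separators in numbers are tolerated, since
#' published tables print them. Validation failures name the offending row.
#'
#' @param path Path to a CSV file.
#' @return A [survey_series()] tibble.
#' @examples
#' read_surveys(system.file("extdata", "grand_cayman_surveys.csv",
#'                          package = "iguanaharvest"))
#' @export
read_surveys <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L)
    abort(sprintf("no data: '%s' has a header but no rows", path),
          class = "iguanaharvest_io_error")
  need <- c("year", "mean", "se")
  if (!all(need %in% names(raw)))
    abort(sprintf("'%s' must have columns year, mean, se (found: %s)",
                  path, toString(names(raw))),
          class = "iguanaharvest_io_error")
  num <- function(x, col) {
    out <- suppressWarnings(readr::parse_number(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
      abort(sprintf("unparseable %s '%s' in '%s' row %d", col, x[bad[1]],
                    path, bad[1]),
            class = "iguanaharvest_io_error")
    out
  }
  survey_series(num(raw$year, "year"), num(raw$mean, "mean"),
                num(raw$se, "se"))
}

#' Read a harvest schedule from CSV
#'
#' Expects columns `year` and `rate` and/or `total`; each row must give
#' exactly one of the two (leave the other empty or `NA`).
#'
#' @param path Path to a CSV file.
#' @return A [harvest_schedule()] tibble.
#' @export
read_harvest <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "n"),
                         progress = FALSE)
  if (!"year" %in% names(raw))
    abort(sprintf("'%s' must have a `year` column", path),
          class = "iguanaharvest_io_error")
  harvest_schedule(raw$year,
                   rate = if ("rate" %in% names(raw)) raw$rate else NULL,
                   total = if ("total" %in% names(raw)) raw$total else NULL)
}

#' Write a survey series / harvest schedule to CSV
#'
#' Full-precision plain CSV; [read_surveys()] / [read_harvest()] of the
#' written file reproduce the object exactly.
#'
#' @param x The object to write.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(x, path) {
  x <- as_survey_series(x)
  readr::write_csv(x[, c("year", "mean", "se")], path)
  invisible(path)
}

#' @rdname write_surveys
#' @export
write_harvest <- function(x, path) {
  x <- as_harvest_schedule(x)
  readr::write_csv(x[, c("year", "rate", "total")], path)
  invisible(path)
}

#' Write / read a synthetic study as plain-text files
#'
#' A study is persisted as `surveys.csv`, `harvest.csv` and a `truth.json`
#' sidecar holding the generating parameters, latent trajectory, CV design
#' and seed, so a written study round-trips field-for-field.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or a `synthetic_study` (read).
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study"))
    abort("`study` must come from generate_study()",
          class = "iguanaharvest_structure_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surveys(study$surveys, file.path(dir, "surveys.csv"))
  write_harvest(study$harvest, file.path(dir, "harvest.csv"))
  truth <- list(
    params = unclass(study$truth$params),
    N0 = study$truth$N0,
    trajectory = list(year = study$truth$trajectory$year,
                      N = study$truth$trajectory$N),
    cv_design = study$cv_design,
    seed = study$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  params <- growth_params(truth$params$K, truth$params$r_max,
                          truth$params$sigma_proc)
  schedule <- read_harvest(file.path(dir, "harvest.csv"))
  traj <- tibble(time_index = seq_along(truth$trajectory$year) - 1L,
                 year = as.integer(truth$trajectory$year),
                 N = truth$trajectory$N)
  class(traj) <- c("trajectory", class(traj))
  structure(list(
    surveys = read_surveys(file.path(dir, "surveys.csv")),
    harvest = schedule,
    truth = list(params = params, N0 = truth$N0, trajectory = traj),
    cv_design = truth$cv_design, seed = truth$seed
  ), class = "synthetic_study")
}

#' Lognormal confidence interval for a survey estimate
#'
#' The standard lognormal interval for a positive estimate with standard
#' error `se`: with \eqn{C = \exp(z \sqrt{\ln(1 + (se/mean)^2)})} the
#' interval is `(mean / C, mean * C)`, so `lower * upper = mean^2` exactly.
#'
#' @param mean Point estimate (`> 0`).
#' @param se Standard error (`> 0`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A named numeric `c(lower, upper)`.
#' @examples
#' lognormal_ci(87751, 34706) # ~ (41.6k, 185.3k)
#' @export
lognormal_ci <- function(mean, se, level = 0.95) {
  check_scalar(mean, "mean", lower = 0, strict_lower = TRUE)
  check_scalar(se, "se", lower = 0)
  check_scalar(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log(1 + (se / mean)^2)))
  c(lower = mean / C, upper = mean * C)
}

#' Packaged Grand Cayman green iguana data
#'
#' `iguana_surveys()` returns the eight annual August survey-based abundance
#' estimates (2014-2021, distance-sampling means with bootstrapped SEs;
#' age and sex classes combined). `iguana_harvest()` returns the matching
#' harvest schedule for the seven inter-survey intervals: no harvesting
#' before the October 2018 cull, then annual harvest rates 0.629, 0.374 and
#' 0.082. (An alternative reading of the 2018-2019 interval, 0.568, is noted
#' in the default configuration.)
#'
#' @return A [survey_series()] or [harvest_schedule()] tibble.
#' @examples
#' iguana_surveys()
#' iguana_harvest()
#' @export
iguana_surveys <- function() {
  read_surveys(system.file("extdata", "grand_cayman_surveys.csv",
                           package = "iguanaharvest", mustWork = TRUE))
}

#' @rdname iguana_surveys
#' @export
iguana_harvest <- function() {
  read_harvest(system.file("extdata", "grand_cayman_harvest.csv",
                           package = "iguanaharvest", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# run configuration (YAML)
# ---------------------------------------------------------------------------

default_config <- function() {
  list(
    surveys = NULL, harvest = NULL, # NULL = packaged Grand Cayman data
    priors = list(K = c(9e5, 2e6), r_max = c(0.5, 2.0),
                  sigma_proc = c(0.01, 1.0)),
    mcmc = list(chains = 4L, iter = 50000L, burn = 25000L, thin = 10L,
                seed = 1L),
    scenarios = list(
      list(lower = 0.001, upper = 0.100), list(lower = 0.101, upper = 0.300),
      list(lower = 0.301, upper = 0.500), list(lower = 0.501, upper = 0.700),
      list(lower = 0.701, upper = 0.900), list(lower = 0.001, upper = 0.900)
    ),
    horizon = 9L,
    h_mode = "per_year",
    # alternative annualisation of the first cull interval (see config docs)
    alternative_first_cull_rate = 0.568,
    out_dir = "iguanaharvest-output"
  )
}

#' Read and validate a run configuration
#'
#' A YAML file with any of the keys `surveys`, `harvest` (CSV paths),
#' `priors` (`K`, `r_max`, `sigma_proc` bounds), `mcmc` (`chains`, `iter`,
#' `burn`, `thin`, `seed`), `scenarios` (list of `lower`/`upper` bands),
#' `horizon`, `h_mode`, `out_dir`. Missing keys take the packaged defaults
#' (the Grand Cayman analysis); unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      abort(sprintf("unknown config key(s): %s", toString(unknown)),
            class = "iguanaharvest_io_error")
    # scenarios is an unnamed list: replace wholesale, never merge elementwise
    if (!is.null(user$scenarios)) {
      cfg$scenarios <- user$scenarios
      user$scenarios <- NULL
    }
    cfg <- modifyList(cfg, user)
  }
  # validate through the same constructors the model uses
  pr <- cfg$priors
  prior_spec(as.numeric(pr$K), as.numeric(pr$r_max),
             as.numeric(pr$sigma_proc))
  for (s in cfg$scenarios)
    scenario_band(s$lower, s$upper, horizon = cfg$horizon)
  m <- cfg$mcmc
  if (!(m$iter > m$burn && m$burn >= 0))
    stop_domain("mcmc", "need iter > burn >= 0")
  structure(cfg, class = "run_config")
}

config_priors <- function(cfg) {
  prior_spec(as.numeric(cfg$priors$K), as.numeric(cfg$priors$r_max),
             as.numeric(cfg$priors$sigma_proc))
}

config_bands <- function(cfg) {
  purrr::map(cfg$scenarios,
             ~scenario_band(.x$lower, .x$upper, horizon = cfg$horizon,
                            h_mode = cfg$h_mode))
}
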