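#' Harvest-rate scenario band
#'
#' A scenario is a uniform band of annual harvest rates,
#' \eqn{h \sim U(\mathrm{lower}, \mathrm{upper})}, applied over a projection
#' horizon. By default a fresh rate is drawn independently for every
#' projected year and every posterior draw; `h_mode = "per_trajectory"`
#' instead draws one rate per trajectory and holds it for the whole horizon.
#'
#' @param lower,upper Band limits, `0 <= lower <= upper < 1`. Set both to 0
#'   (or use `no_harvest = TRUE`) for the no-harvest scenario.
#' @param label Scenario label; defaults to `"lower-upper"` or
#'   `"no_harvest"`.
#' @param horizon Projection horizon in years (`>= 1`).
#' @param h_mode `"per_year"` (default) or `"per_trajectory"`.
#' @param no_harvest Convenience flag forcing `lower = upper = 0`.
#' @return An object of class `scenario_band`.
#' @examples
#' scenario_band(0.701, 0.900)
#' scenario_band(no_harvest = TRUE)
#' @export
scenario_band <- function(lower = 0, upper = 0, label = NULL, horizon = 9,
                          h_mode = c("per_year", "per_trajectory"),
                          no_harvest = FALSE) {
  h_mode <- match.arg(h_mode)
  if (no_harvest) { lower <- 0; upper <- 0 }
  check_scalar(lower, "lower", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(upper, "upper", lower = lower, upper = 1, strict_upper = TRUE)
  check_scalar(horizon, "horizon", lower = 1)
  if (is.null(label)) {
    label <- if (lower == 0 && upper == 0) "no_harvest"
             else sprintf("%.3f-%.3f", lower, upper)
  }
  structure(list(lower = lower, upper = upper, label = label,
                 horizon = as.integer(horizon), h_mode = h_mode),
            class = "scenario_band")
}

#' @export
print.scenario_band <- function(x, ...) {
  cat(sprintf("<scenario_band> %s: h ~ Uniform(%.3f, %.3f), %d years, %s\n",
              x$label, x$lower, x$upper, x$horizon, x$h_mode))
  invisible(x)
}

#' The six Grand Cayman harvest scenarios
#'
#' The six uniform harvest-rate bands used to bracket plausible future
#' harvesting effort: (0.001, 0.100), (0.101, 0.300), (0.301, 0.500),
#' (0.501, 0.700), (0.701, 0.900) and the wide band (0.001, 0.900).
#'
#' @param horizon Projection horizon in years.
#' @return A list of [scenario_band()] objects.
#' @export
default_scenario_bands <- function(horizon = 9) {
  lo <- c(0.001, 0.101, 0.301, 0.501, 0.701, 0.001)
  hi <- c(0.100, 0.300, 0.500, 0.700, 0.900, 0.900)
  purrr::map2(lo, hi, scenario_band, horizon = horizon)
}

get_draws <- function(x) {
  if (inherits(x, "ssm_fit")) x$draws
  else if (is.data.frame(x)) x
  else abort("expected an ssm_fit or a draws tibble",
             class = "iguanaharvest_structure_error")
}

#' Project the fitted population under a harvest scenario
#'
#' Forward Monte Carlo: each posterior draw is pushed forward from its own
#' terminal latent state (the last survey year) through the harvested
#' logistic update, with fresh lognormal process noise
#' (SD = that draw's `sigma_proc`) and annual harvest rates drawn from the
#' scenario band. Observation uncertainty therefore propagates coherently:
#' the ensemble mixes over the joint posterior of parameters and the
#' terminal state.
#'
#' @param x An `ssm_fit` from [fit_logistic_ssm()], or a draws tibble
#'   carrying `K`, `r_max`, `sigma_proc` and a terminal `N_<year>` column.
#' @param scenario A [scenario_band()].
#' @param seed Integer seed for harvest rates and process noise.
#' @param n_ensemble Minimum ensemble size; posterior draws are recycled by
#'   seeded resampling if fewer are available. `NULL` uses every draw once.
#' @param process_noise Set `FALSE` to project the deterministic skeletons
#'   (no process noise), e.g. for illustration plots.
#' @param start_year First projected year minus one; defaults to the latest
#'   `N_<year>` column.
#' @param timing,noise_centering Model form, as in [logistic_step()] and
#'   [simulate_trajectory()]; default to the form the fit was run with
#'   (when `x` is an `ssm_fit`) so projection and fit always share one
#'   model.
#' @return An object of class `ssm_projection`: `$summary` is a tibble with
#'   per-year ensemble `mean`, `sd`, `median`, `q2.5`, `q97.5`; `$trajectories`
#'   is the ensemble matrix (one row per member, one column per year,
#'   including the start year); plus the scenario, seed and surveys (when
#'   available) for plotting.
#' @examples
#' \donttest{
#' fit <- fit_logistic_ssm(iguana_surveys(), iguana_harvest(),
#'                         iter = 4000, burn = 2000, seed = 1)
#' project(fit, scenario_band(no_harvest = TRUE), seed = 1)
#' }
#' @export
project <- function(x, scenario, seed = 1, n_ensemble = NULL,
                    process_noise = TRUE, start_year = NULL,
                    timing = NULL, noise_centering = NULL) {
  if (!inherits(scenario, "scenario_band"))
    abort("`scenario` must be a scenario_band", class = "iguanaharvest_structure_error")
  if (inherits(x, "ssm_fit")) {
    timing <- timing %||% x$settings$timing
    noise_centering <- noise_centering %||% x$settings$noise_centering
  }
  timing <- match.arg(timing %||% "sequential",
                      c("sequential", "simultaneous"))
  noise_centering <- match.arg(noise_centering %||% "mean",
                               c("mean", "median"))
  draws <- get_draws(x)
  ncols <- grep("^N_[0-9]+$", names(draws), value = TRUE)
  if (!length(ncols))
    abort("draws carry no latent-state `N_<year>` column; cannot locate the terminal state",
          class = "iguanaharvest_structure_error")
  yrs <- as.integer(sub("^N_", "", ncols))
  start_year <- start_year %||% max(yrs)
  terminal_col <- paste0("N_", start_year)
  if (!terminal_col %in% ncols)
    abort(sprintf("no latent state for start year %d", start_year),
          class = "iguanaharvest_structure_error")
  if (nrow(draws) == 0L)
    abort("empty draws", class = "iguanaharvest_domain_error")

  withr::with_seed(as.integer(seed), {
    idx <- seq_len(nrow(draws))
    if (!is.null(n_ensemble) && nrow(draws) < n_ensemble)
      idx <- sample.int(nrow(draws), n_ensemble, replace = TRUE)
    K <- draws$K[idx]; r <- draws$r_max[idx]
    sig <- if (process_noise) draws$sigma_proc[idx] else 0
    n <- length(idx)
    H <- scenario$horizon
    traj <- matrix(NA_real_, n, H + 1L)
    traj[, 1L] <- draws[[terminal_col]][idx]
    h_traj <- if (scenario$h_mode == "per_trajectory")
      runif(n, scenario$lower, scenario$upper) else NULL
    shift <- noise_shift(sig, noise_centering)
    for (t in seq_len(H)) {
      h <- h_traj %||% runif(n, scenario$lower, scenario$upper)
      eps <- if (process_noise) rnorm(n, 0, 1) * sig + shift else 0
      traj[, t + 1L] <- step_kernel(traj[, t], K, r, h,
                                    sequential = timing == "sequential") *
        exp(eps)
    }
  })
  years <- start_year + 0:scenario$horizon
  colnames(traj) <- years
  qs <- apply(traj, 2L, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  sds <- apply(traj, 2L, sd)
  if (nrow(traj) == 1L) sds[] <- 0 # a single member has no spread
  summary <- tibble(
    scenario = scenario$label, year = as.integer(years),
    mean = unname(colMeans(traj)), sd = unname(sds),
    median = unname(qs[2L, ]), q2.5 = unname(qs[1L, ]),
    q97.5 = unname(qs[3L, ])
  )
  structure(list(
    summary = summary, trajectories = traj, scenario = scenario,
    seed = seed, n_ensemble = nrow(traj), start_year = start_year,
    surveys = if (inherits(x, "ssm_fit")) x$surveys else NULL,
    draw_K = K
  ), class = "ssm_projection")
}

#' @export
print.ssm_projection <- function(x, ...) {
  cat(sprintf("Scenario projection '%s' (%d members, %d-%d)\n",
              x$scenario$label, x$n_ensemble, min(x$summary$year),
              max(x$summary$year)))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname project
#' @param ... Unused.
#' @export
tidy.ssm_projection <- function(x, ...) x$summary

#' First-passage times of a projected ensemble
#'
#' For each ensemble trajectory, the first projected year in which abundance
#' crosses a threshold in the stated direction; trajectories that never
#' cross within the horizon are reported as censored. With
#' `threshold = "K"` each trajectory is compared against its own posterior
#' draw of carrying capacity (scaled by `frac`), which is how "reaching
#' carrying capacity" is assessed.
#'
#' @param projection An `ssm_projection` from [project()].
#' @param threshold A positive abundance, or the string `"K"` for each
#'   draw's own carrying capacity.
#' @param direction `"above"` or `"below"`.
#' @param frac Multiplier applied to the threshold (useful as
#'   `threshold = "K", frac = 0.95`).
#' @return A list of class `first_passage`: `$events` is a tibble
#'   (`member`, `year`, `censored`), `$median_year` the ensemble median
#'   first-passage year (`NA` if most trajectories never cross).
#' @export
time_to_threshold <- function(projection, threshold,
                              direction = c("above", "below"), frac = 1) {
  direction <- match.arg(direction)
  if (!inherits(projection, "ssm_projection"))
    abort("`projection` must come from project()",
          class = "iguanaharvest_structure_error")
  traj <- projection$trajectories
  if (is.null(traj) || nrow(traj) == 0L)
    abort("empty projection ensemble", class = "iguanaharvest_domain_error")
  if (identical(threshold, "K")) {
    thr <- projection$draw_K * frac
  } else {
    check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
    thr <- rep(threshold * frac, nrow(traj))
  }
  years <- as.integer(colnames(traj))
  proj_cols <- 2:ncol(traj) # exclude the start year
  hit <- if (direction == "above") traj[, proj_cols, drop = FALSE] >= thr
         else traj[, proj_cols, drop = FALSE] <= thr
  first <- apply(hit, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  events <- tibble(
    member = seq_len(nrow(traj)),
    year = years[proj_cols][first],
    censored = is.na(first)
  )
  med <- {
    yr <- ifelse(events$censored, Inf, events$year)
    m <- median(yr)
    if (is.finite(m)) as.integer(m) else NA_integer_
  }
  structure(list(events = events, median_year = med,
                 threshold = threshold, direction = direction, frac = frac),
            class = "first_passage")
}

#' @export
print.first_passage <- function(x, ...) {
  cat(sprintf("First passage %s threshold: median year %s; %.1f%% censored\n",
              x$direction, ifelse(is.na(x$median_year), "never (censored)",
                                  x$median_year),
              100 * mean(x$events$censored)))
  invisible(x)
}

#' Scenario comparison table for a target year
#'
#' Runs [project()] for each scenario band and extracts the ensemble
#' summaries at a target year, in the order the bands are given — the
#' layout of the management comparison table (mean, median, SD, 2.5th and
#' 97.5th percentiles of predicted abundance per harvest-rate band).
#'
#' @inheritParams project
#' @param bands A list of [scenario_band()] objects (default: the six
#'   Grand Cayman bands).
#' @param target_year Calendar year to tabulate; defaults to the projection
#'   horizon's final year.
#' @return A tibble with one row per band: `scenario`, `lower`, `upper`,
#'   `year`, `mean`, `sd`, `median`, `q2.5`, `q97.5`.
#' @export
scenario_table <- function(x, bands = default_scenario_bands(),
                           target_year = NULL, seed = 1, n_ensemble = NULL) {
  purrr::map_dfr(bands, function(b) {
    pr <- project(x, b, seed = seed, n_ensemble = n_ensemble)
    yr <- target_year %||% max(pr$summary$year)
    row <- pr$summary[pr$summary$year == yr, ]
    if (nrow(row) == 0L)
      abort(sprintf("target year %d is outside the %s projection horizon",
                    yr, b$label),
            class = "iguanaharvest_domain_error")
    tibble(scenario = b$label, lower = b$lower, upper = b$upper,
           year = as.integer(yr), mean = row$mean, sd = row$sd,
           median = row$median, q2.5 = row$q2.5, q97.5 = row$q97.5)
  })
}
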