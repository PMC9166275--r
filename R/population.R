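#' Biological parameters of the logistic population model
#'
#' Bundles the three parameters of the discrete-time logistic
#' (surplus-production) model: the carrying capacity \eqn{K}, the abundance
#' above which density dependence drives the population into decline; the
#' maximum intrinsic growth rate \eqn{r_{max}}, the exponential per-year rate
#' of increase at low density; and the standard deviation of multiplicative
#' process noise on the natural-log scale, \eqn{\sigma_{proc}}.
#'
#' @param K Carrying capacity, individuals. Must be a finite positive number.
#' @param r_max Maximum intrinsic growth rate, per year. Finite, positive.
#' @param sigma_proc Log-scale SD of multiplicative process noise
#'   (dimensionless, `>= 0`). Defaults to 0 (deterministic dynamics).
#'
#' @return An object of class `growth_params`: a named list with elements
#'   `K`, `r_max`, `sigma_proc`.
#' @examples
#' growth_params(K = 1378259, r_max = 1.323, sigma_proc = 0.05)
#' @export
growth_params <- function(K, r_max, sigma_proc = 0) {
  check_scalar(K, "K", lower = 0, strict_lower = TRUE)
  check_scalar(r_max, "r_max", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_proc, "sigma_proc", lower = 0)
  structure(list(K = K, r_max = r_max, sigma_proc = sigma_proc),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  K          = %s individuals\n", format(x$K, big.mark = ",")))
  cat(sprintf("  r_max      = %.4g per year\n", x$r_max))
  cat(sprintf("  sigma_proc = %.4g (log-scale SD)\n", x$sigma_proc))
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  if (is.list(x) && all(c("K", "r_max") %in% names(x)))
    return(growth_params(x$K, x$r_max, x$sigma_proc %||% 0))
  stop_domain("params", "must be a growth_params object")
}

#' Per-interval harvest schedule
#'
#' A harvest schedule holds, for each inter-survey interval `[t, t+1)`,
#' either a harvest rate \eqn{h_t \in [0, 1)} (a proportion of the current
#' true abundance, so that total harvest \eqn{H_t = N_t h_t}) or a total
#' number removed \eqn{H_t \ge 0} — exactly one of the two per interval.
#'
#' @param year Integer vector labelling the start year of each interval.
#' @param rate Per-interval harvest rates in `[0, 1)`, `NA` where a total is
#'   given instead.
#' @param total Per-interval harvest totals (individuals, `>= 0`), `NA` where
#'   a rate is given instead.
#'
#' @return A tibble of class `harvest_schedule` with columns `year`, `rate`,
#'   `total`, `type` (`"rate"` or `"total"`).
#' @examples
#' # Grand Cayman cull: no harvest 2014-2018, then the reported annual rates
#' harvest_schedule(2014:2020, rate = c(0, 0, 0, 0, 0.629, 0.374, 0.082))
#' @export
harvest_schedule <- function(year, rate = NULL, total = NULL) {
  n <- length(year)
  if (n < 1L) stop_domain("year", "schedule must be non-empty")
  if (any(diff(year) <= 0)) stop_domain("year", "years must be strictly increasing")
  rate <- rate %||% rep(NA_real_, n)
  total <- total %||% rep(NA_real_, n)
  if (length(rate) != n || length(total) != n)
    stop_domain("rate/total", "must match the length of `year`")
  has_rate <- !is.na(rate)
  has_total <- !is.na(total)
  if (any(has_rate == has_total))
    stop_domain("rate/total", "exactly one of rate or total per interval")
  if (any(rate[has_rate] < 0 | rate[has_rate] >= 1))
    stop_domain("rate", "harvest rates must lie in [0, 1)")
  if (any(total[has_total] < 0))
    stop_domain("total", "harvest totals must be >= 0")
  out <- tibble(
    year = as.integer(year), rate = as.numeric(rate), total = as.numeric(total),
    type = ifelse(has_rate, "rate", "total")
  )
  class(out) <- c("harvest_schedule", class(out))
  out
}

as_harvest_schedule <- function(x) {
  if (inherits(x, "harvest_schedule")) return(x)
  if (is.data.frame(x) && "year" %in% names(x)) {
    return(harvest_schedule(
      x$year,
      rate = if ("rate" %in% names(x)) x$rate else NULL,
      total = if ("total" %in% names(x)) x$total else NULL
    ))
  }
  stop_domain("harvest", "must be a harvest_schedule or a data frame with year/rate/total")
}

#' One step of the harvested logistic map
#'
#' Advances abundance one year under the discrete-time harvested logistic
#' update. With post-reproduction growth \eqn{G_t = N_t + r_{max} N_t (1 -
#' N_t/K)}, the default `timing = "sequential"` removes the harvest from the
#' grown population,
#' \deqn{N_{t+1} = \max(0,\; G_t (1 - h_t))\, e^{\varepsilon_t},}
#' which matches an August post-reproduction survey design: the year's
#' recruitment is counted first and culling then removes a proportion of the
#' whole grown population. `timing = "simultaneous"` is the classical
#' Schaefer surplus-production form,
#' \deqn{N_{t+1} = \max(0,\; G_t - h_t N_t)\, e^{\varepsilon_t},}
#' whose equilibrium algebra (sustained-yield abundance
#' \eqn{N^* = K(1 - h/r_{max})}, MSY rate \eqn{r_{max}/2}) is exact. In
#' total-removal form the given count is capped at the grown abundance and
#' the two timings coincide. The floor at zero makes extinction absorbing
#' under over-harvest.
#'
#' @param N Current abundance, individuals (`>= 0`).
#' @param params A [growth_params()] object (`sigma_proc` is not used here;
#'   pass the deviate explicitly via `noise`).
#' @param rate Harvest rate in `[0, 1)` for this interval. Give `rate` or
#'   `total`, not both.
#' @param total Total individuals removed this interval (`>= 0`).
#' @param noise Log-scale process deviate \eqn{\varepsilon_t}; `NULL` (default)
#'   for the deterministic skeleton.
#' @param timing Harvest ordering: `"sequential"` (default, growth then
#'   proportional removal) or `"simultaneous"` (Schaefer form).
#'
#' @return Next-year abundance (a single non-negative number).
#' @examples
#' p <- growth_params(K = 1378259, r_max = 1.323)
#' logistic_step(100000, p)            # unharvested growth
#' logistic_step(100000, p, rate = 0.7) # heavy cull
#' @export
logistic_step <- function(N, params, rate = NULL, total = NULL, noise = NULL,
                          timing = c("sequential", "simultaneous")) {
  params <- as_growth_params(params)
  timing <- match.arg(timing)
  check_scalar(N, "N", lower = 0)
  if (!is.null(rate) && !is.null(total) && !is.na(rate) && !is.na(total))
    stop_domain("rate/total", "give a harvest rate or a total, not both")
  growth <- N + params$r_max * N * (1 - N / params$K)
  if (!is.null(total) && !is.na(total)) {
    check_scalar(total, "total", lower = 0)
    out <- max(0, growth - min(total, max(growth, 0)))
  } else {
    h <- if (is.null(rate) || is.na(rate)) 0 else rate
    check_scalar(h, "rate", lower = 0, upper = 1, strict_upper = TRUE)
    out <- if (timing == "sequential") max(0, growth * (1 - h))
           else max(0, growth - h * N)
  }
  if (!is.null(noise)) {
    check_scalar(noise, "noise")
    out <- out * exp(noise)
  }
  out
}

# bare-metal kernel used by the sampler and projector: no validation,
# vectorised over N (and optionally h)
step_kernel <- function(N, K, r_max, h, sequential = TRUE) {
  G <- N + r_max * N * (1 - N / K)
  if (sequential) pmax(0, G * (1 - h)) else pmax(0, G - h * N)
}

# process-noise deviates: mean-unbiased lognormal by default, so that
# E[N_{t+1} | N_t] equals the deterministic prediction; "median" leaves the
# deterministic prediction at the lognormal median instead
noise_shift <- function(sigma, centering) {
  if (centering == "mean") -sigma^2 / 2 else 0
}

#' Simulate a harvested logistic trajectory
#'
#' Iterates [logistic_step()] over a harvest schedule, optionally with
#' multiplicative lognormal process noise drawn under a fixed seed. With the
#' default `noise_centering = "mean"` the deviates are
#' \eqn{\varepsilon_t \sim N(-\sigma_{proc}^2/2, \sigma_{proc}^2)}, so the
#' expected next abundance equals the deterministic prediction;
#' `"median"` centres the deviates at zero instead (median-unbiased).
#'
#' @param N0 Initial abundance, individuals (`>= 0`).
#' @param params A [growth_params()] object; its `sigma_proc` sets the process
#'   noise SD.
#' @param schedule A [harvest_schedule()] (or data frame coercible to one);
#'   one row per simulated interval.
#' @param seed Integer seed for the process deviates, or `NULL` for the
#'   deterministic skeleton (noise is also off when `sigma_proc = 0`).
#' @param timing Harvest ordering, as in [logistic_step()].
#' @param noise_centering `"mean"` (default) or `"median"`.
#'
#' @return A tibble of class `trajectory` with columns `time_index`
#'   (0-based survey epoch), `year`, `N`. The generating parameters, schedule
#'   and seed are attached as attributes `params`, `schedule`, `seed`.
#' @examples
#' p <- growth_params(K = 1.3e6, r_max = 1.3, sigma_proc = 0.05)
#' sched <- harvest_schedule(2014:2020, rate = c(0, 0, 0, 0, 0.629, 0.374, 0.082))
#' simulate_trajectory(254162, p, sched, seed = 1)
#' @export
simulate_trajectory <- function(N0, params, schedule, seed = NULL,
                                timing = c("sequential", "simultaneous"),
                                noise_centering = c("mean", "median")) {
  params <- as_growth_params(params)
  schedule <- as_harvest_schedule(schedule)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  check_scalar(N0, "N0", lower = 0)
  n_step <- nrow(schedule)
  eps <- rep(0, n_step)
  if (!is.null(seed) && params$sigma_proc > 0) {
    eps <- withr::with_seed(as.integer(seed),
                            rnorm(n_step, noise_shift(params$sigma_proc,
                                                      noise_centering),
                                  params$sigma_proc))
  }
  N <- numeric(n_step + 1L)
  N[1L] <- N0
  for (t in seq_len(n_step)) {
    N[t + 1L] <- logistic_step(
      N[t], params,
      rate = if (schedule$type[t] == "rate") schedule$rate[t] else NULL,
      total = if (schedule$type[t] == "total") schedule$total[t] else NULL,
      noise = eps[t], timing = timing
    )
  }
  years <- c(schedule$year, schedule$year[n_step] + 1L)
  out <- tibble(time_index = 0:n_step, year = as.integer(years), N = N)
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  class(out) <- c("trajectory", class(out))
  out
}

#' Maximum sustained harvest rate
#'
#' Under the logistic (Schaefer) model the harvest rate that maximises the
#' long-run sustainable removal is half the maximum intrinsic growth rate,
#' \eqn{h_{msy} = r_{max}/2}.
#'
#' @param r_max Maximum intrinsic growth rate, per year (`> 0`). Vectorised.
#' @return `r_max / 2`.
#' @examples
#' h_msy(1.354) # 0.677
#' @export
h_msy <- function(r_max) {
  if (!is.numeric(r_max) || any(!is.finite(r_max)) || any(r_max <= 0))
    stop_domain("r_max", "must be finite and > 0")
  r_max / 2
}

#' Population doubling time in months
#'
#' Time for an exponentially growing population to double,
#' \eqn{T = \ln(2)/r_{max} \times 12} months.
#'
#' @inheritParams h_msy
#' @return Doubling time in months. Vectorised.
#' @examples
#' doubling_time_months(c(0.548, 1.965)) # about 15 and 4 months
#' @export
doubling_time_months <- function(r_max) {
  if (!is.numeric(r_max) || any(!is.finite(r_max)) || any(r_max <= 0))
    stop_domain("r_max", "must be finite and > 0")
  log(2) / r_max * 12
}

#' Minimum whole-animal harvest achieving a target rate
#'
#' The smallest integer number of removals that achieves at least the target
#' harvest rate at the given abundance, `ceiling(N * target_rate)`. The
#' ceiling guarantees a strictly-met management recommendation such as
#' "harvest rate > 0.700".
#'
#' @param N Abundance, individuals (`>= 0`).
#' @param target_rate Target harvest rate in `[0, 1)`.
#' @return Integer number of individuals.
#' @examples
#' harvest_needed(87751, 0.700) # 61426
#' @export
harvest_needed <- function(N, target_rate) {
  check_scalar(N, "N", lower = 0)
  check_scalar(target_rate, "target_rate", lower = 0, upper = 1, strict_upper = TRUE)
  ceiling(N * target_rate)
}
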