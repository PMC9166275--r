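#' Prior specification for the state-space logistic fit
#'
#' Uniform priors on the three model parameters. The defaults are the
#' Grand Cayman analysis priors: \eqn{K \sim U(900{,}000,\ 2{,}000{,}000)}
#' individuals and \eqn{r_{max} \sim U(0.5,\ 2.0)} per year, with a wide
#' uniform prior on the log-scale process SD, bounded away from zero to avoid
#' a degenerate process layer. The initial latent abundance has a lognormal
#' prior centred on the first survey estimate with that survey's CV; it is
#' part of the model, not of this object.
#'
#' @param K Length-2 numeric `c(lower, upper)`, individuals.
#' @param r_max Length-2 numeric, per year.
#' @param sigma_proc Length-2 numeric, log-scale SD.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()
#' prior_spec(K = c(5e5, 3e6))
#' @export
prior_spec <- function(K = c(9e5, 2e6), r_max = c(0.5, 2.0),
                       sigma_proc = c(0.01, 1.0)) {
  chk <- function(x, field, lower_min = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
      stop_domain(field, "must be a finite numeric c(lower, upper)")
    if (x[1] >= x[2]) stop_domain(field, "lower must be < upper")
    if (strict && x[1] <= lower_min)
      stop_domain(field, sprintf("lower must be > %s", lower_min))
    if (!strict && x[1] < lower_min)
      stop_domain(field, sprintf("lower must be >= %s", lower_min))
    x
  }
  structure(list(
    K = chk(K, "K"),
    r_max = chk(r_max, "r_max"),
    sigma_proc = chk(sigma_proc, "sigma_proc", strict = FALSE)
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s ~ Uniform(%s, %s)\n", nm,
                format(x[[nm]][1], big.mark = ","),
                format(x[[nm]][2], big.mark = ",")))
  invisible(x)
}

# survey-series validation shared by the reader and the constructors ---------

#' Construct a validated survey series
#'
#' A survey series is the observation layer's data: one row per annual
#' survey with the design-based abundance estimate and its standard error.
#' The coefficient of variation `cv = se/mean` is derived and carried along;
#' it fixes the lognormal observation SD on the log scale,
#' \eqn{\sigma_{obs,t} = \sqrt{\ln(1 + CV_t^2)}}.
#'
#' @param year Integer survey years, strictly increasing.
#' @param mean Survey abundance estimates, individuals (`> 0`).
#' @param se Standard errors of the estimates (`> 0`).
#' @return A tibble of class `survey_series` with columns `year`, `mean`,
#'   `se`, `cv`.
#' @examples
#' survey_series(2019:2021, c(103020, 25259, 87751), c(42925, 9485, 34706))
#' @export
survey_series <- function(year, mean, se) {
  n <- length(year)
  if (n == 0L) stop_domain("year", "no data: the survey series is empty")
  if (length(mean) != n || length(se) != n)
    stop_domain("mean/se", "must match the length of `year`")
  year <- as.integer(year)
  if (anyNA(year)) stop_domain("year", "years must parse as integers")
  if (anyDuplicated(year)) {
    stop_domain("year", sprintf("duplicate year %d", year[anyDuplicated(year)]))
  }
  if (is.unsorted(year, strictly = TRUE))
    stop_domain("year", "years must be strictly increasing")
  bad <- which(!is.finite(mean) | mean <= 0)
  if (length(bad))
    stop_domain("mean", sprintf("must be > 0 (year %d, row %d)", year[bad[1]], bad[1]))
  bad <- which(!is.finite(se) | se <= 0)
  if (length(bad))
    stop_domain("se", sprintf("must be > 0 (year %d, row %d)", year[bad[1]], bad[1]))
  out <- tibble(year = year, mean = as.numeric(mean), se = as.numeric(se),
                cv = as.numeric(se) / as.numeric(mean))
  class(out) <- c("survey_series", class(out))
  out
}

as_survey_series <- function(x) {
  if (inherits(x, "survey_series")) return(x)
  if (is.data.frame(x) && all(c("year", "mean", "se") %in% names(x)))
    return(survey_series(x$year, x$mean, x$se))
  stop_domain("surveys", "must be a survey_series or data frame with year, mean, se")
}

# lognormal observation SD from a survey CV
obs_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Observation-layer log likelihood
#'
#' Sum over surveys of the lognormal log density of the observed abundance
#' estimate given the latent true abundance, with the log-scale SD fixed per
#' survey from its CV via \eqn{\sigma_{obs} = \sqrt{\ln(1 + CV^2)}}. The
#' latent state is the lognormal median, so the log likelihood is maximised
#' when every latent state equals its observed estimate.
#'
#' @param N Latent abundances, one per survey (`> 0`).
#' @param surveys A [survey_series()] (or coercible data frame).
#' @return A single log density.
#' @examples
#' s <- survey_series(2020:2021, c(25259, 87751), c(9485, 34706))
#' observation_loglik(c(25259, 87751), s)
#' @export
observation_loglik <- function(N, surveys) {
  surveys <- as_survey_series(surveys)
  if (length(N) != nrow(surveys))
    abort(sprintf("`N` has %d states but the series has %d surveys",
                  length(N), nrow(surveys)),
          class = "iguanaharvest_structure_error")
  if (any(!is.finite(N) | N <= 0)) stop_domain("N", "latent states must be > 0")
  sum(dlnorm(surveys$mean, meanlog = log(N), sdlog = obs_sdlog(surveys$cv),
             log = TRUE))
}

#' Process-layer log likelihood
#'
#' Sum over inter-survey intervals of the Normal log density, on the log
#' scale, of the deviation of each latent state from the deterministic
#' harvested-logistic prediction from its predecessor. Intervals whose
#' deterministic prediction is non-positive (the harvest drives the skeleton
#' to or below zero) contribute `-Inf`: the lognormal process layer has no
#' support there. With `sigma_proc = 0` any non-zero deviation likewise gives
#' `-Inf` (a documented degenerate limit, not an error).
#'
#' @param N Latent abundances, one per survey epoch (`> 0`).
#' @param params A [growth_params()] object (its `sigma_proc` is used).
#' @param schedule A [harvest_schedule()] covering every interval
#'   (`length(N) - 1` rows).
#' @param timing Harvest ordering, as in [logistic_step()].
#' @param noise_centering Process-noise parameterisation, as in
#'   [simulate_trajectory()]; with `"mean"` the Normal deviation is centred
#'   at \eqn{-\sigma_{proc}^2/2}.
#' @return A single log density.
#' @export
process_loglik <- function(N, params, schedule,
                           timing = c("sequential", "simultaneous"),
                           noise_centering = c("mean", "median")) {
  params <- as_growth_params(params)
  schedule <- as_harvest_schedule(schedule)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  T_ <- length(N)
  if (nrow(schedule) != T_ - 1L)
    abort(sprintf("schedule has %d intervals but %d are needed for %d states",
                  nrow(schedule), T_ - 1L, T_),
          class = "iguanaharvest_structure_error")
  if (any(!is.finite(N) | N <= 0)) stop_domain("N", "latent states must be > 0")
  Nt <- N[-T_]
  growth <- Nt + params$r_max * Nt * (1 - Nt / params$K)
  pred <- ifelse(schedule$type == "rate",
                 if (timing == "sequential") growth * (1 - schedule$rate)
                 else growth - schedule$rate * Nt,
                 growth - pmin(schedule$total, pmax(growth, 0)))
  if (any(pred <= 0)) return(-Inf)
  mu <- noise_shift(params$sigma_proc, noise_centering)
  sum(dnorm(log(N[-1L]) - log(pred), mu, params$sigma_proc, log = TRUE))
}

#' Joint log posterior of the state-space logistic model
#'
#' The (unnormalised, but constant-complete) log posterior density over the
#' sampling coordinates \eqn{(K, r_{max}, \sigma_{proc}, \ln N_0 \ldots \ln
#' N_T)}: uniform prior log densities for the three parameters, a lognormal
#' prior on the initial latent state centred on the first survey estimate
#' with its CV, the process layer ([process_loglik()]) and the observation
#' layer ([observation_loglik()]). This is the exact function the MCMC
#' sampler targets; it is exported so the density can be audited point-wise.
#'
#' @inheritParams process_loglik
#' @param surveys A [survey_series()] aligned 1:1 with `N`.
#' @param priors A [prior_spec()].
#' @return A single log density (`-Inf` outside the support).
#' @export
log_posterior <- function(N, params, surveys, schedule, priors = prior_spec(),
                          timing = c("sequential", "simultaneous"),
                          noise_centering = c("mean", "median")) {
  params <- as_growth_params(params)
  surveys <- as_survey_series(surveys)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  lp_unif <- function(x, b) if (x < b[1] || x > b[2]) -Inf else -log(b[2] - b[1])
  lp <- lp_unif(params$K, priors$K) +
    lp_unif(params$r_max, priors$r_max) +
    lp_unif(params$sigma_proc, priors$sigma_proc)
  if (!is.finite(lp)) return(-Inf)
  if (any(!is.finite(N) | N <= 0)) return(-Inf)
  # N0 prior in the log coordinate: Normal(log first estimate, obs sdlog)
  lp <- lp + dnorm(log(N[1]), log(surveys$mean[1]), obs_sdlog(surveys$cv[1]),
                   log = TRUE)
  lp + process_loglik(N, params, schedule, timing, noise_centering) +
    observation_loglik(N, surveys)
}

# ---------------------------------------------------------------------------
# MCMC engine: adaptive scalar random-walk Metropolis-within-Gibbs over
# (K, r_max, sigma_proc, lnN_0..lnN_T). Step sizes adapt in batches during
# burn-in only and are frozen afterwards, keeping the retained chain
# Markovian. Proposals falling outside the uniform prior support are
# rejected, so the priors stay exact.
# ---------------------------------------------------------------------------

# fast closure-based log posterior over theta = c(K, r, sigma, lnN...)
make_lp <- function(surveys, schedule, priors, sequential = TRUE,
                    mean_centered = TRUE) {
  y <- surveys$mean
  logy <- log(y)
  sobs <- obs_sdlog(surveys$cv)
  T_ <- length(y)
  is_rate <- schedule$type == "rate"
  hvec <- ifelse(is_rate, schedule$rate, 0)
  tvec <- ifelse(is_rate, 0, schedule$total)
  surv <- if (sequential) 1 - hvec else 1 # sequential: multiplicative removal
  Kb <- priors$K; rb <- priors$r_max; sb <- priors$sigma_proc
  lp_const <- -log(Kb[2] - Kb[1]) - log(rb[2] - rb[1]) - log(sb[2] - sb[1])
  obs_const <- -sum(logy) # dlnorm(y) = dnorm(log y) - log y
  function(theta) {
    K <- theta[1L]; r <- theta[2L]; sig <- theta[3L]
    if (K < Kb[1] || K > Kb[2] || r < rb[1] || r > rb[2] ||
        sig < sb[1] || sig > sb[2]) return(-Inf)
    lnN <- theta[-(1:3)]
    N <- exp(lnN)
    Nt <- N[-T_]
    growth <- Nt + r * Nt * (1 - Nt / K)
    pred <- if (sequential) growth * surv - pmin(tvec, pmax(growth, 0))
            else growth - hvec * Nt - pmin(tvec, pmax(growth, 0))
    if (any(pred <= 0)) return(-Inf)
    mu <- if (mean_centered) log(pred) - sig^2 / 2 else log(pred)
    lp_const +
      dnorm(lnN[1L], logy[1L], sobs[1L], log = TRUE) +
      sum(dnorm(lnN[-1L], mu, sig, log = TRUE)) +
      sum(dnorm(logy, lnN, sobs, log = TRUE)) + obs_const
  }
}

# overdispersed start: parameters from the priors, latent states jittered
# around the observed series; redrawn until the posterior is finite
draw_start <- function(lp_fun, surveys, priors, max_tries = 2000L) {
  T_ <- nrow(surveys)
  for (i in seq_len(max_tries)) {
    theta <- c(runif(1, priors$K[1], priors$K[2]),
               runif(1, priors$r_max[1], priors$r_max[2]),
               runif(1, priors$sigma_proc[1], priors$sigma_proc[2]),
               log(surveys$mean) + rnorm(T_, 0, 0.05))
    if (is.finite(lp_fun(theta))) return(theta)
  }
  abort("could not find a finite-posterior starting point; check that the harvest schedule is compatible with the survey series",
        class = "iguanaharvest_mcmc_error")
}

run_one_chain <- function(lp_fun, theta, n_iter, n_burn, thin, step) {
  d <- length(theta)
  lp <- lp_fun(theta)
  n_keep <- (n_iter - n_burn) %/% thin
  out <- matrix(NA_real_, n_keep, d)
  acc <- integer(d); batch_acc <- integer(d)
  batch <- 100L
  k <- 0L
  for (i in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- theta
      prop[j] <- theta[j] + rnorm(1L) * step[j]
      lp_new <- lp_fun(prop)
      if (lp_new - lp > log(runif(1L))) {
        theta <- prop; lp <- lp_new
        acc[j] <- acc[j] + 1L; batch_acc[j] <- batch_acc[j] + 1L
      }
    }
    if (i <= n_burn && i %% batch == 0L) {
      rate <- batch_acc / batch
      step <- step * exp(pmin(0.5, pmax(-0.5, rate - 0.44)) * 0.5)
      batch_acc[] <- 0L
    }
    if (i > n_burn && (i - n_burn) %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- theta
    }
  }
  list(draws = out, acceptance = acc / n_iter, step = step)
}

#' Run the MCMC sampler for the state-space logistic model
#'
#' Adaptive random-walk Metropolis-within-Gibbs over
#' \eqn{(K, r_{max}, \sigma_{proc}, \ln N_0, \ldots, \ln N_T)}, targeting
#' [log_posterior()]. Step sizes adapt toward a 44\% scalar acceptance rate
#' in batches of 100 during burn-in and are frozen afterwards. Chains start
#' overdispersed, with parameters drawn from their priors. Fully reproducible
#' for a fixed seed.
#'
#' @param surveys A [survey_series()] with at least 3 surveys.
#' @param schedule A [harvest_schedule()] with one interval per survey gap.
#' @param priors A [prior_spec()].
#' @param chains Number of chains (`>= 2` so convergence can be assessed).
#' @param iter Iterations per chain (including burn-in).
#' @param burn Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed.
#' @param timing Harvest ordering, as in [logistic_step()].
#' @param noise_centering Process-noise parameterisation, as in
#'   [simulate_trajectory()].
#' @return A tibble with one row per retained draw: columns `.chain`,
#'   `.iteration`, `K`, `r_max`, `sigma_proc` and one `N_<year>` column per
#'   survey. Acceptance rates and frozen step sizes are attached as
#'   attributes `acceptance` and `step`.
#' @seealso [fit_logistic_ssm()] for the high-level interface.
#' @export
run_mcmc <- function(surveys, schedule, priors = prior_spec(), chains = 4,
                     iter = 50000, burn = iter %/% 2, thin = 10, seed = 1,
                     timing = c("sequential", "simultaneous"),
                     noise_centering = c("mean", "median")) {
  surveys <- as_survey_series(surveys)
  schedule <- as_harvest_schedule(schedule)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  if (nrow(surveys) < 3L)
    abort("at least 3 surveys are required to fit the model",
          class = "iguanaharvest_domain_error")
  if (nrow(schedule) != nrow(surveys) - 1L)
    abort(sprintf("schedule has %d intervals; %d surveys need %d",
                  nrow(schedule), nrow(surveys), nrow(surveys) - 1L),
          class = "iguanaharvest_structure_error")
  if (chains < 2L) stop_domain("chains", "must be >= 2")
  if (!(iter > burn && burn >= 0)) stop_domain("iter/burn", "need iter > burn >= 0")
  lp_fun <- make_lp(surveys, schedule, priors,
                    sequential = timing == "sequential",
                    mean_centered = noise_centering == "mean")
  T_ <- nrow(surveys)
  step0 <- c(0.1 * diff(priors$K), 0.1 * diff(priors$r_max),
             0.1 * diff(priors$sigma_proc), rep(0.4, T_))
  res <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(chains), function(ch) {
      theta0 <- draw_start(lp_fun, surveys, priors)
      run_one_chain(lp_fun, theta0, as.integer(iter), as.integer(burn),
                    as.integer(thin), step0)
    })
  })
  acc <- vapply(res, `[[`, numeric(3L + T_), "acceptance")
  if (all(acc == 0))
    abort("zero acceptance after adaptation; widen or narrow the proposal steps",
          class = "iguanaharvest_mcmc_error")
  cols <- c("K", "r_max", "sigma_proc", paste0("N_", surveys$year))
  draws <- purrr::map_dfr(seq_len(chains), function(ch) {
    m <- res[[ch]]$draws
    m[, -(1:3)] <- exp(m[, -(1:3)])
    colnames(m) <- cols
    d <- as_tibble(m)
    d$.chain <- ch
    d$.iteration <- seq_len(nrow(m))
    d[, c(".chain", ".iteration", cols)]
  })
  attr(draws, "acceptance") <- acc
  attr(draws, "step") <- vapply(res, `[[`, numeric(3L + T_), "step")
  draws
}

# ---------------------------------------------------------------------------
# convergence diagnostics (split-chain Rhat, Geyer initial-monotone ESS)
# ---------------------------------------------------------------------------

split_chains <- function(x_by_chain) {
  unlist(lapply(x_by_chain, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the split halves; values near 1 indicate that the
#' chains have mixed.
#'
#' @param x Numeric vector of draws.
#' @param chain Integer chain id per draw.
#' @return The split-chain Rhat statistic.
#' @export
rhat_split <- function(x, chain) {
  halves <- split_chains(split(x, chain))
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Geyer's initial-monotone-sequence estimator applied per chain and pooled:
#' autocorrelations are summed in consecutive pairs until a pair turns
#' negative.
#'
#' @inheritParams rhat_split
#' @return Estimated effective sample size.
#' @export
ess_draws <- function(x, chain) {
  by_chain <- split(x, chain)
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho_chain <- lapply(by_chain, function(xc) {
    nc <- length(xc)
    a <- stats::acf(xc, lag.max = min(nc - 1L, 500L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  })
  lag_max <- min(lengths(rho_chain))
  rho <- rowMeans(vapply(rho_chain, function(a) a[seq_len(lag_max)],
                         numeric(lag_max)))
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; stop when non-positive,
  # enforce monotone decrease
  tau <- 1
  prev <- Inf
  k <- 1L
  while (k + 1L <= lag_max) {
    g <- rho[k + 1L] + ifelse(k + 2L <= lag_max, rho[k + 2L], 0)
    if (g <= 0) break
    g <- min(g, prev)
    tau <- tau + 2 * g
    prev <- g
    k <- k + 2L
  }
  max(1, n / tau)
}

#' Summarise posterior draws
#'
#' Per-quantity posterior mean, SD, median, 2.5th and 97.5th percentiles,
#' effective sample size and split-chain Rhat. The maximum sustained harvest
#' rate `h_msy` is summarised by transforming every retained draw via
#' [h_msy()] — never by halving the summaries of `r_max`.
#'
#' @param draws A draws tibble from [run_mcmc()] (or the `$draws` element of
#'   an [fit_logistic_ssm()] fit).
#' @param quantities Character vector of columns to summarise; `"h_msy"` is
#'   always available as a derived quantity. Defaults to the three model
#'   parameters plus `h_msy`.
#' @return A tibble with one row per quantity: `term`, `mean`, `sd`,
#'   `median`, `q2.5`, `q97.5`, `ess`, `rhat`.
#' @export
summarize_posterior <- function(draws,
                                quantities = c("K", "r_max", "h_msy",
                                               "sigma_proc")) {
  if (is.null(draws) || nrow(draws) == 0L)
    abort("no draws to summarise", class = "iguanaharvest_domain_error")
  if (!"h_msy" %in% names(draws) && "r_max" %in% names(draws))
    draws$h_msy <- h_msy(draws$r_max)
  missing_q <- setdiff(quantities, names(draws))
  if (length(missing_q))
    stop_domain("quantities", paste("not in draws:", toString(missing_q)))
  chain <- if (".chain" %in% names(draws)) draws$.chain else rep(1L, nrow(draws))
  purrr::map_dfr(quantities, function(q) {
    x <- draws[[q]]
    qs <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    tibble(term = q, mean = mean(x), sd = sd(x), median = qs[2],
           q2.5 = qs[1], q97.5 = qs[3],
           ess = ess_draws(x, chain), rhat = rhat_split(x, chain))
  })
}

#' Fit the Bayesian state-space logistic model
#'
#' The high-level fitting interface: validates the survey series and harvest
#' schedule, runs [run_mcmc()], and returns a fit object carrying the
#' retained draws, posterior summary, data and settings. Use [tidy()] for
#' the summary table, [glance()] for one-row diagnostics, [project()] to
#' push the fit forward under harvest scenarios, and [autoplot()] for the
#' posterior marginals.
#'
#' @inheritParams run_mcmc
#' @return An object of class `ssm_fit`.
#' @examples
#' \donttest{
#' fit <- fit_logistic_ssm(iguana_surveys(), iguana_harvest(),
#'                         iter = 4000, burn = 2000, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_logistic_ssm <- function(surveys, schedule, priors = prior_spec(),
                             chains = 4, iter = 50000, burn = iter %/% 2,
                             thin = 10, seed = 1,
                             timing = c("sequential", "simultaneous"),
                             noise_centering = c("mean", "median")) {
  surveys <- as_survey_series(surveys)
  schedule <- as_harvest_schedule(schedule)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  t0 <- Sys.time()
  draws <- run_mcmc(surveys, schedule, priors, chains = chains, iter = iter,
                    burn = burn, thin = thin, seed = seed, timing = timing,
                    noise_centering = noise_centering)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  latent <- paste0("N_", surveys$year)
  summary <- summarize_posterior(
    draws, quantities = c("K", "r_max", "h_msy", "sigma_proc", latent))
  structure(list(
    draws = draws, summary = summary, surveys = surveys, schedule = schedule,
    priors = priors,
    settings = list(chains = chains, iter = iter, burn = burn, thin = thin,
                    seed = seed, timing = timing,
                    noise_centering = noise_centering),
    runtime = elapsed
  ), class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat("Bayesian state-space logistic model fit\n")
  cat(sprintf("  %d surveys (%d-%d), %d chains x %d iterations (burn %d, thin %d), %d draws\n",
              nrow(x$surveys), min(x$surveys$year), max(x$surveys$year),
              x$settings$chains, x$settings$iter, x$settings$burn,
              x$settings$thin, nrow(x$draws)))
  print(as.data.frame(head(x$summary, 4)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy the posterior summary of a state-space fit
#'
#' @param x An `ssm_fit` object.
#' @param ... Unused.
#' @return The posterior summary tibble (one row per parameter, derived
#'   quantity and latent state).
#' @export
tidy.ssm_fit <- function(x, ...) x$summary

#' One-row diagnostics for a state-space fit
#'
#' @param x An `ssm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: draw counts, worst Rhat and smallest ESS over
#'   the model parameters, a convergence flag (`max_rhat < 1.05`), and
#'   runtime in seconds.
#' @export
glance.ssm_fit <- function(x, ...) {
  pars <- x$summary[x$summary$term %in% c("K", "r_max", "sigma_proc"), ]
  tibble(n_draws = nrow(x$draws), n_chains = x$settings$chains,
         n_iter = x$settings$iter, max_rhat = max(pars$rhat),
         min_ess = min(pars$ess), converged = max(pars$rhat) < 1.05,
         runtime_s = x$runtime)
}
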