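#' Generate a fully synthetic harvest study
#'
#' Builds a complete synthetic data set with the statistical structure the
#' analysis assumes: a latent logistic trajectory with multiplicative
#' lognormal process noise, removals proportional to abundance (or fixed
#' totals), and survey estimates drawn lognormally around the *latent*
#' states with per-year CVs fixed by design — the hierarchical structure the
#' state-space fit estimates. Standard errors are reported as
#' `se = cv * mean`, mirroring how survey CVs are computed from real data.
#'
#' @param params True [growth_params()] (including `sigma_proc`).
#' @param N0 True initial abundance.
#' @param schedule A [harvest_schedule()]; the study spans
#'   `nrow(schedule) + 1` surveys.
#' @param cv_design Survey CV design: a single CV or one per survey year
#'   (`> 0`). Defaults to the eight empirical Grand Cayman survey CVs so
#'   recovery experiments reflect realistic survey precision (requires a
#'   7-interval schedule).
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param timing,noise_centering Model form for the latent trajectory, as in
#'   [simulate_trajectory()].
#' @return An object of class `synthetic_study`: `$surveys` (a
#'   [survey_series()]), `$harvest` (the schedule), `$truth` (a list with
#'   `params`, `N0` and the latent `trajectory`), `$cv_design`, `$seed`.
#' @examples
#' st <- generate_study(growth_params(1.3e6, 1.3, 0.05), N0 = 254162,
#'                      schedule = iguana_harvest(), seed = 42)
#' st$surveys
#' @export
generate_study <- function(params, N0, schedule,
                           cv_design = NULL, seed = 1,
                           timing = c("sequential", "simultaneous"),
                           noise_centering = c("mean", "median")) {
  params <- as_growth_params(params)
  schedule <- as_harvest_schedule(schedule)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  n_years <- nrow(schedule) + 1L
  if (n_years < 3L) stop_domain("schedule", "need at least 3 survey years")
  cv_design <- cv_design %||% iguana_surveys()$cv[seq_len(n_years)]
  if (length(cv_design) == 1L) cv_design <- rep(cv_design, n_years)
  if (length(cv_design) != n_years)
    stop_domain("cv_design", sprintf("need 1 or %d CVs", n_years))
  if (any(!is.finite(cv_design) | cv_design <= 0))
    stop_domain("cv_design", "CVs must be > 0")
  res <- withr::with_seed(as.integer(seed), {
    traj <- simulate_trajectory(N0, params, schedule,
                                seed = sample.int(2^31 - 1L, 1L),
                                timing = timing,
                                noise_centering = noise_centering)
    if (any(traj$N <= 0))
      abort("the latent trajectory hit zero; synthetic surveys need a positive population",
            class = "iguanaharvest_domain_error")
    sdlog <- obs_sdlog(cv_design)
    obs <- stats::rlnorm(n_years, meanlog = log(traj$N), sdlog = sdlog)
    list(traj = traj, obs = obs)
  })
  surveys <- survey_series(res$traj$year, res$obs, cv_design * res$obs)
  structure(list(
    surveys = surveys, harvest = schedule,
    truth = list(params = params, N0 = N0, trajectory = res$traj),
    cv_design = cv_design, seed = as.integer(seed)
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d surveys, seed %d\n", nrow(x$surveys), x$seed))
  cat(sprintf("  truth: K = %s, r_max = %.3f, sigma_proc = %.3f\n",
              format(x$truth$params$K, big.mark = ","),
              x$truth$params$r_max, x$truth$params$sigma_proc))
  print(as.data.frame(x$surveys), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' The end-to-end validation harness for the whole pipeline: repeatedly
#' generates a synthetic study from known truth ([generate_study()]), fits
#' it ([fit_logistic_ssm()]), and records, per replicate and parameter, the
#' posterior mean error and whether the central 95\% posterior interval
#' covers the truth. Replicates failing the convergence gate
#' (split-chain Rhat `>= 1.05` on any model parameter) are flagged in the
#' output, never silently dropped.
#'
#' @param params True [growth_params()].
#' @param N0 True initial abundance.
#' @param schedule Harvest schedule shared by all replicates.
#' @param cv_design Survey CV design (see [generate_study()]).
#' @param n_replicates Number of replicate studies (`>= 10` for coverage
#'   claims).
#' @param priors,chains,iter,burn,thin MCMC settings passed to
#'   [fit_logistic_ssm()].
#' @param seed Integer master seed; replicate seeds derive from it.
#' @return A list of class `recovery_report`: `$replicates` has one row per
#'   replicate and parameter (`replicate`, `term`, `truth`, `estimate`,
#'   `q2.5`, `q97.5`, `covered`, `rel_error`, `converged`); `$summary`
#'   aggregates per parameter (`bias`, `rel_bias`, `rmse`, `coverage`,
#'   `n_converged`).
#' @export
recovery_experiment <- function(params, N0, schedule, cv_design = NULL,
                                n_replicates = 20, priors = prior_spec(),
                                chains = 2, iter = 20000, burn = iter %/% 2,
                                thin = 5, seed = 1,
                                timing = c("sequential", "simultaneous"),
                                noise_centering = c("mean", "median")) {
  params <- as_growth_params(params)
  timing <- match.arg(timing)
  noise_centering <- match.arg(noise_centering)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  truth <- c(K = params$K, r_max = params$r_max,
             sigma_proc = params$sigma_proc)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(2^31 - 2L, n_replicates))
  replicates <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    st <- generate_study(params, N0, schedule, cv_design, seed = rep_seeds[i],
                         timing = timing, noise_centering = noise_centering)
    fit <- fit_logistic_ssm(st$surveys, st$harvest, priors = priors,
                            chains = chains, iter = iter, burn = burn,
                            thin = thin, seed = rep_seeds[i],
                            timing = timing, noise_centering = noise_centering)
    s <- fit$summary[fit$summary$term %in% names(truth), ]
    conv <- max(s$rhat) < 1.05
    tr <- unname(truth[s$term])
    tibble(replicate = i, term = s$term, truth = tr,
           estimate = s$mean, q2.5 = s$q2.5, q97.5 = s$q97.5,
           covered = s$q2.5 <= tr & tr <= s$q97.5,
           rel_error = (s$mean - tr) / tr,
           converged = conv)
  })
  summary <- replicates |>
    group_by(.data$term) |>
    summarise(
      truth = first(.data$truth),
      bias = mean(.data$estimate - .data$truth),
      rel_bias = mean(.data$rel_error),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      n_converged = sum(.data$converged),
      .groups = "drop"
    )
  structure(list(replicates = replicates, summary = summary,
                 n_replicates = n_replicates, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d synthetic replicates\n",
              x$n_replicates))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) x$summary
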