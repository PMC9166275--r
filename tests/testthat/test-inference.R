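test_that("observation log likelihood matches the closed-form lognormal density", {
  # single survey, estimate 100, CV chosen so the log-scale SD is exactly 1
  cv <- sqrt(exp(1) - 1)
  s <- survey_series(2020, 100, se = 100 * cv)
  expect_equal(observation_loglik(100, s), -log(100) - 0.5 * log(2 * pi))
  # and against the longhand oracle at several latent states
  for (N in c(10, 100, 1000))
    expect_equal(observation_loglik(N, s), oracle_dlnorm(100, log(N), 1))
})

test_that("observation log likelihood peaks when latent states equal the estimates", {
  s <- tiny_surveys()
  base <- observation_loglik(s$mean, s)
  for (j in seq_len(nrow(s))) for (f in c(0.8, 1.25)) {
    N <- s$mean
    N[j] <- N[j] * f
    expect_lt(observation_loglik(N, s), base)
  }
  expect_lt(observation_loglik(2 * s$mean, s), base)
})

test_that("process log likelihood is exact on the deterministic skeleton and vanishes off-support", {
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0.2)
  sched <- harvest_schedule(2019:2020, rate = c(0.374, 0.082))
  det <- simulate_trajectory(103020, p, sched) # no seed: skeleton
  # median-centred: every deviation is 0, so each term is dnorm(0, 0, sigma)
  expect_equal(process_loglik(det$N, p, sched, noise_centering = "median"),
               2 * oracle_dnorm(0, 0, 0.2))
  # mean-centred: deviations sit at +sigma^2/2 relative to the shifted mean
  expect_equal(process_loglik(det$N, p, sched, noise_centering = "mean"),
               2 * oracle_dnorm(0, -0.2^2 / 2, 0.2))
  # one interval against the scalar normal pdf oracle
  s1 <- harvest_schedule(2019, rate = 0.374)
  pred <- oracle_step(103020, 1.3e6, 1.3, 0.374)
  expect_equal(process_loglik(c(103020, 25259), p, s1, noise_centering = "median"),
               oracle_dnorm(log(25259) - log(pred), 0, 0.2))
  # harvest total exceeding the grown population: prediction <= 0
  s2 <- harvest_schedule(2019, total = 1e9)
  expect_identical(process_loglik(c(103020, 25259), p, s2), -Inf)
  # degenerate sigma_proc = 0 with a non-zero deviation
  p0 <- growth_params(1.3e6, 1.3, sigma_proc = 0)
  expect_identical(process_loglik(c(103020, 25259), p0, s1), -Inf)
})

test_that("misaligned latent states raise structural errors", {
  s <- tiny_surveys()
  expect_error(observation_loglik(c(1, 2), s), "3 surveys")
  p <- growth_params(1e6, 1.2, 0.1)
  expect_error(process_loglik(c(100, 200), p, cayman_schedule()), "intervals")
})

test_that("log posterior equals an independently coded brute-force density sum", {
  surveys <- iguana_surveys()
  sched <- iguana_harvest()
  priors <- prior_spec()
  points <- list(
    list(K = 1378259, r = 1.323, sig = 0.2, N = surveys$mean),
    list(K = 1e6, r = 0.6, sig = 0.8, N = surveys$mean * 0.7),
    list(K = 1.9e6, r = 1.9, sig = 0.05, N = surveys$mean * 1.3),
    list(K = 1.2e6, r = 1.0, sig = 0.5,
         N = c(2e5, 4e5, 8e5, 1.1e6, 1.3e6, 2e5, 5e4, 9e4)),
    list(K = 1.5e6, r = 1.5, sig = 0.99, N = rep(5e5, 8))
  )
  for (pt in points) for (timing in c("sequential", "simultaneous"))
    for (centering in c("mean", "median")) {
      got <- log_posterior(pt$N, growth_params(pt$K, pt$r, pt$sig),
                           surveys, sched, priors,
                           timing = timing, noise_centering = centering)
      want <- oracle_log_posterior(surveys, sched, pt$K, pt$r, pt$sig, pt$N,
                                   timing == "sequential",
                                   centering == "mean")
      expect_equal(got, want, tolerance = 1e-8)
    }
})

test_that("the sampler is seed-reproducible and respects prior support", {
  s <- iguana_surveys()
  h <- iguana_harvest()
  d1 <- run_mcmc(s, h, chains = 2, iter = 1500, burn = 500, thin = 2, seed = 5)
  d2 <- run_mcmc(s, h, chains = 2, iter = 1500, burn = 500, thin = 2, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$K >= 9e5 & d1$K <= 2e6))
  expect_true(all(d1$r_max >= 0.5 & d1$r_max <= 2))
  expect_true(all(d1$sigma_proc >= 0.01 & d1$sigma_proc <= 1))
  latent <- as.matrix(d1[, grep("^N_", names(d1))])
  expect_true(all(latent > 0))
})

test_that("near-degenerate priors dominate the posterior", {
  eps <- 1e-4
  pr <- prior_spec(K = c(1.3e6, 1.3e6 * (1 + eps)),
                   r_max = c(1.2, 1.2 * (1 + eps)),
                   sigma_proc = c(0.5, 0.5 * (1 + eps)))
  d <- run_mcmc(iguana_surveys(), iguana_harvest(), priors = pr,
                chains = 2, iter = 1000, burn = 500, thin = 1, seed = 3)
  expect_equal(mean(d$K), 1.3e6, tolerance = eps)
  expect_equal(mean(d$r_max), 1.2, tolerance = eps)
  expect_equal(mean(d$sigma_proc), 0.5, tolerance = eps)
})

test_that("posterior summaries transform draws, not summaries", {
  d <- tibble::tibble(.chain = rep(1:2, each = 50), r_max = seq(0.5, 2, length.out = 100),
                      K = seq(9e5, 2e6, length.out = 100))
  s <- summarize_posterior(d, quantities = c("K", "r_max", "h_msy"))
  # monotone map: quantiles commute
  expect_equal(s$median[s$term == "h_msy"], s$median[s$term == "r_max"] / 2)
  expect_equal(s$mean[s$term == "h_msy"], mean(d$r_max) / 2)
  # all-identical draws collapse every summary
  d2 <- tibble::tibble(.chain = rep(1:2, each = 10), K = rep(1e6, 20))
  s2 <- summarize_posterior(d2, quantities = "K")
  expect_equal(s2$sd, 0)
  expect_equal(s2$q2.5, s2$q97.5)
  expect_error(summarize_posterior(tibble::tibble()), "no draws")
})

test_that("sampler refuses invalid designs", {
  s <- tiny_surveys()
  expect_error(run_mcmc(s[1:2, ], harvest_schedule(2019, rate = 0.1),
                        chains = 2, iter = 100, burn = 10, seed = 1),
               "at least 3")
  expect_error(run_mcmc(s, harvest_schedule(2019, rate = 0.1),
                        chains = 2, iter = 100, burn = 10, seed = 1),
               "intervals")
  expect_error(fit_logistic_ssm(s, harvest_schedule(2019:2020, rate = c(0, 0)),
                                chains = 1, iter = 100, burn = 10, seed = 1),
               "chains")
})

test_that("split-chain rhat and ESS behave on known draw patterns", {
  set.seed(1)
  x <- rnorm(4000)
  chain <- rep(1:4, each = 1000)
  expect_lt(abs(rhat_split(x, chain) - 1), 0.02)
  # iid draws: ESS close to the sample size
  expect_gt(ess_draws(x, chain), 2000)
  # disjoint chains: rhat far above 1
  y <- rnorm(2000) + rep(c(0, 50), each = 1000)
  expect_gt(rhat_split(y, rep(1:2, each = 1000)), 2)
  # highly autocorrelated chain: ESS much smaller than n
  z <- as.numeric(stats::filter(rnorm(4000), 0.95, method = "recursive"))
  expect_lt(ess_draws(z, chain), 1000)
})
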