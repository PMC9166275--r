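test_that("the generator reproduces the latent states in the noise-free limit", {
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0)
  st <- generate_study(p, N0 = 254162, schedule = cayman_schedule(),
                       cv_design = 1e-9, seed = 7)
  skel <- simulate_trajectory(254162, p, cayman_schedule())
  expect_equal(st$surveys$mean, skel$N, tolerance = 1e-6)
  expect_equal(st$surveys$se, 1e-9 * st$surveys$mean)
})

test_that("identical seeds give identical studies", {
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0.05)
  a <- generate_study(p, 254162, cayman_schedule(), seed = 101)
  b <- generate_study(p, 254162, cayman_schedule(), seed = 101)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$truth$trajectory$N, b$truth$trajectory$N)
  c <- generate_study(p, 254162, cayman_schedule(), seed = 102)
  expect_false(identical(a$surveys$mean, c$surveys$mean))
})

test_that("an iguana-like preset rises toward K then declines after harvest onset", {
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0.05)
  st <- generate_study(p, 254162, cayman_schedule(), seed = 42)
  latent <- st$truth$trajectory$N
  # harvest starts in the 2018 interval: the latent peak is the pre-harvest year
  expect_equal(which.max(latent), 5L) # 2018
  # the printed annual rates knock the population down at onset but cannot
  # hold it down: rates below h_msy let it rebound
  expect_lt(latent[6], 0.5 * max(latent))
  expect_gt(latent[8], latent[6])
  # the default CV design copies the empirical survey CVs
  expect_equal(st$cv_design, iguana_surveys()$cv)
  # the effective annual removals of the real cull (~0.92 then ~0.80)
  # reproduce the observed deep collapse: minimum under 10% of the peak,
  # in the latent and the observed series alike at this seed
  eff <- harvest_schedule(2014:2020, rate = c(0, 0, 0, 0, 0.92, 0.80, 0.082))
  st2 <- generate_study(p, 254162, eff, seed = 42)
  lat2 <- st2$truth$trajectory$N
  expect_equal(which.max(lat2), 5L)
  expect_lt(min(lat2[6:8]), 0.1 * max(lat2))
  # the observed peak lands in a pre-harvest year (survey noise can swap
  # neighbouring high years), and the observed collapse is deep
  expect_lte(which.max(st2$surveys$mean), 5L)
  expect_lt(min(st2$surveys$mean[6:8]), 0.15 * max(st2$surveys$mean))
})

test_that("observed estimates obey the lognormal mean identity", {
  # constant latent population at K, fixed CV: across ~10,000 draws the
  # sample mean of the observed estimates must sit within 3 Monte-Carlo SEs
  # of N * exp(sdlog^2 / 2)
  p <- growth_params(1e6, 1.0, sigma_proc = 0)
  sched <- harvest_schedule(1:2, rate = c(0, 0))
  cv <- 0.3
  obs <- unlist(lapply(1:3334, function(i)
    generate_study(p, 1e6, sched, cv_design = cv, seed = i)$surveys$mean))
  sdlog <- sqrt(log(1 + cv^2))
  expected <- 1e6 * exp(sdlog^2 / 2)
  mcse <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * mcse)
})

test_that("studies round-trip through the plain-text writers field-for-field", {
  dir <- withr::local_tempdir()
  p <- growth_params(1.25e6, 1.4, sigma_proc = 0.08)
  st <- generate_study(p, 2e5, cayman_schedule(), seed = 31)
  write_study(st, dir)
  expect_setequal(list.files(dir), c("surveys.csv", "harvest.csv", "truth.json"))
  back <- read_study(dir)
  expect_equal(back$surveys, st$surveys)
  expect_equal(back$harvest$rate, st$harvest$rate)
  expect_equal(unclass(back$truth$params), unclass(st$truth$params))
  expect_equal(back$truth$trajectory$N, st$truth$trajectory$N)
  expect_equal(back$cv_design, st$cv_design)
  expect_identical(back$seed, st$seed)
})

test_that("CV design is validated", {
  p <- growth_params(1.3e6, 1.3, 0.05)
  expect_error(generate_study(p, 1e5, cayman_schedule(), cv_design = -0.1,
                              seed = 1), "cv_design")
  expect_error(generate_study(p, 1e5, cayman_schedule(),
                              cv_design = rep(0.2, 3), seed = 1), "cv_design")
})

test_that("fitting a shuffled-year series is flagged by the harness", {
  # strong-signal study: tight surveys, tiny process noise
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0.03)
  st <- generate_study(p, 254162, cayman_schedule(), cv_design = 0.05,
                       seed = 11)
  fit_clean <- fit_logistic_ssm(st$surveys, st$harvest, chains = 2,
                                iter = 4000, burn = 2000, thin = 2, seed = 1)
  s_clean <- tidy(fit_clean)
  sig_clean <- s_clean[s_clean$term == "sigma_proc", ]
  expect_true(sig_clean$q2.5 <= 3 * 0.03) # clean fit: sigma_proc plausible
  # permute the survey labels: same numbers, impossible dynamics
  perm <- c(6, 3, 8, 1, 5, 2, 7, 4)
  shuffled <- survey_series(st$surveys$year, st$surveys$mean[perm],
                            st$surveys$se[perm])
  fit_bad <- fit_logistic_ssm(shuffled, st$harvest, chains = 2,
                              iter = 4000, burn = 2000, thin = 2, seed = 1)
  s_bad <- tidy(fit_bad)
  sig_bad <- s_bad[s_bad$term == "sigma_proc", ]
  gate_failed <- max(s_bad$rhat[s_bad$term %in% c("K", "r_max", "sigma_proc")]) >= 1.05
  # either the chains fail the convergence gate or the process-noise interval
  # collapses away from the truth (coverage failure on sigma_proc)
  expect_true(gate_failed || sig_bad$q2.5 > 3 * 0.03)
})

test_that("a small recovery experiment reports bias, RMSE, coverage and convergence", {
  p <- growth_params(1.3e6, 1.3, sigma_proc = 0.05)
  rec <- recovery_experiment(p, N0 = 254162, schedule = cayman_schedule(),
                             cv_design = 0.1, n_replicates = 3, chains = 2,
                             iter = 2500, burn = 1500, thin = 2, seed = 5)
  expect_equal(nrow(rec$replicates), 9L) # 3 replicates x 3 parameters
  expect_setequal(rec$summary$term, c("K", "r_max", "sigma_proc"))
  expect_true(all(c("bias", "rel_bias", "rmse", "coverage", "n_converged") %in%
                    names(rec$summary)))
  expect_true(all(rec$summary$coverage >= 0 & rec$summary$coverage <= 1))
  # convergence flags are carried per replicate, never dropped
  expect_true(all(!is.na(rec$replicates$converged)))
})
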