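# shared fixtures, built in code

pars_paper <- function(sigma = 0) growth_params(K = 1378259, r_max = 1.323,
                                                sigma_proc = sigma)

cayman_schedule <- function() {
  harvest_schedule(2014:2020, rate = c(0, 0, 0, 0, 0.629, 0.374, 0.082))
}

tiny_surveys <- function() {
  survey_series(2019:2021, c(103020, 25259, 87751), c(42925, 9485, 34706))
}

# one small-but-converged fit on the packaged data, shared across test files
small_cayman_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit))
      fit <<- fit_logistic_ssm(iguana_surveys(), iguana_harvest(),
                               chains = 2, iter = 6000, burn = 3000,
                               thin = 2, seed = 99)
    fit
  }
})

# independent one-step oracle: plain arithmetic, no package code
oracle_step <- function(N, K, r, h = 0, sequential = TRUE) {
  G <- N + r * N * (1 - N / K)
  if (sequential) max(0, G * (1 - h)) else max(0, G - h * N)
}

# independent normal/lognormal log densities, written out longhand
oracle_dnorm <- function(x, mu, sd) {
  -0.5 * log(2 * pi) - log(sd) - 0.5 * ((x - mu) / sd)^2
}
oracle_dlnorm <- function(x, meanlog, sdlog) {
  oracle_dnorm(log(x), meanlog, sdlog) - log(x)
}

# brute-force joint log posterior under the default priors, written term by
# term with the longhand densities above; independent of the package kernel
oracle_log_posterior <- function(surveys, sched, K, r, sig, N,
                                 sequential = TRUE, mean_centered = TRUE) {
  if (K < 9e5 || K > 2e6 || r < 0.5 || r > 2 || sig < 0.01 || sig > 1)
    return(-Inf)
  T_ <- nrow(surveys)
  sdlog <- sqrt(log(1 + (surveys$se / surveys$mean)^2))
  lp <- -log(2e6 - 9e5) - log(2 - 0.5) - log(1 - 0.01) +
    oracle_dnorm(log(N[1]), log(surveys$mean[1]), sdlog[1])
  for (t in seq_len(T_ - 1)) {
    pred <- oracle_step(N[t], K, r, sched$rate[t], sequential)
    if (pred <= 0) return(-Inf)
    mu <- log(pred) - if (mean_centered) sig^2 / 2 else 0
    lp <- lp + oracle_dnorm(log(N[t + 1]), mu, sig)
  }
  for (t in seq_len(T_))
    lp <- lp + oracle_dlnorm(surveys$mean[t], log(N[t]), sdlog[t])
  lp
}
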