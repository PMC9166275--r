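#' Plot a scenario projection against the observed series
#'
#' Reproduces the standard monitoring figure: observed survey estimates as
#' crosses with vertical standard-error bars, projected ensemble means as
#' points with vertical SD bars, and dashed lines for the ensemble median
#' and 2.5th/97.5th percentiles.
#'
#' @param object An `ssm_projection` from [project()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_projection <- function(object, ...) {
  s <- object$summary
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = s, ggplot2::aes(x = .data$year, ymin = .data$q2.5,
                             ymax = .data$q97.5),
      fill = "grey85", alpha = 0.6) +
    ggplot2::geom_line(data = s,
                       ggplot2::aes(x = .data$year, y = .data$median),
                       linetype = "dashed") +
    ggplot2::geom_line(data = s,
                       ggplot2::aes(x = .data$year, y = .data$q2.5),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(data = s,
                       ggplot2::aes(x = .data$year, y = .data$q97.5),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(
      data = s, ggplot2::aes(x = .data$year, y = .data$mean,
                             ymin = pmax(.data$mean - .data$sd, 0),
                             ymax = .data$mean + .data$sd),
      shape = 16)
  if (!is.null(object$surveys)) {
    obs <- object$surveys
    p <- p +
      ggplot2::geom_pointrange(
        data = obs, ggplot2::aes(x = .data$year, y = .data$mean,
                                 ymin = pmax(.data$mean - .data$se, 0),
                                 ymax = .data$mean + .data$se),
        shape = 4, colour = "firebrick")
  }
  p +
    ggplot2::scale_y_continuous(labels = function(x) format(x, big.mark = ",",
                                                            scientific = FALSE)) +
    ggplot2::labs(
      x = "Year (August survey)", y = "Abundance (individuals)",
      title = sprintf("Projected abundance, scenario %s",
                      object$scenario$label),
      subtitle = sprintf("%d ensemble members; crosses = survey estimates ± SE, points = ensemble mean ± SD",
                         object$n_ensemble)) +
    ggplot2::theme_minimal()
}

#' @export
plot.ssm_projection <- function(x, ...) print(autoplot(x, ...))

#' Plot posterior marginals of a state-space fit
#'
#' Histograms of the retained draws of the carrying capacity, maximum
#' intrinsic growth rate, maximum sustained harvest rate and process SD,
#' with the posterior mean marked.
#'
#' @param object An `ssm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_fit <- function(object, ...) {
  d <- object$draws
  d$h_msy <- h_msy(d$r_max)
  long <- tidyr::pivot_longer(d[, c("K", "r_max", "h_msy", "sigma_proc")],
                              dplyr::everything(),
                              names_to = "term", values_to = "value")
  means <- long |> group_by(.data$term) |>
    summarise(mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "draws",
                  title = "Posterior marginals (dashed = posterior mean)") +
    ggplot2::theme_minimal()
}

#' @export
plot.ssm_fit <- function(x, ...) print(autoplot(x, ...))

#' Plot a synthetic study: latent truth and noisy surveys
#'
#' @param object A `synthetic_study` from [generate_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_study <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(data = object$truth$trajectory,
                       ggplot2::aes(x = .data$year, y = .data$N),
                       colour = "grey40") +
    ggplot2::geom_pointrange(
      data = object$surveys,
      ggplot2::aes(x = .data$year, y = .data$mean,
                   ymin = pmax(.data$mean - .data$se, 0),
                   ymax = .data$mean + .data$se),
      shape = 4, colour = "firebrick") +
    ggplot2::labs(x = "Year", y = "Abundance",
                  title = "Synthetic study: latent trajectory (line) and surveys (crosses ± SE)") +
    ggplot2::theme_minimal()
}

#' @export
plot.synthetic_study <- function(x, ...) print(autoplot(x, ...))
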