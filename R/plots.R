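#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_histogram labs scale_x_log10 theme_minimal geom_abline
#'   stat_function
#' @export
ggplot2::autoplot

#' Plot a current trace
#'
#' Long traces are thinned to at most `max_points` for display.
#'
#' @param object A `tk_trace`.
#' @param max_points Display cap.
#' @param ... Unused.
#' @export
autoplot.tk_trace <- function(object, max_points = 2e5, ...) {
  d <- object
  if (nrow(d) > max_points) {
    d <- d[seq(1, nrow(d), length.out = max_points), ]
  }
  ggplot(d, aes(x = .data$time, y = .data$current)) +
    geom_line(linewidth = 0.2, colour = "grey30") +
    labs(x = "time (s)", y = "relative conductance") +
    theme_minimal()
}

#' Plot an idealized trace over the raw samples
#'
#' @param object A `tk_idealized`.
#' @inheritParams autoplot.tk_trace
#' @export
autoplot.tk_idealized <- function(object, max_points = 2e5, ...) {
  hmm <- attr(object, "hmm")
  d <- object
  if (nrow(d) > max_points) d <- d[seq(1, nrow(d), length.out = max_points), ]
  d$level <- hmm$means[d$state + 1L]
  ggplot(d, aes(x = .data$time)) +
    geom_line(aes(y = .data$current), linewidth = 0.2, colour = "grey70") +
    geom_step(aes(y = .data$level), colour = "firebrick", linewidth = 0.4) +
    labs(x = "time (s)", y = "relative conductance") +
    theme_minimal()
}

#' Dwell-time histogram with fitted exponential mixture
#'
#' @param object A `tk_dwell_fit`.
#' @param dwells The dwell table the fit was computed from.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @export
autoplot.tk_dwell_fit <- function(object, dwells = NULL, bins = 50, ...) {
  comp <- object$components
  dens <- function(t) {
    rowSums(vapply(seq_len(nrow(comp)), function(k) {
      comp$weight[k] / comp$tau[k] * exp(-t / comp$tau[k])
    }, numeric(length(t))))
  }
  p <- ggplot()
  if (!is.null(dwells)) {
    d <- uncensored_dwells_(dwells, object$state)
    p <- p + geom_histogram(
      data = d, aes(x = .data$duration_s, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey80", colour = "grey50"
    )
  }
  p + stat_function(fun = dens, colour = "firebrick", n = 400) +
    labs(x = "dwell time (s)", y = "density") +
    theme_minimal()
}

#' Dose-response curve with Hill fit
#'
#' @param object A `tk_hill`.
#' @param ... Unused.
#' @export
autoplot.tk_hill <- function(object, ...) {
  d <- object$data
  kd <- object$kd; n <- object$n_hill
  ggplot(d, aes(x = .data$conc_M, y = .data$alpha)) +
    geom_point() +
    stat_function(fun = function(C) C^n / (kd^n + C^n),
                  colour = "firebrick", n = 400) +
    scale_x_log10() +
    labs(x = "concentration (M)", y = "bound-state population") +
    theme_minimal()
}

#' Arrhenius diagram (ln k versus 1/T)
#'
#' @param object A `tk_arrhenius`.
#' @param ... Unused.
#' @export
autoplot.tk_arrhenius <- function(object, ...) {
  d <- object$data
  d$inv_t <- 1 / d$temperature_K
  ggplot(d, aes(x = .data$inv_t, y = log(.data$k))) +
    geom_point() +
    geom_abline(intercept = object$ln_a,
                slope = -object$ea / R_GAS, colour = "firebrick") +
    labs(x = "1/T (1/K)", y = "ln k") +
    theme_minimal()
}

#' van't Hoff diagram (ln K versus 1/T)
#'
#' @param object A `tk_vanthoff`.
#' @param ... Unused.
#' @export
autoplot.tk_vanthoff <- function(object, ...) {
  d <- object$data
  d$inv_t <- 1 / d$temperature_K
  ggplot(d, aes(x = .data$inv_t, y = log(.data$K_diss))) +
    geom_point() +
    geom_abline(intercept = object$ds / R_GAS,
                slope = -object$dh / R_GAS, colour = "firebrick") +
    labs(x = "1/T (1/K)", y = "ln K (dissociation)") +
    theme_minimal()
}

#' Observed binding rate versus concentration with induced-fit curve
#'
#' @param object A `tk_induced_fit`.
#' @param ... Unused.
#' @export
autoplot.tk_induced_fit <- function(object, ...) {
  d <- object$curve
  kf <- object$k_f; kr <- object$k_r; K1 <- object$K_1
  ggplot(d, aes(x = .data$conc_M, y = .data$kobs_per_s)) +
    geom_point() +
    stat_function(fun = function(C) kr + kf * C / (K1 + C),
                  colour = "firebrick", n = 400) +
    scale_x_log10() +
    labs(x = "concentration (M)", y = expression(k[obs] ~ (s^-1))) +
    theme_minimal()
}
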