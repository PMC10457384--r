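#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.tk_hmm <- function(x, ...) {
  tibble::tibble(state = seq_len(x$n_states) - 1L, mean = x$means,
                 sd = x$sds, initial_prob = x$initial_probs,
                 self_transition = diag(x$transition_probs))
}

#' @export
glance.tk_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
tidy.tk_dwell_fit <- function(x, ...) {
  out <- x$components
  out$state <- x$state %||% NA_integer_
  dplyr::relocate(out, "state")
}

#' @export
glance.tk_dwell_fit <- function(x, ...) {
  tibble::tibble(n_dwells = x$n_dwells, n_components = x$n_components,
                 loglik = x$loglik, bic = x$bic, dead_time = x$dead_time)
}

#' @export
tidy.tk_hill <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "n_hill"),
    estimate = c(x$kd, x$n_hill),
    conf.low = c(x$kd_lo, x$n_lo),
    conf.high = c(x$kd_hi, x$n_hi)
  )
}

#' @export
glance.tk_hill <- function(x, ...) {
  tibble::tibble(kd = x$kd, n_hill = x$n_hill, rss = x$rss,
                 apparent = x$apparent,
                 inhibitor_conc_M = x$inhibitor_conc_M %||% NA_real_,
                 n_points = nrow(x$data))
}

#' @export
tidy.tk_arrhenius <- function(x, ...) {
  tibble::tibble(term = c("ea", "ln_a"),
                 estimate = c(x$ea, x$ln_a),
                 conf.low = c(x$ea_lo, NA_real_),
                 conf.high = c(x$ea_hi, NA_real_))
}

#' @export
glance.tk_arrhenius <- function(x, ...) {
  tibble::tibble(ea = x$ea, ln_a = x$ln_a, r_squared = x$r_squared,
                 n_temps = x$n_temps)
}

#' @export
tidy.tk_vanthoff <- function(x, ...) {
  tibble::tibble(term = c("dh", "ds"),
                 estimate = c(x$dh, x$ds),
                 conf.low = c(x$dh_lo, x$ds_lo),
                 conf.high = c(x$dh_hi, x$ds_hi))
}

#' @export
glance.tk_vanthoff <- function(x, ...) {
  tibble::tibble(dh = x$dh, ds = x$ds, r_squared = x$r_squared,
                 n_temps = x$n_temps)
}

#' @export
tidy.tk_induced_fit <- function(x, ...) {
  est <- c(x$k_f, x$k_r, x$K_1)
  tibble::tibble(term = c("k_f", "k_r", "K_1"), estimate = est,
                 std.error = unname(x$se[c("k_f", "k_r", "K_1")]),
                 conf.low = unname(x$ci[c("k_f", "k_r", "K_1"), 1]),
                 conf.high = unname(x$ci[c("k_f", "k_r", "K_1"), 2]))
}

#' @export
glance.tk_induced_fit <- function(x, ...) {
  tibble::tibble(k_f = x$k_f, k_r = x$k_r, K_1 = x$K_1,
                 identifiable = x$identifiable, n_points = nrow(x$curve))
}

#' @export
tidy.tk_disorder <- function(x, ...) {
  x$per_window
}

#' @export
glance.tk_disorder <- function(x, ...) {
  tibble::tibble(state = x$state, window_s = x$window, cv = x$cv,
                 iqr = x$iqr, n_windows = x$n_windows)
}
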