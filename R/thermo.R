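#' Bound-state population of idealized traces
#'
#' Time fraction of samples assigned to the bound state, pooled over traces,
#' with a Wilson binomial-style interval on the pooled sample count. Because
#' neighbouring samples are correlated within a dwell, the interval is
#' computed on the effective number of independent observations, taken as
#' the number of dwells rather than the number of samples.
#'
#' @param idealized A `tk_idealized` or a list of them.
#' @param bound_state Bound-state index (0-based).
#' @param conf Confidence level.
#' @return A one-row tibble: `alpha`, `lo`, `hi`, `n_samples`, `n_traces`.
#' @export
bound_fraction <- function(idealized, bound_state, conf = 0.95) {
  traces <- if (inherits(idealized, "tk_idealized")) list(idealized) else idealized
  n_bound <- 0; n_tot <- 0; n_dwell <- 0
  for (tr in traces) {
    n_bound <- n_bound + sum(tr$state == bound_state)
    n_tot <- n_tot + nrow(tr)
    n_dwell <- n_dwell + sum(tr$state[-1] != tr$state[-nrow(tr)]) + 1
  }
  alpha <- n_bound / n_tot
  z <- qnorm(1 - (1 - conf) / 2)
  n_eff <- max(n_dwell, 1)
  denom <- 1 + z^2 / n_eff
  centre <- (alpha + z^2 / (2 * n_eff)) / denom
  half <- z * sqrt(alpha * (1 - alpha) / n_eff + z^2 / (4 * n_eff^2)) / denom
  tibble::tibble(alpha = alpha, lo = max(0, centre - half),
                 hi = min(1, centre + half), n_samples = n_tot,
                 n_traces = length(traces))
}

#' Assemble a dose-response table
#'
#' @param concentrations Concentrations, mol/L (strictly increasing).
#' @param alpha Bound-state populations in `[0, 1]`.
#' @param se Optional standard errors (used as inverse-variance weights in
#'   [fit_hill()]).
#' @param n_traces Traces per point.
#' @param inhibitor_conc_M,temperature_K,ph Optional condition metadata.
#' @return A `tk_dose_response` tibble.
#' @export
dose_response <- function(concentrations, alpha, se = NULL, n_traces = 1L,
                          inhibitor_conc_M = NULL, temperature_K = NULL,
                          ph = NULL) {
  concentrations <- parse_concentration(concentrations)
  if (any(diff(concentrations) <= 0)) {
    abort("`concentrations` must be strictly increasing.")
  }
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1].")
  out <- tibble::tibble(conc_M = concentrations, alpha = alpha,
                        n_traces = n_traces)
  if (!is.null(se)) out$se <- se
  structure(out,
            condition = list(inhibitor_conc_M = inhibitor_conc_M,
                             temperature_K = temperature_K, ph = ph),
            class = c("tk_dose_response", class(out)))
}

#' Fit the Hill equation to a dose-response curve
#'
#' Least-squares fit of `alpha(C) = C^n / (K_D^n + C^n)` with the
#' dissociation constant parameterised on the log scale (K_D > 0 by
#' construction, Wald CI back-transformed) and the Hill exponent bounded to
#' `[0.2, 4]`. Points with a finite `se` column are weighted by inverse
#' variance.
#'
#' @param dr A `tk_dose_response` (or tibble with `conc_M` and `alpha`).
#' @param fix_n Optionally fix the Hill exponent (e.g. `fix_n = 1`).
#' @return A `tk_hill`: `kd` (mol/L), `n_hill`, standard errors, 95% CIs
#'   (`kd_lo`, `kd_hi`, `n_lo`, `n_hi`), residual sum of squares, and the
#'   underlying `nls` fit. `n_flag` is TRUE when the CI for `n` excludes 1.
#' @export
fit_hill <- function(dr, fix_n = NULL) {
  if (!all(c("conc_M", "alpha") %in% names(dr))) {
    abort("`dr` needs columns `conc_M` and `alpha`.")
  }
  C <- dr$conc_M
  a <- dr$alpha
  if (length(C) < 4) abort("Need >= 4 concentrations.")
  if (max(C) / min(C) < 10 - 1e-6) {
    abort("Dose series must span at least a 10x range.")
  }
  if (all(a <= 1e-12) || all(a >= 1 - 1e-12)) {
    abort("Response is flat at 0 or 1: K_D is not identifiable.")
  }
  w <- if ("se" %in% names(dr) && all(is.finite(dr$se)) && all(dr$se > 0)) {
    1 / dr$se^2
  } else {
    rep(1, length(C))
  }
  # log-interpolated half-saturation as the K_D start value
  lkd0 <- log(C[which.min(abs(a - 0.5))])
  if (is.null(fix_n)) {
    fit <- minpack.lm::nlsLM(
      a ~ C^n / (exp(lkd)^n + C^n),
      start = list(lkd = lkd0, n = 1),
      lower = c(log(min(C)) - 12, 0.2), upper = c(log(max(C)) + 12, 4),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
    names(se) <- names(est)
    n_hill <- est[["n"]]; n_se <- se[["n"]]
  } else {
    n_fixed <- fix_n
    fit <- minpack.lm::nlsLM(
      a ~ C^n_fixed / (exp(lkd)^n_fixed + C^n_fixed),
      start = list(lkd = lkd0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NA_real_)
    names(se) <- names(est)
    n_hill <- n_fixed; n_se <- NA_real_
  }
  kd <- exp(est[["lkd"]])
  kd_se_log <- se[["lkd"]]
  n_lo <- if (is.na(n_se)) NA_real_ else n_hill - 1.96 * n_se
  n_hi <- if (is.na(n_se)) NA_real_ else n_hill + 1.96 * n_se
  cond <- attr(dr, "condition") %||% list()
  structure(
    list(kd = kd, n_hill = n_hill,
         kd_lo = kd * exp(-1.96 * kd_se_log), kd_hi = kd * exp(1.96 * kd_se_log),
         kd_se_log = kd_se_log, n_se = n_se, n_lo = n_lo, n_hi = n_hi,
         n_flag = isTRUE(n_lo > 1 || n_hi < 1),
         rss = sum(w * stats::residuals(fit)^2),
         inhibitor_conc_M = cond$inhibitor_conc_M,
         apparent = !is.null(cond$inhibitor_conc_M) && cond$inhibitor_conc_M > 0,
         fit = fit, data = tibble::as_tibble(dr)),
    class = "tk_hill"
  )
}

#' @export
print.tk_hill <- function(x, ...) {
  cat("<tk_hill>", if (x$apparent) " (apparent, with inhibitor)", " K_D = ",
      format(x$kd, digits = 4), " M [", format(x$kd_lo, digits = 4), ", ",
      format(x$kd_hi, digits = 4), "], n = ", format(x$n_hill, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Apparent dissociation constant in the presence of an inhibitor
#'
#' Applies the Hill estimator of [fit_hill()] to a partner dose series
#' measured at a fixed inhibitor concentration and labels the result as an
#' apparent constant. For a purely competitive mechanism the expectation is
#' `K_D,app = K_D (1 + I / K_I)`.
#'
#' @inheritParams fit_hill
#' @param inhibitor_conc_M Inhibitor concentration, mol/L; taken from the
#'   dose-response metadata when omitted.
#' @return A `tk_hill` with `apparent = TRUE`.
#' @export
apparent_kd <- function(dr, inhibitor_conc_M = NULL, fix_n = NULL) {
  cond <- attr(dr, "condition") %||% list()
  inhibitor_conc_M <- inhibitor_conc_M %||% cond$inhibitor_conc_M
  if (is.null(inhibitor_conc_M)) {
    abort("Inhibitor concentration must be recorded in the dose-response metadata.")
  }
  cond$inhibitor_conc_M <- inhibitor_conc_M
  attr(dr, "condition") <- cond
  fit_hill(dr, fix_n = fix_n)
}

#' Equilibrium constants from dwell time constants per temperature
#'
#' In the dissociation orientation, `K_diss = k_diss / k_bind` with
#' `k_diss = 1 / tau_bound` and `k_bind = 1 / tau_unbound` (the
#' encounter-intermediate dwell), i.e. `K_diss = tau_unbound / tau_bound`
#' at each temperature. Temperatures missing either state are skipped with
#' a warning.
#'
#' @param fits A tibble with columns `temperature_K`, `tau_bound_s`,
#'   `tau_unbound_s` (e.g. assembled from [fit_exponential_mixture()]
#'   results per temperature).
#' @return A tibble `temperature_K`, `K_diss`.
#' @export
equilibrium_constants <- function(fits) {
  need <- c("temperature_K", "tau_bound_s", "tau_unbound_s")
  if (!all(need %in% names(fits))) {
    abort(paste0("`fits` needs columns ", paste(need, collapse = ", "), "."))
  }
  ok <- complete.cases(fits[, need]) & fits$tau_bound_s > 0 &
    fits$tau_unbound_s > 0
  if (any(!ok)) {
    warn(sprintf("Skipping %d temperature(s) with a missing state.", sum(!ok)))
  }
  f <- fits[ok, ]
  tibble::tibble(temperature_K = f$temperature_K,
                 K_diss = f$tau_unbound_s / f$tau_bound_s)
}

#' Fit the Arrhenius equation to rate constants
#'
#' Ordinary least squares of `ln k` on `1/T`; the activation energy is
#' `Ea = -slope * R` and `ln A` the intercept.
#'
#' @param rates A tibble with columns `temperature_K` and `k` (1/s), k > 0.
#' @return A `tk_arrhenius`: `ea` (J/mol), `ln_a`, `r_squared`, 95% CIs, and
#'   the underlying `lm`.
#' @export
fit_arrhenius <- function(rates) {
  if (!all(c("temperature_K", "k") %in% names(rates))) {
    abort("`rates` needs columns `temperature_K` and `k`.")
  }
  r <- dplyr::distinct(tibble::as_tibble(rates[, c("temperature_K", "k")]))
  r <- dplyr::summarise(dplyr::group_by(r, .data$temperature_K),
                        k = mean(.data$k), .groups = "drop")
  if (nrow(r) < 2) abort("Need >= 2 distinct temperatures.")
  if (any(r$k <= 0)) abort("Rate constants must be > 0.")
  inv_t <- 1 / r$temperature_K
  m <- lm(log(r$k) ~ inv_t)
  slope <- coef(m)[[2]]; intercept <- coef(m)[[1]]
  ci <- if (nrow(r) > 2) suppressWarnings(suppressMessages(confint(m))) else
    matrix(NA_real_, 2, 2, dimnames = list(c("(Intercept)", "inv_t"), NULL))
  structure(
    list(ea = -slope * R_GAS, ln_a = intercept,
         ea_lo = -ci["inv_t", 2] * R_GAS, ea_hi = -ci["inv_t", 1] * R_GAS,
         r_squared = suppressWarnings(summary(m))$r.squared, n_temps = nrow(r), lm = m,
         data = r),
    class = "tk_arrhenius"
  )
}

#' @export
print.tk_arrhenius <- function(x, ...) {
  cat("<tk_arrhenius> Ea = ", format(x$ea / 1000, digits = 4), " kJ/mol, ",
      "ln A = ", format(x$ln_a, digits = 4), ", R^2 = ",
      format(x$r_squared, digits = 4), " (", x$n_temps, " temperatures)\n",
      sep = "")
  invisible(x)
}

#' Fit the van't Hoff relation to equilibrium constants
#'
#' OLS of `ln K` on `1/T`: `dH = -slope * R`, `dS = intercept * R`. Fitted
#' in the dissociation orientation, so positive `dH`/`dS` mean dissociation
#' is endothermic and entropy-gaining. The thermodynamic identity
#' `dG(T) = dH - T dS = -R T ln K_pred(T)` holds exactly for the fitted
#' line.
#'
#' @param eq A tibble with columns `temperature_K` and `K_diss` (> 0).
#' @return A `tk_vanthoff`: `dh`, `ds` (J/mol, J/(mol K)), 95% CIs, and a
#'   `predict_K(T)` closure.
#' @export
fit_vant_hoff <- function(eq) {
  if (!all(c("temperature_K", "K_diss") %in% names(eq))) {
    abort("`eq` needs columns `temperature_K` and `K_diss`.")
  }
  r <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(eq), .data$temperature_K),
                        K_diss = mean(.data$K_diss), .groups = "drop")
  if (nrow(r) < 2) abort("Need >= 2 distinct temperatures.")
  if (any(r$K_diss <= 0)) abort("Equilibrium constants must be > 0.")
  inv_t <- 1 / r$temperature_K
  m <- lm(log(r$K_diss) ~ inv_t)
  slope <- coef(m)[[2]]; intercept <- coef(m)[[1]]
  ci <- if (nrow(r) > 2) suppressWarnings(suppressMessages(confint(m))) else
    matrix(NA_real_, 2, 2, dimnames = list(c("(Intercept)", "inv_t"), NULL))
  dh <- -slope * R_GAS
  ds <- intercept * R_GAS
  structure(
    list(dh = dh, ds = ds,
         dh_lo = -ci["inv_t", 2] * R_GAS, dh_hi = -ci["inv_t", 1] * R_GAS,
         ds_lo = ci["(Intercept)", 1] * R_GAS,
         ds_hi = ci["(Intercept)", 2] * R_GAS,
         r_squared = suppressWarnings(summary(m))$r.squared, n_temps = nrow(r), lm = m,
         data = r,
         predict_K = function(T) exp(-dh / (R_GAS * T) + ds / R_GAS)),
    class = "tk_vanthoff"
  )
}

#' @export
print.tk_vanthoff <- function(x, ...) {
  cat("<tk_vanthoff> dH = ", format(x$dh / 1000, digits = 4), " kJ/mol, ",
      "dS = ", format(x$ds, digits = 4), " J/(mol K) (dissociation, ",
      x$n_temps, " temperatures)\n", sep = "")
  invisible(x)
}
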