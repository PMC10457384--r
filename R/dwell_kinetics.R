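uncensored_dwells_ <- function(dwells, state = NULL, include_censored = FALSE) {
  d <- dwells
  if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
  if (!include_censored && "censored" %in% names(d)) {
    d <- d[!d$censored, , drop = FALSE]
  }
  d
}

# EM for an exponential mixture on left-truncated data. By memorylessness,
# durations minus the dead time are again an exponential mixture with the
# same taus; only the weights need mapping back through the survival
# probabilities exp(-dead_time / tau).
exp_mixture_em_ <- function(s, n_components, max_iter = 1000L, tol = 1e-10) {
  n <- length(s)
  K <- n_components
  if (K == 1L) {
    tau <- mean(s)
    return(list(tau = tau, eta = 1,
                loglik = sum(-log(tau) - s / tau), n_iter = 0L))
  }
  # deterministic init: geometric spread around quantiles
  qs <- quantile(s, seq(0.15, 0.85, length.out = K), names = FALSE)
  tau <- pmax(sort(unique(qs)), 1e-12)
  if (length(tau) < K) tau <- mean(s) * 2^(seq_len(K) - (K + 1) / 2)
  eta <- rep(1 / K, K)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K),
                   function(k) log(eta[k]) - log(tau[k]) - s / tau[k],
                   numeric(n))
    m <- apply(logd, 1, max)
    p <- exp(logd - m)
    tot <- rowSums(p)
    ll <- sum(m + log(tot))
    resp <- p / tot
    nk <- colSums(resp)
    eta <- nk / n
    tau <- pmax(colSums(resp * s) / nk, 1e-15)
    if (is.finite(prev) && ll - prev < tol * n) break
    prev <- ll
  }
  o <- order(tau)
  list(tau = tau[o], eta = eta[o], loglik = ll, n_iter = it)
}

#' Fit a left-truncated exponential mixture to dwell times
#'
#' Maximum-likelihood fit of `n_components` exponential components to the
#' uncensored dwells of one state, accounting for the idealization dead time
#' by left truncation: dwells shorter than `dead_time` are discarded and the
#' remainder, shifted by `dead_time`, retain exponential form with unchanged
#' time constants (memorylessness), so the shifted-data MLE is the truncated
#' MLE. Mixture weights are mapped back to the untruncated process through
#' each component's survival probability.
#'
#' Confidence intervals are percentile bootstrap over dwell resampling.
#'
#' @param dwells A `tk_dwells` table (censored dwells are excluded).
#' @param n_components Number of exponential components.
#' @param dead_time Dead time in seconds (left-truncation point).
#' @param state State index to fit; `NULL` uses all rows.
#' @param seed Seed for the bootstrap.
#' @param n_boot Bootstrap resamples (0 skips CIs).
#' @param conf Confidence level.
#' @return A `tk_dwell_fit`: `components` tibble (`tau`, `weight`,
#'   `tau_lo`, `tau_hi`), `loglik`, `n_dwells`, `bic`.
#' @export
fit_exponential_mixture <- function(dwells, n_components = 1L, dead_time = 0,
                                    state = NULL, seed = NULL, n_boot = 500L,
                                    conf = 0.95) {
  d <- uncensored_dwells_(dwells, state)
  t_obs <- d$duration_s[d$duration_s > dead_time]
  n <- length(t_obs)
  if (n < 10) abort("Need at least 10 uncensored dwells beyond the dead time.")
  if (n_components > n / 10) {
    abort("Too many components for the number of dwells (need >= 10 per component).")
  }
  s <- t_obs - dead_time

  fit_one <- function(sv) {
    em <- exp_mixture_em_(sv, n_components)
    # untruncated weights: observed eta_k is proportional to w_k * exp(-d/tau_k)
    w <- em$eta * exp(dead_time / em$tau)
    w <- w / sum(w)
    list(tau = em$tau, weight = w, eta = em$eta, loglik = em$loglik)
  }
  fit <- fit_one(s)
  if (any(fit$weight < 1e-4)) {
    warn("Degenerate mixture component (weight < 1e-4).")
  }
  comp <- tibble::tibble(component = seq_len(n_components),
                         tau = fit$tau, weight = fit$weight)
  if (n_boot > 0) {
    boots <- with_seed_(seed, {
      replicate(n_boot, {
        f <- fit_one(sample(s, n, replace = TRUE))
        c(f$tau, f$weight)
      })
    })
    a <- (1 - conf) / 2
    qs <- apply(boots, 1, quantile, probs = c(a, 1 - a), names = FALSE)
    comp$tau_lo <- qs[1, seq_len(n_components)]
    comp$tau_hi <- qs[2, seq_len(n_components)]
    comp$weight_lo <- qs[1, n_components + seq_len(n_components)]
    comp$weight_hi <- qs[2, n_components + seq_len(n_components)]
  }
  p <- 2 * n_components - 1
  structure(
    list(state = state, components = comp, loglik = fit$loglik,
         n_dwells = n, dead_time = dead_time, n_components = n_components,
         bic = -2 * fit$loglik + p * log(n), conf = conf),
    class = "tk_dwell_fit"
  )
}

#' @export
print.tk_dwell_fit <- function(x, ...) {
  cat("<tk_dwell_fit> state ", x$state %||% "(all)", ", ", x$n_dwells,
      " dwells, ", x$n_components, " component(s), loglik = ",
      format(x$loglik, digits = 8), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Select the number of exponential components by BIC
#'
#' Detects kinetically distinct dwell populations sharing one current level
#' (for instance a long-lived intermediate hidden inside the medium current
#' state) by fitting 1..`max_components` mixtures and scoring each with
#' `BIC = -2 loglik + (2K - 1) log(n)`.
#'
#' @inheritParams fit_exponential_mixture
#' @param max_components Largest component count to try.
#' @return A tibble (`n_components`, `loglik`, `bic`, `best`) with attribute
#'   `best`; fitted objects in the `fits` list-column.
#' @export
choose_components <- function(dwells, max_components = 3L, dead_time = 0,
                              state = NULL, seed = NULL) {
  rows <- purrr::map(seq_len(max_components), function(K) {
    fit <- tryCatch(
      fit_exponential_mixture(dwells, K, dead_time = dead_time, state = state,
                              seed = seed, n_boot = 0),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    tibble::tibble(n_components = K, loglik = fit$loglik, bic = fit$bic,
                   fits = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("No mixture size could be fitted.")
  out$best <- out$bic == min(out$bic)
  structure(out, best = out$n_components[which.min(out$bic)],
            class = c("tk_component_selection", class(out)))
}

#' Rate constants from a dwell fit
#'
#' Inverts each mixture component's time constant into a first-order rate
#' constant, `k = 1/tau`, propagating bootstrap CIs (interval endpoints swap
#' under inversion). Without a bootstrap, asymptotic exponential-MLE
#' intervals `k (1 ± z/sqrt(n_k))` are used, with `n_k` the effective
#' component count.
#'
#' @param fit A `tk_dwell_fit`.
#' @param condition Optional named list (e.g. `temperature_K`, `conc_M`)
#'   attached to every row.
#' @return A tibble: `state`, `component`, `tau`, `weight`, `k`, `k_lo`,
#'   `k_hi`, plus condition columns.
#' @export
rate_constants <- function(fit, condition = NULL) {
  stopifnot(inherits(fit, "tk_dwell_fit"))
  comp <- fit$components
  z <- qnorm(1 - (1 - fit$conf) / 2)
  out <- tibble::tibble(
    state = fit$state %||% NA_integer_,
    component = comp$component,
    tau = comp$tau,
    weight = comp$weight,
    k = 1 / comp$tau
  )
  if ("tau_lo" %in% names(comp)) {
    out$k_lo <- 1 / comp$tau_hi
    out$k_hi <- 1 / comp$tau_lo
  } else {
    n_k <- pmax(comp$weight * fit$n_dwells, 1)
    out$k_lo <- out$k * (1 - z / sqrt(n_k))
    out$k_hi <- out$k * (1 + z / sqrt(n_k))
  }
  for (nm in names(condition %||% list())) out[[nm]] <- condition[[nm]]
  out
}

#' Windowed mean-dwell spread (dynamic disorder)
#'
#' Computes the arithmetic mean dwell of one state in consecutive time
#' windows (default 1 s, i.e. second by second) and summarises the spread of
#' those means. For a homogeneous memoryless process with m dwells per
#' window the coefficient of variation of window means is ~ 1/sqrt(m);
#' excess CV indicates dynamic disorder — slow fluctuation of the underlying
#' rates.
#'
#' @param dwells A `tk_dwells` table.
#' @param state State index to analyse.
#' @param window Window length, s.
#' @return A `tk_disorder`: tibble of per-window means plus summary fields
#'   `cv`, `iqr`, `n_windows`.
#' @export
dynamic_disorder <- function(dwells, state, window = 1) {
  stopifnot(window > 0)
  d <- uncensored_dwells_(dwells, state)
  total <- max(dwells$start_s + dwells$duration_s) - min(dwells$start_s)
  if (total < 10 * window) {
    abort("Need at least 10 windows of observation for a disorder analysis.")
  }
  if (nrow(d) == 0) abort("No uncensored dwells for this state.")
  win <- floor(d$start_s / window)
  means <- tapply(d$duration_s, win, mean)
  counts <- tapply(d$duration_s, win, length)
  if (length(means) < 3) abort("Fewer than 3 non-empty windows.")
  per_window <- tibble::tibble(
    window = as.integer(names(means)),
    mean_dwell_s = as.numeric(means),
    n_dwells = as.integer(counts)
  )
  structure(
    list(per_window = per_window, state = state, window = window,
         cv = sd(per_window$mean_dwell_s) / mean(per_window$mean_dwell_s),
         iqr = stats::IQR(per_window$mean_dwell_s),
         n_windows = nrow(per_window)),
    class = "tk_disorder"
  )
}

#' @export
print.tk_disorder <- function(x, ...) {
  cat("<tk_disorder> state ", x$state, ": CV = ", format(x$cv, digits = 4),
      " over ", x$n_windows, " windows of ", x$window, " s (IQR = ",
      format(x$iqr, digits = 4), " s)\n", sep = "")
  invisible(x)
}

#' Observed binding rate versus concentration
#'
#' For each concentration, counts the entries into the bound state (the
#' number of binding-complex events) per second of observation. Input is a
#' dwell table carrying a concentration column (as produced by
#' [segment_dwells()] on traces with metadata, or [true_dwells()] plus a
#' joined condition column).
#'
#' @param dwells A `tk_dwells` table with a concentration column.
#' @param bound_state Bound-state index.
#' @param conc_col Name of the concentration column (mol/L).
#' @return A `tk_kobs` tibble: `conc_M`, `n_entries`, `total_time_s`,
#'   `kobs_per_s`, sorted by concentration.
#' @export
compute_kobs <- function(dwells, bound_state, conc_col = "conc_partner") {
  if (!conc_col %in% names(dwells)) {
    abort(paste0("Column '", conc_col, "' not found in the dwell table."))
  }
  # an entry is any bound-state dwell that is not the opening dwell of its
  # trace (that one was not observed to start)
  d <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(dwells, .data$trace_id),
                                    .first = dplyr::row_number() == 1L))
  grp <- dplyr::group_by(d, .conc = .data[[conc_col]])
  out <- dplyr::summarise(
    grp,
    n_entries = sum(.data$state == bound_state & !.data$.first),
    total_time_s = sum(.data$duration_s),
    .groups = "drop"
  )
  if (any(out$total_time_s <= 0)) abort("Zero observation time in a group.")
  out <- dplyr::arrange(out, .data$.conc)
  out <- dplyr::transmute(out, conc_M = .data$.conc,
                          n_entries = .data$n_entries,
                          total_time_s = .data$total_time_s,
                          kobs_per_s = .data$n_entries / .data$total_time_s)
  structure(out, bound_state = bound_state,
            class = c("tk_kobs", class(out)))
}

#' Fit a two-step induced-fit model to an observed-rate curve
#'
#' Weighted least squares of the hyperbolically increasing observed-rate
#' form of the induced-fit mechanism,
#' `k_obs(C) = k_r + k_f * C / (K_1 + C)`:
#' the ligand first docks in a rapid pre-equilibrium (dissociation constant
#' `K_1`) and the complex then isomerises forward (`k_f`) or back (`k_r`).
#' A rising hyperbola distinguishes induced fit from the decreasing
#' concentration dependence typical of conformational selection.
#'
#' @param curve A `tk_kobs` tibble (or any tibble with `conc_M` and
#'   `kobs_per_s`; an `n_entries` column, if present, supplies Poisson
#'   weights).
#' @return A `tk_induced_fit` with fields `k_f`, `k_r`, `K_1`, their
#'   standard errors and Wald CIs, and `identifiable` (FALSE when the `k_f`
#'   CI spans 0, i.e. the curve is flat).
#' @export
fit_induced_fit <- function(curve) {
  if (!all(c("conc_M", "kobs_per_s") %in% names(curve))) {
    abort("`curve` needs columns `conc_M` and `kobs_per_s`.")
  }
  if (nrow(curve) < 4) abort("Need >= 4 concentrations to fit induced fit.")
  C <- curve$conc_M
  y <- curve$kobs_per_s
  w <- if ("n_entries" %in% names(curve)) pmax(curve$n_entries, 1) else
    rep(1, length(y))
  # fit in scaled concentration units so all parameters are O(1)
  cs <- median(C)
  Cs <- C / cs
  k_r0 <- max(min(y), 1e-12)
  # keep the start away from the k_f = 0 ridge, where the K_1 gradient
  # vanishes and the model matrix is singular
  k_f0 <- max(max(y) - min(y), 0.05 * mean(y), 1e-9)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ k_r + k_f * Cs / (K_1s + Cs),
      start = list(k_r = k_r0, k_f = k_f0, K_1s = 1),
      lower = c(0, 0, 1e-9), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # flat curve: the optimiser hits the k_f = 0 boundary, where K_1 drops
    # out of the model; report the degenerate fit with K_1 fixed
    lf <- lm(y ~ I(Cs / (1 + Cs)), weights = w)
    vc <- suppressWarnings(diag(vcov(lf)))
    se <- c(k_r = sqrt(vc[[1]]), k_f = sqrt(vc[[2]]), K_1 = NA_real_)
    est <- c(k_r = max(coef(lf)[[1]], 0), k_f = max(coef(lf)[[2]], 0),
             K_1 = cs)
  } else {
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
    names(se) <- names(est)
    est[["K_1s"]] <- est[["K_1s"]] * cs
    se[["K_1s"]] <- se[["K_1s"]] * cs
    names(est)[names(est) == "K_1s"] <- "K_1"
    names(se)[names(se) == "K_1s"] <- "K_1"
  }
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  identifiable <- is.finite(ci["k_f", 1]) && ci["k_f", 1] > 0
  structure(
    list(k_f = est[["k_f"]], k_r = est[["k_r"]], K_1 = est[["K_1"]],
         se = se, ci = ci, identifiable = identifiable, fit = fit,
         curve = tibble::as_tibble(curve[, c("conc_M", "kobs_per_s")])),
    class = "tk_induced_fit"
  )
}

#' @export
print.tk_induced_fit <- function(x, ...) {
  cat("<tk_induced_fit> k_f = ", format(x$k_f, digits = 4), " 1/s, k_r = ",
      format(x$k_r, digits = 4), " 1/s, K_1 = ", format(x$K_1, digits = 4),
      " M", if (!x$identifiable) "  [k_f CI spans 0: flat curve]", "\n",
      sep = "")
  invisible(x)
}
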