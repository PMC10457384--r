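dwell_table <- function(durations, state = 0L, start = NULL,
                        censored = NULL) {
  n <- length(durations)
  start <- start %||% c(0, cumsum(durations)[-n])
  structure(
    tibble::tibble(trace_id = "t", state = as.integer(state),
                   start_s = start, duration_s = durations,
                   censored = censored %||% rep(FALSE, n)),
    class = c("tk_dwells", "tbl_df", "tbl", "data.frame")
  )
}

test_that("single-exponential MLE equals the arithmetic mean", {
  set.seed(1)
  d <- dwell_table(rexp(500, 1 / 2e-3))
  fit <- fit_exponential_mixture(d, 1, dead_time = 0, n_boot = 0)
  expect_equal(fit$components$tau, mean(d$duration_s))
  expect_equal(fit$components$weight, 1)
})

test_that("two-component mixtures are recovered from 2000 dwells", {
  set.seed(2)
  n <- 2000
  z <- runif(n) < 0.5
  d <- dwell_table(ifelse(z, rexp(n, 1 / 1e-4), rexp(n, 1 / 1e-3)))
  fit <- fit_exponential_mixture(d, 2, dead_time = 0, n_boot = 0)
  expect_equal(fit$components$tau[1], 1e-4, tolerance = 0.15)
  expect_equal(fit$components$tau[2], 1e-3, tolerance = 0.15)
  expect_lt(max(abs(fit$components$weight - 0.5)), 0.1)
  expect_true(all(diff(fit$components$tau) > 0))  # sorted ascending
})

test_that("left truncation corrects the dead-time bias", {
  set.seed(3)
  d <- dwell_table(rexp(4000, 1 / 1e-3))
  dead <- 1e-4
  surviving <- d$duration_s[d$duration_s > dead]
  # naive mean of surviving dwells over-estimates tau
  expect_gt(mean(surviving), 1e-3)
  fit <- fit_exponential_mixture(d, 1, dead_time = dead, n_boot = 0)
  expect_equal(fit$components$tau, 1e-3, tolerance = 0.05)
  # analytic truncated-exponential oracle: E[T | T > d] = d + tau
  expect_equal(fit$components$tau, mean(surviving) - dead, tolerance = 1e-12)
})

test_that("component-count selection distinguishes 1 from 2 populations", {
  set.seed(4)
  d1 <- dwell_table(rexp(1000, 1 / 5e-4))
  sel1 <- choose_components(d1, max_components = 3)
  expect_equal(attr(sel1, "best"), 1L)

  z <- runif(1000) < 0.5
  d2 <- dwell_table(ifelse(z, rexp(1000, 1 / 1e-4), rexp(1000, 1 / 5e-4)))
  sel2 <- choose_components(d2, max_components = 3)
  expect_equal(attr(sel2, "best"), 2L)
})

test_that("medium-level dwells of the apo scheme reveal two populations", {
  sc <- apo_scheme(tau1 = 1e-4, tau1_star = 5e-4)
  p <- simulate_path(sc, 6, seed = 19)
  dw <- true_dwells(p, sc, by = "level")
  med <- dw[dw$state == 1L & !dw$censored, ]
  expect_gt(nrow(med), 1000)
  sel <- choose_components(med, max_components = 3)
  expect_equal(attr(sel, "best"), 2L)
  fit <- sel$fits[[2]]
  expect_equal(fit$components$tau[1], 1e-4, tolerance = 0.2)
  expect_equal(fit$components$tau[2], 5e-4, tolerance = 0.2)
})

test_that("rate constants invert dwell time constants with CIs", {
  fit <- structure(
    list(state = 1L,
         components = tibble::tibble(component = 1L, tau = 2e-3, weight = 1),
         loglik = 0, n_dwells = 1000, dead_time = 0, n_components = 1L,
         conf = 0.95),
    class = "tk_dwell_fit"
  )
  rc <- rate_constants(fit, condition = list(temperature_K = 310.15))
  expect_equal(rc$k, 500)
  expect_equal(rc$temperature_K, 310.15)
  # asymptotic CI width ~ 2 * 1.96 * k / sqrt(n)
  expect_equal(rc$k_hi - rc$k_lo, 2 * 1.96 * 500 / sqrt(1000),
               tolerance = 0.2)

  # bootstrap CI on real draws matches the asymptotic width within 20%
  set.seed(5)
  d <- dwell_table(rexp(1000, 500))
  fb <- fit_exponential_mixture(d, 1, n_boot = 500, seed = 9)
  rb <- rate_constants(fb)
  k <- rb$k
  expect_equal(rb$k_hi - rb$k_lo, 2 * 1.96 * k / sqrt(1000), tolerance = 0.2)
  # component ordering: smallest tau gives largest k
  set.seed(6)
  z <- runif(2000) < 0.5
  d2 <- dwell_table(ifelse(z, rexp(2000, 1e4), rexp(2000, 2e3)))
  f2 <- fit_exponential_mixture(d2, 2, n_boot = 0)
  r2 <- rate_constants(f2)
  expect_true(all(diff(r2$k) < 0))
})

test_that("windowed mean dwells quantify dynamic disorder", {
  # constant dwells: zero CV
  d <- dwell_table(rep(1e-2, 2000))
  dd <- dynamic_disorder(d, state = 0L, window = 1)
  expect_equal(dd$cv, 0)

  # homogeneous exponential process: CV ~ 1/sqrt(m)
  set.seed(7)
  tau <- 5e-3
  durations <- rexp(42000, 1 / tau)
  d2 <- dwell_table(durations)
  d2 <- d2[d2$start_s < 200, ]
  dd2 <- dynamic_disorder(d2, state = 0L, window = 1)
  m <- mean(dd2$per_window$n_dwells)
  expect_equal(dd2$cv, 1 / sqrt(m), tolerance = 0.3)
  expect_gte(dd2$n_windows, 190)

  expect_error(dynamic_disorder(dwell_table(rep(0.5, 4)), 0L, window = 1),
               "10 windows")
})

test_that("modulated kinetics raise the windowed CV above the control", {
  sc <- kinetic_scheme(
    states = data.frame(name = c("u", "b"), level = c(1, 0.94)),
    Q = matrix(c(0, 50, 50, 0), 2, 2, byrow = TRUE)
  )
  mod <- rate_modulation("two_regime", timescale = 10, amplitude = 5)
  wins <- function(p) {
    dw <- true_dwells(p, sc, by = "state")
    dynamic_disorder(dw, state = 0L, window = 1)$cv
  }
  cv_mod <- wins(simulate_path(sc, 60, seed = 23, modulation = mod))
  cv_ctl <- wins(simulate_path(sc, 60, seed = 23))
  expect_gt(cv_mod, cv_ctl)
})

test_that("k_obs counts bound-state entries per second", {
  # no bound visits: zero
  d0 <- dwell_table(rep(1e-2, 20), state = 0L)
  d0$conc_partner <- 1e-7
  k0 <- compute_kobs(d0, bound_state = 1L)
  expect_equal(k0$kobs_per_s, 0)

  # two-state chain: expected entries/s = pi_unbound * k_on_eff
  kd <- 205e-9; k_diss <- 200
  sc <- binding_scheme(kd = kd, k_diss = k_diss)
  concs <- c(5e-8, 2e-7, 1e-6)
  dws <- purrr::map(seq_along(concs), function(i) {
    p <- simulate_path(sc, 40, concentrations = list(partner = concs[i]),
                       seed = 100 + i)
    dw <- true_dwells(p, sc, by = "state")
    dw$conc_partner <- concs[i]
    dw$trace_id <- paste0("t", i)
    dw
  })
  kc <- compute_kobs(bind_dwells(dws), bound_state = 1L)
  k_on <- k_diss / kd
  for (i in seq_along(concs)) {
    pi_u <- kd / (kd + concs[i])
    expected <- pi_u * k_on * concs[i]
    n_exp <- expected * 40
    se <- sqrt(n_exp) / 40
    expect_lt(abs(kc$kobs_per_s[i] - expected), 3 * se)
  }
  # monotone in concentration under pseudo-first-order association
  expect_true(all(diff(kc$kobs_per_s) > 0))
})

test_that("induced-fit fits recover hyperbolic k_obs parameters", {
  C <- c(1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6)
  k_f <- 120; k_r <- 15; K_1 <- 2e-7
  curve <- tibble::tibble(conc_M = C,
                          kobs_per_s = k_r + k_f * C / (K_1 + C))
  fit <- fit_induced_fit(curve)
  expect_equal(fit$k_f, k_f, tolerance = 1e-6)
  expect_equal(fit$k_r, k_r, tolerance = 1e-6)
  expect_equal(fit$K_1, K_1, tolerance = 1e-6)
  expect_true(fit$identifiable)

  # saturation limit: fitted plateau approaches k_f + k_r
  plateau <- fit$k_r + fit$k_f
  expect_equal(plateau, k_r + k_f, tolerance = 1e-6)

  # flat curve: k_f pinned near zero, k_r near the constant, flagged
  flat <- tibble::tibble(conc_M = C, kobs_per_s = rep(20, length(C)))
  ff <- fit_induced_fit(flat)
  expect_lt(ff$k_f, 1e-6)
  expect_equal(ff$k_r, 20, tolerance = 1e-6)
  expect_false(ff$identifiable)
})
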