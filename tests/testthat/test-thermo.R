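R_GAS <- 8.314462618

make_labels <- function(states, fs = 1000, means = c(1, 0.94)) {
  hmm <- as_tk_hmm(list(init = rep(0.5, 2),
                        trans = matrix(0.5, 2, 2),
                        means = means, sds = c(0.01, 0.01)))
  out <- tibble::tibble(time = (seq_along(states) - 1) / fs,
                        current = means[states + 1L],
                        state = as.integer(states))
  structure(out, hmm = hmm, loglik = NA_real_, sampling_rate = fs,
            metadata = NULL,
            class = c("tk_idealized", "tbl_df", "tbl", "data.frame"))
}

test_that("bound fraction is the time fraction of the bound state", {
  id_all <- make_labels(rep(1L, 100))
  expect_equal(bound_fraction(id_all, 1L)$alpha, 1)

  # noiseless trace: equals the exact time fraction of the true path
  sc <- binding_scheme(kd = 205e-9, k_diss = 200)
  p <- simulate_path(sc, 1, concentrations = list(partner = 205e-9), seed = 41)
  tr <- suppressWarnings(render_trace(p, sc, noise = noise_spec(0, 0),
    acq = acquisition_spec(filter_cutoff = NULL, duration = 1)))
  id <- threshold_idealize(tr, c(1, 0.94))
  truth <- sum(p$duration[p$state == 2]) / sum(p$duration)
  n_dwell <- nrow(p)
  expect_equal(bound_fraction(id, 1L)$alpha, truth,
               tolerance = n_dwell / nrow(tr) + 1e-6)

  # two-state occupancy at C = K_D is one half
  p2 <- simulate_path(sc, 30, concentrations = list(partner = 205e-9),
                      seed = 42)
  occ <- sum(p2$duration[p2$state == 2]) / 30
  se <- 0.5 / sqrt(nrow(p2))
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("Hill fits recover exact n = 1 curves across the affinity range", {
  for (kd in c(1e-9, 205e-9, 1e-6, 1e-4)) {
    C <- kd * 10^seq(-2, 2, length.out = 7)
    dr <- dose_response(C, C / (C + kd))
    fit <- fit_hill(dr)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$n_hill, 1, tolerance = 1e-6)
    expect_false(fit$apparent)
  }
  # exact n = 2 curve
  kd <- 205e-9
  C <- kd * 10^seq(-1.5, 1.5, length.out = 7)
  dr2 <- dose_response(C, C^2 / (kd^2 + C^2))
  fit2 <- fit_hill(dr2)
  expect_equal(fit2$n_hill, 2, tolerance = 1e-6)
  expect_error(fit_hill(dose_response(C, rep(0, 7))), "identifiable")
})

test_that("binomial sampling keeps the true K_D inside the 95% CI", {
  kd <- 205e-9
  C <- kd * 10^seq(-1.5, 1.5, length.out = 7)
  n_eff <- 3e5  # three traces of ~1e5 effective samples
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    a_true <- C / (C + kd)
    a_obs <- rbinom(length(C), n_eff, a_true) / n_eff
    se <- sqrt(pmax(a_obs * (1 - a_obs), 1e-9) / n_eff)
    fit <- fit_hill(dose_response(C, a_obs, se = se))
    if (fit$kd_lo <= kd && kd <= fit$kd_hi) hits <- hits + 1
  }
  expect_gte(hits, 26)  # ~95% nominal coverage, small-sample slack
})

test_that("equilibrium constants follow the dwell-ratio convention", {
  eq <- equilibrium_constants(tibble::tibble(
    temperature_K = 310.15, tau_bound_s = 2e-3, tau_unbound_s = 2e-3))
  expect_equal(eq$K_diss, 1)

  # two-state simulation: K_diss equals pi_unbound / pi_bound
  sc <- binding_scheme(kd = 205e-9, k_diss = 200)
  C <- 4e-7
  p <- simulate_path(sc, 40, concentrations = list(partner = C), seed = 51)
  d <- p[-c(1, nrow(p)), ]
  tau_b <- mean(d$duration[d$state == 2])
  tau_u <- mean(d$duration[d$state == 1])
  K_dwell <- tau_u / tau_b
  pi <- stationary_distribution(sc, concentrations = list(partner = C))
  K_occ <- pi[["Myc*"]] / pi[["bound"]]
  n <- nrow(d) / 2
  expect_lt(abs(K_dwell - K_occ) / K_occ, 3 * sqrt(2 / n))
})

test_that("K_diss rises with temperature when Ea_diss exceeds Ea_bind", {
  sc <- binding_scheme(kd = 205e-9, k_diss = 200, ea_bind = 71e3,
                       ea_diss = 109e3)
  temps <- celsius_to_kelvin(c(25, 35, 45))
  K <- vapply(temps, function(T) {
    Q <- rates_at_temperature(sc, T)
    (Q[2, 1]) / (Q[1, 2] * 205e-9)  # k_diss over k_bind at C = K_D(ref)
  }, numeric(1))
  expect_true(all(diff(K) > 0))
})

test_that("Arrhenius estimation is exact on noiseless rates and robust to noise", {
  # flat rates: Ea = 0
  flat <- fit_arrhenius(tibble::tibble(
    temperature_K = celsius_to_kelvin(c(25, 30, 35, 40, 45)), k = 200))
  expect_equal(flat$ea, 0, tolerance = 1e-9)

  # two points from Ea = 100 kJ/mol: closed-form recovery
  Ea <- 100e3; A <- 1e12
  temps2 <- c(298.15, 318.15)
  k2 <- A * exp(-Ea / (R_GAS * temps2))
  fit2 <- fit_arrhenius(tibble::tibble(temperature_K = temps2, k = k2))
  expect_equal(fit2$ea, Ea, tolerance = 1e-9)
  expect_equal(fit2$ln_a, log(A), tolerance = 1e-9)

  # 5 temperatures, 5% multiplicative noise: Ea within 15% across seeds
  temps5 <- celsius_to_kelvin(seq(25, 45, by = 5))
  k5 <- A * exp(-Ea / (R_GAS * temps5))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    kn <- k5 * exp(rnorm(5, 0, 0.05))
    abs(fit_arrhenius(tibble::tibble(temperature_K = temps5,
                                     k = kn))$ea - Ea) / Ea
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})

test_that("van't Hoff fits satisfy the thermodynamic identity", {
  # flat K: dH = 0 and dS = R ln K
  K0 <- 2.5
  flat <- fit_vant_hoff(tibble::tibble(
    temperature_K = celsius_to_kelvin(c(25, 35, 45)), K_diss = K0))
  expect_equal(flat$dh, 0, tolerance = 1e-9)
  expect_equal(flat$ds, R_GAS * log(K0), tolerance = 1e-9)

  # exact data: recovery to machine precision
  dH <- 24e3; dS <- 50
  temps <- celsius_to_kelvin(seq(25, 45, by = 5))
  K <- exp(-dH / (R_GAS * temps) + dS / R_GAS)
  fit <- fit_vant_hoff(tibble::tibble(temperature_K = temps, K_diss = K))
  expect_equal(fit$dh, dH, tolerance = 1e-9)
  expect_equal(fit$ds, dS, tolerance = 1e-9)

  # dG(T) = dH - T dS = -R T ln K_pred(T) at every input temperature
  for (T in temps) {
    dG <- fit$dh - T * fit$ds
    expect_lt(abs(dG - (-R_GAS * T * log(fit$predict_K(T)))), 1e-9)
  }
})

test_that("apparent K_D under competition follows Cheng-Prusoff", {
  kd <- 205e-9; ki <- 33e-6
  comp <- competition_scheme(kd_partner = kd, kd_inhibitor = ki,
                             topology = "shared")
  dose_alpha <- function(I) {
    C <- kd * (1 + I / ki) * 10^seq(-1.5, 1.5, length.out = 7)
    a <- vapply(C, function(c) {
      unname(stationary_distribution(comp,
        concentrations = list(partner = c, inhibitor = I))["boundP"])
    }, numeric(1))
    dose_response(C, a, inhibitor_conc_M = I)
  }
  # zero inhibitor: apparent equals the true constant
  f0 <- apparent_kd(dose_alpha(0))
  expect_equal(f0$kd, kd, tolerance = 1e-6)
  expect_false(f0$apparent)

  # 100 uM inhibitor: Cheng-Prusoff shift, within fit tolerance
  I <- 100e-6
  fI <- apparent_kd(dose_alpha(I))
  expect_equal(fI$kd, kd * (1 + I / ki), tolerance = 1e-6)
  expect_true(fI$apparent)
  expect_gt(fI$kd, kd)

  # the distinct-intermediate topology also shows apparent K_D > K_D
  compd <- competition_scheme(kd_partner = kd, kd_inhibitor = ki,
                              topology = "distinct")
  C <- kd * 10^seq(-1.5, 2.5, length.out = 9)
  a_d <- vapply(C, function(c) {
    unname(stationary_distribution(compd,
      concentrations = list(partner = c, inhibitor = I))["boundP"])
  }, numeric(1))
  fd <- apparent_kd(dose_response(C, a_d, inhibitor_conc_M = I))
  expect_gt(fd$kd, kd)
})

test_that("alpha is monotone in concentration on stationary occupancies", {
  sc <- binding_scheme(kd = 205e-9, k_diss = 200)
  C <- 10^seq(-9, -5, length.out = 12)
  a <- vapply(C, function(c) {
    unname(stationary_distribution(sc,
      concentrations = list(partner = c))["bound"])
  }, numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("cross-route K_D agreement on a two-state binding simulation", {
  kd <- 205e-9; k_diss <- 200
  sc <- binding_scheme(kd = kd, k_diss = k_diss)
  C <- kd * 10^seq(-1.5, 1.5, length.out = 7)
  # dose series from path-level occupancy
  a <- vapply(seq_along(C), function(i) {
    p <- simulate_path(sc, 30, concentrations = list(partner = C[i]),
                       seed = 300 + i)
    sum(p$duration[p$state == 2]) / 30
  }, numeric(1))
  hill <- fit_hill(dose_response(C, a))
  # dwell-route: at C = K_D, k_bind_eff = k_on * C, K_D = C tau_u / tau_b
  p <- simulate_path(sc, 30, concentrations = list(partner = kd), seed = 999)
  d <- p[-c(1, nrow(p)), ]
  kd_dwell <- kd * mean(d$duration[d$state == 1]) /
    mean(d$duration[d$state == 2])
  expect_lt(abs(hill$kd - kd_dwell) / kd_dwell, 0.1)
})
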