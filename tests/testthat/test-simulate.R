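two_state_scheme <- function(k12 = 500, k21 = 500) {
  kinetic_scheme(
    states = data.frame(name = c("u", "b"), level = c(1, 0.94)),
    Q = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE)
  )
}

test_that("Gillespie dwells match the exponential law", {
  sc <- two_state_scheme(500, 500)
  p <- simulate_path(sc, 25, seed = 42)  # ~ 12500 events
  d <- p[-c(1, nrow(p)), ]
  for (s in 1:2) {
    dw <- d$duration[d$state == s]
    expect_gt(length(dw), 4000)
    se <- sd(dw) / sqrt(length(dw))
    expect_lt(abs(mean(dw) - 1 / 500), 3 * se)
  }
})

test_that("an absorbing state ends the path with one covering dwell", {
  sc <- kinetic_scheme(
    states = data.frame(name = c("a", "b"), level = c(1, 0.94)),
    Q = matrix(c(0, 0, 50, 0), 2, 2, byrow = TRUE)
  )
  p <- simulate_path(sc, 3, seed = 1, initial_state = 1L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$duration, 3)
  expect_equal(p$state, 1L)
})

test_that("medium-state dwells of the apo scheme sit on the 1e-4 s scale", {
  sc <- apo_scheme()  # state 1 exit rate 1e4/s
  p <- simulate_path(sc, 3, seed = 5)
  d <- p[-c(1, nrow(p)), ]
  m <- mean(d$duration[d$state == 2])
  expect_gt(m, 0.5e-4)
  expect_lt(m, 2e-4)
})

test_that("long-run state occupancy matches the stationary distribution", {
  sc <- two_state_scheme(300, 700)
  pi <- stationary_distribution(sc)
  p <- simulate_path(sc, 60, seed = 9)
  occ <- tapply(p$duration, p$state, sum) / sum(p$duration)
  n_ev <- nrow(p)
  # binomial-ish Monte-Carlo error on the time fraction
  se <- sqrt(pi[1] * (1 - pi[1]) / n_ev) * 2
  expect_lt(abs(occ[[1]] - pi[[1]]), 3 * se)
})

test_that("paths and traces are bit-identical under the same seed", {
  sc <- two_state_scheme()
  p1 <- simulate_path(sc, 0.5, seed = 77)
  p2 <- simulate_path(sc, 0.5, seed = 77)
  expect_identical(p1$state, p2$state)
  expect_identical(p1$exit_time, p2$exit_time)
  acq <- acquisition_spec(duration = 0.4)
  t1 <- suppressWarnings(render_trace(p1, sc, seed = 5, acq = acq))
  t2 <- suppressWarnings(render_trace(p2, sc, seed = 5, acq = acq))
  expect_identical(t1$current, t2$current)
  p3 <- simulate_path(sc, 0.5, seed = 78)
  expect_false(identical(p3$exit_time, p1$exit_time))
})

test_that("pink noise has the requested spectral slope and is seeded", {
  expect_identical(pink_noise(64, 0, 1, seed = 1), numeric(64))
  expect_identical(pink_noise(4096, 1, 1, seed = 3),
                   pink_noise(4096, 1, 1, seed = 3))
  for (ex in c(0.5, 1, 1.5)) {
    x <- pink_noise(2^16, 1, ex, seed = 11)
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-12)
    expect_lt(abs(periodogram_slope(x) + ex), 0.15)
  }
})

test_that("noiseless unfiltered rendering reproduces the state levels", {
  sc <- two_state_scheme()
  acq <- acquisition_spec(sampling_rate = 1000, filter_cutoff = NULL,
                          duration = 1)
  # transitions aligned to the fine grid so no cell straddles an edge
  p <- manual_path(c(1, 2, 1, 2), c(0.25, 0.25, 0.3, 0.2), sc)
  tr <- render_trace(p, sc, noise = noise_spec(0, 0), acq = acq)
  lev <- sc$states$level
  expected <- ifelse(tr$time < 0.25, lev[1],
               ifelse(tr$time < 0.5, lev[2],
               ifelse(tr$time < 0.8, lev[1], lev[2])))
  expect_equal(tr$current, expected, tolerance = 1e-12)
  # level ordering is preserved dwell by dwell
  expect_gt(min(tr$current[tr$time >= 0.5 & tr$time < 0.8]),
            max(tr$current[tr$time >= 0.8]))
})

test_that("sampling at 57.6 kHz gives 17.4 microsecond spacing", {
  sc <- two_state_scheme()
  p <- simulate_path(sc, 0.02, seed = 2)
  tr <- suppressWarnings(render_trace(p, sc, noise = noise_spec(0, 0),
                     acq = acquisition_spec(duration = 0.02)))
  expect_equal(diff(tr$time)[1], 1 / 57600, tolerance = 1e-12)
  expect_equal(nrow(tr), round(0.02 * 57600))
})

test_that("filtered white noise has the SD predicted by a Monte-Carlo oracle", {
  sc <- kinetic_scheme(
    states = data.frame(name = c("only", "ghost"), level = c(1, 1)),
    Q = matrix(c(0, 1e-9, 1e-9, 0), 2, 2, byrow = TRUE)
  )
  p <- manual_path(1, 2, sc)
  acq <- acquisition_spec(duration = 2)
  tr <- render_trace(p, sc, noise = noise_spec(0.01, 0), acq = acq, seed = 31)
  # oracle: filter long iid noise through the same chain, independent seed
  set.seed(1234)
  fine_fs <- acq$sampling_rate * acq$oversample
  bf <- signal::butter(acq$filter_order, acq$filter_cutoff / (fine_fs / 2),
                       "low")
  sim <- signal::filtfilt(bf, rnorm(2e6, 0, 0.01))
  sd_oracle <- sd(sim[seq(1, length(sim), by = acq$oversample)])
  expect_lt(abs(sd(tr$current) - sd_oracle) / sd_oracle, 0.1)
})

test_that("sub-grid dwells are averaged with a warning", {
  sc <- two_state_scheme()
  acq <- acquisition_spec(sampling_rate = 1000, filter_cutoff = NULL,
                          duration = 0.01, oversample = 1)
  p <- manual_path(c(1, 2, 1), c(0.0052, 1e-5, 0.0058), sc)
  expect_warning(render_trace(p, sc, noise = noise_spec(0, 0), acq = acq),
                 "time-weighted")
})

test_that("make_dataset builds the experimental grids with full metadata", {
  sc <- binding_scheme(kd = 205e-9, k_diss = 200)
  dose <- c("5 nM", "20 nM", "50 nM", "100 nM", "500 nM", "1 uM", "5 uM")
  ds <- make_dataset(sc, concentrations = list(partner = dose),
                     duration = 0.05, seed = 3, render = FALSE)
  expect_equal(nrow(ds), 7L)
  expect_equal(ds$conc_partner, parse_concentration(dose))
  expect_equal(length(unique(ds$seed)), 7L)

  temps <- celsius_to_kelvin(seq(25, 45, by = 5))
  ds2 <- make_dataset(sc, concentrations = list(partner = 205e-9),
                      temperatures = temps, duration = 0.05, seed = 3,
                      render = FALSE)
  expect_equal(nrow(ds2), 5L)
  expect_equal(sort(ds2$temperature_K), temps)

  expect_error(
    make_dataset(sc, temperatures = 400, duration = 0.1, render = FALSE),
    "273"
  )
  expect_error(
    make_dataset(sc, concentrations = list(partner = c(2e-6, 1e-6)),
                 duration = 0.1, render = FALSE),
    "increasing"
  )
  # trace length is duration times sampling rate
  ds3 <- make_dataset(sc, concentrations = list(partner = 1e-6),
                      duration = 0.1, seed = 4,
                      acq = acquisition_spec(duration = 0.1))
  expect_equal(nrow(ds3$trace[[1]]), round(0.1 * 57600))
})

test_that("two-regime modulation widens the dwell distribution", {
  sc <- two_state_scheme(50, 50)
  mod <- rate_modulation("two_regime", timescale = 5, amplitude = 5)
  p_mod <- simulate_path(sc, 40, seed = 21, modulation = mod)
  p_ctl <- simulate_path(sc, 40, seed = 21)
  d_mod <- p_mod$duration[-c(1, nrow(p_mod))]
  d_ctl <- p_ctl$duration[-c(1, nrow(p_ctl))]
  # modulated dwell-time distribution is overdispersed relative to control
  expect_gt(sd(d_mod) / mean(d_mod), sd(d_ctl) / mean(d_ctl))
})
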