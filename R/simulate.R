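#' Noise specification for trace rendering
#'
#' @param white_sd Standard deviation of Gaussian white noise, in
#'   relative-conductance units.
#' @param pink_amplitude Standard deviation of the 1/f (pink) component.
#' @param pink_exponent Spectral exponent: power spectral density scales as
#'   `1/f^exponent`; must lie in `[0.5, 1.5]`.
#' @return A list of class `tk_noise`.
#' @export
noise_spec <- function(white_sd = 0.006, pink_amplitude = white_sd / 2,
                       pink_exponent = 1) {
  stopifnot(white_sd >= 0, pink_amplitude >= 0,
            pink_exponent >= 0.5, pink_exponent <= 1.5)
  structure(list(white_sd = white_sd, pink_amplitude = pink_amplitude,
                 pink_exponent = pink_exponent), class = "tk_noise")
}

#' Acquisition specification
#'
#' Defaults mirror a typical nanowire-transistor recording chain: 57.6 kHz
#' sampling (17.4 microsecond resolution) behind a 10 kHz low-pass filter.
#' Set `filter_cutoff = NULL` to disable filtering.
#'
#' @param sampling_rate Output sampling rate, Hz.
#' @param filter_cutoff Low-pass cutoff, Hz; must be below the Nyquist
#'   frequency. `NULL` disables the filter.
#' @param filter_order Filter order (poles).
#' @param duration Trace duration, s.
#' @param oversample Internal rendering grid density as a multiple of
#'   `sampling_rate` (>= 4 recommended).
#' @return A list of class `tk_acq`.
#' @export
acquisition_spec <- function(sampling_rate = 57600, filter_cutoff = 10000,
                             filter_order = 4, duration = 1, oversample = 4) {
  stopifnot(sampling_rate > 0, duration > 0, oversample >= 1)
  if (!is.null(filter_cutoff) && filter_cutoff >= sampling_rate / 2) {
    abort("`filter_cutoff` must be below the Nyquist frequency.")
  }
  structure(list(sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 filter_order = filter_order, duration = duration,
                 oversample = oversample), class = "tk_acq")
}

#' Slow rate-modulation specification (dynamic disorder)
#'
#' Multiplies all rates by a slowly varying factor, modelling dynamic
#' disorder: `"two_regime"` alternates between 1 and `amplitude` every
#' `timescale` seconds; `"lognormal"` redraws a log-normal factor with
#' `sdlog = log(amplitude)` on the same grid.
#'
#' @param mode `"none"`, `"two_regime"` or `"lognormal"`.
#' @param timescale Regime duration, s; should greatly exceed the mean dwell.
#' @param amplitude Fold-change between regimes (dimensionless, > 0).
#' @return A list of class `tk_modulation`.
#' @export
rate_modulation <- function(mode = c("none", "two_regime", "lognormal"),
                            timescale = 10, amplitude = 5) {
  mode <- match.arg(mode)
  stopifnot(timescale > 0, amplitude > 0)
  structure(list(mode = mode, timescale = timescale, amplitude = amplitude),
            class = "tk_modulation")
}

#' Simulate a state path from a kinetic scheme
#'
#' Draws an exact continuous-time Markov chain trajectory (Gillespie
#' algorithm): the dwell in state i is exponential with the total exit rate,
#' and the successor is chosen proportionally to the outgoing rates. Under a
#' rate modulation the factor is piecewise constant; dwells crossing a regime
#' boundary are resampled there, which is exact by memorylessness.
#'
#' @inheritParams effective_rates
#' @param duration Path duration, s.
#' @param seed Integer seed for reproducibility (optional).
#' @param modulation A [rate_modulation()] or `NULL`.
#' @param initial_state Starting state (1-based index or name); default is a
#'   draw from the stationary distribution (or state 1 if the chain is
#'   reducible).
#' @return A tibble of class `tk_path` with columns `state` (1-based index),
#'   `name`, `entry_time`, `exit_time`, `duration`; attribute
#'   `total_duration`.
#' @export
simulate_path <- function(scheme, duration, temperature = NULL,
                          concentrations = NULL, seed = NULL,
                          modulation = NULL, initial_state = NULL) {
  stopifnot(inherits(scheme, "tk_scheme"), duration > 0)
  Q <- effective_rates(scheme, temperature, concentrations)
  n <- nrow(Q)
  exit <- -diag(Q)
  if (any(!is.finite(exit))) abort("Effective rates must be finite.")
  mod <- modulation %||% rate_modulation("none")
  if (mod$mode != "none") {
    mean_dwell <- 1 / max(exit[exit > 0], 1e-12)
    if (mod$timescale < 10 * mean_dwell) {
      warn("Modulation timescale is not much larger than the mean dwell.")
    }
  }

  with_seed_(seed, {
    if (is.null(initial_state)) {
      pi0 <- tryCatch(stationary_distribution(Q),
                      error = function(e) rep(1 / n, n) * 0 + c(1, rep(0, n - 1)))
      s <- sample.int(n, 1, prob = pmax(pi0, 0))
    } else if (is.character(initial_state)) {
      s <- match(initial_state, scheme$states$name)
      if (is.na(s)) abort("Unknown `initial_state` name.")
    } else {
      s <- as.integer(initial_state)
    }

    # regime factors, piecewise constant on a fixed grid
    n_reg <- ceiling(duration / mod$timescale) + 1L
    factors <- switch(mod$mode,
      none = rep(1, n_reg),
      two_regime = rep(c(1, mod$amplitude), length.out = n_reg),
      lognormal = exp(rnorm(n_reg, 0, log(mod$amplitude)))
    )
    regime_at <- function(t) min(floor(t / mod$timescale) + 1, n_reg)

    states <- integer(0); t_in <- numeric(0); t_out <- numeric(0)
    t <- 0
    entry <- 0
    while (t < duration) {
      r <- exit[s]
      if (r <= 0) { # absorbing: remain for the rest of the trace
        t <- duration
        break
      }
      reg <- regime_at(t)
      f <- factors[reg]
      dt <- rexp(1, rate = r * f)
      reg_end <- reg * mod$timescale
      if (mod$mode != "none" && t + dt > reg_end && reg_end < duration) {
        t <- reg_end  # memoryless: resample in the next regime
        next
      }
      t <- t + dt
      if (t >= duration) { t <- duration; break }
      states <- c(states, s); t_in <- c(t_in, entry); t_out <- c(t_out, t)
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(n, 1, prob = probs)
      entry <- t
    }
    states <- c(states, s); t_in <- c(t_in, entry); t_out <- c(t_out, duration)
    out <- tibble::tibble(
      state = states,
      name = scheme$states$name[states],
      entry_time = t_in,
      exit_time = t_out,
      duration = t_out - t_in
    )
    structure(out, total_duration = duration, scheme_id = scheme$id,
              class = c("tk_path", class(out)))
  })
}

#' Ground-truth dwell table from a simulated path
#'
#' Converts a `tk_path` into the same tabular dwell format produced by
#' [segment_dwells()], either per state or per current level (consecutive
#' visits to states sharing a level are merged, matching what any
#' idealization of the trace could resolve).
#'
#' @param path A `tk_path`.
#' @param scheme The scheme that generated it.
#' @param by `"state"` or `"level"`.
#' @param trace_id Identifier copied into the table.
#' @return A tibble with columns `trace_id`, `state` (0-based,
#'   highest-current level = 0 when `by = "level"`), `start_s`,
#'   `duration_s`, `censored`.
#' @export
true_dwells <- function(path, scheme, by = c("state", "level"),
                        trace_id = "path") {
  by <- match.arg(by)
  stopifnot(inherits(path, "tk_path"))
  if (by == "state") {
    lab <- path$state - 1L
  } else {
    lev <- scheme$states$level[path$state]
    ulev <- sort(unique(scheme$states$level), decreasing = TRUE)
    lab <- match(lev, ulev) - 1L
  }
  # merge consecutive identical labels
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  grp <- cumsum(keep)
  start <- tapply(path$entry_time, grp, min)
  end <- tapply(path$exit_time, grp, max)
  st <- lab[keep]
  n <- length(st)
  tibble::tibble(
    trace_id = trace_id,
    state = st,
    start_s = as.numeric(start),
    duration_s = as.numeric(end - start),
    censored = seq_len(n) %in% c(1L, n)
  )
}

#' Synthesize 1/f ("pink") noise
#'
#' Generates a zero-mean Gaussian series whose power spectral density scales
#' as `1/f^exponent`, by spectrally shaping white noise in the frequency
#' domain and normalising to the requested standard deviation.
#'
#' @param n Number of samples (>= 1).
#' @param amplitude Target standard deviation; 0 returns zeros.
#' @param exponent Spectral exponent in `[0.5, 1.5]`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, amplitude = 1, exponent = 1, seed = NULL) {
  stopifnot(n >= 1)
  if (amplitude == 0) return(numeric(n))
  with_seed_(seed, {
    w <- rnorm(n)
    W <- fft(w)
    k <- seq_len(n) - 1L
    fidx <- pmin(k, n - k)          # symmetric frequency index
    shape <- numeric(n)
    shape[fidx > 0] <- fidx[fidx > 0]^(-exponent / 2)
    X <- W * shape
    x <- Re(fft(X, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- sd(x)
    if (s > 0) x <- x * (amplitude / s)
    x
  })
}

#' Render a state path into a sampled current trace
#'
#' Evaluates the piecewise-constant conductance level of the path on a fine
#' internal grid (`oversample` times the output rate, exact time-weighted
#' averaging within each grid cell), adds white and 1/f noise, applies a
#' zero-phase low-pass filter at the acquisition cutoff, and decimates to
#' the output sampling rate. State-to-level mapping preserves ordering: more
#' folded or bound states render at lower relative conductance.
#'
#' @param path A `tk_path` covering at least `acq$duration`.
#' @param scheme The generating `tk_scheme` (supplies conductance levels).
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()].
#' @param seed Optional integer seed for the noise draws.
#' @param metadata Named list merged into the trace metadata (temperature_K,
#'   concentrations, ...).
#' @return A tibble of class `tk_trace` with columns `time` and `current`;
#'   attributes `sampling_rate` and `metadata`.
#' @export
render_trace <- function(path, scheme, noise = noise_spec(),
                         acq = acquisition_spec(), seed = NULL,
                         metadata = list()) {
  stopifnot(inherits(path, "tk_path"), inherits(scheme, "tk_scheme"))
  total <- attr(path, "total_duration")
  if (total < acq$duration - 1e-12) {
    abort("Path is shorter than the acquisition duration.")
  }
  fs <- acq$sampling_rate
  fine_fs <- fs * acq$oversample
  n_out <- round(acq$duration * fs)
  n_fine <- n_out * acq$oversample

  if (any(path$duration < 1 / fine_fs)) {
    warn(sprintf("%d dwell(s) shorter than the internal grid step (%.3g s) rendered by time-weighted averaging.",
                 sum(path$duration < 1 / fine_fs), 1 / fine_fs))
  }

  lev <- scheme$states$level[path$state]
  # cumulative integral of the level function at event boundaries
  bounds <- c(path$entry_time[1], path$exit_time)
  cum <- c(0, cumsum(lev * path$duration))
  grid <- seq(0, by = 1 / fine_fs, length.out = n_fine + 1L)
  grid[n_fine + 1L] <- min(grid[n_fine + 1L], total)
  I <- approx(bounds, cum, xout = grid, rule = 2)$y
  x <- diff(I) * fine_fs   # cell-averaged level; equals the level away from edges

  if (noise$white_sd > 0) x <- x + rnorm2_(n_fine, noise$white_sd, seed)
  if (noise$pink_amplitude > 0) {
    x <- x + pink_noise(n_fine, noise$pink_amplitude, noise$pink_exponent,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  }
  if (!is.null(acq$filter_cutoff) && acq$filter_cutoff < fine_fs / 2) {
    bf <- signal::butter(acq$filter_order, acq$filter_cutoff / (fine_fs / 2),
                         type = "low")
    # filter about the DC level: the acquisition filter runs in steady state,
    # so the zero-initial-condition start-up transient is unphysical
    m <- mean(x)
    x <- m + signal::filtfilt(bf, x - m)
  }
  idx <- seq(1L, n_fine, by = acq$oversample)
  out <- tibble::tibble(time = (idx - 1L) / fine_fs, current = x[idx])
  md <- utils::modifyList(
    list(seed = seed, scheme_id = scheme$id,
         filter_cutoff = acq$filter_cutoff, oversample = acq$oversample),
    metadata
  )
  structure(out, sampling_rate = fs, metadata = md,
            class = c("tk_trace", class(out)))
}

rnorm2_ <- function(n, sd, seed) {
  if (is.null(seed)) rnorm(n, 0, sd) else with_seed_(seed, rnorm(n, 0, sd))
}

#' Simulate a multi-condition dataset
#'
#' Builds the experimental grids of a single-molecule study: a ligand dose
#' series, a temperature series, or their crossing (e.g. a competition
#' series at fixed inhibitor concentration). Each condition receives
#' `n_traces` independent traces with seeds derived deterministically from
#' the top-level seed.
#'
#' @param scheme A `tk_scheme`.
#' @param concentrations Named list of concentration vectors (mol/L or
#'   strings with units), one entry per ligand species, each strictly
#'   increasing; conditions are formed from aligned vectors (a dose series)
#'   crossed with `temperatures`.
#' @param temperatures Temperatures in K (273–350) or `NULL` for the scheme
#'   reference temperature.
#' @param duration Trace duration per condition, s.
#' @param n_traces Replicate traces per condition.
#' @param noise,acq Rendering specifications; `acq$duration` is overridden
#'   by `duration`.
#' @param seed Top-level seed.
#' @param render If `FALSE`, only state paths are simulated (fast; for
#'   path-level analyses).
#' @param modulation Optional [rate_modulation()] applied to every trace.
#' @return A tibble with one row per trace: condition columns
#'   (`temperature_K`, one `conc_<species>` column per ligand), `replicate`,
#'   `seed`, and list-columns `path` (tk_path) and `trace` (tk_trace or
#'   `NULL`).
#' @export
make_dataset <- function(scheme, concentrations = NULL, temperatures = NULL,
                         duration = 10, n_traces = 1,
                         noise = noise_spec(), acq = acquisition_spec(),
                         seed = 1, render = TRUE, modulation = NULL) {
  stopifnot(inherits(scheme, "tk_scheme"))
  temps <- temperatures %||% scheme$t_ref
  if (any(temps < 273) || any(temps > 350)) {
    abort("`temperatures` must lie in 273–350 K (physiological range).")
  }
  if (!is.null(concentrations)) {
    concentrations <- lapply(concentrations, parse_concentration)
    lens <- lengths(concentrations)
    if (length(unique(lens[lens > 1])) > 1) {
      abort("Concentration vectors must have equal length (aligned dose series).")
    }
    n_dose <- max(lens)
    concentrations <- lapply(concentrations, function(v) {
      if (length(v) == 1L) rep(v, n_dose) else v
    })
    for (sp in names(concentrations)) {
      v <- concentrations[[sp]]
      if (length(unique(v)) > 1 && any(diff(v) <= 0)) {
        abort(paste0("Concentration series for '", sp,
                     "' must be strictly increasing."))
      }
    }
  } else {
    n_dose <- 1L
  }
  grid <- tidyr::crossing(dose_idx = seq_len(n_dose), temperature_K = temps,
                          replicate = seq_len(n_traces))
  seeds <- spawn_seeds_(seed, nrow(grid))
  acq$duration <- duration

  rows <- purrr::pmap(
    list(grid$dose_idx, grid$temperature_K, grid$replicate, seeds,
         seq_len(nrow(grid))),
    function(di, tK, rep_i, sd_i, row_i) {
      conc <- if (is.null(concentrations)) NULL else
        lapply(concentrations, function(v) v[di])
      path <- simulate_path(scheme, duration, temperature = tK,
                            concentrations = conc, seed = sd_i,
                            modulation = modulation)
      trace <- NULL
      if (render) {
        md <- c(list(temperature_K = tK),
                if (!is.null(conc)) setNames(conc, paste0("conc_", names(conc))))
        trace <- render_trace(path, scheme, noise = noise, acq = acq,
                              seed = sd_i + 10000L, metadata = md)
      }
      out <- tibble::tibble(temperature_K = tK, replicate = rep_i,
                            seed = sd_i, path = list(path),
                            trace = list(trace))
      if (!is.null(conc)) {
        for (sp in names(conc)) out[[paste0("conc_", sp)]] <- conc[[sp]]
      }
      out
    }
  )
  out <- dplyr::bind_rows(rows)
  conc_cols <- grep("^conc_", names(out), value = TRUE)
  out <- dplyr::relocate(out, dplyr::all_of(conc_cols), .before = "replicate")
  structure(out, scheme = scheme, class = c("tk_dataset", class(out)))
}

#' Default noise for a scheme at a target signal-to-noise ratio
#'
#' White-noise SD set so the smallest conductance-level separation divided by
#' the SD equals `snr` (default 5: resolvable but realistically noisy), with
#' the 1/f amplitude at half the white SD.
#'
#' @param scheme A `tk_scheme`.
#' @param snr Level separation over white-noise SD.
#' @param pink_ratio Pink amplitude as a fraction of the white SD.
#' @param pink_exponent Spectral exponent of the 1/f component.
#' @return A [noise_spec()].
#' @export
noise_for_scheme <- function(scheme, snr = 5, pink_ratio = 0.5,
                             pink_exponent = 1) {
  lv <- sort(unique(scheme$states$level))
  if (length(lv) < 2) return(noise_spec(0, 0, pink_exponent))
  sep <- min(diff(lv))
  noise_spec(white_sd = sep / snr, pink_amplitude = sep / snr * pink_ratio,
             pink_exponent = pink_exponent)
}
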