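TRACE_SCHEMA_VERSION <- 1L

#' Save and load a current trace
#'
#' `save_trace()` writes the samples as a two-column CSV (`time_s`,
#' `current`) next to a JSON metadata sidecar (`<path>.json`) holding the
#' sampling rate, acquisition metadata and a schema version; the round trip
#' through `load_trace()` is lossless (doubles are written with
#' round-trippable precision). A plain CSV export without the sidecar loses
#' the metadata and is refused by `load_trace()` unless `metadata = FALSE`.
#'
#' @param trace A `tk_trace`.
#' @param path CSV file path.
#' @return `save_trace()`: the path, invisibly. `load_trace()`: a
#'   `tk_trace`.
#' @export
save_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tk_trace"))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  writeLines(c("time_s,current",
               sprintf("%.17g,%.17g", trace$time, trace$current)), path)
  meta <- list(
    schema_version = TRACE_SCHEMA_VERSION,
    sampling_rate = attr(trace, "sampling_rate"),
    metadata = attr(trace, "metadata") %||% list()
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_trace
#' @param metadata Require the JSON sidecar (default). With `FALSE`, a bare
#'   CSV is accepted and the sampling rate is inferred from the time column.
#' @export
load_trace <- function(path, metadata = TRUE) {
  dat <- tryCatch(
    utils::read.csv(path, colClasses = c(time_s = "numeric",
                                         current = "numeric")),
    error = function(e) abort(paste0("Cannot read trace CSV: ",
                                     conditionMessage(e)))
  )
  if (!all(c("time_s", "current") %in% names(dat)) ||
      anyNA(dat$time_s) || anyNA(dat$current)) {
    abort("Corrupt or truncated trace file (expect complete columns time_s, current).")
  }
  md <- list(); fs <- NULL
  side <- paste0(path, ".json")
  if (metadata) {
    if (!file.exists(side)) {
      abort("Metadata sidecar not found; pass `metadata = FALSE` for bare CSV.")
    }
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(as.integer(meta$schema_version), TRACE_SCHEMA_VERSION)) {
      abort(paste0("Trace schema version mismatch: file has ",
                   meta$schema_version, ", package expects ",
                   TRACE_SCHEMA_VERSION, "."))
    }
    fs <- meta$sampling_rate
    md <- meta$metadata
  } else {
    fs <- 1 / stats::median(diff(dat$time_s))
  }
  out <- tibble::tibble(time = dat$time_s, current = dat$current)
  structure(out, sampling_rate = fs, metadata = md,
            class = c("tk_trace", class(out)))
}

#' Save and load a dwell table
#'
#' CSV with the canonical column set (`trace_id`, `state`, `start_s`,
#' `duration_s`, `censored`) plus any condition columns.
#'
#' @param dwells A `tk_dwells` tibble.
#' @param path CSV path.
#' @export
save_dwells <- function(dwells, path) {
  readr::write_csv(dwells, path)
  invisible(path)
}

#' @rdname save_dwells
#' @export
load_dwells <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  structure(out, class = c("tk_dwells", class(out)))
}

scheme_from_config_ <- function(sc) {
  type <- sc$type %||% "binding"
  switch(type,
    binding = binding_scheme(
      kd = parse_concentration(sc$kd %||% 205e-9),
      k_diss = sc$k_diss %||% 200,
      ea_bind = sc$ea_bind, ea_diss = sc$ea_diss,
      t_ref = sc$t_ref %||% 310.15
    ),
    apo = apo_scheme(
      tau1 = sc$tau1 %||% 1e-4, tau1_star = sc$tau1_star %||% 5e-4,
      tau0 = sc$tau0 %||% 5e-4, tau2 = sc$tau2 %||% 2e-4,
      p_star = sc$p_star %||% 0.3
    ),
    competition = competition_scheme(
      kd_partner = parse_concentration(sc$kd_partner %||% 205e-9),
      kd_inhibitor = parse_concentration(sc$kd_inhibitor %||% 33e-6),
      k_diss_partner = sc$k_diss_partner %||% 200,
      k_diss_inhibitor = sc$k_diss_inhibitor %||% 200,
      topology = sc$topology %||% "distinct"
    ),
    abort(paste0("Unknown scheme type '", type, "'"))
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains the stages end to end: build the kinetic scheme, simulate the
#' condition grid, idealize every trace with the HMM, segment dwells, fit
#' dwell mixtures, and estimate a Hill curve (dose series) and/or Arrhenius
#' and van't Hoff parameters (temperature series). The run is deterministic
#' given the seed; the returned bundle records the configuration hash, seed
#' and package version, and `output_dir` (optional) receives CSV/JSON
#' artifacts and a Markdown report.
#'
#' @param config A nested list or path to a YAML file with entries `scheme`
#'   (`type` plus parameters), `conditions` (`concentrations`,
#'   `temperatures`, `duration`, `n_traces`), `noise`, `acquisition`,
#'   `analysis` (`n_states`, `dead_time_samples`, `n_components`,
#'   `n_boot`), `seed`.
#' @param output_dir Optional directory for artifacts.
#' @return A list of class `tk_bundle`: `dataset`, `dwells`, `dwell_fits`,
#'   `hill`, `arrhenius`, `vanthoff`, `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  scheme <- scheme_from_config_(config$scheme %||% list())
  cnd <- config$conditions %||% list()
  noise <- do.call(noise_spec, config$noise %||% list())
  acq <- do.call(acquisition_spec, config$acquisition %||% list())
  an <- config$analysis %||% list()
  n_states <- an$n_states %||% nrow(scheme$states)
  dead_time <- an$dead_time_samples %||% 2L
  n_comp <- an$n_components %||% 1L
  n_boot <- an$n_boot %||% 0L

  conc <- cnd$concentrations
  if (!is.null(conc)) conc <- lapply(conc, parse_concentration)
  temps <- cnd$temperatures
  if (!is.null(temps) && isTRUE(cnd$celsius)) temps <- celsius_to_kelvin(temps)

  ds <- make_dataset(scheme, concentrations = conc, temperatures = temps,
                     duration = cnd$duration %||% 10,
                     n_traces = cnd$n_traces %||% 1L,
                     noise = noise, acq = acq, seed = seed)

  bound_state <- which.min(scheme$states$level) - 1L
  # map to idealized label space: levels sorted descending
  ulev <- sort(unique(scheme$states$level), decreasing = TRUE)
  bound_label <- match(min(scheme$states$level), ulev) - 1L

  per_trace <- purrr::map(seq_len(nrow(ds)), function(i) {
    tr <- ds$trace[[i]]
    hmm <- fit_hmm(tr, n_states, seed = seed)
    ideal <- viterbi(tr, hmm)
    dw <- segment_dwells(ideal, dead_time = dead_time,
                         trace_id = paste0("trace", i))
    list(ideal = ideal, dwells = dw)
  })
  dwells <- bind_dwells(purrr::map(per_trace, "dwells"))

  fits <- list()
  hill <- NULL
  arr <- NULL
  vh <- NULL

  conc_cols <- grep("^conc_", names(ds), value = TRUE)
  if (length(conc_cols) >= 1 &&
      length(unique(ds[[conc_cols[1]]])) >= 4) {
    cc <- conc_cols[1]
    alpha_tbl <- purrr::map_dfr(split(seq_len(nrow(ds)), ds[[cc]]),
      function(idx) {
        bf <- bound_fraction(purrr::map(per_trace[idx], "ideal"), bound_label)
        tibble::tibble(conc_M = ds[[cc]][idx[1]], alpha = bf$alpha,
                       se = (bf$hi - bf$lo) / (2 * 1.96),
                       n_traces = length(idx))
      })
    alpha_tbl <- dplyr::arrange(alpha_tbl, .data$conc_M)
    dr <- dose_response(alpha_tbl$conc_M, alpha_tbl$alpha,
                        se = pmax(alpha_tbl$se, 1e-6),
                        n_traces = alpha_tbl$n_traces)
    hill <- fit_hill(dr)
  }
  temps_used <- unique(ds$temperature_K)
  if (length(temps_used) >= 2) {
    by_T <- purrr::map_dfr(temps_used, function(tK) {
      dw <- dwells[dwells$temperature_K == tK, ]
      fb <- fit_exponential_mixture(dw, n_comp, state = bound_label,
                                    dead_time = 0, n_boot = 0)
      fu <- fit_exponential_mixture(dw, n_comp, state = bound_label - 1L,
                                    dead_time = 0, n_boot = 0)
      tibble::tibble(temperature_K = tK,
                     tau_bound_s = fb$components$tau[1],
                     tau_unbound_s = fu$components$tau[1])
    })
    arr <- list(
      diss = fit_arrhenius(tibble::tibble(temperature_K = by_T$temperature_K,
                                          k = 1 / by_T$tau_bound_s)),
      bind = fit_arrhenius(tibble::tibble(temperature_K = by_T$temperature_K,
                                          k = 1 / by_T$tau_unbound_s))
    )
    vh <- fit_vant_hoff(equilibrium_constants(by_T))
    fits$by_temperature <- by_T
  }
  fits$overall <- tryCatch(
    fit_exponential_mixture(dwells, n_comp, state = bound_label,
                            dead_time = 0, seed = seed, n_boot = n_boot),
    error = function(e) NULL
  )

  provenance <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("tracekin")),
    n_traces = nrow(ds)
  )
  bundle <- structure(
    list(dataset = ds, dwells = dwells, dwell_fits = fits, hill = hill,
         arrhenius = arr, vanthoff = vh, provenance = provenance),
    class = "tk_bundle"
  )
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

#' Write a results bundle to disk
#'
#' Emits the dwell table as CSV, fitted parameters as a JSON results file
#' (tagged with the configuration hash, seed and package version), and a
#' Markdown report of all fitted parameters with confidence intervals.
#'
#' @param bundle A `tk_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_dwells(bundle$dwells, file.path(dir, "dwells.csv"))
  res <- list(provenance = bundle$provenance)
  if (!is.null(bundle$hill)) {
    res$hill <- bundle$hill[c("kd", "kd_lo", "kd_hi", "n_hill")]
  }
  if (!is.null(bundle$arrhenius)) {
    res$arrhenius <- list(
      ea_diss_J_mol = bundle$arrhenius$diss$ea,
      ea_bind_J_mol = bundle$arrhenius$bind$ea
    )
  }
  if (!is.null(bundle$vanthoff)) {
    res$vant_hoff <- bundle$vanthoff[c("dh", "ds")]
  }
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lines <- c("# Kinetic analysis report", "",
             paste0("- config hash: `", bundle$provenance$config_hash, "`"),
             paste0("- seed: ", bundle$provenance$seed),
             paste0("- package version: ", bundle$provenance$package_version),
             "")
  if (!is.null(bundle$hill)) {
    lines <- c(lines, "## Hill fit", "",
               sprintf("- K_D = %.4g M  [%.4g, %.4g]", bundle$hill$kd,
                       bundle$hill$kd_lo, bundle$hill$kd_hi),
               sprintf("- n = %.3g", bundle$hill$n_hill), "")
  }
  if (!is.null(bundle$arrhenius)) {
    lines <- c(lines, "## Arrhenius", "",
               sprintf("- Ea(dissociation) = %.4g kJ/mol",
                       bundle$arrhenius$diss$ea / 1000),
               sprintf("- Ea(binding) = %.4g kJ/mol",
                       bundle$arrhenius$bind$ea / 1000), "")
  }
  if (!is.null(bundle$vanthoff)) {
    lines <- c(lines, "## van't Hoff (dissociation)", "",
               sprintf("- dH = %.4g kJ/mol", bundle$vanthoff$dh / 1000),
               sprintf("- dS = %.4g J/(mol K)", bundle$vanthoff$ds), "")
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
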