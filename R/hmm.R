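trace_samples_ <- function(trace) {
  if (inherits(trace, "tk_trace") || (is.data.frame(trace) && "current" %in% names(trace))) {
    return(trace$current)
  }
  as.numeric(trace)
}

validate_hmm_ <- function(hmm) {
  stopifnot(inherits(hmm, "tk_hmm"))
  K <- hmm$n_states
  if (length(hmm$initial_probs) != K || any(hmm$initial_probs < 0) ||
      abs(sum(hmm$initial_probs) - 1) > 1e-9) {
    abort("Invalid initial probabilities.")
  }
  if (!all(dim(hmm$transition_probs) == c(K, K)) ||
      any(abs(rowSums(hmm$transition_probs) - 1) > 1e-9)) {
    abort("Transition matrix must be row-stochastic.")
  }
  if (any(hmm$sds <= 0)) abort("Emission SDs must be > 0.")
  invisible(hmm)
}

new_hmm_ <- function(init, trans, means, sds, loglik = NA_real_,
                     n_iter = NA_integer_, converged = NA) {
  # canonical state order: descending mean, so state 0 = highest current
  o <- order(means, decreasing = TRUE)
  structure(
    list(n_states = length(means), initial_probs = init[o],
         transition_probs = trans[o, o, drop = FALSE],
         means = means[o], sds = sds[o], loglik = loglik,
         n_iter = n_iter, converged = converged),
    class = "tk_hmm"
  )
}

#' @export
print.tk_hmm <- function(x, ...) {
  cat("<tk_hmm> ", x$n_states, " states, loglik = ",
      format(x$loglik, digits = 8), ", ", x$n_iter, " EM iterations",
      if (isTRUE(x$converged)) " (converged)" else "", "\n", sep = "")
  print(tibble::tibble(state = seq_len(x$n_states) - 1L,
                       mean = x$means, sd = x$sds))
  invisible(x)
}

#' Fit a Gaussian-emission hidden Markov model to a current trace
#'
#' Baum-Welch expectation-maximisation with scaled (numerically stable)
#' forward-backward recursions. Emission means are initialised at evenly
#' spaced quantiles of the sample distribution, emission SDs at the pooled
#' SD divided by `sqrt(n_states)`, and transitions at 0.99 self-transition
#' probability — a deterministic initialisation that is robust for
#' well-separated conductance levels. States are relabelled by descending
#' mean on return, so state 0 is the highest-current (least folded) state.
#'
#' If the EM collapses an emission variance (below 1e-12 of the trace
#' variance), the fit is restarted with seed-jittered means, up to 3
#' attempts.
#'
#' @param trace A `tk_trace` (or numeric vector of samples).
#' @param n_states Number of hidden states (>= 1).
#' @param tol Convergence threshold on the per-sample log-likelihood
#'   increase, nats.
#' @param max_iter Maximum EM iterations.
#' @param seed Seed for restart jitter (the base fit is deterministic).
#' @return A `tk_hmm`: initial probabilities, transition matrix, emission
#'   means/SDs, final log-likelihood, iteration count, and the per-iteration
#'   log-likelihood trace (attribute `loglik_trace`).
#' @export
fit_hmm <- function(trace, n_states, tol = 1e-6, max_iter = 500L,
                    seed = NULL) {
  x <- trace_samples_(trace)
  Tn <- length(x)
  stopifnot(n_states >= 1)
  if (Tn < 10 * n_states) abort("Trace too short: need >= 10 samples per state.")
  if (n_states == 1L) {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # MLE
    ll <- sum(dnorm_log_(x, m, s))
    hmm <- new_hmm_(1, matrix(1, 1, 1), m, s, loglik = ll, n_iter = 0L,
                    converged = TRUE)
    attr(hmm, "loglik_trace") <- ll
    return(hmm)
  }
  var_x <- stats::var(x)
  probs <- seq(0.5 / n_states, 1 - 0.5 / n_states, length.out = n_states)
  base_means <- as.numeric(quantile(x, probs, names = FALSE))

  run_em <- function(means0) {
    sds0 <- rep(max(sd(x) / sqrt(n_states), 1e-8), n_states)
    trans0 <- matrix((1 - 0.99) / (n_states - 1), n_states, n_states)
    diag(trans0) <- 0.99
    init0 <- rep(1 / n_states, n_states)
    means <- means0; sds <- sds0; trans <- trans0; init <- init0
    lls <- numeric(0)
    converged <- FALSE
    it <- 0L
    prev <- -Inf
    while (it < max_iter) {
      it <- it + 1L
      st <- .tk_em_step_cpp(x, init, trans, means, sds)
      if (!isTRUE(st$ok)) return(list(ok = FALSE))
      lls <- c(lls, st$loglik)
      if (any(st$sds^2 < 1e-12 * var_x)) return(list(ok = FALSE))
      init <- pmax(st$init, 0); init <- init / sum(init)
      trans <- st$trans
      means <- st$means
      sds <- pmax(st$sds, 1e-12)
      if (is.finite(prev) && (st$loglik - prev) / Tn < tol) {
        converged <- TRUE
        break
      }
      prev <- st$loglik
    }
    ll <- .tk_forward_cpp(x, init, trans, means, sds)
    lls <- c(lls, ll)
    list(ok = TRUE, init = init, trans = trans, means = means, sds = sds,
         loglik = ll, n_iter = it, converged = converged, lls = lls)
  }

  res <- run_em(base_means)
  attempt <- 1L
  while (!isTRUE(res$ok) && attempt < 3L) {
    attempt <- attempt + 1L
    jitter <- with_seed_((seed %||% 0L) + attempt,
                         rnorm(n_states, 0, sd(x) / 4))
    res <- run_em(sort(base_means + jitter))
  }
  if (!isTRUE(res$ok)) {
    abort("EM failed after 3 restarts (emission variance collapse).")
  }
  hmm <- new_hmm_(res$init, res$trans, res$means, res$sds,
                  loglik = res$loglik, n_iter = res$n_iter,
                  converged = res$converged)
  attr(hmm, "loglik_trace") <- res$lls
  validate_hmm_(hmm)
}

dnorm_log_ <- function(x, mean, sd) stats::dnorm(x, mean, sd, log = TRUE)

#' Forward log-likelihood of a trace under an HMM
#'
#' Total probability of the sample sequence summed over all hidden paths,
#' computed with scaled forward recursions.
#'
#' @inheritParams fit_hmm
#' @param hmm A `tk_hmm`.
#' @return Log-likelihood in nats.
#' @export
hmm_loglik <- function(trace, hmm) {
  validate_hmm_(hmm)
  x <- trace_samples_(trace)
  .tk_forward_cpp(x, hmm$initial_probs, hmm$transition_probs, hmm$means,
                  hmm$sds)
}

#' Viterbi idealization of a trace
#'
#' Maximum a posteriori hidden-state path; ties are broken toward the lower
#' state index (the higher-current state).
#'
#' @inheritParams hmm_loglik
#' @return A tibble of class `tk_idealized` with columns `time`, `current`,
#'   `state` (0-based, state 0 = highest mean current); attributes `hmm`,
#'   `loglik`, `sampling_rate`, `metadata`.
#' @export
viterbi <- function(trace, hmm) {
  validate_hmm_(hmm)
  x <- trace_samples_(trace)
  lab <- .tk_viterbi_cpp(x, hmm$initial_probs, hmm$transition_probs,
                         hmm$means, hmm$sds)
  fs <- attr(trace, "sampling_rate")
  tm <- if (is.data.frame(trace) && "time" %in% names(trace)) trace$time
        else if (!is.null(fs)) (seq_along(x) - 1L) / fs
        else seq_along(x) - 1L
  out <- tibble::tibble(time = tm, current = x, state = as.integer(lab))
  structure(out, hmm = hmm, loglik = hmm_loglik(x, hmm),
            sampling_rate = fs %||% (1 / diff(tm[1:2])),
            metadata = attr(trace, "metadata"),
            class = c("tk_idealized", class(out)))
}

#' Half-amplitude threshold idealization
#'
#' Assigns each sample to the nearest of the supplied conductance levels by
#' midpoint thresholds — the classic half-amplitude criterion, used here as
#' an independent baseline for validating the HMM idealization. A sample
#' lying exactly on a midpoint is assigned to the higher-current state.
#'
#' @inheritParams fit_hmm
#' @param levels Conductance levels (>= 2), any order.
#' @return A `tk_idealized` tibble (state 0 = highest level).
#' @export
threshold_idealize <- function(trace, levels) {
  if (length(levels) < 2) abort("Supply at least 2 levels.")
  lv <- sort(as.numeric(levels), decreasing = TRUE)
  mids <- (lv[-1] + lv[-length(lv)]) / 2
  x <- trace_samples_(trace)
  # state = number of midpoints strictly above the sample
  state <- rowSums(outer(x, mids, FUN = "<"))
  fs <- attr(trace, "sampling_rate")
  tm <- if (is.data.frame(trace) && "time" %in% names(trace)) trace$time
        else if (!is.null(fs)) (seq_along(x) - 1L) / fs
        else seq_along(x) - 1L
  hmm <- new_hmm_(rep(1 / length(lv), length(lv)),
                  matrix(1 / length(lv), length(lv), length(lv)),
                  lv, rep(1e-6, length(lv)))
  out <- tibble::tibble(time = tm, current = x, state = as.integer(state))
  structure(out, hmm = hmm, loglik = NA_real_,
            sampling_rate = fs %||% (1 / diff(tm[1:2])),
            metadata = attr(trace, "metadata"),
            class = c("tk_idealized", class(out)))
}

#' Choose the number of HMM states by BIC
#'
#' Fits candidate state counts and scores each by
#' `BIC = -2 loglik + p log(T)` with
#' `p = n^2 - n + 2 n + (n - 1)` free parameters (transitions, emissions,
#' initial distribution). Candidates whose EM fails are skipped with a
#' warning.
#'
#' @inheritParams fit_hmm
#' @param candidates Integer vector of state counts to try, within 1–6.
#' @return A tibble with columns `n_states`, `df`, `loglik`, `bic`, `best`
#'   (logical); the selected `tk_hmm` objects are kept in the `fits`
#'   list-column. Attribute `best` holds the minimum-BIC state count.
#' @export
select_n_states <- function(trace, candidates = 1:4, tol = 1e-6,
                            max_iter = 500L, seed = NULL) {
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1) || any(candidates > 6)) {
    abort("`candidates` must lie within 1–6.")
  }
  x <- trace_samples_(trace)
  Tn <- length(x)
  rows <- purrr::map(candidates, function(K) {
    fit <- tryCatch(fit_hmm(x, K, tol = tol, max_iter = max_iter, seed = seed),
                    error = function(e) {
                      warn(paste0("EM failed for n_states = ", K, "; skipped (",
                                  conditionMessage(e), ")"))
                      NULL
                    })
    if (is.null(fit)) return(NULL)
    p <- K^2 - K + 2 * K + (K - 1)
    tibble::tibble(n_states = K, df = p, loglik = fit$loglik,
                   bic = -2 * fit$loglik + p * log(Tn), fits = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("All candidate fits failed.")
  out$best <- out$bic == min(out$bic)
  structure(out, best = out$n_states[which.min(out$bic)],
            class = c("tk_model_selection", class(out)))
}
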