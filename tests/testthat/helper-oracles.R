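# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: log-likelihoods and decodings are computed by
# exhaustive enumeration over all hidden paths (feasible for T <= 8).

enumerate_paths_ <- function(n_states, T_len) {
  as.matrix(expand.grid(rep(list(seq_len(n_states)), T_len)))
}

# log P(x) by summing over every hidden path
brute_force_loglik <- function(x, init, trans, means, sds) {
  K <- length(means)
  paths <- enumerate_paths_(K, length(x))
  lp <- apply(paths, 1, function(z) {
    l <- log(init[z[1]]) + dnorm(x[1], means[z[1]], sds[z[1]], log = TRUE)
    for (t in seq_along(x)[-1]) {
      l <- l + log(trans[z[t - 1], z[t]]) +
        dnorm(x[t], means[z[t]], sds[z[t]], log = TRUE)
    }
    l
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# argmax path by exhaustive search; ties toward lower state indices
# (lexicographically smallest path among maxima)
brute_force_viterbi <- function(x, init, trans, means, sds) {
  K <- length(means)
  paths <- enumerate_paths_(K, length(x))
  lp <- apply(paths, 1, function(z) {
    l <- log(init[z[1]]) + dnorm(x[1], means[z[1]], sds[z[1]], log = TRUE)
    for (t in seq_along(x)[-1]) {
      l <- l + log(trans[z[t - 1], z[t]]) +
        dnorm(x[t], means[z[t]], sds[z[t]], log = TRUE)
    }
    l
  })
  best <- which(lp > max(lp) - 1e-12)
  if (length(best) > 1) {
    ord <- do.call(order, as.data.frame(paths[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  as.integer(paths[best, ]) - 1L
}

# random valid Gaussian HMM with means sorted descending
random_hmm <- function(n_states, seed) {
  set.seed(seed)
  means <- sort(runif(n_states, -2, 2), decreasing = TRUE)
  sds <- runif(n_states, 0.3, 1.2)
  trans <- matrix(rexp(n_states^2), n_states)
  trans <- trans / rowSums(trans)
  init <- rexp(n_states)
  init <- init / sum(init)
  list(init = init, trans = trans, means = means, sds = sds)
}

as_tk_hmm <- function(h) {
  hmm <- structure(
    list(n_states = length(h$means), initial_probs = h$init,
         transition_probs = h$trans, means = h$means, sds = h$sds,
         loglik = NA_real_, n_iter = NA_integer_, converged = NA),
    class = "tk_hmm"
  )
  hmm
}

# wrap a numeric vector as a minimal tk_trace
as_tk_trace <- function(x, fs = 57600, metadata = list()) {
  structure(tibble::tibble(time = (seq_along(x) - 1) / fs, current = x),
            sampling_rate = fs, metadata = metadata,
            class = c("tk_trace", "tbl_df", "tbl", "data.frame"))
}

# build a tk_path directly from dwell specs (states 1-based, durations in s)
manual_path <- function(states, durations, scheme) {
  ends <- cumsum(durations)
  starts <- c(0, head(ends, -1))
  structure(
    tibble::tibble(state = as.integer(states),
                   name = scheme$states$name[states],
                   entry_time = starts, exit_time = ends,
                   duration = durations),
    total_duration = sum(durations), scheme_id = scheme$id,
    class = c("tk_path", "tbl_df", "tbl", "data.frame")
  )
}

# log-log periodogram slope via Welch segment averaging
periodogram_slope <- function(x, n_seg = 8) {
  n <- length(x)
  seg <- floor(n / n_seg)
  ps <- 0
  for (i in seq_len(n_seg)) {
    y <- x[((i - 1) * seg + 1):(i * seg)]
    p <- Mod(fft(y))^2 / seg
    ps <- ps + p[2:(seg %/% 2)]
  }
  f <- (1:(seg %/% 2 - 1)) / seg
  keep <- f > 2 / seg & f < 0.25
  coef(lm(log(ps[keep]) ~ log(f[keep])))[[2]]
}
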