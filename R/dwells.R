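#' Segment an idealized trace into dwells
#'
#' Converts maximal constant-label runs into a dwell table. Runs of at most
#' `dead_time` samples — too short to be resolved reliably by the recording
#' chain — are merged into the neighbouring dwell whose state mean is nearer
#' in current, and merging is repeated until no short run remains. The first
#' and last dwells of every trace are flagged censored: their true durations
#' are cut by the observation window.
#'
#' @param idealized A `tk_idealized` (from [viterbi()] or
#'   [threshold_idealize()]).
#' @param dead_time Dead time in samples (>= 0); default 2 samples, about
#'   35 microseconds at 57.6 kHz — well below hundred-microsecond folding
#'   pulses, so genuine events survive.
#' @param trace_id Identifier stored with each dwell.
#' @return A tibble of class `tk_dwells` with columns `trace_id`, `state`,
#'   `start_s`, `duration_s`, `censored`, plus any condition metadata
#'   (`temperature_K`, `conc_*`) found on the trace.
#' @export
segment_dwells <- function(idealized, dead_time = 2L, trace_id = "trace") {
  stopifnot(inherits(idealized, "tk_idealized"), dead_time >= 0)
  fs <- attr(idealized, "sampling_rate")
  hmm <- attr(idealized, "hmm")
  lab <- idealized$state
  if (length(lab) == 0) abort("Empty idealized trace.")

  r <- rle(lab)
  dead_time <- as.integer(dead_time)
  if (dead_time > 0L) {
    means <- hmm$means
    for (pass in seq_len(100L)) {
      nr <- length(r$lengths)
      short <- which(r$lengths <= dead_time)
      short <- short[!(short %in% c(1L, nr))]  # edge runs are censored, keep them
      if (length(short) == 0L || nr <= 2L) break
      prev_state <- r$values[short - 1L]
      next_state <- r$values[short + 1L]
      cur_mean <- means[r$values[short] + 1L]
      to_prev <- abs(means[prev_state + 1L] - cur_mean) <=
        abs(means[next_state + 1L] - cur_mean)
      r$values[short] <- ifelse(to_prev, prev_state, next_state)
      r <- rle(inverse.rle(r))  # collapse newly adjacent equal runs
    }
  }
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-n])
  out <- tibble::tibble(
    trace_id = trace_id,
    state = as.integer(r$values),
    start_s = starts / fs,
    duration_s = r$lengths / fs,
    censored = seq_len(n) %in% c(1L, n)
  )
  md <- attr(idealized, "metadata")
  if (!is.null(md)) {
    for (key in intersect(names(md), c("temperature_K",
                                       grep("^conc_", names(md), value = TRUE)))) {
      out[[key]] <- md[[key]]
    }
  }
  structure(out, sampling_rate = fs, hmm = hmm,
            class = c("tk_dwells", class(out)))
}

#' Bind dwell tables from several traces
#'
#' @param ... `tk_dwells` tables (or a single list of them).
#' @return A combined `tk_dwells` tibble.
#' @export
bind_dwells <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]])) {
    args <- args[[1]]
  }
  out <- dplyr::bind_rows(args)
  structure(out, class = unique(c("tk_dwells", class(out))))
}
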