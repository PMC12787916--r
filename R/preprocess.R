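#' Preprocessing configuration
#'
#' Parameters of the MVC extraction: Butterworth low-pass cutoff
#' (15 Hz retains voluntary force content, which lives well below
#' 10 Hz, while rejecting tremor harmonics and electrical artifacts),
#' filter order (4th order, applied zero-phase so the effective
#' magnitude response is 8th order), the sliding-window length
#' (1.5 s: the minimum duration an effort must be sustained) and the
#' window placement step in samples (1 = every placement).
#'
#' @param cutoff Low-pass cutoff in Hz (default 15).
#' @param filter_order Butterworth order per pass (default 4).
#' @param window Sliding-window length in seconds (default 1.5).
#' @param window_step Window placement step in samples (default 1).
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(cutoff = 15, filter_order = 4L,
                              window = 1.5, window_step = 1L) {
  stopifnot(cutoff > 0, filter_order >= 1, window > 0, window_step >= 1)
  structure(list(cutoff = cutoff, filter_order = as.integer(filter_order),
                 window = window, window_step = as.integer(window_step)),
            class = "preprocess_config")
}

# Zero-phase Butterworth on a single channel.  signal::filtfilt starts
# both passes from zero state, which corrupts the trace ends, so the
# signal is extended by odd reflection (about the end samples) long
# enough for the filter transient to die out before the retained
# region; 12 / cutoff seconds of padding holds DC transmission to
# better than 1e-9.
lowpass_channel <- function(x, fs, cfg = preprocess_config()) {
  nyq <- fs / 2
  if (cfg$cutoff >= nyq)
    stop("cutoff (", cfg$cutoff, " Hz) must be below Nyquist (", nyq, " Hz)")
  n <- length(x)
  min_n <- 3L * (cfg$filter_order + 1L)
  if (n < min_n)
    stop("trace too short for edge handling: ", n, " < ", min_n, " samples")
  bf <- signal::butter(cfg$filter_order, cfg$cutoff / nyq, type = "low")
  p <- min(n - 1L, as.integer(ceiling(12 * fs / cfg$cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(p + 1L)]), x,
          2 * x[n] - rev(x[(n - p):(n - 1L)]))
  signal::filtfilt(bf, xp)[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth low-pass filter of a force trace
#'
#' Filters every channel forward and backward (zero phase lag) with a
#' Butterworth low-pass of the configured order and cutoff.  Constant
#' (DC) signals pass unchanged; edges are handled by odd-reflection
#' padding.
#'
#' @param trace A [force_trace()].
#' @param cfg A [preprocess_config()].
#' @return A filtered `force_trace` of identical shape.
#' @export
lowpass_filter <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "force_trace"))
  force_trace(trace$fs,
              lowpass_channel(trace$fx, trace$fs, cfg),
              lowpass_channel(trace$fy, trace$fs, cfg),
              lowpass_channel(trace$fz, trace$fs, cfg))
}

#' Sliding-window maximum-mean MVC extraction
#'
#' The strength score of a trial is not the single highest sample but
#' the highest mean force sustained over any continuous window
#' (default 1.5 s) of the trial: momentary spikes that do not reflect
#' true muscular capacity are averaged away, while a sustained maximal
#' plateau is captured wherever in the trial it occurs.  Ties are
#' broken in favour of the earliest window.
#'
#' @param x Numeric vector, one (filtered, effort-signed) force
#'   channel in newtons.
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()]; `window` and `window_step` are
#'   used.
#' @param channel Optional axis label stored in the result.
#' @return An object of class `"mvc_result"`: `mvc` (N),
#'   `window_start` (s), `window_len` (s), `channel`.
#' @export
sliding_window_mvc <- function(x, fs, cfg = preprocess_config(),
                               channel = NA_character_) {
  w <- as.integer(round(cfg$window * fs))
  n <- length(x)
  if (n < w)
    stop("trace too short: ", n, " samples < one ", cfg$window,
         " s window (", w, " samples); the effort must be sustained ",
         "for at least the window length")
  starts <- seq.int(1L, n - w + 1L, by = cfg$window_step)
  cs <- cumsum(c(0, x))
  means <- (cs[starts + w] - cs[starts]) / w
  i <- which.max(means)  # first occurrence wins ties
  structure(list(mvc = means[i], window_start = (starts[i] - 1L) / fs,
                 window_len = w / fs, channel = channel),
            class = "mvc_result")
}

#' @export
print.mvc_result <- function(x, ...) {
  cat(sprintf("MVC %.2f N (%.2g s window starting at %.3f s%s)\n",
              x$mvc, x$window_len, x$window_start,
              if (is.na(x$channel)) "" else paste0(", ", x$channel)))
  invisible(x)
}

#' Best-of-trials rule
#'
#' The definitive maximal strength output for a direction is the
#' highest MVC recorded across its (nominally three) trials.
#'
#' @param mvc_values Non-empty numeric vector of per-trial MVCs (N).
#' @return The maximum, in newtons.
#' @export
best_of_trials <- function(mvc_values) {
  if (length(mvc_values) == 0L) stop("no trials supplied")
  if (anyNA(mvc_values)) stop("NA MVC value in trials")
  max(mvc_values)
}
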