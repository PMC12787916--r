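#' Triaxial force trace
#'
#' A uniformly sampled triaxial force series in newtons: `fx`
#' (mediolateral), `fy` (anteroposterior) and `fz` (vertical) ground
#' reaction components at sampling rate `fs`.  This is the physical
#' signal every pipeline stage consumes or produces.
#'
#' @param fs Sampling rate in Hz (> 0), nominally 1400.
#' @param fx,fy,fz Equal-length numeric vectors of forces (N), finite.
#' @return An object of class `"force_trace"` with fields `fs`, `fx`,
#'   `fy`, `fz`, `n` (samples) and `duration` (seconds).
#' @export
force_trace <- function(fs, fx, fy, fz) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  n <- length(fx)
  if (n < 1L) stop("force trace must contain at least one sample")
  if (length(fy) != n || length(fz) != n)
    stop("channels fx, fy, fz must have equal length")
  if (!all(is.finite(fx)) || !all(is.finite(fy)) || !all(is.finite(fz)))
    stop("force trace contains non-finite values")
  structure(list(fs = fs, fx = as.numeric(fx), fy = as.numeric(fy),
                 fz = as.numeric(fz), n = n, duration = n / fs),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz (%.3f s)\n",
              x$n, x$fs, x$duration))
  for (ch in c("fx", "fy", "fz"))
    cat(sprintf("  %s: range [%.2f, %.2f] N\n",
                ch, min(x[[ch]]), max(x[[ch]])))
  invisible(x)
}

#' Read and write force/voltage trace CSV files
#'
#' Two dialects are supported and distinguished by header:
#' force traces use `time_s,fx_n,fy_n,fz_n` and conditioned raw
#' voltages use `time_s,fx_mv,fy_mv,fz_mv`.  The reader checks that
#' the time column is uniformly sampled within 1e-6 s jitter.  A
#' voltage-dialect file is returned as class `"voltage_trace"`; pass
#' it through [voltage_trace_to_force()] with per-axis calibrations
#' to obtain newtons.
#'
#' @param path CSV file path.
#' @return A `force_trace` or `voltage_trace`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  nm <- names(d)
  if (!identical(nm[1], "time_s"))
    stop("trace CSV must start with a 'time_s' column: ", path)
  n <- nrow(d)
  if (n < 2L) stop("trace CSV has fewer than 2 samples: ", path)
  dt <- diff(d$time_s)
  if (max(dt) - min(dt) > 1e-6)
    stop("non-uniform sampling (jitter > 1e-6 s): ", path)
  fs <- 1 / mean(dt)
  if (identical(nm, c("time_s", "fx_n", "fy_n", "fz_n"))) {
    force_trace(fs, d$fx_n, d$fy_n, d$fz_n)
  } else if (identical(nm, c("time_s", "fx_mv", "fy_mv", "fz_mv"))) {
    structure(list(fs = fs, fx = d$fx_mv, fy = d$fy_mv, fz = d$fz_mv,
                   n = n, duration = n / fs),
              class = "voltage_trace")
  } else {
    stop("unrecognized trace CSV header in ", path)
  }
}

#' @param trace A `force_trace` to write (force dialect).
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  d <- data.frame(time_s = (seq_len(trace$n) - 1L) / trace$fs,
                  fx_n = trace$fx, fy_n = trace$fy, fz_n = trace$fz)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a raw voltage trace to forces
#'
#' Applies the per-axis affine calibration of the acquisition chain
#' (see [voltage_to_force()]) to each channel of a voltage-dialect
#' trace.
#'
#' @param vtrace A `"voltage_trace"` from [read_trace_csv()].
#' @param chain A [sensor_chain_spec()] carrying per-axis calibrations.
#' @return A [force_trace()].
#' @export
voltage_trace_to_force <- function(vtrace, chain) {
  stopifnot(inherits(vtrace, "voltage_trace"),
            inherits(chain, "sensor_chain_spec"))
  force_trace(vtrace$fs,
              voltage_to_force(vtrace$fx, chain$calibration$fx),
              voltage_to_force(vtrace$fy, chain$calibration$fy),
              voltage_to_force(vtrace$fz, chain$calibration$fz))
}

#' Simulate the digitization of a force trace
#'
#' Runs each channel through the inverse calibration, clips at the
#' rails, quantizes onto the ADC grid, and converts back to newtons —
#' the batch equivalent of the device's acquisition loop (read,
#' average, convert, emit).  Useful for bounding the error the
#' electronics add to a known physical signal.
#'
#' @param trace A [force_trace()].
#' @param chain A [sensor_chain_spec()].
#' @return A `force_trace` of digitized forces.
#' @export
digitize_trace <- function(trace, chain) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(chain, "sensor_chain_spec"))
  ch <- lapply(c(fx = "fx", fy = "fy", fz = "fz"), function(ax) {
    cal <- chain$calibration[[ax]]
    v <- force_to_voltage(trace[[ax]], cal, supply = chain$adc$supply)
    voltage_to_force(quantize(as.numeric(v), chain$adc), cal)
  })
  force_trace(trace$fs, ch$fx, ch$fy, ch$fz)
}
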