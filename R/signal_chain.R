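#' Acquisition-chain component specifications
#'
#' Constructors for the electronic constants of the platform's
#' acquisition chain: the sensor supply regulator, the instrumentation
#' amplifier, the ADC and the per-axis force calibration.  Each
#' constructor validates its invariants and returns a plain classed
#' list, so a chain can be described in a JSON config block and
#' round-tripped losslessly.
#'
#' The default values describe the reference design: an amplifier gain
#' of 360 lifting a ~10 mV full-scale bridge signal into a 3.6 V ADC
#' range, a 16-bit converter with 14 noise-free bits, a mid-rail zero
#' offset of 1800 mV, and a 10 V sensor supply regulated over
#' 9.950-10.050 V in 1000 PWM steps.
#'
#' @param v_ref_internal Regulator internal reference voltage (V).
#' @param r1,r2 Feedback resistors (ohm); `r1 > 0`, `r2 >= 0`.
#' @param v_out_range Length-2 numeric, attainable output range (V).
#' @param pwm_counts Integer, PWM steps per period (>= 1).
#' @return An object of class `"regulator_spec"`.
#' @seealso [regulator_vout()], [regulation_resolution()]
#' @export
regulator_spec <- function(v_ref_internal = 1.25, r1 = 240, r2 = 1680,
                           v_out_range = c(9.950, 10.050),
                           pwm_counts = 1000L) {
  stopifnot(is.numeric(v_ref_internal), v_ref_internal > 0,
            is.numeric(r1), length(r1) == 1L,
            is.numeric(r2), length(r2) == 1L, r2 >= 0,
            length(v_out_range) == 2L, v_out_range[1] < v_out_range[2],
            pwm_counts >= 1)
  if (r1 <= 0) stop("'r1' must be strictly positive (division by r1)")
  structure(list(v_ref_internal = v_ref_internal, r1 = r1, r2 = r2,
                 v_out_range = as.numeric(v_out_range),
                 pwm_counts = as.integer(pwm_counts)),
            class = "regulator_spec")
}

#' @param gain Dimensionless differential gain G (> 0).
#' @param v_ref_offset Output offset voltage (mV), nominally mid-rail.
#' @param supply Amplifier supply rail (mV).
#' @return An object of class `"amplifier_spec"`.
#' @rdname regulator_spec
#' @export
amplifier_spec <- function(gain = 360, v_ref_offset = 1800, supply = 3600) {
  stopifnot(gain > 0, supply > 0,
            v_ref_offset >= 0, v_ref_offset <= supply)
  structure(list(gain = gain, v_ref_offset = v_ref_offset, supply = supply),
            class = "amplifier_spec")
}

#' @param bits Total ADC resolution in bits.
#' @param noise_free_bits Effective noise-free resolution in bits.
#' @return An object of class `"adc_spec"`.
#' @rdname regulator_spec
#' @export
adc_spec <- function(bits = 16L, noise_free_bits = 14L, supply = 3600) {
  stopifnot(noise_free_bits >= 1, noise_free_bits <= bits, bits <= 32,
            supply > 0)
  structure(list(bits = as.integer(bits),
                 noise_free_bits = as.integer(noise_free_bits),
                 supply = supply),
            class = "adc_spec")
}

#' @param zero_offset Conditioned voltage at zero force (mV).
#' @param gain_factor Newtons per millivolt for the axis (> 0).
#' @return An object of class `"calibration_spec"`.
#' @rdname regulator_spec
#' @export
calibration_spec <- function(zero_offset = 1800, gain_factor) {
  stopifnot(is.numeric(zero_offset), length(zero_offset) == 1L,
            is.numeric(gain_factor), length(gain_factor) == 1L)
  if (gain_factor <= 0) stop("'gain_factor' must be positive")
  structure(list(zero_offset = zero_offset, gain_factor = gain_factor),
            class = "calibration_spec")
}

#' Regulator output voltage from the feedback divider
#'
#' Settled output of an adjustable LDO regulator,
#' `V_out = V_ref * (1 + R2/R1)`.  The closed-loop PWM trimming of the
#' physical device is modelled statically: only the settled value is
#' of interest downstream.
#'
#' @param spec A [regulator_spec()].
#' @return Output voltage in volts.
#' @export
regulator_vout <- function(spec) {
  stopifnot(inherits(spec, "regulator_spec"))
  if (spec$r1 == 0) stop("division by zero: r1 = 0")
  spec$v_ref_internal * (1 + spec$r2 / spec$r1)
}

#' Voltage-regulation resolution per PWM step
#'
#' @param v_low,v_high Ends of the regulated range (V), `v_high > v_low`.
#' @param steps Number of control steps (>= 1).
#' @return Volts per step.
#' @export
regulation_resolution <- function(v_low, v_high, steps) {
  if (steps < 1) stop("'steps' must be >= 1")
  if (v_high <= v_low) stop("'v_high' must exceed 'v_low'")
  (v_high - v_low) / steps
}

#' Instrumentation-amplifier output with rail saturation
#'
#' `V_out = G * (V+ - V-) + V_ref`, clipped to `[0, supply]`.  A
#' maximal effort may legitimately drive the amplifier into a rail, so
#' saturation is reported as a logical attribute rather than an error.
#'
#' @param v_plus,v_minus Differential input signals (mV); vectorized.
#' @param spec An [amplifier_spec()].
#' @return Output voltage(s) in mV with attribute `"saturated"`
#'   (logical, same length).
#' @export
amplifier_out <- function(v_plus, v_minus, spec) {
  stopifnot(inherits(spec, "amplifier_spec"))
  raw <- spec$gain * (v_plus - v_minus) + spec$v_ref_offset
  out <- pmin(pmax(raw, 0), spec$supply)
  attr(out, "saturated") <- raw < 0 | raw > spec$supply
  out
}

#' ADC least-significant-bit size
#'
#' `LSB = supply / 2^bits`.  With `use_noise_free = TRUE` the effective
#' (noise-free) bit count is used instead, giving the resolution
#' actually usable above the converter's own noise floor.
#'
#' @param spec An [adc_spec()].
#' @param use_noise_free Use `noise_free_bits` instead of `bits`.
#' @return LSB in mV.
#' @export
adc_lsb <- function(spec, use_noise_free = FALSE) {
  stopifnot(inherits(spec, "adc_spec"))
  b <- if (use_noise_free) spec$noise_free_bits else spec$bits
  spec$supply / 2^b
}

#' Quantize a conditioned voltage onto the ADC grid
#'
#' Rounds to the nearest multiple of the LSB, so the round-trip error
#' is bounded by LSB/2.  Voltages outside `[0, supply]` are an error:
#' saturation is handled upstream by [amplifier_out()].
#'
#' @param voltage_mv Voltage(s) in mV, within `[0, supply]`.
#' @inheritParams adc_lsb
#' @return Quantized voltage(s) in mV.
#' @export
quantize <- function(voltage_mv, spec, use_noise_free = FALSE) {
  stopifnot(inherits(spec, "adc_spec"))
  eps <- 1e-9
  if (any(voltage_mv < -eps | voltage_mv > spec$supply + eps))
    stop("voltage outside ADC input range [0, ", spec$supply, "] mV")
  lsb <- adc_lsb(spec, use_noise_free)
  round(voltage_mv / lsb) * lsb
}

#' Convert conditioned voltage to force
#'
#' `F = (ADC_mV - ZeroOffset) * GainFactor`.  The sign carries the
#' direction of loading: voltages above the zero offset are tension
#' (positive), below are compression (negative).
#'
#' @param adc_mv Conditioned voltage(s) in mV.
#' @param cal A [calibration_spec()].
#' @return Force in newtons.
#' @export
voltage_to_force <- function(adc_mv, cal) {
  stopifnot(inherits(cal, "calibration_spec"))
  (adc_mv - cal$zero_offset) * cal$gain_factor
}

#' Convert force to conditioned voltage (simulator inverse)
#'
#' Exact inverse of [voltage_to_force()] before quantization.  Values
#' falling outside `[0, supply]` are clipped and flagged via the
#' `"saturated"` attribute.
#'
#' @param force_n Force(s) in newtons.
#' @param cal A [calibration_spec()].
#' @param supply Rail limit in mV used for the saturation flag.
#' @return Voltage(s) in mV with attribute `"saturated"`.
#' @export
force_to_voltage <- function(force_n, cal, supply = 3600) {
  stopifnot(inherits(cal, "calibration_spec"))
  raw <- cal$zero_offset + force_n / cal$gain_factor
  out <- pmin(pmax(raw, 0), supply)
  attr(out, "saturated") <- raw < 0 | raw > supply
  out
}

#' Two-point calibration from unloaded and loaded readings
#'
#' Manufacturing imperfections shift each axis's zero-force output, so
#' the zero offset is measured with the sensor unloaded and the gain
#' factor from a known reference load:
#' `zero_offset = mean(unloaded)`,
#' `gain_factor = known_force / (mean(loaded) - mean(unloaded))`.
#'
#' @param unloaded_mv Conditioned voltages (mV) with no load.
#' @param loaded_mv Conditioned voltages (mV) under `known_force`.
#' @param known_force Reference load in newtons (> 0).
#' @return A [calibration_spec()].
#' @export
calibrate <- function(unloaded_mv, loaded_mv, known_force) {
  if (length(unloaded_mv) == 0L || length(loaded_mv) == 0L)
    stop("calibration traces must be non-empty")
  if (known_force <= 0) stop("'known_force' must be positive")
  z <- mean(unloaded_mv)
  d <- mean(loaded_mv) - z
  if (d == 0) stop("degenerate calibration: loaded and unloaded means equal")
  calibration_spec(zero_offset = z, gain_factor = known_force / d)
}

#' Full acquisition-chain specification
#'
#' Bundles the amplifier, ADC and per-axis calibrations together with
#' the sampling rate, and serializes to/from a JSON config block.  The
#' defaults are the reference design constants: G = 360, 3600 mV
#' supply, 16-bit ADC (14 noise-free), 1800 mV zero offset, 1400 Hz.
#'
#' @param amplifier An [amplifier_spec()].
#' @param adc An [adc_spec()].
#' @param calibration A single [calibration_spec()] applied to all
#'   three axes, or a named list with elements `fx`, `fy`, `fz`.
#' @param fs Sampling rate (Hz).
#' @return An object of class `"sensor_chain_spec"`.
#' @export
sensor_chain_spec <- function(amplifier = amplifier_spec(),
                              adc = adc_spec(),
                              calibration = calibration_spec(1800, 0.4),
                              fs = 1400) {
  stopifnot(inherits(amplifier, "amplifier_spec"),
            inherits(adc, "adc_spec"), fs > 0)
  if (inherits(calibration, "calibration_spec"))
    calibration <- list(fx = calibration, fy = calibration, fz = calibration)
  stopifnot(all(c("fx", "fy", "fz") %in% names(calibration)))
  structure(list(amplifier = amplifier, adc = adc,
                 calibration = calibration, fs = fs),
            class = "sensor_chain_spec")
}

#' @param path File to read or write.
#' @rdname sensor_chain_spec
#' @export
write_sensor_config <- function(spec, path) {
  stopifnot(inherits(spec, "sensor_chain_spec"))
  jsonlite::write_json(rapply(unclass(spec), identity, how = "list"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param spec A `sensor_chain_spec` (for writing).
#' @rdname sensor_chain_spec
#' @export
read_sensor_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor_chain_spec(
    amplifier = do.call(amplifier_spec, x$amplifier),
    adc = do.call(adc_spec, x$adc),
    calibration = lapply(x$calibration,
                         function(cc) do.call(calibration_spec, cc)),
    fs = x$fs)
}
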