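test_that("regulator output follows the feedback-divider formula", {
  expect_equal(regulator_vout(regulator_spec(v_ref_internal = 1.25, r2 = 0)),
               1.25)
  expect_equal(regulator_vout(regulator_spec(v_ref_internal = 1.00,
                                             r1 = 510, r2 = 510)), 2.00)
  # 1.25 * (1 + 1680/240) = 1.25 * 8
  expect_equal(regulator_vout(regulator_spec(1.25, r1 = 240, r2 = 1680)),
               10.00)
  expect_error(regulator_spec(1.25, r1 = 0, r2 = 100), "r1")
})

test_that("regulator output increases in r2 and is divider-scale invariant", {
  v <- vapply(c(100, 500, 1200, 2000), function(r2)
    regulator_vout(regulator_spec(1.25, r1 = 240, r2 = r2)), numeric(1))
  expect_true(all(diff(v) > 0))
  for (c_ in c(0.5, 3, 17))
    expect_equal(regulator_vout(regulator_spec(1.25, 240 * c_, 1680 * c_)),
                 regulator_vout(regulator_spec(1.25, 240, 1680)))
})

test_that("regulation resolution is range over steps", {
  expect_equal(regulation_resolution(9.950, 10.050, 1000), 100e-6)
  expect_equal(regulation_resolution(0, 1, 1), 1)
  expect_equal(regulation_resolution(0, 2.32, 50000), 46.4e-6)
  expect_error(regulation_resolution(0, 1, 0), "steps")
  expect_error(regulation_resolution(2, 1, 10), "exceed")
})

test_that("amplifier output is offset-shifted gain with rail saturation", {
  amp <- amplifier_spec(gain = 360, v_ref_offset = 1800, supply = 3600)
  expect_equal(as.numeric(amplifier_out(5, 5, amp)), 1800)
  amp0 <- amplifier_spec(gain = 360, v_ref_offset = 0, supply = 3600)
  expect_equal(as.numeric(amplifier_out(10, 0, amp0)), 3600)
  sat <- amplifier_out(5, 0, amp)  # 360*5 + 1800 = 3600, exactly at rail
  expect_equal(as.numeric(sat), 3600)
  expect_false(attr(sat, "saturated"))
  over <- amplifier_out(6, 0, amp)
  expect_equal(as.numeric(over), 3600)
  expect_true(attr(over, "saturated"))
})

test_that("amplifier is affine over its linear range", {
  amp <- amplifier_spec(gain = 360, v_ref_offset = 1800, supply = 3600)
  a <- runif(20, -2, 2); b <- runif(20, -2, 2)
  expect_equal(as.numeric(amplifier_out(a, 0, amp)) -
                 as.numeric(amplifier_out(b, 0, amp)),
               360 * (a - b))
})

test_that("ADC LSB matches datasheet values and halves per bit", {
  adc33 <- function(bits) adc_spec(bits = bits, noise_free_bits = min(bits, 14),
                                   supply = 3300)
  expect_equal(adc_lsb(adc33(16)), 0.05, tolerance = 0.01)
  expect_equal(adc_lsb(adc33(12)), 0.8, tolerance = 0.01)
  expect_equal(adc_lsb(adc33(14)), 0.2, tolerance = 0.01)
  for (b in 2:20)
    expect_equal(adc_lsb(adc_spec(b + 1, 1, 3300)),
                 adc_lsb(adc_spec(b, 1, 3300)) / 2)
  expect_equal(adc_lsb(adc_spec(16, 14, 3300), use_noise_free = TRUE),
               3300 / 2^14)
})

test_that("quantization snaps to the grid within half an LSB", {
  adc <- adc_spec(16, 14, 3600)
  expect_equal(quantize(1800, adc), 1800)
  adc2 <- adc_spec(16, 14, 0.05 * 2^16)  # LSB exactly 0.05 mV
  expect_equal(quantize(1800.026, adc2), 1800.05)
  v <- runif(200, 0, 3600)
  q <- quantize(v, adc)
  expect_true(all(abs(q - v) <= adc_lsb(adc) / 2 + 1e-12))
  expect_error(quantize(-0.1, adc), "range")
  expect_error(quantize(3600.1, adc), "range")
})

test_that("force-voltage conversion is a signed affine map", {
  cal <- calibration_spec(zero_offset = 1800, gain_factor = 0.4)
  expect_equal(voltage_to_force(1800, cal), 0)
  expect_equal(voltage_to_force(2800, cal), 400)
  expect_equal(voltage_to_force(800, cal), -400)
  expect_equal(as.numeric(force_to_voltage(0, cal)), 1800)
  expect_equal(as.numeric(force_to_voltage(400, cal)), 2800)
})

test_that("force survives the voltage/quantization round trip within bound", {
  cal <- calibration_spec(1800, 0.4)
  adc <- adc_spec(16, 14, 3600)
  bound <- cal$gain_factor * adc_lsb(adc) / 2
  set.seed(11)
  f <- runif(500, -700, 700)
  v <- quantize(as.numeric(force_to_voltage(f, cal)), adc)
  expect_true(all(abs(voltage_to_force(v, cal) - f) <= bound + 1e-12))
  # exact inverse before quantization
  expect_equal(voltage_to_force(as.numeric(force_to_voltage(f, cal)), cal), f)
})

test_that("two-point calibration recovers offset and gain", {
  expect_equal(calibrate(rep(1800, 100), rep(2050, 100), 98.1)$gain_factor,
               0.3924)
  expect_equal(calibrate(rep(1795, 50), rep(2000, 50), 98.1)$zero_offset,
               1795)
  expect_error(calibrate(rep(1800, 5), rep(1800, 5), 98.1), "degenerate")
  expect_error(calibrate(numeric(0), rep(1, 5), 98.1), "non-empty")
})

test_that("calibration on quantized synthetic readings recovers the truth", {
  true_cal <- calibration_spec(zero_offset = 1812.4, gain_factor = 0.385)
  adc <- adc_spec(16, 14, 3600)
  set.seed(4)
  noise <- function(n) rnorm(n, 0, 0.3)  # mV-level conditioning noise
  unloaded <- quantize(
    pmin(pmax(as.numeric(force_to_voltage(0, true_cal)) + noise(2000), 0), 3600),
    adc)
  loaded <- quantize(
    pmin(pmax(as.numeric(force_to_voltage(98.1, true_cal)) + noise(2000), 0), 3600),
    adc)
  est <- calibrate(unloaded, loaded, 98.1)
  expect_equal(est$zero_offset, 1812.4, tolerance = 1e-3)
  expect_equal(est$gain_factor, 0.385, tolerance = 1e-2)
  # re-measuring the known weight through the estimated calibration
  v <- quantize(as.numeric(force_to_voltage(98.1, true_cal)), adc)
  expect_equal(voltage_to_force(v, est), 98.1,
               tolerance = 1e-2)
})

test_that("sensor chain config round-trips through JSON", {
  spec <- sensor_chain_spec(
    calibration = list(fx = calibration_spec(1801, 0.39),
                       fy = calibration_spec(1799, 0.41),
                       fz = calibration_spec(1800, 1.2)))
  path <- withr::local_tempfile(fileext = ".json")
  write_sensor_config(spec, path)
  back <- read_sensor_config(path)
  expect_equal(back$amplifier$gain, 360)
  expect_equal(back$calibration$fy$gain_factor, 0.41)
  expect_equal(back$fs, 1400)
})

test_that("digitizing a trace perturbs forces by at most the quantization bound", {
  chain <- sensor_chain_spec(calibration = calibration_spec(1800, 0.4))
  set.seed(9)
  # stay inside the representable span: (3600 - 1800) * 0.4 = 720 N
  tr <- force_trace(1400, runif(100, -300, 300), runif(100, -300, 300),
                    runif(100, 200, 650))
  dz <- digitize_trace(tr, chain)
  bound <- 0.4 * adc_lsb(chain$adc) / 2
  for (ch in c("fx", "fy", "fz"))
    expect_true(all(abs(dz[[ch]] - tr[[ch]]) <= bound + 1e-12))
})
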