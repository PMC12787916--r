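# Independent oracles, deliberately naive.

# Exhaustive sliding-window maximum mean: plain loop over every start.
brute_mvc <- function(x, w, step = 1L) {
  best <- -Inf; best_start <- NA_integer_
  for (s in seq.int(1L, length(x) - w + 1L, by = step)) {
    m <- mean(x[s:(s + w - 1L)])
    if (m > best) { best <- m; best_start <- s }
  }
  list(mvc = best, start = best_start)
}

# Squared-magnitude response of an order-n Butterworth low-pass at
# frequency f (zero-phase forward-backward application squares the
# single-pass magnitude, which for Butterworth is 1/sqrt(1+(f/fc)^2n)).
butter_zero_phase_gain <- function(f, fc, order) {
  1 / (1 + (f / fc)^(2 * order))
}

# Pooled-variance two-sample t from first principles.
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2,
       p = 2 * pt(-abs(t), nx + ny - 2))
}

# Plateau trace shorthand used across protocol tests.
const_trace <- function(fx = 0, fy = 0, fz = 700, n = 4200, fs = 1400)
  force_trace(fs, rep(fx, n), rep(fy, n), rep(fz, n))
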