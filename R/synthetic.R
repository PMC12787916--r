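# Anthropometrics by stratum: height/mass normal draws truncated to
# the observed ranges, age uniform over the stratum decade.
anthro_table <- function() {
  data.frame(
    sex = rep(c("male", "female"), 3L),
    age_group = rep(c("G25", "G45", "G65"), each = 2L),
    height_mean = c(186.47, 168.22, 186.35, 168.67, 177.27, 168.80),
    height_sd   = c(8.50, 7.29, 8.05, 15.95, 5.58, 5.04),
    height_lo   = c(175, 158, 176, 160, 169, 162),
    height_hi   = c(205, 183, 202, 175, 186, 179),
    mass_mean   = c(86.11, 63.00, 91.53, 71.07, 81.27, 71.00),
    mass_sd     = c(15.52, 11.12, 15.91, 10.99, 12.83, 11.05),
    mass_lo     = c(61, 44, 75, 53, 62, 59),
    mass_hi     = c(117, 91, 123, 95, 106, 98),
    age_lo = rep(c(20, 40, 60), each = 2L),
    age_hi = rep(c(30, 50, 70), each = 2L),
    stringsAsFactors = FALSE)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Default stratum mean relative strength (N/kg)
#'
#' The 36 cell means (2 sexes x 3 age groups x 6 directions) used by
#' the cohort generator.  Within each direction the cells are built
#' additively — a female G25 baseline, a constant male offset, and
#' constant G45/G65 age offsets — so that by construction sex and age
#' do not interact, matching the near-null interactions the two-way
#' analysis is expected to show.  The anchors reproduce reported
#' normative values: direction A young-adult means 1.8504 (men) and
#' 1.3659 N/kg (women); direction D2 middle-age means 2.3039 and
#' 1.6909 N/kg; male advantages of roughly 16-36% and age-related
#' declines of roughly 25-45% from the youngest to the oldest group,
#' strongest in the pull directions.
#'
#' @return A data.frame with columns `sex`, `age_group`, `direction`,
#'   `mean`.
#' @export
default_strength_means <- function() {
  base <- data.frame(
    direction = c("A", "B", "D1", "D2", "K1", "K2"),
    f25 = c(1.3659, 1.60, 2.10, 1.90, 2.12, 1.70),
    d_male = c(0.4845, 0.26, 0.46, 0.6130, 0.48, 0.40),
    d_g45 = -c(0.2407, 0.15, 0.20, 0.209, 0.21, 0.22),
    d_g65 = -c(0.5378, 0.369, 0.532, 0.5694, 0.55, 0.5325))
  grid <- expand.grid(sex = c("male", "female"),
                      age_group = c("G25", "G45", "G65"),
                      direction = base$direction,
                      stringsAsFactors = FALSE)
  i <- match(grid$direction, base$direction)
  grid$mean <- base$f25[i] +
    ifelse(grid$sex == "male", base$d_male[i], 0) +
    ifelse(grid$age_group == "G45", base$d_g45[i],
           ifelse(grid$age_group == "G65", base$d_g65[i], 0))
  grid
}

#' Force-trace generator configuration
#'
#' Describes one synthetic maximal effort: quiet baseline, a smooth
#' (C2-continuous) ramp, then a plateau at `target_mvc` overlaid with
#' band-limited physiological tremor (8-12 Hz, below the 15 Hz
#' analysis cutoff), wideband sensor noise, and sparse single-sample
#' spike artifacts emulating impacts.
#'
#' @param target_mvc Plateau force in newtons (> 0).
#' @param ramp_time Ramp duration in s (default 1.0).
#' @param plateau_time Plateau duration in s (default 3.0; must be at
#'   least 1.5 s, the analysis window).
#' @param baseline_time Quiet baseline before the ramp in s.
#' @param tremor_band Tremor band edges in Hz (default 8-12).
#' @param tremor_sd Tremor amplitude as SD in N (default 2% of
#'   target).
#' @param wideband_sd Wideband noise SD in N (default 1% of target).
#' @param spike_rate Expected spike artifacts per second (default
#'   0.5).
#' @param spike_amplitude Maximum spike height in N (default half the
#'   target).
#' @param seed Optional integer; when given, the trace is a pure
#'   function of the configuration.
#' @return An object of class `"trace_gen_config"`.
#' @export
trace_gen_config <- function(target_mvc, ramp_time = 1.0,
                             plateau_time = 3.0, baseline_time = 0.5,
                             tremor_band = c(8, 12),
                             tremor_sd = 0.02 * target_mvc,
                             wideband_sd = 0.01 * target_mvc,
                             spike_rate = 0.5,
                             spike_amplitude = 0.5 * target_mvc,
                             seed = NULL) {
  stopifnot(target_mvc > 0, ramp_time > 0, baseline_time >= 0,
            length(tremor_band) == 2L, tremor_band[1] < tremor_band[2],
            tremor_sd >= 0, wideband_sd >= 0, spike_rate >= 0,
            spike_amplitude >= 0)
  if (plateau_time < 1.5)
    stop("plateau_time must be >= 1.5 s: the protocol requires the ",
         "effort to be sustained for at least the analysis window")
  structure(list(target_mvc = target_mvc, ramp_time = ramp_time,
                 plateau_time = plateau_time,
                 baseline_time = baseline_time,
                 tremor_band = as.numeric(tremor_band),
                 tremor_sd = tremor_sd, wideband_sd = wideband_sd,
                 spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude, seed = seed),
            class = "trace_gen_config")
}

# smootherstep: C2 sigmoid, keeps filter overshoot at the ramp-plateau
# junction negligible relative to the plateau level
smoothstep5 <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3

#' Generate one synthetic maximal-effort trace
#'
#' Builds the effort profile of [trace_gen_config()] on the axis and
#' polarity of the given direction (default: positive `fx`), with the
#' two passive channels carrying wideband noise only and `fz` held at
#' the standing body weight if `body_weight_n` is given.
#'
#' @param cfg A [trace_gen_config()].
#' @param fs Sampling rate in Hz (default 1400).
#' @param direction Optional direction code; places the effort on the
#'   mapped axis with the conventional sign.
#' @param body_weight_n Optional standing weight in N for the `fz`
#'   channel (quiet-stance value; ignored when the effort itself is on
#'   `fz`).
#' @return A [force_trace()].
#' @export
generate_trace <- function(cfg, fs = 1400, direction = NULL,
                           body_weight_n = 0) {
  stopifnot(inherits(cfg, "trace_gen_config"), fs > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nb <- round(cfg$baseline_time * fs)
  nr <- round(cfg$ramp_time * fs)
  np <- round(cfg$plateau_time * fs)
  n <- nb + nr + np
  profile <- c(rep(0, nb),
               cfg$target_mvc * smoothstep5(seq_len(nr) / nr),
               rep(cfg$target_mvc, np))
  active <- profile
  if (cfg$tremor_sd > 0) {
    bp <- signal::butter(2, cfg$tremor_band / (fs / 2), type = "pass")
    tremor <- signal::filtfilt(bp, stats::rnorm(n))
    tremor <- tremor / stats::sd(tremor) * cfg$tremor_sd
    active <- active + tremor * (profile / cfg$target_mvc)
  }
  if (cfg$wideband_sd > 0)
    active <- active + stats::rnorm(n, 0, cfg$wideband_sd)
  if (cfg$spike_rate > 0 && cfg$spike_amplitude > 0) {
    k <- stats::rpois(1, cfg$spike_rate * n / fs)
    if (k > 0) {
      at <- sample.int(n, min(k, n))
      active[at] <- active[at] +
        stats::runif(length(at), 0, cfg$spike_amplitude)
    }
  }
  passive <- function() if (cfg$wideband_sd > 0)
    stats::rnorm(n, 0, cfg$wideband_sd) else rep(0, n)
  ch <- list(fx = passive(), fy = passive(),
             fz = passive() + body_weight_n)
  if (is.null(direction)) {
    ch$fx <- ch$fx + active
  } else {
    dr <- direction_row(direction)
    ch[[dr$axis]] <- ch[[dr$axis]] + dr$effort_sign * active
  }
  force_trace(fs, ch$fx, ch$fy, ch$fz)
}

#' Cohort generator configuration
#'
#' Study-condition defaults: six sex-by-age strata with the reported
#' group sizes (men 19/17/15, women 18/17/15 for G25/G45/G65; N =
#' 101), anthropometrics drawn from the reported stratum means, SDs
#' and ranges, additive (non-interacting) sex and age effects on mean
#' relative strength via [default_strength_means()], and a common
#' within-stratum SD of 0.35 N/kg.
#'
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration.
#' @param n Named integer vector of per-stratum sizes with names
#'   `male.G25`, `female.G25`, ..., each >= 2.
#' @param means Cell-mean table as from [default_strength_means()].
#' @param sd Within-stratum SD of relative strength (N/kg), scalar.
#' @param fs Sampling rate for materialized traces (Hz).
#' @param trace_args List of overrides passed to [trace_gen_config()]
#'   when traces are materialized (e.g. `tremor_sd`).
#' @return An object of class `"cohort_gen_config"`.
#' @export
cohort_gen_config <- function(seed = 1L,
                              n = c(male.G25 = 19L, female.G25 = 18L,
                                    male.G45 = 17L, female.G45 = 17L,
                                    male.G65 = 15L, female.G65 = 15L),
                              means = default_strength_means(),
                              sd = 0.35, fs = 1400,
                              trace_args = list()) {
  stopifnot(all(n >= 2), sd > 0, fs > 0,
            all(c("sex", "age_group", "direction", "mean") %in%
                  names(means)),
            all(means$mean > 0))
  structure(list(seed = as.integer(seed), n = n, means = means, sd = sd,
                 fs = fs, trace_args = trace_args),
            class = "cohort_gen_config")
}

#' Draw one participant from a stratum
#'
#' Height and mass are drawn from the stratum's normal distribution
#' truncated to the stratum's observed range; age is uniform over the
#' stratum decade; BMI is recomputed from the draw.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_group `"G25"`, `"G45"` or `"G65"`.
#' @param id Identifier for the record.
#' @return A [participant()].
#' @export
generate_participant <- function(sex, age_group, id = "sim") {
  a <- anthro_table()
  row <- a[a$sex == sex & a$age_group == age_group, ]
  if (nrow(row) != 1L) stop("unknown stratum: ", sex, " ", age_group)
  participant(
    id = id, sex = sex,
    age = stats::runif(1, row$age_lo, row$age_hi),
    height = rnorm_trunc(1, row$height_mean, row$height_sd,
                         row$height_lo, row$height_hi),
    mass = rnorm_trunc(1, row$mass_mean, row$mass_sd,
                       row$mass_lo, row$mass_hi))
}

#' Generate a synthetic cohort of assessment scores
#'
#' Draws participants stratum by stratum and, per participant and
#' direction, a best relative strength from
#' `Normal(cell mean, sd)` truncated at zero.  With
#' `traces = FALSE` (the default) the drawn scores are returned
#' directly as the assessment results — the fast path for statistical
#' simulation.  [simulate_assessments()] runs the same draws through
#' materialized force traces and the full extraction pipeline.
#'
#' @param cfg A [cohort_gen_config()].
#' @return An object of class `"strength_cohort"`: `participants`
#'   (one row each) and `scores` (long data.frame: `participant_id`,
#'   `sex`, `age_group`, `mass`, `direction`, `relative`, `best_n`).
#' @export
generate_cohort <- function(cfg = cohort_gen_config()) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  set.seed(cfg$seed)
  strata <- expand.grid(sex = c("male", "female"),
                        age_group = c("G25", "G45", "G65"),
                        stringsAsFactors = FALSE)
  total <- sum(vapply(seq_len(nrow(strata)), function(s)
    cfg$n[[paste(strata$sex[s], strata$age_group[s], sep = ".")]], 1L))
  pid <- character(total); psex <- character(total)
  page <- numeric(total); pag <- character(total)
  ph <- numeric(total); pm <- numeric(total)
  srel <- vector("list", total); sdir <- vector("list", total)
  k <- 0L
  for (s in seq_len(nrow(strata))) {
    sex <- strata$sex[s]; ag <- strata$age_group[s]
    ns <- cfg$n[[paste(sex, ag, sep = ".")]]
    cell <- cfg$means[cfg$means$sex == sex & cfg$means$age_group == ag, ]
    for (j in seq_len(ns)) {
      k <- k + 1L
      p <- generate_participant(sex, ag, id = sprintf("P%03d", k))
      pid[k] <- p$id; psex[k] <- p$sex; page[k] <- p$age
      pag[k] <- p$age_group; ph[k] <- p$height; pm[k] <- p$mass
      srel[[k]] <- rnorm_trunc(nrow(cell), cell$mean, cfg$sd, lo = 0)
      sdir[[k]] <- cell$direction
    }
  }
  nd <- lengths(srel)
  rel <- unlist(srel, use.names = FALSE)
  participants <- data.frame(
    participant_id = pid, sex = psex, age = page, age_group = pag,
    height = ph, mass = pm, bmi = pm / (ph / 100)^2,
    stringsAsFactors = FALSE)
  scores <- data.frame(
    participant_id = rep(pid, nd), sex = rep(psex, nd),
    age_group = rep(pag, nd), mass = rep(pm, nd),
    direction = unlist(sdir, use.names = FALSE), relative = rel,
    best_n = rel * rep(pm, nd), stringsAsFactors = FALSE)
  structure(list(participants = participants, scores = scores,
                 config = cfg),
            class = "strength_cohort")
}

#' @export
print.strength_cohort <- function(x, ...) {
  tab <- table(x$participants$sex, x$participants$age_group)
  cat(sprintf("<strength_cohort> %d participants, %d scores (seed %d)\n",
              nrow(x$participants), nrow(x$scores), x$config$seed))
  print(tab)
  invisible(x)
}

#' Materialize traces and run the full extraction pipeline
#'
#' For every participant of a generated cohort, synthesizes three
#' maximal-effort traces per direction targeting the participant's
#' drawn absolute strength, then runs the complete analysis chain
#' (filtering, sliding-window MVC, best of three, mass
#' normalization).  Traces are processed one participant at a time
#' and discarded, so memory stays flat.  The result has the same
#' shape as `generate_cohort()$scores` but every `relative` value has
#' passed through the signal pipeline.
#'
#' @param cfg A [cohort_gen_config()].
#' @param preprocess A [preprocess_config()].
#' @return A list: `scores` (extracted), `target` (the drawn scores
#'   the traces aimed for), `participants`.
#' @export
simulate_assessments <- function(cfg = cohort_gen_config(),
                                 preprocess = preprocess_config()) {
  cohort <- generate_cohort(cfg)
  set.seed(cfg$seed + 1L)  # independent trace-noise stream
  out <- cohort$scores
  out$relative <- NA_real_; out$best_n <- NA_real_
  for (pid in unique(cohort$scores$participant_id)) {
    rows <- which(cohort$scores$participant_id == pid)
    mass <- cohort$scores$mass[rows[1]]
    trials <- list()
    for (r in rows) {
      code <- cohort$scores$direction[r]
      target <- cohort$scores$best_n[r]
      tcfg <- do.call(trace_gen_config,
                      c(list(target_mvc = target), cfg$trace_args))
      trials[[code]] <- lapply(1:3, function(i)
        generate_trace(tcfg, fs = cfg$fs, direction = code,
                       body_weight_n = mass * 9.81))
    }
    p <- cohort$participants[cohort$participants$participant_id == pid, ]
    pp <- participant(pid, p$sex, p$age, p$height, p$mass)
    ass <- run_assessment(pp, trials, preprocess)
    i <- match(ass$scores$direction, cohort$scores$direction[rows])
    out$best_n[rows[i]] <- ass$scores$best_n
    out$relative[rows[i]] <- ass$scores$relative
  }
  list(scores = out, target = cohort$scores,
       participants = cohort$participants)
}
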