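#' The six assessment directions
#'
#' Direction table of the standing strength protocol.  The frontal
#' pair acts on the mediolateral axis `fx` with both feet side by
#' side: A (adduction) pulls the platform sides inward, B (abduction)
#' pushes them outward.  The sagittal pairs act on the anteroposterior
#' axis `fy` in a staggered stance: D1/D2 with the right leg forward
#' (forward push / backward pull), K1/K2 the same with the left leg
#' forward.  `effort_sign` fixes the sensor polarity convention for
#' each direction: inward pulls (A) and backward pulls (D2, K2) read
#' negative on their axis and are rectified to positive effort before
#' scoring.
#'
#' @return A data.frame with columns `code`, `plane`, `axis`,
#'   `effort_sign`, `front_leg`.
#' @export
directions <- function() {
  data.frame(
    code = c("A", "B", "D1", "D2", "K1", "K2"),
    plane = c("frontal", "frontal", rep("sagittal", 4L)),
    axis = c("fx", "fx", rep("fy", 4L)),
    effort_sign = c(-1, 1, 1, -1, 1, -1),
    front_leg = c("both", "both", "right", "right", "left", "left"),
    stringsAsFactors = FALSE)
}

direction_row <- function(code) {
  d <- directions()
  i <- match(code, d$code)
  if (is.na(i)) stop("unknown direction code: ", code)
  d[i, , drop = FALSE]
}

age_group_of <- function(age) {
  if (age >= 20 && age <= 30) "G25"
  else if (age >= 40 && age <= 50) "G45"
  else if (age >= 60 && age <= 70) "G65"
  else stop("age ", age, " falls outside the studied decades ",
            "(20-30, 40-50, 60-70)")
}

#' Participant record
#'
#' @param id Participant identifier.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years; must fall in one of the studied decades
#'   (20-30, 40-50, 60-70), from which the age group (G25/G45/G65) is
#'   derived.
#' @param height Standing height in cm.
#' @param mass Body mass in kg.
#' @return An object of class `"participant"` with derived `age_group`
#'   and `bmi` (kg/m^2).
#' @export
participant <- function(id, sex, age, height, mass) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(height > 0, mass > 0)
  structure(list(id = as.character(id), sex = sex, age = age,
                 age_group = age_group_of(age), height = height,
                 mass = mass, bmi = mass / (height / 100)^2),
            class = "participant")
}

#' Body mass from quiet-stance vertical force
#'
#' The vertical channel Fz during quiet standing equals body weight,
#' so `mass = mean(Fz) / g`.  Used when strength is normalized from
#' platform data alone, without a separate scale measurement.
#'
#' @param quiet_stance A [force_trace()] of at least 1 s of quiet
#'   standing with strictly positive Fz.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return Body mass in kg.
#' @export
mass_from_fz <- function(quiet_stance, g = 9.81) {
  stopifnot(inherits(quiet_stance, "force_trace"))
  if (quiet_stance$duration < 1)
    stop("quiet-stance segment shorter than 1 s")
  if (any(quiet_stance$fz <= 0))
    stop("non-positive Fz: participant not standing on the platform")
  mean(quiet_stance$fz) / g
}

#' Extract one trial's MVC
#'
#' Selects the direction's mapped axis channel, applies the
#' direction's effort sign (so the expected effort reads positive),
#' low-pass filters it, and runs the sliding-window maximum-mean
#' search.  The other two channels are ignored entirely.
#'
#' @param trace A [force_trace()] of one maximal effort.
#' @param direction A direction code (`"A"`, `"B"`, `"D1"`, `"D2"`,
#'   `"K1"`, `"K2"`).
#' @param cfg A [preprocess_config()].
#' @param rest_before Rest before the attempt in seconds (recorded as
#'   metadata, never enforced).
#' @return An object of class `"trial"`: `direction`, `mvc` (N),
#'   `window_start` (s), `rest_before` (s, metadata only).
#' @export
extract_trial <- function(trace, direction, cfg = preprocess_config(),
                          rest_before = 60) {
  stopifnot(inherits(trace, "force_trace"))
  dr <- direction_row(direction)
  x <- dr$effort_sign * trace[[dr$axis]]
  xf <- lowpass_channel(x, trace$fs, cfg)
  res <- sliding_window_mvc(xf, trace$fs, cfg, channel = dr$axis)
  structure(list(direction = direction, mvc = res$mvc,
                 window_start = res$window_start,
                 rest_before = rest_before),
            class = "trial")
}

#' Run a full six-direction assessment
#'
#' Applies the protocol to one participant: for each of the six
#' directions, the best (maximum) of the three per-trial MVCs is
#' taken, then normalized by body mass to relative strength in N/kg.
#'
#' @param participant A [participant()].
#' @param trials Named list keyed by direction code (`A`, `B`, `D1`,
#'   `D2`, `K1`, `K2`), each element a list of three [force_trace()]s
#'   (or, with `allow_partial = TRUE`, one to three, for clinical use
#'   with an incomplete session).
#' @param cfg A [preprocess_config()].
#' @param mass Normalizing mass in kg; defaults to the participant
#'   record's mass.  Supply [mass_from_fz()] output to normalize from
#'   platform data instead.
#' @param allow_partial Permit 1-3 trials per direction instead of
#'   exactly 3.
#' @return An object of class `"strength_assessment"`: the participant
#'   plus a `scores` data.frame with one row per direction
#'   (`direction`, `best_n`, `relative`).
#' @export
run_assessment <- function(participant, trials, cfg = preprocess_config(),
                           mass = NULL, allow_partial = FALSE) {
  stopifnot(inherits(participant, "participant"))
  codes <- directions()$code
  missing <- setdiff(codes, names(trials))
  if (length(missing))
    stop("protocol violation: missing direction(s) ",
         paste(missing, collapse = ", "))
  if (is.null(mass)) mass <- participant$mass
  scores <- do.call(rbind, lapply(codes, function(code) {
    tr <- trials[[code]]
    nt <- length(tr)
    if (!allow_partial && nt != 3L)
      stop("protocol violation: direction ", code, " has ", nt,
           " trials, expected 3 (set allow_partial = TRUE to override)")
    if (allow_partial && (nt < 1L || nt > 3L))
      stop("direction ", code, " must have 1-3 trials, got ", nt)
    mvcs <- vapply(tr, function(t) extract_trial(t, code, cfg)$mvc,
                   numeric(1))
    best <- best_of_trials(mvcs)
    data.frame(direction = code, best_n = best, relative = best / mass,
               stringsAsFactors = FALSE)
  }))
  structure(list(participant = participant, mass = mass, scores = scores),
            class = "strength_assessment")
}

#' @export
print.strength_assessment <- function(x, ...) {
  p <- x$participant
  cat(sprintf("Strength assessment: %s (%s, %d y, %s, %.1f kg)\n",
              p$id, p$sex, round(p$age), p$age_group, x$mass))
  s <- x$scores
  cat(sprintf("  %-3s best %7.1f N   relative %5.2f N/kg\n",
              s$direction, s$best_n, s$relative), sep = "")
  invisible(x)
}

#' @export
as.data.frame.strength_assessment <- function(x, ...) {
  p <- x$participant
  cbind(data.frame(participant_id = p$id, sex = p$sex,
                   age_group = p$age_group, mass = x$mass,
                   stringsAsFactors = FALSE),
        x$scores, row.names = NULL)
}
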