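# End-to-end pipeline driver: session directories on disk, the
# extract step, and the benchmark report.  CSV for tabular data, JSON
# for nested config and reports; every manifest records the seed and a
# config hash so re-runs are auditable.

config_hash <- function(cfg) {
  raw <- as.integer(serialize(cfg, NULL, version = 2L))
  # polynomial rolling hash over the serialized bytes, in double
  # arithmetic to stay exact below 2^53
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a full measurement session to disk
#'
#' Generates a cohort, materializes all 18 traces per participant
#' (six directions x three trials), and writes a session directory:
#' `participants.csv`, `traces/<participant>_<direction>_<trial>.csv`
#' (force-dialect CSV) and `manifest.json` carrying the seed, the
#' config hash and the per-trial targets.  Byte-identical across runs
#' with the same configuration.
#'
#' @param cfg A [cohort_gen_config()].  For session-sized output
#'   consider small `n` and short plateaus via `trace_args`.
#' @param dir Output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing session directory.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_session <- function(cfg, dir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("session already exists at ", dir,
         " (use overwrite = TRUE to replace)")
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(cfg)
  utils::write.csv(cohort$participants,
                   file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  set.seed(cfg$seed + 1L)
  trace_files <- list(); k <- 0L
  for (r in seq_len(nrow(cohort$scores))) {
    row <- cohort$scores[r, ]
    tcfg <- do.call(trace_gen_config,
                    c(list(target_mvc = row$best_n), cfg$trace_args))
    for (trial in 1:3) {
      tr <- generate_trace(tcfg, fs = cfg$fs, direction = row$direction,
                           body_weight_n = row$mass * 9.81)
      fn <- sprintf("%s_%s_%d.csv", row$participant_id, row$direction,
                    trial)
      write_trace_csv(tr, file.path(dir, "traces", fn))
      k <- k + 1L
      trace_files[[k]] <- list(file = fn,
                               participant = row$participant_id,
                               direction = row$direction, trial = trial,
                               target_n = row$best_n)
    }
  }
  manifest <- list(seed = cfg$seed, fs = cfg$fs,
                   config_hash = config_hash(cfg),
                   n_participants = nrow(cohort$participants),
                   traces = trace_files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Extract assessments from a session directory
#'
#' Reads every trace of a simulated or recorded session, runs the
#' filtering / sliding-window / best-of-three pipeline per participant
#' and direction, normalizes by the recorded body mass, and writes
#' `assessment.csv`.  A malformed or too-short trace is logged and
#' skipped; the direction falls back to its remaining trials (with a
#' warning), and only a direction left with no usable trial is an
#' error.
#'
#' @param dir Session directory (from [simulate_session()] or
#'   hand-assembled in the same layout).
#' @param cfg A [preprocess_config()].
#' @param chain Optional [sensor_chain_spec()] used to convert
#'   voltage-dialect traces; force-dialect traces are used as-is.
#' @return The assessment data.frame (one row per participant x
#'   direction: `participant_id`, `sex`, `age_group`, `mass`,
#'   `direction`, `best_n`, `relative`), invisibly also written to
#'   `assessment.csv` in `dir`.
#' @export
extract_session <- function(dir, cfg = preprocess_config(),
                            chain = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  traces <- manifest$traces
  out <- list(); k <- 0L
  for (pid in participants$participant_id) {
    prow <- participants[participants$participant_id == pid, ]
    ptraces <- traces[traces$participant == pid, ]
    for (code in unique(ptraces$direction)) {
      files <- ptraces$file[ptraces$direction == code]
      mvcs <- numeric(0)
      for (fn in files) {
        tr <- tryCatch({
          t0 <- read_trace_csv(file.path(dir, "traces", fn))
          if (inherits(t0, "voltage_trace")) {
            if (is.null(chain))
              stop("voltage-dialect trace but no sensor chain given")
            t0 <- voltage_trace_to_force(t0, chain)
          }
          t0
        }, error = function(e) e)
        if (inherits(tr, "error")) {
          message("skipping trace ", fn, ": ", conditionMessage(tr))
          next
        }
        mvc <- tryCatch(extract_trial(tr, code, cfg)$mvc,
                        error = function(e) {
                          message("skipping trial ", fn, ": ",
                                  conditionMessage(e))
                          NA_real_
                        })
        if (!is.na(mvc)) mvcs <- c(mvcs, mvc)
      }
      if (length(mvcs) == 0L)
        stop("direction ", code, " of ", pid,
             " has no usable trial: session incomplete")
      if (length(mvcs) < length(files))
        warning(pid, " ", code, ": using ", length(mvcs), " of ",
                length(files), " trials")
      best <- best_of_trials(mvcs)
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = pid, sex = prow$sex,
        age_group = prow$age_group, mass = prow$mass,
        direction = code, best_n = best, relative = best / prow$mass,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  utils::write.csv(res, file.path(dir, "assessment.csv"),
                   row.names = FALSE, quote = FALSE)
  res
}

#' Benchmark a cohort of assessments
#'
#' Runs the full statistical battery on assessment scores: the
#' normative table; male-vs-female t-tests (overall and per age
#' group, with percent differences); per-sex one-way ANOVA across age
#' groups with Games-Howell post hoc pairs; and a two-way (sex x age
#' group) ANOVA with partial eta squared per direction.  No
#' multiple-testing correction is applied across the six directions
#' by default; `bonferroni = TRUE` adjusts the t-test p-values.
#'
#' @param scores Assessment data.frame (see [extract_session()]).
#' @param t_variant `"student"` or `"welch"`.
#' @param ss_type Two-way ANOVA sum-of-squares type, 2 or 3.
#' @param bonferroni Bonferroni-adjust t-test p-values across the six
#'   directions.
#' @return A list of class `"strength_benchmark"`: `normative`,
#'   `ttests` (data.frame), `oneway` (per sex: ANOVA + Games-Howell),
#'   `twoway` (per direction).
#' @export
benchmark_assessments <- function(scores,
                                  t_variant = c("student", "welch"),
                                  ss_type = 2, bonferroni = FALSE) {
  t_variant <- match.arg(t_variant)
  normative <- build_normative_table(scores)
  dirs <- sort(unique(scores$direction))
  sexes <- unique(scores$sex)
  ages <- unique(scores$age_group)
  both_sexes <- length(sexes) == 2L
  ttests <- NULL
  if (both_sexes) {
    blocks <- c(list(all = scores),
                stats::setNames(lapply(ages, function(a)
                  scores[scores$age_group == a, ]), ages))
    rows <- list()
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      for (dir in dirs) {
        m <- b$relative[b$direction == dir & b$sex == "male"]
        f <- b$relative[b$direction == dir & b$sex == "female"]
        if (length(m) < 2L || length(f) < 2L) next
        tt <- independent_t(m, f, variant = t_variant,
                            labels = c("male", "female"))
        rows[[length(rows) + 1L]] <- data.frame(
          block = bn, direction = dir, n_male = tt$n[1],
          n_female = tt$n[2], mean_male = tt$mean[1],
          mean_female = tt$mean[2], pct_diff = tt$pct_diff, t = tt$t,
          df = tt$df, p = tt$p, stringsAsFactors = FALSE)
      }
    }
    ttests <- do.call(rbind, rows)
    if (bonferroni && !is.null(ttests))
      ttests$p_adj <- pmin(1, ttests$p * length(dirs))
  } else {
    message("single-sex input: male-female t-tests skipped")
  }
  oneway <- list()
  if (length(ages) >= 2L) {
    for (sx in sexes) {
      per_dir <- list()
      for (dir in dirs) {
        gr <- lapply(stats::setNames(ages, ages), function(a)
          scores$relative[scores$sex == sx & scores$age_group == a &
                            scores$direction == dir])
        gr <- gr[vapply(gr, length, 1L) >= 2L]
        if (length(gr) < 2L) next
        per_dir[[dir]] <- list(anova = one_way_anova(gr),
                               games_howell = games_howell(gr))
      }
      oneway[[sx]] <- per_dir
    }
  } else {
    message("single age group: one-way ANOVA skipped")
  }
  twoway <- list()
  if (both_sexes && length(ages) >= 2L) {
    for (dir in dirs)
      twoway[[dir]] <- two_way_anova(scores[scores$direction == dir, ],
                                     ss_type = ss_type)
  } else {
    message("incomplete sex x age design: two-way ANOVA skipped")
  }
  structure(list(normative = normative, ttests = ttests,
                 oneway = oneway, twoway = twoway),
            class = "strength_benchmark")
}

#' @export
print.strength_benchmark <- function(x, ...) {
  print(x$normative)
  if (!is.null(x$ttests)) {
    cat("\nMale vs female t-tests (pct_diff = male advantage, %):\n")
    y <- x$ttests
    for (col in c("mean_male", "mean_female", "t"))
      y[[col]] <- round(y[[col]], 3)
    y$pct_diff <- round(y$pct_diff, 2); y$df <- round(y$df, 1)
    y$p <- signif(y$p, 3)
    print.data.frame(y, row.names = FALSE)
  }
  for (dir in names(x$twoway)) {
    cat("\nTwo-way ANOVA, direction ", dir, ":\n", sep = "")
    print(x$twoway[[dir]])
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Writes `normative.csv`, `ttests.csv`, one `anova_<direction>.csv`
#' per two-way table, and (optionally) a per-patient deficit report
#' JSON.
#'
#' @param bench A [benchmark_assessments()] result.
#' @param dir Output directory.
#' @param patient Optional patient (see [deficit_score()]) to score
#'   against the normative table into `deficit.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_benchmark <- function(bench, dir, patient = NULL) {
  stopifnot(inherits(bench, "strength_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  norm <- as.data.frame(bench$normative)
  names(norm) <- c("sex", "age_group", "direction", "n",
                   "mean_n_per_kg", "sd_n_per_kg")
  f <- file.path(dir, "normative.csv")
  utils::write.csv(norm, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  if (!is.null(bench$ttests)) {
    f <- file.path(dir, "ttests.csv")
    utils::write.csv(bench$ttests, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (dirn in names(bench$twoway)) {
    f <- file.path(dir, paste0("anova_", dirn, ".csv"))
    utils::write.csv(as.data.frame(bench$twoway[[dirn]]), f,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(patient)) {
    rep <- deficit_score(patient, bench$normative)
    f <- file.path(dir, "deficit.json")
    jsonlite::write_json(as.data.frame(rep), f, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
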