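#' Build a normative strength table from a cohort
#'
#' Summarizes relative strength (N/kg) per stratum (sex x age group)
#' and direction into n, mean and SD — the normative benchmark a
#' clinician compares a patient against.  Strata with fewer than two
#' participants are omitted with a warning.
#'
#' @param scores Long data.frame with columns `participant_id`, `sex`,
#'   `age_group`, `direction`, `relative` (e.g.
#'   `generate_cohort()$scores` or [extract_session()] output).
#' @return A data.frame of class `"normative_table"` with columns
#'   `sex`, `age_group`, `direction`, `n`, `mean`, `sd`.
#' @export
build_normative_table <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("participant_id", "sex", "age_group", "direction",
                  "relative") %in% names(scores)))
  if (nrow(scores) == 0L) stop("empty cohort")
  agg <- stats::aggregate(relative ~ sex + age_group + direction,
                          data = scores,
                          FUN = function(x) c(n = length(x),
                                              mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(sex = agg$sex, age_group = agg$age_group,
                    direction = agg$direction,
                    n = as.integer(agg$relative[, "n"]),
                    mean = agg$relative[, "mean"],
                    sd = agg$relative[, "sd"],
                    stringsAsFactors = FALSE)
  small <- out$n < 2L
  if (any(small)) {
    bad <- unique(paste(out$sex[small], out$age_group[small]))
    warning("omitting strata with n < 2: ", paste(bad, collapse = ", "))
    out <- out[!small, ]
  }
  out <- out[order(out$sex, out$age_group, out$direction), ]
  rownames(out) <- NULL
  class(out) <- c("normative_table", "data.frame")
  out
}

#' @export
print.normative_table <- function(x, ...) {
  cat("Normative relative strength (N/kg) by stratum and direction\n")
  y <- x; y$mean <- round(y$mean, 3); y$sd <- round(y$sd, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.normative_table <- function(object, ...) {
  cat(sprintf("Normative table: %d strata x direction cells, n %d-%d\n",
              nrow(object), min(object$n), max(object$n)))
  for (dir in unique(object$direction)) {
    d <- object[object$direction == dir, ]
    cat(sprintf("  %-3s mean range %.2f-%.2f N/kg\n",
                dir, min(d$mean), max(d$mean)))
  }
  invisible(object)
}

#' Score a patient against a normative table
#'
#' For each assessed direction, compares the patient's relative
#' strength with the matching stratum norm: z-score
#' `(x - mean) / sd`, percent of norm `100 * x / mean`, and percent
#' deficit `100 * (x - mean) / mean` (negative when below the norm).
#'
#' @param patient A `"strength_assessment"` from [run_assessment()],
#'   or a data.frame with columns `sex`, `age_group`, `direction`,
#'   `relative`.
#' @param table A [build_normative_table()] result.
#' @return A data.frame of class `"deficit_report"`: one row per
#'   direction with `relative`, `norm_mean`, `norm_sd`, `z`,
#'   `pct_of_norm`, `pct_deficit`.
#' @export
deficit_score <- function(patient, table) {
  stopifnot(inherits(table, "normative_table"))
  if (inherits(patient, "strength_assessment")) {
    p <- patient$participant
    pd <- data.frame(sex = p$sex, age_group = p$age_group,
                     direction = patient$scores$direction,
                     relative = patient$scores$relative,
                     stringsAsFactors = FALSE)
  } else {
    pd <- patient
    stopifnot(all(c("sex", "age_group", "direction", "relative") %in%
                    names(pd)))
  }
  sex <- pd$sex[1]; ag <- pd$age_group[1]
  norm <- table[table$sex == sex & table$age_group == ag, ]
  if (nrow(norm) == 0L) {
    have <- unique(paste(table$sex, table$age_group))
    stop("stratum ", sex, " ", ag, " not present in the normative ",
         "table; available strata: ", paste(have, collapse = ", "))
  }
  i <- match(pd$direction, norm$direction)
  if (anyNA(i))
    stop("direction(s) missing from the normative table: ",
         paste(pd$direction[is.na(i)], collapse = ", "))
  out <- data.frame(
    direction = pd$direction, relative = pd$relative,
    norm_mean = norm$mean[i], norm_sd = norm$sd[i],
    z = (pd$relative - norm$mean[i]) / norm$sd[i],
    pct_of_norm = 100 * pd$relative / norm$mean[i],
    pct_deficit = percent_difference(pd$relative, norm$mean[i]),
    stringsAsFactors = FALSE)
  attr(out, "stratum") <- c(sex = sex, age_group = ag)
  class(out) <- c("deficit_report", "data.frame")
  out
}

#' @param object A `normative_table`.
#' @param newdata Passed to [deficit_score()] as `patient`.
#' @rdname deficit_score
#' @export
predict.normative_table <- function(object, newdata, ...) {
  deficit_score(newdata, object)
}

#' @export
print.deficit_report <- function(x, ...) {
  st <- attr(x, "stratum")
  cat(sprintf("Deficit report vs stratum %s %s\n", st["sex"],
              st["age_group"]))
  y <- x
  for (col in c("relative", "norm_mean", "norm_sd", "z"))
    y[[col]] <- round(y[[col]], 3)
  y$pct_of_norm <- round(y$pct_of_norm, 1)
  y$pct_deficit <- round(y$pct_deficit, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
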