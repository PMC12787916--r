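#' Percent difference between two group means
#'
#' `100 * (m1 - m2) / m2`: the difference of the first mean from the
#' second, expressed as a percentage of the second.  Used throughout
#' the benchmarking layer to report, e.g., the male strength advantage
#' over the female mean.
#'
#' @param m1,m2 Group means; `m2` must be non-zero.
#' @return Percent difference (signed).
#' @export
percent_difference <- function(m1, m2) {
  if (any(m2 == 0)) stop("reference mean m2 is zero")
  100 * (m1 - m2) / m2
}

#' Independent-samples t-test with percent difference
#'
#' Two-sided comparison of two independent groups, pooled-variance
#' (Student) by default or Welch, with the mean difference also
#' expressed as a percentage of the second group's mean.
#'
#' @param group1,group2 Numeric samples, each of size >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param labels Length-2 character labels for the groups.
#' @return An object of class `"t_comparison"`: per-group `n`, `mean`,
#'   `sd`, plus `t`, `df`, `p`, `pct_diff`, `variant`.
#' @export
independent_t <- function(group1, group2,
                          variant = c("student", "welch"),
                          labels = c("group1", "group2")) {
  variant <- match.arg(variant)
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(group1) == 0 && stats::var(group2) == 0 &&
      mean(group1) == mean(group2))
    stop("undefined t: both groups constant with equal means")
  ht <- stats::t.test(group1, group2, var.equal = variant == "student")
  structure(list(
    labels = labels,
    n = c(length(group1), length(group2)),
    mean = c(mean(group1), mean(group2)),
    sd = c(stats::sd(group1), stats::sd(group2)),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value,
    pct_diff = percent_difference(mean(group1), mean(group2)),
    variant = variant), class = "t_comparison")
}

#' @export
print.t_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %.4f vs %.4f (%+.2f%%), t(%.4g) = %.3f, p = %.4g [%s]\n",
              x$labels[1], x$labels[2], x$mean[1], x$mean[2],
              x$pct_diff, x$df, x$t, x$p, x$variant))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across k groups, returned as
#' a machine-readable table (between/within sums of squares, F, p).
#'
#' @param groups List of >= 2 numeric samples, each of size >= 2.
#' @return A data.frame of class `"anova_table"` with rows
#'   `between`/`within` and columns `source`, `ss`, `df`, `ms`, `f`,
#'   `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  a <- stats::anova(stats::lm(y ~ g))
  out <- data.frame(source = c("between", "within"),
                    ss = a$`Sum Sq`, df = a$Df, ms = a$`Mean Sq`,
                    f = c(a$`F value`[1], NA_real_),
                    p = c(a$`Pr(>F)`[1], NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise group comparisons robust to unequal variances and
#' sample sizes: each pair uses the unpooled standard error
#' `se = sqrt(s_i^2/n_i + s_j^2/n_j)`, Welch-Satterthwaite degrees of
#' freedom, the studentized-range statistic `q = |diff| * sqrt(2) / se`,
#' and an adjusted p-value from the studentized-range distribution
#' with k groups.  With k = 2 this reduces exactly to the two-sided
#' Welch t-test.
#'
#' @param groups Named list of >= 2 numeric samples, each of size
#'   >= 2 with positive variance.
#' @return A data.frame of class `"games_howell"`: one row per pair
#'   with `group1`, `group2`, `mean_diff`, `se`, `df`, `q`, `p_adj`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("degenerate group with zero variance")
  m <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) * sqrt(2) / sqrt(se2)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               mean_diff = m[i] - m[j], se = sqrt(se2), df = df, q = q,
               p_adj = stats::ptukey(q, nmeans = k, df = df,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("games_howell", "data.frame")
  out
}

#' Two-way analysis of variance with partial eta squared
#'
#' Fixed-effects two-factor ANOVA (sex x age group by default) of
#' relative strength, reporting for each source the sum of squares,
#' degrees of freedom, mean square, F, p and partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.  Sums of squares are Type II
#' by default, which coincides with the classical decomposition when
#' the design is balanced; Type III (with sum-to-zero contrasts) is
#' available by flag.
#'
#' @param data Data.frame containing the response and both factors;
#'   every factor-level cell must be non-empty.
#' @param response Response column name (default `"relative"`).
#' @param factors Length-2 character vector of factor column names.
#' @param ss_type 2 (default) or 3.
#' @return A data.frame of class `"anova_table"` with rows for the two
#'   main effects, their interaction, and error.
#' @export
two_way_anova <- function(data, response = "relative",
                          factors = c("sex", "age_group"),
                          ss_type = 2) {
  stopifnot(is.data.frame(data),
            all(c(response, factors) %in% names(data)),
            ss_type %in% c(2, 3))
  f1 <- factor(data[[factors[1]]]); f2 <- factor(data[[factors[2]]])
  if (any(table(f1, f2) == 0L))
    stop("empty factor cell: every ", factors[1], " x ", factors[2],
         " combination needs data")
  y <- data[[response]]
  # sums of squares by model comparison on the design-matrix columns:
  # Type II drops each main effect from the additive model, Type III
  # (sum-to-zero contrasts) drops each term from the full model
  contr <- if (ss_type == 3)
    list(f1 = "contr.sum", f2 = "contr.sum") else NULL
  d <- data.frame(f1 = f1, f2 = f2)
  X <- stats::model.matrix(~ f1 * f2, d, contrasts.arg = contr)
  asgn <- attr(X, "assign")  # 0 intercept, 1 f1, 2 f2, 3 interaction
  rss <- function(terms) {
    sum(stats::lm.fit(X[, asgn %in% terms, drop = FALSE], y)$residuals^2)
  }
  rss_full <- rss(0:3)
  rss_add <- rss(0:2)
  if (ss_type == 3) {
    ss_f1 <- rss(c(0, 2, 3)) - rss_full
    ss_f2 <- rss(c(0, 1, 3)) - rss_full
  } else {
    ss_f1 <- rss(c(0, 2)) - rss_add
    ss_f2 <- rss(c(0, 1)) - rss_add
  }
  ss_int <- rss_add - rss_full
  a <- nlevels(f1); b <- nlevels(f2)
  df <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L),
          length(y) - a * b)
  ss <- pmax(c(ss_f1, ss_f2, ss_int, rss_full), 0)
  src <- c(factors[1], factors[2], "interaction", "error")
  ss_err <- ss[4]; df_err <- df[4]
  if (ss_err > 0) {
    fstat <- (ss[1:3] / df[1:3]) / (ss_err / df_err)
    pval <- stats::pf(fstat, df[1:3], df_err, lower.tail = FALSE)
    eta <- ss[1:3] / (ss[1:3] + ss_err)
  } else {
    # saturated fit (e.g. noiseless cell means): SS are still defined
    fstat <- pval <- eta <- rep(NA_real_, 3)
  }
  out <- data.frame(
    source = src, ss = ss, df = df, ms = ss / df,
    f = c(fstat, NA_real_), p = c(pval, NA_real_),
    eta_p2 = c(eta, NA_real_), stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- x
  for (col in c("ss", "ms", "f")) y[[col]] <- round(y[[col]], 3)
  if ("eta_p2" %in% names(y)) y$eta_p2 <- round(y$eta_p2, 3)
  y$p <- signif(y$p, 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' F statistic from sums of squares
#'
#' `F = (SS_effect / df_effect) / (SS_error / df_error)` — the ratio
#' of variance explained by a factor to unexplained variance.  Lets a
#' published ANOVA table be checked for self-consistency from its
#' printed sums of squares and degrees of freedom alone.
#'
#' @param ss_effect,ss_error Sums of squares (>= 0; `ss_error` > 0).
#' @param df_effect,df_error Degrees of freedom (>= 1).
#' @return The F statistic.
#' @export
f_from_ss <- function(ss_effect, df_effect, ss_error, df_error) {
  if (any(ss_error <= 0)) stop("ss_error must be positive")
  if (any(df_effect < 1) || any(df_error < 1)) stop("dfs must be >= 1")
  (ss_effect / df_effect) / (ss_error / df_error)
}

#' Partial eta squared effect size
#'
#' `SS_effect / (SS_effect + SS_error)`: the proportion of variance
#' uniquely attributable to a factor after controlling for the other
#' model terms.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_error Error sum of squares (> 0 unless `ss_effect` > 0).
#' @return Proportion in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0)) stop("ss_effect must be >= 0")
  if (any(ss_effect + ss_error == 0))
    stop("undefined effect size: both sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}
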