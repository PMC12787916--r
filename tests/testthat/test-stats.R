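test_that("percent difference reproduces the normative worked examples", {
  expect_equal(round(percent_difference(1.8504, 1.3659), 2), 35.47)
  expect_equal(round(percent_difference(2.3039, 1.6909), 2), 36.25)
  expect_equal(percent_difference(1.25, 1.25), 0)
  expect_error(percent_difference(1, 0), "zero")
})

test_that("independent t matches the pooled-variance formula oracle", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), runif(1, 0, 2), runif(1, 0.2, 1))
    y <- rnorm(sample(5:30, 1), runif(1, 0, 2), runif(1, 0.2, 1))
    got <- independent_t(x, y, "student")
    want <- pooled_t(x, y)
    expect_equal(got$t, want$t)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p)
    # antisymmetry
    swapped <- independent_t(y, x, "student")
    expect_equal(swapped$t, -got$t)
    expect_equal(swapped$p, got$p)
  }
})

test_that("identical groups give t = 0, p = 1 and degenerate input errors", {
  x <- c(1.2, 1.5, 1.9, 2.1)
  tt <- independent_t(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$pct_diff, 0)
  expect_error(independent_t(rep(1, 5), rep(1, 5)), "undefined t")
  expect_error(independent_t(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA on two groups equals the squared pooled t", {
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(12, 0, 1); y <- rnorm(15, 0.8, 1.3)
    a <- one_way_anova(list(x, y))
    tt <- independent_t(x, y, "student")
    expect_equal(a$f[1], tt$t^2, tolerance = 1e-9)
    expect_equal(a$p[1], tt$p, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA degenerates sensibly", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  a <- one_way_anova(g)
  expect_equal(a$ss[a$source == "between"], 0)
  expect_equal(a$f[1], 0)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
})

test_that("one-way ANOVA F is near 1 under the null", {
  set.seed(40)
  fs <- vapply(1:200, function(i) {
    g <- lapply(1:3, function(j) rnorm(10))
    one_way_anova(g)$f[1]
  }, numeric(1))
  # E[F] = df2/(df2-2) = 27/25
  expect_equal(mean(fs), 27 / 25, tolerance = 0.1)
})

test_that("Games-Howell with two groups equals the Welch t-test", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(6:25, 1), 0, runif(1, 0.5, 2))
    y <- rnorm(sample(6:25, 1), runif(1, 0, 1.5), runif(1, 0.5, 2))
    gh <- games_howell(list(a = x, b = y))
    wt <- independent_t(x, y, "welch")
    expect_equal(gh$p_adj, wt$p, tolerance = 1e-6)
    expect_equal(gh$df, wt$df, tolerance = 1e-9)
    expect_equal(gh$q, abs(wt$t) * sqrt(2), tolerance = 1e-9)
  }
})

test_that("Games-Howell flags a shifted group and not null pairs", {
  hits_shift <- 0; hits_null <- 0
  for (s in 1:60) {
    set.seed(s)
    g <- list(g1 = rnorm(15, 0, 1), g2 = rnorm(15, 0, 1.4),
              g3 = rnorm(15, 2.0, 1))
    gh <- games_howell(g)
    p12 <- gh$p_adj[gh$group1 == "g1" & gh$group2 == "g2"]
    p13 <- gh$p_adj[gh$group1 == "g1" & gh$group2 == "g3"]
    hits_shift <- hits_shift + (p13 < 0.05)
    hits_null <- hits_null + (p12 > 0.05)
  }
  expect_gte(hits_shift / 60, 0.95)
  expect_gte(hits_null / 60, 0.85)
})

test_that("Games-Howell near-identical groups give p near 1 and
           zero-variance groups error", {
  x <- c(1.0, 1.2, 1.4, 1.6)
  gh <- games_howell(list(a = x, b = x + 1e-12))
  expect_equal(gh$mean_diff, -1e-12)
  expect_gte(gh$p_adj, 0.999)
  expect_error(games_howell(list(a = rep(1, 4), b = x)), "zero variance")
})

test_that("two-way ANOVA decomposes balanced data exactly", {
  set.seed(66)
  d <- expand.grid(sex = c("male", "female"),
                   age_group = c("G25", "G45", "G65"),
                   rep = 1:8, stringsAsFactors = FALSE)
  d$relative <- rnorm(nrow(d), 2, 0.4)
  a <- two_way_anova(d)
  ss_total <- sum((d$relative - mean(d$relative))^2)
  expect_equal(sum(a$ss), ss_total, tolerance = 1e-9)
  expect_equal(a$df, c(1, 2, 2, nrow(d) - 6))
  expect_equal(a$ms, a$ss / a$df)
  expect_true(all(a$eta_p2[1:3] >= 0 & a$eta_p2[1:3] <= 1))
})

test_that("purely additive cell means give zero interaction SS", {
  d <- expand.grid(sex = c("male", "female"),
                   age_group = c("G25", "G45", "G65"),
                   rep = 1:5, stringsAsFactors = FALSE)
  sex_eff <- ifelse(d$sex == "male", 0.5, 0)
  age_eff <- c(G25 = 0, G45 = -0.2, G65 = -0.5)[d$age_group]
  d$relative <- 1.5 + sex_eff + age_eff
  a <- two_way_anova(d)
  expect_equal(a$ss[a$source == "interaction"], 0, tolerance = 1e-12)
})

test_that("unbalanced Type II and balanced classical SS agree where they
           must, and error df matches the design", {
  set.seed(12)
  # unbalanced with the reported group sizes: N = 99 leaves 93 error df
  n <- c(19, 18, 17, 17, 15, 13)
  cells <- expand.grid(sex = c("male", "female"),
                       age_group = c("G25", "G45", "G65"),
                       stringsAsFactors = FALSE)
  d <- do.call(rbind, lapply(seq_len(6), function(i)
    data.frame(sex = cells$sex[i], age_group = cells$age_group[i],
               relative = rnorm(n[i], 2, 0.4))))
  expect_equal(sum(n), 99)
  a <- two_way_anova(d)
  expect_equal(a$df[a$source == "error"], 93)
  a3 <- two_way_anova(d, ss_type = 3)
  expect_equal(a3$df, a$df)
  # types agree on the interaction term
  expect_equal(a3$ss[3], a$ss[3], tolerance = 1e-9)
  expect_error(two_way_anova(d[d$age_group != "G65" | d$sex != "male", ]),
               "empty factor cell")
})

test_that("F and partial eta squared recompute from sums of squares", {
  expect_equal(f_from_ss(3.64, 1, 8.47, 93), 39.97, tolerance = 2e-4)
  expect_equal(f_from_ss(6.85, 2, 14.05, 93), 22.67, tolerance = 2e-4)
  expect_equal(f_from_ss(0, 3, 5, 50), 0)
  expect_error(f_from_ss(1, 1, 0, 10), "positive")
  expect_equal(partial_eta_squared(3.64, 8.47), 0.301, tolerance = 2e-3)
  expect_equal(partial_eta_squared(6.28, 10.73), 0.369, tolerance = 2e-3)
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_error(partial_eta_squared(0, 0), "undefined")
})

test_that("two-way ANOVA internal F/eta agree with the from-SS helpers", {
  set.seed(19)
  co <- generate_cohort(cohort_gen_config(seed = 19))
  a <- two_way_anova(co$scores[co$scores$direction == "D2", ])
  err <- a[a$source == "error", ]
  for (i in 1:3) {
    expect_equal(a$f[i], f_from_ss(a$ss[i], a$df[i], err$ss, err$df))
    expect_equal(a$eta_p2[i], partial_eta_squared(a$ss[i], err$ss))
  }
})

test_that("Type II and III sums of squares match the established
           implementation on unbalanced noisy data", {
  skip_if_not_installed("car")
  set.seed(55)
  n <- c(19, 18, 17, 17, 15, 15)
  cells <- expand.grid(sex = c("male", "female"),
                       age_group = c("G25", "G45", "G65"),
                       stringsAsFactors = FALSE)
  d <- do.call(rbind, lapply(seq_len(6), function(i)
    data.frame(sex = cells$sex[i], age_group = cells$age_group[i],
               relative = rnorm(n[i], 2 - 0.1 * i, 0.4))))
  a2 <- two_way_anova(d)
  fit <- lm(relative ~ sex * age_group, data = d)
  ref2 <- car::Anova(fit, type = 2)
  expect_equal(a2$ss, ref2$`Sum Sq`, tolerance = 1e-9)
  expect_equal(a2$p[1:3], ref2$`Pr(>F)`[1:3], tolerance = 1e-9)
  fit3 <- lm(relative ~ sex * age_group, data = d,
             contrasts = list(sex = "contr.sum",
                              age_group = "contr.sum"))
  ref3 <- car::Anova(fit3, type = 3)
  ref3 <- ref3[rownames(ref3) != "(Intercept)", ]
  a3 <- two_way_anova(d, ss_type = 3)
  expect_equal(a3$ss, ref3$`Sum Sq`, tolerance = 1e-9)
})
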