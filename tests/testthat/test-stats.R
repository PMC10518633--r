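test_that("ladder transform preserves order and rejects bad input", {
  set.seed(1)
  for (rep in 1:4) {
    x <- rnorm(40, sd = 5) + rexp(40)        # mixed-sign, skewed
    tr <- tukey_transform(x)
    expect_equal(order(x), order(tr$values))
    expect_true(tr$lambda %in% c(-2, -1, -0.5, 0, 0.5, 1, 2))
  }
  expect_error(tukey_transform(c(1, 2)), "at least 3")
  expect_error(tukey_transform(rep(3, 10)), "constant")
})

test_that("ladder selection matches the shape of the data", {
  set.seed(99)
  loglam <- tukey_transform(rlnorm(500, 0, 1))$lambda
  expect_lte(loglam, 0.5)
  normlam <- tukey_transform(rnorm(500, 50, 5))$lambda
  expect_true(normlam >= 0.5 && normlam <= 2)
  # nonpositive data are shifted, transform still monotone
  x <- rnorm(100, 0, 2)
  tr <- tukey_transform(x)
  expect_equal(tr$shift, 1e-6 + abs(min(x)))
  expect_equal(order(tr$values), order(x))
})

sim_cases <- function(n_group = 2L, n_case = 6L, n_obs = 4L, delta = 0,
                      case_sd = 0, resid_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(LETTERS[seq_len(n_group)], each = n_case * n_obs)
    case <- rep(sprintf("%s%d", rep(LETTERS[seq_len(n_group)], each = n_case),
                        rep(seq_len(n_case), n_group)), each = n_obs)
    eff <- (as.integer(factor(g)) - 1) * delta
    b <- rnorm(n_group * n_case, 0, case_sd)[as.integer(factor(case))]
    data.frame(group = g, case = case,
               y = 10 + eff + b + rnorm(length(g), 0, resid_sd))
  })
}

test_that("with zero case variance the mixed F matches one-way ANOVA", {
  d <- sim_cases(delta = 1.2, case_sd = 0, seed = 3)
  d$y <- d$y - stats::ave(d$y, d$case) + stats::ave(d$y, d$group)
  fit <- fit_group_model(d, "y", "group", "case", transform = FALSE)
  f_mixed <- fit$anova$`F value`[fit$anova$term == "group"]
  f_aov <- summary(stats::aov(y ~ group, data = d))[[1]]["group", "F value"]
  expect_lt(abs(f_mixed - f_aov) / f_aov, 0.05)
  expect_true(fit$singular)          # zero variance is flagged, not hidden
})

test_that("the 95% CI for a planted effect covers it at the nominal rate", {
  delta <- 1
  covered <- vapply(1:200, function(i) {
    d <- sim_cases(n_case = 6L, n_obs = 3L, delta = delta, case_sd = 0.5,
                   seed = 1000 + i)
    fit <- fit_group_model(d, "y", "group", "case", transform = FALSE)
    co <- summary(fit$fit)$coefficients["groupB", ]
    lo <- co["Estimate"] - stats::qt(0.975, co["df"]) * co["Std. Error"]
    hi <- co["Estimate"] + stats::qt(0.975, co["df"]) * co["Std. Error"]
    lo <= delta && delta <= hi
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("contrasts: family of one equals unadjusted; identical groups null", {
  d <- sim_cases(delta = 0.8, case_sd = 0.3, seed = 5)
  fit <- fit_group_model(d, "y", "group", "case", transform = FALSE)
  ctr <- pairwise_contrasts(fit, "group")
  expect_equal(nrow(ctr), 1L)
  p_anova <- fit$anova$`Pr(>F)`[fit$anova$term == "group"]
  expect_equal(ctr$p_adjusted, p_anova, tolerance = 1e-6)

  # literally identical data in both groups: zero contrast, p = 1
  d2 <- sim_cases(delta = 0, case_sd = 0, seed = 6)
  d2$y <- rep(d2$y[d2$group == "A"], 2)
  fit2 <- fit_group_model(d2, "y", "group", "case", transform = FALSE)
  ctr2 <- pairwise_contrasts(fit2, "group")
  expect_equal(ctr2$estimate, 0, tolerance = 1e-10)
  expect_gt(ctr2$p_adjusted, 0.99)

  expect_error(pairwise_contrasts(fit, "nope"), "unknown factor")
})

test_that("three-group null keeps the family-wise error controlled", {
  rej <- vapply(1:200, function(i) {
    d <- sim_cases(n_group = 3L, n_case = 5L, n_obs = 3L, delta = 0,
                   case_sd = 0.4, seed = 3000 + i)
    fit <- fit_group_model(d, "y", "group", "case", transform = FALSE)
    any(pairwise_contrasts(fit, "group")$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(rej), 0.10)
})

test_that("fold change is the ratio of case-level means, bootstrap seeded", {
  d <- data.frame(group = rep(c("AD", "ctrl"), each = 6),
                  case = rep(c("a1", "a2", "c1", "c2"), each = 3),
                  y = c(rep(4.2, 6), rep(2.0, 6)))
  fc <- fold_change(d, "y", "case", "group", "AD", "ctrl", n_boot = 50L)
  expect_equal(fc$ratio, 2.1)
  expect_identical(fc$ci,
                   fold_change(d, "y", "case", "group", "AD", "ctrl",
                               n_boot = 50L)$ci)
  expect_equal(fold_change(d, "y", "case", "group", "ctrl", "ctrl")$ratio, 1)

  # duplicating observations within cases cannot inflate the estimate
  d2 <- rbind(d, d)
  expect_equal(fold_change(d2, "y", "case", "group", "AD", "ctrl")$ratio,
               fc$ratio)
  expect_error(fold_change(d, "y", "case", "group", "AD", "nope"), "empty")
})

test_that("log-ladder fits are invariant to outcome scaling", {
  set.seed(8)
  d <- sim_cases(delta = 0, case_sd = 0.3, seed = 11)
  d$y <- rlnorm(nrow(d), meanlog = as.integer(factor(d$group)) * 0.5)
  fit1 <- fit_group_model(d, "y", "group", "case")
  d$y <- d$y * 1000
  fit2 <- fit_group_model(d, "y", "group", "case")
  if (fit1$transform$lambda == 0 && fit2$transform$lambda == 0) {
    expect_equal(fit1$anova$`F value`, fit2$anova$`F value`,
                 tolerance = 1e-6)
  }
  succeed()
})

test_that("correlations behave at the extremes", {
  expect_equal(correlate(1:10, 10:1)$coefficient, -1)
  set.seed(12)
  ind <- correlate(rnorm(1000), rnorm(1000))
  expect_lt(abs(ind$coefficient), 0.1)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 2:1), "n >= 3")
  lin <- correlate(1:20, (1:20) * 2 + rnorm(20, 0, 0.1), method = "linear")
  expect_gt(lin$coefficient, 0.99)
})
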