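test_that("absolute difference matches the endpoint-percentage convention", {
  d <- absolute_difference(3361 / 51665, 51665, 3408 / 47507, 47507)
  expect_equal(round_half_up(d$estimate, 1), 0.7)
  expect_equal(round_half_up(d$lower, 1), 0.4)
  expect_equal(round_half_up(d$upper, 1), 1.0)

  d2 <- absolute_difference(1441 / 51665, 51665, 765 / 47507, 47507)
  expect_equal(round_half_up(d2$estimate, 1), -1.2)

  same <- absolute_difference(0.05, 1000, 0.05, 2000)
  expect_equal(same$estimate, 0)
  expect_lt(same$lower, 0); expect_gt(same$upper, 0)
  expect_error(absolute_difference(0.1, 0, 0.2, 10), class = "gestage_domain_error")
})

test_that("relative difference is computed on unrounded proportions", {
  expect_equal(round_half_up(relative_difference(1441 / 51665, 765 / 47507), 1), -42.3)
  expect_equal(round_half_up(relative_difference(3361 / 51665, 3408 / 47507), 1), 10.3)
  expect_equal(relative_difference(0.07, 0.07), 0)
  expect_true(is.na(relative_difference(0, 0.1)))
})

test_that("delta-method CI for the relative difference behaves at the limits", {
  # equal proportions: the CI must bracket zero
  eq <- relative_difference_ci(0.06, 50000, 0.06, 50000)
  expect_lt(eq$lower, 0); expect_gt(eq$upper, 0)
  expect_equal(eq$estimate, 0)
  # enormous n: width collapses onto the point estimate
  lim <- relative_difference_ci(0.5, 1e8, 0.55, 1e8)
  expect_equal(lim$estimate, 10, tolerance = 1e-9)
  expect_lt(lim$upper - lim$lower, 0.1)
  expect_true(is.na(relative_difference_ci(0, 100, 0.1, 100)$estimate))
})

test_that("delta-method CI agrees with a parametric bootstrap oracle", {
  p1 <- 3361 / 51665; n1 <- 51665
  p2 <- 3408 / 47507; n2 <- 47507
  ci <- relative_difference_ci(p1, n1, p2, n2)
  set.seed(31)
  B <- 1e5
  r <- (rbinom(B, n2, p2) / n2) / (rbinom(B, n1, p1) / n1)
  boot_se <- sd(100 * (r - 1))
  est <- 100 * (p2 / p1 - 1)
  expect_lt(abs(ci$lower - (est - 1.96 * boot_se)), 0.1)
  expect_lt(abs(ci$upper - (est + 1.96 * boot_se)), 0.1)
})

test_that("a two-point fit reproduces the closed-form odds ratio exactly", {
  fit <- fit_binomial_trend(c(100, 200), c(1000, 1000), c(2005, 2006))
  # saturated two-point logit line: OR = (0.2/0.8)/(0.1/0.9)
  expect_equal(unname(or_per_year(fit)["or"]), 2.25, tolerance = 1e-9)
  expect_equal(fit$deviance, 0, tolerance = 1e-8)
})

test_that("a flat series gives an odds ratio of one", {
  fit <- fit_binomial_trend(rep(60, 5), rep(1000, 5), 2015:2019)
  expect_equal(unname(coef(fit)["year"]), 0, tolerance = 1e-10)
  expect_equal(unname(or_per_year(fit)["or"]), 1, tolerance = 1e-10)
})

test_that("the fitted odds ratio is invariant to year centering", {
  ev <- c(120, 130, 150, 160, 170); tr <- rep(2000, 5)
  f1 <- fit_binomial_trend(ev, tr, 2015:2019)
  f2 <- fit_binomial_trend(ev, tr, (2015:2019) - 2017)
  expect_equal(unname(coef(f1)["year"]), unname(coef(f2)["year"]), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(vcov(f1)))["year"]),
               unname(sqrt(diag(vcov(f2)))["year"]), tolerance = 1e-8)
})

test_that("the aggregate events/trials fit equals the expanded per-birth fit", {
  set.seed(17)
  year <- 2015:2019
  trials <- c(350, 420, 380, 400, 450)
  p <- 1 / (1 + exp(-(-2.5 + 0.08 * (year - 2017))))
  events <- rbinom(5, trials, p)
  agg <- fit_binomial_trend(events, trials, year)
  long <- data.frame(year = rep(year, trials),
                     y = unlist(mapply(function(e, t) c(rep(1, e), rep(0, t - e)),
                                       events, trials)))
  ind <- glm(y ~ year, data = long, family = binomial)
  expect_equal(unname(coef(agg)), unname(coef(ind)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(agg)))), unname(sqrt(diag(vcov(ind)))),
               tolerance = 1e-5)
})

test_that("degenerate and pathological inputs raise fit errors", {
  expect_error(fit_binomial_trend(c(0, 0, 0), c(10, 10, 10), 2017:2019),
               class = "gestage_fit_error")
  expect_error(fit_binomial_trend(c(10, 10), c(10, 10), 2018:2019),
               class = "gestage_fit_error")
  expect_error(fit_binomial_trend(c(5, 6), c(10, 10), 2019), class = "gestage_config_error")
  expect_error(fit_binomial_trend(c(5, 6), c(10, 10), c(2019, 2019)),
               class = "gestage_config_error")
  expect_error(fit_binomial_trend(c(11, 5), c(10, 10), 2018:2019),
               class = "gestage_domain_error")
})

test_that("binom_trend methods are coherent", {
  fit <- fit_binomial_trend(c(100, 120, 145, 150), rep(1000, 4), 2016:2019)
  expect_equal(length(fitted(fit)), 4)
  expect_equal(predict(fit, data.frame(year = 2016:2019), type = "response"),
               fitted(fit), ignore_attr = TRUE)
  expect_equal(nobs(fit), 4)
  ci <- confint(fit)
  expect_true(ci["year", 1] < coef(fit)["year"] && coef(fit)["year"] < ci["year", 2])
  expect_equal(sum(residuals(fit)^2), fit$deviance, tolerance = 1e-8)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(4, 3))
  expect_true(all(sims <= 1000 & sims >= 0))
  expect_output(print(summary(fit)), "Per-year odds ratio")
})

test_that("trend summaries agree with direct recomputation from any table", {
  set.seed(41)
  for (i in 1:5) {
    years <- 2010:2019
    trials <- sample(5000:9000, 10, TRUE)
    pre <- rbinom(10, trials, 0.06)
    post <- rbinom(10, trials, 0.02)
    df <- data.frame(year = years, total = trials, unknown_gestation = 0,
                     preterm = pre, post_term = post,
                     term = trials - pre - post)
    tab <- yearly_count_table(df, "singleton")
    tr <- gestage_trend(tab, "preterm")
    expect_equal(tr$p_start, pre[1] / trials[1])
    expect_equal(tr$p_end, pre[10] / trials[10])
    direct <- absolute_difference(pre[1] / trials[1], trials[1],
                                  pre[10] / trials[10], trials[10])
    expect_equal(tr$abs_diff, direct)
    expect_equal(tr$rel_diff,
                 relative_difference(pre[1] / trials[1], pre[10] / trials[10]))
    expect_equal(unname(tr$or["or"]),
                 unname(or_per_year(fit_binomial_trend(pre, trials, years))["or"]))
    expect_true(tr$abs_diff$lower <= tr$abs_diff$estimate &&
                  tr$abs_diff$estimate <= tr$abs_diff$upper)
    expect_true(tr$or["lower"] <= tr$or["or"] && tr$or["or"] <= tr$or["upper"])
    expect_gt(tr$or["or"], 0)
  }
})

test_that("parameter recovery: the fitted log-OR tracks the generative slope", {
  b <- 0.05
  cfg <- synthetic_config(years = 2013:2019, births_per_year = 4000,
                          preterm_year_slope = b, seed = 77)
  rec <- generate_records(cfg)
  tab <- count_births(rec, "singleton")
  fit <- gestage_trend(tab, "preterm")$fit
  se <- sqrt(diag(vcov(fit))["year"])
  # single replicate: the Wald SE bounds the Monte-Carlo spread
  expect_lt(abs(coef(fit)["year"] - b), 4 * se)
})
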