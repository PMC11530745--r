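# Trend statistics: endpoint differences with CIs, and the per-year odds
# ratio from aggregate birth-weighted logistic regression.

#' Absolute difference between two percentages
#'
#' Endpoint-minus-baseline difference in percentage points between two
#' independent binomial proportions, with a Wald confidence interval:
#' point = 100 (p_end - p_start), CI = point +/- z * 100 *
#' sqrt(p_start (1 - p_start) / n_start + p_end (1 - p_end) / n_end).
#'
#' @param p_start,p_end proportions (in \[0, 1\], unrounded).
#' @param n_start,n_end denominators (births with known gestation, etc.).
#' @param alpha two-sided level (default 0.05 for a 95% CI).
#' @return list with `estimate` (percentage points), `lower`, `upper`.
#' @examples
#' absolute_difference(3361 / 51665, 51665, 3408 / 47507, 47507)
#' @export
absolute_difference <- function(p_start, n_start, p_end, n_end, alpha = 0.05) {
  if (n_start < 1 || n_end < 1)
    gestage_error("denominators must be >= 1", "gestage_domain_error")
  stopifnot(p_start >= 0, p_start <= 1, p_end >= 0, p_end <= 1)
  est <- 100 * (p_end - p_start)
  se <- 100 * sqrt(p_start * (1 - p_start) / n_start + p_end * (1 - p_end) / n_end)
  z <- z_crit(alpha)
  list(estimate = est, lower = est - z * se, upper = est + z * se)
}

#' Relative (percent) difference between two proportions
#'
#' The absolute difference divided by the baseline proportion, times 100:
#' 100 (p_end - p_start) / p_start, computed on unrounded proportions.
#' Undefined (NA) when the baseline is zero.
#'
#' @param p_start,p_end proportions (unrounded).
#' @return percent change (scalar), `NA` if `p_start` is 0.
#' @examples
#' relative_difference(1441 / 51665, 765 / 47507)  # about -42.3
#' @export
relative_difference <- function(p_start, p_end) {
  if (p_start == 0) return(NA_real_)
  100 * (p_end - p_start) / p_start
}

#' Delta-method confidence interval for a relative difference
#'
#' Confidence interval for the percent change 100 (r - 1), where
#' r = p_end / p_start is the ratio of two independent binomial proportions.
#' The variance of r is approximated by the delta method as
#' r^2 (cv_start^2 + cv_end^2) with cv_i^2 = (1 - p_i) / (n_i p_i), giving
#' the symmetric interval 100 (r - 1) +/- z * 100 * sqrt(var(r)). Published
#' tables sometimes print asymmetric intervals for this quantity from other
#' approximations; this package documents and ships the delta-method form.
#'
#' @inheritParams absolute_difference
#' @return list with `estimate` (percent change), `lower`, `upper`;
#'   all `NA` when `p_start` is 0.
#' @export
relative_difference_ci <- function(p_start, n_start, p_end, n_end, alpha = 0.05) {
  if (n_start < 1 || n_end < 1)
    gestage_error("denominators must be >= 1", "gestage_domain_error")
  if (p_start == 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  r <- p_end / p_start
  cv2 <- (1 - p_start) / (n_start * p_start) + (1 - p_end) / (n_end * p_end)
  se <- 100 * sqrt(r^2 * cv2)
  est <- 100 * (r - 1)
  z <- z_crit(alpha)
  list(estimate = est, lower = est - z * se, upper = est + z * se)
}

#' Aggregate binomial logistic trend fit (events/trials IRLS)
#'
#' Fits logit(p_year) = b0 + b1 * year to yearly events/trials counts by
#' iteratively reweighted least squares on the binomial log-likelihood.
#' Because the binomial likelihood for aggregated counts equals the
#' individual-level Bernoulli likelihood, each year's contribution is
#' weighted by its number of births — the aggregate, birth-weighted
#' univariate logistic regression used for registry trend estimation.
#' exp(b1) is the per-year odds ratio.
#'
#' Convergence is declared when the largest absolute coefficient update
#' falls below `tol` (default 1e-10) within `max_iter` (default 50)
#' iterations; non-convergence and degenerate inputs (zero events or zero
#' non-events everywhere) are errors, never silent partial results.
#'
#' @param events integer vector of yearly event counts.
#' @param trials integer vector of yearly totals (same length, >= events).
#' @param year numeric vector of calendar years.
#' @param tol convergence tolerance on the coefficient update.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `binom_trend` with methods [coef()], [vcov()],
#'   [confint()], [predict()], [fitted()], [residuals()], [simulate()],
#'   [summary()] and [or_per_year()].
#' @examples
#' fit <- fit_binomial_trend(c(100, 120, 145), c(1000, 1000, 1000), 2017:2019)
#' or_per_year(fit)
#' @export
fit_binomial_trend <- function(events, trials, year, tol = 1e-10, max_iter = 50L) {
  events <- as.numeric(events); trials <- as.numeric(trials); year <- as.numeric(year)
  n <- length(events)
  if (length(trials) != n || length(year) != n)
    gestage_error("events, trials and year must have equal length", "gestage_config_error")
  if (n < 2 || length(unique(year)) < 2)
    gestage_error("need at least two distinct years", "gestage_config_error")
  if (any(trials <= 0) || any(events < 0) || any(events > trials))
    gestage_error("need 0 <= events <= trials with positive trials", "gestage_domain_error")
  if (sum(events) == 0 || sum(trials - events) == 0)
    gestage_error("all-zero events (or non-events): odds ratio is not identifiable",
                  "gestage_fit_error")

  # centre the covariate for numerical conditioning; the slope is invariant
  # and the intercept is mapped back to the calendar scale afterwards
  ctr <- mean(year)
  X <- cbind(`(Intercept)` = 1, year = year - ctr)
  # start from the empirical logit of the shrunk proportions
  mu <- (events + 0.5) / (trials + 1)
  eta <- logit(mu)
  beta <- c(0, 0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- inv_logit(eta)
    w <- trials * mu * (1 - mu)
    if (any(!is.finite(w)) || all(w < 1e-12))
      gestage_error("IRLS weights degenerate (complete separation?)", "gestage_fit_error")
    z <- eta + (events - trials * mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1],
                         error = function(e) gestage_error(
                           paste("IRLS normal equations are singular",
                                 "(complete separation or empty strata):",
                                 conditionMessage(e)),
                           "gestage_fit_error"))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (iter > 1 && delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    gestage_error(sprintf("IRLS did not converge in %d iterations (last update %.3g)",
                          max_iter, delta), "gestage_fit_error")
  mu <- inv_logit(eta)
  w <- trials * mu * (1 - mu)
  vc <- solve(t(X * w) %*% X)
  # undo the centring: eta = (a - b*ctr) + b*year
  A <- rbind(c(1, -ctr), c(0, 1))
  beta <- drop(A %*% beta)
  vc <- A %*% vc %*% t(A)
  dimnames(vc) <- list(colnames(X), colnames(X))
  dev_term <- function(y, m, mu) {
    t1 <- ifelse(y > 0, y * log(y / (m * mu)), 0)
    t2 <- ifelse(y < m, (m - y) * log((m - y) / (m * (1 - mu))), 0)
    2 * (t1 + t2)
  }
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vc, fitted = mu, linear_predictors = eta,
                 events = events, trials = trials, year = year,
                 deviance = sum(dev_term(events, trials, mu)),
                 df_residual = n - 2L, iterations = iter, converged = TRUE),
            class = "binom_trend")
}

#' @export
coef.binom_trend <- function(object, ...) object$coefficients

#' @export
vcov.binom_trend <- function(object, ...) object$vcov

#' @export
nobs.binom_trend <- function(object, ...) length(object$events)

#' @export
fitted.binom_trend <- function(object, ...) object$fitted

#' @export
confint.binom_trend <- function(object, parm = names(coef(object)), level = 0.95, ...) {
  z <- z_crit(1 - level)
  est <- coef(object)[parm]
  se <- sqrt(diag(object$vcov))[parm]
  out <- cbind(est - z * se, est + z * se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  out
}

#' Per-year odds ratio from a fitted trend
#'
#' @param object a `binom_trend` fit.
#' @param level confidence level (default 0.95).
#' @return named vector: `or`, `lower`, `upper` (Wald interval on the
#'   log-odds scale, exponentiated).
#' @export
or_per_year <- function(object, level = 0.95) {
  stopifnot(inherits(object, "binom_trend"))
  ci <- exp(confint(object, "year", level))
  c(or = unname(exp(coef(object)["year"])), lower = ci[1], upper = ci[2])
}

#' @export
predict.binom_trend <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  year <- if (is.null(newdata)) object$year else newdata$year
  eta <- coef(object)[1] + coef(object)[2] * year
  if (type == "response") inv_logit(eta) else eta
}

#' @export
residuals.binom_trend <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$events; m <- object$trials; mu <- object$fitted
  if (type == "pearson") return((y - m * mu) / sqrt(m * mu * (1 - mu)))
  t1 <- ifelse(y > 0, y * log(y / (m * mu)), 0)
  t2 <- ifelse(y < m, (m - y) * log((m - y) / (m * (1 - mu))), 0)
  sign(y - m * mu) * sqrt(2 * (t1 + t2))
}

#' @export
simulate.binom_trend <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(with_seed(seed, simulate(object, nsim)))
  as.data.frame(stats::setNames(
    lapply(seq_len(nsim), function(i)
      stats::rbinom(length(object$trials), object$trials, object$fitted)),
    paste0("sim_", seq_len(nsim))))
}

#' @export
print.binom_trend <- function(x, ...) {
  orci <- or_per_year(x)
  cat(sprintf("Aggregate binomial trend over %d years (%d-%d)\n",
              length(x$year), min(x$year), max(x$year)))
  cat(sprintf("  per-year OR %.4f (95%% CI %.4f - %.4f); deviance %.2f on %d df\n",
              orci["or"], orci["lower"], orci["upper"], x$deviance, x$df_residual))
  invisible(x)
}

#' @export
summary.binom_trend <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  zval <- coef(object) / se
  tab <- cbind(Estimate = coef(object), `Std. Error` = se, `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(coefficients = tab, or = or_per_year(object),
              deviance = object$deviance, df = object$df_residual,
              iterations = object$iterations)
  class(out) <- "summary.binom_trend"
  out
}

#' @export
print.summary.binom_trend <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nPer-year odds ratio: %.4f (95%% CI %.4f - %.4f)\n",
              x$or["or"], x$or["lower"], x$or["upper"]))
  cat(sprintf("Residual deviance %.3f on %d df; %d IRLS iterations\n",
              x$deviance, x$df, x$iterations))
  invisible(x)
}

#' Per-category gestational trend summary
#'
#' The package's main fitting interface: for one outcome category of a
#' [count_table()] (or raw yearly events/trials vectors) it computes the
#' endpoint proportions, the absolute difference in percentage points with
#' a Wald CI, the relative (percent) difference with a delta-method CI, and
#' the per-year odds ratio from the aggregate birth-weighted logistic
#' regression ([fit_binomial_trend()]).
#'
#' @param x a `count_table`, or a numeric vector of yearly event counts.
#' @param ... passed to methods.
#' @return an object of class `gestage_trend`; its fields mirror the
#'   standard published trend-table columns, and `$fit` holds the underlying
#'   `binom_trend` object.
#' @export
gestage_trend <- function(x, ...) UseMethod("gestage_trend")

#' @rdname gestage_trend
#' @param trials yearly totals matching `x`.
#' @param year calendar years matching `x`.
#' @param start_year,end_year endpoint years for the differences (default
#'   first and last year).
#' @param alpha two-sided level for all intervals (default 0.05).
#' @param category_key label for the outcome (used in printing).
#' @export
gestage_trend.default <- function(x, trials, year, start_year = min(year),
                                  end_year = max(year), alpha = 0.05,
                                  category_key = "events", ...) {
  events <- x
  if (!start_year %in% year || !end_year %in% year)
    gestage_error("start_year and end_year must be observed years", "gestage_config_error")
  if (start_year >= end_year)
    gestage_error("start_year must precede end_year", "gestage_config_error")
  i0 <- match(start_year, year); i1 <- match(end_year, year)
  p0 <- events[i0] / trials[i0]; p1 <- events[i1] / trials[i1]
  fit <- fit_binomial_trend(events, trials, year)
  structure(list(
    category_key = category_key,
    start_year = start_year, end_year = end_year,
    p_start = p0, p_end = p1,
    n_start = trials[i0], n_end = trials[i1],
    abs_diff = absolute_difference(p0, trials[i0], p1, trials[i1], alpha),
    rel_diff = relative_difference(p0, p1),
    rel_diff_ci = relative_difference_ci(p0, trials[i0], p1, trials[i1], alpha),
    or = or_per_year(fit, 1 - alpha),
    fit = fit, alpha = alpha), class = "gestage_trend")
}

#' @rdname gestage_trend
#' @param category which category of the table to model (e.g. "preterm").
#' @param stratum which stratum (default "all").
#' @export
gestage_trend.count_table <- function(x, category, stratum = "all", ...) {
  p <- percentages(x)
  p <- p[p$category == category & p$stratum == stratum, ]
  if (!nrow(p))
    gestage_error(paste("no cells for category", category, "stratum", stratum),
                  "gestage_config_error")
  p <- p[order(p$year), ]
  keep <- p$denominator > 0
  gestage_trend.default(p$count[keep], p$denominator[keep], p$year[keep],
                        category_key = category, ...)
}

#' @export
print.gestage_trend <- function(x, ...) {
  cat(sprintf("Trend for '%s', %d vs %d:\n", x$category_key, x$end_year, x$start_year))
  cat(sprintf("  %% at endpoints: %.1f -> %.1f\n",
              round_half_up(100 * x$p_start, 1), round_half_up(100 * x$p_end, 1)))
  cat(sprintf("  absolute difference %.1f pp (%.1f - %.1f)\n",
              round_half_up(x$abs_diff$estimate, 1),
              round_half_up(x$abs_diff$lower, 1), round_half_up(x$abs_diff$upper, 1)))
  cat(sprintf("  relative difference %.1f%% (%.1f - %.1f)\n",
              round_half_up(x$rel_diff, 1),
              round_half_up(x$rel_diff_ci$lower, 1), round_half_up(x$rel_diff_ci$upper, 1)))
  cat(sprintf("  per-year OR %.2f (%.2f - %.2f)\n",
              round_half_up(x$or["or"], 2), round_half_up(x$or["lower"], 2),
              round_half_up(x$or["upper"], 2)))
  invisible(x)
}

#' @export
summary.gestage_trend <- function(object, ...) {
  out <- as.data.frame(object[c("category_key", "start_year", "end_year",
                                "p_start", "p_end")])
  out$abs_diff_pp <- object$abs_diff$estimate
  out$abs_diff_lower <- object$abs_diff$lower
  out$abs_diff_upper <- object$abs_diff$upper
  out$rel_diff_pct <- object$rel_diff
  out$rel_diff_lower <- object$rel_diff_ci$lower
  out$rel_diff_upper <- object$rel_diff_ci$upper
  out$or_per_year <- object$or["or"]
  out$or_lower <- object$or["lower"]
  out$or_upper <- object$or["upper"]
  rownames(out) <- NULL
  out
}

#' @export
plot.gestage_trend <- function(x, ...) {
  f <- x$fit
  pct <- 100 * f$events / f$trials
  graphics::plot(f$year, pct, xlab = "year", ylab = "% of births",
                 main = sprintf("Trend for '%s'", x$category_key), pch = 16, ...)
  yy <- seq(min(f$year), max(f$year), length.out = 200)
  graphics::lines(yy, 100 * predict(f, data.frame(year = yy), type = "response"))
  invisible(x)
}
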