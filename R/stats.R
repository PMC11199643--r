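# Cohort-level statistics: group comparisons with a normality diagnostic,
# Bonferroni thresholding, the conductance-volume linear mixed model and
# the inter-rater ICC(2,1). Standard tests delegate to established
# routines; the ICC is computed from its two-way ANOVA decomposition so it
# stays an independent oracle.

#' Compare two groups with Student's t-test
#'
#' Two-sided t-test (paired or unpaired) with a Lilliefors
#' (Kolmogorov-Smirnov) normality diagnostic attached per group.
#'
#' @param values_a,values_b numeric samples (paired requires equal
#'   length).
#' @param paired logical.
#' @return list of class `group_comparison`: `statistic`, `p_value`,
#'   `df`, `normality` (Lilliefors p per group, `NA` when n < 5 or the
#'   sample is degenerate), `method`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  tt <- tryCatch(
    stats::t.test(values_a, values_b, paired = paired, var.equal = !paired),
    error = function(e) stop("degenerate comparison: ", conditionMessage(e)))
  lil <- function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(NA_real_)
    tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
  }
  norm <- if (paired) c(differences = lil(values_a - values_b))
          else c(a = lil(values_a), b = lil(values_b))
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), normality = norm,
                 method = tt$method,
                 n = c(length(values_a), length(values_b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, df = %.1f, p = %.4g\n", x$method, x$statistic,
              x$df, x$p_value))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests` (monotone decreasing in `n_tests`).
#' @seealso [format_significance_threshold()] for the one-significant-
#'   figure reporting convention (0.05/18 prints as "0.003").
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' @param threshold a threshold from [bonferroni_threshold()].
#' @rdname bonferroni_threshold
#' @export
format_significance_threshold <- function(threshold) {
  format(signif(threshold, 1), scientific = FALSE)
}

#' Conductance-volume linear mixed model
#'
#' REML fit of territorial conductance on territorial brain volume with
#' hemisphere class (ipsilateral / contralateral / non-stenotic) as fixed
#' factor and a random intercept per subject:
#' `conductance ~ hemisphere_class + volume_c + (1 | subject_id)`.
#' The volume covariate is grand-mean centred, so the intercept is the
#' expected conductance at the cohort's mean territorial volume. When the
#' data are degenerate (zero variance components, e.g. exactly linear
#' noise-free records) the equivalent fixed-effects least-squares fit is
#' returned, with a note.
#'
#' @param records data.frame with columns `subject_id`,
#'   `hemisphere_class`, `conductance` (ml/(mmHg s)) and `volume_ml`.
#' @param level confidence level for the Wald intervals.
#' @return list of class `cvr_lmm`: `intercept` and `volume_slope`
#'   (each with `estimate`, `ci`, `se`), `slope_p_value`, `volume_mean`,
#'   `note`, and the underlying `fit`.
#' @export
fit_conductance_volume_lmm <- function(records, level = 0.95) {
  need <- c("subject_id", "hemisphere_class", "conductance", "volume_ml")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(records$subject_id)) < 2)
    stop("need at least 2 subjects")
  if (stats::sd(records$volume_ml) == 0)
    stop("volume covariate is constant: slope is not identifiable")
  d <- records
  d$volume_c <- d$volume_ml - mean(d$volume_ml)
  use_class <- length(unique(d$hemisphere_class)) > 1
  form <- if (use_class)
    conductance ~ hemisphere_class + volume_c + (1 | subject_id)
  else conductance ~ volume_c + (1 | subject_id)

  note <- ""
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    if (anyNA(co[, "Std. Error"])) fit <- NULL
  }
  if (is.null(fit)) {
    # zero-variance degenerate data: fixed-effects fit is identical
    lmform <- if (use_class) conductance ~ hemisphere_class + volume_c
              else conductance ~ volume_c
    fit <- stats::lm(lmform, data = d)
    co <- summary(fit)$coefficients
    co <- cbind(co[, 1:2, drop = FALSE],
                df = stats::df.residual(fit),
                `t value` = co[, 3], `Pr(>|t|)` = co[, 4])
    note <- "degenerate variance components; fixed-effects least squares fit"
  } else {
    co <- summary(fit)$coefficients
  }
  z <- stats::qt(1 - (1 - level) / 2, co["volume_c", "df"])
  slope <- list(estimate = co["volume_c", "Estimate"],
                se = co["volume_c", "Std. Error"],
                ci = co["volume_c", "Estimate"] +
                  c(-1, 1) * z * co["volume_c", "Std. Error"])
  zi <- stats::qt(1 - (1 - level) / 2, co["(Intercept)", "df"])
  intercept <- list(estimate = co["(Intercept)", "Estimate"],
                    se = co["(Intercept)", "Std. Error"],
                    ci = co["(Intercept)", "Estimate"] +
                      c(-1, 1) * zi * co["(Intercept)", "Std. Error"])
  structure(list(intercept = intercept, volume_slope = slope,
                 slope_p_value = co["volume_c", "Pr(>|t|)"],
                 volume_mean = mean(records$volume_ml), note = note,
                 fit = fit),
            class = "cvr_lmm")
}

#' @export
print.cvr_lmm <- function(x, ...) {
  cat(sprintf("Conductance-volume mixed model (volume grand-mean centred at %.1f ml)\n",
              x$volume_mean))
  cat(sprintf("  intercept: %.4g ml/(mmHg s), 95%% CI [%.4g, %.4g]\n",
              x$intercept$estimate, x$intercept$ci[1], x$intercept$ci[2]))
  cat(sprintf("  volume slope: %.4g 1/(mmHg s), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$volume_slope$estimate, x$volume_slope$ci[1],
              x$volume_slope$ci[2], x$slope_p_value))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater/measurement,
#' computed from the two-way ANOVA decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with MSR the
#' between-subject, MSC the between-rater and MSE the residual mean
#' square. The confidence interval follows the standard F-based
#' construction for this form. Absolute agreement penalises a constant
#' offset between raters (MSC enters the denominator).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns;
#'   complete (no missing cells), >= 5 subjects, >= 2 raters.
#' @param level confidence level.
#' @return list of class `icc`: `value`, `ci`, `p_value` (test of
#'   ICC = 0 via F = MSR/MSE), mean squares and dimensions.
#' @export
icc_two_way_random <- function(ratings, level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings table must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters")
  m <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  mse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - level
  ci <- c(NA_real_, NA_real_)
  if (mse > 0 || msc > 0) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    ci[1] <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci[2] <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  p <- if (mse > 0) stats::pf(msr / mse, n - 1, (n - 1) * (k - 1),
                              lower.tail = FALSE) else 0
  structure(list(value = icc, ci = ci, p_value = p, msr = msr, msc = msc,
                 mse = mse, n = n, k = k, level = level),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) two-way random, absolute agreement, single rater:\n"))
  cat(sprintf("  r = %.3f, %d%% CI [%.3f, %.3f], p = %.3g (n = %d, k = %d)\n",
              x$value, round(100 * x$level), x$ci[1], x$ci[2], x$p_value,
              x$n, x$k))
  invisible(x)
}
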