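#' Per-subject percentage errors
#'
#' `100 * (predicted - actual) / actual`, the signed percentage error
#' underlying MPE (bias), MAPE and RMSPE (precision) and PW10/PW20
#' (accuracy).
#'
#' @param actual actual weights in kg, all > 0.
#' @param predicted predicted weights in kg.
#' @return numeric vector of signed percentage errors.
#' @export
percentage_errors <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("actual weights must be positive and finite", call. = FALSE)
  if (any(!is.finite(predicted)))
    stop("predicted weights must be finite", call. = FALSE)
  100 * (predicted - actual) / actual
}

#' Agreement summary for one method
#'
#' The full error-metric battery on paired actual/predicted weights:
#' mean percentage error (MPE), mean absolute percentage error (MAPE),
#' root-mean-square percentage error (RMSPE), RMSE in kg, the
#' Bland--Altman mean difference and 95% limits of agreement
#' (mean difference +/- 1.96 sd of the differences, direction
#' predicted - actual), and the proportions of estimates within 10% and
#' 20% of actual weight (PW10/PW20, boundary inclusive).
#'
#' @inheritParams percentage_errors
#' @param sd_type `"population"` (divide by n; default, which makes
#'   `rmse^2 = mean_diff^2 + sd^2` exact) or `"sample"` (divide by n-1).
#' @param z quantile for the limits of agreement (1.96 for 95%).
#' @param pw_thresholds percentage thresholds for the within-X accuracy
#'   proportions.
#' @return an `agreement_report` list: `n`, `mpe`, `mape`, `rmspe`,
#'   `rmse`, `mean_diff`, `loa_lower`, `loa_upper`, `pw` (named vector,
#'   percent).
#' @export
agreement_summary <- function(actual, predicted,
                              sd_type = c("population", "sample"),
                              z = 1.96, pw_thresholds = c(10, 20)) {
  sd_type <- match.arg(sd_type)
  if (length(actual) < 2)
    stop("need at least 2 paired observations", call. = FALSE)
  e <- percentage_errors(actual, predicted)
  d <- predicted - actual
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_type == "population") sd_d <- sd_d * sqrt((n - 1) / n)
  if (!is.finite(sd_d)) sd_d <- 0
  mean_d <- mean(d)
  pw <- vapply(pw_thresholds, function(th) 100 * mean(abs(e) <= th),
               numeric(1))
  names(pw) <- paste0("pw", pw_thresholds)
  structure(list(
    n = n,
    mpe = mean(e),
    mape = mean(abs(e)),
    rmspe = sqrt(mean(e^2)),
    rmse = sqrt(mean(d^2)),
    mean_diff = mean_d,
    loa_lower = mean_d - z * sd_d,
    loa_upper = mean_d + z * sd_d,
    pw = pw,
    sd_type = sd_type, z = z
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d)\n", x$n))
  cat(sprintf("  MPE %.2f%%  MAPE %.2f%%  RMSPE %.2f%%  RMSE %.2f kg\n",
              x$mpe, x$mape, x$rmspe, x$rmse))
  cat(sprintf("  LOA [%.2f, %.2f] kg (mean diff %.2f)\n",
              x$loa_lower, x$loa_upper, x$mean_diff))
  cat("  ", paste(sprintf("%s %.1f%%", toupper(names(x$pw)), x$pw),
                  collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct RMSE from printed limits of agreement
#'
#' Inverts the Bland--Altman construction: with limits `L`, `U` at
#' `mean +/- z * sd`, the mean difference is `(U + L)/2` and the sd is
#' `(U - L)/(2z)`; the root-mean-square difference then follows from the
#' identity `rmse^2 = mean^2 + sd^2` (population-sd convention). Lets
#' published LOA rows be checked against published RMS error cells.
#'
#' @param lower,upper limits of agreement in kg.
#' @param z the quantile used to form the limits (default 1.96).
#' @return RMSE in kg.
#' @export
rmse_from_loa <- function(lower, upper, z = 1.96) {
  if (any(upper < lower))
    stop("upper limit must be >= lower limit", call. = FALSE)
  m <- (upper + lower) / 2
  s <- (upper - lower) / (2 * z)
  sqrt(m^2 + s^2)
}

#' ICC band labels
#'
#' Classifies an intraclass correlation as poor (< 0.25), low
#' (0.25--0.49), moderate (0.50--0.69), good (0.70--0.89) or excellent
#' (>= 0.90).
#'
#' @param icc ICC value(s).
#' @return character band label(s).
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.25, 0.50, 0.70, 0.90, Inf), right = FALSE,
      labels = c("poor", "low", "moderate", "good", "excellent")) |>
    as.character()
}

#' Two-way absolute-agreement single-measures ICC
#'
#' ICC(A,1): the agreement between predicted and actual weights treated
#' as two raters over n subjects, computed from the two-way ANOVA mean
#' squares (rows = subjects, columns = methods):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2.
#' The 95% confidence interval uses the F-distribution method with
#' Satterthwaite degrees of freedom; the p-value tests ICC = 0 via
#' `F = MSR / MSE` on (n-1, (n-1)(k-1)) degrees of freedom.
#'
#' @inheritParams percentage_errors
#' @param conf_level confidence level for the interval.
#' @return an `icc_result` list: `icc`, `ci_lower`, `ci_upper`,
#'   `p_value`, `band`, `n`.
#' @export
icc_agreement <- function(actual, predicted, conf_level = 0.95) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  n <- length(actual)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  x <- cbind(actual, predicted)
  k <- 2L
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  if (stats::var(row_m) < 1e-300)
    stop("ICC undefined: no variance across subjects", call. = FALSE)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, ci_lower = lower, ci_upper = upper,
                 p_value = p, band = icc_band(icc), n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f-%.3f), p = %.3g: %s\n",
              x$icc, x$ci_lower, x$ci_upper, x$p_value, x$band))
  invisible(x)
}

#' Assign age subgroups
#'
#' Partitions ages in months into the three analysis strata: 1--12
#' months (infant), 13--71 months (includes 13--23-month-olds so the
#' partition is exhaustive), 72--155 months.
#'
#' @param age_months ages in months, all within [1, 155].
#' @return factor with levels `infant`, `middle`, `older`.
#' @export
age_subgroup <- function(age_months) {
  if (any(age_months < 1 | age_months > 155))
    stop("ages must lie in [1, 155] months", call. = FALSE)
  cut(age_months, breaks = c(0, 12, 71, 155),
      labels = c("infant", "middle", "older"))
}

#' Agreement and ICC per age subgroup
#'
#' Runs [agreement_summary()] and [icc_agreement()] on the full cohort
#' and on each age stratum.
#'
#' @param pairs data.frame with columns `actual_kg`, `predicted_kg`,
#'   `age_months`.
#' @param ... passed to [agreement_summary()].
#' @return named list (`overall`, `infant`, `middle`, `older`) of lists
#'   with elements `report` and `icc` (NULL when a stratum is too small).
#' @export
subgroup_reports <- function(pairs, ...) {
  grp <- age_subgroup(pairs$age_months)
  one <- function(sub) {
    if (nrow(sub) < 2) return(list(report = NULL, icc = NULL))
    list(report = agreement_summary(sub$actual_kg, sub$predicted_kg, ...),
         icc = if (nrow(sub) >= 5)
           icc_agreement(sub$actual_kg, sub$predicted_kg))
  }
  out <- list(overall = one(pairs))
  for (g in levels(grp)) out[[g]] <- one(pairs[grp == g, , drop = FALSE])
  out
}

#' Two-sided two-proportion sample size
#'
#' Smallest per-group n for the normal-approximation two-proportion
#' z-test: `n = (z_{a/2} sqrt(2 pbar qbar) + z_beta sqrt(p1 q1 + p2 q2))^2
#' / (p2 - p1)^2`, ceiled.
#'
#' @param p1,p2 the two proportions, distinct, in (0, 1).
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @return integer n per group.
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8) {
  if (any(c(p1, p2, alpha, power) <= 0) || any(c(p1, p2, alpha, power) >= 1))
    stop("p1, p2, alpha and power must lie in (0, 1)", call. = FALSE)
  if (p1 == p2) stop("p1 and p2 must differ", call. = FALSE)
  pbar <- (p1 + p2) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  num <- (za * sqrt(2 * pbar * (1 - pbar)) +
            zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  as.integer(ceiling(num / (p2 - p1)^2))
}

#' Bland--Altman plot
#'
#' Difference (predicted - actual) against the pair mean, with the mean
#' difference and 95% limits of agreement drawn as horizontal lines.
#'
#' @inheritParams agreement_summary
#' @param main plot title.
#' @export
bland_altman_plot <- function(actual, predicted, main = "Bland-Altman",
                              sd_type = "population", z = 1.96) {
  rep <- agreement_summary(actual, predicted, sd_type = sd_type, z = z)
  m <- (actual + predicted) / 2
  d <- predicted - actual
  graphics::plot(m, d, xlab = "Mean of actual and predicted (kg)",
                 ylab = "Predicted - actual (kg)", main = main, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::abline(h = rep$mean_diff, col = "black", lwd = 2)
  graphics::abline(h = c(rep$loa_lower, rep$loa_upper), col = "firebrick",
                   lty = 2, lwd = 2)
  invisible(rep)
}
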