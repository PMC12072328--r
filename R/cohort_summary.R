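q_iqr <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), type = 7,
                                     names = FALSE)

pct_1dp <- function(count, total) round(100 * count / total, 1)

#' Cohort characteristics table
#'
#' Median [IQR] for continuous variables (age in years, weight, height,
#' BMI = kg/m^2) and count (%) for categorical variables (sex, body
#' type), overall and per age stratum. Quantiles use the
#' linear-interpolation convention; percentages are rounded
#' half-to-even to one decimal place (raw fractions are retained in the
#' numeric columns).
#'
#' @param subjects data.frame with columns `age_months`, `sex`,
#'   `body_type`, `height_cm`, `weight_kg`.
#' @return a `cohort_summary` data.frame in long form with columns
#'   `group`, `variable`, `level`, `n`, `count`, `percent`, `median`,
#'   `q1`, `q3`.
#' @export
cohort_summary <- function(subjects) {
  if (nrow(subjects) < 1) stop("need at least one subject", call. = FALSE)
  grp <- age_subgroup(subjects$age_months)
  groups <- c(list(total = subjects),
              split(subjects, grp))
  rows <- list()
  for (g in names(groups)) {
    s <- groups[[g]]
    n <- nrow(s)
    if (n == 0) next
    cont <- list(
      age_years = s$age_months / 12,
      weight_kg = s$weight_kg,
      height_cm = s$height_cm,
      bmi = s$weight_kg / (s$height_cm / 100)^2
    )
    for (v in names(cont)) {
      q <- q_iqr(cont[[v]])
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, level = NA_character_, n = n,
        count = NA_real_, percent = NA_real_,
        median = q[1], q1 = q[2], q3 = q[3], stringsAsFactors = FALSE)
    }
    cats <- list(sex = c("male", "female"), body_type = body_types)
    for (v in names(cats)) {
      for (lev in cats[[v]]) {
        cnt <- sum(s[[v]] == lev)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, variable = v, level = lev, n = n,
          count = cnt, percent = pct_1dp(cnt, n),
          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Format a cohort summary for display
#'
#' @param x a `cohort_summary`.
#' @param ... unused.
#' @return data.frame of formatted strings, variables by group.
#' @export
format.cohort_summary <- function(x, ...) {
  x$cell <- ifelse(is.na(x$count),
                   sprintf("%.1f [%.1f-%.1f]", x$median, x$q1, x$q3),
                   sprintf("%d (%.1f)", x$count, x$percent))
  key <- ifelse(is.na(x$level), x$variable, paste(x$variable, x$level))
  wide <- stats::reshape(
    data.frame(key = key, group = x$group, cell = x$cell,
               stringsAsFactors = FALSE),
    idvar = "key", timevar = "group", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' @export
print.cohort_summary <- function(x, ...) {
  print(format(x))
  invisible(x)
}
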