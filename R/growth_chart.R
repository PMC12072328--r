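#' Body-type categories
#'
#' The three visual habitus categories used throughout the package,
#' anchored to the 25th and 75th weight-for-age percentiles:
#' thin (< 25th), normal (25th--75th inclusive), overweight (> 75th).
#'
#' @export
body_types <- c("thin", "normal", "overweight")

#' Synthetic pediatric growth reference
#'
#' Builds a sex-by-age-month growth chart with log-normal height and weight
#' distributions, parameterized by a median and a coefficient of variation
#' per cell. The median curves are smooth parametric stand-ins for a national
#' growth reference: rapid, decelerating growth in infancy followed by a
#' near-linear childhood phase, with weight coupled to height through an
#' age-varying BMI curve (high in infancy, dipping in mid-childhood, rising
#' again towards adolescence). Real reference tables with the same column
#' schema can be dropped in via [read_growth_chart()].
#'
#' @param ages integer vector of ages in months covered by the grid
#'   (default 1--155, i.e. 1 month to 12 years inclusive).
#' @return A `growth_chart`: a data.frame with columns `sex`,
#'   `age_months`, `height_median_cm`, `height_cv`, `weight_median_kg`,
#'   `weight_cv`.
#' @examples
#' chart <- growth_chart()
#' percentile_weight(chart, "male", 36, 0.5)
#' @export
growth_chart <- function(ages = 1:155) {
  ages <- sort(unique(as.integer(ages)))
  rows <- lapply(c("male", "female"), function(sex) {
    a <- ages
    h <- 51 + 24.25 * (1 - exp(-(a - 1) / 7)) + 0.55 * (a - 1)
    if (sex == "female") h <- 0.99 * h
    bmi <- 15.4 + 2.6 * exp(-a / 15) + 1.8 * (a / 155)^2
    data.frame(
      sex = sex,
      age_months = a,
      height_median_cm = h,
      height_cv = 0.035 + 0.015 * a / 155,
      weight_median_kg = bmi * (h / 100)^2,
      weight_cv = 0.11 + 0.10 * a / 155,
      stringsAsFactors = FALSE
    )
  })
  new_growth_chart(do.call(rbind, rows))
}

new_growth_chart <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("growth_chart", "data.frame")
  validate_growth_chart(df)
  df
}

validate_growth_chart <- function(chart) {
  req <- c("sex", "age_months", "height_median_cm", "height_cv",
           "weight_median_kg", "weight_cv")
  missing_cols <- setdiff(req, names(chart))
  if (length(missing_cols))
    stop("growth chart is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(c("male", "female") %in% chart$sex))
    stop("growth chart must cover both sexes", call. = FALSE)
  for (sx in unique(chart$sex)) {
    sub <- chart[chart$sex == sx, ]
    sub <- sub[order(sub$age_months), ]
    if (anyDuplicated(sub$age_months))
      stop("duplicate age rows for sex ", sx, call. = FALSE)
    if (any(diff(sub$height_median_cm) <= 0))
      stop("height medians must strictly increase with age (", sx, ")",
           call. = FALSE)
    if (any(diff(sub$weight_median_kg) <= 0))
      stop("weight medians must strictly increase with age (", sx, ")",
           call. = FALSE)
  }
  cv <- c(chart$height_cv, chart$weight_cv)
  if (any(cv <= 0 | cv >= 0.5))
    stop("coefficients of variation must lie in (0, 0.5)", call. = FALSE)
  invisible(chart)
}

#' Read or write a growth-chart CSV
#'
#' The file format is a plain UTF-8 CSV with header columns `sex`,
#' `age_months`, `height_median_cm`, `height_cv`, `weight_median_kg`,
#' `weight_cv`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `read_growth_chart()` returns a validated `growth_chart`.
#' @export
read_growth_chart <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  new_growth_chart(df)
}

#' @rdname read_growth_chart
#' @param chart a `growth_chart`.
#' @export
write_growth_chart <- function(chart, path) {
  validate_growth_chart(chart)
  utils::write.csv(as.data.frame(chart), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.growth_chart <- function(x, ...) {
  cat(sprintf("Growth chart: %d ages x %d sexes (%d-%d months)\n",
              length(unique(x$age_months)), length(unique(x$sex)),
              min(x$age_months), max(x$age_months)))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

check_sex <- function(sex) {
  if (length(sex) != 1L || !sex %in% c("male", "female"))
    stop("sex must be \"male\" or \"female\"", call. = FALSE)
  sex
}

# Interpolated (median, cv) parameters at a possibly fractional age.
chart_params <- function(chart, sex, age) {
  check_sex(sex)
  sub <- chart[chart$sex == sex, ]
  sub <- sub[order(sub$age_months), ]
  rng <- range(sub$age_months)
  if (any(age < rng[1] | age > rng[2]))
    stop(sprintf("age %s months outside chart grid [%d, %d]",
                 paste(signif(age[age < rng[1] | age > rng[2]], 4),
                       collapse = ", "), rng[1], rng[2]), call. = FALSE)
  interp <- function(col)
    stats::approx(sub$age_months, sub[[col]], xout = age)$y
  list(height_median = interp("height_median_cm"),
       height_cv = interp("height_cv"),
       weight_median = interp("weight_median_kg"),
       weight_cv = interp("weight_cv"))
}

# Quantile of a log-normal given its median and coefficient of variation.
lnorm_quantile <- function(p, median, cv) {
  stats::qlnorm(p, meanlog = log(median), sdlog = sqrt(log1p(cv^2)))
}

#' Weight-for-age percentile lookup
#'
#' Returns the `p`-quantile of the log-normal weight-for-age distribution
#' at the given sex and age. The distribution is parameterized by the chart
#' cell's median `m` and coefficient of variation `cv`:
#' `meanlog = log(m)`, `sdlog = sqrt(log(1 + cv^2))`, so the median is
#' recovered exactly at `p = 0.5`. Fractional ages interpolate the cell
#' parameters linearly.
#'
#' @param chart a `growth_chart`.
#' @param sex `"male"` or `"female"`.
#' @param age age in months; must lie within the chart grid.
#' @param p percentile as a fraction, strictly inside (0, 1).
#' @return weight in kg (vectorized over `age`/`p`).
#' @export
percentile_weight <- function(chart, sex, age, p) {
  if (any(p <= 0 | p >= 1))
    stop("percentile p must lie strictly inside (0, 1)", call. = FALSE)
  par <- chart_params(chart, sex, age)
  lnorm_quantile(p, par$weight_median, par$weight_cv)
}

#' Height-for-age percentile lookup
#'
#' Log-normal height-for-age quantile, the height analogue of
#' [percentile_weight()]; used by the synthetic cohort generator.
#'
#' @inheritParams percentile_weight
#' @return height in cm.
#' @export
percentile_height <- function(chart, sex, age, p) {
  if (any(p <= 0 | p >= 1))
    stop("percentile p must lie strictly inside (0, 1)", call. = FALSE)
  par <- chart_params(chart, sex, age)
  lnorm_quantile(p, par$height_median, par$height_cv)
}

#' Classify body type from weight-for-age
#'
#' Thin below the 25th weight-for-age percentile, overweight above the
#' 75th; both boundaries belong to "normal" (the strict inequalities
#' define the outer bands).
#'
#' @inheritParams percentile_weight
#' @param weight observed weight in kg, > 0.
#' @return one of `"thin"`, `"normal"`, `"overweight"` (vectorized).
#' @export
classify_body_type <- function(chart, sex, age, weight) {
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  q25 <- percentile_weight(chart, sex, age, 0.25)
  q75 <- percentile_weight(chart, sex, age, 0.75)
  ifelse(weight < q25, "thin", ifelse(weight > q75, "overweight", "normal"))
}

#' Weight from age and body type
#'
#' Maps a body-type band to a single representative weight-for-age
#' percentile and returns that quantile: by default the band midpoints
#' 12.5% (thin), 50% (normal) and 87.5% (overweight). This is the final
#' step of the height-based estimator: the regressor's height estimate is
#' first converted to an age equivalent, then to weight through this band.
#'
#' @inheritParams percentile_weight
#' @param body_type one of `"thin"`, `"normal"`, `"overweight"`.
#' @param band_percentiles named numeric of representative percentiles
#'   per band.
#' @return weight in kg.
#' @export
derive_weight <- function(chart, sex, age, body_type,
                          band_percentiles = c(thin = 0.125, normal = 0.5,
                                               overweight = 0.875)) {
  if (any(!body_type %in% body_types))
    stop("unknown body type: ",
         paste(setdiff(body_type, body_types), collapse = ", "),
         call. = FALSE)
  p <- unname(band_percentiles[body_type])
  percentile_weight(chart, sex, age, p)
}

#' Age equivalent of a height on the median curve
#'
#' Inverts the sex-specific median height curve by linear interpolation:
#' returns the (possibly fractional) age in months whose median height
#' equals the input. Bridges the regressor's height output to the
#' age-indexed weight lookup.
#'
#' @inheritParams percentile_weight
#' @param height height in cm; must lie within the median curve's range
#'   for that sex.
#' @return age in months (fractional).
#' @export
height_to_age <- function(chart, sex, height) {
  check_sex(sex)
  sub <- chart[chart$sex == sex, ]
  sub <- sub[order(sub$age_months), ]
  rng <- range(sub$height_median_cm)
  if (any(height < rng[1] | height > rng[2]))
    stop(sprintf(
      "height %s cm outside the median-curve range [%.1f, %.1f] for %s",
      paste(signif(height[height < rng[1] | height > rng[2]], 4),
            collapse = ", "), rng[1], rng[2], sex), call. = FALSE)
  stats::approx(sub$height_median_cm, sub$age_months, xout = height)$y
}

#' Median height at an age
#'
#' Convenience accessor for the sex-specific median height curve
#' (linearly interpolated at fractional ages).
#'
#' @inheritParams percentile_weight
#' @return height in cm.
#' @export
median_height <- function(chart, sex, age) {
  chart_params(chart, sex, age)$height_median
}
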