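test_that("percentage errors follow the signed definition", {
  expect_equal(percentage_errors(c(10, 10), c(10, 10)), c(0, 0))
  expect_equal(percentage_errors(10, 11), 10)
  expect_equal(percentage_errors(c(8, 20), c(9, 18)), c(12.5, -10))
  expect_error(percentage_errors(c(0, 1), c(1, 1)), "positive")
  expect_error(percentage_errors(1:3, 1:2), "equal length")
})

test_that("the agreement summary reproduces hand-computed metrics", {
  r <- agreement_summary(c(8, 20), c(9, 18))
  expect_equal(r$mpe, 1.25)
  expect_equal(r$mape, 11.25)
  expect_equal(r$rmspe, sqrt((12.5^2 + 10^2) / 2))
  expect_equal(r$rmse, sqrt((1^2 + 2^2) / 2))
  expect_equal(r$mean_diff, -0.5)

  perfect <- agreement_summary(c(5, 9, 30), c(5, 9, 30))
  expect_equal(perfect$mpe, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(c(perfect$loa_lower, perfect$loa_upper), c(0, 0))
  expect_equal(unname(perfect$pw), c(100, 100))
})

test_that("limits of agreement are symmetric about the mean difference", {
  withr::with_seed(40, {
    a <- runif(50, 5, 40)
    p <- a + rnorm(50, 1, 2)
  })
  r <- agreement_summary(a, p)
  expect_equal((r$loa_lower + r$loa_upper) / 2, r$mean_diff,
               tolerance = 1e-12)
})

test_that("RMSE reconstruction from LOA is the algebraic identity", {
  expect_equal(rmse_from_loa(-3, 3), 3 / 1.96, tolerance = 1e-12)
  expect_error(rmse_from_loa(2, 1), ">=")
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- runif(30, 5, 40)
      p <- a * exp(rnorm(30, 0.02, 0.1))
      r <- agreement_summary(a, p, sd_type = "population")
      expect_equal(rmse_from_loa(r$loa_lower, r$loa_upper, z = r$z),
                   r$rmse, tolerance = 1e-9)
    }
  })
})

test_that("ICC matches a brute-force ANOVA mean-squares oracle", {
  # independent oracle: explicit two-way ANOVA decomposition
  icc_oracle <- function(a, p) {
    x <- cbind(a, p); n <- nrow(x); k <- 2
    ssr <- k * sum((rowMeans(x) - mean(x))^2)
    ssc <- n * sum((colMeans(x) - mean(x))^2)
    sst <- sum((x - mean(x))^2)
    msr <- ssr / (n - 1); msc <- ssc / (k - 1)
    mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:15, 1)
      a <- runif(n, 5, 40)
      p <- a + rnorm(n, 0.5, 2)
      expect_equal(icc_agreement(a, p)$icc, icc_oracle(a, p),
                   tolerance = 1e-9)
    }
  })
  # cross-check the mean squares against stats::aov on one fixture
  withr::with_seed(43, {
    a <- runif(12, 5, 40); p <- a + rnorm(12, 1, 3)
  })
  long <- data.frame(y = c(a, p),
                     subj = factor(rep(1:12, 2)),
                     meth = factor(rep(1:2, each = 12)))
  ms <- summary(stats::aov(y ~ subj + meth, data = long))[[1]][, "Mean Sq"]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 / 12 * (ms[2] - ms[3]))
  expect_equal(icc_agreement(a, p)$icc, unname(icc_aov), tolerance = 1e-9)
})

test_that("ICC is 1 for identity, banded, and CI-ordered", {
  withr::with_seed(44, a <- runif(20, 5, 40))
  r <- icc_agreement(a, a)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  expect_identical(r$band, "excellent")
  expect_identical(icc_band(c(0.959, 0.870, 0.60, 0.30, 0.1)),
                   c("excellent", "good", "moderate", "low", "poor"))
  r2 <- icc_agreement(a, a + rnorm(20, 0, 3))
  expect_true(r2$ci_lower <= r2$icc && r2$icc <= r2$ci_upper)
  expect_error(icc_agreement(rep(3, 6), rep(3, 6)), "no variance")
  expect_error(icc_agreement(a[1:3], a[1:3]), "at least 5")
})

test_that("absolute-agreement ICC is shift/scale equivariant as claimed", {
  withr::with_seed(45, {
    a <- runif(25, 5, 40)
    p <- a + rnorm(25, 0, 2)
  })
  base <- icc_agreement(a, p)$icc
  expect_equal(icc_agreement(a + 7, p + 7)$icc, base, tolerance = 1e-9)
  expect_equal(icc_agreement(3 * a, 3 * p)$icc, base, tolerance = 1e-9)
  expect_lt(icc_agreement(a, p + 5)$icc, base)
})

test_that("age subgroups partition the cohort at the stated boundaries", {
  expect_identical(as.character(age_subgroup(c(1, 12, 13, 71, 72, 155))),
                   c("infant", "infant", "middle", "middle",
                     "older", "older"))
  expect_error(age_subgroup(0), "\\[1, 155\\]")
  pairs <- paired_fixture(n = 120)
  reps <- subgroup_reports(pairs)
  ns <- vapply(reps[c("infant", "middle", "older")],
               function(r) if (is.null(r$report)) 0L else r$report$n,
               integer(1))
  expect_equal(sum(ns), reps$overall$report$n)
})

test_that("pooled percentage errors combine as means and quadrature", {
  withr::with_seed(46, {
    a1 <- runif(40, 5, 40); p1 <- a1 * exp(rnorm(40, 0, 0.1))
    a2 <- runif(40, 5, 40); p2 <- a2 * exp(rnorm(40, 0.05, 0.1))
  })
  r1 <- agreement_summary(a1, p1)
  r2 <- agreement_summary(a2, p2)
  rall <- agreement_summary(c(a1, a2), c(p1, p2))
  expect_equal(rall$mpe, (r1$mpe + r2$mpe) / 2, tolerance = 1e-9)
  expect_equal(rall$rmspe, sqrt((r1$rmspe^2 + r2$rmspe^2) / 2),
               tolerance = 1e-9)
})

test_that("cohort summary reports medians, IQRs and 1-dp percentages", {
  # counts arranged to match known count/percentage pairs
  n <- 825
  subj <- data.frame(
    age_months = rep(36, n),
    sex = rep(c("male", "female"), c(480, 345)),
    body_type = rep("normal", n),
    height_cm = rep(95, n), weight_kg = rep(14, n),
    stringsAsFactors = FALSE)
  cs <- cohort_summary(subj)
  male <- cs[cs$group == "total" & cs$variable == "sex" &
               cs$level == "male", ]
  expect_equal(male$count, 480)
  expect_equal(male$percent, 58.2)

  one <- cohort_summary(data.frame(age_months = 24, sex = "male",
                                   body_type = "thin", height_cm = 85,
                                   weight_kg = 11))
  row <- one[one$variable == "weight_kg" & one$group == "total", ]
  expect_equal(row$median, 11)
  expect_equal(row$q1, 11)
  expect_equal(row$q3, 11)

  # median/IQR agree with a sort-based linear-interpolation oracle
  withr::with_seed(47, {
    for (m in c(9, 10)) {
      w <- runif(m, 5, 40)
      subj2 <- data.frame(age_months = rep(100, m), sex = rep("male", m),
                          body_type = rep("normal", m),
                          height_cm = rep(120, m), weight_kg = w)
      got <- cohort_summary(subj2)
      got <- got[got$variable == "weight_kg" & got$group == "total", ]
      srt <- sort(w)
      qo <- function(p) {
        hpos <- (m - 1) * p + 1
        lo <- floor(hpos); hi <- ceiling(hpos)
        srt[lo] + (hpos - lo) * (srt[hi] - srt[lo])
      }
      expect_equal(c(got$median, got$q1, got$q3),
                   c(qo(0.5), qo(0.25), qo(0.75)), tolerance = 1e-12)
    }
  })
})

test_that("two-proportion sample size is symmetric and power-monotone", {
  expect_identical(sample_size_two_proportions(0.6, 0.7), 356L)
  expect_identical(sample_size_two_proportions(0.7, 0.6),
                   sample_size_two_proportions(0.6, 0.7))
  n_lo <- sample_size_two_proportions(0.6, 0.7, power = 0.7)
  n_hi <- sample_size_two_proportions(0.6, 0.7, power = 0.9)
  expect_true(n_lo <= 356L && 356L <= n_hi)
  expect_error(sample_size_two_proportions(0.5, 0.5), "differ")
  expect_error(sample_size_two_proportions(0, 0.5), "\\(0, 1\\)")
})
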