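# Shared fixtures, built in code.

# A pose frame with chosen normalized coordinates; unspecified keypoints
# collapse onto `default_at`.
frame_at <- function(coords = list(), default_at = c(0.5, 0.5),
                     id = "fx", w = 640, h = 640) {
  kp <- data.frame(name = keypoint_names,
                   x = default_at[1], y = default_at[2],
                   confidence = 0.9, stringsAsFactors = FALSE)
  for (nm in names(coords)) {
    i <- match(nm, kp$name)
    kp$x[i] <- coords[[nm]][1]
    kp$y[i] <- coords[[nm]][2]
  }
  pose_frame(id, kp, w, h)
}

random_frame <- function(w = 640, h = 640, id = "rf") {
  kp <- data.frame(name = keypoint_names,
                   x = runif(17), y = runif(17),
                   confidence = runif(17, 0.5, 1), stringsAsFactors = FALSE)
  pose_frame(id, kp, w, h)
}

# Minimal two-age chart with hand-chosen parameters, used where a test
# needs full control of a single (sex, age) cell.
tiny_chart <- function(medians = c(15, 16), cv = 0.12) {
  df <- expand.grid(sex = c("male", "female"), age_months = c(36L, 48L),
                    stringsAsFactors = FALSE)
  df <- df[order(df$sex, df$age_months), ]
  df$height_median_cm <- rep(c(95, 102), 2)
  df$height_cv <- 0.04
  df$weight_median_kg <- rep(medians, 2)
  df$weight_cv <- cv
  pedipose:::new_growth_chart(df)
}

# Paired-weights fixture with known subgroup structure.
paired_fixture <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    age <- sample(1:155, n, replace = TRUE)
    actual <- runif(n, 5, 40)
    data.frame(id = seq_len(n), age_months = age, actual_kg = actual,
               predicted_kg = actual * exp(rnorm(n, 0, 0.1)))
  })
}
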