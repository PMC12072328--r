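# Age strata (months): infants, preschool, school-age.
age_strata <- list(infant = c(1L, 12L), middle = c(13L, 71L),
                   older = c(72L, 155L))

with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Sample a synthetic pediatric cohort
#'
#' Draws subjects with the age mix of a pediatric emergency cohort
#' (three strata: 1--12 months, 13--71 months, 72--155 months), sex
#' balanced, and a latent habitus percentile driving correlated height
#' and weight through the growth chart. Height is the chart height
#' quantile at the latent percentile; weight is the chart weight quantile
#' at a percentile coupled to the latent one through a Gaussian copula
#' with rank correlation `rank_rho`. Body type is the chart
#' classification of the sampled weight, optionally flipped to an
#' adjacent category to emulate assessor error.
#'
#' @param n number of subjects.
#' @param chart a `growth_chart`.
#' @param age_mix three fractions (infant, middle, older) summing to 1;
#'   default matches a 150/825/360 enrollment out of 1335.
#' @param assessor_error_rate probability that the recorded body type is
#'   flipped to an adjacent category.
#' @param rank_rho Spearman rank correlation between the height and
#'   weight percentiles (default 0.7).
#' @param seed integer seed; the cohort is byte-identical across calls
#'   with the same seed.
#' @return a `synthetic_cohort` data.frame: `id`, `age_months`, `sex`,
#'   `latent_percentile`, `body_type`, `height_cm`, `weight_kg`.
#' @export
sample_cohort <- function(n, chart = growth_chart(),
                          age_mix = c(150, 825, 360) / 1335,
                          assessor_error_rate = 0.15, rank_rho = 0.7,
                          seed = NULL) {
  if (length(n) != 1L || n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(age_mix) != 3L || any(age_mix < 0) ||
      abs(sum(age_mix) - 1) > 1e-8)
    stop("age_mix must be three non-negative fractions summing to 1",
         call. = FALSE)
  if (assessor_error_rate < 0 || assessor_error_rate > 1)
    stop("assessor_error_rate must lie in [0, 1]", call. = FALSE)
  with_seed_(seed, {
    stratum <- sample.int(3L, n, replace = TRUE, prob = age_mix)
    age <- vapply(stratum, function(s) {
      rng <- age_strata[[s]]
      as.integer(sample(seq(rng[1], rng[2]), 1L))
    }, integer(1))
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    latent <- stats::runif(n, 0.02, 0.98)
    # Gaussian copula: convert rank (Spearman) to Pearson correlation.
    r <- 2 * sin(pi * rank_rho / 6)
    z1 <- stats::qnorm(latent)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    wp <- pmin(0.999, pmax(0.001, stats::pnorm(z2)))
    height <- vapply(seq_len(n), function(i)
      percentile_height(chart, sex[i], age[i], latent[i]), numeric(1))
    weight <- vapply(seq_len(n), function(i)
      percentile_weight(chart, sex[i], age[i], wp[i]), numeric(1))
    bt <- vapply(seq_len(n), function(i)
      classify_body_type(chart, sex[i], age[i], weight[i]), character(1))
    flip <- stats::runif(n) < assessor_error_rate
    if (any(flip)) {
      bt[flip] <- vapply(bt[flip], function(b) {
        switch(b,
               thin = "normal",
               overweight = "normal",
               normal = sample(c("thin", "overweight"), 1L))
      }, character(1))
    }
    out <- data.frame(
      id = sprintf("S%05d", seq_len(n)),
      age_months = age, sex = sex,
      latent_percentile = latent, body_type = bt,
      height_cm = height, weight_kg = weight,
      stringsAsFactors = FALSE
    )
    class(out) <- c("synthetic_cohort", "data.frame")
    out
  })
}

#' Age-dependent pose template
#'
#' Body-segment lengths as proportions of stature for a stick-figure
#' layout of the 17 canonical keypoints. Head share shrinks from about
#' 1/4 of stature in early infancy to about 1/7 at 12 years (linear in
#' log-age), and the leg share of the remaining stature grows with age;
#' the vertical chain head + trunk + thigh + shank sums to exactly 1 so
#' the crown-to-ankle span equals stature. Width proportions (shoulder,
#' hip, arm segments) are fixed. The crown of the head is placed at the
#' nose keypoint so that the nose-to-ankle span measures stature.
#'
#' @param age_months age in months, 1--155.
#' @return a `pose_template` list of proportions.
#' @export
pose_template <- function(age_months) {
  if (age_months < 1 || age_months > 155)
    stop("age_months must lie in [1, 155]", call. = FALSE)
  f <- log(age_months) / log(155)       # 0 at 1 month, 1 at 155 months
  head <- 0.25 - (0.25 - 1 / 7) * f
  rest <- 1 - head
  leg <- rest * (0.50 + 0.08 * f)
  trunk <- rest - leg
  tpl <- list(
    head = head, trunk = trunk, thigh = leg / 2, shank = leg / 2,
    upper_arm = 0.16, forearm = 0.13,
    shoulder_width = 0.20, hip_width = 0.15,
    # head-feature offsets as fractions of head height
    eye_dx = 0.15, eye_dy = 0.30, ear_dx = 0.25, ear_dy = 0.35
  )
  stopifnot(abs(tpl$head + tpl$trunk + tpl$thigh + tpl$shank - 1) < 1e-12)
  class(tpl) <- "pose_template"
  tpl
}

#' Capture configuration for the pose renderer
#'
#' Noise model for the photographic capture: a global log-normal scale
#' jitter (monocular distance ambiguity), a small in-plane rotation,
#' translation jitter, and iid Gaussian pixel noise per landmark.
#'
#' @param pixels_per_cm nominal image scale.
#' @param scale_jitter_sd sd of the log scale factor (fraction).
#' @param rotation_sd sd of the in-plane rotation, degrees.
#' @param landmark_noise_sd per-coordinate Gaussian noise, pixels.
#' @param translation_jitter half-width of the uniform figure-center
#'   offset, as a fraction of each image dimension.
#' @param image_width,image_height image size in pixels.
#' @param seed integer seed used by [make_dataset()].
#' @return a `capture_config` list.
#' @export
capture_config <- function(pixels_per_cm = 5, scale_jitter_sd = 0.08,
                           rotation_sd = 3, landmark_noise_sd = 3,
                           translation_jitter = 0.03,
                           image_width = 768, image_height = 1024,
                           seed = NULL) {
  cfg <- list(pixels_per_cm = pixels_per_cm,
              scale_jitter_sd = scale_jitter_sd,
              rotation_sd = rotation_sd,
              landmark_noise_sd = landmark_noise_sd,
              translation_jitter = translation_jitter,
              image_width = image_width, image_height = image_height,
              seed = seed)
  if (pixels_per_cm <= 0) stop("pixels_per_cm must be > 0", call. = FALSE)
  if (any(unlist(cfg[c("scale_jitter_sd", "rotation_sd",
                       "landmark_noise_sd", "translation_jitter")]) < 0))
    stop("noise scales must be >= 0", call. = FALSE)
  class(cfg) <- "capture_config"
  cfg
}

# 17 x 2 matrix of keypoint positions in cm, crown at (0, 0), y downward.
skeleton_points_cm <- function(height_cm, tpl) {
  h <- tpl$head * height_cm
  trunk_y <- (tpl$head + tpl$trunk) * height_cm
  knee_y <- trunk_y + tpl$thigh * height_cm
  sw <- tpl$shoulder_width * height_cm / 2
  hw <- tpl$hip_width * height_cm / 2
  ua <- tpl$upper_arm * height_cm
  fa <- tpl$forearm * height_cm
  pts <- rbind(
    nose = c(0, 0),
    left_eye = c(-tpl$eye_dx * h, tpl$eye_dy * h),
    right_eye = c(tpl$eye_dx * h, tpl$eye_dy * h),
    left_ear = c(-tpl$ear_dx * h, tpl$ear_dy * h),
    right_ear = c(tpl$ear_dx * h, tpl$ear_dy * h),
    left_shoulder = c(-sw, h),
    right_shoulder = c(sw, h),
    left_elbow = c(-sw - 0.02 * height_cm, h + ua),
    right_elbow = c(sw + 0.02 * height_cm, h + ua),
    left_wrist = c(-sw - 0.03 * height_cm, h + ua + fa),
    right_wrist = c(sw + 0.03 * height_cm, h + ua + fa),
    left_hip = c(-hw, trunk_y),
    right_hip = c(hw, trunk_y),
    left_knee = c(-hw, knee_y),
    right_knee = c(hw, knee_y),
    left_ankle = c(-hw, height_cm),
    right_ankle = c(hw, height_cm)
  )
  pts[keypoint_names, , drop = FALSE]
}

#' Render a noisy pose frame for one subject
#'
#' Places the 17 keypoints from the age-dependent segment proportions,
#' scales them to stature times `pixels_per_cm` times a log-normal jitter
#' factor, applies a small random rotation about the figure centroid and a
#' translation towards the image center, then adds iid Gaussian pixel noise
#' and assigns confidences. Keypoints pushed outside the image by noise are
#' clamped to the border and flagged with low confidence. Before noise the
#' crown(nose)-to-ankle pixel distance equals stature times the effective
#' scale. Uses the current RNG state; seed at the dataset level via
#' [make_dataset()] or [withr::with_seed()].
#'
#' @param subject one row of a [sample_cohort()] data.frame (or any list
#'   with `id`, `age_months`, `height_cm`).
#' @param template a `pose_template`; defaults to the subject's age.
#' @param cfg a `capture_config`.
#' @return a normalized `pose_frame`.
#' @export
render_pose <- function(subject, template = NULL, cfg = capture_config()) {
  if (is.null(template)) template <- pose_template(subject$age_months)
  pts <- skeleton_points_cm(subject$height_cm, template)
  scale <- cfg$pixels_per_cm *
    exp(stats::rnorm(1, 0, cfg$scale_jitter_sd))
  pts <- pts * scale
  theta <- stats::rnorm(1, 0, cfg$rotation_sd) * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr) %*% rot
  target <- c(cfg$image_width / 2, cfg$image_height / 2) +
    stats::runif(2, -cfg$translation_jitter, cfg$translation_jitter) *
    c(cfg$image_width, cfg$image_height)
  pts <- sweep(pts, 2, target, "+")
  if (cfg$landmark_noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, cfg$landmark_noise_sd),
                        ncol = 2)
  clamped <- pts[, 1] < 0 | pts[, 1] > cfg$image_width |
    pts[, 2] < 0 | pts[, 2] > cfg$image_height
  pts[, 1] <- pmin(cfg$image_width, pmax(0, pts[, 1]))
  pts[, 2] <- pmin(cfg$image_height, pmax(0, pts[, 2]))
  conf <- stats::runif(nrow(pts), 0.6, 0.99)
  conf[clamped] <- stats::runif(sum(clamped), 0.1, 0.3)
  kp <- data.frame(name = rownames(pts), x = pts[, 1], y = pts[, 2],
                   confidence = conf, stringsAsFactors = FALSE)
  normalize_keypoints(kp, cfg$image_width, cfg$image_height,
                      id = subject$id)
}

#' Generate and write a synthetic dataset
#'
#' Samples a cohort, renders one pose frame per subject, and writes the
#' pose CSV (`poses.csv`: id, image dims, then `kp_<name>_x/_y/_conf` in
#' normalized coordinates), the subject metadata CSV (`subjects.csv`) and
#' a JSON manifest recording the seed, stratum counts and file hashes.
#' Each CSV carries the seed in a leading `#` comment line.
#'
#' @inheritParams sample_cohort
#' @param cfg a `capture_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the cohort, frames and manifest.
#' @export
make_dataset <- function(n, chart = growth_chart(), cfg = capture_config(),
                         out_dir, seed = 1,
                         age_mix = c(150, 825, 360) / 1335,
                         assessor_error_rate = 0.15, rank_rho = 0.7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- sample_cohort(n, chart, age_mix, assessor_error_rate,
                          rank_rho, seed = seed)
  frames <- with_seed_(seed + 1L, lapply(seq_len(n), function(i)
    render_pose(cohort[i, ], cfg = cfg)))
  pose_path <- file.path(out_dir, "poses.csv")
  subj_path <- file.path(out_dir, "subjects.csv")
  write_pose_frames(frames, pose_path, seed = seed)
  write_header_csv(as.data.frame(cohort)[, c("id", "age_months", "sex",
                                             "body_type", "height_cm",
                                             "weight_kg")],
                   subj_path, seed = seed)
  manifest <- list(
    seed = seed, n = n,
    stratum_counts = as.list(table(cut(cohort$age_months,
                                       c(0, 12, 71, 155),
                                       labels = names(age_strata)))),
    files = as.list(tools::md5sum(c(pose_path, subj_path)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, frames = frames, manifest = manifest))
}

write_header_csv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write or read pose frames as CSV
#'
#' Wide schema: `id`, `image_w`, `image_h`, then `kp_<name>_x`,
#' `kp_<name>_y`, `kp_<name>_conf` for each canonical keypoint, in
#' normalized coordinates.
#'
#' @param frames list of `pose_frame` objects.
#' @param path file path.
#' @param seed optional seed recorded in a leading comment line.
#' @export
write_pose_frames <- function(frames, path, seed = NULL) {
  rows <- lapply(frames, function(f) {
    kp <- f$keypoints
    vals <- c(rbind(kp$x, kp$y, kp$confidence))
    nm <- as.vector(rbind(paste0("kp_", kp$name, "_x"),
                          paste0("kp_", kp$name, "_y"),
                          paste0("kp_", kp$name, "_conf")))
    out <- data.frame(id = f$id, image_w = f$image_width,
                      image_h = f$image_height, stringsAsFactors = FALSE)
    out[nm] <- as.list(vals)
    out
  })
  write_header_csv(do.call(rbind, rows), path, seed = seed)
}

#' @rdname write_pose_frames
#' @export
read_pose_frames <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    kp <- data.frame(
      name = keypoint_names,
      x = as.numeric(r[paste0("kp_", keypoint_names, "_x")]),
      y = as.numeric(r[paste0("kp_", keypoint_names, "_y")]),
      confidence = as.numeric(r[paste0("kp_", keypoint_names, "_conf")]),
      stringsAsFactors = FALSE
    )
    pose_frame(r$id, kp, r$image_w, r$image_h)
  })
}

#' Read a subject metadata CSV
#'
#' @param path file written by [make_dataset()].
#' @export
read_subjects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
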