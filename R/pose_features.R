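#' Canonical keypoint names
#'
#' The 17 named body landmarks emitted by standard human pose-estimation
#' models, in canonical order.
#'
#' @export
keypoint_names <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' Skeletal edge set
#'
#' The fixed, ordered list of anatomically connected keypoint pairs whose
#' Euclidean distances form the pose part of the feature vector. The
#' default is the canonical 16-edge skeleton over the 17 landmarks. The
#' order is part of the feature schema and must not change between
#' training and inference.
#'
#' @param pairs optional data.frame with columns `a`, `b` naming keypoint
#'   pairs; defaults to the canonical 16 edges.
#' @return a `skeleton_edges` data.frame with columns `a`, `b`.
#' @export
skeleton_edges <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(
      a = c("nose", "nose", "left_eye", "right_eye", "left_shoulder",
            "left_shoulder", "left_elbow", "right_shoulder", "right_elbow",
            "left_shoulder", "right_shoulder", "left_hip", "left_hip",
            "left_knee", "right_hip", "right_knee"),
      b = c("left_eye", "right_eye", "left_ear", "right_ear",
            "right_shoulder", "left_elbow", "left_wrist", "right_elbow",
            "right_wrist", "left_hip", "right_hip", "right_hip",
            "left_knee", "left_ankle", "right_knee", "right_ankle"),
      stringsAsFactors = FALSE
    )
  }
  bad <- setdiff(c(pairs$a, pairs$b), keypoint_names)
  if (length(bad))
    stop("edge references unknown keypoints: ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
  if (anyDuplicated(key)) stop("duplicate edges in edge set", call. = FALSE)
  class(pairs) <- c("skeleton_edges", "data.frame")
  pairs
}

#' Read a skeletal edge set from CSV
#'
#' @param path CSV with header columns `a`, `b`.
#' @export
read_skeleton_edges <- function(path) {
  skeleton_edges(utils::read.csv(path, stringsAsFactors = FALSE,
                                 comment.char = "#"))
}

#' Pose frame constructor
#'
#' One subject photo's worth of pose data: the 17 canonical keypoints in
#' normalized image coordinates (x and y in `[0, 1]`, each divided by the
#' image dimension) with per-point confidences.
#'
#' @param id subject identifier.
#' @param keypoints data.frame with columns `name`, `x`, `y`, `confidence`;
#'   all 17 canonical names exactly once, coordinates already normalized.
#' @param image_width,image_height source image dimensions in pixels.
#' @return a `pose_frame`.
#' @export
pose_frame <- function(id, keypoints, image_width, image_height) {
  req <- c("name", "x", "y", "confidence")
  if (!all(req %in% names(keypoints)))
    stop("keypoints need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  missing_kp <- setdiff(keypoint_names, keypoints$name)
  extra_kp <- setdiff(keypoints$name, keypoint_names)
  if (length(missing_kp) || length(extra_kp) ||
      nrow(keypoints) != length(keypoint_names))
    stop("pose frame must contain each of the 17 canonical keypoints ",
         "exactly once",
         if (length(missing_kp)) paste0(" (missing: ",
                                        paste(missing_kp, collapse = ", "), ")"),
         call. = FALSE)
  if (image_width <= 0 || image_height <= 0)
    stop("image dimensions must be positive", call. = FALSE)
  keypoints <- keypoints[match(keypoint_names, keypoints$name),
                         req, drop = FALSE]
  if (any(keypoints$x < 0 | keypoints$x > 1 |
          keypoints$y < 0 | keypoints$y > 1))
    stop("normalized coordinates must lie in [0, 1]", call. = FALSE)
  rownames(keypoints) <- NULL
  structure(list(id = as.character(id), keypoints = keypoints,
                 image_width = image_width, image_height = image_height),
            class = "pose_frame")
}

#' @export
print.pose_frame <- function(x, ...) {
  cat(sprintf("Pose frame %s (%d x %d px), 17 keypoints\n",
              x$id, x$image_width, x$image_height))
  invisible(x)
}

#' Normalize raw pixel keypoints into a pose frame
#'
#' Divides pixel coordinates by the image dimensions and clamps to
#' `[0, 1]`. Applying it to an already-normalized `pose_frame` is the
#' identity, so the operation is idempotent.
#'
#' @param keypoints data.frame with columns `name`, `x`, `y`, `confidence`
#'   in pixel units, or an existing `pose_frame`.
#' @param image_width,image_height image dimensions in pixels (ignored for
#'   a `pose_frame` input).
#' @param id subject identifier.
#' @return a `pose_frame` with coordinates in `[0, 1]`.
#' @export
normalize_keypoints <- function(keypoints, image_width = NULL,
                                image_height = NULL, id = "subject") {
  if (inherits(keypoints, "pose_frame")) return(keypoints)
  if (is.null(image_width) || is.null(image_height))
    stop("image_width and image_height are required for raw keypoints",
         call. = FALSE)
  kp <- keypoints
  kp$x <- pmin(1, pmax(0, kp$x / image_width))
  kp$y <- pmin(1, pmax(0, kp$y / image_height))
  pose_frame(id, kp, image_width, image_height)
}

#' Skeletal edge distances
#'
#' Euclidean distances between the normalized coordinates of each
#' anatomically connected keypoint pair, in the fixed order of the edge
#' set. Distances are in normalized-coordinate units (dimensionless).
#'
#' @param frame a `pose_frame`.
#' @param edges a `skeleton_edges` set (default: the canonical 16).
#' @return named numeric vector, one distance per edge, names
#'   `d_<a>_<b>`.
#' @export
edge_distances <- function(frame, edges = skeleton_edges()) {
  if (!inherits(frame, "pose_frame"))
    stop("frame must be a pose_frame (see normalize_keypoints())",
         call. = FALSE)
  kp <- frame$keypoints
  ia <- match(edges$a, kp$name)
  ib <- match(edges$b, kp$name)
  d <- sqrt((kp$x[ia] - kp$x[ib])^2 + (kp$y[ia] - kp$y[ib])^2)
  names(d) <- paste0("d_", edges$a, "_", edges$b)
  d
}

#' Encode demographic metadata
#'
#' Fixed 5-element encoding: sex (male 0, female 1), age scaled by the
#' maximum enrollable age of 155 months, and a one-hot body-type triple
#' (thin, normal, overweight).
#'
#' @param sex `"male"` or `"female"`.
#' @param age_months age in months, 1--155.
#' @param body_type one of [body_types].
#' @return named numeric vector of length 5.
#' @export
encode_metadata <- function(sex, age_months, body_type) {
  check_sex(sex)
  if (length(age_months) != 1L || age_months < 1 || age_months > 155)
    stop("age_months must lie in [1, 155]", call. = FALSE)
  if (!body_type %in% body_types)
    stop("unknown body type: ", body_type, call. = FALSE)
  c(sex = as.numeric(sex == "female"),
    age_scaled = age_months / 155,
    bt_thin = as.numeric(body_type == "thin"),
    bt_normal = as.numeric(body_type == "normal"),
    bt_overweight = as.numeric(body_type == "overweight"))
}

#' Build the length-21 feature vector
#'
#' Concatenates the 16 skeletal edge distances with the 5 encoded metadata
#' values, in that fixed order. This is the exact input schema of the
#' weight regressor.
#'
#' @inheritParams edge_distances
#' @inheritParams encode_metadata
#' @return named numeric vector of length 21.
#' @export
build_features <- function(frame, sex, age_months, body_type,
                           edges = skeleton_edges()) {
  c(edge_distances(frame, edges), encode_metadata(sex, age_months, body_type))
}

#' Feature matrix for a cohort
#'
#' Applies [build_features()] across a list of pose frames and their
#' matching subject metadata rows (matched by `id`).
#'
#' @param frames list of `pose_frame` objects.
#' @param subjects data.frame with columns `id`, `sex`, `age_months`,
#'   `body_type`.
#' @param edges a `skeleton_edges` set.
#' @return numeric matrix, one row per subject, 21 named columns;
#'   rownames are subject ids.
#' @export
feature_matrix <- function(frames, subjects, edges = skeleton_edges()) {
  ids <- vapply(frames, function(f) f$id, character(1))
  idx <- match(ids, subjects$id)
  if (anyNA(idx))
    stop("pose frames without matching subject metadata: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_along(frames), function(i) {
    s <- subjects[idx[i], ]
    build_features(frames[[i]], s$sex, s$age_months, s$body_type, edges)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  x
}

#' Write or read a feature matrix CSV
#'
#' @param x feature matrix from [feature_matrix()].
#' @param path file path.
#' @export
write_features <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#")
  x <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(x) <- df$id
  x
}
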