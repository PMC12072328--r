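#' Regressor hyperparameters
#'
#' Configuration of the feedforward weight/height regressor: two hidden
#' layers of 256 and 128 rectified-linear units, a linear output, dropout
#' 0.1 on the hidden layers, mean-squared-error loss minimized with Adam
#' at learning rate 0.001, batches of 16, at most 200 epochs with early
#' stopping on validation loss (patience 20 epochs, best weights
#' restored), He-normal initialization, and an 80:20 train--validation
#' split.
#'
#' @param hidden_units integer vector of hidden-layer widths.
#' @param dropout_rate hidden-layer dropout probability during training.
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param split_fraction training fraction of the 80:20 split.
#' @param patience early-stopping patience in epochs.
#' @param restore_best return the parameters of the epoch with minimum
#'   validation loss (default) rather than the final epoch's.
#' @param seed integer seed; training is deterministic given the seed.
#' @param target `"height_cm"` (default: height regression, weight
#'   derived through the growth chart) or `"weight_kg"` (direct weight
#'   regression).
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(hidden_units = c(256L, 128L), dropout_rate = 0.1,
                       learning_rate = 0.001, epochs = 200L,
                       batch_size = 16L, split_fraction = 0.8,
                       patience = 20L, restore_best = TRUE, seed = 1L,
                       target = c("height_cm", "weight_kg")) {
  target <- match.arg(target)
  if (any(hidden_units < 1) || learning_rate <= 0 || epochs < 1 ||
      batch_size < 1 || patience < 1)
    stop("all hyperparameters must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction,
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed), target = target),
            class = "mlp_config")
}

#' Shuffled train--validation split
#'
#' Random permutation split with the floor convention for the training
#' size, so 278 records at fraction 0.8 give exactly 222 training and 56
#' validation cases. Indices are disjoint and exhaustive.
#'
#' @param n number of records.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed; the split is identical across calls with the
#'   same seed.
#' @return list with integer vectors `train` and `validation`.
#' @export
split_dataset <- function(n, fraction = 0.8, seed = 1L) {
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty partition for n = ", n, call. = FALSE)
  idx <- with_seed_(seed, sample.int(n))
  list(train = idx[seq_len(n_train)], validation = idx[-seq_len(n_train)])
}

relu <- function(x) x * (x > 0)

he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
         fan_in, fan_out)
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    state[[k]]$m <- b1 * state[[k]]$m + (1 - b1) * grads[[k]]
    state[[k]]$v <- b2 * state[[k]]$v + (1 - b2) * grads[[k]]^2
    mhat <- state[[k]]$m / (1 - b1^t)
    vhat <- state[[k]]$v / (1 - b2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

mlp_forward <- function(params, x) {
  h1 <- relu(sweep(x %*% params$W1, 2, params$b1, "+"))
  h2 <- relu(sweep(h1 %*% params$W2, 2, params$b2, "+"))
  drop(h2 %*% params$W3 + params$b3)
}

#' Train the feedforward regressor
#'
#' Minimizes mean-squared error over the specified architecture with
#' Adam, minibatches, inverted dropout on the hidden layers, early
#' stopping on validation loss and restoration of the best-epoch
#' weights. Features and targets are z-standardized internally (the
#' standardization constants are stored in the model and undone at
#' prediction time); the reported per-epoch losses are on the original
#' target scale. Training is deterministic given `cfg$seed`.
#'
#' @param x numeric feature matrix (n x 21 for the standard schema; any
#'   width is accepted and recorded).
#' @param y numeric target vector (height in cm or weight in kg,
#'   matching `cfg$target`).
#' @param cfg an [mlp_config()].
#' @return an `mlp_model` with elements `params`, `scaling`,
#'   `feature_names`, `config`, and `report` (per-epoch train/validation
#'   loss, split sizes, best and stopping epoch, seed).
#' @export
mlp_train <- function(x, y, cfg = mlp_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 records to train", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("features and targets must be finite", call. = FALSE)
  sp <- split_dataset(nrow(x), cfg$split_fraction, cfg$seed)

  xc <- colMeans(x[sp$train, , drop = FALSE])
  xs <- apply(x[sp$train, , drop = FALSE], 2, stats::sd)
  xs[xs < 1e-12] <- 1
  yc <- mean(y[sp$train])
  ys <- stats::sd(y[sp$train])
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  xz <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yz <- (y - yc) / ys
  xtr <- xz[sp$train, , drop = FALSE]
  ytr <- yz[sp$train]
  xva <- xz[sp$validation, , drop = FALSE]
  yva <- yz[sp$validation]

  d <- ncol(x)
  h <- cfg$hidden_units
  keep <- 1 - cfg$dropout_rate

  with_seed_(cfg$seed, {
    params <- list(W1 = he_init(d, h[1]), b1 = rep(0, h[1]),
                   W2 = he_init(h[1], h[2]), b2 = rep(0, h[2]),
                   W3 = he_init(h[2], 1L), b3 = 0)
    opt <- adam_new(params)
    t <- 0L
    best <- list(val = Inf, epoch = 0L, params = params)
    wait <- 0L
    tr_loss <- va_loss <- numeric(0)
    n_tr <- nrow(xtr)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      for (s in starts) {
        ib <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
        xb <- xtr[ib, , drop = FALSE]
        yb <- ytr[ib]
        m <- length(ib)

        a1 <- sweep(xb %*% params$W1, 2, params$b1, "+")
        h1 <- relu(a1)
        if (keep < 1) {
          m1 <- matrix(stats::runif(m * h[1]) < keep, m, h[1]) / keep
          h1 <- h1 * m1
        }
        a2 <- sweep(h1 %*% params$W2, 2, params$b2, "+")
        h2 <- relu(a2)
        if (keep < 1) {
          m2 <- matrix(stats::runif(m * h[2]) < keep, m, h[2]) / keep
          h2 <- h2 * m2
        }
        pred <- drop(h2 %*% params$W3 + params$b3)

        # MSE gradient
        dout <- matrix(2 * (pred - yb) / m, ncol = 1)
        gW3 <- crossprod(h2, dout)
        gb3 <- sum(dout)
        dh2 <- dout %*% t(params$W3)
        if (keep < 1) dh2 <- dh2 * m2
        dh2 <- dh2 * (a2 > 0)
        gW2 <- crossprod(h1, dh2)
        gb2 <- colSums(dh2)
        dh1 <- dh2 %*% t(params$W2)
        if (keep < 1) dh1 <- dh1 * m1
        dh1 <- dh1 * (a1 > 0)
        gW1 <- crossprod(xb, dh1)
        gb1 <- colSums(dh1)

        t <- t + 1L
        st <- adam_step(params,
                        list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                             W3 = gW3, b3 = gb3),
                        opt, cfg$learning_rate, t)
        params <- st$params
        opt <- st$state
      }
      ptr <- mlp_forward(params, xtr)
      pva <- mlp_forward(params, xva)
      ltr <- mean((ptr - ytr)^2) * ys^2
      lva <- mean((pva - yva)^2) * ys^2
      if (!is.finite(ltr) || !is.finite(lva))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      tr_loss <- c(tr_loss, ltr)
      va_loss <- c(va_loss, lva)
      if (lva < best$val - 1e-12) {
        best <- list(val = lva, epoch = epoch, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    report <- list(train_loss = tr_loss, val_loss = va_loss,
                   best_epoch = best$epoch, stopped_epoch = length(tr_loss),
                   best_val_loss = best$val,
                   n_train = length(sp$train),
                   n_validation = length(sp$validation),
                   split = sp, seed = cfg$seed)
    structure(list(params = if (cfg$restore_best) best$params else params,
                   scaling = list(x_center = xc, x_scale = xs,
                                  y_center = yc, y_scale = ys),
                   feature_names = colnames(x),
                   config = cfg, report = report),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  h <- x$config$hidden_units
  cat(sprintf(
    "Feedforward regressor %d-%d-%d-1 (target %s)\n", length(x$scaling$x_center),
    h[1], h[2], x$config$target))
  cat(sprintf("  trained %d epochs, best epoch %d, val MSE %.4g\n",
              x$report$stopped_epoch, x$report$best_epoch,
              x$report$best_val_loss))
  invisible(x)
}

#' Predict from a trained regressor
#'
#' Deterministic inference: dropout is disabled, the stored feature
#' standardization is applied, and the output is mapped back to the
#' original target scale. Column names, when present on both the model
#' and the input, are verified against the training schema.
#'
#' @param object an `mlp_model`.
#' @param newdata numeric vector of one feature row, or a matrix.
#' @param ... unused.
#' @return numeric vector of predictions (cm or kg per the configured
#'   target).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  d <- length(object$scaling$x_center)
  if (ncol(newdata) != d)
    stop("expected ", d, " features, got ", ncol(newdata), call. = FALSE)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature column order does not match the training schema",
         call. = FALSE)
  xz <- sweep(sweep(as.matrix(newdata), 2, object$scaling$x_center),
              2, object$scaling$x_scale, "/")
  drop(mlp_forward(object$params, xz)) * object$scaling$y_scale +
    object$scaling$y_center
}

#' End-to-end height and weight estimate for one subject
#'
#' Builds the feature vector from the pose frame and metadata, predicts
#' with the trained regressor, and converts between height and weight
#' through the growth chart. In the default height-target mode the
#' predicted height is mapped to its median-curve age equivalent and the
#' weight is the body-type band quantile at that age; in direct
#' weight-target mode the prediction is the weight and the reported
#' height is the chart inverse of that weight. A prediction outside the
#' chart's median range raises an error that carries the raw prediction
#' in its message.
#'
#' @param model a trained `mlp_model`.
#' @param frame the subject's `pose_frame`.
#' @param sex,age_months,body_type subject metadata.
#' @param chart a `growth_chart`.
#' @param edges the `skeleton_edges` used at training time.
#' @param band_percentiles passed to [derive_weight()].
#' @return list with `height_cm` and `weight_kg`.
#' @export
estimate_weight <- function(model, frame, sex, age_months, body_type,
                            chart = growth_chart(),
                            edges = skeleton_edges(),
                            band_percentiles = c(thin = 0.125, normal = 0.5,
                                                 overweight = 0.875)) {
  feats <- build_features(frame, sex, age_months, body_type, edges)
  pred <- predict(model, feats)
  if (model$config$target == "height_cm") {
    age_eq <- tryCatch(height_to_age(chart, sex, pred), error = function(e)
      stop("predicted height ", signif(pred, 5),
           " cm is outside the chart range: ", conditionMessage(e),
           call. = FALSE))
    list(height_cm = pred,
         weight_kg = derive_weight(chart, sex, age_eq, body_type,
                                   band_percentiles))
  } else {
    sub <- chart[chart$sex == check_sex(sex), ]
    sub <- sub[order(sub$age_months), ]
    rng <- range(sub$weight_median_kg)
    if (pred < rng[1] || pred > rng[2])
      stop("predicted weight ", signif(pred, 5),
           " kg is outside the chart median range", call. = FALSE)
    age_eq <- stats::approx(sub$weight_median_kg, sub$age_months,
                            xout = pred)$y
    list(height_cm = median_height(chart, sex, age_eq), weight_kg = pred)
  }
}

#' Save or load a model checkpoint
#'
#' Single portable JSON file holding the configuration echo, the feature
#' column order, the standardization constants and all layer weights at
#' full precision. `load_model()` verifies the feature schema length.
#'
#' @param model an `mlp_model`.
#' @param path file path (`.json`).
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    feature_names = model$feature_names,
    scaling = model$scaling,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    }),
    report = model$report[c("best_epoch", "stopped_epoch", "best_val_loss",
                            "n_train", "n_validation", "seed")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  params <- lapply(p$params, function(q) {
    d <- unlist(q$dim)
    x <- as.numeric(unlist(q$data))
    if (length(d) == 2) matrix(x, d[1], d[2]) else x
  })
  keep <- intersect(c("hidden_units", "dropout_rate", "learning_rate",
                      "epochs", "batch_size", "split_fraction", "patience",
                      "restore_best", "seed", "target"), names(p$config))
  cfg <- do.call(mlp_config, p$config[keep])
  scaling <- p$scaling
  if (length(scaling$x_center) != nrow(params$W1))
    stop("checkpoint is inconsistent: feature count does not match W1",
         call. = FALSE)
  structure(list(params = params, scaling = scaling,
                 feature_names = p$feature_names, config = cfg,
                 report = as.list(p$report)),
            class = "mlp_model")
}

#' Write the per-epoch training log as CSV
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @export
write_training_log <- function(model, path) {
  r <- model$report
  utils::write.csv(data.frame(epoch = seq_along(r$train_loss),
                              train_loss = r$train_loss,
                              val_loss = r$val_loss),
                   path, row.names = FALSE)
  invisible(path)
}
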