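# One-vs-rest probabilistic decoding of voxel-tier data, following the
# reference training protocol: leave-one-run-out cross-validation, per-run
# linear detrending, per-test-set feature standardization, L2-regularized
# logistic regression (C = 1) with inverse-frequency class weights, and
# peak-TR feature extraction 4 s after stimulus onset.

#' Classifier configuration
#'
#' @param cost_C Inverse regularization strength of the L2 penalty (> 0).
#' @param max_iterations Optimizer iteration cap.
#' @param tolerance Convergence tolerance.
#' @param seed Integer seed (kept for reproducibility bookkeeping; the fits
#'   themselves are deterministic).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(cost_C = 1.0, max_iterations = 4000L,
                              tolerance = 1e-4, seed = 1L) {
  stopifnot(cost_C > 0, max_iterations >= 1L, tolerance > 0)
  structure(list(cost_C = cost_C, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Remove per-feature linear trends within a run
#'
#' @param mat Samples x features matrix (>= 2 samples).
#' @return Matrix of residuals after removing each feature's least-squares
#'   linear trend (the mean is removed with it).
#' @export
detrend_run <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) {
    warning("fewer than 2 samples; returning input unchanged")
    return(mat)
  }
  t_idx <- seq_len(nrow(mat))
  stats::resid(stats::lm.fit(cbind(1, t_idx), mat))
}

#' Standardize features to zero mean and unit variance
#'
#' @param mat Samples x features matrix (>= 2 samples).
#' @return Z-scored matrix; zero-variance features are set to 0.
#' @export
zscore_features <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2L)
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  out <- sweep(mat, 2L, mu)
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdv[nz], "/")
  out[, !nz] <- 0
  out
}

#' Volume index of the expected response peak
#'
#' Adds 4 s to the stimulus onset and returns the (0-based) volume closest
#' to that time point. At TR = 1.25 s and onset 0 this is volume 3, i.e.
#' the fourth TR (window 3.75-5 s).
#'
#' @param onset_seconds Stimulus onset(s) relative to run start, >= 0.
#' @param tr_seconds TR duration in seconds.
#' @return Integer 0-based volume index (vectorized).
#' @export
peak_tr_index <- function(onset_seconds, tr_seconds = 1.25) {
  stopifnot(all(onset_seconds >= 0), tr_seconds > 0)
  as.integer(round((onset_seconds + 4) / tr_seconds))
}

#' Train a one-vs-rest logistic regression ensemble
#'
#' Five independent L2-regularized binary logistic regressions, one per
#' class, each trained on the full data with all other classes relabeled
#' "other". Observation weights are inversely proportional to the binary
#' class frequencies of the training fold (nominally 1/5 target vs 4/5
#' other), so imbalances do not bias the probability estimates. The ridge
#' penalty is matched to an inverse-regularization constant `C` via
#' `lambda = 1 / (C * n)`.
#'
#' @param train_matrix Samples x features matrix (already detrended and
#'   standardized).
#' @param labels Integer class labels 1..5, one per sample.
#' @param config A [classifier_config()].
#' @param classes The class set (default `1:5`).
#' @return An object of class `ovr_ensemble`.
#' @export
train_ovr <- function(train_matrix, labels, config = classifier_config(),
                      classes = 1:5) {
  train_matrix <- as.matrix(train_matrix)
  labels <- as.integer(labels)
  stopifnot(nrow(train_matrix) == length(labels))
  n <- nrow(train_matrix)
  fits <- lapply(classes, function(k) {
    y <- as.integer(labels == k)
    if (length(unique(y)) < 2L)
      stop(sprintf("degenerate training fold: class %d is %s", k,
                   if (all(y == 1L)) "the only class present" else "absent"),
           call. = FALSE)
    freq <- c(mean(y == 0L), mean(y == 1L))
    w <- ifelse(y == 1L, 1 / freq[2L], 1 / freq[1L])
    w <- w / mean(w)
    glmnet::glmnet(train_matrix, y, family = "binomial", alpha = 0,
                   lambda = 1 / (config$cost_C * n), weights = w,
                   standardize = FALSE, maxit = config$max_iterations,
                   thresh = config$tolerance * 1e-3)
  })
  structure(list(fits = fits, classes = classes, config = config),
            class = "ovr_ensemble")
}

#' Per-class probabilities from an ensemble
#'
#' @param ensemble An `ovr_ensemble` from [train_ovr()].
#' @param mat Samples x features matrix.
#' @return Samples x classes matrix of raw one-vs-rest probabilities (rows
#'   are not forced to sum to 1; normalization is downstream).
#' @export
predict_ovr <- function(ensemble, mat) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  mat <- as.matrix(mat)
  out <- vapply(ensemble$fits, function(f)
    as.numeric(stats::predict(f, mat, type = "response")),
    numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat),
         dimnames = list(NULL, as.character(ensemble$classes)))
}

#' Leave-one-run-out cross-validation scheme
#'
#' @param run_ids Integer run id per sample.
#' @return List of folds, each with `held_out_run`, `train_idx`, `test_idx`;
#'   training folds never include the held-out run.
#' @export
loro_folds <- function(run_ids) {
  runs <- sort(unique(run_ids))
  lapply(runs, function(r)
    list(held_out_run = r,
         train_idx = which(run_ids != r),
         test_idx = which(run_ids == r)))
}

#' Predict probability time courses for scheduled trials
#'
#' Applies a trained ensemble to every volume of each trial window of a run
#' (all volumes from sequence onset to the end of the window, 13 per trial
#' by default), yielding one raw probability time course per trial.
#'
#' @param ensemble An `ovr_ensemble`.
#' @param run_matrix TR x features matrix of one run (preprocessed).
#' @param trial_onset_trs Integer vector of 1-based TR indices of each
#'   trial's sequence onset within the run.
#' @param window_trs Number of TRs per trial window (13 for sequence and
#'   repetition trials, 7 for slow trials).
#' @param position_maps Optional list of position maps, one per trial.
#' @param trial_ids Optional trial identifiers.
#' @return List of [probability_timecourse()]s (raw, un-normalized rows).
#' @export
predict_timecourses <- function(ensemble, run_matrix, trial_onset_trs,
                                window_trs = 13L, position_maps = NULL,
                                trial_ids = seq_along(trial_onset_trs)) {
  run_matrix <- as.matrix(run_matrix)
  ends <- trial_onset_trs + window_trs - 1L
  bad <- which(trial_onset_trs < 1L | ends > nrow(run_matrix))
  if (length(bad))
    stop("trial window(s) exceed run bounds for trial id(s): ",
         paste(trial_ids[bad], collapse = ", "), call. = FALSE)
  lapply(seq_along(trial_onset_trs), function(i) {
    rows <- trial_onset_trs[i]:ends[i]
    pr <- predict_ovr(ensemble, run_matrix[rows, , drop = FALSE])
    pm <- if (is.null(position_maps)) seq_len(ncol(pr)) else position_maps[[i]]
    probability_timecourse(pr, position_map = pm, trial_id = trial_ids[i])
  })
}

#' Cross-validated decoding of slow-trial events
#'
#' Full leave-one-run-out pipeline on voxel-tier data: per-run detrending,
#' per-test-set standardization, one-vs-rest training on upright slow-trial
#' peak volumes of the training runs, and prediction of the held-out run's
#' peak volumes.
#'
#' @param voxel_data A `voxel_data` object from [simulate_voxels()].
#' @param config A [classifier_config()].
#' @return List with `accuracy` (overall proportion of correct argmax
#'   predictions), `fold_accuracy`, `predictions` (data.frame with true and
#'   predicted class per event).
#' @export
cv_decode_slow <- function(voxel_data, config = classifier_config()) {
  ev <- voxel_data$events
  keep <- ev$condition == "slow" & ev$orientation == "upright"
  ev <- ev[keep, ]
  runs <- sort(unique(ev$run_id))
  prep <- lapply(voxel_data$runs, function(m) detrend_run(m))
  feats <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    prep[[as.character(ev$run_id[i])]][ev$peak_tr[i], , drop = FALSE]))
  folds <- loro_folds(ev$run_id)
  pred <- integer(nrow(ev))
  fold_acc <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    xtr <- zscore_features(feats[f$train_idx, , drop = FALSE])
    xte <- zscore_features(feats[f$test_idx, , drop = FALSE])
    ens <- train_ovr(xtr, ev$item_class[f$train_idx], config)
    pr <- predict_ovr(ens, xte)
    pred[f$test_idx] <- max.col(pr, ties.method = "first")
    fold_acc[fi] <- mean(pred[f$test_idx] == ev$item_class[f$test_idx])
  }
  list(accuracy = mean(pred == ev$item_class),
       fold_accuracy = fold_acc,
       predictions = data.frame(run_id = ev$run_id, true = ev$item_class,
                                predicted = pred))
}
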