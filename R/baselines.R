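#' Root-mean-square of a window
#'
#' @param window Numeric vector.
#' @return sqrt(mean(window^2)).
#' @export
feature_rms <- function(window) {
  stopifnot(length(window) > 0)
  sqrt(mean(window^2))
}

#' Mean power of a window
#'
#' Mean of squared magnitudes; equals the squared RMS exactly.
#'
#' @inheritParams feature_rms
#' @export
feature_power <- function(window) {
  stopifnot(length(window) > 0)
  mean(window^2)
}

#' Spike rate of a window
#'
#' Threshold-detected event count normalized by the window length.
#'
#' @inheritParams feature_rms
#' @param fs Sampling rate in Hz.
#' @param k SD multiplier for detection.
#' @param dead_time_s Detection dead time.
#' @param threshold Optional fixed absolute threshold.
#' @return Rate in Hz.
#' @export
feature_spike_rate <- function(window, fs, k = 3.5, dead_time_s = 0.001,
                               threshold = NULL) {
  st <- suppressWarnings(
    detect_spikes(window, fs, k, dead_time_s, threshold))
  length(st$times) / (length(window) / fs)
}

#' Feature vector of a 100 ms sample
#'
#' Per channel, the feature is computed on two non-overlapping 50 ms
#' sub-windows and concatenated channel-major: the vector index of
#' (channel ch, sub-window w) is `2 * (ch - 1) + w`. With 56 channels
#' the vector has 112 entries, matching the double-encoding width.
#'
#' @param segment A `labeled_segment` of 100 ms.
#' @param kind `"rms"`, `"power"` or `"spike_rate"`.
#' @param sub_window_s Sub-window length in seconds.
#' @param k,dead_time_s,thresholds Detection parameters for
#'   `"spike_rate"` (per-channel `thresholds` as in
#'   [channel_thresholds()]).
#' @return Numeric vector of length 2 x channels with a `label`
#'   attribute.
#' @export
build_feature_vector <- function(segment,
                                 kind = c("rms", "power", "spike_rate"),
                                 sub_window_s = 0.05, k = 3.5,
                                 dead_time_s = 0.001, thresholds = NULL) {
  kind <- match.arg(kind)
  x <- segment$data
  fs <- segment$fs
  nsub <- ncol(x) / fs / sub_window_s
  if (abs(nsub - 2) > 1e-9) {
    stop("sample length ", ncol(x) / fs, " s is not two sub-windows of ",
         sub_window_s, " s")
  }
  spl <- floor(sub_window_s * fs)
  v <- numeric(2 * nrow(x))
  for (ch in seq_len(nrow(x))) {
    for (w in 1:2) {
      win <- x[ch, ((w - 1) * spl + 1):(w * spl)]
      v[2 * (ch - 1) + w] <- switch(kind,
        rms = feature_rms(win),
        power = feature_power(win),
        spike_rate = feature_spike_rate(win, fs, k, dead_time_s,
                                        thresholds[ch]))
    }
  }
  attr(v, "label") <- segment$label
  v
}

#' Feature matrix for a list of segments
#'
#' @param segments List of `labeled_segment`s.
#' @inheritParams build_feature_vector
#' @return List with `features` (samples x 2channels matrix) and
#'   `labels`.
#' @export
feature_dataset <- function(segments, kind = "rms", sub_window_s = 0.05,
                            k = 3.5, dead_time_s = 0.001,
                            thresholds = NULL) {
  feats <- t(vapply(segments, function(s) {
    as.numeric(build_feature_vector(s, kind, sub_window_s, k,
                                    dead_time_s, thresholds))
  }, numeric(2 * nrow(segments[[1]]$data))))
  list(features = feats,
       labels = vapply(segments, function(s) s$label, character(1)))
}

# standardization fitted on the training fold only
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

#' Cross-validated conventional decoders
#'
#' Linear-kernel SVM or single-hidden-layer MLP (236 hidden units, 210%
#' of the 112-dim feature width) on a feature matrix, with the same
#' stratified folds as the spiking classifier. Features are standardized
#' on the training fold only; the test fold reuses the training-fold
#' scaler, so no information leaks across the split. An RBF-kernel SVM
#' is available but excluded from headline comparisons.
#'
#' @param kind `"svm_linear"`, `"mlp"` or `"svm_rbf"`.
#' @param features Samples x features matrix.
#' @param labels Class label per sample.
#' @param n_folds Number of stratified folds.
#' @param folds Optional precomputed fold assignment (shared with the
#'   SNN).
#' @param seed Fold/initialization seed.
#' @param svm_cost SVM regularization constant.
#' @param mlp_hidden Hidden-layer width.
#' @param mlp_maxit MLP optimizer iteration budget.
#' @return A `decode_result`.
#' @export
train_baseline <- function(kind = c("svm_linear", "mlp", "svm_rbf"),
                           features, labels, n_folds = 5, folds = NULL,
                           seed = 1, svm_cost = 1, mlp_hidden = 236,
                           mlp_maxit = 500) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(folds)) folds <- make_folds(labels, n_folds, seed)
  n_folds <- max(folds)
  fold_acc <- numeric(n_folds)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    sc <- fit_scaler(features[tr, , drop = FALSE])
    xtr <- apply_scaler(features[tr, , drop = FALSE], sc)
    xte <- apply_scaler(features[!tr, , drop = FALSE], sc)
    ytr <- factor(labels[tr], classes)
    if (kind %in% c("svm_linear", "svm_rbf")) {
      fit <- e1071::svm(xtr, ytr,
                        kernel = if (kind == "svm_linear") "linear"
                                 else "radial",
                        cost = svm_cost, scale = FALSE)
      pred <- as.character(predict(fit, xte))
    } else {
      set.seed(seed)
      fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = mlp_hidden,
                        softmax = TRUE, maxit = mlp_maxit,
                        MaxNWts = 1e6, trace = FALSE)
      pr <- predict(fit, xte)
      pred <- classes[max.col(pr, ties.method = "first")]
    }
    truth <- labels[!tr]
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(truth)) conf[truth[i], pred[i]] <-
      conf[truth[i], pred[i]] + 1
  }
  conf <- conf / pmax(rowSums(conf), 1)
  new_decode_result(fold_acc, conf, classes, folds)
}
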