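#' Configuration of the shallow spiking classifier
#'
#' A single fully connected layer of leaky integrate-and-fire output
#' units with exponentially decaying synaptic current:
#' \deqn{I_{syn}[t] = \alpha I_{syn}[t-1] + W x[t]}
#' \deqn{U[t] = \beta U[t-1] + I_{syn}[t] - S[t-1] U_{thr}}
#' \deqn{S[t] = 1 \iff U[t] \ge U_{thr}}
#' (soft reset by threshold subtraction). Weights and per-unit thresholds
#' are trained by surrogate-gradient descent (fast-sigmoid surrogate
#' derivative) on the MSE spike-count loss: the correct unit is pushed
#' towards firing in a fraction `target_rate` of time steps, all others
#' towards `off_target_rate`, with the Adam optimizer.
#'
#' @param n_inputs Input width (56 for single encodings, 112 for the
#'   double encoding, 14/28/42 for electrode subsets).
#' @param n_outputs Number of movement classes (6, or 4 when knee data
#'   are unavailable).
#' @param alpha Synaptic current decay per step.
#' @param beta Membrane potential decay per step.
#' @param u_thr Initial firing threshold (trainable).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch Batch size.
#' @param target_rate,off_target_rate Target firing fractions of the
#'   correct and incorrect output units.
#' @param steps Time steps per sample (40 = 100 ms at 2.5 ms bins).
#' @param seed Seed for weight initialization and batch shuffling.
#' @param surrogate_slope Slope of the fast-sigmoid surrogate
#'   derivative 1 / (1 + slope * |U - U_thr|)^2.
#' @param loss `"mse_count"` (primary: MSE on firing fractions against
#'   `target_rate`/`off_target_rate`) or `"ce_count"` (cross-entropy
#'   with output spike counts as logits).
#' @return A list of class `snn_config`.
#' @export
snn_config <- function(n_inputs = 56, n_outputs = 6, alpha = 0.95,
                       beta = 0.98, u_thr = 0.5, lr = 1e-3,
                       epochs = 500L, batch = 70L, target_rate = 0.8,
                       off_target_rate = 0.001, steps = 40L, seed = 1L,
                       surrogate_slope = 25,
                       loss = c("mse_count", "ce_count")) {
  loss <- match.arg(loss)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1,
            off_target_rate >= 0, off_target_rate < target_rate,
            target_rate <= 1, n_inputs >= 1, n_outputs >= 2)
  structure(list(n_inputs = n_inputs, n_outputs = n_outputs,
                 alpha = alpha, beta = beta, u_thr = u_thr, lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 target_rate = target_rate,
                 off_target_rate = off_target_rate,
                 steps = as.integer(steps), seed = as.integer(seed),
                 surrogate_slope = surrogate_slope, loss = loss),
            class = "snn_config")
}

# Non-negative uniform init scaled by 1/sqrt(n_inputs): event-count
# inputs are non-negative, so a signed init leaves some output units
# net-inhibited and permanently silent (the surrogate gradient vanishes
# far below threshold); starting every unit excitatory guarantees initial
# firing and gradient flow.
snn_init <- function(config) {
  set.seed(config$seed)
  W <- matrix(runif(config$n_inputs * config$n_outputs, 0, 1) /
                sqrt(config$n_inputs),
              config$n_inputs, config$n_outputs)
  list(W = W, thr = rep(config$u_thr, config$n_outputs))
}

# samples x steps x inputs -> cube with slice t = batch x inputs
as_snn_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))  # single tensor
  aperm(x, c(1, 3, 2))
}

#' Forward pass of the spiking classifier
#'
#' @param events An `event_tensor` (steps x inputs), or an array
#'   samples x steps x inputs.
#' @param model A trained `snn_model` (or a list with `W`, `thr` and a
#'   `config`).
#' @return Matrix of output spike counts, samples x classes (a vector
#'   for a single tensor).
#' @export
snn_forward <- function(events, model) {
  single <- is.matrix(events)
  X <- as_snn_cube(if (single) unclass(events) else events)
  if (dim(X)[2] != nrow(model$W)) {
    stop("input width ", dim(X)[2], " does not match model width ",
         nrow(model$W))
  }
  counts <- snn_forward_cpp(X, model$W, model$thr,
                            model$config$alpha, model$config$beta)$counts
  colnames(counts) <- model$classes
  if (single) counts[1, ] else counts
}

#' Train the spiking classifier
#'
#' Surrogate-gradient descent with Adam on the MSE spike-count loss;
#' weights and per-unit thresholds are co-trained (thresholds kept
#' positive). Reproducible for a fixed config seed.
#'
#' @param x Array samples x steps x inputs of event counts.
#' @param labels Class label per sample.
#' @param config An [snn_config()].
#' @param epochs Override of `config$epochs`.
#' @return An `snn_model`: `W`, `thr`, `classes`, `config`,
#'   `loss_history` (mean loss per epoch).
#' @export
train_snn <- function(x, labels, config = snn_config(), epochs = NULL) {
  classes <- if (is.factor(labels)) levels(labels)
             else sort(unique(as.character(labels)))
  if (length(classes) != config$n_outputs) {
    config$n_outputs <- length(classes)
  }
  if (any(table(factor(labels, classes)) == 0)) {
    stop("empty class in training set")
  }
  if (dim(x)[3] != config$n_inputs) config$n_inputs <- dim(x)[3]
  epochs <- if (is.null(epochs)) config$epochs else as.integer(epochs)
  n <- dim(x)[1]
  steps <- dim(x)[2]
  y <- match(as.character(labels), classes)
  loss_type <- if (identical(config$loss, "ce_count")) 1L else 0L
  if (loss_type == 1L) {
    targets <- matrix(0, n, config$n_outputs)    # one-hot for CE
    targets[cbind(seq_len(n), y)] <- 1
  } else {
    targets <- matrix(config$off_target_rate, n, config$n_outputs)
    targets[cbind(seq_len(n), y)] <- config$target_rate
  }

  par <- snn_init(config)  # also seeds the shuffling RNG
  W <- par$W; thr <- par$thr
  mW <- vW <- matrix(0, nrow(W), ncol(W))
  mT <- vT <- rep(0, length(thr))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  loss_history <- numeric(epochs)
  xs <- if (is.integer(x)) x + 0 else x  # numeric for armadillo

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * config$batch + 1):min(bi * config$batch, n)]
      X <- aperm(xs[idx, , , drop = FALSE], c(1, 3, 2))
      g <- snn_grad_cpp(X, W, thr, config$alpha, config$beta,
                        targets[idx, , drop = FALSE],
                        config$surrogate_slope, loss_type)
      t_step <- t_step + 1
      mW <- b1 * mW + (1 - b1) * g$gW
      vW <- b2 * vW + (1 - b2) * g$gW^2
      W <- W - config$lr * (mW / (1 - b1^t_step)) /
        (sqrt(vW / (1 - b2^t_step)) + eps)
      gt <- as.numeric(g$gthr)
      mT <- b1 * mT + (1 - b1) * gt
      vT <- b2 * vT + (1 - b2) * gt^2
      thr <- thr - config$lr * (mT / (1 - b1^t_step)) /
        (sqrt(vT / (1 - b2^t_step)) + eps)
      thr <- pmax(thr, 1e-3)
      ep_loss <- ep_loss + g$loss * length(idx)
    }
    loss_history[ep] <- ep_loss / n
  }
  structure(list(W = W, thr = thr, classes = classes, config = config,
                 steps = steps, loss_history = loss_history),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("<snn_model> %d inputs -> %d classes (%s)\n",
              nrow(x$W), ncol(x$W), paste(x$classes, collapse = ", ")))
  cat(sprintf("  final training loss %.4g after %d epochs\n",
              x$loss_history[length(x$loss_history)],
              length(x$loss_history)))
  invisible(x)
}

#' Predict movement classes from event tensors
#'
#' The predicted class is the output unit with the highest spike count;
#' ties are broken towards the lowest class index and flagged in the
#' `"tie"` attribute.
#'
#' @param object A trained `snn_model`.
#' @param newdata An `event_tensor` or samples x steps x inputs array.
#' @param ... Unused.
#' @return Character vector of class labels with a logical `"tie"`
#'   attribute.
#' @export
predict.snn_model <- function(object, newdata, ...) {
  counts <- snn_forward(newdata, object)
  if (is.null(dim(counts))) counts <- matrix(counts, 1)
  best <- max.col(counts, ties.method = "first")
  tie <- vapply(seq_len(nrow(counts)), function(i) {
    sum(counts[i, ] == counts[i, best[i]]) > 1
  }, logical(1))
  structure(object$classes[best], tie = tie)
}

#' Stratified cross-validation folds
#'
#' Per-class round-robin assignment after a seeded shuffle, so folds are
#' class-balanced and identical across decoders compared on the same
#' data split.
#'
#' @param labels Class label per sample.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment per sample.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("class(es) with fewer samples than folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "))
  }
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  folds
}

new_decode_result <- function(fold_acc, confusion, classes, folds) {
  structure(list(fold_accuracies = fold_acc, mean = mean(fold_acc),
                 sd = sd(fold_acc), confusion = confusion,
                 chance = 1 / length(classes), classes = classes,
                 folds = folds),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d-fold test accuracy %.2f%% +/- %.2f%% (chance %.2f%%)\n",
              length(x$fold_accuracies), 100 * x$mean, 100 * x$sd,
              100 * x$chance))
  invisible(x)
}

#' Cross-validated evaluation of the spiking classifier
#'
#' @inheritParams train_snn
#' @param n_folds Number of stratified folds.
#' @param folds Optional precomputed fold assignment (to share the split
#'   with baseline decoders).
#' @return A `decode_result`: per-fold test accuracies, mean, SD, pooled
#'   row-normalized confusion matrix, chance level and the fold
#'   assignment used.
#' @export
snn_crossval <- function(x, labels, config = snn_config(), n_folds = 5,
                         folds = NULL, epochs = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(folds)) folds <- make_folds(labels, n_folds, config$seed)
  n_folds <- max(folds)
  fold_acc <- train_acc <- numeric(n_folds)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    model <- train_snn(x[tr, , , drop = FALSE], labels[tr], config,
                       epochs = epochs)
    train_acc[f] <- mean(predict(model, x[tr, , , drop = FALSE]) ==
                           labels[tr])
    pred <- predict(model, x[!tr, , , drop = FALSE])
    truth <- labels[!tr]
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(truth)) conf[truth[i], pred[i]] <-
      conf[truth[i], pred[i]] + 1
  }
  conf <- conf / pmax(rowSums(conf), 1)
  res <- new_decode_result(fold_acc, conf, classes, folds)
  res$fold_train_accuracies <- train_acc
  res
}

#' Decodability from electrode subsets
#'
#' Trains and cross-validates the spiking classifier on every
#' combination of 1..4 electrodes (channel groups of 14), reporting
#' per-combination and size-averaged accuracies and the Pearson
#' correlation between electrode count and accuracy.
#'
#' @inheritParams snn_crossval
#' @param groups Named list mapping each electrode to its channel
#'   indices on the input axis of `x`.
#' @param sizes Subset sizes to evaluate.
#' @param required_group_size Expected channels per electrode (14); a
#'   mismatch is an error.
#' @return List with `per_combo` (data.frame: size, combo, accuracy),
#'   `size_means` and `pearson_r`.
#' @export
electrode_subset_eval <- function(x, labels, groups, sizes = 1:4,
                                  config = snn_config(), n_folds = 5,
                                  epochs = NULL,
                                  required_group_size = 14) {
  sizes <- sort(sizes)
  len <- vapply(groups, length, integer(1))
  if (!is.null(required_group_size) && any(len != required_group_size)) {
    stop("electrode group size(s) ", paste(len, collapse = ","),
         " != ", required_group_size)
  }
  folds <- make_folds(labels, n_folds, config$seed)
  rows <- list()
  for (s in sizes) {
    combos <- combn(length(groups), s)
    for (ci in seq_len(ncol(combos))) {
      ch <- unlist(groups[combos[, ci]])
      res <- snn_crossval(x[, , ch, drop = FALSE], labels, config,
                          folds = folds, epochs = epochs)
      rows[[length(rows) + 1]] <- data.frame(
        size = s,
        combo = paste(combos[, ci], collapse = "+"),
        accuracy = res$mean)
    }
  }
  per_combo <- do.call(rbind, rows)
  size_means <- vapply(split(per_combo$accuracy, per_combo$size), mean,
                       numeric(1))
  list(per_combo = per_combo, size_means = size_means,
       pearson_r = stats::cor(per_combo$size, per_combo$accuracy))
}
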