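test_that("forward pass matches the scalar oracle on random instances", {
  set.seed(81)
  for (rep_i in 1:30) {
    n_in <- sample(2:4, 1); n_out <- sample(2:4, 1)
    T_ <- sample(3:10, 1)
    x <- matrix(rpois(T_ * n_in, 0.6), T_, n_in)
    W <- matrix(rnorm(n_in * n_out, 0, 0.8), n_in, n_out)
    thr <- runif(n_out, 0.2, 1)
    cfg <- snn_config(n_inputs = n_in, n_outputs = n_out)
    model <- list(W = W, thr = thr, config = cfg, classes = NULL)
    got <- snn_forward(x, model)
    ref <- snn_scalar_oracle(x, W, thr, cfg$alpha, cfg$beta)
    expect_equal(unname(got), ref, tolerance = 1e-10)
  }
})

test_that("a spike soft-resets the membrane by exactly the threshold", {
  # one input spike at t=0 through weight 1, threshold 0.5:
  # U[0] = 1 -> spike; U[1] = beta*U[0] + Isyn[1] - U_thr
  cfg <- snn_config(n_inputs = 1, n_outputs = 2)
  model <- list(W = matrix(c(1, 0), 1, 2), thr = c(0.5, 0.5),
                config = cfg, classes = NULL)
  X <- array(0, c(1, 1, 3))   # batch x inputs x steps
  X[1, 1, 1] <- 1
  out <- engdecode:::snn_forward_cpp(X, model$W, model$thr,
                                     cfg$alpha, cfg$beta,
                                     return_spikes = TRUE)
  U <- out$membrane[1, 1, ]   # unit 1 membrane over time
  expect_equal(U[1], 1)                         # charged by the spike
  expect_equal(U[2], cfg$beta * U[1] + cfg$alpha * 1 - 0.5)
  expect_equal(out$counts[1, 2], 0)             # zero-weight unit silent
})

test_that("prediction takes the max-count unit with first-index ties", {
  cfg <- snn_config(n_inputs = 6, n_outputs = 6)
  model <- structure(list(W = diag(6) * 10, thr = rep(0.5, 6),
                          config = cfg, classes = letters[1:6]),
                     class = "snn_model")
  mk <- function(active) {
    x <- matrix(0, 4, 6); x[, active] <- 3; x
  }
  expect_equal(as.character(predict(model, mk(1))), "a")
  expect_equal(as.character(predict(model, mk(4))), "d")
  p <- predict(model, mk(c(2, 3)))              # tie between b and c
  expect_equal(as.character(p), "b")
  expect_true(attr(p, "tie"))
  # argmax oracle on random count patterns
  set.seed(82)
  for (i in 1:20) {
    act <- sample(6, sample(1:3, 1))
    p <- predict(model, mk(act))
    expect_equal(as.character(p), letters[min(act)])
  }
})

test_that("training reaches the degenerate single-class optimum", {
  set.seed(83)
  x <- array(rpois(10 * 20 * 4, 0.5), c(10, 20, 4))
  m <- train_snn(x, rep("only", 10),
                 snn_config(n_inputs = 4, n_outputs = 2), epochs = 5)
  expect_equal(as.character(predict(m, x)), rep("only", 10))
  expect_error(train_snn(x, factor(rep("a", 10), levels = c("a", "b")),
                         snn_config(n_inputs = 4, n_outputs = 2)),
               "empty class")
})

test_that("stratified folds partition samples and balance classes", {
  labels <- rep(movement_classes(), times = c(10, 10, 11, 12, 10, 13))
  folds <- make_folds(labels, 5, seed = 7)
  expect_equal(length(folds), length(labels))
  expect_true(all(folds %in% 1:5))
  # every sample tested exactly once; per-class fold counts differ by <= 1
  for (cl in movement_classes()) {
    tab <- table(folds[labels == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
  expect_error(make_folds(c("a", "a", "b"), 5), "fewer samples")
  # identical seed -> identical split (shared across decoders)
  expect_identical(folds, make_folds(labels, 5, seed = 7))
})

test_that("training is reproducible and its loss decreases", {
  d <- make_rate_dataset(n_per = 25, seed = 84)
  cfg <- snn_config(n_inputs = 18, n_outputs = 6, seed = 5)
  m1 <- train_snn(d$x, d$labels, cfg, epochs = 30)
  m2 <- train_snn(d$x, d$labels, cfg, epochs = 30)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$loss_history, m2$loss_history)
  m <- train_snn(d$x, d$labels, cfg, epochs = 50)
  # monotone trend of the epoch-averaged loss, <= 5% violations
  expect_lte(mean(diff(m$loss_history) > 0), 0.05)
  expect_lt(m$loss_history[50], m$loss_history[1])
})

test_that("the cross-entropy count loss also learns separable data", {
  d <- make_rate_dataset(n_per = 20, seed = 88)
  cfg <- snn_config(n_inputs = 18, n_outputs = 6, seed = 5,
                    loss = "ce_count")
  m <- train_snn(d$x, d$labels, cfg, epochs = 150)
  expect_gt(mean(predict(m, d$x) == d$labels), 0.8)
  expect_lt(m$loss_history[150], m$loss_history[1])
})

test_that("cross-validation separates separable data and not noise", {
  d <- make_rate_dataset(n_per = 25, seed = 85)
  cfg <- snn_config(n_inputs = 18, n_outputs = 6, seed = 5)
  res <- snn_crossval(d$x, d$labels, cfg, epochs = 60)
  expect_gte(res$mean, 0.9)
  expect_equal(rowSums(res$confusion), rep(1, 6), ignore_attr = TRUE)
  expect_equal(res$chance, 1 / 6)
  # fold assignment is a partition: every sample tested exactly once
  expect_equal(sort(unique(res$folds)), 1:5)
  # permuted labels: accuracy near chance
  set.seed(86)
  resn <- snn_crossval(d$x, sample(d$labels), cfg, epochs = 30)
  expect_lt(abs(resn$mean - 1 / 6), 0.12)
  # reproducibility of the whole procedure
  res2 <- snn_crossval(d$x, d$labels, cfg, epochs = 60)
  expect_identical(res$fold_accuracies, res2$fold_accuracies)
})

test_that("electrode-subset evaluation enumerates combinations", {
  d <- make_rate_dataset(n_per = 10, n_inputs = 6, seed = 87,
                         classes = c("a_flexion", "b_flexion"))
  groups <- list(e1 = 1:2, e2 = 3:4, e3 = 5:6)
  expect_error(
    electrode_subset_eval(d$x, d$labels, groups,
                          config = snn_config(n_inputs = 6,
                                              n_outputs = 2)),
    "group size")
  ev <- electrode_subset_eval(d$x, d$labels, groups, sizes = 1:3,
                              config = snn_config(n_inputs = 6,
                                                  n_outputs = 2),
                              epochs = 5, required_group_size = 2)
  expect_equal(table(ev$per_combo$size), c(`1` = 3, `2` = 3, `3` = 1),
               ignore_attr = TRUE)
  expect_named(ev$size_means, c("1", "2", "3"))
  expect_true(is.finite(ev$pearson_r))
})
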