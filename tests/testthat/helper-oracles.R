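# Independent scalar simulator of the spiking classifier recurrences,
# used as the oracle against the vectorized forward pass. Plain R loops
# over samples, time steps and output units; no shared code with the
# implementation.
snn_scalar_oracle <- function(x_steps_by_inputs, W, thr, alpha, beta) {
  T_ <- nrow(x_steps_by_inputs)
  n_out <- ncol(W)
  counts <- numeric(n_out)
  for (j in seq_len(n_out)) {
    isyn <- 0; u <- 0; s_prev <- 0
    for (t in seq_len(T_)) {
      inp <- sum(x_steps_by_inputs[t, ] * W[, j])
      isyn <- alpha * isyn + inp
      u <- beta * u + isyn - s_prev * thr[j]
      s <- if (u >= thr[j]) 1 else 0
      counts[j] <- counts[j] + s
      s_prev <- s
    }
  }
  counts
}

# quick labeled_segment builder
make_segment <- function(data, fs = 30000, label = "knee_flexion",
                         phase = "flexion", t0 = 0) {
  structure(list(data = data, label = label, phase = phase, t0 = t0,
                 fs = fs),
            class = "labeled_segment")
}

# small separable event dataset: class c drives channels (c mod K) at a
# higher Poisson rate
make_rate_dataset <- function(n_per = 40, n_inputs = 18, steps = 40,
                              classes = movement_classes(), seed = 1,
                              hi = 0.25, lo = 0.05) {
  set.seed(seed)
  labels <- rep(classes, each = n_per)
  x <- array(0, c(length(labels), steps, n_inputs))
  for (i in seq_along(labels)) {
    cl <- match(labels[i], classes)
    rates <- rep(lo, n_inputs)
    rates[(seq_len(n_inputs) - 1) %% length(classes) + 1 == cl] <- hi
    x[i, , ] <- matrix(rpois(steps * n_inputs, rep(rates, each = steps)),
                       steps, n_inputs)
  }
  list(x = x, labels = labels)
}

# shared cache for the expensive end-to-end datasets used by several
# acceptance checks (built lazily, reused within the test run)
.eng_cache <- new.env(parent = emptyenv())

high_snr_dataset <- function(seed) {
  key <- paste0("hs", seed)
  if (is.null(.eng_cache[[key]])) {
    cfg <- synthetic_presets("high-snr-separable", blocks = 1, seed = seed)
    .eng_cache[[key]] <- synthetic_dataset(cfg, encoder = "thr")
  }
  .eng_cache[[key]]
}
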