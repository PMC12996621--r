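#' Parameters of the LIF event encoder
#'
#' One independent leaky integrate-and-fire neuron per channel converts
#' the preprocessed continuous signal into events: the membrane U
#' integrates the drive with time constant `tau_mem_s`, emits an event
#' and resets to `reset_mV` when it reaches `threshold_mV`, and is
#' clamped for `refractory_s`. The drive is the per-channel z-scored,
#' full-wave rectified signal scaled by `drive_gain`. Integration runs at
#' the signal's own sampling step (`sim_dt_s = 1/fs` by default); events
#' are then binned into `bin_s` windows.
#'
#' @param tau_mem_s Membrane time constant in seconds.
#' @param threshold_mV Spike threshold (drive units are mV-equivalent).
#' @param reset_mV Reset potential.
#' @param refractory_s Refractory period in seconds.
#' @param sim_dt_s Integration step in seconds; `NULL` means the sampling
#'   step of the encoded segment.
#' @param bin_s Event binning window in seconds.
#' @param drive_gain Scale from z-scored rectified signal to drive. The
#'   default places the mean drive of a unit-variance Gaussian channel
#'   (about 0.8 * gain) just below threshold, so events mark amplitude
#'   excursions rather than free-running charging.
#' @param rectify Apply full-wave rectification after z-scoring.
#' @param binarize Clip binned counts to 0/1 (default keeps counts,
#'   which preserve information; the refractory period caps them at
#'   `bin_s / refractory_s` rounded up).
#' @return A list of class `encoder_params`.
#' @export
encoder_params <- function(tau_mem_s = 0.010, threshold_mV = 350,
                           reset_mV = 0, refractory_s = 0.001,
                           sim_dt_s = NULL, bin_s = 0.0025,
                           drive_gain = 400, rectify = TRUE,
                           binarize = FALSE) {
  stopifnot(threshold_mV > reset_mV, tau_mem_s > 0, bin_s > 0)
  if (!is.null(sim_dt_s)) {
    stopifnot(refractory_s >= sim_dt_s,
              abs(bin_s / sim_dt_s - round(bin_s / sim_dt_s)) < 1e-6)
  }
  structure(list(tau_mem_s = tau_mem_s, threshold_mV = threshold_mV,
                 reset_mV = reset_mV, refractory_s = refractory_s,
                 sim_dt_s = sim_dt_s, bin_s = bin_s,
                 drive_gain = drive_gain, rectify = rectify,
                 binarize = binarize),
            class = "encoder_params")
}

new_event_tensor <- function(counts, bin_s, label = NA_character_) {
  structure(counts, bin_s = bin_s, label = label,
            class = c("event_tensor", class(counts)))
}

#' @export
print.event_tensor <- function(x, ...) {
  cat(sprintf("<event_tensor> %d steps x %d channels, bin %.4g ms, label %s\n",
              nrow(x), ncol(x), 1000 * attr(x, "bin_s"),
              attr(x, "label")))
  cat(sprintf("  total events: %d\n", sum(x)))
  invisible(x)
}

#' Threshold (multiunit) event encoding of a segment
#'
#' Spike detection per channel at `k` SDs (or fixed per-channel
#' thresholds computed on the full recording), events binned into
#' non-overlapping `bin_s` windows as counts.
#'
#' @param segment A `labeled_segment`.
#' @param k SD multiplier for detection.
#' @param bin_s Bin width in seconds.
#' @param dead_time_s Detection dead time.
#' @param thresholds Optional per-channel absolute thresholds (from
#'   [channel_thresholds()] on the full filtered recording).
#' @param binarize Clip binned counts to 0/1.
#' @return An `event_tensor`: time-steps x channels integer counts.
#' @export
threshold_encode <- function(segment, k = 3.5, bin_s = 0.0025,
                             dead_time_s = 0.001, thresholds = NULL,
                             binarize = FALSE) {
  x <- segment$data
  fs <- segment$fs
  nbins <- floor(ncol(x) / fs / bin_s + 1e-9)
  counts <- matrix(0L, nbins, nrow(x))
  for (ch in seq_len(nrow(x))) {
    st <- detect_spikes(x[ch, ], fs, k, dead_time_s,
                        threshold = thresholds[ch])
    b <- floor(st$times / bin_s + 1e-9)
    b <- b[b < nbins]
    counts[, ch] <- tabulate(b + 1, nbins)
  }
  if (binarize) counts[counts > 1L] <- 1L
  new_event_tensor(counts, bin_s, segment$label)
}

# per-channel z-score + optional rectification + gain -> LIF drive.
# center/scale are recording-level per-channel statistics when the
# encoder is run the way the source protocol did (normalization over the
# whole recording, so absolute power modulation survives); without them
# the segment's own statistics are used.
lif_drive <- function(x, params, center = NULL, scale = NULL) {
  if (any(!is.finite(x))) stop("non-finite input to LIF encoder")
  mu <- if (is.null(center)) rowMeans(x) else center
  sdv <- if (is.null(scale)) apply(x, 1, sd) else scale
  sdv[sdv == 0] <- 1  # flat channel carries no drive
  z <- (x - mu) / sdv
  if (params$rectify) z <- abs(z)
  z * params$drive_gain
}

#' LIF membrane event encoding of a segment
#'
#' Per-channel Euler integration of the leaky membrane
#' dU/dt = (drive - U) / tau at the signal sampling step; an event is
#' emitted when U reaches the threshold, U resets, and integration is
#' clamped for the refractory period. Events are binned into `bin_s`
#' windows as counts.
#'
#' @param segment A `labeled_segment` (preprocessed signal).
#' @param params An [encoder_params()].
#' @param center,scale Optional per-channel normalization statistics
#'   computed on the full recording (mean and SD of the filtered
#'   trace). When given, the z-scoring preserves absolute power
#'   modulation across segments, matching an encoder run over the
#'   whole recording; when omitted, each segment is normalized by its
#'   own statistics.
#' @return An `event_tensor`: time-steps x channels integer counts.
#' @export
lif_encode <- function(segment, params = encoder_params(),
                       center = NULL, scale = NULL) {
  dt <- if (is.null(params$sim_dt_s)) 1 / segment$fs else params$sim_dt_s
  drive <- lif_drive(segment$data, params, center, scale)
  counts <- lif_encode_cpp(drive, dt, params$tau_mem_s,
                           params$threshold_mV, params$reset_mV,
                           params$refractory_s, params$bin_s)
  if (isTRUE(params$binarize)) counts[counts > 1L] <- 1L
  new_event_tensor(counts, params$bin_s, segment$label)
}

#' Double encoding: threshold and LIF channels concatenated
#'
#' The channel axis holds the threshold-encoded channels followed by the
#' LIF-encoded channels, doubling the input width (56 -> 112).
#'
#' @inheritParams threshold_encode
#' @inheritParams lif_encode
#' @return An `event_tensor` of doubled channel width.
#' @export
double_encode <- function(segment, k = 3.5, params = encoder_params(),
                          dead_time_s = 0.001, thresholds = NULL,
                          center = NULL, scale = NULL) {
  a <- threshold_encode(segment, k, params$bin_s, dead_time_s,
                        thresholds, binarize = isTRUE(params$binarize))
  b <- lif_encode(segment, params, center, scale)
  if (nrow(a) != nrow(b)) {
    stop("bin mismatch between threshold and LIF encodings")
  }
  new_event_tensor(cbind(unclass(a), unclass(b)), params$bin_s,
                   segment$label)
}

#' Encode a list of segments into an event dataset
#'
#' @param segments List of `labeled_segment`s (same duration and channel
#'   count).
#' @param method `"thr"`, `"lif"` or `"double"`.
#' @inheritParams double_encode
#' @return List with `x` (samples x steps x channels array), `labels`
#'   (character) and `bin_s`.
#' @export
encode_segments <- function(segments, method = c("thr", "lif", "double"),
                            k = 3.5, params = encoder_params(),
                            dead_time_s = 0.001, thresholds = NULL,
                            center = NULL, scale = NULL) {
  method <- match.arg(method)
  enc1 <- function(seg) {
    switch(method,
      thr = threshold_encode(seg, k, params$bin_s, dead_time_s,
                             thresholds),
      lif = lif_encode(seg, params, center, scale),
      double = double_encode(seg, k, params, dead_time_s, thresholds,
                             center, scale))
  }
  first <- enc1(segments[[1]])
  x <- array(0L, dim = c(length(segments), nrow(first), ncol(first)))
  x[1, , ] <- first
  if (length(segments) > 1) {
    for (i in 2:length(segments)) x[i, , ] <- enc1(segments[[i]])
  }
  list(x = x,
       labels = vapply(segments, function(s) s$label, character(1)),
       bin_s = params$bin_s)
}
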