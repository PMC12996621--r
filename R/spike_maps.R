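#' Multiunit spike detection at a standard-deviation threshold
#'
#' Events are emitted where the absolute value of the band-passed signal
#' crosses `k` times its standard deviation from below; after each event,
#' further crossings within the dead time are suppressed. The threshold is
#' determined separately for each recording channel (subject-level factors
#' in the source protocol: k = 3.5 for subject 1, k = 4 for subject 2).
#'
#' @param signal Numeric vector, one band-passed channel.
#' @param fs Sampling rate in Hz.
#' @param k Threshold factor in SDs of the signal.
#' @param dead_time_s Minimum separation between events in seconds.
#' @param threshold Absolute threshold in signal units; overrides `k * SD`
#'   (used when thresholds are fixed on a longer stretch of signal than
#'   the one being scanned).
#' @return A list of class `spike_train` with element `times` (seconds,
#'   0-based from the first sample).
#' @export
detect_spikes <- function(signal, fs, k = 3.5, dead_time_s = 0.001,
                          threshold = NULL) {
  stopifnot(k > 0, fs > 0)
  if (is.null(threshold)) {
    s <- sd(signal)
    if (s == 0 || !is.finite(s)) {
      warning("signal SD is zero; returning empty spike train")
      return(structure(list(times = numeric(0)), class = "spike_train"))
    }
    threshold <- k * s
  }
  a <- abs(signal)
  above <- a >= threshold
  # crossings from below (first sample counts if already above)
  idx <- which(above & !c(FALSE, above[-length(above)]))
  if (length(idx) > 1) {
    idx <- prune_dead_time_cpp(as.integer(idx),
                               as.integer(round(dead_time_s * fs)))
  }
  structure(list(times = (idx - 1) / fs), class = "spike_train")
}

#' Detect spikes on every channel of a recording
#'
#' @param recording A band-passed `eng_recording`.
#' @inheritParams detect_spikes
#' @param thresholds Optional per-channel absolute thresholds.
#' @return List of `spike_train`s, one per channel.
#' @export
detect_spikes_recording <- function(recording, k = 3.5,
                                    dead_time_s = 0.001,
                                    thresholds = NULL) {
  lapply(seq_len(nrow(recording$data)), function(ch) {
    detect_spikes(recording$data[ch, ], recording$fs, k, dead_time_s,
                  threshold = thresholds[ch])
  })
}

#' Per-channel detection thresholds
#' @param recording A band-passed `eng_recording`.
#' @param k SD multiplier.
#' @return Numeric vector, `k * SD` per channel.
#' @export
channel_thresholds <- function(recording, k = 3.5) {
  k * apply(recording$data, 1, sd)
}

#' Binned firing rate of a spike train
#'
#' Counts per non-overlapping half-open bin divided by the bin width.
#' An event exactly on a bin boundary is counted in the right-hand bin.
#'
#' @param train A `spike_train` (or numeric vector of times in seconds).
#' @param t0,t1 Window in seconds, half-open `[t0, t1)`.
#' @param bin_width Bin width in seconds (0.1 in the source protocol).
#' @return Numeric vector of rates in Hz, length `floor((t1-t0)/bin_width)`.
#' @export
firing_rate <- function(train, t0, t1, bin_width = 0.1) {
  stopifnot(t1 > t0)
  times <- if (inherits(train, "spike_train")) train$times else train
  nbins <- floor((t1 - t0) / bin_width + 1e-9)
  b <- floor((times - t0) / bin_width + 1e-9)
  b <- b[b >= 0 & b < nbins]
  tabulate(b + 1, nbins) / bin_width
}

#' Firing-rate matrix for a set of spike trains
#'
#' @param trains List of `spike_train`s.
#' @inheritParams firing_rate
#' @return Channels x bins matrix of rates in Hz with attributes
#'   `bin_width` and `t0`.
#' @export
rate_matrix <- function(trains, t0, t1, bin_width = 0.1) {
  m <- t(vapply(trains, firing_rate, t0 = t0, t1 = t1,
                bin_width = bin_width,
                numeric(floor((t1 - t0) / bin_width + 1e-9))))
  attr(m, "bin_width") <- bin_width
  attr(m, "t0") <- t0
  m
}

#' Modulation z-score of a channel for one condition
#'
#' z = (mean action rate - mean rest rate) / SD of rest rate. The channel
#' is considered responsive ("significant") when z exceeds `z_threshold`
#' (0.5 in the source protocol). A zero rest SD makes the score
#' undefined: with excess action rate the sentinel `+Inf` is returned,
#' otherwise 0, with a warning either way.
#'
#' @param action_rates,rest_rates Firing rates in Hz (100 ms bins pooled
#'   over repetitions).
#' @return The z-score (dimensionless).
#' @export
modulation_zscore <- function(action_rates, rest_rates) {
  stopifnot(length(action_rates) > 0, length(rest_rates) > 0)
  s <- sd(rest_rates)
  d <- mean(action_rates) - mean(rest_rates)
  if (is.na(s) || s == 0) {
    warning("rest-rate SD is zero; z-score undefined")
    return(if (d > 0) Inf else 0)
  }
  d / s
}

#' Build the modulation map of a recording
#'
#' For every channel and movement class, firing rates in 100 ms bins are
#' pooled over all repetitions of the class: the action window is the
#' 1 s phase matching the class direction, the rest window the 2 s pause
#' after the movement. The per-condition z-score and significance flag
#' follow [modulation_zscore()].
#'
#' @param recording A band-passed `eng_recording`.
#' @param trials A `trial_table`.
#' @param k SD multiplier for spike detection.
#' @param dead_time_s Detection dead time in seconds.
#' @param bin_width Rate bin width in seconds.
#' @param z_threshold Significance gate on the z-score.
#' @param trains Optional precomputed spike trains (skips detection).
#' @return A data.frame of class `modulation_map` with one row per
#'   channel x condition: `channel`, `condition`, `joint`, `direction`,
#'   `z`, `significant`, `mean_action_hz`, `mean_rest_hz`, `sd_rest_hz`.
#' @export
build_modulation_map <- function(recording, trials, k = 3.5,
                                 dead_time_s = 0.001, bin_width = 0.1,
                                 z_threshold = 0.5, trains = NULL) {
  if (is.null(trains)) {
    trains <- detect_spikes_recording(recording, k, dead_time_s)
  }
  classes <- unique(trials$class)
  nch <- length(trains)
  rows <- vector("list", nch * length(classes))
  r <- 0
  for (cl in classes) {
    tt <- trials[trials$class == cl, ]
    dir <- tt$direction[1]
    for (ch in seq_len(nch)) {
      action <- unlist(lapply(seq_len(nrow(tt)), function(i) {
        w <- if (dir == "flexion") {
          c(tt$flexion_start[i], tt$flexion_end[i])
        } else c(tt$extension_start[i], tt$extension_end[i])
        firing_rate(trains[[ch]], w[1], w[2], bin_width)
      }))
      rest <- unlist(lapply(seq_len(nrow(tt)), function(i) {
        firing_rate(trains[[ch]], tt$rest_start[i], tt$rest_end[i],
                    bin_width)
      }))
      z <- suppressWarnings(modulation_zscore(action, rest))
      r <- r + 1
      rows[[r]] <- data.frame(
        channel = ch, condition = cl, joint = class_joint(cl),
        direction = dir, z = z, significant = (z > z_threshold),
        mean_action_hz = mean(action), mean_rest_hz = mean(rest),
        sd_rest_hz = sd(rest), stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  attr(map, "z_threshold") <- z_threshold
  class(map) <- c("modulation_map", "data.frame")
  map
}

#' Joint selectivity matrices
#'
#' Per joint, channels are partitioned into flexion-only / extension-only
#' / both / silent by their significance flags; percentages are taken
#' over the full channel set. Each channel also gets a joint-selectivity
#' category (silent, the single responsive joint, or "multi_joint").
#'
#' @param map A `modulation_map`.
#' @param n_channels Total channel count (56 in the source protocol);
#'   defaults to the number of channels in the map.
#' @return List with `per_joint` (data.frame of percentages, rows
#'   summing to 100) and `per_channel` (category per channel).
#' @export
selectivity_matrix <- function(map, n_channels = max(map$channel)) {
  joints <- unique(map$joint)
  per_joint <- do.call(rbind, lapply(joints, function(j) {
    flex <- map$channel[map$joint == j & map$direction == "flexion" &
                          map$significant]
    ext <- map$channel[map$joint == j & map$direction == "extension" &
                         map$significant]
    n_both <- length(intersect(flex, ext))
    n_flex <- length(setdiff(flex, ext))
    n_ext <- length(setdiff(ext, flex))
    n_silent <- n_channels - n_both - n_flex - n_ext
    data.frame(joint = j,
               flexion_only = 100 * n_flex / n_channels,
               extension_only = 100 * n_ext / n_channels,
               both = 100 * n_both / n_channels,
               silent = 100 * n_silent / n_channels,
               stringsAsFactors = FALSE)
  }))
  per_channel <- vapply(seq_len(n_channels), function(ch) {
    jj <- unique(map$joint[map$channel == ch & map$significant])
    if (length(jj) == 0) "silent"
    else if (length(jj) == 1) jj
    else "multi_joint"
  }, character(1))
  list(per_joint = per_joint, per_channel = per_channel)
}

#' Overlap between motor modulation and sensory maps
#'
#' Per anatomical region, the percentage of channels that modulate only
#' during movement of the mapped joint, evoke only sensations in the
#' region, do both, or neither.
#'
#' @param map A `modulation_map`.
#' @param sensory Character vector: per-channel evoked-sensation region
#'   label (`"none"` for channels evoking nothing).
#' @param region_of_joint Named mapping joint -> region label.
#' @param n_channels Total channel count.
#' @return Data.frame with one row per region; the four percentage
#'   columns sum to 100.
#' @export
motor_sensory_overlap <- function(map, sensory,
                                  region_of_joint = c(
                                    knee = "knee_calf",
                                    ankle = "ankle_heel",
                                    toes = "foot_toes"),
                                  n_channels = length(sensory)) {
  do.call(rbind, lapply(names(region_of_joint), function(j) {
    region <- region_of_joint[[j]]
    motor <- unique(map$channel[map$joint == j & map$significant])
    sens <- which(sensory == region)
    n_both <- length(intersect(motor, sens))
    n_motor <- length(setdiff(motor, sens))
    n_sens <- length(setdiff(sens, motor))
    n_neither <- n_channels - n_both - n_motor - n_sens
    data.frame(joint = j, region = region,
               motor_only = 100 * n_motor / n_channels,
               sensory_only = 100 * n_sens / n_channels,
               both = 100 * n_both / n_channels,
               neither = 100 * n_neither / n_channels,
               stringsAsFactors = FALSE)
  }))
}

#' Herdin correlation-matrix distance
#'
#' d(R1, R2) = 1 - tr(R1 R2) / (||R1||_F ||R2||_F), clipped to `[0, 1]`
#' against rounding. Zero when the matrices are equal up to scaling, one
#' when they are trace-orthogonal (maximally different).
#'
#' @param R1,R2 Square matrices of identical dimension with non-zero
#'   Frobenius norm.
#' @return Distance in `[0, 1]`.
#' @export
herdin_distance <- function(R1, R2) {
  R1 <- as.matrix(R1); R2 <- as.matrix(R2)
  stopifnot(nrow(R1) == ncol(R1), all(dim(R1) == dim(R2)))
  n1 <- sqrt(sum(R1^2)); n2 <- sqrt(sum(R2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm input matrix")
  d <- 1 - sum(R1 * t(R2)) / (n1 * n2)
  min(max(d, 0), 1)
}

#' Jaccard overlap matrix of a list of sets
#'
#' Symmetric matrix of intersection counts normalized by union size
#' (diagonal 1 for non-empty sets). This is the correlation-like matrix
#' fed to [herdin_distance()] when comparing neural and muscular
#' activation overlaps.
#'
#' @param sets Named list of vectors (channel indices or muscle names).
#' @return Square matrix, one row/column per set.
#' @export
set_overlap_matrix <- function(sets) {
  n <- length(sets)
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    stop("empty set for: ", paste(names(sets)[empty], collapse = ", "))
  }
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  m
}

#' Muscle involvement table (synthetic reconstruction)
#'
#' Binary muscles x movements involvement matrix for muscles innervated
#' by the sciatic nerve or its branches below an above-knee amputation:
#' 7 flexor-compartment and 4 extensor-compartment muscles. The table is
#' reconstructed from standard lower-leg anatomy (the flexor compartment
#' drives knee flexion, ankle plantarflexion and toe flexion; the
#' extensor compartment ankle dorsiflexion and toe extension) and is a
#' synthetic stand-in, shipped as
#' `inst/extdata/muscle_matrix_synthetic.csv`.
#'
#' @param path CSV with columns `muscle`, `group`, then one 0/1 column
#'   per movement class.
#' @return Data.frame with `muscle`, `group` and the six class columns.
#' @export
muscle_matrix <- function(path = system.file("extdata",
                                             "muscle_matrix_synthetic.csv",
                                             package = "engdecode")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load a sensory map from CSV
#'
#' Per-channel label of the region where intraneural stimulation evokes
#' sensation (columns `channel`, `region`; regions like `knee_calf`,
#'  `ankle_heel`, `foot_toes`, or `none`). The map is consumed as a
#' given table — psychophysical acquisition is outside this package.
#'
#' @param path CSV path.
#' @param n_channels Total channel count; channels absent from the
#'   table are labeled `"none"`.
#' @return Character vector of region labels, one per channel.
#' @export
load_sensory_map <- function(path, n_channels = 56) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "region") %in% names(tab)))
  out <- rep("none", n_channels)
  out[tab$channel] <- tab$region
  out
}

#' Similarity between neural activation and muscular involvement
#'
#' Builds a joint x joint Jaccard overlap matrix of the channels
#' significantly modulating for each joint in `neural_direction`, the
#' analogous matrix of the muscles involved in each joint's movement in
#' `muscle_direction` (restricted to the matching muscle compartment:
#' flexors for flexion, extensors for extension), and returns the Herdin
#' distance between the two.
#'
#' @param map A `modulation_map`.
#' @param muscles A muscle involvement table, see [muscle_matrix()].
#' @param neural_direction,muscle_direction `"flexion"` or
#'   `"extension"`; they may differ (cross-direction comparisons are part
#'   of the source analysis).
#' @param joints Joints to compare (default: all joints in the map).
#'   Knee extension is driven by muscles lost above the amputation, so
#'   extension-direction comparisons typically restrict to ankle/toes.
#' @return The Herdin distance in `[0, 1]`.
#' @export
muscle_similarity <- function(map, muscles,
                              neural_direction = "flexion",
                              muscle_direction = neural_direction,
                              joints = unique(map$joint)) {
  neural_sets <- lapply(joints, function(j) {
    map$channel[map$joint == j & map$direction == neural_direction &
                  map$significant]
  })
  names(neural_sets) <- joints
  grp <- if (muscle_direction == "flexion") "flexor" else "extensor"
  sub <- muscles[muscles$group == grp, ]
  muscle_sets <- lapply(joints, function(j) {
    col <- paste(j, muscle_direction, sep = "_")
    if (!col %in% names(sub)) stop("no muscle column for ", col)
    sub$muscle[sub[[col]] == 1]
  })
  names(muscle_sets) <- joints
  herdin_distance(set_overlap_matrix(neural_sets),
                  set_overlap_matrix(muscle_sets))
}

#' Friedman test for repeated rate measures
#'
#' Nonparametric repeated-measures comparison of firing-rate
#' distributions (channels as subjects, conditions as groups), as used to
#' compare joint and direction rate distributions.
#'
#' @param samples Numeric matrix, groups x subjects (each subject
#'   measured once per group).
#' @return List with `statistic` (Friedman chi-square), `df` and
#'   `p.value`.
#' @export
rate_friedman <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2 || ncol(samples) < 2) {
    stop("need at least 2 groups and 2 subjects")
  }
  if (any(!is.finite(samples))) {
    stop("missing or non-finite value in repeated-measures table")
  }
  k <- nrow(samples)
  # fully tied data (identical groups): the statistic is 0 by
  # definition, but the tie-corrected denominator degenerates to 0/0
  ranks <- apply(samples, 2, rank)
  if (all(apply(ranks, 2, function(r) max(r) == min(r)))) {
    return(list(statistic = 0, df = k - 1, p.value = 1))
  }
  ft <- friedman.test(t(samples))
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}
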