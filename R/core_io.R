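#' Movement class labels
#'
#' The six attempted-movement classes: three joints (knee, ankle, toes)
#' crossed with two directions (flexion, extension). For the ankle,
#' "flexion" denotes dorsiflexion and "extension" plantarflexion.
#'
#' @param joints Character vector of joints to include.
#' @return Character vector of class labels, joint-major.
#' @export
movement_classes <- function(joints = c("knee", "ankle", "toes")) {
  as.vector(t(outer(joints, c("flexion", "extension"), paste, sep = "_")))
}

class_joint <- function(class) sub("_(flexion|extension)$", "", class)
class_direction <- function(class) sub("^.*_", "", class)

#' Default intrafascicular channel layout
#'
#' Four transversal intrafascicular multichannel electrodes (TIMEs), each
#' with 14 active sites split over a left and a right side (sites 1-7 on L,
#' 8-14 on R), giving 56 addressable recording channels. Ground contacts
#' are carried in metadata only and excluded from decoding.
#'
#' @param n_electrodes Number of implanted electrodes.
#' @param n_sites Active sites per electrode.
#' @return A data.frame with columns `electrode`, `site`, `side`, `ground`.
#' @export
default_channels <- function(n_electrodes = 4, n_sites = 14) {
  data.frame(
    electrode = rep(seq_len(n_electrodes), each = n_sites),
    site = rep(seq_len(n_sites), times = n_electrodes),
    side = rep(ifelse(seq_len(n_sites) <= n_sites / 2, "L", "R"),
               times = n_electrodes),
    ground = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Construct a multichannel ENG recording
#'
#' @param data Numeric matrix, channels x samples (volts or normalized).
#' @param fs Sampling rate in Hz.
#' @param channels Channel metadata as from [default_channels()]; defaults
#'   to a generic layout matching `nrow(data)`.
#' @param subject_id Subject identifier.
#' @return An object of class `eng_recording`.
#' @export
eng_recording <- function(data, fs = 30000, channels = NULL,
                          subject_id = "S1") {
  data <- as.matrix(data)
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (is.null(channels)) {
    channels <- default_channels()
    if (nrow(channels) != nrow(data)) {
      channels <- data.frame(electrode = 1L, site = seq_len(nrow(data)),
                             side = "L", ground = FALSE)
    }
  }
  if (nrow(data) != nrow(channels)) {
    stop("data has ", nrow(data), " rows but channel table describes ",
         nrow(channels), " channels")
  }
  for (ch in seq_len(nrow(data))) {  # per channel: no full-size temporary
    if (anyNA(data[ch, ]) || any(is.infinite(data[ch, ]))) {
      stop("non-finite samples on channel ", ch)
    }
  }
  structure(
    list(data = data, fs = fs, channels = channels, subject_id = subject_id),
    class = "eng_recording"
  )
}

#' @export
print.eng_recording <- function(x, ...) {
  cat(sprintf(
    "<eng_recording> subject %s: %d channels x %d samples (%.2f s at %g Hz)\n",
    x$subject_id, nrow(x$data), ncol(x$data),
    ncol(x$data) / x$fs, x$fs))
  cat(sprintf("  electrodes: %s; ground channels: %d\n",
              paste(unique(x$channels$electrode), collapse = ","),
              sum(x$channels$ground)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An `eng_recording`.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Build a trial annotation table
#'
#' Each trial is one attempted movement: a 2 s movement window split into a
#' 1 s flexion sub-window immediately followed by a 1 s extension
#' sub-window, then a 2 s rest window. Windows are half-open `[start, end)`
#' in seconds from recording start.
#'
#' @param class Character vector of class labels (`joint_direction`).
#' @param block,repetition Integer vectors.
#' @param movement_start Numeric vector of movement onsets in seconds.
#' @param movement_s,rest_s Movement and rest durations in seconds.
#' @return A data.frame of class `trial_table` with the phase windows as
#'   columns.
#' @export
trial_table <- function(class, block, repetition, movement_start,
                        movement_s = 2, rest_s = 2) {
  n <- length(class)
  stopifnot(length(block) == n, length(repetition) == n,
            length(movement_start) == n)
  tt <- data.frame(
    class = as.character(class),
    joint = class_joint(class),
    direction = class_direction(class),
    block = as.integer(block),
    repetition = as.integer(repetition),
    movement_start = as.numeric(movement_start),
    movement_end = as.numeric(movement_start) + movement_s,
    stringsAsFactors = FALSE
  )
  half <- movement_s / 2
  tt$flexion_start <- tt$movement_start
  tt$flexion_end <- tt$movement_start + half
  tt$extension_start <- tt$movement_start + half
  tt$extension_end <- tt$movement_end
  tt$rest_start <- tt$movement_end
  tt$rest_end <- tt$movement_end + rest_s
  class(tt) <- c("trial_table", "data.frame")
  tt
}

empty_trial_table <- function() {
  trial_table(character(0), integer(0), integer(0), numeric(0))
}

validate_trials <- function(trials, duration_s) {
  if (nrow(trials) == 0) return(invisible(trials))
  bad <- which(trials$movement_start < 0 | trials$rest_end > duration_s + 1e-9)
  if (length(bad) > 0) {
    stop("trial window(s) outside recording extent [0, ", duration_s,
         "): row(s) ", paste(bad, collapse = ", "))
  }
  invisible(trials)
}

#' Write a recording container to disk
#'
#' The container is a pair of files sharing a stem: `<stem>.json` holding
#' the sampling rate, subject id and channel table, and `<stem>.bin`
#' holding the sample matrix as little-endian float64, channel-major.
#' The round trip through [load_recording()] is bit-exact.
#'
#' @param recording An `eng_recording`.
#' @param stem File path without extension.
#' @return The stem, invisibly.
#' @export
write_recording <- function(recording, stem) {
  header <- list(
    fs = recording$fs,
    subject_id = recording$subject_id,
    n_channels = nrow(recording$data),
    n_samples = ncol(recording$data),
    channels = recording$channels
  )
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_recording
#' @param trials A `trial_table`.
#' @param path CSV output path.
#' @export
write_trials <- function(trials, path) {
  cols <- c("class", "joint", "direction", "block", "repetition",
            "movement_start", "movement_end")
  write.csv(as.data.frame(trials)[, cols, drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' Load a recording container and its trial annotations
#'
#' @param container_path Path to the container header (`<stem>.json`).
#' @param annotation_path Path to the trial CSV (columns `class`, `joint`,
#'   `direction`, `block`, `repetition`, `movement_start`, `movement_end`).
#'   `NULL` yields an empty trial table.
#' @return A list with elements `recording` and `trials`.
#' @export
load_recording <- function(container_path, annotation_path = NULL) {
  header <- jsonlite::read_json(container_path, simplifyVector = TRUE)
  if (is.null(header$fs)) {
    stop("container header is missing the sampling rate 'fs'")
  }
  stem <- sub("\\.json$", "", container_path)
  n <- header$n_channels * header$n_samples
  con <- file(paste0(stem, ".bin"), "rb")
  raw <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(raw) != n) {
    stop("payload holds ", length(raw), " samples, header promises ", n)
  }
  data <- matrix(raw, nrow = header$n_channels)
  rec <- eng_recording(data, fs = header$fs,
                       channels = as.data.frame(header$channels),
                       subject_id = header$subject_id)
  if (is.null(annotation_path)) {
    trials <- empty_trial_table()
  } else {
    ann <- read.csv(annotation_path, stringsAsFactors = FALSE)
    need <- c("class", "block", "repetition", "movement_start")
    miss <- setdiff(need, names(ann))
    if (length(miss) > 0) {
      stop("annotation table is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    movement_s <- if (nrow(ann) > 0 && "movement_end" %in% names(ann)) {
      ann$movement_end[1] - ann$movement_start[1]
    } else 2
    trials <- trial_table(ann$class, ann$block, ann$repetition,
                          ann$movement_start, movement_s = movement_s)
    validate_trials(trials, recording_duration(rec))
  }
  list(recording = rec, trials = trials)
}

#' Cut a recording into labeled phase windows
#'
#' For each trial, the requested phase window is partitioned into
#' contiguous, non-overlapping windows of `window_s` seconds. Half-open
#' sample indexing `floor(t * fs) ... floor((t + window) * fs)` guarantees
#' that the emitted windows tile the phase exactly.
#'
#' @param recording An `eng_recording`.
#' @param trials A `trial_table`.
#' @param phase One of `"flexion"`, `"extension"`, `"rest"`, `"movement"`,
#'   or `"direction"` (the phase window matching each trial's own
#'   direction label).
#' @param window_s Window length in seconds; must divide the phase
#'   duration.
#' @return A list of `labeled_segment` objects (fields `data`, `label`,
#'   `phase`, `t0`, `fs`).
#' @export
segment_trials <- function(recording, trials, phase = "direction",
                           window_s = 0.1) {
  phase <- match.arg(phase,
                     c("direction", "flexion", "extension", "rest",
                       "movement"))
  fs <- recording$fs
  out <- vector("list", 0)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    ph <- if (phase == "direction") tr$direction else phase
    win <- switch(ph,
      flexion = c(tr$flexion_start, tr$flexion_end),
      extension = c(tr$extension_start, tr$extension_end),
      rest = c(tr$rest_start, tr$rest_end),
      movement = c(tr$movement_start, tr$movement_end))
    dur <- win[2] - win[1]
    k <- dur / window_s
    if (abs(k - round(k)) > 1e-9) {
      stop("window_s = ", window_s, " does not divide the ", ph,
           " phase duration ", dur, " (trial row ", i, ")")
    }
    k <- as.integer(round(k))
    for (j in seq_len(k)) {
      t0 <- win[1] + (j - 1) * window_s
      # half-open sample window floor(t*fs) .. floor((t+w)*fs); the
      # epsilon absorbs binary representation error (4.1*30000 is
      # 122999.999... in doubles) so all windows have equal width
      i0 <- floor(t0 * fs + 1e-6)
      i1 <- floor((t0 + window_s) * fs + 1e-6)
      if (i1 > ncol(recording$data)) {
        stop("segment beyond recording extent (trial row ", i, ")")
      }
      seg <- structure(
        list(data = recording$data[, (i0 + 1):i1, drop = FALSE],
             label = tr$class,
             phase = if (ph %in% c("flexion", "extension", "rest")) ph
                     else tr$direction,
             t0 = t0, fs = fs),
        class = "labeled_segment")
      out[[length(out) + 1]] <- seg
    }
  }
  out
}

#' Automated quality-control gate for channels
#'
#' Flags channels whose trace is constant or contains more than
#' `max_nonfinite_frac` non-finite samples. A reproducible surrogate for
#' manual removal of corrupted recordings.
#'
#' @param data Channels x samples matrix (may contain non-finite values).
#' @param max_nonfinite_frac Tolerated fraction of non-finite samples.
#' @return A data.frame with columns `channel`, `flagged`, `reason`.
#' @export
qc_channels <- function(data, max_nonfinite_frac = 0.01) {
  nch <- nrow(data)
  res <- data.frame(channel = seq_len(nch), flagged = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (ch in seq_len(nch)) {
    x <- data[ch, ]
    frac_bad <- mean(!is.finite(x))
    finite <- x[is.finite(x)]
    if (frac_bad > max_nonfinite_frac) {
      res$flagged[ch] <- TRUE
      res$reason[ch] <- sprintf("%.1f%% non-finite samples", 100 * frac_bad)
    } else if (length(finite) > 0 && max(finite) == min(finite)) {
      res$flagged[ch] <- TRUE
      res$reason[ch] <- "constant signal"
    }
  }
  res
}

#' Indices of decodable channels (grounds removed)
#' @param recording An `eng_recording`.
#' @export
decoding_channels <- function(recording) {
  which(!recording$channels$ground)
}
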