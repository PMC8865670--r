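#' Epoched multichannel LFP recordings
#'
#' An `epoch_set` bundles a trials x channels x time array of local field
#' potentials with its sampling rate, time axis (seconds relative to stimulus
#' onset), and per-channel metadata (area, layer, depth).
#'
#' @param signals numeric array, trials x channels x time.
#' @param fs sampling rate in Hz.
#' @param time numeric time axis in seconds, length `dim(signals)[3]`,
#'   uniformly spaced at `1/fs`.
#' @param channels tibble with one row per channel; columns `area`, `layer`
#'   (one of `"L1"`..`"L6"` or `NA`), `depth` (micrometers). Extra columns are
#'   kept.
#' @param condition optional condition label (e.g. `"high"`, `"low"`).
#' @param animal optional animal identifier.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(signals, fs, time, channels, condition = NA_character_,
                      animal = NA_character_) {
  if (length(dim(signals)) != 3L) stopf("`signals` must be a 3-d array (trials x channels x time)")
  if (length(time) != dim(signals)[3]) stopf("time axis length (%d) != number of samples (%d)", length(time), dim(signals)[3])
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(abs(dt - 1 / fs)) > 1e-6 / fs) stopf("time axis is not uniform with step 1/fs")
  }
  channels <- tibble::as_tibble(channels)
  if (nrow(channels) != dim(signals)[2]) stopf("channel metadata has %d rows but signals have %d channels", nrow(channels), dim(signals)[2])
  if (anyNA(signals) || any(!is.finite(signals))) stopf("`signals` contains non-finite samples")
  structure(
    list(signals = signals, fs = fs, time = as.numeric(time),
         channels = channels, condition = condition, animal = animal),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n", d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g s, condition %s, animal %s\n",
              min(x$time), max(x$time), x$condition, x$animal))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$signals)

#' Cut continuous recordings into stimulus-locked epochs
#'
#' Extracts one epoch per event from a continuous channels x time recording.
#' Each epoch spans `window[1]` to `window[2]` seconds around its event.
#'
#' @param continuous numeric matrix, channels x time.
#' @param fs sampling rate of `continuous` in Hz.
#' @param events event (stimulus onset) times in seconds.
#' @param window length-2 numeric, epoch window in seconds relative to each
#'   event, e.g. `c(-0.3, 1)`.
#' @param channels channel metadata tibble (see [epoch_set()]); defaults to
#'   minimal metadata.
#' @inheritParams epoch_set
#'
#' @return An [epoch_set()] whose trials are ordered as `events`.
#' @export
epoch_signals <- function(continuous, fs, events, window, channels = NULL,
                          condition = NA_character_, animal = NA_character_) {
  if (!is.matrix(continuous)) continuous <- as.matrix(continuous)
  n_samp <- ncol(continuous)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  idx0 <- round(events * fs) + 1L # sample index of each event (1-based, t = 0 at sample 1)
  lo <- idx0 + rel[1]
  hi <- idx0 + rel[length(rel)]
  bad <- which(lo < 1 | hi > n_samp)
  if (length(bad)) {
    stopf("events too close to the recording edge: %s (s)",
          paste(signif(events[bad], 6), collapse = ", "))
  }
  n_ch <- nrow(continuous)
  sig <- array(0, dim = c(length(events), n_ch, length(rel)))
  for (i in seq_along(events)) {
    sig[i, , ] <- continuous[, seq(lo[i], hi[i]), drop = FALSE]
  }
  if (is.null(channels)) {
    channels <- tibble::tibble(area = NA_character_, layer = NA_character_,
                               depth = NA_real_, .rows = n_ch)
  }
  epoch_set(sig, fs, rel / fs, channels, condition = condition, animal = animal)
}

#' Bipolar re-referencing at layer-representative channels
#'
#' Derives one bipolar channel per (area, layer) by subtracting the LFP of the
#' electrode immediately above the representative channel from the one
#' immediately below it (below minus above). With 40-um contact spacing and
#' `offset = 1` the two electrodes are 80 um apart. Removes any signal
#' component common to all channels (e.g. the recording reference).
#'
#' @param epochs an [epoch_set()] whose channel metadata include `area`,
#'   `layer`, `depth`. Channels of one area must be depth-ordered.
#' @param representatives tibble with columns `area`, `layer`, `channel`
#'   (index into the channels of `epochs`) naming the representative channel
#'   per (area, layer).
#' @param offset neighbor offset in channels (default 1: immediate neighbors).
#'
#' @return An [epoch_set()] with one derived channel per (area, layer); the
#'   metadata carry the representative depth.
#' @export
bipolar_reference <- function(epochs, representatives, offset = 1L) {
  reps <- tibble::as_tibble(representatives)
  n_ch <- nrow(epochs$channels)
  below <- reps$channel + offset # deeper neighbor (larger index = deeper)
  above <- reps$channel - offset
  bad <- which(above < 1 | below > n_ch |
                 # neighbors must belong to the same area (probe)
                 epochs$channels$area[pmin(pmax(above, 1), n_ch)] != epochs$channels$area[reps$channel] |
                 epochs$channels$area[pmin(pmax(below, 1), n_ch)] != epochs$channels$area[reps$channel])
  if (length(bad)) {
    stopf("missing bipolar neighbor at probe edge for: %s",
          paste(sprintf("%s %s", reps$area[bad], reps$layer[bad]), collapse = ", "))
  }
  sig <- epochs$signals[, below, , drop = FALSE] - epochs$signals[, above, , drop = FALSE]
  meta <- tibble::tibble(
    area = reps$area, layer = reps$layer,
    depth = epochs$channels$depth[reps$channel]
  )
  epoch_set(sig, epochs$fs, epochs$time, meta,
            condition = epochs$condition, animal = epochs$animal)
}

#' Anti-aliased downsampling
#'
#' Low-pass filters each channel with a zero-phase FIR filter (cutoff
#' `0.4 * fs_target`) and then decimates to the target rate. The passband
#' (below `0.4 * fs_target`) is preserved within 1 percent and the stopband
#' (above `fs_target / 2`) is attenuated by more than 40 dB.
#'
#' @param epochs an [epoch_set()].
#' @param fs_target target sampling rate in Hz; `fs / fs_target` must be a
#'   positive integer.
#'
#' @return A downsampled [epoch_set()].
#' @export
downsample <- function(epochs, fs_target) {
  fs <- epochs$fs
  if (fs_target >= fs) stopf("fs_target (%g) must be below fs (%g)", fs_target, fs)
  fac <- fs / fs_target
  if (abs(fac - round(fac)) > 1e-8) stopf("fs / fs_target must be an integer (got %g)", fac)
  fac <- as.integer(round(fac))
  # Windowed-sinc FIR: transition band 0.4*fs_target .. 0.5*fs_target.
  trans <- 0.1 * fs_target / fs # normalized transition width
  n_taps <- min(2L * ceiling(3.3 / (2 * trans)) , 4000L) # hamming: ~3.3/N transition
  n_taps <- max(n_taps, 10L)
  h <- as.numeric(signal::fir1(n_taps, 0.45 * fs_target / (fs / 2), type = "low"))
  d <- dim(epochs$signals)
  keep <- seq(1L, d[3], by = fac)
  out <- array(0, dim = c(d[1], d[2], length(keep)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      filt <- signal::filtfilt(h, 1, epochs$signals[tr, ch, ])
      out[tr, ch, ] <- filt[keep]
    }
  }
  epoch_set(out, fs_target, epochs$time[keep], epochs$channels,
            condition = epochs$condition, animal = epochs$animal)
}
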