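#' Low-pass filter parameters for gravity separation
#'
#' A second-order elliptic (Cauer) IIR low-pass with 0.5 Hz cut-off separates
#' the slowly varying gravity component from body motion at a 40 Hz sampling
#' rate. Ripple figures are not critical; the defaults (0.5 dB passband,
#' 20 dB stopband) are realisable at order 2. The designed filter is
#' normalised to unity DC gain so that a constant (resting) input passes
#' through unchanged.
#'
#' @param order Filter order (default 2).
#' @param cutoff Cut-off frequency in Hz (default 0.5); must lie below the
#'   Nyquist frequency.
#' @param passband_ripple Passband ripple in dB (default 0.5).
#' @param stopband_atten Stopband attenuation in dB (default 20).
#' @param sample_rate Sampling rate in Hz (default 40).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(order = 2, cutoff = 0.5, passband_ripple = 0.5,
                          stopband_atten = 20, sample_rate = 40) {
  if (order < 1) stop("filter 'order' must be >= 1")
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("filter 'cutoff' must lie in (0, sample_rate/2)")
  structure(list(order = order, cutoff = cutoff,
                 passband_ripple = passband_ripple,
                 stopband_atten = stopband_atten,
                 sample_rate = sample_rate),
            class = "filter_params")
}

# Elliptic low-pass coefficients, DC-normalised. Even-order elliptic designs
# sit Rp dB below unity at DC; gravity must pass with gain exactly 1.
design_lowpass <- function(params) {
  fl <- signal::ellip(params$order, params$passband_ripple,
                      params$stopband_atten,
                      params$cutoff / (params$sample_rate / 2), "low")
  dc <- sum(fl$b) / sum(fl$a)
  list(b = fl$b / dc, a = fl$a)
}

#' Separate gravity and body motion
#'
#' Applies the low-pass causally to each axis; the output is the gravity
#' estimate and the motion component is the per-sample difference raw minus
#' gravity, so `gravity + motion == raw` holds exactly. Start-up transients
#' are suppressed by priming the filter with 10 s of the first sample
#' (steady-state initial conditions for a device at rest), which is discarded
#' after filtering.
#'
#' @param trace An [accel_trace()] uniformly sampled at
#'   `params$sample_rate`.
#' @param params A [filter_params()].
#' @return List with elements `gravity` and `motion`, both [accel_trace()]
#'   objects aligned sample-for-sample with the input.
#' @export
separate_gravity <- function(trace, params = filter_params()) {
  if (nrow(trace) == 0) {
    return(list(gravity = trace, motion = trace))
  }
  if (nrow(trace) > 1) {
    dt <- diff(trace$t)
    if (max(abs(dt - 1 / params$sample_rate)) > 1e-6)
      stop("trace timestamps are not uniform at the configured sample rate")
  }
  warmup_s <- 10
  if (nrow(trace) < warmup_s * params$sample_rate)
    warning("trace shorter than filter warm-up (", warmup_s,
            " s); gravity estimate may be less settled")
  fl  <- design_lowpass(params)
  pad <- round(warmup_s * params$sample_rate)
  grav <- sapply(c("ax", "ay", "az"), function(axis) {
    x <- trace[[axis]]
    y <- signal::filter(fl$b, fl$a, c(rep(x[1], pad), x))
    as.numeric(y)[(pad + 1):(pad + length(x))]
  })
  grav <- matrix(grav, ncol = 3)
  gravity <- accel_trace(trace$t, grav[, 1], grav[, 2], grav[, 3],
                         params$sample_rate)
  motion <- accel_trace(trace$t,
                        trace$ax - grav[, 1],
                        trace$ay - grav[, 2],
                        trace$az - grav[, 3],
                        params$sample_rate)
  list(gravity = gravity, motion = motion)
}

#' Split a motion trace into fixed-length windows
#'
#' Consecutive, non-overlapping windows of `window_s` seconds; a trailing
#' partial window is dropped (the classifier operates on a fixed 2 s buffer).
#'
#' @param motion An [accel_trace()].
#' @param window_s Window length in seconds (default 2).
#' @return List of `window_s * sample_rate`-row data frames with columns
#'   `ax, ay, az`.
#' @export
segment_windows <- function(motion, window_s = 2) {
  sr <- sample_rate(motion)
  len <- round(window_s * sr)
  n_win <- nrow(motion) %/% len
  if (n_win == 0) return(list())
  lapply(seq_len(n_win), function(i) {
    rows <- ((i - 1) * len + 1):(i * len)
    motion[rows, c("ax", "ay", "az"), drop = FALSE]
  })
}

#' Extract the per-window feature vector
#'
#' Features: SMV (mean per-sample Euclidean magnitude), SMA (mean per-sample
#' sum of absolute axis values), the maxima of the y and z axes, and the three
#' largest non-DC FFT magnitude bins of the per-sample magnitude signal with
#' their frequencies. Magnitudes are scaled by 2/N so a unit sinusoid in the
#' magnitude signal shows magnitude ~1. Ties in magnitude resolve to the lower
#' frequency. SMV and SMA are means, not sums, so features are invariant to
#' window length.
#'
#' @param window A `window_s * sample_rate`-row matrix/data.frame with columns
#'   ax, ay, az (motion acceleration in g).
#' @param sr Sampling rate in Hz (default 40).
#' @param window_s Expected window length in seconds (default 2).
#' @return Named numeric vector `smv, sma, max_y, max_z, fft_mag1..3,
#'   fft_freq1..3`.
#' @export
extract_features <- function(window, sr = 40, window_s = 2) {
  w <- as.matrix(window)
  n <- nrow(w)
  if (n != round(window_s * sr))
    stop("window has ", n, " samples; expected ", round(window_s * sr))
  mag <- unname(sqrt(rowSums(w^2)))
  smv <- mean(mag)
  sma <- mean(rowSums(abs(w)))
  spec  <- Mod(stats::fft(mag)) * 2 / n
  k     <- seq_len(n %/% 2)              # non-DC bins up to Nyquist
  mags  <- spec[k + 1]
  freqs <- k * sr / n
  ord <- order(-mags, freqs)[1:3]
  c(smv = smv, sma = sma, max_y = max(w[, 2]), max_z = max(w[, 3]),
    fft_mag1 = mags[ord[1]], fft_mag2 = mags[ord[2]], fft_mag3 = mags[ord[3]],
    fft_freq1 = freqs[ord[1]], fft_freq2 = freqs[ord[2]],
    fft_freq3 = freqs[ord[3]])
}

#' Run preprocessing + segmentation + feature extraction on one trace
#'
#' @param trace Raw [accel_trace()].
#' @param params [filter_params()].
#' @param window_s Window length in seconds.
#' @return Data frame with one row of features per 2 s window (zero rows for
#'   traces shorter than one window).
#' @export
trace_features <- function(trace, params = filter_params(), window_s = 2) {
  sep  <- separate_gravity(trace, params)
  wins <- segment_windows(sep$motion, window_s)
  if (length(wins) == 0) {
    return(as.data.frame(as.list(stats::setNames(numeric(10),
      c("smv", "sma", "max_y", "max_z", "fft_mag1", "fft_mag2", "fft_mag3",
        "fft_freq1", "fft_freq2", "fft_freq3"))))[0, ])
  }
  as.data.frame(do.call(rbind, lapply(wins, extract_features,
                                      sr = params$sample_rate,
                                      window_s = window_s)))
}

#' Feature table for a labeled trace collection
#'
#' @param dataset A `labeled_traces` collection from
#'   [generate_labeled_dataset()].
#' @param params [filter_params()].
#' @return Data frame of per-window features with a `label` factor column.
#' @export
dataset_features <- function(dataset, params = filter_params()) {
  parts <- lapply(seq_along(dataset$traces), function(i) {
    f <- suppressWarnings(trace_features(dataset$traces[[i]], params))
    if (nrow(f) > 0) f$label <- dataset$labels[i]
    f
  })
  out <- do.call(rbind, parts)
  out$label <- factor(out$label, levels = levels(dataset$labels))
  rownames(out) <- NULL
  out
}

#' Classify a raw trace into per-window activity categories
#'
#' Full pipeline: gravity separation, 2 s segmentation, feature extraction and
#' decision-tree prediction, one label per window in temporal order.
#'
#' @param model A trained `activity_tree` from [train_tree()] (or loaded with
#'   [read_model()]).
#' @param trace Raw [accel_trace()].
#' @param params [filter_params()].
#' @return Factor of per-window category labels (empty for an empty trace).
#' @export
classify_trace <- function(model, trace, params = filter_params()) {
  feats <- trace_features(trace, params)
  if (nrow(feats) == 0) return(factor(character(0), levels = model$classes))
  predict_tree(model, feats)
}

#' Aggregate per-window labels into a daily MET-minute total
#'
#' The day's amount of physical activity is the MET value of each window
#' multiplied by its duration in minutes, summed over non-stationary windows
#' (idle wear time carries no exercise credit). 300 moderate 2 s windows
#' (10 min at 5 METs) give MT = 50.
#'
#' @param labels Factor/character vector of per-window categories.
#' @param date Day of the recording (`Date` or ISO string).
#' @param window_s Window length in seconds (default 2).
#' @param met Named MET mapping, see [met_values()].
#' @return One-row data.frame `date, MT` (a daily ledger entry).
#' @export
aggregate_daily <- function(labels, date = Sys.Date(), window_s = 2,
                            met = met_values()) {
  labels <- as.character(labels)
  active <- labels[labels != "stationary"]
  unknown <- setdiff(unique(active), names(met))
  if (length(unknown) > 0)
    stop("unknown activity categories: ", paste(unknown, collapse = ", "))
  mt <- sum(met[active]) * window_s / 60
  data.frame(date = as.Date(date), MT = if (length(active)) mt else 0)
}
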