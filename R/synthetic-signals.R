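#' Default activity classes for the synthetic signal generator
#'
#' The five activity-level categories recognised by the pipeline, with the
#' gait parameters used to synthesise each one and its representative MET
#' value. Step frequency and oscillation amplitude increase monotonically
#' with intensity: stationary 0 Hz / 0 g, light 1.5 Hz / 0.15 g, moderate
#' 2 Hz / 0.35 g, vigorous 2.5 Hz / 0.6 g, very vigorous 3 Hz / 0.9 g.
#'
#' @return A data.frame with columns `category`, `step_frequency` (Hz),
#'   `amplitude` (g), `noise_sd` (g) and `met`.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  data.frame(
    category       = c("stationary", "light", "moderate", "vigorous", "very_vigorous"),
    step_frequency = c(0, 1.5, 2.0, 2.5, 3.0),
    amplitude      = c(0, 0.15, 0.35, 0.60, 0.90),
    noise_sd       = c(0.02, 0.05, 0.05, 0.05, 0.05),
    met            = c(1, 2, 5, 7.5, 10),
    stringsAsFactors = FALSE
  )
}

#' Representative MET value per activity category
#'
#' Category midpoints on the MET scale: stationary 1, light 2, moderate 5,
#' vigorous 7.5, very vigorous 10. "Moderate = 5" is anchored by the
#' calibration that 10 minutes of moderately intense walking equals 50
#' MET·minutes.
#'
#' @return Named numeric vector of MET values.
#' @export
met_values <- function() {
  c(stationary = 1, light = 2, moderate = 5, vigorous = 7.5, very_vigorous = 10)
}

#' Specification of a synthetic accelerometer trace
#'
#' Describes one arm-worn recording to synthesise: a gravity component of
#' exactly 1 g along `gravity_orientation`, a periodic gait oscillation
#' (fundamental sinusoid plus a half-weight second harmonic) applied along the
#' same axis, and white Gaussian noise on every axis.
#'
#' @param category Activity-category label (free text; conventionally one of
#'   `activity_classes()$category`).
#' @param step_frequency Gait fundamental frequency in Hz; 0 only for a
#'   stationary recording.
#' @param amplitude Oscillation amplitude in g.
#' @param gravity_orientation Unit 3-vector giving the direction of gravity in
#'   the device frame.
#' @param noise_sd Per-axis Gaussian noise standard deviation in g.
#' @param duration Recording length in seconds.
#' @param sample_rate Sampling rate in Hz (default 40).
#' @param seed Integer seed making the trace reproducible; `NULL` draws from
#'   the session RNG stream.
#'
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(category, step_frequency, amplitude,
                        gravity_orientation = c(0, 0, 1),
                        noise_sd = 0.05, duration = 10,
                        sample_rate = 40, seed = NULL) {
  stopifnot(is.character(category), length(category) == 1)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("invalid signal spec: 'duration' must be a positive number")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("invalid signal spec: 'sample_rate' must be a positive number")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid signal spec: 'noise_sd' must be >= 0")
  if (!is.numeric(step_frequency) || step_frequency < 0)
    stop("invalid signal spec: 'step_frequency' must be >= 0")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("invalid signal spec: 'amplitude' must be >= 0")
  g <- as.numeric(gravity_orientation)
  if (length(g) != 3 || abs(sqrt(sum(g^2)) - 1) > 1e-9)
    stop("invalid signal spec: 'gravity_orientation' must be a unit 3-vector")
  structure(
    list(category = category, step_frequency = step_frequency,
         amplitude = amplitude, gravity_orientation = g,
         noise_sd = noise_sd, duration = duration,
         sample_rate = sample_rate, seed = seed),
    class = "signal_spec"
  )
}

#' Construct an accelerometer trace object
#'
#' @param t Time stamps in seconds.
#' @param ax,ay,az Per-axis acceleration in g.
#' @param sample_rate Sampling rate in Hz.
#' @return A data.frame of class `accel_trace` with columns `t, ax, ay, az`
#'   and a `sample_rate` attribute.
#' @export
accel_trace <- function(t, ax, ay, az, sample_rate = 40) {
  stopifnot(length(t) == length(ax), length(ax) == length(ay),
            length(ay) == length(az))
  out <- data.frame(t = t, ax = ax, ay = ay, az = az)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' Sampling rate of a trace
#' @param trace An `accel_trace`.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) {
    if (nrow(trace) > 1) sr <- 1 / stats::median(diff(trace$t)) else sr <- 40
  }
  sr
}

#' Generate a synthetic accelerometer trace
#'
#' The synthesised signal is
#' `a(t) = gravity_orientation * (1 + m(t)) + noise`, where the gait component
#' `m(t) = amplitude * (sin(2*pi*f*t) + 0.5 * sin(4*pi*f*t))` oscillates along
#' the gravity (arm) axis. Placing the oscillation along gravity makes the
#' per-sample magnitude approximately `1 + m(t)`, so the dominant non-DC
#' frequency of the magnitude signal equals the step frequency.
#'
#' @param spec A [signal_spec()].
#' @return An [accel_trace()] of `duration * sample_rate` samples.
#' @export
#' @examples
#' tr <- generate_trace(signal_spec("moderate", 2, 0.35, seed = 1))
#' head(tr)
generate_trace <- function(spec) {
  if (!inherits(spec, "signal_spec")) stop("'spec' must be a signal_spec")
  n  <- round(spec$duration * spec$sample_rate)
  tt <- (seq_len(n) - 1) / spec$sample_rate
  m  <- if (spec$step_frequency > 0) {
    spec$amplitude * (sin(2 * pi * spec$step_frequency * tt) +
                        0.5 * sin(4 * pi * spec$step_frequency * tt))
  } else {
    rep(0, n)
  }
  gen <- function() {
    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(3 * n, sd = spec$noise_sd), ncol = 3)
    } else {
      matrix(0, nrow = n, ncol = 3)
    }
    acc <- outer(1 + m, spec$gravity_orientation) + noise
    accel_trace(tt, acc[, 1], acc[, 2], acc[, 3], spec$sample_rate)
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Generate a labeled collection of synthetic traces
#'
#' Draws `n_per_class` traces for each activity class with within-class jitter:
#' step frequency and amplitude each multiplied by U(0.9, 1.1), and the gravity
#' orientation tilted by a random angle up to 15 degrees about a random
#' azimuth (arm not held perfectly vertical). Deterministic under `seed`.
#'
#' @param n_per_class Traces per class (>= 1).
#' @param seed Integer seed.
#' @param duration Per-trace duration in seconds (default 10).
#' @param classes Class schedule, see [activity_classes()].
#' @return A list of class `labeled_traces` with elements `traces` (list of
#'   [accel_trace()]), `labels` (factor) and `specs` (data.frame of realised
#'   parameters).
#' @export
generate_labeled_dataset <- function(n_per_class, seed = 1, duration = 10,
                                     classes = activity_classes()) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("'n_per_class' must be >= 1")
  n_per_class <- as.integer(n_per_class)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(nrow(classes) * n_per_class), function(i) {
      list(jf = stats::runif(1, 0.9, 1.1),
           ja = stats::runif(1, 0.9, 1.1),
           tilt = stats::runif(1, 0, 15 * pi / 180),
           azim = stats::runif(1, 0, 2 * pi),
           seed = sample.int(.Machine$integer.max, 1))
    })
  })
  traces <- vector("list", length(draws))
  labels <- character(length(draws))
  specs  <- vector("list", length(draws))
  idx <- 0
  for (ci in seq_len(nrow(classes))) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1
      d <- draws[[idx]]
      ori <- c(sin(d$tilt) * cos(d$azim), sin(d$tilt) * sin(d$azim), cos(d$tilt))
      sp <- signal_spec(
        category       = classes$category[ci],
        step_frequency = classes$step_frequency[ci] * d$jf,
        amplitude      = classes$amplitude[ci] * d$ja,
        gravity_orientation = ori,
        noise_sd       = classes$noise_sd[ci],
        duration       = duration,
        seed           = d$seed
      )
      traces[[idx]] <- generate_trace(sp)
      labels[idx]   <- classes$category[ci]
      specs[[idx]]  <- data.frame(category = sp$category,
                                  step_frequency = sp$step_frequency,
                                  amplitude = sp$amplitude,
                                  noise_sd = sp$noise_sd,
                                  duration = sp$duration,
                                  seed = sp$seed)
    }
  }
  structure(
    list(traces = traces,
         labels = factor(labels, levels = classes$category),
         specs  = do.call(rbind, specs)),
    class = "labeled_traces"
  )
}

#' @export
print.labeled_traces <- function(x, ...) {
  cat("Labeled synthetic accelerometer traces\n")
  print(table(x$labels))
  invisible(x)
}
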