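# Delimited-text readers/writers. All tables are comma-delimited with a
# single header row; dates are ISO-8601. Writers go through a temp file in
# the target directory and rename, so no partial output survives an error.

atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read and write accelerometer trace files
#'
#' Traces are CSV with header `t,ax,ay,az`: time in seconds, acceleration in
#' g. Malformed rows are reported with their line number.
#'
#' @param path File path.
#' @param sample_rate Sampling rate assumed for the loaded trace (default:
#'   inferred from the time stamps).
#' @return `read_trace` returns an [accel_trace()]; `write_trace` its path,
#'   invisibly.
#' @export
read_trace <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!identical(names(d), c("t", "ax", "ay", "az")))
    stop("trace file must have header t,ax,ay,az: ", path)
  num <- lapply(d, function(col) suppressWarnings(as.numeric(col)))
  for (col in names(num)) {
    bad <- which(is.na(num[[col]]) & !is.na(d[[col]]) & nzchar(d[[col]]))
    bad <- c(bad, which(is.na(d[[col]]) | !nzchar(d[[col]])))
    if (length(bad) > 0)
      stop("malformed value in column '", col, "' at line ",
           min(bad) + 1, " of ", path)
  }
  sr <- if (is.null(sample_rate)) {
    if (length(num$t) > 1) round(1 / stats::median(diff(num$t)), 6) else 40
  } else sample_rate
  accel_trace(num$t, num$ax, num$ay, num$az, sr)
}

#' @rdname read_trace
#' @param trace An [accel_trace()].
#' @export
write_trace <- function(trace, path) {
  atomic_write(function(p) {
    utils::write.csv(as.data.frame(trace)[, c("t", "ax", "ay", "az")],
                     p, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read and write daily activity ledgers
#'
#' Ledgers are CSV `date,MT`: ISO dates and daily MET·minute totals.
#'
#' @param path File path.
#' @return `read_ledger` returns a data.frame `date, MT`.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("ledger file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "MT") %in% names(d)))
    stop("ledger file must have columns date,MT: ", path)
  dates <- as.Date(d$date)
  if (anyNA(dates)) stop("unparseable date in ledger ", path)
  mt <- suppressWarnings(as.numeric(d$MT))
  if (anyNA(mt)) stop("malformed MT value at line ",
                      min(which(is.na(mt))) + 1, " of ", path)
  data.frame(date = dates, MT = mt)
}

#' @rdname read_ledger
#' @param ledger Data frame `date, MT`.
#' @export
write_ledger <- function(ledger, path) {
  atomic_write(function(p) {
    out <- data.frame(date = format(as.Date(ledger$date)), MT = ledger$MT)
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read and write AAEI series tables
#'
#' Series tables are CSV `date,MT,I,E,alpha,avg7,avg30` as produced by
#' [run_series()].
#'
#' @param path File path.
#' @return `read_series` returns the series data.frame.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "MT", "I", "E", "alpha", "avg7", "avg30")
  if (!all(need %in% names(d)))
    stop("series file must have columns ", paste(need, collapse = ","))
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable date in series ", path)
  d
}

#' @rdname read_series
#' @param series Series data.frame.
#' @export
write_series <- function(series, path) {
  atomic_write(function(p) {
    out <- series
    out$date <- format(as.Date(out$date))
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Default structured configuration
#'
#' One YAML-serialisable configuration feeds every command: filter design,
#' MET mapping, AAEI parameters, fuzzy goal/threshold/memberships and
#' simulation defaults. Membership entries are 4-vectors of trapezoid
#' breakpoints (`.inf` in YAML for one-sided ramps).
#'
#' @return Nested list of class `aaei_config`.
#' @export
default_config <- function() {
  mems <- default_memberships()
  mem_list <- lapply(mems, function(pair) {
    lapply(pair, function(tz) c(tz$a, tz$b, tz$c, tz$d))
  })
  structure(list(
    filter = list(order = 2, cutoff = 0.5, passband_ripple = 0.5,
                  stopband_atten = 20, sample_rate = 40),
    met = as.list(met_values()),
    aaei = list(k = 1, C = 2, W = 0.5, alpha_min = -2, divisor = 7),
    goal = 600,
    threshold = 5,
    n_grid = 1001,
    pl_range = c(0, 10),
    min_progress = 50,
    memberships = mem_list,
    simulation = list(mean_met = 5, mean_duration = 30,
                      sessions_per_week = 3, days = 60,
                      prompting = FALSE, compliance = 1),
    seed = 1
  ), class = "aaei_config")
}

#' Read / write a configuration file
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `aaei_config` (unspecified
#'   fields take their defaults).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  if (!is.null(user)) cfg <- merge_in(cfg, user)
  cfg <- structure(cfg, class = "aaei_config")
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config An `aaei_config`.
#' @export
write_config <- function(config, path) {
  atomic_write(function(p) yaml::write_yaml(unclass(config), p), path)
}

# validation funnels through the owning modules' constructors
validate_config <- function(config) {
  config_filter_params(config)
  config_aaei_params(config)
  config_prompt_config(config)
  do.call(simulation_config,
          c(config$simulation, list(seed = config$seed, goal = config$goal,
                                    aaei = config_aaei_params(config),
                                    prompt = config_prompt_config(config))))
  invisible(config)
}

config_filter_params <- function(config) {
  do.call(filter_params, config$filter)
}

config_aaei_params <- function(config) {
  do.call(aaei_params, config$aaei)
}

config_prompt_config <- function(config) {
  mems <- lapply(config$memberships, function(pair) {
    lapply(pair, function(bp) {
      bp <- as.numeric(bp)
      if (length(bp) != 4 || anyNA(bp))
        stop("membership breakpoints must be numeric 4-vectors")
      trapezoid(bp[1], bp[2], bp[3], bp[4])
    })
  })
  prompt_config(goal = config$goal, threshold = config$threshold,
                n_grid = config$n_grid,
                pl_range = as.numeric(config$pl_range),
                min_progress = config$min_progress,
                memberships = mems)
}

config_simulation <- function(config, overrides = list()) {
  args <- config$simulation
  args$seed <- config$seed
  args[names(overrides)] <- overrides
  do.call(simulation_config,
          c(args, list(goal = config$goal,
                       aaei = config_aaei_params(config),
                       prompt = config_prompt_config(config))))
}
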