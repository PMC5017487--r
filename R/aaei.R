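#' Parameters of the AAEI recursion
#'
#' The Accumulated Activity Effective Index (AAEI) is a day-resolution
#' recursion
#' \deqn{I(t_2) = \max(0,\; I(t_2-1) + k\,MT(t_2) - E(t_2))}
#' whose decay threshold \eqn{E(t_2) = A(t_2-1)\,C^{-\alpha}} scales the
#' accumulated daily average \eqn{A = I/7} by the base \eqn{C} raised to the
#' negative of a weighted relative-surplus coefficient
#' \deqn{\alpha = \sum_{i\ge 1} \frac{MT(t_2-i) - A(t_2-i)}{A(t_2-i)}\,W^{i-1},}
#' clamped below at \eqn{-2} (the geometric-series limit of pure rest at
#' W = 0.5). Under constant daily activity \eqn{MT = m} the index has the
#' exact fixed point \eqn{I = 7m}; seven consecutive rest days from a fixed
#' point bring it below 5 percent of its starting value.
#'
#' @param k Gain on the daily MET-minute amount (default 1).
#' @param C Decay base (default 2, must exceed 1).
#' @param W Geometric weight of past days in alpha (default 0.5, in (0,1)).
#' @param alpha_min Lower clamp on alpha (default -2).
#' @param divisor Days in the accumulated average A = I/divisor (default 7).
#' @return Object of class `aaei_params`.
#' @export
aaei_params <- function(k = 1, C = 2, W = 0.5, alpha_min = -2, divisor = 7) {
  if (k <= 0) stop("'k' must be > 0")
  if (C <= 1) stop("'C' must be > 1")
  if (W <= 0 || W >= 1) stop("'W' must lie in (0, 1)")
  structure(list(k = k, C = C, W = W, alpha_min = alpha_min,
                 divisor = divisor),
            class = "aaei_params")
}

#' AAEI state
#'
#' Holds the monitoring history needed to advance the recursion one day:
#' per-day MT, index I, the threshold E applied on each day and the alpha
#' used. A new user starts with empty history and I = 0. History vectors may
#' be supplied to reconstruct a state (e.g. from a stored series table).
#'
#' @param params [aaei_params()].
#' @param mt,I,E,alpha Equal-length per-day history vectors (optional).
#' @return Object of class `aaei_state`.
#' @export
aaei_state <- function(params = aaei_params(), mt = numeric(0),
                       I = numeric(0), E = numeric(0),
                       alpha = numeric(0)) {
  n <- length(mt)
  if (length(I) != n) stop("'mt' and 'I' histories must align")
  if (length(E) == 0) E <- rep(0, n)
  if (length(alpha) == 0) alpha <- rep(0, n)
  if (length(E) != n || length(alpha) != n)
    stop("history vectors must have equal length")
  if (any(I < 0)) stop("index history must be non-negative")
  if (any(mt < 0)) stop("MT history must be non-negative")
  structure(list(params = params, mt = as.numeric(mt), I = as.numeric(I),
                 E = as.numeric(E), alpha = as.numeric(alpha)),
            class = "aaei_state")
}

#' Current index value of a state
#' @param state An `aaei_state`.
#' @return Latest I (0 for a fresh state).
#' @export
current_index <- function(state) {
  if (length(state$I) == 0) 0 else state$I[length(state$I)]
}

#' Weighted activity-surplus coefficient alpha
#'
#' Sums the relative surplus (MT - A)/A of each past day, weighted W^(i-1)
#' with i = 1 the most recent day, over the entire monitoring history (distant
#' terms are geometrically negligible, so no truncation is applied). Days with
#' A = 0 contribute 0: no accumulated activity exerts no decay pressure. The
#' result is clamped to [alpha_min, Inf).
#'
#' @param mt_history Per-day MT values, oldest first.
#' @param I_history Aligned per-day index values.
#' @param params [aaei_params()].
#' @return alpha (dimensionless).
#' @export
compute_alpha <- function(mt_history, I_history, params = aaei_params()) {
  L <- length(mt_history)
  if (length(I_history) != L) stop("histories must align")
  if (L == 0) return(0)
  A <- rev(I_history) / params$divisor        # A[i] for the i-th day back
  m <- rev(mt_history)
  terms <- ifelse(A > 0, (m - A) / A, 0) * params$W^(seq_len(L) - 1)
  max(params$alpha_min, sum(terms))
}

#' Decay threshold for the next day
#'
#' `E = A(previous day) * C^(-alpha)`, with alpha computed over the full
#' recorded history. For a state holding days up to t2 this is E(t2+1); inside
#' [update_index()] it is evaluated before the day is appended and is E of the
#' day being processed.
#'
#' @param state An `aaei_state`.
#' @param params Parameters; defaults to the state's own.
#' @return Named list `E`, `alpha`.
#' @export
compute_threshold <- function(state, params = state$params) {
  alpha <- compute_alpha(state$mt, state$I, params)
  A_prev <- current_index(state) / params$divisor
  list(E = A_prev * params$C^(-alpha), alpha = alpha)
}

#' Advance the AAEI by one day
#'
#' @param state An `aaei_state` holding days before the one being recorded.
#' @param mt_today Today's amount of physical activity in MET·minutes (>= 0).
#' @return The state extended by one day.
#' @export
#' @examples
#' s <- aaei_state()
#' for (d in 1:14) s <- update_index(s, 100)
#' current_index(s)
update_index <- function(state, mt_today) {
  if (!is.numeric(mt_today) || length(mt_today) != 1 || is.na(mt_today) ||
      mt_today < 0)
    stop("'mt_today' must be a single non-negative number")
  p <- state$params
  th <- compute_threshold(state, p)
  I_new <- max(0, current_index(state) + p$k * mt_today - th$E)
  state$mt    <- c(state$mt, mt_today)
  state$I     <- c(state$I, I_new)
  state$E     <- c(state$E, th$E)
  state$alpha <- c(state$alpha, th$alpha)
  state
}

#' Predict tomorrow's index under zero activity
#'
#' Sets tomorrow's physical activity to zero: `I_pred = max(0, I - E(t2+1))`,
#' with the threshold computed over the history through today. Never exceeds
#' the current index.
#'
#' @param state An `aaei_state`.
#' @return Predicted index value.
#' @export
predict_next <- function(state) {
  max(0, current_index(state) - compute_threshold(state)$E)
}

#' Run the AAEI recursion over a daily ledger
#'
#' Normalises the ledger (dates must be unique and increasing; missing
#' calendar days are filled with MT = 0), then advances the recursion day by
#' day. Rolling averages are trailing means over the available days, so they
#' are shorter at the start of the series.
#'
#' @param ledger Data frame `date, MT` (dates coercible to `Date`; MT in
#'   MET·minutes).
#' @param params [aaei_params()].
#' @return Data frame `date, MT, I, E, alpha, avg7, avg30`, one row per
#'   calendar day, with the final `aaei_state` attached as attribute
#'   `"state"`.
#' @export
run_series <- function(ledger, params = aaei_params()) {
  stopifnot(all(c("date", "MT") %in% names(ledger)))
  dates <- as.Date(ledger$date)
  if (anyNA(dates)) stop("unparseable dates in ledger")
  if (anyDuplicated(dates)) stop("duplicate dates in ledger")
  if (is.unsorted(dates, strictly = TRUE)) stop("ledger dates must be increasing")
  if (any(ledger$MT < 0)) stop("MT values must be non-negative")
  if (nrow(ledger) == 0) {
    out <- data.frame(date = as.Date(character(0)), MT = numeric(0),
                      I = numeric(0), E = numeric(0), alpha = numeric(0),
                      avg7 = numeric(0), avg30 = numeric(0))
    attr(out, "state") <- aaei_state(params)
    return(out)
  }
  full <- seq(dates[1], dates[length(dates)], by = "day")
  mt <- rep(0, length(full))
  mt[match(dates, full)] <- ledger$MT
  state <- aaei_state(params)
  for (d in seq_along(full)) state <- update_index(state, mt[d])
  trailing <- function(x, w) {
    vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
  }
  out <- data.frame(date = full, MT = mt, I = state$I, E = state$E,
                    alpha = state$alpha,
                    avg7 = trailing(state$I, 7),
                    avg30 = trailing(state$I, 30))
  attr(out, "state") <- state
  out
}

#' Rebuild an AAEI state from a stored series table
#'
#' @param series Data frame as produced by [run_series()].
#' @param params [aaei_params()].
#' @return An `aaei_state` positioned at the last day of the series.
#' @export
as_aaei_state <- function(series, params = aaei_params()) {
  stopifnot(all(c("MT", "I") %in% names(series)))
  aaei_state(params, mt = series$MT, I = series$I,
             E = if ("E" %in% names(series)) series$E else numeric(0),
             alpha = if ("alpha" %in% names(series)) series$alpha else numeric(0))
}

#' @export
print.aaei_state <- function(x, ...) {
  cat("AAEI state:", length(x$I), "day(s) recorded; I =",
      format(current_index(x), digits = 6), "\n")
  invisible(x)
}
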