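#' Trapezoidal membership function
#'
#' Degree rises linearly 0 to 1 on `[a, b]`, is 1 on `[b, c]` and falls to 0
#' on `[c, d]`. Infinite breakpoints give one-sided ramps (e.g.
#' `trapezoid(0, 100, Inf, Inf)` is a saturating rising ramp;
#' `trapezoid(-Inf, -Inf, -100, 0)` the mirrored falling ramp).
#'
#' @param a,b,c,d Breakpoints with `a <= b <= c <= d`.
#' @return Object of class `trapezoid`.
#' @export
trapezoid <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (anyNA(v) || is.unsorted(v)) stop("trapezoid needs a <= b <= c <= d")
  structure(list(a = a, b = b, c = c, d = d), class = "trapezoid")
}

#' Membership degree of a value
#'
#' @param x Numeric vector on the factor axis.
#' @param mf A [trapezoid()].
#' @return Degrees in `[0, 1]` (piecewise linear).
#' @export
fuzzify <- function(x, mf) {
  out <- numeric(length(x))
  plateau <- x >= mf$b & x <= mf$c
  out[plateau] <- 1
  rise <- x > mf$a & x < mf$b
  out[rise] <- (x[rise] - mf$a) / (mf$b - mf$a)
  fall <- x > mf$c & x < mf$d
  out[fall] <- (mf$d - x[fall]) / (mf$d - mf$c)
  out
}

#' Default membership functions
#'
#' The published membership shapes are trapezoids in High/Low pairs per
#' factor, without printed breakpoints; these defaults are the package's
#' calibration. P1, P2 and P3 share one pair: High rises over `[0, 100]`
#' MET-minute-scale points and Low is the mirrored falling ramp over
#' `[-100, 0]`; P4 uses the tighter `[0, 50]` / `[-50, 0]` pair. 50 is one
#' minimum-progress unit (10 min of moderate walking), 100 is two. The
#' prompting-level universe is `[0, 10]`: Low is full on `[0, 3]` falling to
#' 5, High rises from 5 to 7 and is full to 10. With these shapes a user at a
#' comfortable fixed point above goal defuzzifies to PL about 2.04 (no
#' prompt) and a fully inactive user to about 7.96 (prompt).
#'
#' @return Named list of High/Low [trapezoid()] pairs for P1..P4 and PL.
#' @export
default_memberships <- function() {
  wide  <- list(high = trapezoid(0, 100, Inf, Inf),
                low  = trapezoid(-Inf, -Inf, -100, 0))
  tight <- list(high = trapezoid(0, 50, Inf, Inf),
                low  = trapezoid(-Inf, -Inf, -50, 0))
  list(P1 = wide, P2 = wide, P3 = wide, P4 = tight,
       PL = list(high = trapezoid(5, 7, 10, 10),
                 low  = trapezoid(0, 0, 3, 5)))
}

#' The eight-rule prompting rule base
#'
#' Rules 1-4 pair the predictive factor P1 with the phase-locating factor P2
#' (achievement-phase principle: the index should sit above its own 7-day
#' average); rules 5-8 pair the phase factor P3 with the maintenance factor
#' P4 (maintenance principle: the 7-day average should sit above the goal).
#' Consequents: 1 H, 2-4 L, 5-7 H, 8 L.
#'
#' @return Data frame with columns `factor1, level1, factor2, level2,
#'   consequent`.
#' @export
default_rulebase <- function() {
  data.frame(
    factor1 = c(rep("P1", 4), rep("P3", 4)),
    level1  = c("high", "high", "low", "low", "high", "high", "low", "low"),
    factor2 = c(rep("P2", 4), rep("P4", 4)),
    level2  = c("high", "low", "high", "low", "high", "low", "high", "low"),
    consequent = c("high", "low", "low", "low", "high", "high", "high", "low"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the fuzzy prompting engine
#'
#' @param goal Fitness goal G in AAEI points (default 600, a high standard of
#'   sufficient activity; 400 is the lower sufficiency bound).
#' @param threshold Deliver a prompt when PL strictly exceeds this (default 5).
#' @param n_grid Quantisation levels of the PL universe for centre-of-area
#'   defuzzification (default 1001, centroid error well below 0.01).
#' @param pl_range PL universe (default `c(0, 10)`).
#' @param min_progress Floor of the progress value in MET·minutes (default
#'   50 = 10 min of moderate 5-MET walking).
#' @param memberships See [default_memberships()].
#' @param rules See [default_rulebase()].
#' @return Object of class `prompt_config`.
#' @export
prompt_config <- function(goal = 600, threshold = 5, n_grid = 1001,
                          pl_range = c(0, 10), min_progress = 50,
                          memberships = default_memberships(),
                          rules = default_rulebase()) {
  if (goal <= 0) stop("'goal' must be positive")
  if (n_grid < 2) stop("'n_grid' must be at least 2")
  needed <- unique(c(rules$factor1, rules$factor2, "PL"))
  for (f in needed) {
    if (is.null(memberships[[f]]))
      stop("memberships missing for factor ", f)
    for (lv in c("high", "low")) {
      mf <- memberships[[f]][[lv]]
      if (!inherits(mf, "trapezoid"))
        stop("membership ", f, "/", lv, " is not a trapezoid")
    }
  }
  structure(list(goal = goal, threshold = threshold, n_grid = n_grid,
                 pl_range = pl_range, min_progress = min_progress,
                 memberships = memberships, rules = rules),
            class = "prompt_config")
}

# last n index values, padded with zeros for days before monitoring started
pad_tail <- function(x, n) {
  utils::tail(c(rep(0, n), x), n)
}

#' Prompting factors P1-P4
#'
#' All four factors are differences on the AAEI scale, built from the
#' recorded index history (days before monitoring started count as 0), the
#' zero-activity prediction `I_pred = max(0, I - E(t2+1))` and the goal G:
#' P1 = PAI - I_pred (predictive factor; PAI is the predictive 7-day average,
#' six known index values plus the prediction), P2 = G - I_pred (phase
#' locating), P3 = G - 7-day mean of I (phase), and P4 = G minus the
#' predictive 3-day average (maintenance).
#'
#' @param state An [aaei_state()].
#' @param goal Fitness goal in AAEI points.
#' @return List `P1, P2, P3, P4, PAI, I_pred, mean7`.
#' @export
compute_factors <- function(state, goal = 600) {
  I_pred <- predict_next(state)
  last6 <- pad_tail(state$I, 6)
  last7 <- pad_tail(state$I, 7)
  last2 <- pad_tail(state$I, 2)
  PAI   <- (sum(last6) + I_pred) / 7
  mean7 <- sum(last7) / 7
  list(P1 = PAI - I_pred,
       P2 = goal - I_pred,
       P3 = goal - mean7,
       P4 = goal - (sum(last2) + I_pred) / 3,
       PAI = PAI, I_pred = I_pred, mean7 = mean7)
}

#' Mamdani min-max inference
#'
#' Each rule fires at the minimum of its two antecedent degrees; its
#' consequent PL set is clipped at that strength; the aggregate output set is
#' the pointwise maximum of the clipped sets, sampled on the quantised PL
#' grid. The `n_grid` quantisation levels are the midpoints of equal cells
#' spanning the PL universe, which keeps the discrete centre-of-area free of
#' endpoint bias (the plain endpoint grid overweights the universe edges by
#' half a cell).
#'
#' @param factors Output of [compute_factors()].
#' @param config [prompt_config()].
#' @return List `grid`, `mu` (aggregate degrees), `degrees` (high/low degree
#'   per factor) and `strengths` (per rule).
#' @export
infer <- function(factors, config = prompt_config()) {
  mem <- config$memberships
  fnames <- unique(c(config$rules$factor1, config$rules$factor2))
  degrees <- lapply(stats::setNames(fnames, fnames), function(f) {
    c(high = fuzzify(factors[[f]], mem[[f]]$high),
      low  = fuzzify(factors[[f]], mem[[f]]$low))
  })
  h <- (config$pl_range[2] - config$pl_range[1]) / config$n_grid
  grid <- config$pl_range[1] + (seq_len(config$n_grid) - 0.5) * h
  mu <- numeric(length(grid))
  strengths <- numeric(nrow(config$rules))
  for (r in seq_len(nrow(config$rules))) {
    rule <- config$rules[r, ]
    s <- min(degrees[[rule$factor1]][[rule$level1]],
             degrees[[rule$factor2]][[rule$level2]])
    strengths[r] <- s
    if (s > 0) {
      mu <- pmax(mu, pmin(s, fuzzify(grid, mem$PL[[rule$consequent]])))
    }
  }
  list(grid = grid, mu = mu, degrees = degrees, strengths = strengths)
}

#' Centre-of-area defuzzification
#'
#' `PL = sum(w * mu(w)) / sum(mu(w))` over the quantised universe; 0 when the
#' aggregate set is identically zero.
#'
#' @param grid Quantisation points.
#' @param mu Aggregate membership degrees on `grid`.
#' @return The crisp prompting level.
#' @export
defuzzify <- function(grid, mu) {
  s <- sum(mu)
  if (s == 0) return(0)
  sum(grid * mu) / s
}

#' Prompting value in MET-minutes
#'
#' Two components: the amount needed to get back to the trailing 7-day
#' average index (including today's threshold E(t2), which tomorrow's update
#' will subtract), and a progress component `ps` equal to the 7-day average
#' scaled by PL percent, floored at `min_progress` (50 = 10 min of moderate
#' walking). The total is floored at the progress value so a delivered prompt
#' never suggests a non-positive amount.
#'
#' @param state An [aaei_state()].
#' @param pl Crisp prompting level; must exceed `threshold` (a prompting value
#'   is only defined once a prompt has been decided).
#' @param goal Fitness goal (unused in the arithmetic, kept for context).
#' @param threshold Delivery threshold (default 5).
#' @param min_progress Progress floor (default 50).
#' @return List `ps`, `progress_value`, `PV`.
#' @export
prompting_value <- function(state, pl, goal = 600, threshold = 5,
                            min_progress = 50) {
  if (pl <= threshold)
    stop("prompting value requested although no prompt was decided (PL <= ",
         threshold, ")")
  mean7 <- sum(pad_tail(state$I, 7)) / 7
  ps <- mean7 * pl / 100
  progress <- if (ps <= min_progress) min_progress else ps
  E_today <- if (length(state$E) == 0) 0 else state$E[length(state$E)]
  pv <- max(progress, mean7 - current_index(state) + E_today + progress)
  list(ps = ps, progress_value = progress, PV = pv)
}

#' Daily prompting decision
#'
#' Runs the full once-a-day chain on an end-of-day state: factors,
#' fuzzification, min-max rule inference, centre-of-area defuzzification,
#' threshold test (strictly greater than), and — when a prompt is delivered —
#' the prompting value. A pure function of (state, config).
#'
#' @param state An [aaei_state()] through the end of the current day.
#' @param config [prompt_config()].
#' @param date Optional date tag carried into the decision.
#' @return Object of class `prompt_decision`: `factors`, `degrees`, `PL`,
#'   `deliver`, and `ps`/`progress_value`/`PV` when delivering (NA
#'   otherwise).
#' @export
#' @examples
#' decide(aaei_state())          # inactive user: prompt, PV = 50
decide <- function(state, config = prompt_config(), date = NULL) {
  factors <- compute_factors(state, config$goal)
  inf <- infer(factors, config)
  pl <- defuzzify(inf$grid, inf$mu)
  deliver <- pl > config$threshold
  pv <- list(ps = NA_real_, progress_value = NA_real_, PV = NA_real_)
  if (deliver) {
    pv <- prompting_value(state, pl, config$goal, config$threshold,
                          config$min_progress)
  }
  structure(list(date = date, factors = factors, degrees = inf$degrees,
                 PL = pl, deliver = deliver, ps = pv$ps,
                 progress_value = pv$progress_value, PV = pv$PV),
            class = "prompt_decision")
}

#' @export
print.prompt_decision <- function(x, ...) {
  cat("Prompt decision", if (!is.null(x$date)) paste0("(", x$date, ")"), "\n")
  cat(sprintf("  P1 = %.2f  P2 = %.2f  P3 = %.2f  P4 = %.2f\n",
              x$factors$P1, x$factors$P2, x$factors$P3, x$factors$P4))
  cat(sprintf("  PL = %.3f -> %s\n", x$PL,
              if (x$deliver) sprintf("prompt, PV = %.1f MET·min", x$PV)
              else "no prompt"))
  invisible(x)
}
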