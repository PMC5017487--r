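test_that("trapezoidal membership is piecewise linear with saturation", {
  mf <- trapezoid(0, 100, Inf, Inf)
  expect_equal(fuzzify(c(-50, 0), mf), c(0, 0))
  expect_equal(fuzzify(50, mf), 0.5)
  expect_equal(fuzzify(c(100, 1e6), mf), c(1, 1))
  lo <- trapezoid(-Inf, -Inf, -100, 0)
  expect_equal(fuzzify(c(-200, -100), lo), c(1, 1))
  expect_equal(fuzzify(-25, lo), 0.25)
  expect_equal(fuzzify(0, lo), 0)
  expect_error(trapezoid(1, 0, 2, 3), "a <= b")
})

test_that("factors reproduce the worked fixed-point and inactive cases", {
  f <- compute_factors(fixed_point_state(100))
  expect_equal(f$I_pred, 600)
  expect_equal(f$P1, (6 / 7) * 100, tolerance = 1e-9)
  expect_equal(f$P2, 0)
  expect_equal(f$P3, -100)
  expect_equal(f$P4, 600 - (700 + 700 + 600) / 3, tolerance = 1e-9)
  z <- compute_factors(aaei_state())
  expect_equal(c(z$P1, z$P2, z$P3, z$P4), c(0, 600, 600, 600))
  # algebraic identity P2 - P1 = G - PAI, for arbitrary states
  withr::with_seed(81, {
    for (rep in 1:10) {
      n <- sample(3:20, 1)
      I <- cumsum(abs(rnorm(n, 50, 40)))
      st <- aaei_state(mt = abs(rnorm(n, 60, 30)), I = I)
      fr <- compute_factors(st)
      expect_equal(fr$P2 - fr$P1, 600 - fr$PAI, tolerance = 1e-9)
    }
  })
})

test_that("min-max inference clips and aggregates the rule consequents", {
  cfg <- prompt_config()
  # every factor fully High: rules 1 and 5 fire at 1 -> full High set
  hi <- infer(list(P1 = 1e4, P2 = 1e4, P3 = 1e4, P4 = 1e4), cfg)
  expect_equal(hi$mu, fuzzify(hi$grid, cfg$memberships$PL$high))
  # every factor fully Low: only Low-consequent rules fire -> full Low set
  lo <- infer(list(P1 = -1e4, P2 = -1e4, P3 = -1e4, P4 = -1e4), cfg)
  expect_equal(lo$mu, fuzzify(lo$grid, cfg$memberships$PL$low))
  expect_equal(lo$strengths, c(0, 0, 0, 1, 0, 0, 0, 1))
  # dead zone between the Low and High ramps: nothing fires
  off <- infer(list(P1 = 0, P2 = 0, P3 = 0, P4 = 0), cfg)
  expect_true(all(off$mu == 0))
  expect_equal(defuzzify(off$grid, off$mu), 0)
})

test_that("centre-of-area defuzzification matches a dense-grid oracle", {
  cfg <- prompt_config()
  grid <- infer(list(P1 = 0, P2 = 0, P3 = 0, P4 = 0), cfg)$grid
  muH <- fuzzify(grid, cfg$memberships$PL$high)
  expect_equal(defuzzify(grid, muH),
               dense_centroid(function(w)
                 fuzzify(w, cfg$memberships$PL$high)),
               tolerance = 1e-3)
  expect_equal(defuzzify(grid, muH), 31.8333 / 4, tolerance = 5e-3)
  muL <- fuzzify(grid, cfg$memberships$PL$low)
  expect_equal(defuzzify(grid, muL),
               dense_centroid(function(w)
                 fuzzify(w, cfg$memberships$PL$low)),
               tolerance = 1e-3)
  # clipped sets too, at several strengths
  for (s in c(0.25, 0.6, 0.9)) {
    mu <- pmin(s, muH)
    expect_equal(defuzzify(grid, mu),
                 dense_centroid(function(w)
                   pmin(s, fuzzify(w, cfg$memberships$PL$high))),
                 tolerance = 1e-3)
  }
  # symmetric aggregate centres on the midpoint
  sym <- pmax(pmin(0.5, fuzzify(grid, cfg$memberships$PL$low)),
              pmin(0.5, fuzzify(grid, cfg$memberships$PL$high)))
  expect_equal(defuzzify(grid, sym), 5, tolerance = 1e-9)
})

test_that("prompting value tops up to the 7-day average with a progress floor", {
  st <- aaei_state(mt = rep(600 / 7, 7), I = rep(600, 7), E = rep(30, 7))
  pv <- prompting_value(st, pl = 6)
  expect_equal(pv$ps, 36)
  expect_equal(pv$progress_value, 50)
  expect_equal(pv$PV, 80)
  pv10 <- prompting_value(st, pl = 10)
  expect_equal(pv10$ps, 60)
  expect_equal(pv10$progress_value, 60)   # above the floor, ps carries
  expect_error(prompting_value(st, pl = 4), "no prompt")
  # the floor binds whenever the scaled average is at or below 50
  for (case in list(c(400, 6), c(100, 9), c(833, 6))) {
    sti <- aaei_state(mt = rep(case[1] / 7, 7), I = rep(case[1], 7))
    expect_equal(prompting_value(sti, case[2])$progress_value,
                 max(50, case[1] * case[2] / 100))
  }
})

test_that("end-to-end decisions match the worked users", {
  fp <- decide(fixed_point_state(100))
  expect_equal(fp$PL, 2.04, tolerance = 0.01)
  expect_false(fp$deliver)
  expect_true(is.na(fp$PV))
  z <- decide(aaei_state())
  expect_equal(z$PL, 7.96, tolerance = 0.01)
  expect_true(z$deliver)
  expect_equal(z$PV, 50)
  # pure function of (state, config)
  expect_equal(unclass(decide(aaei_state())), unclass(z))
})

test_that("decisions follow the achievement and maintenance principles", {
  # below goal with the prediction under the predicted average: prompt
  below <- fixed_point_state(300 / 7)
  fb <- compute_factors(below)
  expect_lt(fb$I_pred, fb$PAI)
  expect_lt(fb$mean7, 600)
  expect_true(decide(below)$deliver)
  # above goal with the prediction holding above the predicted average: none
  above <- aaei_state(mt = rep(400, 7),
                      I = c(650, 700, 750, 800, 850, 900, 950))
  fa <- compute_factors(above)
  expect_gte(fa$I_pred, fa$PAI)
  expect_gte(fa$mean7, 600)
  expect_false(decide(above)$deliver)
  # PL in range, and the deliver flag flips once across fixed-point levels
  pls <- vapply(seq(0, 150, 5), function(m) {
    st <- if (m == 0) aaei_state() else fixed_point_state(m)
    decide(st)$PL
  }, numeric(1))
  expect_true(all(pls >= 0 & pls <= 10))
  delivered <- pls > 5
  expect_true(all(delivered[seq(0, 150, 5) <= 85]))
  expect_true(!any(delivered[seq(0, 150, 5) >= 95]))
})

test_that("prompting level rises with the goal deficit", {
  cfg <- prompt_config()
  pl_of <- function(f) { i <- infer(f, cfg); defuzzify(i$grid, i$mu) }
  # maintenance factors: worsening 7-day-average deficit, P4 in proportion
  pls <- vapply(seq(-150, 150, 10), function(v)
    pl_of(list(P1 = 20, P2 = 100, P3 = v, P4 = v / 2)), numeric(1))
  expect_true(all(diff(pls) >= -1e-9))
  # a user that follows every prompting value sees a non-decreasing 7-day
  # average until the goal is first reached
  r <- run_simulation(simulation_config(sessions_per_week = 0, days = 60,
                                        prompting = TRUE, seed = 9))
  a7 <- r$daily$avg7
  first <- which(a7 >= 600)[1]
  expect_false(is.na(first))
  expect_true(all(diff(a7[1:first]) >= -1e-9))
})
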