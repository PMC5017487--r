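test_that("parameter and state constructors enforce their invariants", {
  expect_error(aaei_params(k = 0), "'k'")
  expect_error(aaei_params(C = 1), "'C'")
  expect_error(aaei_params(W = 1), "'W'")
  expect_error(aaei_state(mt = c(1, 2), I = c(1, 2, 3)), "align")
  expect_error(aaei_state(mt = -1, I = 1), "non-negative")
  expect_error(update_index(aaei_state(), -5), "non-negative")
})

test_that("alpha follows the weighted relative-surplus definition", {
  p <- aaei_params()
  expect_equal(compute_alpha(numeric(0), numeric(0), p), 0)
  # constant regime at the fixed point: every term vanishes
  expect_equal(compute_alpha(rep(100, 20), rep(700, 20), p), 0)
  # all-rest after exercise: geometric series -1/(1-W), clamped at -2
  expect_equal(compute_alpha(rep(0, 40), rep(350, 40), p), -2,
               tolerance = 1e-9)
  # days with A = 0 contribute nothing
  expect_equal(compute_alpha(c(50, 0), c(0, 0), p), 0)
  # hand-computed two-day history: i=1 term full weight, i=2 halved
  a <- compute_alpha(c(70, 0), c(700, 600), p)
  expect_equal(a, (0 - 600 / 7) / (600 / 7) + (70 - 100) / 100 * 0.5)
})

test_that("threshold reproduces the worked rest-day values", {
  p <- aaei_params()
  expect_equal(compute_threshold(aaei_state(p))$E, 0)
  fp <- fixed_point_state(100)
  expect_equal(compute_threshold(fp)$E, 100)
  # second consecutive rest day from the fixed point
  s <- update_index(fp, 0)
  expect_equal(current_index(s), 600)
  th <- compute_threshold(s)
  expect_equal(th$alpha, -1)
  expect_equal(th$E, (600 / 7) * 2, tolerance = 1e-9)
})

test_that("constant activity holds the index at its exact fixed point", {
  for (m in c(50, 100, 150)) {
    s <- fixed_point_state(m)
    for (d in 1:10) s <- update_index(s, m)
    expect_equal(current_index(s), 7 * m, tolerance = 1e-12)
  }
  s0 <- update_index(aaei_state(), 0)
  expect_equal(current_index(s0), 0)
})

test_that("seven rest days collapse the index below 5% of its start", {
  s <- fixed_point_state(100)
  path <- numeric(7)
  for (d in 1:7) { s <- update_index(s, 0); path[d] <- current_index(s) }
  oracle <- naive_aaei(rep(0, 7), init_mt = rep(100, 30),
                       init_I = rep(700, 30))
  expect_equal(path, oracle$I, tolerance = 1e-9)
  expect_equal(path[1], 600)
  expect_equal(path[2], 600 - (600 / 7) * 2, tolerance = 1e-9)
  expect_lt(path[7], 0.05 * 700)
  expect_equal(path[7], 12.6057, tolerance = 1e-4)
})

test_that("prediction subtracts tomorrow's threshold and never exceeds I", {
  expect_equal(predict_next(aaei_state()), 0)
  fp <- fixed_point_state(100)
  expect_equal(predict_next(fp), 600)
  for (m in c(10, 40, 90)) {
    s <- fixed_point_state(m)
    expect_lte(predict_next(s), current_index(s))
    expect_gte(predict_next(s), 0)
  }
})

test_that("run_series matches a naive from-scratch re-derivation", {
  withr::with_seed(71, {
    mts <- round(pmax(0, rnorm(90, 60, 60)), 1)
  })
  ledger <- data.frame(date = seq(as.Date("2026-01-01"), by = "day",
                                  length.out = 90), MT = mts)
  series <- run_series(ledger)
  oracle <- naive_aaei(mts)
  expect_equal(series$I, oracle$I, tolerance = 1e-9)
  expect_equal(series$E, oracle$E, tolerance = 1e-9)
  expect_true(all(series$I >= 0))
  expect_true(all(series$E >= 0))
  expect_true(all(series$alpha >= -2))
})

test_that("run_series normalises calendars and computes trailing averages", {
  ledger <- data.frame(date = as.Date(c("2026-01-01", "2026-01-04")),
                       MT = c(100, 100))
  series <- run_series(ledger)
  expect_equal(nrow(series), 4)           # gap days filled with zero
  expect_equal(series$MT, c(100, 0, 0, 100))
  zero <- run_series(data.frame(date = seq(as.Date("2026-01-01"), by = "day",
                                           length.out = 10), MT = 0))
  expect_true(all(zero$I == 0))
  const <- run_series(data.frame(date = seq(as.Date("2026-01-01"), by = "day",
                                            length.out = 60), MT = 100))
  # underdamped approach: monotone rise to a small overshoot, then settling
  # within 5% of the 7m fixed point
  peak <- which.max(const$I)
  expect_true(all(diff(const$I[1:peak]) >= -1e-9))
  expect_lt(const$I[peak], 1.05 * 700)
  expect_lt(abs(const$I[60] - 700) / 700, 0.05)
  expect_equal(const$avg7[60], mean(const$I[54:60]))
  flat <- run_series(data.frame(date = seq(as.Date("2026-01-01"), by = "day",
                                           length.out = 12), MT = 0))
  expect_equal(flat$avg7, rep(0, 12))
  expect_error(run_series(data.frame(date = as.Date(c("2026-01-02",
                                                      "2026-01-01")),
                                     MT = c(1, 1))), "increasing")
  expect_error(run_series(data.frame(date = as.Date(c("2026-01-01",
                                                      "2026-01-01")),
                                     MT = c(1, 1))), "duplicate")
})

test_that("index response has the published qualitative features", {
  # (a) strictly increasing in today's MT, history held fixed
  s <- fixed_point_state(80)
  Is <- vapply(seq(0, 200, 20),
               function(m) current_index(update_index(s, m)), numeric(1))
  expect_true(all(diff(Is) > 0))
  # (b)/(c) three rest days interleaved with exercise cost less index than
  # three consecutive rest days (compare right after the third rest day)
  inter <- naive_aaei(c(0, 100, 0, 100, 0), init_mt = rep(100, 30),
                      init_I = rep(700, 30))
  block <- naive_aaei(c(0, 0, 0), init_mt = rep(100, 30),
                      init_I = rep(700, 30))
  expect_gt(tail(inter$I, 1), tail(block$I, 1))
  # (d) the first rest day is punished less than later consecutive ones
  rest <- naive_aaei(c(0, 0, 0), init_mt = rep(100, 30),
                     init_I = rep(700, 30))
  expect_lt(rest$E[1], rest$E[2])
  expect_lt(rest$E[2], rest$E[3])
  # (e) checked in detail above: 7 rest days fall below 5% of the start
})
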