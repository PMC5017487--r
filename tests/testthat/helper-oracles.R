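# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (full recomputation each day, dense-grid
# integration) rather than calling the package's incremental code paths.

# Naive AAEI re-derivation: for every day, recompute alpha over the whole
# prior history from scratch, then apply threshold and index update.
# Optional init_mt/init_I seed the recursion with a pre-existing history
# (e.g. an exact fixed point); only the days in `mts` are returned.
naive_aaei <- function(mts, k = 1, C = 2, W = 0.5, alpha_min = -2,
                       divisor = 7, init_mt = numeric(0),
                       init_I = numeric(0)) {
  n0 <- length(init_mt)
  mt_all <- c(init_mt, mts)
  I <- c(init_I, numeric(length(mts)))
  E <- c(rep(NA_real_, n0), numeric(length(mts)))
  for (t in (n0 + 1):(n0 + length(mts))) {
    L <- t - 1
    a <- 0
    if (L > 0) {
      for (i in 1:L) {
        A <- I[L - i + 1] / divisor
        m <- mt_all[L - i + 1]
        if (A > 0) a <- a + (m - A) / A * W^(i - 1)
      }
    }
    a <- max(alpha_min, a)
    E[t] <- (if (t == 1) 0 else I[t - 1] / divisor) * C^(-a)
    I[t] <- max(0, (if (t == 1) 0 else I[t - 1]) + k * mt_all[t] - E[t])
  }
  keep <- (n0 + 1):(n0 + length(mts))
  list(I = I[keep], E = E[keep])
}

# Dense-grid centre-of-area centroid of an arbitrary membership curve.
dense_centroid <- function(mu_fun, lo = 0, hi = 10, n = 100001) {
  w <- seq(lo, hi, length.out = n)
  mu <- mu_fun(w)
  if (sum(mu) == 0) return(0)
  sum(w * mu) / sum(mu)
}

# A user sitting exactly at the constant-activity fixed point I = 7m.
fixed_point_state <- function(m, days = 30, params = aaei_params()) {
  aaei_state(params, mt = rep(m, days), I = rep(7 * m, days),
             E = rep(m, days), alpha = rep(0, days))
}
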