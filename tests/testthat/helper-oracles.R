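# Independent oracles used by the simulator tests. These deliberately avoid
# the package's own code paths: plain-R numeric integration and plain-R
# simulation loops, so that an implementation bug cannot cancel out.

# P(accumulator 1 wins) for the LBA with positive-truncated normal drifts,
# by numeric integration of P(T1 <= T2) over the start-point and drift
# densities: F_i(t) = E_d[P(Uniform(0, A) >= b - d t)], then
# P = integral (1 - F2) dF1 on a log-spaced time grid.
lba_win_prob_oracle <- function(vc, ve, s, A, b, n_d = 1500, n_t = 4000) {
  d_hi <- max(vc, ve) + 8 * s
  dg <- seq(1e-9, d_hi, length.out = n_d)
  dd <- dg[2] - dg[1]
  tg <- exp(seq(log(1e-3), log(1e4), length.out = n_t))
  cross_cdf <- function(v) {
    w <- dnorm(dg, v, s) / pnorm(v / s) * dd
    vapply(tg, function(t) {
      pr <- if (A == 0) as.numeric(dg * t >= b)
            else pmin(1, pmax(0, (A - b + dg * t) / A))
      sum(w * pr)
    }, numeric(1))
  }
  f1 <- cross_cdf(vc)
  f2 <- cross_cdf(ve)
  d_f1 <- diff(c(0, f1))
  surv2_mid <- 1 - (c(0, head(f2, -1)) + f2) / 2
  sum(surv2_mid * d_f1) + (1 - f1[length(f1)])
}

# plain-R brute-force simulation of K independent, floored, drifting
# accumulators racing to a common threshold (the beta = lam = 0 LCA)
race_oracle_sim <- function(n, v, b, t0, sigma, h, max_steps) {
  k <- length(v)
  x <- matrix(0, n, k)
  resp <- integer(n)
  steps <- integer(n)
  active <- seq_len(n)
  sq <- sigma * sqrt(h)
  for (s in seq_len(max_steps)) {
    na <- length(active)
    eps <- matrix(rnorm(na * k), na, k)
    x[active, ] <- pmax(0, x[active, , drop = FALSE] +
                          matrix(v * h, na, k, byrow = TRUE) + sq * eps)
    crossed <- x[active, , drop = FALSE] >= b
    hit <- which(rowSums(crossed) > 0)
    if (length(hit)) {
      resp[active[hit]] <- apply(crossed[hit, , drop = FALSE], 1, which.max)
      steps[active[hit]] <- s
      active <- active[-hit]
    }
    if (!length(active)) break
  }
  rt <- ifelse(resp == 0L, NA_real_, t0 + steps * h)
  list(resp = resp, rt = rt)
}

# noise-free UGM recursion, iterated directly: returns the first step at
# which the decision variable reaches the threshold (NA if never)
ugm_deterministic_steps <- function(v, a, tau, u_slope, u_intercept, h,
                                    max_steps) {
  e <- 0
  for (s in seq_len(max_steps)) {
    e <- e + (h / tau) * (v - e)
    y <- e * (u_intercept + u_slope * 1000 * s * h)
    if (abs(y) >= a) return(s)
  }
  NA_integer_
}

# three-sigma binomial tolerance for an empirical proportion
prop_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# 1% two-sample Kolmogorov-Smirnov critical value
ks_crit_1pct <- function(n, m = n) 1.628 * sqrt((n + m) / (n * m))
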