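diff_p <- list(v = 0.1, a = 0.1, z = 0.05, ter = 0.2)
lca_p <- list(v = c(0.25, 0.2), b = 0.06, t0 = 0.2, beta = 0.2, lam = 0.2)
ugm_p <- list(v = 0.2, a = 50, ter = 0.2, tau = 0.1)
stp <- step_config(h = 0.001, max_steps = 1000)

test_that("parameter and profile validation reject broken inputs", {
  expect_error(diffusion_params(v = 0.1, a = 0.1, z = 0.15), "z")
  expect_error(diffusion_params(v = 0.1, a = 0.1, z = 0.05, sz = 0.2),
               "start-point")
  expect_error(lca_params(v = 0.2, b = 0.06), "alternative")
  expect_error(ugm_params(v = 0.2, a = 50, tau = 0), "tau")
  expect_error(
    simulate_diffusion(10, diff_p, stp,
                       schedule_pack(upper_profile = rep(0.1, 10))),
    "length max_steps")
  expect_error(
    simulate_diffusion(10, diff_p, stp,
                       schedule_pack(upper_profile = rep(0.0, 1000),
                                     lower_profile = rep(0.1, 1000))),
    "exceed")
  expect_error(
    simulate_lca(10, lca_p, stp,
                 schedule_pack(drift_profile = matrix(0.2, 1000, 3))),
    "matrix")
  expect_error(schedule_pack(swap_time = 0.2), "v2")
  expect_error(schedule_pack(v2 = 0.3), "swap_time")
  expect_error(schedule_pack(drift_profile = 1:10, swap_time = 0.1, v2 = 1),
               "cannot be combined")
})

test_that("all stochastic simulators are seed-deterministic", {
  runs <- list(
    function() simulate_diffusion(500, diff_p, stp),
    function() simulate_lca(500, lca_p, stp),
    function() simulate_ugm(500, ugm_p, stp))
  for (f in runs) {
    set.seed(101); a <- f()
    set.seed(101); b <- f()
    expect_identical(a$resp, b$resp)
    expect_identical(a$rt, b$rt)
  }
})

test_that("an unbiased noise-driven diffusion splits choices evenly", {
  set.seed(103)
  n <- 5e4
  ts <- simulate_diffusion(n, list(v = 0, a = 0.1, z = 0.05, ter = 0.2), stp)
  expect_lt(abs(mean(ts$resp == 1) - 0.5), prop_tol(0.5, n))
})

test_that("a noise-free diffusion ramps deterministically to the boundary", {
  set.seed(104)
  p <- list(v = 0.2, a = 0.1, z = 0.05, ter = 0.2, sigma = 0)
  ts <- simulate_diffusion(200, p, stp)
  need <- ceiling((0.1 - 0.05) / (0.2 * stp$h))  # 250 steps
  expect_true(all(ts$resp == 1L))
  expect_equal(ts$rt, rep(0.2 + need * stp$h, 200))
})

test_that("diffusion choice probabilities match the closed-form Wiener
           absorption probability", {
  # frozen from the closed form (1-exp(-2vz/s^2))/(1-exp(-2va/s^2)) and
  # cross-checked against a fine-step (h = 1e-5) run before freezing
  expect_equal(wiener_absorption_prob(0.1, a = 0.1, z = 0.05), 0.7310586,
               tolerance = 1e-6)
  expect_equal(wiener_absorption_prob(0, a = 0.1, z = 0.05), 0.5)
  expect_equal(wiener_absorption_prob(-0.2, a = 0.1, z = 0.08),
               1 - wiener_absorption_prob(0.2, a = 0.1, z = 0.02),
               tolerance = 1e-12)
  expect_error(wiener_absorption_prob(0.1, a = 0.1, z = 0.2), "z < a")

  n <- 5e4
  set.seed(105)
  ts <- simulate_diffusion(n, diff_p, step_config(0.001, 4000))
  p_true <- wiener_absorption_prob(0.1, 0.1, 0.05)
  p_emp <- mean(ts$resp[ts$resp > 0L] == 1L)
  # O(sqrt(h)) slack: discrete boundary checks push absorption outward
  expect_lt(abs(p_emp - p_true), prop_tol(p_true, n) + 0.012)
})

test_that("halving the time-step leaves the choice probability stable", {
  set.seed(106)
  p1 <- mean(simulate_diffusion(5e4, diff_p, step_config(0.001, 1000))$resp == 1)
  p2 <- mean(simulate_diffusion(5e4, diff_p, step_config(0.0005, 2000))$resp == 1)
  expect_lt(abs(p1 - p2), 2 * prop_tol(0.73, 5e4) + 0.01)
})

test_that("explicit constant profiles reproduce the unscheduled run bitwise", {
  sc_d <- schedule_pack(upper_profile = rep(diff_p$a, 1000),
                        lower_profile = rep(0, 1000),
                        drift_profile = rep(diff_p$v, 1000))
  set.seed(107); base <- simulate_diffusion(3000, diff_p, stp)
  set.seed(107); prof <- simulate_diffusion(3000, diff_p, stp, sc_d)
  expect_identical(prof$resp, base$resp)
  expect_identical(prof$rt, base$rt)

  sc_l <- schedule_pack(drift_profile = matrix(lca_p$v, 1000, 2, byrow = TRUE),
                        threshold_profile = matrix(lca_p$b, 1000, 2))
  set.seed(108); base <- simulate_lca(3000, lca_p, stp)
  set.seed(108); prof <- simulate_lca(3000, lca_p, stp, sc_l)
  expect_identical(prof$resp, base$resp)
  expect_identical(prof$rt, base$rt)

  sc_u <- schedule_pack(drift_profile = rep(ugm_p$v, 1000))
  set.seed(109); base <- simulate_ugm(3000, ugm_p, stp)
  set.seed(109); prof <- simulate_ugm(3000, ugm_p, stp, sc_u)
  expect_identical(prof$resp, base$resp)
  expect_identical(prof$rt, base$rt)
})

test_that("null piecewise schedules reduce to the base models in
           distribution", {
  n <- 1e5
  crit <- ks_crit_1pct(n)
  sc_d <- schedule_pack(swap_time = 0.15, t_delay = 0.05, v2 = diff_p$v)
  set.seed(110); base <- simulate_diffusion(n, diff_p, stp)
  set.seed(111); pw <- simulate_diffusion(n, diff_p, stp, sc_d)
  expect_lt(ks_two_sample(signed_rt(base), signed_rt(pw))$ks_stat, crit)

  sc_l <- schedule_pack(swap_time = 0.1, t_delay = 0.02, v2 = lca_p$v)
  set.seed(112); base <- simulate_lca(n, lca_p, stp)
  set.seed(113); pw <- simulate_lca(n, lca_p, stp, sc_l)
  expect_lt(ks_two_sample(signed_rt(base), signed_rt(pw))$ks_stat, crit)
})

test_that("a mid-trial drift reversal flips late diffusion responses", {
  n <- 5e4
  sc <- schedule_pack(swap_time = 0.1, t_delay = 0.05, v2 = -diff_p$v)
  set.seed(114); base <- simulate_diffusion(n, diff_p, stp)
  set.seed(114); pw <- simulate_diffusion(n, diff_p, stp, sc)
  late <- function(ts) {
    keep <- ts$resp > 0L & ts$rt > 0.2 + 0.15
    mean(ts$resp[keep] == 2L)
  }
  expect_gt(late(pw), late(base))
})

test_that("collapsing-threshold profiles are monotone and speed up
           responses", {
  lin <- linear_collapse(0.1, rate = 0.1, stp, floor = 0.02)
  wei <- weibull_collapse(0.1, a_inf = 0.055, lambda = 0.3, k = 2, stp)
  expect_false(is.unsorted(rev(lin)))
  expect_false(is.unsorted(rev(wei)))
  expect_equal(wei[1], 0.1, tolerance = 1e-3)
  expect_equal(wei[1000], 0.055, tolerance = 1e-3)

  upper <- 0.05 + weibull_collapse(0.05, 0.005, 0.25, 2, stp)
  lower <- 0.05 - weibull_collapse(0.05, 0.005, 0.25, 2, stp)
  sc <- schedule_pack(upper_profile = upper, lower_profile = lower)
  set.seed(115); base <- simulate_diffusion(2e4, diff_p, stp)
  set.seed(115); col <- simulate_diffusion(2e4, diff_p, stp, sc)
  expect_lt(mean(col$rt, na.rm = TRUE), mean(base$rt, na.rm = TRUE))
  expect_identical(n_nonterminated(col), 0L)
})

test_that("mean response time rises with the threshold on matched seeds", {
  rt_at_a <- function(a) {
    set.seed(116)
    p <- modifyList(diff_p, list(a = a, z = a / 2))
    mean(simulate_diffusion(2e4, p, stp)$rt, na.rm = TRUE)
  }
  rts <- vapply(c(0.08, 0.1, 0.12), rt_at_a, numeric(1))
  expect_false(is.unsorted(rts))

  rt_at_b <- function(b) {
    set.seed(117)
    mean(simulate_lca(2e4, modifyList(lca_p, list(b = b)), stp)$rt,
         na.rm = TRUE)
  }
  rts_b <- vapply(c(0.05, 0.06, 0.07), rt_at_b, numeric(1))
  expect_false(is.unsorted(rts_b))
})

test_that("exchangeable LCA alternatives are chosen equally often", {
  n <- 5e4
  set.seed(118)
  ts <- simulate_lca(n, list(v = c(0.25, 0.25, 0.25), b = 0.06, t0 = 0.2,
                             beta = 0.1, lam = 0.2), stp)
  props <- as.numeric(table(factor(ts$resp, levels = 1:3))) / n
  expect_true(all(abs(props - 1 / 3) < prop_tol(1 / 3, n)))
})

test_that("with no leakage or inhibition the LCA is an independent race", {
  n <- 4e4
  p <- list(v = c(0.25, 0.2), b = 0.05, t0 = 0.2, beta = 0, lam = 0)
  st <- step_config(0.001, 1500)
  set.seed(119)
  ts <- simulate_lca(n, p, st, noise = "normal")
  set.seed(120)
  or <- race_oracle_sim(n, p$v, p$b, p$t0, 0.1, 0.001, 1500)
  p_sim <- mean(ts$resp == 1L)
  p_or <- mean(or$resp == 1L)
  expect_lt(abs(p_sim - p_or), 2 * prop_tol(p_or, n))
  ks <- ks_two_sample(ts$rt[ts$resp > 0], or$rt[or$resp > 0])
  expect_lt(ks$ks_stat, ks_crit_1pct(n))
})

test_that("an unreachable LCA threshold leaves every trial unterminated", {
  set.seed(121)
  ts <- simulate_lca(500, list(v = c(0, 0), b = 10, t0 = 0.2, beta = 0,
                               lam = 0, sigma = 0.001),
                     step_config(0.001, 100))
  expect_identical(n_nonterminated(ts), 500L)
  expect_true(all(ts$resp == 0L))
  expect_true(all(is.na(ts$rt)))
})

test_that("an unbiased UGM splits choices evenly", {
  set.seed(122)
  n <- 5e4
  ts <- simulate_ugm(n, modifyList(ugm_p, list(v = 0)), stp)
  expect_lt(abs(mean(ts$resp == 1) - 0.5), prop_tol(0.5, n))
})

test_that("the noise-free UGM crosses exactly when the direct recursion
           does", {
  for (v in c(0.15, 0.3)) {
    p <- modifyList(ugm_p, list(v = v, sigma = 0))
    s_oracle <- ugm_deterministic_steps(v, p$a, p$tau, 1, 0, stp$h,
                                        stp$max_steps)
    set.seed(123)
    ts <- simulate_ugm(50, p, stp)
    expect_true(all(ts$resp == 1L))
    expect_equal(ts$rt, rep(p$ter + s_oracle * stp$h, 50))
  }
})

test_that("look-up-table noise is indistinguishable from exact normal noise
           for every model variant", {
  ms <- 1000
  ramp <- seq(0.05, 0.3, length.out = ms)
  half <- weibull_collapse(0.05, 0.005, 0.25, 2, stp)
  variants <- list(
    lba = function(no) simulate_lba(1e5, lba_params(3, 2, 0.5, 1, 0.2),
                                    noise = no),
    plba = function(no) simulate_plba(
      1e5, plba_params(3, 2, 0.5, 1, 0.2, v2c = 2, v2e = 3, tdelay = 0.05,
                       swaptime = 0.25), noise = no),
    diff = function(no) simulate_diffusion(1e5, diff_p, stp, noise = no),
    diff_p = function(no) simulate_diffusion(
      1e5, diff_p, stp, schedule_pack(swap_time = 0.15, t_delay = 0.05,
                                      v2 = 0.25), noise = no),
    diff_tv = function(no) simulate_diffusion(
      1e5, diff_p, stp, schedule_pack(drift_profile = ramp), noise = no),
    diff_db = function(no) simulate_diffusion(
      1e5, diff_p, stp, schedule_pack(upper_profile = 0.05 + half,
                                      lower_profile = 0.05 - half),
      noise = no),
    lca = function(no) simulate_lca(1e5, lca_p, stp, noise = no),
    lca_p = function(no) simulate_lca(
      1e5, lca_p, stp, schedule_pack(swap_time = 0.1, t_delay = 0.02,
                                     v2 = rev(lca_p$v)), noise = no),
    lca_tv = function(no) simulate_lca(
      1e5, lca_p, stp, schedule_pack(drift_profile = cbind(ramp, rev(ramp))),
      noise = no),
    lca_db = function(no) simulate_lca(
      1e5, lca_p, stp,
      schedule_pack(threshold_profile =
                      cbind(weibull_collapse(0.06, 0.03, 0.3, 2, stp),
                            weibull_collapse(0.06, 0.03, 0.3, 2, stp))),
      noise = no),
    ugm = function(no) simulate_ugm(1e5, ugm_p, stp, noise = no),
    ugm_tv = function(no) simulate_ugm(
      1e5, ugm_p, stp, schedule_pack(drift_profile = ramp * 2), noise = no))
  for (nm in names(variants)) {
    pass <- 0L
    for (seed in 1:5) {
      set.seed(seed)
      s_lut <- variants[[nm]]("lut")
      s_nrm <- variants[[nm]]("normal")
      ks <- ks_two_sample(signed_rt(s_lut), signed_rt(s_nrm))
      if (ks$p_value > 0.01) pass <- pass + 1L
    }
    expect_gte(pass, 4L)
  }
})
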