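#' Parameter sets for the stochastic simulators
#'
#' Validated containers for the diffusion model, the leaky competing
#' accumulator (LCA), and the urgency-gating model (UGM). The simulators
#' also accept plain named lists with the same keys.
#'
#' **Diffusion**: relative evidence `x` starts at `z` between absorbing
#' boundaries 0 and `a` and follows `dx = v dt + sigma dW` (`sigma` fixed
#' to 0.1 by convention to set the scale). Between-trial variability:
#' drift `Normal(v, sv)`, start point `Uniform(z - sz/2, z + sz/2)`,
#' non-decision time `Uniform(ter - ster/2, ter + ster/2)` (uniform widths
#' centred on `z` and `ter`).
#'
#' **LCA**: one accumulator per alternative, all starting at 0, with
#' leakage `lam`, lateral inhibition/excitation balance `beta` (positive =
#' net inhibition), within-trial noise `sigma`, a reflecting floor at 0,
#' and a shared threshold `b`.
#'
#' **UGM**: momentary evidence is low-pass filtered with time constant
#' `tau` (conventionally under 0.25 s) and multiplied by a linearly
#' increasing urgency signal `u(t) = u_intercept + u_slope * t_ms` (`t_ms`
#' the decision time in milliseconds); the decision variable crosses
#' symmetric thresholds at `+a` / `-a`.
#'
#' @param v mean drift rate (a vector with one entry per alternative for
#'   the LCA).
#' @param a threshold: upper boundary for the diffusion (lower boundary at
#'   0), symmetric threshold magnitude for the UGM.
#' @param z diffusion start point, strictly between 0 and `a`.
#' @param ter,t0 non-decision time in seconds.
#' @param sv,sz,ster between-trial variability of drift (normal SD), start
#'   point, and non-decision time (uniform widths); all `>= 0`.
#' @param sigma within-trial noise scale (default 0.1).
#' @param b LCA threshold shared by all accumulators.
#' @param beta LCA lateral inhibition/excitation balance.
#' @param lam LCA leakage rate (per second).
#' @param tau UGM low-pass filter time constant in seconds.
#' @param u_slope UGM urgency gain per millisecond.
#' @param u_intercept UGM urgency at decision time zero.
#' @return A named list of class `"diffusion_params"`, `"lca_params"` or
#'   `"ugm_params"`.
#' @export
diffusion_params <- function(v, a, z = a / 2, ter = 0, sv = 0, sz = 0,
                             ster = 0, sigma = 0.1) {
  p <- list(v = as.numeric(v), a = as.numeric(a), z = as.numeric(z),
            ter = as.numeric(ter), sv = as.numeric(sv), sz = as.numeric(sz),
            ster = as.numeric(ster), sigma = as.numeric(sigma))
  if (any(!vapply(p, function(x) length(x) == 1L && is.finite(x), TRUE)))
    stop("all diffusion parameters must be single finite numbers",
         call. = FALSE)
  if (p$a <= 0) stop("`a` must be positive", call. = FALSE)
  if (p$z <= 0 || p$z >= p$a)
    stop("`z` must lie strictly between 0 and `a`", call. = FALSE)
  if (p$sv < 0 || p$sz < 0 || p$ster < 0)
    stop("`sv`, `sz`, `ster` must be non-negative", call. = FALSE)
  if (p$z - p$sz / 2 <= 0 || p$z + p$sz / 2 >= p$a)
    stop("start-point range `z +/- sz/2` must stay inside (0, a)",
         call. = FALSE)
  if (p$ter - p$ster / 2 < 0)
    stop("non-decision-time range must be non-negative", call. = FALSE)
  if (p$sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  structure(p, class = "diffusion_params")
}

#' @rdname diffusion_params
#' @export
lca_params <- function(v, b, t0 = 0, beta = 0, lam = 0, sigma = 0.1) {
  v <- as.numeric(v)
  if (length(v) < 2L || anyNA(v) || !all(is.finite(v)))
    stop("`v` must be a finite vector with one drift per alternative (>= 2)",
         call. = FALSE)
  p <- list(v = v, b = as.numeric(b), t0 = as.numeric(t0),
            beta = as.numeric(beta), lam = as.numeric(lam),
            sigma = as.numeric(sigma), n_alt = length(v))
  scal <- p[c("b", "t0", "beta", "lam", "sigma")]
  if (any(!vapply(scal, function(x) length(x) == 1L && is.finite(x), TRUE)))
    stop("LCA scalar parameters must be single finite numbers", call. = FALSE)
  if (p$b <= 0) stop("`b` must be positive", call. = FALSE)
  if (p$t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  if (p$sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  structure(p, class = "lca_params")
}

#' @rdname diffusion_params
#' @export
ugm_params <- function(v, a, ter = 0, tau = 0.1, u_slope = 1,
                       u_intercept = 0, sigma = 0.1) {
  p <- list(v = as.numeric(v), a = as.numeric(a), ter = as.numeric(ter),
            tau = as.numeric(tau), u_slope = as.numeric(u_slope),
            u_intercept = as.numeric(u_intercept), sigma = as.numeric(sigma))
  if (any(!vapply(p, function(x) length(x) == 1L && is.finite(x), TRUE)))
    stop("all UGM parameters must be single finite numbers", call. = FALSE)
  if (p$a <= 0) stop("`a` must be positive", call. = FALSE)
  if (p$tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (p$u_slope < 0) stop("`u_slope` must be non-negative", call. = FALSE)
  if (p$ter < 0) stop("`ter` must be non-negative", call. = FALSE)
  if (p$sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  structure(p, class = "ugm_params")
}

as_params <- function(params, constructor, class) {
  if (inherits(params, class)) return(params)
  do.call(constructor, as.list(params))
}

#' Simulate the diffusion model
#'
#' Euler--Maruyama simulation of the (full) diffusion model: per trial the
#' relative evidence starts at `z_trial` and is updated by
#' `x <- x + v_eff * h + sigma * sqrt(h) * eps` until it reaches the upper
#' boundary (`resp = 1`) or the lower boundary (`resp = 2`), checked after
#' each update with inclusive crossings. `eps` comes from the look-up
#' table (default) or from exact normal draws. Between-trial variability
#' (`sv`, `sz`, `ster`) is drawn per trial before stepping. Trials still
#' between the boundaries after `max_steps` steps are non-terminated
#' (`resp = 0`, `rt = NA`).
#'
#' Schedules: a `drift_profile` replaces the drift parameter per step; a
#' piecewise schedule (`swap_time`, `t_delay`, `v2`) switches the drift to
#' `v2` once decision time reaches `swap_time + t_delay`; `upper_profile` /
#' `lower_profile` replace the constant boundaries `a` and 0 (e.g.
#' collapsing thresholds from [weibull_collapse()]).
#'
#' @param n number of trials.
#' @param params a [diffusion_params()] object or named list.
#' @param step a [step_config()].
#' @param schedule an optional [schedule_pack()].
#' @param noise `"lut"` (default) or `"normal"` within-trial noise source.
#' @param lut optional `"normal_lut"`; defaults to [build_lut()] when
#'   `noise = "lut"`.
#' @return A [trial_set()] with `rt = ter_trial + steps * h`.
#' @examples
#' set.seed(1)
#' ts <- simulate_diffusion(500, list(v = 0.2, a = 0.1, ter = 0.2))
#' mean(ts$resp == 1)
#' @export
simulate_diffusion <- function(n, params, step = step_config(),
                               schedule = NULL, noise = c("lut", "normal"),
                               lut = NULL) {
  n <- check_count(n)
  p <- as_params(params, diffusion_params, "diffusion_params")
  sc <- as_schedule(schedule)
  ns <- resolve_noise(noise, lut)
  ms <- step$max_steps

  if (!is.null(sc$threshold_profile))
    stop("`threshold_profile` is an LCA schedule; use `upper_profile` / ",
         "`lower_profile` for the diffusion", call. = FALSE)
  upper <- check_profile(sc$upper_profile, ms, "upper_profile")
  lower <- check_profile(sc$lower_profile, ms, "lower_profile")
  if (is.null(upper)) upper <- rep(p$a, ms)
  if (is.null(lower)) lower <- rep(0, ms)
  if (!all(upper > lower))
    stop("`upper_profile` must exceed `lower_profile` at every step",
         call. = FALSE)
  drift <- check_profile(sc$drift_profile, ms, "drift_profile")

  if (n == 0L) return(trial_set(integer(0), numeric(0)))

  v_trial <- rnorm(n, p$v, p$sv)
  z_trial <- runif(n, p$z - p$sz / 2, p$z + p$sz / 2)
  ter_trial <- runif(n, p$ter - p$ster / 2, p$ter + p$ster / 2)

  if (!is.null(sc$swap_time)) {
    if (length(sc$v2) != 1L)
      stop("diffusion piecewise `v2` must be a single drift", call. = FALSE)
    swap_step <- swap_step_index(sc$swap_time, sc$t_delay, step$h, ms)
    v2_trial <- rnorm(n, sc$v2, p$sv)
  } else {
    swap_step <- ms
    v2_trial <- numeric(0)
  }

  out <- sim_diffusion_cpp(v_trial, z_trial, p$sigma, step$h, ms,
                           upper, lower,
                           if (is.null(drift)) numeric(0) else drift,
                           swap_step, v2_trial,
                           lut_values(ns), ns$noise == "lut")
  finish_sde(out, ter_trial, step$h)
}

lut_values <- function(ns) if (ns$noise == "lut") ns$lut$values else numeric(0)

finish_sde <- function(out, ter, h) {
  rt <- ifelse(out$resp == 0L, NA_real_, ter + out$steps * h)
  trial_set(out$resp, rt)
}

#' Simulate the leaky competing accumulator
#'
#' Euler--Maruyama simulation of the LCA: all accumulators start at 0 and
#' accumulator `i` is updated by
#' `x_i <- max(0, x_i + (v_i - lam * x_i - beta * sum(x_j, j != i)) * h +
#' sigma * sqrt(h) * eps_i)` with independent noise per accumulator. The
#' reflecting floor at 0 is applied after the full update, noise included.
#' The response is the first accumulator to reach its threshold, checked
#' after each step; simultaneous crossings go to the lowest accumulator
#' index.
#'
#' Schedules: `drift_profile` is a `max_steps x n_alt` matrix replacing
#' `v`; a piecewise schedule switches `v` to the vector `v2`;
#' `threshold_profile` is a `max_steps x n_alt` matrix replacing the shared
#' constant threshold `b`.
#'
#' @inheritParams simulate_diffusion
#' @param params an [lca_params()] object or named list.
#' @return A [trial_set()] with `rt = t0 + steps * h`.
#' @export
simulate_lca <- function(n, params, step = step_config(), schedule = NULL,
                         noise = c("lut", "normal"), lut = NULL) {
  n <- check_count(n)
  p <- as_params(params, lca_params, "lca_params")
  sc <- as_schedule(schedule)
  ns <- resolve_noise(noise, lut)
  ms <- step$max_steps
  k <- p$n_alt

  if (!is.null(sc$upper_profile) || !is.null(sc$lower_profile))
    stop("the LCA takes a per-alternative `threshold_profile` matrix, not ",
         "`upper_profile`/`lower_profile`", call. = FALSE)
  thresh <- check_profile(sc$threshold_profile, ms, "threshold_profile", k)
  if (is.null(thresh)) thresh <- matrix(p$b, ms, k)
  drift <- check_profile(sc$drift_profile, ms, "drift_profile", k)

  if (!is.null(sc$swap_time)) {
    v2 <- as.numeric(sc$v2)
    if (length(v2) != k)
      stop("LCA piecewise `v2` must give one drift per alternative",
           call. = FALSE)
    swap_step <- swap_step_index(sc$swap_time, sc$t_delay, step$h, ms)
  } else {
    v2 <- numeric(0)
    swap_step <- ms
  }

  if (n == 0L) return(trial_set(integer(0), numeric(0)))

  out <- sim_lca_cpp(n, p$v, v2, swap_step,
                     if (is.null(drift)) matrix(0, 0, k) else drift,
                     thresh, p$lam, p$beta, p$sigma, step$h, ms,
                     lut_values(ns), ns$noise == "lut")
  finish_sde(out, p$t0, step$h)
}

#' Simulate the urgency-gating model
#'
#' Euler simulation of the UGM: the instantaneous input
#' `r = v_eff + sigma * eps / sqrt(h)` is low-pass filtered,
#' `E <- E + (h / tau) * (r - E)`, and the decision variable
#' `y = E * (u_intercept + u_slope * 1000 * t)` (urgency linear in
#' milliseconds of decision time) is compared against symmetric thresholds:
#' `resp = 1` at `y >= a`, `resp = 2` at `y <= -a`. An optional
#' `drift_profile` vector makes the mean input time-varying.
#'
#' @inheritParams simulate_diffusion
#' @param params a [ugm_params()] object or named list.
#' @return A [trial_set()] with `rt = ter + steps * h`.
#' @export
simulate_ugm <- function(n, params, step = step_config(), schedule = NULL,
                         noise = c("lut", "normal"), lut = NULL) {
  n <- check_count(n)
  p <- as_params(params, ugm_params, "ugm_params")
  sc <- as_schedule(schedule)
  ns <- resolve_noise(noise, lut)
  ms <- step$max_steps

  if (!is.null(sc$upper_profile) || !is.null(sc$lower_profile) ||
      !is.null(sc$threshold_profile) || !is.null(sc$swap_time))
    stop("the UGM supports only a `drift_profile` schedule", call. = FALSE)
  drift <- check_profile(sc$drift_profile, ms, "drift_profile")

  if (n == 0L) return(trial_set(integer(0), numeric(0)))

  out <- sim_ugm_cpp(n, p$v,
                     if (is.null(drift)) numeric(0) else drift,
                     p$a, p$tau, p$u_slope, p$u_intercept, p$sigma,
                     step$h, ms, lut_values(ns), ns$noise == "lut")
  finish_sde(out, p$ter, step$h)
}

#' Probability that a Wiener process is absorbed at the upper boundary
#'
#' Closed-form first-passage probability for a drifting Wiener process
#' between absorbing boundaries 0 and `a`, starting at `z`:
#' `P(upper) = (1 - exp(-2 v z / sigma^2)) / (1 - exp(-2 v a / sigma^2))`,
#' with the zero-drift limit `z / a`. This is the analytic benchmark that
#' the Euler--Maruyama diffusion simulator is tested against.
#'
#' @param v drift rate.
#' @param a upper boundary (`> 0`).
#' @param z start point, strictly between 0 and `a`.
#' @param sigma noise scale (`> 0`), default 0.1.
#' @return Probability of upper-boundary absorption.
#' @examples
#' wiener_absorption_prob(0, a = 0.1, z = 0.05)        # 0.5
#' wiener_absorption_prob(0.1, a = 0.1, z = 0.05)      # plogis(1)
#' @export
wiener_absorption_prob <- function(v, a, z, sigma = 0.1) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(z) || z <= 0 || z >= a)
    stop("need 0 < z < a", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  k <- 2 * v / sigma^2
  if (abs(k * a) < 1e-12) return(z / a)
  expm1(-k * z) / expm1(-k * a)
}
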