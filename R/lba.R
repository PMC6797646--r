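#' Linear ballistic accumulator parameter sets
#'
#' Validated parameter containers for the LBA and its piecewise extension.
#' Simulators also accept plain named lists or vectors using the same keys
#' (`vc, ve, A, b, t0, s` plus `v2c, v2e, tdelay, swaptime` for the
#' piecewise model), which are coerced through these constructors.
#'
#' Parameters: `vc`/`ve` are the mean drift rates of the accumulators that
#' match/mismatch the stimulus (evidence per second); `s` the between-trial
#' drift standard deviation (fixed to 1 by convention to set the evidence
#' scale); `A` the width of the uniform start-point distribution; `b` the
#' response threshold (`A` never exceeds `b`); `t0` the non-decision time in
#' seconds. The piecewise model adds post-change drifts `v2c`/`v2e`, the
#' objective time of the evidence change `swaptime`, and the uptake delay
#' `tdelay` (both in seconds of decision time, i.e. excluding `t0`).
#'
#' @param vc,ve stage-1 mean drift rates (matching / mismatching).
#' @param A start-point range (`>= 0`).
#' @param b threshold (`>= A`, `> 0`).
#' @param t0 non-decision time in seconds (`>= 0`).
#' @param s drift standard deviation (`>= 0`; 0 is a degenerate point mass
#'   useful for deterministic checks).
#' @param v2c,v2e stage-2 mean drift rates.
#' @param tdelay uptake delay in seconds (`>= 0`).
#' @param swaptime time of the evidence change in seconds (`>= 0`).
#' @return A named list of class `"lba_params"` or `"plba_params"`.
#' @export
lba_params <- function(vc, ve, A, b, t0, s = 1) {
  p <- list(vc = as.numeric(vc), ve = as.numeric(ve), A = as.numeric(A),
            b = as.numeric(b), t0 = as.numeric(t0), s = as.numeric(s))
  if (any(!vapply(p, function(z) length(z) == 1L && is.finite(z), TRUE)))
    stop("all LBA parameters must be single finite numbers", call. = FALSE)
  if (p$A < 0) stop("`A` must be non-negative", call. = FALSE)
  if (p$b <= 0 || p$b < p$A)
    stop("`b` must be positive and at least `A`", call. = FALSE)
  if (p$s < 0) stop("`s` must be non-negative", call. = FALSE)
  if (p$t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  structure(p, class = "lba_params")
}

#' @rdname lba_params
#' @export
plba_params <- function(vc, ve, A, b, t0, v2c, v2e, tdelay, swaptime, s = 1) {
  p1 <- lba_params(vc, ve, A, b, t0, s)
  ext <- list(v2c = as.numeric(v2c), v2e = as.numeric(v2e),
              tdelay = as.numeric(tdelay), swaptime = as.numeric(swaptime))
  if (any(!vapply(ext, function(z) length(z) == 1L &&
                    (is.finite(z) || z == Inf), TRUE)))
    stop("all piecewise parameters must be single numbers", call. = FALSE)
  if (ext$tdelay < 0) stop("`tdelay` must be non-negative", call. = FALSE)
  if (ext$swaptime < 0) stop("`swaptime` must be non-negative", call. = FALSE)
  structure(c(unclass(p1), ext), class = "plba_params")
}

coerce_params <- function(params, keys, constructor) {
  params <- as.list(params)
  if (is.null(params[["s"]])) params[["s"]] <- 1
  missing_keys <- setdiff(keys, names(params))
  if (length(missing_keys))
    stop("missing parameter(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  do.call(constructor, params[keys])
}

as_lba_params <- function(params) {
  if (inherits(params, "lba_params")) return(params)
  coerce_params(params, c("vc", "ve", "A", "b", "t0", "s"), lba_params)
}

as_plba_params <- function(params) {
  if (inherits(params, "plba_params")) return(params)
  coerce_params(params, c("vc", "ve", "A", "b", "t0", "v2c", "v2e",
                          "tdelay", "swaptime", "s"), plba_params)
}

# n draws from Normal(mean, s) conditioned on > 0, by rejection; the raw
# normals come either from rnorm or from the look-up table.
draw_trunc_pos <- function(n, mean, s, noise = "normal", lut = NULL,
                           truncate = TRUE, max_rounds = 10000L) {
  if (n == 0L) return(numeric(0))
  if (s == 0) return(rep(mean, n))  # degenerate point mass, not truncated
  d <- mean + s * noise_draw(n, noise, lut)
  if (!truncate) return(d)
  bad <- which(d <= 0)
  rounds <- 0L
  while (length(bad)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("rejection sampling of positive drifts failed to terminate; ",
           "P(drift > 0) is vanishingly small for mean ", mean, ", s ", s,
           call. = FALSE)
    d[bad] <- mean + s * noise_draw(length(bad), noise, lut)
    bad <- bad[d[bad] <= 0]
  }
  d
}

noise_draw <- function(n, noise, lut) {
  if (noise == "normal") return(rnorm(n))
  draw_standard_normal(lut, n)
}

resolve_noise <- function(noise, lut) {
  noise <- match.arg(noise, c("lut", "normal"))
  if (noise == "lut" && is.null(lut)) lut <- build_lut()
  list(noise = noise, lut = lut)
}

# one LBA race stage: start points then drifts, in a fixed draw order so
# that matched seeds give matched races across callers
lba_stage <- function(n, vc, ve, A, b, s, noise, lut, truncate) {
  k1 <- runif(n, 0, A)
  k2 <- runif(n, 0, A)
  d1 <- draw_trunc_pos(n, vc, s, noise, lut, truncate)
  d2 <- draw_trunc_pos(n, ve, s, noise, lut, truncate)
  t1 <- ifelse(d1 > 0, (b - k1) / d1, Inf)
  t2 <- ifelse(d2 > 0, (b - k2) / d2, Inf)
  list(k1 = k1, k2 = k2, d1 = d1, d2 = d2, t1 = t1, t2 = t2)
}

#' Simulate the linear ballistic accumulator
#'
#' Each trial races two independent noiseless accumulators: accumulator `i`
#' starts at `k_i ~ Uniform(0, A)` and rises linearly at drift
#' `d_i ~ Normal(v_i, s)` truncated to positive values, crossing the
#' threshold at `(b - k_i)/d_i`. The first accumulator to reach `b` gives
#' the response (1 = matching, 2 = mismatching) and
#' `rt = t0 + crossing time`. With `truncate_drift = FALSE` the original
#' untruncated drift distribution is used and trials where both drifts are
#' non-positive never terminate (`resp = 0`).
#'
#' @param n number of trials.
#' @param params an [lba_params()] object or named list/vector with keys
#'   `vc, ve, A, b, t0` (and optionally `s`).
#' @param truncate_drift draw drifts from the positive-truncated normal
#'   (default) rather than the unrestricted normal.
#' @param noise source of the standardised drift variates: the look-up
#'   table (`"lut"`, default) or exact normal draws (`"normal"`).
#' @param lut optional `"normal_lut"`; defaults to [build_lut()] when
#'   `noise = "lut"`.
#' @return A [trial_set()].
#' @examples
#' set.seed(1)
#' ts <- simulate_lba(1000, list(vc = 3, ve = 2, A = 0.5, b = 1, t0 = 0.2))
#' mean(ts$resp == 1)
#' @export
simulate_lba <- function(n, params, truncate_drift = TRUE,
                         noise = c("lut", "normal"), lut = NULL) {
  n <- check_count(n)
  p <- as_lba_params(params)
  ns <- resolve_noise(noise, lut)
  st <- lba_stage(n, p$vc, p$ve, p$A, p$b, p$s, ns$noise, ns$lut,
                  truncate_drift)
  race_outcome(st$t1, st$t2, p$t0)
}

race_outcome <- function(t1, t2, t0, offset = 0) {
  tmin <- pmin(t1, t2)
  resp <- ifelse(is.infinite(tmin), 0L, ifelse(t1 <= t2, 1L, 2L))
  rt <- ifelse(resp == 0L, NA_real_, t0 + offset + tmin)
  trial_set(resp, rt)
}

#' Simulate the piecewise linear ballistic accumulator
#'
#' A standard LBA race runs until decision time `T* = swaptime + tdelay`
#' (measured from decision onset, excluding `t0`): the objective evidence
#' changes at `swaptime` but takes `tdelay` seconds to affect accumulation.
#' Trials whose race finishes by `T*` are unchanged. For the rest, each
#' accumulator keeps the evidence level it reached at `T*` and continues
#' with a freshly drawn stage-2 drift `d2_i ~ Normal(v2_i, s)` (truncated
#' positive by default), independent of its stage-1 drift.
#'
#' @inheritParams simulate_lba
#' @param params a [plba_params()] object or named list/vector with the
#'   stage-1 keys plus `v2c, v2e, tdelay, swaptime`.
#' @return A [trial_set()].
#' @export
simulate_plba <- function(n, params, truncate_drift = TRUE,
                          noise = c("lut", "normal"), lut = NULL) {
  n <- check_count(n)
  p <- as_plba_params(params)
  ns <- resolve_noise(noise, lut)
  t_star <- p$swaptime + p$tdelay
  st <- lba_stage(n, p$vc, p$ve, p$A, p$b, p$s, ns$noise, ns$lut,
                  truncate_drift)
  tmin <- pmin(st$t1, st$t2)
  surv <- which(tmin > t_star)   # includes never-terminating stage-1 trials

  resp <- ifelse(is.infinite(tmin), 0L, ifelse(st$t1 <= st$t2, 1L, 2L))
  rt <- ifelse(resp == 0L, NA_real_, p$t0 + tmin)

  if (length(surv)) {
    x1 <- st$k1[surv] + st$d1[surv] * t_star
    x2 <- st$k2[surv] + st$d2[surv] * t_star
    e1 <- draw_trunc_pos(length(surv), p$v2c, p$s, ns$noise, ns$lut,
                         truncate_drift)
    e2 <- draw_trunc_pos(length(surv), p$v2e, p$s, ns$noise, ns$lut,
                         truncate_drift)
    u1 <- ifelse(e1 > 0, (p$b - x1) / e1, Inf)
    u2 <- ifelse(e2 > 0, (p$b - x2) / e2, Inf)
    umin <- pmin(u1, u2)
    resp[surv] <- ifelse(is.infinite(umin), 0L, ifelse(u1 <= u2, 1L, 2L))
    rt[surv] <- ifelse(is.infinite(umin), NA_real_, p$t0 + t_star + umin)
  }
  trial_set(resp, rt)
}
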