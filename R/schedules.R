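#' Time-step configuration for the stochastic simulators
#'
#' @param h Euler--Maruyama time-step in seconds (default 1 ms).
#' @param max_steps maximum number of steps before a trial is declared
#'   non-terminated.
#' @return A list of class `"step_config"`.
#' @export
step_config <- function(h = 0.001, max_steps = 1000L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a single positive number (seconds)", call. = FALSE)
  max_steps <- check_count(max_steps, "max_steps")
  if (max_steps < 1L) stop("`max_steps` must be at least 1", call. = FALSE)
  structure(list(h = h, max_steps = max_steps), class = "step_config")
}

#' Per-time-step schedules for the stochastic simulators
#'
#' Bundles the optional time-varying and piecewise components of a
#' simulation. All profiles are per-time-step (row/element `s` applies
#' during step `s`) and must match `max_steps` in length (rows).
#'
#' * `drift_profile`: per-step drift; a vector for the diffusion and UGM, a
#'   `max_steps x n_alt` matrix for the LCA. Replaces the drift parameter
#'   entirely (time-varying drift variants).
#' * `upper_profile` / `lower_profile`: per-step decision boundaries for the
#'   diffusion (vectors; e.g. collapsing thresholds).
#' * `threshold_profile`: per-step, per-alternative thresholds for the LCA
#'   (a `max_steps x n_alt` matrix).
#' * `swap_time`, `t_delay`, `v2`: piecewise drift change — the drift
#'   switches to `v2` at decision time `swap_time + t_delay` (a scalar for
#'   the diffusion, a vector per alternative for the LCA). Cannot be
#'   combined with `drift_profile`.
#'
#' @param drift_profile optional numeric vector or matrix of per-step drift.
#' @param upper_profile,lower_profile optional numeric vectors of per-step
#'   boundaries (diffusion only).
#' @param threshold_profile optional numeric matrix of per-step thresholds
#'   (LCA only).
#' @param swap_time optional objective evidence-change time in seconds.
#' @param t_delay uptake delay in seconds added to `swap_time`.
#' @param v2 post-change drift (scalar or per-alternative vector).
#' @return A list of class `"schedule_pack"`.
#' @seealso [linear_collapse()], [weibull_collapse()], [read_schedule_csv()]
#' @export
schedule_pack <- function(drift_profile = NULL, upper_profile = NULL,
                          lower_profile = NULL, threshold_profile = NULL,
                          swap_time = NULL, t_delay = 0, v2 = NULL) {
  if (!is.null(swap_time)) {
    if (!is.numeric(swap_time) || length(swap_time) != 1L || swap_time < 0)
      stop("`swap_time` must be a single non-negative number", call. = FALSE)
    if (is.null(v2))
      stop("piecewise schedules need post-change drift `v2`", call. = FALSE)
    if (!is.numeric(t_delay) || length(t_delay) != 1L || t_delay < 0)
      stop("`t_delay` must be a single non-negative number", call. = FALSE)
    if (!is.null(drift_profile))
      stop("a piecewise drift change cannot be combined with a ",
           "`drift_profile`", call. = FALSE)
  } else if (!is.null(v2)) {
    stop("`v2` requires a `swap_time`", call. = FALSE)
  }
  structure(list(drift_profile = drift_profile,
                 upper_profile = upper_profile,
                 lower_profile = lower_profile,
                 threshold_profile = threshold_profile,
                 swap_time = swap_time, t_delay = t_delay, v2 = v2),
            class = "schedule_pack")
}

as_schedule <- function(schedule) {
  if (is.null(schedule)) return(schedule_pack())
  if (inherits(schedule, "schedule_pack")) return(schedule)
  do.call(schedule_pack, as.list(schedule))
}

check_profile <- function(x, max_steps, name, ncol_expect = NULL) {
  if (is.null(x)) return(NULL)
  if (is.null(ncol_expect)) {
    x <- as.numeric(x)
    if (length(x) != max_steps)
      stop(sprintf("`%s` must have length max_steps (%d), got %d",
                   name, max_steps, length(x)), call. = FALSE)
  } else {
    x <- as.matrix(x)
    if (nrow(x) != max_steps || ncol(x) != ncol_expect)
      stop(sprintf("`%s` must be a %d x %d matrix (steps x alternatives)",
                   name, max_steps, ncol_expect), call. = FALSE)
  }
  if (anyNA(x) || !all(is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  x
}

# first step index (0-based) at which the post-change drift applies;
# step s spans decision time [s*h, (s+1)*h), so stage 1 runs while s*h < T*
swap_step_index <- function(swap_time, t_delay, h, max_steps) {
  t_star <- swap_time + t_delay
  if (!is.finite(t_star) || t_star >= max_steps * h) return(max_steps)
  as.integer(ceiling(t_star / h - 1e-9))
}

#' Collapsing-threshold profile generators
#'
#' Helpers that build per-time-step threshold profiles for the time-varying
#' threshold model variants. `linear_collapse()` decreases the threshold
#' linearly in decision time down to a floor; `weibull_collapse()` relaxes
#' it from `a0` towards an asymptote `a_inf` following a Weibull survival
#' curve `a(t) = a_inf + (a0 - a_inf) * exp(-(t/lambda)^k)`, the common
#' three-parameter family for collapsing bounds (initial level, scale,
#' shape). There is no consensus functional form for dynamic thresholds,
#' so profiles are plain vectors and any user-supplied curve can be used
#' instead.
#'
#' @param a0 threshold at decision time zero.
#' @param rate linear collapse rate (evidence units per second).
#' @param floor lowest threshold value allowed.
#' @param a_inf asymptotic threshold.
#' @param lambda Weibull scale (seconds).
#' @param k Weibull shape (`> 0`).
#' @param step a [step_config()] giving the profile length and spacing.
#' @return Numeric vector of length `step$max_steps`.
#' @export
linear_collapse <- function(a0, rate, step = step_config(), floor = 0) {
  t <- seq_len(step$max_steps) * step$h
  pmax(floor, a0 - rate * t)
}

#' @rdname linear_collapse
#' @export
weibull_collapse <- function(a0, a_inf, lambda, k, step = step_config()) {
  if (lambda <= 0 || k <= 0)
    stop("`lambda` and `k` must be positive", call. = FALSE)
  t <- seq_len(step$max_steps) * step$h
  a_inf + (a0 - a_inf) * exp(-(t / lambda)^k)
}

#' Read per-time-step profiles from CSV
#'
#' Reads a profile table with one row per time-step. Recognised columns:
#' `v` (scalar drift profile) or `v1..vK` (per-alternative drift matrix),
#' `aU`/`aL` (diffusion upper/lower boundaries), and `a1..aK`
#' (per-alternative LCA threshold matrix). The row count must equal the
#' `max_steps` of the simulation that consumes the profiles.
#'
#' @param path CSV file path.
#' @return A `"schedule_pack"` holding the profiles found in the file.
#' @export
read_schedule_csv <- function(path) {
  df <- read.csv(path)
  if (nrow(df) == 0L) stop("profile CSV is empty", call. = FALSE)
  nm <- names(df)
  pick_matrix <- function(prefix) {
    cols <- grep(paste0("^", prefix, "[0-9]+$"), nm, value = TRUE)
    if (!length(cols)) return(NULL)
    cols <- cols[order(as.integer(sub(prefix, "", cols)))]
    as.matrix(df[cols])
  }
  drift <- if ("v" %in% nm) as.numeric(df$v) else pick_matrix("v")
  schedule_pack(
    drift_profile = drift,
    upper_profile = if ("aU" %in% nm) as.numeric(df$aU) else NULL,
    lower_profile = if ("aL" %in% nm) as.numeric(df$aL) else NULL,
    threshold_profile = pick_matrix("a"))
}
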