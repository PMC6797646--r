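#' Silverman's rule-of-thumb kernel bandwidth
#'
#' `0.9 * min(SD, IQR/1.34) * n^(-1/5)`, the standard rule of thumb for a
#' Gaussian kernel. Used by default on each alternative's simulated
#' response times before smoothing them into a defective density.
#'
#' @param rts numeric vector of response times (length at least 2, with
#'   positive spread).
#' @return Bandwidth in the units of `rts`.
#' @examples
#' silverman_bandwidth(rnorm(1e4))  # about 0.9 * 1e4^(-1/5)
#' @export
silverman_bandwidth <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 2L)
    stop("need at least 2 observations for a bandwidth", call. = FALSE)
  spread <- min(sd(rts), IQR(rts) / 1.34)
  if (!is.finite(spread) || spread <= 0)
    stop("degenerate sample: zero spread, bandwidth undefined", call. = FALSE)
  0.9 * spread * length(rts)^(-1 / 5)
}

#' Defective kernel density estimates from simulated trials
#'
#' The core of probability density approximation: each response
#' alternative's simulated response times are smoothed with a Gaussian
#' kernel into a density on a 512-point grid spanning
#' `[min - 3 bw, max + 3 bw]`, evaluated at the observed response times by
#' linear interpolation, and scaled by the *defective* weight — the share
#' of all simulated trials (including non-terminated ones) that chose the
#' alternative — so that choice probabilities enter the likelihood and the
#' densities jointly integrate to the terminated fraction. Density values
#' below `density_floor` (including query points outside the simulated
#' support) are floored so log-likelihoods stay finite.
#'
#' @param sim a [trial_set()] of simulated trials.
#' @param query_rts_by_resp named list mapping response alternatives (as
#'   names coercible to integers, e.g. `"1"`, `"2"`) to numeric vectors of
#'   response times at which the density is needed.
#' @param bandwidth kernel bandwidth in seconds; `NULL` (default) applies
#'   [silverman_bandwidth()] to each alternative's simulated times.
#' @param defective scale each alternative's density by its response
#'   proportion (default). With `FALSE`, each density integrates to 1 and
#'   choice probabilities do not enter.
#' @param density_floor lower bound applied to all returned densities.
#' @param grid_n number of equally spaced density grid points.
#' @return A list of class `"pda_result"`: `densities_by_resp` (named list
#'   of density vectors matching `query_rts_by_resp`), `n_nonterminated`,
#'   and `grids` (per alternative: grid `x`, scaled density `y`, and the
#'   defective `weight`), useful for plotting and normalisation checks.
#' @export
defective_kde <- function(sim, query_rts_by_resp, bandwidth = NULL,
                          defective = TRUE, density_floor = 1e-10,
                          grid_n = 512L) {
  if (!is.null(bandwidth) && (!is.numeric(bandwidth) || bandwidth <= 0))
    stop("`bandwidth` must be positive", call. = FALSE)
  if (is.null(names(query_rts_by_resp)))
    stop("`query_rts_by_resp` must be a named list (alternative -> times)",
         call. = FALSE)
  n_total <- nrow(sim)
  dens <- vector("list", length(query_rts_by_resp))
  names(dens) <- names(query_rts_by_resp)
  grids <- dens
  for (r in names(query_rts_by_resp)) {
    q <- as.numeric(query_rts_by_resp[[r]])
    rts <- sim$rt[sim$resp == as.integer(r)]
    if (length(rts) < 2L) {
      # too few simulated trials for this alternative: everything floored
      dens[[r]] <- rep(density_floor, length(q))
      grids[[r]] <- list(x = numeric(0), y = numeric(0),
                         weight = length(rts) / n_total)
      next
    }
    bw <- if (is.null(bandwidth)) silverman_bandwidth(rts) else bandwidth
    weight <- if (defective) length(rts) / n_total else 1
    d <- density(rts, bw = bw, n = grid_n,
                 from = min(rts) - 3 * bw, to = max(rts) + 3 * bw)
    y <- d$y * weight
    at <- approx(d$x, y, xout = q, rule = 1)$y  # NA outside the grid
    at[is.na(at) | at < density_floor] <- density_floor
    dens[[r]] <- at
    grids[[r]] <- list(x = d$x, y = y, weight = weight)
  }
  structure(list(densities_by_resp = dens,
                 n_nonterminated = n_nonterminated(sim),
                 grids = grids),
            class = "pda_result")
}

#' Pseudo-log-likelihood of observed trials by probability density
#' approximation
#'
#' For each experimental condition: simulate `n_sim` trials from the model
#' at that condition's parameters, smooth them into defective densities
#' per response alternative with [defective_kde()], interpolate the
#' densities at the condition's observed (response, response time) pairs,
#' and sum the log densities. The grand sum over conditions approximates
#' the log-likelihood of the data under the model, usable inside any
#' maximum-likelihood or Bayesian machinery. Because the simulators share
#' R's global RNG, `set.seed()` before the call fixes the simulation noise
#' in the likelihood surface.
#'
#' Counts of non-terminated simulated trials per condition are attached as
#' attribute `"n_nonterminated"`; no penalty is added for them by default,
#' but callers can use the counts to penalise parameter sets that leave
#' many trials unabsorbed.
#'
#' @param params_by_cond named list mapping each condition label to the
#'   parameter object passed to `model` (a single unnamed parameter set is
#'   recycled for all conditions).
#' @param data observed trials: a data frame with columns `cond`, `resp`
#'   (integer `>= 1`) and `time` (seconds, `> 0`), as returned by
#'   [read_dataset()].
#' @param model a simulator: a function `(n, params, ...)` returning a
#'   [trial_set()], or the name of one of the built-in simulators
#'   (`"lba"`, `"plba"`, `"diffusion"`, `"lca"`, `"ugm"`).
#' @param conds conditions to evaluate; defaults to the conditions present
#'   in `data`. Every condition must have parameters.
#' @param n_sim simulated trials per condition (default `1e4`).
#' @param bandwidth fixed kernel bandwidth, or `NULL` for Silverman's rule
#'   on each alternative's simulated times.
#' @param defective,density_floor passed to [defective_kde()].
#' @param ... further arguments passed to `model` (e.g. `step`,
#'   `schedule`, `noise`, `lut`).
#' @return A single log-likelihood value with attribute
#'   `"n_nonterminated"` (named per-condition counts).
#' @export
log_dens_like <- function(params_by_cond, data, model, conds = NULL,
                          n_sim = 1e4, bandwidth = NULL, defective = TRUE,
                          density_floor = 1e-10, ...) {
  model <- resolve_model(model)
  data <- validate_dataset(data)
  if (is.null(conds))
    conds <- unique(as.character(data$cond))
  conds <- as.character(conds)
  if (!all(as.character(data$cond) %in% conds))
    stop("`data` contains conditions outside `conds`", call. = FALSE)
  # a plain list whose names mention any condition is a per-condition map;
  # anything else (a parameter object / named parameter vector) is recycled
  per_cond <- is.list(params_by_cond) &&
    is.null(attr(params_by_cond, "class")) &&
    !is.null(names(params_by_cond)) &&
    any(names(params_by_cond) %in% conds)
  if (per_cond) {
    missing_cond <- setdiff(conds, names(params_by_cond))
    if (length(missing_cond))
      stop("no parameters for condition(s): ",
           paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  single <- !per_cond
  total <- 0
  nt <- integer(0)
  for (cn in conds) {
    p <- if (single) params_by_cond else params_by_cond[[cn]]
    rows <- data[as.character(data$cond) == cn, , drop = FALSE]
    sim <- model(n_sim, p, ...)
    nt[cn] <- n_nonterminated(sim)
    if (nrow(rows) == 0L) next
    alts <- sort(unique(rows$resp))
    queries <- lapply(alts, function(a) rows$time[rows$resp == a])
    names(queries) <- as.character(alts)
    kde <- defective_kde(sim, queries, bandwidth = bandwidth,
                         defective = defective,
                         density_floor = density_floor)
    total <- total + sum(vapply(kde$densities_by_resp,
                                function(d) sum(log(d)), numeric(1)))
  }
  structure(total, n_nonterminated = nt)
}

resolve_model <- function(model) {
  if (is.function(model)) return(model)
  switch(match.arg(model, c("lba", "plba", "diffusion", "lca", "ugm")),
         lba = simulate_lba, plba = simulate_plba,
         diffusion = simulate_diffusion, lca = simulate_lca,
         ugm = simulate_ugm)
}

validate_dataset <- function(data) {
  need <- c("cond", "resp", "time")
  if (!all(need %in% names(data)))
    stop("`data` must have columns cond, resp, time", call. = FALSE)
  if (nrow(data)) {
    if (any(!is.finite(data$time)) || any(data$time <= 0))
      stop("observed `time` must be finite and positive", call. = FALSE)
    if (any(data$resp < 1L))
      stop("observed `resp` must be >= 1", call. = FALSE)
  }
  data
}
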