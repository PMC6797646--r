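#' Two-sample Kolmogorov--Smirnov statistic
#'
#' Computes the supremum distance between the empirical CDFs of two samples
#' and an asymptotic p-value from the Kolmogorov distribution with the
#' effective sample size `n m / (n + m)`. Ties (which are the norm for
#' look-up-table draws, a discrete distribution) are handled exactly in the
#' statistic by evaluating the ECDF difference only at the end of each tied
#' run; the asymptotic p-value is the standard continuous approximation,
#' adequate at the large sample sizes (`>= 1e4`) this harness uses.
#'
#' @param a,b numeric sample vectors (non-empty).
#' @return A list with `ks_stat` and `p_value`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$ks_stat  # 1/3
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("samples must not contain NA", call. = FALSE)
  n <- as.numeric(length(a)); m <- as.numeric(length(b))
  comb <- c(a, b)
  o <- order(comb)
  step <- rep(c(1 / n, -1 / m), c(n, m))[o]
  gap <- cumsum(step)
  srt <- comb[o]
  at_run_end <- c(diff(srt) != 0, TRUE)
  d <- max(abs(gap[at_run_end]))
  lambda <- sqrt(n * m / (n + m)) * d
  list(ks_stat = d, p_value = kolmogorov_sf(lambda))
}

# asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^{k-1} e^{-2k^2 l^2}
kolmogorov_sf <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Measure the accuracy of the look-up-table approximation
#'
#' Reproduces the granularity assessment behind the package's choice of
#' default table size. In the `"normal"` context it compares `n`
#' look-up-table draws against `n` exact standard normal draws with a
#' two-sample KS test. In a model context (`"diffusion"`, `"lba"`,
#' `"plba"`, `"lca"`, `"ugm"`) it simulates `n` trials with
#' look-up-table noise and `n` trials with exact normal noise and compares
#' the pooled signed response times (alternative 2 negated, so one KS
#' statistic summarises choices and response times jointly).
#'
#' Coarse tables truncate the normal's tails and are detectable (at
#' granularity 0.01 the KS statistic is about 0.01 with a million draws);
#' at the default granularity of `1e-4` the statistic falls to sampling
#' noise (about 0.001) and the test is non-significant.
#'
#' @param granularity look-up-table granularity, as in [build_lut()].
#' @param n draws (or trials) per sample; at least `1e4`.
#' @param context `"normal"` or a simulator name.
#' @param seed optional integer seed applied before sampling.
#' @param params model parameters for a model context (defaults are
#'   built in for each model).
#' @param step a [step_config()] for the stochastic models.
#' @param per_alternative also report per-alternative KS statistics for
#'   model contexts.
#' @return A list of class `"ks_report"`: `granularity`, `n`, `ks_stat`,
#'   `p_value`, `context` (and `per_alternative` when requested).
#' @export
validate_granularity <- function(granularity, n = 1e6, context = "normal",
                                 seed = NULL, params = NULL,
                                 step = step_config(),
                                 per_alternative = FALSE) {
  n <- check_count(n)
  if (n < 1e4)
    stop("granularity validation needs at least 1e4 samples", call. = FALSE)
  context <- match.arg(context,
                       c("normal", "diffusion", "lba", "plba", "lca", "ugm"))
  if (!is.null(seed)) set.seed(seed)
  lut <- build_lut(granularity)
  per_alt <- NULL
  if (context == "normal") {
    a <- draw_standard_normal(lut, n)
    b <- rnorm(n)
  } else {
    if (is.null(params)) params <- default_validation_params(context)
    sim <- resolve_model(context)
    args <- list(params = params)
    if (context %in% c("diffusion", "lca", "ugm")) args$step <- step
    s_lut <- do.call(sim, c(list(n = n), args, list(noise = "lut", lut = lut)))
    s_nrm <- do.call(sim, c(list(n = n), args, list(noise = "normal")))
    a <- signed_rt(s_lut)
    b <- signed_rt(s_nrm)
    if (per_alternative) {
      per_alt <- lapply(c(1L, 2L), function(r) {
        ks_two_sample(s_lut$rt[s_lut$resp == r], s_nrm$rt[s_nrm$resp == r])
      })
      names(per_alt) <- c("resp1", "resp2")
    }
  }
  ks <- ks_two_sample(a, b)
  structure(list(granularity = granularity, n = n, ks_stat = ks$ks_stat,
                 p_value = ks$p_value, context = context,
                 per_alternative = per_alt),
            class = "ks_report")
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("<ks_report> %s, granularity %g, n = %g\n  KS = %.4g, p = %.3g\n",
              x$context, x$granularity, x$n, x$ks_stat, x$p_value))
  if (!is.null(x$per_alternative))
    for (nm in names(x$per_alternative))
      cat(sprintf("  %s: KS = %.4g, p = %.3g\n", nm,
                  x$per_alternative[[nm]]$ks_stat,
                  x$per_alternative[[nm]]$p_value))
  invisible(x)
}

# workable reference parameter sets for the validation harness
default_validation_params <- function(context) {
  switch(context,
         diffusion = diffusion_params(v = 0.1, a = 0.1, z = 0.05, ter = 0.2),
         lba = lba_params(vc = 3, ve = 2, A = 0.5, b = 1, t0 = 0.2),
         plba = plba_params(vc = 3, ve = 2, A = 0.5, b = 1, t0 = 0.2,
                            v2c = 2, v2e = 3, tdelay = 0.05,
                            swaptime = 0.25),
         lca = lca_params(v = c(0.25, 0.2), b = 0.06, t0 = 0.2,
                          beta = 0.2, lam = 0.2),
         ugm = ugm_params(v = 0.2, a = 50, ter = 0.2, tau = 0.1))
}
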