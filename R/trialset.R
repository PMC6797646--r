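#' Construct a set of simulated trials
#'
#' Container returned by every simulator in the package: a data frame with a
#' `resp` column (integer chosen alternative; `0` marks a trial that never
#' reached threshold within the step budget) and an `rt` column (response
#' time in seconds; `NA` for non-terminated trials).
#'
#' @param resp integer vector of chosen alternatives (0 = non-terminated).
#' @param rt numeric vector of response times in seconds, same length.
#' @return A data frame of class `"trial_set"` with attribute
#'   `n_nonterminated`.
#' @seealso [n_nonterminated()], [signed_rt()]
#' @export
trial_set <- function(resp, rt) {
  resp <- as.integer(resp)
  rt <- as.numeric(rt)
  if (length(resp) != length(rt))
    stop("`resp` and `rt` must have the same length", call. = FALSE)
  if (any(resp < 0L, na.rm = TRUE))
    stop("`resp` must be non-negative (0 = non-terminated)", call. = FALSE)
  rt[resp == 0L] <- NA_real_
  term <- resp > 0L
  if (any(term & !(rt > 0), na.rm = TRUE) || anyNA(rt[term]))
    stop("terminated trials must have rt > 0", call. = FALSE)
  structure(data.frame(resp = resp, rt = rt),
            n_nonterminated = sum(resp == 0L),
            class = c("trial_set", "data.frame"))
}

#' Number of non-terminated trials in a trial set
#'
#' @param x a `"trial_set"` (or any data frame with a `resp` column).
#' @return Integer count of trials with `resp == 0`.
#' @export
n_nonterminated <- function(x) {
  nt <- attr(x, "n_nonterminated")
  if (!is.null(nt)) return(nt)
  sum(x$resp == 0L)
}

#' Pool responses and response times onto a signed axis
#'
#' Response times for one alternative are negated so that a single vector
#' summarises choices and response times jointly (the usual plotting and
#' testing convention for two-choice data: alternative 2 on the negative
#' axis). Non-terminated trials are dropped.
#'
#' @param x a `"trial_set"`.
#' @param negate which response alternative to place on the negative axis.
#' @return Numeric vector of signed response times.
#' @export
signed_rt <- function(x, negate = 2L) {
  keep <- x$resp > 0L
  s <- ifelse(x$resp[keep] == negate, -1, 1)
  s * x$rt[keep]
}

#' @export
print.trial_set <- function(x, ...) {
  n <- nrow(x)
  nt <- n_nonterminated(x)
  cat(sprintf("<trial_set> %d trials, %d non-terminated\n", n, nt))
  if (n > nt) {
    tab <- table(x$resp[x$resp > 0L])
    cat("  choice proportions:",
        paste(sprintf("%s: %.3f", names(tab), as.numeric(tab) / n),
              collapse = ", "), "\n")
    cat(sprintf("  rt (terminated): median %.3f s, range [%.3f, %.3f]\n",
                median(x$rt, na.rm = TRUE), min(x$rt, na.rm = TRUE),
                max(x$rt, na.rm = TRUE)))
  }
  invisible(x)
}

#' @importFrom stats median
NULL
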