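#' Build a look-up-table approximation to the standard normal inverse CDF
#'
#' Precomputes the standard normal quantile function on a symmetric, equally
#' spaced probability grid `x, 2x, ..., 1 - x` (granularity `x`). Sampling
#' then reduces to drawing a uniform integer index into this table: because
#' the grid is equally spaced and symmetric about 0.5, a uniform index is an
#' unbiased discretisation of a uniform probability, and the indexed table
#' entry is an (approximate) standard normal draw. The endpoints 0 and 1 are
#' excluded since they map to minus and plus infinity.
#'
#' The table has `N = (1 - x)/x` elements, so the granularity must divide the
#' unit interval exactly (e.g. `0.1` gives 9 elements, `1e-4` gives 9999).
#' Coarse tables truncate the tails of the distribution; `1e-4` is the
#' default granularity throughout the package, at which a million draws are
#' statistically indistinguishable from exact normal draws by a two-sample
#' Kolmogorov--Smirnov test (see [validate_granularity()]).
#'
#' @param granularity probability spacing of the grid, in `(0, 0.1]`;
#'   `(1 - granularity)/granularity` must be an integer.
#' @return An object of class `"normal_lut"`: a list with elements
#'   `granularity`, `values` (ordered quantiles), `size` (element count `N`),
#'   `index_low` (0) and `index_high` (`N - 1`).
#' @examples
#' lut <- build_lut(0.1)
#' lut$size            # 9
#' lut$values[6]       # qnorm(0.6), about 0.253
#' @seealso [draw_standard_normal()], [halve_lut()], [write_lut()]
#' @export
build_lut <- function(granularity = 1e-4) {
  if (!is.numeric(granularity) || length(granularity) != 1L ||
      !is.finite(granularity))
    stop("`granularity` must be a single finite number", call. = FALSE)
  if (granularity <= 0 || granularity > 0.1)
    stop("`granularity` must lie in (0, 0.1]", call. = FALSE)
  n_elem <- (1 - granularity) / granularity
  if (abs(n_elem - round(n_elem)) > 1e-9)
    stop("(1 - granularity)/granularity must be an integer: ",
         "the probability grid x, 2x, ..., 1 - x has to close exactly on 1 - x",
         call. = FALSE)
  n_elem <- as.integer(round(n_elem))
  # k/(N+1) is the exact grid k * granularity without accumulated float error
  probs <- seq_len(n_elem) / (n_elem + 1)
  structure(
    list(granularity = granularity,
         values = qnorm(probs),
         size = n_elem,
         index_low = 0L,
         index_high = n_elem - 1L),
    class = "normal_lut")
}

#' @export
print.normal_lut <- function(x, ...) {
  cat(sprintf("<normal_lut> granularity %g, %d elements, range [%.4f, %.4f]\n",
              x$granularity, x$size, x$values[1L], x$values[x$size]))
  invisible(x)
}

#' Halve a look-up table by keeping only its non-negative half
#'
#' The inverse-CDF table is antisymmetric (the quantile at probability `p`
#' is the negative of the quantile at `1 - p`), so the negative half carries
#' no extra information. The halved table stores only the non-negative
#' quantiles; [draw_halved()] maps a uniform integer spanning the full index
#' range onto the half table by reflection, so its draw distribution is
#' identical to the full-table sampler of the same granularity.
#'
#' @param lut a `"normal_lut"` from [build_lut()].
#' @return An object of class `"halved_lut"`: list with `granularity`,
#'   `values` (non-negative quantiles, increasing), `size` (half-table
#'   element count), and `full_size` (element count of the parent table).
#' @export
halve_lut <- function(lut) {
  stopifnot(inherits(lut, "normal_lut"))
  vals <- lut$values[lut$values >= 0]
  structure(
    list(granularity = lut$granularity,
         values = vals,
         size = length(vals),
         full_size = lut$size),
    class = "halved_lut")
}

#' @rdname halve_lut
#' @param granularity probability spacing, as in [build_lut()].
#' @export
build_halved_lut <- function(granularity = 1e-4) {
  halve_lut(build_lut(granularity))
}

#' Reconstruct the full table from a halved table
#'
#' Mirrors the non-negative half back into a full, antisymmetric quantile
#' vector; used to verify that halving is lossless.
#'
#' @param hlut a `"halved_lut"`.
#' @return Numeric vector equal to the parent `normal_lut$values`.
#' @export
mirror_halved <- function(hlut) {
  stopifnot(inherits(hlut, "halved_lut"))
  v <- hlut$values
  if (hlut$full_size %% 2L == 1L) {
    # odd parent table: v[1] is the central zero, mirrored once
    c(-rev(v[-1L]), v)
  } else {
    c(-rev(v), v)
  }
}

#' Draw approximate standard normal variates from a look-up table
#'
#' Draws `n` uniform integer indices on `[index_low, index_high]` (through
#' R's global RNG, so `set.seed()` gives reproducible draws) and returns the
#' indexed table values. Every draw is one of the `N` table atoms; the
#' resulting discrete distribution deviates from the standard normal CDF by
#' at most the granularity.
#'
#' @param lut a `"normal_lut"` from [build_lut()].
#' @param n number of draws (non-negative).
#' @return Numeric vector of `n` approximate standard normal draws.
#' @examples
#' set.seed(1)
#' draw_standard_normal(build_lut(1e-3), 5)
#' @export
draw_standard_normal <- function(lut, n) {
  stopifnot(inherits(lut, "normal_lut"))
  n <- check_count(n, "n")
  if (n == 0L) return(numeric(0))
  lut$values[sample.int(lut$size, n, replace = TRUE)]
}

#' Draw from a halved look-up table
#'
#' Draws a uniform integer over the parent table's full index range and maps
#' it onto the half table by reflection about the centre, flipping the sign
#' for indices in the (absent) negative half. No per-draw branch on a
#' separate sign variate is needed, and the draw distribution is identical
#' to [draw_standard_normal()] at the same granularity.
#'
#' @param hlut a `"halved_lut"` from [halve_lut()].
#' @param n number of draws (non-negative).
#' @return Numeric vector of `n` approximate standard normal draws.
#' @export
draw_halved <- function(hlut, n) {
  stopifnot(inherits(hlut, "halved_lut"))
  n <- check_count(n, "n")
  if (n == 0L) return(numeric(0))
  k <- sample.int(hlut$full_size, n, replace = TRUE) - 1L  # 0-based full index
  if (hlut$full_size %% 2L == 1L) {
    mid <- (hlut$full_size - 1L) %/% 2L
    j <- k - mid
    sign(j) * hlut$values[abs(j) + 1L]
  } else {
    m <- hlut$full_size %/% 2L
    ifelse(k >= m, hlut$values[k - m + 1L], -hlut$values[m - k])
  }
}

#' Export or import a look-up table as CSV
#'
#' Writes the table as a single-column CSV with header `icdf_value`, one
#' quantile per row, for external inspection. `read_lut()` restores the
#' table; the granularity is recovered from the row count (`1/(N + 1)`).
#'
#' @param lut a `"normal_lut"`.
#' @param path file path.
#' @return `write_lut()` returns `path` invisibly; `read_lut()` returns a
#'   `"normal_lut"`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "normal_lut"))
  df <- data.frame(icdf_value = lut$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), "icdf_value"))
    stop("expected a single-column CSV with header `icdf_value`", call. = FALSE)
  vals <- as.numeric(df$icdf_value)
  if (anyNA(vals) || is.unsorted(vals, strictly = TRUE))
    stop("table values must be finite and strictly increasing", call. = FALSE)
  n_elem <- length(vals)
  structure(
    list(granularity = 1 / (n_elem + 1),
         values = vals,
         size = n_elem,
         index_low = 0L,
         index_high = n_elem - 1L),
    class = "normal_lut")
}

# single non-negative integer-ish count
check_count <- function(n, name = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      abs(n - round(n)) > 1e-8)
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  as.integer(round(n))
}
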