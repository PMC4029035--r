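#' Prefix statistics for O(1) interval residual sums of squares
#'
#' Cumulative sums of the values and their squares, from which the residual
#' sum of squares (RSS) of any probe interval around its own mean is
#' available in constant time.
#'
#' @param values numeric vector of probe log ratios (non-empty).
#' @return an object of class `cumstats`: list with `n`, `s1` (prefix sums,
#'   length `n + 1`) and `s2` (prefix sums of squares).
#' @seealso [interval_rss()]
#' @export
cumulative_stats <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (!is.numeric(values) || anyNA(values)) stop("values must be numeric and non-missing")
  structure(
    list(n = length(values), s1 = c(0, cumsum(values)), s2 = c(0, cumsum(values^2))),
    class = "cumstats"
  )
}

#' Residual sum of squares of a probe interval
#'
#' RSS of probes `i..j` (1-based, inclusive) around their arithmetic mean,
#' computed as sum(y^2) - (sum y)^2 / n from prefix statistics. Negative
#' round-off is clamped at zero. Vectorized over `i`, `j`.
#'
#' @param stats a [cumulative_stats()] object.
#' @param i,j interval endpoints, `1 <= i <= j <= n`.
#' @return numeric RSS values.
#' @export
interval_rss <- function(stats, i, j) {
  stopifnot(inherits(stats, "cumstats"))
  if (any(i < 1L) || any(j > stats$n) || any(i > j)) stop("interval out of range")
  s <- stats$s1[j + 1L] - stats$s1[i]
  q <- stats$s2[j + 1L] - stats$s2[i]
  pmax(0, q - s^2 / (j - i + 1L))
}

#' Exact least-squares segmentations for every segment count
#'
#' Segment-neighborhood dynamic programming: for each k = 1..kmax, the
#' piecewise-constant model with k segments minimizing the residual sum of
#' squares over all possible placements of the k - 1 changepoints. This is
#' an exact minimizer, not a heuristic; runtime is O(kmax * d^2) for d
#' probes. Ties between equal-cost placements are broken deterministically
#' toward earlier change indices.
#'
#' @param values numeric vector of probe log ratios for one chromosome.
#' @param kmax maximum number of segments, `1 <= kmax <= length(values)`.
#' @return an object of class `segmentation_sequence`: list with `models`
#'   (list of `segmentation_model`, one per k), `d` (probe count) and
#'   `kmax`. Each model has fields `k`, `change_indices` (1-based index of
#'   the last probe of each non-final segment), `segment_means`, `rss`.
#' @examples
#' fit <- fit_models(c(0, 0, 5, 5), kmax = 2)
#' fit$models[[2]]$change_indices  # 2
#' @export
fit_models <- function(values, kmax) {
  if (!is.numeric(values) || length(values) < 1L) stop("values must be a non-empty numeric vector")
  if (anyNA(values)) stop("values must be non-missing")
  kmax <- as.integer(kmax)
  if (is.na(kmax) || kmax < 1L) stop("kmax must be a positive integer")
  if (kmax > length(values)) stop("kmax cannot exceed the number of probes")
  models <- .dp_segment(as.numeric(values), kmax)
  models <- lapply(models, function(m) structure(m, class = "segmentation_model"))
  structure(
    list(models = models, d = length(values), kmax = kmax),
    class = "segmentation_sequence"
  )
}

#' @export
print.segmentation_sequence <- function(x, ...) {
  cat(sprintf(
    "Least-squares segmentations: %d probes, k = 1..%d, rss(kmax) = %.4g\n",
    x$d, x$kmax, x$models[[x$kmax]]$rss
  ))
  invisible(x)
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf(
    "Segmentation with k = %d segment(s), rss = %.4g\n  changes after probes: %s\n",
    x$k, x$rss,
    if (x$k > 1L) paste(x$change_indices, collapse = ", ") else "(none)"
  ))
  invisible(x)
}
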