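# Independent brute-force oracles. These deliberately avoid the package's
# dynamic programs: costs are recomputed from prefix statistics over
# exhaustively enumerated placements.

# Exact minimal RSS of a k-segment model by enumerating all C(d-1, k-1)
# changepoint placements.
oracle_best_rss <- function(values, k) {
  d <- length(values)
  st <- cumulative_stats(values)
  if (k == 1L) return(interval_rss(st, 1L, d))
  combos <- utils::combn(d - 1L, k - 1L)
  b <- rbind(0L, combos, d)
  i <- b[-nrow(b), , drop = FALSE] + 1L
  j <- b[-1L, , drop = FALSE]
  costs <- matrix(interval_rss(st, as.vector(i), as.vector(j)), nrow = k)
  min(colSums(costs))
}

# Exact minimal RSS over all feasible constrained placements: one gap chosen
# per 1breakpoint region.
oracle_constrained_rss <- function(values, gap_sets) {
  d <- length(values)
  st <- cumulative_stats(values)
  placements <- t(as.matrix(expand.grid(gap_sets, KEEP.OUT.ATTRS = FALSE)))
  b <- rbind(0L, placements, d)
  i <- b[-nrow(b), , drop = FALSE] + 1L
  j <- b[-1L, , drop = FALSE]
  costs <- matrix(interval_rss(st, as.vector(i), as.vector(j)),
                  nrow = length(gap_sets) + 1L)
  min(colSums(costs))
}

# Exhaustive threshold scan: every midpoint between consecutive distinct
# pooled means plus sentinels; returns the minimal achievable error count.
oracle_threshold <- function(lower, upper) {
  v <- sort(unique(c(lower, upper)))
  m <- length(v)
  candidates <- if (m == 1L) c(v - 1, v + 1) else c(v[1L] - 1, (v[-m] + v[-1L]) / 2, v[m] + 1)
  errors <- vapply(candidates, function(tau) {
    sum(lower >= tau) + sum(upper < tau)
  }, numeric(1))
  list(candidates = candidates, errors = errors, min_error = min(errors))
}

# Direct penalized selection at one penalty: argmin_k rss(k) + lambda * k,
# ties toward the smaller k.
oracle_select_k <- function(rss, lambda) {
  crit <- rss + lambda * seq_along(rss)
  which(crit == min(crit))[1L]
}
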