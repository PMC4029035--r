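#' Candidate changepoints inside an annotated region
#'
#' Probe gap indices j whose breakpoint midpoint floor((p_j + p_{j+1}) / 2)
#' falls in the half-open region [start, end). A change placed after probe j
#' produces a breakpoint exactly at that midpoint, so these are the feasible
#' changepoints for a `1breakpoint` constraint on the region.
#'
#' @param probe_positions strictly increasing probe base pairs.
#' @param start,end region bounds, 0-based half-open.
#' @return increasing integer vector of gap indices (possibly empty).
#' @export
candidate_gaps <- function(probe_positions, start, end) {
  d <- length(probe_positions)
  if (d < 2L) return(integer(0))
  j <- seq_len(d - 1L)
  mids <- floor((probe_positions[j] + probe_positions[j + 1L]) / 2)
  j[mids >= start & mids < end]
}

#' Exact segmentation constrained by breakpoint annotations
#'
#' Least-squares piecewise-constant model constrained to have exactly one
#' change inside every `1breakpoint` region and no changes anywhere else,
#' so its annotation error is zero by construction (including every
#' `0breakpoints` region, which cannot contain a change since changes only
#' occur inside `1breakpoint` regions). Used when no unconstrained model is
#' consistent with the annotations.
#'
#' The optimum is found by dynamic programming over the `1breakpoint`
#' regions in genomic order; the state is the chosen gap in the current
#' region and transition costs are interval RSS between consecutive chosen
#' gaps. Ties are broken toward the lexicographically smallest gap tuple.
#'
#' @param values probe log ratios for one chromosome.
#' @param probe_positions matching base-pair positions.
#' @param anns breakpoint annotations on this chromosome; `0breakpoints`
#'   regions are validated but impose no extra work.
#' @return a `segmentation_model` with one segment per `1breakpoint` region
#'   boundary plus one; its `annotation_error()` on `anns` is 0.
#' @export
fit_constrained <- function(values, probe_positions, anns) {
  d <- length(values)
  stopifnot(d == length(probe_positions), d >= 1L)
  if (is.null(anns)) anns <- empty_annotations()
  if (nrow(anns)) validate_breakpoint_annotations(anns)
  one <- anns[anns$label == "1breakpoint", , drop = FALSE]
  one <- one[order(one$start), , drop = FALSE]
  st <- cumulative_stats(values)
  R <- nrow(one)
  if (R == 0L) {
    model <- structure(
      list(k = 1L, change_indices = integer(0),
           segment_means = mean(values), rss = interval_rss(st, 1L, d)),
      class = "segmentation_model"
    )
    return(model)
  }
  gaps <- vector("list", R)
  for (r in seq_len(R)) {
    g <- candidate_gaps(probe_positions, one$start[r], one$end[r])
    if (length(g) == 0L) {
      stop(sprintf(
        "infeasible 1breakpoint region %s:[%d,%d): no probe gap midpoint falls inside",
        one$chrom[r], as.integer(one$start[r]), as.integer(one$end[r])
      ))
    }
    gaps[[r]] <- g
  }
  # disjoint sorted regions => candidate sets are disjoint and ordered
  if (R > 1L) {
    for (r in 1:(R - 1L)) stopifnot(max(gaps[[r]]) < min(gaps[[r + 1L]]))
  }

  # f[[r]][i]: minimal RSS of probes 1..gaps[[r]][i] with one change in each
  # of regions 1..r, the last at gap i.  Scanning predecessors in ascending
  # order with strict improvement keeps the lexicographically smallest tuple.
  f <- vector("list", R)
  bptr <- vector("list", R)
  f[[1L]] <- interval_rss(st, 1L, gaps[[1L]])
  for (r in seq_len(R)[-1L]) {
    gr <- gaps[[r]]
    gprev <- gaps[[r - 1L]]
    f[[r]] <- numeric(length(gr))
    bptr[[r]] <- integer(length(gr))
    for (i in seq_along(gr)) {
      cand <- f[[r - 1L]] + interval_rss(st, gprev + 1L, gr[i])
      best <- which.min(cand)  # first minimum = smallest predecessor gap
      f[[r]][i] <- cand[best]
      bptr[[r]][i] <- best
    }
  }
  total <- f[[R]] + interval_rss(st, gaps[[R]] + 1L, d)
  ilast <- which.min(total)
  chosen <- integer(R)
  chosen[R] <- ilast
  if (R > 1L) {
    for (r in R:2L) chosen[r - 1L] <- bptr[[r]][chosen[r]]
  }
  changes <- vapply(seq_len(R), function(r) gaps[[r]][chosen[r]], integer(1))
  bounds <- c(0L, changes, d)
  means <- vapply(seq_len(R + 1L), function(s) {
    mean(values[(bounds[s] + 1L):bounds[s + 1L]])
  }, numeric(1))
  model <- structure(
    list(k = R + 1L, change_indices = changes, segment_means = means,
         rss = total[ilast]),
    class = "segmentation_model"
  )
  stopifnot(annotation_error(model, probe_positions, anns) == 0L)
  model
}

empty_annotations <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             label = character(0), stringsAsFactors = FALSE)
}
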