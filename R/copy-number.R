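#' Ordered copy-number state vocabulary
#'
#' The five states in natural copy-count order, lowest to highest.
#' @return character vector.
#' @export
copy_states <- function() {
  c("deletion", "loss", "normal", "gain", "amplification")
}

#' Genomic spans of a model's segments
#'
#' Half-open [start, end) base-pair spans, one per segment. The spans
#' partition [first probe position, last probe position + 1); interior
#' boundaries are the midpoint breakpoint positions.
#'
#' @param model a `segmentation_model`.
#' @param probe_positions probe base pairs.
#' @return data.frame with columns `start`, `end`, one row per segment.
#' @export
segment_spans <- function(model, probe_positions) {
  b <- breakpoint_positions(model, probe_positions)
  lo <- c(probe_positions[1L], b)
  hi <- c(b, probe_positions[length(probe_positions)] + 1L)
  data.frame(start = as.integer(lo), end = as.integer(hi))
}

#' Training labels of segments from copy-number annotations
#'
#' A segment overlapped (>= 1 shared base) by annotations of exactly one
#' state receives that state; overlap with two or more distinct states
#' marks it `conflict`; no overlap leaves it NA.
#'
#' @param model a `segmentation_model`.
#' @param probe_positions probe base pairs.
#' @param cn_anns data.frame of copy-number annotations (`chrom`, `start`,
#'   `end`, `label`) on this chromosome; may be empty.
#' @return character vector, one entry per segment: a state, "conflict" or
#'   NA.
#' @export
training_labels <- function(model, probe_positions, cn_anns) {
  spans <- segment_spans(model, probe_positions)
  out <- rep(NA_character_, nrow(spans))
  if (is.null(cn_anns) || nrow(cn_anns) == 0L) return(out)
  bad <- setdiff(unique(cn_anns$label), copy_states())
  if (length(bad)) stop(sprintf("unknown copy-number state(s): %s", paste(bad, collapse = ", ")))
  for (s in seq_len(nrow(spans))) {
    hit <- cn_anns$start < spans$end[s] & cn_anns$end > spans$start[s]
    states <- unique(cn_anns$label[hit])
    if (length(states) == 1L) out[s] <- states
    else if (length(states) >= 2L) out[s] <- "conflict"
  }
  out
}

#' Best threshold between two ordered copy-number classes
#'
#' The threshold tau minimizing the number of misclassified training
#' means: a lower-class mean errs when >= tau, an upper-class mean errs
#' when < tau. Candidates are the midpoints between consecutive distinct
#' pooled means plus one sentinel below the minimum and one above the
#' maximum, which attains every achievable error value; the sweep is a
#' single pass over the pooled sorted means. Ties on error are broken
#' toward the candidate with the widest margin to the nearest training
#' mean, then toward the smaller threshold.
#'
#' @param lower_means segment means annotated with the lower state.
#' @param upper_means segment means annotated with the upper state.
#' @return the threshold (numeric scalar).
#' @export
learn_threshold <- function(lower_means, upper_means) {
  if (length(lower_means) == 0L || length(upper_means) == 0L) {
    stop("both classes need at least one training mean; omit this boundary")
  }
  pooled <- c(lower_means, upper_means)
  v <- sort(unique(pooled))
  m <- length(v)
  candidates <- if (m == 1L) c(v - 1, v + 1) else c(v[1L] - 1, (v[-m] + v[-1L]) / 2, v[m] + 1)
  # error at the candidate below all values: every lower mean is >= tau
  nl <- vapply(v, function(x) sum(lower_means == x), integer(1))
  nu <- vapply(v, function(x) sum(upper_means == x), integer(1))
  errors <- length(lower_means) + c(0L, cumsum(nu - nl))
  best <- which(errors == min(errors))
  margin <- vapply(candidates[best], function(tau) min(abs(pooled - tau)), numeric(1))
  best <- best[margin == max(margin)]
  candidates[min(best)]
}

#' Classify segment means into ordered states by thresholds
#'
#' With thresholds tau_1 <= ... <= tau_{m-1} between m ordered states, a
#' mean below tau_1 takes the first state, a mean in [tau_i, tau_{i+1})
#' takes state i + 1, and a mean at or above the last threshold takes the
#' last state (boundaries are left-closed on the upper side). If sparse
#' annotations produce a non-monotone threshold sequence, means falling in
#' an inverted zone — where the ">= tau_i" pattern is not of the form
#' TRUE..TRUE FALSE..FALSE — are labeled `conflict` and a warning is
#' issued once.
#'
#' @param means numeric segment means (vectorized).
#' @param thresholds numeric vector, length one less than `states`.
#' @param states ordered state names.
#' @return character vector of states (or "conflict"), same length as
#'   `means`.
#' @export
classify_state <- function(means, thresholds, states) {
  stopifnot(length(thresholds) == length(states) - 1L)
  if (length(states) == 1L) return(rep(states, length(means)))
  monotone <- !is.unsorted(thresholds)
  if (!monotone) {
    warning("non-monotone thresholds learned from sparse annotations; ",
            "means in inverted zones are labeled conflict")
  }
  vapply(means, function(x) {
    ge <- x >= thresholds
    cnt <- sum(ge)
    if (!monotone && cnt > 0L && cnt < length(ge) && !all(ge[seq_len(cnt)])) {
      return("conflict")
    }
    states[cnt + 1L]
  }, character(1))
}

#' Learn all thresholds present in a set of labeled segments
#'
#' Thresholds are learned independently for each adjacent pair of states
#' that both appear among the single-state training labels, using only the
#' means labeled with those two states. States that never appear are
#' skipped entirely: with only `normal` and `gain` annotated, every
#' prediction is normal or gain.
#'
#' @param labels per-segment training labels from [training_labels()]
#'   (states, "conflict" or NA).
#' @param means per-segment means aligned with `labels`.
#' @return list with `states` (ordered states present) and `thresholds`
#'   (numeric, length `length(states) - 1`), or NULL when no usable label
#'   exists.
#' @export
learn_state_thresholds <- function(labels, means) {
  stopifnot(length(labels) == length(means))
  usable <- !is.na(labels) & labels %in% copy_states()
  if (!any(usable)) return(NULL)
  present <- copy_states()[copy_states() %in% labels[usable]]
  thresholds <- numeric(0)
  if (length(present) > 1L) {
    thresholds <- vapply(seq_len(length(present) - 1L), function(i) {
      learn_threshold(
        means[usable & labels == present[i]],
        means[usable & labels == present[i + 1L]]
      )
    }, numeric(1))
  }
  list(states = present, thresholds = thresholds)
}

#' Call per-segment copy-number state for a displayed model
#'
#' With no copy-number annotations on the profile every segment is
#' `unlabeled` (drawn green). Otherwise thresholds learned between
#' adjacent annotated states classify every segment mean; segments whose
#' training label is `conflict` (overlapping annotations of different
#' states) stay `conflict` (drawn black).
#'
#' @param displayed a `displayed_model`.
#' @param probe_positions probe base pairs.
#' @param cn_anns copy-number annotations on this chromosome.
#' @param thresholds optional result of [learn_state_thresholds()] pooled
#'   over a whole profile; when NULL, thresholds are learned from this
#'   chromosome's own annotated segments.
#' @return the `displayed_model` with its `states` field filled.
#' @export
call_copy_number <- function(displayed, probe_positions, cn_anns, thresholds = NULL) {
  stopifnot(inherits(displayed, "displayed_model"))
  model <- displayed$model
  labels <- training_labels(model, probe_positions, cn_anns)
  if (is.null(thresholds)) {
    thresholds <- learn_state_thresholds(labels, model$segment_means)
  }
  if (is.null(thresholds)) {
    displayed$states <- rep("unlabeled", model$k)
    return(displayed)
  }
  states <- classify_state(model$segment_means, thresholds$thresholds, thresholds$states)
  states[!is.na(labels) & labels == "conflict"] <- "conflict"
  displayed$states <- states
  displayed
}
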