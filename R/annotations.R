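#' @keywords internal
#' @noRd
.bp_labels <- c("0breakpoints", "1breakpoint")

#' Base-pair breakpoint positions of a segmentation model
#'
#' Each change between probes j and j + 1 is placed at the base pair halfway
#' between them: floor((p_j + p_{j+1}) / 2). Midpoints can be half-integral;
#' flooring keeps positions on integral bases as genome browsers require.
#'
#' @param model a `segmentation_model` from [fit_models()] or
#'   [fit_constrained()].
#' @param probe_positions integer base-pair positions of the probes, strictly
#'   increasing, aligned with the values the model was fitted to.
#' @return sorted integer vector of breakpoint base pairs (empty for k = 1);
#'   every position is strictly between the first and last probe positions.
#' @export
breakpoint_positions <- function(model, probe_positions) {
  stopifnot(inherits(model, "segmentation_model"))
  d <- length(probe_positions)
  if (model$k > 1L && (max(model$change_indices) >= d || min(model$change_indices) < 1L)) {
    stop("model change indices do not fit the position vector")
  }
  j <- model$change_indices
  as.integer(floor((probe_positions[j] + probe_positions[j + 1L]) / 2))
}

#' Count breakpoints falling in a half-open region
#'
#' Number of positions `b` with `start <= b < end`.
#'
#' @param positions sorted integer breakpoint base pairs.
#' @param start,end region bounds, 0-based half-open.
#' @return non-negative integer count.
#' @export
count_in_region <- function(positions, start, end) {
  sum(positions >= start & positions < end)
}

#' Zero-one breakpoint-annotation error of a model
#'
#' Sum over annotated regions of the indicator that the model predicts the
#' wrong number of breakpoints in that region: a `0breakpoints` region
#' errs when it contains any breakpoint, a `1breakpoint` region errs when
#' it does not contain exactly one. Zero means the model is consistent with
#' the annotations. Regions use half-open [start, end) membership.
#'
#' @param model a `segmentation_model`.
#' @param probe_positions probe base-pair positions.
#' @param anns data.frame of breakpoint annotations with columns
#'   `chrom`, `start`, `end`, `label` (all on the model's chromosome).
#' @return non-negative integer; 0 iff the model is consistent.
#' @export
annotation_error <- function(model, probe_positions, anns) {
  if (is.null(anns) || nrow(anns) == 0L) return(0L)
  validate_breakpoint_annotations(anns)
  bset <- breakpoint_positions(model, probe_positions)
  err <- 0L
  for (r in seq_len(nrow(anns))) {
    cnt <- count_in_region(bset, anns$start[r], anns$end[r])
    want <- if (anns$label[r] == "1breakpoint") 1L else 0L
    err <- err + as.integer(cnt != want)
  }
  err
}

#' Segment counts of all annotation-consistent models
#'
#' The set of k in 1..kmax whose least-squares model has zero annotation
#' error; with no annotations every k is consistent.
#'
#' @param seq a `segmentation_sequence` from [fit_models()].
#' @param probe_positions probe base-pair positions.
#' @param anns breakpoint annotations (may be empty or NULL).
#' @return increasing integer vector of consistent segment counts (possibly
#'   empty).
#' @export
consistent_models <- function(seq, probe_positions, anns) {
  stopifnot(inherits(seq, "segmentation_sequence"))
  ks <- seq_len(seq$kmax)
  if (is.null(anns) || nrow(anns) == 0L) return(ks)
  keep <- vapply(
    seq$models,
    function(m) annotation_error(m, probe_positions, anns) == 0L,
    logical(1)
  )
  ks[keep]
}

# Shared validation of an in-memory breakpoint-annotation frame. A region
# spanning fewer than two probes can never contain a breakpoint; a
# 1breakpoint label there is unsatisfiable, which candidate_gaps /
# fit_constrained report explicitly.
validate_breakpoint_annotations <- function(anns) {
  stopifnot(is.data.frame(anns))
  need <- c("chrom", "start", "end", "label")
  if (!all(need %in% names(anns))) stop("annotations need columns chrom/start/end/label")
  bad <- setdiff(unique(anns$label), .bp_labels)
  if (length(bad)) {
    stop(sprintf("unknown breakpoint annotation label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(anns$start >= anns$end)) stop("annotation regions must satisfy start < end")
  for (ch in unique(anns$chrom)) {
    a <- anns[anns$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)])) {
      stop(sprintf("overlapping breakpoint annotation regions on %s", ch))
    }
  }
  invisible(anns)
}
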