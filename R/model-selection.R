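#' Penalized model-selection path over the segmentation sequence
#'
#' For a penalty lambda > 0, the selected segment count is
#' k(lambda) = argmin_k rss(k) + lambda * k, ties toward fewer segments.
#' The selection is a piecewise-constant, non-increasing step function of
#' lambda whose pieces correspond to the lower convex hull of the points
#' (k, rss(k)). Each hull model owns one lambda interval; the boundary
#' penalty belongs to the smaller k (the tie rule).
#'
#' @param seq a `segmentation_sequence`.
#' @return data.frame with columns `k`, `lambda_lo`, `lambda_hi`, ordered by
#'   increasing lambda (decreasing k); `lambda_lo` of the first row is 0 and
#'   `lambda_hi` of the last is Inf. At a boundary the row with the larger
#'   `lambda_lo` (smaller k) applies.
#' @export
model_complexity_path <- function(seq) {
  stopifnot(inherits(seq, "segmentation_sequence"))
  rss <- vapply(seq$models, `[[`, numeric(1), "rss")
  ks <- seq_len(seq$kmax)
  # walk from the small-lambda end: the k minimizing rss, then rss + eps*k
  cur <- ks[which.min(rss)]  # which.min takes the smallest k on rss ties
  out_k <- cur
  out_lo <- 0
  repeat {
    smaller <- ks[ks < cur]
    if (length(smaller) == 0L) break
    # k beats cur once lambda >= (rss(k) - rss(cur)) / (cur - k)
    cross <- (rss[smaller] - rss[cur]) / (cur - smaller)
    lam <- min(cross)
    nxt <- min(smaller[cross == lam])  # jump as far as possible on ties
    out_k <- c(out_k, nxt)
    out_lo <- c(out_lo, lam)
    cur <- nxt
  }
  data.frame(
    k = out_k,
    lambda_lo = out_lo,
    lambda_hi = c(out_lo[-1L], Inf)
  )
}

# Selected k at one penalty value; boundary penalties go to the smaller k.
select_at_penalty <- function(path, lambda) {
  path$k[max(which(path$lambda_lo <= lambda))]
}

#' Robust per-chromosome noise scale
#'
#' Median absolute deviation (scaled for Gaussian consistency) of successive
#' log-ratio differences, divided by sqrt(2). Differencing removes the
#' piecewise-constant signal except at the few changepoints, so the
#' estimate tracks the probe noise standard deviation.
#'
#' @param values probe log ratios (length >= 2).
#' @return positive scale estimate.
#' @export
robust_scale <- function(values) {
  stopifnot(length(values) >= 2L)
  s <- stats::mad(diff(values)) / sqrt(2)
  if (s <= 0) s <- max(stats::sd(values), .Machine$double.eps)
  s
}

#' Build one interval-regression training example from an annotated chromosome
#'
#' Features are (1, log d, log s-hat) with d the probe count and s-hat the
#' robust noise scale of [robust_scale()]. The target is the widest maximal
#' interval on the log-penalty axis whose selected model has zero
#' annotation error; endpoints may be -Inf/Inf. Chromosomes for which no
#' penalty achieves zero error (the constrained-segmentation cases) yield
#' no example.
#'
#' @param seq a `segmentation_sequence` for the chromosome.
#' @param probe_positions probe base pairs.
#' @param values probe log ratios.
#' @param anns breakpoint annotations on this chromosome (>= 1 region).
#' @return a `penalty_example` (list with `features`, `lo`, `hi`) or NULL.
#' @export
make_example <- function(seq, probe_positions, values, anns) {
  stopifnot(inherits(seq, "segmentation_sequence"))
  path <- model_complexity_path(seq)
  ok <- vapply(
    path$k,
    function(k) annotation_error(seq$models[[k]], probe_positions, anns) == 0L,
    logical(1)
  )
  if (!any(ok)) return(NULL)
  # maximal runs of consecutive zero-error lambda intervals
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lo <- log(pmax(path$lambda_lo[starts[runs$values]], 0))  # log(0) = -Inf
  hi <- log(path$lambda_hi[ends[runs$values]])
  width <- hi - lo
  width[is.nan(width)] <- Inf  # (-Inf, Inf)
  pick <- which(width == max(width))
  pick <- pick[length(pick)]  # ties: prefer the higher-penalty run (parsimony)
  structure(
    list(
      features = c(intercept = 1, log_d = log(seq$d), log_s = log(robust_scale(values))),
      lo = lo[pick], hi = hi[pick]
    ),
    class = "penalty_example"
  )
}

#' Max-margin interval regression for the log-penalty
#'
#' Learns linear weights w minimizing the squared-hinge interval loss
#' sum_i h(lo_i + m - w.x_i)^2 + h(w.x_i - hi_i + m)^2, h(z) = max(0, z),
#' with margin m on the log-penalty scale. Infinite interval endpoints
#' contribute nothing. Optimization is full-batch gradient descent from the
#' zero vector with Armijo backtracking, stopping at gradient norm < 1e-8
#' or 10^4 iterations — deterministic, so refitting on the same examples
#' reproduces the same weights.
#'
#' @param examples list of `penalty_example` objects (at least 2).
#' @param margin positive margin on the log-penalty axis (default 1).
#' @return an `interval_regression` object: list with `weights`, `margin`,
#'   `trained_on`.
#' @export
fit_interval_regression <- function(examples, margin = 1) {
  examples <- examples[!vapply(examples, is.null, logical(1))]
  if (length(examples) < 2L) {
    stop("need at least 2 training examples; use the fallback penalty instead")
  }
  X <- t(vapply(examples, `[[`, numeric(3), "features"))
  colnames(X) <- names(examples[[1L]]$features) %||% c("intercept", "log_d", "log_s")
  lo <- vapply(examples, `[[`, numeric(1), "lo")
  hi <- vapply(examples, `[[`, numeric(1), "hi")
  stopifnot(all(lo < hi))
  loss <- function(w) {
    f <- drop(X %*% w)
    sum(pmax(0, lo + margin - f)[is.finite(lo)]^2) +
      sum(pmax(0, f - hi + margin)[is.finite(hi)]^2)
  }
  grad <- function(w) {
    f <- drop(X %*% w)
    gl <- pmax(0, lo + margin - f)
    gl[!is.finite(lo)] <- 0
    gu <- pmax(0, f - hi + margin)
    gu[!is.finite(hi)] <- 0
    drop(crossprod(X, 2 * (gu - gl)))
  }
  w <- numeric(ncol(X))
  L <- loss(w)
  step <- 1
  for (it in seq_len(10000L)) {
    g <- grad(w)
    gn2 <- sum(g^2)
    if (sqrt(gn2) < 1e-8) break
    step <- min(step * 2, 1e3)  # allow the step to grow back after cuts
    repeat {
      w2 <- w - step * g
      L2 <- loss(w2)
      if (L2 <= L - 0.5 * step * gn2 || step < 1e-16) break
      step <- step / 2
    }
    w <- w2
    L <- L2
  }
  structure(
    list(weights = stats::setNames(w, colnames(X)), margin = margin,
         trained_on = length(examples)),
    class = "interval_regression"
  )
}

#' @export
print.interval_regression <- function(x, ...) {
  cat(sprintf(
    "Interval regression on log-penalty: %d examples, margin %.3g\n  weights: %s\n",
    x$trained_on, x$margin,
    paste(sprintf("%s=%.4g", names(x$weights), x$weights), collapse = ", ")
  ))
  invisible(x)
}

#' Predicted segment count for a chromosome
#'
#' Evaluates the learned log-penalty f(x) at the chromosome's features and
#' selects k on the model-complexity path at lambda-hat = exp(f(x)). When no
#' regression is available (fewer than two annotated chromosomes), a
#' BIC-flavored default penalty lambda-hat = s-hat^2 * log(d) is used.
#'
#' @param reg an `interval_regression` or NULL for the fallback.
#' @param seq a `segmentation_sequence`.
#' @param probe_positions probe base pairs (unused by the default features
#'   but part of the prediction interface).
#' @param values probe log ratios.
#' @return predicted segment count k-hat.
#' @export
predict_segments <- function(reg, seq, probe_positions, values) {
  stopifnot(inherits(seq, "segmentation_sequence"))
  s <- robust_scale(values)
  lambda <- if (is.null(reg)) {
    s^2 * log(seq$d)
  } else {
    x <- c(1, log(seq$d), log(s))
    exp(sum(reg$weights * x))
  }
  select_at_penalty(model_complexity_path(seq), lambda)
}

#' Select the displayed segmentation for one chromosome
#'
#' If any unconstrained model is consistent with the breakpoint
#' annotations, the displayed model is the consistent one whose segment
#' count is closest to the predicted count k-hat (ties toward fewer
#' segments). Otherwise the exact annotation-constrained segmentation of
#' [fit_constrained()] is displayed. Either way the displayed model has
#' zero annotation error.
#'
#' @param seq a `segmentation_sequence`.
#' @param probe_positions probe base pairs.
#' @param values probe log ratios.
#' @param anns breakpoint annotations on this chromosome (may be empty).
#' @param reg optional `interval_regression` (NULL = fallback penalty).
#' @return a `displayed_model`: list with `model`, `breakpoints`,
#'   `algorithm` ("pruneddp" or "segannot"), `k_hat`, `states` (NULL until
#'   [call_copy_number()]).
#' @export
select_displayed <- function(seq, probe_positions, values, anns, reg = NULL) {
  stopifnot(inherits(seq, "segmentation_sequence"))
  if (is.null(anns)) anns <- empty_annotations()
  one <- anns[anns$label == "1breakpoint", , drop = FALSE]
  for (r in seq_len(nrow(one))) {
    if (length(candidate_gaps(probe_positions, one$start[r], one$end[r])) == 0L) {
      warning(sprintf(
        "1breakpoint region %s:[%d,%d) contains no probe gap midpoint and cannot be satisfied",
        one$chrom[r], as.integer(one$start[r]), as.integer(one$end[r])
      ))
    }
  }
  khat <- predict_segments(reg, seq, probe_positions, values)
  cons <- consistent_models(seq, probe_positions, anns)
  if (length(cons)) {
    kstar <- cons[which.min(abs(cons - khat))]  # first min = smaller k
    model <- seq$models[[kstar]]
    algorithm <- "pruneddp"
  } else {
    model <- fit_constrained(values, probe_positions, anns)
    algorithm <- "segannot"
  }
  stopifnot(annotation_error(model, probe_positions, anns) == 0L)
  structure(
    list(
      model = model,
      breakpoints = breakpoint_positions(model, probe_positions),
      spans = segment_spans(model, probe_positions),
      algorithm = algorithm,
      k_hat = khat,
      states = NULL
    ),
    class = "displayed_model"
  )
}

#' @export
print.displayed_model <- function(x, ...) {
  cat(sprintf(
    "Displayed segmentation: k = %d (%s, k_hat = %d), %d breakpoint(s)\n",
    x$model$k, x$algorithm, x$k_hat, length(x$breakpoints)
  ))
  invisible(x)
}

#' Serialize / restore a trained interval regression
#'
#' Small key=value text format (weights, margin, example count).
#'
#' @param reg an `interval_regression`.
#' @param path file to write / read.
#' @return `read_regression` returns the restored object.
#' @export
write_regression <- function(reg, path) {
  stopifnot(inherits(reg, "interval_regression"))
  lines <- c(
    sprintf("margin=%.17g", reg$margin),
    sprintf("trained_on=%d", reg$trained_on),
    sprintf("weight.%s=%.17g", names(reg$weights), reg$weights)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_regression
#' @export
read_regression <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  wsel <- startsWith(keys, "weight.")
  structure(
    list(
      weights = stats::setNames(as.numeric(vals[wsel]), sub("^weight\\.", "", keys[wsel])),
      margin = as.numeric(vals[keys == "margin"]),
      trained_on = as.integer(vals[keys == "trained_on"])
    ),
    class = "interval_regression"
  )
}
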