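#' Pipeline run configuration
#'
#' Settings that override the uploaded track header: `kmax` caps the
#' segment count per chromosome (NULL defers to the header's
#' `maxSegments`, itself defaulting to 20), `seed` fixes all randomness,
#' `verbosity` 0 is silent, 1 logs one line per chromosome.
#'
#' @param kmax optional positive integer cap on segments per chromosome.
#' @param seed integer seed.
#' @param verbosity 0 or 1.
#' @return a `run_config` list.
#' @export
run_config <- function(kmax = NULL, seed = 1L, verbosity = 0L) {
  if (!is.null(kmax)) {
    kmax <- as.integer(kmax)
    stopifnot(kmax >= 1L)
  }
  structure(list(kmax = kmax, seed = as.integer(seed), verbosity = verbosity),
            class = "run_config")
}

#' Run the full annotation-guided segmentation workflow
#'
#' For every chromosome of the uploaded profile: fit the least-squares
#' segmentation sequence up to `min(kmax, probe count)`; select the
#' displayed model guided by the breakpoint annotations, with the
#' penalty-prediction regression trained on the other annotated
#' chromosomes of the profile (leave-one-chromosome-out); call per-segment
#' copy-number state from thresholds learned on the profile's pooled
#' copy-number annotations; and export UCSC tracks, the alterations table
#' and a JSON-lines log. The displayed model's annotation error is zero
#' for every completed chromosome, by construction.
#'
#' An infeasible annotation (a `1breakpoint` region containing no probe
#' gap midpoint) aborts the run with an error naming the chromosome and
#' region, and removes any partially written outputs.
#'
#' @param probes_path bedGraph of probe log ratios (plain or gzipped).
#' @param bp_ann_path optional BED4 of breakpoint annotations.
#' @param cn_ann_path optional BED4 of copy-number annotations.
#' @param outdir output directory.
#' @param config a [run_config()].
#' @return (invisibly) list with `profile`, `displayed` (per-chromosome),
#'   `regression` (per-chromosome list, NULL entries = fallback penalty),
#'   `thresholds`, `paths`, `log` (list of per-chromosome records).
#' @export
run_pipeline <- function(probes_path, bp_ann_path = NULL, cn_ann_path = NULL,
                         outdir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  profile <- read_probes(probes_path)
  bp_anns <- if (is.null(bp_ann_path)) empty_annotations() else {
    read_annotations(bp_ann_path, "breakpoint")
  }
  cn_anns <- if (is.null(cn_ann_path)) empty_annotations() else {
    read_annotations(cn_ann_path, "copynumber")
  }
  cap <- config$kmax %||% profile$meta$max_segments
  chroms <- names(profile$chromosomes)

  out_files <- file.path(outdir, c(
    "probes.bedGraph", "annotations.bed", "segments.bedGraph",
    "breakpoints.bed", "copy_states.bed", "alterations.tsv", "run_log.jsonl"
  ))
  wrote_any <- FALSE
  cleanup <- function() if (wrote_any) unlink(out_files)

  result <- tryCatch({
    seqs <- list()
    for (ch in chroms) {
      probes <- profile$chromosomes[[ch]]
      seqs[[ch]] <- fit_models(probes$logratio, min(cap, nrow(probes)))
    }
    examples <- list()
    for (ch in chroms) {
      a <- bp_anns[bp_anns$chrom == ch, , drop = FALSE]
      if (nrow(a) == 0L) next
      probes <- profile$chromosomes[[ch]]
      ex <- make_example(seqs[[ch]], probes$start, probes$logratio, a)
      if (!is.null(ex)) examples[[ch]] <- ex
    }
    displayed <- list()
    regressions <- list()
    log <- list()
    for (ch in chroms) {
      probes <- profile$chromosomes[[ch]]
      a <- bp_anns[bp_anns$chrom == ch, , drop = FALSE]
      pool <- examples[setdiff(names(examples), ch)]
      reg <- if (length(pool) >= 2L) fit_interval_regression(pool) else NULL
      regressions[[ch]] <- reg
      dm <- select_displayed(seqs[[ch]], probes$start, probes$logratio, a, reg)
      err <- annotation_error(dm$model, probes$start, a)
      stopifnot(err == 0L)
      displayed[[ch]] <- dm
      log[[ch]] <- list(
        chrom = ch, algorithm = dm$algorithm, k = dm$model$k,
        k_hat = dm$k_hat, annotation_error = err, n_probes = nrow(probes)
      )
    }
    # copy-number state is generalized across segments of the whole profile
    all_labels <- character(0)
    all_means <- numeric(0)
    for (ch in chroms) {
      probes <- profile$chromosomes[[ch]]
      a <- cn_anns[cn_anns$chrom == ch, , drop = FALSE]
      lab <- training_labels(displayed[[ch]]$model, probes$start, a)
      all_labels <- c(all_labels, lab)
      all_means <- c(all_means, displayed[[ch]]$model$segment_means)
    }
    thresholds <- if (nrow(cn_anns)) learn_state_thresholds(all_labels, all_means) else NULL
    for (ch in chroms) {
      probes <- profile$chromosomes[[ch]]
      a <- cn_anns[cn_anns$chrom == ch, , drop = FALSE]
      if (is.null(thresholds)) {
        displayed[[ch]]$states <- rep("unlabeled", displayed[[ch]]$model$k)
      } else {
        displayed[[ch]] <- call_copy_number(displayed[[ch]], probes$start, a, thresholds)
      }
      log[[ch]]$states <- displayed[[ch]]$states
      if (config$verbosity >= 1L) {
        message(sprintf("%s: %s k=%d (k_hat=%d), annotation error 0",
                        ch, displayed[[ch]]$algorithm, displayed[[ch]]$model$k,
                        displayed[[ch]]$k_hat))
      }
    }
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wrote_any <- TRUE
    paths <- write_ucsc_tracks(profile, displayed, bp_anns, cn_anns, outdir)
    alt_path <- file.path(outdir, "alterations.tsv")
    utils::write.table(alteration_table(displayed), alt_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_path <- file.path(outdir, "run_log.jsonl")
    log_lines <- vapply(log, function(rec) {
      jsonlite::toJSON(c(rec, list(thresholds = thresholds)), auto_unbox = TRUE,
                       digits = NA, null = "null")
    }, character(1))
    writeLines(log_lines, log_path)
    list(profile = profile, displayed = displayed, regression = regressions,
         thresholds = thresholds, paths = c(paths, alterations = alt_path,
                                            log = log_path),
         log = log)
  }, error = function(e) {
    cleanup()
    stop(e)
  })
  invisible(result)
}
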