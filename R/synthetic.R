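#' Default mean log ratios of the five copy states
#'
#' Ordered with the state vocabulary: deletion -2.0, loss -0.5, normal
#' 0.0, gain 0.5, amplification 1.5. Arbitrary but ordered and
#' configurable in the simulator.
#'
#' @return named numeric vector.
#' @export
default_state_means <- function() {
  c(deletion = -2.0, loss = -0.5, normal = 0.0, gain = 0.5, amplification = 1.5)
}

#' Simulate a piecewise-constant copy-number profile with known truth
#'
#' Probes sit on a regular base-pair grid; the log ratio of each probe is
#' its true segment mean plus Gaussian noise. The true changepoints,
#' means and (optional) copy states are returned alongside the profile so
#' every downstream module can be validated against ground truth.
#' Generation is reproducible given `seed`; the caller's RNG stream is
#' left untouched.
#'
#' @param n_probes number of probes (>= 2).
#' @param chrom chromosome name for the generated probes.
#' @param changes strictly increasing probe indices (1-based, in
#'   `1..n_probes-1`) after which the true mean changes.
#' @param means true segment means, length `length(changes) + 1`. Defaults
#'   to alternating `normal`/`gain` levels of [default_state_means()].
#' @param states optional true copy state per segment, aligned with
#'   `means` (higher state must mean higher mean).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param spacing base pairs between consecutive probe starts.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return list with `profile` (a `profile` with one chromosome) and
#'   `truth` (a `sim_truth`: `chrom`, `changes`, `means`, `states`,
#'   `noise_sd`, `positions`, `seed`).
#' @export
simulate_profile <- function(n_probes, chrom = "chr1", changes = integer(0),
                             means = NULL, states = NULL, noise_sd = 0.1,
                             spacing = 1000L, seed = NULL) {
  n_probes <- as.integer(n_probes)
  stopifnot(n_probes >= 2L, noise_sd >= 0, spacing >= 2L)
  changes <- as.integer(sort(changes))
  if (length(changes)) {
    if (min(changes) < 1L || max(changes) >= n_probes) stop("invalid change indices")
    if (anyDuplicated(changes)) stop("duplicate change indices")
  }
  n_seg <- length(changes) + 1L
  if (is.null(means)) {
    means <- rep(default_state_means()[c("normal", "gain")], length.out = n_seg)
    names(means) <- NULL
  }
  stopifnot(length(means) == n_seg)
  if (!is.null(states)) {
    stopifnot(length(states) == n_seg, all(states %in% copy_states()))
    rank <- match(states, copy_states())
    hi_by_rank <- tapply(means, rank, max)
    lo_by_rank <- tapply(means, rank, min)
    if (length(hi_by_rank) > 1L &&
        any(hi_by_rank[-length(hi_by_rank)] >= lo_by_rank[-1L])) {
      stop("segment means must increase with copy state")
    }
  }
  positions <- as.integer(seq.int(0L, by = spacing, length.out = n_probes))
  seg_id <- findInterval(seq_len(n_probes) - 1L, changes) + 1L
  signal <- means[seg_id]
  y <- with_seed(seed, signal + stats::rnorm(n_probes, sd = noise_sd))
  probes <- data.frame(start = positions, end = positions + 1L, logratio = y)
  profile <- structure(
    list(
      meta = structure(
        list(genome_build = "hg19", max_segments = 20L, share = "private"),
        class = "upload_meta"
      ),
      chromosomes = stats::setNames(list(probes), chrom)
    ),
    class = "profile"
  )
  truth <- structure(
    list(chrom = chrom, changes = changes, means = means, states = states,
         noise_sd = noise_sd, positions = positions, seed = seed),
    class = "sim_truth"
  )
  list(profile = profile, truth = truth)
}

#' Add measurement artifacts to a simulated profile
#'
#' Reproduces the artifact types seen in real arrays: outlier spikes (a
#' Bernoulli subset of probes displaced by `outlier_scale` with random
#' sign), sinusoidal wave noise along the chromosome, and a constant
#' baseline shift (normal copy number away from log ratio 0). All
#' parameters at 0 return the profile unchanged.
#'
#' @param profile a `profile`.
#' @param outlier_rate per-probe spike probability in `[0, 1]`.
#' @param outlier_scale spike magnitude (log-ratio units).
#' @param wave_amplitude amplitude of the added sine wave.
#' @param wave_period wave period in base pairs.
#' @param baseline_shift constant added to every log ratio.
#' @param seed integer seed for the spike draws.
#' @return the modified `profile`.
#' @export
add_artifacts <- function(profile, outlier_rate = 0, outlier_scale = 3,
                          wave_amplitude = 0, wave_period = 100000,
                          baseline_shift = 0, seed = NULL) {
  stopifnot(inherits(profile, "profile"),
            outlier_rate >= 0, outlier_rate <= 1,
            outlier_scale >= 0, wave_amplitude >= 0, wave_period > 0)
  profile$chromosomes <- with_seed(seed, lapply(profile$chromosomes, function(probes) {
    y <- probes$logratio
    if (outlier_rate > 0 && outlier_scale > 0) {
      hit <- stats::runif(length(y)) < outlier_rate
      y[hit] <- y[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) * outlier_scale
    }
    if (wave_amplitude > 0) {
      y <- y + wave_amplitude * sin(2 * pi * probes$start / wave_period)
    }
    probes$logratio <- y + baseline_shift
    probes
  }))
  profile
}

#' Derive feasible annotations from simulation truth
#'
#' Emulates an expert annotator with access to the ground truth: a
#' fraction of the true changes receive a `1breakpoint` region containing
#' exactly that change's midpoint breakpoint; the interior of each true
#' segment (kept clear of every `1breakpoint` region) receives a
#' `0breakpoints` region; and, optionally, one sub-segment region per
#' distinct true copy state receives a copy-number annotation. All
#' regions are pairwise disjoint, pass [read_annotations()]-style
#' validation, and are feasible for [fit_constrained()] by construction.
#'
#' @param truth a `sim_truth` from [simulate_profile()].
#' @param fraction_breaks_annotated fraction of true changes to annotate
#'   (0..1).
#' @param flank_bp half-width of each `1breakpoint` region around the true
#'   midpoint; NULL picks the widest feasible flank automatically. Too
#'   large a flank (regions would overlap) is an error.
#' @param include_cn also emit copy-number annotations (requires
#'   `truth$states`).
#' @param seed integer seed for the choice of annotated changes.
#' @return list with `breakpoint` and `copynumber` annotation data.frames.
#' @export
annotations_from_truth <- function(truth, fraction_breaks_annotated = 1,
                                   flank_bp = NULL, include_cn = FALSE,
                                   seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"),
            fraction_breaks_annotated >= 0, fraction_breaks_annotated <= 1)
  p <- truth$positions
  d <- length(p)
  ch <- truth$chrom
  changes <- truth$changes
  mids <- if (length(changes)) as.integer(floor((p[changes] + p[changes + 1L]) / 2)) else integer(0)
  # regions stay disjoint up to a flank of half the smallest midpoint gap;
  # the default quarter-gap flank leaves interior room for 0breakpoints
  # and copy-number windows
  gaps <- diff(c(p[1L], mids, p[d]))
  max_flank <- if (length(mids)) max(0L, floor((min(gaps) - 2L) / 2)) else 0L
  if (is.null(flank_bp)) {
    flank_bp <- if (length(mids)) max(0L, floor((min(gaps) - 2L) / 4)) else 0L
  } else if (length(mids) && flank_bp > max_flank) {
    stop(sprintf("flank_bp too large: regions would overlap (max feasible %d)", max_flank))
  }
  n_sel <- round(fraction_breaks_annotated * length(changes))
  sel <- sort(with_seed(seed, sample(seq_along(changes), n_sel)))
  bp <- empty_annotations()
  if (n_sel > 0L) {
    bp <- data.frame(
      chrom = ch, start = mids[sel] - flank_bp, end = mids[sel] + flank_bp + 1L,
      label = "1breakpoint", stringsAsFactors = FALSE
    )
  }
  # one 0breakpoints region in the clear interior of each true segment
  bounds <- c(p[1L] - 1L, mids, p[d])  # open zone between consecutive midpoints
  zero <- lapply(seq_len(length(changes) + 1L), function(s) {
    lo <- bounds[s] + flank_bp + 2L
    hi <- bounds[s + 1L] - flank_bp - 1L
    if (hi - lo >= 1L) data.frame(chrom = ch, start = lo, end = hi,
                                  label = "0breakpoints", stringsAsFactors = FALSE)
  })
  bp <- rbind(bp, do.call(rbind, zero[!vapply(zero, is.null, logical(1))]))
  bp <- bp[order(bp$start), , drop = FALSE]
  rownames(bp) <- NULL
  validate_breakpoint_annotations(bp)

  cn <- empty_annotations()
  if (include_cn) {
    if (is.null(truth$states)) stop("truth carries no copy states")
    first_seg <- match(unique(truth$states), truth$states)
    cn_rows <- lapply(first_seg, function(s) {
      lo <- bounds[s] + flank_bp + 2L
      hi <- bounds[s + 1L] - flank_bp - 1L
      if (hi - lo >= 1L) data.frame(chrom = ch, start = lo, end = hi,
                                    label = truth$states[s], stringsAsFactors = FALSE)
    })
    cn_rows <- cn_rows[!vapply(cn_rows, is.null, logical(1))]
    if (length(cn_rows)) cn <- do.call(rbind, cn_rows)
  }
  list(breakpoint = bp, copynumber = cn)
}

#' Simulate a cohort of annotated chromosomes
#'
#' The package's reference study conditions for validation: each
#' chromosome draws its probe count from 50-2000, its number of true
#' changes from 0-8, its Gaussian noise sd from 0.05-0.5 and its
#' annotation coverage fraction from 0.25-1; jump magnitudes between
#' adjacent true means are 0.3-1.0 with random sign, so the cohort mixes
#' easy chromosomes with hard ones whose unconstrained models need the
#' constrained fallback. Each chromosome derives its own RNG stream from
#' the cohort seed, so cohorts are reproducible and adding chromosomes
#' does not perturb earlier ones.
#'
#' @param n_chrom number of chromosomes.
#' @param seed cohort seed (integer).
#' @param n_probes_range,changes_range integer ranges sampled uniformly.
#' @param noise_sd_range,fraction_range,jump_range numeric ranges sampled
#'   uniformly.
#' @return list of per-chromosome lists: `chrom`, `values`, `positions`,
#'   `truth`, `anns` (breakpoint annotations), `noise_sd`, `fraction`.
#' @export
simulate_cohort <- function(n_chrom, seed,
                            n_probes_range = c(50L, 2000L),
                            changes_range = c(0L, 8L),
                            noise_sd_range = c(0.05, 0.5),
                            fraction_range = c(0.25, 1),
                            jump_range = c(0.3, 1.0)) {
  lapply(seq_len(n_chrom), function(i) {
    subseed <- (seed * 1000L + i) %% .Machine$integer.max
    cfg <- with_seed(subseed, {
      n <- sample(n_probes_range[1L]:n_probes_range[2L], 1L)
      n_changes <- min(sample(changes_range[1L]:changes_range[2L], 1L), n - 1L)
      list(
        n = n,
        changes = sort(sample(seq_len(n - 1L), n_changes)),
        sd = stats::runif(1L, noise_sd_range[1L], noise_sd_range[2L]),
        jumps = stats::runif(n_changes, jump_range[1L], jump_range[2L]) *
          sample(c(-1, 1), n_changes, replace = TRUE),
        fraction = stats::runif(1L, fraction_range[1L], fraction_range[2L])
      )
    })
    sim <- simulate_profile(cfg$n, chrom = paste0("c", i), changes = cfg$changes,
                            means = cumsum(c(0, cfg$jumps)), noise_sd = cfg$sd,
                            seed = subseed + 1L)
    anns <- annotations_from_truth(sim$truth,
                                   fraction_breaks_annotated = cfg$fraction,
                                   seed = subseed + 2L)
    probes <- sim$profile$chromosomes[[1L]]
    list(chrom = paste0("c", i), values = probes$logratio,
         positions = probes$start, truth = sim$truth,
         anns = anns$breakpoint, noise_sd = cfg$sd, fraction = cfg$fraction)
  })
}
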