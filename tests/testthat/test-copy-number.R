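cn_ann <- function(start, end, label, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

mk_model <- function(means, changes) {
  structure(list(k = length(means), change_indices = as.integer(changes),
                 segment_means = means, rss = 0),
            class = "segmentation_model")
}

test_that("segment spans partition the probe extent at midpoint boundaries", {
  pos <- seq(100, 500, by = 100)
  spans <- segment_spans(mk_model(c(0, 1), 2L), pos)
  expect_equal(spans$start, c(100L, 250L))
  expect_equal(spans$end, c(250L, 501L))

  spans <- segment_spans(mk_model(0, integer(0)), pos)
  expect_equal(spans, data.frame(start = 100L, end = 501L))

  set.seed(51)
  for (i in 1:10) {
    pos <- sort(sample(1:100000, 30))
    ch <- sort(sample(1:29, 4))
    spans <- segment_spans(mk_model(rnorm(5), ch), pos)
    expect_equal(spans$start[1], pos[1])
    expect_equal(spans$end[5], pos[30] + 1L)
    expect_equal(spans$start[-1], spans$end[-5])  # contiguous, disjoint
  }
})

test_that("training labels follow overlap state rules", {
  pos <- seq(0, by = 100, length.out = 30)
  m <- mk_model(c(0, 0.5, 0), c(10L, 20L))  # spans [0,950) [950,1950) [1950,2901)
  expect_equal(training_labels(m, pos, cn_ann(1000, 1500, "gain")),
               c(NA, "gain", NA))
  # two states overlapping one segment conflict
  expect_equal(
    training_labels(m, pos, rbind(cn_ann(1000, 1200, "normal"),
                                  cn_ann(1100, 1500, "gain")))[2],
    "conflict"
  )
  # same-state overlap is not a conflict
  expect_equal(
    training_labels(m, pos, rbind(cn_ann(1000, 1200, "normal"),
                                  cn_ann(1100, 1500, "normal")))[2],
    "normal"
  )
  # zero-length intersection does not label: annotation ends where span starts
  expect_equal(training_labels(m, pos, cn_ann(0, 950, "loss")),
               c("loss", NA, NA))
  expect_error(training_labels(m, pos, cn_ann(0, 10, "duplication")), "unknown")
})

test_that("threshold learning matches the exhaustive candidate scan", {
  expect_equal(learn_threshold(0, 1), 0.5)
  # overlapping classes: the optimum achieves exactly one mistake
  tau <- learn_threshold(c(0, 0.6), c(0.4, 1))
  orc <- oracle_threshold(c(0, 0.6), c(0.4, 1))
  err <- sum(c(0, 0.6) >= tau) + sum(c(0.4, 1) < tau)
  expect_equal(err, orc$min_error)
  expect_equal(orc$min_error, 1)

  # identical values force one mistake; the widest-margin sentinel wins,
  # and of the two equal-margin sentinels the smaller is returned
  expect_equal(learn_threshold(0.2, 0.2), -0.8)

  set.seed(52)
  for (i in 1:60) {
    nl <- sample(1:6, 1); nu <- sample(1:6, 1)
    lower <- round(rnorm(nl), 2)
    upper <- round(rnorm(nu, mean = 0.3), 2)
    tau <- learn_threshold(lower, upper)
    err <- sum(lower >= tau) + sum(upper < tau)
    expect_equal(err, oracle_threshold(lower, upper)$min_error)
  }
})

test_that("classification is ordinal in the mean with left-closed boundaries", {
  expect_equal(classify_state(0.3, 0.5, c("normal", "gain")), "normal")
  expect_equal(classify_state(0.5, 0.5, c("normal", "gain")), "gain")  # >= tau
  states <- c("loss", "normal", "gain")
  set.seed(53)
  means <- runif(100, -2, 2)
  got <- classify_state(means, c(-0.3, 0.4), states)
  expect_equal(got, states[findInterval(means, c(-0.3, 0.4), left.open = FALSE) + 1L])
  # ordinal coherence: predicted state index is non-decreasing in the mean
  ord <- match(got[order(means)], states)
  expect_true(all(diff(ord) >= 0))
})

test_that("non-monotone thresholds warn and send inverted-zone means to conflict", {
  states <- c("loss", "normal", "gain")
  expect_warning(got <- classify_state(c(-1, 0.2, 1), c(0.5, -0.1), states),
                 "non-monotone")
  expect_equal(got[1], "loss")
  expect_equal(got[2], "conflict")  # in [-0.1, 0.5): above tau2, below tau1
  expect_equal(got[3], "gain")
})

test_that("copy-number calling generalizes annotated states across segments", {
  pos <- seq(0, by = 100, length.out = 60)
  changes <- c(10L, 20L, 30L, 40L)
  means <- c(-1.2, -0.4, 0, 0.5, 2)
  m <- mk_model(means, changes)
  dm <- structure(list(model = m, breakpoints = breakpoint_positions(m, pos),
                       spans = segment_spans(m, pos), algorithm = "pruneddp",
                       k_hat = 5L, states = NULL),
                  class = "displayed_model")

  # no annotations: everything unlabeled
  expect_equal(call_copy_number(dm, pos, NULL)$states, rep("unlabeled", 5))

  # one annotation per state on the matching segment recovers every state
  anns <- cn_ann(dm$spans$start + 10, dm$spans$start + 30,
                 c("deletion", "loss", "normal", "gain", "amplification"))
  expect_equal(call_copy_number(dm, pos, anns)$states,
               c("deletion", "loss", "normal", "gain", "amplification"))

  # with only normal + gain annotated, no other state is ever predicted
  anns2 <- anns[3:4, ]
  states2 <- call_copy_number(dm, pos, anns2)$states
  expect_true(all(states2 %in% c("normal", "gain")))
  expect_equal(states2[4:5], c("gain", "gain"))

  # invariant to annotation order and to splitting a region in two
  expect_equal(call_copy_number(dm, pos, anns[sample(5), ])$states,
               call_copy_number(dm, pos, anns)$states)
  split_ann <- rbind(cn_ann(310, 320, "normal"), cn_ann(320, 330, "normal"),
                     anns[4, ])
  expect_equal(call_copy_number(dm, pos, split_ann)$states,
               call_copy_number(dm, pos, rbind(cn_ann(310, 330, "normal"),
                                               anns[4, ]))$states)

  # conflicting overlap stays black
  clash <- rbind(anns[3:4, ], cn_ann(dm$spans$start[3] + 40,
                                     dm$spans$start[3] + 60, "gain"))
  expect_equal(call_copy_number(dm, pos, clash)$states[3], "conflict")
})
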