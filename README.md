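# annotseg

Annotation-guided DNA copy-number segmentation in R.

Copy-number profiles (aCGH / SNP-array log ratios) are piecewise-constant
signals corrupted by noise; the analysis problem is to place breakpoints
and call each segment's state (deletion, loss, normal, gain,
amplification). Automatic segmenters need tuning, and no setting is right
for every profile — but an expert looking at the scatterplot can say at a
glance where a breakpoint obviously is (or isn't). `annotseg` is for
analysts who have such judgements: you express them as annotated regions,
and the package computes a segmentation that is **exactly consistent**
with them — its training annotation error is zero by construction.

## The model

For log ratios $y_1,\dots,y_d$ at positions $p_1 < \dots < p_d$,
`fit_models()` computes, for every $k = 1..k_{\max}$, the exact
least-squares piecewise-constant model

$$\hat y^k = \arg\min_{\text{$k$ segments}} \sum_{j=1}^d (y_j - \mu_{s(j)})^2$$

by segment-neighborhood dynamic programming. Each change between probes
$j$ and $j+1$ becomes a breakpoint at
$\lfloor (p_j + p_{j+1})/2 \rfloor$. Breakpoint annotations label regions
`1breakpoint` (exactly one breakpoint inside) or `0breakpoints` (none);
a model's annotation error is the number of regions whose predicted
breakpoint count contradicts its label (zero–one loss). The displayed
model is the consistent $\hat y^k$ whose $k$ is closest to a complexity
$\hat k$ predicted by max-margin interval regression on
$(1, \log d, \log \hat s)$ — trained on the other annotated chromosomes —
or, when no unconstrained model is consistent, the exact least-squares
segmentation constrained to one change per `1breakpoint` region and none
elsewhere. Copy-number annotations then train up to four thresholds on
segment means, between adjacent annotated states, which classify every
segment of the profile.

## Worked example

```r
library(annotseg)

sim <- simulate_profile(300, changes = c(100L, 200L), means = c(0, 0.9, 0),
                        states = c("normal", "gain", "normal"),
                        noise_sd = 0.1, seed = 1)
pr   <- sim$profile$chromosomes$chr1
anns <- annotations_from_truth(sim$truth, include_cn = TRUE, seed = 2)

fit <- fit_models(pr$logratio, kmax = 20)
dm  <- select_displayed(fit, pr$start, pr$logratio, anns$breakpoint)
dm  <- call_copy_number(dm, pr$start, anns$copynumber)

dm
#> Displayed segmentation: k = 3 (pruneddp, k_hat = 3), 2 breakpoint(s)
dm$breakpoints
#> [1]  99500 199500
dm$states
#> [1] "normal" "gain"   "normal"
annotation_error(dm$model, pr$start, anns$breakpoint)
#> [1] 0
round(dm$model$segment_means, 3)
#> [1] 0.011 0.896 0.003
```

The simulated chromosome has true changes after probes 100 and 200 (probe
spacing 1 kb, so true breakpoints near 100 kb and 200 kb) with a gained
middle segment at log ratio 0.9. Guided by the truth-derived annotations,
the displayed model places both breakpoints at the probe-gap midpoints,
recovers the segment means, labels the middle segment `gain`, and — the
package's defining property — disagrees with none of the annotated
regions.

The same workflow runs from the shell on bedGraph/BED files:

```sh
Rscript inst/cli/annotseg.R simulate --out sim/ --n-probes 500 --changes 4 --seed 1
Rscript inst/cli/annotseg.R run --probes sim/probes.bedGraph \
    --breakpoints sim/breakpoint_annotations.bed \
    --copynumber sim/copynumber_annotations.bed --outdir out/
```

writing five UCSC tracks (probes, annotations, segment means, breakpoints,
copy states), an alterations table and a JSON-lines log to `out/`.

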