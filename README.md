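# scanpathr

Sequence analysis of driver gaze over dynamic areas of interest (AOIs).

Most eye-tracking summaries of driving answer *where* drivers look.
`scanpathr` is for the complementary question: in what *order*. It is aimed
at researchers in driving behaviour and visual attention who have fixation
events already coded over the seven dynamic AOIs of a car-following scene —
0 speedometer, 1 leading vehicle, 2 near road, 3 road around the leader,
4 far road, 5/6 left/right scenery — and who want to quantify stereotyped
gaze sequences and how vehicle automation changes them.

## The model

A fixation stream is filtered by a minimum fixation duration (80 ms,
inclusive), then run-length collapsed into an AOI **visit** sequence (no
two adjacent codes equal). A **scan path** of length *L* is any window of
*L* consecutive visits, taken at every start position, so *N* visits yield
*N − L + 1* scan paths; the space of possible scan paths has size
7 × 6^(L−1) (42 at L = 2; 1,959,552 at L = 8). Working length defaults to
L = 4, where the observed-vs-possible diversity curve has its elbow.

Length-4 scan paths are classified by positional rules into six functional
classes — with X a wildcard, a pivot AOI in position 2 or 3 must be framed
by qualifying AOIs somewhere before and after:

* **forward polling** (trajectory planning): pivot 4 framed by 1/3
* **backwards polling** (stabilising control): pivot 2 framed by 1/3;
  pivot 1 framed by 2; X13X/X31X framed by 2
* **guidance** (steering control): pivot 1 or 3 framed by 1/3
* **right scenery**: pivot 6 framed by 1/2
* **speed monitoring**: pivot 0 framed by 1/2/3; 0XX0 with 1/2/3 inside
* **supervision** (automation monitoring): the residual class, assignable
  only under highly automated driving (HAD), gated on the frequent subset

Length-3 scan paths ("triplets") are classified by a fixed 28-entry
catalogue (sizes 4/2/4/9/5/4 across the same classes). Class frequencies
are computed participant by participant and then averaged; manual driving
(MD) and HAD are compared per class with Pearson chi-squared homogeneity
tests on pooled counts (Fisher's exact test when the smallest expected
count is ≤ 5) under Benjamini–Hochberg correction.

A seeded motif-mixture generator (`simulate_fixations()`) produces
fixation tables with planted, recoverable class structure, so the whole
pipeline is testable without access to raw recordings.

## Worked example

A hand-verifiable one-participant fixture ships with the package:

```r
library(scanpathr)
we <- make_worked_example()          # 27 fixations, 3 of them sub-80 ms
fix <- filter_min_duration(we$fixations, min_ms = 80)
(visits <- collapse_to_visits(fix))
#> <aoi_visits> participant P01 | MD | 13 visits
#>   1412126201313

d <- extract_scanpaths(visits, length = 4)   # 13 - 4 + 1 = 10 windows
classify_quad(names(d$counts), condition = "MD")
#>  [1] "guidance"          "backwards_polling" "right_scenery"
#>  [4] "guidance"          "forward_polling"   "speed_monitoring"
#>  [7] "backwards_polling" "right_scenery"     "backwards_polling"
#> [10] "speed_monitoring"
```

The driver alternates between the leading vehicle and the far road
(forward polling, `1412`), the near road (backwards polling, `1212`), the
right scenery (`1262`), the speedometer (`6201`, `2013`) and the road
around the leader (guidance, `1313`) — all five manual-driving classes in
thirteen visits.

On synthetic data at the emulated study's scale (16 participants × 2
conditions, ~103 visits each):

```r
sim <- simulate_fixations(generator_config(seed = 1))
seqs <- visit_sequences(sim$fixations)
md  <- class_frequencies(scanpath_distributions(seqs, 4, condition = "MD"))
had <- class_frequencies(scanpath_distributions(seqs, 4, condition = "HAD"))
cmp <- compare_conditions(md, had)
cmp$per_class[, c("class", "method", "p_adj", "significant", "direction")]
#>   class             method              p_adj significant direction
#> 1 forward_polling   chi2_homogeneity 2.13e- 1 FALSE               1
#> 2 guidance          chi2_homogeneity 1.88e-24 TRUE                1
#> 3 backwards_polling chi2_homogeneity 1.87e-20 TRUE               -1
#> 4 right_scenery     chi2_homogeneity 1.07e- 6 TRUE                1
#> 5 speed_monitoring  chi2_homogeneity 2.81e-17 TRUE               -1
#> 6 supervision       chi2_homogeneity 1.18e-15 TRUE                1
```

Automation increases guidance and supervision sequences and decreases
backwards polling — the planted structure, recovered through the full
pipeline. `direction` is the sign of the HAD-minus-MD proportion
difference; `p_adj` is BH-adjusted within the six-class family.

`run_report(outdir = "out", seed = 1)` writes the complete artifact set
(AOI frequencies, length-selection curve, per-condition scan-path and
classification tables, class frequencies, the statistics report, a JSON
summary and a run log); `inst/scripts/scanpath-cli.R` exposes the same
pipeline as shell subcommands (`simulate`, `extract`, `classify`,
`compare`, `report`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analysis from scratch against the installed
package: it simulates the default synthetic world under `--seed`, runs
filtering, collapsing, scan-path extraction, length-4 classification on
the 0.4% frequent subset for both conditions, and the full MD-vs-HAD
statistical comparison, then writes the target report to `--out`.
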