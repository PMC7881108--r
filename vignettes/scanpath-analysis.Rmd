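---
title: "Dynamic scan-path analysis of driver gaze: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic scan-path analysis of driver gaze: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpathr)
```

## The analysis in one paragraph

Gaze in a dynamic task such as car following is not a bag of independent
fixations: drivers cycle through stereotyped *sequences* of looks — at the
leading vehicle, the road around and beyond it, the near road, the
speedometer, the scenery. `scanpathr` quantifies that sequential structure.
Fixation events coded over seven dynamic areas of interest (AOIs 0–6) are
filtered by a minimum duration, collapsed into AOI *visits* (consecutive
fixations inside one AOI count once), and cut into fixed-length *scan paths*
by a window sliding over every start position. Scan paths are then assigned
to six functional classes — forward polling (trajectory planning), guidance
(steering control), backwards polling (stabilising control and headway
monitoring), right scenery, speed monitoring, and supervision (automation
monitoring) — either by positional rules at length 4 or by a 28-triplet
catalogue at length 3. Class frequencies are computed participant by
participant, averaged, and compared between manual driving (MD) and highly
automated driving (HAD) with chi-squared homogeneity tests, a Fisher exact
fallback for small expected counts, and Benjamini–Hochberg (BH) correction.

```{r pipeline-sketch}
we <- make_worked_example()
fix <- filter_min_duration(we$fixations, min_ms = 80)
visits <- collapse_to_visits(fix)
visits
dist <- extract_scanpaths(visits, length = 4)
classify_quad(names(dist$counts), condition = "MD")
```

## Input model and filtering

The unit of input is the fixation event: participant, condition, onset
(ms), duration (ms), AOI code 0–6. The package performs no fixation
detection and no gaze-to-AOI assignment; both are upstream concerns.

* **Minimum fixation duration: 80 ms, inclusive.** A duration of exactly
  80 ms is kept; the threshold describes the detection floor of typical
  50 Hz eye-tracking pipelines (four samples).
* **Filter before collapsing.** The threshold speaks to fixation detection
  quality, which logically precedes AOI-visit semantics. The alternative
  order (collapse, then drop short *visits*) would conflate detection noise
  with genuinely brief visits. This choice matters only when a stream's
  sole fixation in a visit is sub-threshold, in which case the visit
  disappears — which is the intended reading.
* **Gaps are ignored.** Saccades, blinks and off-screen intervals between
  fixations carry no information here: visits are defined purely by the
  order of fixations, because scan paths are built from fixation
  successions only.

## Scan paths and their diversity

A scan path of length L is any window of L consecutive visits; all
`N − L + 1` start positions are used. Since visits never repeat
consecutively, the space of possible scan paths has size
`7 × 6^(L−1)`: 42 at L = 2, 1 959 552 at L = 8. The fraction of that space
actually observed collapses as L grows; the elbow of that curve motivates
the working length. The elbow is a judgment call, so
`length_selection_curve()` reports the raw curve and `suggest_elbow()`
offers a second-difference heuristic on the log-percent curve, clearly
advisory — the length stays a user parameter with default 4.

Two distribution-level quantities mirror the standard reporting: the
cumulative relative frequency of scan-path types sorted by frequency
(ties broken by the type string, so output is deterministic), and the
frequent subset at a relative-frequency cutoff, default 0.4%, *inclusive*
(a type at exactly the cutoff is retained). The cutoff is evaluated on the
distribution pooled across participants within a condition, whereas class
frequencies downstream are per-participant-then-averaged; the two
denominators are deliberately different and both are exposed.

## The taxonomy

At length 4, five rule sets operate on a *pivot* AOI in window position 2
or 3 with qualifying AOIs required before and after it:

| class | pivot | before/after |
|---|---|---|
| forward polling | 4 | 1 or 3 |
| backwards polling | 2 — or pivot 1 framed by 2 — or `X13X`/`X31X` framed by 2 | see left |
| guidance | 1 or 3 | 1 or 3 |
| right scenery | 6 | 1 or 2 |
| speed monitoring | 0 (also `0XX0` with 1/2/3 inside) | 1, 2 or 3 |

"Before and after" is existential over the whole window (any position
before the pivot, any after), not adjacency: the wildcard patterns `X4XX`
and `XX4X` admit non-adjacent qualifiers.

**Precedence.** Several rules can fire for one window (e.g. `1341`
satisfies both the forward-polling and the guidance predicate). Rules are
evaluated in a fixed order — forward polling, backwards polling, guidance,
right scenery, speed monitoring — exposed as a parameter. The
road-structure classes outrank the auxiliary-AOI classes because the
reported class contents place mixed sequences containing speedometer,
scenery or far-road visits under the structural classes; forward polling
outranks guidance because windows with a far-road pivot framed by guiding
fixations are the defining feature of trajectory planning. This order is a
documented reconstruction, not a unique solution; `classify_quad()` accepts
any permutation.

**The supervision residual.** Under HAD, a window matching no rule is a
*supervision* scan path; under MD it stays unclassified. Supervision is
additionally gated on membership in the frequent subset even when
classifying the full dataset, because the class is defined among the
frequent types: ungated, the residual would absorb arbitrary rare junction
patterns (in synthetic data this inflates HAD supervision by roughly
3–4 percentage points), turning a substantive class into a wastebasket.

At length 3, classification is exact lookup in the 28-triplet catalogue
(4 forward, 2 guidance, 4 backwards, 9 scenery, 5 speed, 4 supervision),
applied to the full dataset in both conditions.

**Catalogue–rule consistency.** `audit_catalogue_consistency()` embeds
each triplet in every compatible length-4 window and reports where the
length-4 rules disagree with the catalogue. Known, documented exceptions:
scenery triplets with AOI-3 partners (363, 361, 163, 263, 362) are not
expressible by the length-4 scenery rule, which admits only AOIs 1/2
around the pivot; the supervision triplets 402/204 contain a 0–2 adjacency
that the speed rule captures; and precedence lets guidance capture some
embeddings of 101/303/161. The road-structure triplets embed consistently
in every context. Exceptions are reported, never silently reconciled.

## Statistics

* Chi-squared tests run on **pooled counts** (summed over participants):
  the display tables average per-participant frequencies, but Pearson
  statistics require counts. Both surfaces are reported.
* **No Yates continuity correction** — plain Pearson throughout.
* **Fisher trigger:** the exact test replaces the 2×2 chi-squared whenever
  the smallest expected cell count is ≤ 5 (inclusive).
* **BH family:** the set of per-class MD-vs-HAD tests within one analysis
  (six class tests, or seven AOI-visit tests), not a global correction
  across analyses.
* Classes with zero counts in both conditions are dropped from the overall
  homogeneity test (expected counts of zero) and reported as `NA` per
  class.

## The synthetic world

The generator stands in for the study's raw recordings: 16 participants ×
2 conditions, visit counts per stream drawn negative-binomially with mean
103 and size 5 (matching a ±49 between-participant spread of scan-path
totals), class mixtures equal to the reported class shares per condition,
15% unstructured noise visits, and log-normal fixation durations
(meanlog = log 250 ms, sdlog = 0.45, floored at 80 ms) with a 5% sub-80 ms
contamination fraction to exercise the filter. Left scenery (AOI 5) occurs
only as noise, since no class engages it.

**Why bouts, not independent motifs.** Drafts of the generator sampled a
class independently for every motif. That version is unusable: windows
spanning motif junctions are dense in the guidance rule's pattern space
(junctions of AOI-1/3-rich motifs look like `131`/`313`), and recovered
guidance frequencies exceeded the planted mass by 7–21 percentage points.
Gaze strategies in real data persist over seconds, so the generator emits
*bouts*: one class per bout, a geometric number of motifs (mean 4,
i.e. roughly nine visits ≈ 3–4 s of gaze), consecutive motifs
overlap-chained on the shared visit. Within a bout every window classifies
to the bout's class; junctions are rare and their windows spread over many
rare types.

**Emission pools.** The generator plants only the catalogue motifs that
the length-4 rules classify back into their own class when chained:
scenery uses {161, 162, 261, 262}, supervision {242, 040}; the other
classes use their full triplet sets. The excluded motifs remain in the
*classification* catalogue — the asymmetry reflects the documented
catalogue–rule exceptions above, and planting them would silently leak
mass between classes.

**Ground truth and recovery.** The ledger records planted visits per class
and stream. Recovered class frequencies (full pipeline, length 4) track
the ledger's realized mixture to within ±5 percentage points at 10⁴ visits
per condition; measured worst case over ten seeds was 2.6 (MD) and 3.3
(HAD) points. Residual bias has two sources: junction windows absorbed by
the greedy backwards rule, and class-dependent window yield (a guidance
bout of the same visit length produces slightly more classifiable windows
than a scenery bout). The second effect also means that shifting mass
between two classes slightly moves the *shares* of untouched classes, so
"only the shifted classes are flagged" holds for class counts drawn from
the mixtures (verified by multinomial simulation) but not asymptotically
for pipeline shares at very large n.

**What a green test does not establish.** The generator emulates symbolic
structure, not eye movements: no gaze coordinates, no AOI geometry or
occlusion, no calibration error, no duration differences between AOIs, no
temporal drift (fatigue, learning), no non-stationary bout lengths, and
participant heterogeneity only through the negative-binomial visit count.
Pipeline-recovery tests validate the bookkeeping and the classifier's
internal consistency — not the taxonomy's validity on human data.

## Numerical and degenerate-input choices

* Scan-path types sort by descending count with the type string as a
  deterministic tie-break.
* Sequences shorter than the window yield zero windows, not an error;
  empty distributions propagate as empty tables.
* Participants with no classifiable scan path are excluded from class
  frequency averaging with a logged warning, never silently.
* The HAD class shares sum to 100.01% from rounding of the source values;
  the mixture validator tolerates 1e-3 and the sampler normalises.
* Per-participant frequencies sum to 1 up to 1e-9; tests assert that
  tolerance.
* All randomness flows through a single seed (`withr::with_seed`), and
  generation leaves the caller's RNG stream untouched.

## Limitations

The taxonomy is a reconstruction of a rule text plus a catalogue; where
the two disagree, this package follows the rules at length 4 and the
catalogue at length 3 and surfaces the conflict via the audit. The
precedence order resolves overlaps plausibly but not uniquely. The
statistics operate on pooled counts and therefore ignore within-participant
dependence of windows (overlapping windows are not independent
observations); the per-participant-then-averaged frequencies are the
descriptive counterpart, and mixed models are out of scope. Scan-path
similarity metrics (string edit distances and friends) are deliberately
absent: identity of the AOI tuple is the only equivalence used.
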