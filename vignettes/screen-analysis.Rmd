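---
title: "Methods: mixture-normalized qPCR screen analysis and network enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-normalized qPCR screen analysis and network enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribiscreen)
library(dplyr)
```

## The measurement model

ribiscreen analyses genome-wide reporter screens read out by duplex
quantitative PCR. Each well of a 96-well plate holds one deletion strain;
two TaqMan probes measure, in the same reaction, a stress-repressed
ribosome-biogenesis reporter transcript (FAM channel, *NSR1* in the
motivating study) and a housekeeping control transcript (JOE channel,
*PEX6* or *NTF2*). Under perfect amplification efficiency the cycle
threshold Ct falls by one cycle per doubling of transcript, so the
difference

$$F\!-\!J \;=\; \mathrm{Ct}_{\mathrm{FAM}} - \mathrm{Ct}_{\mathrm{JOE}}$$

is, up to sign, the log2 reporter/housekeeping expression ratio. Strains
that fail to repress the reporter during osmotic stress have *more*
reporter transcript, hence *lower* F−J. After normalization all values are
multiplied by −1 so that a repression defect is a positive log2 ratio.

Wells in which either channel crosses its fluorescence threshold after more
than 28 cycles are discarded before analysis (`filter_wells()`); these are
almost always poorly growing strains with too little RNA. The boundary is
strict: a Ct of exactly 28.0 is retained. A missing Ct is treated as failed
amplification and discarded with the same rule.

## Plate normalization by a two-population mixture

Separate qPCR runs shift the reporter channel by 0.3–0.6 cycles, so raw
F−J values are only comparable within a plate. Each plate is therefore
centered independently. Because a plate mixes two populations — a majority
of strains with no expression defect and a minority of outliers — centering
on the plain plate mean would be biased by the outliers. Instead
`fit_mixture_em()` fits a two-component 1-D Gaussian mixture (free
per-component variances, floored at 1e−3 to avoid singularities) and
`normalize_plate()` subtracts the mean F−J of the wells assigned to the
majority component (posterior responsibility ≥ 0.5), setting the plate mean
*minus the outliers* to zero, then flips the sign. Hard assignment rather
than the responsibility-weighted component mean is used so that the
majority-member average is exactly zero after centering.

EM is run from deterministic starts so results need no seed: component
means at the 25th/75th percentiles, at the 5th/95th percentiles, and a
third start that splits the sorted values at their largest adjacent gap
(equal or proportional weights, pooled or within-cluster SDs). The
best-likelihood run is kept. The gap-split start matters: a 5–10% outlier
population lies outside the interquartile range, and with free variances a
quantile start can converge to a local optimum whose minority component
also swallows the tail of the majority. Parameter updates that would lower
the likelihood (possible only through the variance floor) are rejected, so
the log-likelihood trace is non-decreasing by construction.

A plate with no resolvable outlier population — component means closer
than 0.5 log2 units, or a "minority" weight above 0.4 — is flagged
degenerate and centered on its 20% trimmed mean instead; since the mixture
step has little effect on outlier-free plates, robustness there matters
more than mixture fidelity. Plates with fewer than 8 wells (the trailing
partial plate of a library) are likewise centered on the trimmed mean.

Re-arrayed plates (rescreen and subscreens) are deliberately hit-enriched,
which breaks the majority assumption. They instead carry *center-peak
control* wells — strains whose primary value sat at the mode of the screen
distribution — and `normalize_with_controls()` zeroes each plate on its own
controls' mean (at least 4 control wells per plate). Per-plate rather than
per-experiment centering also removes the per-plate run offsets; with
offsets and noise switched off in the generator, re-arrayed hits recover
their true effects exactly, which the tests assert.

## Error model and two-stage hit calling

The null spread of a strain with no defect is estimated from replicate
runs: plates screened twice, weeks apart. `replicate_concordance()`
computes the Pearson correlation and the mean absolute difference over
shared strains; `fit_null_model()` takes the latter as the error estimate
and rounds to one decimal, giving the null N(0, 0.3) for a mean |Δ| of
0.29. At the calling threshold of log2 = 1.0 this null puts a strain at

```{r}
model <- fit_null_model(0.29)
z_score(1.0, model)
tail_probability(1.0, model)
```

i.e. Z ≈ 3.3, with a one-sided tail probability of ~4.3×10⁻⁴ — under 0.1%.
Whether the replicate "average difference" is the mean absolute difference
or the SD of differences is ambiguous; both are computed and the null model
uses the configured choice (mean |Δ| by default).

Hit calling is two-stage. The primary screen calls strains with normalized
ratio strictly above 1.0. Strains above 1.3 are re-arrayed with 72
center-peak controls and re-run against a *second* housekeeping gene; a
strain is confirmed only if its control-normalized rescreen value again
exceeds 1.0. The second stage protects against plate-to-plate error
variation and against strains whose apparent reporter increase was really a
housekeeping decrease. All thresholds use strict `>` for calling; the one
exception is the rapamycin subscreen classification below, which uses `≥ 1`
following the convention of the network figure it feeds. Over repeated
null-only simulations the two-stage design reduces false positives
relative to single-stage calling at the same final threshold, which the
test suite asserts on generator truth.

## Epistasis subscreens

Confirmed hits with primary log2 > 1.4 (a stricter cutoff than the
rescreen's 1.3, reflecting the four-plate capacity of one subscreen run)
are re-arrayed with 48 center-peak controls and measured under two further
conditions:

* **mock stress** — log-growth conditions. A strain whose
  control-normalized mock value exceeds 1.0 expresses the reporter highly
  even without stress: its phenotype is *constitutive*, not a repression
  defect, and it is excluded from epistasis interpretation (precedence:
  constitutive > downstream).
* **rapamycin** — direct chemical inhibition of TORC1, bypassing all
  upstream signaling. A strain that still fails to downregulate the
  reporter (normalized value ≥ 1.0) is missing a gene acting *downstream
  of TORC1*; assayed strains below the cutoff act upstream of, or parallel
  to, the TORC1 pathway.

Confirmed hits never assayed in the subscreens (primary values between 1.0
and 1.4) are reported as `unclassified` rather than guessed.

## Network connectivity test

Whether the confirmed hits are functionally coherent is tested on a
protein-interaction edge list (BioGRID-style TSV; evidence labels collapse
to `affinity` > `interaction_screen` > `other`, and duplicate pairs merge
at the highest-precedence class). The statistic is the number of unique
unordered interaction pairs within the hit set, excluding
self-interactions. `permutation_test()` draws gene sets of the same size
uniformly without replacement from the screened universe, recomputes the
induced edge count for each, and reports the add-one empirical p-value
$(\#\{\text{null} \ge \text{obs}\}+1)/(B+1)$, which can never be zero: with
10,000 permutations the smallest reportable p is 1/10001, just under
0.01%. The null mean agrees with the closed-form uniform-placement
expectation $M\,k(k-1)/(N(N-1))$ within Monte-Carlo error, and the p-value
is uniform when the observed set is itself a null draw — both are asserted
in the tests. A merged reference node (e.g. TORC1 = Tor1/Kog1/Lst8/Tco89),
added for display, is excluded from the tested set.

Highly promiscuous chaperone-class hubs can dominate such graphs;
`prune_hubs()` removes named hubs together with nodes whose every edge went
to a hub, and `component_stats()` reports the major-component size and the
count of unconnected genes. `hypergeometric_enrichment()` provides the
generic upper-tail overlap test used for GO-style annotation enrichment;
annotation sets are supplied by the caller (no ontology database is
bundled or fetched).

## What the synthetic generator emulates

Every stage is exercised against `simulate_screen()` /
`simulate_graph()`, whose defaults *are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_strains` | 4709 | library size, 96-well plates, last plate partial |
| `hit_fraction` | 0.10 | strains with a true repression defect |
| `hit_effect_range` | [1.0, 4.5] | defect effects, uniform, log2 units |
| `well_noise_sd` | 0.26 | composite technical SD of one measurement |
| `null_bio_sd` | 0.20 | strain-intrinsic biological spread |
| `plate_offset_range` | [0.3, 0.6] | per-plate offsets, random sign |
| `dropout_rate` | 0.04 | wells that amplify late (Ct > 28) |
| `mock_shift` | 2.3 | reporter elevation in unstressed cultures |
| `downstream_fraction` | 53/332 | hits that stay high under rapamycin |
| `constitutive_fraction` | 5/332 | hits high in every condition |

Each Ct channel receives independent Gaussian noise with SD
`well_noise_sd`/√2, so the F−J composite has SD 0.26; two replicates of
one strain then differ by mean |Δ| = 0.26·√2·√(2/π) ≈ 0.29 and correlate
at r ≈ 0.9 across a default strain mix — the generator reproduces the
replicate statistics by construction, and the tests check exactly that.
The 0.26 technical / 0.20 biological split is an assumption: the study
data do not separate the two, only their combination is identifiable from
a single screen, and the replicate design isolates the technical part.
Both plate offsets are modelled: a shared offset on both channels (which
cancels in F−J) and a reporter-only run offset (which does not, and is
what plate normalization must remove — otherwise the normalization step
would be vacuous).

Constitutive strains are simulated as elevated by their defect effect *on
top of* the normal unstressed level (mock level = `mock_shift` + effect),
matching the observed behaviour of constitutively de-repressed deletions,
and they remain elevated under rapamycin. Upstream hits repress fully
under rapamycin (level 0), as direct TORC1 inhibition bypasses them.

The graph generator places background edges uniformly over gene pairs and
plants extra edges inside a designated gene set. Defaults (56,500
background edges, 440-gene set, 584 planted extras over a 4709-gene
universe) are calibrated so a random 440-gene set induces ~492 edges in
expectation and the planted set ~1076. At other screen sizes the pipeline
scales both counts to preserve edge density.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about instrument data: housekeeping-gene expression changes
in mutants (the dominant source of unconfirmed primary hits in real
screens, which is why simulated confirmation rates run higher than real
ones), plate-position and growth-stage artefacts, amplification-efficiency
differences between probes, and the heavy-tailed degree distribution of
real interaction databases (uniform background edges leave far fewer
isolated genes than a real network with equal edge count).

## Numerical choices and problem sizes

* EM: convergence when the log-likelihood gain drops below 1e−8, at most
  500 iterations; variance floor 1e−3 (log2 units²); majority component =
  higher weight, ties broken toward the higher-F−J (lower-expression)
  component, since defects lower F−J.
* Degeneracy: mean separation < 0.5 log2 units or minority weight > 0.4.
* Thresholds are strict `>` everywhere except the rapamycin call (`≥`).
* The null-model SD is rounded to one decimal, mirroring the 0.29 → 0.3
  convention of the replicate analysis it implements.
* Empirical p uses the add-one convention; permutation draws are without
  replacement within a draw, independent across draws, one documented seed.
* Test-suite simulations are sized to finish in minutes on one CPU:
  calibration loops use 96-well single-plate screens (200 of them),
  sensitivity checks 960-strain screens, permutation checks 150–2000
  draws on graphs of 200–1000 genes. The acceptance script runs the full
  4709-strain, 10,000-permutation study.

## Known limitations

* The mixture is strictly two-component; plates with three populations
  (e.g. a contaminated batch) are not detected beyond the degeneracy flag.
* Per-plate normalization cannot correct within-plate spatial gradients.
* The confirmation stage models only measurement error, so its simulated
  confirmation rate is an upper bound on real-data behaviour (see the
  generator's non-goals above).
* `run_study()` orchestrates the synthetic study; with instrument data,
  the stage functions are called individually on tables from
  `read_wells()`, and the re-array layouts come from the wet-lab robot
  rather than `simulate_rearray()`.
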