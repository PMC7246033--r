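---
title: "Quantifying protein expression from IP-HPLC chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein expression from IP-HPLC chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iphplc)
```

## The measurement model

IP-HPLC estimates *relative* protein abundance. A lysate aliquot is
incubated with protein A/G agarose beads loaded with one specific antibody;
the captured protein is eluted and pushed through an HPLC column (0.4
mL/min, 30 min run) with UV detection at 280 nm. The chromatogram shows a
single dominant elution peak riding on instrument baseline drift and
detector noise. The quantity the assay trusts is the **peak area in
mAU·s**, not the peak height, and comparisons are made between a treated
and a control lysate run sequentially under identical conditions.

The pipeline applies, in order:

1. a **local linear baseline**: the straight line through the signal at the
   two endpoints of a fixed elution window is subtracted inside the window;
2. **trapezoidal integration** on the native time grid, with minutes
   converted to seconds so areas come out in mAU·s;
3. **negative-control subtraction**: an irrelevant antibody's peak area
   estimates nonspecific binding and is subtracted from every raw area;
   a difference that would go negative is floored at zero and flagged
   (`clamped`) — a flagged value signals a failed pulldown, and the flag is
   carried into the results rather than silently repaired;
4. the **square root** of the net area as the expression level. Absorbance
   is proportional to eluted mass, and the square root is the assay's
   variance-stabilising convention; it compresses area ratios, so a percent
   level of *R* corresponds to an area ratio of (R/100)².

Percent levels are `100 * treated / control`, paired by replicate: each
replicate is an independent bench repetition of both arms, and pairing
cancels shared injection-to-injection variation before any statistics are
computed.

Because no concentration standard exists (the assay cannot report absolute
protein concentration), all downstream numbers are percents of the control
arm.

## Housekeeping adjustment

α-tubulin, β-actin and GAPDH are assumed expression-stable. After the
percent levels of one sample (one timepoint × replicate) are computed,
every level is multiplied by `k = 100 / mean(housekeeping percents)` — the
"proportional basal line". Interpreting the adjustment as a *single
multiplicative rescale to a housekeeping mean of 100* is a design choice:
"proportional" implies a multiplicative correction, and the mean of the
three proteins is the simplest symmetric target. The stated ±5 % behaviour
of the housekeeping set is then **verified** per protein and reported
(`within_tolerance`), never forced: if the three proteins disagree with
each other by more than the tolerance, rescaling their mean cannot (and
should not) hide it.

The adjustment is applied per replicate rather than to replicate means, so
the replicate SD and the QC flag are computed on adjusted values — the same
scale on which the assay's ≤ ±5 % repeatability criterion is stated.

## Replicate statistics and QC

With *n* ∈ [2, 6] replicates the pipeline reports the arithmetic mean, the
**population** SD σ, and the SEM `s = sqrt(σ²/n)`. The population variance
(no n−1 correction) follows the assay's own formula for s; the sample
convention is available via `pipeline_config(variance = "sample")`. QC
passes when σ ≤ 5 percentage points. At the bench a failing antibody would
simply be re-run; software cannot re-run the instrument, so the failure is
flagged in every output instead of dropping the antibody.

## Change bands

|Δ| ≤ 5 → *minimal*, 5 < |Δ| ≤ 10 → *slight*, 10 < |Δ| ≤ 20 →
*meaningful*, |Δ| > 20 → *marked*, with Δ = percent level − 100. The
printed band definitions overlap at their edges (≤±5, ±5–10, ±10–20, ≥±20),
so a deterministic convention is needed: boundary values belong to the
**lower** band, making the partition exhaustive and mutually exclusive
(property-tested on a grid from −30 to +30 in 0.1 steps). Band edges are
parameters of `pipeline_config()`. Note the knife edge: an antibody whose
true change sits *exactly* on an edge can be classified either way by
floating-point-sized noise; validation grids therefore avoid exact-edge
truths.

Whether the reported ±% figures are changes of the percent level itself or
of some further-normalised quantity is not decidable from the assay
description; the pipeline reports `delta_pct = percent_level − 100` and
labels it as such everywhere.

## The antibody panel

The packaged catalog (`load_panel()`) lists 218 primary antibodies in 20
functional categories plus 73 *overlap references* — antibodies measured
once but cross-listed in additional pathway groups. Overlap references
resolve by exact, case-sensitive string match to exactly one primary entry
in another category; no fuzzy matching is attempted, because silent fuzzy
resolution would be untestable. Vendor footnote markers are stored as an
opaque `source_tag`. The source listing's name lists disagree with its
printed counts in four places; the reconciliations (one promoted primary,
three replaced overlap slots, four spelling normalisations) are recorded in
the fixture file's comment changelog rather than applied silently.

## The synthetic-data generator

`simulation_spec()` + `simulate_cohort()` generate complete cohorts with
known ground truth. Each trace is

> linear baseline (intercept 1 mAU, slope 0.05 mAU/min) + Gaussian peak
> (centre 15 min, SD 30 s) + white detector noise (SD 0.02 mAU),

sampled at 1 s over the 30-min run. Defaults for the peak geometry and the
control net area (500 mAU·s) are order-of-magnitude choices for a
protein-scale UV peak — the assay's real dynamic range is not published —
and are recorded as configuration, not asserted as facts.

Ground truth is encoded in the quantity the pipeline reports: for true
percent level *R*, the treated **net** area is `control_area · (R/100)²`,
and every channel (treated, control, negative) additionally carries the
same nonspecific-binding area `control_area · negative_fraction` (default
0.1), which is exactly what the negative-control channel measures alone.
Subtraction then recovers the encoded net areas, and the sqrt ratio
recovers *R* — making noise-free parameter recovery a sharp test of the
subtract-then-sqrt contract rather than of the generator. A single
negative-control channel per replicate is shared across antibodies
(`per_antibody_negative = TRUE` switches to per-antibody matching).

Replicate variability has two seeded components:

* a **shared per-injection factor** (`replicate_cv`, lognormal sdlog
  0.042) multiplying all areas of one (arm, timepoint, replicate) sample —
  this is the dominant bench-to-bench variation, it produces an unadjusted
  percent-level replicate SD of about 3 points (100·cv/√2), and it is the
  component the housekeeping rescale exists to cancel;
* an **independent per-antibody factor** (`antibody_cv`, sdlog 0.008) that
  survives the rescale and sets the residual replicate spread, well inside
  the ≤ ±5-point QC regime.

The calibration of `replicate_cv` to a ~3-point unadjusted SD was chosen
once, from the assay's stated ≤ ±5 % repeatability, before any validation
was run. Every random draw is a deterministic function of the spec seed
and the trace identity (a 31-bit FNV-1a hash), so a fixed seed yields
byte-identical trace files and manifests, and a single trace can be
regenerated without regenerating the cohort.

What the generator does **not** emulate: multiple or overlapping elution
peaks, retention-time drift between runs, antibody cross-reactivity,
column carryover, heteroscedastic detector noise, and failed
immunoprecipitations. Passing validation on synthetic cohorts therefore
demonstrates that the *computation* is correct under the stated noise
model, not that the assay itself is accurate on real lysates.

## Numerical choices

* **Integration window**: fixed per cohort; the generator's default window
  is peak centre ± 5 SD. At that width the tail truncation plus the
  endpoint baseline subtraction cost well under 0.1 % of the peak area
  (at ± 4 SD the cost is ~0.11 %, which is why the wider default was
  chosen); integration error cancels almost exactly in the treated/control
  ratio because both arms share the window geometry.
* **Trapezoid on the native grid**: no resampling or smoothing; halving
  the 1-s sampling step moves a Gaussian peak's area by < 0.05 %
  (property-tested against `stats::integrate` as the quadrature oracle).
* **Clamping**: negative net areas are floored at zero *before* the square
  root (which would otherwise be undefined) and flagged.
* **Zero control level** raises an error — a vanished control peak means a
  failed control pulldown, and a percent level against it is meaningless.
* **Trace files** are plain text with `# key: value` headers; numeric
  round-trip error is below 1e-6 relative, and the reader accepts any
  strictly increasing grid (the assay's detector sampling rate is not
  specified).

## Proliferation index

The in situ proliferation index per photographed field is
`100 · (final − initial)/initial`; fields (ten per arm) are averaged
unweighted, and the dispersion is reported explicitly as the SD across
fields (whether the assay's printed ± values are SD or SEM is not stated,
so the label is explicit). Whether counts were pooled or averaged is also
not stated; the unweighted mean matches a "mean proliferation index", and
with equal initial counts both computations coincide (tested). The
treated-minus-control difference is reported to one decimal, the precision
at which the indices themselves are reported.

## Validation problem sizes

The shipped validation uses cohorts the pipeline solves in seconds: exact
recovery on a noise-free 50-antibody cohort with truths spanning 70–135 %
(max error and band agreement), and a noisy 200-antibody, 4-replicate
cohort at the calibrated variability (fraction of antibodies recovered
within ±2 points, QC pass rate, and band agreement excluding truths within
1 point of a band edge, where classification is legitimately
undecidable). These sizes exercise every code path at full trace
resolution (1801 points per trace) while keeping a complete run under a
minute on one core.

## Known limitations

* One peak per trace: no deconvolution of co-eluting species and no
  exponentially-modified-Gaussian fitting; a shouldered or split peak will
  be integrated as-is.
* The fixed shared window assumes stable retention times across a cohort.
* The linear endpoint baseline is exact for linear drift only; curved
  drift leaves a residual that the treated/control ratio only partially
  cancels. The baseline model is recorded in every peak record
  (`baseline_model`) so alternative models remain distinguishable.
* No inferential statistics across antibodies (the assay defines none):
  SEM and bands are descriptive, and no multiplicity correction applies.
* Housekeeping adjustment assumes the three internal controls are truly
  unresponsive; a treatment that shifts them coherently is indistinguishable
  from a global scale change.
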