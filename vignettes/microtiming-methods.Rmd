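---
title: "Measuring and manipulating microtiming in swung performances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and manipulating microtiming in swung performances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingtime)
```

## The measurement model

swingtime analyses solo performances of swung eighth notes recorded against a
metronome. Swung eighths occupy the first and third notes of an eighth-note
triplet: the first ("base", *b*) nominally coincides with the quarter-note
click, the third ("swing", *s*) forms the offbeat. On the canonical MIDI
timeline of 960 ticks per quarter note the triplet anchors sit at 0, 320 and
640 ticks; a tick lasts `60000 / (bpm * 960)` milliseconds.

Every onset is classified by its residue modulo 960 into the nearest anchor's
class, using a half-open window of one half-triplet, `[-160, 160)` ticks,
around each anchor. The three windows tile the quarter exactly, so
classification is a total function: residues in `[800, 960)` wrap to the next
quarter's base anchor (a note played slightly *early* counts as a negative
offset on the following beat, which is what keeps the mean base position from
being corrupted by near-zero residues of 959). The tie points are resolved by
the half-openness: a residue of exactly 480 is a swing note at offset −160,
which is also what makes a straight-eighth performance (swing ratio 1)
classifiable at all. Notes at the middle anchor (320) are "disregarded":
they are reported and carried along but never measured or moved. We fixed the
window half-width at 160 ticks rather than exposing it as a parameter: any
narrower window would leave residues unclassified and break the partition
property that the class counts and the middle-note fraction rely on.

Microtiming deviations (MTDs) are defined *about the recording's own mean
class positions*. For each performance we compute the mean base offset
$\bar b$ and mean swing position $\bar s$; the deviation of a base note is
its offset minus $\bar b$, of a swing note its offset minus
$(\bar s - 640)$. Deviations are therefore mean-zero per class by
construction, and an intentional, consistent ahead/behind-the-beat placement
(nonzero $\bar b$, a "laid-back feel") is *not* part of the deviations — it
survives every manipulation below.

**Chords.** When several notes fall in the same (quarter, anchor) cell they
form one temporal bin, and only the earliest onset in the bin carries timing
information. This rule is stated for the correlation analysis in the source
methodology; we apply it uniformly to the class means, the deviations and the
manipulation (all notes of a bin move rigidly by the bin head's delta), which
keeps the three stages consistent with each other. Both choices are
switchable: `per_bin = FALSE` in the analysis functions uses every note, and
`chord_mode = "per_note"` rescales each chord tone individually.

**Swing ratio.** Each swing note at position $p$ (mod 960) has the per-note
ratio $r_i = \frac{p \bmod 960}{960 - (p \bmod 960)}$ — the long-to-short
length ratio the swung pair would have if base notes sat exactly on the
click. $r$ is the mean of the $r_i$ and $\delta_r$ their standard deviation.
Because the map $p \mapsto r_i$ is convex, $r$ exceeds the ratio evaluated at
the mean position $\bar s/(960-\bar s)$ once positions are noisy (Jensen's
inequality); at realistic noise (≈ 18.5 ms at 150 BPM) the gap is ≈ 0.05.
Both quantities are reported (`r` and `anchor_ratio` in the profile), and
recovery of a generator's target ratio is checked on `anchor_ratio`, which
estimates the anchor consistently.

**Serial correlations.** Each base bin is paired with the following swing
bin at distance ≤ 960 ticks, and vice versa; Spearman's rank correlation
(average ranks on ties, which are common after integer-tick rounding) is
computed per direction. Distances are measured between bin anchor times by
default so a strongly dragged note still pairs with its own beat
(`distance = "onset"` switches to raw onsets). Fewer than three pairs, or a
constant margin (e.g. a perfectly quantized piece), yields `NA` rather than
a number.

## Manipulation

A manipulation replaces every deviation by $m \cdot d_i$: each bin's onset
becomes `quarter·960 + anchor + class_mean_offset + m·d_i`. The named
presets are quantized ($m=0$), exaggerated ($m=2$), inverted ($m=-1$) and
original ($m=1$). Because deviations are mean-zero, $\bar b$ and $\bar s$
are invariant for every $m$; $m=0$ zeroes both spreads, $m=-1$ preserves
them, $m=2$ doubles them exactly as long as onsets stay fractional.
Everything else — velocity, duration, channel, sustain-pedal and all other
non-note events — is passed through byte-identically. Middle-triplet notes
are never moved, even at $m=0$. Integerisation to MIDI ticks happens only at
file write time (half-away-from-zero), so composing manipulations does not
accumulate rounding; all exactness statements above are pre-rounding, and
post-write checks use the 0.5-tick bound. Onsets that would become negative
are clamped to zero with a warning, and order crossings (possible for large
$|m|$, rare at the study's $m \le 2$ and ≈ 18 ms spreads) are warned about
and re-sorted.

`verify_manipulation()` re-analyses both versions and reports the
invariances as pass/fail deltas; `interval_flip_fraction()` measures how
often a locally short-long pair of inter-onset intervals becomes long-short
under a manipulation. The latter quantifies the mechanism by which inversion
is perceptually mild: when neighbouring deviations are positively correlated
they usually share a sign, so negating them rarely reverses a local interval
ordering. The package's tests confirm the flip fraction decreases
monotonically in the serial correlation (ρ ∈ {0, 0.5, 0.9}).

## The synthetic generator

`generate_performance()` exists so that every stage is testable against
known ground truth. It emulates the statistical structure of professional
jazz piano recorded to a click, not its musical content:

* base anchors on the click, swing anchors at `960·r/(1+r)` ticks for a
  target mean swing ratio `r`;
* per-note timing noise of configurable spread (default **18.5 ms**, the
  fitted spread of real recordings), as i.i.d. Gaussian, AR(1) with lag-1
  correlation `serial_rho` (default **0.5**, the typical observed serial
  rank correlation), or spectrally synthesised `1/f^β` noise (real MTD
  sequences are power-law correlated; β is free, default 0.8, since no
  single canonical exponent exists — observed per-piece correlations range
  from 0.1 to 0.8);
* default tempo 150 BPM and target ratio 1.9, the midpoints of the reference
  recordings' ranges (120–190 BPM, r 1.57–2.11; see
  `inst/extdata/reference_recordings.csv`);
* chords with probability 0.3 per bin (2–4 notes, 1–12 tick strum — piano
  textures are chord-rich; the value is a plausibility choice, not an
  estimate) and middle-triplet notes on **0.7%** of quarters (the observed
  average fraction);
* a silent lead-in quarter, so an early-played first note cannot produce a
  negative onset.

Deviations that would leave the ±160-tick classification window are redrawn
(preserving the Gaussian shape; clipping would distort the spread the tests
recover) and counted. Pitches are random diatonic notes and velocities
uniform in 60–100: *only timing is modelled*; nothing about melody,
harmony, dynamics or the backing track is realistic, so passing recovery
tests says nothing about those aspects of real data. What the generator also
does not emulate: tempo drift (the model assumes a metronomic performance),
expressive timing tied to phrase structure, and any dependence of deviations
on pitch or dynamics.

Recovery at n = 5000 bins is tested at 3 standard errors with two
theory-driven adjustments: the SD estimator's variance is inflated by the
AR(1) factor `1 + 2ρ²/(1−ρ²)`, and the generator's Pearson ρ is compared to
Spearman's expectation for a Gaussian pair, `(6/π)·asin(ρ/2)` (0.483 at
ρ = 0.5). Problem sizes in the test-suite simulations (5000 bins for
recovery, 10000 quarters for the flip-fraction comparison, 1000 replicates
for CI coverage) were chosen as the smallest that make the 3-SE bands
meaningfully tight.

## Rating comparison

Ordinal 4-point swing ratings of two conditions are compared by
`AUC = P(X > Y) + ½·P(X = Y)` over all pairs (Mann–Whitney kernel), with X
the manipulated and Y the original condition, so AUC < 0.5 means the
original was preferred. The confidence interval uses DeLong's asymptotic
variance computed from the structural components of each observation with
the 0/0.5/1 tie kernel — on a 4-point scale ties dominate, so the tie-aware
components are the substantive choice, and the implementation is
cross-checked against pROC's DeLong routine in the tests. The design is
treated as unpaired (each listener heard only one version of a piece). A CI
containing 0.5 maps to the "no significant difference" flag; no
multiple-testing correction is applied across pieces, mirroring how such
per-piece intervals are conventionally reported. Degenerate samples (all
structural components constant, e.g. complete separation or identical
constant ratings) produce a zero-width CI with a warning rather than an
error. The ROC curve itself is the cumulative-proportion polygon over
categories ordered 4 → 1; its trapezoidal area equals the pairwise AUC,
which the tests assert.

`export_long_table()` writes the one-row-per-rating layout (participant,
piece, condition, musician category, rating) that mixed ordinal-regression
software consumes, enforcing the one-version-per-piece design constraint.
Fitting such cumulative-link mixed models is deliberately out of scope —
established packages do it well once the table is exported.

## Numerical and design choices

* All internal timing math is double-precision ticks; the only rounding in
  the pipeline is MIDI write integerisation. Exact statements in the tests
  use 1e-9 (pre-rounding) or 0.5 ticks (post-write).
* σ and δ_r use the n−1 divisor (sample convention).
* A class with fewer than two deviations reports `NA` spreads; fewer than
  three correlation pairs reports `NA` ρ — missing, never invented.
* SMF reading matches note-on/note-off first-in-first-out per channel and
  pitch (the prevailing dialect for overlapping same-pitch notes);
  unmatched note-ons close at end of track with a warning. Source divisions
  are rescaled to 960 ticks per quarter by exact rational scaling. A single
  constant tempo is assumed: the first tempo event wins, later ones are
  preserved but ignored for ms conversion, with a warning.
* The twelve reference recordings' published summary statistics ship as
  `inst/extdata/reference_recordings.csv`; the recordings themselves are
  distributed with the study, and the full per-piece reproduction test runs
  only where they are placed under `extdata/deposited/`.

## Known limitations

Only the swung-eighth triplet grid is supported (no sixteenth grids or odd
meters), tempo is assumed constant, and channel-10 percussion is not treated
specially. The generator's realism ends at timing statistics. AUC
confidence intervals are asymptotic; for very small samples (n < ~20 per
condition) their coverage degrades, as is usual for DeLong intervals.
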