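# swingtime

Does the "human" micro-variability of a jazz soloist's timing make the music
swing? To test that experimentally one needs to take a real performance and
surgically alter *only* its microtiming — leaving dynamics, durations, pedal,
harmony and the player's intentional feel untouched — and then measure how
listeners rate the altered versions. **swingtime** is an R toolkit for
exactly that workflow, aimed at music-perception researchers working with
MIDI recordings of swung eighth notes played to a metronome.

## What it computes

On a canonical grid of 960 ticks per quarter note, swung eighths occupy the
first ("base", *b*) and third ("swing", *s*) notes of an eighth-note
triplet. Each onset is classified to the nearest triplet anchor
{0, 320, 640} modulo the quarter (half-open ±160-tick windows; middle-triplet
notes are disregarded). Per recording the package measures:

* mean positions $\bar b$ and $\bar s$ (ticks) — intentional ahead/behind-the-beat feel;
* microtiming deviations $d_i$ = offset − class mean, so mean-zero per class,
  with spreads $\sigma_b$, $\sigma_s$ in milliseconds;
* the average swing ratio
  $r = \overline{ \frac{p_i \bmod 960}{960 - (p_i \bmod 960)} }$
  over swing positions $p_i$ (2 = perfect triplets, 1 = straight eighths),
  with spread $\delta_r$;
* serial Spearman correlations $\rho_{b\to s}$, $\rho_{s\to b}$ between
  neighbouring deviations (pairs at most one quarter note apart, earliest
  onset per chord bin).

Deviations can then be rescaled by a factor $m$ — quantized ($m=0$),
exaggerated ($m=2$), inverted ($m=-1$) — producing a new MIDI file in which
*nothing else* changed. Ordinal listener ratings of the versions are compared
with ROC/AUC (Mann–Whitney kernel with ½-ties) and DeLong confidence
intervals. A synthetic-performance generator with controlled timing
statistics (i.i.d., AR(1) or 1/f^β noise) makes the whole chain testable
against ground truth.

## Worked example

```r
library(swingtime)

g    <- generate_performance(synth_spec(n_quarters = 400, seed = 42))
prof <- mtd_profile(g$performance)
prof
#> <mtd_profile>
#>   1243 notes at 150 BPM; bins: 400 base, 400 swing; 0.00% middle-triplet
#>   b_bar = -3.99 ticks, s_bar = 625.59 ticks
#>   sigma_b = 17.34 ms, sigma_s = 18.35 ms (pooled 17.84 ms, mean -0.00 ms)
#>   swing ratio r = 1.924 (delta_r = 0.414; ratio at s_bar = 1.871)
#>   serial Spearman rho: base->swing 0.513 (n=400), swing->base 0.469 (n=399)
```

The generator was asked for ≈ 18.5 ms of AR(1) noise (ρ = 0.5) around a
swing ratio of 1.9 at 150 BPM, and the analysis recovers those numbers: the
spreads are ≈ 18 ms, the serial rank correlations ≈ 0.5, and the per-note
swing ratio 1.924 sits slightly above the ratio at the mean position (1.871)
because averaging per-note ratios is convex in position. A negative
`b_bar` means this (synthetic) player tends slightly ahead of the click —
that offset is feel, not deviation, and survives manipulation:

```r
quant <- apply_manipulation(g$performance, manipulation_spec(preset = "quantized"))
verify_manipulation(g$performance, quant, m = 0)
#> <manipulation_report> m = 0: PASS
#>                  check        delta tol pass
#>        b_bar preserved 6.756373e-12 0.5 TRUE
#>        s_bar preserved 1.705303e-12 0.5 TRUE
#>             d' = m * d 1.512035e-11 0.5 TRUE
#>   velocities identical 0.000000e+00 0.0 TRUE
#>    durations identical 0.000000e+00 0.0 TRUE
#>  passthrough identical 0.000000e+00 0.0 TRUE
#>         bins preserved 0.000000e+00 0.0 TRUE

write_performance(quant, "quantized.mid")   # listen to it
```

Comparing 4-point swing ratings of an inverted version against the original
(60 simulated listeners each):

```r
roc_auc(inverted_ratings, original_ratings)
#> <roc_result> AUC = 0.338, 95% CI 0.249-0.427 (n = 60 vs 60)
#>   conditions differ (CI excludes 0.5)
```

AUC < 0.5 reads "the original was preferred"; a CI containing 0.5 would
read "no significant difference".

Real recordings enter through `read_performance("solo.mid")` (SMF type 0/1,
any source division, sustain pedal and all other events carried through) and
leave through `write_performance()`. `mtd_report()` tabulates many
recordings at once; `inst/cli/swingtime.R` wraps the whole workflow for the
shell (`analyze`, `manipulate`, `synth`, `roc`).

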