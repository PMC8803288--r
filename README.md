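# nightsong

Accelerometer-based detection of song behavior in free-living nocturnal
birds.

Male European Nightjars (*Caprimulgus europaeus*) sing a sustained trilled
"churring" song from stationary perches at night. The body vibration that
accompanies song is visible in single-axis (Z) accelerometer data sampled at
25 Hz by a light-weight tail-mounted tag — which means an individual's
complete nightly song output can be logged continuously, whereas stationary
audio recorders capture only the bouts sung within their ~20 m audible
radius. `nightsong` implements the full analysis chain for this setting, for
behavioral ecologists and biologging practitioners:

1. **Preprocessing** — decompose raw acceleration a(t) into a static
   component (2-s centered running mean; gravity and tag angle) and a
   dynamic component d(t) = a(t) − smooth(a)(t) (movement-induced).
2. **Segmentation** — an unsupervised K-state hidden Markov model with
   univariate Gaussian emissions, d(t) | s(t)=k ~ N(μ_k, σ_k²), fitted by
   Baum–Welch EM (scaled forward–backward in C++, 10 seeded random restarts,
   up to 10,000 iterations) on a contiguous 50% training half of one night,
   decoded by the Viterbi algorithm, with BIC comparison over K = 4…7 and
   the five-state model pinned by default (two states for inactive
   behavior).
3. **Behavior decoding** — states ordered by emission sd map onto the
   ethogram {rest, sing, fly, leap}; labels are subsampled to a 1-s grid by
   per-second majority; maximal runs become bouts; song bouts shorter than
   10 s are discarded.
4. **Validation** — classified song bouts are gated by GPS distance to the
   audio recorders (< 20 m vs > 20 m, haversine, fix nearest the bout
   midpoint), matched one-to-one to audio-annotated bouts (±1 s tolerance),
   tabulated as confusion counts per distance class, and compared in
   duration (Shapiro–Wilk gate at W = 0.9, Spearman rank correlation with
   ρ = 1 − 6S/(n(n²−1)), Wilcoxon signed-rank, and a paired t test on bouts
   recorded ≥ 20 s).
5. **Synthetic nights** — a seeded generator (semi-Markov behavior script,
   behavior-specific acceleration amplitudes, 3-min GPS fixes with ±20 m
   error, recorders that hear only within 20 m) makes every stage testable
   without field data.

## Worked example

Simulate a full 9-h night, fit, classify and validate, all from one seed:

```r
library(nightsong)
run <- run_pipeline(pipeline_config(master_seed = 1))
print(run)
#> Synthetic-night pipeline run
#>   359 script intervals, 124 song bouts classified
#>   per-second agreement with truth: 99.9%; song Jaccard: 1.00
#>   distance model audio match model_only audio_only
#> 1      <20    40    40    40          0          0
#> 2      >20    84     5     5         79          0
#> 3      All   124    45    45         79          0
#>   accuracy 100%, near-class audio detection 100%, overall 36%
print(run$duration_stats)
#> Matched song-bout duration comparison (n = 45)
#>   Spearman: rho = 0.997, S = 46.05, p = 2.536e-49
#>   Wilcoxon signed-rank: V = 589.0, p = 0.4229; mean diff 0.08 s
#>   Paired t (audio >= threshold): t = -0.282, df = 33, p = 0.7795
```

Reading this: the model classified 124 song bouts of ≥ 10 s over the night;
the 40 sung within 20 m of a recorder were all present in the audio truth
(near-class detection 100%), while beyond 20 m the recorders captured only
5 of 84 (6%) — the distance-gated contrast that motivates tag-based song
logging. Decoded per-second behavior agrees with the generating script for
99.9% of the night, and matched bout durations agree to a rank correlation
of 0.997.

The same summary operations reproduce the published validation arithmetic
when fed the printed confusion counts:

```r
counts <- data.frame(class = c("near", "far"),
                     n_model = c(12, 56), n_audio = c(11, 4),
                     n_match = c(10, 4), n_model_only = c(2, 52),
                     n_audio_only = c(1, 0))
tab <- build_table2(counts)
tab
#>   distance model audio match model_only audio_only
#> 1      <20    12    11    10          2          1
#> 2      >20    56     4     4         52          0
#> 3      All    68    15    14         54          1
s <- validation_summary(tab)
round(c(s$accuracy_pct, s$audio_detection_near_pct, s$audio_detection_all_pct))
#> [1] 92 85 22
spearman_from_S(21.7, 10)
#> [1] 0.8684848
```

A thin command-line wrapper over the same functions lives in
`inst/cli/nightsong.R` with subcommands `simulate`, `preprocess`, `fit`,
`classify`, `validate` and `run-all`; file dialects are plain CSV/TSV with
ISO-8601 GMT timestamps, and fitted models serialize to a human-readable
text format that round-trips exactly.

See `vignettes/song-detection-methods.Rmd` for the model, the generator's
assumptions, and the design decisions.

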