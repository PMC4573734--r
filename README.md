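# afentropy

Beat-by-beat screening of **atrial fibrillation (AF)** in RR-interval
(heart-rate) streams, built for real-time use: every beat costs a constant
number of integer operations, one multiply and one divide.

AF produces a highly irregular, nearly memoryless ventricular response. The
detector exploits this by watching how widely the instantaneous heart rate
scatters over its recent history:

1. **Symbolization.** Each RR interval becomes an instantaneous heart rate
   `hr = 60000 / rr_ms` (bpm), coarse-grained into 5-bpm states:
   `sy = min(floor(hr / 5), 63)` — a 64-letter alphabet, capped at 315 bpm.
2. **Word encoding.** Three consecutive symbols are packed into an 18-bit
   word `wv = (sy₂ << 12) + (sy₁ << 6) + sy₀`, e.g. symbols `0,1,3` → 67.
3. **Coarse Shannon entropy.** Over a sliding window of the last `N = 127`
   words, with `k` distinct words of counts `Nᵢ` and `pᵢ = Nᵢ/N`,

   H″ = −(k / (N log₂N)) · Σᵢ pᵢ log₂ pᵢ  ∈ [0, 1].

   Sinus rhythm concentrates the window on a handful of words (H″ near 0);
   AF spreads it across the alphabet (H″ near 1). A beat is called **AF
   when H″ meets or exceeds the decision threshold** (default 0.639, the
   ROC-optimal operating point on a large long-term AF training corpus).
4. **Integer recursion.** The entropy is never recomputed from scratch. A
   lookup table `PiMap[i] = floor((10⁶/log₂127) · (−(i/127) log₂(i/127)))`
   (entries 7874, …, 71790, 71291, …, 0) turns each window slide into a few
   integer adds/subtracts on an accumulator `sh′`, and
   H″ = k · sh′ / 127 000 000.

The package also provides the floating-point entropy oracle the recursion
is validated against, beat-level confusion metrics (Se/Sp/PPV/ACC) with ROC
threshold sweeps and AUC, readers/writers for beat CSV and rdann-style
rhythm-annotation text, and a seeded synthetic generator of sinus-rhythm,
AF and paroxysmal beat streams with ground-truth labels.

## Worked example

```r
library(afentropy)

bs <- gen_paroxysmal(sim_config(seed = 42))   # NSR 500 / AF 500 / NSR 500 beats
bs
#> <beat_stream> record sim_parox: 1500 beats, HR 60.0-199.4 bpm, 500 AF / 1000 non-AF labelled

d <- detect_stream(bs, detector_config(threshold = 0.639))

# score outside warm-up and one 130-beat window after each rhythm switch
keep <- d$label != "WARMUP" & !(d$beat_index %in% c(500:629, 1000:1129))
cm <- confusion(d$label[keep], bs$labels[keep])
cm
#> <confusion_counts> TP 370  FN 0  FP 0  TN 742 (1112 beats)
classification_metrics(cm)
#>  se  sp ppv acc
#>   1   1   1   1

roc_sweep(d$h[d$label != "WARMUP"], bs$labels[d$label != "WARMUP"])
#> <roc_curve> 1001 thresholds, AUC 0.9718; best threshold 0.287 (distance 0.1234 to ideal)
```

The detector separates the synthetic rhythms perfectly away from the
transitions; the AUC of 0.97 over *all* defined beats reflects the ~130-beat
stretches around each rhythm switch where the entropy window inevitably
mixes both rhythms (the detector's intrinsic latency is about half a window,
~65 beats). The first 128 beats are `WARMUP`: two beats form the first word
and 126 more fill the window.

A thin command-line wrapper ships in `inst/exec/afdetect`:

```sh
Rscript inst/exec/afdetect simulate --spec "NSR:500,AF:500,NSR:500" --seed 42 --out beats.csv
Rscript inst/exec/afdetect detect --input beats.csv --threshold 0.639 --output decisions.csv
Rscript inst/exec/afdetect eval --decisions decisions.csv --reference beats.csv
Rscript inst/exec/afdetect roc --input beats.csv --step 0.001 --out roc.csv
```

Evaluating against PhysioNet databases (LTAFDB, AFDB, MITDB, NSRDB) is
supported as an optional workflow: export beat times and rhythm annotations
with WFDB's `rdann`, read them with `read_beats(..., format = "rdann")` and
`read_rhythm_annotations()`, and expand interval annotations to per-beat
labels with `expand_rhythm_labels()` (only `"(AFIB"` maps to AF by default;
atrial flutter is configurable).

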