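---
title: "Symbolic dynamics and coarse Shannon entropy for beat-by-beat AF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic dynamics and coarse Shannon entropy for beat-by-beat AF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afentropy)
```

## The model

Atrial fibrillation disorganizes atrial activation; the ventricles respond
irregularly, so consecutive RR intervals lose the slow, correlated structure
of sinus rhythm and behave almost memorylessly over a wide heart-rate range.
`afentropy` quantifies this with three coarse-graining stages followed by an
entropy statistic.

**Symbols.** Each beat's instantaneous heart rate `hr = 60000 / rr_ms`
(bpm) is floored into 5-bpm states, capped at 315 bpm:

$$sy_n = \begin{cases} 63 & hr_n \ge 315\\ \lfloor hr_n/5 \rfloor & \text{otherwise,}\end{cases}$$

a 64-letter alphabet (6 bits). The heart rate is kept real-valued up to this
single floor — pre-rounding it would move beats near bin edges. A rate
exactly on an edge falls in the upper bin by floor semantics; values within
floating-point error of an edge follow IEEE floor, with no epsilon guard.
Zero or negative RR intervals are rejected rather than clamped: they are
physiologically impossible and indicate an upstream annotation fault.

**Words.** Three consecutive symbols are packed into one integer,
$wv_n = (sy_{n-2} \ll 12) + (sy_{n-1} \ll 6) + sy_n \in [0, 262143]$.
The encoding is a bijection (verified exhaustively over all $64^3$ triples in
the test suite), so the word distribution is exactly the distribution of
symbol triples — sensitive to both the range of heart rates visited and the
order in which they are visited.

**Coarse Shannon entropy.** Over the last $N = 127$ words, with $k$
distinct words of counts $N_i$ and $p_i = N_i/N$:

$$H'' = -\frac{k}{N\log_2 N}\sum_{i=1}^{k} p_i \log_2 p_i \in [0,1].$$

$H'' = 0$ for a window of one repeated word; $H'' = 1$ (in the
floating-point oracle) when all 127 words are distinct. The extra factor
$k/N$ relative to ordinary normalized Shannon entropy sharpens the contrast
between narrow (sinus) and wide (AF) word occupancy. A beat is called AF
when $H''$ *meets or exceeds* the decision threshold — the tie goes to AF,
and the comparison is at full floating-point precision.

## The integer recursion

Recomputing $H''$ each beat would cost $O(N)$ with logarithms.
Because every count is an integer in $0..N$, every possible entropy term can
be tabulated once:

$$\mathrm{PiMap}[i] = \left\lfloor \frac{\mathit{Cons}}{\log_2 N}\,
\bigl(-\tfrac{i}{N}\log_2\tfrac{i}{N}\bigr) \right\rfloor,\qquad
\mathrm{PiMap}[0] = \mathrm{PiMap}[N] = 0,$$

with $\mathit{Cons} = 10^6$ (entries 7874, …, 71790, 71291, …, 0 for
$N = 127$; `build_pimap()`). The rolling state is the circular window, a
dense count buffer over the $2^{18}$-word space (the direct analogue of an
embedded count array, with O(1) access), the distinct-word tally $k$, and an
integer accumulator $acc = \sum_i \mathrm{PiMap}[N_i]$. Each beat,
`push_word()`:

1. slides the oldest word out — subtract its table entry at the old count,
   decrement the count, add the entry at the new count, decrement $k$ if the
   count reached zero;
2. slides the new word in symmetrically, incrementing $k$ if the word is new;
3. emits $H'' = k \cdot acc / (N \cdot \mathit{Cons})$.

The terse published update rules leave the $k$ bookkeeping implicit; we
resolve them as above — $k$ falls when a slide-out empties a count and rises
when a slide-in introduces a new word — which is the only reading consistent
with $k$ being the number of distinct words in the window, an identity the
test suite re-verifies by brute-force recount after random push sequences.

Numerical consequences of the quantization:

* Each table entry carries a floor error below 1, so with at most $k \le N$
  live terms the emitted entropy deviates from the exact $H''$ by at most
  $k^2/(N \cdot \mathit{Cons}) < 1.3\times 10^{-4}$. The suite asserts
  agreement within $2\times 10^{-4}$ against an independent from-scratch
  oracle (`entropy_direct()`) over 1000 seeded random word streams.
* An all-distinct window yields $127 \times 7874 / 127{\cdot}10^6 =
  0.999998$, not exactly 1 — only the oracle attains the upper bound.
* $acc \le N \cdot \max(\mathrm{PiMap}) = 127 \times 75941 < 2^{31}$, so
  the accumulator fits a 32-bit integer; the final multiply by $k$ is done
  in double precision.

**Warm-up.** The recursion indexes the table by raw counts, which amounts to
using the fixed denominator $p_i = N_i/127$ even while the window is
filling; the oracle mirrors this, so recursion and oracle agree from the
very first word. A consequence is that $H'' > 0$ during warm-up even for a
constant rhythm (a single word at count $< 127$ has a positive table entry),
and $H'' = 0$ exactly when a *saturated* window holds one repeated word.
The first fully-windowed decision needs $128$ beats ($2$ to form the first
word, $126$ more words to fill the window). How the published evaluation
labelled those beats is unstated, so the policy is explicit:
`warmup_policy = "mark"` (default) labels them `WARMUP` and excludes them
from metrics, `"nonaf"` forces non-AF, `"drop"` removes them. Decisions are
attached to the current beat; the ~65-beat intrinsic latency of the centred
window is documented rather than compensated by shifting outputs. Detector
state is reset between records — records are independent subjects, and
metrics are pooled over beats.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 0.639 | — | AF decision level on $H''$; ROC-optimal point from a ~9-million-beat long-term AF training corpus |
| `N` | 127 | words | entropy window; ~2 min of beats at 65 bpm |
| `hr_cap` | 315 | bpm | top of the symbol range; HR above it saturates at symbol 63 |
| `bin_width` | 5 | bpm | symbol resolution; 64 states with the default cap |
| `Cons` | $10^6$ | — | integer scale of the lookup table; sets the $<1.3\times10^{-4}$ quantization bound |

## The synthetic generator

`gen_nsr()`, `gen_af()` and `gen_paroxysmal()` produce labelled beat streams
exhibiting exactly the statistical contrast the detector exploits:

* **Sinus rhythm:** $hr_i = 70 + 3\sin(2\pi i/60) + \mathcal N(0, 2^2)$ bpm
  — a slow respiratory-scale drift with small beat-to-beat variability. The
  resulting heart rates occupy $\le 4$ adjacent 5-bpm states, so the window
  holds few distinct words and $H''$ stays low (median ≈ 0.1). The 70 bpm
  mean and few-bpm variability are typical resting sinus values; the drift
  period of 60 beats approximates respiratory sinus arrhythmia slowed to a
  circulation-scale envelope.
* **AF:** RR drawn i.i.d. uniform on [300, 1000] ms (60–200 bpm), the
  simplest model of AF's near-memoryless irregular ventricular response —
  about 28 symbol states, so nearly every window word is distinct and
  $H''$ sits near 1. An AR(1) heart-rate model was considered for sinus
  drift and rejected in favour of the sinusoid for analytic transparency
  (the symbol band it occupies is readable off the parameters).
* **Paroxysmal:** segments concatenated per `episode_spec` under a single
  RNG stream, labels switching exactly at the cumulative segment boundaries.

What the generator does *not* emulate: ectopic beats, bigeminy, AV-nodal
conduction structure, annotation noise, QRS-detection error. Passing the
synthetic recovery tests therefore demonstrates that the implementation
realizes the intended mapping from rhythm irregularity to entropy, not that
the 0.639 threshold reproduces clinical sensitivity/specificity; clinical
figures require the PhysioNet workflow described in the README. In
segment-level scoring the tests exclude 130 beats (one full window plus the
word length) after each rhythm switch, where the window unavoidably mixes
rhythms.

## Evaluation machinery

Beat-level confusion counts treat AF as the positive class; warm-up beats
are excluded per policy. A metric with a zero denominator (e.g. sensitivity
on a record with no AF reference beats) is reported `NA`, never 0. Interval
rhythm annotations expand to per-beat labels with half-open
`[onset, next onset)` semantics — standard rdann behaviour; only `"(AFIB"`
maps to AF by default, with atrial flutter `"(AFL"` classed non-AF unless
reconfigured, since published evaluations rarely state the flutter
convention.

`roc_sweep()` evaluates thresholds 0.0–1.0 in increments of 0.001. The AUC
integrator is trapezoidal over the swept $(1-Sp, Se)$ points with the
$(0,0)$ and $(1,1)$ corners appended if the grid does not reach them (the
integrator behind published AUC figures is unstated; trapezoid-on-grid can
differ from exact concordance only by the grid discretization, which the
suite bounds at 0.01 against a Mann–Whitney oracle). The optimal operating
point minimizes the Euclidean distance to the ideal corner $(0, 1)$; ties
break to the smallest threshold.

## Problem sizes and determinism

The test suite runs entirely on synthetic data built at test time:
oracle-equivalence over 1000 streams of 500 words with alphabet sizes 1–300,
the exhaustive $64^3$ bijection check, 1500-beat paroxysmal recovery runs,
and 200–500-beat ROC fixtures — sizes at which every oracle can be evaluated
from scratch at every position. All randomness is seeded; identical input
and configuration give bit-identical decisions, and truncating a stream
leaves the retained prefix of decisions unchanged (causality).

## Known limitations

* No ectopic-beat filtering: isolated premature beats in sinus rhythm can
  transiently inflate the window entropy.
* Per-beat classification only; no episode-level smoothing or
  minimum-duration post-processing.
* The ~65-beat latency makes very short AF bursts (≲ half a window)
  hard to flag at full amplitude.
* Binary WFDB files are out of scope; beat times and rhythm annotations
  enter via rdann-style text exports.
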